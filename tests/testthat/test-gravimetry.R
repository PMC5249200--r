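test_that("soak correction combines specimen loss and control gain", {
  mk <- function(w, c) weight_series("s", "XLPE", seq(0, 2, 0.4), w, c)
  flat_ctrl <- rep(20000, 6)
  # control flat, specimen loses 5 mg
  s1 <- mk(c(30000, 29999, 29998, 29997, 29996, 29995), flat_ctrl)
  expect_equal(soak_correct(s1), c(0, 1, 2, 3, 4, 5))
  # specimen flat, control gains 2 mg: 2 mg corrected loss
  s2 <- mk(rep(30000, 6), c(20000, 20000.5, 20001, 20001.5, 20001.8, 20002))
  expect_equal(soak_correct(s2)[6], 2)
  # shifting all specimen weights by a constant leaves losses unchanged
  s3 <- mk(c(30000, 29999, 29998, 29997, 29996, 29995) + 123, flat_ctrl)
  expect_equal(soak_correct(s3), soak_correct(s1))
})

test_that("soak-corrected generator series recovers the linear trend exactly", {
  ws <- simulate_weight_series(rate = 5, soak_amplitude = 1, soak_tau = 0.5,
                               balance_sd = 0, seed = 1)
  losses <- soak_correct(ws)
  expect_equal(losses, 5 * ws$cycles, tolerance = 1e-12)
  wr <- wear_rate(losses, ws$cycles)
  expect_equal(wr$rate, 5, tolerance = 1e-12)
  expect_equal(wr$r_squared, 1, tolerance = 1e-12)
})

test_that("wear-rate regression matches closed-form least squares", {
  # exact linear series
  wr <- wear_rate(c(0, 2.04, 4.08, 6.12, 8.16, 10.2), seq(0, 2, 0.4))
  expect_equal(wr$rate, 5.1, tolerance = 1e-12)
  expect_equal(wr$r_squared, 1)
  # cross-linked PE mean losses on the 0.4 Mc grid vs hand OLS
  x <- seq(0.4, 2.0, by = 0.4)
  y <- c(2.1, 3.7, 5.8, 8.1, 10.2)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  wr2 <- wear_rate(c(0, y), c(0, x), steady_state_from = 0.4)
  expect_equal(wr2$rate, slope_hand, tolerance = 1e-12)
  expect_equal(slope_hand, 5.15)
  # constant losses: zero slope, R^2 undefined
  wr3 <- wear_rate(rep(2, 5), seq(0.4, 2, 0.4))
  expect_equal(wr3$rate, 0)
  expect_true(is.na(wr3$r_squared))
  expect_error(wear_rate(1:5, seq(0.4, 2, 0.4), steady_state_from = 2),
               "at least 2 points")
})

test_that("wear-rate regression recovers the generator rate across seeds", {
  rates <- vapply(1:50, function(s) {
    ws <- simulate_weight_series(rate = 10, soak_amplitude = 1,
                                 balance_sd = 0.01, seed = s)
    wear_rate(soak_correct(ws), ws$cycles)$rate
  }, numeric(1))
  se <- sd(rates) / sqrt(50)
  expect_lt(abs(mean(rates) - 10), 3 * max(se, 1e-6))
})

test_that("Kruskal-Wallis H matches stats::kruskal.test and handles ties", {
  set.seed(31)
  g <- list(rnorm(5), rnorm(6) + 0.5, rnorm(4))
  kw <- kruskal_wallis(g, method = "chisq")
  ref <- kruskal.test(g)
  expect_equal(kw$H, unname(ref$statistic))
  expect_equal(kw$p_value, ref$p.value)
  # identical groups: H = 0, p = 1
  kw0 <- kruskal_wallis(list(rep(2, 3), rep(2, 3), rep(2, 3)))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p_value, 1)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty group")
})

test_that("exact Kruskal-Wallis enumerates all rank partitions", {
  kw <- kruskal_wallis(list(1:3, 4:6, 7:9), method = "exact")
  expect_equal(kw$H, 7.2)
  expect_equal(kw$n_partitions, 1680)
  expect_equal(kw$p_value, 6 / 1680)
  # exact p is invariant under monotone transformation of the data
  kw2 <- kruskal_wallis(list(exp(1:3), exp(4:6), exp(7:9)), method = "exact")
  expect_equal(kw2$p_value, kw$p_value)
  expect_equal(kw2$H, kw$H)
  # two-group enumeration agrees with the closed count choose(5, 2) = 10
  # two-group enumeration: {4,5} and {1,2} are equally extreme, so p = 2/10
  kw3 <- kruskal_wallis(list(c(10, 20), c(1, 2, 3)), method = "exact")
  expect_equal(kw3$n_partitions, 10)
  expect_equal(kw3$p_value, 2 / 10)
})

test_that("exact and chi-square p-values agree for moderate samples", {
  set.seed(77)
  g <- list(rnorm(5), rnorm(5), rnorm(5))
  ke <- kruskal_wallis(g, method = "exact")
  kc <- kruskal_wallis(g, method = "chisq")
  expect_equal(ke$n_partitions, choose(15, 5) * choose(10, 5))
  expect_lt(abs(ke$p_value - kc$p_value), 0.02)
})

test_that("weight-series CSV schema round-trips", {
  ws <- simulate_weight_series(5, seed = 3, specimen_id = "A", material = "XLPE")
  ws2 <- simulate_weight_series(8, seed = 4, specimen_id = "B",
                                material = "STD_PE")
  path <- tempfile(fileext = ".csv")
  write_weight_series(list(ws, ws2), path)
  back <- read_weight_series(path)
  expect_named(back, c("A", "B"))
  expect_equal(back$A$weights, ws$weights)
  expect_equal(back$B$control_weights, ws2$control_weights)
  expect_equal(analyze_weight_series(back$A)$wear_rate_mg_per_mc,
               analyze_weight_series(ws)$wear_rate_mg_per_mc)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_weight_series(bad), "missing column")
})
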