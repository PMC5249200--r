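test_that("method pairs enforce the CT-minus-gravimetric convention", {
  p <- method_pairs(c("a", "b"), c(1, 2), c(2, 1))
  expect_equal(p$difference_mg, c(-1, 1))
  expect_error(method_pairs("a", 1, c(1, 2)), "equal length")
  expect_error(method_pairs("a", NA_real_, 1), "finite")
})

test_that("linear fit matches the closed-form correlation formula", {
  # perfect agreement
  p <- method_pairs(letters[1:4], c(1, 2, 3, 4), c(1, 2, 3, 4))
  f <- linear_fit(p)
  expect_equal(f$slope, 1)
  expect_equal(f$r_squared, 1)
  # arbitrary points vs direct Pearson formula
  set.seed(8)
  x <- c(2.3, 5.1, 7.7, 9.2)
  y <- c(1.9, 6.0, 7.1, 10.3)
  f2 <- linear_fit(method_pairs(letters[1:4], y, x))
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(f2$r_squared, r^2, tolerance = 1e-12)
  expect_error(linear_fit(method_pairs(letters[1:3], 1:3, rep(2, 3))),
               "zero variance")
  expect_error(linear_fit(method_pairs(c("a", "b"), 1:2, 1:2)), "3 pairs")
})

test_that("Bland-Altman limits follow bias +/- k * sample SD", {
  # differences {1, 3}: bias 2, sd sqrt(2)
  p <- method_pairs(c("a", "b"), c(2, 5), c(1, 2))
  ba <- bland_altman(p)
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_upper, 2 + 1.96 * sqrt(2))
  expect_equal(ba$loa_lower, 2 - 1.96 * sqrt(2))
  expect_equal(ba$points$mean, c(1.5, 3.5))
  # identical methods: zero-width limits
  q <- method_pairs(letters[1:3], 1:3, 1:3)
  ba0 <- bland_altman(q)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_upper, 0)
  # k = 0 collapses both limits onto the bias
  bak <- bland_altman(p, k = 0)
  expect_equal(bak$loa_lower, bak$bias)
  expect_equal(bak$loa_upper, bak$bias)
})

test_that("R-squared is invariant under affine rescaling of either axis", {
  set.seed(13)
  x <- runif(8, 5, 25)
  y <- x + rnorm(8)
  r2 <- linear_fit(method_pairs(letters[1:8], y, x))$r_squared
  r2_scaled <- linear_fit(method_pairs(letters[1:8], 3 * y - 7,
                                       0.5 * x + 11))$r_squared
  expect_equal(r2_scaled, r2, tolerance = 1e-12)
})

test_that("Shapiro-Wilk wrapper behaves across sample shapes", {
  sym <- shapiro_normality(c(-1, 0, 1))
  expect_gt(sym$W, 0.9)
  set.seed(21)
  skewed <- shapiro_normality(rexp(50))
  expect_lt(skewed$p_value, 0.05)
  expect_error(shapiro_normality(c(1, 2)), "3 <= n")
})

test_that("percentage differences flag the worst specimen", {
  p1 <- method_pairs("only", 2.97, 5.40)
  expect_error(linear_fit(p1), "3 pairs")
  pd <- percent_differences(p1)
  expect_equal(pd$per_pair$percent, 100 * (2.97 - 5.40) / 5.40)
  expect_equal(round(pd$per_pair$percent, 1), -45)
  same <- percent_differences(method_pairs(letters[1:3], 1:3, 1:3))
  expect_true(all(same$per_pair$percent == 0))
  expect_error(percent_differences(method_pairs("z", 1, 0)), "zero gravimetric")
})

test_that("limits of agreement cover ~95% of normally distributed differences", {
  set.seed(99)
  cover <- vapply(1:200, function(s) {
    grav <- runif(50, 5, 25)
    ct <- grav + rnorm(50, mean = -1, sd = 2)
    ba <- bland_altman(method_pairs(seq_len(50), ct, grav))
    d <- ct - grav
    mean(d >= ba$loa_lower & d <= ba$loa_upper)
  }, numeric(1))
  expect_lt(abs(mean(cover) - 0.95), 0.03)
})

test_that("the reference nine-cup dataset reproduces the published statistics", {
  fit <- method_agreement(reference_mass_loss_pairs())
  s <- summary(fit)
  expect_equal(round(s$r_squared, 4), 0.9219)
  expect_equal(round(s$bias_mg), -1)
  expect_equal(round(s$loa_upper_mg, 1), 3.1)
  expect_equal(round(s$loa_lower_mg, 1), -5.2)
  expect_equal(round(s$shapiro_p, 2), 0.14)
  expect_equal(round(abs(s$mean_signed_percent)), 11)
  expect_equal(round(s$max_abs_percent), 45)
  expect_identical(s$max_abs_specimen, "XLPE_1")
  expect_identical(unname(round(coef(fit)["slope"], 2)), 1.04)
})

test_that("agreement object prints, summarizes and plots", {
  fit <- method_agreement(reference_mass_loss_pairs())
  expect_output(print(fit), "R\\^2 = 0.9219")
  expect_output(print(summary(fit)), "max_abs_specimen")
  png_path <- tempfile(fileext = ".png")
  grDevices::png(png_path)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(png_path))
  json <- tempfile(fileext = ".json")
  write_agreement_json(fit, json)
  back <- jsonlite::read_json(json)
  expect_equal(back$r_squared, summary(fit)$r_squared, tolerance = 1e-12)
})
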