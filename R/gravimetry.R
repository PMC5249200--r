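#' Gravimetric weighing series with paired soak control
#'
#' Cumulative weighings of one specimen on the cycle grid (each weight
#' already the mean of replicate balance readings) together with the
#' weights of its unloaded soak-control cup on the same grid.
#'
#' @param specimen_id,material Identifiers.
#' @param cycles Cycle grid in Mc, strictly increasing from 0.
#' @param weights Specimen weights, mg (positive).
#' @param control_weights Soak-control weights on the same grid, mg.
#' @return An object of class `weight_series`.
#' @export
weight_series <- function(specimen_id, material, cycles, weights,
                          control_weights) {
  if (length(cycles) < 2 || cycles[1] != 0 || any(diff(cycles) <= 0))
    stop_validation("cycles must be strictly increasing and start at 0")
  if (length(weights) != length(cycles) ||
      length(control_weights) != length(cycles))
    stop_validation("weights and control_weights must match the cycle grid")
  if (any(weights <= 0) || any(control_weights <= 0))
    stop_validation("weights must be positive")
  structure(list(specimen_id = specimen_id, material = material,
                 cycles = as.numeric(cycles), weights = as.numeric(weights),
                 control_weights = as.numeric(control_weights)),
            class = "weight_series")
}

#' @export
print.weight_series <- function(x, ...) {
  cat(sprintf("weight_series %s (%s): %d stops, 0-%g Mc\n", x$specimen_id,
              x$material, length(x$cycles), max(x$cycles)))
  invisible(x)
}

#' Soak-corrected cumulative mass loss
#'
#' The apparent weight change of a loaded specimen mixes wear loss with
#' fluid-uptake gain; the paired unloaded control experiences the uptake
#' only.  The corrected loss at each stop is the specimen's weight loss
#' plus the control's gain over the same interval:
#' \deqn{loss(t) = (w(0) - w(t)) + (c(t) - c(0))}
#'
#' @param series A [weight_series()].
#' @return Numeric vector of cumulative losses (mg) on the cycle grid;
#'   the first element is 0 by construction.
#' @export
soak_correct <- function(series) {
  stopifnot(inherits(series, "weight_series"))
  (series$weights[1] - series$weights) +
    (series$control_weights - series$control_weights[1])
}

#' Steady-state wear rate by least-squares regression
#'
#' Ordinary least-squares slope of cumulative loss versus cycles, using
#' only stops at or after `steady_state_from` (default 0.4 Mc, i.e. the
#' zero point is dropped; break-in exclusion is configurable because the
#' steady-state window is a protocol choice).
#'
#' @param losses Cumulative losses, mg.
#' @param cycles Cycle grid, Mc.
#' @param steady_state_from First cycle count included in the fit, Mc.
#' @return List with `rate` (mg/Mc), `r_squared` (`NA` when the losses are
#'   constant), and `n_points`.
#' @export
wear_rate <- function(losses, cycles, steady_state_from = 0.4) {
  if (length(losses) != length(cycles))
    stop_validation("losses and cycles must have equal length")
  keep <- cycles >= steady_state_from
  if (sum(keep) < 2)
    stop_validation("need at least 2 points at or after steady_state_from")
  x <- cycles[keep]; y <- losses[keep]
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot <= 0) NA_real_ else stats::cor(x, y)^2
  list(rate = unname(coef(fit)[2]), r_squared = r2, n_points = sum(keep))
}

#' Analyze a gravimetric weighing series
#'
#' Soak correction followed by the steady-state wear-rate regression.
#'
#' @param series A [weight_series()].
#' @param steady_state_from See [wear_rate()].
#' @return An object of class `gravimetric_result`: `cumulative_loss_mg`,
#'   `wear_rate_mg_per_mc`, `rate_fit_r2`, `cycles_mc`, and the identifiers.
#' @export
analyze_weight_series <- function(series, steady_state_from = 0.4) {
  losses <- soak_correct(series)
  wr <- wear_rate(losses, series$cycles, steady_state_from)
  structure(list(specimen_id = series$specimen_id,
                 material = series$material,
                 cycles_mc = series$cycles,
                 cumulative_loss_mg = losses,
                 wear_rate_mg_per_mc = wr$rate,
                 rate_fit_r2 = wr$r_squared),
            class = "gravimetric_result")
}

#' @export
print.gravimetric_result <- function(x, ...) {
  cat(sprintf("gravimetric_result %s (%s): loss %.2f mg at %g Mc, rate %.3f mg/Mc (R^2 %.4f)\n",
              x$specimen_id, x$material, max(x$cumulative_loss_mg),
              max(x$cycles_mc), x$wear_rate_mg_per_mc, x$rate_fit_r2))
  invisible(x)
}

# Kruskal-Wallis H with tie correction for given pooled ranks split by group
kw_H_from_ranks <- function(rank_sums, sizes, N, tie_term) {
  H0 <- 12 / (N * (N + 1)) * sum(rank_sums^2 / sizes) - 3 * (N + 1)
  C <- 1 - tie_term / (N^3 - N)
  if (C <= 0) return(0)
  H0 / C
}

#' Kruskal-Wallis test with an exact small-sample option
#'
#' Computes the tie-corrected Kruskal-Wallis H statistic.  For the tiny
#' group sizes typical of simulator studies (n = 3 per material) the
#' chi-square approximation is unreliable, so the p-value is obtained by
#' complete enumeration of all distinct assignments of the pooled ranks to
#' the groups when the total sample size allows it; otherwise the usual
#' chi-square approximation on k-1 degrees of freedom is used.  The method
#' actually used is reported.
#'
#' @param groups List of >= 2 numeric vectors (each non-empty, total >= 3).
#' @param method `"auto"` (exact when total N <= `exact_limit`),
#'   `"exact"`, or `"chisq"`.
#' @param exact_limit Largest total N for automatic exact enumeration
#'   (default 12).
#' @return List with `H`, `p_value`, `method` (`"exact"`/`"chisq"`),
#'   `n_partitions` (exact only), and `df`.
#' @export
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))
kruskal_wallis <- function(groups, method = c("auto", "exact", "chisq"),
                           exact_limit = 12) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2)
    stop_validation("groups must be a list of at least two numeric vectors")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop_validation("empty group")
  N <- sum(sizes)
  if (N < 3) stop_validation("need at least 3 values in total")
  pooled <- unlist(groups, use.names = FALSE)
  r <- rank(pooled)
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab)
  grp <- rep(seq_along(groups), sizes)
  rank_sums <- as.vector(rowsum(r, grp))
  H <- kw_H_from_ranks(rank_sums, sizes, N, tie_term)

  if (method == "auto") method <- if (N <= exact_limit) "exact" else "chisq"
  if (method == "chisq") {
    p <- pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
    return(list(H = H, p_value = p, method = "chisq",
                df = length(groups) - 1))
  }
  # exact: enumerate all distinct assignments of the pooled rank multiset
  hs <- kw_enumerate_H(r, sizes, N, tie_term)
  p <- mean(hs >= H - 1e-9)
  list(H = H, p_value = p, method = "exact", n_partitions = length(hs),
       df = length(groups) - 1)
}

# H statistic over every distinct partition of the ranks into the given
# group sizes (order of values within a group is irrelevant)
kw_enumerate_H <- function(r, sizes, N, tie_term) {
  k <- length(sizes)
  if (k == 2) {
    cmb <- combn(N, sizes[1])
    s1 <- colSums(matrix(r[cmb], nrow = sizes[1]))
    total <- sum(r)
    return(vapply(seq_along(s1), function(i)
      kw_H_from_ranks(c(s1[i], total - s1[i]), sizes, N, tie_term),
      numeric(1)))
  }
  if (k == 3) {
    total <- sum(r)
    cmb1 <- combn(N, sizes[1])
    out <- vector("list", ncol(cmb1))
    for (i in seq_len(ncol(cmb1))) {
      idx1 <- cmb1[, i]
      s1 <- sum(r[idx1])
      rest <- r[-idx1]
      cmb2 <- combn(length(rest), sizes[2])
      s2 <- colSums(matrix(rest[cmb2], nrow = sizes[2]))
      s3 <- (total - s1) - s2
      C <- 1 - tie_term / (N^3 - N)
      H0 <- 12 / (N * (N + 1)) *
        (s1^2 / sizes[1] + s2^2 / sizes[2] + s3^2 / sizes[3]) - 3 * (N + 1)
      out[[i]] <- if (C <= 0) rep(0, length(s2)) else H0 / C
    }
    return(unlist(out))
  }
  # generic recursion for k > 3 groups
  res <- numeric(0)
  rec <- function(avail, gi, sums) {
    if (gi == k) {
      res[length(res) + 1] <<- kw_H_from_ranks(c(sums, sum(r[avail])),
                                               sizes, N, tie_term)
      return()
    }
    cmb <- combn(length(avail), sizes[gi])
    for (j in seq_len(ncol(cmb))) {
      pick <- avail[cmb[, j]]
      rec(setdiff(avail, pick), gi + 1, c(sums, sum(r[pick])))
    }
  }
  rec(seq_len(N), 1, numeric(0))
  res
}

#' Read / write weight-series CSV files
#'
#' Schema: one row per weighing stop with columns `specimen_id`,
#' `material`, `cycles_Mc`, `weight_mg`, `control_weight_mg`.
#'
#' @param path CSV path.
#' @return `read_weight_series()` returns a named list of
#'   [weight_series()] (one per specimen).
#' @export
read_weight_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "material", "cycles_Mc", "weight_mg",
            "control_weight_mg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_validation("weight-series CSV missing column(s): ",
                    paste(miss, collapse = ", "))
  out <- lapply(split(df, df$specimen_id), function(d) {
    d <- d[order(d$cycles_Mc), ]
    weight_series(d$specimen_id[1], d$material[1], d$cycles_Mc,
                  d$weight_mg, d$control_weight_mg)
  })
  out
}

#' @rdname read_weight_series
#' @param series_list A list of [weight_series()].
#' @export
write_weight_series <- function(series_list, path) {
  if (inherits(series_list, "weight_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s)
    data.frame(specimen_id = s$specimen_id, material = s$material,
               cycles_Mc = s$cycles, weight_mg = s$weights,
               control_weight_mg = s$control_weights))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
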