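#' P0-method mutation rate from a fluctuation assay
#'
#' The Luria-Delbruck P0 estimator: with `P0 = n_zero / n_cultures` the
#' fraction of parallel cultures with no resistant colonies, the expected
#' number of mutations per culture is `m = -ln(P0)` and the mutation rate
#' per cell per division is `m / Nt` (optionally `m / (Nt - N0)`). The
#' confidence interval is a Wilson binomial interval on P0 transformed
#' through `-ln(.) / Nt`.
#'
#' @param assay A [fluctuation_assay()].
#' @param conf_level Confidence level for the Wilson interval (default 0.95).
#' @param denominator `"Nt"` (default, the usual convention) or `"Nt-N0"`.
#' @return A `data.frame` with `P0`, `m`, `rate`, `rate_lower`, `rate_upper`,
#'   `n_cultures`, `n_zero`. When every culture has zero mutants the point
#'   estimate is 0 with a one-sided upper bound.
#' @export
p0_mutation_rate <- function(assay, conf_level = 0.95,
                             denominator = c("Nt", "Nt-N0")) {
  stopifnot(inherits(assay, "fluctuation_assay"))
  denominator <- match.arg(denominator)
  n <- assay$n_cultures; z <- assay$n_zero
  if (z == 0)
    stop("P0 method inapplicable (no zero-mutant cultures)")
  den <- if (denominator == "Nt") assay$Nt else assay$Nt - assay$N0
  wilson <- function(p_hat, n, level) {
    zq <- stats::qnorm(1 - (1 - level) / 2)
    c((p_hat + zq^2 / (2 * n) - zq * sqrt(p_hat * (1 - p_hat) / n + zq^2 / (4 * n^2))) /
        (1 + zq^2 / n),
      (p_hat + zq^2 / (2 * n) + zq * sqrt(p_hat * (1 - p_hat) / n + zq^2 / (4 * n^2))) /
        (1 + zq^2 / n))
  }
  p0_hat <- z / n
  ci <- wilson(p0_hat, n, conf_level)
  if (z == n) {
    # boundary: no mutants anywhere; one-sided upper bound from the Wilson
    # lower bound on P0
    return(data.frame(P0 = 1, m = 0, rate = 0, rate_lower = 0,
                      rate_upper = -log(ci[1]) / den,
                      n_cultures = n, n_zero = z))
  }
  m <- -log(p0_hat)
  data.frame(P0 = p0_hat, m = m, rate = m / den,
             rate_lower = -log(ci[2]) / den,  # larger P0 -> smaller rate
             rate_upper = -log(ci[1]) / den,
             n_cultures = n, n_zero = z)
}

#' Fold change between two mutation rates, with bootstrap CI
#'
#' Point estimate `rate_A / rate_B` from the P0 method, with a percentile
#' bootstrap confidence interval obtained by resampling each assay's
#' zero-culture count from `Binomial(n_cultures, P0_hat)`. Resampled
#' boundary counts (0 or `n_cultures` zeros, where the P0 estimator is
#' undefined or degenerate) are pulled half a culture inward.
#'
#' @param assayA,assayB [fluctuation_assay()] objects.
#' @param n_bootstrap Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf_level Confidence level (default 0.95).
#' @return A `data.frame` with `fold`, `fold_lower`, `fold_upper`.
#' @export
rate_ratio <- function(assayA, assayB, n_bootstrap = 1000, seed,
                       conf_level = 0.95) {
  if (missing(seed)) stop("seed must be provided for reproducibility")
  set.seed(as.integer(seed))
  rateA <- p0_mutation_rate(assayA)$rate
  rateB <- p0_mutation_rate(assayB)$rate
  if (rateB <= 0) stop("reference assay has zero estimated rate")
  boot_rate <- function(assay) {
    z <- stats::rbinom(n_bootstrap, assay$n_cultures, assay$n_zero / assay$n_cultures)
    z <- pmin(pmax(z, 0.5), assay$n_cultures - 0.5)
    -log(z / assay$n_cultures) / assay$Nt
  }
  folds <- boot_rate(assayA) / boot_rate(assayB)
  qs <- stats::quantile(folds, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                        names = FALSE)
  data.frame(fold = rateA / rateB, fold_lower = qs[1], fold_upper = qs[2])
}

#' Growth curve of OD600 readings
#'
#' @param time_min Increasing measurement times (min).
#' @param od600 Positive OD600 values.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(time_min, od600) {
  time_min <- as.numeric(time_min); od600 <- as.numeric(od600)
  stopifnot(length(time_min) == length(od600))
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  if (any(od600 <= 0)) stop("OD600 values must be > 0")
  structure(list(time_min = time_min, od600 = od600), class = "growth_curve")
}

#' Doubling time from an OD600 curve
#'
#' Ordinary least squares of `ln(OD600)` on time over the exponential
#' window; `T = ln(2) / slope`, with the SE propagated by the delta method
#' (`se_T = T * se_slope / slope`).
#'
#' @param curve A [growth_curve()].
#' @param window Optional `c(t_start, t_end)` restricting the fit to the
#'   exponential phase; needs >= 3 points.
#' @return A `data.frame` with `doubling_time_min`, `doubling_time_se_min`,
#'   `n_points`.
#' @export
doubling_time_from_od <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "growth_curve"))
  sel <- if (is.null(window)) rep(TRUE, length(curve$time_min))
  else curve$time_min >= window[1] & curve$time_min <= window[2]
  if (sum(sel) < 3) stop("need at least 3 points in the fitting window")
  fit <- stats::lm(log(curve$od600[sel]) ~ curve$time_min[sel])
  sm <- summary(fit)$coefficients
  slope <- sm[2, 1]; se <- sm[2, 2]
  if (slope <= 0) stop("no growth detected (non-positive slope)")
  T <- log(2) / slope
  data.frame(doubling_time_min = T, doubling_time_se_min = T * se / slope,
             n_points = sum(sel))
}

#' Multiplicative null expectation for a double mutant's doubling time
#'
#' Under the multiplicative fitness model growth-rate ratios combine by
#' multiplication, so the expected doubling time of a strain carrying both
#' perturbations A and B is `T_A * T_B / T_control`. The function is
#' symmetric in A and B and returns `T_B` when `T_A = T_control`.
#'
#' @param T_control,T_A,T_B Doubling times (min), all > 0.
#' @return Expected doubling time of the AB strain (min).
#' @export
multiplicative_expected_doubling <- function(T_control, T_A, T_B) {
  stopifnot(T_control > 0, T_A > 0, T_B > 0)
  T_A * T_B / T_control
}

#' Relative fitness from a competition count table
#'
#' The standard competition definition: the ratio of realized Malthusian
#' parameters, `W = ln(A_final / A_initial) / ln(B_final / B_initial)`, with
#' A the test strain and B the reference. A neutral-marker control
#' competition can be factored out by dividing through its fitness:
#' `W_corrected = W_raw / marker_control_W`. The estimate is invariant to
#' rescaling all counts by a common factor.
#'
#' @param counts A `data.frame` with columns `strain` (`"test"` and
#'   `"reference"`), `n_initial`, `n_final` — as produced by
#'   [simulate_competition()]. Replicate competitions may be supplied as
#'   additional row pairs; the returned `W` is then the replicate mean with
#'   its standard error.
#' @param marker_control_W Fitness of the marked reference against an
#'   unmarked one (default 1 = no correction).
#' @return A `data.frame` with `W` (corrected), `W_raw`, `W_se`
#'   (NA for a single pair), `n_replicates`.
#' @export
relative_fitness <- function(counts, marker_control_W = 1) {
  stopifnot(is.data.frame(counts),
            all(c("strain", "n_initial", "n_final") %in% names(counts)),
            marker_control_W > 0)
  if (any(counts$n_initial <= 0 | counts$n_final <= 0))
    stop("count error: all counts must be > 0")
  test <- counts[counts$strain == "test", , drop = FALSE]
  ref <- counts[counts$strain == "reference", , drop = FALSE]
  if (nrow(test) == 0 || nrow(ref) == 0 || nrow(test) != nrow(ref))
    stop("counts must pair one 'test' with one 'reference' row per replicate")
  w <- log(test$n_final / test$n_initial) / log(ref$n_final / ref$n_initial)
  W_raw <- mean(w)
  data.frame(W = W_raw / marker_control_W, W_raw = W_raw,
             W_se = if (length(w) > 1) stats::sd(w) / sqrt(length(w)) / marker_control_W
             else NA_real_,
             n_replicates = length(w))
}
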