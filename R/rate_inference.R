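#' Fit piecewise-linear segments to an asynchronous dosage profile
#'
#' The core inference step: under steady-state exponential growth the log2
#' dosage declines linearly with replichore distance at rate `a = 1/(v T)`
#' per Mbp, so per-segment slopes of the profile give per-segment fork
#' velocities. Probes are mapped to replichore coordinates and each
#' boundary-delimited segment is fitted by least squares.
#'
#' Two continuity conventions are supported:
#' \describe{
#'   \item{`independent`}{ordinary least squares per segment; the reported
#'     `slope_se` is the OLS slope standard error.}
#'   \item{`continuous`}{a single constrained fit per replichore forcing
#'     adjacent segment lines to meet at the boundaries (a linear spline in
#'     hinge basis); per-segment slope SEs are derived from the coefficient
#'     covariance.}
#' }
#'
#' Slopes are reported as positive magnitudes of the dosage decline with
#' distance (the plotted track falls away from oriC on both arms).
#'
#' @param profile A [dosage_profile()] in strain coordinates (rearrangements
#'   already applied).
#' @param map A [genome_map()].
#' @param boundaries Internal segment boundaries as replichore distances in
#'   Mbp: either a numeric vector applied to both replichores or a named
#'   list `list(left =, right =)`. `numeric(0)` fits one segment per arm.
#' @param continuity `"independent"` or `"continuous"`.
#' @param min_probes Minimum probes per segment (default 10).
#' @return A `data.frame` of class `segment_fits` with columns `replichore`,
#'   `start_Mbp`, `end_Mbp`, `n_probes`, `slope` (per Mbp, positive decline),
#'   `slope_se`, `intercept`.
#' @export
fit_segments <- function(profile, map, boundaries = numeric(0),
                         continuity = c("independent", "continuous"),
                         min_probes = 10) {
  stopifnot(inherits(profile, "dosage_profile"), inherits(map, "genome_map"))
  continuity <- match.arg(continuity)
  if (!is.list(boundaries)) boundaries <- list(left = boundaries, right = boundaries)
  rc <- replichore_coordinate(profile$probes$position_bp, map)
  out <- list()
  for (arm in c("right", "left")) {
    sel <- rc$replichore == arm
    if (!any(sel)) next
    d <- rc$distance_Mbp[sel]
    y <- profile$probes$log2_ratio[sel]
    bnd <- sort(as.numeric(boundaries[[arm]]))
    edges <- c(0, bnd, max(d) + 1e-9)
    if (any(diff(edges) <= 0)) stop("geometry error: degenerate segment bounds")
    seg_id <- findInterval(d, edges, rightmost.closed = TRUE)
    n_seg <- length(edges) - 1
    counts <- tabulate(seg_id, n_seg)
    if (any(counts < min_probes))
      stop(sprintf("data-sufficiency error: segment with < %d probes on %s replichore",
                   min_probes, arm))
    if (continuity == "independent") {
      for (s in seq_len(n_seg)) {
        fit <- stats::lm(y[seg_id == s] ~ d[seg_id == s])
        sm <- summary(fit)$coefficients
        if (nrow(sm) < 2 || stats::var(d[seg_id == s]) == 0)
          stop("geometry error: segment has no spatial extent")
        out[[length(out) + 1]] <- data.frame(
          replichore = arm, start_Mbp = edges[s], end_Mbp = min(edges[s + 1], max(d)),
          n_probes = counts[s], slope = -sm[2, 1], slope_se = sm[2, 2],
          intercept = sm[1, 1], stringsAsFactors = FALSE)
      }
    } else {
      # linear spline: y ~ d + sum_k max(0, d - b_k); segment slope j is the
      # cumulative sum of the base slope and hinge coefficients up to j
      X <- cbind(d, vapply(bnd, function(b) pmax(0, d - b), numeric(length(d))))
      colnames(X) <- c("d", if (length(bnd)) paste0("h", seq_along(bnd)))
      fit <- stats::lm(y ~ X)
      beta <- stats::coef(fit)[-1]
      V <- stats::vcov(fit)[-1, -1, drop = FALSE]
      icpt <- stats::coef(fit)[1]
      for (s in seq_len(n_seg)) {
        w <- as.numeric(seq_len(length(beta)) <= s)
        out[[length(out) + 1]] <- data.frame(
          replichore = arm, start_Mbp = edges[s], end_Mbp = min(edges[s + 1], max(d)),
          n_probes = counts[s], slope = -sum(w * beta),
          slope_se = sqrt(drop(t(w) %*% V %*% w)),
          intercept = icpt, stringsAsFactors = FALSE)
      }
    }
  }
  fits <- do.call(rbind, out)
  class(fits) <- c("segment_fits", "data.frame")
  fits
}

#' Convert a dosage-decline slope to a fork velocity
#'
#' Under the steady-state model the local slope of the log2 dosage decline is
#' `a = 1/(v T)` per Mbp, so `v = 1/(a T)` Mbp/min, reported in kb/min. The
#' velocity SE is propagated by the delta method: `se_v = v * se_a / a`.
#'
#' @param slope Positive slope magnitude in log2 units per Mbp, or a
#'   one-row `segment_fits` data frame (from [fit_segments()]).
#' @param growth A [growth_law()] or a doubling time in minutes.
#' @param slope_se Slope standard error (taken from the fit row if one is
#'   supplied).
#' @return A `data.frame` with `velocity_kb_min` and `velocity_se_kb_min`.
#' @export
velocity_from_slope <- function(slope, growth, slope_se = 0) {
  if (is.data.frame(slope)) {
    stopifnot(nrow(slope) == 1)
    slope_se <- slope$slope_se
    slope <- slope$slope
  }
  T <- if (inherits(growth, "growth_law")) growth$doubling_time_min else as.numeric(growth)
  stopifnot(T > 0)
  if (slope <= 0) stop("non-declining dosage; velocity undefined")
  v <- 1000 / (slope * T)  # kb/min
  data.frame(velocity_kb_min = v, velocity_se_kb_min = v * slope_se / slope)
}

#' Velocity table from segment fits
#'
#' Applies [velocity_from_slope()] to every row of a [fit_segments()] result.
#'
#' @param fits A `segment_fits` data frame.
#' @param growth A [growth_law()] or doubling time in minutes.
#' @return `fits` with `velocity_kb_min` and `velocity_se_kb_min` appended.
#' @export
velocity_table <- function(fits, growth) {
  v <- do.call(rbind, lapply(seq_len(nrow(fits)), function(i)
    velocity_from_slope(fits[i, , drop = FALSE], growth)))
  cbind(as.data.frame(fits), v)
}

#' Percent fork-speed decrease between two segments
#'
#' Since `v` is proportional to `1/a` (the doubling time cancels), the speed
#' decrease of a test segment relative to a reference segment is
#' `100 * (1 - a_ref / a_test)`.
#'
#' @param fit_test,fit_reference Slope magnitudes (per Mbp) or one-row
#'   `segment_fits` data frames.
#' @return Percent decrease (positive when the test segment is slower).
#' @export
percent_speed_change <- function(fit_test, fit_reference) {
  a_t <- if (is.data.frame(fit_test)) fit_test$slope else as.numeric(fit_test)
  a_r <- if (is.data.frame(fit_reference)) fit_reference$slope else as.numeric(fit_reference)
  if (a_t <= 0 || a_r <= 0) stop("percent change undefined for non-positive slopes")
  100 * (1 - a_r / a_t)
}

#' Flag stall segments
#'
#' Flags segments whose slope exceeds `fold_threshold` times the median slope
#' of the *other* segments on the same replichore — an operational definition
#' of strong, localized fork impedance (e.g. at head-on rRNA operons).
#'
#' @param fits A `segment_fits` data frame with at least 2 segments on a
#'   replichore for a comparison to be made.
#' @param fold_threshold Flag a segment when
#'   `slope > fold_threshold * median(other slopes)` (default 2).
#' @return `fits` with a logical `stall` column.
#' @export
stall_segments <- function(fits, fold_threshold = 2) {
  stopifnot(fold_threshold > 0)
  fits <- as.data.frame(fits)
  fits$stall <- FALSE
  for (arm in unique(fits$replichore)) {
    idx <- which(fits$replichore == arm)
    if (length(idx) < 2) next
    for (i in idx)
      fits$stall[i] <- fits$slope[i] >
        fold_threshold * stats::median(fits$slope[setdiff(idx, i)])
  }
  fits
}

# exact RSS of an OLS line over y[i..j] given cumulative sums (O(1))
.seg_rss <- function(cs, i, j) {
  n <- j - i + 1
  sx <- cs$x[j + 1] - cs$x[i]; sy <- cs$y[j + 1] - cs$y[i]
  sxx <- cs$xx[j + 1] - cs$xx[i]; syy <- cs$yy[j + 1] - cs$yy[i]
  sxy <- cs$xy[j + 1] - cs$xy[i]
  vx <- sxx - sx * sx / n
  cxy <- sxy - sx * sy / n
  vy <- syy - sy * sy / n
  rss <- vy - ifelse(vx > 0, cxy * cxy / vx, 0)
  pmax(rss, 0)
}

#' Detect slope changepoints on a replichore
#'
#' Optimal-partitioning dynamic programming over probe positions in
#' replichore coordinates: minimizes the total residual sum of squares of
#' independent per-segment straight-line fits plus `penalty` per additional
#' segment. This automates the location of the sharp slope changes visible
#' at inverted rRNA loci.
#'
#' The default penalty is BIC-flavored: `4 * sigma^2 * log(n)`, with
#' `sigma^2` estimated robustly from the median absolute first difference of
#' the track (two extra parameters per segment). Ties are broken toward
#' fewer segments.
#'
#' @param profile A [dosage_profile()] in strain coordinates.
#' @param map A [genome_map()].
#' @param replichore `"right"` or `"left"`.
#' @param penalty Positive penalty per additional segment (RSS units), or
#'   `NULL` for the default.
#' @param min_segment_probes Minimum probes per segment (default 50).
#' @return Numeric vector of breakpoint positions (replichore Mbp), possibly
#'   empty.
#' @export
detect_changepoints <- function(profile, map, replichore = c("right", "left"),
                                penalty = NULL, min_segment_probes = 50) {
  stopifnot(inherits(profile, "dosage_profile"), inherits(map, "genome_map"))
  replichore <- match.arg(replichore)
  rc <- replichore_coordinate(profile$probes$position_bp, map)
  sel <- rc$replichore == replichore
  ord <- order(rc$distance_Mbp[sel])
  x <- rc$distance_Mbp[sel][ord]
  y <- profile$probes$log2_ratio[sel][ord]
  n <- length(x)
  if (n < 2 * min_segment_probes)
    stop("need at least 2 * min_segment_probes probes")
  if (is.null(penalty)) {
    sigma <- stats::median(abs(diff(y))) / (sqrt(2) * 0.6744898)
    penalty <- 4 * sigma^2 * log(n)
  }
  if (penalty <= 0) stop("parameter error: penalty must be > 0")
  cs <- list(x = c(0, cumsum(x)), y = c(0, cumsum(y)),
             xx = c(0, cumsum(x^2)), yy = c(0, cumsum(y^2)),
             xy = c(0, cumsum(x * y)))
  F <- rep(Inf, n + 1); F[1] <- -penalty   # F[j+1]: best cost of y[1..j]
  nseg <- integer(n + 1)
  back <- integer(n + 1)
  for (j in seq.int(min_segment_probes, n)) {
    starts <- which(is.finite(F[seq_len(j - min_segment_probes + 1)])) # candidate i+1 values
    i0 <- starts - 1                       # previous segment ends
    cost <- F[starts] + penalty + .seg_rss(cs, starts, j)
    best <- which(cost < min(cost) + 1e-12)
    # tie-break toward fewer segments
    best <- best[which.min(nseg[starts[best]])]
    F[j + 1] <- cost[best]
    back[j + 1] <- i0[best]
    nseg[j + 1] <- nseg[starts[best]] + 1L
  }
  ends <- integer(0); j <- n
  while (j > 0) { ends <- c(back[j + 1], ends); j <- back[j + 1] }
  ends <- ends[ends > 0]
  # breakpoint position: midpoint between the flanking probes
  if (length(ends)) (x[ends] + x[ends + 1]) / 2 else numeric(0)
}
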