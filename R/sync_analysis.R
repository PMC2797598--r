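#' Initiation fraction from a synchronized-release profile
#'
#' After a synchronized release, loci behind the fork front are present at
#' `1 + f` copies relative to the pre-initiation reference, where `f` is the
#' fraction of cells that initiated replication. The estimator takes the
#' median log2 ratio over an oriC-proximal (replicated) region as the
#' plateau, the median over a distal (unreplicated) region as the baseline,
#' and returns `f = 2^(plateau - baseline) - 1`, clipped to `[0, 1]`.
#'
#' By default the proximal and distal regions are the first and last 10% of
#' the replichore's probes. The estimate is invariant to adding a constant
#' to the whole profile.
#'
#' @param profile A [dosage_profile()] (smooth first, e.g. with
#'   [rolling_average()], or pass `window`).
#' @param map A [genome_map()].
#' @param replichore `"right"` or `"left"`.
#' @param proximal_region,distal_region Optional `c(start, end)` intervals in
#'   replichore Mbp overriding the 10% defaults; each must contain >= 20
#'   probes.
#' @param window Optional probe-count smoothing window applied before
#'   estimation (`NULL` = profile used as given).
#' @return A list with `f`, `plateau_log2`, `baseline_log2`, `replichore`.
#' @export
estimate_initiation_fraction <- function(profile, map,
                                         replichore = c("right", "left"),
                                         proximal_region = NULL,
                                         distal_region = NULL,
                                         window = NULL) {
  stopifnot(inherits(profile, "dosage_profile"), inherits(map, "genome_map"))
  replichore <- match.arg(replichore)
  if (!is.null(window)) profile <- rolling_average(profile, window)
  rc <- replichore_coordinate(profile$probes$position_bp, map)
  sel <- rc$replichore == replichore
  if (!any(sel)) stop("no probes on the requested replichore")
  d <- rc$distance_Mbp[sel]
  y <- profile$probes$log2_ratio[sel]
  ord <- order(d); d <- d[ord]; y <- y[ord]
  n <- length(d)
  in_region <- function(region, default_idx) {
    if (is.null(region)) return(default_idx)
    which(d >= region[1] & d < region[2])
  }
  prox <- in_region(proximal_region, seq_len(max(1, floor(0.1 * n))))
  dist <- in_region(distal_region, seq.int(n - max(1, floor(0.1 * n)) + 1, n))
  if (length(prox) < 20 || length(dist) < 20)
    stop("proximal and distal regions must each contain at least 20 probes")
  plateau <- stats::median(y[prox])
  baseline <- stats::median(y[dist])
  noise <- stats::mad(c(y[prox] - plateau, y[dist] - baseline))
  if (plateau < baseline - 3 * max(noise, .Machine$double.eps))
    stop("inverted profile: plateau below baseline by more than 3x noise")
  f <- min(1, max(0, 2^(plateau - baseline) - 1))
  list(f = f, plateau_log2 = plateau, baseline_log2 = baseline,
       replichore = replichore)
}

#' Fork position as the transition midpoint
#'
#' Estimates the average fork position on a replichore as the point where
#' the (smoothed) log2 ratio first crosses the level halfway between the
#' replicated plateau and the unreplicated baseline, moving away from oriC,
#' with linear interpolation between the flanking probes. The crossing level
#' is defined in log2 space by default; `space = "linear"` uses the halfway
#' point of the linear ratios instead.
#'
#' @inheritParams estimate_initiation_fraction
#' @param space `"log2"` or `"linear"`: where the halfway level is defined.
#' @return A list with `fork_position_Mbp`, `f`, `plateau_log2`,
#'   `baseline_log2`, `replichore`.
#' @export
estimate_fork_position <- function(profile, map, replichore = c("right", "left"),
                                   proximal_region = NULL, distal_region = NULL,
                                   window = NULL, space = c("log2", "linear")) {
  replichore <- match.arg(replichore)
  space <- match.arg(space)
  est <- estimate_initiation_fraction(profile, map, replichore,
                                      proximal_region, distal_region, window)
  if (!is.null(window)) profile <- rolling_average(profile, window)
  rc <- replichore_coordinate(profile$probes$position_bp, map)
  sel <- rc$replichore == replichore
  d <- rc$distance_Mbp[sel]
  y <- profile$probes$log2_ratio[sel]
  ord <- order(d); d <- d[ord]; y <- y[ord]
  level <- if (space == "log2") (est$plateau_log2 + est$baseline_log2) / 2
  else log2((2^est$plateau_log2 + 2^est$baseline_log2) / 2)
  if (est$f <= 0 || est$plateau_log2 - est$baseline_log2 < .Machine$double.eps^0.5)
    stop("no transition detected")
  below <- y < level
  k <- which(below & !c(TRUE, below[-length(below)]))[1]  # first downward crossing
  if (is.na(k) || k == 1) stop("no transition detected")
  # linear interpolation between probes k-1 (above) and k (below)
  x0 <- d[k - 1]; x1 <- d[k]; y0 <- y[k - 1]; y1 <- y[k]
  pos <- x0 + (level - y0) * (x1 - x0) / (y1 - y0)
  c(list(fork_position_Mbp = pos), est)
}

#' Predicted fork position under a velocity schedule
#'
#' Integrates the fork velocity over the time phases of a schedule: the
#' distance a fork has travelled `elapsed_min` minutes after release.
#'
#' @param velocity_schedule A [velocity_schedule()] covering
#'   `[0, elapsed_min]`.
#' @param elapsed_min Minutes since release.
#' @param replichore `"right"` or `"left"`.
#' @return Distance from oriC in Mbp.
#' @export
predicted_fork_position <- function(velocity_schedule, elapsed_min,
                                    replichore = c("right", "left")) {
  stopifnot(inherits(velocity_schedule, "velocity_schedule"))
  replichore <- match.arg(replichore)
  .front_after(velocity_schedule, elapsed_min, replichore)
}
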