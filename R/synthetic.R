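#' Piecewise-constant fork velocity along a replichore
#'
#' A replichore's velocity field v(x): `k` segment velocities (kb/min)
#' separated by `k - 1` strictly increasing internal breakpoints (Mbp from
#' oriC). The first segment starts at oriC; the last extends to the end of
#' the replichore.
#'
#' @param velocities_kb_min Positive segment velocities, kb/min.
#' @param breakpoints_Mbp Internal breakpoints (Mbp), strictly increasing,
#'   length `length(velocities_kb_min) - 1`.
#' @return An object of class `replichore_velocity`.
#' @export
replichore_velocity <- function(velocities_kb_min, breakpoints_Mbp = numeric(0)) {
  v <- as.numeric(velocities_kb_min); b <- as.numeric(breakpoints_Mbp)
  if (any(v <= 0)) stop("velocities must be > 0")
  if (length(b) != length(v) - 1)
    stop("need one fewer breakpoint than velocities")
  if (length(b) > 1 && any(diff(b) <= 0))
    stop("breakpoints must be strictly increasing")
  if (length(b) && any(b <= 0)) stop("breakpoints must be > 0")
  structure(list(velocities_kb_min = v, breakpoints_Mbp = b),
            class = "replichore_velocity")
}

#' Chromosome-wide velocity profile
#'
#' Bundles a [replichore_velocity()] for each arm. A single
#' `replichore_velocity` may be given for `left` to use it on both arms.
#'
#' @param left,right [replichore_velocity()] objects (right defaults to left).
#' @return An object of class `velocity_profile` with elements `$left`,
#'   `$right`.
#' @export
velocity_profile <- function(left, right = left) {
  stopifnot(inherits(left, "replichore_velocity"),
            inherits(right, "replichore_velocity"))
  structure(list(left = left, right = right), class = "velocity_profile")
}

#' Exponential growth law
#'
#' @param doubling_time_min Mass doubling time T, minutes, > 0.
#' @return An object of class `growth_law`.
#' @export
growth_law <- function(doubling_time_min) {
  T <- as.numeric(doubling_time_min)
  stopifnot(length(T) == 1L, T > 0)
  structure(list(doubling_time_min = T), class = "growth_law")
}

#' Time for a fork to reach a replichore distance
#'
#' Integrates `1 / v(s)` over `[0, x]` for a piecewise-constant velocity
#' field: the replication time t(x) in minutes.
#'
#' @param rv A [replichore_velocity()].
#' @param distance_Mbp Vector of distances from oriC, Mbp, >= 0.
#' @return Numeric vector of times (min).
#' @export
time_to_distance <- function(rv, distance_Mbp) {
  stopifnot(inherits(rv, "replichore_velocity"))
  x <- as.numeric(distance_Mbp)
  if (any(x < 0)) stop("distance must be >= 0")
  edges <- c(0, rv$breakpoints_Mbp)           # segment start positions, Mbp
  v_Mbp <- rv$velocities_kb_min / 1000        # Mbp/min
  # cumulative time at each segment start
  seg_len <- diff(c(edges, Inf))
  t_start <- c(0, cumsum(utils::head(seg_len, -1) / utils::head(v_Mbp, -1)))
  idx <- findInterval(x, edges)
  t_start[idx] + (x - edges[idx]) / v_Mbp[idx]
}

#' Distance a fork travels in a given time
#'
#' Inverse of [time_to_distance()] for a piecewise-constant velocity field.
#'
#' @param rv A [replichore_velocity()].
#' @param time_min Vector of elapsed times, min, >= 0.
#' @return Distances from oriC, Mbp.
#' @export
distance_at_time <- function(rv, time_min) {
  stopifnot(inherits(rv, "replichore_velocity"))
  t <- as.numeric(time_min)
  if (any(t < 0)) stop("time must be >= 0")
  edges <- c(0, rv$breakpoints_Mbp)
  v_Mbp <- rv$velocities_kb_min / 1000
  seg_len <- diff(c(edges, Inf))
  t_start <- c(0, cumsum(utils::head(seg_len, -1) / utils::head(v_Mbp, -1)))
  idx <- findInterval(t, t_start)
  edges[idx] + (t - t_start[idx]) * v_Mbp[idx]
}

#' Time-varying velocity schedule
#'
#' A contiguous, non-overlapping sequence of time phases each with its own
#' [velocity_profile()], e.g. slow fork movement for the first 4 minutes
#' after a synchronized release and faster movement after transcription is
#' shut off with rifampicin.
#'
#' @param start_min,end_min Phase boundaries (min); must be contiguous
#'   (`end_min[i] == start_min[i+1]`) with `start_min[1]` the release time 0.
#' @param profiles List of [velocity_profile()] objects, one per phase.
#' @return An object of class `velocity_schedule`.
#' @export
velocity_schedule <- function(start_min, end_min, profiles) {
  start_min <- as.numeric(start_min); end_min <- as.numeric(end_min)
  stopifnot(length(start_min) == length(end_min),
            length(profiles) == length(start_min))
  if (any(end_min <= start_min)) stop("each phase must have end > start")
  if (length(start_min) > 1 &&
      any(abs(utils::head(end_min, -1) - start_min[-1]) > 1e-9))
    stop("schedule error: phases must be contiguous and non-overlapping")
  if (!all(vapply(profiles, inherits, logical(1), "velocity_profile")))
    stop("profiles must be velocity_profile objects")
  structure(list(start_min = start_min, end_min = end_min, profiles = profiles),
            class = "velocity_schedule")
}

# fork front distance (Mbp) on one arm after `elapsed` minutes of a schedule
.front_after <- function(schedule, elapsed, arm = c("right", "left")) {
  arm <- match.arg(arm)
  if (elapsed < min(schedule$start_min) - 1e-9 ||
      elapsed > max(schedule$end_min) + 1e-9)
    stop("schedule error: schedule does not cover the elapsed interval")
  d <- 0
  for (i in seq_along(schedule$start_min)) {
    t0 <- schedule$start_min[i]; t1 <- min(schedule$end_min[i], elapsed)
    if (t1 <= t0) break
    rv <- schedule$profiles[[i]][[arm]]
    # advance the front through rv for (t1 - t0) minutes starting from d
    t_at_d <- time_to_distance(rv, d)
    d <- distance_at_time(rv, t_at_d + (t1 - t0))
    if (elapsed <= schedule$end_min[i] + 1e-9) break
  }
  d
}

#' Expected asynchronous steady-state dosage profile
#'
#' Closed form of the steady-state model: in a population growing
#' exponentially with doubling time T, the log2 gene dosage at replichore
#' distance x is `g(x) = g(0) - t(x) / T`, where `t(x)` is the fork's travel
#' time to x. The intercept convention is `g(0) = 0` at oriC, so the local
#' slope of the decline is `1 / (v(x) * T)` per Mbp.
#'
#' @param velocity A [velocity_profile()].
#' @param growth A [growth_law()].
#' @param map A [genome_map()].
#' @param probe_positions Probe positions in bp (strain coordinates),
#'   strictly increasing.
#' @return A [dosage_profile()] with `doubling_time_min` set.
#' @export
expected_async_profile <- function(velocity, growth, map, probe_positions) {
  stopifnot(inherits(velocity, "velocity_profile"),
            inherits(growth, "growth_law"), inherits(map, "genome_map"))
  rc <- replichore_coordinate(probe_positions, map)
  t <- numeric(nrow(rc))
  for (arm in c("left", "right")) {
    sel <- rc$replichore == arm
    if (any(sel)) t[sel] <- time_to_distance(velocity[[arm]], rc$distance_Mbp[sel])
  }
  dosage_profile(probe_positions, -t / growth$doubling_time_min,
                 doubling_time_min = growth$doubling_time_min)
}

#' Sample a noisy asynchronous dosage profile
#'
#' Two noise models on top of the steady-state expectation:
#' \describe{
#'   \item{`probe_noise`}{adds i.i.d. Gaussian noise (sd `noise_sd`, log2
#'     units) to the closed-form profile — an aCGH-like measurement model.}
#'   \item{`cell_sampling`}{simulates `n_cells` cells. Each cell's most
#'     recent initiation happened a fraction phi of a doubling ago, with phi
#'     drawn from the exponential-growth phase density `2 ln2 * 2^(-phi)` on
#'     [0, 1); earlier initiations happened at phi + 1, phi + 2, ... doublings
#'     back. A locus's copy number relative to oriC is `2^(-m)` where m is
#'     the number of initiations whose fork has not yet passed it. The probe
#'     value is the log2 of the population mean copy number, normalized to
#'     oriC.}
#' }
#'
#' @inheritParams expected_async_profile
#' @param noise_sd Gaussian noise sd in log2 units (probe_noise mode).
#' @param mode `"probe_noise"` or `"cell_sampling"`.
#' @param n_cells Number of simulated cells (cell_sampling mode, >= 100).
#' @param seed Integer seed; the sampler is deterministic given it.
#' @return A [dosage_profile()].
#' @export
sample_async_profile <- function(velocity, growth, map, probe_positions,
                                 noise_sd = 0.05,
                                 mode = c("probe_noise", "cell_sampling"),
                                 n_cells = 10000, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed must be provided for reproducibility")
  set.seed(as.integer(seed))
  if (mode == "probe_noise") {
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    prof <- expected_async_profile(velocity, growth, map, probe_positions)
    prof$probes$log2_ratio <- prof$probes$log2_ratio +
      stats::rnorm(n_probes(prof), sd = noise_sd)
    return(prof)
  }
  if (n_cells < 100) stop("sampling-size error: n_cells must be >= 100")
  rc <- replichore_coordinate(probe_positions, map)
  T <- growth$doubling_time_min
  t <- numeric(nrow(rc))
  for (arm in c("left", "right")) {
    sel <- rc$replichore == arm
    if (any(sel)) t[sel] <- time_to_distance(velocity[[arm]], rc$distance_Mbp[sel])
  }
  u <- t / T                                   # replication time in doublings
  # inverse-CDF draw from density 2 ln2 * 2^(-phi), phi in [0, 1)
  phi <- -log2(1 - stats::runif(n_cells) / 2)
  mean_copy <- vapply(u, function(ui) {
    m <- ceiling(ui - phi)
    m[m < 0] <- 0
    mean(2^(-m))
  }, numeric(1))
  dosage_profile(probe_positions, log2(mean_copy), doubling_time_min = T)
}

#' Expected synchronized-release dosage profile
#'
#' After a synchronized release in which a fraction `f_init` of cells
#' initiate replication, the dosage ratio against a pre-initiation reference
#' is a two-plateau step on each replichore: `1 + f_init` behind the fork
#' front and 1 beyond it, reported in log2. The front position after
#' `elapsed_min` minutes is obtained by propagating the fork through the
#' (possibly time-varying) velocity schedule.
#'
#' @param velocity_schedule A [velocity_schedule()] covering
#'   `[0, elapsed_min]`.
#' @param f_init Fraction of cells that initiated, in `[0, 1]`.
#' @param elapsed_min Minutes since release.
#' @param map A [genome_map()].
#' @param probe_positions Probe positions in bp.
#' @return A [dosage_profile()] with `time_min = elapsed_min`.
#' @export
expected_sync_profile <- function(velocity_schedule, f_init, elapsed_min, map,
                                  probe_positions) {
  stopifnot(inherits(velocity_schedule, "velocity_schedule"))
  if (f_init < 0 || f_init > 1) stop("f_init must be in [0, 1]")
  rc <- replichore_coordinate(probe_positions, map)
  y <- numeric(nrow(rc))
  for (arm in c("left", "right")) {
    sel <- rc$replichore == arm
    if (!any(sel)) next
    front <- .front_after(velocity_schedule, elapsed_min, arm)
    y[sel] <- log2(1 + f_init * (rc$distance_Mbp[sel] <= front))
  }
  dosage_profile(probe_positions, y, time_min = elapsed_min)
}

#' Sample a noisy synchronized-release profile
#'
#' Adds i.i.d. Gaussian probe noise to [expected_sync_profile()].
#'
#' @inheritParams expected_sync_profile
#' @param noise_sd Gaussian noise sd in log2 units, >= 0.
#' @param seed Integer seed.
#' @return A [dosage_profile()].
#' @export
sample_sync_profile <- function(velocity_schedule, f_init, elapsed_min, map,
                                probe_positions, noise_sd = 0.05, seed) {
  if (missing(seed)) stop("seed must be provided for reproducibility")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  prof <- expected_sync_profile(velocity_schedule, f_init, elapsed_min, map,
                                probe_positions)
  prof$probes$log2_ratio <- prof$probes$log2_ratio +
    stats::rnorm(n_probes(prof), sd = noise_sd)
  prof
}

#' Fluctuation assay data
#'
#' Parallel-culture mutant counts for a Luria-Delbruck fluctuation test.
#' Either full per-culture counts or only the number of zero-mutant cultures
#' may be supplied (the P0 method needs only the latter).
#'
#' @param mutant_counts Integer vector of per-culture mutant counts, or
#'   `NULL` if only `n_zero` is known.
#' @param Nt Final cells per culture (> N0).
#' @param N0 Initial cells per culture (>= 1).
#' @param n_cultures Number of parallel cultures (required when
#'   `mutant_counts` is `NULL`).
#' @param n_zero Number of cultures with zero mutants (derived from counts
#'   when they are given).
#' @return An object of class `fluctuation_assay`.
#' @export
fluctuation_assay <- function(mutant_counts = NULL, Nt, N0 = 1,
                              n_cultures = length(mutant_counts),
                              n_zero = NULL) {
  Nt <- as.numeric(Nt); N0 <- as.numeric(N0)
  stopifnot(Nt > N0, N0 >= 1)
  if (!is.null(mutant_counts)) {
    mutant_counts <- as.numeric(mutant_counts)
    if (any(mutant_counts < 0)) stop("mutant counts must be >= 0")
    n_zero <- sum(mutant_counts == 0)
    n_cultures <- length(mutant_counts)
  } else {
    if (is.null(n_zero)) stop("supply mutant_counts or n_zero")
    stopifnot(n_zero >= 0, n_zero <= n_cultures, n_cultures >= 1)
  }
  structure(list(mutant_counts = mutant_counts, n_cultures = as.integer(n_cultures),
                 n_zero = as.integer(n_zero), Nt = Nt, N0 = N0),
            class = "fluctuation_assay")
}

#' @export
print.fluctuation_assay <- function(x, ...) {
  cat(sprintf("fluctuation_assay: %d cultures, %d with zero mutants; Nt = %g, N0 = %g\n",
              x$n_cultures, x$n_zero, x$Nt, x$N0))
  invisible(x)
}

#' Simulate a Luria-Delbruck fluctuation assay
#'
#' Discrete-generation (Lea-Coulson) sampler. Each culture grows from N0 to
#' Nt cells over `g = log2(Nt / N0)` doublings; the number of new mutations
#' arising while the population grows from `N[k-1]` to `N[k]` is Poisson with
#' mean `mu * (N[k] - N[k-1])`, and each mutation founds a clone whose final
#' size is `2^(g - k)` (at least 1). Generations are taken at exact
#' fractional spacing (`N[k] = min(N0 * 2^k, Nt)`), so the zero-mutant
#' probability is exactly `exp(-mu * (Nt - N0))`. Plating efficiency is 1.
#'
#' @param mutation_rate Mutations per cell per division, mu >= 0 (values
#'   <= 0 give exactly zero mutants).
#' @param N0 Initial cells per culture.
#' @param Nt Final cells per culture.
#' @param n_cultures Number of parallel cultures.
#' @param seed Integer seed.
#' @return A [fluctuation_assay()] with per-culture counts.
#' @export
simulate_fluctuation_assay <- function(mutation_rate, N0 = 1, Nt, n_cultures = 50,
                                       seed) {
  if (missing(seed)) stop("seed must be provided for reproducibility")
  set.seed(as.integer(seed))
  mu <- max(0, as.numeric(mutation_rate))
  if (mu * Nt >= 10)
    warning("mu * Nt >= 10: nearly no zero-mutant cultures expected (P0 ~ 0)")
  g <- log2(Nt / N0)
  K <- ceiling(g)
  Nk <- pmin(N0 * 2^seq_len(K), Nt)
  dN <- diff(c(N0, Nk))
  clone_size <- pmax(1, round(2^(g - seq_len(K))))
  counts <- if (mu == 0) rep(0, n_cultures) else {
    muts <- matrix(stats::rpois(K * n_cultures, lambda = mu * dN),
                   nrow = K, ncol = n_cultures)
    as.numeric(crossprod(muts, clone_size))
  }
  fluctuation_assay(mutant_counts = counts, Nt = Nt, N0 = N0)
}

#' Simulate a pairwise competition
#'
#' The reference strain expands by `generations_ref` doublings; the test
#' strain, with relative fitness `true_W` (ratio of Malthusian parameters),
#' expands by `true_W * generations_ref` doublings over the same period.
#' Final counts receive multiplicative lognormal noise with mean 1 and
#' coefficient of variation `count_noise_cv`.
#'
#' @param true_W True relative fitness of the test strain, > 0.
#' @param generations_ref Reference-strain doublings over the competition.
#' @param N0_each Starting count of each competitor.
#' @param count_noise_cv CV of the lognormal count noise (0 = noiseless).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `strain` (`"test"`, `"reference"`),
#'   `n_initial`, `n_final`.
#' @export
simulate_competition <- function(true_W, generations_ref = 10, N0_each = 1e5,
                                 count_noise_cv = 0.02, seed) {
  if (missing(seed)) stop("seed must be provided for reproducibility")
  set.seed(as.integer(seed))
  stopifnot(true_W > 0, generations_ref > 0, N0_each > 0, count_noise_cv >= 0)
  noise <- function() {
    if (count_noise_cv == 0) return(1)
    sdlog <- sqrt(log(1 + count_noise_cv^2))
    stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean exactly 1
  }
  data.frame(
    strain = c("test", "reference"),
    n_initial = c(N0_each, N0_each),
    n_final = c(N0_each * 2^(true_W * generations_ref) * noise(),
                N0_each * 2^generations_ref * noise()),
    stringsAsFactors = FALSE)
}

#' Velocity profiles matching the published HT-strain slope structure
#'
#' Builds a [velocity_profile()] whose per-segment fork velocities reproduce
#' the published piecewise slopes of the HT inversion strain's asynchronous
#' dosage profiles (`v = 1/(a T)` per segment), for growth in minimal medium
#' ("Min": left replichore 0.408 per Mbp; inverted right-replichore head-on
#' region 0.646; co-directional 0.462) or minimal + casamino acids ("CAA":
#' left 0.450; head-on sub-segments 0.640 / 0.615 / 0.654 with a steep
#' 1.51-per-Mbp stall segment over the inverted rrnGHI-aprE interval; then
#' 0.456). Segment boundaries sit at the rRNA landmark loci (13, 40, 80 deg)
#' and the inversion edge aprE (94 deg) / pksE (153 deg), converted to
#' replichore Mbp.
#'
#' @param medium `"Min"` or `"CAA"`.
#' @param doubling_time_min Doubling time used for the slope-to-velocity
#'   conversion (default 44 min, the Min-medium doubling time of the
#'   stabilized HT strain; for CAA the published value is 55 min).
#' @param map The HT [genome_map()] (used to place segment boundaries).
#' @return A [velocity_profile()].
#' @export
ht_velocity_profile <- function(medium = c("Min", "CAA"),
                                doubling_time_min = if (match.arg(medium) == "Min") 44 else 55,
                                map = bsub_genome_map("HT")) {
  medium <- match.arg(medium)
  T <- doubling_time_min
  Mbp_per_deg <- map$genome_length_bp / 360 / 1e6
  v <- function(a) 1000 / (a * T)  # kb/min from slope (per Mbp)
  if (medium == "Min") {
    right <- replichore_velocity(v(c(0.646, 0.462)),
                                 breakpoints_Mbp = 94 * Mbp_per_deg)
    left <- replichore_velocity(v(0.408))
  } else {
    right <- replichore_velocity(v(c(0.640, 0.615, 0.654, 1.51, 0.456)),
                                 breakpoints_Mbp = c(13, 40, 80, 94) * Mbp_per_deg)
    left <- replichore_velocity(v(0.450))
  }
  velocity_profile(left = left, right = right)
}
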