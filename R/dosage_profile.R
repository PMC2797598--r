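#' Gene-dosage profile
#'
#' A track of microarray-style probes: genomic position (bp) and log2 dosage
#' ratio versus a reference, with growth metadata. In an exponentially growing
#' asynchronous population the log2 ratio declines from oriC along each
#' replichore with local slope `1/(v(x) * T)` per Mbp, which is what the
#' inference functions exploit.
#'
#' @param position_bp Strictly increasing probe positions (bp).
#' @param log2_ratio Finite log2 dosage ratios, one per probe.
#' @param condition,strain Optional labels.
#' @param time_min Optional measurement time (min), e.g. minutes after a
#'   synchronized release.
#' @param doubling_time_min Optional mass doubling time T (min) of the
#'   culture the profile was taken from.
#' @param extra Optional `data.frame` of additional per-probe columns,
#'   preserved by I/O.
#' @return An object of class `dosage_profile` with elements `probes`
#'   (a data.frame) and the metadata fields.
#' @export
dosage_profile <- function(position_bp, log2_ratio, condition = NA_character_,
                           strain = NA_character_, time_min = NA_real_,
                           doubling_time_min = NA_real_, extra = NULL) {
  position_bp <- as.numeric(position_bp)
  log2_ratio <- as.numeric(log2_ratio)
  if (length(position_bp) != length(log2_ratio))
    stop("position_bp and log2_ratio must have equal length")
  if (length(position_bp) == 0) stop("profile must contain at least one probe")
  if (any(!is.finite(position_bp)) || any(!is.finite(log2_ratio)))
    stop("positions and log2 ratios must be finite")
  if (any(diff(position_bp) <= 0))
    stop("probe positions must be strictly increasing (no duplicates)")
  probes <- data.frame(position_bp = position_bp, log2_ratio = log2_ratio)
  if (!is.null(extra)) {
    stopifnot(is.data.frame(extra), nrow(extra) == nrow(probes))
    probes <- cbind(probes, extra)
  }
  structure(list(probes = probes, condition = condition, strain = strain,
                 time_min = as.numeric(time_min),
                 doubling_time_min = as.numeric(doubling_time_min)),
            class = "dosage_profile")
}

#' @export
print.dosage_profile <- function(x, ...) {
  cat(sprintf("dosage_profile: %d probes, %s..%s bp, log2 range [%.3f, %.3f]\n",
              nrow(x$probes), format(min(x$probes$position_bp), big.mark = ","),
              format(max(x$probes$position_bp), big.mark = ","),
              min(x$probes$log2_ratio), max(x$probes$log2_ratio)))
  meta <- c(condition = x$condition, strain = x$strain)
  meta <- meta[!is.na(meta)]
  if (length(meta)) cat(" ", paste(names(meta), meta, sep = ": ", collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.dosage_profile <- function(x, ...) x$probes

#' Number of probes in a profile
#' @param profile A [dosage_profile()].
#' @return Integer probe count.
#' @export
n_probes <- function(profile) nrow(profile$probes)

# metadata fields serialized as "# key<TAB>value" header comments
.profile_meta_fields <- c("condition", "strain", "time_min", "doubling_time_min")

#' Read / write dosage profiles as TSV
#'
#' The on-disk format is a tab-separated table with header columns
#' `position_bp` and `log2_ratio`; any extra columns are carried through.
#' Metadata (condition, strain, times) are stored in `# key<TAB>value`
#' comment lines above the header and restored on read. The round trip is
#' faithful to at least 12 significant digits.
#'
#' @param path File path.
#' @return `read_profile`: a [dosage_profile()].
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "\t", fixed = TRUE)[[1]]
    if (length(kv) == 2 && kv[1] %in% .profile_meta_fields) meta[[kv[1]]] <- kv[2]
  }
  tab <- utils::read.delim(text = lines, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("position_bp", "log2_ratio") %in% names(tab)))
    stop("format error: header must contain position_bp and log2_ratio")
  if (!is.numeric(tab$position_bp) || !is.numeric(tab$log2_ratio))
    stop("parse error: non-numeric position_bp or log2_ratio values")
  if (anyNA(tab$position_bp) || anyNA(tab$log2_ratio))
    stop("parse error: missing values in position_bp or log2_ratio")
  if (any(diff(tab$position_bp) <= 0))
    stop("format error: positions must be strictly increasing")
  extra_cols <- setdiff(names(tab), c("position_bp", "log2_ratio"))
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  dosage_profile(tab$position_bp, tab$log2_ratio,
                 condition = if (is.null(meta$condition)) NA_character_ else meta$condition,
                 strain = if (is.null(meta$strain)) NA_character_ else meta$strain,
                 time_min = num_or_na(meta$time_min),
                 doubling_time_min = num_or_na(meta$doubling_time_min),
                 extra = if (length(extra_cols)) tab[extra_cols] else NULL)
}

#' @rdname read_profile
#' @param profile A [dosage_profile()].
#' @return `write_profile`: the path, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "dosage_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in .profile_meta_fields) {
    v <- profile[[f]]
    if (length(v) == 1 && !is.na(v))
      writeLines(sprintf("# %s\t%s", f, format(v, digits = 15)), con)
  }
  tab <- profile$probes
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) format(v, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a profile as bedGraph
#'
#' Each probe becomes a 1-bp interval: `chrom<TAB>start<TAB>start+1<TAB>value`.
#'
#' @param profile A [dosage_profile()].
#' @param path Output path.
#' @param chrom Chromosome name to print (default `"chr"`).
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(profile, path, chrom = "chr") {
  stopifnot(inherits(profile, "dosage_profile"))
  p <- profile$probes
  lines <- sprintf("%s\t%d\t%d\t%s", chrom, as.integer(p$position_bp),
                   as.integer(p$position_bp) + 1L,
                   format(p$log2_ratio, digits = 15, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Rolling average of a dosage profile
#'
#' Smooths the log2 ratios with an unweighted mean over `window` consecutive
#' probes; the smoothed value is reported at the midpoint of the window's
#' first and last probe positions. Only full windows are emitted, so the
#' output has `n - window + 1` probes. Windows count probes, not bp.
#'
#' @param profile A [dosage_profile()].
#' @param window Window size in probes, `1 <= window <= n_probes(profile)`.
#' @return A smoothed [dosage_profile()] (metadata preserved).
#' @export
rolling_average <- function(profile, window) {
  stopifnot(inherits(profile, "dosage_profile"))
  window <- as.integer(window)
  n <- n_probes(profile)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("size error: window larger than number of probes")
  y <- zoo::rollmean(profile$probes$log2_ratio, k = window, align = "left")
  pos <- profile$probes$position_bp
  mid <- (pos[seq_len(n - window + 1)] + pos[seq.int(window, n)]) / 2
  dosage_profile(mid, y, condition = profile$condition, strain = profile$strain,
                 time_min = profile$time_min,
                 doubling_time_min = profile$doubling_time_min)
}

#' Per-position difference of two profiles
#'
#' Computes `log2 A - log2 B` at shared positions, e.g. the rich-vs-minimal
#' relative dosage track that localizes nutrient-dependent fork stalling.
#' With `interpolate = TRUE`, B is linearly interpolated onto A's positions
#' (no extrapolation: A probes outside B's range are dropped).
#'
#' @param profileA,profileB [dosage_profile()] objects on the same genome.
#' @param interpolate Interpolate B onto A's positions instead of
#'   intersecting probe sets.
#' @return A [dosage_profile()] of differences (metadata from A).
#' @export
relative_profile <- function(profileA, profileB, interpolate = FALSE) {
  stopifnot(inherits(profileA, "dosage_profile"),
            inherits(profileB, "dosage_profile"))
  a <- profileA$probes; b <- profileB$probes
  if (interpolate) {
    keep <- a$position_bp >= min(b$position_bp) & a$position_bp <= max(b$position_bp)
    if (!any(keep)) stop("alignment error: no A probes within B's range")
    bi <- stats::approx(b$position_bp, b$log2_ratio, xout = a$position_bp[keep],
                        method = "linear", rule = 1)$y
    pos <- a$position_bp[keep]
    diff <- a$log2_ratio[keep] - bi
  } else {
    pos <- intersect(a$position_bp, b$position_bp)
    if (length(pos) == 0)
      stop("alignment error: empty probe intersection (set interpolate = TRUE?)")
    pos <- sort(pos)
    diff <- a$log2_ratio[match(pos, a$position_bp)] -
      b$log2_ratio[match(pos, b$position_bp)]
  }
  dosage_profile(pos, diff, condition = profileA$condition,
                 strain = profileA$strain)
}

#' Center a profile on a reference region
#'
#' Log2 dosage ratios carry an arbitrary intercept set by the hybridization
#' normalization; this subtracts the median log2 ratio over a reference
#' region (default: the whole profile) so that profiles can be compared.
#'
#' @param profile A [dosage_profile()].
#' @param reference_region Optional `c(start_bp, end_bp)` half-open interval;
#'   must contain at least 10 probes.
#' @return A centered [dosage_profile()]. Centering is idempotent.
#' @export
center_profile <- function(profile, reference_region = NULL) {
  stopifnot(inherits(profile, "dosage_profile"))
  y <- profile$probes$log2_ratio
  if (is.null(reference_region)) {
    sel <- rep(TRUE, length(y))
  } else {
    stopifnot(length(reference_region) == 2)
    sel <- profile$probes$position_bp >= reference_region[1] &
      profile$probes$position_bp < reference_region[2]
  }
  if (sum(sel) < 10)
    stop("region error: reference region must contain at least 10 probes")
  out <- profile
  out$probes$log2_ratio <- y - stats::median(y[sel])
  out
}
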