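#' Genome map for a circular bacterial chromosome
#'
#' Describes the coordinate system used throughout the package: a circular
#' chromosome of `genome_length_bp` base pairs with a replication origin
#' (`oriC_bp`) and terminus (`terC_bp`), optional annotated features, and an
#' ordered list of rearrangements (inversions, deletions) relative to the
#' reference coordinate system. Coordinates are 0-based; all intervals are
#' half-open `[start, end)`.
#'
#' The two replichores are the arcs swept by the bidirectional replication
#' forks: the *right* replichore is the clockwise arc from oriC to terC
#' (increasing bp, modulo the genome length), the *left* replichore the
#' counterclockwise arc.
#'
#' @param genome_length_bp Chromosome length in bp.
#' @param oriC_bp Position of the replication origin (0-based bp).
#' @param terC_bp Position of the replication terminus (0-based bp).
#' @param features Optional `data.frame` with columns `name`, `start_bp`,
#'   `end_bp`, `strand`. Intervals are half-open and must lie within the
#'   genome.
#' @param rearrangements Ordered list of objects built by [rearrangement()].
#'   List order is the order of application.
#' @return An object of class `genome_map`.
#' @seealso [bsub_genome_map()] for ready-made B. subtilis 168 maps.
#' @export
genome_map <- function(genome_length_bp, oriC_bp = 0L, terC_bp,
                       features = NULL, rearrangements = list()) {
  genome_length_bp <- as.numeric(genome_length_bp)
  stopifnot(length(genome_length_bp) == 1L, genome_length_bp > 0)
  if (missing(terC_bp)) terC_bp <- floor(genome_length_bp / 2)
  oriC_bp <- as.numeric(oriC_bp); terC_bp <- as.numeric(terC_bp)
  if (oriC_bp < 0 || oriC_bp >= genome_length_bp ||
      terC_bp < 0 || terC_bp >= genome_length_bp)
    stop("oriC_bp and terC_bp must lie in [0, genome_length_bp)")
  if (oriC_bp == terC_bp) stop("oriC and terC must differ")
  if (is.null(features)) {
    features <- data.frame(name = character(), start_bp = numeric(),
                           end_bp = numeric(), strand = character(),
                           stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("name", "start_bp", "end_bp") %in% names(features)))
    if (is.null(features$strand)) features$strand <- "*"
    if (any(features$start_bp < 0 | features$end_bp > genome_length_bp |
            features$start_bp >= features$end_bp))
      stop("feature intervals must be half-open and within the genome")
  }
  if (length(rearrangements) > 0) {
    if (!all(vapply(rearrangements, inherits, logical(1), "rearrangement")))
      stop("rearrangements must be a list of rearrangement() objects")
    iv <- t(vapply(rearrangements, function(r) c(r$start_bp, r$end_bp),
                   numeric(2)))
    if (any(iv[, 2] > genome_length_bp))
      stop("rearrangement interval outside genome")
    o <- order(iv[, 1])
    if (any(iv[o, 1][-1] < iv[o, 2][-nrow(iv)]))
      stop("rearrangement intervals must not overlap")
  }
  structure(list(genome_length_bp = genome_length_bp, oriC_bp = oriC_bp,
                 terC_bp = terC_bp, features = features,
                 rearrangements = rearrangements),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("genome_map: %s bp circular; oriC %s bp (%.1f deg), terC %s bp (%.1f deg)\n",
              format(x$genome_length_bp, big.mark = ","),
              format(x$oriC_bp, big.mark = ","), bp_to_degrees(x$oriC_bp, x),
              format(x$terC_bp, big.mark = ","), bp_to_degrees(x$terC_bp, x)))
  if (nrow(x$features)) cat(" features:", paste(x$features$name, collapse = ", "), "\n")
  if (length(x$rearrangements))
    cat(" rearrangements:", paste(vapply(x$rearrangements, function(r)
      sprintf("%s[%g,%g)", r$kind, r$start_bp, r$end_bp), character(1)),
      collapse = ", "), "\n")
  invisible(x)
}

#' Chromosomal rearrangement
#'
#' A single inversion or deletion of a half-open interval `[start_bp, end_bp)`
#' in reference coordinates.
#'
#' @param kind `"inversion"` or `"deletion"`.
#' @param start_bp,end_bp Half-open interval bounds, `start_bp < end_bp`.
#' @return An object of class `rearrangement`.
#' @export
rearrangement <- function(kind = c("inversion", "deletion"), start_bp, end_bp) {
  kind <- match.arg(kind)
  start_bp <- as.numeric(start_bp); end_bp <- as.numeric(end_bp)
  if (!(start_bp < end_bp)) stop("start_bp must be < end_bp")
  if (start_bp < 0) stop("start_bp must be >= 0")
  structure(list(kind = kind, start_bp = start_bp, end_bp = end_bp),
            class = "rearrangement")
}

#' Convert between bp and degree coordinates
#'
#' Positions on circular bacterial chromosomes are conventionally reported in
#' degrees (oriC at 0, one full turn = the genome length). These helpers
#' convert; degrees are a display/exchange convention only and all internal
#' arithmetic is in bp.
#'
#' @param position_bp Vector of positions in bp, each in `[0, genome_length)`.
#' @param map A [genome_map()].
#' @return `bp_to_degrees`: numeric degrees in `[0, 360)`.
#' @export
bp_to_degrees <- function(position_bp, map) {
  position_bp <- as.numeric(position_bp)
  if (any(position_bp < 0 | position_bp >= map$genome_length_bp))
    stop("position out of range [0, genome_length_bp)")
  360 * position_bp / map$genome_length_bp
}

#' @rdname bp_to_degrees
#' @param degrees Vector of positions in degrees, each in `[0, 360)`.
#' @return `degrees_to_bp`: integer-rounded bp positions.
#' @export
degrees_to_bp <- function(degrees, map) {
  degrees <- as.numeric(degrees)
  if (any(degrees < 0 | degrees >= 360))
    stop("degrees out of range [0, 360)")
  round(degrees / 360 * map$genome_length_bp) %% map$genome_length_bp
}

#' Replichore coordinates of genomic positions
#'
#' Maps reference positions to the arm of the chromosome that replicates them
#' and the distance travelled by the fork from oriC to reach them. The right
#' replichore is the clockwise arc oriC -> terC; the left replichore the
#' counterclockwise arc. The signed plotting coordinate is `+distance` on the
#' right and `-distance` on the left, the convention used for origin-centered
#' dosage plots.
#'
#' Positions are assumed to be in the rearranged (strain) coordinate system,
#' i.e. [apply_rearrangements()] has already been applied where relevant.
#'
#' @param position_bp Vector of positions in bp.
#' @param map A [genome_map()].
#' @return A `data.frame` with columns `position_bp`, `replichore`
#'   (`"left"`/`"right"`), `distance_Mbp` (>= 0) and `signed_Mbp`.
#' @export
replichore_coordinate <- function(position_bp, map) {
  position_bp <- as.numeric(position_bp)
  L <- map$genome_length_bp
  if (any(position_bp < 0 | position_bp >= L))
    stop("position out of range [0, genome_length_bp)")
  d_cw <- (position_bp - map$oriC_bp) %% L
  d_ccw <- (map$oriC_bp - position_bp) %% L
  right_len <- (map$terC_bp - map$oriC_bp) %% L
  is_right <- d_cw <= right_len
  dist_bp <- ifelse(is_right, d_cw, d_ccw)
  data.frame(position_bp = position_bp,
             replichore = ifelse(is_right, "right", "left"),
             distance_Mbp = dist_bp / 1e6,
             signed_Mbp = ifelse(is_right, 1, -1) * dist_bp / 1e6,
             stringsAsFactors = FALSE)
}

#' Replichore lengths
#'
#' @param map A [genome_map()].
#' @return Named numeric vector `c(right =, left =)` in bp; sums to the
#'   genome length.
#' @export
replichore_lengths <- function(map) {
  L <- map$genome_length_bp
  right <- (map$terC_bp - map$oriC_bp) %% L
  c(right = right, left = L - right)
}

#' Remap positions through a map's rearrangements
#'
#' Applies the map's ordered rearrangement list to reference positions,
#' producing positions in the rearranged (strain) coordinate system. An
#' inversion `[s, e)` mirrors positions inside the interval
#' (`x -> s + e - 1 - x`) and leaves the rest untouched; a deletion `[s, e)`
#' shifts positions at or beyond `e` left by the deleted length and removes
#' positions inside the interval (an error if any input falls there).
#'
#' @param position_bp Vector of positions in bp (reference coordinates).
#' @param map A [genome_map()] whose `rearrangements` are applied in list
#'   order.
#' @return Numeric vector of remapped positions.
#' @export
apply_rearrangements <- function(position_bp, map) {
  x <- as.numeric(position_bp)
  for (r in map$rearrangements) {
    if (r$kind == "inversion") {
      inside <- x >= r$start_bp & x < r$end_bp
      x[inside] <- r$start_bp + r$end_bp - 1 - x[inside]
    } else { # deletion
      if (any(x >= r$start_bp & x < r$end_bp))
        stop("position removed by rearrangement (inside deleted interval)")
      shift <- x >= r$end_bp
      x[shift] <- x[shift] - (r$end_bp - r$start_bp)
    }
  }
  x
}

#' Ready-made B. subtilis 168 genome maps
#'
#' Convenience constructors for the chromosome geometries used in the worked
#' analyses: the wild-type chromosome (4,214,810 bp; oriC at 0 deg, terC at
#' 172 deg) and engineered variants. Annotated features are the rRNA operon
#' clusters and landmark loci at their published degree positions (rrnD 13,
#' rrnE 40, rrnGHI 80, aprE 94, pksE 153).
#'
#' Variants:
#' \describe{
#'   \item{`wt`}{no rearrangements.}
#'   \item{`HT`}{inversion of `[0, 94 deg)`: head-on transcription over the
#'     oriC-proximal right replichore, equal replichores.}
#'   \item{`UR`}{oriC relocated to 94 deg, no inversion: unequal replichores,
#'     transcription bias preserved.}
#'   \item{`HT-left`}{inversion of the oriC-proximal half of the left
#'     replichore, `[266 deg, 360 deg)`.}
#'   \item{`rrnIHG`}{inversion of the rrnIHG operon cluster,
#'     `[159778, 176408)` bp.}
#' }
#'
#' @param variant One of `"wt"`, `"HT"`, `"UR"`, `"HT-left"`, `"rrnIHG"`.
#' @param genome_length_bp Chromosome length in bp (default published
#'   B. subtilis 168 length).
#' @return A [genome_map()].
#' @export
bsub_genome_map <- function(variant = c("wt", "HT", "UR", "HT-left", "rrnIHG"),
                            genome_length_bp = 4214810) {
  variant <- match.arg(variant)
  deg <- function(d) round(d / 360 * genome_length_bp)
  feat <- data.frame(
    name = c("rrnD", "rrnE", "rrnGHI", "aprE", "pksE"),
    start_bp = deg(c(13, 40, 80, 94, 153)),
    end_bp = deg(c(13, 40, 80, 94, 153)) + 1,
    strand = "*", stringsAsFactors = FALSE)
  oriC <- 0
  rearr <- list()
  if (variant == "HT") {
    rearr <- list(rearrangement("inversion", 0, deg(94)))
  } else if (variant == "UR") {
    oriC <- deg(94)
  } else if (variant == "HT-left") {
    rearr <- list(rearrangement("inversion", deg(266), genome_length_bp))
  } else if (variant == "rrnIHG") {
    rearr <- list(rearrangement("inversion", 159778, 176408))
  }
  genome_map(genome_length_bp, oriC_bp = oriC, terC_bp = deg(172),
             features = feat, rearrangements = rearr)
}
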