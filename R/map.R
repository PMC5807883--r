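#' Construct a genetic (linkage) map
#'
#' A `genetic_map` holds ordered marker positions, in Haldane centimorgans,
#' on the nine cauliflower chromosomes O1--O9 (or any user-supplied set of
#' linkage groups). Positions are absolute within a chromosome, starting at 0
#' at the first marker.
#'
#' @param marker character vector of globally unique marker names.
#' @param chromosome character vector of chromosome ids, same length.
#' @param position_cM numeric vector of map positions (cM), non-negative and
#'   non-decreasing within each chromosome.
#' @return an object of class `genetic_map`: a data.frame with columns
#'   `marker`, `chromosome`, `position_cM`, chromosomes kept in first-seen
#'   order, plus attributes `chromosomes` and `length_cM` (total map length,
#'   the sum of per-chromosome spans).
#' @examples
#' gm <- genetic_map(c("mA", "mB", "mC"), c("O1", "O1", "O2"), c(0, 10, 0))
#' total_map_length(gm)
#' @export
genetic_map <- function(marker, chromosome, position_cM) {
  marker <- as.character(marker)
  chromosome <- as.character(chromosome)
  position_cM <- as.numeric(position_cM)
  n <- length(marker)
  if (length(chromosome) != n || length(position_cM) != n) {
    abort_validation("marker, chromosome and position_cM must have equal length")
  }
  if (n == 0L) abort_validation("a genetic map needs at least one marker")
  if (anyDuplicated(marker)) abort_validation("marker names must be globally unique")
  if (any(!is.finite(position_cM)) || any(position_cM < 0)) {
    abort_validation("positions must be finite and non-negative")
  }
  chroms <- unique(chromosome)
  ord <- order(match(chromosome, chroms), position_cM)
  df <- data.frame(
    marker = marker[ord], chromosome = chromosome[ord],
    position_cM = position_cM[ord], stringsAsFactors = FALSE
  )
  spans <- vapply(
    split(df$position_cM, factor(df$chromosome, levels = chroms)),
    function(p) max(p) - min(p), numeric(1)
  )
  structure(df,
    chromosomes = chroms,
    length_cM = sum(spans),
    class = c("genetic_map", "data.frame")
  )
}

#' @export
print.genetic_map <- function(x, ...) {
  chroms <- attr(x, "chromosomes")
  cat(sprintf(
    "Genetic map: %d markers on %d chromosome(s), %.1f cM total\n",
    nrow(x), length(chroms), attr(x, "length_cM")
  ))
  per <- table(factor(x$chromosome, levels = chroms))
  cat("  markers per chromosome: ",
      paste(sprintf("%s:%d", names(per), as.integer(per)), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.genetic_map <- function(object, ...) {
  chroms <- attr(object, "chromosomes")
  spans <- vapply(chroms, function(ch) {
    p <- object$position_cM[object$chromosome == ch]
    max(p) - min(p)
  }, numeric(1))
  data.frame(
    chromosome = chroms,
    n_markers = as.integer(table(factor(object$chromosome, levels = chroms))),
    span_cM = spans,
    row.names = NULL
  )
}

#' Total map length in cM
#' @param map a `genetic_map`.
#' @return numeric, sum of per-chromosome spans.
#' @export
total_map_length <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  attr(map, "length_cM")
}

#' Haldane map function: distance to recombination fraction
#'
#' Converts a map distance under the Haldane (no-interference) model,
#' r = (1 - exp(-2 d)) / 2 with d in Morgans. Distances here are in
#' centimorgans and divided by 100 inside the formula.
#'
#' @param d map distance in cM, non-negative (vectorised).
#' @return recombination fraction(s) in [0, 0.5).
#' @examples
#' haldane_cm_to_r(10) # 0.0906
#' @export
haldane_cm_to_r <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) abort_validation("map distance must be >= 0")
  0.5 * (1 - exp(-2 * d / 100))
}

#' Inverse Haldane map function: recombination fraction to distance
#'
#' @param r recombination fraction(s) in [0, 0.5).
#' @return map distance(s) in cM.
#' @export
haldane_r_to_cm <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5)) {
    abort_validation("recombination fraction must lie in [0, 0.5)")
  }
  -50 * log(1 - 2 * r)
}

#' Average adjacent-marker spacing of a map
#'
#' Total map length divided by the number of adjacent-marker intervals,
#' i.e. (number of markers - number of chromosomes). Reported rounded to one
#' decimal, the convention used for published map summaries.
#'
#' @param map a `genetic_map`.
#' @param digits decimals to round to (default 1).
#' @return average spacing in cM.
#' @export
average_marker_spacing <- function(map, digits = 1) {
  stopifnot(inherits(map, "genetic_map"))
  n_int <- nrow(map) - length(attr(map, "chromosomes"))
  if (n_int <= 0) abort_validation("map has no adjacent-marker intervals")
  round(attr(map, "length_cM") / n_int, digits)
}

#' Flanking markers of a map position
#'
#' Returns the nearest markers bracketing `position_cM` on `chromosome`. At a
#' marker position the marker is returned as both flanks with zero distances.
#'
#' @param map a `genetic_map`.
#' @param chromosome chromosome id.
#' @param position_cM position within the chromosome span.
#' @return list with `left`, `right` (marker names), `d_left`, `d_right`
#'   (distances in cM) and the marker row indices `i_left`, `i_right`.
#' @export
flanking_markers <- function(map, chromosome, position_cM) {
  stopifnot(inherits(map, "genetic_map"))
  idx <- which(map$chromosome == chromosome)
  if (length(idx) == 0L) abort_validation(sprintf("unknown chromosome '%s'", chromosome))
  pos <- map$position_cM[idx]
  if (position_cM < min(pos) || position_cM > max(pos)) {
    abort_validation(sprintf(
      "position %.3f cM outside span [%.3f, %.3f] of %s",
      position_cM, min(pos), max(pos), chromosome
    ))
  }
  at <- which(abs(pos - position_cM) < 1e-9)
  if (length(at) > 0L) {
    i <- idx[at[1L]]
    return(list(
      left = map$marker[i], right = map$marker[i],
      d_left = 0, d_right = 0, i_left = i, i_right = i
    ))
  }
  iL <- max(which(pos < position_cM))
  iR <- min(which(pos > position_cM))
  list(
    left = map$marker[idx[iL]], right = map$marker[idx[iR]],
    d_left = position_cM - pos[iL], d_right = pos[iR] - position_cM,
    i_left = idx[iL], i_right = idx[iR]
  )
}

#' Nearest marker to a map position
#' @param map a `genetic_map`.
#' @param chromosome chromosome id.
#' @param position_cM position in cM.
#' @return row index (into `map`) of the closest marker on that chromosome.
#' @export
nearest_marker <- function(map, chromosome, position_cM) {
  idx <- which(map$chromosome == chromosome)
  if (length(idx) == 0L) abort_validation(sprintf("unknown chromosome '%s'", chromosome))
  idx[which.min(abs(map$position_cM[idx] - position_cM))]
}

#' Default synthetic linkage map
#'
#' A nine-chromosome map with 176 markers and a total length of 891.2 cM,
#' matching the published summary of the cauliflower DH mapping population
#' (average spacing 5.3 cM). Chromosome lengths are proportional to a fixed
#' vector; markers are placed at jittered ~5.3 cM spacing, deterministically
#' from `seed`.
#'
#' @param seed integer seed for the spacing jitter (default 1; the default map
#'   is therefore a fixed object).
#' @return a `genetic_map` with 176 markers named S001...S176 on O1--O9.
#' @export
default_map <- function(seed = 1L) {
  total_len <- 891.2
  n_markers <- 176L
  n_chrom <- 9L
  # relative chromosome lengths, loosely unequal as in real Brassica maps
  rel <- c(1.30, 0.85, 1.00, 1.25, 0.90, 1.00, 1.05, 0.80, 1.10)
  lens <- rel / sum(rel) * total_len
  # markers per chromosome proportional to length, adjusted to sum to 176
  n_per <- pmax(2L, round(lens / total_len * n_markers))
  while (sum(n_per) != n_markers) {
    i <- if (sum(n_per) > n_markers) which.max(n_per) else which.min(n_per)
    n_per[i] <- n_per[i] + sign(n_markers - sum(n_per))
  }
  rng <- local({
    set.seed(seed)
    lapply(seq_len(n_chrom), function(i) stats::runif(n_per[i] - 1L, 0.5, 1.5))
  })
  marker <- character(0); chromosome <- character(0); position <- numeric(0)
  k <- 0L
  for (i in seq_len(n_chrom)) {
    gaps <- rng[[i]]
    pos <- c(0, cumsum(gaps))
    pos <- pos / max(pos) * lens[i] # rescale so the chromosome span is exact
    nm <- sprintf("S%03d", k + seq_len(n_per[i]))
    k <- k + n_per[i]
    marker <- c(marker, nm)
    chromosome <- c(chromosome, rep(sprintf("O%d", i), n_per[i]))
    position <- c(position, round(pos, 2))
  }
  genetic_map(marker, chromosome, position)
}

#' Read a genetic map from a tab-separated file
#'
#' Expected columns (header required): `marker`, `chromosome`, `position_cM`.
#'
#' @param path file path.
#' @return a `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "chromosome", "position_cM")
  if (!all(need %in% names(df))) {
    abort_validation(sprintf("map file must have columns: %s", paste(need, collapse = ", ")))
  }
  genetic_map(df$marker, df$chromosome, df$position_cM)
}

#' Write a genetic map to a tab-separated file
#' @param map a `genetic_map`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  utils::write.table(as.data.frame(map), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
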