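#' Doubled-haploid population container
#'
#' Bundles a lines x markers genotype matrix with the `genetic_map` its
#' columns refer to. DH lines are fully homozygous, so genotypes are coded
#' +1 (parent-1 allele) / -1 (parent-2 allele); test hybrids produced by
#' [make_test_hybrids()] may additionally carry 0 (heterozygous).
#'
#' @param genotypes numeric matrix, rows = lines, columns = markers in map
#'   order; entries in \{-1, 0, +1\}.
#' @param map the `genetic_map` describing the columns.
#' @param line_ids optional character vector of row ids.
#' @return an object of class `dh_population` with elements `genotypes`
#'   (matrix with dimnames) and `map`.
#' @export
dh_population <- function(genotypes, map, line_ids = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != nrow(map)) {
    abort_validation("genotype matrix columns must match map markers")
  }
  if (nrow(genotypes) > 0 && !all(genotypes %in% c(-1, 0, 1))) {
    abort_validation("genotypes must be coded -1, 0 or +1")
  }
  if (is.null(line_ids)) {
    line_ids <- if (!is.null(rownames(genotypes))) rownames(genotypes)
                else sprintf("L%03d", seq_len(nrow(genotypes)))
  }
  dimnames(genotypes) <- list(line_ids, map$marker)
  structure(list(genotypes = genotypes, map = map), class = "dh_population")
}

#' @export
print.dh_population <- function(x, ...) {
  cat(sprintf(
    "DH population: %d line(s) x %d markers (%d chromosomes, %.1f cM)\n",
    nrow(x$genotypes), ncol(x$genotypes),
    length(attr(x$map, "chromosomes")), attr(x$map, "length_cM")
  ))
  invisible(x)
}

#' Number of lines in a population
#' @param pop a `dh_population`.
#' @return integer.
#' @export
n_lines <- function(pop) nrow(pop$genotypes)

#' Simulate doubled-haploid genomes from a biparental cross
#'
#' Each DH line is a single F1 gamete with its genome doubled: per
#' chromosome, the crossover count is Poisson(length in Morgans), breakpoints
#' are uniform along the chromosome and the starting parental phase is
#' Bernoulli(0.5). This no-interference meiosis reproduces Haldane map
#' distances: the recombination frequency between adjacent markers converges
#' to [haldane_cm_to_r()] of their spacing, and every marker has expected
#' allele frequency 0.5.
#'
#' @param map a `genetic_map`.
#' @param n_lines number of DH lines to simulate (>= 0).
#' @param seed integer seed.
#' @param line_prefix prefix for generated line ids.
#' @return a `dh_population`.
#' @export
simulate_dh_genomes <- function(map, n_lines, seed = 1L, line_prefix = "L") {
  stopifnot(inherits(map, "genetic_map"))
  if (n_lines < 0) abort_validation("n_lines must be >= 0")
  chroms <- attr(map, "chromosomes")
  set.seed(seed)
  G <- matrix(NA_real_, nrow = n_lines, ncol = nrow(map))
  for (ch in chroms) {
    idx <- which(map$chromosome == ch)
    pos <- map$position_cM[idx]
    span <- max(pos) - min(pos)
    for (i in seq_len(n_lines)) {
      nco <- stats::rpois(1L, span / 100)
      phase <- if (stats::runif(1L) < 0.5) 1 else -1
      if (nco == 0L || span == 0) {
        G[i, idx] <- phase
      } else {
        bp <- sort(stats::runif(nco, min(pos), max(pos)))
        nflip <- findInterval(pos, bp)
        G[i, idx] <- phase * (-1)^nflip
      }
    }
  }
  dh_population(G, map, sprintf("%s%04d", line_prefix, seq_len(max(n_lines, 0L))))
}

#' Cross DH lines to a fixed tester
#'
#' Produces F1 test hybrids of every line in `pop` with a tester genotype.
#' Hybrid genotype codes are the parental column means (so -1/0/+1), and the
#' hybrid's true phenology parameters are mid-parent values -- the additive
#' model that dominates genetic variance in this material -- plus optional
#' specific-combining-ability noise.
#'
#' @param pop a `dh_population` of DH lines.
#' @param true_params data.frame of the lines' true parameters
#'   (columns `LAR`, `S`, `T0`), rows aligned with `pop`.
#' @param tester_genotype numeric vector (+1/-1) on the same map.
#' @param tester_params one-row data.frame (or named list) with the tester's
#'   `LAR`, `S`, `T0`.
#' @param sca_sd standard deviations of specific-combining noise added to the
#'   mid-parent values; either a single number applied to all three
#'   parameters or a named vector. Default 0 (purely additive).
#' @param seed integer seed (used only if `sca_sd > 0`).
#' @return list with `pop` (a `dh_population` of hybrids, ids suffixed "xT")
#'   and `true_params` (data.frame of hybrid parameters).
#' @export
make_test_hybrids <- function(pop, true_params, tester_genotype, tester_params,
                              sca_sd = 0, seed = 1L) {
  stopifnot(inherits(pop, "dh_population"))
  if (length(tester_genotype) != ncol(pop$genotypes)) {
    abort_validation("tester genotype length must match the population's markers")
  }
  if (nrow(true_params) != n_lines(pop)) {
    abort_validation("true_params rows must match the population's lines")
  }
  Gh <- sweep(pop$genotypes, 2, as.numeric(tester_genotype), FUN = "+") / 2
  ids <- paste0(rownames(pop$genotypes), "xT")
  traits <- c("LAR", "S", "T0")
  sca <- if (length(sca_sd) == 1L) stats::setNames(rep(sca_sd, 3), traits) else sca_sd[traits]
  hp <- as.data.frame(lapply(traits, function(tr) {
    (true_params[[tr]] + as.numeric(tester_params[[tr]])) / 2
  }))
  names(hp) <- traits
  if (any(sca > 0)) {
    set.seed(seed)
    for (tr in traits) hp[[tr]] <- hp[[tr]] + stats::rnorm(nrow(hp), 0, sca[tr])
  }
  rownames(hp) <- ids
  list(pop = dh_population(Gh, pop$map, ids), true_params = hp)
}

#' Write genotypes to CSV
#'
#' Format: first column `line`, remaining columns one per marker, values
#' -1/+1 (0 allowed for hybrids).
#' @param pop a `dh_population`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(pop, path) {
  df <- data.frame(line = rownames(pop$genotypes), pop$genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotypes from CSV into a population
#' @param path CSV written by [write_genotypes()].
#' @param map the `genetic_map` the columns refer to.
#' @return a `dh_population`.
#' @export
read_genotypes <- function(path, map) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "line") abort_validation("genotype CSV must start with a 'line' column")
  G <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(G) <- "double"
  if (!identical(colnames(G), map$marker)) {
    miss <- setdiff(map$marker, colnames(G))
    if (length(miss)) abort_validation("genotype CSV is missing map markers")
    G <- G[, map$marker, drop = FALSE]
  }
  dh_population(G, map, df$line)
}
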