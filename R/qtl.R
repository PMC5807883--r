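#' Expected genotype at an arbitrary map position
#'
#' Haley-Knott style imputation for DH lines: given the flanking marker
#' genotypes (gL, gR) and Haldane recombination fractions r1 (left flank to
#' position), r2 (position to right flank) and r12 (flank to flank), the
#' conditional probability of the parent-1 allele follows from the four
#' no-interference gamete classes, e.g.
#' `P(+1 | +1, +1) = (1 - r1)(1 - r2) / (1 - r12)`, and the expected code is
#' `2 P(+1) - 1`. At a marker the marker's own genotype is returned.
#'
#' @param pop a `dh_population` (genotypes strictly -1/+1).
#' @param chromosome chromosome id.
#' @param position_cM position on that chromosome.
#' @return numeric vector (one value per line) in [-1, +1].
#' @export
impute_interval_genotype <- function(pop, chromosome, position_cM) {
  stopifnot(inherits(pop, "dh_population"))
  fl <- flanking_markers(pop$map, chromosome, position_cM)
  gL <- pop$genotypes[, fl$i_left]
  if (fl$i_left == fl$i_right) return(as.numeric(gL))
  gR <- pop$genotypes[, fl$i_right]
  r1 <- haldane_cm_to_r(fl$d_left)
  r2 <- haldane_cm_to_r(fl$d_right)
  r12 <- r1 + r2 - 2 * r1 * r2
  # P(g = +1 | gL, gR) for the four flank configurations
  p <- numeric(length(gL))
  both_p <- gL == 1 & gR == 1
  both_m <- gL == -1 & gR == -1
  pm <- gL == 1 & gR == -1
  mp <- gL == -1 & gR == 1
  p[both_p] <- (1 - r1) * (1 - r2) / (1 - r12)
  p[both_m] <- r1 * r2 / (1 - r12)
  p[pm] <- (1 - r1) * r2 / r12
  p[mp] <- r1 * (1 - r2) / r12
  2 * p - 1
}

#' Forward stepwise cofactor selection for composite interval mapping
#'
#' Selects background markers by forward stepwise regression minimising BIC,
#' capped at `n / 5` markers. Candidates are orthogonalised against the
#' current model at each step, so each addition is O(n p).
#'
#' @param pop a `dh_population`.
#' @param phenotype numeric per-line values (complete; length = lines).
#' @param max_cofactors cap on the number selected (default `floor(n / 5)`).
#' @return character vector of selected marker names (possibly empty).
#' @export
select_cofactors <- function(pop, phenotype, max_cofactors = NULL) {
  stopifnot(inherits(pop, "dh_population"))
  n <- n_lines(pop)
  if (n < 30L) abort_validation("cofactor selection needs at least 30 lines")
  if (length(phenotype) != n || any(!is.finite(phenotype))) {
    abort_validation("phenotype must be complete and match the population")
  }
  if (is.null(max_cofactors)) max_cofactors <- floor(n / 5)
  M <- scale(pop$genotypes, center = TRUE, scale = FALSE)
  yr <- phenotype - mean(phenotype)
  rss <- sum(yr^2)
  if (rss <= 0) return(character(0))
  bic <- n * log(rss / n) + 2 * log(n) # intercept + sigma
  selected <- integer(0)
  candidates <- seq_len(ncol(M))
  while (length(selected) < max_cofactors && length(candidates) > 0L) {
    xx <- colSums(M[, candidates, drop = FALSE]^2)
    xy <- as.numeric(crossprod(M[, candidates, drop = FALSE], yr))
    gain <- ifelse(xx > 1e-8 * n, xy^2 / xx, 0)
    best <- which.max(gain)
    new_rss <- rss - gain[best]
    k <- length(selected) + 1L
    new_bic <- n * log(max(new_rss, 1e-300) / n) + (k + 2) * log(n)
    if (new_bic >= bic) break
    j <- candidates[best]
    x <- M[, j]
    # orthogonalise remaining candidates and the response against x
    candidates <- candidates[-best]
    if (length(candidates) > 0L) {
      proj <- as.numeric(crossprod(M[, candidates, drop = FALSE], x)) / sum(x^2)
      M[, candidates] <- M[, candidates, drop = FALSE] -
        outer(x, proj)
    }
    yr <- yr - x * sum(x * yr) / sum(x^2)
    rss <- new_rss
    bic <- new_bic
    selected <- c(selected, j)
  }
  colnames(pop$genotypes)[selected]
}

# grid of scan positions for one chromosome (step cM, endpoints included)
scan_grid <- function(pos, step) {
  g <- seq(min(pos), max(pos), by = step)
  if (max(g) < max(pos) - 1e-9) g <- c(g, max(pos))
  g
}

#' Composite interval mapping scan
#'
#' At every grid position the phenotype is regressed on the expected
#' interval genotype plus the cofactor markers, with cofactors lying within
#' `window` cM of the tested position (same chromosome) excluded. The LOD
#' score is `(n / 2) * log10(RSS_reduced / RSS_full)`, the reduced model
#' omitting the interval term; the reported additive effect is the fitted
#' interval-genotype coefficient (half the contrast between the +1 and -1
#' codes).
#'
#' @param pop a `dh_population`.
#' @param phenotype numeric per-line values.
#' @param cofactors character vector of cofactor marker names (possibly
#'   empty), e.g. from [select_cofactors()].
#' @param step scan step in cM (default 2).
#' @param window cofactor exclusion window in cM (default 10).
#' @return object of class `cim_scan`: data.frame with `chromosome`,
#'   `position_cM`, `lod`, `effect`, plus attributes `cofactors`, `n`,
#'   `step`, `window`.
#' @export
cim_scan <- function(pop, phenotype, cofactors = character(0), step = 2,
                     window = 10) {
  stopifnot(inherits(pop, "dh_population"))
  if (step <= 0) abort_validation("step must be > 0")
  n <- n_lines(pop)
  if (length(phenotype) != n || any(!is.finite(phenotype))) {
    abort_validation("phenotype must be complete and match the population")
  }
  map <- pop$map
  cof_idx <- match(cofactors, map$marker)
  if (any(is.na(cof_idx))) abort_validation("unknown cofactor marker")
  out <- list()
  for (ch in attr(map, "chromosomes")) {
    idx <- which(map$chromosome == ch)
    grid <- scan_grid(map$position_cM[idx], step)
    lod <- numeric(length(grid))
    eff <- numeric(length(grid))
    for (gi in seq_along(grid)) {
      g <- impute_interval_genotype(pop, ch, grid[gi])
      keep_cof <- cof_idx[!(map$chromosome[cof_idx] == ch &
                              abs(map$position_cM[cof_idx] - grid[gi]) <= window)]
      Xc <- cbind(1, pop$genotypes[, keep_cof, drop = FALSE])
      fit_red <- stats::lm.fit(Xc, phenotype)
      rss_red <- sum(fit_red$residuals^2)
      fit_full <- stats::lm.fit(cbind(Xc, g = g), phenotype)
      rss_full <- sum(fit_full$residuals^2)
      co <- fit_full$coefficients["g"]
      if (!is.finite(co) || rss_full <= 0) { # collinear interval term
        lod[gi] <- 0; eff[gi] <- 0
      } else {
        lod[gi] <- max(0, (n / 2) * log10(rss_red / rss_full))
        eff[gi] <- co
      }
    }
    out[[ch]] <- data.frame(
      chromosome = ch, position_cM = grid, lod = lod, effect = eff,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, cofactors = cofactors, n = n, step = step, window = window,
            class = c("cim_scan", "data.frame"))
}

#' @export
print.cim_scan <- function(x, ...) {
  cat(sprintf(
    "CIM scan: %d positions on %d chromosome(s), %d cofactor(s), max LOD %.2f\n",
    nrow(x), length(unique(x$chromosome)), length(attr(x, "cofactors")),
    max(x$lod)
  ))
  invisible(x)
}

#' @export
plot.cim_scan <- function(x, threshold = 2.5, ...) {
  chroms <- unique(x$chromosome)
  offs <- 0
  xs <- numeric(nrow(x))
  mids <- numeric(length(chroms))
  for (i in seq_along(chroms)) {
    sel <- x$chromosome == chroms[i]
    xs[sel] <- x$position_cM[sel] + offs
    mids[i] <- offs + mean(range(x$position_cM[sel]))
    offs <- max(xs[sel]) + 10
  }
  plot(xs, x$lod, type = "n", xlab = "", ylab = "LOD", xaxt = "n", ...)
  for (ch in chroms) {
    sel <- x$chromosome == ch
    graphics::lines(xs[sel], x$lod[sel])
  }
  graphics::axis(1, at = mids, labels = chroms)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Declare QTL from a CIM scan
#'
#' Local scan maxima with LOD at or above `threshold` are declared QTL.
#' Peaks on the same chromosome must be separated by at least `min_sep` cM
#' or by a valley dropping at least 1 LOD below the smaller peak. The
#' support interval is the 1-LOD drop on each side of the peak. Additive
#' effects `e_i` and the trait mean `m` are re-estimated by one joint
#' multiple regression of the phenotype on the nearest-marker genotypes of
#' all declared loci; each locus also gets a joint-model partial R^2.
#'
#' @param scan a `cim_scan`.
#' @param pop the scanned `dh_population`.
#' @param phenotype the scanned phenotype.
#' @param threshold LOD declaration threshold (default 2.5).
#' @param min_sep minimum peak separation in cM (default 20).
#' @param trait optional trait name stored in the model.
#' @return an object of class `qtl_model`: list with `trait`, `m`, and
#'   `loci` (data.frame `chromosome`, `position_cM`, `marker`, `effect`,
#'   `lod`, `ci_lo`, `ci_hi`, `r_squared`). An empty model (no locus above
#'   threshold) has `m` = the phenotype mean.
#' @export
declare_qtl <- function(scan, pop, phenotype, threshold = 2.5, min_sep = 20,
                        trait = NA_character_) {
  stopifnot(inherits(scan, "cim_scan"))
  peaks <- list()
  for (ch in unique(scan$chromosome)) {
    d <- scan[scan$chromosome == ch, ]
    d <- d[order(d$position_cM), ]
    cand <- which(d$lod >= threshold &
                    d$lod >= c(-Inf, d$lod[-nrow(d)]) &
                    d$lod >= c(d$lod[-1], -Inf))
    if (length(cand) == 0L) next
    cand <- cand[order(-d$lod[cand])]
    acc <- integer(0)
    for (i in cand) {
      ok <- TRUE
      for (a in acc) {
        if (abs(d$position_cM[i] - d$position_cM[a]) >= min_sep) next
        lo <- min(i, a); hi <- max(i, a)
        valley <- min(d$lod[lo:hi])
        if (valley > min(d$lod[i], d$lod[a]) - 1) { ok <- FALSE; break }
      }
      if (ok) acc <- c(acc, i)
    }
    for (a in acc) {
      # 1-LOD support interval
      drop <- d$lod[a] - 1
      li <- a; while (li > 1L && d$lod[li - 1L] >= drop) li <- li - 1L
      ri <- a; while (ri < nrow(d) && d$lod[ri + 1L] >= drop) ri <- ri + 1L
      peaks[[length(peaks) + 1L]] <- data.frame(
        chromosome = ch, position_cM = d$position_cM[a], lod = d$lod[a],
        ci_lo = d$position_cM[li], ci_hi = d$position_cM[ri],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(peaks) == 0L) {
    return(structure(
      list(trait = trait, m = mean(phenotype),
           loci = data.frame(
             chromosome = character(0), position_cM = numeric(0),
             marker = character(0), effect = numeric(0), lod = numeric(0),
             ci_lo = numeric(0), ci_hi = numeric(0), r_squared = numeric(0)
           )),
      class = "qtl_model"
    ))
  }
  loci <- do.call(rbind, peaks)
  loci <- loci[order(match(loci$chromosome, attr(pop$map, "chromosomes")),
                     loci$position_cM), , drop = FALSE]
  mk <- vapply(seq_len(nrow(loci)), function(i) {
    nearest_marker(pop$map, loci$chromosome[i], loci$position_cM[i])
  }, integer(1))
  loci$marker <- pop$map$marker[mk]
  G <- pop$genotypes[, mk, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, G)
  fit <- stats::lm.fit(X, phenotype)
  rss_full <- sum(fit$residuals^2)
  sst <- sum((phenotype - mean(phenotype))^2)
  loci$effect <- as.numeric(fit$coefficients[-1L])
  loci$r_squared <- vapply(seq_len(nrow(loci)), function(i) {
    rss_i <- sum(stats::lm.fit(X[, -(i + 1L), drop = FALSE], phenotype)$residuals^2)
    (rss_i - rss_full) / sst
  }, numeric(1))
  structure(
    list(trait = trait, m = as.numeric(fit$coefficients[1L]),
         loci = loci[, c("chromosome", "position_cM", "marker", "effect",
                         "lod", "ci_lo", "ci_hi", "r_squared")]),
    class = "qtl_model"
  )
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("QTL model%s: m = %.4g, %d locus/loci\n",
              if (is.na(x$trait)) "" else paste0(" for ", x$trait),
              x$m, nrow(x$loci)))
  if (nrow(x$loci)) {
    print(format(x$loci, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.qtl_model <- function(object, ...) {
  stats::setNames(c(object$m, object$loci$effect),
                  c("(Intercept)", object$loci$marker))
}

#' Predict per-line parameter values from a QTL model
#'
#' `y_j = m + sum_i e_i g_ij` over the declared loci, each read from its
#' nearest marker. Hybrid genotypes of 0 contribute nothing (mid-parent).
#'
#' @param object a `qtl_model`.
#' @param pop a `dh_population` (or genotype matrix with the model's marker
#'   columns).
#' @param ... unused.
#' @return named numeric vector of predictions; an empty model returns `m`
#'   for every line.
#' @export
predict.qtl_model <- function(object, pop, ...) {
  G <- if (inherits(pop, "dh_population")) pop$genotypes else as.matrix(pop)
  if (nrow(object$loci) == 0L) {
    return(stats::setNames(rep(object$m, nrow(G)), rownames(G)))
  }
  if (!all(object$loci$marker %in% colnames(G))) {
    abort_validation("genotypes are missing markers required by the QTL model")
  }
  stats::setNames(
    as.numeric(object$m + G[, object$loci$marker, drop = FALSE] %*% object$loci$effect),
    rownames(G)
  )
}

#' Pairwise QTL x QTL interaction scan
#'
#' For every pair of declared loci, fits phenotype on both main effects plus
#' their product and reports the interaction estimate with its (unadjusted)
#' p-value; Bonferroni correction over the pairs is optional.
#'
#' @param model a `qtl_model` with at least 2 loci.
#' @param pop the `dh_population`.
#' @param phenotype per-line values.
#' @param alpha significance level (default 0.05).
#' @param bonferroni adjust p-values for the number of pairs (default FALSE,
#'   matching single-pair reporting conventions).
#' @return data.frame with one row per pair: markers, interaction `effect`,
#'   `p_value` and `significant`.
#' @export
epistasis_scan <- function(model, pop, phenotype, alpha = 0.05,
                           bonferroni = FALSE) {
  stopifnot(inherits(model, "qtl_model"))
  if (nrow(model$loci) < 2L) abort_validation("epistasis scan needs >= 2 declared QTL")
  mk <- model$loci$marker
  G <- pop$genotypes[, mk, drop = FALSE]
  pairs <- utils::combn(length(mk), 2)
  out <- data.frame(
    marker1 = mk[pairs[1, ]], marker2 = mk[pairs[2, ]],
    effect = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE
  )
  for (p in seq_len(ncol(pairs))) {
    g1 <- G[, pairs[1, p]]; g2 <- G[, pairs[2, p]]
    fit <- stats::lm(phenotype ~ g1 + g2 + I(g1 * g2))
    sm <- stats::coef(summary(fit))
    if ("I(g1 * g2)" %in% rownames(sm)) {
      out$effect[p] <- sm["I(g1 * g2)", "Estimate"]
      out$p_value[p] <- sm["I(g1 * g2)", "Pr(>|t|)"]
    }
  }
  padj <- if (bonferroni) stats::p.adjust(out$p_value, "bonferroni") else out$p_value
  out$significant <- !is.na(padj) & padj < alpha
  out
}

#' Write a CIM scan to CSV (`trait,chromosome,position_cM,LOD,effect`)
#' @param scan a `cim_scan`.
#' @param path destination path.
#' @param trait trait label for the first column.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, trait = "") {
  utils::write.csv(
    data.frame(trait = trait, chromosome = scan$chromosome,
               position_cM = scan$position_cM, LOD = scan$lod,
               effect = scan$effect),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write a QTL model to JSON
#' @param model a `qtl_model`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_qtl_model <- function(model, path) {
  jsonlite::write_json(
    list(trait = model$trait, m = model$m,
         loci = lapply(seq_len(nrow(model$loci)), function(i) {
           as.list(model$loci[i, c("chromosome", "position_cM", "marker",
                                   "effect", "lod", "ci_lo", "ci_hi",
                                   "r_squared")])
         })),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
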