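#' Ridge-regression BLUP of genome-wide marker effects
#'
#' Fits the mixed model `y = X beta + Z v + e` with `X` a column of ones,
#' `Z` the lines x markers genotype matrix (-1/+1 coding), i.i.d. normal
#' marker effects `v ~ N(0, sigma2_v I)` and residuals
#' `e ~ N(0, sigma2_e I)`. The variance components are estimated by REML: the
#' restricted log-likelihood is profiled down to the single shrinkage ratio
#' `lambda = sigma2_e / sigma2_v` using the spectral decomposition of
#' `Z Z'`, and maximised by bounded scalar search on log(lambda). Marker
#' effects are then the BLUP
#' `v = Z' (Z Z' + lambda I)^{-1} (y - X beta_hat)` with `beta_hat` the GLS
#' intercept.
#'
#' @param genotypes lines x markers numeric matrix, no missing values.
#' @param phenotype per-line parameter values (length = lines, complete).
#' @param trait optional trait name stored in the model.
#' @param interval search interval for log(lambda) (natural log).
#' @param tol optimisation tolerance on log(lambda).
#' @return an object of class `rrblup`: list with `trait`, `beta`
#'   (intercept), `effects` (named marker-effect vector), `sigma2_v`,
#'   `sigma2_e`, `lambda`, `loglik` (restricted, up to a constant).
#' @export
rrblup <- function(genotypes, phenotype, trait = NA_character_,
                   interval = c(-20, 20), tol = 1e-6) {
  Z <- as.matrix(genotypes)
  y <- as.numeric(phenotype)
  n <- nrow(Z)
  if (n < 20L) abort_validation("rrBLUP needs at least 20 lines")
  if (length(y) != n || any(!is.finite(y))) {
    abort_validation("phenotype must be complete and match the genotypes")
  }
  if (anyNA(Z)) abort_validation("genotypes must be complete (impute first)")
  if (stats::var(y) <= 0) abort_validation("phenotype has zero variance")
  K <- tcrossprod(Z)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- as.numeric(crossprod(U, y))
  xs <- as.numeric(crossprod(U, rep(1, n)))
  p <- 1L
  restricted_ll <- function(s) {
    lambda <- exp(s)
    w <- 1 / (d + lambda)
    xwx <- sum(xs^2 * w)
    beta <- sum(xs * ys * w) / xwx
    r <- ys - xs * beta
    q <- sum(r^2 * w)
    -0.5 * ((n - p) * log(q) + sum(log(d + lambda)) + log(xwx))
  }
  opt <- stats::optimize(restricted_ll, interval = interval, maximum = TRUE,
                         tol = tol)
  if (!is.finite(opt$objective)) abort_validation("REML likelihood is not finite")
  lambda <- exp(opt$maximum)
  w <- 1 / (d + lambda)
  xwx <- sum(xs^2 * w)
  beta <- sum(xs * ys * w) / xwx
  r <- ys - xs * beta
  sigma2_v <- sum(r^2 * w) / (n - p)
  sigma2_e <- lambda * sigma2_v
  # v = Z' U diag(w) U' (y - beta)
  v <- as.numeric(crossprod(Z, U %*% (w * r)))
  structure(
    list(trait = trait, beta = beta,
         effects = stats::setNames(v, colnames(Z)),
         sigma2_v = sigma2_v, sigma2_e = sigma2_e, lambda = lambda,
         loglik = opt$objective),
    class = "rrblup"
  )
}

#' @export
print.rrblup <- function(x, ...) {
  cat(sprintf(
    "rrBLUP model%s: %d marker effects, beta = %.4g\n",
    if (is.na(x$trait)) "" else paste0(" for ", x$trait),
    length(x$effects), x$beta
  ))
  cat(sprintf("  sigma2_v = %.4g, sigma2_e = %.4g, lambda = %.4g\n",
              x$sigma2_v, x$sigma2_e, x$lambda))
  invisible(x)
}

#' @export
coef.rrblup <- function(object, ...) {
  c("(Intercept)" = object$beta, object$effects)
}

#' @export
predict.rrblup <- function(object, genotypes, ...) {
  gebv(object, genotypes)
}

#' Genomic estimated breeding values
#'
#' `GEBV_j = beta + sum_m v_m g_jm`: the intercept plus the sum of estimated
#' marker effects over the line's genotype. Hybrid codes of 0 contribute
#' nothing at that marker (mid-parent).
#'
#' @param model an `rrblup` model.
#' @param genotypes a `dh_population` or lines x markers matrix whose
#'   columns match the model's markers.
#' @return named numeric vector of predictions.
#' @export
gebv <- function(model, genotypes) {
  stopifnot(inherits(model, "rrblup"))
  G <- if (inherits(genotypes, "dh_population")) genotypes$genotypes
       else as.matrix(genotypes)
  if (ncol(G) != length(model$effects) ||
      (!is.null(colnames(G)) &&
       !identical(colnames(G), names(model$effects)))) {
    abort_validation("genotype columns do not match the model's markers")
  }
  stats::setNames(as.numeric(model$beta + G %*% model$effects), rownames(G))
}

#' Write marker effects to CSV (`trait,marker,effect`)
#' @param model an `rrblup` model.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_marker_effects <- function(model, path) {
  utils::write.csv(
    data.frame(trait = model$trait, marker = names(model$effects),
               effect = as.numeric(model$effects)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write an rrBLUP model to JSON
#' @param model an `rrblup` model.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_gs_model <- function(model, path) {
  jsonlite::write_json(
    list(trait = model$trait, beta = model$beta,
         sigma2_v = model$sigma2_v, sigma2_e = model$sigma2_e,
         lambda = model$lambda,
         effects = as.list(stats::setNames(as.numeric(model$effects),
                                           names(model$effects)))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
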