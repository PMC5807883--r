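#' Fit per-line phenology parameters from greenhouse trials
#'
#' The model-parameterization step. For every line:
#' \enumerate{
#'   \item LAR is estimated within each treatment as the OLS slope of leaf
#'     count on cumulative degree-days, then pooled across treatments as a
#'     mean weighted by each treatment's degree-day span;
#'   \item the juvenile sum TSf = 7 / LAR converts each uncensored
#'     treatment's induction day into adult-phase thermal time
#'     `T * day - TSf`;
#'   \item S (slope) and T0 (intercept) come from the OLS regression of
#'     adult-phase thermal time on treatment temperature, with the fit R^2
#'     retained as a per-line quality measure.
#' }
#' Censored treatments are dropped from step 3. Lines with fewer than
#' `min_treatments` distinct uncensored treatments, or with an invalid LAR,
#' are excluded and listed in the result: a two-point temperature response
#' has no residual degrees of freedom (R^2 is identically 1) and its slope
#' is unusable, so at least three treatments are required by default.
#'
#' @param trials list of `greenhouse_trial` objects (distinct temperatures).
#' @param min_treatments minimum number of distinct uncensored treatments a
#'   line needs to be fitted (default 3).
#' @return an object of class `pheno_fit`: list with `params` (data.frame
#'   `line`, `LAR`, `S`, `T0`, `r_squared`, `n_treatments`), `excluded`
#'   (character), `temperatures`, and `observed` (wide matrix of observed
#'   induction days, lines x treatments, NA = censored).
#' @export
fit_phenology <- function(trials, min_treatments = 3L) {
  if (length(trials) < 2L) abort_validation("need at least 2 greenhouse trials")
  temps <- vapply(trials, function(tr) tr$temperature, numeric(1))
  ids <- trials[[1L]]$induction$line
  obs <- matrix(NA_real_, length(ids), length(trials),
                dimnames = list(ids, sprintf("T%.2f", temps)))
  lar_slopes <- matrix(NA_real_, length(ids), length(trials))
  lar_weights <- matrix(NA_real_, length(ids), length(trials))
  for (t in seq_along(trials)) {
    tr <- trials[[t]]
    ind <- tr$induction[match(ids, tr$induction$line), ]
    obs[, t] <- ifelse(ind$censored, NA_real_, ind$induction_day)
    lo <- split(tr$leaf_obs, tr$leaf_obs$line)
    for (j in seq_along(ids)) {
      d <- lo[[ids[j]]]
      if (is.null(d) || nrow(d) < 3L) next
      dd <- d$day * tr$temperature
      sl <- try(estimate_lar(dd, d$leaf_count), silent = TRUE)
      if (!inherits(sl, "try-error")) {
        lar_slopes[j, t] <- sl
        lar_weights[j, t] <- max(dd) - min(dd)
      }
    }
  }
  params <- data.frame(
    line = ids, LAR = NA_real_, S = NA_real_, T0 = NA_real_,
    r_squared = NA_real_, n_treatments = NA_integer_,
    stringsAsFactors = FALSE
  )
  excluded <- character(0)
  for (j in seq_along(ids)) {
    w <- lar_weights[j, ]
    ok <- is.finite(lar_slopes[j, ]) & is.finite(w)
    if (!any(ok)) { excluded <- c(excluded, ids[j]); next }
    lar <- sum(lar_slopes[j, ok] * w[ok]) / sum(w[ok])
    use <- is.finite(obs[j, ])
    if (length(unique(temps[use])) < min_treatments) {
      excluded <- c(excluded, ids[j]); next
    }
    fit <- fit_temperature_response(temps[use], obs[j, use], lar)
    params$LAR[j] <- lar
    params$S[j] <- fit$S
    params$T0[j] <- fit$T0
    params$r_squared[j] <- fit$r_squared
    params$n_treatments[j] <- fit$n
  }
  keep <- !(params$line %in% excluded)
  structure(
    list(
      params = params[keep, , drop = FALSE],
      excluded = excluded,
      temperatures = temps,
      observed = obs[keep, , drop = FALSE]
    ),
    class = "pheno_fit"
  )
}

#' @export
print.pheno_fit <- function(x, ...) {
  cat(sprintf(
    "Phenology parameterization: %d line(s) fitted over %d treatments (%s C)%s\n",
    nrow(x$params), length(x$temperatures),
    paste(sprintf("%.1f", sort(x$temperatures)), collapse = ", "),
    if (length(x$excluded)) sprintf("; %d excluded", length(x$excluded)) else ""
  ))
  invisible(x)
}

#' @export
summary.pheno_fit <- function(object, ...) {
  p <- object$params
  out <- data.frame(
    parameter = c("LAR", "S", "T0", "r_squared"),
    mean = c(mean(p$LAR), mean(p$S), mean(p$T0), mean(p$r_squared)),
    sd = c(stats::sd(p$LAR), stats::sd(p$S), stats::sd(p$T0), stats::sd(p$r_squared)),
    min = c(min(p$LAR), min(p$S), min(p$T0), min(p$r_squared)),
    max = c(max(p$LAR), max(p$S), max(p$T0), max(p$r_squared))
  )
  class(out) <- c("summary.pheno_fit", "data.frame")
  out
}

#' @export
coef.pheno_fit <- function(object, ...) {
  m <- as.matrix(object$params[, c("LAR", "S", "T0")])
  rownames(m) <- object$params$line
  m
}

#' Predict induction days from a phenology fit
#'
#' For a constant `temperature`, the closed-form two-phase solution per
#' line; for a daily series, the forward simulation.
#'
#' @param object a `pheno_fit`.
#' @param temperature a single constant temperature (degree C).
#' @param temps alternatively, a daily temperature series.
#' @param ... unused.
#' @return named numeric vector of predicted induction days (NA where the
#'   parameters are invalid at the given temperatures or development is
#'   censored).
#' @export
predict.pheno_fit <- function(object, temperature = NULL, temps = NULL, ...) {
  predict_induction(object$params, temperature = temperature, temps = temps)
}

# shared prediction engine over a parameter table (line, LAR, S, T0)
predict_induction <- function(params, temperature = NULL, temps = NULL) {
  n <- nrow(params)
  out <- stats::setNames(rep(NA_real_, n), params$line)
  for (j in seq_len(n)) {
    pj <- list(LAR = params$LAR[j], S = params$S[j], T0 = params$T0[j])
    if (!is.null(temperature)) {
      v <- try(time_to_induction_constant(pj, temperature)$days, silent = TRUE)
      if (!inherits(v, "try-error")) out[j] <- v
    } else {
      dev <- try(simulate_development(pj, temps), silent = TRUE)
      if (!inherits(dev, "try-error") && !dev$censored) out[j] <- dev$induction_day
    }
  }
  out
}

#' Closed-loop self-prediction of the parameterization trials
#'
#' For every fitted line, predicts the induction day at each of the fit's
#' treatment temperatures from the line's own fitted parameters (closed-form
#' constant-temperature model) and averages both predicted and observed days
#' over the line's uncensored treatments. The squared correlation of the two
#' means measures how much of the between-line variation the fitted
#' three-parameter model retains.
#'
#' @param fit a `pheno_fit`.
#' @return data.frame with `line`, `observed_mean`, `predicted_mean`
#'   (days).
#' @export
self_prediction_means <- function(fit) {
  stopifnot(inherits(fit, "pheno_fit"))
  p <- fit$params
  temps <- fit$temperatures
  pred <- matrix(NA_real_, nrow(p), length(temps))
  for (t in seq_along(temps)) {
    ok <- is.finite(fit$observed[, t])
    pr <- (7 / p$LAR + p$S * temps[t] + p$T0) / temps[t]
    pred[ok, t] <- pr[ok]
  }
  data.frame(
    line = p$line,
    observed_mean = rowMeans(fit$observed, na.rm = TRUE),
    predicted_mean = rowMeans(pred, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Write a fitted parameter table to CSV (`line,LAR,S,T0,R2`)
#' @param fit a `pheno_fit` (or data.frame with the parameter columns).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_params <- function(fit, path) {
  p <- if (inherits(fit, "pheno_fit")) fit$params else fit
  out <- data.frame(line = p$line, LAR = p$LAR, S = p$S, T0 = p$T0,
                    R2 = p$r_squared)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
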