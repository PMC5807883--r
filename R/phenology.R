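#' Phenology parameter set for one genotype
#'
#' The two-phase curd-induction model of a genotype is fully described by
#' three parameters: the leaf appearance rate `LAR` (leaves per degree-day,
#' base temperature 0), the temperature sensitivity `S` (degree-days per
#' degree C) and the extrapolated minimum adult-phase thermal time `T0`
#' (degree-days). Derived quantities are the phyllochron `P = 1/LAR`
#' (degree-days per leaf) and the juvenile temperature sum `TSf = 7 * P`:
#' juvenility ends for every genotype once seven leaves are visible.
#'
#' @param LAR leaf appearance rate, > 0.
#' @param S temperature sensitivity slope.
#' @param T0 minimum adult-phase thermal time intercept.
#' @param r_squared optional fit R^2 carried along from estimation.
#' @return an object of class `pheno_params` (a list with LAR, P, TSf, S,
#'   T0, r_squared).
#' @export
pheno_params <- function(LAR, S, T0, r_squared = NA_real_) {
  if (!is.finite(LAR) || LAR <= 0) abort_validation("LAR must be > 0")
  structure(
    list(LAR = LAR, P = 1 / LAR, TSf = 7 / LAR, S = S, T0 = T0,
         r_squared = r_squared),
    class = "pheno_params"
  )
}

#' @export
print.pheno_params <- function(x, ...) {
  cat(sprintf(
    "Phenology parameters: LAR = %.4g leaves/Cd (TSf = %.1f Cd), S = %.2f Cd/C, T0 = %.1f Cd\n",
    x$LAR, x$TSf, x$S, x$T0
  ))
  if (is.finite(x$r_squared)) cat(sprintf("  temperature-response fit R^2 = %.3f\n", x$r_squared))
  invisible(x)
}

#' Juvenile-phase temperature sum
#'
#' `TSf = 7 * P = 7 / LAR`: thermal time to produce the seven visible leaves
#' that end the (temperature-insensitive) juvenile phase.
#'
#' @param LAR leaf appearance rate in leaves per degree-day, > 0 (vectorised).
#' @return juvenile temperature sum in degree-days.
#' @export
juvenile_ts <- function(LAR) {
  if (any(!is.finite(LAR)) || any(LAR <= 0)) abort_validation("LAR must be > 0")
  7 / LAR
}

#' Estimate leaf appearance rate from leaf-count observations
#'
#' LAR is the ordinary-least-squares slope of leaf number on cumulative
#' growing degree-days (base temperature 0). The regression includes an
#' intercept, since plants already carry two to three leaves at
#' transplanting.
#'
#' @param degree_days cumulative degree-days at each scoring.
#' @param leaf_count observed leaf numbers.
#' @return the slope (LAR). Errors if there are fewer than 3 observations,
#'   the degree-day span is degenerate, or the slope is not positive.
#' @export
estimate_lar <- function(degree_days, leaf_count) {
  if (length(degree_days) != length(leaf_count)) {
    abort_validation("degree_days and leaf_count must have equal length")
  }
  if (length(degree_days) < 3L) abort_validation("need at least 3 leaf-count observations")
  sxx <- sum((degree_days - mean(degree_days))^2)
  if (sxx <= 0) abort_validation("degree-day span is degenerate")
  slope <- sum((degree_days - mean(degree_days)) * (leaf_count - mean(leaf_count))) / sxx
  if (!is.finite(slope) || slope <= 0) {
    abort_validation("estimated LAR is not positive; invalid leaf-count series")
  }
  slope
}

#' Fit the linear temperature response of thermal time to curd induction
#'
#' Across constant-temperature treatments, adult-phase thermal time to
#' visible curd induction (total thermal time minus the juvenile sum TSf)
#' is regressed on treatment temperature. The slope `S` is the temperature
#' sensitivity (S = 0: insensitive; large positive S: strong vernalization
#' response) and the intercept `T0` the extrapolated minimum thermal time.
#' Censored treatments must be excluded by the caller. The reported R^2 is
#' unchanged by the per-line constant TSf shift.
#'
#' @param temperature treatment mean temperatures (degree C), >= 2 distinct.
#' @param induction_day observed day of visible curd induction per treatment.
#' @param LAR the line's leaf appearance rate (used for TSf).
#' @return list with `S`, `T0`, `r_squared` and `n` (treatments used).
#' @export
fit_temperature_response <- function(temperature, induction_day, LAR) {
  keep <- is.finite(temperature) & is.finite(induction_day)
  temperature <- temperature[keep]
  induction_day <- induction_day[keep]
  if (length(unique(temperature)) < 2L) {
    abort_validation("need at least 2 distinct uncensored treatment temperatures")
  }
  tsf <- juvenile_ts(LAR)
  adult_tt <- temperature * induction_day - tsf
  xc <- temperature - mean(temperature)
  yc <- adult_tt - mean(adult_tt)
  S <- sum(xc * yc) / sum(xc^2)
  T0 <- mean(adult_tt) - S * mean(temperature)
  sst <- sum(yc^2)
  r2 <- if (sst > 0) 1 - sum((yc - S * xc)^2) / sst else NA_real_
  list(S = S, T0 = T0, r_squared = r2, n = length(temperature))
}

#' Daily development rate in the adult vegetative phase
#'
#' `k = T / (T * S + T0)` per day: the reciprocal of the number of days a
#' constant temperature T would need to complete the adult phase.
#'
#' @param temperature daily mean air temperature, > 0 (vectorised).
#' @param S temperature sensitivity.
#' @param T0 minimum adult-phase thermal time.
#' @return development rate(s), 1/day.
#' @export
daily_rate <- function(temperature, S, T0) {
  if (any(temperature <= 0)) abort_validation("temperature must be > 0")
  den <- temperature * S + T0
  if (any(den <= 0)) {
    abort_validation("T * S + T0 must be > 0 for a valid development rate")
  }
  temperature / den
}

#' Closed-form time to curd induction at constant temperature
#'
#' Juvenile phase: TSf / T days. Adult phase: (S * T + T0) / T days. Total
#' thermal time is therefore TSf + S * T + T0 degree-days.
#'
#' @param params a `pheno_params` (or list with LAR, S, T0).
#' @param temperature constant temperature, degree C (vectorised).
#' @return list with `days` and `thermal_time` (degree-days).
#' @export
time_to_induction_constant <- function(params, temperature) {
  tsf <- juvenile_ts(params$LAR)
  if (any(temperature <= 0)) abort_validation("temperature must be > 0")
  den <- temperature * params$S + params$T0
  if (any(den <= 0)) abort_validation("T * S + T0 must be > 0")
  tt <- tsf + den
  list(days = tt / temperature, thermal_time = tt)
}

#' Simulate development through the two phases under a daily series
#'
#' Phase 1 (juvenile): daily mean temperatures accumulate as degree-days
#' (base 0) until the cumulative sum reaches TSf; the crossing day is
#' linearly interpolated. Phase 2 (adult vegetative): daily rates
#' `k_i = T_i / (T_i * S + T0)` accumulate from the fractional juvenile end
#' until the cumulative k reaches 1, again interpolated inside the crossing
#' day, which marks visible curd induction. If the series ends before a
#' crossing, the result is censored with the partial trace.
#'
#' @param params a `pheno_params` (or list with LAR, S, T0).
#' @param temps numeric vector of daily mean temperatures (degree C), all
#'   > 0; day i covers the interval (i-1, i] after transplanting.
#' @return an object of class `development_result`: list with
#'   `juvenile_end_day`, `induction_day` (fractional; NA if censored),
#'   `censored`, and `trace` (cumulative adult-phase development at the end
#'   of each day).
#' @export
simulate_development <- function(params, temps) {
  temps <- as.numeric(temps)
  nd <- length(temps)
  if (nd == 0L) {
    return(structure(
      list(juvenile_end_day = NA_real_, induction_day = NA_real_,
           censored = TRUE, trace = numeric(0)),
      class = "development_result"
    ))
  }
  if (any(temps <= 0)) abort_validation("all daily temperatures must be > 0")
  tsf <- juvenile_ts(params$LAR)
  k <- daily_rate(temps, params$S, params$T0) # validates the denominator
  cum_dd <- cumsum(temps)
  if (cum_dd[nd] < tsf) {
    return(structure(
      list(juvenile_end_day = NA_real_, induction_day = NA_real_,
           censored = TRUE, trace = rep(0, nd)),
      class = "development_result"
    ))
  }
  i1 <- which(cum_dd >= tsf)[1L]
  prev_dd <- if (i1 > 1L) cum_dd[i1 - 1L] else 0
  t1 <- (i1 - 1L) + (tsf - prev_dd) / temps[i1]
  # adult-phase accumulation: partial day i1 then whole days
  trace <- rep(0, nd)
  trace[i1] <- (i1 - t1) * k[i1]
  if (i1 < nd) trace[(i1 + 1L):nd] <- trace[i1] + cumsum(k[(i1 + 1L):nd])
  if (trace[nd] < 1) {
    return(structure(
      list(juvenile_end_day = t1, induction_day = NA_real_,
           censored = TRUE, trace = trace),
      class = "development_result"
    ))
  }
  i2 <- which(trace >= 1)[1L]
  prev_k <- if (i2 > i1) trace[i2 - 1L] else 0
  start <- if (i2 > i1) i2 - 1L else t1
  t2 <- start + (1 - prev_k) / k[i2]
  structure(
    list(juvenile_end_day = t1, induction_day = t2, censored = FALSE,
         trace = trace),
    class = "development_result"
  )
}

#' @export
print.development_result <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("Development censored at day %d (juvenile end %s)\n",
                length(x$trace),
                if (is.na(x$juvenile_end_day)) "not reached"
                else sprintf("%.2f", x$juvenile_end_day)))
  } else {
    cat(sprintf("Juvenile end day %.2f; curd induction day %.2f\n",
                x$juvenile_end_day, x$induction_day))
  }
  invisible(x)
}

#' Sowing and harvest dates from an induction day
#'
#' Convention for field trials: sowing 30 days before transplanting, and a
#' fixed 30 days from visible curd induction to harvest.
#'
#' @param induction_day fractional days after transplanting, >= 0.
#' @param transplant_date a `Date` (or numeric day index).
#' @return list with `sowing_date` and `harvest_date`; for `Date` input the
#'   harvest date is rounded up to the next whole day.
#' @export
harvest_date <- function(induction_day, transplant_date) {
  if (any(induction_day < 0)) abort_validation("induction_day must be >= 0")
  if (inherits(transplant_date, "Date")) {
    list(
      sowing_date = transplant_date - 30,
      harvest_date = transplant_date + ceiling(induction_day + 30)
    )
  } else {
    list(
      sowing_date = transplant_date - 30,
      harvest_date = transplant_date + induction_day + 30
    )
  }
}
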