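#' Simulate a constant-temperature greenhouse parameterization trial
#'
#' Generates, for every line, (i) twice-weekly leaf counts
#' `round(LAR * T * t)` plus small integer mis-count noise (kept
#' non-decreasing), and (ii) the day of visible curd induction
#' `(TSf + S*T + T0 + eps) / T` with thermal-time noise
#' `eps ~ N(0, sigma_ts(T)^2)` in degree-days; the noise is heteroscedastic
#' across treatments, growing with temperature as in the real trials.
#' Inductions after `duration_days` are censored; trials terminate after 120
#' days by default.
#'
#' @param true_params data.frame with per-line `LAR`, `S`, `T0`.
#' @param temperature treatment mean temperature (degree C), > 0.
#' @param arch a `qtl_architecture` (supplies `sigma_ts`).
#' @param duration_days trial duration (default 120).
#' @param seed integer seed.
#' @param count_noise_prob probability a scoring is off by one leaf (split
#'   evenly between -1 and +1).
#' @param round_counts round leaf counts to whole leaves (default TRUE).
#'   `FALSE` gives exact continuous counts, useful for noise-free
#'   consistency checks of the estimation chain.
#' @return object of class `greenhouse_trial`: list with `temperature`,
#'   `duration_days`, `leaf_obs` (data.frame line/day/leaf_count) and
#'   `induction` (data.frame line/induction_day/censored).
#' @export
simulate_greenhouse_trial <- function(true_params, temperature, arch,
                                      duration_days = 120, seed = 1L,
                                      count_noise_prob = 0.3,
                                      round_counts = TRUE) {
  if (temperature <= 0) abort_validation("temperature must be > 0")
  stopifnot(inherits(arch, "qtl_architecture"))
  den <- temperature * true_params$S + true_params$T0
  if (any(den <= 0)) {
    abort_validation("some lines have S*T + T0 <= 0 at this temperature")
  }
  n <- nrow(true_params)
  ids <- rownames(true_params)
  if (is.null(ids)) ids <- sprintf("L%04d", seq_len(n))
  score_days <- unique(round(seq(3.5, duration_days, by = 3.5)))
  set.seed(seed)
  # leaf counts, long format
  eps_cnt <- matrix(
    sample(c(-1L, 0L, 1L), n * length(score_days), replace = TRUE,
           prob = c(count_noise_prob / 2, 1 - count_noise_prob, count_noise_prob / 2)),
    nrow = n
  )
  counts <- outer(true_params$LAR * temperature, score_days)
  if (round_counts) {
    counts <- round(counts) + eps_cnt
    counts <- t(apply(counts, 1L, cummax)) # scores can miss leaves, not lose them
    counts[counts < 0] <- 0
  }
  leaf_obs <- data.frame(
    line = rep(ids, times = length(score_days)),
    day = rep(score_days, each = n),
    leaf_count = as.numeric(counts),
    stringsAsFactors = FALSE
  )
  # induction day in thermal time, heteroscedastic noise
  tsf <- juvenile_ts(true_params$LAR)
  eps_tt <- stats::rnorm(n, 0, sigma_ts_at(arch, temperature))
  tt <- tsf + pmax(den + eps_tt, 1) # adult phase cannot complete before it starts
  day <- tt / temperature
  censored <- day > duration_days
  induction <- data.frame(
    line = ids,
    induction_day = ifelse(censored, NA_real_, day),
    censored = censored,
    stringsAsFactors = FALSE
  )
  structure(
    list(temperature = temperature, duration_days = duration_days,
         leaf_obs = leaf_obs, induction = induction),
    class = "greenhouse_trial"
  )
}

#' @export
print.greenhouse_trial <- function(x, ...) {
  cat(sprintf(
    "Greenhouse trial at %.2f C: %d lines, %d censored, %d-day duration\n",
    x$temperature, nrow(x$induction), sum(x$induction$censored), x$duration_days
  ))
  invisible(x)
}

#' Field-site temperature presets
#'
#' Mean/min/max daily temperature summaries of the six validation trial
#' sites (degree C).
#'
#' @param site one of "Zeewolde2011", "Zeewolde2012", "Ruthe", "Rostock",
#'   "Ocsa2011", "Ocsa2012".
#' @return list with `mean`, `min`, `max`.
#' @export
site_preset <- function(site = c("Zeewolde2011", "Zeewolde2012", "Ruthe",
                                 "Rostock", "Ocsa2011", "Ocsa2012")) {
  site <- match.arg(site)
  presets <- list(
    Zeewolde2011 = list(mean = 17.4, min = 13.0, max = 25.4),
    Zeewolde2012 = list(mean = 17.2, min = 9.1, max = 21.9),
    Ruthe        = list(mean = 19.0, min = 12.1, max = 26.9),
    Rostock      = list(mean = 17.9, min = 11.7, max = 27.4),
    Ocsa2011     = list(mean = 21.4, min = 14.9, max = 29.6),
    Ocsa2012     = list(mean = 22.0, min = 13.6, max = 29.4)
  )
  presets[[site]]
}

#' Simulate a daily mean temperature series for a field site
#'
#' A seasonal sinusoid plus AR(1) daily noise, affinely rescaled so the
#' realized series mean equals `mean` exactly and the realized extremes lie
#' within `[min, max]`.
#'
#' @param mean,min,max target mean and admissible extremes (degree C);
#'   `0 < min < mean < max` required.
#' @param n_days series length (default 120).
#' @param seed integer seed.
#' @param amplitude seasonal amplitude of the unscaled sinusoid.
#' @param noise_sd innovation SD of the AR(1) noise; `amplitude = 0` and
#'   `noise_sd = 0` give a constant series at `mean`.
#' @param ar autocorrelation of the daily noise.
#' @return numeric vector of daily mean temperatures, class
#'   `temperature_series`.
#' @export
simulate_field_temperatures <- function(mean, min, max, n_days = 120, seed = 1L,
                                        amplitude = 1, noise_sd = 1.5, ar = 0.7) {
  if (!(min < mean && mean < max)) abort_validation("need min < mean < max")
  if (min <= 0) abort_validation("min temperature must be > 0 (base temperature 0)")
  if (n_days < 1) abort_validation("n_days must be >= 1")
  set.seed(seed)
  i <- seq_len(n_days)
  seasonal <- amplitude * sin(2 * pi * i / 365 + stats::runif(1, 0, 2 * pi))
  eps <- stats::rnorm(n_days, 0, noise_sd)
  noise <- as.numeric(stats::filter(eps, ar, method = "recursive"))
  z <- seasonal + noise
  zc <- z - base::mean(z)
  hi <- base::max(zc); lo <- base::min(zc)
  b <- if (hi <= 0 || lo >= 0) 0 else base::min((max - mean) / hi, (mean - min) / (-lo))
  out <- mean + b * zc
  structure(out, class = c("temperature_series", "numeric"))
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("Daily temperature series: %d days, mean %.2f C, range [%.1f, %.1f] C\n",
              length(x), mean(unclass(x)), min(x), max(x)))
  invisible(x)
}

#' Simulate a field validation trial
#'
#' Runs the two-phase development model forward for every line under the
#' daily temperature series, adds Gaussian observation noise in days, and
#' rounds up to the next twice-weekly scoring day. Lines that do not reach
#' induction within the series are censored.
#'
#' @param true_params data.frame with per-line `LAR`, `S`, `T0`.
#' @param temps daily temperature series.
#' @param obs_noise_sd SD of observation noise in days (default 2).
#' @param seed integer seed.
#' @param scoring_interval days between scorings (default 3.5, twice weekly).
#' @return object of class `field_trial`: list with `temps` and
#'   `observations` (data.frame line/induction_day/censored).
#' @export
simulate_field_trial <- function(true_params, temps, obs_noise_sd = 2, seed = 1L,
                                 scoring_interval = 3.5) {
  temps <- as.numeric(temps)
  if (length(temps) == 0L) abort_validation("temperature series is empty")
  n <- nrow(true_params)
  ids <- rownames(true_params)
  if (is.null(ids)) ids <- sprintf("L%04d", seq_len(n))
  set.seed(seed)
  noise <- stats::rnorm(n, 0, obs_noise_sd)
  day <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    dev <- simulate_development(
      list(LAR = true_params$LAR[j], S = true_params$S[j], T0 = true_params$T0[j]),
      temps
    )
    if (!dev$censored) day[j] <- dev$induction_day
  }
  obs <- day + noise
  obs <- ceiling(pmax(obs, scoring_interval) / scoring_interval) * scoring_interval
  censored <- is.na(day) | obs > length(temps)
  structure(
    list(
      temps = temps,
      observations = data.frame(
        line = ids,
        induction_day = ifelse(censored, NA_real_, obs),
        censored = censored,
        stringsAsFactors = FALSE
      )
    ),
    class = "field_trial"
  )
}

#' @export
print.field_trial <- function(x, ...) {
  cat(sprintf(
    "Field trial: %d days, %d lines, %d censored, mean observed induction day %.1f\n",
    length(x$temps), nrow(x$observations), sum(x$observations$censored),
    mean(x$observations$induction_day, na.rm = TRUE)
  ))
  invisible(x)
}

#' Write greenhouse trials to phenotype CSV files
#'
#' Induction records go to `<prefix>_induction.csv` with columns
#' `line,treatment_temperature,induction_day,censored`; leaf counts to
#' `<prefix>_leaves.csv` with `line,treatment_temperature,day,leaf_count`.
#'
#' @param trials list of `greenhouse_trial` objects.
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_phenotypes <- function(trials, prefix) {
  ind <- do.call(rbind, lapply(trials, function(tr) {
    cbind(tr$induction[, "line", drop = FALSE],
          treatment_temperature = tr$temperature,
          tr$induction[, c("induction_day", "censored")])
  }))
  lv <- do.call(rbind, lapply(trials, function(tr) {
    cbind(tr$leaf_obs[, "line", drop = FALSE],
          treatment_temperature = tr$temperature,
          tr$leaf_obs[, c("day", "leaf_count")])
  }))
  p1 <- paste0(prefix, "_induction.csv")
  p2 <- paste0(prefix, "_leaves.csv")
  utils::write.csv(ind, p1, row.names = FALSE, quote = FALSE)
  utils::write.csv(lv, p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

#' Write a temperature series to CSV (`day_index,tmean_c`)
#' @param temps numeric series.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_temperature_series <- function(temps, path) {
  utils::write.csv(
    data.frame(day_index = seq_along(temps), tmean_c = as.numeric(temps)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a temperature series from CSV
#' @param path CSV with columns `day_index`, `tmean_c`.
#' @return `temperature_series`.
#' @export
read_temperature_series <- function(path) {
  df <- utils::read.csv(path)
  structure(df$tmean_c[order(df$day_index)],
            class = c("temperature_series", "numeric"))
}
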