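#' QTL architecture for the three phenology parameters
#'
#' Defines the generative genetic model of the synthetic population: per
#' trait (LAR, S, T0) a set of additive loci with parent-1 allele effects,
#' the trait mean and total standard deviation, the correlation of the
#' polygenic (residual) components of S and T0, and the per-temperature
#' thermal-time measurement noise of the greenhouse trials.
#'
#' @param qtl data.frame with columns `trait` ("LAR", "S", "T0"),
#'   `chromosome`, `position_cM`, `effect` (additive effect of the parent-1
#'   allele, on the trait scale).
#' @param means named numeric vector of trait means (`LAR`, `S`, `T0`).
#' @param sds named numeric vector of total trait standard deviations.
#' @param rho_res correlation between the S and T0 polygenic residuals
#'   (|rho| < 1). LAR residuals are independent.
#' @param sigma_ts named numeric vector: thermal-time measurement noise SD
#'   (degree-days) at each greenhouse treatment temperature (names are
#'   temperatures in degree C); intermediate temperatures are linearly
#'   interpolated, extremes extended flat.
#' @return an object of class `qtl_architecture`.
#' @seealso [default_architecture()] for the calibrated defaults.
#' @export
qtl_architecture <- function(qtl, means, sds, rho_res, sigma_ts) {
  traits <- c("LAR", "S", "T0")
  stopifnot(all(c("trait", "chromosome", "position_cM", "effect") %in% names(qtl)))
  if (!all(qtl$trait %in% traits)) abort_validation("qtl traits must be LAR, S or T0")
  if (!all(traits %in% names(means)) || !all(traits %in% names(sds))) {
    abort_validation("means and sds must be named for LAR, S and T0")
  }
  if (abs(rho_res) >= 1) abort_validation("|rho_res| must be < 1")
  for (tr in traits) {
    ss <- sum(qtl$effect[qtl$trait == tr]^2)
    if (ss > sds[tr]^2 + 1e-12) {
      abort_validation(sprintf(
        "trait %s: sum of squared QTL effects (%.4g) exceeds total variance (%.4g)",
        tr, ss, sds[tr]^2
      ))
    }
  }
  structure(
    list(
      qtl = qtl, means = means[traits], sds = sds[traits],
      rho_res = rho_res,
      sigma_ts = sigma_ts[order(as.numeric(names(sigma_ts)))]
    ),
    class = "qtl_architecture"
  )
}

#' @export
print.qtl_architecture <- function(x, ...) {
  cat("QTL architecture:\n")
  for (tr in c("LAR", "S", "T0")) {
    k <- sum(x$qtl$trait == tr)
    cat(sprintf(
      "  %-3s mean %.4g sd %.4g, %d QTL (sum e^2 = %.4g)\n",
      tr, x$means[tr], x$sds[tr], k, sum(x$qtl$effect[x$qtl$trait == tr]^2)
    ))
  }
  cat(sprintf("  S/T0 residual correlation: %.2f\n", x$rho_res))
  invisible(x)
}

#' Default calibrated architecture of the cauliflower DH population
#'
#' Encodes the mapped QTL of the biparental cauliflower population: ten loci
#' for leaf appearance rate (LAR), five for the temperature-sensitivity slope
#' S and two for the minimum adult-phase thermal time T0, with their additive
#' parent-1 allele effects, plus the population means and standard
#' deviations of the three parameters (LAR 0.0216 +/- 0.0021 leaves/degree-day,
#' S 50.0 +/- 20.5 degree-day/degree C, T0 631.3 +/- 296.5 degree-days).
#' LAR effects are on the 1e-3 leaves per degree-day scale, the only reading
#' consistent with the trait's total variance.
#'
#' The residual S/T0 correlation `rho_res` and the per-temperature
#' thermal-time noise `sigma_ts` are calibration constants, tuned once so
#' that parameter estimates fitted from the simulated seven-temperature
#' trials reproduce the estimate-level statistics of the real population
#' (correlation of fitted S and T0 near -0.95; mean per-line regression R^2
#' near 0.65). See the methods vignette for the calibration procedure.
#'
#' @return a `qtl_architecture`.
#' @export
default_architecture <- function() {
  qtl <- data.frame(
    trait = c(rep("LAR", 10), rep("S", 5), rep("T0", 2)),
    chromosome = c(
      "O1", "O1", "O1", "O3", "O5", "O5", "O6", "O7", "O7", "O9",
      "O1", "O4", "O6", "O6", "O9",
      "O1", "O6"
    ),
    position_cM = c(
      24, 58, 78, 32, 0, 20, 32, 28, 80, 38,
      74, 114, 12, 32, 48,
      74, 12
    ),
    effect = c(
      c(-0.504, 0.795, -0.508, -0.388, -0.425, 0.541, 0.593, 0.504, -0.398, 0.623) * 1e-3,
      -4.972, -5.217, -8.885, -6.891, -4.797,
      64.62, 100.54
    ),
    stringsAsFactors = FALSE
  )
  qtl_architecture(
    qtl,
    means = c(LAR = 0.0216, S = 50.0, T0 = 631.3),
    sds = c(LAR = 0.0021, S = 20.5, T0 = 296.5),
    rho_res = -0.97,
    sigma_ts = c(
      "11.75" = 60, "15.51" = 65, "17.33" = 85, "19.03" = 85,
      "21.44" = 220, "26.49" = 185, "27" = 340
    )
  )
}

#' Thermal-time measurement noise SD at a temperature
#'
#' Linear interpolation of the architecture's `sigma_ts` table; constant
#' extrapolation beyond its range.
#'
#' @param arch a `qtl_architecture`.
#' @param temperature degrees C (vectorised).
#' @return noise SD in degree-days.
#' @export
sigma_ts_at <- function(arch, temperature) {
  tt <- as.numeric(names(arch$sigma_ts))
  if (length(tt) == 1L) return(rep(unname(arch$sigma_ts), length(temperature)))
  stats::approx(tt, as.numeric(arch$sigma_ts), xout = temperature, rule = 2)$y
}

# genetic variance of a trait's QTL term in a DH population:
# sum_i e_i^2 + sum_{i != j, same chromosome} e_i e_j (1 - 2 r_ij)
qtl_genetic_variance <- function(q) {
  v <- sum(q$effect^2)
  if (nrow(q) > 1L) {
    for (i in seq_len(nrow(q) - 1L)) {
      for (j in (i + 1L):nrow(q)) {
        if (q$chromosome[i] == q$chromosome[j]) {
          r <- haldane_cm_to_r(abs(q$position_cM[i] - q$position_cM[j]))
          v <- v + 2 * q$effect[i] * q$effect[j] * (1 - 2 * r)
        }
      }
    }
  }
  v
}

#' Draw true phenology parameters under a QTL architecture
#'
#' For each trait the true per-line value is
#' `mean + sum_i effect_i * g_i + residual`, where `g_i` is the line's
#' genotype at the marker nearest the QTL position. The polygenic residual
#' is Gaussian with variance `sd^2 - V_g`, where `V_g` is the full genetic
#' variance of the QTL term including linkage covariance between
#' same-chromosome loci (DH genotypes at loci r apart correlate as
#' `1 - 2 r`), so the realized trait SD matches the architecture's total
#' SD. The S and T0 residuals are drawn jointly with correlation
#' `rho_res`; the LAR residual is independent.
#'
#' @param pop a `dh_population`.
#' @param arch a `qtl_architecture`; all QTL positions must lie on the map.
#' @param seed integer seed.
#' @return data.frame with columns `LAR`, `S`, `T0`, rows = lines of `pop`
#'   (LAR is truncated below at a small positive floor so rates stay valid).
#' @export
assign_true_params <- function(pop, arch, seed = 1L) {
  stopifnot(inherits(pop, "dh_population"), inherits(arch, "qtl_architecture"))
  n <- n_lines(pop)
  traits <- c("LAR", "S", "T0")
  gval <- function(chrom, pos) {
    pop$genotypes[, nearest_marker(pop$map, chrom, pos), drop = TRUE]
  }
  genetic <- stats::setNames(vector("list", 3), traits)
  res_var <- stats::setNames(numeric(3), traits)
  for (tr in traits) {
    q <- arch$qtl[arch$qtl$trait == tr, , drop = FALSE]
    g <- rep(0, n)
    if (nrow(q) > 0 && n > 0) {
      for (i in seq_len(nrow(q))) {
        g <- g + q$effect[i] * gval(q$chromosome[i], q$position_cM[i])
      }
    }
    genetic[[tr]] <- g
    res_var[tr] <- arch$sds[tr]^2 - qtl_genetic_variance(q)
    if (res_var[tr] < -1e-12) abort_validation("negative residual variance")
    res_var[tr] <- max(res_var[tr], 0)
  }
  set.seed(seed)
  z_lar <- stats::rnorm(n)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  rho <- arch$rho_res
  res_S <- sqrt(res_var["S"]) * z1
  res_T0 <- sqrt(res_var["T0"]) * (rho * z1 + sqrt(1 - rho^2) * z2)
  out <- data.frame(
    LAR = arch$means["LAR"] + genetic$LAR + sqrt(res_var["LAR"]) * z_lar,
    S = arch$means["S"] + genetic$S + res_S,
    T0 = arch$means["T0"] + genetic$T0 + res_T0,
    row.names = rownames(pop$genotypes)
  )
  out$LAR <- pmax(out$LAR, 1e-4)
  out
}
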