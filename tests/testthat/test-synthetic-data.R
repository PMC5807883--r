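test_that("DH genome simulation: edge cases and zero-distance identity", {
  gm <- toy_map()
  pop0 <- simulate_dh_genomes(gm, 0)
  expect_equal(n_lines(pop0), 0)
  # markers at identical position recombine never
  gm_same <- genetic_map(c("a", "b", "c"), rep("O1", 3), c(0, 5, 5))
  pop <- simulate_dh_genomes(gm_same, 300, seed = 2)
  expect_identical(pop$genotypes[, "b"], pop$genotypes[, "c"])
  expect_true(all(pop$genotypes %in% c(-1, 1)))
})

test_that("adjacent-marker recombination converges to the Haldane fraction", {
  gm <- genetic_map(c("a", "b"), c("O1", "O1"), c(0, 10))
  pop <- simulate_dh_genomes(gm, 10000, seed = 7)
  rec <- mean(pop$genotypes[, "a"] != pop$genotypes[, "b"])
  r_true <- haldane_cm_to_r(10)
  se <- sqrt(r_true * (1 - r_true) / 10000)
  expect_lt(abs(rec - r_true), 3 * se)
})

test_that("marker allele frequencies centre on one half", {
  pop <- simulate_dh_genomes(default_map(), 1000, seed = 11)
  freq <- colMeans(pop$genotypes == 1)
  expect_lt(mean(abs(freq - 0.5)), 0.05)
})

test_that("true parameters: means, printed-effect arithmetic, residual structure", {
  gm <- toy_map()
  pop <- simulate_dh_genomes(gm, 50, seed = 3)
  # no QTL, zero residual -> every line sits at the trait mean
  arch0 <- null_architecture(sds = c(LAR = 0, S = 0, T0 = 0))
  tp <- assign_true_params(pop, arch0, seed = 1)
  expect_true(all(tp$LAR == 0.0216))
  expect_true(all(tp$S == 50.0))
  expect_true(all(tp$T0 == 631.3))
  # T0 with its two mapped loci and no residual: mean + both printed effects
  arch_t0 <- qtl_architecture(
    qtl = data.frame(trait = "T0", chromosome = c("O1", "O2"),
                     position_cM = c(0, 0), effect = c(64.62, 100.54)),
    means = c(LAR = 0.0216, S = 50, T0 = 631.3),
    sds = c(LAR = 0, S = 0, T0 = sqrt(64.62^2 + 100.54^2)),
    rho_res = 0, sigma_ts = c("19" = 0)
  )
  tp2 <- assign_true_params(pop, arch_t0, seed = 1)
  all_p1 <- pop$genotypes[, "m1"] == 1 & pop$genotypes[, "n1"] == 1
  all_p2 <- pop$genotypes[, "m1"] == -1 & pop$genotypes[, "n1"] == -1
  expect_true(all(abs(tp2$T0[all_p1] - 796.46) < 1e-9))
  expect_true(all(abs(tp2$T0[all_p2] - 466.14) < 1e-9))
})

test_that("trait variance matches the architecture totals (variance decomposition)", {
  pop <- simulate_dh_genomes(default_map(), 4000, seed = 5)
  arch <- default_architecture()
  tp <- assign_true_params(pop, arch, seed = 6)
  # residual variance is set against full genetic variance (incl. linkage
  # covariance), so realized SDs track the architecture totals
  expect_rel_equal(stats::sd(tp$S), arch$sds["S"], 0.05)
  expect_rel_equal(stats::sd(tp$T0), arch$sds["T0"], 0.05)
  expect_rel_equal(stats::sd(tp$LAR), arch$sds["LAR"], 0.05)
  expect_rel_equal(mean(tp$S), arch$means["S"], 0.03)
  expect_error(
    assign_true_params(pop, qtl_architecture(
      qtl = data.frame(trait = "S", chromosome = "O1", position_cM = 0,
                       effect = 30),
      means = c(LAR = 0.02, S = 50, T0 = 600),
      sds = c(LAR = 0.002, S = 20, T0 = 300), # 30^2 > 20^2
      rho_res = 0, sigma_ts = c("19" = 10)
    ), seed = 1),
    class = "caulipheno_validation_error"
  )
})

test_that("greenhouse trial reproduces the closed-form induction day when noiseless", {
  arch0 <- noiseless_architecture()
  tp <- fixed_params()["mid", ] # population-mean line
  tr <- simulate_greenhouse_trial(tp, 19.03, arch0, seed = 1)
  want <- (7 / 0.0216 + 50 * 19.03 + 631.3) / 19.03 # 100.20 d
  expect_equal(tr$induction$induction_day, want, tolerance = 1e-10)
  expect_false(tr$induction$censored)
  # the same line at 11.75 C needs ~131 d and is censored at 120
  tr_cold <- simulate_greenhouse_trial(tp, 11.75, arch0, seed = 1)
  expect_gt((7 / 0.0216 + 50 * 11.75 + 631.3) / 11.75, 120)
  expect_true(tr_cold$induction$censored)
  expect_true(is.na(tr_cold$induction$induction_day))
  expect_error(simulate_greenhouse_trial(tp, -1, arch0),
               class = "caulipheno_validation_error")
  # S*T + T0 <= 0 rejected
  bad <- data.frame(LAR = 0.02, S = -50, T0 = 100)
  expect_error(simulate_greenhouse_trial(bad, 20, arch0),
               class = "caulipheno_validation_error")
})

test_that("noise-free leaf counts lie exactly on the LAR slope", {
  arch0 <- noiseless_architecture()
  tp <- fixed_params()
  tr <- simulate_greenhouse_trial(tp, 19.03, arch0, seed = 1,
                                  count_noise_prob = 0, round_counts = FALSE)
  for (id in rownames(tp)) {
    d <- tr$leaf_obs[tr$leaf_obs$line == id, ]
    expect_equal(estimate_lar(d$day * 19.03, d$leaf_count), tp[id, "LAR"],
                 tolerance = 1e-12)
  }
  # integer-rounded counts stay non-decreasing under observation noise
  tr2 <- simulate_greenhouse_trial(tp, 19.03, default_architecture(), seed = 2)
  for (id in rownames(tp)) {
    d <- tr2$leaf_obs[tr2$leaf_obs$line == id, ]
    expect_true(all(diff(d$leaf_count[order(d$day)]) >= 0))
  }
})

test_that("field temperature series honour mean, bounds and determinism", {
  ps <- site_preset("Rostock")
  temps <- simulate_field_temperatures(ps$mean, ps$min, ps$max, n_days = 100,
                                       seed = 4)
  expect_equal(mean(temps), 17.9, tolerance = 1e-9)
  expect_gte(min(temps), 11.7 - 1e-9)
  expect_lte(max(temps), 27.4 + 1e-9)
  expect_true(all(temps > 0))
  # flat configuration collapses to a constant series at the mean
  flat <- simulate_field_temperatures(17.9, 11.7, 27.4, n_days = 50, seed = 1,
                                      amplitude = 0, noise_sd = 0)
  expect_true(all(abs(flat - 17.9) < 1e-12))
  # different seeds: different series, identical rescaled mean
  t1 <- simulate_field_temperatures(17.9, 11.7, 27.4, n_days = 100, seed = 1)
  t2 <- simulate_field_temperatures(17.9, 11.7, 27.4, n_days = 100, seed = 2)
  expect_false(isTRUE(all.equal(as.numeric(t1), as.numeric(t2))))
  expect_equal(mean(t1), mean(t2), tolerance = 1e-9)
  expect_error(simulate_field_temperatures(10, 12, 20),
               class = "caulipheno_validation_error")
})

test_that("field trial matches the constant-temperature closed form and censors", {
  tp <- fixed_params()
  temps <- rep(17, 120)
  ft <- simulate_field_trial(tp, temps, obs_noise_sd = 0, seed = 1)
  want_mid <- (7 / 0.0216 + 50 * 17 + 631.3) / 17
  got <- ft$observations$induction_day[ft$observations$line == "mid"]
  expect_lte(abs(got - want_mid), 3.5) # within one scoring interval
  expect_gte(got, want_mid)            # scoring happens at the next visit
  # identical parameters -> identical observed days
  tp_same <- fixed_params()[c("mid", "mid", "mid"), ]
  rownames(tp_same) <- c("a", "b", "c")
  ft2 <- simulate_field_trial(tp_same, temps, obs_noise_sd = 0, seed = 1)
  expect_equal(length(unique(ft2$observations$induction_day)), 1L)
  expect_error(simulate_field_trial(tp, numeric(0)),
               class = "caulipheno_validation_error")
})

test_that("default Zeewolde-style field trial censors under 10% of lines", {
  pop <- simulate_dh_genomes(default_map(), 72, seed = 21)
  truth <- assign_true_params(pop, default_architecture(), seed = 22)
  ps <- site_preset("Zeewolde2011")
  temps <- simulate_field_temperatures(ps$mean, ps$min, ps$max, n_days = 120,
                                       seed = 23)
  ft <- simulate_field_trial(truth, temps, seed = 24)
  expect_lt(mean(ft$observations$censored), 0.10)
})

test_that("test hybrids are mid-parent in genotype and parameters", {
  gm <- toy_map()
  pop <- simulate_dh_genomes(gm, 20, seed = 8)
  tp <- assign_true_params(pop, null_architecture(), seed = 9)
  # tester identical to line 1: that hybrid reproduces line 1 exactly
  hyb <- make_test_hybrids(pop, tp, pop$genotypes[1, ], tp[1, ])
  expect_equal(unname(hyb$pop$genotypes[1, ]), unname(pop$genotypes[1, ]))
  expect_equal(hyb$true_params$S[1], tp$S[1])
  expect_true(all(hyb$pop$genotypes %in% c(-1, 0, 1)))
  # explicit mid-parent arithmetic
  tp2 <- fixed_params()[c("mid", "steep"), ]
  tp2$S <- c(70, 30)
  pop2 <- dh_population(matrix(c(1, 1, 1, -1, -1, -1, 1, -1, 1, -1),
                               nrow = 2, byrow = TRUE), gm,
                        c("a", "b"))
  hyb2 <- make_test_hybrids(pop2, tp2, rep(-1, 5),
                            list(LAR = 0.02, S = 40, T0 = 500))
  expect_equal(hyb2$true_params$S, c((70 + 40) / 2, (30 + 40) / 2))
  # tester at the population mean halves the spread
  tester_mean <- list(LAR = mean(tp$LAR), S = mean(tp$S), T0 = mean(tp$T0))
  hyb3 <- make_test_hybrids(pop, tp, rep(1, 5), tester_mean)
  expect_equal(stats::sd(hyb3$true_params$S), stats::sd(tp$S) / 2)
})

test_that("genotype CSV round-trips through a population", {
  gm <- toy_map()
  pop <- simulate_dh_genomes(gm, 10, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(pop, path)
  pop2 <- read_genotypes(path, gm)
  expect_identical(pop2$genotypes, pop$genotypes)
})

test_that("seed splitting is deterministic, distinct and within integer range", {
  s1 <- split_seed(42, 10)
  expect_identical(s1, split_seed(42, 10))
  expect_equal(length(unique(s1)), 10)
  expect_true(all(s1 >= 0 & s1 < 2^31))
  expect_false(any(split_seed(42, 10, salt = 7) == s1))
})
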