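test_that("interval genotype imputation matches the gamete-class enumeration", {
  gm <- genetic_map(c("a", "b"), c("O1", "O1"), c(0, 20))
  G <- matrix(c(1, 1, -1, -1, 1, -1, -1, 1), nrow = 4, byrow = TRUE)
  pop <- dh_population(G, gm, c("pp", "mm", "pm", "mp"))
  # at a marker: the marker column itself
  expect_equal(impute_interval_genotype(pop, "O1", 0), G[, 1])
  # midpoint of a 20 cM interval, both flanks +1:
  # P(+1) = (1-r)^2 / (1-r12) with r = haldane(10), r12 = haldane(20)
  r <- haldane_cm_to_r(10)
  r12 <- haldane_cm_to_r(20)
  want_pp <- 2 * (1 - r)^2 / (1 - r12) - 1 # 0.980328
  g <- impute_interval_genotype(pop, "O1", 10)
  expect_equal(g[1], want_pp, tolerance = 1e-12)
  expect_equal(g[1], 0.98033, tolerance = 1e-5)
  expect_equal(g[2], -want_pp, tolerance = 1e-12)
  # opposite flanks at the midpoint: zero by symmetry
  expect_equal(g[3], 0, tolerance = 1e-12)
  expect_equal(g[4], 0, tolerance = 1e-12)
  # law of total probability: averaging P(+1 | flanks) over the four flank
  # classes recovers the marginal allele frequency 1/2
  p_pp <- (1 - r)^2 / (1 - r12)      # given (+1, +1)
  p_mm <- r^2 / (1 - r12)            # given (-1, -1)
  p_pm <- (1 - r) * r / r12          # given (+1, -1)
  p_mp <- r * (1 - r) / r12          # given (-1, +1)
  marg <- (1 - r12) / 2 * (p_pp + p_mm) + r12 / 2 * (p_pm + p_mp)
  expect_equal(marg, 0.5, tolerance = 1e-12)
  expect_error(impute_interval_genotype(pop, "O1", 25),
               class = "caulipheno_validation_error")
})

test_that("cofactor selection finds planted signal and ignores noise", {
  map <- default_map()
  pop <- simulate_dh_genomes(map, 200, seed = 51)
  # constant phenotype: nothing to select
  expect_identical(select_cofactors(pop, rep(3, 200)), character(0))
  # one huge planted QTL: its nearest marker is picked first
  i_qtl <- nearest_marker(map, "O6", 12)
  set.seed(52)
  y <- 10 * pop$genotypes[, i_qtl] + rnorm(200)
  sel <- select_cofactors(pop, y)
  d <- abs(map$position_cM - map$position_cM[i_qtl])
  expect_true(map$marker[i_qtl] == sel[1] ||
                (map$chromosome[match(sel[1], map$marker)] == "O6" &&
                   d[match(sel[1], map$marker)] < 6))
  expect_error(select_cofactors(pop, rep(1, 10)),
               class = "caulipheno_validation_error")
})

test_that("pure-noise phenotypes select at most a couple of cofactors (n = 1000)", {
  pop <- simulate_dh_genomes(default_map(), 1000, seed = 53)
  nsel <- sapply(1:10, function(s) {
    set.seed(1300 + s)
    length(select_cofactors(pop, rnorm(1000)))
  })
  expect_gte(mean(nsel <= 2), 0.8)
})

test_that("CIM scan equals the explicit normal-equations oracle on small instances", {
  gm <- genetic_map(c("m1", "m2", "m3"), rep("O1", 3), c(0, 10, 30))
  set.seed(55)
  G <- matrix(sample(c(-1, 1), 20 * 3, replace = TRUE), nrow = 20)
  pop <- dh_population(G, gm)
  y <- 0.8 * G[, 2] + rnorm(20)
  # no cofactors
  scan <- cim_scan(pop, y, character(0), step = 2)
  for (i in seq_len(nrow(scan))) {
    g <- impute_interval_genotype(pop, "O1", scan$position_cM[i])
    X1 <- cbind(1, g)
    b <- solve(crossprod(X1), crossprod(X1, y))
    rss_full <- sum((y - X1 %*% b)^2)
    rss_red <- sum((y - mean(y))^2)
    expect_equal(scan$lod[i], 10 * log10(rss_red / rss_full), tolerance = 1e-8)
    expect_equal(scan$effect[i], b[2], tolerance = 1e-8)
  }
  # with a cofactor at m3 (30 cM), excluded within 10 cM of the test position
  scan2 <- cim_scan(pop, y, "m3", step = 2, window = 10)
  for (i in seq_len(nrow(scan2))) {
    pos <- scan2$position_cM[i]
    g <- impute_interval_genotype(pop, "O1", pos)
    Xc <- if (abs(30 - pos) <= 10) cbind(rep(1, 20)) else cbind(1, G[, 3])
    bR <- solve(crossprod(Xc), crossprod(Xc, y))
    rss_red <- sum((y - Xc %*% bR)^2)
    Xf <- cbind(Xc, g)
    bF <- solve(crossprod(Xf), crossprod(Xf, y))
    rss_full <- sum((y - Xf %*% bF)^2)
    expect_equal(scan2$lod[i], max(0, 10 * log10(rss_red / rss_full)),
                 tolerance = 1e-8)
  }
})

test_that("marker-position LOD equals the single-regression identity", {
  pop <- simulate_dh_genomes(default_map(), 120, seed = 57)
  # use a chromosome's first marker: its position is always on the scan grid
  i_mk <- which(pop$map$chromosome == "O3")[1]
  set.seed(58)
  y <- pop$genotypes[, i_mk] + rnorm(120, 0, 2)
  scan <- cim_scan(pop, y, character(0), step = 2)
  mk <- pop$map[i_mk, ]
  row <- which(scan$chromosome == mk$chromosome &
                 abs(scan$position_cM - mk$position_cM) < 1e-9)
  expect_length(row, 1L)
  r2 <- summary(stats::lm(y ~ pop$genotypes[, i_mk]))$r.squared
  expect_equal(scan$lod[row], (120 / 2) * log10(1 / (1 - r2)), tolerance = 1e-8)
})

test_that("LOD scores are invariant to affine rescaling of the phenotype", {
  pop <- simulate_dh_genomes(default_map(), 100, seed = 59)
  set.seed(60)
  y <- pop$genotypes[, 10] + rnorm(100)
  cof <- select_cofactors(pop, y)
  s1 <- cim_scan(pop, y, cof)
  s2 <- cim_scan(pop, 3.7 * y - 12, cof)
  expect_equal(s1$lod, s2$lod, tolerance = 1e-8)
  expect_equal(s2$effect, 3.7 * s1$effect, tolerance = 1e-8)
})

test_that("a planted QTL is located within 4 cM at n = 1000", {
  map <- default_map()
  i_qtl <- nearest_marker(map, "O3", 40)
  pos_true <- map$position_cM[i_qtl]
  hits <- sapply(1:5, function(s) {
    pop <- simulate_dh_genomes(map, 1000, seed = 600 + s)
    set.seed(700 + s)
    y <- pop$genotypes[, i_qtl] + rnorm(1000) # effect = 1 phenotype SD approx
    cof <- select_cofactors(pop, y)
    scan <- cim_scan(pop, y, cof)
    peak <- scan[which.max(scan$lod), ]
    peak$chromosome == "O3" && abs(peak$position_cM - pos_true) <= 4
  })
  expect_gte(mean(hits), 0.8)
})

test_that("QTL declaration: empty scans, single peaks and linked pairs", {
  map <- default_map()
  pop <- simulate_dh_genomes(map, 400, seed = 61)
  # flat low scan -> empty model carrying the phenotype mean
  set.seed(62)
  y0 <- rnorm(400, 5, 1)
  scan0 <- cim_scan(pop, y0, character(0))
  if (max(scan0$lod) < 2.5) {
    m0 <- declare_qtl(scan0, pop, y0)
    expect_equal(nrow(m0$loci), 0)
    expect_equal(m0$m, mean(y0))
    expect_equal(unname(predict(m0, pop)[3]), mean(y0))
  }
  # one clean additive locus: declared with a support interval around it
  i1 <- nearest_marker(map, "O2", 30)
  set.seed(63)
  y1 <- 1.2 * pop$genotypes[, i1] + rnorm(400)
  m1 <- declare_qtl(cim_scan(pop, y1, character(0)), pop, y1, trait = "demo")
  expect_gte(nrow(m1$loci), 1)
  top <- m1$loci[which.max(m1$loci$lod), ]
  expect_identical(top$chromosome, "O2")
  expect_true(top$ci_lo <= top$position_cM && top$position_cM <= top$ci_hi)
  expect_equal(top$effect, 1.2, tolerance = 0.2)
  # two planted loci 40 cM apart on one chromosome both declared at n = 1000
  pop2 <- simulate_dh_genomes(map, 1000, seed = 64)
  ia <- nearest_marker(map, "O1", 30)
  ib <- nearest_marker(map, "O1", 70)
  set.seed(65)
  y2 <- pop2$genotypes[, ia] + pop2$genotypes[, ib] + rnorm(1000)
  cof2 <- select_cofactors(pop2, y2)
  m2 <- declare_qtl(cim_scan(pop2, y2, cof2), pop2, y2)
  o1 <- m2$loci[m2$loci$chromosome == "O1", ]
  expect_gte(nrow(o1), 2)
  expect_true(any(abs(o1$position_cM - 30) < 10) &&
                any(abs(o1$position_cM - 70) < 10))
})

test_that("QTL-model predictions follow m + sum(e g), including hybrids", {
  loci <- data.frame(
    chromosome = c("O1", "O6"), position_cM = c(74, 12),
    marker = c("mA", "mB"), effect = c(64.62, 100.54),
    lod = c(2.91, 4.49), ci_lo = c(66, 4), ci_hi = c(80, 20),
    r_squared = c(0.085, 0.126), stringsAsFactors = FALSE
  )
  model <- structure(list(trait = "T0", m = 631.3, loci = loci),
                     class = "qtl_model")
  G <- matrix(c(1, 1, -1, -1, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("allP1", "allP2", "hybrid"), c("mA", "mB")))
  pr <- predict(model, G)
  expect_equal(unname(pr["allP1"]), 796.46)
  expect_equal(unname(pr["allP2"]), 466.14)
  expect_equal(unname(pr["hybrid"]), 631.3)
  # predictions are symmetric about m for mirrored genotypes
  expect_equal(pr[["allP1"]] - 631.3, 631.3 - pr[["allP2"]])
  expect_error(predict(model, G[, 1, drop = FALSE]),
               class = "caulipheno_validation_error")
})

test_that("joint re-estimation recovers planted effects without bias at low noise", {
  map <- default_map()
  pop <- simulate_dh_genomes(map, 800, seed = 67)
  ia <- nearest_marker(map, "O4", 114)
  ib <- nearest_marker(map, "O6", 12)
  set.seed(68)
  y <- 631.3 + 100.54 * pop$genotypes[, ib] + 64.62 * pop$genotypes[, ia] +
    rnorm(800, 0, 10)
  cof <- select_cofactors(pop, y)
  m <- declare_qtl(cim_scan(pop, y, cof), pop, y, trait = "T0")
  expect_equal(m$m, 631.3, tolerance = 1)
  eff_b <- m$loci$effect[m$loci$chromosome == "O6"][1]
  expect_equal(eff_b, 100.54, tolerance = 0.1 * 100.54)
  expect_true(all(m$loci$r_squared >= 0 & m$loci$r_squared <= 1))
})

test_that("epistasis scan: type-I control, planted interaction, degenerate input", {
  map <- default_map()
  pop <- simulate_dh_genomes(map, 1000, seed = 71)
  ia <- nearest_marker(map, "O4", 114)
  ib <- nearest_marker(map, "O6", 12)
  loci <- data.frame(
    chromosome = c("O4", "O6"), position_cM = c(114, 12),
    marker = map$marker[c(ia, ib)], effect = c(1, 1), lod = c(5, 5),
    ci_lo = c(110, 8), ci_hi = c(116, 16), r_squared = c(0.1, 0.1),
    stringsAsFactors = FALSE
  )
  model <- structure(list(trait = "S", m = 0, loci = loci), class = "qtl_model")
  g1 <- pop$genotypes[, ia]; g2 <- pop$genotypes[, ib]
  # planted interaction of one phenotype SD is detected
  set.seed(72)
  y_int <- g1 + g2 + 1 * g1 * g2 + rnorm(1000)
  res <- epistasis_scan(model, pop, y_int)
  expect_true(res$significant[1])
  expect_equal(res$effect[1], 1, tolerance = 0.2)
  # purely additive trait: rejection rate compatible with alpha = 0.05
  set.seed(73)
  rej <- replicate(30, {
    y_add <- g1 + g2 + rnorm(1000)
    epistasis_scan(model, pop, y_add)$significant[1]
  })
  expect_lte(sum(rej), 6) # P(X > 6 | binom(30, 0.05)) < 0.1%
  # fewer than two loci is an error
  m1 <- structure(list(trait = "S", m = 0, loci = loci[1, ]), class = "qtl_model")
  expect_error(epistasis_scan(m1, pop, y_int),
               class = "caulipheno_validation_error")
})

test_that("scan and model artefacts serialise to CSV and JSON", {
  pop <- simulate_dh_genomes(default_map(), 150, seed = 75)
  set.seed(76)
  y <- pop$genotypes[, 100] * 1.5 + rnorm(150)
  scan <- cim_scan(pop, y, character(0))
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_scan(scan, f1, trait = "S")
  df <- utils::read.csv(f1)
  expect_identical(names(df), c("trait", "chromosome", "position_cM", "LOD", "effect"))
  expect_equal(nrow(df), nrow(scan))
  m <- declare_qtl(scan, pop, y, trait = "S")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_qtl_model(m, f2)
  parsed <- jsonlite::read_json(f2)
  expect_equal(parsed$m, m$m, tolerance = 1e-12)
  expect_equal(length(parsed$loci), nrow(m$loci))
})
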