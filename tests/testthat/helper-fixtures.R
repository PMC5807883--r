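# small in-code fixtures shared across test files

# two-chromosome toy map: O1 with markers at 0/10/30 cM, O2 with 0/20 cM
toy_map <- function() {
  genetic_map(
    marker = c("m1", "m2", "m3", "n1", "n2"),
    chromosome = c("O1", "O1", "O1", "O2", "O2"),
    position_cM = c(0, 10, 30, 0, 20)
  )
}

# architecture with no QTL and zero trial noise: every line gets the means
null_architecture <- function(sds = c(LAR = 0.0021, S = 20.5, T0 = 296.5)) {
  qtl_architecture(
    qtl = data.frame(trait = character(0), chromosome = character(0),
                     position_cM = numeric(0), effect = numeric(0)),
    means = c(LAR = 0.0216, S = 50.0, T0 = 631.3),
    sds = sds,
    rho_res = 0,
    sigma_ts = c("15" = 0, "27" = 0)
  )
}

# default architecture with all trial noise switched off
noiseless_architecture <- function() {
  arch <- default_architecture()
  arch$sigma_ts[] <- 0
  arch
}

# deterministic parameter table spanning the population range
fixed_params <- function() {
  data.frame(
    LAR = c(0.0161, 0.0216, 0.0293, 0.0250),
    S = c(39.8, 50.0, 75.0, 20.0),
    T0 = c(1133.2, 631.3, 100.0, 400.0),
    row.names = c("P1like", "mid", "steep", "flat")
  )
}

expect_rel_equal <- function(x, y, tol) {
  expect_true(all(abs(x - y) <= tol * abs(y)),
              label = sprintf("%s within %g of %s", format(x), tol, format(y)))
}
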