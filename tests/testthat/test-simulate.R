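# Synthetic GWAS generator: reproducibility, SE formulas, null
# centering, and the LD panel construction.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(pleiotropy_mode = "none", pleiotropy_sd = 0.1),
               "requires pleiotropy_mean = pleiotropy_sd = 0")
  expect_error(sim_config(pleiotropy_mode = "balanced", pleiotropy_mean = 0.1,
                          pleiotropy_sd = 0.1), "pleiotropy_mean = 0")
  expect_warning(sim_config(n_snps = 10, invalid_fraction = 0.25,
                            pleiotropy_mode = "balanced", pleiotropy_sd = 0.1),
                 "not integral")
  expect_error(sim_config(n_snps = 10, ld_blocks = list(c(3, 0.5), c(3, 0.5))),
               "sizes sum to 6")
  expect_error(sim_config(ld_blocks = list(c(50, 1.0))), "rho")
})

test_that("seeded runs are bit-reproducible", {
  cfg <- sim_config(n_snps = 20, beta_causal = 0.1, seed = 99)
  s1 <- simulate_two_sample(cfg)
  s2 <- simulate_two_sample(cfg)
  expect_identical(s1, s2)
  p1 <- simulate_ld_panel(sim_config(n_snps = 6, n_ref = 200, seed = 3))
  p2 <- simulate_ld_panel(sim_config(n_snps = 6, n_ref = 200, seed = 3))
  expect_identical(p1, p2)
})

test_that("marginal SE formulas behave as the sampling theory dictates", {
  se <- mrkit:::.se_marginal
  # decreasing in n, maximized as maf goes extreme
  expect_true(se(1e4, 0.2) > se(1e5, 0.2))
  expect_true(se(1e4, 0.01) > se(1e4, 0.3))
  expect_true(se(1e4, 0.49) < se(1e4, 0.05))
  # binary formula is the continuous one scaled by 1/sqrt(phi(1-phi))
  phi <- 0.11
  expect_equal(se(5e4, 0.3, "binary", phi),
               se(5e4, 0.3) / sqrt(phi * (1 - phi)))
})

test_that("under the null the Wald ratios are centred on zero", {
  ratios <- vapply(1:200, function(r) {
    sim <- simulate_two_sample(sim_config(n_snps = 50, beta_causal = 0,
                                          seed = 5000 + r))
    mean(sim$outcome$records$beta / sim$exposure$records$beta)
  }, numeric(1))
  expect_lt(abs(mean(ratios)), 3 * sd(ratios) / sqrt(length(ratios)))
})

test_that("IVW recovers the causal effect and tightens with outcome sample size", {
  # exposure estimation noise induces the known first-order attenuation
  # beta * gamma_sd^2 / (gamma_sd^2 + mean(se_x^2)); the estimate should
  # match that dilution-corrected target within Monte-Carlo error at
  # every outcome sample size, with the Monte-Carlo noise shrinking
  beta <- 0.2
  run_at <- function(n_out, reps = 150) {
    out <- vapply(seq_len(reps), function(r) {
      cfg <- sim_config(n_snps = 50, beta_causal = beta, n_outcome = n_out,
                        seed = 7000 + r)
      sim <- simulate_two_sample(cfg)
      c(mr_ivw(hset_from_sim(sim))$estimate,
        mean(sim$truth$se_exposure^2))
    }, numeric(2))
    lambda <- 0.05^2 / (0.05^2 + mean(out[2, ]))
    c(err = mean(out[1, ]) - beta * lambda,
      mcse = sd(out[1, ]) / sqrt(reps))
  }
  b4 <- run_at(1e4); b5 <- run_at(1e5); b6 <- run_at(1e6)
  expect_lt(abs(b4["err"]), 3 * b4["mcse"])
  expect_lt(abs(b5["err"]), 3 * b5["mcse"])
  expect_lt(abs(b6["err"]), 3 * b6["mcse"])
  expect_lt(b6["mcse"], b4["mcse"])
})

test_that("the LD panel has unit diagonal, symmetry, and block structure", {
  cfg0 <- sim_config(n_snps = 8, n_ref = 2000, seed = 31)
  p0 <- simulate_ld_panel(cfg0)
  expect_equal(diag(p0$r2), rep(1, 8), ignore_attr = TRUE)
  expect_equal(p0$r2, t(p0$r2))
  off <- p0$r2[upper.tri(p0$r2)]
  expect_true(all(off < 0.05))  # independent variants
  expect_true(all(p0$r2 >= 0 & p0$r2 <= 1))

  # a tight AR block: compare against a direct simulation oracle of the
  # same thresholded-Gaussian construction at large n_ref
  cfg1 <- sim_config(n_snps = 2, maf_range = c(0.25, 0.30),
                     ld_blocks = list(c(2, 0.99)), n_ref = 10000, seed = 17)
  p1 <- simulate_ld_panel(cfg1)
  oracle <- local({
    set.seed(170)
    n <- 10000; rho <- 0.99
    f <- runif(2, 0.25, 0.30)
    hap <- function() {
      z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
      cbind(z1, z2)
    }
    h1 <- hap(); h2 <- hap()
    d <- sweep(h1, 2, qnorm(f), `<`) + sweep(h2, 2, qnorm(f), `<`)
    cor(d[, 1], d[, 2])^2
  })
  expect_equal(p1$r2[1, 2], oracle, tolerance = 0.05)
  expect_gt(p1$r2[1, 2], 0.7)
})

test_that("the panel round-trips through TSV with dosages", {
  cfg <- sim_config(n_snps = 5, n_ref = 50, ld_blocks = list(c(5, 0.8)),
                    seed = 12)
  p <- simulate_ld_panel(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_panel(p, path)
  back <- read_ld_panel(path)
  expect_equal(back$ids, p$ids)
  expect_equal(back$r2, p$r2, tolerance = 1e-9)
  expect_equal(unname(back$dosage), unname(p$dosage))
})

test_that("directional pleiotropy enters through the invalid fraction", {
  cfg <- sim_config(n_snps = 40, pleiotropy_mode = "directional",
                    pleiotropy_mean = 0.05, pleiotropy_sd = 0.01,
                    invalid_fraction = 0.5, seed = 77)
  sim <- simulate_two_sample(cfg)
  tr <- sim$truth
  expect_length(tr$invalid_ids, 20L)
  expect_equal(tr$Gamma, cfg$beta_causal * tr$gamma + tr$alpha)
  expect_true(all(tr$alpha[!(tr$variant_id %in% tr$invalid_ids)] == 0))
})
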