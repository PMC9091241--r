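# Allele harmonization between exposure and outcome studies.

two_tables <- function(exp_rec, out_rec) {
  list(exposure = sumstats_table(exp_rec, "exp"),
       outcome = sumstats_table(out_rec, "out"))
}

test_that("allele-label matching drives the harmonization action", {
  exp_rec <- make_records(4, effect_allele = c("A", "A", "A", "A"),
                          other_allele = c("G", "G", "G", "G"),
                          beta = rep(0.10, 4))
  out_rec <- make_records(4, effect_allele = c("A", "G", "T", "C"),
                          other_allele = c("G", "A", "C", "T"),
                          beta = rep(0.05, 4), eaf = rep(0.30, 4))
  tt <- two_tables(exp_rec, out_rec)
  h <- harmonize(tt$exposure, tt$outcome, exp_rec$variant_id)
  expect_equal(h$action,
               c("unchanged", "sign_flipped", "strand_flipped",
                 "strand_flipped_and_sign_flipped"))
  expect_equal(h$beta_outcome, c(0.05, -0.05, 0.05, -0.05))
})

test_that("allele swap negates the outcome beta and reflects its frequency", {
  exp_rec <- make_records(1, effect_allele = "A", other_allele = "G", beta = 0.10)
  out_rec <- make_records(1, effect_allele = "G", other_allele = "A",
                          beta = 0.05, eaf = 0.30)
  tt <- two_tables(exp_rec, out_rec)
  h <- harmonize(tt$exposure, tt$outcome, "rs001")
  expect_equal(h$action, "sign_flipped")
  expect_equal(h$beta_outcome, -0.05)
})

test_that("palindromic variants are resolved by frequency or dropped", {
  # eaf exactly 0.5 cannot disambiguate the strand
  exp_rec <- make_records(3, effect_allele = c("A", "A", "C"),
                          other_allele = c("T", "T", "G"),
                          eaf = c(0.50, 0.20, 0.45), beta = rep(0.1, 3))
  out_rec <- make_records(3, effect_allele = c("A", "T", "C"),
                          other_allele = c("T", "A", "G"),
                          eaf = c(0.30, 0.75, 0.44), beta = rep(0.05, 3))
  tt <- two_tables(exp_rec, out_rec)
  h <- harmonize(tt$exposure, tt$outcome, exp_rec$variant_id)
  expect_equal(h$action[1], "dropped_palindromic")
  # rs002: labels swapped, aligned outcome eaf 0.25, same side as 0.20,
  # both MAFs below the limit -> retained with a sign flip
  expect_equal(h$action[2], "sign_flipped")
  expect_equal(h$beta_outcome[2], -0.05)
  # rs003: MAF 0.45 exceeds the 0.42 limit -> dropped
  expect_equal(h$action[3], "dropped_palindromic")

  # discordant frequency sides -> dropped even at low MAF
  out2 <- make_records(3, effect_allele = c("A", "T", "C"),
                       other_allele = c("T", "A", "G"),
                       eaf = c(0.30, 0.25, 0.44), beta = rep(0.05, 3))
  h2 <- harmonize(tt$exposure, sumstats_table(out2, "out"), "rs002")
  expect_equal(h2$action, "dropped_palindromic")

  # missing frequency -> dropped
  out3 <- out_rec; out3$eaf[2] <- NA
  h3 <- harmonize(tt$exposure, sumstats_table(out3, "out"), "rs002")
  expect_equal(h3$action, "dropped_palindromic")
})

test_that("unmatched and mismatching variants are dropped, and counts partition", {
  exp_rec <- make_records(3, effect_allele = c("A", "A", "A"),
                          other_allele = c("G", "G", "G"))
  out_rec <- make_records(2, variant_id = c("rs001", "rs002"),
                          effect_allele = c("A", "A"),
                          other_allele = c("G", "C"))
  tt <- two_tables(exp_rec, out_rec)
  h <- harmonize(tt$exposure, tt$outcome, exp_rec$variant_id)
  expect_equal(h$action, c("unchanged", "dropped_unmatched", "dropped_unmatched"))
  expect_equal(nrow(retained(h)) + sum(startsWith(h$action, "dropped")),
               length(exp_rec$variant_id))
  expect_error(harmonize(tt$exposure, tt$outcome, "rs999"),
               "not present in exposure")
  expect_error(harmonize(tt$exposure, tt$outcome, "rs001",
                         palindromic_maf_limit = 0.5), "0, 0.5")
})

test_that("harmonizing an already-harmonized pair is the identity", {
  set.seed(4)
  cfg <- sim_config(n_snps = 40, include_palindromic = TRUE, seed = 21)
  sim <- simulate_two_sample(cfg)
  h1 <- harmonize(sim$exposure, sim$outcome, sim$truth$variant_id)
  kept <- retained(h1)
  # rebuild outcome on the exposure's convention and harmonize again
  out2 <- sim$outcome
  idx <- match(kept$variant_id, out2$records$variant_id)
  out2$records <- out2$records[idx, ]
  ex_idx <- match(kept$variant_id, sim$exposure$records$variant_id)
  out2$records$effect_allele <- sim$exposure$records$effect_allele[ex_idx]
  out2$records$other_allele <- sim$exposure$records$other_allele[ex_idx]
  out2$records$beta <- kept$beta_outcome
  out2$records$eaf <- sim$exposure$records$eaf[ex_idx]
  rownames(out2$records) <- NULL
  h2 <- harmonize(sim$exposure, out2, kept$variant_id)
  expect_true(all(h2$action == "unchanged"))
  expect_equal(h2$beta_outcome, kept$beta_outcome)
})

test_that("negating every beta in both studies leaves Wald ratios unchanged", {
  cfg <- sim_config(n_snps = 25, beta_causal = 0.3, seed = 5)
  sim <- simulate_two_sample(cfg)
  h1 <- harmonize(sim$exposure, sim$outcome, sim$truth$variant_id)
  neg <- function(tab) { tab$records$beta <- -tab$records$beta; tab }
  h2 <- harmonize(neg(sim$exposure), neg(sim$outcome), sim$truth$variant_id)
  r1 <- retained(h1); r2 <- retained(h2)
  expect_equal(r2$beta_outcome / r2$beta_exposure,
               r1$beta_outcome / r1$beta_exposure)
  expect_equal(mr_ivw(h2)$estimate, mr_ivw(h1)$estimate)
})

test_that("the harmonization audit lists every requested variant", {
  cfg <- sim_config(n_snps = 10, include_palindromic = TRUE, seed = 8)
  sim <- simulate_two_sample(cfg)
  h <- harmonize(sim$exposure, sim$outcome, sim$truth$variant_id)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonization_audit(h, path)
  audit <- read.delim(path)
  expect_equal(audit$variant_id, sim$truth$variant_id)
  expect_true(all(audit$action %in% c(
    "unchanged", "sign_flipped", "strand_flipped",
    "strand_flipped_and_sign_flipped", "dropped_palindromic",
    "dropped_unmatched")))
})
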