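# Multi-exposure synthetic study fixture: files on disk plus a ready
# study_config, with the generating truth saved as a JSON sidecar.

#' Generate a complete synthetic MR study on disk
#'
#' Writes `n_exposures` exposure summary-statistics tables with mixed true
#' causal effects (strong positive/negative, weak positive/negative, and
#' null, cycling), one shared binary outcome ("IA", case fraction and
#' total size mirroring a large intracranial-aneurysm case-control GWAS:
#' 10754 cases of 317636) plus two smaller outcome strata ("SAH" for
#' ruptured, "uIA" for unruptured — same true effects, independent
#' estimation noise), an LD reference panel covering every variant
#' (AR-correlated blocks so clumping and proxy search have work to do), an
#' optional cross-trait table marking a few variants as multi-trait, and
#' the generating truth as `truth.json`. A fraction of variants is
#' withheld from the outcome tables to exercise proxy substitution. The
#' whole fixture is a deterministic function of `seed`.
#'
#' @param n_exposures number of exposure traits (>= 1).
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param snps_per_exposure variants simulated per exposure.
#' @param block_size,block_rho LD-block structure: blocks of
#'   `block_size` adjacent variants with latent AR(1) correlation
#'   `block_rho`; `snps_per_exposure` must be a multiple of `block_size`.
#' @param missing_outcome_frac fraction of variants withheld from the
#'   outcome tables.
#' @return A [study_config()] pointing at the written files, with the
#'   true causal effects attached as attribute `truth`.
#' @export
make_study_fixture <- function(n_exposures, seed, dir,
                               snps_per_exposure = 18L,
                               block_size = 3L, block_rho = 0.9,
                               missing_outcome_frac = 0.06) {
  stopifnot(n_exposures >= 1, snps_per_exposure %% block_size == 0L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  J <- as.integer(snps_per_exposure)
  blocks_per <- J %/% block_size

  # mixed true effects, log-odds per SD of exposure
  beta_pool <- c(0.5, -0.5, 0.2, -0.2, 0, 0)
  betas <- rep_len(beta_pool, n_exposures)

  outcome_specs <- list(
    IA  = list(n = 317636L, phi = 10754 / 317636),
    SAH = list(n = 250000L, phi = 0.018),
    uIA = list(n = 250000L, phi = 0.012)
  )

  exposure_rows <- data.frame(name = character(0), path = character(0),
                              trait_type = character(0), stringsAsFactors = FALSE)
  outcome_records <- stats::setNames(vector("list", length(outcome_specs)),
                                     names(outcome_specs))
  truth <- list()
  xtab_rows <- list()

  for (k in seq_len(n_exposures)) {
    ename <- sprintf("exposure_%02d", k)
    cfg <- sim_config(
      n_snps = J, maf_range = c(0.10, 0.40), gamma_sd = 0.06,
      beta_causal = betas[k], n_exposure = 200000L,
      n_outcome = outcome_specs$IA$n, outcome_type = "binary",
      case_fraction = outcome_specs$IA$phi,
      seed = as.integer((as.numeric(seed) * 10007 + k) %% 2147483629))
    sim <- simulate_two_sample(cfg, exposure_name = ename, outcome_name = "IA",
                               id_start = (k - 1L) * J + 1L)
    # strata draws continue the per-exposure RNG stream deterministically
    tr <- sim$truth
    strata <- lapply(outcome_specs[-1L], function(sp) {
      se <- .se_marginal(sp$n, tr$maf, "binary", sp$phi)
      list(by = stats::rnorm(J, tr$Gamma, se), se = se, n = sp$n)
    })
    withheld <- stats::runif(J) < missing_outcome_frac

    path <- file.path(dir, paste0(ename, ".tsv"))
    write_sumstats(sim$exposure, path)
    exposure_rows <- rbind(exposure_rows,
                           data.frame(name = ename, path = path,
                                      trait_type = "continuous",
                                      stringsAsFactors = FALSE))

    base <- sim$outcome$records[!withheld, , drop = FALSE]
    outcome_records$IA[[k]] <- base
    for (s in names(strata)) {
      st <- strata[[s]]
      rec <- sim$outcome$records
      rec$beta <- st$by
      rec$se <- st$se
      rec$pvalue <- .two_sided_p(st$by, st$se)
      rec$n <- st$n
      outcome_records[[s]][[k]] <- rec[!withheld, , drop = FALSE]
    }

    truth[[ename]] <- list(beta_causal = betas[k], variant_id = tr$variant_id,
                           gamma = tr$gamma, alpha = tr$alpha,
                           withheld_from_outcome = tr$variant_id[withheld])
    if (k %% 7L == 3L) {
      v <- tr$variant_id[1L]
      xtab_rows[[length(xtab_rows) + 1L]] <-
        data.frame(variant_id = v, trait = c(ename, "other_trait"),
                   stringsAsFactors = FALSE)
    }
  }

  outcome_rows <- data.frame(name = character(0), path = character(0),
                             trait_type = character(0), stringsAsFactors = FALSE)
  for (s in names(outcome_specs)) {
    rec <- do.call(rbind, outcome_records[[s]])
    tab <- sumstats_table(rec, trait_name = s, trait_type = "binary",
                          ancestry = "synthetic")
    path <- file.path(dir, paste0("outcome_", s, ".tsv"))
    write_sumstats(tab, path)
    outcome_rows <- rbind(outcome_rows,
                          data.frame(name = s, path = path,
                                     trait_type = "binary",
                                     stringsAsFactors = FALSE))
  }

  panel_cfg <- sim_config(
    n_snps = n_exposures * J, maf_range = c(0.10, 0.40),
    ld_blocks = rep(list(c(block_size, block_rho)), n_exposures * blocks_per),
    n_ref = 2000L, seed = as.integer(seed) %% 2147483629)
  panel <- simulate_ld_panel(panel_cfg, id_start = 1L)
  panel_path <- file.path(dir, "panel.tsv")
  write_ld_panel(panel, panel_path)

  xtab_path <- NULL
  if (length(xtab_rows)) {
    xtab_path <- file.path(dir, "cross_trait.tsv")
    .write_tsv(do.call(rbind, xtab_rows), xtab_path)
  }

  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)

  config <- study_config(exposure_rows, outcome_rows, panel_path,
                         cross_trait = xtab_path,
                         seed = as.integer(seed))
  write_study_config(config, file.path(dir, "study.yaml"))
  attr(config, "truth") <- truth
  config
}
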