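# Replicate simulation studies over the estimator suite: the package's
# own tool for verifying coverage, bias and pleiotropy sensitivity
# against the generator's ground truth.

#' Replicate estimator calibration study
#'
#' Simulates `n_reps` independent two-sample datasets from a common
#' configuration and runs the requested estimators on each, returning one
#' row per replicate and estimator with the estimate, CI, p-value and
#' (for MR-Egger) the pleiotropy intercept and its test. Instruments are
#' taken as simulated — no significance selection — so the study measures
#' the estimators themselves, not winner's curse.
#'
#' @param n_reps number of replicate datasets.
#' @param estimators subset of `c("ivw", "egger", "simple_median",
#'   "weighted_median")`.
#' @param n_boot bootstrap replicates for the median estimators.
#' @param select_p optional genome-wide significance threshold applied to
#'   the simulated exposure associations before estimation (via
#'   [filter_significant()]), to study the estimators on selected
#'   instruments — the regime MR actually operates in — including any
#'   winner's-curse effect of selecting and estimating on one sample.
#' @param seed base seed; replicate r uses `seed + r` for the data and
#'   a derived seed for the bootstrap.
#' @param ... configuration passed to [sim_config()] (e.g. `n_snps`,
#'   `beta_causal`, `pleiotropy_mode`, sample sizes).
#' @return A data.frame with columns `rep`, `method`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`, `egger_intercept`,
#'   `egger_intercept_p`, plus the true `beta_causal` as an attribute.
#' @export
mr_calibration_study <- function(n_reps, estimators = c("ivw", "egger",
                                                        "simple_median",
                                                        "weighted_median"),
                                 n_boot = 1000L, select_p = NULL,
                                 seed = 1L, ...) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  cfg_args <- list(...)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- do.call(sim_config, c(cfg_args, list(
      seed = as.integer((as.numeric(seed) + r) %% 2147483629))))
    sim <- simulate_two_sample(cfg)
    if (!is.null(select_p)) {
      keep_ids <- filter_significant(sim$exposure, select_p)
      keep <- sim$exposure$records$variant_id %in% keep_ids
      sim$exposure$records <- sim$exposure$records[keep, , drop = FALSE]
      sim$outcome$records <- sim$outcome$records[keep, , drop = FALSE]
    }
    h <- data.frame(variant_id = sim$exposure$records$variant_id,
                    beta_exposure = sim$exposure$records$beta,
                    se_exposure = sim$exposure$records$se,
                    beta_outcome = sim$outcome$records$beta,
                    se_outcome = sim$outcome$records$se,
                    stringsAsFactors = FALSE)
    out <- list()
    if ("ivw" %in% estimators) out$ivw <- mr_ivw(h)
    if ("egger" %in% estimators) {
      eg <- mr_egger(h)
      s <- eg$slope
      out$egger <- s
      attr(out$egger, "intercept") <- eg$intercept
      attr(out$egger, "intercept_p") <- eg$intercept_pvalue
    }
    bseed <- as.integer((as.numeric(seed) * 31 + r * 7 + 3) %% 2147483629)
    if ("simple_median" %in% estimators) {
      out$simple_median <- mr_median(h, "simple", n_boot = n_boot, seed = bseed)
    }
    if ("weighted_median" %in% estimators) {
      out$weighted_median <- mr_median(h, "inverse_variance",
                                       n_boot = n_boot, seed = bseed + 1L)
    }
    rows[[r]] <- do.call(rbind, lapply(names(out), function(m) {
      x <- out[[m]]
      data.frame(rep = r, method = m, estimate = x$estimate, se = x$se,
                 ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
                 egger_intercept = attr(x, "intercept") %||% NA_real_,
                 egger_intercept_p = attr(x, "intercept_p") %||% NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  res <- do.call(rbind, rows)
  attr(res, "beta_causal") <- cfg_args$beta_causal %||% 0
  res
}
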