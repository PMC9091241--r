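# Summary-level GWAS simulator with known causal effect, horizontal
# pleiotropy and LD structure.
#
# Effects live on the standardized-genotype scale: a variant with allele
# frequency f contributes variance 2 f (1 - f) per allele, which is what
# sets the standard error of its marginal association,
#   se = 1 / sqrt(2 n f (1 - f))            (continuous trait)
#   se = 1 / sqrt(2 n f (1 - f) phi (1 - phi))  (binary, log-odds scale,
#                                                case fraction phi).
# The exposure and outcome samples are non-overlapping, so estimation
# errors are independent — the defining feature of the two-sample design.

#' Simulation configuration
#'
#' Describes one two-sample MR data-generating process. Per variant j with
#' allele frequency f_j: a true exposure effect gamma_j, a direct
#' (pleiotropic) outcome effect alpha_j, and a true outcome effect
#' Gamma_j = beta_causal * gamma_j + alpha_j. Observed effects are the true
#' effects plus independent Gaussian estimation noise at the standard
#' errors implied by the sample sizes. No significance selection happens at
#' generation; winner's curse enters only through downstream instrument
#' selection, so its effect can be measured.
#'
#' @param n_snps number of variants J.
#' @param maf_range allele-frequency range, a length-2 vector inside
#'   (0, 0.5).
#' @param gamma_sd scale of true exposure effects (per standardized
#'   allele). The default keeps the total variance explained by the
#'   default 50 instruments near 12% and the mean per-variant
#'   F-statistic near 90 at the default exposure sample size — strong
#'   instruments, but with the small residual regression-dilution bias
#'   of order 1/F that any ratio-based estimator inherits.
#' @param gamma_dist `"normal"` (mean-zero, sign-symmetric) or
#'   `"halfnormal"` (all effects positive — consistently oriented
#'   instruments, as needed for a directional pleiotropy signal to survive
#'   effect-orientation conventions).
#' @param beta_causal true causal effect of exposure on outcome (log-odds
#'   units when `outcome_type = "binary"`).
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct effects centred
#'   on zero) or `"directional"` (non-zero mean).
#' @param pleiotropy_mean,pleiotropy_sd mean and sd of the direct effects
#'   alpha_j of the invalid variants. Must both be 0 when
#'   `pleiotropy_mode = "none"`; the mean must be 0 for `"balanced"`.
#' @param invalid_fraction fraction of variants given a direct effect;
#'   `round(invalid_fraction * n_snps)` variants are invalid (a warning is
#'   issued when the product is not integral).
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param case_fraction case fraction phi of the binary outcome GWAS.
#' @param ld_blocks LD structure for the genotype reference panel: a list
#'   of `c(size, rho)` pairs whose sizes sum to `n_snps`; within a block
#'   the latent correlation is AR(1), `rho^|i-j|`; blocks are independent.
#'   `NULL` means all variants independent.
#' @param n_ref reference-panel size used by [simulate_ld_panel()].
#' @param include_palindromic if `TRUE`, allele pairs are drawn from all
#'   six unordered pairs (so one third are strand-ambiguous A/T or G/C);
#'   if `FALSE` (default) only the four unambiguous pairs are used.
#' @param seed integer seed; every draw is derived from it.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 50,
                       maf_range = c(0.05, 0.45),
                       gamma_sd = 0.05,
                       gamma_dist = c("normal", "halfnormal"),
                       beta_causal = 0,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       invalid_fraction = 0,
                       n_exposure = 1e5,
                       n_outcome = 1e5,
                       outcome_type = c("continuous", "binary"),
                       case_fraction = 0.034,
                       ld_blocks = NULL,
                       n_ref = 2000,
                       include_palindromic = FALSE,
                       seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outcome_type <- match.arg(outcome_type)
  gamma_dist <- match.arg(gamma_dist)
  stopifnot(n_snps >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] < 0.5,
            maf_range[1] <= maf_range[2],
            gamma_sd > 0, pleiotropy_sd >= 0,
            invalid_fraction >= 0, invalid_fraction <= 1,
            n_exposure > 2, n_outcome > 2,
            case_fraction > 0, case_fraction < 1,
            n_ref >= 2)
  if (pleiotropy_mode == "none" && (pleiotropy_mean != 0 || pleiotropy_sd != 0)) {
    stop("pleiotropy_mode 'none' requires pleiotropy_mean = pleiotropy_sd = 0",
         call. = FALSE)
  }
  if (pleiotropy_mode == "balanced" && pleiotropy_mean != 0) {
    stop("pleiotropy_mode 'balanced' requires pleiotropy_mean = 0", call. = FALSE)
  }
  if (!is.null(ld_blocks)) {
    sizes <- vapply(ld_blocks, `[`, numeric(1), 1L)
    rhos <- vapply(ld_blocks, `[`, numeric(1), 2L)
    if (sum(sizes) != n_snps) {
      stop("ld_blocks sizes sum to ", sum(sizes), ", not n_snps = ", n_snps,
           call. = FALSE)
    }
    if (any(rhos < 0 | rhos >= 1)) stop("block rho must lie in [0, 1)", call. = FALSE)
  }
  n_invalid_raw <- invalid_fraction * n_snps
  if (abs(n_invalid_raw - round(n_invalid_raw)) > 1e-9) {
    warning(sprintf("invalid_fraction * n_snps = %.3f is not integral; rounding to %d",
                    n_invalid_raw, round(n_invalid_raw)), call. = FALSE)
  }
  structure(list(
    n_snps = as.integer(n_snps), maf_range = maf_range,
    gamma_sd = gamma_sd, gamma_dist = gamma_dist,
    beta_causal = beta_causal,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd,
    n_invalid = as.integer(round(n_invalid_raw)),
    n_exposure = as.integer(n_exposure), n_outcome = as.integer(n_outcome),
    outcome_type = outcome_type, case_fraction = case_fraction,
    ld_blocks = ld_blocks, n_ref = as.integer(n_ref),
    include_palindromic = include_palindromic,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# standard error of a marginal per-allele effect on a standardized trait
.se_marginal <- function(n, f, outcome_type = "continuous", phi = NULL) {
  v <- 2 * n * f * (1 - f)
  if (outcome_type == "binary") v <- v * phi * (1 - phi)
  1 / sqrt(v)
}

.ALLELE_PAIRS_PLAIN <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
.ALLELE_PAIRS_ALL <- c(.ALLELE_PAIRS_PLAIN, list(c("A", "T"), c("C", "G")))

.two_sided_p <- function(beta, se) {
  pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Draws allele frequencies, true effects and observed (noisy) effects per
#' the configuration, and returns exposure and outcome `sumstats` tables
#' together with the generating truth. Seeded runs are bit-reproducible.
#'
#' @param config a [sim_config()].
#' @param exposure_name,outcome_name trait labels.
#' @param id_start first variant index used to build rsID-like ids (lets a
#'   caller generate several non-overlapping variant sets).
#'
#' @return A list with elements `exposure` and `outcome` (both `sumstats`)
#'   and `truth`: a list carrying `beta_causal`, per-variant `gamma`
#'   (true exposure effects), `alpha` (direct effects), `Gamma`
#'   (true outcome effects), `maf`, `se_exposure`, `se_outcome` and the
#'   invalid-variant ids.
#' @export
simulate_two_sample <- function(config, exposure_name = "exposure",
                                outcome_name = "outcome", id_start = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  J <- config$n_snps

  f <- stats::runif(J, config$maf_range[1], config$maf_range[2])
  gamma <- stats::rnorm(J, 0, config$gamma_sd)
  if (config$gamma_dist == "halfnormal") gamma <- abs(gamma)

  alpha <- numeric(J)
  invalid <- integer(0)
  if (config$pleiotropy_mode != "none" && config$n_invalid > 0L) {
    invalid <- sort(sample.int(J, config$n_invalid))
    alpha[invalid] <- stats::rnorm(config$n_invalid, config$pleiotropy_mean,
                                   config$pleiotropy_sd)
  }
  Gamma <- config$beta_causal * gamma + alpha

  se_x <- .se_marginal(config$n_exposure, f)
  se_y <- .se_marginal(config$n_outcome, f, config$outcome_type,
                       config$case_fraction)
  bx <- stats::rnorm(J, gamma, se_x)
  by <- stats::rnorm(J, Gamma, se_y)

  idx <- seq.int(id_start, length.out = J)
  ids <- sprintf("rs%07d", idx)
  pairs <- if (config$include_palindromic) .ALLELE_PAIRS_ALL else .ALLELE_PAIRS_PLAIN
  pick <- sample.int(length(pairs), J, replace = TRUE)
  ea <- vapply(pairs[pick], `[`, character(1), 1L)
  oa <- vapply(pairs[pick], `[`, character(1), 2L)
  swap <- sample(c(TRUE, FALSE), J, replace = TRUE)
  tmp <- ea[swap]; ea[swap] <- oa[swap]; oa[swap] <- tmp

  base <- data.frame(
    variant_id = ids,
    chrom = as.character((idx - 1L) %% 22L + 1L),
    pos = idx * 5000L,
    effect_allele = ea, other_allele = oa, eaf = f,
    stringsAsFactors = FALSE
  )
  exposure <- sumstats_table(
    cbind(base, data.frame(beta = bx, se = se_x,
                           pvalue = .two_sided_p(bx, se_x),
                           n = config$n_exposure)),
    trait_name = exposure_name, trait_type = "continuous",
    ancestry = "synthetic")
  outcome <- sumstats_table(
    cbind(base, data.frame(beta = by, se = se_y,
                           pvalue = .two_sided_p(by, se_y),
                           n = config$n_outcome)),
    trait_name = outcome_name, trait_type = config$outcome_type,
    ancestry = "synthetic")

  list(exposure = exposure, outcome = outcome,
       truth = list(beta_causal = config$beta_causal,
                    variant_id = ids, maf = f, gamma = gamma, alpha = alpha,
                    Gamma = Gamma, se_exposure = se_x, se_outcome = se_y,
                    invalid_ids = ids[invalid]))
}

#' Simulate an LD reference panel
#'
#' Draws `n_ref` diploid genotypes at the configured variants. Each
#' haplotype is a latent Gaussian vector with AR(1) correlation
#' `rho^|i-j|` inside each LD block (blocks independent), thresholded at
#' each variant's allele frequency; the dosage is the sum of the two
#' haplotype alleles, so Hardy-Weinberg holds per variant. Squared
#' correlations are computed empirically from the dosages.
#'
#' @param config a [sim_config()]; `ld_blocks`, `n_ref`, `maf_range` and
#'   `seed` are used. The variant ids (and allele frequencies) match what
#'   [simulate_two_sample()] generates from the same configuration.
#' @param id_start as in [simulate_two_sample()].
#'
#' @return An object of class `ld_panel`: a list with `ids`, `r2`
#'   (symmetric J x J matrix, unit diagonal) and `dosage`
#'   (`n_ref` x J integer matrix, values 0/1/2).
#' @export
simulate_ld_panel <- function(config, id_start = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  J <- config$n_snps
  f <- stats::runif(J, config$maf_range[1], config$maf_range[2])

  blocks <- config$ld_blocks
  if (is.null(blocks)) blocks <- lapply(seq_len(J), function(i) c(1, 0))

  # derive a separate deterministic stream for the panel so panel and
  # summary statistics can share a config without sharing draws
  set.seed((config$seed + 777L) %% .Machine$integer.max)
  n <- config$n_ref
  dosage <- matrix(0L, n, J)
  col <- 1L
  for (b in blocks) {
    m <- as.integer(b[1]); rho <- b[2]
    hap <- function() {
      z <- matrix(stats::rnorm(n * m), n, m)
      if (m > 1L && rho > 0) {
        for (j in 2:m) z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
      }
      z
    }
    q <- stats::qnorm(f[col:(col + m - 1L)])
    a1 <- sweep(hap(), 2L, q, `<`)
    a2 <- sweep(hap(), 2L, q, `<`)
    dosage[, col:(col + m - 1L)] <- a1 + a2
    col <- col + m
  }
  ids <- sprintf("rs%07d", seq.int(id_start, length.out = J))
  colnames(dosage) <- ids

  cc <- suppressWarnings(stats::cor(dosage))
  cc[!is.finite(cc)] <- 0  # monomorphic columns: no usable correlation
  r2 <- cc^2
  diag(r2) <- 1
  dimnames(r2) <- list(ids, ids)

  structure(list(ids = ids, r2 = r2, dosage = dosage), class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("LD panel: %d variants%s\n", length(x$ids),
              if (!is.null(x$dosage)) sprintf(", %d reference genotypes", nrow(x$dosage)) else ""))
  invisible(x)
}

#' Write / read an LD panel r2 matrix as TSV
#'
#' The matrix is written with an id header row and id first column. The
#' dosage matrix, when present, is written alongside with suffix
#' `_dosage.tsv`.
#'
#' @param panel an `ld_panel`.
#' @param path output path for the r2 matrix.
#' @return `path`, invisibly.
#' @export
write_ld_panel <- function(panel, path) {
  stopifnot(inherits(panel, "ld_panel"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("variant_id", panel$ids), collapse = "\t"), con)
  lines <- vapply(seq_along(panel$ids), function(i) {
    paste(c(panel$ids[i], sprintf("%.10g", panel$r2[i, ])), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  if (!is.null(panel$dosage)) {
    dpath <- sub("\\.tsv$", "", path)
    dpath <- paste0(dpath, "_dosage.tsv")
    dcon <- file(dpath, "w")
    writeLines(paste(panel$ids, collapse = "\t"), dcon)
    writeLines(apply(panel$dosage, 1L, paste, collapse = "\t"), dcon)
    close(dcon)
  }
  invisible(path)
}

#' @rdname write_ld_panel
#' @param path path to an r2 TSV written by [write_ld_panel()].
#' @return `read_ld_panel`: an `ld_panel` (with dosages if the sidecar
#'   file exists).
#' @export
read_ld_panel <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = 1L)
  r2 <- as.matrix(tab)
  ids <- rownames(r2)
  colnames(r2) <- ids
  dpath <- paste0(sub("\\.tsv$", "", path), "_dosage.tsv")
  dosage <- NULL
  if (file.exists(dpath)) {
    dosage <- as.matrix(utils::read.table(dpath, header = TRUE, sep = "\t",
                                          check.names = FALSE))
    colnames(dosage) <- ids
  }
  structure(list(ids = ids, r2 = r2, dosage = dosage), class = "ld_panel")
}
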