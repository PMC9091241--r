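# Instrument-strength and sensitivity diagnostics.

#' Variance explained by a single variant
#'
#' r2 = beta^2 / (se^2 * (n - 2) + beta^2): the fraction of exposure
#' variance explained by one variant, recovered from its summary
#' statistics alone (it is the squared correlation implied by the t
#' statistic of the association).
#'
#' @param beta,se association effect and standard error (se > 0).
#' @param n GWAS sample size (> 2).
#' @return r2 in \[0, 1).
#' @export
snp_r2 <- function(beta, se, n) {
  stopifnot(se > 0)
  if (any(n <= 2)) stop("n must exceed 2", call. = FALSE)
  beta^2 / (se^2 * (n - 2) + beta^2)
}

#' Total variance explained by an instrument set
#'
#' Sum of per-variant r2 values. Additivity assumes the instruments are
#' approximately independent, which holds after LD clumping; on invalid
#' input the raw sum can reach 1, so the result is clamped just below 1
#' with a warning.
#'
#' @param beta,se vectors of association effects and SEs.
#' @param n sample size(s), scalar or per-variant.
#' @return Total r2 in \[0, 1). Empty input gives 0.
#' @export
total_r2 <- function(beta, se, n) {
  if (length(beta) == 0L) return(0)
  r2 <- sum(snp_r2(beta, se, n))
  if (r2 >= 1) {
    warning("summed r2 >= 1; clamping — instruments are unlikely to be independent",
            call. = FALSE)
    r2 <- 1 - 1e-9
  }
  r2
}

#' F-statistic for instrument strength
#'
#' F = r2 (n - k - 1) / (k (1 - r2)) for k instruments jointly explaining
#' r2 of the exposure in a sample of size n. Values above ~10 are the
#' conventional indication that weak-instrument bias is negligible.
#'
#' @param r2_total total variance explained, in \[0, 1).
#' @param n exposure GWAS sample size.
#' @param k number of instruments.
#' @return F >= 0.
#' @export
f_statistic <- function(r2_total, n, k) {
  if (!(r2_total >= 0 && r2_total < 1)) stop("r2_total must lie in [0, 1)", call. = FALSE)
  if (!(k >= 1)) stop("k must be at least 1", call. = FALSE)
  if (!(n > k + 1)) stop("n must exceed k + 1", call. = FALSE)
  r2_total * (n - k - 1) / (k * (1 - r2_total))
}

#' Instrument diagnostics for a harmonized set
#'
#' Per-variant and total variance explained plus the F-statistic, using
#' per-variant exposure sample sizes when supplied (falling back to
#' `n_fallback`, e.g. the exposure GWAS maximum, where missing).
#'
#' @param hset a `harmonized_set`.
#' @param n per-variant exposure sample sizes (recycled if scalar).
#' @param n_fallback sample size used where `n` is missing.
#' @return A list with `r2_j`, `r2_total`, `f_stat`, `n` (the size used
#'   for F: the maximum of the per-variant values), `k`.
#' @export
instrument_diagnostics <- function(hset, n, n_fallback = max(n, na.rm = TRUE)) {
  d <- .instruments(hset)
  k <- length(d$bx)
  n <- rep_len(as.numeric(n), k)
  n[is.na(n)] <- n_fallback
  r2_j <- snp_r2(d$bx, d$sx, n)
  r2_tot <- total_r2(d$bx, d$sx, n)
  nf <- max(n)
  list(r2_j = r2_j, r2_total = r2_tot,
       f_stat = f_statistic(r2_tot, nf, k), n = nf, k = k)
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the IVW estimate excluding each variant in turn. A variant
#' is flagged as possibly driving the association when the full-set
#' p-value is below `threshold` but rises to or above it on that
#' variant's exclusion. With two variants each leave-one-out result is
#' the remaining variant's Wald ratio (fixed-effect IVW).
#'
#' @param hset a `harmonized_set` with >= 2 retained variants.
#' @param threshold significance threshold for flagging (default 0.05).
#' @param model IVW model, as in [mr_ivw()]; single-variant subsets fall
#'   back to the fixed-effect model.
#' @return An object of class `loo_result`: list with `full` (the
#'   full-set `mr_result`), `results` (data.frame: excluded_id, estimate,
#'   se, pvalue, flag) and `flagged` (character vector of flagged ids).
#' @export
leave_one_out <- function(hset, threshold = 0.05,
                          model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  d <- .instruments(hset)
  J <- length(d$bx)
  if (J < 2L) stop("leave-one-out requires at least 2 SNPs", call. = FALSE)
  sub_model <- function(nj) if (nj < 2L) "fixed" else model
  full <- mr_ivw(hset, model = sub_model(J))
  df <- if (inherits(hset, "harmonized_set")) retained(hset) else as.data.frame(hset)
  rows <- lapply(seq_len(J), function(j) {
    sub <- df[-j, , drop = FALSE]
    attr(sub, "outcome_type") <- attr(hset, "outcome_type")
    r <- mr_ivw(sub, model = sub_model(J - 1L))
    data.frame(excluded_id = d$ids[j], estimate = r$estimate, se = r$se,
               pvalue = r$pvalue, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$flag <- full$pvalue < threshold & res$pvalue >= threshold
  structure(list(full = full, results = res,
                 flagged = res$excluded_id[res$flag]),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("Leave-one-out over %d SNPs; full estimate %.4g (p = %.3g)\n",
              nrow(x$results), x$full$estimate, x$full$pvalue))
  if (length(x$flagged)) {
    cat("  possibly driven by:", paste(x$flagged, collapse = ", "), "\n")
  } else {
    cat("  no single variant drives the association\n")
  }
  invisible(x)
}
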