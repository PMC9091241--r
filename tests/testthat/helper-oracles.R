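# Independent oracles and small builders shared across tests. The
# oracles deliberately use different code paths (lm fits, explicit
# scans) than the package implementations they check.

# weighted least squares through the origin, via lm
oracle_wls_origin <- function(bx, by, sy) {
  unname(coef(lm(by ~ 0 + bx, weights = 1 / sy^2)))
}

# weighted regression with intercept, via lm
oracle_wls_line <- function(x, y, w) {
  unname(coef(lm(y ~ x, weights = w)))  # (intercept, slope)
}

# weighted median by an explicit scan over cumulative mid-weights
oracle_weighted_median <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  p <- numeric(length(w))
  s <- 0
  for (j in seq_along(w)) {
    p[j] <- s + w[j] / 2
    s <- s + w[j]
  }
  if (0.5 <= p[1]) return(theta[1])
  if (0.5 >= p[length(p)]) return(theta[length(theta)])
  for (j in seq_len(length(p) - 1)) {
    if (p[j] <= 0.5 && 0.5 < p[j + 1]) {
      return(theta[j] + (theta[j + 1] - theta[j]) * (0.5 - p[j]) / (p[j + 1] - p[j]))
    }
  }
  stop("unreachable")
}

# brute-force greedy clump: explicit accept/discard loop over a sorted
# copy, written without the package's vectorized pruning
oracle_clump <- function(ids, pvalues, r2, thr) {
  ord <- order(pvalues, ids)
  pool <- ids[ord]
  kept <- character(0)
  discarded <- character(0)
  for (v in pool) {
    if (v %in% discarded) next
    kept <- c(kept, v)
    for (u in pool) {
      if (u != v && !(u %in% kept) && r2[v, u] >= thr) {
        discarded <- union(discarded, u)
      }
    }
  }
  kept
}

# random symmetric r2 matrix with unit diagonal
random_r2 <- function(n, ids = sprintf("rs%03d", seq_len(n))) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

panel_from_r2 <- function(r2, dosage = NULL) {
  structure(list(ids = rownames(r2), r2 = r2, dosage = dosage),
            class = "ld_panel")
}

# plain instrument table usable by the estimators
make_hset <- function(bx, sx, by, sy, binary = FALSE,
                      ids = sprintf("rs%03d", seq_along(bx))) {
  df <- data.frame(variant_id = ids, beta_exposure = bx, se_exposure = sx,
                   beta_outcome = by, se_outcome = sy,
                   stringsAsFactors = FALSE)
  attr(df, "outcome_type") <- if (binary) "binary" else "continuous"
  df
}

# instrument table straight out of simulate_two_sample (same allele
# orientation in both tables, so no harmonization actions are needed)
hset_from_sim <- function(sim) {
  make_hset(sim$exposure$records$beta, sim$exposure$records$se,
            sim$outcome$records$beta, sim$outcome$records$se,
            binary = sim$outcome$trait_type == "binary",
            ids = sim$exposure$records$variant_id)
}

# minimal valid records data.frame
make_records <- function(n = 3, variant_id = sprintf("rs%03d", seq_len(n)),
                         effect_allele = rep("A", n), other_allele = rep("G", n),
                         eaf = rep(0.3, n), beta = seq_len(n) / 100,
                         se = rep(0.01, n), pvalue = rep(1e-4, n),
                         n_samples = rep(10000L, n)) {
  data.frame(variant_id = variant_id, chrom = rep("1", n), pos = seq_len(n) * 1000L,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n_samples,
             stringsAsFactors = FALSE)
}
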