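# Causal-effect estimators for two-sample MR: Wald ratio, IVW meta-
# analysis, MR-Egger regression, simple/weighted median, multivariable MR.
#
# Notation: per harmonized variant j, bx_j (se sx_j) is the exposure
# association and by_j (se sy_j) the outcome association; the Wald ratio
# is theta_j = by_j / bx_j with first-order SE |sy_j / bx_j|.

.CI_Z <- 1.96  # Gaussian 95% multiplier for ivw/median CIs

# extract retained instruments from a harmonized_set (or any data.frame
# with the harmonized columns)
.instruments <- function(hset) {
  df <- if (inherits(hset, "harmonized_set")) retained(hset) else as.data.frame(hset)
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  stopifnot(all(need %in% names(df)))
  list(ids = if ("variant_id" %in% names(df)) df$variant_id else
         sprintf("snp%d", seq_len(nrow(df))),
       bx = df$beta_exposure, sx = df$se_exposure,
       by = df$beta_outcome, sy = df$se_outcome,
       binary = identical(attr(hset, "outcome_type"), "binary"))
}

.mr_result <- function(method, estimate, se, pvalue, n_snps, ci_low, ci_high,
                       binary = FALSE) {
  res <- list(method = method, estimate = estimate, se = se,
              ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
              n_snps = as.integer(n_snps))
  if (binary) {
    res$or <- exp(estimate)
    res$or_ci_low <- exp(ci_low)
    res$or_ci_high <- exp(ci_high)
  }
  structure(res, class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method, x$n_snps))
  cat(sprintf("  estimate %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$estimate, x$se, x$ci_low, x$ci_high, x$pvalue))
  if (!is.null(x$or)) {
    cat(sprintf("  OR %.3f, 95%% CI [%.3f, %.3f]\n",
                x$or, x$or_ci_low, x$or_ci_high))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, estimate = x$estimate,
             se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
             pvalue = x$pvalue,
             or = if (is.null(x$or)) NA_real_ else x$or,
             or_ci_low = if (is.null(x$or)) NA_real_ else x$or_ci_low,
             or_ci_high = if (is.null(x$or)) NA_real_ else x$or_ci_high,
             stringsAsFactors = FALSE)
}

#' Wald ratio estimate for a single variant
#'
#' theta = by / bx with first-order (delta-method) standard error
#' `|sy / bx|`; the uncertainty of the exposure association is ignored at
#' first order.
#'
#' @param gx exposure association, numeric `c(beta, se)`.
#' @param gy outcome association, numeric `c(beta, se)`.
#' @param variant_id optional id carried through.
#' @return A list with `variant_id`, `theta_j`, `se_j`.
#' @export
wald_ratio <- function(gx, gy, variant_id = NA_character_) {
  stopifnot(length(gx) == 2, length(gy) == 2)
  if (gx[1] == 0) stop("exposure beta is zero: Wald ratio undefined", call. = FALSE)
  list(variant_id = variant_id,
       theta_j = unname(gy[1] / gx[1]),
       se_j = unname(abs(gy[2] / gx[1])))
}

#' Inverse-variance-weighted MR estimate
#'
#' The primary two-sample MR estimator: pooled causal effect
#' `theta = sum(bx * by / sy^2) / sum(bx^2 / sy^2)`, i.e. weighted
#' regression of outcome on exposure associations through the origin —
#' algebraically the inverse-variance pooling of per-variant Wald ratios
#' with first-order SEs. The fixed-effect SE is
#' `(sum(bx^2 / sy^2))^(-1/2)`; the multiplicative random-effects model
#' (default) inflates it by `max(1, sqrt(Q / (J - 1)))` where Q is the
#' heterogeneity statistic `sum((by - theta * bx)^2 / sy^2)`, never
#' shrinking below the fixed-effect SE. 95% CI uses the Gaussian
#' multiplier; p-value is two-sided Gaussian.
#'
#' @param hset a `harmonized_set` (retained rows are used) or data.frame
#'   with columns `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`.
#' @param model `"multiplicative_random"` (default; needs >= 2 variants)
#'   or `"fixed"` (>= 1).
#' @return An `mr_result` with method `ivw_mre` or `ivw_fe`; for binary
#'   outcomes also the odds ratio `exp(estimate)` with exponentiated CI.
#' @export
mr_ivw <- function(hset, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  d <- .instruments(hset)
  J <- length(d$bx)
  if (model == "fixed" && J < 1L) stop("IVW requires at least 1 SNP", call. = FALSE)
  if (model == "multiplicative_random" && J < 2L) {
    stop("multiplicative random-effects IVW requires at least 2 SNPs", call. = FALSE)
  }
  w <- 1 / d$sy^2
  theta <- sum(w * d$bx * d$by) / sum(w * d$bx^2)
  se_fe <- 1 / sqrt(sum(w * d$bx^2))
  if (model == "multiplicative_random") {
    Q <- sum(w * (d$by - theta * d$bx)^2)
    se <- se_fe * max(1, sqrt(Q / (J - 1)))
    method <- "ivw_mre"
  } else {
    se <- se_fe
    method <- "ivw_fe"
  }
  p <- .two_sided_p(theta, se)
  .mr_result(method, theta, se, p, J,
             theta - .CI_Z * se, theta + .CI_Z * se, d$binary)
}

# weighted linear regression with intercept, closed form; weights w.
# Returns coef, unscaled covariance factors and the residual scale with
# its floor at 1 (never more precise than the fixed-weight model).
.wls_line <- function(x, y, w) {
  W <- sum(w)
  xb <- sum(w * x) / W
  yb <- sum(w * y) / W
  Sxx <- sum(w * (x - xb)^2)
  if (Sxx <= 0) stop("degenerate regression: no variation in exposure effects",
                     call. = FALSE)
  slope <- sum(w * (x - xb) * (y - yb)) / Sxx
  intercept <- yb - slope * xb
  resid <- y - intercept - slope * x
  J <- length(x)
  sigma2 <- sum(w * resid^2) / (J - 2L)
  scale <- max(1, sqrt(sigma2))
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(1 / Sxx) * scale,
       se_intercept = sqrt(1 / W + xb^2 / Sxx) * scale,
       df = J - 2L)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure associations *with* an
#' intercept, after orienting every variant so its exposure effect is
#' non-negative (both betas negated where needed — required for the
#' intercept to be identifiable). The slope is the pleiotropy-adjusted
#' causal estimate (consistent under InSIDE); a non-zero intercept is the
#' signature of directional horizontal pleiotropy. SEs come from the
#' weighted-regression covariance scaled by `max(1, residual scale)`;
#' p-values use a t distribution on J - 2 degrees of freedom, and the
#' slope CI uses the matching t quantile.
#'
#' @inheritParams mr_ivw
#' @return An object of class `mr_egger_result`: list with `slope` (an
#'   `mr_result`), `intercept`, `intercept_se`, `intercept_pvalue`.
#' @export
mr_egger <- function(hset) {
  d <- .instruments(hset)
  J <- length(d$bx)
  if (J < 3L) stop("MR-Egger requires at least 3 SNPs", call. = FALSE)
  flip <- d$bx < 0
  bx <- abs(d$bx)
  by <- ifelse(flip, -d$by, d$by)
  w <- 1 / d$sy^2
  fit <- .wls_line(bx, by, w)
  tcrit <- stats::qt(0.975, fit$df)
  slope_p <- 2 * stats::pt(-abs(fit$slope / fit$se_slope), fit$df)
  int_p <- max(2 * stats::pt(-abs(fit$intercept / fit$se_intercept), fit$df),
               .Machine$double.xmin)
  slope <- .mr_result("egger", fit$slope, fit$se_slope,
                      max(slope_p, .Machine$double.xmin), J,
                      fit$slope - tcrit * fit$se_slope,
                      fit$slope + tcrit * fit$se_slope, d$binary)
  structure(list(slope = slope, intercept = fit$intercept,
                 intercept_se = fit$se_intercept, intercept_pvalue = int_p),
            class = "mr_egger_result")
}

#' @export
print.mr_egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept %.4g (se %.4g), p = %.3g\n",
              x$intercept, x$intercept_se, x$intercept_pvalue))
  invisible(x)
}

# weighted median by cumulative mid-weight interpolation; w need not be
# normalized
.weighted_median <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1L]) return(theta[1L])
  J <- length(theta)
  if (0.5 >= p[J]) return(theta[J])
  k <- findInterval(0.5, p)
  theta[k] + (theta[k + 1L] - theta[k]) * (0.5 - p[k]) / (p[k + 1L] - p[k])
}

#' Simple and weighted median MR estimators
#'
#' Computes per-variant Wald ratios, orders them, and takes the weighted
#' median by linear interpolation of the cumulative mid-weights
#' `p_j = (S_j - w_j/2) / S_J` at probability 0.5. Weights are equal
#' (`simple`) or proportional to the inverse Wald-ratio variance
#' (`inverse_variance`). The estimator is consistent when under half of
#' the weight comes from invalid instruments. The SE is a parametric
#' bootstrap: exposure and outcome associations are resampled from
#' Gaussians at their observed values and SEs, the weighted median of
#' the resampled ratios is recomputed `n_boot` times (weights held at
#' their observed values, the standard convention), and the SE is the
#' standard deviation of the bootstrap estimates. CI and p-value are
#' Gaussian.
#'
#' @inheritParams mr_ivw
#' @param weighting `"simple"` or `"inverse_variance"`.
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed seed for the bootstrap; explicit so results are
#'   reproducible.
#' @return An `mr_result` with method `simple_median` or
#'   `weighted_median`.
#' @export
mr_median <- function(hset, weighting = c("simple", "inverse_variance"),
                      n_boot = 1000L, seed = 1L) {
  weighting <- match.arg(weighting)
  d <- .instruments(hset)
  J <- length(d$bx)
  if (J < 3L) stop("median estimators require at least 3 SNPs", call. = FALSE)
  if (n_boot < 100L) stop("n_boot must be at least 100", call. = FALSE)

  w <- if (weighting == "simple") rep(1 / J, J) else (d$bx / d$sy)^2
  est <- .weighted_median(d$by / d$bx, w)

  set.seed(as.integer(seed))
  bxs <- matrix(stats::rnorm(J * n_boot, d$bx, d$sx), J, n_boot)
  bys <- matrix(stats::rnorm(J * n_boot, d$by, d$sy), J, n_boot)
  boots <- vapply(seq_len(n_boot), function(b) {
    .weighted_median(bys[, b] / bxs[, b], w)
  }, numeric(1))
  se <- stats::sd(boots)
  p <- .two_sided_p(est, se)
  method <- if (weighting == "simple") "simple_median" else "weighted_median"
  .mr_result(method, est, se, p, J,
             est - .CI_Z * se, est + .CI_Z * se, d$binary)
}

#' Multivariable MR
#'
#' Joint direct effects of K exposures from shared instruments: weighted
#' multivariable regression of the outcome associations on the J x K
#' matrix of exposure associations, no intercept, weights `1 / sy^2`.
#' Per-exposure SEs come from the weighted covariance scaled by
#' `max(1, residual scale)`; p-values and CIs use a t distribution on
#' J - K degrees of freedom. With K = 1 the point estimate and SE equal
#' the univariable multiplicative random-effects IVW.
#'
#' @param beta_exposures J x K numeric matrix of exposure associations
#'   (one column per exposure), harmonized to one allele convention.
#' @param beta_outcome,se_outcome outcome associations and SEs, length J.
#' @param exposure_names optional column labels.
#' @param outcome_binary report odds ratios alongside log-odds estimates.
#' @return A list of `mr_result`, one per exposure, named.
#' @export
mr_mvmr <- function(beta_exposures, beta_outcome, se_outcome,
                    exposure_names = colnames(beta_exposures),
                    outcome_binary = FALSE) {
  X <- as.matrix(beta_exposures)
  J <- nrow(X); K <- ncol(X)
  stopifnot(length(beta_outcome) == J, length(se_outcome) == J)
  if (J <= K) stop("multivariable MR requires more SNPs than exposures (J > K)",
                   call. = FALSE)
  if (qr(X)$rank < K) stop("exposure-effect matrix is rank deficient", call. = FALSE)
  if (is.null(exposure_names)) exposure_names <- sprintf("exposure%d", seq_len(K))

  w <- 1 / se_outcome^2
  XtWX <- crossprod(X, X * w)
  est <- unname(drop(solve(XtWX, crossprod(X, beta_outcome * w))))
  resid <- beta_outcome - drop(X %*% est)
  sigma2 <- sum(w * resid^2) / (J - K)
  scale <- max(1, sqrt(sigma2))
  ses <- unname(sqrt(diag(solve(XtWX)))) * scale
  df <- J - K
  tcrit <- stats::qt(0.975, df)
  out <- lapply(seq_len(K), function(k) {
    p <- max(2 * stats::pt(-abs(est[k] / ses[k]), df), .Machine$double.xmin)
    .mr_result("mvmr", est[k], ses[k], p, J,
               est[k] - tcrit * ses[k], est[k] + tcrit * ses[k],
               outcome_binary)
  })
  names(out) <- exposure_names
  out
}
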