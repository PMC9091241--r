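# The causal-effect estimator suite.

test_that("Wald ratio arithmetic and degenerate input", {
  r <- wald_ratio(c(0.10, 0.01), c(0.05, 0.02))
  expect_equal(r$theta_j, 0.5)
  expect_equal(r$se_j, 0.2)
  r2 <- wald_ratio(c(0.10, 0.01), c(0, 0.02))
  expect_equal(r2$theta_j, 0)
  expect_equal(r2$se_j, 0.2)
  r3 <- wald_ratio(c(-0.2, 0.01), c(0.04, 0.05))
  expect_equal(r3$theta_j, -0.2)
  expect_equal(r3$se_j, 0.25)
  expect_error(wald_ratio(c(0, 0.01), c(0.1, 0.2)), "zero")
})

test_that("IVW reduces to the Wald ratio at one SNP and is exact on homogeneity", {
  h1 <- make_hset(0.1, 0.01, 0.05, 0.02)
  ivw1 <- mr_ivw(h1, model = "fixed")
  w <- wald_ratio(c(0.1, 0.01), c(0.05, 0.02))
  expect_equal(ivw1$estimate, w$theta_j)
  expect_equal(ivw1$se, w$se_j)
  expect_error(mr_ivw(h1, model = "multiplicative_random"), "at least 2")

  # all Wald ratios equal: the pooled estimate is that ratio and Q = 0,
  # so the random-effects SE floors at the fixed-effect SE
  bx <- c(0.1, 0.2, 0.4); by <- 0.5 * bx
  h <- make_hset(bx, rep(0.01, 3), by, c(0.01, 0.02, 0.015))
  fe <- mr_ivw(h, "fixed"); re <- mr_ivw(h, "multiplicative_random")
  expect_equal(fe$estimate, 0.5)
  expect_equal(re$estimate, 0.5)
  expect_equal(re$se, fe$se)
})

test_that("IVW equals the weighted-regression-through-origin oracle", {
  h <- make_hset(c(0.1, 0.2, 0.3), rep(0.01, 3),
                 c(0.02, 0.06, 0.03), c(0.01, 0.02, 0.015))
  expect_equal(mr_ivw(h, "fixed")$estimate,
               oracle_wls_origin(c(0.1, 0.2, 0.3), c(0.02, 0.06, 0.03),
                                 c(0.01, 0.02, 0.015)),
               tolerance = 1e-12)
  # random-effects never narrower than fixed, same point estimate
  set.seed(1)
  for (i in 1:20) {
    J <- sample(2:12, 1)
    h <- make_hset(rnorm(J, 0, 0.1), runif(J, 0.005, 0.02),
                   rnorm(J, 0, 0.05), runif(J, 0.005, 0.03))
    fe <- mr_ivw(h, "fixed"); re <- mr_ivw(h, "multiplicative_random")
    expect_equal(re$estimate, fe$estimate)
    expect_gte(re$se, fe$se)
    expect_true(re$ci_low < re$estimate && re$estimate < re$ci_high)
  }
})

test_that("MR-Egger recovers an exact linear relation and needs 3 SNPs", {
  bx <- c(0.05, 0.10, 0.15, 0.20, 0.25)
  by <- 0.01 + 0.3 * bx
  h <- make_hset(bx, rep(0.01, 5), by, c(0.01, 0.02, 0.01, 0.03, 0.02))
  e <- mr_egger(h)
  expect_equal(e$slope$estimate, 0.3, tolerance = 1e-12)
  expect_equal(e$intercept, 0.01, tolerance = 1e-12)
  expect_gt(e$slope$se, 0)  # residual factor floored, never zero SE
  expect_error(mr_egger(make_hset(bx[1:2], 0.01, by[1:2], 0.01)), "at least 3")
})

test_that("MR-Egger is invariant to reported allele orientation", {
  set.seed(2)
  J <- 15
  bx <- rnorm(J, 0, 0.1); by <- 0.02 + 0.4 * bx + rnorm(J, 0, 0.01)
  sy <- runif(J, 0.005, 0.02)
  h1 <- make_hset(bx, 0.01, by, sy)
  flip <- rbinom(J, 1, 0.5) == 1
  h2 <- make_hset(ifelse(flip, -bx, bx), 0.01, ifelse(flip, -by, by), sy)
  e1 <- mr_egger(h1); e2 <- mr_egger(h2)
  expect_equal(e2$slope$estimate, e1$slope$estimate)
  expect_equal(e2$intercept, e1$intercept)
  expect_equal(e2$intercept_se, e1$intercept_se)
})

test_that("median estimators interpolate cumulative mid-weights", {
  # odd J, equal weights: the middle ratio
  h <- make_hset(c(1, 1, 1), 0.01, c(0.1, 0.2, 0.9), 0.01)
  m <- mr_median(h, "simple", n_boot = 200, seed = 1)
  expect_equal(m$estimate, 0.2)
  # identical ratios: estimate is that ratio, bootstrap se small but > 0
  h2 <- make_hset(c(0.1, 0.2, 0.4), 0.001, c(0.05, 0.10, 0.20), 0.001)
  m2 <- mr_median(h2, "inverse_variance", n_boot = 200, seed = 1)
  expect_equal(m2$estimate, 0.5, tolerance = 1e-9)
  expect_gt(m2$se, 0); expect_lt(m2$se, 0.05)
  expect_error(mr_median(h, "simple", n_boot = 50, seed = 1), "at least 100")
  expect_error(mr_median(make_hset(1, 0.1, 1, 0.1), "simple"), "at least 3")
})

test_that("the weighted median matches the interpolation oracle", {
  # ratios (0.0, 0.1, 0.2, 0.9) with weights (1, 1, 3, 1)
  bx <- rep(1, 4); sy <- 1 / sqrt(c(1, 1, 3, 1))
  by <- c(0.0, 0.1, 0.2, 0.9)
  h <- make_hset(bx, 0.01, by, sy)
  m <- mr_median(h, "inverse_variance", n_boot = 200, seed = 1)
  expect_equal(m$estimate, oracle_weighted_median(by, c(1, 1, 3, 1)),
               tolerance = 1e-12)
  set.seed(9)
  for (i in 1:50) {
    J <- sample(3:12, 1)
    theta <- rnorm(J); w <- runif(J, 0.1, 2)
    h <- make_hset(rep(1, J), 0.01, theta, 1 / sqrt(w))
    m <- mr_median(h, "inverse_variance", n_boot = 200, seed = i)
    expect_equal(m$estimate, oracle_weighted_median(theta, w), tolerance = 1e-12)
  }
})

test_that("equal-weight weighted median coincides with the simple median", {
  set.seed(5)
  J <- 9
  bx <- rnorm(J, 0.2, 0.05)
  h_eq <- make_hset(bx, 0.01, rnorm(J, 0.1, 0.02), abs(bx) * 0.37)
  # identical ratio weights: se_j^-2 proportional to a constant
  m_w <- mr_median(h_eq, "inverse_variance", n_boot = 200, seed = 4)
  m_s <- mr_median(h_eq, "simple", n_boot = 200, seed = 4)
  expect_equal(m_w$estimate, m_s$estimate, tolerance = 1e-12)
})

test_that("estimators are scale-equivariant in the exposure units", {
  set.seed(6)
  J <- 12
  h <- make_hset(rnorm(J, 0.1, 0.05), runif(J, 0.005, 0.02),
                 rnorm(J, 0.05, 0.02), runif(J, 0.005, 0.02))
  c0 <- 2.5
  h2 <- h
  h2$beta_exposure <- h$beta_exposure * c0
  h2$se_exposure <- h$se_exposure * c0
  expect_equal(mr_ivw(h2)$estimate, mr_ivw(h)$estimate / c0)
  expect_equal(mr_egger(h2)$slope$estimate, mr_egger(h)$slope$estimate / c0)
  expect_equal(mr_median(h2, "inverse_variance", n_boot = 300, seed = 2)$estimate,
               mr_median(h, "inverse_variance", n_boot = 300, seed = 2)$estimate / c0,
               tolerance = 1e-10)
})

test_that("binary outcomes carry a consistent odds-ratio scale", {
  h <- make_hset(c(0.1, 0.2, 0.3), 0.01, c(0.05, 0.1, 0.14), 0.02,
                 binary = TRUE)
  r <- mr_ivw(h)
  expect_equal(log(r$or), r$estimate, tolerance = 1e-12)
  expect_equal(r$or_ci_low, exp(r$ci_low))
  expect_equal(r$or_ci_high, exp(r$ci_high))
})

test_that("multivariable MR decouples orthogonal exposures and checks rank", {
  # K = 1 reduces exactly to univariable random-effects IVW
  set.seed(8)
  J <- 10
  bx <- rnorm(J, 0.1, 0.05); by <- 0.3 * bx + rnorm(J, 0, 0.02)
  sy <- runif(J, 0.01, 0.03)
  uni <- mr_ivw(make_hset(bx, 0.01, by, sy), "multiplicative_random")
  mv <- mr_mvmr(matrix(bx, ncol = 1), by, sy)[[1]]
  expect_equal(mv$estimate, uni$estimate, tolerance = 1e-12)
  expect_equal(mv$se, uni$se, tolerance = 1e-12)

  # orthogonal exposure columns: each joint estimate equals its own
  # univariable IVW (weights equal so the cross-terms vanish)
  x1 <- c(rnorm(5, 0.2, 0.03), rep(0, 5))
  x2 <- c(rep(0, 5), rnorm(5, 0.15, 0.03))
  sy2 <- rep(0.02, J)
  y <- 0.5 * x1 - 0.3 * x2 + rnorm(J, 0, 0.01)
  mv2 <- mr_mvmr(cbind(a = x1, b = x2), y, sy2)
  u1 <- mr_ivw(make_hset(x1[1:5], 0.01, y[1:5], sy2[1:5]), "fixed")
  u2 <- mr_ivw(make_hset(x2[6:10], 0.01, y[6:10], sy2[6:10]), "fixed")
  expect_equal(mv2$a$estimate, u1$estimate, tolerance = 1e-10)
  expect_equal(mv2$b$estimate, u2$estimate, tolerance = 1e-10)

  expect_error(mr_mvmr(cbind(x1, x1), y, sy2), "rank deficient")
  expect_error(mr_mvmr(cbind(x1[1:2], x2[1:2]), y[1:2], sy2[1:2]),
               "J > K")
})
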