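test_that("orthonormal Hermite polynomials pass the quadrature oracle", {
  # degree 0 is the constant 1; degree 1 is odd
  expect_equal(hermite_eval(c(-2, 0, 3.5), 0), c(1, 1, 1))
  expect_equal(hermite_eval(0, 1), 0)
  # Gauss-Hermite quadrature (physicists' weight): the Gram matrix of the
  # first 9 polynomials under the standard normal is the identity
  gh <- pracma::gaussHermite(25)
  x <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  H <- hermite_design(x, 8)
  G <- t(H) %*% (H * w)
  expect_lt(max(abs(G - diag(9))), 1e-10)
})

test_that("basis size is the binomial coefficient", {
  expect_equal(basis_size(2, 3), 10)
  expect_equal(basis_size(2, 0), 1)
  expect_equal(basis_size(1, 5), 6)
  for (K in 1:4) for (p in 0:6)
    expect_equal(basis_size(K, p), choose(K + p, p))
  expect_error(basis_size(0, 2), "K >= 1")
})

test_that("tensor basis enumerates graded-lex and is empirically orthonormal", {
  tb <- tensor_basis(2, 1)
  expect_equal(unname(tb$indices),
               matrix(c(0L, 0L, 1L, 0L, 0L, 1L), 3, 2, byrow = TRUE))
  # at the origin only even-degree-free terms survive
  e0 <- tb$evaluate(matrix(c(0, 0), 1))
  expect_equal(drop(e0), c(1, 0, 0))
  # index count matches the closed-form basis size
  expect_equal(nrow(tensor_basis(3, 4)$indices), basis_size(3, 4))
  # Monte-Carlo Gram matrix: every entry within 3 sigma of the identity
  tb2 <- tensor_basis(2, 3)
  set.seed(99)
  n <- 2e5
  xi <- matrix(stats::rnorm(2 * n), n, 2)
  Psi <- tb2$evaluate(xi)
  P <- ncol(Psi)
  target <- diag(P)
  for (a in seq_len(P)) for (b in a:P) {
    prod_ab <- Psi[, a] * Psi[, b]
    se <- stats::sd(prod_ab) / sqrt(n)
    expect_lt(abs(mean(prod_ab) - target[a, b]), 3 * se + 1e-12)
  }
})

test_that("LHS occupies every stratum exactly once and is seed-deterministic", {
  dist <- default_pose_distribution()
  for (n in c(1, 10, 100)) {
    des <- lhs_design(n, dist, seed = 123)
    expect_equal(dim(des$x), c(n, 2L))
    for (j in 1:2) {
      expect_true(all(des$x[, j] >= dist$lower[j] & des$x[, j] <= dist$upper[j]))
      # map back to the uniform scale of the truncated marginal
      fa <- stats::pnorm(dist$lower[j], dist$mean[j], dist$sd[j])
      fb <- stats::pnorm(dist$upper[j], dist$mean[j], dist$sd[j])
      u <- (stats::pnorm(des$x[, j], dist$mean[j], dist$sd[j]) - fa) / (fb - fa)
      expect_equal(unname(sort(ceiling(u * n))), seq_len(n))
    }
  }
  expect_identical(lhs_design(50, dist, seed = 7)$x,
                   lhs_design(50, dist, seed = 7)$x)
  expect_false(identical(lhs_design(50, dist, seed = 7)$x,
                         lhs_design(50, dist, seed = 8)$x))
  expect_error(lhs_design(0, dist, seed = 1), ">= 1")
})

test_that("standardization centres, scales and inverts exactly", {
  dist <- default_pose_distribution()
  expect_equal(drop(standardize(c(0, 0), dist)), c(0, 0))
  # the truncation bounds sit at +/- 3 sd by construction
  expect_equal(drop(standardize(c(0.10, 5), dist)), c(3, 3), tolerance = 1e-12)
  set.seed(12)
  x <- cbind(stats::runif(20, -0.1, 0.1), stats::runif(20, -5, 5))
  expect_equal(unstandardize(standardize(x, dist), dist),
               unname(x), tolerance = 1e-12)
})

test_that("LAR-OLS recovers exact polynomial data and the constant model", {
  dist <- input_distribution(c(0, 0), c(1, 1), c(-4, -4), c(4, 4))
  des <- lhs_design(60, dist, seed = 31)
  tb <- tensor_basis(2, 2)
  Psi <- tb$evaluate(standardize(des$x, dist))
  a_true <- c(2, 1.5, -0.8, 0.6, 0, 0.3)  # sparse in the chaos basis
  y <- drop(Psi %*% a_true)
  fit <- fit_lar(des, y, p = 2)
  pred_coef <- numeric(6)
  key <- apply(tb$indices, 1, paste, collapse = ",")
  fit_key <- apply(fit$indices, 1, paste, collapse = ",")
  pred_coef[match(fit_key, key)] <- fit$coefficients
  expect_equal(pred_coef, a_true, tolerance = 1e-8)
  expect_lt(fit$diagnostics$rel_err, 1e-10)
  # evaluate at design points reproduces the training observations
  expect_equal(predict(fit, des$x), y, tolerance = 1e-8)

  # constant observations: intercept only
  fitc <- fit_lar(des, rep(4.2, 60), p = 3)
  expect_equal(fitc$diagnostics$n_active, 1L)
  expect_equal(fitc$coefficients[1], 4.2, tolerance = 1e-12)
  expect_equal(unname(predict(fitc, cbind(c(-1, 2), c(0.5, 1)))), c(4.2, 4.2),
               tolerance = 1e-12)
})

test_that("single-variable linear fit matches closed-form least squares", {
  dist <- input_distribution(0, 2, -6, 6, names = "x")
  des <- lhs_design(40, dist, seed = 77)
  set.seed(78)
  y <- 1.2 + 0.9 * des$x[, 1] + stats::rnorm(40, 0, 0.05)
  fit <- fit_lar(des, y, p = 1)
  # independent normal-equations solution on the same basis
  Phi <- cbind(1, standardize(des$x, dist))
  beta <- solve(crossprod(Phi), crossprod(Phi, y))
  expect_equal(fit$coefficients, drop(beta), tolerance = 1e-10)
})

test_that("term-by-term manual summation equals predict", {
  dist <- default_pose_distribution()
  des <- lhs_design(50, dist, seed = 13)
  set.seed(14)
  y <- sin(des$x[, 1] * 20) + 0.3 * des$x[, 2] + stats::rnorm(50, 0, 0.01)
  fit <- fit_lar(des, y, p = 3)
  xnew <- cbind(stats::runif(5, -0.08, 0.08), stats::runif(5, -4, 4))
  xi <- standardize(xnew, dist)
  manual <- sapply(seq_len(5), function(i) {
    s <- 0
    for (r in seq_len(nrow(fit$indices)))
      s <- s + fit$coefficients[r] *
        hermite_eval(xi[i, 1], fit$indices[r, 1]) *
        hermite_eval(xi[i, 2], fit$indices[r, 2])
    s
  })
  expect_equal(unname(predict(fit, xnew)), manual, tolerance = 1e-10)
})

test_that("hat-matrix LOO equals the literal refit oracle", {
  set.seed(55)
  for (rep in 1:6) {
    n <- 20; P <- 5
    Phi <- cbind(1, matrix(stats::rnorm(n * (P - 1)), n))
    y <- stats::rnorm(n)
    lo <- loo_error(Phi, y, corrected = FALSE)
    expect_equal(lo$eps_loo, oracle_loo_refit(Phi, y), tolerance = 1e-10)
  }
  # noiseless polynomial limit: eps ~ 0, Q2 ~ 1
  dist <- input_distribution(c(0, 0), c(1, 1), c(-4, -4), c(4, 4))
  des <- lhs_design(50, dist, seed = 66)
  Psi <- tensor_basis(2, 2)$evaluate(standardize(des$x, dist))
  y <- drop(Psi %*% c(1, 0.5, 0.2, 0.1, -0.4, 0))
  expect_lt(loo_error(Psi, y)$eps_loo / stats::var(y), 1e-12)
  # errors: interpolating design and rank deficiency
  expect_error(loo_error(diag(4), stats::rnorm(4)), "terms as observations")
  expect_error(loo_error(cbind(1, rep(1, 4), rep(2, 4)), stats::rnorm(4)),
               "rank")
})

test_that("pure-noise data yield nonpositive Q2 on average", {
  set.seed(91)
  q2 <- replicate(60, {
    y <- stats::rnorm(25)
    lo <- loo_error(matrix(1, 25, 1), y, corrected = TRUE)
    1 - lo$eps_loo / stats::var(y)
  })
  expect_lte(mean(q2), 0)
})

test_that("adaptive refinement stops at the first adequate model", {
  dist <- input_distribution(c(0, 0), c(1, 1), c(-3.5, -3.5), c(3.5, 3.5))
  sampler <- function(n) lhs_design(n, dist, seed = 100 + n)
  runner <- function(x) 2 + x[, 1] - 0.5 * x[, 2] + 0.25 * x[, 1]^2
  fit <- adaptive_fit(sampler, runner, p_range = 1:4,
                      n_schedule = c(25, 50), threshold = 1e-3)
  expect_true(fit$converged)
  expect_equal(fit$diagnostics$p, 2)          # first adequate degree
  expect_equal(fit$diagnostics$n, 25)         # first design size
  # vacuous criterion: the very first fitted surrogate is returned
  fit0 <- adaptive_fit(sampler, runner, p_range = 1:4,
                       n_schedule = c(25, 50), threshold = Inf)
  expect_equal(fit0$diagnostics$p, 1)
  # unreachable threshold on noisy data: best effort, flagged
  runner_n <- function(x) {
    set.seed(nrow(x)); runner(x) + stats::rnorm(nrow(x), 0, 0.5)
  }
  expect_warning(
    fitb <- adaptive_fit(sampler, runner_n, p_range = 1:2,
                         n_schedule = c(25), threshold = 1e-12),
    "best effort")
  expect_false(fitb$converged)
})

test_that("surrogates serialize to JSON and back", {
  dist <- default_pose_distribution()
  des <- lhs_design(40, dist, seed = 3)
  y <- 1 + des$x[, 1] * 5 + des$x[, 2]^2 * 0.1
  fit <- fit_lar(des, y, p = 2, metric = "wbSAR")
  f <- tempfile(fileext = ".json")
  write_surrogate(fit, f)
  back <- read_surrogate(f)
  xnew <- cbind(c(0.01, -0.05), c(2, -1))
  expect_equal(predict(back, xnew), predict(fit, xnew), tolerance = 1e-12)
  expect_equal(back$metric, "wbSAR")
})
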