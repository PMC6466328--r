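#' Orthonormal probabilists' Hermite polynomials
#'
#' Evaluates the family of probabilists' Hermite polynomials normalized to
#' unit norm under the standard normal weight:
#' \eqn{\psi_k = He_k / \sqrt{k!}}, via the stable recurrence
#' \eqn{\psi_k = (x \psi_{k-1} - \sqrt{k-1}\, \psi_{k-2}) / \sqrt{k}}.
#' Paired with Gaussian inputs these are the natural chaos basis.
#'
#' @param x numeric vector of evaluation points (standard-normal scale).
#' @param max_degree highest degree required (>= 0).
#' @return a `length(x)` x `(max_degree + 1)` matrix, column k + 1 holding
#'   degree k.
#' @export
hermite_design <- function(x, max_degree) {
  if (max_degree < 0) stop("max_degree must be >= 0")
  H <- matrix(0, length(x), max_degree + 1L)
  H[, 1] <- 1
  if (max_degree >= 1) H[, 2] <- x
  if (max_degree >= 2)
    for (k in 2:max_degree)
      H[, k + 1] <- (x * H[, k] - sqrt(k - 1) * H[, k - 1]) / sqrt(k)
  H
}

#' @rdname hermite_design
#' @param k degree of the single polynomial to evaluate.
#' @export
hermite_eval <- function(x, k) hermite_design(x, k)[, k + 1L]

#' Size of the total-degree polynomial basis
#'
#' Number of multi-indices of K variables with total degree at most p:
#' the binomial coefficient C(K + p, p).
#'
#' @param K number of input variables (>= 1).
#' @param p maximum total degree (>= 0).
#' @return integer basis size.
#' @export
basis_size <- function(K, p) {
  if (K < 1 || p < 0) stop("need K >= 1 and p >= 0")
  choose(K + p, p)
}

# all compositions of g into K parts, graded-lex (larger leading part first)
compositions_glex <- function(g, K) {
  if (K == 1L) return(matrix(g, 1L, 1L))
  do.call(rbind, lapply(g:0, function(a1)
    cbind(a1, compositions_glex(g - a1, K - 1L))))
}

#' Tensor-product Hermite basis over K variables
#'
#' Enumerates all multi-indices with total degree at most p in
#' graded-lexicographic order and provides the evaluator
#' \eqn{\psi_\alpha(\xi) = \prod_j \psi_{\alpha_j}(\xi_j)} built from the
#' univariate orthonormal Hermite factors.
#'
#' @inheritParams basis_size
#' @return list with `indices` (a `basis_size(K, p)` x K integer matrix) and
#'   `evaluate(xi)`, mapping an n x K matrix of standardized points to the
#'   n x P design matrix.
#' @export
tensor_basis <- function(K, p) {
  idx <- do.call(rbind, lapply(0:p, compositions_glex, K = K))
  colnames(idx) <- NULL
  storage.mode(idx) <- "integer"
  evaluate <- function(xi) {
    xi <- matrix(xi, ncol = K)
    uni <- lapply(seq_len(K), function(j) hermite_design(xi[, j], p))
    Psi <- matrix(1, nrow(xi), nrow(idx))
    for (j in seq_len(K))
      Psi <- Psi * uni[[j]][, idx[, j] + 1L, drop = FALSE]
    Psi
  }
  list(indices = idx, evaluate = evaluate)
}

#' Truncated-Gaussian input distribution of the pose variables
#'
#' Per input variable: mean, standard deviation and truncation bounds, all in
#' physical units. The default pose law places the motion limits at three
#' standard deviations: Z shift ~ N(0, (10/3 cm)^2) truncated at +/- 10 cm,
#' tilt ~ N(0, (5/3 deg)^2) truncated at +/- 5 degrees.
#'
#' @param mean,sd,lower,upper numeric vectors, one entry per variable.
#' @param names variable names.
#' @return object of class `input_distribution`.
#' @export
input_distribution <- function(mean, sd, lower, upper,
                               names = paste0("x", seq_along(mean))) {
  stopifnot(all(sd > 0), all(lower < upper),
            length(sd) == length(mean), length(lower) == length(mean),
            length(upper) == length(mean))
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 names = names, K = length(mean)),
            class = "input_distribution")
}

#' @rdname input_distribution
#' @export
default_pose_distribution <- function() {
  input_distribution(mean = c(0, 0), sd = c(0.10 / 3, 5 / 3),
                     lower = c(-0.10, -5), upper = c(0.10, 5),
                     names = c("z_shift_m", "tilt_deg"))
}

#' Standardize physical poses to the Hermite weight scale
#'
#' \eqn{\xi_j = (x_j - \mu_j) / s_j} per variable (and back). The truncation
#' is respected by the samplers but deliberately ignored in the polynomial
#' weight: at +/- 3 sd it removes about 0.27% of probability mass, a declared
#' approximation.
#'
#' @param x n x K matrix (or length-K vector) in physical units.
#' @param dist an [input_distribution()].
#' @return matrix of the same shape on the standardized scale.
#' @export
standardize <- function(x, dist) {
  x <- matrix(x, ncol = dist$K)
  sweep(sweep(x, 2L, dist$mean, "-"), 2L, dist$sd, "/")
}

#' @rdname standardize
#' @param xi standardized matrix.
#' @export
unstandardize <- function(xi, dist) {
  xi <- matrix(xi, ncol = dist$K)
  sweep(sweep(xi, 2L, dist$sd, "*"), 2L, dist$mean, "+")
}

#' Latin-hypercube experimental design over the pose distribution
#'
#' One sample per equal-probability stratum of each truncated-Gaussian
#' marginal: a Latin-hypercube uniform design (via [lhs::randomLHS()]) is
#' pushed through the truncated-normal inverse CDF per dimension. The stratum
#' assignment is randomly permuted across dimensions and fully reproducible
#' from the seed.
#'
#' @param n number of design points (>= 1).
#' @param dist an [input_distribution()].
#' @param seed integer RNG seed (mandatory; all randomness flows from it).
#' @return object of class `experimental_design`: `x` (n x K physical-unit
#'   matrix), `dist`, `seed`.
#' @export
lhs_design <- function(n, dist, seed) {
  if (n < 1) stop("n must be >= 1")
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  U <- lhs::randomLHS(n, dist$K)
  x <- vapply(seq_len(dist$K), function(j) {
    fa <- stats::pnorm(dist$lower[j], dist$mean[j], dist$sd[j])
    fb <- stats::pnorm(dist$upper[j], dist$mean[j], dist$sd[j])
    stats::qnorm(fa + U[, j] * (fb - fa), dist$mean[j], dist$sd[j])
  }, numeric(n))
  x <- matrix(x, ncol = dist$K, dimnames = list(NULL, dist$names))
  structure(list(x = x, dist = dist, seed = seed),
            class = "experimental_design")
}

#' Sample poses directly from the truncated-Gaussian law
#'
#' Inverse-CDF sampling (not stratified); used for the output-distribution
#' draws of the stochastic pipeline.
#'
#' @inheritParams lhs_design
#' @return n x K matrix in physical units.
#' @export
sample_pose_distribution <- function(n, dist, seed) {
  if (!missing(seed)) set.seed(seed)
  x <- vapply(seq_len(dist$K), function(j) {
    fa <- stats::pnorm(dist$lower[j], dist$mean[j], dist$sd[j])
    fb <- stats::pnorm(dist$upper[j], dist$mean[j], dist$sd[j])
    stats::qnorm(fa + stats::runif(n) * (fb - fa), dist$mean[j], dist$sd[j])
  }, numeric(n))
  matrix(x, ncol = dist$K, dimnames = list(NULL, dist$names))
}

#' Leave-one-out cross-validation error of a linear regression basis
#'
#' The mean-squared leave-one-out error of the least-squares fit of `y` on
#' the columns of `Phi`, computed exactly through the hat-matrix identity
#' (residual divided by 1 - h_i, squared, averaged) — algebraically equal to
#' refitting N times with one point held out. With `corrected = TRUE` the
#' finite-sample correction factor
#' \eqn{T = N/(N - P) \, (1 + \mathrm{tr}((\Phi^T\Phi)^{-1}))}
#' is applied multiplicatively, penalizing designs whose information matrix
#' is poorly conditioned.
#'
#' @param Phi n x P regression matrix (full column rank, P < n).
#' @param y observations.
#' @param corrected apply the correction factor (default TRUE).
#' @return list: `eps_loo`, `eps_loo_raw`, `correction`, `residuals`,
#'   `leverage`, `coef`.
#' @export
loo_error <- function(Phi, y, corrected = TRUE) {
  Phi <- as.matrix(Phi)
  n <- nrow(Phi); P <- ncol(Phi)
  if (P >= n) stop("model has as many terms as observations")
  qr_ <- qr(Phi)
  if (qr_$rank < P) stop("regression matrix is rank deficient")
  beta <- qr.coef(qr_, y)
  h <- rowSums(qr.Q(qr_)^2)
  if (any(h > 1 - 1e-10))
    stop("interpolating design point (leverage 1); LOO undefined")
  r <- y - drop(Phi %*% beta)
  eps_raw <- mean((r / (1 - h))^2)
  Rinv <- backsolve(qr.R(qr_), diag(P))
  corr <- n / (n - P) * (1 + sum(Rinv^2))
  list(eps_loo = if (corrected) eps_raw * corr else eps_raw,
       eps_loo_raw = eps_raw, correction = corr,
       residuals = r, leverage = h, coef = beta)
}

# classic equiangular LAR path on centred, unit-norm columns; returns the
# sequence of active-column index sets (ties broken by lowest column index)
lar_path <- function(X, y, max_steps) {
  n <- nrow(X); m <- ncol(X)
  mu <- numeric(n)
  active <- integer(0)
  path <- list()
  for (step in seq_len(max_steps)) {
    c_all <- drop(crossprod(X, y - mu))
    inactive <- setdiff(seq_len(m), active)
    if (!length(inactive)) break
    C <- max(abs(c_all[inactive]))
    if (C < 1e-12) break
    j <- inactive[which.max(abs(c_all[inactive]))]
    active <- c(active, j)
    s <- sign(c_all[active])
    Xs <- X[, active, drop = FALSE] * rep(s, each = n)
    G <- crossprod(Xs)
    w <- tryCatch(solve(G, rep(1, length(active))), error = function(e) NULL)
    if (is.null(w) || any(!is.finite(w)) || sum(w) <= 0) {
      active <- active[-length(active)]
      break
    }
    AA <- 1 / sqrt(sum(w))
    u <- drop(Xs %*% (AA * w))
    path[[length(path) + 1L]] <- active
    inactive <- setdiff(seq_len(m), active)
    if (!length(inactive)) break
    a <- drop(crossprod(X[, inactive, drop = FALSE], u))
    cI <- c_all[inactive]
    CA <- max(abs(c_all[active]))
    cand <- c((CA - cI) / (AA - a), (CA + cI) / (AA + a))
    cand <- cand[is.finite(cand) & cand > 1e-12]
    gamma <- if (length(cand)) min(cand, CA / AA) else CA / AA
    mu <- mu + gamma * u
  }
  path
}

#' Fit a sparse polynomial-chaos surrogate by least-angle regression
#'
#' Builds the orthonormal Hermite tensor basis of total degree at most `p`
#' on the standardized design, runs the least-angle-regression path over the
#' non-constant basis columns (the intercept is always active), refits each
#' path model's active set by ordinary least squares (hybrid LAR-OLS), and
#' keeps the path model minimizing the corrected leave-one-out error.
#'
#' @param design an [lhs_design()] result, or an n x K physical-unit matrix
#'   (then `dist` is required).
#' @param y observations aligned with the design rows (finite, length n >= 3).
#' @param p maximum total polynomial degree.
#' @param dist an [input_distribution()]; taken from `design` when omitted.
#' @param metric optional tag naming the modelled quantity.
#' @return object of class `pc_surrogate`: multi-`indices` of the active
#'   terms, `coefficients`, the input `dist`, and `diagnostics`
#'   (`eps_loo`, `eps_loo_raw`, `q2`, `rel_err` = 1 - Q^2, `sigma2`,
#'   `n_active`, `p`, `n`).
#' @export
fit_lar <- function(design, y, p, dist = NULL, metric = NULL) {
  if (inherits(design, "experimental_design")) {
    if (is.null(dist)) dist <- design$dist
    x <- design$x
  } else x <- as.matrix(design)
  if (is.null(dist)) stop("an input_distribution is required")
  n <- nrow(x)
  if (n < 3) stop("need at least 3 observations")
  if (any(!is.finite(y))) stop("observations must be finite")
  if (length(y) != n) stop("design and observations differ in length")
  xi <- standardize(x, dist)
  basis <- tensor_basis(dist$K, p)
  Psi <- basis$evaluate(xi)
  sigma2 <- stats::var(y)
  # candidate columns beyond the intercept, centred and unit-norm for LAR
  Xc <- Psi[, -1L, drop = FALSE]
  Xc <- sweep(Xc, 2L, colMeans(Xc), "-")
  nrm <- sqrt(colSums(Xc^2))
  keep <- which(nrm > 1e-12)
  make <- function(active_cols) {
    Phi <- Psi[, c(1L, active_cols), drop = FALSE]
    lo <- tryCatch(loo_error(Phi, y), error = function(e) NULL)
    if (is.null(lo)) return(NULL)
    list(active = c(1L, active_cols), loo = lo)
  }
  models <- list(make(integer(0)))
  if (length(keep) && sigma2 > 0) {
    Xl <- sweep(Xc[, keep, drop = FALSE], 2L, nrm[keep], "/")
    max_steps <- min(length(keep), n - 2L)
    path <- lar_path(Xl, y - mean(y), max_steps)
    for (A in path) {
      mod <- make(1L + keep[sort(A)])
      if (!is.null(mod)) models[[length(models) + 1L]] <- mod
    }
  }
  models <- Filter(Negate(is.null), models)
  eps <- vapply(models, function(m) m$loo$eps_loo, numeric(1))
  best <- models[[which.min(eps)]]
  rel <- if (sigma2 > 0) best$loo$eps_loo / sigma2 else 0
  structure(list(
    indices = basis$indices[best$active, , drop = FALSE],
    coefficients = unname(best$loo$coef),
    dist = dist, metric = metric,
    diagnostics = list(eps_loo = best$loo$eps_loo,
                       eps_loo_raw = best$loo$eps_loo_raw,
                       sigma2 = sigma2, q2 = 1 - rel, rel_err = rel,
                       n_active = length(best$active), p = p, n = n)),
    class = "pc_surrogate")
}

#' Predict SAR from a polynomial-chaos surrogate
#'
#' \eqn{\sum_j a_j \psi_j(\xi(x))} over the active multi-indices. Points
#' outside the truncation bounds of the input law trigger a warning (the
#' surrogate extrapolates there).
#'
#' @param object a [fit_lar()] surrogate.
#' @param newdata n x K matrix (or length-K vector) of poses, physical units.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pc_surrogate <- function(object, newdata, ...) {
  x <- matrix(newdata, ncol = object$dist$K)
  out_lo <- sweep(x, 2L, object$dist$lower, "<")
  out_hi <- sweep(x, 2L, object$dist$upper, ">")
  if (any(out_lo | out_hi))
    warning("poses outside the truncation bounds; surrogate extrapolates")
  xi <- standardize(x, object$dist)
  pmax_deg <- max(object$indices)
  uni <- lapply(seq_len(ncol(xi)), function(j) hermite_design(xi[, j], pmax_deg))
  Psi <- matrix(1, nrow(xi), nrow(object$indices))
  for (j in seq_len(ncol(xi)))
    Psi <- Psi * uni[[j]][, object$indices[, j] + 1L, drop = FALSE]
  drop(Psi %*% object$coefficients)
}

#' @export
print.pc_surrogate <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("pc_surrogate%s: K = %d, p = %d, %d active terms (of %d), N = %d\n",
              if (is.null(x$metric)) "" else paste0(" [", x$metric, "]"),
              ncol(x$indices), d$p, d$n_active, basis_size(ncol(x$indices), d$p),
              d$n))
  cat(sprintf("  corrected eps_LOO = %.3g, Q2 = %.5f (1 - Q2 = %.3g)\n",
              d$eps_loo, d$q2, d$rel_err))
  invisible(x)
}

#' Adaptive surrogate refinement over design size and degree
#'
#' Iterates over a schedule of design sizes N and, for each, over candidate
#' maximum degrees p, accepting the first surrogate whose relative corrected
#' leave-one-out error 1 - Q^2 falls below the threshold. If none converges,
#' the best (smallest 1 - Q^2) surrogate is returned with `converged = FALSE`
#' and a warning.
#'
#' @param design_sampler function(n) returning an [lhs_design()]-style
#'   design of size n.
#' @param model_runner function(x) mapping an n x K pose matrix to n SAR
#'   observations (the deterministic forward model).
#' @param p_range candidate maximum degrees (default 1:5).
#' @param n_schedule design sizes (default c(25, 50, 100)).
#' @param threshold convergence level for 1 - Q^2 (default 0.01).
#' @param metric optional tag passed to [fit_lar()].
#' @return the selected `pc_surrogate`, with fields `converged` and the
#'   design/observations (`design`, `y`) it was fitted on.
#' @export
adaptive_fit <- function(design_sampler, model_runner,
                         p_range = 1:5, n_schedule = c(25, 50, 100),
                         threshold = 0.01, metric = NULL) {
  if (!length(p_range) || !length(n_schedule)) stop("empty schedule")
  if (threshold <= 0) stop("threshold must be > 0")
  best <- NULL
  for (n in n_schedule) {
    design <- design_sampler(n)
    y <- model_runner(design$x)
    for (p in p_range) {
      fit <- tryCatch(fit_lar(design, y, p, metric = metric),
                      error = function(e) NULL)
      if (is.null(fit)) next
      fit$design <- design
      fit$y <- y
      if (is.null(best) || fit$diagnostics$rel_err < best$diagnostics$rel_err)
        best <- fit
      if (fit$diagnostics$rel_err <= threshold) {
        fit$converged <- TRUE
        return(fit)
      }
    }
  }
  if (is.null(best)) stop("no surrogate could be fitted")
  warning("no surrogate reached the threshold; returning best effort")
  best$converged <- FALSE
  best
}

#' Serialize a surrogate to JSON (and back)
#'
#' Multi-indices, coefficients, the standardizing transform, diagnostics and
#' the metric tag, as a plain JSON object.
#'
#' @param surrogate a `pc_surrogate`.
#' @param path output file.
#' @export
write_surrogate <- function(surrogate, path) {
  s <- surrogate
  obj <- list(indices = unclass(s$indices),
              coefficients = s$coefficients,
              dist = unclass(s$dist)[c("mean", "sd", "lower", "upper", "names")],
              metric = s$metric,
              diagnostics = s$diagnostics,
              converged = isTRUE(s$converged))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$dist
  structure(list(indices = matrix(as.integer(obj$indices), ncol = length(d$mean)),
                 coefficients = as.numeric(obj$coefficients),
                 dist = input_distribution(d$mean, d$sd, d$lower, d$upper, d$names),
                 metric = obj$metric,
                 diagnostics = obj$diagnostics,
                 converged = isTRUE(obj$converged)),
            class = "pc_surrogate")
}
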