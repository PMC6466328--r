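# Independent oracles and small fixtures used across the suite.
# These deliberately use plain loops / direct definitions, not the package's
# vectorized implementations.

# brute-force peak spatial-average SAR: for every tissue voxel, evaluate every
# centred cube size until the enclosed tissue mass reaches the target, apply
# the linear fractional weighting of the outermost shell, and take the max
# (ties -> lexicographically smallest index)
oracle_psar <- function(sar, labels, rho_by_label, voxel_size, target = 0.010) {
  d <- dim(labels)
  vol <- voxel_size^3
  mass <- array(0, d)
  tis <- labels != 0L
  mass[tis] <- vol * rho_by_label[labels[tis]]
  pow <- sar * mass
  best <- -Inf; best_loc <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (labels[i, j, k] == 0L) next
    kmax <- min(i - 1, d[1] - i, j - 1, d[2] - j, k - 1, d[3] - k)
    m_prev <- 0; p_prev <- 0; val <- NA_real_
    for (kk in 0:kmax) {
      ii <- (i - kk):(i + kk); jj <- (j - kk):(j + kk); zz <- (k - kk):(k + kk)
      m_cur <- sum(mass[ii, jj, zz]); p_cur <- sum(pow[ii, jj, zz])
      if (m_cur >= target) {
        f <- (target - m_prev) / (m_cur - m_prev)
        val <- (p_prev + f * (p_cur - p_prev)) / target
        break
      }
      m_prev <- m_cur; p_prev <- p_cur
    }
    if (is.na(val)) next
    if (val > best + 1e-15 ||
        (abs(val - best) <= 1e-15 &&
         !is.null(best_loc) &&
         (i < best_loc[1] ||
          (i == best_loc[1] && (j < best_loc[2] ||
           (j == best_loc[2] && k < best_loc[3])))))) {
      best <- val; best_loc <- c(i, j, k)
    }
  }
  list(value = best, location = best_loc)
}

# literal leave-one-out: refit N times with one observation held out and
# average the squared prediction error at the held-out point
oracle_loo_refit <- function(Phi, y) {
  n <- nrow(Phi)
  errs <- numeric(n)
  for (i in seq_len(n)) {
    b <- qr.coef(qr(Phi[-i, , drop = FALSE]), y[-i])
    errs[i] <- (y[i] - sum(Phi[i, ] * b))^2
  }
  mean(errs)
}

# random blocky phantom: background margin + a few random tissue boxes
random_phantom <- function(n, n_tissues = 3, seed, voxel_size = 0.004) {
  set.seed(seed)
  labels <- array(0L, c(n, n, n))
  for (t in seq_len(n_tissues)) {
    lo <- pmax(2L, sample.int(n - 4L, 3L))
    hi <- pmin(n - 1L, lo + sample(2:(n %/% 2), 3L, replace = TRUE))
    labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- t
  }
  rho <- stats::runif(n_tissues, 900, 1900)
  sigma <- stats::runif(n_tissues, 0.05, 1.5)
  props <- tissue_table(c("Background", paste0("T", seq_len(n_tissues))),
                        0:n_tissues, c(0, sigma),
                        c(1, stats::runif(n_tissues, 10, 120)), c(0, rho))
  phantom <- voxel_phantom(labels, voxel_size, alignment_z = n * voxel_size / 2)
  list(phantom = phantom, props = props, rho = rho)
}

# small fixture pair shared across pipeline tests (built once per run)
small_recipe <- function(seed = 7L)
  phantom_recipe(height = 0.16, dim = c(32, 32, 80), voxel_size = 0.002,
                 seed = seed)

small_pair_cache <- new.env(parent = emptyenv())
small_pair <- function() {
  if (is.null(small_pair_cache$pair))
    small_pair_cache$pair <- make_fixture_pair(small_recipe(), seed = 7L)
  small_pair_cache$pair
}
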