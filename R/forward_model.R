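#' Coil field configuration
#'
#' A simplified circularly polarized transmit-coil field: a uniform rotating
#' B1 magnitude inside the coil window, tapering smoothly to zero over a
#' taper length at both ends. The coil axis is the Z line through
#' (x = 0, y = 0) of the coil frame. The default geometry (short flat
#' window, long raised-cosine taper) emulates the bell-shaped axial B1
#' profile of a real birdcage resonator at the scale of the synthetic
#' phantoms.
#'
#' @param frequency Larmor frequency in Hz (default 64 MHz, i.e. 1.5 T).
#' @param b1 B1 amplitude in tesla (peak), default 1 uT.
#' @param length axial length L of the flat field window, metres.
#' @param taper taper length at each end over which the field falls to zero
#'   (raised-cosine), metres.
#' @param centre axial coordinate of the coil midplane, metres (default 0).
#' @return an object of class `coil_field`.
#' @export
coil_field <- function(frequency = 64e6, b1 = 1e-6,
                       length = 0.02, taper = 0.10, centre = 0) {
  stopifnot(frequency > 0, b1 > 0, length > 0, taper >= 0)
  structure(list(frequency = frequency, b1 = b1, length = length,
                 taper = taper, centre = centre),
            class = "coil_field")
}

#' Body pose inside the coil
#'
#' A pose perturbation about the standard position: a shift along the coil
#' Z-axis and a tilt angle. The study's pose distributions span a shift of
#' +/- 10 cm and a tilt of +/- 5 degrees; poses outside those bounds are
#' allowed but flagged with a warning by the pipeline.
#'
#' @param z_shift axial shift in metres.
#' @param tilt tilt angle in degrees.
#' @return an object of class `pose`.
#' @export
pose <- function(z_shift = 0, tilt = 0) {
  stopifnot(is.finite(z_shift), is.finite(tilt))
  structure(list(z_shift = z_shift, tilt = tilt), class = "pose")
}

#' Axial field profile of the coil
#'
#' 1 inside the flat window `|z - centre| <= L/2`, raised-cosine
#' `cos^2(pi (|z - centre| - L/2) / (2 L_t))` over the taper, 0 beyond.
#'
#' @param z axial coordinates, metres.
#' @param coil a [coil_field()].
#' @return profile values in \[0, 1\].
#' @export
axial_profile <- function(z, coil) {
  u <- abs(z - coil$centre) - coil$length / 2
  w <- numeric(length(z))
  w[u <= 0] <- 1
  if (coil$taper > 0) {
    i <- u > 0 & u < coil$taper
    w[i] <- cos(pi * u[i] / (2 * coil$taper))^2
  }
  w
}

#' Voxel-centre positions in the coil frame under a pose
#'
#' Places the body with its long axis parallel to the coil Z-axis, its
#' alignment plane (central heart level) at the coil midplane, and its own
#' long axis offset below the coil axis by `table_offset`. The pose is then
#' applied: a rotation by the tilt angle about either the body's own long
#' axis (`tilt_axis = "long"`, the default) or a transverse (pitch) axis
#' through the alignment point, followed by the Z shift.
#'
#' @param phantom a [voxel_phantom()] with a finite `alignment_z`.
#' @param pose a [pose()].
#' @param coil a [coil_field()].
#' @param table_offset vertical offset of the body axis below the coil axis,
#'   metres (default 0.05).
#' @param tilt_axis `"long"` (roll about the body long axis) or `"pitch"`
#'   (rotation about a transverse axis through the alignment point).
#' @param idx optional integer matrix of voxel index triples (1-based); by
#'   default all voxels.
#' @return an n x 3 matrix of coil-frame coordinates (x, y, z) in metres.
#' @export
pose_transform <- function(phantom, pose, coil,
                           table_offset = 0.05,
                           tilt_axis = c("long", "pitch"),
                           idx = NULL) {
  tilt_axis <- match.arg(tilt_axis)
  if (!is.finite(phantom$alignment_z))
    stop("phantom has no alignment plane (alignment_z)")
  d <- dim(phantom$labels)
  if (is.null(idx)) {
    idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                                 k = seq_len(d[3])))
  }
  # body-frame voxel-centre coordinates
  p <- sweep(sweep(idx - 0.5, 2L, phantom$voxel_size, "*"),
             2L, phantom$origin, "+")
  la <- phantom$long_axis
  tr <- setdiff(1:3, la)
  zb <- p[, la]
  # body's own long axis: centre of the grid extent in the transverse axes
  ctr <- phantom$origin + d * phantom$voxel_size / 2
  x <- p[, tr[1]] - ctr[tr[1]]
  y <- p[, tr[2]] - ctr[tr[2]] - table_offset
  z <- zb - phantom$alignment_z + coil$centre
  th <- pose$tilt * pi / 180
  if (th != 0) {
    if (tilt_axis == "long") {
      # roll about the body axis line (0, -table_offset) in the x-y plane
      ys <- y + table_offset
      x2 <- cos(th) * x - sin(th) * ys
      y2 <- sin(th) * x + cos(th) * ys - table_offset
      x <- x2; y <- y2
    } else {
      # pitch about the transverse x-axis through (0, -table_offset, centre)
      ys <- y + table_offset
      zs <- z - coil$centre
      y2 <- cos(th) * ys - sin(th) * zs - table_offset
      z2 <- sin(th) * ys + cos(th) * zs + coil$centre
      y <- y2; z <- z2
    }
  }
  z <- z + pose$z_shift
  cbind(x = x, y = y, z = z)
}

#' Quasi-static SAR field of a posed phantom
#'
#' A desk-scale stand-in for full-wave electromagnetic simulation. The
#' induced electric field of the rotating B1 field is taken in the
#' quasi-static (eddy-current) approximation,
#' \deqn{E(r) = (\omega B_1 / 2)\, d(r)\, w(z),}
#' where \eqn{d(r)} is the perpendicular distance from the coil axis and
#' \eqn{w(z)} the axial profile, and the local SAR follows the
#' peak-amplitude convention \eqn{SAR = \sigma E^2 / (2 \rho)}. Background
#' voxels carry zero SAR. Absolute values are not comparable to full-wave
#' results; the model preserves the dependencies the stochastic analysis
#' needs (conductivity and density structure, Z-shift through the axial
#' profile, tilt through off-axis geometry).
#'
#' @inheritParams pose_transform
#' @param props a [tissue_table()] covering the phantom labels.
#' @return a 3-D numeric array of per-voxel SAR in W/kg.
#' @export
sar_field <- function(phantom, props, coil, pose = sarpce::pose(),
                      table_offset = 0.05, tilt_axis = c("long", "pitch")) {
  tilt_axis <- match.arg(tilt_axis)
  props <- validate_tissue_table(props)
  check_phantom_labels(phantom, props)
  d <- dim(phantom$labels)
  lin <- which(phantom$labels != 0L)
  sar <- array(0, d)
  if (!length(lin)) return(sar)
  idx <- arrayInd(lin, d)
  pos <- pose_transform(phantom, pose, coil, table_offset, tilt_axis, idx)
  row <- match(phantom$labels[lin], props$label)
  sig <- props$sigma_S_per_m[row]
  rho <- props$rho_kg_per_m3[row]
  if (any(rho <= 0)) stop("tissue voxel with non-positive density")
  omega <- 2 * pi * coil$frequency
  E <- (omega * coil$b1 / 2) * sqrt(pos[, 1]^2 + pos[, 2]^2) *
    axial_profile(pos[, 3], coil)
  sar[lin] <- sig * E^2 / (2 * rho)
  sar
}

voxel_mass_grid <- function(phantom, props) {
  d <- dim(phantom$labels)
  m <- array(0, d)
  lin <- which(phantom$labels != 0L)
  row <- match(phantom$labels[lin], props$label)
  m[lin] <- prod(phantom$voxel_size) * props$rho_kg_per_m3[row]
  m
}

#' Whole-body and head averaged SAR
#'
#' Mass-weighted mean SAR over all tissue voxels (`wb_sar`) or over the head
#' mask (`hd_sar`): \eqn{\sum SAR_i m_i / \sum m_i}.
#'
#' @param sar SAR grid from [sar_field()].
#' @param phantom a [voxel_phantom()].
#' @param props a [tissue_table()].
#' @return scalar SAR in W/kg.
#' @export
wb_sar <- function(sar, phantom, props) {
  m <- voxel_mass_grid(phantom, props)
  tot <- sum(m)
  if (tot <= 0) stop("phantom has no tissue mass")
  sum(sar * m) / tot
}

#' @rdname wb_sar
#' @export
hd_sar <- function(sar, phantom, props) {
  if (!any(phantom$head_mask)) stop("phantom has an empty head mask")
  m <- voxel_mass_grid(phantom, props)
  m[!phantom$head_mask] <- 0
  sum(sar * m) / sum(m)
}

# 3-D summed-volume table, zero-padded: S[i+1, j+1, k+1] = sum of a[1:i, 1:j, 1:k]
integral_image3 <- function(a) {
  d <- dim(a)
  S <- array(0, d + 1L)
  S[-1, -1, -1] <- a
  S <- apply(S, c(2, 3), cumsum)
  S <- aperm(apply(S, c(1, 3), cumsum), c(2, 1, 3))
  aperm(apply(S, c(1, 2), cumsum), c(2, 3, 1))
}

# sums over centred cubes of half-width k at centres given as an n x 3 index
# matrix, via 8-term inclusion-exclusion on the padded integral image
cube_sums <- function(S, centres, k) {
  D <- dim(S)
  lo <- centres - k      # i1 (>= 1 guaranteed by caller)
  hi <- centres + k + 1L # i2 + 1 in padded indexing
  lin <- function(i, j, kk) i + (j - 1) * D[1] + (kk - 1) * D[1] * D[2]
  S[lin(hi[, 1], hi[, 2], hi[, 3])] -
    S[lin(lo[, 1], hi[, 2], hi[, 3])] -
    S[lin(hi[, 1], lo[, 2], hi[, 3])] -
    S[lin(hi[, 1], hi[, 2], lo[, 3])] +
    S[lin(lo[, 1], lo[, 2], hi[, 3])] +
    S[lin(lo[, 1], hi[, 2], lo[, 3])] +
    S[lin(hi[, 1], lo[, 2], lo[, 3])] -
    S[lin(lo[, 1], lo[, 2], lo[, 3])]
}

#' Precompute the cube-growth geometry for peak spatial-average SAR
#'
#' The averaging cube around each tissue voxel depends only on the mass grid,
#' not on the SAR field, so it can be computed once per phantom and reused
#' across poses: for every tissue voxel the half-width `k` of the smallest
#' centred cube whose enclosed tissue mass reaches `target_mass`, and the
#' linear weight of the outermost shell that trims the enclosed mass to
#' exactly `target_mass`. Voxels whose cube would leave the grid before
#' reaching the target are marked invalid.
#'
#' @inheritParams wb_sar
#' @param target_mass averaging mass in kg (default 0.010, i.e. 10 g).
#' @return a list used by [psar10g()].
#' @export
psar10g_cache <- function(phantom, props, target_mass = 0.010) {
  props <- validate_tissue_table(props)
  d <- dim(phantom$labels)
  mgrid <- voxel_mass_grid(phantom, props)
  Sm <- integral_image3(mgrid)
  lin <- which(phantom$labels != 0L)
  if (!length(lin)) stop("no tissue voxels")
  ctr <- arrayInd(lin, d)
  kmax <- pmin(ctr[, 1] - 1L, d[1] - ctr[, 1],
               ctr[, 2] - 1L, d[2] - ctr[, 2],
               ctr[, 3] - 1L, d[3] - ctr[, 3])
  n <- length(lin)
  kstar <- rep(NA_integer_, n)
  frac <- rep(NA_real_, n)
  prev_mass <- numeric(n)
  active <- rep(TRUE, n)
  k <- 0L
  while (any(active)) {
    can <- active & kmax >= k
    # voxels that can no longer grow are invalid
    active[active & kmax < k] <- FALSE
    if (!any(can)) break
    mk <- cube_sums(Sm, ctr[can, , drop = FALSE], k)
    hit <- mk >= target_mass
    if (any(hit)) {
      ids <- which(can)[hit]
      kstar[ids] <- k
      frac[ids] <- (target_mass - prev_mass[ids]) / (mk[hit] - prev_mass[ids])
      active[ids] <- FALSE
    }
    ids2 <- which(can)[!hit]
    prev_mass[ids2] <- mk[!hit]
    k <- k + 1L
  }
  valid <- !is.na(kstar)
  if (!any(valid)) stop("no voxel can reach the averaging mass inside the grid")
  list(dim = d, lin = lin, centres = ctr, kstar = kstar, frac = frac,
       valid = valid, target_mass = target_mass, mass_grid = mgrid)
}

#' Peak spatial-average SAR over a 10 g cube
#'
#' For each tissue voxel a centred cube is grown in odd voxel-side steps
#' until the enclosed tissue mass reaches `target_mass`; the spatial-average
#' SAR is the enclosed power of the inner cube plus a linearly weighted
#' fraction of the outermost shell, divided by the target mass (background
#' contributes neither mass nor power). Voxels whose cube reaches the grid
#' boundary before reaching the target mass are excluded. Returns the
#' maximum over valid voxels and its location; ties resolve to the
#' lexicographically smallest voxel index.
#'
#' @inheritParams psar10g_cache
#' @param sar SAR grid from [sar_field()].
#' @param cache optional precomputed [psar10g_cache()]; must match
#'   `target_mass` when supplied.
#' @return list with `value` (W/kg), `location` (1-based voxel index triple)
#'   and `target_mass`.
#' @export
psar10g <- function(sar, phantom, props, target_mass = 0.010, cache = NULL) {
  if (is.null(cache)) cache <- psar10g_cache(phantom, props, target_mass)
  if (cache$target_mass != target_mass)
    stop("cache was built for a different target mass")
  Sp <- integral_image3(sar * cache$mass_grid)
  v <- which(cache$valid)
  avg <- rep(NA_real_, length(cache$lin))
  for (k in sort(unique(cache$kstar[v]))) {
    ids <- v[cache$kstar[v] == k]
    ctr <- cache$centres[ids, , drop = FALSE]
    outer_p <- cube_sums(Sp, ctr, k)
    inner_p <- if (k > 0L) cube_sums(Sp, ctr, k - 1L) else numeric(length(ids))
    avg[ids] <- (inner_p + cache$frac[ids] * (outer_p - inner_p)) / target_mass
  }
  best <- max(avg[v])
  ties <- v[avg[v] == best]
  loc <- cache$centres[ties, , drop = FALSE]
  pick <- order(loc[, 1], loc[, 2], loc[, 3])[1L]
  list(value = best, location = unname(loc[pick, ]), target_mass = target_mass)
}

#' Normalize a SAR grid
#'
#' `raw_B1` leaves the grid on the incident-B1 scale; `absorbed_power_1W`
#' rescales it so the total absorbed power \eqn{\sum SAR_i m_i} equals 1 W —
#' an absorbed-power approximation of net-incident-power normalization (no
#' coil circuit model exists in the quasi-static stand-in).
#'
#' @inheritParams wb_sar
#' @param mode `"raw_B1"` or `"absorbed_power_1W"`.
#' @return the (possibly rescaled) SAR grid.
#' @export
normalize_sar <- function(sar, phantom, props,
                          mode = c("raw_B1", "absorbed_power_1W")) {
  mode <- match.arg(mode)
  if (mode == "raw_B1") return(sar)
  p <- sum(sar * voxel_mass_grid(phantom, props))
  if (p <= 0) stop("zero total absorbed power; cannot normalize")
  sar / p
}

#' One deterministic forward evaluation
#'
#' Runs [sar_field()] at a pose and extracts the three SAR metrics.
#'
#' @inheritParams sar_field
#' @param normalization `"raw_B1"` or `"absorbed_power_1W"`.
#' @param cache optional [psar10g_cache()] for repeated calls.
#' @return list of class `sar_result`: `wbSAR`, `hdSAR` (NA when the phantom
#'   has no head mask), `pSAR10g`, `psar10g_location`, `normalization`,
#'   `pose`.
#' @export
sar_metrics <- function(phantom, props, coil, pose = sarpce::pose(),
                        table_offset = 0.05, tilt_axis = c("long", "pitch"),
                        normalization = c("raw_B1", "absorbed_power_1W"),
                        cache = NULL) {
  tilt_axis <- match.arg(tilt_axis)
  normalization <- match.arg(normalization)
  sar <- sar_field(phantom, props, coil, pose, table_offset, tilt_axis)
  sar <- normalize_sar(sar, phantom, props, normalization)
  pk <- psar10g(sar, phantom, props, cache = cache)
  structure(list(
    wbSAR = wb_sar(sar, phantom, props),
    hdSAR = if (any(phantom$head_mask)) hd_sar(sar, phantom, props) else NA_real_,
    pSAR10g = pk$value,
    psar10g_location = pk$location,
    normalization = normalization,
    pose = unclass(pose)), class = "sar_result")
}
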