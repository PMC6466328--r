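#' Recipe for a stylized synthetic body phantom
#'
#' The generator builds a desk-scale voxel body from nested geometric
#' primitives — skin/fat/muscle shells around bone cores in two legs, an
#' elliptic trunk with paired lungs, heart, liver, stomach, spleen, kidneys,
#' intestine and a spine, and a head with skull, layered brain (grey/white
#' matter, cerebellum) and paired eyes. Organ placement is deliberately
#' left-right asymmetric (heart/stomach/spleen left, liver right) so that
#' body tilt has a nonzero dosimetric effect. Later primitives overwrite
#' earlier ones (painter's order).
#'
#' The default grid is 64 x 64 x 160 voxels at 2 mm. Proportions follow a
#' stylized adult plan (legs 45%, trunk 42%, head 13% of height). `jitter`
#' scales a small seed-driven random perturbation of organ sizes and centres
#' so different seeds yield different individuals.
#'
#' @param height body height in metres.
#' @param dim grid dimensions (x, y, z voxel counts).
#' @param voxel_size voxel edge, metres.
#' @param legs_frac,trunk_frac fractions of height below the trunk top
#'   (head takes the rest).
#' @param jitter relative magnitude of the random geometric perturbation.
#' @param seed integer seed driving all randomness of the generator.
#' @return a list of class `phantom_recipe`.
#' @export
phantom_recipe <- function(height = 0.32, dim = c(64, 64, 160),
                           voxel_size = 0.002, legs_frac = 0.45,
                           trunk_frac = 0.42, jitter = 0.03, seed = 1L) {
  stopifnot(height > 0, voxel_size > 0, length(dim) == 3,
            legs_frac > 0, trunk_frac > 0, legs_frac + trunk_frac < 1,
            jitter >= 0)
  if (height > dim[3] * voxel_size)
    stop("grid too short for the requested height")
  structure(list(height = height, dim = as.integer(dim),
                 voxel_size = voxel_size, legs_frac = legs_frac,
                 trunk_frac = trunk_frac, jitter = jitter,
                 seed = as.integer(seed)),
            class = "phantom_recipe")
}

synthetic_tissue_names <- c(
  "Skin", "Fat", "Muscle", "Cortical_bone", "Spongy_bone", "Lung", "Heart",
  "Liver", "Stomach", "Kidney", "Spleen", "Intestine", "Grey_matter",
  "White_matter", "Cerebellum", "Skull", "Eyes", "Cartilage")

#' Default detailed-to-group tissue map of the synthetic phantoms
#'
#' Brain substructures map to "Brain", the two bone types to "Bone",
#' the intestine to "Intestines"; every other tissue is its own group.
#'
#' @return a [tissue_group_map()].
#' @export
default_tissue_groups <- function() {
  map <- stats::setNames(synthetic_tissue_names, synthetic_tissue_names)
  map[c("Grey_matter", "White_matter", "Cerebellum")] <- "Brain"
  map[c("Cortical_bone", "Spongy_bone")] <- "Bone"
  map["Intestine"] <- "Intestines"
  tissue_group_map(map)
}

#' Generate the heterogeneous reference phantom
#'
#' Deterministic given the recipe seed. Returns the phantom (with head mask
#' and heart-level alignment plane), the detailed 64 MHz tissue table, the
#' emitted mass table, the limb mask used later by the tissue-simplification
#' step, and an analytic primitive-volume mass estimate for auditing.
#'
#' @param recipe a [phantom_recipe()].
#' @return list: `phantom`, `props`, `masses`, `limb_mask`,
#'   `analytic_mass_kg`, `recipe`.
#' @export
generate_reference_phantom <- function(recipe = phantom_recipe()) {
  if (!inherits(recipe, "phantom_recipe")) stop("not a phantom_recipe")
  set.seed(recipe$seed)
  props <- packaged_property_tables()$detailed
  lab_of <- function(nm) props$label[match(nm, props$tissue)]
  d <- recipe$dim; h <- recipe$voxel_size
  H <- recipe$height
  cx <- d[1] * h / 2; cy <- d[2] * h / 2
  # voxel-centre coordinate grids, body frame (origin at grid corner)
  xs <- (seq_len(d[1]) - 0.5) * h - cx
  ys <- (seq_len(d[2]) - 0.5) * h - cy
  zs <- (seq_len(d[3]) - 0.5) * h
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)

  labels <- array(0L, d)
  jit <- function(scale = 1) 1 + stats::rnorm(1, 0, recipe$jitter) * scale
  sh <- function() stats::rnorm(1, 0, recipe$jitter * 0.05)

  z_legs <- H * recipe$legs_frac
  z_trunk <- H * (recipe$legs_frac + recipe$trunk_frac)
  paint_ellipsoid <- function(centre, semi, lab) {
    m <- ((X - centre[1]) / semi[1])^2 + ((Y - centre[2]) / semi[2])^2 +
      ((Z - centre[3]) / semi[3])^2 <= 1
    labels[m] <<- lab
    m
  }
  paint_cyl <- function(centre_xy, r, z0, z1, lab, ry = r, wz = 1) {
    m <- ((X - centre_xy[1]) / (r * wz))^2 +
      ((Y - centre_xy[2]) / (ry * wz))^2 <= 1 & Z >= z0 & Z < z1
    labels[m] <<- lab
    m
  }

  # all transverse dimensions are specified for the canonical 0.32 m body and
  # scale linearly with recipe height
  sc <- H / 0.32

  # --- legs: skin / fat / muscle / cortical bone / spongy core
  leg_r <- sc * 0.017 * jit()
  for (sx in c(-1, 1)) {
    c0 <- c(sx * sc * 0.022, sh())
    paint_cyl(c0, leg_r, 0, z_legs, lab_of("Skin"))
    paint_cyl(c0, leg_r - sc * 0.0025, 0, z_legs, lab_of("Fat"))
    paint_cyl(c0, leg_r - sc * 0.0060, 0, z_legs, lab_of("Muscle"))
    paint_cyl(c0, sc * 0.0045, 0, z_legs, lab_of("Cortical_bone"))
    paint_cyl(c0, sc * 0.0025, 0, z_legs, lab_of("Spongy_bone"))
  }

  # --- trunk: skin / fat / muscle shells, then organs in painter's order;
  # the section tapers monotonically from the hips to the shoulders so the
  # body has a unique widest ring (no degenerate constant-width surface)
  ta <- sc * 0.055 * jit(); tb <- sc * 0.035 * jit()
  u <- pmin(pmax((Z - z_legs) / (z_trunk - z_legs), 0), 1)
  trunk_w <- 1 - 0.15 * u
  paint_cyl(c(0, 0), ta, z_legs, z_trunk, lab_of("Skin"), ry = tb,
            wz = trunk_w)
  paint_cyl(c(0, 0), ta - sc * 0.004, z_legs, z_trunk, lab_of("Fat"),
            ry = tb - sc * 0.004, wz = trunk_w)
  paint_cyl(c(0, 0), ta - sc * 0.008, z_legs, z_trunk, lab_of("Muscle"),
            ry = tb - sc * 0.008, wz = trunk_w)
  z_heart <- z_legs + 0.585 * (z_trunk - z_legs) + sh()
  org <- function(name, centre, semi)
    paint_ellipsoid(c(sc * centre[1] + sh(), sc * centre[2] + sh(),
                      centre[3] + sh()),
                    sc * semi * jit(), lab_of(name))
  org("Intestine", c(0, 0.004, z_legs + 0.135 * (z_trunk - z_legs)),
      c(0.032, 0.018, 0.015))
  for (sx in c(-1, 1))
    org("Lung", c(sx * 0.021, -0.002, z_legs + 0.72 * (z_trunk - z_legs)),
        c(0.016, 0.019, 0.026))
  org("Liver", c(0.018, 0.003, z_legs + 0.37 * (z_trunk - z_legs)),
      c(0.024, 0.018, 0.016))
  org("Stomach", c(-0.016, 0.002, z_legs + 0.385 * (z_trunk - z_legs)),
      c(0.014, 0.012, 0.013))
  org("Spleen", c(-0.030, -0.004, z_legs + 0.385 * (z_trunk - z_legs)),
      c(0.008, 0.009, 0.011))
  for (sx in c(-1, 1))
    org("Kidney", c(sx * 0.016, -0.016, z_legs + 0.255 * (z_trunk - z_legs)),
        c(0.008, 0.007, 0.012))
  org("Heart", c(-0.008, 0.004, z_heart), c(0.013, 0.013, 0.014))
  paint_cyl(c(0, -sc * 0.024), sc * 0.008, z_legs, z_trunk, lab_of("Cortical_bone"))
  paint_cyl(c(0, -sc * 0.024), sc * 0.004, z_legs, z_trunk, lab_of("Spongy_bone"))
  paint_cyl(c(0, sc * 0.006), sc * 0.004, z_trunk - sc * 0.025,
            z_trunk + sc * 0.008, lab_of("Cartilage"))

  # --- head: skin / skull / grey / white / cerebellum / eyes
  zc_head <- z_trunk + 0.55 * (H - z_trunk)
  hs <- sc * c(0.027, 0.029, 0.025) * jit()
  paint_ellipsoid(c(0, 0, zc_head), hs, lab_of("Skin"))
  paint_ellipsoid(c(0, 0, zc_head), hs - sc * 0.003, lab_of("Skull"))
  paint_ellipsoid(c(0, 0, zc_head), hs - sc * 0.006, lab_of("Grey_matter"))
  paint_ellipsoid(c(0, 0, zc_head), hs - sc * 0.010, lab_of("White_matter"))
  paint_ellipsoid(c(0, -sc * 0.009, zc_head - sc * 0.013),
                  sc * c(0.009, 0.008, 0.006), lab_of("Cerebellum"))
  for (sx in c(-1, 1))
    paint_ellipsoid(c(sx * sc * 0.010, hs[2] - sc * 0.006, zc_head + sc * 0.004),
                    rep(sc * 0.0035, 3), lab_of("Eyes"))

  head_mask <- labels != 0L & Z >= z_trunk
  limb_mask <- labels != 0L & Z < z_legs
  phantom <- voxel_phantom(labels, h, origin = c(0, 0, 0),
                           head_mask = head_mask, long_axis = 3L,
                           alignment_z = z_heart)
  # analytic envelope estimate: outer primitive volumes at water density;
  # 0.8575 is the mean squared trunk taper, int (1 - 0.15 u)^2 du
  analytic <- (2 * pi * leg_r^2 * z_legs +
               pi * ta * tb * (z_trunk - z_legs) * 0.8575 +
               4 / 3 * pi * prod(hs)) * 1000
  list(phantom = phantom, props = props,
       masses = tissue_masses(phantom, props),
       limb_mask = limb_mask, analytic_mass_kg = analytic, recipe = recipe)
}

#' Derive the tissue-simplified individualized phantom
#'
#' Emulates an individualized body model built from a reference: detailed
#' tissues are relabelled to their homogenized groups, limb voxels are
#' assumed homogeneous muscle, dielectric properties of each group are
#' mass-homogenized from the reference masses, and a small smooth radial
#' perturbation (low-order scaling of the transverse section along the body
#' axis, nearest-neighbour label resampling) emulates registration error.
#' The perturbation amplitude is clamped so that total-body mass deviates by
#' less than 10% from the reference.
#'
#' @param reference output of [generate_reference_phantom()].
#' @param groups a [tissue_group_map()] covering all reference tissues.
#' @param perturbation standard deviation of the radial-scaling coefficients
#'   (0 reproduces the reference geometry exactly).
#' @param seed RNG seed for the perturbation.
#' @return list: `phantom` (group-labelled), `props` (homogenized
#'   [tissue_table()]), `masses`.
#' @export
derive_individual_phantom <- function(reference,
                                      groups = default_tissue_groups(),
                                      perturbation = 0.02, seed = 2L) {
  ref <- reference$phantom
  props <- reference$props
  if (!all(props$tissue[props$label != 0L] %in% names(groups)))
    stop("group map does not cover all reference tissues")
  # homogenize over the tissues actually present (a coarse grid may miss the
  # smallest primitives entirely; absent tissues have no voxels to relabel)
  present <- reference$masses[reference$masses$mass_kg > 0, , drop = FALSE]
  hom <- homogenize_dielectrics(present, props, groups)
  # detailed label -> group label lookup (index by label value)
  g_of <- stats::setNames(hom$label[match(unclass(groups), hom$tissue)],
                          names(groups))
  lut <- integer(max(props$label) + 1L)
  for (r in seq_len(nrow(props))) {
    lb <- props$label[r]
    g <- g_of[props$tissue[r]]
    lut[lb + 1L] <- if (lb == 0L || is.na(g)) 0L else unname(g)
  }
  labels <- array(lut[ref$labels + 1L], dim(ref$labels))
  # limbs homogeneous muscle
  muscle <- hom$label[hom$tissue == "Muscle"]
  if (length(muscle) == 1L) labels[reference$limb_mask] <- muscle
  head_mask <- ref$head_mask

  if (perturbation > 0) {
    set.seed(seed)
    H <- reference$recipe$height
    a <- stats::rnorm(3, 0, perturbation)
    cap <- min(2 * perturbation, 0.048)
    d <- dim(labels); h <- ref$voxel_size
    cx <- d[1] * h[1] / 2; cy <- d[2] * h[2] / 2
    zs <- (seq_len(d[3]) - 0.5) * h[3]
    s <- 1 + a[1] + a[2] * cos(pi * zs / H) + a[3] * sin(pi * zs / H)
    s <- pmin(pmax(s, 1 - cap), 1 + cap)
    # inverse-map output voxel centres into the reference frame (per slice)
    i_idx <- seq_len(d[1]); j_idx <- seq_len(d[2])
    xs <- (i_idx - 0.5) * h[1] - cx
    ys <- (j_idx - 0.5) * h[2] - cy
    new_labels <- array(0L, d)
    new_head <- array(FALSE, d)
    for (k in seq_len(d[3])) {
      si <- round((xs / s[k] + cx) / h[1] + 0.5)
      sj <- round((ys / s[k] + cy) / h[2] + 0.5)
      ok_i <- si >= 1 & si <= d[1]; ok_j <- sj >= 1 & sj <= d[2]
      src <- labels[, , k]
      hm <- head_mask[, , k]
      block <- matrix(0L, d[1], d[2]); hblock <- matrix(FALSE, d[1], d[2])
      block[ok_i, ok_j] <- src[si[ok_i], sj[ok_j]]
      hblock[ok_i, ok_j] <- hm[si[ok_i], sj[ok_j]]
      new_labels[, , k] <- block
      new_head[, , k] <- hblock
    }
    labels <- new_labels
    head_mask <- new_head & labels != 0L
  }

  phantom <- voxel_phantom(labels, ref$voxel_size, ref$origin,
                           head_mask & labels != 0L, ref$long_axis,
                           ref$alignment_z)
  list(phantom = phantom, props = hom,
       masses = tissue_masses(phantom, hom))
}

#' Generate the canonical reference/individual fixture pair
#'
#' One call producing everything the study pipeline consumes: the
#' heterogeneous reference phantom, its tissue-simplified individualized
#' counterpart, their tissue tables and mass tables, and the group map.
#'
#' @param recipe a [phantom_recipe()]; its seed is overridden by `seed`.
#' @param seed master seed (reference uses `seed`, perturbation `seed + 1`).
#' @param perturbation passed to [derive_individual_phantom()].
#' @return list: `reference`, `individual` (each `phantom`/`props`/`masses`),
#'   `groups`, `recipe`.
#' @export
make_fixture_pair <- function(recipe = NULL, seed = 20190325L,
                              perturbation = 0.02) {
  if (is.null(recipe)) recipe <- phantom_recipe(seed = seed)
  else recipe$seed <- as.integer(seed)
  ref <- generate_reference_phantom(recipe)
  groups <- default_tissue_groups()
  ind <- derive_individual_phantom(ref, groups, perturbation,
                                   seed = seed + 1L)
  list(reference = ref[c("phantom", "props", "masses")],
       individual = ind, groups = groups, recipe = recipe,
       reference_extra = ref[c("limb_mask", "analytic_mass_kg")])
}
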