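#' Construct and validate a tissue-property table
#'
#' A tissue-property table holds, for every tissue label that can appear in a
#' voxel phantom, its name, integer label, electrical conductivity \eqn{\sigma}
#' (S/m), relative permittivity \eqn{\epsilon'} (dimensionless) and mass
#' density \eqn{\rho} (kg/m^3) at the working frequency. Exactly one row must
#' describe the background (label 0) with \eqn{\sigma = 0}, \eqn{\epsilon' = 1}
#' and \eqn{\rho = 0}; every tissue row must satisfy \eqn{\sigma \ge 0},
#' \eqn{\epsilon' \ge 1} and \eqn{\rho > 0}.
#'
#' @param tissue character vector of tissue names (unique).
#' @param label integer vector of non-negative, unique voxel labels.
#' @param sigma conductivity in S/m.
#' @param eps_r relative permittivity.
#' @param rho mass density in kg/m^3.
#' @return A `data.frame` of class `tissue_table` with columns
#'   `tissue`, `label`, `sigma_S_per_m`, `eps_r`, `rho_kg_per_m3`.
#' @examples
#' tissue_table(c("Background", "Muscle"), c(0L, 1L),
#'              c(0, 0.69), c(1, 72.24), c(0, 1090))
#' @export
tissue_table <- function(tissue, label, sigma, eps_r, rho) {
  tab <- data.frame(tissue = as.character(tissue),
                    label = as.integer(label),
                    sigma_S_per_m = as.numeric(sigma),
                    eps_r = as.numeric(eps_r),
                    rho_kg_per_m3 = as.numeric(rho),
                    stringsAsFactors = FALSE)
  validate_tissue_table(tab)
}

#' @rdname tissue_table
#' @param tab a data frame with the five tissue-table columns.
#' @export
validate_tissue_table <- function(tab) {
  need <- c("tissue", "label", "sigma_S_per_m", "eps_r", "rho_kg_per_m3")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("tissue table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$label))
    stop("tissue labels must be unique")
  if (anyDuplicated(tab$tissue))
    stop("tissue names must be unique")
  if (any(tab$label < 0))
    stop("tissue labels must be non-negative")
  bg <- tab$label == 0L
  if (sum(bg) != 1L)
    stop("exactly one background row (label 0) is required")
  if (tab$sigma_S_per_m[bg] != 0 || tab$rho_kg_per_m3[bg] != 0)
    stop("background row must have sigma = 0 and rho = 0")
  ts <- tab[!bg, , drop = FALSE]
  if (any(ts$sigma_S_per_m < 0))
    stop("tissue conductivity must be >= 0")
  if (any(ts$eps_r < 1))
    stop("tissue relative permittivity must be >= 1")
  if (any(ts$rho_kg_per_m3 <= 0))
    stop("tissue density must be > 0")
  class(tab) <- c("tissue_table", "data.frame")
  tab
}

#' Read or write a tissue-property table as CSV
#'
#' Plain comma-separated text with the header
#' `tissue,label,sigma_S_per_m,eps_r,rho_kg_per_m3`.
#'
#' @param path file path.
#' @return `read_tissue_table` returns a validated [tissue_table()];
#'   `write_tissue_table` returns `path` invisibly.
#' @export
read_tissue_table <- function(path) {
  if (!file.exists(path)) stop("tissue table file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$label <- as.integer(tab$label)
  validate_tissue_table(tab)
}

#' @rdname read_tissue_table
#' @param tab a [tissue_table()].
#' @export
write_tissue_table <- function(tab, path) {
  tab <- validate_tissue_table(tab)
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged 64 MHz tissue dielectric tables
#'
#' Two constant tables shipped with the package: `detailed`, literature-style
#' dielectric properties and densities of the individual tissues used by the
#' synthetic phantoms, and `homogenized`, published mass-homogenized values for
#' the grouped tissues of a simplified individualized body model (Eyes, Brain,
#' Cartilage, Skull, Muscle, Stomach). The homogenized values are shipped as
#' constants because the constituent masses behind them are not available to
#' recompute them; densities in that table are representative values required
#' by the table invariants, not part of the published data.
#'
#' @return a list with elements `detailed` and `homogenized`, each a
#'   [tissue_table()].
#' @examples
#' tabs <- packaged_property_tables()
#' subset(tabs$homogenized, tissue == "Muscle")
#' @export
packaged_property_tables <- function() {
  dir <- system.file("extdata", package = "sarpce", mustWork = TRUE)
  list(detailed = read_tissue_table(file.path(dir, "detailed_dielectrics_64mhz.csv")),
       homogenized = read_tissue_table(file.path(dir, "homogenized_dielectrics_64mhz.csv")))
}

#' Map detailed tissues onto homogenized groups
#'
#' A tissue-group map sends every detailed tissue name to the name of the
#' simplified group it belongs to (for instance all ocular tissues to "Eyes",
#' or the brain substructures to "Brain"). Used by
#' [homogenize_dielectrics()] and [derive_individual_phantom()].
#'
#' @param map a named character vector: `names(map)` are detailed tissue
#'   names, values are group names.
#' @return the map with class `tissue_group_map`.
#' @export
tissue_group_map <- function(map) {
  if (is.null(names(map)) || any(!nzchar(names(map))))
    stop("group map must be a named character vector (detailed -> group)")
  if (anyDuplicated(names(map)))
    stop("each detailed tissue must map to exactly one group")
  map <- vapply(map, as.character, character(1))
  class(map) <- "tissue_group_map"
  map
}

#' Per-tissue mass accounting
#'
#' Mass of tissue i is (voxel count of label i) x voxel volume x density.
#' The background (label 0) carries zero mass.
#'
#' @param phantom a [voxel_phantom()].
#' @param props a [tissue_table()] covering every label in the phantom.
#' @return a `data.frame` with columns `tissue`, `label`, `mass_kg`, ordered as
#'   in `props` (background excluded).
#' @export
tissue_masses <- function(phantom, props) {
  props <- validate_tissue_table(props)
  check_phantom_labels(phantom, props)
  vox_vol <- prod(phantom$voxel_size)
  counts <- tabulate(match(phantom$labels, props$label), nbins = nrow(props))
  out <- data.frame(tissue = props$tissue,
                    label = props$label,
                    mass_kg = counts * vox_vol * props$rho_kg_per_m3,
                    stringsAsFactors = FALSE)
  out[out$label != 0L, , drop = FALSE]
}

#' Mass-weighted dielectric homogenization
#'
#' Replaces each group of tissues by a single material whose complex
#' permittivity is the mass-weighted mean of its constituents,
#' \deqn{\tilde\epsilon_{hom} = \sum_i \tilde\epsilon_i m_i / \sum_i m_i,}
#' which, the weighting being linear in each component of
#' \eqn{\tilde\epsilon = \sigma + j\omega\epsilon'}, amounts to mass-weighted
#' means of \eqn{\sigma} and \eqn{\epsilon'} separately. Group density is the
#' group's total mass over its total volume (the harmonic mass-weighted mean
#' \eqn{\sum m_i / \sum (m_i/\rho_i)}), so that relabelling the group's
#' voxels to one material preserves total mass exactly.
#'
#' @param masses per-tissue mass table from [tissue_masses()].
#' @param props detailed [tissue_table()].
#' @param groups a [tissue_group_map()] covering every tissue in `masses`.
#' @return a [tissue_table()] with one row per group (plus background),
#'   group labels assigned 1..G in first-appearance order.
#' @examples
#' props <- tissue_table(c("Background", "A", "B"), 0:2,
#'                       c(0, 0.5, 1.0), c(1, 60, 80), c(0, 1000, 1000))
#' masses <- data.frame(tissue = c("A", "B"), label = 1:2, mass_kg = c(1, 3))
#' groups <- tissue_group_map(c(A = "AB", B = "AB"))
#' homogenize_dielectrics(masses, props, groups)  # sigma 0.875 S/m
#' @export
homogenize_dielectrics <- function(masses, props, groups) {
  props <- validate_tissue_table(props)
  if (!all(masses$tissue %in% names(groups)))
    stop("group map does not cover tissues: ",
         paste(setdiff(masses$tissue, names(groups)), collapse = ", "))
  if (!all(masses$tissue %in% props$tissue))
    stop("property table does not cover tissues in the mass table")
  grp <- unname(unclass(groups)[masses$tissue])
  gnames <- unique(grp)
  pr <- props[match(masses$tissue, props$tissue), ]
  agg <- function(v) vapply(gnames, function(g) {
    i <- grp == g
    m <- masses$mass_kg[i]
    tot <- sum(m)
    if (tot <= 0) stop("group with zero total mass: ", g)
    sum(v[i] * m) / tot
  }, numeric(1))
  # density as total mass / total volume: relabelling conserves mass exactly
  rho_g <- vapply(gnames, function(g) {
    i <- grp == g
    sum(masses$mass_kg[i]) / sum(masses$mass_kg[i] / pr$rho_kg_per_m3[i])
  }, numeric(1))
  tissue_table(c("Background", gnames),
               c(0L, seq_along(gnames)),
               c(0, agg(pr$sigma_S_per_m)),
               c(1, agg(pr$eps_r)),
               c(0, rho_g))
}

#' Dice overlap coefficient of two voxel sets, in percent
#'
#' \eqn{2|X \cap Y| / (|X| + |Y|) \times 100}. The sets are given either as
#' logical masks over a common grid or as matrices of voxel indices (rows =
#' voxels). Two empty sets give 0 by convention (documented choice; the
#' overlap of nothing with nothing is reported as no overlap rather than NaN).
#'
#' @param x,y logical arrays of identical dimension, or integer matrices of
#'   voxel index triples over a common grid.
#' @return Dice coefficient in percent, in \[0, 100\].
#' @export
dice_coefficient <- function(x, y) {
  if (is.logical(x) && is.logical(y)) {
    if (!identical(dim(x), dim(y)))
      stop("masks must share a common grid")
    nx <- sum(x); ny <- sum(y); ni <- sum(x & y)
  } else {
    xk <- apply(as.matrix(x), 1L, paste, collapse = ",")
    yk <- apply(as.matrix(y), 1L, paste, collapse = ",")
    nx <- length(unique(xk)); ny <- length(unique(yk))
    ni <- length(intersect(unique(xk), unique(yk)))
  }
  if (nx + ny == 0L) return(0)
  2 * ni / (nx + ny) * 100
}

#' Compare a reference model with its individualized counterpart
#'
#' Produces the per-tissue comparison table used to audit a simplified
#' individualized body model against its reference: masses of both models,
#' weight deviation (individual - reference) / reference x 100, and, when both
#' phantoms are supplied on matching grids, the per-tissue Dice overlap.
#' A "Total" row sums the masses.
#'
#' @param ref_masses,ind_masses mass tables from [tissue_masses()] (or any
#'   data frame with `tissue` and `mass_kg`). Tissues are matched by name;
#'   every tissue of `ref_masses` must appear in `ind_masses`.
#' @param ref_phantom,ind_phantom optional [voxel_phantom()]s on identical
#'   grids; when given, Dice is computed per shared label.
#' @return a `data.frame` with columns `tissue`, `reference_kg`,
#'   `individual_kg`, `weight_deviation_pct` and `dice_pct` (NA when not
#'   computable), the last row being the total.
#' @export
compare_models <- function(ref_masses, ind_masses,
                           ref_phantom = NULL, ind_phantom = NULL) {
  i <- match(ref_masses$tissue, ind_masses$tissue)
  if (anyNA(i))
    stop("individual mass table is missing tissues: ",
         paste(ref_masses$tissue[is.na(i)], collapse = ", "))
  ref <- ref_masses$mass_kg
  ind <- ind_masses$mass_kg[i]
  dice <- rep(NA_real_, length(ref))
  if (!is.null(ref_phantom) && !is.null(ind_phantom)) {
    if (!identical(dim(ref_phantom$labels), dim(ind_phantom$labels)))
      stop("Dice requested but phantom grids differ")
    lab <- ref_masses$label
    if (!is.null(lab) && !is.null(ind_masses$label)) {
      lab_ind <- ind_masses$label[i]
      for (k in seq_along(lab))
        dice[k] <- dice_coefficient(ref_phantom$labels == lab[k],
                                    ind_phantom$labels == lab_ind[k])
    }
  }
  out <- data.frame(tissue = c(ref_masses$tissue, "Total"),
                    reference_kg = c(ref, sum(ref)),
                    individual_kg = c(ind, sum(ind)),
                    stringsAsFactors = FALSE)
  out$weight_deviation_pct <- weight_deviation(out$reference_kg, out$individual_kg)
  out$dice_pct <- c(dice, NA_real_)
  out
}

#' Weight deviation convention
#'
#' (individual - reference) / reference x 100; the reference (manually
#' segmented) model is always the denominator.
#'
#' @param reference,individual masses (kg) or any paired positive quantities.
#' @return deviation in percent.
#' @export
weight_deviation <- function(reference, individual) {
  (individual - reference) / reference * 100
}
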