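#' Voxel phantom container
#'
#' A labelled 3-D tissue grid with its geometry metadata: integer labels
#' (0 = background), isotropic or anisotropic voxel size in metres, the body
#' frame origin (position of the corner of voxel (1,1,1)), a head mask, the
#' grid axis aligned with the superior-inferior body axis, and the body-frame
#' z coordinate of the coil alignment plane (the central heart level used to
#' define the standard position).
#'
#' Voxel centres are at `origin + (index - 1 + 0.5) * voxel_size` (1-based
#' indices, as everywhere in R); serialized locations are 0-based for
#' interoperability.
#'
#' @param labels 3-D integer array of tissue labels, 0 for background.
#' @param voxel_size voxel edge length(s) in metres; length 1 or 3.
#' @param origin numeric length-3, metres; default zero.
#' @param head_mask logical array, same shape, subset of tissue voxels;
#'   default none.
#' @param long_axis which grid axis (1, 2 or 3) runs along the body's long
#'   axis; default 3.
#' @param alignment_z body-frame z (metres, along `long_axis`) of the plane
#'   aligned to the coil centre in the standard position.
#' @return an object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(labels, voxel_size, origin = c(0, 0, 0),
                          head_mask = NULL, long_axis = 3L,
                          alignment_z = NA_real_) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be positive (length 1 or 3, metres)")
  if (is.null(head_mask)) head_mask <- array(FALSE, dim(labels))
  if (!identical(dim(head_mask), dim(labels)))
    stop("head_mask must match the label grid")
  if (any(head_mask & labels == 0L))
    stop("head_mask must be a subset of tissue voxels")
  long_axis <- as.integer(long_axis)
  if (!long_axis %in% 1:3) stop("long_axis must be 1, 2 or 3")
  structure(list(labels = labels,
                 voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin),
                 head_mask = head_mask,
                 long_axis = long_axis,
                 alignment_z = as.numeric(alignment_z)),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("voxel_phantom: %d x %d x %d grid, voxel %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_size * 1000), collapse = " x ")))
  cat(sprintf("  tissue voxels: %d (%d labels), head voxels: %d\n",
              sum(x$labels != 0L), length(setdiff(unique(as.vector(x$labels)), 0L)),
              sum(x$head_mask)))
  cat(sprintf("  long axis: %d, alignment plane z = %s m\n",
              x$long_axis, format(x$alignment_z)))
  invisible(x)
}

check_phantom_labels <- function(phantom, props) {
  labs <- setdiff(sort(unique(as.vector(phantom$labels))), 0L)
  unknown <- setdiff(labs, props$label)
  if (length(unknown))
    stop("labels present in volume but absent from tissue table: ",
         paste(unknown, collapse = ", "))
  invisible(labs)
}

#' Write and read a voxel phantom (raw volume + YAML sidecar)
#'
#' The on-disk format is a raw little-endian int32 volume (`<stem>.raw`,
#' Fortran/column-major order as stored in R arrays), an optional uint8
#' head-mask plane (`<stem>.mask.raw`), and a YAML sidecar (`<stem>.yaml`)
#' holding shape, voxel size, origin, long axis and alignment plane. The
#' sidecar is the source of truth for geometry. When `table_path` is given,
#' `read_phantom` also reads and cross-validates the companion tissue table:
#' any volume label missing from the table is an error.
#'
#' @param phantom a [voxel_phantom()].
#' @param stem path stem (without extension).
#' @return `write_phantom` returns the stem invisibly; `read_phantom` returns
#'   the phantom, or `list(phantom, props)` when `table_path` is given.
#' @export
write_phantom <- function(phantom, stem) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  con <- file(paste0(stem, ".raw"), "wb")
  writeBin(as.vector(phantom$labels), con, size = 4L, endian = "little")
  close(con)
  has_mask <- any(phantom$head_mask)
  if (has_mask) {
    con <- file(paste0(stem, ".mask.raw"), "wb")
    writeBin(as.integer(phantom$head_mask), con, size = 1L)
    close(con)
  }
  meta <- list(format = "sarpce-phantom-v1",
               shape = as.integer(dim(phantom$labels)),
               dtype = "int32-le",
               order = "column-major",
               voxel_size_m = phantom$voxel_size,
               origin_m = phantom$origin,
               long_axis = phantom$long_axis,
               alignment_z_m = phantom$alignment_z,
               head_mask = if (has_mask) basename(paste0(stem, ".mask.raw")) else NULL)
  yaml::write_yaml(meta, paste0(stem, ".yaml"))
  invisible(stem)
}

#' @rdname write_phantom
#' @param table_path optional path to a companion tissue-table CSV.
#' @export
read_phantom <- function(stem, table_path = NULL) {
  side <- paste0(stem, ".yaml")
  if (!file.exists(side)) stop("sidecar not found: ", side)
  meta <- yaml::read_yaml(side)
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  con <- file(paste0(stem, ".raw"), "rb")
  v <- readBin(con, integer(), n = n, size = 4L, endian = "little")
  close(con)
  if (length(v) != n) stop("raw volume shorter than sidecar shape")
  mask <- NULL
  if (!is.null(meta$head_mask)) {
    con <- file(file.path(dirname(stem), meta$head_mask), "rb")
    mask <- array(readBin(con, integer(), n = n, size = 1L) != 0L, shape)
    close(con)
  }
  ph <- voxel_phantom(array(v, shape), meta$voxel_size_m, meta$origin_m,
                      mask, meta$long_axis,
                      if (is.null(meta$alignment_z_m)) NA_real_ else meta$alignment_z_m)
  if (is.null(table_path)) return(ph)
  props <- read_tissue_table(table_path)
  check_phantom_labels(ph, props)
  list(phantom = ph, props = props)
}

#' Export a phantom label volume to NIfTI
#'
#' Convenience interoperability export via the RNifti package; the raw +
#' sidecar format remains the canonical representation.
#'
#' @param phantom a [voxel_phantom()].
#' @param path output `.nii` or `.nii.gz` path.
#' @export
write_phantom_nifti <- function(phantom, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  img <- RNifti::asNifti(phantom$labels)
  RNifti::pixdim(img) <- phantom$voxel_size * 1000  # NIfTI mm convention
  RNifti::writeNifti(img, path)
  invisible(path)
}
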