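#' 3-D image volume
#'
#' Lightweight container for a 3-D scalar volume on a regular grid. Voxel
#' arrays are stored in `(z, y, x)` axis order with 0-based voxel coordinates;
#' the world position of voxel `(i, j, k)` is `origin + c(i, j, k) * spacing`
#' (millimetres).
#'
#' @param data Numeric 3-D array in `(z, y, x)` order.
#' @param spacing Numeric length-3 vector of voxel spacing in mm per axis
#'   (`z`, `y`, `x`); all entries must be positive.
#' @param origin Numeric length-3 world coordinate (mm) of voxel `(0, 0, 0)`.
#' @param modality One of `"PET-activity"` (kBq/mL), `"PET-SUV"`, `"CT-HU"`,
#'   or `"other"`.
#'
#' @return An object of class `volume3d`.
#' @examples
#' v <- volume3d(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
#' voxel_volume_cm3(v)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     modality = c("other", "PET-activity", "PET-SUV", "CT-HU")) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_moesurv("'data' must be a 3-D array")
  if (any(!is.finite(data))) stop_moesurv("volume voxels must be finite")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_moesurv("'spacing' must be 3 positive values")
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin), modality = modality),
    class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d %s  dim %s  spacing %s mm  range [%.3g, %.3g]>\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname volume3d
#' @param v A `volume3d`.
#' @export
voxel_volume_cm3 <- function(v) prod(v$spacing) / 1000

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over \pkg{RNifti}. On disk the array uses the conventional
#' NIfTI `(x, y, z)` order; in memory `volume3d` uses `(z, y, x)`, so axes are
#' permuted on the way through.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param modality Modality tag to attach on read.
#' @return `read_volume` returns a `volume3d`; `write_volume` returns `path`
#'   invisibly.
#' @export
read_volume <- function(path, modality = "other") {
  img <- RNifti::readNifti(path)
  arr <- aperm(as.array(img), c(3, 2, 1))
  sp <- rev(RNifti::pixdim(img))
  volume3d(arr, spacing = sp, modality = modality)
}

#' @rdname read_volume
#' @param v A `volume3d` (or a logical mask array of the same shape).
#' @export
write_volume <- function(v, path) {
  arr <- aperm(v$data, c(3, 2, 1))
  img <- RNifti::asNifti(structure(arr, pixdim = rev(v$spacing)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Trilinear sampler: `coords` is an n x 3 matrix of fractional 0-based (z,y,x)
# voxel indices into `arr`. Points outside the grid return `fill`.
trilinear_sample <- function(arr, coords, fill = NA_real_) {
  d <- dim(arr)
  out <- rep(fill, nrow(coords))
  eps <- 1e-9
  inside <- coords[, 1] >= -eps & coords[, 1] <= d[1] - 1 + eps &
    coords[, 2] >= -eps & coords[, 2] <= d[2] - 1 + eps &
    coords[, 3] >= -eps & coords[, 3] <= d[3] - 1 + eps
  if (!any(inside)) return(out)
  co <- coords[inside, , drop = FALSE]
  co[, 1] <- pmin(pmax(co[, 1], 0), d[1] - 1)
  co[, 2] <- pmin(pmax(co[, 2], 0), d[2] - 1)
  co[, 3] <- pmin(pmax(co[, 3], 0), d[3] - 1)
  f <- floor(co + eps)
  f <- pmin(f, matrix(rep(d - 1, each = nrow(co)), ncol = 3) - 1)
  f <- pmax(f, 0)
  w <- co - f
  w[w < 0] <- 0; w[w > 1] <- 1
  acc <- numeric(nrow(co))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wt <- (if (dz == 1) w[, 1] else 1 - w[, 1]) *
      (if (dy == 1) w[, 2] else 1 - w[, 2]) *
      (if (dx == 1) w[, 3] else 1 - w[, 3])
    idx <- cbind(f[, 1] + dz + 1, f[, 2] + dy + 1, f[, 3] + dx + 1)
    acc <- acc + wt * arr[idx]
  }
  out[inside] <- acc
  out
}

# All voxel-centre fractional input coordinates for an output grid with
# `dims_out` voxels at `spacing_out`, expressed in the input grid's 0-based
# index space (shared origin).
output_grid_coords <- function(dims_out, spacing_out, spacing_in,
                               origin_out = c(0, 0, 0), origin_in = c(0, 0, 0)) {
  gz <- (origin_out[1] - origin_in[1] + (seq_len(dims_out[1]) - 1) * spacing_out[1]) / spacing_in[1]
  gy <- (origin_out[2] - origin_in[2] + (seq_len(dims_out[2]) - 1) * spacing_out[2]) / spacing_in[2]
  gx <- (origin_out[3] - origin_in[3] + (seq_len(dims_out[3]) - 1) * spacing_out[3]) / spacing_in[3]
  as.matrix(expand.grid(z = gz, y = gy, x = gx, KEEP.OUT.ATTRS = FALSE))
}

#' Resample a volume to a target voxel spacing
#'
#' Trilinear interpolation onto a grid with the same origin and physical
#' extent; the new grid has `round(dim * spacing / target_spacing)` voxels per
#' axis (at least 1).
#'
#' @param v A `volume3d` with at least 2 slices along every axis.
#' @param target_spacing Numeric length-3 (or scalar, recycled) spacing in mm.
#' @param ref Optional reference `volume3d`; when given, the output is sampled
#'   on `ref`'s grid (its dims, spacing and origin) instead.
#' @return A resampled `volume3d`.
#' @export
resample_volume <- function(v, target_spacing, ref = NULL) {
  if (any(dim(v$data) < 2L))
    stop_moesurv("cannot resample a degenerate (single-slice) volume")
  if (is.null(ref)) {
    target_spacing <- rep(as.numeric(target_spacing), length.out = 3L)
    if (any(target_spacing <= 0)) stop_moesurv("'target_spacing' must be > 0")
    dims_out <- pmax(1L, as.integer(round(dim(v$data) * v$spacing / target_spacing)))
    origin_out <- v$origin
  } else {
    dims_out <- dim(ref$data)
    target_spacing <- ref$spacing
    origin_out <- ref$origin
  }
  co <- output_grid_coords(dims_out, target_spacing, v$spacing,
                           origin_out, v$origin)
  vals <- trilinear_sample(v$data, co, fill = 0)
  volume3d(array(vals, dims_out), spacing = target_spacing,
           origin = origin_out, modality = v$modality)
}
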