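# Classical radiomics: fixed, versioned feature vector (first-order, shape,
# grey-level co-occurrence) computed on a masked 2-D slice or 3-D VOI.

RADIOMICS_VERSION <- "1.0"

radiomics_feature_names <- function() {
  c("fo_mean", "fo_median", "fo_variance", "fo_skewness", "fo_kurtosis",
    "fo_energy", "fo_entropy", "fo_min", "fo_max", "fo_p10", "fo_p90",
    "shape_size", "shape_boundary", "shape_sphericity",
    "glcm_contrast", "glcm_correlation", "glcm_asm",
    "glcm_homogeneity", "glcm_entropy")
}

quantize_levels <- function(x, bins) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(1L, length(x)))
  pmin(bins, as.integer(floor((x - r[1]) / (r[2] - r[1]) * bins)) + 1L)
}

# Symmetrically normalized co-occurrence matrix of quantized image `q`
# (integer array, NA outside the mask) for one integer offset.
glcm_matrix <- function(q, offset, bins) {
  d <- dim(q)
  nd <- length(d)
  src <- lapply(seq_len(nd), function(ax) {
    i <- seq_len(d[ax])
    i[i + offset[ax] >= 1 & i + offset[ax] <= d[ax]]
  })
  if (any(!lengths(src))) return(NULL)
  dst <- lapply(seq_len(nd), function(ax) src[[ax]] + offset[ax])
  a <- do.call(`[`, c(list(q), src, list(drop = FALSE)))
  b <- do.call(`[`, c(list(q), dst, list(drop = FALSE)))
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(NULL)
  i <- a[keep]; j <- b[keep]
  P <- matrix(0, bins, bins)
  tab <- table(factor(i, levels = 1:bins), factor(j, levels = 1:bins))
  P <- tab + t(tab)          # symmetric accumulation
  P / sum(P)
}

glcm_features <- function(P) {
  lv <- seq_len(nrow(P))
  ii <- matrix(lv, nrow(P), ncol(P))
  jj <- t(ii)
  px <- rowSums(P); py <- colSums(P)
  mx <- sum(lv * px); my <- sum(lv * py)
  sx <- sqrt(sum((lv - mx)^2 * px)); sy <- sqrt(sum((lv - my)^2 * py))
  contrast <- sum(P * (ii - jj)^2)
  correlation <- if (sx > 0 && sy > 0)
    (sum(ii * jj * P) - mx * my) / (sx * sy) else 0
  asm <- sum(P^2)
  homog <- sum(P / (1 + abs(ii - jj)))
  pnz <- P[P > 0]
  ent <- -sum(pnz * log2(pnz))
  c(glcm_contrast = contrast, glcm_correlation = correlation,
    glcm_asm = asm, glcm_homogeneity = homog, glcm_entropy = ent)
}

# Boundary measure: exposed faces (edges in 2-D) times their length/area.
shape_features <- function(mask, spacing) {
  d <- dim(mask)
  nd <- length(d)
  n <- sum(mask)
  size <- n * prod(spacing)
  boundary <- 0
  for (ax in seq_len(nd)) {
    face <- prod(spacing[-ax])
    shifted_lo <- array(FALSE, d); shifted_hi <- array(FALSE, d)
    idx_all <- lapply(d, seq_len)
    lo <- idx_all; lo[[ax]] <- seq_len(d[ax] - 1)
    hi <- idx_all; hi[[ax]] <- seq_len(d[ax] - 1) + 1L
    a <- do.call(`[`, c(list(mask), lo, list(drop = FALSE)))
    b <- do.call(`[`, c(list(mask), hi, list(drop = FALSE)))
    internal <- sum(a & b)
    boundary <- boundary + (2 * n - 2 * internal) * face
    # each voxel has 2 faces per axis; faces shared by two mask voxels are
    # internal and excluded twice
  }
  sph <- if (boundary > 0) {
    if (nd == 2L) 2 * sqrt(pi * size) / boundary
    else pi^(1 / 3) * (6 * size)^(2 / 3) / boundary
  } else 0
  c(shape_size = size, shape_boundary = boundary, shape_sphericity = sph)
}

#' Radiomic feature vector of a masked slice or VOI
#'
#' Computes a fixed, versioned 19-feature vector: first-order statistics
#' (mean, median, variance, skewness, kurtosis, energy, entropy, min, max,
#' 10th/90th percentiles of the masked intensities; entropy over `bin_count`
#' equal-width levels), shape (size = pixel/voxel count times spacing
#' product, boundary = exposed edge length / face area, and a sphericity
#' analogue), and grey-level co-occurrence features (contrast, correlation,
#' angular second moment, homogeneity, entropy) on intensities quantized to
#' `bin_count` equal-width levels over the masked range, accumulated
#' symmetrically and averaged over `offsets`.
#'
#' Degenerate conventions: on a constant region variance, skewness,
#' kurtosis and both entropies are 0 and the GLCM angular second moment
#' is 1; a single-pixel mask has boundary > 0 but no co-occurring pairs, so
#' all GLCM features are 0 except homogeneity/ASM which are 0 as well.
#'
#' @param image 2-D matrix or 3-D array of intensities.
#' @param mask Logical array of the same shape; must contain >= 1 pixel.
#' @param bin_count Number of quantization levels (default 64).
#' @param offsets List of integer offset vectors for the co-occurrence
#'   matrix; defaults to the four standard 2-D directions
#'   `(0,1), (1,0), (1,1), (1,-1)` or the three axis-aligned 3-D offsets.
#' @param spacing Pixel/voxel spacing (recycled to the array rank).
#' @return Named numeric vector of length 19 with attribute `version`.
#' @examples
#' img <- matrix(rep(c(1, 2), 8), 4, 4)          # checkerboard columns
#' radiomics_features(img, matrix(TRUE, 4, 4), bin_count = 2,
#'                    offsets = list(c(0, 1)))["glcm_contrast"]
#' @export
radiomics_features <- function(image, mask = NULL, bin_count = 64L,
                               offsets = NULL, spacing = NULL) {
  if (is.matrix(image)) dim_rank <- 2L
  else if (is.array(image) && length(dim(image)) == 3L) dim_rank <- 3L
  else stop_moesurv("'image' must be a 2-D matrix or 3-D array")
  if (is.null(mask)) mask <- array(TRUE, dim(image))
  if (!identical(dim(mask), dim(image)))
    stop_moesurv("'mask' shape must match 'image'")
  mask <- mask & TRUE
  if (!any(mask)) stop_moesurv("empty mask")
  spacing <- rep(spacing %||% 1, length.out = dim_rank)
  if (is.null(offsets))
    offsets <- if (dim_rank == 2L)
      list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
    else list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

  x <- image[mask]
  v <- stats::var(x); if (is.na(v)) v <- 0
  sdv <- sqrt(v)
  skew <- if (sdv > 0) mean((x - mean(x))^3) / sdv^3 else 0
  kurt <- if (sdv > 0) mean((x - mean(x))^4) / sdv^4 - 3 else 0
  q <- quantize_levels(x, bin_count)
  p <- tabulate(q, bin_count) / length(q)
  pnz <- p[p > 0]
  fo <- c(fo_mean = mean(x), fo_median = stats::median(x), fo_variance = v,
          fo_skewness = skew, fo_kurtosis = kurt, fo_energy = sum(x^2),
          fo_entropy = -sum(pnz * log2(pnz)), fo_min = min(x), fo_max = max(x),
          fo_p10 = stats::quantile(x, 0.1, names = FALSE),
          fo_p90 = stats::quantile(x, 0.9, names = FALSE))

  sh <- shape_features(mask, spacing)

  qimg <- array(NA_integer_, dim(image))
  qimg[mask] <- q
  glist <- list()
  for (off in offsets) {
    P <- glcm_matrix(qimg, off, bin_count)
    if (!is.null(P)) glist[[length(glist) + 1L]] <- glcm_features(P)
  }
  gl <- if (length(glist)) colMeans(do.call(rbind, glist))
  else c(glcm_contrast = 0, glcm_correlation = 0, glcm_asm = 0,
         glcm_homogeneity = 0, glcm_entropy = 0)

  out <- c(fo, sh, gl)
  names(out) <- radiomics_feature_names()
  attr(out, "version") <- RADIOMICS_VERSION
  out
}
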