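#' Convert a PET activity volume to standardized uptake values
#'
#' Body-weight SUV: `SUV = activity[kBq/mL] * body weight[g] / injected
#' dose[kBq]`, with tissue density taken as 1 g/mL, so a patient dosed at
#' `d` MBq/kg shows SUV 1.0 wherever the activity concentration equals
#' `d` kBq/mL.
#'
#' @param vol A `volume3d` with modality `"PET-activity"` in kBq/mL.
#' @param dose_mbq Injected dose in MBq (> 0), decay-corrected to scan time.
#' @param weight_kg Body weight in kg (> 0).
#' @return A `volume3d` with modality `"PET-SUV"`.
#' @examples
#' act <- volume3d(array(5.18, c(4, 4, 4)), modality = "PET-activity")
#' suv <- suv_convert(act, dose_mbq = 5.18 * 70, weight_kg = 70)
#' range(suv$data)  # 1 1
#' @export
suv_convert <- function(vol, dose_mbq, weight_kg) {
  if (vol$modality != "PET-activity")
    stop_moesurv("suv_convert expects a 'PET-activity' volume, got '%s'", vol$modality)
  check_number(dose_mbq, "dose_mbq", positive = TRUE)
  check_number(weight_kg, "weight_kg", positive = TRUE)
  # kBq/mL * (kg * 1000 g) / (MBq * 1000 kBq) = kBq/mL * kg / MBq
  out <- vol
  out$data <- vol$data * weight_kg / dose_mbq
  out$modality <- "PET-SUV"
  out
}

#' Resample a registered PET/CT pair to a common grid and normalize
#'
#' Both volumes are trilinearly resampled to `target_spacing` (the PET onto
#' the CT's output grid, so the pair stays voxel-aligned). CT is clipped to
#' `ct_clip` HU and scaled linearly to `[0, 1]`; PET (SUV) is clipped to
#' `pet_clip` and scaled to `[0, 1]` inside a robust body mask (voxels above
#' the 5th percentile of the nonzero SUVs); voxels outside the mask are 0.
#'
#' @param pet,ct Registered `volume3d` pair (PET in SUV units, CT in HU).
#' @param target_spacing Target voxel spacing in mm (scalar or length 3).
#' @param ct_clip,pet_clip Length-2 clipping ranges (HU and SUV).
#' @param mask_quantile Quantile of nonzero SUV defining the body mask.
#' @return List with elements `pet` and `ct` (normalized `volume3d`s) and
#'   `body_mask` (logical array on the common grid).
#' @export
normalize_and_resample <- function(pet, ct, target_spacing,
                                   ct_clip = c(-1000, 1000),
                                   pet_clip = c(0, 30),
                                   mask_quantile = 0.05) {
  ct_r <- resample_volume(ct, target_spacing)
  pet_r <- resample_volume(pet, target_spacing, ref = ct_r)
  cv <- pmin(pmax(ct_r$data, ct_clip[1]), ct_clip[2])
  ct_r$data <- (cv - ct_clip[1]) / diff(ct_clip)
  pv <- pmin(pmax(pet_r$data, pet_clip[1]), pet_clip[2])
  nz <- pet_r$data[pet_r$data > 0]
  thr <- if (length(nz)) stats::quantile(nz, mask_quantile, names = FALSE) else Inf
  mask <- pet_r$data > thr
  pvn <- (pv - pet_clip[1]) / diff(pet_clip)
  pvn[!mask] <- 0
  pet_r$data <- pvn
  list(pet = pet_r, ct = ct_r, body_mask = mask)
}

# 26-connected region growing: expand `seed` (logical array) inside
# `eligible` (logical array of the same shape) to a fixed point.
grow_region_26 <- function(eligible, seed) {
  d <- dim(eligible)
  cur <- seed & eligible
  repeat {
    grown <- cur
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      sz <- intersect(seq_len(d[1]), seq_len(d[1]) - dz)
      sy <- intersect(seq_len(d[2]), seq_len(d[2]) - dy)
      sx <- intersect(seq_len(d[3]), seq_len(d[3]) - dx)
      if (!length(sz) || !length(sy) || !length(sx)) next
      shifted <- array(FALSE, d)
      shifted[sz + dz, sy + dy, sx + dx] <- cur[sz, sy, sx]
      grown <- grown | shifted
    }
    grown <- grown & eligible
    if (identical(grown, cur)) break
    cur <- grown
  }
  cur
}

#' Label 26-connected components of a binary 3-D mask
#'
#' @param mask Logical 3-D array.
#' @return Integer array of the same shape: 0 outside the mask, components
#'   numbered 1..k in discovery order (array order of their first voxel).
#' @export
label_components <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop_moesurv("'mask' must be a logical 3-D array")
  mask <- mask & TRUE
  labels <- array(0L, dim(mask))
  remaining <- mask
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    first <- which(remaining)[1]
    seed <- array(FALSE, dim(mask)); seed[first] <- TRUE
    comp <- grow_region_26(remaining, seed)
    labels[comp] <- k
    remaining <- remaining & !comp
  }
  labels
}

#' Segment a lesion VOI by the percent-of-SUVmax threshold rule
#'
#' Finds the SUVmax inside `seed_box`, thresholds the whole volume at
#' `frac * SUVmax`, and keeps the voxels 26-connected to the maximum voxel.
#' With the default `frac = 0.41` this is the classical 41 percent-of-SUVmax
#' semi-automatic lesion delineation.
#'
#' @param pet A `volume3d` with modality `"PET-SUV"`.
#' @param seed_box List with integer index ranges `z`, `y`, `x` (each
#'   `c(lo, hi)`, 1-based, inclusive) delimiting the search region for the
#'   maximum. Defaults to the full volume.
#' @param frac Threshold as a fraction of SUVmax, in (0, 1].
#' @return An object of class `voi_mask`: list with `mask` (logical array),
#'   `labels` (integer array, 1 inside this VOI), `threshold`, `suvmax_seed`,
#'   and `spacing`.
#' @examples
#' a <- array(1, c(5, 5, 5)); a[3, 3, 3] <- 10
#' a[c(2, 4), 3, 3] <- 5; a[3, c(2, 4), 3] <- 5; a[3, 3, c(2, 4)] <- 5
#' pet <- volume3d(a, modality = "PET-SUV")
#' sum(threshold_voi(pet)$mask)  # 7
#' @export
threshold_voi <- function(pet, seed_box = NULL, frac = 0.41) {
  if (pet$modality != "PET-SUV")
    stop_moesurv("threshold_voi expects a 'PET-SUV' volume")
  check_fraction(frac, "frac")
  if (frac <= 0) stop_moesurv("'frac' must be in (0, 1]")
  d <- dim(pet$data)
  if (is.null(seed_box))
    seed_box <- list(z = c(1, d[1]), y = c(1, d[2]), x = c(1, d[3]))
  rz <- seed_box$z[1]:seed_box$z[2]
  ry <- seed_box$y[1]:seed_box$y[2]
  rx <- seed_box$x[1]:seed_box$x[2]
  if (max(rz) > d[1] || max(ry) > d[2] || max(rx) > d[3] ||
      min(rz) < 1 || min(ry) < 1 || min(rx) < 1)
    stop_moesurv("'seed_box' is outside the volume")
  sub <- pet$data[rz, ry, rx, drop = FALSE]
  if (all(sub == 0)) stop_moesurv("seed region contains no uptake")
  mx <- max(sub)
  loc <- which(sub == mx, arr.ind = TRUE)[1, , drop = TRUE]
  peak <- c(rz[loc[1]], ry[loc[2]], rx[loc[3]])
  thr <- frac * mx
  eligible <- pet$data >= thr
  seed <- array(FALSE, d); seed[peak[1], peak[2], peak[3]] <- TRUE
  mask <- grow_region_26(eligible, seed)
  structure(list(mask = mask, labels = array(as.integer(mask), d),
                 threshold = thr, suvmax_seed = mx, spacing = pet$spacing),
            class = "voi_mask")
}

#' Metabolic quantification of a PET VOI
#'
#' `SUVmax` is the maximum SUV inside the mask, `TMTV` the masked volume in
#' cubic centimetres (voxel count times voxel volume), and `TLG` the product
#' of the mask's mean SUV and TMTV. For a multi-component mask the totals sum
#' over components (TLG is additive because each component contributes
#' `SUVmean_c * TMTV_c`).
#'
#' @param pet A `volume3d` with modality `"PET-SUV"`.
#' @param voi A `voi_mask`, or a logical array of the same shape as the PET.
#' @return Object of class `metabolic_metrics`: list with `suvmax`,
#'   `tmtv_cm3`, `tlg`, `suvmean`, `n_voxels`.
#' @export
metabolic_metrics <- function(pet, voi) {
  mask <- if (inherits(voi, "voi_mask")) voi$mask else voi & TRUE
  if (!identical(dim(mask), dim(pet$data)))
    stop_moesurv("VOI mask shape does not match the PET volume")
  if (!any(mask)) stop_moesurv("empty VOI mask")
  vals <- pet$data[mask]
  vv <- voxel_volume_cm3(pet)
  tmtv <- sum(mask) * vv
  suvmean <- mean(vals)
  structure(list(suvmax = max(vals), tmtv_cm3 = tmtv,
                 tlg = suvmean * tmtv, suvmean = suvmean,
                 n_voxels = sum(mask)),
            class = "metabolic_metrics")
}

#' @export
print.metabolic_metrics <- function(x, ...) {
  cat(sprintf("SUVmax %.3f  TMTV %.3f cm^3  TLG %.3f (SUVmean %.3f, %d voxels)\n",
              x$suvmax, x$tmtv_cm3, x$tlg, x$suvmean, x$n_voxels))
  invisible(x)
}

#' Rigid (optionally affine-lite) transform
#'
#' Maps moving-volume world coordinates to fixed-volume world coordinates:
#' `p_fixed = S R (p - c) + c + t`, rotating/scaling about the fixed volume's
#' centre `c`.
#'
#' @param translation Length-3 translation in mm (`z`, `y`, `x`).
#' @param rotation Length-3 rotation angles in degrees about the `z`, `y`,
#'   `x` axes.
#' @param scale Length-3 axis scales (affine-lite); all 1 for rigid.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                            scale = c(1, 1, 1)) {
  if (any(scale <= 0)) stop_moesurv("scales must be positive")
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 scale = as.numeric(scale)),
            class = "rigid_transform")
}

# Rotation matrix acting on (z, y, x) world vectors; angles in degrees.
rotation_matrix_zyx <- function(angles) {
  a <- angles * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  # Rotations about the z, y, x axes in (z,y,x) component order.
  Rz <- rbind(c(1, 0, 0), c(0, cz, -sz), c(0, sz, cz))
  Ry <- rbind(c(cy, 0, -sy), c(0, 1, 0), c(sy, 0, cy))
  Rx <- rbind(c(cx, -sx, 0), c(sx, cx, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform, resampling the moving volume onto a fixed grid
#'
#' @param moving,fixed `volume3d` objects.
#' @param transform A `rigid_transform` mapping moving to fixed coordinates.
#' @param fill Value for voxels that map outside the moving volume.
#' @return A `volume3d` on `fixed`'s grid.
#' @export
apply_transform <- function(moving, fixed, transform, fill = NA_real_) {
  d <- dim(fixed$data)
  centre <- fixed$origin + (d - 1) * fixed$spacing / 2
  R <- rotation_matrix_zyx(transform$rotation)
  S <- diag(transform$scale)
  A <- S %*% R
  Ainv <- solve(A)
  gz <- fixed$origin[1] + (seq_len(d[1]) - 1) * fixed$spacing[1]
  gy <- fixed$origin[2] + (seq_len(d[2]) - 1) * fixed$spacing[2]
  gx <- fixed$origin[3] + (seq_len(d[3]) - 1) * fixed$spacing[3]
  world <- as.matrix(expand.grid(z = gz, y = gy, x = gx, KEEP.OUT.ATTRS = FALSE))
  # invert p_fixed = A (p - c) + c + t
  rel <- sweep(world, 2, centre + transform$translation)
  pm <- t(Ainv %*% t(rel)) + matrix(centre, nrow(world), 3, byrow = TRUE)
  co <- sweep(sweep(pm, 2, moving$origin), 2, moving$spacing, "/")
  vals <- trilinear_sample(moving$data, co, fill = fill)
  filled <- ifelse(is.na(vals), 0, vals)
  out <- volume3d(array(filled, d), spacing = fixed$spacing,
                  origin = fixed$origin, modality = moving$modality)
  out$valid <- array(!is.na(vals), d)
  out
}

# Normalized mutual information (H(A)+H(B))/H(A,B) between two equally shaped
# arrays over voxels where `valid` is TRUE, using a `bins` x `bins` joint
# histogram with equal-width bins over each array's finite range.
nmi_score <- function(a, b, valid = NULL, bins = 32L) {
  if (!is.null(valid)) { a <- a[valid]; b <- b[valid] }
  if (!length(a)) stop_moesurv("empty overlap between volumes")
  cut_idx <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(rep(1L, length(x)))
    pmin(bins, pmax(1L, as.integer(floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L)))
  }
  ia <- cut_idx(a); ib <- cut_idx(b)
  joint <- table(factor(ia, levels = 1:bins), factor(ib, levels = 1:bins))
  p <- joint / sum(joint)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  ha <- ent(rowSums(p)); hb <- ent(colSums(p)); hab <- ent(as.vector(p))
  if (hab == 0) return(2)
  (ha + hb) / hab
}

#' Rigid registration by normalized mutual information
#'
#' Aligns `moving` to `fixed` by maximizing the normalized mutual information
#' `NMI = (H(A) + H(B)) / H(A, B)` of the joint intensity histogram, using
#' seeded multi-start coordinate descent with shrinking step sizes.
#' Translations are bounded to half the fixed field of view per axis and
#' rotations to +/-15 degrees, which rules out extreme deformations.
#'
#' @param moving,fixed `volume3d` objects with overlapping fields of view.
#' @param bins Joint-histogram bins per axis.
#' @param dof `"translation"` (3 parameters), `"rigid"` (6), or
#'   `"rigid+scale"` (9).
#' @param n_starts Number of random restarts (jittered initial translations).
#' @param seed Integer seed for the restarts.
#' @param max_sweeps Coordinate-descent sweeps per start and step level.
#' @return A `rigid_transform` with attributes `nmi` (achieved score) and
#'   `nmi_identity`.
#' @export
rigid_register <- function(moving, fixed, bins = 32L,
                           dof = c("translation", "rigid", "rigid+scale"),
                           n_starts = 4L, seed = 1L, max_sweeps = 3L) {
  dof <- match.arg(dof)
  fov <- dim(fixed$data) * fixed$spacing
  t_bound <- fov / 2
  score_of <- function(par) {
    tr <- par_to_transform(par, dof)
    res <- apply_transform(moving, fixed, tr)
    if (!any(res$valid)) return(-Inf)
    nmi_score(res$data, fixed$data, valid = res$valid, bins = bins)
  }
  npar <- switch(dof, translation = 3L, rigid = 6L, `rigid+scale` = 9L)
  lower <- c(-t_bound, rep(-15, 3), rep(0.8, 3))[seq_len(npar)]
  upper <- c(t_bound, rep(15, 3), rep(1.25, 3))[seq_len(npar)]
  steps0 <- c(rep(max(fixed$spacing) * 2, 3), rep(4, 3), rep(0.05, 3))[seq_len(npar)]
  set.seed(seed)
  starts <- matrix(0, n_starts, npar)
  if (n_starts > 1L)
    for (k in 2:n_starts)
      starts[k, 1:3] <- stats::runif(3, -t_bound / 4, t_bound / 4)
  best <- NULL; best_score <- -Inf
  for (k in seq_len(n_starts)) {
    par <- starts[k, ]
    sc <- score_of(par)
    steps <- steps0
    for (level in 1:3) {
      for (sweep in seq_len(max_sweeps)) {
        improved <- FALSE
        for (j in seq_len(npar)) {
          for (sgn in c(1, -1)) {
            cand <- par
            cand[j] <- min(upper[j], max(lower[j], par[j] + sgn * steps[j]))
            if (cand[j] == par[j]) next
            s2 <- score_of(cand)
            if (s2 > sc + 1e-12) { par <- cand; sc <- s2; improved <- TRUE }
          }
        }
        if (!improved) break
      }
      steps <- steps / 4
    }
    if (sc > best_score) { best_score <- sc; best <- par }
  }
  tr <- par_to_transform(best, dof)
  id_par <- c(rep(0, min(npar, 6L)), rep(1, max(0L, npar - 6L)))
  attr(tr, "nmi") <- best_score
  attr(tr, "nmi_identity") <- score_of(id_par)
  tr
}

par_to_transform <- function(par, dof) {
  switch(dof,
    translation = rigid_transform(translation = par[1:3]),
    rigid = rigid_transform(translation = par[1:3], rotation = par[4:6]),
    `rigid+scale` = rigid_transform(translation = par[1:3], rotation = par[4:6],
                                    scale = par[7:9]))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform t=(%.2f, %.2f, %.2f) mm  rot=(%.2f, %.2f, %.2f) deg  scale=(%.3g, %.3g, %.3g)>\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation[1], x$rotation[2], x$rotation[3],
              x$scale[1], x$scale[2], x$scale[3]))
  invisible(x)
}
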