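#' Attention rollout for one expert group
#'
#' Propagates attention from the pooled output back to the input tokens:
#' per layer, head attentions are fused (mean by default), mixed with the
#' residual path as `residual * I + (1 - residual) * A` and row-normalized;
#' the per-layer matrices are multiplied in order and the pooling weights
#' `alpha` are pushed through the product, yielding a per-token importance
#' distribution that sums to 1.
#'
#' @param encoding A `group_encoding` from [intra_encode()] (attention
#'   matrices retained), or the result of [predict_risk()] together with
#'   `group` to select one group.
#' @param residual Residual mixing coefficient in `[0, 1]` (0.5 is the
#'   standard rollout convention; 0 disables residual mixing).
#' @param head_fusion `"mean"` or `"max"` over heads.
#' @param group When `encoding` is a `predict_risk()` result, the group
#'   index to roll out.
#' @return Object of class `attention_map`: list with `importance`
#'   (length `n_g`, sums to 1), `rollout` (the row-stochastic rollout
#'   matrix) and `alpha`.
#' @export
attention_rollout <- function(encoding, residual = 0.5,
                              head_fusion = c("mean", "max"), group = NULL) {
  head_fusion <- match.arg(head_fusion)
  check_fraction(residual, "residual")
  if (!inherits(encoding, "group_encoding")) {
    if (is.list(encoding) && !is.null(encoding$encodings)) {
      if (is.null(group)) stop_moesurv("specify 'group' to roll out")
      encoding <- encoding$encodings[[group]]
    } else stop_moesurv("'encoding' must be a group_encoding (with retained attention)")
  }
  if (is.null(encoding$attn)) stop_moesurv("no retained attention matrices")
  n <- length(encoding$alpha)
  R <- diag(n)
  for (layer_attn in encoding$attn) {
    A <- if (head_fusion == "mean") Reduce(`+`, layer_attn) / length(layer_attn)
    else Reduce(pmax, layer_attn)
    Abar <- residual * diag(n) + (1 - residual) * A
    Abar <- Abar / rowSums(Abar)
    R <- Abar %*% R
  }
  importance <- as.vector(crossprod(R, encoding$alpha))
  importance <- importance / sum(importance)
  structure(list(importance = importance, rollout = R,
                 alpha = encoding$alpha),
            class = "attention_map")
}

#' Overlay slice importances on a registered volume
#'
#' Broadcasts per-token importance across each axial slice (token `i` maps
#' to slice `slice_indices[i]`), linearly interpolates along `z`, and
#' min-max scales the result to `[0, 1]`.
#'
#' @param map An `attention_map` whose tokens are axial slices.
#' @param volume The registered `volume3d` the tokens came from.
#' @param slice_indices Token-to-slice mapping (default `1:n_tokens`, which
#'   requires one token per axial slice).
#' @param png_path Optional path: writes a PNG of the mid-axial heatmap
#'   slice (grey underlay blended with the importance map).
#' @return A `volume3d` heatmap aligned to `volume`'s grid.
#' @export
overlay_heatmap <- function(map, volume, slice_indices = NULL,
                            png_path = NULL) {
  imp <- map$importance
  nz <- dim(volume$data)[1]
  slice_indices <- slice_indices %||% seq_along(imp)
  if (length(slice_indices) != length(imp))
    stop_moesurv("token count (%d) does not match slice indices (%d)",
                 length(imp), length(slice_indices))
  if (max(slice_indices) > nz)
    stop_moesurv("slice indices exceed the volume's %d axial slices", nz)
  prof <- if (length(imp) == 1L) rep(imp, nz)
  else stats::approx(slice_indices, imp, xout = seq_len(nz), rule = 2)$y
  rng <- range(prof)
  prof <- if (diff(rng) > 0) (prof - rng[1]) / diff(rng) else rep(1, nz)
  heat <- array(rep(prof, times = prod(dim(volume$data)[2:3])),
                dim(volume$data))
  hv <- volume3d(heat, spacing = volume$spacing, origin = volume$origin,
                 modality = "other")
  if (!is.null(png_path)) {
    z <- which.max(prof)
    under <- volume$data[z, , ]
    ur <- range(under)
    under <- if (diff(ur) > 0) (under - ur[1]) / diff(ur) else under * 0
    overlay <- prof[z]
    rgb <- array(0, c(dim(under), 3))
    rgb[, , 1] <- pmin(1, under * (1 - 0.5) + overlay * 0.5)
    rgb[, , 2] <- under * (1 - 0.5 * overlay)
    rgb[, , 3] <- under * (1 - 0.5 * overlay)
    png::writePNG(rgb, png_path)
  }
  hv
}

#' Cohort-level gating-weight attribution
#'
#' Collects the gating weights `pi` of every patient in eval mode, averages
#' them per group, and aggregates them per modality (PET = PET groups, CT =
#' CT groups, EHR = the text group) using the group names.
#'
#' @param model A `task_model`.
#' @param cohort A `moe_cohort`.
#' @return Object of class `contribution_report`: list with `per_patient`
#'   (n x G matrix), `mean_pi` (named), `modality` (named aggregate means,
#'   summing to 1).
#' @export
gating_contributions <- function(model, cohort) {
  patients <- cohort_group_matrices(cohort, model$subset_groups)
  names_g <- vapply(cohort$tokens[[1]][model$subset_groups],
                    function(tg) tg$name, character(1))
  pim <- t(vapply(patients, function(p)
    moe_forward(model$params, p, model$arch)$state$pi,
    numeric(model$arch$n_groups)))
  colnames(pim) <- names_g
  mean_pi <- colMeans(pim)
  modality_of <- function(nm) {
    if (grepl("pet", nm)) "PET"
    else if (grepl("ct", nm)) "CT"
    else if (nm == "text") "EHR"
    else "other"
  }
  mods <- vapply(names_g, modality_of, character(1))
  modality <- tapply(mean_pi, mods, sum)
  structure(list(per_patient = pim, mean_pi = mean_pi,
                 modality = modality[!is.na(modality)]),
            class = "contribution_report")
}

#' @export
print.contribution_report <- function(x, ...) {
  cat("Mean gating weights per group:\n")
  print(round(x$mean_pi, 4))
  cat("Modality aggregates:\n")
  print(round(x$modality, 4))
  invisible(x)
}

#' Modality ablation study
#'
#' Retrains the task model on each requested subset of expert groups with
#' identical seeds and configuration, and reports the validation C-index
#' per subset.
#'
#' @param cohort A `moe_cohort`.
#' @param subsets Named list of integer group-id vectors (each non-empty).
#' @param endpoint `"PFS"` or `"OS"`.
#' @param arch_fn Function taking a subset size and returning a
#'   `moe_config` for it (defaults to the cohort's embedding dimension and
#'   a 1-layer intra encoder).
#' @param train A `train_config` shared by every subset.
#' @return Data frame with `subset`, `n_groups`, `cindex`.
#' @export
ablation <- function(cohort, subsets, endpoint = c("PFS", "OS"),
                     arch_fn = NULL, train = train_config()) {
  endpoint <- match.arg(endpoint)
  if (!length(subsets)) stop_moesurv("'subsets' must be non-empty")
  if (any(!lengths(subsets))) stop_moesurv("every subset needs >= 1 group")
  arch_fn <- arch_fn %||% function(k)
    moe_config(n_groups = k, embed_dim = cohort$config$embed_dim,
               n_heads = 2L, intra_layers = 1L,
               input_dims = cohort$config$embed_dim)
  rec <- cohort_records(cohort, endpoint)
  rows <- lapply(seq_along(subsets), function(i) {
    sub <- subsets[[i]]
    m <- train_task(cohort, endpoint, arch = arch_fn(length(sub)),
                    train = train, subset_groups = sub)
    va <- m$split$validation
    ci <- harrell_cindex(predict_cohort(m, cohort, va),
                         list(time = rec$time[va], event = rec$event[va]),
                         n_boot = 0)
    data.frame(subset = names(subsets)[i] %||% paste(sub, collapse = "+"),
               n_groups = length(sub), cindex = ci$c)
  })
  do.call(rbind, rows)
}
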