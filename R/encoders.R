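#' Expert token group
#'
#' One expert group's token sequence for a single patient: image-slice
#' embeddings, radiomic feature vectors, or sentence embeddings, all at a
#' shared embedding dimension after projection.
#'
#' @param group_id Integer group id, unique within a patient.
#' @param tokens Numeric matrix, one token per row (`n_g >= 1`).
#' @param name Group name (e.g. `"radiomics_pet"`).
#' @param metadata Optional per-token metadata (slice index, sentence id,
#'   feature tag); recycled to `nrow(tokens)`.
#' @return Object of class `token_group`.
#' @export
token_group <- function(group_id, tokens, name = paste0("group_", group_id),
                        metadata = NULL) {
  if (!is.matrix(tokens) || nrow(tokens) < 1L)
    stop_moesurv("'tokens' must be a matrix with >= 1 row")
  if (any(!is.finite(tokens))) stop_moesurv("tokens must be finite")
  structure(list(group_id = as.integer(group_id), name = name,
                 tokens = tokens,
                 metadata = if (is.null(metadata)) seq_len(nrow(tokens))
                 else rep(metadata, length.out = nrow(tokens))),
            class = "token_group")
}

#' @export
print.token_group <- function(x, ...) {
  cat(sprintf("<token_group %d '%s'  %d tokens x %d dims>\n",
              x$group_id, x$name, nrow(x$tokens), ncol(x$tokens)))
  invisible(x)
}

#' Encoder plugin contract
#'
#' A deterministic callable mapping a raw input (a 2-D image slice matrix or
#' a sentence string) to a fixed-length native embedding. Pretrained
#' foundation encoders can be wrapped in this contract; the package ships
#' synthetic stand-ins ([synthetic_vision_encoder()],
#' [synthetic_text_encoder()]) that project deterministic input statistics
#' through a seeded random linear map.
#'
#' @param name Encoder name.
#' @param native_dim Output embedding length.
#' @param fn Function taking one input and returning a numeric vector of
#'   length `native_dim`.
#' @return Object of class `encoder_plugin` (callable via [encode_tokens()]).
#' @export
encoder_plugin <- function(name, native_dim, fn) {
  check_number(native_dim, "native_dim", positive = TRUE, integer = TRUE)
  if (!is.function(fn)) stop_moesurv("'fn' must be a function")
  structure(list(name = name, native_dim = as.integer(native_dim), fn = fn),
            class = "encoder_plugin")
}

#' @rdname encoder_plugin
#' @param encoder An `encoder_plugin`.
#' @param inputs A list of raw inputs (slices or sentences).
#' @return `encode_tokens` returns a matrix with one native embedding per row.
#' @export
encode_tokens <- function(encoder, inputs) {
  out <- t(vapply(inputs, function(x) {
    v <- encoder$fn(x)
    if (length(v) != encoder$native_dim)
      stop_moesurv("encoder '%s' returned length %d, expected %d",
                   encoder$name, length(v), encoder$native_dim)
    as.numeric(v)
  }, numeric(encoder$native_dim)))
  if (encoder$native_dim == 1L) out <- matrix(out, ncol = 1L)
  out
}

slice_statistics <- function(m) {
  m <- as.matrix(m)
  n <- length(m)
  rs <- rowMeans(m); cs <- colMeans(m)
  tot <- sum(abs(m))
  comz <- if (tot > 0) sum(abs(m) * row(m)) / tot / nrow(m) else 0.5
  comx <- if (tot > 0) sum(abs(m) * col(m)) / tot / ncol(m) else 0.5
  grad <- mean(abs(diff(m))) + mean(abs(t(diff(t(m)))))
  c(mean(m), stats::sd(as.numeric(m)), min(m), max(m),
    stats::quantile(m, c(0.25, 0.5, 0.75), names = FALSE),
    mean(m > 0), comz, comx, stats::sd(rs), stats::sd(cs), grad / 2,
    sum(m^2) / n)
}

#' Synthetic stand-in encoders
#'
#' Deterministic substitutes for pretrained vision/language encoders: a
#' fixed set of input statistics (intensity moments, centre of mass and
#' gradient energy for slices; length, token-count and hashed bag-of-words
#' statistics for sentences) is passed through a seeded random affine map to
#' `native_dim` dimensions. Fixed input and seed give identical output.
#'
#' @param name Encoder name.
#' @param native_dim Native embedding dimension.
#' @param seed Integer seed for the random projection.
#' @return An `encoder_plugin`.
#' @export
synthetic_vision_encoder <- function(name = "synthetic-vision",
                                     native_dim = 32L, seed = 1L) {
  n_stats <- 14L
  set.seed(seed)
  W <- matrix(stats::rnorm(native_dim * n_stats, sd = 1 / sqrt(n_stats)),
              native_dim, n_stats)
  b <- stats::rnorm(native_dim, sd = 0.01)
  encoder_plugin(name, native_dim, function(slice) {
    as.vector(W %*% slice_statistics(slice) + b)
  })
}

sentence_statistics <- function(s, n_buckets = 16L) {
  words <- unlist(strsplit(tolower(s), "[^a-z0-9]+"))
  words <- words[nzchar(words)]
  buckets <- numeric(n_buckets)
  for (w in words) {
    h <- sum(utf8ToInt(w) * seq_along(utf8ToInt(w))) %% n_buckets + 1
    buckets[h] <- buckets[h] + 1
  }
  c(nchar(s), length(words),
    if (length(words)) mean(nchar(words)) else 0,
    lengths(regmatches(s, gregexpr("[0-9]", s))),
    lengths(regmatches(s, gregexpr("[[:punct:]]", s))),
    buckets)
}

#' @rdname synthetic_vision_encoder
#' @export
synthetic_text_encoder <- function(name = "synthetic-text",
                                   native_dim = 32L, seed = 1L) {
  n_stats <- 21L
  set.seed(seed)
  W <- matrix(stats::rnorm(native_dim * n_stats, sd = 1 / sqrt(n_stats)),
              native_dim, n_stats)
  b <- stats::rnorm(native_dim, sd = 0.01)
  encoder_plugin(name, native_dim, function(sentence) {
    as.vector(W %*% sentence_statistics(sentence) + b)
  })
}

#' Single-layer shared-dimension projection
#'
#' The affine map (single-layer perceptron) taking each group's native
#' embeddings to the shared embedding dimension used by the fusion network.
#'
#' @param native_dim,embed_dim Input and output dimensions.
#' @param seed Seed for random initialization (ignored when `identity`).
#' @param identity Use an identity map (requires equal dimensions).
#' @return Object of class `projection_layer` with fields `W`, `b`.
#' @export
projection_layer <- function(native_dim, embed_dim, seed = 1L,
                             identity = FALSE) {
  if (identity) {
    if (native_dim != embed_dim)
      stop_moesurv("identity projection requires native_dim == embed_dim")
    W <- diag(native_dim)
    b <- numeric(embed_dim)
  } else {
    set.seed(seed)
    W <- matrix(stats::rnorm(native_dim * embed_dim, sd = 1 / sqrt(native_dim)),
                native_dim, embed_dim)
    b <- numeric(embed_dim)
  }
  structure(list(W = W, b = b), class = "projection_layer")
}

#' @rdname projection_layer
#' @param tokens Matrix of native embeddings (rows).
#' @param layer A `projection_layer`.
#' @export
apply_projection <- function(tokens, layer) {
  sweep(tokens %*% layer$W, 2, layer$b, "+")
}

#' Build the seven expert token groups for one patient
#'
#' Decomposes the registered PET and CT volumes into ordered axial slices
#' and encodes them with the semantic and morphology vision encoders (four
#' slice-token groups), computes one radiomic feature vector per VOI
#' component on each modality (two feature-token groups), and encodes the
#' clinical sentences (one text group). Every group's native embeddings pass
#' through their single-layer projection to `embed_dim`.
#'
#' @param pet,ct Registered `volume3d` pair.
#' @param voi A `voi_mask` (or logical array) on the same grid.
#' @param sentences A `sentence_bundle`.
#' @param embed_dim Shared embedding dimension.
#' @param encoders Optional named list overriding the default synthetic
#'   stand-ins; names among `vision_semantic_pet`, `vision_semantic_ct`,
#'   `vision_morphology_pet`, `vision_morphology_ct`, `text`.
#' @param identity_projections Use identity projections (requires every
#'   native dimension to equal `embed_dim`).
#' @param radiomics_bins Quantization levels for the radiomic extractor.
#' @param seed Base seed for default encoders and projections.
#' @return List of 7 `token_group`s in canonical order.
#' @export
build_patient_groups <- function(pet, ct, voi, sentences, embed_dim = 32L,
                                 encoders = NULL,
                                 identity_projections = FALSE,
                                 radiomics_bins = 64L, seed = 1L) {
  if (!inherits(pet, "volume3d") || !inherits(ct, "volume3d"))
    stop_moesurv("'pet' and 'ct' must be volume3d objects")
  if (!identical(dim(pet$data), dim(ct$data)))
    stop_moesurv("PET and CT must be on the same (registered) grid")
  mask <- if (inherits(voi, "voi_mask")) voi$mask else voi & TRUE
  if (!any(mask)) stop_moesurv("empty VOI")
  if (!inherits(sentences, "sentence_bundle"))
    stop_moesurv("'sentences' must be a sentence_bundle")

  names7 <- default_group_names(7L)
  vision_names <- names7[1:4]
  enc <- list()
  for (nm in vision_names)
    enc[[nm]] <- encoders[[nm]] %||%
      synthetic_vision_encoder(nm, native_dim = embed_dim,
                               seed = derive_seed(seed, nm))
  enc[["text"]] <- encoders[["text"]] %||%
    synthetic_text_encoder("text", native_dim = embed_dim,
                           seed = derive_seed(seed, "text"))

  nz <- dim(pet$data)[1]
  pet_slices <- lapply(seq_len(nz), function(i) pet$data[i, , ])
  ct_slices <- lapply(seq_len(nz), function(i) ct$data[i, , ])
  slice_inputs <- list(vision_semantic_pet = pet_slices,
                       vision_semantic_ct = ct_slices,
                       vision_morphology_pet = pet_slices,
                       vision_morphology_ct = ct_slices)

  labels <- if (inherits(voi, "voi_mask") && max(voi$labels) > 0) voi$labels
  else label_components(mask)
  n_comp <- max(labels)
  rad_tokens <- function(volume) {
    t(vapply(seq_len(n_comp), function(k) {
      as.numeric(radiomics_features(volume$data, labels == k,
                                    bin_count = radiomics_bins,
                                    spacing = volume$spacing))
    }, numeric(19L)))
  }

  groups <- vector("list", 7L)
  for (g in 1:4) {
    nm <- vision_names[g]
    native <- encode_tokens(enc[[nm]], slice_inputs[[nm]])
    proj <- projection_layer(ncol(native), embed_dim,
                             seed = derive_seed(seed, paste0("proj_", nm)),
                             identity = identity_projections)
    groups[[g]] <- token_group(g, apply_projection(native, proj), name = nm,
                               metadata = seq_len(nz))
  }
  for (g in 5:6) {
    nm <- names7[g]
    native <- rad_tokens(if (nm == "radiomics_pet") pet else ct)
    proj <- projection_layer(ncol(native), embed_dim,
                             seed = derive_seed(seed, paste0("proj_", nm)),
                             identity = identity_projections)
    groups[[g]] <- token_group(g, apply_projection(native, proj), name = nm,
                               metadata = seq_len(n_comp))
  }
  native_txt <- encode_tokens(enc[["text"]], as.list(sentences$text))
  proj_txt <- projection_layer(ncol(native_txt), embed_dim,
                               seed = derive_seed(seed, "proj_text"),
                               identity = identity_projections)
  groups[[7]] <- token_group(7L, apply_projection(native_txt, proj_txt),
                             name = "text", metadata = sentences$timestamp)
  groups
}
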