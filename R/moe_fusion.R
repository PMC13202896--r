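#' Fusion network architecture configuration
#'
#' Architecture of the attention-based mixture-of-experts fusion network:
#' per-group input projection, an intra-group Transformer encoder with
#' learned-query attention pooling, a cross-group Transformer over the pooled
#' group vectors, a gating MLP producing softmax mixture weights, and a
#' linear risk head.
#'
#' @param n_groups Number of expert groups `G`.
#' @param embed_dim Shared embedding dimension (divisible by `n_heads`).
#' @param n_heads Attention heads per encoder layer.
#' @param intra_layers Transformer layers in each intra-group encoder.
#' @param inter_layers Layers in the cross-group encoder.
#' @param ffn_mult Feed-forward width multiplier.
#' @param gate_hidden Hidden width of the gating MLP.
#' @param input_dims Per-group native token dimensions (default: all equal
#'   to `embed_dim`).
#' @return Object of class `moe_config`.
#' @export
moe_config <- function(n_groups = 7L, embed_dim = 128L, n_heads = 4L,
                       intra_layers = 2L, inter_layers = 1L, ffn_mult = 2L,
                       gate_hidden = 32L, input_dims = NULL) {
  check_number(n_groups, "n_groups", positive = TRUE, integer = TRUE)
  check_number(embed_dim, "embed_dim", positive = TRUE, integer = TRUE)
  if (embed_dim %% n_heads != 0)
    stop_moesurv("'embed_dim' must be divisible by 'n_heads'")
  input_dims <- rep(as.integer(input_dims %||% embed_dim),
                    length.out = n_groups)
  structure(list(n_groups = as.integer(n_groups),
                 embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 intra_layers = as.integer(intra_layers),
                 inter_layers = as.integer(inter_layers),
                 ffn_mult = as.integer(ffn_mult),
                 gate_hidden = as.integer(gate_hidden),
                 input_dims = input_dims),
            class = "moe_config")
}

#' Initialize fusion-network parameters
#'
#' @param config A `moe_config`.
#' @param seed Integer seed; initialization is fully reproducible.
#' @return Nested parameter list (groups / inter / gate / head).
#' @export
moe_init <- function(config, seed = 1L) {
  set.seed(seed)
  d <- config$embed_dim
  groups <- lapply(seq_len(config$n_groups), function(g) {
    din <- config$input_dims[g]
    list(proj = list(W = nn_mat(din, d, 1 / sqrt(din)), b = numeric(d)),
         layers = lapply(seq_len(config$intra_layers), function(l)
           attn_layer_init(d, config$ffn_mult)),
         q = stats::rnorm(d, sd = 1 / sqrt(d)))
  })
  inter <- list(layers = lapply(seq_len(config$inter_layers), function(l)
    attn_layer_init(d, config$ffn_mult)))
  gate <- gate_init(config$n_groups, d, config$gate_hidden)
  head <- list(w = stats::rnorm(d, sd = 1 / sqrt(d)), b = 0)
  list(groups = groups, inter = inter, gate = gate, head = head)
}

#' Encode one expert group and pool it to a single vector
#'
#' Runs the group's tokens through the input projection and the intra-group
#' Transformer encoder, then pools the contextualized tokens with a learned
#' query: `alpha = softmax(H q)`, `z = sum_i alpha_i h_i`. Attention
#' matrices of every layer are retained for rollout.
#'
#' @param group A `token_group` or a plain token matrix.
#' @param gparams One element of `params$groups` from [moe_init()].
#' @param config The `moe_config`.
#' @return Object of class `group_encoding`: list with `H`, `alpha`, `z`,
#'   `attn` (per layer, list of per-head attention matrices) and `cache`.
#' @export
intra_encode <- function(group, gparams, config) {
  tokens <- if (inherits(group, "token_group")) group$tokens else group
  if (!is.matrix(tokens) || nrow(tokens) < 1L)
    stop_moesurv("group tokens must form a matrix with >= 1 row")
  if (ncol(tokens) != nrow(gparams$proj$W))
    stop_moesurv("token dimension %d does not match projection input %d",
                 ncol(tokens), nrow(gparams$proj$W))
  X <- lin(tokens, gparams$proj$W, gparams$proj$b)
  layer_caches <- vector("list", length(gparams$layers))
  attn <- vector("list", length(gparams$layers))
  for (l in seq_along(gparams$layers)) {
    fw <- attn_layer_forward(X, gparams$layers[[l]], config$n_heads)
    layer_caches[[l]] <- fw$cache
    attn[[l]] <- fw$attn
    X <- fw$out
  }
  pl <- pool_forward(X, gparams$q)
  structure(list(H = X, alpha = pl$alpha, z = pl$z, attn = attn,
                 cache = list(tokens = tokens, layers = layer_caches,
                              pool = pl$cache)),
            class = "group_encoding")
}

intra_backward <- function(dz, enc, gparams, config) {
  pb <- pool_backward(dz, enc$cache$pool, gparams$q)
  dH <- pb$dH
  layer_grads <- vector("list", length(gparams$layers))
  for (l in rev(seq_along(gparams$layers))) {
    bk <- attn_layer_backward(dH, enc$cache$layers[[l]],
                              gparams$layers[[l]], config$n_heads)
    layer_grads[[l]] <- bk$grads
    dH <- bk$dX
  }
  tokens <- enc$cache$tokens
  list(proj = list(W = t(tokens) %*% dH, b = colSums(dH)),
       layers = layer_grads, q = pb$dq)
}

#' Fuse pooled group vectors into a patient embedding
#'
#' Refines the `G` pooled group vectors with the cross-group Transformer,
#' scores them with the gating MLP, normalizes the scores to mixture
#' weights `pi = softmax(s)` on the simplex, and forms the patient embedding
#' `u = sum_g pi_g ztilde_g`.
#'
#' @param Z Numeric `G x d` matrix of pooled group vectors.
#' @param params Full parameter list from [moe_init()] (uses `inter`, `gate`).
#' @param config The `moe_config`.
#' @return Object of class `fusion_state`: list with `zt` (refined vectors),
#'   `s` (gate scores), `pi` (mixture weights), `u`, and `cache`.
#' @export
inter_fuse <- function(Z, params, config) {
  if (!is.matrix(Z) || nrow(Z) < 1L) stop_moesurv("'Z' must have >= 1 group row")
  layer_caches <- vector("list", length(params$inter$layers))
  Zt <- Z
  for (l in seq_along(params$inter$layers)) {
    fw <- attn_layer_forward(Zt, params$inter$layers[[l]], config$n_heads)
    layer_caches[[l]] <- fw$cache
    Zt <- fw$out
  }
  gf <- gate_forward(Zt, params$gate)
  pi <- softmax(gf$s)
  u <- as.vector(crossprod(Zt, pi))
  structure(list(zt = Zt, s = gf$s, pi = pi, u = u,
                 cache = list(layers = layer_caches, gate = gf$cache)),
            class = "fusion_state")
}

inter_backward <- function(du, dpi_extra, state, params, config) {
  Zt <- state$zt; pi <- state$pi
  G <- nrow(Zt); d <- ncol(Zt)
  dpi <- as.vector(Zt %*% du) + (dpi_extra %||% 0)
  dZt <- pi %o% du
  ds <- pi * (dpi - sum(dpi * pi))
  gb <- gate_backward(ds, state$cache$gate, params$gate, G, d)
  dZt <- dZt + gb$dZt
  layer_grads <- vector("list", length(params$inter$layers))
  for (l in rev(seq_along(params$inter$layers))) {
    bk <- attn_layer_backward(dZt, state$cache$layers[[l]],
                              params$inter$layers[[l]], config$n_heads)
    layer_grads[[l]] <- bk$grads
    dZt <- bk$dX
  }
  list(dZ = dZt, inter = list(layers = layer_grads), gate = gb$grads)
}

#' Linear risk head
#'
#' @param u Patient embedding vector.
#' @param head List with weight vector `w` and intercept `b`.
#' @return Scalar risk score `w . u + b`.
#' @export
risk_head <- function(u, head) {
  if (any(!is.finite(u))) stop_moesurv("'u' must be finite")
  sum(head$w * u) + head$b
}

# Full forward pass for one patient. `groups` is a list of token_group
# objects (bound to parameters by group_id, so order is irrelevant) or plain
# matrices taken in configured order.
moe_forward <- function(params, groups, config) {
  if (length(groups) != config$n_groups)
    stop_moesurv("patient has %d groups but the model expects %d",
                 length(groups), config$n_groups)
  if (inherits(groups[[1]], "token_group")) {
    ids <- vapply(groups, function(g) g$group_id, integer(1))
    if (any(sort(ids) != seq_len(config$n_groups)))
      stop_moesurv("group ids must be a permutation of 1..G")
    groups <- groups[order(ids)]
  }
  encs <- lapply(seq_len(config$n_groups), function(g)
    intra_encode(groups[[g]], params$groups[[g]], config))
  Z <- do.call(rbind, lapply(encs, function(e) e$z))
  state <- inter_fuse(Z, params, config)
  risk <- risk_head(state$u, params$head)
  state$risk <- risk
  list(risk = risk, state = state, encodings = encs)
}

moe_backward <- function(drisk, fwd, params, config) {
  state <- fwd$state
  du <- drisk * params$head$w
  head_g <- list(w = drisk * state$u, b = drisk)
  ib <- inter_backward(du, NULL, state, params, config)
  group_grads <- lapply(seq_len(config$n_groups), function(g)
    intra_backward(ib$dZ[g, ], fwd$encodings[[g]], params$groups[[g]], config))
  list(groups = group_grads, inter = ib$inter, gate = ib$gate, head = head_g)
}

#' Negative Cox partial log-likelihood
#'
#' `loss = -sum_{i: event} [r_i - log sum_{j: t_j >= t_i} exp(r_j)]` with the
#' Breslow convention for tied event times (the full tie block stays in the
#' risk set of every tied event) and max-subtraction for numerical
#' stability.
#'
#' @param risks Numeric risk scores, one per patient.
#' @param records A `survival_record`, or a data frame / list with `time`
#'   and `event`.
#' @return Scalar loss (sum over events). Zero events yields 0 with a
#'   warning.
#' @examples
#' rec <- survival_record(c(1, 2, 3), c(1, 1, 0))
#' cox_partial_nll(c(0, 0, 0), rec)  # log(3) + log(2)
#' @export
cox_partial_nll <- function(risks, records) {
  cox_nll_grad(risks, records)$loss
}

as_time_event <- function(records) {
  if (inherits(records, "survival_record"))
    list(time = records$time, event = records$event)
  else list(time = records$time, event = records$event)
}

cox_nll_grad <- function(risks, records) {
  te <- as_time_event(records)
  time <- te$time; event <- te$event
  n <- length(risks)
  stopifnot(length(time) == n, length(event) == n)
  if (sum(event) == 0) {
    warning("no events: Cox partial likelihood is identically 0")
    return(list(loss = 0, grad = numeric(n)))
  }
  r <- risks - max(risks)
  er <- exp(r)

  block_ends <- function(t_sorted) {
    rl <- rle(t_sorted)
    ends <- cumsum(rl$lengths)
    rep(ends, rl$lengths)
  }

  desc <- order(time, decreasing = TRUE)
  cs <- cumsum(er[desc])
  denom <- numeric(n)
  denom[desc] <- cs[block_ends(time[desc])]   # sum over {j: t_j >= t_i}

  ev <- event == 1
  loss <- -sum(r[ev] - log(denom[ev]))

  asc <- order(time)
  contrib <- ifelse(ev, 1 / denom, 0)
  ca <- cumsum(contrib[asc])
  S <- numeric(n)
  S[asc] <- ca[block_ends(time[asc])]         # sum over events with t_i <= t_k
  grad <- -as.numeric(ev) + er * S
  list(loss = loss, grad = grad)
}

#' Training configuration for a task model
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size (the Cox partial likelihood is computed
#'   within each batch).
#' @param lr Adam learning rate.
#' @param val_fraction Fraction of patients held out for early stopping.
#' @param patience Early-stopping patience in epochs.
#' @param weight_decay Decoupled L2 weight decay per step (AdamW style).
#' @param seed Global seed controlling initialization, the split and batch
#'   shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 64L, lr = 1e-3,
                         val_fraction = 0.2, patience = 5L,
                         weight_decay = 1e-4, seed = 1L) {
  check_fraction(val_fraction, "val_fraction")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, val_fraction = val_fraction,
                 patience = as.integer(patience),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

cohort_group_matrices <- function(cohort, subset_groups = NULL) {
  lapply(cohort$tokens, function(pat) {
    gs <- if (is.null(subset_groups)) pat else pat[subset_groups]
    lapply(gs, function(tg) tg$tokens)
  })
}

batch_loss <- function(params, patients, time, event, config) {
  risks <- vapply(patients, function(p) moe_forward(params, p, config)$risk,
                  numeric(1))
  if (sum(event) == 0) return(NA_real_)
  cox_nll_grad(risks, list(time = time, event = event))$loss / sum(event)
}

#' Train one endpoint-specific fusion model
#'
#' Minibatch Adam training of the full stack (projections, intra-group
#' encoders, cross-group encoder, gating network, risk head) on the negative
#' Cox partial log-likelihood of the requested endpoint. The gradient is
#' normalized by the batch size; the reported losses are per-event averages.
#' Training is fully seeded; a patient-level validation split drives early
#' stopping (best-validation parameters are kept).
#'
#' @param cohort A `moe_cohort`.
#' @param endpoint `"PFS"` or `"OS"`.
#' @param arch A `moe_config` (its `n_groups`/`input_dims` must match the
#'   cohort).
#' @param train A `train_config`.
#' @param subset_groups Optional integer vector of group ids to train on
#'   (used by the ablation harness); `arch$n_groups` must equal its length.
#' @return Object of class `task_model`: `params`, `arch`, `train`,
#'   `endpoint`, `trace` (per-epoch train/validation loss), `split`
#'   (train/validation indices), `subset_groups`.
#' @export
train_task <- function(cohort, endpoint = c("PFS", "OS"),
                       arch = NULL, train = train_config(),
                       subset_groups = NULL) {
  endpoint <- match.arg(endpoint)
  rec <- cohort_records(cohort, endpoint)
  if (sum(rec$event) < 2L) stop_moesurv("need >= 2 events to train")
  sub <- subset_groups %||% seq_len(cohort$config$n_groups)
  arch <- arch %||% moe_config(n_groups = length(sub),
                               embed_dim = cohort$config$embed_dim,
                               input_dims = cohort$config$embed_dim)
  if (arch$n_groups != length(sub))
    stop_moesurv("arch$n_groups (%d) must match the number of groups used (%d)",
                 arch$n_groups, length(sub))
  patients <- cohort_group_matrices(cohort, sub)
  n <- length(patients)

  sp <- split_cohort(seq_len(n), ratio = 1 - train$val_fraction,
                     seed = derive_seed(train$seed, "split"))
  tr_idx <- sp$train; va_idx <- sp$validation

  params <- moe_init(arch, seed = derive_seed(train$seed, "init"))
  theta <- nn_flatten(params)
  opt <- adam_init(length(theta))
  best_theta <- theta; best_val <- Inf; bad_epochs <- 0L
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))

  for (ep in seq_len(train$epochs)) {
    set.seed(derive_seed(train$seed, paste0("epoch", ep)))
    perm <- sample(tr_idx)
    ep_loss <- 0; ep_events <- 0L
    for (start in seq(1, length(perm), by = train$batch_size)) {
      batch <- perm[start:min(start + train$batch_size - 1L, length(perm))]
      if (length(batch) < 2L) next
      fwd <- lapply(patients[batch], function(p) moe_forward(params, p, arch))
      risks <- vapply(fwd, function(f) f$risk, numeric(1))
      bt <- rec$time[batch]; be <- rec$event[batch]
      if (sum(be) == 0) next
      cg <- cox_nll_grad(risks, list(time = bt, event = be))
      ep_loss <- ep_loss + cg$loss; ep_events <- ep_events + sum(be)
      gtot <- numeric(length(theta))
      for (i in seq_along(batch)) {
        if (cg$grad[i] == 0) next
        gp <- moe_backward(cg$grad[i], fwd[[i]], params, arch)
        gtot <- gtot + nn_flatten(gp)
      }
      gtot <- gtot / length(batch)
      st <- adam_step(theta, gtot, opt, lr = train$lr)
      theta <- st$theta * (1 - train$lr * (train$weight_decay %||% 0))
      opt <- st$state
      params <- nn_unflatten(theta, params)
    }
    train_loss <- if (ep_events > 0) ep_loss / ep_events else NA_real_
    val_loss <- if (length(va_idx) >= 2L)
      batch_loss(params, patients[va_idx], rec$time[va_idx],
                 rec$event[va_idx], arch) else NA_real_
    monitor <- if (is.finite(val_loss %||% NA_real_) && !is.na(val_loss))
      val_loss else train_loss
    trace <- rbind(trace, data.frame(epoch = ep, train_loss = train_loss,
                                     val_loss = val_loss))
    if (!is.na(monitor) && monitor < best_val - 1e-6) {
      best_val <- monitor; best_theta <- theta; bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= train$patience) break
    }
  }
  params <- nn_unflatten(best_theta, params)
  structure(list(params = params, arch = arch, train = train,
                 endpoint = endpoint, trace = trace,
                 split = list(train = tr_idx, validation = va_idx),
                 subset_groups = sub),
            class = "task_model")
}

#' @export
print.task_model <- function(x, ...) {
  cat(sprintf("<task_model %s  G=%d d=%d  %d epochs trained>\n",
              x$endpoint, x$arch$n_groups, x$arch$embed_dim, nrow(x$trace)))
  invisible(x)
}

#' Predict the risk score of one patient
#'
#' Deterministic forward pass; the returned `fusion_state` retains the
#' gating weights, refined group vectors, patient embedding and (through
#' `encodings`) the per-layer attention matrices needed for rollout.
#'
#' @param model A `task_model` (or a list with `params` and `arch`).
#' @param groups List of `token_group`s (bound to parameters by group id) or
#'   plain token matrices in configured order.
#' @return List with `risk`, `state` (a `fusion_state`), and `encodings`
#'   (per-group `group_encoding`s).
#' @export
predict_risk <- function(model, groups) {
  moe_forward(model$params, groups, model$arch)
}

#' Risk scores for every patient of a cohort
#'
#' @param model A `task_model`.
#' @param cohort A `moe_cohort`.
#' @param indices Optional patient indices (default all).
#' @return Numeric vector of risk scores.
#' @export
predict_cohort <- function(model, cohort, indices = NULL) {
  patients <- cohort_group_matrices(cohort, model$subset_groups)
  idx <- indices %||% seq_along(patients)
  vapply(patients[idx], function(p) moe_forward(model$params, p, model$arch)$risk,
         numeric(1))
}
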