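# Shared fixtures and independent brute-force oracles.

# O(n^2) negative Cox partial log-likelihood by explicit risk-set
# enumeration (Breslow ties).
cox_nll_brute <- function(r, time, event) {
  s <- 0
  for (i in seq_along(r)) {
    if (event[i] != 1) next
    rs <- which(time >= time[i])
    s <- s - (r[i] - log(sum(exp(r[rs]))))
  }
  s
}

# Pair-enumeration Harrell C-index.
cindex_brute <- function(r, time, event) {
  num <- den <- 0
  n <- length(r)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!comparable) next
    den <- den + 1
    if (r[i] > r[j]) num <- num + 1
    else if (r[i] == r[j]) num <- num + 0.5
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Plain binary AUC by pair counting.
auc_binary <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Small fusion architecture used throughout the tests.
tiny_arch <- function(G = 3L, d = 8L, input_dims = d, layers = 1L,
                      heads = 2L) {
  moe_config(n_groups = G, embed_dim = d, n_heads = heads,
             intra_layers = layers, gate_hidden = 6L,
             input_dims = input_dims)
}

random_patient <- function(G = 3L, d = 8L, n_tokens = 4L) {
  lapply(seq_len(G), function(g) matrix(stats::rnorm(n_tokens * d), n_tokens, d))
}

# Hand-buildable group encoding for rollout tests.
fake_encoding <- function(alpha, attn_layers) {
  structure(list(H = NULL, alpha = alpha, z = NULL, attn = attn_layers,
                 cache = NULL),
            class = "group_encoding")
}

ns <- asNamespace("moesurv")
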