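test_that("attention pooling collapses correctly for degenerate groups", {
  cfg <- tiny_arch(G = 1L, d = 8L, layers = 2L)
  params <- moe_init(cfg, seed = 1)

  one <- matrix(rnorm(8), 1, 8)
  enc <- intra_encode(one, params$groups[[1]], cfg)
  expect_equal(enc$alpha, 1)
  expect_equal(enc$z, as.vector(enc$H))

  same <- matrix(rep(rnorm(8), 5), 5, 8, byrow = TRUE)
  enc2 <- intra_encode(same, params$groups[[1]], cfg)
  expect_equal(enc2$alpha, rep(1 / 5, 5), tolerance = 1e-12)
  expect_equal(enc2$z, as.vector(enc2$H[1, ]), tolerance = 1e-12)
})

test_that("pooling weights are the softmax of the query logits", {
  # encoder bypassed: zero intra layers, identity projection
  cfg <- moe_config(n_groups = 1, embed_dim = 2, n_heads = 1,
                    intra_layers = 0L, gate_hidden = 2, input_dims = 2)
  params <- moe_init(cfg, seed = 1)
  params$groups[[1]]$proj <- list(W = diag(2), b = c(0, 0))
  params$groups[[1]]$q <- c(1, 0)
  tokens <- rbind(c(1, 5), c(0, -3))       # logits = (1, 0)
  enc <- intra_encode(tokens, params$groups[[1]], cfg)
  expect_equal(enc$alpha, c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-12)
  expect_equal(round(enc$alpha, 4), c(0.7311, 0.2689))
})

test_that("gating weights live on the simplex and mix the refined vectors", {
  cfg <- tiny_arch(G = 7L, d = 8L)
  params <- moe_init(cfg, seed = 2)
  Z <- matrix(rnorm(7 * 8), 7, 8)

  # equal gate scores: zero the gating network
  p0 <- params
  p0$gate$W1[] <- 0; p0$gate$b1[] <- 0; p0$gate$W2[] <- 0; p0$gate$b2[] <- 0
  st <- inter_fuse(Z, p0, cfg)
  expect_equal(st$pi, rep(1 / 7, 7), tolerance = 1e-12)

  # G = 1 collapses
  cfg1 <- tiny_arch(G = 1L, d = 8L)
  p1 <- moe_init(cfg1, seed = 3)
  st1 <- inter_fuse(matrix(rnorm(8), 1, 8), p1, cfg1)
  expect_equal(st1$pi, 1)
  expect_equal(st1$u, as.vector(st1$zt))

  # u is a convex combination of the refined vectors, coordinate-wise
  st2 <- inter_fuse(Z, params, cfg)
  expect_true(all(st2$pi >= 0))
  expect_equal(sum(st2$pi), 1, tolerance = 1e-9)
  expect_true(all(st2$u >= apply(st2$zt, 2, min) - 1e-12))
  expect_true(all(st2$u <= apply(st2$zt, 2, max) + 1e-12))
  expect_equal(st2$u, as.vector(crossprod(st2$zt, st2$pi)), tolerance = 1e-12)
})

test_that("the risk head is linear with the documented identities", {
  u <- rnorm(8)
  expect_equal(risk_head(u, list(w = rep(0, 8), b = 1.5)), 1.5)
  head <- list(w = rnorm(8), b = 0)
  expect_equal(risk_head(2 * u, head), 2 * risk_head(u, head))
  expect_equal(risk_head(u + head$w, head) - risk_head(u, head),
               sum(head$w^2), tolerance = 1e-12)
})

test_that("the Cox partial likelihood matches closed forms and the oracle", {
  rec <- survival_record(c(1, 2, 3), c(1, 1, 0))
  expect_equal(cox_partial_nll(c(0, 0, 0), rec), log(6), tolerance = 1e-12)

  # single event among n equal risks
  n <- 11
  rec1 <- survival_record(c(0.5, seq(1, length.out = n - 1)),
                          c(1, rep(0, n - 1)))
  expect_equal(cox_partial_nll(rep(0, n), rec1), log(n), tolerance = 1e-12)

  # brute-force risk-set enumeration with ties
  set.seed(10)
  for (k in 1:25) {
    m <- sample(4:8, 1)
    time <- sample(1:4, m, replace = TRUE)
    event <- rbinom(m, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    r <- rnorm(m)
    expect_equal(cox_partial_nll(r, list(time = time, event = event)),
                 cox_nll_brute(r, time, event), tolerance = 1e-10)
  }

  expect_warning(loss0 <- cox_partial_nll(rnorm(3),
                                          list(time = 1:3, event = c(0, 0, 0))),
                 "no events")
  expect_equal(loss0, 0)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- tiny_arch(G = 2L, d = 6L, layers = 2L, heads = 2L)
  params <- moe_init(cfg, seed = 4)
  set.seed(5)
  pats <- lapply(1:4, function(i) random_patient(G = 2L, d = 6L, n_tokens = 3L))
  time <- c(2, 1, 3, 3); event <- c(1, 1, 1, 0)

  theta <- ns$nn_flatten(params)
  loss_of <- function(th) {
    p <- ns$nn_unflatten(th, params)
    risks <- vapply(pats, function(pt) ns$moe_forward(p, pt, cfg)$risk,
                    numeric(1))
    ns$cox_nll_grad(risks, list(time = time, event = event))$loss
  }
  fwd <- lapply(pats, function(pt) ns$moe_forward(params, pt, cfg))
  risks <- vapply(fwd, function(f) f$risk, numeric(1))
  cg <- ns$cox_nll_grad(risks, list(time = time, event = event))
  ga <- Reduce(`+`, lapply(seq_along(pats), function(i)
    ns$nn_flatten(ns$moe_backward(cg$grad[i], fwd[[i]], params, cfg))))

  set.seed(6)
  idx <- sample(length(theta), 40)
  eps <- 1e-5
  gn <- vapply(idx, function(j) {
    tp <- theta; tp[j] <- tp[j] + eps
    tm <- theta; tm[j] <- tm[j] - eps
    (loss_of(tp) - loss_of(tm)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(gn - ga[idx])), 1e-6)
})

test_that("prediction is deterministic and binds groups by id", {
  coh <- generate_cohort(cohort_config(40, embed_dim = 8,
                                       tokens_per_group = c(3, 5), seed = 12))
  arch <- tiny_arch(G = 7L, d = 8L)
  m <- train_task(coh, "PFS", arch = arch,
                  train = train_config(epochs = 2, batch_size = 20, seed = 3))
  pat <- coh$tokens[[1]]
  r1 <- predict_risk(m, pat)$risk
  r2 <- predict_risk(m, pat)$risk
  expect_identical(r1, r2)
  # permuting the group list leaves the risk unchanged (bound by group_id)
  r3 <- predict_risk(m, rev(pat))$risk
  expect_equal(r3, r1, tolerance = 1e-12)
  expect_error(predict_risk(m, pat[1:3]), "expects")
})

test_that("the two endpoint heads are fully independent", {
  coh <- generate_cohort(cohort_config(40, embed_dim = 8,
                                       tokens_per_group = c(3, 5), seed = 13))
  arch <- tiny_arch(G = 7L, d = 8L)
  mp <- train_task(coh, "PFS", arch = arch,
                   train = train_config(epochs = 2, batch_size = 20, seed = 4))
  mo <- train_task(coh, "OS", arch = arch,
                   train = train_config(epochs = 2, batch_size = 20, seed = 4))
  pat <- coh$tokens[[2]]
  rp <- predict_risk(mp, pat)$risk
  ro <- predict_risk(mo, pat)$risk
  expect_false(isTRUE(all.equal(rp, ro)))
  # perturbing the OS model leaves PFS predictions bit-identical
  mo$params$head$w <- mo$params$head$w + 1
  expect_identical(predict_risk(mp, pat)$risk, rp)
})

test_that("training descends on a signal cohort", {
  coh <- generate_cohort(cohort_config(80, embed_dim = 8,
                                       group_signal = rep(1, 7),
                                       tokens_per_group = c(3, 5),
                                       beta_r = 1.5, seed = 14))
  arch <- tiny_arch(G = 7L, d = 8L)
  m <- train_task(coh, "PFS", arch = arch,
                  train = train_config(epochs = 6, batch_size = 64, seed = 5))
  tr <- m$trace$train_loss
  expect_lt(tr[length(tr)], tr[1])
})
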