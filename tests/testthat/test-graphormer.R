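test_that("spatial bias is a pure table lookup with a slot for -1", {
  phi <- matrix(c(0L, 1L, -1L,
                  1L, 0L, 2L,
                  -1L, 2L, 0L), 3, 3, byrow = TRUE)
  tab <- c(9, 0.5, 1.5, 2.5, 3.5)       # slots: -1, 0, 1, 2, 3 (hop_max 3)
  B <- spatial_bias(phi, tab)
  expect_equal(B[1, 2], 1.5)
  expect_equal(B[1, 3], 9)               # unreachable slot, no error
  expect_equal(diag(B), rep(0.5, 3))
  expect_true(isSymmetric(B))
  expect_equal(spatial_bias(phi, rep(0, 5)), matrix(0, 3, 3))
  # equal phi values share a bias entry
  expect_equal(B[2, 1], B[1, 2])
  expect_error(spatial_bias(matrix(7L, 1, 1), tab), "phi values")

  # per-head tables give one matrix per head
  Bs <- spatial_bias(phi, rbind(tab, 2 * tab))
  expect_length(Bs, 2L)
  expect_equal(Bs[[2]][1, 2], 3)
})

test_that("edge bias averages position-indexed dot products", {
  wE <- matrix(0, 5, 8)
  expect_equal(edge_bias(matrix(1, 3, 8), wE), 0)
  # worked arithmetic: <x, w> = 2 + 2 over one edge
  x <- c(0, 0, 0, 0, 1, 0, 0, 4.0)
  w1 <- c(0, 0, 0, 0, 2, 0, 0, 0.5)
  wE[1, ] <- w1; wE[2, ] <- w1
  expect_equal(edge_bias(x, wE), 4.0)
  # averaging preserves a constant per-edge dot product
  expect_equal(edge_bias(rbind(x, x), wE), 4.0)
  expect_error(edge_bias(matrix(1, 6, 8), wE), "hop_max")
})

make_layer <- function(d, dff, seed = 1) {
  set.seed(seed)
  g <- function(a, b) matrix(rnorm(a * b, sd = 0.3), a, b)
  list(Wq = g(d, d), Wk = g(d, d), Wv = g(d, d), Wo = g(d, d),
       bo = rnorm(d, sd = 0.1), g1 = rep(1, d), be1 = numeric(d),
       W1 = g(d, dff), b1 = numeric(dff), W2 = g(dff, d), b2 = numeric(d),
       g2 = rep(1, d), be2 = numeric(d))
}

test_that("with zero biases the attention core matches a plain oracle", {
  set.seed(2)
  for (trial in 1:5) {
    n <- 5; d <- 6
    H <- matrix(rnorm(n * d), n, d)
    layer <- make_layer(d, 12, seed = trial)
    out <- biased_attention(H, layer, matrix(0, n, n), n_heads = 1L)
    P <- attr(out, "attention")[[1]]
    oracle <- plain_attention_oracle(H, layer$Wq, layer$Wk, layer$Wv)
    expect_equal(P, oracle$P, tolerance = 1e-12)
    # every softmax row is a probability vector
    expect_equal(rowSums(P), rep(1, n), tolerance = 1e-12)
    # and the attended values match
    core <- shellscore:::attention_core(H, layer$Wq, layer$Wk, layer$Wv,
                                        matrix(0, n, n), 1L)
    expect_equal(core$O, oracle$O, tolerance = 1e-12)
  }
})

test_that("a large positive bias toward one column concentrates attention there", {
  set.seed(3)
  n <- 6; d <- 4
  H <- matrix(rnorm(n * d), n, d)
  layer <- make_layer(d, 8)
  B0 <- matrix(0, n, n)
  P0 <- attr(biased_attention(H, layer, B0, 1L), "attention")[[1]]
  Bj <- B0; Bj[, 4] <- 10
  Pj <- attr(biased_attention(H, layer, Bj, 1L), "attention")[[1]]
  expect_true(all(Pj[, 4] > P0[, 4]))
  expect_true(all(Pj[, 4] > 0.95))
  expect_error(biased_attention(H, layer, matrix(0, 2, 2), 1L), "dimensions")
})

test_that("shell embeddings have the configured length and tolerate empty shells", {
  lay <- shell_layout(d0 = 3, d = 3, n_shells = 2)
  cfg <- gs_config(layout = lay, d_hidden = 16, n_heads = 2, n_layers = 1,
                   d_ff = 32, d_embed = 128, head_widths = c(8), seed = 1)
  set.seed(1)
  model <- init_model(cfg)
  cp <- make_toy_complex(n_protein = 10, pocket_radius = 4, seed = 1)
  feats <- featurize_pose(cp, lay)
  e1 <- encode_shell_graph(feats$graphs[[1]], model)   # no protein in shell 1
  e2 <- encode_shell_graph(feats$graphs[[2]], model)
  expect_length(e1, 128L)
  expect_length(e2, 128L)
  expect_true(all(is.finite(e1)))
  expect_equal(feats$graphs[[1]]$n_protein, 0L)        # ligand-only graph
})

test_that("shell embeddings are invariant under consistent node permutation", {
  lay <- shell_layout(d0 = 3, d = 3, n_shells = 2)
  for (ro in c("cls", "mean")) {
    cfg <- gs_config(layout = lay, d_hidden = 16, n_heads = 2, n_layers = 2,
                     d_ff = 32, d_embed = 32, head_widths = c(8),
                     readout = ro, seed = 5)
    set.seed(5)
    model <- init_model(cfg)
    # give the learnable biases structure so the test is not vacuous
    model$shells[[2]]$bias_tab[] <- rnorm(length(model$shells[[2]]$bias_tab))
    model$shells[[2]]$wE[] <- rnorm(length(model$shells[[2]]$wE), sd = 0.2)
    cp <- make_toy_complex(n_protein = 12, pocket_radius = c(3.2, 5.8), seed = 2)
    g <- featurize_pose(cp, lay)$graphs[[2]]
    e0 <- encode_shell_graph(g, model)
    for (trial in 1:10) {
      set.seed(100 + trial)
      perm <- sample(nrow(g$X))
      e1 <- encode_shell_graph(permute_shell_graph(g, perm), model)
      expect_equal(e1, e0, tolerance = 1e-10)
    }
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  lay <- shell_layout(d0 = 3, d = 3, n_shells = 2)
  cfg <- gs_config(layout = lay, d_hidden = 8, n_heads = 2, n_layers = 2,
                   d_ff = 16, d_embed = 6, head_widths = c(5, 4), seed = 3)
  cp <- make_toy_complex(n_protein = 8, pocket_radius = c(2.5, 5.5), seed = 2)
  feats <- featurize_pose(cp, lay, hop_max = cfg$hop_max)
  feats$prep <- lapply(feats$graphs, shellscore:::prep_graph_tensors)
  set.seed(cfg$seed)
  model <- init_model(cfg)
  # seed the bias parameters so their gradients are exercised off-zero
  for (k in 1:2) {
    model$shells[[k]]$bias_tab[] <- rnorm(length(model$shells[[k]]$bias_tab),
                                          sd = 0.3)
    model$shells[[k]]$wE[] <- rnorm(length(model$shells[[k]]$wE), sd = 0.2)
  }
  y <- 1.7
  skel <- list(shells = model$shells, head = model$head)
  theta <- shellscore:::pflatten(skel)
  loss_of <- function(th) {
    up <- shellscore:::punflatten(th, skel)
    model$shells <- up$shells; model$head <- up$head
    (shellscore:::pose_forward(model, feats)$pred - y)^2
  }
  fw <- shellscore:::pose_forward(model, feats, keep_cache = TRUE)
  fw$graphs <- feats$graphs
  grads <- shellscore:::pose_backward(model, fw, dpred = 2 * (fw$pred - y))
  gflat <- shellscore:::pflatten(grads)
  set.seed(9)
  idx <- sample(length(theta), 80)
  eps <- 1e-6
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (loss_of(tp) - loss_of(tm)) / (2 * eps)
  }, 1.0)
  rel <- abs(num - gflat[idx]) / pmax(1e-6, abs(num) + abs(gflat[idx]))
  expect_lt(max(rel), 1e-4)

  # differentiability smoke test: every parameter family receives gradient
  fam_sum <- function(gs, nm) sum(abs(unlist(lapply(gs$shells, function(s)
    if (nm %in% names(s)) s[[nm]] else lapply(s$layers, `[[`, nm)))))
  for (nm in c("W_in", "b_in", "h_cls", "bias_tab", "wE", "W_emb", "b_emb",
               "Wq", "Wk", "Wv", "Wo", "W1", "W2", "g1", "g2"))
    expect_gt(fam_sum(grads, nm), 0)
  expect_gt(sum(abs(unlist(grads$head))), 0)
})

test_that("model checkpoints round-trip through JSON", {
  lay <- shell_layout(d0 = 3, d = 3, n_shells = 2)
  cfg <- gs_config(layout = lay, d_hidden = 8, n_heads = 2, n_layers = 1,
                   d_ff = 16, d_embed = 16, head_widths = c(6), seed = 4)
  set.seed(4)
  model <- init_model(cfg)
  cp <- make_toy_complex(n_protein = 10, pocket_radius = c(3, 5.5), seed = 1)
  s0 <- forward_score(cp, model)
  tf <- withr::local_tempfile(fileext = ".json")
  save_model(model, tf)
  back <- load_model(tf)
  expect_equal(forward_score(cp, back), s0, tolerance = 1e-12)
  expect_equal(back$config$d_hidden, 8L)
  expect_equal(back$config$readout, "cls")
})
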