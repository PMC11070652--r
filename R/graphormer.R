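# Graph transformer encoder with shortest-path (spatial) and edge-path
# attention biases. Centrality (degree) encoding is deliberately absent: in
# ablation it does not help this task. All numerics are base-R double
# precision matrix algebra; the matching hand-derived backward pass lives in
# backprop.R.

#' Spatial attention bias from shortest-path hop counts
#'
#' Looks up one learnable scalar per shortest-path value: entry (i, j) of the
#' returned matrix is `bias_table[phi(i, j)]`. The unreachable sentinel -1
#' owns the first table slot, hop 0 (self pairs) the second, and hops
#' `1..hop_max` the rest, so the table has `hop_max + 2` columns.
#'
#' @param phi Integer matrix of hop counts in `{-1, 0, ..., hop_max}`.
#' @param bias_table Numeric vector of length `hop_max + 2` (one head), or a
#'   matrix with one row per head.
#' @return A bias matrix shaped like `phi`, or a list of per-head matrices
#'   when `bias_table` is a matrix.
#' @export
spatial_bias <- function(phi, bias_table) {
  tab <- if (is.matrix(bias_table)) bias_table else matrix(bias_table, 1L)
  n_slots <- ncol(tab)
  hop_max <- n_slots - 2L
  if (any(phi < -1L) || any(phi > hop_max))
    stop2("phi values must lie in {-1, 0, ..., %d} for a %d-slot bias table",
          hop_max, n_slots)
  idx <- phi + 2L  # -1 -> slot 1, 0 -> slot 2, ...
  out <- lapply(seq_len(nrow(tab)), function(h)
    matrix(tab[h, idx], nrow(phi), ncol(phi)))
  if (is.matrix(bias_table)) out else out[[1L]]
}

#' Edge-encoding bias along one shortest path
#'
#' Averages, over the path positions, the dot product of each edge's feature
#' vector with the learnable weight vector of that position:
#' `c = (1/N) * sum_p <x_{e_p}, w_p>`. Pairs with no path (hop 0 or -1)
#' contribute a bias of 0 and are handled by the caller.
#'
#' @param edge_path_feats N x d_E matrix of edge features along the path
#'   (already truncated to `hop_max` rows).
#' @param w_e hop_max x d_E matrix of position-indexed learnable weights.
#' @return Scalar bias value.
#' @examples
#' edge_bias(matrix(c(0, 0, 0, 0, 1, 0, 0, 4), 1),
#'           matrix(c(0, 0, 0, 0, 2, 0, 0, 0.5), 1))  # 4
#' @export
edge_bias <- function(edge_path_feats, w_e) {
  x <- if (is.matrix(edge_path_feats)) edge_path_feats
       else matrix(edge_path_feats, 1L)
  n <- nrow(x)
  if (n < 1L) stop2("empty edge path")
  if (n > nrow(w_e))
    stop2("path length %d exceeds hop_max %d: paths must arrive pre-truncated",
          n, nrow(w_e))
  if (ncol(x) != ncol(w_e)) stop2("edge feature width mismatch")
  mean(rowSums(x * w_e[seq_len(n), , drop = FALSE]))
}

# dense M x M edge-bias matrix from the precomputed path tensors
edge_bias_matrix <- function(prep, edge_feat, w_e) {
  M <- nrow(prep$ninv)
  C <- matrix(0, M, M)
  for (p in seq_along(prep$pos_idx)) {
    idx <- prep$pos_idx[[p]]
    if (!length(idx)) next
    dp <- as.vector(edge_feat %*% w_e[p, ])
    C[idx] <- C[idx] + dp[prep$pos_eid[[p]]]
  }
  C * prep$ninv
}

# precompute index structures for one shell graph (+ readout token as the
# last node): bias-table slot matrix, per-slot index groups, per-position
# edge-id lookups, and 1/N factors for the edge-path average
prep_graph_tensors <- function(g) {
  m0 <- nrow(g$X)
  M <- m0 + 1L
  hop_max <- g$hop_max
  slot <- matrix(0L, M, M)
  slot[seq_len(m0), seq_len(m0)] <- g$phi + 2L  # readout pairs keep slot 0
  slot_groups <- lapply(seq_len(hop_max + 2L), function(s) which(slot == s))
  ninv <- matrix(0, M, M)
  pl <- g$path_len
  sub <- matrix(0, m0, m0)
  sub[pl > 0L] <- 1 / pl[pl > 0L]
  ninv[seq_len(m0), seq_len(m0)] <- sub
  pos_idx <- vector("list", hop_max); pos_eid <- vector("list", hop_max)
  for (p in seq_len(hop_max)) {
    ep <- matrix(0L, M, M)
    ep[seq_len(m0), seq_len(m0)] <- g$path_eids[, , p]
    idx <- which(ep > 0L)
    pos_idx[[p]] <- idx
    pos_eid[[p]] <- ep[idx]
  }
  list(M = M, m0 = m0, slot = slot, slot_groups = slot_groups,
       ninv = ninv, pos_idx = pos_idx, pos_eid = pos_eid)
}

row_softmax <- function(A) {
  A <- A - apply(A, 1L, max)
  E <- exp(A)
  E / rowSums(E)
}

relu <- function(x) (x > 0) * x

layer_norm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd
  list(y = sweep(xhat, 2L, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, sd = sd)
}

# multi-head biased self-attention core: A_h = Q_h K_h^T / sqrt(d_h) + bias_h
attention_core <- function(H, Wq, Wk, Wv, bias, n_heads) {
  d <- ncol(H)
  if (d %% n_heads != 0L) stop2("hidden dim %d not divisible by %d heads", d, n_heads)
  dh <- d %/% n_heads
  if (!is.list(bias)) bias <- rep(list(bias), n_heads)
  if (length(bias) != n_heads) stop2("need one bias matrix per head")
  Q <- H %*% Wq; K <- H %*% Wk; V <- H %*% Wv
  O <- matrix(0, nrow(H), d)
  P <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    if (!identical(dim(bias[[h]]), dim(A)))
      stop2("bias matrix dimensions do not match the node count")
    A <- A + bias[[h]]
    P[[h]] <- row_softmax(A)
    O[, cols] <- P[[h]] %*% V[, cols, drop = FALSE]
  }
  list(O = O, P = P, Q = Q, K = K, V = V)
}

#' One graph-transformer layer with biased self-attention
#'
#' Multi-head scaled dot-product attention whose pre-softmax scores receive
#' the spatial bias `b_phi(i,j)` and edge-path bias `c_ij` per head, followed
#' by the output projection, residual connection, layer normalisation, a
#' two-layer feed-forward block, and a second residual + normalisation.
#' With all biases zero this is a plain transformer encoder layer.
#'
#' @param H M x d matrix of node representations (one row per node).
#' @param layer Layer parameter list (fields `Wq, Wk, Wv, Wo, bo, g1, be1,
#'   W1, b1, W2, b2, g2, be2`) as created by [init_model()].
#' @param bias A single M x M bias matrix, or a list of one per head.
#' @param n_heads Number of attention heads.
#' @return Updated M x d matrix. The softmax attention matrices are attached
#'   as attribute `"attention"` (one per head; each row sums to 1).
#' @export
biased_attention <- function(H, layer, bias, n_heads = 1L) {
  fw <- layer_forward(H, layer, bias, n_heads)
  out <- fw$H2
  attr(out, "attention") <- fw$att$P
  out
}

layer_forward <- function(H, layer, bias, n_heads) {
  att <- attention_core(H, layer$Wq, layer$Wk, layer$Wv, bias, n_heads)
  O <- att$O %*% layer$Wo + rep(layer$bo, each = nrow(H))
  R1 <- H + O
  ln1 <- layer_norm_fwd(R1, layer$g1, layer$be1)
  H1 <- ln1$y
  Z1 <- H1 %*% layer$W1 + rep(layer$b1, each = nrow(H))
  F1 <- relu(Z1)
  Ff <- F1 %*% layer$W2 + rep(layer$b2, each = nrow(H))
  R2 <- H1 + Ff
  ln2 <- layer_norm_fwd(R2, layer$g2, layer$be2)
  list(H_in = H, att = att, O = O, R1 = R1, ln1 = ln1, H1 = H1,
       Z1 = Z1, F1 = F1, Ff = Ff, R2 = R2, ln2 = ln2, H2 = ln2$y)
}

# full encoder forward for one shell graph; returns the 128-dim embedding
# and (optionally) every intermediate needed by the backward pass.
# readout: "cls" reads the virtual token's final row, "mean" pools the atom
# rows (the virtual node still participates in attention either way)
shell_forward <- function(sp, g, prep, keep_cache = FALSE, readout = "cls") {
  m0 <- prep$m0; M <- prep$M
  H <- rbind(g$X %*% sp$W_in + rep(sp$b_in, each = m0), sp$h_cls)
  C <- edge_bias_matrix(prep, g$edge_feat, sp$wE)
  n_heads <- nrow(sp$bias_tab)
  bias <- lapply(seq_len(n_heads), function(h) {
    tabh <- c(0, sp$bias_tab[h, ])        # slot 0 (readout pairs) -> bias 0
    matrix(tabh[prep$slot + 1L], M, M) + C
  })
  caches <- if (keep_cache) vector("list", length(sp$layers)) else NULL
  Hl <- H
  for (l in seq_along(sp$layers)) {
    fw <- layer_forward(Hl, sp$layers[[l]], bias, n_heads)
    if (keep_cache) caches[[l]] <- fw
    Hl <- fw$H2
  }
  h_read <- if (readout == "mean") colMeans(Hl[seq_len(m0), , drop = FALSE])
            else Hl[M, ]
  e <- as.vector(h_read %*% sp$W_emb) + sp$b_emb
  if (!keep_cache) return(list(e = e))
  list(e = e, H0 = H, C = C, bias = bias, caches = caches, H_out = Hl,
       h_read = h_read, readout = readout)
}

#' Encode one shell graph into its fixed-length embedding
#'
#' Projects the 171-dimensional node features to the hidden width, applies
#' the biased attention layer stack, and reads out through a dedicated
#' virtual readout node that attends to every atom (its bias slots are fixed
#' at zero), finally projecting to the embedding width (128 by default).
#' A shell graph with zero protein atoms still embeds (ligand-only graph).
#'
#' @param graph A [build_shell_graph()] result.
#' @param model A [init_model()] / [train_model()] model whose shell `graph$k`
#'   encoder is used.
#' @return Numeric embedding vector (length `model$config$d_embed`).
#' @export
encode_shell_graph <- function(graph, model) {
  stopifnot(inherits(graph, "shell_graph"))
  sp <- model$shells[[graph$k]]
  if (is.null(sp)) stop2("model has no encoder for shell %d", graph$k)
  if (graph$hop_max != model$config$hop_max)
    stop2("graph hop_max (%d) differs from model hop_max (%d)",
          graph$hop_max, model$config$hop_max)
  shell_forward(sp, graph, prep_graph_tensors(graph),
                readout = model$config$readout)$e
}
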