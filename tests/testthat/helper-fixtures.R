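# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain loops, independent of the package's vectorised implementations.

# -- molecules ---------------------------------------------------------------

make_benzene <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  ligand_molecule(rep("C", 6),
                  cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
                  data.frame(i = 1:6, j = c(2:6, 1), type = "AROMATIC"))
}

make_chain <- function(elements, types = NULL) {
  n <- length(elements)
  types <- types %||% rep("SINGLE", n - 1L)
  ligand_molecule(elements, cbind(1.5 * seq_len(n), 0, 0),
                  if (n > 1L) data.frame(i = seq_len(n - 1L),
                                         j = 2:n, type = types) else NULL)
}

rotate_z <- function(xyz, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  xyz %*% t(R)
}

# a tiny PDB file: 3 protein atoms, 1 water, 1 zinc HETATM
write_tiny_pdb <- function(path, resolution = 2.1) {
  lines <- c(
    sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution),
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "HETATM    4  O   HOH A 101       8.000   8.000   8.000  1.00  0.00           O",
    "HETATM    5 ZN    ZN A 201       5.000   5.000   5.000  1.00  0.00          ZN",
    "END")
  writeLines(lines, path)
  path
}

# -- graph oracles -----------------------------------------------------------

# BFS hop counts, written independently of floyd_warshall_paths
bfs_hops <- function(edges, n) {
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    adj[[edges$i[e]]] <- c(adj[[edges$i[e]]], edges$j[e])
    adj[[edges$j[e]]] <- c(adj[[edges$j[e]]], edges$i[e])
  }
  out <- matrix(-1L, n, n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); dist[s] <- 0L
    q <- s
    while (length(q)) {
      v <- q[1L]; q <- q[-1L]
      for (w in adj[[v]]) if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L; q <- c(q, w)
      }
    }
    out[s, ] <- dist
  }
  out
}

random_edge_list <- function(n, p = 0.2) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  data.frame(i = pairs[keep, 1L], j = pairs[keep, 2L])
}

# plain single-head attention oracle (explicit loops, no biases)
plain_attention_oracle <- function(H, Wq, Wk, Wv) {
  Q <- H %*% Wq; K <- H %*% Wk; V <- H %*% Wv
  n <- nrow(H); d <- ncol(Wq)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    scores <- numeric(n)
    for (j in seq_len(n)) scores[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    e <- exp(scores - max(scores))
    P[i, ] <- e / sum(e)
  }
  list(P = P, O = P %*% V)
}

# brute-force minimum RMSD over element- and bond-preserving permutations
brute_force_sym_rmsd <- function(pose, ref) {
  n <- length(ref$elements)
  adj <- matrix("", n, n)
  for (e in seq_len(nrow(ref$bonds))) {
    adj[ref$bonds$i[e], ref$bonds$j[e]] <- ref$bonds$type[e]
    adj[ref$bonds$j[e], ref$bonds$i[e]] <- ref$bonds$type[e]
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (q in seq_along(v))
      out <- c(out, lapply(perms(v[-q]), function(p) c(v[q], p)))
    out
  }
  best <- Inf
  for (perm in perms(seq_len(n))) {
    if (any(ref$elements[perm] != ref$elements)) next
    ok <- TRUE
    for (a in seq_len(n)) for (b in seq_len(n))
      if (adj[perm[a], perm[b]] != adj[a, b]) { ok <- FALSE; break }
    if (!ok) next
    v <- sqrt(mean(rowSums((pose$xyz[perm, , drop = FALSE] - ref$xyz)^2)))
    best <- min(best, v)
  }
  best
}

# consistently permute every node-indexed structure of a shell graph
permute_shell_graph <- function(g, perm) {
  inv <- order(perm)   # new index of old node i is inv[i]
  g2 <- g
  g2$X <- g$X[perm, , drop = FALSE]
  g2$edges$i <- inv[g$edges$i]
  g2$edges$j <- inv[g$edges$j]
  g2$phi <- g$phi[perm, perm, drop = FALSE]
  g2$path_len <- g$path_len[perm, perm, drop = FALSE]
  for (p in seq_len(dim(g$path_eids)[3L]))
    g2$path_eids[, , p] <- g$path_eids[perm, perm, p]
  g2
}

# brute-force ranking metric counters (independent loops)
brute_docking_power <- function(df, k, thr) {
  cids <- unique(df$complex_id)
  hits <- 0L
  for (cid in cids) {
    sub <- df[df$complex_id == cid, ]
    sub <- sub[order(sub$score), ]
    if (any(sub$rmsd[seq_len(min(k, nrow(sub)))] < thr)) hits <- hits + 1L
  }
  hits / length(cids)
}

brute_hit_rate <- function(df, k, thr) {
  cids <- unique(df$complex_id)
  vals <- c()
  for (cid in cids) {
    sub <- df[df$complex_id == cid, ]
    P <- sum(sub$rmsd < thr)
    if (P == 0L) next
    sub <- sub[order(sub$score), ]
    h <- sum(sub$rmsd[seq_len(min(k, nrow(sub)))] < thr)
    vals <- c(vals, h / P)
  }
  mean(vals)
}

brute_ef <- function(df, k, thr) {
  cids <- unique(df$complex_id)
  vals <- c()
  for (cid in cids) {
    sub <- df[df$complex_id == cid, ]
    P <- sum(sub$rmsd < thr)
    if (P == 0L) next
    sub <- sub[order(sub$score), ]
    h <- sum(sub$rmsd[seq_len(min(k, nrow(sub)))] < thr)
    vals <- c(vals, h / (P * (k / nrow(sub))))
  }
  mean(vals)
}

random_ranking_fixture <- function(n_complexes, max_poses, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_complexes), function(ci) {
    np <- sample(5:max_poses, 1L)
    data.frame(complex_id = sprintf("c%02d", ci),
               pose_id = sprintf("p%03d", seq_len(np)),
               score = runif(np, 0, 10),
               rmsd = runif(np, 0, 8))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reduced desk-scale configuration used by the training tests
desk_layout <- function() shell_layout(d0 = 3, d = 3, n_shells = 2)

desk_config <- function(seed = 1L, ...) {
  gs_config(layout = desk_layout(), d_hidden = 32L, n_heads = 4L,
            n_layers = 1L, d_ff = 64L, d_embed = 128L,
            head_widths = c(32L, 16L), readout = "mean", seed = seed, ...)
}
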