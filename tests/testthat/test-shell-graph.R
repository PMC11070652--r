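one_atom_ligand <- function() {
  ligand_molecule("C", matrix(0, 1, 3))
}

protein_at <- function(xyz) {
  n <- nrow(xyz)
  protein_structure(data.frame(
    element = "C", atom_name = "CA", resname = "ALA", resid = seq_len(n),
    chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    is_hetatm = FALSE), resolution = 2.0)
}

test_that("shell assignment follows the boundary formula with (lower, upper]", {
  lay <- shell_layout(d0 = 3, d = 1, n_shells = 10)
  expect_equal(shell_boundary(lay, 1:3), c(3, 4, 5))
  lig <- one_atom_ligand()
  expect_equal(assign_shell(c(1.5, 0, 0), lig, lay), 1L)   # r = 0.5*d0
  expect_equal(assign_shell(c(3, 0, 0), lig, lay), 1L)     # boundary value
  expect_equal(assign_shell(c(3.0001, 0, 0), lig, lay), 2L)
  expect_equal(assign_shell(c(12.5, 0, 0), lig, lay), NA_integer_)  # > 12
  expect_equal(assign_shell(c(12, 0, 0), lig, lay), 10L)
})

test_that("shell membership partitions the in-range protein atoms exactly", {
  lay <- shell_layout()
  for (seed in 1:5) {
    cp <- make_toy_complex(n_protein = 40, pocket_radius = c(2, 14),
                           seed = seed)
    xyz <- as.matrix(cp$protein$atoms[, c("x", "y", "z")])
    r <- apply(shellscore:::cross_dist(xyz, cp$ligand$xyz), 1, min)
    ks <- assign_shell(xyz, cp$ligand, lay)
    built <- build_all_shells(cp, lay)
    member <- matrix(FALSE, nrow(xyz), lay$n_shells)
    for (k in seq_len(lay$n_shells))
      member[built$graphs[[k]]$protein_atom_idx, k] <- TRUE
    counts <- rowSums(member)
    expect_equal(counts, ifelse(is.na(ks), 0L, 1L))  # exactly one shell
    for (k in seq_len(lay$n_shells))
      expect_setequal(built$graphs[[k]]$protein_atom_idx, which(ks == k))
  }
})

test_that("protein-ligand edges carry DistMax, not the true distance", {
  lay <- shell_layout(d0 = 3, d = 1, n_shells = 10)
  cp <- complex_pose(protein_at(matrix(c(2, 0, 0), 1)), one_atom_ligand())
  g <- build_shell_graph(cp, 1, lay)
  expect_equal(g$n_protein, 1L)
  pl <- g$edges[g$edges$category == "NONCOVALENT", ]
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$dist, 3.0)                       # DistMax, not 2.0
  expect_equal(g$edge_feat[nrow(g$edge_feat), 8], 3.0)
  expect_error(build_shell_graph(cp, 11, lay), "out of range")
})

test_that("ligand bonds keep a fixed distance feature of 1", {
  lay <- shell_layout()
  cp <- make_toy_complex(n_protein = 5, pocket_radius = 4, seed = 1)
  g <- build_shell_graph(cp, 2, lay)
  lig_edges <- g$edges$category != "NONCOVALENT"
  expect_true(all(g$edges$dist[lig_edges] == 1))
  expect_equal(sum(lig_edges), nrow(cp$ligand$bonds))
})

test_that("no edge ever joins two protein atoms, and every protein node touches the ligand", {
  lay <- shell_layout()
  for (seed in 1:4) {
    cp <- make_toy_complex(n_protein = 30, pocket_radius = c(2, 12),
                           seed = seed)
    built <- build_all_shells(cp, lay)
    for (g in built$graphs) {
      if (nrow(g$edges) == 0) next
      both_protein <- g$edges$i > g$n_ligand & g$edges$j > g$n_ligand
      expect_false(any(both_protein))
      if (g$n_protein > 0) {
        pnodes <- g$n_ligand + seq_len(g$n_protein)
        touched <- pnodes %in% c(g$edges$i, g$edges$j)
        expect_true(all(touched))
      }
    }
  }
})

test_that("shell graphs are invariant under rigid motion of the whole complex", {
  lay <- shell_layout()
  cp <- make_toy_complex(n_protein = 20, pocket_radius = c(2.5, 8), seed = 3)
  set.seed(11)
  R <- shellscore:::random_rotation()
  t_vec <- c(5, -3, 2)
  cp2 <- cp
  cp2$ligand$xyz <- cp$ligand$xyz %*% t(R) + rep(t_vec, each = nrow(cp$ligand$xyz))
  pxyz <- as.matrix(cp$protein$atoms[, c("x", "y", "z")])
  moved <- pxyz %*% t(R) + rep(t_vec, each = nrow(pxyz))
  cp2$protein$atoms[, c("x", "y", "z")] <- moved
  a <- build_all_shells(cp, lay)
  b <- build_all_shells(cp2, lay)
  for (k in seq_len(lay$n_shells)) {
    expect_equal(a$graphs[[k]]$protein_atom_idx, b$graphs[[k]]$protein_atom_idx)
    expect_equal(a$graphs[[k]]$X, b$graphs[[k]]$X)
    expect_equal(a$graphs[[k]]$edges, b$graphs[[k]]$edges)
    expect_equal(a$graphs[[k]]$phi, b$graphs[[k]]$phi)
  }
})

test_that("Floyd-Warshall hop counts handle paths, gaps and truncation", {
  # path graph 1-2-3
  sp <- floyd_warshall_paths(data.frame(i = c(1, 2), j = c(2, 3)), 3)
  expect_equal(sp$phi[1, 3], 2L)
  expect_equal(diag(sp$phi), rep(0L, 3))
  # disconnected pair
  sp2 <- floyd_warshall_paths(data.frame(i = 1, j = 2), 3)
  expect_equal(sp2$phi[1, 3], -1L)
  expect_equal(sp2$phi[3, 1], -1L)
  # 8-node path with hop_max 5: capped count and truncated edge path
  sp3 <- floyd_warshall_paths(data.frame(i = 1:7, j = 2:8), 8, hop_max = 5)
  expect_equal(sp3$phi[1, 8], 5L)
  expect_equal(sp3$path_len[1, 8], 5L)
  expect_equal(as.vector(sp3$path_eids[1, 8, ]), 1:5)  # first five edges
  expect_equal(sp3$phi[1, 4], 3L)
})

test_that("Floyd-Warshall agrees with a BFS oracle on random graphs", {
  set.seed(20)
  for (trial in 1:50) {
    n <- sample(4:30, 1)
    edges <- random_edge_list(n, p = runif(1, 0.05, 0.3))
    hop_max <- sample(2:6, 1)
    sp <- floyd_warshall_paths(edges, n, hop_max)
    oracle <- bfs_hops(edges, n)
    capped <- oracle
    capped[oracle > hop_max] <- hop_max
    expect_identical(sp$phi, capped)
    # stored paths are real paths of the declared length
    for (probe in seq_len(3)) {
      i <- sample(n, 1); j <- sample(n, 1)
      len <- sp$path_len[i, j]
      if (len > 0) {
        eids <- sp$path_eids[i, j, seq_len(len)]
        expect_true(all(eids >= 1 & eids <= nrow(edges)))
      }
    }
  }
})

test_that("dissociated poses are flagged only when every shell is empty", {
  lay <- shell_layout()
  far <- make_toy_complex(n_protein = 10, pocket_radius = 50, seed = 2)
  expect_true(build_all_shells(far, lay)$dissociated)

  # a single atom in shell 3 keeps the pose associated
  cp <- complex_pose(protein_at(matrix(c(4.5, 0, 0), 1)), one_atom_ligand())
  built <- build_all_shells(cp, lay)
  expect_false(built$dissociated)
  expect_equal(vapply(built$graphs, function(g) g$n_protein, 1L),
               c(0L, 0L, 1L, rep(0L, 7L)))
  expect_equal(length(built$graphs), lay$n_shells)
})

test_that("pose features survive a JSON round trip", {
  lay <- shell_layout(d0 = 3, d = 3, n_shells = 2)
  cp <- make_toy_complex(n_protein = 8, pocket_radius = c(2.5, 5.5), seed = 5)
  f <- featurize_pose(cp, lay)
  tf <- withr::local_tempfile(fileext = ".json")
  save_pose_features(f, tf)
  g <- load_pose_features(tf)
  expect_equal(g$complex_id, f$complex_id)
  expect_equal(g$graphs[[1]]$X, f$graphs[[1]]$X)
  expect_equal(g$graphs[[2]]$phi, f$graphs[[2]]$phi)
  expect_equal(g$graphs[[1]]$path_eids, f$graphs[[1]]$path_eids)
  expect_equal(g$graphs[[1]]$edge_feat, f$graphs[[1]]$edge_feat)
})
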