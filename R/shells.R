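#' Concentric shell layout around the whole ligand
#'
#' Shell k spans radial distances `(d0 + (k-2)*d, d0 + (k-1)*d]` from the
#' nearest ligand atom (shell 1 spans `(0, d0]`), so the outer boundary of
#' shell k is `d0 + (k-1)*d`. Defaults: `d0 = 3` A, `d = 1` A, 10 shells
#' (outer boundary 12 A), covering the usual non-covalent interaction range.
#'
#' @param d0 Outer boundary of the first shell (A), > 0.
#' @param d Inter-shell spacing (A), > 0.
#' @param n_shells Number of shells, >= 1.
#' @return An object of class `shell_layout`.
#' @export
shell_layout <- function(d0 = 3.0, d = 1.0, n_shells = 10L) {
  if (d0 <= 0 || d <= 0 || n_shells < 1L)
    stop2("invalid layout: need d0 > 0, d > 0, n_shells >= 1")
  structure(list(d0 = d0, d = d, n_shells = as.integer(n_shells)),
            class = "shell_layout")
}

#' @export
print.shell_layout <- function(x, ...) {
  cat(sprintf("shell layout: %d shells, boundaries %s A\n", x$n_shells,
              paste(shell_boundary(x, seq_len(x$n_shells)), collapse = ", ")))
  invisible(x)
}

#' Outer boundary of shell k
#' @param layout A [shell_layout()].
#' @param k Shell index (vectorised).
#' @return `d0 + (k-1)*d` in Angstrom.
#' @export
shell_boundary <- function(layout, k) layout$d0 + (k - 1) * layout$d

# vectorised: shell index for radial distances r (NA when beyond the outer
# boundary); half-open intervals (lower, upper], so r == d0 is shell 1
shell_index_of <- function(r, layout) {
  k <- ifelse(r <= layout$d0, 1L,
              1L + ceiling((r - layout$d0) / layout$d))
  k <- as.integer(k)
  k[r <= 0] <- 1L
  k[k > layout$n_shells] <- NA_integer_
  k
}

#' Assign a protein atom to its shell
#'
#' The shell of an atom is determined by its distance to the nearest ligand
#' atom: the smallest k whose outer boundary contains that distance
#' (half-open intervals, boundary values belong to the inner shell).
#'
#' @param atom_xyz Length-3 coordinate vector, or an n x 3 matrix.
#' @param ligand A [ligand_molecule()].
#' @param layout A [shell_layout()].
#' @return Integer shell index (vector for matrix input); `NA` when the atom
#'   lies beyond the outermost boundary.
#' @export
assign_shell <- function(atom_xyz, ligand, layout) {
  m <- if (is.matrix(atom_xyz)) atom_xyz else matrix(atom_xyz, ncol = 3L)
  if (!is_finite_coords(m)) stop2("non-finite coordinates")
  r <- apply(cross_dist(m, ligand$xyz), 1L, min)
  shell_index_of(r, layout)
}

# ---------------------------------------------------------------------------
# Shortest paths
# ---------------------------------------------------------------------------

#' All-pairs shortest hop counts and edge paths (Floyd-Warshall)
#'
#' Hop counts come from the Floyd-Warshall recurrence on the unweighted
#' graph; values above `hop_max` are capped at `hop_max` and unreachable
#' pairs are marked `-1` (their own slot in the spatial-bias table). For each
#' reachable pair one shortest path is reconstructed deterministically
#' (breadth-first search whose queue and adjacency are processed in
#' increasing node id, so ties resolve to the smallest intermediate id) and
#' its first `min(N, hop_max)` edge ids are stored for the edge-encoding
#' bias.
#'
#' @param edges data.frame with 1-based node columns `i`, `j` (undirected).
#' @param n_nodes Number of nodes (>= 1).
#' @param hop_max Path truncation length (>= 1).
#' @return List: `phi` (n x n integer matrix in `{-1, 0, ..., hop_max}`),
#'   `path_eids` (n x n x hop_max integer array of edge ids, 0-padded) and
#'   `path_len` (n x n count of stored edges per pair).
#' @export
floyd_warshall_paths <- function(edges, n_nodes, hop_max = 5L) {
  n <- as.integer(n_nodes)
  if (n < 1L) stop2("need at least one node")
  if (hop_max < 1L) stop2("hop_max must be >= 1")
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  eidm <- matrix(0L, n, n)
  ne <- nrow(edges)
  if (ne) {
    ii <- as.integer(edges$i); jj <- as.integer(edges$j)
    D[cbind(ii, jj)] <- 1; D[cbind(jj, ii)] <- 1
    eidm[cbind(ii, jj)] <- seq_len(ne); eidm[cbind(jj, ii)] <- seq_len(ne)
  }
  for (k in seq_len(n)) {
    via <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, via)
  }
  phi <- matrix(-1L, n, n)
  reach <- is.finite(D)
  phi[reach] <- pmin(as.integer(D[reach]), as.integer(hop_max))

  path_eids <- array(0L, dim = c(n, n, hop_max))
  path_len <- matrix(0L, n, n)
  if (ne) {
    adj <- vector("list", n)
    for (e in seq_len(ne)) {
      adj[[edges$i[e]]] <- c(adj[[edges$i[e]]], edges$j[e])
      adj[[edges$j[e]]] <- c(adj[[edges$j[e]]], edges$i[e])
    }
    adj <- lapply(adj, function(v) sort(unique(v)))
    for (s in seq_len(n)) {
      parent <- integer(n); dist <- rep(NA_integer_, n)
      dist[s] <- 0L; queue <- s; qpos <- 1L
      while (qpos <= length(queue)) {
        v <- queue[qpos]; qpos <- qpos + 1L
        for (w in adj[[v]]) if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L; parent[w] <- v
          queue <- c(queue, w)
        }
      }
      for (t in which(!is.na(dist) & dist > 0L)) {
        # walk t -> s, then take the first hop_max edges from the s side
        node_path <- integer(dist[t] + 1L)
        v <- t; p <- dist[t] + 1L
        while (p >= 1L) { node_path[p] <- v; if (p > 1L) v <- parent[v]; p <- p - 1L }
        nkeep <- min(dist[t], hop_max)
        for (q in seq_len(nkeep))
          path_eids[s, t, q] <- eidm[node_path[q], node_path[q + 1L]]
        path_len[s, t] <- nkeep
      }
    }
  }
  list(phi = phi, path_eids = path_eids, path_len = path_len)
}

# ---------------------------------------------------------------------------
# Shell graph construction
# ---------------------------------------------------------------------------

#' Build the bipartite-plus-ligand graph of shell k
#'
#' Nodes are all ligand atoms plus the protein atoms whose nearest-ligand
#' distance falls in `(DistMin, DistMax]` for shell k. Ligand covalent bonds
#' become edges with their bond category and a fixed distance feature of 1;
#' every protein-ligand atom pair with Euclidean distance in
#' `(DistMin, DistMax]` becomes a Non-covalent edge whose distance feature is
#' DistMax (the shell's outer boundary, not the true pairwise distance). No
#' protein-protein edges are ever created.
#'
#' @param complex A [complex_pose()].
#' @param k Shell index in `1..n_shells`.
#' @param layout A [shell_layout()].
#' @param schema A [feature_schema()].
#' @param hop_max Shortest-path truncation (default 5).
#' @return An object of class `shell_graph` with node feature matrix `X`
#'   (rows: ligand atoms then protein atoms; 171 columns), edge table and
#'   8-column edge feature matrix, shortest-path matrix `phi` and edge-path
#'   arrays for the attention biases.
#' @export
build_shell_graph <- function(complex, k, layout, schema = feature_schema(),
                              hop_max = 5L) {
  if (k < 1L || k > layout$n_shells)
    stop2("shell index %d out of range 1..%d", k, layout$n_shells)
  pa <- complex$protein$atoms
  dmat <- cross_dist(as.matrix(pa[, c("x", "y", "z")]), complex$ligand$xyz)
  build_shell_graph_impl(complex, k, layout, schema, hop_max, dmat)
}

build_shell_graph_impl <- function(complex, k, layout, schema, hop_max, dmat) {
  lig <- complex$ligand
  pa <- complex$protein$atoms
  nl <- length(lig$elements)
  dist_max <- shell_boundary(layout, k)
  dist_min <- if (k == 1L) 0 else shell_boundary(layout, k - 1L)
  r <- apply(dmat, 1L, min)
  members <- which(r > dist_min & r <= dist_max)
  np <- length(members)
  m0 <- nl + np

  X <- matrix(0, m0, schema$node_width)
  for (a in seq_len(nl)) {
    d <- lig$derived[a, ]
    X[a, ] <- encode_ligand_node(list(
      element = lig$elements[a], degree = d$degree,
      implicit_valence = d$implicit_valence, n_hydrogen = d$n_hydrogen,
      hybridization = d$hybridization, formal_charge = lig$formal_charges[a],
      ring_size = d$ring_size, aromatic = d$aromatic), schema)
  }
  for (q in seq_len(np)) {
    row <- pa[members[q], ]
    X[nl + q, ] <- encode_protein_node(list(
      element = row$element, degree = row$degree,
      implicit_valence = row$implicit_valence, n_hydrogen = row$n_hydrogen,
      hybridization = row$hybridization, resname = row$resname,
      atom_name = row$atom_name), schema)
  }

  # edges: ligand covalent bonds (distance feature fixed at 1) ...
  ei <- lig$bonds$i; ej <- lig$bonds$j
  ecat <- lig$bonds$type
  edist <- rep(1.0, length(ei))
  # ... plus protein-ligand contacts in (DistMin, DistMax], feature = DistMax
  if (np) {
    sub <- dmat[members, , drop = FALSE]
    hits <- which(sub > dist_min & sub <= dist_max, arr.ind = TRUE)
    if (nrow(hits)) {
      ei <- c(ei, nl + hits[, 1L]); ej <- c(ej, hits[, 2L])
      ecat <- c(ecat, rep("NONCOVALENT", nrow(hits)))
      edist <- c(edist, rep(dist_max, nrow(hits)))
    }
  }
  edges <- data.frame(i = as.integer(ei), j = as.integer(ej),
                      category = ecat, dist = edist,
                      stringsAsFactors = FALSE)
  E <- matrix(0, nrow(edges), schema$edge_width)
  for (e in seq_len(nrow(edges)))
    E[e, ] <- encode_edge(edges$category[e], edges$dist[e], schema)

  sp <- floyd_warshall_paths(edges, m0, hop_max)
  structure(list(
    k = k, n_ligand = nl, n_protein = np,
    protein_atom_idx = members,
    dist_min = dist_min, dist_max = dist_max, hop_max = as.integer(hop_max),
    X = X, edges = edges, edge_feat = E,
    phi = sp$phi, path_eids = sp$path_eids, path_len = sp$path_len),
    class = "shell_graph")
}

#' @export
print.shell_graph <- function(x, ...) {
  cat(sprintf("shell graph k=%d: %d ligand + %d protein nodes, %d edges\n",
              x$k, x$n_ligand, x$n_protein, nrow(x$edges)))
  invisible(x)
}

#' Build every shell graph of a pose and flag dissociated conformations
#'
#' Returns the n shell graphs plus a `dissociated` flag that is `TRUE` when
#' no protein atom falls inside any shell (ligand drifted away from the
#' protein); such poses are scored as RMSD `+Inf` downstream rather than
#' passed through the model.
#'
#' @inheritParams build_shell_graph
#' @return List with `graphs` (length `n_shells`) and `dissociated` flag.
#' @export
build_all_shells <- function(complex, layout, schema = feature_schema(),
                             hop_max = 5L) {
  pa <- complex$protein$atoms
  dmat <- cross_dist(as.matrix(pa[, c("x", "y", "z")]), complex$ligand$xyz)
  graphs <- lapply(seq_len(layout$n_shells), function(k)
    build_shell_graph_impl(complex, k, layout, schema, hop_max, dmat))
  list(graphs = graphs,
       dissociated = all(vapply(graphs, function(g) g$n_protein, 1L) == 0L))
}

#' Featurize a pose for scoring or training
#'
#' Wraps [build_all_shells()] and carries the pose identity and label along,
#' producing the unit consumed by [forward_score()] and [train_model()].
#'
#' @inheritParams build_shell_graph
#' @return An object of class `pose_features`.
#' @export
featurize_pose <- function(complex, layout, schema = feature_schema(),
                           hop_max = 5L) {
  built <- build_all_shells(complex, layout, schema, hop_max)
  structure(list(graphs = built$graphs, dissociated = built$dissociated,
                 complex_id = complex$complex_id, pose_id = complex$pose_id,
                 rmsd_label = complex$rmsd_label),
            class = "pose_features")
}

#' Serialize / restore shell graphs (JSON container)
#'
#' Caches featurized poses between runs: node matrix, edge list, edge
#' features, shortest-path matrix and edge-path table per shell graph.
#'
#' @param feats A `pose_features` object.
#' @param path Output JSON path.
#' @return `path` / the restored `pose_features`.
#' @export
save_pose_features <- function(feats, path) {
  jsonlite::write_json(serialize_pose_features(feats), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

serialize_pose_features <- function(feats) {
  list(complex_id = feats$complex_id, pose_id = feats$pose_id,
       rmsd_label = feats$rmsd_label, dissociated = feats$dissociated,
       graphs = lapply(feats$graphs, function(g) list(
         k = g$k, n_ligand = g$n_ligand, n_protein = g$n_protein,
         protein_atom_idx = g$protein_atom_idx,
         dist_min = g$dist_min, dist_max = g$dist_max, hop_max = g$hop_max,
         X = g$X, edges = g$edges, edge_feat = g$edge_feat,
         phi = g$phi, path_eids = as.vector(g$path_eids),
         path_dim = dim(g$path_eids), path_len = g$path_len)))
}

#' @rdname save_pose_features
#' @export
load_pose_features <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  graphs <- lapply(seq_len(if (is.data.frame(s$graphs)) nrow(s$graphs)
                           else length(s$graphs)),
                   function(q) {
    g <- if (is.data.frame(s$graphs)) lapply(s$graphs, `[[`, q)
         else s$graphs[[q]]
    structure(list(
      k = g$k, n_ligand = g$n_ligand, n_protein = g$n_protein,
      protein_atom_idx = g$protein_atom_idx,
      dist_min = g$dist_min, dist_max = g$dist_max, hop_max = g$hop_max,
      X = as.matrix(g$X),
      edges = as.data.frame(g$edges),
      edge_feat = matrix(as.numeric(as.matrix(g$edge_feat)),
                         nrow = NROW(g$edge_feat)),
      phi = matrix(as.integer(as.matrix(g$phi)), nrow = NROW(g$phi)),
      path_eids = array(as.integer(unlist(g$path_eids)), dim = unlist(g$path_dim)),
      path_len = matrix(as.integer(as.matrix(g$path_len)), nrow = NROW(g$path_len))),
      class = "shell_graph")
  })
  structure(list(graphs = graphs,
                 dissociated = isTRUE(s$dissociated),
                 complex_id = s$complex_id, pose_id = s$pose_id,
                 rmsd_label = s$rmsd_label %||% NA_real_),
            class = "pose_features")
}
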