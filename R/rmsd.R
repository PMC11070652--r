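#' Root-mean-square deviation between two conformers of the same molecule
#'
#' Docking RMSD: computed in the common coordinate frame, with no
#' superposition. With `symmetry = FALSE` atoms correspond by position in the
#' atom list; with `symmetry = TRUE` the minimum RMSD over all graph
#' automorphisms of the ligand (element- and bond-preserving permutations,
#' enumerated with VF2) is returned, so chemically equivalent atoms such as
#' the two ortho carbons of a phenyl ring can swap without penalty.
#'
#' @param pose,reference [ligand_molecule()] objects with the same molecular
#'   graph (same atom count and element multiset after hydrogen filtering).
#' @param symmetry Minimise over graph automorphisms (default `FALSE`).
#' @param heavy_only Restrict to heavy atoms (default `TRUE`).
#' @return RMSD in Angstrom (non-negative scalar).
#' @examples
#' lig <- ligand_molecule(c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)),
#'                        data.frame(i = 1, j = 2, type = "DOUBLE"))
#' shifted <- lig; shifted$xyz <- lig$xyz + rep(c(3, 0, 0), each = 2)
#' compute_rmsd(shifted, lig)  # 3: rigid translation by |t|
#' @export
compute_rmsd <- function(pose, reference, symmetry = FALSE, heavy_only = TRUE) {
  stopifnot(inherits(pose, "ligand_molecule"),
            inherits(reference, "ligand_molecule"))
  p <- ligand_subset(pose, heavy_only)
  r <- ligand_subset(reference, heavy_only)
  if (nrow(p$xyz) != nrow(r$xyz))
    stop2("incompatible molecules: %d vs %d atoms", nrow(p$xyz), nrow(r$xyz))
  if (!identical(sort(p$elements), sort(r$elements)))
    stop2("incompatible molecules: element multisets differ")
  plain <- rmsd_identity(p$xyz, r$xyz)
  if (!symmetry) return(plain)
  perms <- ligand_automorphisms(r)
  best <- plain
  for (perm in perms) {
    v <- rmsd_identity(p$xyz[perm, , drop = FALSE], r$xyz)
    if (v < best) best <- v
  }
  best
}

rmsd_identity <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

ligand_subset <- function(lig, heavy_only) {
  if (!heavy_only) return(lig)
  keep <- lig$elements != "H"
  idx <- which(keep)
  remap <- match(seq_along(lig$elements), idx)
  b <- lig$bonds[lig$bonds$i %in% idx & lig$bonds$j %in% idx, , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  list(elements = lig$elements[keep],
       xyz = lig$xyz[keep, , drop = FALSE],
       bonds = b)
}

#' Enumerate the graph automorphisms of a ligand
#'
#' Permutations of the atom list that preserve element identities and the
#' bonded structure (bond categories as edge colours), found with igraph's
#' VF2 matcher. Isolated atoms of the same element are also interchangeable.
#'
#' @param lig A [ligand_molecule()] or the list produced by the internal
#'   heavy-atom subset.
#' @param limit Safety cap on the number of mappings returned.
#' @return List of integer permutations (each maps reference index ->
#'   equivalent atom index).
#' @export
ligand_automorphisms <- function(lig, limit = 10000L) {
  n <- length(lig$elements)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  ec <- integer(0)
  if (nrow(lig$bonds)) {
    g <- igraph::add_edges(g, rbind(lig$bonds$i, lig$bonds$j))
    ec <- as.integer(factor(lig$bonds$type,
                            levels = c("SINGLE", "DOUBLE", "TRIPLE",
                                       "AROMATIC", "OTHER", "UNKNOWN")))
  }
  vc <- as.integer(factor(lig$elements))
  maps <- igraph::isomorphisms(g, g, method = "vf2",
                               vertex.color1 = vc, vertex.color2 = vc,
                               edge.color1 = ec, edge.color2 = ec)
  if (length(maps) > limit) {
    warning(sprintf("automorphism count %d exceeds cap %d; truncating",
                    length(maps), limit))
    maps <- maps[seq_len(limit)]
  }
  lapply(maps, as.integer)
}

# ---------------------------------------------------------------------------
# Curation predicates
# ---------------------------------------------------------------------------

#' Default curation rule set for complex filtering
#'
#' Resolution at most 3.0 A, 5-60 ligand heavy atoms, no covalent
#' ligand-protein bond, at most `max_rotatable_bonds` rotatable bonds. The
#' rotatable-bond cap and the covalent-contact cutoff are configurable
#' because no canonical values exist; the defaults are standard practice.
#'
#' @param max_resolution Maximum resolution (A).
#' @param min_ligand_atoms,max_ligand_atoms Heavy-atom count window.
#' @param max_rotatable_bonds Rotatable-bond cap.
#' @param covalent_cutoff Inter-molecular heavy-atom distance (A) below which
#'   a ligand-protein pair is flagged covalent (metals exempt).
#' @return A named list of rule parameters.
#' @export
curation_rules <- function(max_resolution = 3.0, min_ligand_atoms = 5L,
                           max_ligand_atoms = 60L, max_rotatable_bonds = 20L,
                           covalent_cutoff = 1.8) {
  list(max_resolution = max_resolution, min_ligand_atoms = min_ligand_atoms,
       max_ligand_atoms = max_ligand_atoms,
       max_rotatable_bonds = max_rotatable_bonds,
       covalent_cutoff = covalent_cutoff)
}

#' Apply the dataset curation predicates to one complex
#'
#' Evaluates every enabled rule and reports all failures (not just the
#' first). A predicate whose required metadata is missing (e.g. unknown
#' resolution) is skipped and reported as such rather than failing.
#'
#' @param complex A [complex_pose()].
#' @param rules A [curation_rules()] list.
#' @return List with `pass` (logical), `failed` (character vector of rule
#'   names) and `skipped` (character vector).
#' @export
passes_curation <- function(complex, rules = curation_rules()) {
  stopifnot(inherits(complex, "complex_pose"))
  failed <- character(); skipped <- character()

  res <- complex$protein$resolution
  if (is.null(res) || is.na(res)) skipped <- c(skipped, "resolution")
  else if (res > rules$max_resolution) failed <- c(failed, "resolution")

  n_heavy <- sum(complex$ligand$elements != "H")
  if (n_heavy < rules$min_ligand_atoms || n_heavy > rules$max_ligand_atoms)
    failed <- c(failed, "ligand_atom_count")

  if (has_covalent_contact(complex, rules$covalent_cutoff))
    failed <- c(failed, "covalent_bond")

  if (count_rotatable_bonds(complex$ligand) > rules$max_rotatable_bonds)
    failed <- c(failed, "rotatable_bonds")

  list(pass = length(failed) == 0L, failed = failed, skipped = skipped)
}

# any non-metal heavy ligand atom within `cutoff` of a non-metal heavy
# protein atom indicates a covalent link
has_covalent_contact <- function(complex, cutoff = 1.8) {
  pa <- complex$protein$atoms
  pk <- pa$element != "H" & !(pa$element %in% .metals)
  lk <- complex$ligand$elements != "H" &
    !(complex$ligand$elements %in% .metals)
  if (!any(pk) || !any(lk)) return(FALSE)
  d <- cross_dist(complex$ligand$xyz[lk, , drop = FALSE],
                  as.matrix(pa[pk, c("x", "y", "z")]))
  any(d < cutoff)
}

#' Count rotatable bonds of a ligand
#'
#' A bond is rotatable when it is a single (order-1) bond, not part of a
#' ring, and both end atoms have at least one further heavy-atom neighbour
#' (terminal bonds cannot rotate anything).
#'
#' @param lig A [ligand_molecule()].
#' @return Integer count.
#' @export
count_rotatable_bonds <- function(lig) {
  b <- lig$bonds
  if (!nrow(b)) return(0L)
  ring <- atom_ring_sizes(length(lig$elements), b)$bond_in_ring
  heavy <- lig$elements != "H"
  heavy_deg <- integer(length(lig$elements))
  for (r in seq_len(nrow(b))) {
    if (heavy[b$i[r]] && heavy[b$j[r]]) {
      heavy_deg[b$i[r]] <- heavy_deg[b$i[r]] + 1L
      heavy_deg[b$j[r]] <- heavy_deg[b$j[r]] + 1L
    }
  }
  sum(b$type == "SINGLE" & !ring &
        heavy[b$i] & heavy[b$j] &
        heavy_deg[b$i] >= 2L & heavy_deg[b$j] >= 2L)
}
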