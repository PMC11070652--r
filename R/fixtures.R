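# Synthetic fixtures: toy complexes, pose sets with analytically exact RMSD
# labels, and a learnable dataset. Decoys are rigid translations of the
# native ligand because a whole-molecule translation by t has RMSD exactly
# |t| -- the labels are free of any numerical RMSD machinery.

#' A small rigid ligand template
#'
#' A 2-acylpyridine-like molecule: an aromatic six-ring (5 C + 1 N), an
#' exocyclic sp2 carbon and a carbonyl oxygen. Eight heavy atoms, one ring,
#' mixed hybridizations -- enough chemistry to exercise every ligand feature
#' block.
#'
#' @return A [ligand_molecule()] centred near the origin.
#' @export
ligand_template <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  xyz <- rbind(ring,
               c(2.89, 0, 0),      # exocyclic C bonded to ring atom 1
               c(3.53, 1.05, 0))   # carbonyl O
  elements <- c("C", "C", "C", "C", "C", "N", "C", "O")
  bonds <- data.frame(
    i = c(1, 2, 3, 4, 5, 6, 1, 7),
    j = c(2, 3, 4, 5, 6, 1, 7, 8),
    type = c(rep("AROMATIC", 6), "SINGLE", "DOUBLE"))
  ligand_molecule(elements, xyz, bonds, name = "toy-ligand")
}

# residue/atom-name/element triples used for synthetic protein atoms
.toy_atoms <- data.frame(
  resname = c("ALA", "ALA", "ALA", "ALA", "SER", "ASP", "ASN", "MET",
              "LYS", "PHE", "THR", "GLU"),
  atom_name = c("N", "CA", "C", "O", "OG", "OD1", "ND2", "SD",
                "NZ", "CZ", "CG2", "OE1"),
  element = c("N", "C", "C", "O", "O", "O", "N", "S", "N", "C", "C", "O"),
  stringsAsFactors = FALSE)

#' Generate a toy protein-ligand complex
#'
#' Places the template ligand at the origin and samples protein atoms in
#' random directions such that each atom's distance to the nearest ligand
#' atom equals the requested pocket radius exactly (solved by root finding
#' along the ray). With a scalar radius every protein atom therefore lands in
#' the same shell of any layout whose boundaries bracket it; with a
#' length-two range, per-atom radii are drawn uniformly from it.
#'
#' @param n_protein Number of protein atoms (>= 1).
#' @param pocket_radius Scalar nearest-ligand-atom distance in Angstrom, or a
#'   length-2 range to sample from.
#' @param seed RNG seed; the construction is byte-identical under a fixed
#'   seed.
#' @param ligand Ligand to centre on (default [ligand_template()]).
#' @param resolution Resolution metadata attached to the structure.
#' @param complex_id Complex identifier.
#' @return A [complex_pose()] with `rmsd_label = 0` (native pose).
#' @examples
#' cp <- make_toy_complex(n_protein = 10, pocket_radius = 4, seed = 1)
#' @export
make_toy_complex <- function(n_protein = 40L, pocket_radius = 4.0, seed = 1L,
                             ligand = ligand_template(), resolution = 2.0,
                             complex_id = "toy1") {
  stopifnot(n_protein >= 1L)
  set.seed(seed)
  radii <- if (length(pocket_radius) == 2L)
    stats::runif(n_protein, pocket_radius[1L], pocket_radius[2L])
  else rep(pocket_radius, n_protein)
  if (any(radii <= min(sqrt(rowSums(ligand$xyz^2)))))
    stop2("pocket radius too small: atoms would sit inside the ligand")
  dirs <- runif_unit3(n_protein)
  lx <- ligand$xyz
  pos <- matrix(0, n_protein, 3L)
  for (q in seq_len(n_protein)) {
    u <- dirs[q, ]
    f <- function(a) min(sqrt(rowSums((matrix(a * u, nrow(lx), 3L,
                                              byrow = TRUE) - lx)^2))) - radii[q]
    upper <- radii[q] + max(sqrt(rowSums(lx^2))) + 2
    # aim 1e-6 A inside the requested radius: a boundary radius must stay in
    # its own shell even under the ~1e-8 float noise of distance formulas
    a <- stats::uniroot(function(x) f(x) + 1e-6, c(0, upper), tol = 1e-10)$root
    while (f(a) > -1e-7) a <- a - 1e-7
    pos[q, ] <- a * u
  }
  pick <- .toy_atoms[1L + (seq_len(n_protein) - 1L) %% nrow(.toy_atoms), ]
  atoms <- data.frame(
    element = pick$element, atom_name = pick$atom_name,
    resname = pick$resname, resid = seq_len(n_protein), chain = "A",
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
    is_hetatm = FALSE, stringsAsFactors = FALSE)
  protein <- protein_structure(atoms, resolution = resolution)
  complex_pose(protein, ligand, pose_id = "native", complex_id = complex_id,
               rmsd_label = 0)
}

#' Generate a pose set with exact RMSD labels
#'
#' Each pose is the reference ligand rigidly translated along a random unit
#' vector scaled to the target RMSD; a whole-molecule translation by t gives
#' RMSD |t| exactly, so the attached labels need no RMSD computation. A
#' target of 0 reproduces the native pose.
#'
#' @param reference A [complex_pose()] holding the native ligand.
#' @param target_rmsds Non-negative numeric vector of desired RMSDs (A).
#' @param seed RNG seed for the translation directions.
#' @return List of [complex_pose()] objects with `rmsd_label` set.
#' @export
make_pose_set <- function(reference, target_rmsds, seed = 1L) {
  stopifnot(inherits(reference, "complex_pose"), all(target_rmsds >= 0))
  set.seed(seed)
  dirs <- runif_unit3(length(target_rmsds))
  lapply(seq_along(target_rmsds), function(q) {
    lig <- reference$ligand
    t_vec <- dirs[q, ] * target_rmsds[q]
    lig$xyz <- lig$xyz + matrix(t_vec, nrow(lig$xyz), 3L, byrow = TRUE)
    complex_pose(reference$protein, lig,
                 pose_id = sprintf("pose_%03d", q),
                 complex_id = reference$complex_id,
                 rmsd_label = target_rmsds[q])
  })
}

#' Generate a learnable synthetic docking dataset
#'
#' Builds `n_complexes` toy complexes (protein atoms at radii drawn from
#' `radius_range`, so the native pose already mixes shell occupancies) and,
#' per complex, `poses_per_complex` translated decoys with RMSD labels drawn
#' uniformly from `(0, max_rmsd]` plus `n_native` replicated native poses
#' (mirroring the native-ligand replication used when the training set is
#' split into ensemble parts). Labels are exact by construction, and shell
#' occupancy shifts monotonically with the displacement magnitude, so the
#' shell-graph features carry recoverable signal.
#'
#' @param n_complexes Number of complexes (>= 4 for ensemble splitting).
#' @param poses_per_complex Decoys per complex.
#' @param n_native Native replicates per complex (default 4).
#' @param max_rmsd Largest decoy RMSD (A).
#' @param n_protein Protein atoms per complex.
#' @param radius_range Pocket radii range (A).
#' @param seed RNG seed.
#' @return A flat list of labelled [complex_pose()] objects
#'   (`n_complexes * (poses_per_complex + n_native)` records).
#' @export
make_learnable_dataset <- function(n_complexes = 10L, poses_per_complex = 20L,
                                   n_native = 4L, max_rmsd = 3.0,
                                   n_protein = 60L,
                                   radius_range = c(2.5, 5.5), seed = 1L) {
  stopifnot(n_complexes >= 1L, poses_per_complex >= 0L)
  out <- list()
  for (ci in seq_len(n_complexes)) {
    cid <- sprintf("cplx_%02d", ci)
    ref <- make_toy_complex(n_protein = n_protein,
                            pocket_radius = radius_range,
                            seed = seed * 1000L + ci,
                            complex_id = cid)
    set.seed(seed * 2000L + ci)
    targets <- c(rep(0, n_native),
                 stats::runif(poses_per_complex, 0, max_rmsd))
    poses <- make_pose_set(ref, targets, seed = seed * 3000L + ci)
    for (q in seq_along(poses))
      poses[[q]]$pose_id <- sprintf("%s_pose_%03d", cid, q)
    out <- c(out, poses)
  }
  out
}

# ---------------------------------------------------------------------------
# Fixture writers (standard text formats, exercising the full I/O path)
# ---------------------------------------------------------------------------

#' Write a protein structure as a PDB file
#'
#' @param protein A [protein_structure()] (or [complex_pose()], whose protein
#'   is taken).
#' @param path Output path.
#' @param resolution Optional resolution to record in a REMARK 2 header.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(protein, path, resolution = NULL) {
  if (inherits(protein, "complex_pose")) {
    resolution <- resolution %||% protein$protein$resolution
    protein <- protein$protein
  }
  a <- protein$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$is_hetatm, "HETATM", "ATOM"),
                   resno = a$resid, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$atom_name,
                   chain = a$chain, elesy = a$element)
  if (!is.null(resolution) && !is.na(resolution)) {
    lines <- readLines(path, warn = FALSE)
    writeLines(c(sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                         resolution), lines), path)
  }
  invisible(path)
}

#' Write ligand molecules as a (multi-record) V2000 SDF file
#'
#' A plain V2000 emitter: atom block, bond block (Single/Double/Triple/
#' Aromatic map to codes 1-4; Other/Unknown to the generic code 8, which
#' reads back as Unknown) and `M  CHG` lines for non-zero formal charges.
#' Files written here round-trip through [read_ligand()].
#'
#' @param ligands A [ligand_molecule()] or list of them (multi-pose SDF).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ligand_sdf <- function(ligands, path) {
  if (inherits(ligands, "ligand_molecule")) ligands <- list(ligands)
  con <- file(path, "w")
  on.exit(close(con))
  code <- c(SINGLE = 1L, DOUBLE = 2L, TRIPLE = 3L, AROMATIC = 4L,
            OTHER = 8L, UNKNOWN = 8L)
  for (lig in ligands) {
    n <- length(lig$elements); nb <- nrow(lig$bonds)
    writeLines(c(lig$name, "  shellscore", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    for (a in seq_len(n))
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         lig$xyz[a, 1L], lig$xyz[a, 2L], lig$xyz[a, 3L],
                         lig$elements[a]), con)
    for (b in seq_len(nb))
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", lig$bonds$i[b],
                         lig$bonds$j[b], code[[lig$bonds$type[b]]]), con)
    charged <- which(lig$formal_charges != 0L)
    for (s in if (length(charged)) seq(1L, length(charged), by = 8L) else integer()) {
      idx <- charged[s:min(s + 7L, length(charged))]
      writeLines(paste0("M  CHG", sprintf("%3d", length(idx)),
                        paste0(sprintf("%4d%4d", idx,
                                       lig$formal_charges[idx]),
                               collapse = "")), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Write a fixture tree (PDB + SDF + labels) for a pose list
#'
#' One PDB per complex, one multi-record SDF of its poses, and a TSV of RMSD
#' labels -- the on-disk layout the command-line interface consumes.
#'
#' @param poses List of labelled [complex_pose()] objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_tree <- function(poses, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  by_complex <- split(poses, vapply(poses, function(p) p$complex_id, ""))
  labels <- data.frame(pose_id = vapply(poses, function(p) p$pose_id, ""),
                       complex_id = vapply(poses, function(p) p$complex_id, ""),
                       rmsd = vapply(poses, function(p) p$rmsd_label, 1.0))
  for (cid in names(by_complex)) {
    grp <- by_complex[[cid]]
    write_complex_pdb(grp[[1L]], file.path(dir, paste0(cid, ".pdb")))
    ligs <- lapply(grp, function(p) {
      l <- p$ligand; l$name <- p$pose_id; l
    })
    write_ligand_sdf(ligs, file.path(dir, paste0(cid, "_poses.sdf")))
  }
  write_rmsd_labels(labels, file.path(dir, "labels.tsv"))
  invisible(dir)
}
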