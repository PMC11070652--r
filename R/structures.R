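#' @importFrom methods as
NULL

# single-bond covalent radii (Angstrom) for distance-based bond perception
.cov_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
                F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39, Se = 1.20, B = 0.84)
.cov_default <- 0.80
.water_resnames <- c("HOH", "WAT", "DOD", "H2O")
.known_2letter <- c(.metals, .halogens[-1L], "Se", "Cu", "Ni", "Co", "Cd",
                    "Hg", "Li", "Al", "As", "Si")

cov_radius <- function(el) {
  r <- .cov_radii[el]
  r[is.na(r)] <- .cov_default
  unname(r)
}

# ---------------------------------------------------------------------------
# ProteinStructure
# ---------------------------------------------------------------------------

#' Construct a protein structure from an atom table
#'
#' Normally created by [read_protein()] or [make_toy_complex()]. Waters are
#' dropped, coordinates must be finite, and per-atom context needed by the
#' featurizer (degree, implicit valence, hydrogen count, hybridization) is
#' derived once here from distance-based covalent bond perception.
#'
#' @param atoms data.frame with columns `element`, `atom_name`, `resname`,
#'   `resid`, `chain`, `x`, `y`, `z`, `is_hetatm`.
#' @param resolution Crystallographic resolution in Angstrom, or `NA`.
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, resolution = NA_real_) {
  need <- c("element", "atom_name", "resname", "resid", "chain",
            "x", "y", "z", "is_hetatm")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop2("atom table lacks columns: %s", paste(miss, collapse = ", "))
  atoms <- atoms[!(toupper(atoms$resname) %in% .water_resnames), , drop = FALSE]
  if (nrow(atoms) == 0L) stop2("empty structure: no atoms left after water removal")
  if (!is_finite_coords(atoms[, c("x", "y", "z")]))
    stop2("non-finite protein coordinates")
  if (any(!nzchar(trimws(atoms$atom_name))))
    stop2("protein atom names must be non-empty")
  atoms$element <- vapply(atoms$element, normalize_element, "")
  rownames(atoms) <- NULL
  atoms <- derive_protein_properties(atoms)
  structure(list(atoms = atoms, resolution = resolution),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein structure: %d atoms (%d HETATM), resolution %s\n",
              nrow(x$atoms), sum(x$atoms$is_hetatm),
              ifelse(is.na(x$resolution), "unknown",
                     sprintf("%.2f A", x$resolution))))
  invisible(x)
}

# distance-based covalent bond perception among protein atoms (metals form no
# covalent bonds); adds degree / implicit_valence / n_hydrogen / hybridization
derive_protein_properties <- function(atoms) {
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  el <- atoms$element
  is_metal <- el %in% .metals
  rad <- cov_radius(el)
  deg <- integer(n)
  n_h <- integer(n)
  # chunked O(n^2) neighbour search, max covalent reach ~ 2.4 + 0.4 A
  chunk <- 512L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d <- cross_dist(xyz[s:e, , drop = FALSE], xyz)
    cut <- outer(rad[s:e], rad, "+") + 0.4
    hit <- d < cut & d > 0.4
    hit[, is_metal] <- FALSE
    hit[is_metal[s:e], ] <- FALSE
    deg[s:e] <- rowSums(hit)
    n_h[s:e] <- as.integer(hit %*% (el == "H"))
  }
  stdval <- c(H = 1, C = 4, N = 3, O = 2, S = 2, P = 5)[el]
  stdval[is.na(stdval)] <- 0
  impl <- pmax(0L, as.integer(stdval) - deg)
  atoms$degree <- deg
  atoms$implicit_valence <- impl
  atoms$n_hydrogen <- n_h + impl
  atoms$hybridization <- protein_hybridization(el, atoms$atom_name,
                                               atoms$resname, is_metal)
  atoms
}

# template-based hybridization for protein atoms (no bond orders in PDB)
protein_hybridization <- function(el, name, resname, is_metal) {
  name <- toupper(trimws(name)); resname <- toupper(trimws(resname))
  aromatic_tab <- list(
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))
  sp2_tab <- list(
    ASP = c("CG", "OD1", "OD2"), ASN = c("CG", "OD1", "ND2"),
    GLU = c("CD", "OE1", "OE2"), GLN = c("CD", "OE1", "NE2"),
    ARG = c("CZ", "NE", "NH1", "NH2"))
  hyb <- rep("SP3", length(el))
  hyb[el == "H"] <- "S"
  hyb[name %in% c("C", "O", "OXT", "N")] <- "SP2"  # peptide bond plane
  for (rn in names(aromatic_tab))
    hyb[resname == rn & name %in% aromatic_tab[[rn]]] <- "AROMATIC"
  for (rn in names(sp2_tab))
    hyb[resname == rn & name %in% sp2_tab[[rn]]] <- "SP2"
  hyb[is_metal] <- "UNSPECIFIED"
  hyb[!(el %in% c("H", "C", "N", "O", "P", "S")) & !is_metal] <- "UNSPECIFIED"
  hyb
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (first MODEL only) with bio3d, strips all
#' waters, keeps a single alternate location (blank or 'A'), and preserves
#' atom names verbatim from PDB columns 13-16 (whitespace-stripped). HETATM
#' small molecules and ions bound near the ligand can influence the pose and
#' are treated as part of the receptor when `keep_hetatm` is set.
#'
#' The crystallographic resolution is taken from the `REMARK   2` header when
#' present; curation predicates treat a missing resolution as "skipped".
#'
#' @param path PDB file path.
#' @param keep_hetatm Keep non-water HETATM records (default `TRUE`).
#' @return A [protein_structure()].
#' @export
read_protein <- function(path, keep_hetatm = TRUE) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop2("failed to parse PDB file '%s': %s",
                              path, conditionMessage(e)))
  a <- pdb$atom
  keep <- a$alt %in% c("", " ", "A") | is.na(a$alt)
  if (!keep_hetatm) keep <- keep & a$type == "ATOM"
  a <- a[keep, , drop = FALSE]
  el <- element_from_pdb(a$elesy, a$elety, a$resid, a$type == "HETATM")
  atoms <- data.frame(
    element = el,
    atom_name = trimws(a$elety),
    resname = trimws(a$resid),
    resid = a$resno,
    chain = ifelse(is.na(a$chain), "", a$chain),
    x = a$x, y = a$y, z = a$z,
    is_hetatm = a$type == "HETATM",
    stringsAsFactors = FALSE)
  protein_structure(atoms, resolution = pdb_resolution(path))
}

# element symbol: PDB columns 77-78 when present, else inferred from the atom
# name (two-letter elements only accepted for HETATM ions/metals, so that a
# protein "CA" stays a carbon while a calcium HETATM "CA"/"CA" is calcium)
element_from_pdb <- function(elesy, elety, resid, is_het) {
  out <- character(length(elety))
  for (i in seq_along(elety)) {
    es <- if (i <= length(elesy)) trimws(elesy[i]) else ""
    if (!is.na(es) && nzchar(es) && !grepl("[0-9]", es)) {
      out[i] <- normalize_element(es)
      next
    }
    nm <- gsub("[^A-Za-z]", "", trimws(elety[i]))
    cand2 <- normalize_element(substr(nm, 1L, 2L))
    if (is_het[i] && cand2 %in% .known_2letter &&
        toupper(trimws(resid[i])) == toupper(nm)) {
      out[i] <- cand2
    } else {
      out[i] <- normalize_element(substr(nm, 1L, 1L))
    }
  }
  out
}

pdb_resolution <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(rl)) return(NA_real_)
  m <- regmatches(rl[1L], regexpr("[0-9]+\\.[0-9]+", rl[1L]))
  if (!length(m)) NA_real_ else as.numeric(m)
}

# ---------------------------------------------------------------------------
# LigandMolecule
# ---------------------------------------------------------------------------

#' Construct a ligand molecule and derive its per-atom chemistry
#'
#' Derived properties (degree, implicit valence, attached hydrogens,
#' hybridization, ring membership, aromaticity) are computed from the bond
#' graph: implicit valence is the gap between an element's standard valence
#' (charge-adjusted) and its explicit bond-order sum; the attached-hydrogen
#' count adds implicit hydrogens to explicit H neighbours; hybridization is
#' rule-based (aromatic > triple/cumulated-double SP > double SP2 > SP3);
#' the ring-size of an atom is the largest ring containing it among the
#' shortest cycles through each bond.
#'
#' @param elements Character vector of element symbols.
#' @param xyz n x 3 numeric matrix of coordinates in Angstrom.
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices),
#'   `type` (one of SINGLE, DOUBLE, TRIPLE, AROMATIC, OTHER, UNKNOWN).
#' @param formal_charges Integer vector (default all 0).
#' @param name Optional molecule name.
#' @return An object of class `ligand_molecule`.
#' @export
ligand_molecule <- function(elements, xyz, bonds = NULL, formal_charges = NULL,
                            name = "ligand") {
  n <- length(elements)
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  if (nrow(xyz) != n) stop2("coordinate rows (%d) != atom count (%d)", nrow(xyz), n)
  if (!is_finite_coords(xyz)) stop2("non-finite ligand coordinates")
  elements <- vapply(elements, normalize_element, "")
  if (sum(elements != "H") < 1L) stop2("ligand must contain at least one heavy atom")
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(),
                                          type = character())
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
  if (nrow(bonds) && (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n)
                      || any(bonds$i == bonds$j)))
    stop2("bond indices out of range for %d atoms", n)
  bonds$type <- toupper(as.character(bonds$type))
  known <- c("SINGLE", "DOUBLE", "TRIPLE", "AROMATIC", "OTHER", "UNKNOWN")
  bonds$type[!(bonds$type %in% known)] <- "UNKNOWN"
  bonds$order <- c(SINGLE = 1, DOUBLE = 2, TRIPLE = 3, AROMATIC = 1.5,
                   OTHER = 1, UNKNOWN = 1)[bonds$type]
  fc <- as.integer(formal_charges %||% integer(n))
  if (length(fc) != n) stop2("formal charge vector length mismatch")

  lig <- structure(list(elements = elements, xyz = xyz, bonds = bonds,
                        formal_charges = fc, name = name),
                   class = "ligand_molecule")
  lig$derived <- derive_ligand_properties(lig)
  lig
}

#' @export
print.ligand_molecule <- function(x, ...) {
  cat(sprintf("ligand '%s': %d atoms (%d heavy), %d bonds\n", x$name,
              length(x$elements), sum(x$elements != "H"), nrow(x$bonds)))
  invisible(x)
}

derive_ligand_properties <- function(lig) {
  n <- length(lig$elements)
  el <- lig$elements
  b <- lig$bonds
  deg <- integer(n); ordsum <- numeric(n); n_h_exp <- integer(n)
  n_triple <- integer(n); n_double <- integer(n); arom <- logical(n)
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {
      i <- b$i[r]; j <- b$j[r]
      deg[c(i, j)] <- deg[c(i, j)] + 1L
      ordsum[c(i, j)] <- ordsum[c(i, j)] + b$order[r]
      if (el[j] == "H") n_h_exp[i] <- n_h_exp[i] + 1L
      if (el[i] == "H") n_h_exp[j] <- n_h_exp[j] + 1L
      if (b$type[r] == "TRIPLE") n_triple[c(i, j)] <- n_triple[c(i, j)] + 1L
      if (b$type[r] == "DOUBLE") n_double[c(i, j)] <- n_double[c(i, j)] + 1L
      if (b$type[r] == "AROMATIC") arom[c(i, j)] <- TRUE
    }
  }
  stdval <- c(H = 1, C = 4, N = 3, O = 2, S = 2, P = 5,
              F = 1, Cl = 1, Br = 1, I = 1)[el]
  stdval[is.na(stdval)] <- 0
  allowed <- pmax(0, as.numeric(stdval) + lig$formal_charges)
  impl <- pmax(0L, as.integer(round(allowed - ordsum)))
  hyb <- rep("SP3", n)
  hyb[el == "H"] <- "S"
  hyb[n_double >= 1L] <- "SP2"
  hyb[n_triple >= 1L | n_double >= 2L] <- "SP"
  hyb[arom] <- "AROMATIC"
  hyb[!(el %in% c("H", "C", "N", "O", "P", "S", .halogens))] <- "UNSPECIFIED"
  ring <- atom_ring_sizes(n, b)
  data.frame(degree = deg, implicit_valence = impl,
             n_hydrogen = n_h_exp + impl, hybridization = hyb,
             ring_size = ring$size, in_ring = ring$size > 0L,
             aromatic = arom, stringsAsFactors = FALSE)
}

# shortest cycle through every bond (BFS with that bond removed); returns the
# largest such ring containing each atom, and flags the bonds that lie in a ring
atom_ring_sizes <- function(n, bonds) {
  size <- integer(n)
  bond_in_ring <- logical(nrow(bonds))
  if (nrow(bonds) == 0L || n < 3L)
    return(list(size = size, bond_in_ring = bond_in_ring))
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  for (r in seq_len(nrow(bonds))) {
    src <- bonds$i[r]; dst <- bonds$j[r]
    # BFS src -> dst avoiding the direct edge
    dist <- rep(NA_integer_, n); dist[src] <- 0L
    queue <- src
    while (length(queue) && is.na(dist[dst])) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (v == src && w == dst) next
        if (is.na(dist[w])) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
      }
    }
    if (!is.na(dist[dst])) {
      ring_len <- dist[dst] + 1L
      bond_in_ring[r] <- TRUE
      size[c(src, dst)] <- pmax(size[c(src, dst)], ring_len)
    }
  }
  # membership for atoms interior to a cycle: any atom with two in-ring bonds
  # gets at least the max ring size of its in-ring neighbours; iterate to fix
  if (any(bond_in_ring)) {
    for (pass in 1:2) {
      for (r in which(bond_in_ring)) {
        m <- max(size[bonds$i[r]], size[bonds$j[r]])
        size[c(bonds$i[r], bonds$j[r])] <- pmax(size[c(bonds$i[r], bonds$j[r])], m)
      }
    }
  }
  list(size = size, bond_in_ring = bond_in_ring)
}

#' Read ligand molecules (docked poses) from an SDF or Mol2 file
#'
#' Multi-record SDF files (one record per pose) yield one `ligand_molecule`
#' per record; multi-molecule Mol2 files are split on their MOLECULE headers.
#' Bond orders come from the bond block; SDF formal charges come from the
#' `M  CHG` properties (the atom-block charge column is ignored, as modern
#' writers do), Mol2 formal charges from rounding the charge column.
#'
#' @param path SDF (`.sdf`/`.mol`) or Mol2 (`.mol2`) file.
#' @return A list of [ligand_molecule()] objects, one per record.
#' @export
read_ligand <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sdf", "mol")) read_ligand_sdf(path)
  else if (ext == "mol2") read_ligand_mol2(path)
  else stop2("unsupported ligand format '%s' (expected .sdf, .mol or .mol2)", ext)
}

read_ligand_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split records on the $$$$ delimiter (trailing delimiter optional)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- list()
  for (ri in seq_along(starts)) {
    rec <- lines[starts[ri]:ends[ri]]
    if (all(!nzchar(trimws(rec)))) next
    sdf <- tryCatch({
      tf <- tempfile(fileext = ".sdf")
      on.exit(unlink(tf), add = TRUE)
      writeLines(c(rec[!grepl("^\\$\\$\\$\\$", rec)], "$$$$"), tf)
      set <- ChemmineR::read.SDFset(tf)
      if (!ChemmineR::validSDF(set)) stop("invalid SDF block")
      set[[1L]]
    }, error = function(e)
      stop2("failed to parse SDF record %d of '%s': %s", ri, path,
            conditionMessage(e)))
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    nat <- nrow(ab)
    elements <- sub("_[0-9]+$", "", rownames(ab))
    xyz <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
    bonds <- NULL
    if (!is.null(bb) && nrow(bb) > 0L) {
      code <- as.integer(bb[, 3L])
      ty <- rep("UNKNOWN", length(code))
      ok <- !is.na(code) & code >= 1L & code <= 4L
      ty[ok] <- c("SINGLE", "DOUBLE", "TRIPLE", "AROMATIC")[code[ok]]
      bonds <- data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
                          type = ty)
    }
    if (!is.null(bonds) && any(bonds$i > nat | bonds$j > nat))
      stop2("failed to parse SDF record %d of '%s': bond block references atom beyond atom block",
            ri, path)
    fc <- integer(nat)
    for (cl in grep("^M  CHG", rec, value = TRUE)) {
      nums <- as.integer(strsplit(trimws(substr(cl, 7L, nchar(cl))), "\\s+")[[1L]])
      cnt <- nums[1L]
      for (kk in seq_len(cnt)) {
        ai <- nums[2L * kk]; ch <- nums[2L * kk + 1L]
        if (!is.na(ai) && ai >= 1L && ai <= nat) fc[ai] <- ch
      }
    }
    nm <- trimws(rec[1L])
    out[[length(out) + 1L]] <- ligand_molecule(elements, xyz, bonds, fc,
                                               name = if (nzchar(nm)) nm else "ligand")
  }
  if (!length(out)) stop2("no SDF records found in '%s'", path)
  out
}

read_ligand_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(starts)) stop2("no MOLECULE record in mol2 file '%s'", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (ri in seq_along(starts)) {
    tf <- tempfile(fileext = ".mol2")
    writeLines(lines[starts[ri]:ends[ri]], tf)
    m <- tryCatch(bio3d::read.mol2(tf),
                  error = function(e)
                    stop2("failed to parse mol2 record %d of '%s': %s",
                          ri, path, conditionMessage(e)))
    unlink(tf)
    a <- m$atom
    elements <- sub("\\..*$", "", a$elety)
    xyz <- cbind(a$x, a$y, a$z)
    bonds <- NULL
    if (!is.null(m$bond) && nrow(m$bond)) {
      ty <- tolower(trimws(m$bond$type))
      map <- c(`1` = "SINGLE", `2` = "DOUBLE", `3` = "TRIPLE",
               ar = "AROMATIC", am = "SINGLE", du = "UNKNOWN", un = "UNKNOWN")
      keep <- ty != "nc"
      bonds <- data.frame(i = as.integer(m$bond$origin[keep]),
                          j = as.integer(m$bond$target[keep]),
                          type = unname(ifelse(is.na(map[ty[keep]]), "UNKNOWN",
                                               map[ty[keep]])))
    }
    fc <- as.integer(round(a$charge %||% numeric(nrow(a))))
    out[[ri]] <- ligand_molecule(elements, xyz, bonds, fc,
                                 name = m$name %||% "ligand")
  }
  out
}

# ---------------------------------------------------------------------------
# ComplexPose
# ---------------------------------------------------------------------------

#' Bundle one protein structure with one ligand pose
#'
#' @param protein A [protein_structure()].
#' @param ligand A [ligand_molecule()] giving the pose coordinates.
#' @param pose_id Identifier for the pose.
#' @param complex_id Identifier for the parent complex.
#' @param rmsd_label Known RMSD to the native pose in Angstrom, or `NA`.
#' @return An object of class `complex_pose`.
#' @export
complex_pose <- function(protein, ligand, pose_id = "pose1",
                         complex_id = "complex1", rmsd_label = NA_real_) {
  stopifnot(inherits(protein, "protein_structure"),
            inherits(ligand, "ligand_molecule"))
  if (!is.na(rmsd_label) && rmsd_label < 0)
    stop2("rmsd_label must be >= 0")
  structure(list(protein = protein, ligand = ligand, pose_id = pose_id,
                 complex_id = complex_id, rmsd_label = rmsd_label),
            class = "complex_pose")
}

#' @export
print.complex_pose <- function(x, ...) {
  cat(sprintf("pose '%s' of complex '%s' (label: %s)\n", x$pose_id,
              x$complex_id,
              ifelse(is.na(x$rmsd_label), "unlabelled",
                     sprintf("%.3f A", x$rmsd_label))))
  invisible(x)
}

#' Read / write per-pose RMSD label tables (TSV)
#'
#' Columns: `pose_id`, `complex_id`, `rmsd`.
#' @param path TSV file path.
#' @return `read_rmsd_labels` returns a data.frame; `write_rmsd_labels`
#'   returns `path` invisibly.
#' @export
read_rmsd_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pose_id", "complex_id", "rmsd")
  if (!all(need %in% names(df)))
    stop2("label table must have columns %s", paste(need, collapse = ", "))
  df
}

#' @rdname read_rmsd_labels
#' @param labels data.frame with columns `pose_id`, `complex_id`, `rmsd`.
#' @export
write_rmsd_labels <- function(labels, path) {
  utils::write.table(labels[, c("pose_id", "complex_id", "rmsd")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
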