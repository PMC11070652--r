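#' Fixed one-hot feature schema for shell-graph nodes and edges
#'
#' Builds the block layout used to featurize atoms: protein nodes occupy the
#' first 97 dimensions of a 171-dimensional vector, ligand nodes the last 74,
#' and the complementary block is zero-padded so the two atom roles never
#' overlap. Edge vectors have 8 dimensions: a 7-way one-hot bond/contact
#' category followed by a single distance value in Angstrom.
#'
#' Block widths are fixed (they define the 171/97/74/8 layout); the category
#' vocabulary behind each block lives in this one object so it can be revised
#' without touching the encoders. Atom-type blocks reserve no explicit slot
#' for the residual "other" category: an element outside the seven named
#' categories encodes as all-zeros in that block, which is what keeps the
#' protein block at exactly 97 dimensions. All remaining blocks carry a
#' dedicated final OTHER slot.
#'
#' @return An object of class `feature_schema`: named lists `protein`,
#'   `ligand` and `edge` of block vocabularies, plus cached widths and
#'   offsets. `node_width` is 171, `protein_width` 97, `ligand_width` 74 and
#'   `edge_width` 8.
#' @examples
#' sc <- feature_schema()
#' sc$node_width     # 171
#' sc$protein_width  # 97
#' @export
feature_schema <- function() {
  aa20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")
  atom_names36 <- c("N", "CA", "C", "O", "CB", "CG", "CG1", "CG2", "CD",
                    "CD1", "CD2", "CE", "CE1", "CE2", "CE3", "CZ", "CZ2",
                    "CZ3", "CH2", "ND1", "ND2", "NE", "NE1", "NE2", "NH1",
                    "NH2", "NZ", "OD1", "OD2", "OE1", "OE2", "OG", "OG1",
                    "OH", "SD", "SG")
  hybrid <- c("S", "SP", "SP2", "SP3", "SP3D", "SP3D2", "AROMATIC",
              "UNSPECIFIED", "OTHER")

  protein <- list(
    atom_type            = c("H", "C", "N", "O", "P", "S", "METAL"),
    atom_degree          = c(as.character(0:8), "OTHER"),
    implicit_valence     = c(as.character(0:4), "OTHER"),
    neighboring_hydrogen = c(as.character(0:4), "OTHER"),
    hybridization        = hybrid,
    amino_acid_type      = c(aa20, "NONSTANDARD", "OTHER"),
    atom_name            = c(atom_names36, "OTHER")
  )
  ligand <- list(
    atom_type            = c("H", "C", "N", "O", "P", "S", "HALOGEN"),
    atom_degree          = c(as.character(0:8), "OTHER"),
    implicit_valence     = c(as.character(0:4), "OTHER"),
    neighboring_hydrogen = c(as.character(0:4), "OTHER"),
    hybridization        = hybrid,
    formal_charge        = c(as.character(-10:10), "OTHER"),
    # two trailing reserved slots keep the printed block width of 12
    ring_size            = c("none", as.character(3:10), "OTHER",
                             "RESERVED1", "RESERVED2"),
    aromatic             = c("FALSE", "TRUE")
  )
  edge <- list(
    bond_type = c("SINGLE", "DOUBLE", "TRIPLE", "AROMATIC", "NONCOVALENT",
                  "OTHER", "UNKNOWN"),
    distance  = "DISTMAX"
  )

  pw <- vapply(protein, length, 1L)
  lw <- vapply(ligand, length, 1L)
  po <- c(0L, cumsum(pw))[seq_along(pw)]; names(po) <- names(pw)
  lo <- sum(pw) + c(0L, cumsum(lw))[seq_along(lw)]; names(lo) <- names(lw)
  sc <- list(
    protein = protein, ligand = ligand, edge = edge,
    protein_width = sum(pw), ligand_width = sum(lw),
    node_width = sum(pw) + sum(lw),
    edge_width = length(edge$bond_type) + 1L,
    protein_offsets = po,
    ligand_offsets  = lo
  )
  class(sc) <- "feature_schema"
  sc
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("feature schema: %d node dims (%d protein + %d ligand), %d edge dims\n",
              x$node_width, x$protein_width, x$ligand_width, x$edge_width))
  invisible(x)
}

# metal / halogen element sets (fixed vocabulary)
.metals   <- c("Ca", "Fe", "K", "Mg", "Mn", "Na", "Zn")
.halogens <- c("F", "Cl", "Br", "I")

#' Classify an element symbol into its atom-type category
#'
#' Protein atoms fall into H, C, N, O, P, S, METAL (Ca, Fe, K, Mg, Mn, Na,
#' Zn) or OTHER; ligand atoms into H, C, N, O, P, S, HALOGEN (F, Cl, Br, I)
#' or OTHER. OTHER has no one-hot slot and encodes as all-zeros.
#'
#' @param element Element symbol (case-insensitive, e.g. "Zn", "CL").
#' @param role `"protein"` or `"ligand"`.
#' @return One of the category names above (character scalar).
#' @examples
#' classify_element("Zn", "protein")  # "METAL"
#' classify_element("Cl", "ligand")   # "HALOGEN"
#' @export
classify_element <- function(element, role = c("protein", "ligand")) {
  role <- match.arg(role)
  el <- normalize_element(element)
  if (el %in% c("H", "C", "N", "O", "P", "S")) return(el)
  if (role == "protein" && el %in% .metals) return("METAL")
  if (role == "ligand" && el %in% .halogens) return("HALOGEN")
  "OTHER"
}

# canonical element capitalization: "CL" -> "Cl", "zn" -> "Zn"
normalize_element <- function(element) {
  el <- trimws(as.character(element))
  if (!nzchar(el)) return("")
  paste0(toupper(substr(el, 1L, 1L)),
         tolower(substr(el, 2L, nchar(el))))
}

# slot index of `value` in vocabulary `vocab`; unknown values go to the
# trailing OTHER slot when the block has one, otherwise 0 (all-zeros)
slot_index <- function(value, vocab) {
  i <- match(as.character(value), vocab)
  if (!is.na(i)) return(i)
  j <- match("OTHER", vocab)
  if (!is.na(j)) j else 0L
}

# clamp numeric categories into their vocabulary (e.g. degree 12 -> OTHER)
num_slot <- function(value, vocab) {
  if (is.na(value)) return(match("OTHER", vocab) %||% 0L)
  slot_index(as.character(as.integer(value)), vocab)
}

.nonstandard_aa <- c("MSE", "SEC", "PYL", "HYP", "CSO", "PTR", "SEP", "TPO",
                     "KCX", "LLP", "MLY", "CME", "CSD", "OCS")

#' Encode one protein atom as a 171-dimensional node feature vector
#'
#' Fills the leading 97 dimensions (atom type, degree, implicit valence,
#' neighbouring hydrogens, hybridization, amino-acid type, PDB atom name);
#' the trailing 74 ligand dimensions stay zero.
#'
#' @param atom A list with fields `element`, `degree`, `implicit_valence`,
#'   `n_hydrogen`, `hybridization`, `resname`, `atom_name` (as produced by
#'   [read_protein()] rows via [protein_atom_context()]).
#' @param schema A [feature_schema()].
#' @return Numeric vector of length `schema$node_width` (171).
#' @export
encode_protein_node <- function(atom, schema = feature_schema()) {
  v <- numeric(schema$node_width)
  blocks <- schema$protein
  off <- schema$protein_offsets

  put <- function(block, idx) {
    if (idx > 0L) v[off[[block]] + idx] <<- 1
  }
  at <- classify_element(atom$element, "protein")
  at_idx <- match(at, blocks$atom_type)
  put("atom_type", if (is.na(at_idx)) 0L else at_idx)  # OTHER: all-zeros
  put("atom_degree", num_slot(atom$degree, blocks$atom_degree))
  put("implicit_valence", num_slot(atom$implicit_valence, blocks$implicit_valence))
  put("neighboring_hydrogen", num_slot(atom$n_hydrogen, blocks$neighboring_hydrogen))
  put("hybridization", slot_index(atom$hybridization, blocks$hybridization))
  resname <- toupper(trimws(atom$resname %||% ""))
  aa_idx <- match(resname, blocks$amino_acid_type)
  if (is.na(aa_idx)) {
    aa_idx <- if (resname %in% .nonstandard_aa)
      match("NONSTANDARD", blocks$amino_acid_type)
    else match("OTHER", blocks$amino_acid_type)
  }
  put("amino_acid_type", aa_idx)
  put("atom_name", slot_index(toupper(trimws(atom$atom_name %||% "")),
                              blocks$atom_name))
  v
}

#' Encode one ligand atom as a 171-dimensional node feature vector
#'
#' Fills the trailing 74 dimensions (atom type, degree, implicit valence,
#' neighbouring hydrogens, hybridization, formal charge, ring size,
#' aromaticity); the leading 97 protein dimensions stay zero. Ring size uses
#' the largest ring containing the atom (fused systems), with rings above 10
#' atoms collapsing to the OTHER slot and acyclic atoms to the "none" slot.
#'
#' @param atom A list with fields `element`, `degree`, `implicit_valence`,
#'   `n_hydrogen`, `hybridization`, `formal_charge`, `ring_size` (0 for
#'   acyclic atoms), `aromatic` (logical).
#' @param schema A [feature_schema()].
#' @return Numeric vector of length `schema$node_width` (171).
#' @export
encode_ligand_node <- function(atom, schema = feature_schema()) {
  v <- numeric(schema$node_width)
  blocks <- schema$ligand
  off <- schema$ligand_offsets

  put <- function(block, idx) {
    if (idx > 0L) v[off[[block]] + idx] <<- 1
  }
  at <- classify_element(atom$element, "ligand")
  idx <- match(at, blocks$atom_type)
  put("atom_type", if (is.na(idx)) 0L else idx)  # OTHER: all-zeros
  put("atom_degree", num_slot(atom$degree, blocks$atom_degree))
  put("implicit_valence", num_slot(atom$implicit_valence, blocks$implicit_valence))
  put("neighboring_hydrogen", num_slot(atom$n_hydrogen, blocks$neighboring_hydrogen))
  put("hybridization", slot_index(atom$hybridization, blocks$hybridization))
  fc <- atom$formal_charge %||% 0
  fc_idx <- match(as.character(as.integer(fc)), blocks$formal_charge)
  put("formal_charge", if (is.na(fc_idx)) match("OTHER", blocks$formal_charge) else fc_idx)
  rs <- atom$ring_size %||% 0L
  ring_idx <- if (is.na(rs) || rs == 0L) match("none", blocks$ring_size)
  else if (rs >= 3L && rs <= 10L) match(as.character(rs), blocks$ring_size)
  else match("OTHER", blocks$ring_size)
  put("ring_size", ring_idx)
  put("aromatic", if (isTRUE(atom$aromatic)) match("TRUE", blocks$aromatic)
      else match("FALSE", blocks$aromatic))
  v
}

#' Encode one edge as an 8-dimensional feature vector
#'
#' The first seven entries one-hot encode the edge category (Single, Double,
#' Triple, Aromatic, Non-covalent, Other, Unknown); the eighth is the
#' distance value. For protein-ligand contacts the distance is the outer
#' boundary of the shell (DistMax) rather than the true pairwise distance;
#' ligand-ligand covalent bonds carry a fixed distance of 1.
#'
#' @param category Edge category, one of
#'   `"SINGLE","DOUBLE","TRIPLE","AROMATIC","NONCOVALENT","OTHER","UNKNOWN"`.
#' @param dist_max Positive distance feature in Angstrom.
#' @param schema A [feature_schema()].
#' @return Numeric vector of length 8.
#' @examples
#' encode_edge("NONCOVALENT", 4.0)  # c(0,0,0,0,1,0,0,4)
#' @export
encode_edge <- function(category, dist_max, schema = feature_schema()) {
  cats <- schema$edge$bond_type
  i <- match(toupper(category), cats)
  if (is.na(i)) stop2("unknown edge category '%s' (expected one of %s)",
                      category, paste(cats, collapse = ", "))
  if (!is.finite(dist_max) || dist_max <= 0)
    stop2("edge distance feature must be a positive finite number")
  c(one_hot(i, length(cats)), dist_max)
}

#' Export the feature schema as JSON (provenance record)
#'
#' @param schema A [feature_schema()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema_json <- function(schema, path) {
  jsonlite::write_json(
    list(protein = schema$protein, ligand = schema$ligand, edge = schema$edge,
         widths = list(node = schema$node_width, protein = schema$protein_width,
                       ligand = schema$ligand_width, edge = schema$edge_width)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
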