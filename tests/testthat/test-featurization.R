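schema <- feature_schema()

protein_atom <- function(element = "C", degree = 3, iv = 1, nh = 1,
                         hyb = "SP3", resname = "ALA", name = "CA") {
  list(element = element, degree = degree, implicit_valence = iv,
       n_hydrogen = nh, hybridization = hyb, resname = resname,
       atom_name = name)
}

ligand_atom <- function(element = "C", degree = 3, iv = 1, nh = 1,
                        hyb = "AROMATIC", fc = 0, ring = 6, arom = TRUE) {
  list(element = element, degree = degree, implicit_valence = iv,
       n_hydrogen = nh, hybridization = hyb, formal_charge = fc,
       ring_size = ring, aromatic = arom)
}

test_that("schema widths reproduce the fixed 171/97/74/8 layout", {
  expect_equal(schema$protein_width, 97L)
  expect_equal(schema$ligand_width, 74L)
  expect_equal(schema$node_width, 171L)
  expect_equal(schema$edge_width, 8L)
  expect_equal(unname(vapply(schema$protein, length, 1L)),
               c(7L, 10L, 6L, 6L, 9L, 22L, 37L))
  expect_equal(unname(vapply(schema$ligand, length, 1L)),
               c(7L, 10L, 6L, 6L, 9L, 22L, 12L, 2L))
  expect_length(schema$edge$bond_type, 7L)
})

test_that("element classification uses the exact metal and halogen sets", {
  expect_equal(classify_element("Zn", "protein"), "METAL")
  expect_equal(classify_element("Mg", "protein"), "METAL")
  expect_equal(classify_element("Cl", "ligand"), "HALOGEN")
  expect_equal(classify_element("I", "ligand"), "HALOGEN")
  expect_equal(classify_element("Se", "protein"), "OTHER")
  expect_equal(classify_element("Cl", "protein"), "OTHER")  # no protein halogen
  expect_equal(classify_element("Zn", "ligand"), "OTHER")   # no ligand metal
  expect_equal(classify_element("c", "ligand"), "C")        # case-insensitive
})

test_that("protein nodes fill the leading 97 dims, zeros elsewhere", {
  v <- encode_protein_node(protein_atom(), schema)
  expect_length(v, 171L)
  expect_true(all(v[98:171] == 0))
  # CA carbon of ALA: atom type C, amino acid ALA, atom name CA
  off <- schema$protein_offsets
  expect_equal(v[off[["atom_type"]] + match("C", schema$protein$atom_type)], 1)
  expect_equal(v[off[["amino_acid_type"]] +
                   match("ALA", schema$protein$amino_acid_type)], 1)
  expect_equal(v[off[["atom_name"]] + match("CA", schema$protein$atom_name)], 1)
})

test_that("an out-of-vocabulary element leaves the atom-type block all-zero", {
  v <- encode_protein_node(protein_atom(element = "Se", resname = "MSE",
                                        name = "SE"), schema)
  off <- schema$protein_offsets
  expect_equal(sum(v[off[["atom_type"]] + 1:7]), 0)     # OTHER-as-zeros
  expect_equal(v[off[["amino_acid_type"]] +
                   match("NONSTANDARD", schema$protein$amino_acid_type)], 1)
  expect_equal(v[off[["atom_name"]] +
                   match("OTHER", schema$protein$atom_name)], 1)
})

test_that("ligand nodes fill the trailing 74 dims with ring/aromatic slots", {
  v <- encode_ligand_node(ligand_atom(), schema)
  expect_length(v, 171L)
  expect_true(all(v[1:97] == 0))
  off <- schema$ligand_offsets
  expect_equal(v[off[["ring_size"]] + match("6", schema$ligand$ring_size)], 1)
  expect_equal(v[off[["aromatic"]] + match("TRUE", schema$ligand$aromatic)], 1)
  expect_equal(v[off[["atom_degree"]] + match("3", schema$ligand$atom_degree)], 1)

  # acyclic sp3 carbon
  v2 <- encode_ligand_node(ligand_atom(degree = 0, iv = 4, nh = 4,
                                       hyb = "SP3", ring = 0, arom = FALSE),
                           schema)
  expect_equal(v2[off[["ring_size"]] + match("none", schema$ligand$ring_size)], 1)
  expect_equal(v2[off[["aromatic"]] + match("FALSE", schema$ligand$aromatic)], 1)

  # 12-membered macrocycle collapses to the ring OTHER slot
  v3 <- encode_ligand_node(ligand_atom(ring = 12), schema)
  expect_equal(v3[off[["ring_size"]] + match("OTHER", schema$ligand$ring_size)], 1)
})

test_that("protein and ligand node vectors are zero-padding complementary", {
  vp <- encode_protein_node(protein_atom(), schema)
  vl <- encode_ligand_node(ligand_atom(), schema)
  expect_true(all(vp * vl == 0))
})

test_that("every one-hot block sums to 0 or 1 over randomized atom contexts", {
  set.seed(4)
  blocks <- function(v, off, widths) {
    vapply(seq_along(off), function(q) sum(v[off[q] + seq_len(widths[q])]), 1.0)
  }
  pw <- vapply(schema$protein, length, 1L)
  lw <- vapply(schema$ligand, length, 1L)
  for (q in 1:25) {
    a <- protein_atom(element = sample(c("C", "N", "O", "S", "Zn", "Se"), 1),
                      degree = sample(0:12, 1), iv = sample(0:6, 1),
                      nh = sample(0:6, 1),
                      hyb = sample(c("SP2", "SP3", "AROMATIC", "weird"), 1),
                      resname = sample(c("ALA", "TRP", "MSE", "LIG"), 1),
                      name = sample(c("CA", "OD1", "XX9"), 1))
    bp <- blocks(encode_protein_node(a, schema), schema$protein_offsets, pw)
    expect_true(all(bp %in% c(0, 1)))
    l <- ligand_atom(element = sample(c("C", "N", "Cl", "B"), 1),
                     degree = sample(0:12, 1), fc = sample(-12:12, 1),
                     ring = sample(c(0, 3, 6, 11, 14), 1),
                     arom = sample(c(TRUE, FALSE), 1))
    bl <- blocks(encode_ligand_node(l, schema), schema$ligand_offsets, lw)
    expect_true(all(bl %in% c(0, 1)))
  }
})

test_that("encoding is a pure function of the atom context", {
  a <- protein_atom()
  expect_identical(encode_protein_node(a, schema), encode_protein_node(a, schema))
  l <- ligand_atom()
  expect_identical(encode_ligand_node(l, schema), encode_ligand_node(l, schema))
})

test_that("edge encoding one-hots the category and stores DistMax", {
  expect_equal(encode_edge("NONCOVALENT", 4.0), c(0, 0, 0, 0, 1, 0, 0, 4))
  expect_equal(encode_edge("SINGLE", 1.0), c(1, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(encode_edge("UNKNOWN", 2.5)[7], 1)
  expect_error(encode_edge("HYDROGEN-BOND", 3.0), "unknown edge category")
  expect_error(encode_edge("SINGLE", 0), "positive")
})

test_that("the schema serializes to JSON for provenance", {
  tf <- withr::local_tempfile(fileext = ".json")
  write_schema_json(schema, tf)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(back$widths$node, 171L)
  expect_equal(back$widths$protein, 97L)
})
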