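test_that("PDB reading strips waters and honours the HETATM flag", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(tf)

  p <- read_protein(tf, keep_hetatm = TRUE)
  expect_false(any(p$atoms$resname %in% c("HOH", "WAT")))
  expect_equal(nrow(p$atoms), 4L)             # 3 protein + ZN, water gone
  expect_true("Zn" %in% p$atoms$element)
  expect_true(p$atoms$is_hetatm[p$atoms$element == "Zn"])
  expect_equal(p$atoms$atom_name[1:3], c("N", "CA", "C"))  # names verbatim
  expect_equal(p$resolution, 2.1)

  p2 <- read_protein(tf, keep_hetatm = FALSE)
  expect_equal(nrow(p2$atoms), 3L)
  expect_false("Zn" %in% p2$atoms$element)
})

test_that("unreadable or empty PDB input raises a format error", {
  expect_error(read_protein(tempfile(fileext = ".pdb")), "parse")
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
               "END"), tf)
  expect_error(read_protein(tf), "empty|parse")
})

test_that("multi-record SDF reading yields one molecule per pose", {
  lig <- ligand_template()
  poses <- lapply(1:10, function(q) { l <- lig; l$xyz <- l$xyz + q; l })
  tf <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(poses, tf)
  got <- read_ligand(tf)
  expect_length(got, 10L)
  expect_equal(got[[3]]$xyz, poses[[3]]$xyz, tolerance = 1e-3)
  expect_equal(got[[1]]$bonds$type, lig$bonds$type)
})

test_that("SDF formal charges round-trip through M CHG lines", {
  lig <- make_chain(c("C", "N", "O"))
  lig$formal_charges <- c(0L, 1L, -1L)
  tf <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(lig, tf)
  got <- read_ligand(tf)[[1]]
  expect_equal(got$formal_charges, c(0L, 1L, -1L))
})

test_that("a bond block referencing missing atoms is a parse error naming the record", {
  tf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("bad", "", "",
               "  2  1  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
               "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
               "  1  7  1  0  0  0  0",
               "M  END", "$$$$"), tf)
  expect_error(read_ligand(tf), "record 1")
})

test_that("Mol2 benzene parses with aromatic ring chemistry", {
  tf <- withr::local_tempfile(fileext = ".mol2")
  b <- make_benzene()
  writeLines(c("@<TRIPOS>MOLECULE", "benzene", " 6 6 1 0 0", "SMALL",
               "USER_CHARGES", "@<TRIPOS>ATOM",
               sprintf("%7d C%-10d %9.4f %9.4f %9.4f C.ar      1 BNZ         0.0000",
                       1:6, 1:6, b$xyz[, 1], b$xyz[, 2], b$xyz[, 3]),
               "@<TRIPOS>BOND",
               sprintf("%6d %4d %4d ar", 1:6, 1:6, c(2:6, 1))), tf)
  got <- read_ligand(tf)[[1]]
  expect_equal(sum(got$elements != "H"), 6L)
  expect_true(all(got$derived$aromatic))
  expect_true(all(got$derived$ring_size == 6L))
  expect_equal(got$derived$hybridization, rep("AROMATIC", 6))
})

test_that("curation predicates report all failures and skip missing metadata", {
  cp <- make_toy_complex(n_protein = 10, pocket_radius = 4, seed = 1)
  expect_true(passes_curation(cp)$pass)   # resolution 2.1-ish, 8 heavy atoms

  # too-small ligand
  small <- complex_pose(cp$protein, make_chain(c("C", "O")), "p", "c")
  res <- passes_curation(small)
  expect_false(res$pass)
  expect_true("ligand_atom_count" %in% res$failed)

  # bad resolution fails; several rules can fail at once
  bad <- cp
  bad$protein$resolution <- 3.5
  bad$ligand <- make_chain(c("C", "O"))
  res2 <- passes_curation(complex_pose(bad$protein, bad$ligand, "p", "c"))
  expect_setequal(res2$failed, c("resolution", "ligand_atom_count"))

  # unknown resolution is skipped, not failed
  unk <- cp
  unk$protein$resolution <- NA_real_
  res3 <- passes_curation(unk)
  expect_true("resolution" %in% res3$skipped)
  expect_false("resolution" %in% res3$failed)
})

test_that("covalent ligand-protein contacts are flagged", {
  cp <- make_toy_complex(n_protein = 10, pocket_radius = 4, seed = 1)
  clash <- cp
  # drop a protein atom 1.0 A from a ligand atom
  clash$protein$atoms[1, c("x", "y", "z")] <-
    as.list(cp$ligand$xyz[1, ] + c(1.0, 0, 0))
  expect_true("covalent_bond" %in% passes_curation(clash)$failed)
})

test_that("rotatable bond counting follows the single/acyclic/non-terminal rule", {
  expect_equal(count_rotatable_bonds(make_benzene()), 0L)      # ring bonds
  expect_equal(count_rotatable_bonds(make_chain(c("C", "C", "C", "C"))), 1L)
  expect_equal(count_rotatable_bonds(make_chain(c("C", "C"))), 0L)  # terminal
  expect_equal(count_rotatable_bonds(ligand_template()), 1L)   # ring-CO link
})

test_that("plain RMSD matches identity-mapping arithmetic", {
  lig <- ligand_template()
  expect_identical(compute_rmsd(lig, lig), 0)
  moved <- lig
  moved$xyz <- lig$xyz + matrix(c(3, 0, 0), nrow(lig$xyz), 3, byrow = TRUE)
  expect_equal(compute_rmsd(moved, lig), 3)   # |t| exactly
  expect_equal(compute_rmsd(moved, lig), compute_rmsd(lig, moved))  # symmetry
  expect_error(compute_rmsd(make_chain(c("C", "C")), lig), "incompatible")
})

test_that("symmetry correction equals the brute-force automorphism minimum", {
  b <- make_benzene()
  rot <- b
  rot$xyz <- rotate_z(b$xyz, 60)
  expect_gt(compute_rmsd(rot, b), 0.5)
  expect_equal(compute_rmsd(rot, b, symmetry = TRUE), 0, tolerance = 1e-9)
  expect_length(ligand_automorphisms(b), 12L)  # dihedral group of the hexagon

  # randomized conformers of a molecule with symmetric branches
  mol <- ligand_molecule(
    c("C", "O", "O", "C", "C"),
    rbind(c(0, 0, 0), c(1.2, 0.5, 0), c(1.2, -0.5, 0),
          c(-1.5, 0, 0), c(-2.2, 1.2, 0)),
    data.frame(i = c(1, 1, 1, 4), j = c(2, 3, 4, 5),
               type = c("DOUBLE", "DOUBLE", "SINGLE", "SINGLE")))
  for (seed in 1:5) {
    set.seed(seed)
    pose <- mol
    pose$xyz <- mol$xyz + matrix(rnorm(15, sd = 0.6), 5, 3)
    expect_equal(compute_rmsd(pose, mol, symmetry = TRUE),
                 brute_force_sym_rmsd(pose, mol), tolerance = 1e-9)
    expect_lte(compute_rmsd(pose, mol, symmetry = TRUE),
               compute_rmsd(pose, mol) + 1e-12)
  }
})

test_that("RMSD label tables round-trip as TSV", {
  df <- data.frame(pose_id = c("p1", "p2"), complex_id = "c1",
                   rmsd = c(0, 2.5))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_rmsd_labels(df, tf)
  expect_equal(read_rmsd_labels(tf), df)
})
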