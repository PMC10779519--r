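test_that("PDB parsing fills atoms, MODRES map and REMARK 350 assemblies", {
  path <- write_temp_pdb(make_mini_protein(5, chains = "A", modres = TRUE,
                                           assembly_copies = 1))
  s <- parse_pdb(path)
  expect_equal(length(s$chain_order), 1)
  expect_equal(s$modres[["MSE"]], "MET")
  expect_equal(length(s$assemblies), 1)
  expect_equal(length(s$assemblies[[1]]$transforms), 1)
  expect_equal(s$assemblies[[1]]$transforms[[1]],
               cbind(diag(3), c(0, 0, 0)))
  expect_equal(s$assemblies[[1]]$chains, "A")

  two <- write_temp_pdb(c(
    zcmesh:::pdb_atom_line(1, "CA", "ALA", "A", 1, c(0, 0, 0)),
    zcmesh:::pdb_atom_line(2, "CB", "ALA", "A", 1, c(1, 1, 1)),
    "END"))
  s2 <- parse_pdb(two)
  expect_equal(nrow(s2$atoms), 2)
  expect_equal(length(s2$assemblies), 0)
})

test_that("cleaning removes waters and hydrogens and resolves altlocs", {
  path <- write_temp_pdb(make_mini_protein(6, waters = 4, altloc = TRUE))
  s <- clean_structure(parse_pdb(path))
  expect_false(any(s$atoms$resid == "HOH"))
  kept <- s$atoms[s$atoms$resno == 2 & s$atoms$elety == "CB", ]
  expect_equal(nrow(kept), 1)
  expect_equal(kept$o, 0.6)              # highest occupancy wins

  # equal occupancies: the first rotamer in the file (A) wins
  tie <- write_temp_pdb(c(
    zcmesh:::pdb_atom_line(1, "N", "ALA", "A", 1, c(0, 0, 0)),
    zcmesh:::pdb_atom_line(2, "CA", "ALA", "A", 1, c(1, 0, 0),
                           occ = 0.5, alt = "A"),
    zcmesh:::pdb_atom_line(3, "CA", "ALA", "A", 1, c(9, 0, 0),
                           occ = 0.5, alt = "B"),
    "END"))
  st <- clean_structure(parse_pdb(tie))
  ca <- st$atoms[st$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1)

  # a structure of only waters cleans to an empty structure
  wat <- write_temp_pdb(c(
    zcmesh:::pdb_atom_line(1, "O", "HOH", "W", 1, c(0, 0, 0),
                           record = "HETATM", element = "O"),
    "END"))
  expect_equal(nrow(clean_structure(parse_pdb(wat))$atoms), 0)

  # idempotence
  s2 <- clean_structure(s)
  expect_identical(s2$atoms, s$atoms)
})

test_that("MODRES residues survive cleaning as protein", {
  path <- write_temp_pdb(make_mini_protein(6, modres = TRUE))
  s <- clean_structure(parse_pdb(path))
  expect_true("MSE" %in% s$atoms$resid)
  expect_equal(sum(s$atoms$resid == "MSE"), 5)
})

test_that("selection grammar handles lists, ranges and parenthesised forms", {
  path <- write_temp_pdb(make_mini_protein(10,
                                           chains = c("A", "B", "C", "D",
                                                      "E")))
  s <- clean_structure(parse_pdb(path))
  expect_equal(select_fragment(s, "1KFV:A+D")$chain_order, c("A", "D"))
  expect_equal(select_fragment(s, "X:B-D")$chain_order, c("B", "C", "D"))
  expect_equal(select_fragment(s, "X:B−D")$chain_order,
               c("B", "C", "D"))                     # Unicode minus
  sub <- select_fragment(s, "X:(A+B)(3–7)")     # en-dash range
  expect_equal(sub$chain_order, c("A", "B"))
  expect_equal(sort(unique(sub$atoms$resno)), 3:7)
  expect_equal(nrow(select_fragment(s, "X:")$atoms), nrow(s$atoms))
  expect_error(select_fragment(s, "X:Q"), "chain 'Q'")
  expect_error(select_fragment(s, "X:(A+B)(3-7"), "malformed")
})

test_that("selection and effective atoms commute with label filtering", {
  path <- write_temp_pdb(make_mini_protein(8, chains = c("A", "B")))
  s <- clean_structure(parse_pdb(path))
  ea_then_filter <- effective_atoms(select_fragment(s, "X:B"))
  ea_all <- effective_atoms(s)
  keep <- grepl("^B:", ea_all$labels)
  expect_equal(ea_then_filter$coords, ea_all$coords[keep, , drop = FALSE])
})

test_that("assembly expansion copies chains rigidly with fresh identifiers", {
  path <- write_temp_pdb(make_mini_protein(10, assembly_copies = 2))
  s <- clean_structure(parse_pdb(path))
  asm <- build_assembly(s, 1)
  expect_equal(nrow(asm$atoms), 2 * nrow(s$atoms))
  expect_equal(length(asm$chain_order), 2)
  # intra-copy pairwise distances are preserved by the rigid transform
  xyz0 <- as.matrix(s$atoms[1:20, c("x", "y", "z")])
  xyz2 <- as.matrix(asm$atoms[asm$atoms$chain == "A2", ][1:20,
                                                         c("x", "y", "z")])
  d0 <- dist(xyz0); d2 <- dist(xyz2)
  expect_lt(max(abs(d0 - d2) / pmax(d0, 1e-9)), 1e-9)
  expect_error(build_assembly(s, "nope"), "unknown assembly")

  # identity-only assembly leaves coordinates unchanged
  one <- write_temp_pdb(make_mini_protein(5, assembly_copies = 1))
  s1 <- clean_structure(parse_pdb(one))
  a1 <- build_assembly(s1, 1)
  expect_equal(a1$atoms$x, s1$atoms$x)
  expect_equal(nrow(a1$atoms), nrow(s1$atoms))
})

test_that("effective atoms are unweighted heavy-atom centroids", {
  path <- write_temp_pdb(c(
    zcmesh:::pdb_atom_line(1, "N", "GLY", "A", 1, c(0, 0, 0)),
    zcmesh:::pdb_atom_line(2, "CA", "GLY", "A", 1, c(2, 0, 0)),
    "END"))
  ea <- effective_atoms(clean_structure(parse_pdb(path)))
  expect_equal(ea$coords[1, ], c(1, 0, 0))
  expect_equal(ea$labels, "A:1")

  # a single 149-residue chain yields 149 effective atoms
  big <- write_temp_pdb(make_mini_protein(149))
  ea2 <- effective_atoms(clean_structure(parse_pdb(big)))
  expect_equal(nrow(ea2$coords), 149)
})

test_that("backbone splitting keeps exactly N, CA, C, O per chain", {
  path <- write_temp_pdb(make_mini_protein(10, chains = c("A", "B")))
  s <- clean_structure(parse_pdb(path))
  bb <- backbone_chains(s)
  expect_equal(length(bb), 2)
  expect_equal(nrow(bb[["A"]]$atoms), 40)
  expect_true(all(bb[["A"]]$atoms$elety %in% c("N", "CA", "C", "O")))
  expect_false(any(c("CB", "OXT") %in% bb[["A"]]$atoms$elety))
})

test_that("xyzr export formats radii and resolves MODRES through parents", {
  one <- write_temp_pdb(c(
    zcmesh:::pdb_atom_line(1, "CA", "ALA", "A", 1, c(1, 2, 3)),
    "END"))
  s <- clean_structure(parse_pdb(one))
  out <- withr::local_tempfile()
  write_xyzr(s, out)
  expect_equal(readLines(out), "1.000 2.000 3.000 1.870")

  mse <- write_temp_pdb(make_mini_protein(6, modres = TRUE))
  sm <- clean_structure(parse_pdb(mse))
  write_xyzr(sm, out)
  lines <- readLines(out)
  expect_equal(length(lines), nrow(sm$atoms))
  # the MSE CA inherits the MET CA radius (1.87); its SE atom falls back
  # to the element table
  ca_mse <- which(sm$atoms$resid == "MSE" & sm$atoms$elety == "CA")
  expect_match(lines[ca_mse], "1.870$")
  se <- which(sm$atoms$elety == "SE")
  expect_match(lines[se], "1.900$")

  # unresolvable atoms are reported
  sm2 <- sm
  sm2$atoms$elety[1] <- "XX"
  sm2$atoms$elesy[1] <- "XQ"
  expect_error(write_xyzr(sm2, out), "no radius")
})
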