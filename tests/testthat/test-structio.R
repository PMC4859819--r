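test_that("PDB text parses with fields preserved and round-trips", {
  txt <- toy_complex_text(n_res = 3)
  s <- parse_structure(txt, id = "toy")
  expect_s3_class(s, "mol_structure")
  expect_equal(nrow(s$atoms), 3 * 3 + 4)
  expect_equal(sort(unique(s$atoms$chain)), c("A", "L"))
  lig <- s$atoms[s$atoms$res_name == "LIG", ]
  expect_true(all(lig$is_hetero))
  expect_false(any(s$atoms$is_hetero[s$atoms$res_name == "GLY"]))

  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$chain, s$atoms$chain)
  expect_equal(s2$atoms$res_num, s$atoms$res_num)
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)

  # synthetic generator output round-trips through the same path
  r <- make_two_chain_receptor(seed = 2)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(r, f2)
  n_records <- sum(grepl("^(ATOM  |HETATM)", readLines(f2)))
  expect_equal(n_records, nrow(r$atoms))
  expect_equal(nrow(read_structure(f2)$atoms), nrow(r$atoms))
})

test_that("alternate locations keep ' '/'A' only and insertion codes are rejected", {
  base <- pdb_record(1, "CA", "GLY", "A", 10, 0, 0, 0, element = "C")
  alt_a <- pdb_record(2, "CB", "GLY", "A", 10, 1, 0, 0, element = "C", altloc = "A")
  alt_b <- pdb_record(3, "CB", "GLY", "A", 10, 2, 0, 0, element = "C", altloc = "B")
  s <- parse_structure(c(base, alt_a, alt_b, "END"))
  expect_equal(nrow(s$atoms), 2)

  ins <- pdb_record(2, "CA", "GLY", "A", 10, 1, 0, 0, element = "C", insert = "A")
  expect_error(parse_structure(c(base, ins, "END")), "insertion code")
})

test_that("parse failures name the offending line", {
  expect_error(parse_structure(c("REMARK nothing", "END")), "no ATOM/HETATM")
  bad <- c(pdb_record(1, "CA", "GLY", "A", 1, 0, 0, 0),
           "ATOM      2  CA  GLY A   2         bad coords here",
           "END")
  err <- tryCatch(parse_structure(bad), error = identity)
  expect_s3_class(err, "ligmodes_parse_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("only the first model of a multi-model file is read", {
  m1 <- pdb_record(1, "CA", "GLY", "A", 1, 0, 0, 0)
  m2 <- pdb_record(1, "CA", "GLY", "A", 1, 9, 9, 9)
  s <- parse_structure(c("MODEL     1", m1, "ENDMDL", "MODEL     2", m2,
                         "ENDMDL", "END"))
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$x, 0)
})

test_that("atom selection addresses residues exactly and reports empties", {
  r <- make_two_chain_receptor(seed = 1)
  sel <- select_atoms(r, "B:176")
  expect_equal(nrow(sel), 3)
  expect_true(all(sel$chain == "B" & sel$res_num == 176))

  # empty water selection is a zero-row report, not an error
  expect_equal(nrow(select_atoms(r, "W:999")), 0)

  err <- tryCatch(select_atoms(r, "Q:75"), error = identity)
  expect_s3_class(err, "ligmodes_usage_error")
  expect_match(conditionMessage(err), "available: .*A.*B")

  # partition invariant: panel tokens covering all residues reproduce the
  # protein atom set exactly
  panel <- interface_panel(include_waters = FALSE)
  picked <- do.call(rbind, lapply(seq_len(nrow(panel)), function(j) {
    select_atoms(r, panel[j, , drop = FALSE])
  }))
  protein <- r$atoms[!r$atoms$is_hetero, ]
  expect_setequal(picked$serial, protein$serial)
})

test_that("ligand extraction handles single, duplicate and absent residues", {
  s <- parse_structure(toy_complex_text())
  lig <- extract_ligand(s, "LIG")
  expect_equal(nrow(lig$atoms), 4)
  expect_true(all(lig$atoms$res_name == "LIG"))

  expect_s3_class(tryCatch(extract_ligand(s, "XYZ"), error = identity),
                  "ligmodes_usage_error")
  expect_match(tryCatch(extract_ligand(s, "XYZ"), error = conditionMessage),
               "LIG")

  two <- c(toy_complex_text()[-14],  # drop END
           pdb_record(50, "C1", "LIG", "M", 901, 9, 9, 9, type = "HETATM",
                      element = "C"),
           "END")
  s2 <- parse_structure(two)
  expect_error(extract_ligand(s2, "LIG"), "instance")
  second <- extract_ligand(s2, "LIG", instance = 2)
  expect_equal(second$atoms$chain, "M")
})

test_that("residue panels parse, validate and keep order", {
  p <- residue_panel(c("A:75", "B:176", "W:100"))
  expect_equal(p$kind, c("protein", "protein", "water"))
  expect_equal(p$res_num, c(75L, 176L, 100L))
  expect_equal(residue_panel("A75")$token, "A:75")
  expect_error(residue_panel(c("A:75", "A:75")), "duplicate")
  expect_error(residue_panel("A:x"), "non-integer")
  expect_error(residue_panel(character(0)), "empty")

  expect_equal(nrow(interface_panel()), 37)
  expect_equal(nrow(interface_panel(include_waters = FALSE)), 34)
  expect_equal(sum(interface_panel()$chain == "A"), 13)
  expect_equal(sum(interface_panel()$chain == "B"), 21)

  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# pocket panel", "A:75", "", "B:176"), f)
  expect_equal(read_panel(f)$token, c("A:75", "B:176"))
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(c("A:75", "W:100"), fj)
  expect_equal(read_panel(fj)$token, c("A:75", "W:100"))
})

test_that("vdW radii come from the pinned table with a warned fallback", {
  expect_equal(vdw_radius(c("C", "N", "O", "S")), c(1.70, 1.55, 1.52, 1.80))
  expect_warning(r <- vdw_radius("XX"), "unknown element")
  expect_equal(r, 1.70)
})

test_that("SDF poses read as hetero residues with coordinates and elements", {
  coords <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0), ncol = 3, byrow = TRUE)
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf_text(coords, c("C", "N", "O")), f)
  pose <- read_sdf_pose(f)
  expect_equal(nrow(pose$atoms), 3)
  expect_equal(pose$atoms$element, c("C", "N", "O"))
  expect_equal(as.matrix(pose$atoms[, c("x", "y", "z")]), coords,
               ignore_attr = TRUE)
  expect_true(all(pose$atoms$is_hetero))
})
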