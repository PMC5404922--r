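test_that("a minimal one-atom PDB parses with an assigned radius", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(paste0("ATOM      1  CA  ALA A   1      11.104   6.134",
                      "  -6.504  1.00  0.00           C"), "END"), f)
  m <- read_structure(f)
  expect_equal(n_atoms(m), 1L)
  expect_equal(m$atom$radius, 1.70)
  expect_equal(m$atom$resnum, 1L)
})

test_that("write/read round-trips preserve atoms, waters and coordinates", {
  m <- epitope_fixture()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- read_structure(f)
  expect_equal(n_atoms(m2), n_atoms(m))
  expect_equal(sum(m2$atom$resname == "HOH"), sum(m$atom$resname == "HOH"))
  expect_lt(max(abs(coords(m2) - coords(m))), 1e-3 + 1e-9)
  # write o read o write is idempotent at output precision
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("the altloc policy keeps the highest-occupancy conformer, ties to A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CB AALA A   1       2.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CB BALA A   1       3.000   0.000   0.000  0.50 10.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(n_atoms(m), 2L)
  expect_equal(m$atom$x[m$atom$name == "CA"], 1.0)  # occ 0.6 wins
  expect_equal(m$atom$x[m$atom$name == "CB"], 2.0)  # tie -> altloc A
})

test_that("selection grammar resolves chains and waters, and errors usefully", {
  m <- epitope_fixture()
  g <- select_group(m, "H,L")
  expect_setequal(g$chain_ids, c("H", "L"))
  gw <- select_group(m, "R+waters")
  aw <- group_atoms(m, gw)
  expect_true(any(aw$resname == "HOH"))
  expect_true(all(aw$chain[aw$resname != "HOH"] == "R"))
  expect_error(select_group(m, "Z"), "available chains")
  expect_error(select_group(m, "  "), "empty")
  expect_error(map_contacts(m, select_group(m, "R,H"), select_group(m, "H")),
               "overlap")
})

test_that("atom count is conserved through selection and re-merge", {
  m <- epitope_fixture()
  parts <- lapply(unique(m$atom$chain), function(ch)
    m$atom[m$atom$chain == ch, , drop = FALSE])
  n <- sum(vapply(parts, nrow, integer(1)))
  expect_equal(n, n_atoms(m))
  remerged <- structure_model(do.call(rbind, parts), id = "remerged")
  expect_equal(n_atoms(remerged), n_atoms(m))
})

test_that("write_structure enforces its contracts", {
  m <- epitope_fixture()
  n <- 100000L
  big <- data.frame(serial = seq_len(n), name = "CA", resname = "ALA",
                    chain = "A", resnum = seq_len(n),
                    x = seq_len(n) * 0.01, y = 0, z = 0, element = "C")
  mbig <- structure_model(big, id = "big")
  expect_error(write_structure(mbig, tempfile()), "mmCIF")
  expect_error(structure_model(m$atom[0, ]), "at least one atom")
})

test_that("unknown elements with no radii entry are a hard error", {
  bad <- data.frame(serial = 1L, name = "XX", resname = "UNK", chain = "A",
                    resnum = 1L, x = 0, y = 0, z = 0, element = "XX")
  expect_error(structure_model(bad), "no van der Waals radius")
})
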