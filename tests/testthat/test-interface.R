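test_that("contact mapping honors the cutoff and is deterministically ordered", {
  m <- make_interaction_fixture("hbond", 3.0)
  ga <- select_group(m, "A"); gb <- select_group(m, "B")
  con <- map_contacts(m, ga, gb)
  expect_gt(nrow(con), 0)
  expect_true(all(con$distance <= 4.5))
  expect_equal(sum(con$atom_a == "ND2" & con$atom_b == "O" &
                     abs(con$distance - 3.0) < 1e-9), 1L)
  con2 <- map_contacts(m, ga, gb, contact_params(cutoff = 2.0))
  expect_equal(nrow(con2), 0L)
  expect_identical(con, map_contacts(m, ga, gb))
})

test_that("each designed fixture classifies exactly as constructed", {
  expect_equal(interaction_kinds(make_interaction_fixture("hbond")), "hbond")
  expect_equal(interaction_kinds(make_interaction_fixture("salt_bridge")),
               c("hbond", "salt_bridge"))
  expect_equal(interaction_kinds(make_interaction_fixture("cation_pi")),
               "cation_pi")
  expect_equal(interaction_kinds(make_interaction_fixture("pi_stack")),
               "pi_stack")
  expect_equal(interaction_kinds(make_interaction_fixture("water_bridge")),
               "water_mediated_hbond")
  expect_error(make_interaction_fixture("hbond", 6.0), "qualifying range")
})

test_that("a donor/acceptor pair beyond the contact rule yields nothing", {
  parts <- list(place_residue("ASN", "ND2", c(0, 0, 0), c(1, 0, 0), "A", 1),
                place_residue("ALA", "O", c(5.0, 0, 0), c(-1, 0, 0), "B", 1,
                              spin = 180))
  atoms <- do.call(rbind, parts)
  atoms$serial <- seq_len(nrow(atoms))
  m <- structure_model(atoms, id = "far_pair")
  expect_equal(nrow(map_contacts(m, select_group(m, "A"),
                                 select_group(m, "B"))), 0L)
})

test_that("every contacting residue pair appears in some interaction record", {
  con <- epitope_contacts(); ix <- epitope_interactions()
  ck <- unique(paste(con$chain_a, con$resnum_a, con$chain_b, con$resnum_b))
  ik <- unique(paste(ix$chain_a, ix$resnum_a, ix$chain_b, ix$resnum_b))
  expect_true(all(ck %in% ik))
})

test_that("contact profiles count distinct partner residues", {
  # one aspartate touching three alanines through several atom pairs each
  parts <- list(place_residue("ASP", "OD1", c(0, 0, 0), c(0, 0, 1), "A", 1))
  for (k in 1:3) {
    ang <- 2 * pi * k / 3
    dir <- c(0.45 * cos(ang), 0.45 * sin(ang), 0.89)
    parts[[k + 1]] <- place_residue("ALA", "CB", 3.6 * dir / vlen(dir),
                                    -dir, "B", k)
  }
  atoms <- do.call(rbind, parts); atoms$serial <- seq_len(nrow(atoms))
  m <- structure_model(atoms, id = "triple")
  con <- map_contacts(m, select_group(m, "A"), select_group(m, "B"))
  prof <- contact_profile(con, "a")
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$n_partners, 3L)
  expect_gt(nrow(con), 3)            # more atom pairs than partners
  # the two sides agree on the number of distinct pairs
  pb <- contact_profile(con, "b")
  expect_equal(sum(prof$n_partners), attr(prof, "n_pairs"))
  expect_equal(attr(prof, "n_pairs"), attr(pb, "n_pairs"))
  expect_equal(sum(pb$n_partners), attr(pb, "n_pairs"))
  # empty contacts give an empty profile
  empty <- contact_profile(con[0, ], "a")
  expect_equal(nrow(empty), 0L)
})

test_that("hotspot calling applies the threshold and is monotone in it", {
  prof <- data.frame(chain = "R", resnum = 1:3, icode = "",
                     resname = c("ASP", "ASN", "GLY"),
                     n_partners = c(6L, 5L, 2L))
  class(prof) <- c("contact_profile", "data.frame")
  hs <- call_hotspots(prof, contact_params(hotspot_min_partners = 5))
  expect_equal(hs$residues$resnum, c(1L, 2L))
  ones <- prof; ones$n_partners <- rep(1L, 3)
  expect_equal(nrow(call_hotspots(ones)$residues), 0L)
  for (thr in 2:7) {
    lo <- call_hotspots(prof, contact_params(hotspot_min_partners = thr))
    hi <- call_hotspots(prof, contact_params(hotspot_min_partners = thr + 1))
    expect_true(all(hi$residues$resnum %in% lo$residues$resnum))
  }
})

test_that("the epitope complex yields the published hotspot set and chemistry", {
  hs <- call_hotspots(epitope_profile())
  expect_equal(nrow(hs$residues), 4L)
  expect_setequal(hs$residues$resnum, c(6L, 10L, 68L, 71L))
  expect_setequal(hs$residues$resname, c("ARG", "LYS", "ASN", "ASP"))
  ix <- epitope_interactions()
  # Asp71 salt bridge to Arg50 of the heavy chain
  expect_true(any(ix$kind == "salt_bridge" & ix$resnum_a == 71 &
                    ix$chain_b == "H" & ix$resnum_b == 50))
  # Asn68 side-chain amide: three hydrogen bonds to the light chain
  a68 <- ix[ix$kind == "hbond" & ix$resnum_a == 68 & ix$chain_b == "L" &
              ix$atom_a %in% c("ND2", "OD1"), ]
  expect_equal(nrow(a68), 3L)
  expect_setequal(paste(a68$resnum_b, a68$atom_b),
                  c("91 O", "94 N", "94 O"))
  # Arg6 cation-pi on Trp52 of the heavy chain
  expect_true(any(ix$kind == "cation_pi" & ix$resnum_a == 6 &
                    ix$chain_b == "H" & ix$resnum_b == 52))
  # His3 water-mediated hydrogen bond to the heavy chain
  expect_true(any(ix$kind == "water_mediated_hbond" & ix$resnum_a == 3 &
                    ix$chain_b == "H"))
})

test_that("region annotation assigns contacts to epitope segments", {
  reg <- annotate_regions(epitope_contacts())
  expect_equal(reg$partner_chains[reg$region == "nterm_helix"], "H")
  expect_equal(reg$partner_chains[reg$region == "mir"], "H,L")
  expect_equal(reg$n_atom_pairs[reg$region == "other"], 0L)
  # empty contacts: all-zero summary
  reg0 <- annotate_regions(epitope_contacts()[0, ])
  expect_true(all(reg0$n_atom_pairs == 0L))
  # contacts only inside 67-76 all land in the MIR bucket
  con <- epitope_contacts()
  mir_only <- con[con$resnum_a >= 67 & con$resnum_a <= 76, ]
  regm <- annotate_regions(mir_only)
  expect_equal(sum(regm$n_atom_pairs), nrow(mir_only))
  expect_equal(regm$n_atom_pairs[regm$region == "mir"], nrow(mir_only))
})

test_that("interface outputs are byte-identical across reruns", {
  m <- make_epitope_complex()
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  con1 <- map_contacts(m, select_group(m, "R"), select_group(m, "H,L"))
  con2 <- map_contacts(make_epitope_complex(), select_group(m, "R"),
                       select_group(m, "H,L"))
  write_tsv(con1, f1); write_tsv(con2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
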