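toy_alignment <- function(rows, numbering = NULL) {
  ali <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  aln <- list(id = names(rows), ali = ali)
  class(aln) <- "fasta"
  if (!is.null(numbering)) attr(aln, "ref_numbering") <- numbering
  aln
}

toy_profile <- function(resnums, resnames, weights, chain = "R") {
  p <- data.frame(chain = chain, resnum = resnums, icode = "",
                  resname = resnames, n_partners = weights,
                  stringsAsFactors = FALSE)
  class(p) <- c("contact_profile", "data.frame")
  p
}

test_that("profile residues map onto alignment columns through the reference", {
  aln <- toy_alignment(c(ref = "NDRKY", t1 = "NDRKY"))
  prof <- toy_profile(c(1, 3, 5), c("ASN", "ARG", "TYR"), c(2, 4, 1))
  cm <- map_profile_to_alignment(prof, aln, "ref")
  expect_equal(cm$column, c(1L, 3L, 5L))
  expect_equal(cm$weight, c(2, 4, 1))
  # a gap in the reference shifts downstream columns by one
  gapped <- toy_alignment(c(ref = "ND-RKY", t1 = "NDQRKY"))
  cm2 <- map_profile_to_alignment(prof, gapped, "ref")
  expect_equal(cm2$column, c(1L, 4L, 6L))
  # mismatching reference is rejected with a diff
  bad <- toy_alignment(c(ref = "QQQQQ", t1 = "NDRKY"))
  expect_error(map_profile_to_alignment(prof, bad, "ref"), "identity")
  expect_error(map_profile_to_alignment(prof, aln, "nope"), "not in alignment")
})

test_that("hand-built three-sequence alignment scores as computed by hand", {
  aln <- toy_alignment(c(ref = "NDRKY", same = "NDRKY", sub = "NERKF"))
  prof <- toy_profile(c(1, 2, 5), c("ASN", "ASP", "TYR"), c(5, 2, 1))
  cm <- map_profile_to_alignment(prof, aln, "ref")
  self <- score_compatibility(cm, aln, "same")
  expect_identical(self$score, 1)
  expect_equal(self$verdict, "compatible")
  # sub: N identical (5), D->E conservative (0.5*2), Y->F conservative (0.5*1)
  r <- score_compatibility(cm, aln, "sub")
  expect_equal(r$score, (5 + 1 + 0.5) / 8)
})

test_that("score is monotone under added divergence and blind to zero weights", {
  base <- "NDRKYAG"
  prof <- toy_profile(1:7, c("ASN", "ASP", "ARG", "LYS", "TYR", "ALA", "GLY"),
                      c(5, 4, 3, 2, 1, 0, 0))
  seqs <- c(ref = base)
  mut <- strsplit(base, "")[[1]]
  for (k in 1:5) {
    mut[k] <- "G"   # progressively break contacting positions
    seqs[paste0("m", k)] <- paste(mut, collapse = "")
  }
  seqs["zw"] <- "NDRKYAW"  # change only a zero-weight position
  aln <- toy_alignment(seqs)
  prof <- prof[prof$n_partners > 0 | prof$resnum >= 6, ]
  cm <- map_profile_to_alignment(prof, aln, "ref")
  scores <- vapply(paste0("m", 1:5), function(id)
    score_compatibility(cm, aln, id)$score, numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
  expect_identical(score_compatibility(cm, aln, "zw")$score, 1)
  expect_true(all(scores >= 0 & scores <= 1))
})

test_that("charge-reversal at a hotspot vetoes binding regardless of score", {
  aln <- toy_alignment(c(ref = "NDRKY", rev = "NKRKY"))
  prof <- toy_profile(1:2, c("ASN", "ASP"), c(5, 5))
  cm <- map_profile_to_alignment(prof, aln, "ref")
  hs <- list(residues = data.frame(chain = "R", resnum = 2L, icode = "",
                                   resname = "ASP", n_partners = 5L),
             criterion = "test")
  class(hs) <- "hotspot_call"
  r <- score_compatibility(cm, aln, "rev", hotspots = hs,
                           verdict_threshold = 0.2)
  expect_true(any(grepl("charge_reversal", r$per_position$flags)))
  expect_equal(r$verdict, "likely_disrupted")
})

test_that("the bundled subunit panel reproduces the published binding calls", {
  prof <- epitope_profile()
  hs <- call_hotspots(prof)
  aln <- make_epitope_alignment()
  cm <- map_profile_to_alignment(prof, aln, "human_a1")
  panel <- cross_species_panel(cm, aln, setdiff(aln$id, "human_a1"), hs)
  v <- setNames(panel$verdict, panel$target_id)
  expect_equal(unname(v[c("bovine_a1", "rat_a1", "mouse_a1", "chicken_a1",
                          "torpedo_a1")]),
               rep("compatible", 5))
  expect_equal(unname(v["human_a9"]), "likely_disrupted")
  expect_equal(unname(v["xenopus_a1b"]), "likely_disrupted")
  # the alpha-9 replacements at every hotspot position
  r9 <- attr(panel, "reports")$human_a9
  hot <- r9$per_position[r9$per_position$hotspot, ]
  expect_true(all(hot$class != "identical"))
  # Xenopus alpha-1b: D71K is a flagged charge reversal
  rx <- attr(panel, "reports")$xenopus_a1b
  p71 <- rx$per_position[rx$per_position$resnum == 71, ]
  expect_match(p71$flags, "charge_reversal")
  expect_true(all(diff(panel$score) <= 1e-12))  # sorted by score
})

test_that("a shuffled decoy target scores below 0.3", {
  prof <- epitope_profile()
  aln <- make_epitope_alignment()
  set.seed(123)
  human <- aln$ali[match("human_a1", aln$id), ]
  cols <- map_profile_to_alignment(prof, aln, "human_a1")$column
  decoy <- human
  repeat {                       # derangement of the contacting columns
    perm <- sample(cols)
    if (all(human[perm] != human[cols])) break
  }
  decoy[cols] <- human[perm]
  aln$ali <- rbind(aln$ali, decoy)
  aln$id <- c(aln$id, "decoy")
  cm <- map_profile_to_alignment(prof, aln, "human_a1")
  r <- score_compatibility(cm, aln, "decoy")
  expect_lt(r$score, 0.3)
  expect_equal(r$verdict, "likely_disrupted")
})

test_that("alignments round-trip through FASTA", {
  aln <- make_epitope_alignment()
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  back <- read_alignment(f)
  expect_equal(back$id, aln$id)
  expect_equal(toupper(back$ali), aln$ali, ignore_attr = TRUE)
  # panel letters at the published positions
  pos <- attr(aln, "ref_numbering")
  get <- function(id, p) unname(aln$ali[match(id, aln$id), match(p, pos)])
  expect_equal(get("human_a1", 68), "N")
  expect_equal(get("human_a1", 71), "D")
  expect_equal(get("human_a9", 68), "D")
  expect_equal(get("human_a9", 71), "Q")
  expect_equal(get("xenopus_a1b", 68), "D")
  expect_equal(get("xenopus_a1b", 71), "K")
  expect_equal(get("torpedo_a1", 10), "N")
})
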