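test_that("neighbor search is exact, inclusive at the boundary, and monotone", {
  a <- rbind(c(0, 0, 0))
  expect_equal(nrow(neighbor_pairs(a, rbind(c(10, 0, 0)), 4.5)), 0L)
  expect_equal(nrow(neighbor_pairs(a, rbind(c(4.5, 0, 0)), 4.5)), 1L)
  expect_equal(nrow(neighbor_pairs(a, matrix(numeric(0), 0, 3), 4.5)), 0L)

  set.seed(42)
  xa <- matrix(runif(750, 0, 25), ncol = 3)
  xb <- matrix(runif(750, 0, 25), ncol = 3)
  got <- neighbor_pairs(xa, xb, 4.5)
  want <- brute_pairs(xa, xb, 4.5)
  expect_equal(got$i, want$i)
  expect_equal(got$j, want$j)
  expect_equal(got$distance, want$distance, tolerance = 1e-10)
  # monotonicity in the cutoff
  small <- neighbor_pairs(xa, xb, 3.0)
  key <- function(p) paste(p$i, p$j)
  expect_true(all(key(small) %in% key(got)))
})

test_that("Kabsch recovers random rigid transforms to numerical precision", {
  set.seed(7)
  for (rep in 1:5) {
    P <- matrix(rnorm(45), ncol = 3)
    R <- rotation_about_axis(rnorm(3), runif(1, 0, 360))
    tv <- rnorm(3, sd = 10)
    Q <- t(R %*% t(P)) + matrix(tv, nrow(P), 3, byrow = TRUE)
    fit <- kabsch_superpose(P, Q)
    expect_lt(fit$rmsd, 1e-6)
    expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
    expect_equal(max(abs(crossprod(fit$transform$rotation) - diag(3))), 0,
                 tolerance = 1e-9)
  }
  # identical sets: identity transform, zero RMSD
  P <- matrix(rnorm(30), ncol = 3)
  fit <- kabsch_superpose(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$transform$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_error(kabsch_superpose(P, P[1:5, ]), "length")
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "3")
})

test_that("Kabsch RMSD is invariant under a common rigid transform", {
  set.seed(11)
  P <- matrix(rnorm(36), ncol = 3)
  Q <- P + matrix(rnorm(36, sd = 0.5), ncol = 3)
  base <- kabsch_superpose(P, Q)$rmsd
  tr <- rigid_transform(rotation_about_axis(c(1, 2, -1), 73), c(4, -7, 2))
  moved <- kabsch_superpose(transform_coords(P, tr),
                            transform_coords(Q, tr))$rmsd
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("rigid transforms compose, invert and apply correctly", {
  m <- make_helix(6)
  expect_equal(coords(apply_transform(m, rigid_transform())), coords(m))
  t1 <- rigid_transform(diag(3), c(1, 0, 0))
  t2 <- rigid_transform(diag(3), c(-1, 0, 0))
  expect_equal(coords(apply_transform(apply_transform(m, t1), t2)), coords(m))
  tr <- rigid_transform(rotation_about_axis(c(0, 1, 1), 123), c(3, 1, -9))
  back <- apply_transform(apply_transform(m, tr), invert_transform(tr))
  expect_lt(max(abs(coords(back) - coords(m))), 1e-9)
  expect_error(rigid_transform(diag(3) * -1), "proper")
})

test_that("ring descriptors give centroid and normal of aromatic rings", {
  ring <- place_residue("PHE", "RING", c(0, 0, 0), c(1, 0, 0), "A", 1)
  m <- structure_model(transform(ring, serial = seq_len(nrow(ring)),
                                 het = FALSE), id = "phe")
  rd <- ring_descriptor(m, "A", 1)
  expect_equal(as.numeric(rd$centroid), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(abs(as.numeric(rd$normal)[3]), 1, tolerance = 1e-9)
  # rotate by a known rotation: the normal follows
  R <- rotation_about_axis(c(1, 1, 0), 35)
  m2 <- apply_transform(m, rigid_transform(R, c(0, 0, 0)))
  rd2 <- ring_descriptor(m2, "A", 1)
  want <- as.numeric(R %*% rd$normal)
  expect_lt(min(vlen(rd2$normal - want), vlen(rd2$normal + want)), 1e-9)
  # tryptophan six-membered ring in the epitope fixture
  rd3 <- ring_descriptor(epitope_fixture(), "H", 52)
  expect_equal(rd3$member_atoms, c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
  expect_false(rd3$tentative)
  # missing ring atoms are reported
  broken <- m$atom[m$atom$name != "CZ", ]
  expect_error(ring_descriptor(structure_model(broken, id = "x"), "A", 1),
               "CZ")
})
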