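toy_ternary <- function(pent) {
  # "receptor" = subunit A of the pentamer (chain X), "fab" = a displaced
  # copy (chain F)
  subA <- pent$atom[pent$atom$chain == "A", ]
  subA$chain <- "X"
  fab <- subA
  fab$chain <- "F"
  fab$x <- fab$x + 25
  structure_model(rbind(subA, fab), id = "toy_ternary")
}

test_that("grafting onto the native subunit is the identity", {
  pent <- make_toy_pentamer()
  tern <- toy_ternary(pent)
  g <- graft_fab_onto_pentamer(tern, pent, "A", "X", min_pairs = 5)
  fab <- g$components[[2]]
  expect_equal(fab$provenance$rmsd, 0, tolerance = 1e-9)
  expect_equal(fab$transform$rotation, diag(3), tolerance = 1e-9)
  expect_error(graft_fab_onto_pentamer(tern, pent, "A", "X", min_pairs = 50),
               "mappable")
})

test_that("grafting recovers a known pentamer transform", {
  pent <- make_toy_pentamer()
  tern <- toy_ternary(pent)
  tr <- rigid_transform(rotation_about_axis(c(1, 1, 0), 40), c(3, -5, 8))
  pent2 <- apply_transform(pent, tr)
  g <- graft_fab_onto_pentamer(tern, pent2, "A", "X", min_pairs = 5)
  fab <- realize_component(g, "fab")
  fab0 <- structure_model(tern$atom[tern$atom$chain == "F", ], id = "fab0")
  expect_lt(max(abs(coords(fab) - coords(apply_transform(fab0, tr)))), 1e-9)
  # graft consistency: re-grafting back onto the original recovers identity
  fab_in_orig_frame <- apply_transform(fab, invert_transform(tr))
  expect_lt(max(abs(coords(fab_in_orig_frame) - coords(fab0))), 1e-6)
})

test_that("antibody docking picks the better-fitting arm", {
  db <- make_igg_dumbbell(60, 100)
  # pose: arm I moved by a known transform
  tr <- rigid_transform(rotation_about_axis(c(0, 1, 2), 25), c(10, 4, -2))
  armI <- structure_model(db$atom[db$atom$chain == "I", ], id = "armI")
  pose <- apply_transform(armI, tr)
  g <- build_igg_model(pose, db, arm_chains = list("I", "J"))
  expect_equal(g$components[[1]]$provenance$arm_used, 1L)
  expect_lt(g$components[[1]]$provenance$rmsd, 1e-9)
  posed <- realize_component(g, "igg")
  tipJ <- posed$atom[posed$atom$name == "TIP" & posed$atom$chain == "J", ]
  want <- transform_coords(
    coords(db$atom[db$atom$name == "TIP" & db$atom$chain == "J", ]), tr)
  expect_lt(max(abs(coords(tipJ) - want)), 1e-6)
})

test_that("clash detection matches a brute-force scan and is rigid-invariant", {
  set.seed(5)
  d1 <- make_helix(8); d2 <- make_helix(8)
  for (rep in 1:4) {
    tr <- rigid_transform(rotation_about_axis(rnorm(3), runif(1, 0, 360)),
                          rnorm(3, sd = 4))
    m2 <- apply_transform(d2, tr)
    cl <- detect_clashes(d1, m2)
    # brute force
    n <- 0L
    x1 <- coords(d1); x2 <- coords(m2)
    for (i in seq_len(nrow(x1))) for (j in seq_len(nrow(x2))) {
      d <- sqrt(sum((x1[i, ] - x2[j, ])^2))
      if (d1$atom$radius[i] + m2$atom$radius[j] - d > 0.4) n <- n + 1L
    }
    expect_equal(cl$n_clashes, n)
    # global rigid motion leaves the count unchanged
    g <- rigid_transform(rotation_about_axis(c(1, 0, 1), 77), c(5, 5, 5))
    cl2 <- detect_clashes(apply_transform(d1, g), apply_transform(m2, g))
    expect_equal(cl2$n_clashes, cl$n_clashes)
  }
  # far-apart components never clash
  far <- apply_transform(d2, rigid_transform(diag(3), c(100, 0, 0)))
  expect_equal(detect_clashes(d1, far)$n_clashes, 0L)
})

test_that("toy pentamers have the designed five-fold geometry", {
  pent <- make_toy_pentamer(ring_radius = 40)
  ax <- pentamer_axis(pent)
  expect_lt(min(vlen(ax - c(0, 0, 1)), vlen(ax + c(0, 0, 1))), 1e-6)
  cents <- t(vapply(LETTERS[1:5], function(ch)
    colMeans(coords(pent$atom[pent$atom$chain == ch, ])), numeric(3)))
  ctr <- colMeans(cents)
  for (k in 1:5) {
    k2 <- if (k == 5) 1 else k + 1
    ang <- acos(sum((cents[k, ] - ctr) * (cents[k2, ] - ctr)) /
                  (vlen(cents[k, ] - ctr) * vlen(cents[k2, ] - ctr))) * 180 / pi
    expect_equal(ang, 72, tolerance = 1e-6)
  }
  # adjacent subunits never interpenetrate; tiny radii are refused
  expect_equal(detect_clashes(pent$atom[pent$atom$chain == "A", ],
                              pent$atom[pent$atom$chain == "B", ])$n_clashes, 0L)
  expect_error(make_toy_pentamer(ring_radius = 2), "radius")
})

test_that("the dumbbell span matches its closed form", {
  expect_equal(dumbbell_span(80, 180), 160, tolerance = 1e-6)
  expect_equal(dumbbell_span(80, 60), 80, tolerance = 1e-6)
  for (ang in c(60, 100, 120, 150, 180)) {
    db <- make_igg_dumbbell(80, ang)
    tips <- coords(db$atom[db$atom$name == "TIP", ])
    expect_equal(vlen(tips[1, ] - tips[2, ]), dumbbell_span(80, ang),
                 tolerance = 1e-6)
  }
  # sweep envelope equals the analytic min/max
  igg <- make_igg_dumbbell(75)
  r <- divalent_feasibility(list(fab_frame(c(0, 0, 0), c(0, 0, 1)),
                                 fab_frame(c(300, 0, 0), c(0, 0, 1))),
                            igg, hinge_sweep = seq(30, 150, by = 10))
  expect_equal(r$required_span, c(dumbbell_span(75, 30), dumbbell_span(75, 150)),
               tolerance = 1e-9)
})

test_that("divalent feasibility follows the constructed geometry", {
  igg <- make_igg_dumbbell(75, 120)
  # anchors farther apart than any achievable tip span: infeasible
  r <- divalent_feasibility(list(fab_frame(c(0, 0, 0), c(0, 0, 1)),
                                 fab_frame(c(200, 0, 0), c(0, 0, 1))), igg)
  expect_false(r$feasible)
  expect_match(r$reason, "outside achievable")
  # anchors 120 A apart with matching convergent axes: feasible
  half <- asin(60 / 75)
  f1 <- fab_frame(c(0, 0, 0), c(sin(half), 0, cos(half)))
  f2 <- fab_frame(c(120, 0, 0), c(-sin(half), 0, cos(half)))
  r2 <- divalent_feasibility(list(f1, f2), igg)
  expect_true(r2$feasible)
  # symmetry: swapping the two frames does not change the verdict
  expect_equal(divalent_feasibility(list(f2, f1), igg)$feasible, r2$feasible)
  # widening the hinge sweep never turns feasible into infeasible
  r3 <- divalent_feasibility(list(f1, f2), igg, hinge_sweep = seq(10, 170, 10))
  expect_true(r3$feasible)
  expect_error(divalent_feasibility(list(f1, f2), igg,
                                    hinge_sweep = numeric(0)), "empty")
})

test_that("upright binding blocks intra-pentamer but allows inter-pentamer bridging", {
  pent <- make_toy_pentamer()
  igg <- make_igg_dumbbell(75, 120)
  frames <- lapply(c("A", "C"), function(ch)
    subunit_frame(pent, ch, anchor_offset = 15, tilt_out = 0))
  intra <- divalent_feasibility(frames, igg, obstacles = list(pent),
                                mode = "intra_pentamer")
  expect_false(intra$feasible)
  # labeling the other alpha subunit first gives the same verdict
  intra2 <- divalent_feasibility(rev(frames), igg, obstacles = list(pent),
                                 mode = "intra_pentamer")
  expect_equal(intra2$feasible, intra$feasible)
  pair <- facing_pentamer_pair(pent, tilt = 30)
  inter <- divalent_feasibility(pair$frames, igg, obstacles = pair$pentamers,
                                mode = "inter_pentamer")
  expect_true(inter$feasible)
  expect_gt(tilt_analysis(inter), 0)
})

test_that("tilt analysis measures the angle between pentamer axes", {
  pent <- make_toy_pentamer()
  coax <- apply_transform(pent, rigid_transform(diag(3), c(120, 0, 0)))
  expect_equal(tilt_analysis(list(pent, coax)), 0, tolerance = 1e-6)
  tilted <- apply_transform(pent, rigid_transform(
    rotation_about_axis(c(0, 1, 0), 30), c(120, 0, 0)))
  expect_equal(tilt_analysis(list(pent, tilted)), 30, tolerance = 1e-6)
})
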