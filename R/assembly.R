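# Rigid-body modeling of higher-order antibody-receptor assemblies: grafting
# the antibody pose onto pentamer subunits, docking a two-arm antibody
# template, steric clash detection, and divalent-binding feasibility within
# vs between pentamers.

#' Assembly of rigid components
#'
#' @param components list of components, each a list with `model`
#'   ([structure_model()]), `transform` ([rigid_transform()]), `role` (one of
#'   `"pentamer"`, `"fab"`, `"igg"`, `"receptor_copy"`), `label`, and
#'   free-form `provenance`.
#' @return `assembly_model` object.
#' @export
assembly_model <- function(components) {
  labels <- vapply(components, function(c) c$label, character(1))
  if (anyDuplicated(labels)) stopf("component labels must be unique")
  structure(list(components = components), class = "assembly_model")
}

#' @export
print.assembly_model <- function(x, ...) {
  cat(sprintf("<assembly_model: %d component(s)>\n", length(x$components)))
  for (c in x$components)
    cat(sprintf("  %-12s role=%-13s %d atoms\n", c$label, c$role,
                n_atoms(c$model)))
  invisible(x)
}

#' Realize a component to transformed coordinates
#' @param assembly `assembly_model`.
#' @param label component label.
#' @return [structure_model()] with the component transform applied.
#' @export
realize_component <- function(assembly, label) {
  for (c in assembly$components)
    if (c$label == label) return(apply_transform(c$model, c$transform))
  stopf("no component labelled '%s'", label)
}

#' Graft an antibody-bound receptor pose onto a pentamer subunit
#'
#' Superposes the receptor chain of the binary/ternary complex onto the
#' chosen pentamer subunit using paired C-alpha atoms (matched by residue
#' number), then carries the remaining complex chains (the Fab, and any
#' ligand such as a bound toxin) by the same transform.
#'
#' @param ternary [structure_model()] of the antibody/receptor complex.
#' @param pentamer [structure_model()] of the receptor pentamer.
#' @param subunit_chain chain id of the target subunit in `pentamer`.
#' @param receptor_chain chain id of the receptor in `ternary`.
#' @param carry_chains chains of `ternary` carried by the graft transform;
#'   default: every chain except `receptor_chain`.
#' @param min_pairs minimum number of mappable C-alpha pairs (default 50, as
#'   appropriate for a real receptor domain; lower it for toy fixtures).
#' @param keep_receptor also carry a copy of the superposed receptor chain
#'   (role `receptor_copy`).
#' @return `assembly_model` with the pentamer (identity transform) and the
#'   grafted component; the superposition RMSD is stored in the grafted
#'   component's `provenance`.
#' @export
graft_fab_onto_pentamer <- function(ternary, pentamer, subunit_chain,
                                    receptor_chain, carry_chains = NULL,
                                    min_pairs = 50L, keep_receptor = FALSE) {
  ca_t <- ternary$atom[ternary$atom$chain == receptor_chain &
                         ternary$atom$name == "CA", , drop = FALSE]
  ca_p <- pentamer$atom[pentamer$atom$chain == subunit_chain &
                          pentamer$atom$name == "CA", , drop = FALSE]
  common <- intersect(ca_t$resnum, ca_p$resnum)
  if (length(common) < min_pairs)
    stopf("only %d mappable C-alpha pairs between receptor chain %s and subunit %s (need >= %d)",
          length(common), receptor_chain, subunit_chain, min_pairs)
  common <- sort(common)
  sup <- kabsch_superpose(coords(ca_t[match(common, ca_t$resnum), ]),
                          coords(ca_p[match(common, ca_p$resnum), ]))
  carry_chains <- carry_chains %||%
    setdiff(unique(ternary$atom$chain), receptor_chain)
  carried_atoms <- ternary$atom[ternary$atom$chain %in% carry_chains, ,
                                drop = FALSE]
  comps <- list(list(model = pentamer, transform = rigid_transform(),
                     role = "pentamer", label = "pentamer",
                     provenance = list()))
  if (nrow(carried_atoms) > 0L) {
    comps[[2]] <- list(
      model = structure_model(carried_atoms, id = paste0(ternary$id, "_fab")),
      transform = sup$transform, role = "fab", label = "fab",
      provenance = list(subunit = subunit_chain, rmsd = sup$rmsd,
                        n_pairs = length(common)))
  }
  if (keep_receptor) {
    rec <- ternary$atom[ternary$atom$chain == receptor_chain, , drop = FALSE]
    comps[[length(comps) + 1L]] <- list(
      model = structure_model(rec, id = paste0(ternary$id, "_receptor")),
      transform = sup$transform, role = "receptor_copy",
      label = "receptor_copy",
      provenance = list(subunit = subunit_chain, rmsd = sup$rmsd))
  }
  assembly_model(comps)
}

#' Dock a two-arm antibody template via one Fab arm
#'
#' Transforms the whole antibody template so that one of its arms superposes
#' (C-alpha, matched by residue number within paired chains) onto the posed
#' Fab.  When both arms are candidates the lower-RMSD arm is used and the
#' choice recorded.
#'
#' @param fab_pose [structure_model()] of the bound Fab in its final frame.
#' @param igg_template [structure_model()] of the intact antibody.
#' @param arm_chains list of one or two character vectors: the template
#'   chains making up each candidate arm, in the order matching
#'   `pose_chains`.
#' @param pose_chains chains of `fab_pose` to map (default: all, in order).
#' @param min_pairs minimum mappable C-alpha pairs.
#' @return `assembly_model` with a single `igg` component; provenance
#'   records `arm_used` and `rmsd`.
#' @export
build_igg_model <- function(fab_pose, igg_template, arm_chains,
                            pose_chains = NULL, min_pairs = 3L) {
  if (!is.list(arm_chains)) arm_chains <- list(arm_chains)
  pose_chains <- pose_chains %||% unique(fab_pose$atom$chain)
  fits <- lapply(seq_along(arm_chains), function(ai) {
    chs <- arm_chains[[ai]]
    if (length(chs) != length(pose_chains)) return(NULL)
    mob <- NULL; ref <- NULL
    for (ci in seq_along(chs)) {
      ca_t <- igg_template$atom[igg_template$atom$chain == chs[ci] &
                                  igg_template$atom$name == "CA", ,
                                drop = FALSE]
      ca_p <- fab_pose$atom[fab_pose$atom$chain == pose_chains[ci] &
                              fab_pose$atom$name == "CA", , drop = FALSE]
      common <- sort(intersect(ca_t$resnum, ca_p$resnum))
      if (!length(common)) next
      mob <- rbind(mob, coords(ca_t[match(common, ca_t$resnum), ]))
      ref <- rbind(ref, coords(ca_p[match(common, ca_p$resnum), ]))
    }
    if (is.null(mob) || nrow(mob) < min_pairs) return(NULL)
    c(kabsch_superpose(mob, ref), list(arm = ai, n_pairs = nrow(mob)))
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stopf("no arm of the template maps onto the posed Fab")
  rmsds <- vapply(fits, function(f) f$rmsd, numeric(1))
  # ties (identical arms) resolve to the first candidate arm
  best <- fits[[which(rmsds <= min(rmsds) + 1e-9)[1]]]
  assembly_model(list(list(
    model = igg_template, transform = best$transform, role = "igg",
    label = "igg",
    provenance = list(arm_used = best$arm, rmsd = best$rmsd,
                      n_pairs = best$n_pairs))))
}

#' Detect steric clashes between two rigid bodies
#'
#' Atom pairs whose van der Waals overlap (`r_i + r_j - distance`) exceeds
#' `params$clash_overlap`.
#'
#' @param a,b [structure_model()]s or atom data.frames.
#' @param params [contact_params()] (uses `clash_overlap`).
#' @return `clash_report`: list with `pairs` (data.frame serial_a, serial_b,
#'   distance, overlap), `n_clashes`, `max_overlap`.
#' @export
detect_clashes <- function(a, b, params = contact_params()) {
  at_a <- if (inherits(a, "structure_model")) a$atom else a
  at_b <- if (inherits(b, "structure_model")) b$atom else b
  cut <- max(at_a$radius) + max(at_b$radius)
  np <- neighbor_pairs(coords(at_a), coords(at_b), cut)
  if (nrow(np)) {
    np$overlap <- at_a$radius[np$i] + at_b$radius[np$j] - np$distance
    np <- np[np$overlap > params$clash_overlap, , drop = FALSE]
  } else np$overlap <- numeric(0)
  pairs <- data.frame(serial_a = at_a$serial[np$i], serial_b = at_b$serial[np$j],
                      distance = np$distance, overlap = np$overlap)
  structure(list(pairs = pairs, n_clashes = nrow(pairs),
                 max_overlap = if (nrow(pairs)) max(pairs$overlap) else 0),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("<clash_report: %d clash(es), max overlap %.2f A>\n",
              x$n_clashes, x$max_overlap))
  invisible(x)
}

#' Five-fold symmetry axis of a pentamer
#'
#' The principal axis of the C-alpha inertia tensor closest to the mean of
#' the inter-subunit centroid normals (robust without symmetry annotations).
#'
#' @param model [structure_model()] with one chain per subunit, chains in
#'   ring order.
#' @return unit 3-vector.
#' @export
pentamer_axis <- function(model) {
  chains <- unique(model$atom$chain)
  if (length(chains) < 3) stopf("need at least 3 subunit chains")
  cents <- t(vapply(chains, function(ch)
    colMeans(coords(model$atom[model$atom$chain == ch, , drop = FALSE])),
    numeric(3)))
  center <- colMeans(cents)
  normals <- NULL
  for (k in seq_len(nrow(cents))) {
    k2 <- if (k == nrow(cents)) 1L else k + 1L
    normals <- rbind(normals, unit(cross3(cents[k, ] - center,
                                          cents[k2, ] - center)))
  }
  m <- unit(colMeans(normals))
  ca <- model$atom[model$atom$name == "CA", , drop = FALSE]
  if (nrow(ca) < 3) ca <- model$atom
  cc <- sweep(coords(ca), 2, colMeans(coords(ca)))
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  dots <- abs(as.numeric(t(ev$vectors) %*% m))
  ax <- ev$vectors[, which.max(dots)]
  if (sum(ax * m) < 0) ax <- -ax
  unit(ax)
}

#' Fab binding frame
#'
#' An anchor point (where the paratope sits on the antigen surface) plus the
#' unit direction along which the Fab arm extends away from it (toward the
#' antibody hinge).  Divalent-binding feasibility is a statement about two
#' such frames.
#'
#' @param anchor length-3 point, Angstrom.
#' @param axis length-3 direction (normalized internally).
#' @return `fab_frame` object.
#' @export
fab_frame <- function(anchor, axis) {
  structure(list(anchor = as.numeric(anchor), axis = unit(axis)),
            class = "fab_frame")
}

#' Derive a Fab binding frame from a posed Fab model
#'
#' Anchor = centroid of the paratope selection; axis = direction from the
#' anchor through the Fab's overall centroid (the arm extends away from the
#' antigen).
#'
#' @param fab_model posed [structure_model()] of the Fab.
#' @param paratope_atoms logical or integer index into `fab_model$atom`
#'   selecting the paratope atoms; default: the 10% of atoms with the lowest
#'   coordinate along the Fab long axis is *not* assumed — pass an explicit
#'   selection (e.g. atoms within 4.5 A of the antigen).
#' @return `fab_frame`.
#' @export
derive_fab_frame <- function(fab_model, paratope_atoms) {
  pa <- fab_model$atom[paratope_atoms, , drop = FALSE]
  if (nrow(pa) == 0L) stopf("empty paratope selection")
  anchor <- colMeans(coords(pa))
  cent <- colMeans(coords(fab_model))
  fab_frame(anchor, cent - anchor)
}

#' Subunit binding frame on a toy pentamer
#'
#' Places the anchor above the subunit centroid along the pentamer axis and
#' tilts the Fab axis radially outward by `tilt_out` degrees, emulating the
#' upright, outward-facing binding orientation at the extracellular tip.
#'
#' @param pentamer [structure_model()].
#' @param chain subunit chain id.
#' @param anchor_offset distance from subunit centroid to anchor along the
#'   pentamer axis, Angstrom.
#' @param tilt_out outward tilt of the Fab axis from the pentamer axis,
#'   degrees.
#' @return `fab_frame`.
#' @export
subunit_frame <- function(pentamer, chain, anchor_offset = 15, tilt_out = 20) {
  ax <- pentamer_axis(pentamer)
  sub <- pentamer$atom[pentamer$atom$chain == chain, , drop = FALSE]
  if (nrow(sub) == 0L) stopf("chain %s not in pentamer", chain)
  cent <- colMeans(coords(sub))
  all_cent <- colMeans(coords(pentamer))
  radial <- cent - all_cent
  radial <- radial - sum(radial * ax) * ax
  anchor <- cent + anchor_offset * ax
  dir <- if (vnorm(radial) < 1e-9 || tilt_out == 0) ax else
    as.numeric(rotation_about_axis(unit(cross3(ax, radial)), tilt_out) %*% ax)
  fab_frame(anchor, dir)
}

# Rigid pose of a two-arm template: arms pivot independently about the hinge
# point (hinge model), the stem follows the arm bisector.
pose_igg <- function(template, hinge_at, u1, u2) {
  a <- template$atom
  hng <- a[a$name == "HNG", , drop = FALSE]
  if (nrow(hng) != 1L) stopf("template lacks a single HNG hinge marker atom")
  h0 <- as.numeric(unlist(hng[1, c("x", "y", "z")]))
  tips <- a[a$name == "TIP", , drop = FALSE]
  if (nrow(tips) < 2L) stopf("template lacks two TIP paratope marker atoms")
  arm_chain <- tips$chain[order(tips$serial)][1:2]
  place_part <- function(rows, v_from, v_to) {
    R <- rotation_between(v_from, v_to)
    xyz <- sweep(coords(rows), 2, h0)
    xyz <- xyz %*% t(R)
    sweep(xyz, 2, -hinge_at)
  }
  out <- a
  for (k in 1:2) {
    rows <- a$chain == arm_chain[k]
    tip0 <- as.numeric(unlist(tips[tips$chain == arm_chain[k],
                                   c("x", "y", "z")]))
    u <- if (k == 1) u1 else u2
    xyz <- place_part(a[rows, , drop = FALSE], tip0 - h0, u)
    out$x[rows] <- xyz[, 1]; out$y[rows] <- xyz[, 2]; out$z[rows] <- xyz[, 3]
  }
  stem_rows <- !(a$chain %in% arm_chain)
  if (any(stem_rows)) {
    bis <- u1 + u2
    bis <- if (vnorm(bis) < 1e-9) unit(cross3(u1, c(0, 0, 1) +
                                                1e-3 * c(1, 0, 0))) else unit(bis)
    stem_cent <- colMeans(coords(a[stem_rows & a$name != "HNG", , drop = FALSE]))
    v0 <- stem_cent - h0
    if (vnorm(v0) < 1e-9) v0 <- c(0, -1, 0)
    xyz <- place_part(a[stem_rows, , drop = FALSE], v0, -bis)
    out$x[stem_rows] <- xyz[, 1]; out$y[stem_rows] <- xyz[, 2]
    out$z[stem_rows] <- xyz[, 3]
  }
  structure_model(out, id = paste0(template$id, "_posed"))
}

#' Divalent binding feasibility
#'
#' Tests whether both arms of a two-arm antibody can simultaneously occupy
#' two Fab binding frames.  The antibody is modeled as two rigid arms of
#' length `L` pivoting about a common hinge: a hinge position must exist at
#' distance `L` from both anchors, with each arm direction within
#' `elbow_max` degrees of the frame's Fab axis (the binding orientation is
#' rigid up to elbow flexibility), the inter-arm angle inside the hinge
#' sweep range, and no steric clash between the posed antibody and the
#' receptor bodies.  Hinge positions are sampled on the locus circle;
#' arm pseudo-atoms within `paratope_clearance` of an anchor are excluded
#' from the clash test (the paratope region is *supposed* to touch the
#' antigen).
#'
#' @param frames list of two `fab_frame`s.
#' @param igg_template two-arm template from [make_igg_dumbbell()] (or any
#'   model with `HNG`/`TIP` marker atoms).
#' @param obstacles list of [structure_model()]s (the receptor pentamer(s)).
#' @param mode `"intra_pentamer"` or `"inter_pentamer"` (label recorded in
#'   the result; tilt angle is computed in inter mode when two obstacles are
#'   given).
#' @param hinge_sweep numeric vector of allowed inter-arm hinge angles,
#'   degrees.
#' @param elbow_max maximum deviation of an arm from its frame axis,
#'   degrees.
#' @param n_hinge_samples hinge positions sampled on the locus circle.
#' @param paratope_clearance arm length near the tip excluded from clash
#'   testing, Angstrom.
#' @param params [contact_params()] (clash threshold).
#' @return `feasibility_result`: list with `mode`, `feasible`,
#'   `anchor_separation`, `required_span` (min/max tip separation over the
#'   sweep), `reason`, `clash_summary`, `tilt_angle` (degrees, inter mode),
#'   `hinge_point` (best sampled hinge position or NULL), `posed_igg`.
#' @export
divalent_feasibility <- function(frames, igg_template, obstacles = list(),
                                 mode = c("intra_pentamer", "inter_pentamer"),
                                 hinge_sweep = seq(20, 160, by = 10),
                                 elbow_max = 20, n_hinge_samples = 36,
                                 paratope_clearance = 10,
                                 params = contact_params()) {
  mode <- match.arg(mode)
  if (!length(hinge_sweep)) stopf("hinge sweep grid is empty")
  if (length(frames) != 2L) stopf("exactly two Fab frames are required")
  a <- igg_template$atom
  hng <- a[a$name == "HNG", , drop = FALSE]
  tips <- a[a$name == "TIP", , drop = FALSE]
  if (nrow(hng) != 1L || nrow(tips) < 2L)
    stopf("template must carry one HNG and two TIP marker atoms")
  h0 <- as.numeric(unlist(hng[1, c("x", "y", "z")]))
  L <- mean(sqrt(rowSums(sweep(coords(tips), 2, h0)^2)))
  span <- sort(2 * L * sin(deg2rad(range(hinge_sweep)) / 2))
  a1 <- frames[[1]]$anchor; a2 <- frames[[2]]$anchor
  s <- vnorm(a2 - a1)
  tilt <- NA_real_
  if (length(obstacles) == 2L) {
    ang <- vec_angle(pentamer_axis(obstacles[[1]]),
                     pentamer_axis(obstacles[[2]]))
    tilt <- min(ang, 180 - ang)
  }
  res <- function(feasible, reason, clash = NULL, hinge = NULL, posed = NULL) {
    structure(list(mode = mode, feasible = feasible, anchor_separation = s,
                   required_span = span, reason = reason,
                   clash_summary = clash, tilt_angle = tilt,
                   hinge_point = hinge, posed_igg = posed),
              class = "feasibility_result")
  }
  if (s < span[1] - 1e-9 || s > span[2] + 1e-9)
    return(res(FALSE, sprintf(
      "anchor separation %.1f A outside achievable tip span [%.1f, %.1f] A",
      s, span[1], span[2])))
  # hinge locus: circle at distance L from both anchors
  u <- unit(a2 - a1)
  half <- s / 2
  rc2 <- L^2 - half^2
  if (rc2 < 0) return(res(FALSE, "anchors farther apart than twice the arm length"))
  rc <- sqrt(rc2)
  m <- (a1 + a2) / 2
  e1 <- unit(if (abs(u[1]) < 0.9) cross3(u, c(1, 0, 0)) else cross3(u, c(0, 1, 0)))
  e2 <- unit(cross3(u, e1))
  best_fail <- "no sampled hinge position satisfies the arm-direction constraint"
  for (tt in seq(0, 2 * pi, length.out = n_hinge_samples + 1)[-(n_hinge_samples + 1)]) {
    H <- m + rc * (cos(tt) * e1 + sin(tt) * e2)
    d1 <- unit(a1 - H); d2 <- unit(a2 - H)   # hinge-to-anchor directions
    dev1 <- vec_angle(-d1, frames[[1]]$axis)
    dev2 <- vec_angle(-d2, frames[[2]]$axis)
    if (dev1 > elbow_max || dev2 > elbow_max) next
    posed <- pose_igg(igg_template, H, d1, d2)
    # drop paratope-proximal arm atoms from the clash test
    keep <- rep(TRUE, nrow(posed$atom))
    pxyz <- coords(posed$atom)
    for (anch in list(a1, a2)) {
      dd <- sqrt(rowSums(sweep(pxyz, 2, anch)^2))
      keep <- keep & dd > paratope_clearance
    }
    clash_atoms <- posed$atom[keep, , drop = FALSE]
    n_cl <- 0L; worst <- NULL
    for (ob in obstacles) {
      cl <- detect_clashes(clash_atoms, ob, params)
      n_cl <- n_cl + cl$n_clashes
      if (is.null(worst) || cl$n_clashes > worst$n_clashes) worst <- cl
    }
    if (n_cl == 0L)
      return(res(TRUE, "zero-clash hinge configuration found", worst, H, posed))
    best_fail <- sprintf("all sampled hinge configurations clash (min %d)", n_cl)
  }
  res(FALSE, best_fail)
}

#' @export
print.feasibility_result <- function(x, ...) {
  cat(sprintf(paste0("<feasibility_result %s: %s>\n",
                     "  anchor separation %.1f A; achievable span [%.1f, %.1f] A\n",
                     "  %s\n"),
              x$mode, if (x$feasible) "FEASIBLE" else "infeasible",
              x$anchor_separation, x$required_span[1], x$required_span[2],
              x$reason))
  if (!is.na(x$tilt_angle))
    cat(sprintf("  pentamer axis tilt: %.1f deg\n", x$tilt_angle))
  invisible(x)
}

#' Pentamer tilt angle of a feasible cross-linking model
#'
#' Angle between the two pentamer five-fold axes; 0 degrees means
#' co-parallel (both receptors can sit upright on a flat membrane).
#'
#' @param inter_result `feasibility_result` from an inter-pentamer run, or a
#'   list of two pentamer [structure_model()]s.
#' @return angle in degrees, folded to \\[0, 90\\].
#' @export
tilt_analysis <- function(inter_result) {
  if (inherits(inter_result, "feasibility_result")) {
    if (is.na(inter_result$tilt_angle))
      stopf("no inter-pentamer tilt available (need two receptor bodies)")
    if (!inter_result$feasible)
      stopf("no feasible cross-linking model to analyze")
    return(inter_result$tilt_angle)
  }
  if (is.list(inter_result) && length(inter_result) == 2L) {
    ang <- vec_angle(pentamer_axis(inter_result[[1]]),
                     pentamer_axis(inter_result[[2]]))
    return(min(ang, 180 - ang))
  }
  stopf("expected a feasibility_result or a list of two pentamers")
}
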