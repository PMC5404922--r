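# Synthetic structure generators.  Everything the test-suite and the worked
# examples need is built here from idealized residue templates, so no
# coordinate download is ever required.  All generators are deterministic.

# ---- residue templates ------------------------------------------------------
# Idealized heavy-atom geometries in a local frame: CA at the origin, side
# chain extending along +x.  Bond lengths/angles are near-ideal; aromatic
# rings are regular polygons.  These templates exist to realize designed
# interaction geometries, not to be stereochemically perfect.

.template_cache <- new.env(parent = emptyenv())

build_res_templates <- function() {
  bb <- function() rbind(N = c(-0.57, 1.35, 0), CA = c(0, 0, 0),
                         C = c(-0.57, -1.35, 0), O = c(-1.47, -2.19, 0))
  hexagon <- function(center, r = 1.39, start_deg = 180) {
    ang <- deg2rad(start_deg + c(0, 120, 240, 60, 300, 0))
    # CG CD1 CD2 CE1 CE2 CZ ordering below
    rbind(CG = center + r * c(cos(deg2rad(start_deg)), sin(deg2rad(start_deg)), 0),
          CD1 = center + r * c(cos(deg2rad(start_deg - 60)), sin(deg2rad(start_deg - 60)), 0),
          CD2 = center + r * c(cos(deg2rad(start_deg + 60)), sin(deg2rad(start_deg + 60)), 0),
          CE1 = center + r * c(cos(deg2rad(start_deg - 120)), sin(deg2rad(start_deg - 120)), 0),
          CE2 = center + r * c(cos(deg2rad(start_deg + 120)), sin(deg2rad(start_deg + 120)), 0),
          CZ = center + r * c(cos(deg2rad(start_deg + 180)), sin(deg2rad(start_deg + 180)), 0))
  }
  pentagon5 <- function(center, names, r = 1.17, start_deg = 180) {
    offs <- c(0, -72, 72, -144, 144)
    m <- t(vapply(offs, function(o)
      center + r * c(cos(deg2rad(start_deg + o)), sin(deg2rad(start_deg + o)), 0),
      numeric(3)))
    rownames(m) <- names
    m
  }
  tpl <- list()
  tpl$GLY <- bb()
  tpl$ALA <- rbind(bb(), CB = c(1.34, 0, 0.75))
  tpl$SER <- rbind(tpl$ALA, OG = c(2.64, 0, 0))
  tpl$THR <- rbind(tpl$ALA, OG1 = c(2.64, 0, 0), CG2 = c(1.9, 1.4, 1.4))
  tpl$VAL <- rbind(tpl$ALA, CG1 = c(2.64, 0, 0), CG2 = c(1.9, 1.4, 1.4))
  tpl$ILE <- rbind(tpl$VAL, CD1 = c(3.94, 0, 0.75))
  tpl$ASP <- rbind(tpl$ALA, CG = c(2.64, 0, 0), OD1 = c(3.40, 1.00, 0),
                   OD2 = c(3.40, -1.00, 0))
  tpl$ASN <- rbind(tpl$ALA, CG = c(2.64, 0, 0), OD1 = c(3.40, 1.00, 0),
                   ND2 = c(3.40, -1.00, 0))
  tpl$GLU <- rbind(tpl$ALA, CG = c(2.64, 0, 0), CD = c(3.94, 0, 0.75),
                   OE1 = c(4.70, 1.00, 0.75), OE2 = c(4.70, -1.00, 0.75))
  tpl$GLN <- rbind(tpl$ALA, CG = c(2.64, 0, 0), CD = c(3.94, 0, 0.75),
                   OE1 = c(4.70, 1.00, 0.75), NE2 = c(4.70, -1.00, 0.75))
  tpl$LYS <- rbind(tpl$ALA, CG = c(2.64, 0, 0), CD = c(3.94, 0, 0.75),
                   CE = c(5.24, 0, 0), NZ = c(6.54, 0, 0.75))
  tpl$ARG <- rbind(tpl$ALA, CG = c(2.64, 0, 0), CD = c(3.94, 0, 0.75),
                   NE = c(5.18, 0, 0.30), CZ = c(6.50, 0, 0.30),
                   NH1 = c(7.16, 1.15, 0.30), NH2 = c(7.16, -1.15, 0.30))
  tpl$HIS <- rbind(tpl$ALA, pentagon5(c(3.81, 0, 0),
                                      c("CG", "ND1", "CD2", "CE1", "NE2")))
  ring6 <- hexagon(c(4.03, 0, 0))
  tpl$PHE <- rbind(tpl$ALA, ring6)
  tpl$TYR <- rbind(tpl$ALA, ring6, OH = c(6.78, 0, 0))
  # tryptophan: pyrrole pentagon fused to a hexagon at CD2-CE2
  pent <- pentagon5(c(3.81, 0, 0), c("CG", "CD1", "CD2", "NE1", "CE2"))
  cd2 <- pent["CD2", ]; ce2 <- pent["CE2", ]
  mid <- (cd2 + ce2) / 2
  v <- unit(ce2 - cd2)
  perp <- c(v[2], -v[1], 0)
  if (sum(perp * (mid - c(3.81, 0, 0))) < 0) perp <- -perp
  hx_c <- mid + 1.195 * perp
  ang0 <- atan2(cd2[2] - hx_c[2], cd2[1] - hx_c[1])
  step <- atan2(ce2[2] - hx_c[2], ce2[1] - hx_c[1]) - ang0
  step <- ifelse(step > pi, step - 2 * pi, ifelse(step < -pi, step + 2 * pi, step))
  hexv <- function(k) hx_c + 1.38 * c(cos(ang0 - k * sign(step) * pi / 3),
                                      sin(ang0 - k * sign(step) * pi / 3), 0)
  tpl$TRP <- rbind(tpl$ALA, pent,
                   CE3 = hexv(1), CZ3 = hexv(2), CH2 = hexv(3), CZ2 = hexv(4))
  tpl
}

res_templates <- function() {
  if (is.null(.template_cache$tpl)) .template_cache$tpl <- build_res_templates()
  .template_cache$tpl
}

element_of_name <- function(nm) substr(nm, 1, 1)

#' Available synthetic residue templates
#' @return character vector of three-letter residue codes.
#' @export
residue_template_names <- function() names(res_templates())

res_template <- function(resname) {
  t <- res_templates()[[resname]]
  if (is.null(t)) stopf("no synthetic template for residue '%s'", resname)
  t
}

# Ring centroid of a template (aromatic residues), local frame.
template_ring_centroid <- function(resname) {
  t <- res_template(resname)
  members <- .ring_atoms[[resname]]
  colMeans(t[members, , drop = FALSE])
}

#' Place a template residue
#'
#' Positions an idealized residue so that one designated atom (or, with
#' `key = "RING"`, the aromatic ring centroid) lands at `at` with the
#' CA-to-key direction aligned to `toward`; the residue body trails off
#' opposite `toward`.  `spin` rotates the residue about that axis.  This is
#' the primitive from which all designed interface fixtures are built.
#'
#' @param resname three-letter code (see [residue_template_names()]).
#' @param key atom name in the template, or `"RING"`.
#' @param at target position, Angstrom.
#' @param toward direction the side chain points (normalized internally).
#' @param chain,resnum identifiers for the placed residue.
#' @param spin rotation about the `toward` axis, degrees.
#' @return data.frame of atom rows (no serials; combine and pass to
#'   [structure_model()]).
#' @export
place_residue <- function(resname, key, at, toward, chain, resnum,
                          spin = 0) {
  t <- res_template(resname)
  kpos <- if (identical(key, "RING")) template_ring_centroid(resname)
  else {
    if (!key %in% rownames(t))
      stopf("template %s has no atom '%s'", resname, key)
    t[key, ]
  }
  v <- kpos - t["CA", ]
  if (vnorm(v) < 1e-9) v <- c(1, 0, 0)   # key is CA itself
  d <- unit(toward)
  R <- rotation_between(v, d)
  if (spin != 0) R <- rotation_about_axis(d, spin) %*% R
  xyz <- sweep(t, 2, kpos) %*% t(R)
  xyz <- sweep(xyz, 2, -as.numeric(at))
  data.frame(name = rownames(t), resname = resname, chain = chain,
             resnum = as.integer(resnum), icode = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = element_of_name(rownames(t)),
             stringsAsFactors = FALSE)
}

water_row <- function(at, chain, resnum) {
  data.frame(name = "O", resname = "HOH", chain = chain,
             resnum = as.integer(resnum), icode = "",
             x = at[1], y = at[2], z = at[3], element = "O",
             stringsAsFactors = FALSE)
}

assemble_atoms <- function(parts, id) {
  atoms <- do.call(rbind, parts)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$het <- atoms$resname == "HOH"
  structure_model(atoms, id = id)
}

# Fail when a designed geometry forces sub-bonded overlap between the two
# designed partners.
check_vdw_feasible <- function(model) {
  a <- model$atom
  ch <- unique(a$chain[a$resname != "HOH"])
  if (length(ch) < 2) return(invisible(TRUE))
  xa <- a[a$chain == ch[1] & a$resname != "HOH", , drop = FALSE]
  xb <- a[a$chain != ch[1] & a$resname != "HOH", , drop = FALSE]
  np <- neighbor_pairs(coords(xa), coords(xb), 1.5)
  if (nrow(np))
    stopf("designed geometry forces atoms closer than 1.5 A (min %.2f A)",
          min(np$distance))
  invisible(TRUE)
}

# ---- designed interaction fixtures -----------------------------------------

#' Designed two-chain interaction fixtures
#'
#' Builds a minimal two-chain complex (chain A antigen-like, chain B
#' antibody-like) realizing exactly one designed interaction type under the
#' default classification thresholds.  Geometry outside the qualifying range
#' of the requested type is refused.
#'
#' @param kind one of `"hbond"`, `"salt_bridge"`, `"cation_pi"`,
#'   `"pi_stack"`, `"water_bridge"`.
#' @param distance the designed key distance, Angstrom: donor-acceptor
#'   (hbond), charged-atom pair (salt bridge), cation to ring centroid
#'   (cation-pi), centroid-centroid (pi-stack), or each water leg
#'   (water bridge).
#' @return [structure_model()] with chains `A` and `B` (plus a `W` water
#'   chain for the bridge fixture).
#' @export
make_interaction_fixture <- function(kind = c("hbond", "salt_bridge",
                                              "cation_pi", "pi_stack",
                                              "water_bridge"),
                                     distance = NULL) {
  kind <- match.arg(kind)
  p <- contact_params()
  limits <- c(hbond = p$hbond_da_max, salt_bridge = p$salt_bridge_max,
              cation_pi = p$cation_pi_max, pi_stack = p$pi_stack_max,
              water_bridge = p$hbond_da_max)
  defaults <- c(hbond = 2.9, salt_bridge = 2.9, cation_pi = 4.0,
                pi_stack = 3.8, water_bridge = 2.8)
  d <- distance %||% unname(defaults[kind])
  if (d > limits[kind])
    stopf("%s requested at %.2f A, outside the qualifying range (<= %.2f A)",
          kind, d, limits[kind])
  if (d < 2.2 && kind != "pi_stack" && kind != "cation_pi")
    stopf("designed distance %.2f A would violate van der Waals feasibility", d)
  parts <- switch(kind,
    hbond = list(
      place_residue("ASN", "ND2", c(0, 0, 0), c(1, 0, 0), "A", 1, spin = 0),
      place_residue("ALA", "O", c(d, 0, 0), c(-1, 0, 0), "B", 1, spin = 180)),
    salt_bridge = list(
      place_residue("ASP", "OD1", c(0, 0, 0), c(1, 0, 0), "A", 1),
      place_residue("ARG", "NH1", c(d, 0, 0), c(-1, 0, 0), "B", 1, spin = 180)),
    cation_pi = list(
      place_residue("TRP", "RING", c(0, 0, 0), c(-1, 0, 0), "B", 1),
      place_residue("ARG", "NH1", c(0, 0, d), c(0, 0, -1), "A", 1)),
    pi_stack = list(
      place_residue("TRP", "RING", c(0, 0, 0), c(-1, 0, 0), "B", 1),
      place_residue("TYR", "RING", c(0, 0, d), c(1, 0, 0), "A", 1)),
    water_bridge = list(
      place_residue("ASP", "OD1", c(0, 0, 0), c(1, 0, 0), "A", 1),
      water_row(c(d, 0, 0), "W", 1),
      place_residue("SER", "OG", c(2 * d, 0, 0), c(-1, 0, 0), "B", 1,
                    spin = 180)))
  m <- assemble_atoms(parts, id = paste0("fixture_", kind))
  check_vdw_feasible(m)
  m
}

# ---- analytic SASA bodies ---------------------------------------------------

#' Single-atom sphere fixture
#' @param radius van der Waals radius to assign, Angstrom.
#' @param element element symbol (controls the default radius when `radius`
#'   is NULL).
#' @return one-atom [structure_model()].
#' @export
make_sphere <- function(radius = NULL, element = "C") {
  atoms <- data.frame(serial = 1L, name = element, resname = "ALA",
                      chain = "A", resnum = 1L, icode = "",
                      x = 0, y = 0, z = 0, element = element, het = FALSE,
                      stringsAsFactors = FALSE)
  m <- structure_model(atoms, id = "sphere")
  if (!is.null(radius)) m$atom$radius <- radius
  m
}

#' Two-sphere fixture at a set separation
#' @param separation center-center distance, Angstrom.
#' @param radius per-atom radius, Angstrom.
#' @return two-atom [structure_model()] (chains A and B).
#' @export
make_sphere_pair <- function(separation, radius = 1.7) {
  atoms <- data.frame(serial = 1:2, name = "C", resname = "ALA",
                      chain = c("A", "B"), resnum = c(1L, 1L), icode = "",
                      x = c(0, separation), y = 0, z = 0, element = "C",
                      het = FALSE, stringsAsFactors = FALSE)
  m <- structure_model(atoms, id = "sphere_pair")
  m$atom$radius <- radius
  m
}

# ---- helices and two-body complexes ----------------------------------------

#' Idealized poly-alanine helix
#'
#' Backbone + CB alpha-helix (rise 1.5 A, 100 degrees per residue), axis
#' along z, C-alpha radius 2.3 A.
#'
#' @param n_res number of residues.
#' @param chain chain id.
#' @param start_resnum first residue number.
#' @return [structure_model()].
#' @export
make_helix <- function(n_res = 12, chain = "A", start_resnum = 1L) {
  rows <- list()
  for (i in seq_len(n_res)) {
    th <- deg2rad(100 * (i - 1))
    z0 <- 1.5 * (i - 1)
    at <- function(nm, r, dth, dz)
      data.frame(name = nm, resname = "ALA", chain = chain,
                 resnum = start_resnum + i - 1L, icode = "",
                 x = r * cos(th + deg2rad(dth)), y = r * sin(th + deg2rad(dth)),
                 z = z0 + dz, element = substr(nm, 1, 1),
                 stringsAsFactors = FALSE)
    rows[[i]] <- rbind(at("N", 1.6, -28, -0.9), at("CA", 2.3, 0, 0),
                       at("C", 1.7, 26, 0.45), at("O", 2.0, 23, 1.4),
                       at("CB", 3.3, -5, -0.3))
  }
  assemble_atoms(rows, id = "helix")
}

#' Two-helix toy complex
#'
#' Two parallel poly-alanine helices (chains A, B) with axes separated by
#' `separation` Angstrom — a small designed two-body interface for surface
#' and contact tests.
#'
#' @param separation axis-axis distance, Angstrom.
#' @param n_res residues per helix.
#' @return [structure_model()].
#' @export
make_two_body_complex <- function(separation = 9, n_res = 12) {
  h1 <- make_helix(n_res, chain = "A")
  h2 <- make_helix(n_res, chain = "B")
  h2$atom$x <- h2$atom$x + separation
  m <- merge_models(h1, h2, id = "two_body")
  m
}

# ---- toy pentamers ----------------------------------------------------------

#' Toy C5-symmetric pentamer
#'
#' Rotational copies of a mini-domain about the z axis (chains A-E), the
#' geometry of a receptor extracellular-domain ring at toy scale.  The
#' symmetry axis is z by construction.
#'
#' @param ring_radius distance from the symmetry axis to each subunit
#'   centroid, Angstrom.
#' @param subunit optional [structure_model()] used as the subunit
#'   (centered internally); default: a 12-residue poly-alanine helix.
#' @param n_subunits number of subunits (5 for a pentamer).
#' @return [structure_model()] with chains `A` ... following ring order.
#' @export
make_toy_pentamer <- function(ring_radius = 40, subunit = NULL,
                              n_subunits = 5L) {
  subunit <- subunit %||% make_helix(12)
  sub_atoms <- subunit$atom
  cent <- colMeans(coords(sub_atoms))
  parts <- list()
  for (k in seq_len(n_subunits)) {
    R <- rotation_about_axis(c(0, 0, 1), 360 * (k - 1) / n_subunits)
    xyz <- sweep(coords(sub_atoms), 2, cent)
    xyz <- sweep(xyz, 2, -c(ring_radius, 0, 0)) %*% t(R)
    p <- sub_atoms
    p$x <- xyz[, 1]; p$y <- xyz[, 2]; p$z <- xyz[, 3]
    p$chain <- LETTERS[k]
    parts[[k]] <- p
  }
  m <- assemble_atoms(parts, id = "toy_pentamer")
  # adjacent subunits must not interpenetrate at the requested radius
  for (k in seq_len(n_subunits - 1L)) {
    cl <- detect_clashes(m$atom[m$atom$chain == LETTERS[k], , drop = FALSE],
                         m$atom[m$atom$chain == LETTERS[k + 1L], , drop = FALSE])
    if (cl$n_clashes > 0)
      stopf(paste0("subunits clash at ring radius %.1f A; ",
                   "increase the radius (e.g. >= %.1f A)"),
            ring_radius, ring_radius + cl$max_overlap * 2)
  }
  m
}

# ---- two-arm antibody dumbbell ---------------------------------------------

#' Two-arm antibody dumbbell template
#'
#' Three rigid pseudo-domains: two arms (chains `I`, `J`) of `arm_length`
#' Angstrom meeting at a hinge marker atom (`HNG`, chain `F`) with the
#' given inter-arm angle, plus a stem (chain `F`) along the bisector.  Each
#' arm carries a `TIP` paratope marker at its far end.  Tip-tip separation
#' is the closed form `2 * arm_length * sin(hinge_angle / 2)`.
#'
#' @param arm_length hinge-to-paratope distance, Angstrom.
#' @param hinge_angle inter-arm angle, degrees.
#' @param stem_length Fc stem length, Angstrom.
#' @param bead_spacing spacing of pseudo-atoms along each domain, Angstrom.
#' @return [structure_model()]; attribute `arm_length` records the arm
#'   length.
#' @export
make_igg_dumbbell <- function(arm_length = 75, hinge_angle = 120,
                              stem_length = 40, bead_spacing = 5) {
  if (arm_length <= 0) stopf("arm_length must be positive")
  half <- deg2rad(hinge_angle) / 2
  u1 <- c(sin(half), cos(half), 0)
  u2 <- c(-sin(half), cos(half), 0)
  beads <- function(dir, len, chain, tip_name) {
    # rigid zigzag around the arm axis so each domain has true 3D shape
    # (a straight bead string would leave superposition onto it degenerate)
    p1 <- if (abs(dir[3]) < 0.9) unit(cross3(dir, c(0, 0, 1))) else
      unit(cross3(dir, c(1, 0, 0)))
    p2 <- cross3(dir, p1)
    tseq <- seq(bead_spacing, len - 1e-9, by = bead_spacing)
    rows <- lapply(seq_along(tseq), function(i) {
      w <- 1.2 * c(cos(2.2 * i), sin(2.2 * i))
      pos <- dir * tseq[i] + p1 * w[1] + p2 * w[2]
      data.frame(name = "CA", resname = "ALA", chain = chain,
                 resnum = i, icode = "", x = pos[1], y = pos[2], z = pos[3],
                 element = "C", stringsAsFactors = FALSE)
    })
    tip <- data.frame(name = tip_name, resname = "PTP", chain = chain,
                      resnum = length(tseq) + 1L, icode = "",
                      x = dir[1] * len, y = dir[2] * len, z = dir[3] * len,
                      element = "C", stringsAsFactors = FALSE)
    rbind(do.call(rbind, rows), tip)
  }
  hinge <- data.frame(name = "HNG", resname = "HNG", chain = "F", resnum = 0L,
                      icode = "", x = 0, y = 0, z = 0, element = "C",
                      stringsAsFactors = FALSE)
  stem <- beads(c(0, -1, 0), stem_length, "F", "FCC")
  m <- assemble_atoms(list(hinge, beads(u1, arm_length, "I", "TIP"),
                           beads(u2, arm_length, "J", "TIP"), stem),
                      id = "igg_dumbbell")
  attr(m, "arm_length") <- arm_length
  attr(m, "hinge_angle") <- hinge_angle
  m
}

#' Analytic tip separation of the dumbbell
#' @param arm_length arm length, Angstrom.
#' @param hinge_angle inter-arm angle, degrees.
#' @return tip-tip distance, Angstrom.
#' @export
dumbbell_span <- function(arm_length, hinge_angle) {
  2 * arm_length * sin(deg2rad(hinge_angle) / 2)
}

# ---- the synthetic epitope complex -----------------------------------------

#' Synthetic antibody/receptor epitope complex (stand-in)
#'
#' A designed two-body complex emulating the geometry of the Fab/receptor
#' interface described for the myasthenia-gravis reference antibody: a
#' receptor-like chain `R` carrying the N-terminal-helix residues (His3,
#' Arg6, Lys10) and MIR-loop residues (Asn68, Asp71, Tyr72) in author
#' numbering, facing antibody heavy (`H`) and light (`L`) chains.  The
#' designed interaction network reproduces the published chemistry:
#' Asp71 salt-bridged to Arg50 (H) and hydrogen-bonded to Tyr95 (L); the
#' Asn68 side-chain amide making three hydrogen bonds to the light chain
#' (Tyr91 main-chain carbonyl, Gly94 main-chain amide and carbonyl); Arg6
#' cation-pi stacked on Trp52 (H) and hydrogen-bonded to Asp54 (H); Lys10
#' salt-bridged to Asp53 (H); His3 water-bridged to the heavy chain.  Each
#' of the four hotspot residues contacts five distinct partner residues;
#' every other receptor residue contacts fewer.  This is a synthetic
#' stand-in built from the published residue identities and interaction
#' types, not deposited coordinates.
#'
#' @return [structure_model()] with chains `R`, `H`, `L` and bridging
#'   waters (chain `W`).
#' @export
make_epitope_complex <- function() {
  parts <- list()
  add <- function(p) parts[[length(parts) + 1L]] <<- p
  up <- c(0, 0, 1)

  ## --- site 1: Arg6 / Trp52 / Asp54 (N-terminal helix vs heavy chain) ------
  add(place_residue("ARG", "CZ", c(0, 0, 0), up, "R", 6, spin = 0))
  arg6 <- parts[[length(parts)]]
  nh1 <- as.numeric(arg6[arg6$name == "NH1", c("x", "y", "z")])
  cd6 <- as.numeric(arg6[arg6$name == "CD", c("x", "y", "z")])
  # Trp52 ring face-on 4.0 A above the guanidinium center, body trailing -x
  add(place_residue("TRP", "RING", c(0, 0, 4.0), c(1, 0, 0), "H", 52))
  # Asp54 accepting from NH1, placed up-and-out from the guanidinium
  d54_dir <- unit(c(0, 0.8, 0.6))
  add(place_residue("ASP", "OD1", nh1 + 2.9 * d54_dir, -d54_dir, "H", 54,
                    spin = 90))
  # van der Waals shell completing five distinct partners for Arg6
  add(place_residue("VAL", "CG1", cd6 + 4.0 * unit(c(0.9, -0.6, 0.6)),
                    -unit(c(0.9, -0.6, 0.9)), "H", 58))
  add(place_residue("ALA", "CB", nh1 + 3.6 * unit(c(0.9, 0.3, 0.5)),
                    -unit(c(0.9, 0.3, 0.9)), "H", 56))
  add(place_residue("ALA", "CB", nh1 + 3.6 * unit(c(-0.9, 0.4, 0.5)),
                    -unit(c(-0.9, 0.4, 0.9)), "H", 57))

  ## --- site 2: Lys10 / Asp53 (N-terminal helix vs heavy chain) -------------
  s2 <- c(14, 0, 0)
  add(place_residue("LYS", "NZ", s2, up, "R", 10, spin = 0))
  add(place_residue("ASP", "OD1", s2 + c(0, 0, 2.85), -up, "H", 53,
                    spin = 0))
  add(place_residue("ALA", "CB", s2 + c(3.9, 0, 0.8), -unit(c(0.9, 0, 0.8)),
                    "H", 62))
  add(place_residue("ALA", "CB", s2 + c(-3.9, 0.5, 0.8),
                    -unit(c(-0.9, 0.1, 0.8)), "H", 63))
  add(place_residue("VAL", "CG1", s2 + c(0, 3.9, 0.8), -unit(c(0, 0.9, 0.8)),
                    "H", 64))
  add(place_residue("ALA", "CB", s2 + c(0, -3.9, 0.8), -unit(c(0, -0.9, 0.8)),
                    "H", 66))

  ## --- site 3: Asn68 vs light chain ----------------------------------------
  s3 <- c(0, 14, 0)
  add(place_residue("ASN", "ND2", s3, up, "R", 68, spin = 0))
  asn68 <- parts[[length(parts)]]
  nd2 <- as.numeric(asn68[asn68$name == "ND2", c("x", "y", "z")])
  od1 <- as.numeric(asn68[asn68$name == "OD1", c("x", "y", "z")])
  # Tyr91 main-chain carbonyl accepting from ND2
  y91_dir <- unit(c(-0.55, 0, 0.84))
  add(place_residue("TYR", "O", nd2 + 2.9 * y91_dir, -y91_dir, "L", 91,
                    spin = 200))
  # Gly94: carbonyl accepts from ND2 while its amide donates to OD1; the
  # placement search below picks a deterministic spin satisfying both legs
  g94 <- place_gly94(asn68)
  add(g94)
  add(place_residue("ILE", "CD1", nd2 + 4.0 * unit(c(0.9, -0.5, 0.5)),
                    -unit(c(0.9, -0.5, 0.9)), "L", 92))
  add(place_residue("ALA", "CB", nd2 + 3.6 * unit(c(-0.2, -0.95, 0.45)),
                    -unit(c(-0.2, -0.95, 0.9)), "L", 93))
  add(place_residue("ALA", "CB", nd2 + 3.6 * unit(c(-0.95, -0.5, 0.5)),
                    -unit(c(-0.95, -0.5, 0.9)), "L", 90))

  ## --- site 4: Asp71 / Arg50 (H) / Tyr95 (L) -------------------------------
  s4 <- c(14, 14, 0)
  add(place_residue("ASP", "OD1", s4, up, "R", 71, spin = 0))
  asp71 <- parts[[length(parts)]]
  od1_71 <- as.numeric(asp71[asp71$name == "OD1", c("x", "y", "z")])
  od2_71 <- as.numeric(asp71[asp71$name == "OD2", c("x", "y", "z")])
  add(place_residue("ARG", "NH1", od1_71 + c(0, 0, 2.85), -up, "H", 50,
                    spin = 0))
  y95_dir <- unit(c(0.62, 0, 0.78))
  add(place_residue("TYR", "OH", od2_71 + 2.7 * y95_dir, -y95_dir, "L", 95,
                    spin = 180))
  add(place_residue("ALA", "CB", od1_71 + 4.0 * unit(c(0, 0.9, 0.45)),
                    -unit(c(0, 0.9, 0.9)), "H", 103))
  add(place_residue("ASN", "CB", od1_71 + 4.0 * unit(c(-0.9, 0, 0.45)),
                    -unit(c(-0.9, 0, 0.9)), "H", 105))
  add(place_residue("ALA", "CB", od1_71 + 4.0 * unit(c(0, -0.9, 0.45)),
                    -unit(c(0, -0.9, 0.9)), "H", 104))

  ## --- peripheral receptor residues ----------------------------------------
  # His3 water-bridged to a heavy-chain carbonyl (no direct contact)
  h3_at <- c(-8, -2, 0)
  add(place_residue("HIS", "NE2", h3_at, up, "R", 3, spin = 0))
  add(water_row(h3_at + c(0, 0, 2.8), "W", 201))
  g61_dir <- up
  add(place_residue("ALA", "O", h3_at + c(0, 0, 5.6), -g61_dir, "H", 61,
                    spin = 0))
  # Tyr72 with a single van der Waals partner (below hotspot threshold)
  y72_at <- c(7, 17, -0.5)
  add(place_residue("TYR", "OH", y72_at, up, "R", 72, spin = 0))
  add(place_residue("VAL", "CG1", y72_at + c(0, 0, 3.9), -up, "H", 106))
  # non-contacting receptor residues filling out the two epitope segments
  add(place_residue("GLY", "CA", c(-6, -8, -6), up, "R", 1))
  add(place_residue("GLY", "CA", c(-2, -9, -6), up, "R", 2))
  add(place_residue("GLY", "CA", c(18, -6, -6), up, "R", 13))
  add(place_residue("GLY", "CA", c(22, -4, -6), up, "R", 14))
  add(place_residue("GLY", "CA", c(7, 20, -6), up, "R", 70))

  m <- assemble_atoms(parts, id = "synthetic_epitope_complex")
  m
}

# Deterministic placement search for the bifunctional glycine at the Asn68
# site: its carbonyl O accepts from ND2 (anchored 2.9 A along the site
# normal) while its amide N donates to OD1.  The body direction and spin are
# scanned on a fixed grid; the first orientation satisfying both
# hydrogen-bond geometries with clean van der Waals clearance is used.
place_gly94 <- function(asn) {
  p <- contact_params()
  gxyz <- function(df, nm) as.numeric(df[df$name == nm, c("x", "y", "z")])
  nd2 <- gxyz(asn, "ND2"); od1 <- gxyz(asn, "OD1"); cg <- gxyz(asn, "CG")
  up <- c(0, 0, 1)
  grid <- expand.grid(th = seq(0, 180, by = 15), ph = seq(0, 345, by = 15))
  for (g in seq_len(nrow(grid))) {
    t1 <- c(sin(deg2rad(grid$th[g])) * cos(deg2rad(grid$ph[g])),
            sin(deg2rad(grid$th[g])) * sin(deg2rad(grid$ph[g])),
            cos(deg2rad(grid$th[g])))
    for (spin in seq(0, 355, by = 5)) {
      gl <- place_residue("GLY", "O", nd2 + 2.9 * up, t1, "L", 94, spin = spin)
      gx <- as.matrix(gl[, c("x", "y", "z")])
      rownames(gx) <- gl$name
      dno <- vnorm(gx["N", ] - od1)
      if (dno > 3.4 || dno < 2.6) next
      if (vec_angle(gx["CA", ] - gx["N", ], od1 - gx["N", ]) < 95) next
      if (vec_angle(cg - nd2, gx["O", ] - nd2) < 95) next
      clear <- TRUE
      for (nm in rownames(gx)) for (am in c("ND2", "OD1", "CG", "CB")) {
        if ((nm == "N" && am == "OD1") || (nm == "O" && am == "ND2")) next
        if (vnorm(gx[nm, ] - gxyz(asn, am)) < 2.5) clear <- FALSE
      }
      if (clear) return(gl)
    }
  }
  stopf("no glycine placement satisfies the designed double hydrogen bond")
}

# ---- epitope sequence panel -------------------------------------------------

#' Synthetic epitope-region sequence panel
#'
#' An ungapped alignment covering the two epitope segments — N-terminal
#' helix (positions 1-14) and the MIR window (positions 62-79) — for the
#' receptor subunit panel used in cross-reactivity analysis.  Only the
#' positions with published identities differ between rows (human alpha-1
#' reference; mammalian/avian orthologs conserved; Torpedo with Asn at
#' position 10; Xenopus alpha-1b with N68D and D71K; human alpha-9 with the
#' four binding-position replacements); all remaining filler positions are
#' shared synthetic sequence, identical across rows, chosen to match the
#' synthetic epitope complex where it has residues.
#'
#' @return bio3d-style `fasta` object (matrix `ali`, `id`) with attribute
#'   `ref_numbering` giving the receptor residue number of each column.
#' @export
make_epitope_alignment <- function() {
  nterm <- c("G", "G", "H", "E", "T", "R", "L", "V", "A", "K", "L", "A",
             "G", "G")                                   # positions 1-14
  mir <- c("A", "Y", "N", "A", "A", "T", "N", "P", "G", "D", "Y", "G",
           "G", "A", "K", "A", "A", "A")                 # positions 62-79
  human <- c(nterm, mir)
  pos <- c(1:14, 62:79)
  set_at <- function(seqv, posnum, aa) { seqv[match(posnum, pos)] <- aa; seqv }
  rows <- list(
    human_a1 = human,
    bovine_a1 = human,
    rat_a1 = set_at(human, 5, "S"),        # filler position, zero weight
    mouse_a1 = human,
    chicken_a1 = set_at(human, 12, "S"),   # filler position, zero weight
    torpedo_a1 = set_at(human, 10, "N"),
    xenopus_a1b = set_at(set_at(human, 68, "D"), 71, "K"),
    human_a9 = set_at(set_at(set_at(set_at(human, 6, "K"), 10, "D"),
                             68, "D"), 71, "Q"))
  ali <- do.call(rbind, rows)
  colnames(ali) <- NULL
  aln <- list(id = names(rows), ali = ali, call = match.call())
  class(aln) <- "fasta"
  attr(aln, "ref_numbering") <- pos
  aln
}

#' Write an alignment to FASTA
#' @param alignment bio3d `fasta` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_alignment <- function(alignment, path) {
  bio3d::write.fasta(alignment, file = path)
  invisible(path)
}
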