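# Interface contact mapping under the 4.5 A rule, chemical classification of
# interactions, per-residue contacting profiles and hotspot calling.

#' Contact and classification parameters
#'
#' The 4.5 A contact rule is the mapping criterion; the remaining thresholds
#' are standard structural-biology defaults for typing the chemistry of a
#' contact, all exposed here.
#'
#' @param cutoff contact distance cutoff, Angstrom.
#' @param hbond_da_max donor-acceptor heavy-atom maximum, Angstrom.
#' @param hbond_angle_min minimum antecedent-donor-acceptor angle, degrees.
#' @param salt_bridge_max charged-group heavy-atom maximum, Angstrom.
#' @param cation_pi_max cation to ring-centroid maximum, Angstrom.
#' @param cation_pi_axis_max maximum angle between ring normal and the
#'   centroid-to-cation vector, degrees.
#' @param pi_stack_max ring-centroid separation maximum, Angstrom.
#' @param clash_overlap van der Waals overlap beyond which two atoms of
#'   different rigid bodies count as clashing, Angstrom.
#' @param hotspot_min_partners minimum number of distinct partner residues
#'   for a residue to be called a hotspot.
#' @return `contact_params` object.
#' @export
contact_params <- function(cutoff = 4.5, hbond_da_max = 3.5,
                           hbond_angle_min = 90, salt_bridge_max = 4.0,
                           cation_pi_max = 6.0, cation_pi_axis_max = 45,
                           pi_stack_max = 5.5, clash_overlap = 0.4,
                           hotspot_min_partners = 5L) {
  d <- c(cutoff, hbond_da_max, salt_bridge_max, cation_pi_max, pi_stack_max)
  if (any(d <= 0)) stopf("all distance thresholds must be positive")
  if (hbond_angle_min <= 0 || hbond_angle_min > 180)
    stopf("hbond_angle_min must be in (0, 180]")
  structure(list(cutoff = cutoff, hbond_da_max = hbond_da_max,
                 hbond_angle_min = hbond_angle_min,
                 salt_bridge_max = salt_bridge_max,
                 cation_pi_max = cation_pi_max,
                 cation_pi_axis_max = cation_pi_axis_max,
                 pi_stack_max = pi_stack_max, clash_overlap = clash_overlap,
                 hotspot_min_partners = as.integer(hotspot_min_partners)),
            class = "contact_params")
}

# Heavy, non-water atoms of a group, as used for contact mapping.
contact_atoms <- function(model, group) {
  a <- group_atoms(model, group)
  a[a$resname != "HOH" & a$element != "H", , drop = FALSE]
}

#' Map interfacial contacts
#'
#' Every cross-group heavy-atom pair within `params$cutoff` (inclusive).
#' Waters are excluded from both sides (water bridges are detected
#' separately by [classify_interactions()]).  Output order is deterministic:
#' side-a chain, residue, atom serial, then side-b.
#'
#' @param model [structure_model()].
#' @param group_a,group_b disjoint `chain_group`s.
#' @param params [contact_params()].
#' @return data.frame of class `contact_set`; one row per qualifying atom
#'   pair with residue and atom identifiers of both sides plus `distance`.
#' @export
map_contacts <- function(model, group_a, group_b, params = contact_params()) {
  assert_disjoint(group_a, group_b)
  at_a <- contact_atoms(model, group_a)
  at_b <- contact_atoms(model, group_b)
  if (nrow(at_a) == 0L || nrow(at_b) == 0L)
    stopf("both partner groups must contain non-water atoms")
  np <- neighbor_pairs(coords(at_a), coords(at_b), params$cutoff)
  mk <- function(at, idx, side) {
    d <- data.frame(serial = at$serial[idx], chain = at$chain[idx],
                    resnum = at$resnum[idx], icode = at$icode[idx],
                    resname = at$resname[idx], atom = at$name[idx],
                    stringsAsFactors = FALSE)
    names(d) <- paste0(names(d), "_", side)
    d
  }
  con <- cbind(mk(at_a, np$i, "a"), mk(at_b, np$j, "b"),
               distance = np$distance)
  ord <- order(con$chain_a, con$resnum_a, con$icode_a, con$serial_a,
               con$chain_b, con$resnum_b, con$icode_b, con$serial_b)
  con <- con[ord, , drop = FALSE]
  rownames(con) <- NULL
  class(con) <- c("contact_set", "data.frame")
  attr(con, "group_a") <- group_a
  attr(con, "group_b") <- group_b
  attr(con, "params") <- params
  attr(con, "model_id") <- model$id
  con
}

# -- classification helpers ---------------------------------------------------

# angle antecedent-donor-acceptor at the donor; NA antecedent (water) passes.
hbond_angle_ok <- function(model_atoms, res_chain, res_num, res_icode,
                           resname, donor_atom, donor_xyz, acceptor_xyz,
                           min_angle) {
  ante <- donor_antecedent(resname, donor_atom)
  if (is.na(ante)) return(list(ok = TRUE, angle = NA_real_))
  sel <- model_atoms$chain == res_chain & model_atoms$resnum == res_num &
    model_atoms$icode == res_icode & model_atoms$name == ante
  if (!any(sel)) return(list(ok = FALSE, angle = NA_real_))
  axyz <- unlist(model_atoms[which(sel)[1], c("x", "y", "z")])
  ang <- vec_angle(axyz - donor_xyz, acceptor_xyz - donor_xyz)
  list(ok = ang >= min_angle, angle = ang)
}

atom_xyz <- function(atoms, idx) as.numeric(unlist(atoms[idx, c("x", "y", "z")]))

# rings of a group's aromatic residues; missing ring atoms skip with warning
group_rings <- function(model, atoms) {
  res <- unique(atoms[atoms$resname %in% aromatic_resnames(),
                      c("chain", "resnum", "icode", "resname")])
  out <- list()
  for (k in seq_len(nrow(res))) {
    rd <- tryCatch(ring_descriptor(model, res$chain[k], res$resnum[k],
                                   res$icode[k]),
                   error = function(e) {
                     warnf("skipping ring for %s %s:%s: %s", res$resname[k],
                           res$chain[k], res$resnum[k], conditionMessage(e))
                     NULL
                   })
    if (!is.null(rd)) out[[length(out) + 1L]] <- rd
  }
  out
}

interaction_row <- function(kind, ra, rb, water = NA_character_,
                            distance = NA_real_, angle = NA_real_,
                            tentative = FALSE) {
  data.frame(kind = kind,
             chain_a = ra$chain, resnum_a = ra$resnum, icode_a = ra$icode,
             resname_a = ra$resname, atom_a = ra$atom,
             chain_b = rb$chain, resnum_b = rb$resnum, icode_b = rb$icode,
             resname_b = rb$resname, atom_b = rb$atom,
             water = water, distance = distance, angle = angle,
             tentative = tentative, stringsAsFactors = FALSE)
}

side_ref <- function(con, row, side) {
  list(chain = con[[paste0("chain_", side)]][row],
       resnum = con[[paste0("resnum_", side)]][row],
       icode = con[[paste0("icode_", side)]][row],
       resname = con[[paste0("resname_", side)]][row],
       atom = con[[paste0("atom_", side)]][row])
}

#' Classify interface interactions
#'
#' Assigns chemical types to the mapped contacts: hydrogen bonds (heavy-atom
#' donor/acceptor distance plus antecedent angle; hydrogens are never
#' required), salt bridges (opposite formal-charge group heavy atoms),
#' cation-pi and pi-stacking (ring-descriptor geometry), and water-mediated
#' hydrogen bonds (a water hydrogen-bonded to both partners, searched over
#' the model's waters).  Residue pairs in contact that receive no specific
#' type fall back to van der Waals records, so every contacting residue pair
#' appears in at least one interaction record.
#'
#' @param model [structure_model()] the contacts came from.
#' @param contacts `contact_set` from [map_contacts()].
#' @param params [contact_params()].
#' @return data.frame of class `interaction_set`; columns `kind`
#'   (`hbond`, `water_mediated_hbond`, `salt_bridge`, `cation_pi`,
#'   `pi_stack`, `vdw`), residue/atom identifiers for both sides, `water`
#'   (water residue key for bridges), `distance`, `angle`, `tentative`.
#' @export
classify_interactions <- function(model, contacts, params = contact_params()) {
  group_a <- attr(contacts, "group_a"); group_b <- attr(contacts, "group_b")
  if (is.null(group_a) || is.null(group_b))
    stopf("contacts must come from map_contacts() (group attributes missing)")
  at_a <- contact_atoms(model, group_a)
  at_b <- contact_atoms(model, group_b)
  all_atoms <- model$atom
  recs <- list()
  add <- function(r) recs[[length(recs) + 1L]] <<- r

  con <- as.data.frame(contacts)
  n <- nrow(con)
  pair_key <- if (n) paste(res_key(con$chain_a, con$resnum_a, con$icode_a),
                           res_key(con$chain_b, con$resnum_b, con$icode_b),
                           sep = "|") else character()
  specific_pairs <- character()

  # hydrogen bonds and salt bridges from the contact list
  for (k in seq_len(n)) {
    ra <- side_ref(con, k, "a"); rb <- side_ref(con, k, "b")
    d <- con$distance[k]
    pxa <- c(0, 0, 0); pxb <- c(0, 0, 0)
    # salt bridge
    if (d <= params$salt_bridge_max) {
      an_a <- is_anion_atom(ra$resname, ra$atom)
      ct_a <- is_cation_atom(ra$resname, ra$atom)
      an_b <- is_anion_atom(rb$resname, rb$atom)
      ct_b <- is_cation_atom(rb$resname, rb$atom)
      if ((an_a && ct_b) || (ct_a && an_b)) {
        tent <- (ct_a && ra$resname == "HIS") || (ct_b && rb$resname == "HIS")
        add(interaction_row("salt_bridge", ra, rb, distance = d,
                            tentative = tent))
        specific_pairs <- c(specific_pairs, pair_key[k])
      }
    }
    # hydrogen bond, both donor orientations
    if (d <= params$hbond_da_max) {
      xa <- c(con$serial_a[k]); xb <- c(con$serial_b[k])
      xyz_a <- atom_xyz(all_atoms, match(con$serial_a[k], all_atoms$serial))
      xyz_b <- atom_xyz(all_atoms, match(con$serial_b[k], all_atoms$serial))
      hit <- FALSE
      if (is_donor_atom(ra$resname, ra$atom) &&
          is_acceptor_atom(rb$resname, rb$atom)) {
        chk <- hbond_angle_ok(all_atoms, ra$chain, ra$resnum, ra$icode,
                              ra$resname, ra$atom, xyz_a, xyz_b,
                              params$hbond_angle_min)
        if (chk$ok) {
          add(interaction_row("hbond", ra, rb, distance = d, angle = chk$angle))
          hit <- TRUE
        }
      }
      if (!hit && is_donor_atom(rb$resname, rb$atom) &&
          is_acceptor_atom(ra$resname, ra$atom)) {
        chk <- hbond_angle_ok(all_atoms, rb$chain, rb$resnum, rb$icode,
                              rb$resname, rb$atom, xyz_b, xyz_a,
                              params$hbond_angle_min)
        if (chk$ok) {
          add(interaction_row("hbond", ra, rb, distance = d, angle = chk$angle))
          hit <- TRUE
        }
      }
      if (hit) specific_pairs <- c(specific_pairs, pair_key[k])
    }
  }

  # cation-pi and pi-stacking via ring descriptors
  rings_a <- group_rings(model, at_a)
  rings_b <- group_rings(model, at_b)
  cation_rows <- function(atoms) {
    keep <- mapply(function(rn, nm) {
      tab <- .cation_pi_atoms[[rn]]
      !is.null(tab) && nm %in% tab
    }, atoms$resname, atoms$name)
    atoms[keep, , drop = FALSE]
  }
  cat_a <- cation_rows(at_a); cat_b <- cation_rows(at_b)
  do_cation_pi <- function(cations, rings, cation_side) {
    if (!nrow(cations) || !length(rings)) return()
    ckey <- res_key(cations$chain, cations$resnum, cations$icode)
    for (rg in rings) {
      for (resk in unique(ckey)) {
        rows <- which(ckey == resk)
        dists <- sqrt(colSums((t(coords(cations[rows, , drop = FALSE])) -
                                 rg$centroid)^2))
        best <- rows[which.min(dists)]
        dmin <- min(dists)
        if (dmin > params$cation_pi_max) next
        v <- atom_xyz(cations, best) - rg$centroid
        ax <- vec_angle(v, rg$normal)
        ax <- min(ax, 180 - ax)
        if (ax > params$cation_pi_axis_max) next
        cref <- list(chain = cations$chain[best], resnum = cations$resnum[best],
                     icode = cations$icode[best],
                     resname = cations$resname[best], atom = cations$name[best])
        parts <- strsplit(rg$residue, ":", fixed = TRUE)[[1]]
        rref <- list(chain = parts[1], resnum = as.integer(parts[2]),
                     icode = if (length(parts) > 2) parts[3] else "",
                     resname = rg$resname, atom = "ring")
        tent <- rg$tentative || cref$resname == "HIS"
        if (cation_side == "a") add(interaction_row("cation_pi", cref, rref,
                                                    distance = dmin, angle = ax,
                                                    tentative = tent))
        else add(interaction_row("cation_pi", rref, cref, distance = dmin,
                                 angle = ax, tentative = tent))
        specific_pairs <<- c(specific_pairs,
                             if (cation_side == "a")
                               paste(res_key(cref$chain, cref$resnum, cref$icode),
                                     rg$residue, sep = "|")
                             else paste(rg$residue,
                                        res_key(cref$chain, cref$resnum,
                                                cref$icode), sep = "|"))
      }
    }
  }
  do_cation_pi(cat_a, rings_b, "a")
  do_cation_pi(cat_b, rings_a, "b")

  for (rga in rings_a) for (rgb in rings_b) {
    d <- vnorm(rga$centroid - rgb$centroid)
    if (d > params$pi_stack_max) next
    pa <- strsplit(rga$residue, ":", fixed = TRUE)[[1]]
    pb <- strsplit(rgb$residue, ":", fixed = TRUE)[[1]]
    ra <- list(chain = pa[1], resnum = as.integer(pa[2]),
               icode = if (length(pa) > 2) pa[3] else "", resname = rga$resname,
               atom = "ring")
    rb <- list(chain = pb[1], resnum = as.integer(pb[2]),
               icode = if (length(pb) > 2) pb[3] else "", resname = rgb$resname,
               atom = "ring")
    plane_ang <- vec_angle(rga$normal, rgb$normal)
    plane_ang <- min(plane_ang, 180 - plane_ang)
    add(interaction_row("pi_stack", ra, rb, distance = d, angle = plane_ang,
                        tentative = rga$tentative || rgb$tentative))
    specific_pairs <- c(specific_pairs,
                        paste(rga$residue, rgb$residue, sep = "|"))
  }

  # water-mediated hydrogen bonds: a water within H-bond geometry of both
  # partner groups; one record per bridged (residue-a, water, residue-b)
  waters <- all_atoms[all_atoms$resname == "HOH" & all_atoms$name %in%
                        c("O", "OW", "OH2"), , drop = FALSE]
  if (nrow(waters)) {
    legs <- function(atoms, wxyz) {
      np <- neighbor_pairs(coords(atoms), rbind(wxyz), params$hbond_da_max)
      if (!nrow(np)) return(integer())
      ok <- logical(nrow(np))
      for (q in seq_len(nrow(np))) {
        i <- np$i[q]
        rn <- atoms$resname[i]; nm <- atoms$name[i]
        if (!(is_donor_atom(rn, nm) || is_acceptor_atom(rn, nm))) next
        if (is_donor_atom(rn, nm)) {
          chk <- hbond_angle_ok(atoms, atoms$chain[i], atoms$resnum[i],
                                atoms$icode[i], rn, nm, atom_xyz(atoms, i),
                                wxyz, params$hbond_angle_min)
          if (!chk$ok) next
        }
        ok[q] <- TRUE
      }
      np$i[ok]
    }
    for (w in seq_len(nrow(waters))) {
      wxyz <- atom_xyz(waters, w)
      ia <- legs(at_a, wxyz)
      if (!length(ia)) next
      ib <- legs(at_b, wxyz)
      if (!length(ib)) next
      wk <- res_key(waters$chain[w], waters$resnum[w], waters$icode[w])
      seen <- character()
      for (i in ia) for (j in ib) {
        ra <- list(chain = at_a$chain[i], resnum = at_a$resnum[i],
                   icode = at_a$icode[i], resname = at_a$resname[i],
                   atom = at_a$name[i])
        rb <- list(chain = at_b$chain[j], resnum = at_b$resnum[j],
                   icode = at_b$icode[j], resname = at_b$resname[j],
                   atom = at_b$name[j])
        pk <- paste(res_key(ra$chain, ra$resnum, ra$icode),
                    res_key(rb$chain, rb$resnum, rb$icode), sep = "|")
        if (pk %in% seen) next
        seen <- c(seen, pk)
        da <- vnorm(atom_xyz(at_a, i) - wxyz)
        db <- vnorm(atom_xyz(at_b, j) - wxyz)
        add(interaction_row("water_mediated_hbond", ra, rb, water = wk,
                            distance = max(da, db)))
      }
    }
  }

  # van der Waals fallback: contacting residue pairs with no specific type
  if (n) {
    vdw_rows <- which(!(pair_key %in% specific_pairs))
    for (k in vdw_rows) {
      add(interaction_row("vdw", side_ref(con, k, "a"), side_ref(con, k, "b"),
                          distance = con$distance[k]))
    }
  }

  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(kind = character(), chain_a = character(),
               resnum_a = integer(), icode_a = character(),
               resname_a = character(), atom_a = character(),
               chain_b = character(), resnum_b = integer(),
               icode_b = character(), resname_b = character(),
               atom_b = character(), water = character(),
               distance = numeric(), angle = numeric(),
               tentative = logical(), stringsAsFactors = FALSE)
  ord <- order(out$kind, out$chain_a, out$resnum_a, out$icode_a,
               out$chain_b, out$resnum_b, out$icode_b, out$atom_a, out$atom_b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_set", "data.frame")
  attr(out, "params") <- params
  out
}

#' Per-residue contacting profile
#'
#' For each residue on the chosen side, the number of *distinct* partner
#' residues it contacts (the quantity plotted above epitope sequence
#' alignments).
#'
#' @param contacts `contact_set` from [map_contacts()].
#' @param side `"a"` or `"b"`: which side's residues to profile.
#' @return data.frame of class `contact_profile` with columns `chain`,
#'   `resnum`, `icode`, `resname`, `n_partners`; plus attribute
#'   `n_pairs` (total distinct contacting residue pairs).
#' @export
contact_profile <- function(contacts, side = c("a", "b")) {
  side <- match.arg(side)
  other <- if (side == "a") "b" else "a"
  con <- as.data.frame(contacts)
  mk_key <- function(s) res_key(con[[paste0("chain_", s)]],
                                con[[paste0("resnum_", s)]],
                                con[[paste0("icode_", s)]])
  if (nrow(con) == 0L) {
    out <- data.frame(chain = character(), resnum = integer(),
                      icode = character(), resname = character(),
                      n_partners = integer())
  } else {
    ks <- mk_key(side); ko <- mk_key(other)
    pairs <- unique(data.frame(ks = ks, ko = ko, stringsAsFactors = FALSE))
    cnt <- table(pairs$ks)
    first <- !duplicated(ks)
    out <- data.frame(chain = con[[paste0("chain_", side)]][first],
                      resnum = con[[paste0("resnum_", side)]][first],
                      icode = con[[paste0("icode_", side)]][first],
                      resname = con[[paste0("resname_", side)]][first],
                      stringsAsFactors = FALSE)
    out$n_partners <- as.integer(cnt[res_key(out$chain, out$resnum, out$icode)])
    out <- out[order(out$chain, out$resnum, out$icode), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("contact_profile", "data.frame")
  attr(out, "side") <- side
  attr(out, "n_pairs") <- if (nrow(con)) nrow(unique(data.frame(
    a = mk_key("a"), b = mk_key("b")))) else 0L
  out
}

#' Call interface hotspots
#'
#' Residues whose distinct-partner count reaches
#' `params$hotspot_min_partners`, sorted by count (descending) then residue
#' order.  The criterion applied is recorded verbatim in the result.
#'
#' @param profile `contact_profile`.
#' @param params [contact_params()].
#' @return `hotspot_call`: list with `residues` (data.frame subset of the
#'   profile) and `criterion` (character).
#' @export
call_hotspots <- function(profile, params = contact_params()) {
  thr <- params$hotspot_min_partners
  hits <- profile[profile$n_partners >= thr, , drop = FALSE]
  hits <- hits[order(-hits$n_partners, hits$chain, hits$resnum, hits$icode), ,
               drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- "data.frame"
  structure(list(residues = hits,
                 criterion = sprintf(
                   "distinct contacting partner residues >= %d", thr)),
            class = "hotspot_call")
}

#' @export
print.hotspot_call <- function(x, ...) {
  cat(sprintf("<hotspot_call: %d residue(s); criterion: %s>\n",
              nrow(x$residues), x$criterion))
  if (nrow(x$residues)) print(x$residues)
  invisible(x)
}

#' Summarize contacts by epitope region
#'
#' Buckets the receptor-side residues of a contact set into the epitope
#' regions and reports, per region, the number of contacting residues,
#' distinct residue pairs, atom pairs, and the breakdown of partner chains
#' (e.g. heavy vs light).  Residues outside every region are reported under
#' `other`.
#'
#' @param contacts `contact_set`; side `a` is taken as the receptor.
#' @param epitope [epitope_definition()].
#' @return data.frame with one row per region.
#' @export
annotate_regions <- function(contacts, epitope = epitope_definition()) {
  con <- as.data.frame(contacts)
  regions <- c(names(epitope), "other")
  assign_region <- function(resnum) {
    for (nm in names(epitope)) {
      r <- epitope[[nm]]
      if (resnum >= r[1] && resnum <= r[2]) return(nm)
    }
    "other"
  }
  if (nrow(con)) {
    con$region <- vapply(con$resnum_a, assign_region, character(1))
  }
  rows <- lapply(regions, function(rg) {
    sub <- if (nrow(con)) con[con$region == rg, , drop = FALSE] else con[0, ]
    key_a <- res_key(sub$chain_a, sub$resnum_a, sub$icode_a)
    key_b <- res_key(sub$chain_b, sub$resnum_b, sub$icode_b)
    partner_chains <- sort(unique(sub$chain_b))
    data.frame(region = rg,
               n_residues = length(unique(key_a)),
               n_residue_pairs = if (nrow(sub))
                 nrow(unique(data.frame(key_a, key_b))) else 0L,
               n_atom_pairs = nrow(sub),
               partner_chains = paste(partner_chains, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a contact set or interaction set as TSV
#' @param x data.frame-like result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 4))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
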