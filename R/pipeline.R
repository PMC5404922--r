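# Pipeline orchestration: run the complete interface, cross-reactivity and
# assembly analyses from a declarative configuration and write
# machine-readable report bundles (TSV/JSON plus a hashed MANIFEST).

#' Run configuration
#'
#' Assembles and validates the configuration consumed by the `run_*`
#' pipeline entry points.  Any referenced file must exist at run start.
#'
#' @param structure path to a structure file, or a [structure_model()].
#' @param group_a,group_b partner selection strings (see [select_group()]).
#' @param alignment path to a FASTA alignment, or a bio3d `fasta` object.
#' @param reference_id,targets cross-reactivity settings.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed recorded in outputs and used for any stochastic
#'   step.
#' @param contact,sasa parameter overrides, as named lists passed to
#'   [contact_params()] / [sasa_params()].
#' @param ... further fields kept verbatim (e.g. assembly settings).
#' @return `run_config` list.
#' @export
run_config <- function(structure = NULL, group_a = NULL, group_b = NULL,
                       alignment = NULL, reference_id = NULL, targets = NULL,
                       out_dir = tempfile("epimapr_run_"), seed = 1L,
                       contact = list(), sasa = list(), ...) {
  for (p in list(structure, alignment)) {
    if (is.character(p) && length(p) == 1L && !file.exists(p))
      stopf("input file not found: %s", p)
  }
  cfg <- c(list(structure = structure, group_a = group_a, group_b = group_b,
                alignment = alignment, reference_id = reference_id,
                targets = targets, out_dir = out_dir, seed = as.integer(seed),
                contact = contact, sasa = sasa), list(...))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file with the fields of [run_config()].
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

cfg_params <- function(cfg) {
  list(contact = do.call(contact_params, cfg$contact %||% list()),
       sasa = do.call(sasa_params, cfg$sasa %||% list()))
}

cfg_model <- function(cfg) {
  if (inherits(cfg$structure, "structure_model")) cfg$structure
  else read_structure(cfg$structure)
}

cfg_alignment <- function(cfg) {
  if (inherits(cfg$alignment, "fasta")) cfg$alignment
  else read_alignment(cfg$alignment)
}

serializable_cfg <- function(cfg) {
  s <- unclass(cfg)
  if (inherits(s$structure, "structure_model"))
    s$structure <- sprintf("<in-memory model '%s'>", s$structure$id)
  if (inherits(s$alignment, "fasta"))
    s$alignment <- "<in-memory alignment>"
  s
}

write_manifest <- function(out_dir, files, status = "ok",
                           failed_stage = NULL) {
  files <- files[file.exists(file.path(out_dir, files))]
  hashes <- tools::md5sum(file.path(out_dir, files))
  man <- data.frame(file = files, md5 = unname(hashes))
  lines <- c(sprintf("# status: %s", status),
             if (!is.null(failed_stage))
               sprintf("# failed_stage: %s", failed_stage),
             sprintf("%s  %s", man$md5, man$file))
  writeLines(lines, file.path(out_dir, "MANIFEST"))
}

run_bundle <- function(cfg, stages, outputs) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(serializable_cfg(cfg),
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  written <- "config.json"
  stage <- "(setup)"
  result <- tryCatch({
    env <- new.env()
    for (nm in names(stages)) {
      stage <- nm
      written <- c(written, stages[[nm]](env))
    }
    env
  }, error = function(e) {
    write_manifest(cfg$out_dir, written, status = "failed",
                   failed_stage = stage)
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  write_manifest(cfg$out_dir, written)
  invisible(result)
}

#' Run the interface report
#'
#' Full interface analysis of one structure and two partner groups:
#' contacts under the distance rule, chemical interaction typing, the
#' receptor-side contacting profile, hotspot call, epitope-region summary
#' and buried-surface areas.  Writes `contacts.tsv`, `interactions.tsv`,
#' `profile.tsv`, `regions.tsv`, `hotspots.json`, `interface_area.json` and
#' a hashed `MANIFEST` into `cfg$out_dir`.
#'
#' @param cfg [run_config()] with `structure`, `group_a` (receptor side) and
#'   `group_b` (antibody side).
#' @return invisibly, an environment with the computed objects (`contacts`,
#'   `interactions`, `profile`, `hotspots`, `regions`, `iface`).
#' @export
run_interface_report <- function(cfg) {
  pp <- cfg_params(cfg)
  model <- cfg_model(cfg)
  ga <- select_group(model, cfg$group_a, label = "receptor")
  gb <- select_group(model, cfg$group_b, label = "antibody")
  od <- cfg$out_dir
  run_bundle(cfg, list(
    contacts = function(env) {
      env$contacts <- map_contacts(model, ga, gb, pp$contact)
      write_tsv(env$contacts, file.path(od, "contacts.tsv"))
      "contacts.tsv"
    },
    interactions = function(env) {
      env$interactions <- classify_interactions(model, env$contacts,
                                                pp$contact)
      write_tsv(env$interactions, file.path(od, "interactions.tsv"))
      "interactions.tsv"
    },
    profile = function(env) {
      env$profile <- contact_profile(env$contacts, side = "a")
      write_tsv(env$profile, file.path(od, "profile.tsv"))
      "profile.tsv"
    },
    hotspots = function(env) {
      env$hotspots <- call_hotspots(env$profile, pp$contact)
      jsonlite::write_json(
        list(criterion = env$hotspots$criterion,
             residues = env$hotspots$residues),
        file.path(od, "hotspots.json"), auto_unbox = TRUE, pretty = TRUE)
      "hotspots.json"
    },
    regions = function(env) {
      env$regions <- annotate_regions(env$contacts)
      write_tsv(env$regions, file.path(od, "regions.tsv"))
      "regions.tsv"
    },
    interface_area = function(env) {
      env$iface <- interface_area(model, ga, gb, pp$sasa)
      jsonlite::write_json(
        list(bsa_total = env$iface$bsa_total,
             interface_area = env$iface$interface_area,
             buried_a = env$iface$buried_a, buried_b = env$iface$buried_b,
             params = unclass(pp$sasa)),
        file.path(od, "interface_area.json"), auto_unbox = TRUE,
        pretty = TRUE, digits = NA)
      "interface_area.json"
    }))
}

#' Run the cross-reactivity panel
#'
#' Projects the receptor-side contact profile onto the alignment and scores
#' every target sequence.  Writes `panel.tsv` (one row per target) and
#' `panel_positions.tsv` (per-position detail).
#'
#' @param cfg [run_config()] with `structure`, `group_a`, `group_b`,
#'   `alignment`, `reference_id` and `targets` (NULL = every non-reference
#'   row).
#' @return invisibly, environment with `panel`, `column_map`, `hotspots`.
#' @export
run_crossreactivity <- function(cfg) {
  pp <- cfg_params(cfg)
  model <- cfg_model(cfg)
  ga <- select_group(model, cfg$group_a, label = "receptor")
  gb <- select_group(model, cfg$group_b, label = "antibody")
  aln <- cfg_alignment(cfg)
  targets <- cfg$targets %||% setdiff(aln$id, cfg$reference_id)
  od <- cfg$out_dir
  run_bundle(cfg, list(
    profile = function(env) {
      env$contacts <- map_contacts(model, ga, gb, pp$contact)
      env$profile <- contact_profile(env$contacts, side = "a")
      env$hotspots <- call_hotspots(env$profile, pp$contact)
      character()
    },
    panel = function(env) {
      env$column_map <- map_profile_to_alignment(env$profile, aln,
                                                 cfg$reference_id)
      env$panel <- cross_species_panel(env$column_map, aln, targets,
                                       env$hotspots)
      write_tsv(env$panel, file.path(od, "panel.tsv"))
      detail <- do.call(rbind, lapply(attr(env$panel, "reports"), function(r) {
        d <- r$per_position; d$target_id <- r$target_id; d
      }))
      write_tsv(detail, file.path(od, "panel_positions.tsv"))
      c("panel.tsv", "panel_positions.tsv")
    }))
}

#' Run the assembly / divalent-feasibility analysis
#'
#' Grafts the antibody pose onto two receptor subunits, tests intra- and
#' inter-pentamer divalent binding with the two-arm antibody template, and
#' writes `feasibility.json` plus the posed antibody coordinates (PDB) of
#' any feasible model.
#'
#' Config fields (beyond [run_config()]): `pentamer` (model or path;
#' default toy pentamer), `second_pentamer` (inter mode; default: tilted
#' copy), `subunits` (two chain ids, default non-adjacent pair `A`,`C`),
#' `igg` (template model or NULL for the default dumbbell), `tilt`
#' (inter-pentamer tilt, degrees, default 30), `anchor_offset`,
#' `fab_tilt_out`, `hinge_sweep`, `elbow_max`.
#'
#' @param cfg [run_config()].
#' @return invisibly, environment with `intra`, `inter`, `tilt`.
#' @export
run_assembly <- function(cfg) {
  pp <- cfg_params(cfg)
  pent <- cfg$pentamer %||% make_toy_pentamer()
  if (is.character(pent)) pent <- read_structure(pent)
  igg <- cfg$igg %||% make_igg_dumbbell()
  if (is.character(igg)) igg <- read_structure(igg)
  subunits <- cfg$subunits %||% c("A", "C")
  tilt <- cfg$tilt %||% 30
  aoff <- cfg$anchor_offset %||% 15
  ftilt <- cfg$fab_tilt_out %||% 0
  sweep_grid <- cfg$hinge_sweep %||% seq(20, 160, by = 10)
  elbow <- cfg$elbow_max %||% 20
  od <- cfg$out_dir
  run_bundle(cfg, list(
    intra = function(env) {
      frames <- lapply(subunits, function(ch)
        subunit_frame(pent, ch, anchor_offset = aoff, tilt_out = ftilt))
      env$intra <- divalent_feasibility(frames, igg, obstacles = list(pent),
                                        mode = "intra_pentamer",
                                        hinge_sweep = sweep_grid,
                                        elbow_max = elbow, params = pp$contact)
      character()
    },
    inter = function(env) {
      pair <- facing_pentamer_pair(pent, tilt = tilt, anchor_offset = aoff,
                                   fab_tilt_out = ftilt)
      env$inter <- divalent_feasibility(pair$frames, igg,
                                        obstacles = pair$pentamers,
                                        mode = "inter_pentamer",
                                        hinge_sweep = sweep_grid,
                                        elbow_max = elbow, params = pp$contact)
      env$tilt <- if (env$inter$feasible) tilt_analysis(env$inter) else NA
      if (env$inter$feasible && !is.null(env$inter$posed_igg)) {
        write_structure(env$inter$posed_igg, file.path(od, "posed_igg.pdb"))
        "posed_igg.pdb"
      } else character()
    },
    feasibility = function(env) {
      as_json <- function(r) list(mode = r$mode, feasible = r$feasible,
                                  anchor_separation = r$anchor_separation,
                                  required_span = r$required_span,
                                  reason = r$reason,
                                  tilt_angle = if (is.na(r$tilt_angle)) NULL
                                  else r$tilt_angle)
      jsonlite::write_json(list(intra_pentamer = as_json(env$intra),
                                inter_pentamer = as_json(env$inter)),
                           file.path(od, "feasibility.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      "feasibility.json"
    }))
}

#' Two facing pentamers with convergent Fab frames
#'
#' Builds the canonical inter-pentamer cross-linking geometry: a second
#' copy of the pentamer is tilted toward the first so that the two outward
#' Fab axes converge above the gap between them.
#'
#' @param pentamer [structure_model()].
#' @param tilt tilt of each pentamer axis toward the partner, degrees.
#' @param gap lateral center-center distance, Angstrom.
#' @param anchor_offset,fab_tilt_out forwarded to [subunit_frame()].
#' @param subunit_a,subunit_b anchor subunit chain on the first/second copy.
#' @return list with `pentamers` (list of two models) and `frames` (list of
#'   two `fab_frame`s).
#' @export
facing_pentamer_pair <- function(pentamer, tilt = 30, gap = NULL,
                                 anchor_offset = 15, fab_tilt_out = 0,
                                 subunit = "A", igg_arm_length = 75) {
  # center the template, lean it toward +x by `tilt`
  c1 <- colMeans(coords(pentamer))
  Rt <- rotation_about_axis(c(0, 1, 0), tilt)
  p1 <- apply_transform(pentamer,
                        rigid_transform(Rt, -as.numeric(Rt %*% c1)))
  f1 <- subunit_frame(p1, subunit, anchor_offset, fab_tilt_out)
  # second copy: the first rotated half a turn about z (facing back), then
  # shifted so the two Fab axes converge at one arm length by default
  if (is.null(gap)) {
    a1 <- f1$anchor; ax1 <- f1$axis
    lean <- vec_angle(ax1, c(0, 0, 1))
    gap <- 2 * (a1[1] + igg_arm_length * sin(deg2rad(lean)))
  }
  Rz <- rotation_about_axis(c(0, 0, 1), 180)
  p2 <- apply_transform(p1, rigid_transform(Rz, c(gap, 0, 0)))
  f2 <- subunit_frame(p2, subunit, anchor_offset, fab_tilt_out)
  list(pentamers = list(p1, p2), frames = list(f1, f2), gap = gap)
}
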