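# Reading and writing macromolecular coordinates.  Parsing of the standard
# PDB/mmCIF dialects is delegated to bio3d; this module converts to the
# package's atom-table model, applies the alternate-location policy and
# assigns van der Waals radii.

#' Read a macromolecular structure
#'
#' Reads PDB or mmCIF coordinates into a [structure_model()].  Author
#' numbering is preserved, waters (residue name `HOH`) and hydrogens are
#' retained, and each atom is assigned a van der Waals radius from the
#' bundled element table.  When alternate conformers are present only the
#' highest-occupancy conformer of each atom is kept (ties resolved toward
#' altloc `A`), so downstream geometry always sees a single conformer.
#'
#' @param path file path.
#' @param format one of `"auto"` (by extension), `"pdb"`, `"mmcif"`.
#' @param id model identifier; defaults to the file base name.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE,
                                         rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stopf("failed to parse '%s' as %s: %s",
                              path, format, conditionMessage(e)))
  at <- parsed$atom
  atom <- data.frame(
    serial = at$eleno, name = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    resname = at$resid, chain = ifelse(is.na(at$chain), "", at$chain),
    resnum = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    element = ifelse(is.na(at$elesy) | at$elesy == "", "", at$elesy),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  atom <- apply_altloc_policy(atom)
  structure_model(atom, id = id %||% sub("\\.[^.]*$", "", basename(path)))
}

# Keep the highest-occupancy alternate conformer of each atom; ties go to
# altloc 'A' (alphabetically first).
apply_altloc_policy <- function(atom) {
  has_alt <- atom$alt != ""
  if (!any(has_alt)) return(atom)
  key <- paste(atom$chain, atom$resnum, atom$icode, atom$name, sep = "|")
  keep <- rep(TRUE, nrow(atom))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    ord <- order(-atom$occ[idx], atom$alt[idx])
    keep[idx[-ord[1]]] <- FALSE
  }
  atom[keep, , drop = FALSE]
}

#' Write a structure model in PDB format
#'
#' The emitted file re-reads with identical atom count and coordinates at
#' PDB precision (3 decimals).
#'
#' @param model [structure_model()].
#' @param path output file path.
#' @param format only `"pdb"` is supported.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path, format = "pdb") {
  if (!identical(format, "pdb")) stopf("unsupported output format: %s", format)
  a <- model$atom
  if (nrow(a) == 0L) stopf("refusing to write an empty model")
  if (nrow(a) > 99999L)
    stopf("%d atoms exceed the PDB fixed-width serial field; use mmCIF",
          nrow(a))
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(coords(a))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resnum, resid = a$resname, eleno = a$serial,
    elety = a$name, chain = ifelse(a$chain == "", " ", a$chain),
    insert = ifelse(a$icode == "", "", a$icode),
    alt = ifelse(a$alt == "", "", a$alt),
    o = a$occ, b = a$b, elesy = a$element, end = TRUE)
  invisible(path)
}

#' Select a chain group
#'
#' Partner-selection grammar: comma-separated chain ids with an optional
#' `+waters` suffix, e.g. `"H,L"` or `"A+waters"`.  `+waters` pulls in every
#' water residue of the model regardless of its chain id.
#'
#' @param model [structure_model()].
#' @param spec selection string.
#' @param label group label (e.g. `"receptor"`, `"antibody"`).
#' @return `chain_group` object.
#' @export
select_group <- function(model, spec, label = spec) {
  if (!nzchar(trimws(spec))) stopf("empty selection")
  include_waters <- grepl("\\+waters$", spec)
  body <- sub("\\+waters$", "", spec)
  ids <- trimws(strsplit(body, ",")[[1]])
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stopf("selection '%s' names no chains", spec)
  avail <- unique(model$atom$chain)
  unknown <- setdiff(ids, avail)
  if (length(unknown))
    stopf("unknown chain(s) %s; available chains: %s",
          paste(unknown, collapse = ", "), paste(avail, collapse = ", "))
  structure(list(label = label, chain_ids = ids,
                 include_waters = include_waters),
            class = "chain_group")
}

#' @export
print.chain_group <- function(x, ...) {
  cat(sprintf("<chain_group '%s': chains %s%s>\n", x$label,
              paste(x$chain_ids, collapse = ","),
              if (x$include_waters) " + waters" else ""))
  invisible(x)
}

#' Atoms belonging to a chain group
#'
#' Returns the non-water atoms of the group's chains, plus (if the group was
#' selected with `+waters`) all water atoms of the model.
#'
#' @param model [structure_model()].
#' @param group `chain_group` from [select_group()].
#' @return atom data.frame subset.
#' @export
group_atoms <- function(model, group) {
  a <- model$atom
  sel <- a$chain %in% group$chain_ids & a$resname != "HOH"
  if (group$include_waters) sel <- sel | a$resname == "HOH"
  a[sel, , drop = FALSE]
}

# Two groups used as interface partners must not share chains.
assert_disjoint <- function(group_a, group_b) {
  ov <- intersect(group_a$chain_ids, group_b$chain_ids)
  if (length(ov))
    stopf("partner groups overlap on chain(s): %s", paste(ov, collapse = ", "))
  invisible(TRUE)
}
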