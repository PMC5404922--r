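# The hierarchical coordinate container used by every downstream stage.
# Atoms live in a single data.frame (one row per atom) ordered by chain,
# residue, serial; the chain/residue hierarchy is implied by the key columns,
# which mirrors how crystallographic atom tables are deposited.

#' Construct a structure model from an atom table
#'
#' The atom table is the package's fundamental container: one row per atom
#' with author numbering preserved.  Waters are residues named `HOH`.
#'
#' @param atom data.frame with columns `serial`, `name`, `alt`, `resname`,
#'   `chain`, `resnum`, `icode`, `x`, `y`, `z`, `occ`, `b`, `element`, `het`.
#'   A `radius` column is added from the bundled van der Waals table when
#'   absent.
#' @param id character model identifier.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atom, id = "model") {
  required <- c("serial", "name", "resname", "chain", "resnum",
                "x", "y", "z")
  miss <- setdiff(required, names(atom))
  if (length(miss)) stopf("atom table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(atom) == 0L) stopf("a structure model must contain at least one atom")
  atom$alt <- if (is.null(atom$alt)) "" else ifelse(is.na(atom$alt), "", atom$alt)
  atom$icode <- if (is.null(atom$icode)) "" else
    ifelse(is.na(atom$icode) | atom$icode == " ", "", atom$icode)
  atom$occ <- if (is.null(atom$occ)) 1 else ifelse(is.na(atom$occ), 1, atom$occ)
  atom$b <- if (is.null(atom$b)) 0 else ifelse(is.na(atom$b), 0, atom$b)
  if (is.null(atom$element) || any(is.na(atom$element) | atom$element == "")) {
    inferred <- infer_element(atom$name)
    if (is.null(atom$element)) atom$element <- inferred
    else {
      fill <- is.na(atom$element) | atom$element == ""
      atom$element[fill] <- inferred[fill]
    }
  }
  atom$element <- toupper(atom$element)
  if (is.null(atom$het)) atom$het <- atom$resname %in% c("HOH")
  if (is.null(atom$radius)) atom$radius <- lookup_radius(atom$element, atom$name)
  bad <- !is.finite(atom$x) | !is.finite(atom$y) | !is.finite(atom$z)
  if (any(bad)) stopf("non-finite coordinates for atom serial(s): %s",
                      paste(atom$serial[bad], collapse = ", "))
  # one residue name per (chain, resnum, icode)
  key <- res_key(atom$chain, atom$resnum, atom$icode)
  kn <- tapply(atom$resname, key, function(v) length(unique(v)))
  if (any(kn > 1)) {
    stopf("duplicate residue key(s) with conflicting residue names: %s",
          paste(names(kn)[kn > 1], collapse = ", "))
  }
  rownames(atom) <- NULL
  structure(list(id = id, atom = atom), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atom
  nw <- sum(a$resname == "HOH")
  cat(sprintf("<structure_model '%s': %d atoms, %d chains (%s), %d residues, %d water atoms>\n",
              x$id, nrow(a), length(unique(a$chain)),
              paste(unique(a$chain), collapse = ","),
              length(unique(res_key(a$chain, a$resnum, a$icode))), nw))
  invisible(x)
}

#' Coordinate matrix of a model or atom table
#' @param x `structure_model` or atom data.frame.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(x) {
  a <- if (inherits(x, "structure_model")) x$atom else x
  cbind(x = a$x, y = a$y, z = a$z)
}

#' Number of atoms in a model
#' @param x `structure_model`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) nrow(x$atom)

is_water_row <- function(atom) atom$resname == "HOH"

#' Extract one residue's atoms
#' @param model `structure_model`.
#' @param chain,resnum,icode residue key (author numbering).
#' @return atom data.frame subset.
#' @export
residue_atoms <- function(model, chain, resnum, icode = "") {
  a <- model$atom
  a[a$chain == chain & a$resnum == resnum & a$icode == icode, , drop = FALSE]
}

#' Merge structure models
#'
#' Concatenates the atom tables of several models, renumbering serials.
#' Chains keep their ids; callers are responsible for uniqueness when that
#' matters downstream.
#'
#' @param ... `structure_model` objects.
#' @param id identifier for the merged model.
#' @return `structure_model`.
#' @export
merge_models <- function(..., id = "merged") {
  mods <- list(...)
  atoms <- do.call(rbind, lapply(mods, function(m) m$atom))
  atoms$serial <- seq_len(nrow(atoms))
  structure_model(atoms, id = id)
}

#' Epitope region definition for the receptor subunit
#'
#' Residue intervals (author numbering of the mature subunit) of the regions
#' making up the conformational epitope: the main immunogenic region (MIR)
#' loop, the N-terminal alpha helix, the loop connecting the helix to strand
#' beta-1, and the beta5-beta6 loop that packs against the MIR.
#'
#' @param mir,nterm_helix,helix_b1_loop,b5b6_loop integer length-2 intervals.
#' @return Named list of intervals, class `epitope_definition`.
#' @export
epitope_definition <- function(mir = c(67L, 76L),
                               nterm_helix = c(1L, 14L),
                               helix_b1_loop = c(15L, 23L),
                               b5b6_loop = c(110L, 115L)) {
  regs <- list(nterm_helix = nterm_helix, helix_b1_loop = helix_b1_loop,
               mir = mir, b5b6_loop = b5b6_loop)
  for (nm in names(regs)) {
    r <- regs[[nm]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stopf("invalid interval for region '%s'", nm)
  }
  structure(regs, class = "epitope_definition")
}
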