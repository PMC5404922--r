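# Projection of a receptor-side contact profile onto a multiple sequence
# alignment, and structure-guided compatibility scoring of homologous
# subunits and species orthologs.

#' Read a FASTA multiple sequence alignment
#'
#' Thin wrapper around `bio3d::read.fasta()`; rows must be equal length
#' (aligned, gaps as `-`).
#'
#' @param path FASTA file.
#' @return bio3d `fasta` object (matrix `ali`, ids `id`).
#' @export
read_alignment <- function(path) {
  aln <- bio3d::read.fasta(path)
  if (length(unique(rowSums(!is.na(aln$ali)))) > 1)
    stopf("sequences differ in aligned length; not an alignment")
  aln
}

aln_row <- function(alignment, id) {
  i <- match(id, alignment$id)
  if (is.na(i)) stopf("sequence id '%s' not in alignment (have: %s)", id,
                      paste(alignment$id, collapse = ", "))
  toupper(alignment$ali[i, ])
}

#' Map a contact profile onto alignment columns
#'
#' Assigns each profiled structure residue to a column of the alignment via
#' the reference sequence.  Column assignment uses `ref_numbering` (the
#' author residue number each alignment column corresponds to); when the
#' alignment carries no numbering attribute, ungapped reference positions
#' are numbered 1..n.  The reference row must agree with the structure's
#' residue types at 95% identity or better over the mapped positions.
#'
#' @param profile `contact_profile` (receptor side).
#' @param alignment bio3d `fasta` alignment.
#' @param reference_id id of the row corresponding to the structure's chain.
#' @param ref_numbering optional integer vector, one entry per alignment
#'   column, giving the reference residue number of that column (NA for
#'   columns where the reference has a gap).  Defaults to the alignment's
#'   `ref_numbering` attribute.
#' @param min_identity required reference-vs-structure identity (default
#'   0.95).
#' @return `alignment_column_map`: data.frame with `chain`, `resnum`,
#'   `icode`, `resname`, `column` (NA when unmappable), `weight` (distinct
#'   partner count); attributes `alignment`, `reference_id`.
#' @export
map_profile_to_alignment <- function(profile, alignment, reference_id,
                                     ref_numbering = NULL,
                                     min_identity = 0.95) {
  ref <- aln_row(alignment, reference_id)
  if (is.null(ref_numbering))
    ref_numbering <- attr(alignment, "ref_numbering")
  if (is.null(ref_numbering)) {
    ref_numbering <- rep(NA_integer_, length(ref))
    ref_numbering[ref != "-"] <- seq_len(sum(ref != "-"))
  }
  if (length(ref_numbering) != length(ref))
    stopf("ref_numbering length (%d) != alignment width (%d)",
          length(ref_numbering), length(ref))
  col_of <- match(profile$resnum, ref_numbering)
  out <- data.frame(chain = profile$chain, resnum = profile$resnum,
                    icode = profile$icode, resname = profile$resname,
                    column = col_of, weight = profile$n_partners,
                    stringsAsFactors = FALSE)
  mapped <- !is.na(out$column)
  if (!any(mapped))
    stopf("no profiled residue maps onto the alignment numbering")
  aa1 <- bio3d::aa321(out$resname[mapped])
  ref_aa <- ref[out$column[mapped]]
  ident <- mean(aa1 == ref_aa)
  if (ident < min_identity) {
    bad <- which(aa1 != ref_aa)
    stopf(paste0("reference sequence does not match structure residues ",
                 "(identity %.2f < %.2f); mismatches: %s"),
          ident, min_identity,
          paste(sprintf("res %d %s!=%s", out$resnum[mapped][bad], aa1[bad],
                        ref_aa[bad]), collapse = "; "))
  }
  if (any(!mapped))
    warnf("%d contacting residue(s) could not be mapped to alignment columns",
          sum(!mapped))
  class(out) <- c("alignment_column_map", "data.frame")
  attr(out, "alignment") <- alignment
  attr(out, "reference_id") <- reference_id
  out
}

classify_substitution <- function(ref_aa, tgt_aa) {
  if (tgt_aa == "-") return("gap")
  if (ref_aa == tgt_aa) return("identical")
  if (same_subst_group(ref_aa, tgt_aa)) return("conservative")
  "divergent"
}

substitution_flags <- function(ref_aa, tgt_aa) {
  if (tgt_aa == "-" || ref_aa == tgt_aa) return(character())
  fl <- character()
  cr <- residue_charge1(ref_aa); ct <- residue_charge1(tgt_aa)
  if (cr * ct < 0) fl <- c(fl, "charge_reversal")
  if (cr != 0 && ct == 0) fl <- c(fl, "charge_loss")
  if (ref_aa %in% .polar_set && !(tgt_aa %in% .polar_set))
    fl <- c(fl, "polarity_loss")
  vr <- .residue_volume[ref_aa]; vt <- .residue_volume[tgt_aa]
  if (is.finite(vr) && is.finite(vt)) {
    if (vt - vr > 40) fl <- c(fl, "steric_gain")
    if (vr - vt > 40) fl <- c(fl, "steric_loss")
  }
  fl
}

#' Score binding compatibility of a target sequence
#'
#' Weighted agreement of the target with the reference over the contacting
#' positions: identical positions score 1, conservative substitutions 0.5,
#' divergent substitutions and gaps 0, each weighted by the position's
#' distinct-partner count.  The verdict is `likely_disrupted` when any
#' hotspot position carries a divergent substitution with a charge
#' *reversal* (the situation that introduces electrostatic repulsion into
#' the interface), or when the weighted score falls below
#' `verdict_threshold`; otherwise `compatible`.  Charge-loss substitutions
#' reduce the score but do not by themselves veto binding, which matches the
#' observed cross-reactivity toward orthologs carrying neutral replacements
#' at charged hotspot positions.
#'
#' @param column_map `alignment_column_map` from
#'   [map_profile_to_alignment()].
#' @param alignment bio3d `fasta` alignment (defaults to the one stored in
#'   the column map).
#' @param target_id sequence id to score.
#' @param hotspots optional `hotspot_call`; hotspot positions are the ones
#'   whose charge-reversal substitutions veto binding.
#' @param verdict_threshold minimum weighted score for `compatible`.
#' @return `compatibility_report`: list with `target_id`, `per_position`
#'   data.frame (`column`, `resnum`, `ref_aa`, `target_aa`, `weight`,
#'   `class`, `flags`, `hotspot`), `score`, `verdict`.
#' @export
score_compatibility <- function(column_map, alignment = NULL, target_id,
                                hotspots = NULL, verdict_threshold = 0.7) {
  alignment <- alignment %||% attr(column_map, "alignment")
  ref <- aln_row(alignment, attr(column_map, "reference_id"))
  tgt <- aln_row(alignment, target_id)
  cm <- column_map[!is.na(column_map$column), , drop = FALSE]
  hotkeys <- if (!is.null(hotspots))
    res_key(hotspots$residues$chain, hotspots$residues$resnum,
            hotspots$residues$icode) else character()
  per <- lapply(seq_len(nrow(cm)), function(k) {
    col <- cm$column[k]
    ra <- ref[col]; ta <- tgt[col]
    cls <- classify_substitution(ra, ta)
    fl <- substitution_flags(ra, ta)
    data.frame(column = col, resnum = cm$resnum[k], ref_aa = ra,
               target_aa = ta, weight = cm$weight[k], class = cls,
               flags = paste(fl, collapse = ","),
               hotspot = res_key(cm$chain[k], cm$resnum[k], cm$icode[k]) %in%
                 hotkeys,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  match_val <- c(identical = 1, conservative = 0.5, divergent = 0, gap = 0)
  score <- sum(per$weight * match_val[per$class]) / sum(per$weight)
  veto <- any(per$hotspot & per$class == "divergent" &
                grepl("charge_reversal", per$flags))
  all_gap <- all(per$class == "gap")
  verdict <- if (veto || all_gap || score < verdict_threshold)
    "likely_disrupted" else "compatible"
  structure(list(target_id = target_id, per_position = per,
                 score = unname(score), verdict = verdict),
            class = "compatibility_report")
}

#' @export
print.compatibility_report <- function(x, ...) {
  cat(sprintf("<compatibility_report %s: score %.3f, verdict %s>\n",
              x$target_id, x$score, x$verdict))
  invisible(x)
}

#' Cross-species / cross-subunit compatibility panel
#'
#' One [score_compatibility()] report per target, summarized as a table
#' sorted by score (descending).
#'
#' @param column_map `alignment_column_map`.
#' @param alignment bio3d `fasta` alignment (default: stored in map).
#' @param targets character vector of sequence ids.
#' @param hotspots optional `hotspot_call`.
#' @param verdict_threshold passed through.
#' @return data.frame `target_id`, `score`, `verdict`, `n_divergent`,
#'   `n_flagged`; attribute `reports` holds the full per-target reports.
#' @export
cross_species_panel <- function(column_map, alignment = NULL, targets,
                                hotspots = NULL, verdict_threshold = 0.7) {
  alignment <- alignment %||% attr(column_map, "alignment")
  reports <- lapply(targets, function(id)
    score_compatibility(column_map, alignment, id, hotspots,
                        verdict_threshold))
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(target_id = r$target_id, score = r$score, verdict = r$verdict,
               n_divergent = sum(r$per_position$class == "divergent"),
               n_flagged = sum(nzchar(r$per_position$flags)),
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(-tab$score, tab$target_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "reports") <- stats::setNames(reports, targets)
  tab
}
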