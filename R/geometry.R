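# Geometry kernels: neighbor search over a cell list, Kabsch superposition,
# aromatic ring descriptors and rigid transforms.

#' Rigid transform
#'
#' A proper rotation plus translation, the unit of all superposition and
#' assembly operations.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (Angstrom).
#' @return `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stopf("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stopf("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-6)
    stopf("rotation must be proper (det = +1); got det = %g", det(rotation))
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Invert a rigid transform
#' @param t `rigid_transform`.
#' @return `rigid_transform` such that applying both is the identity.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), -as.numeric(t(t$rotation) %*% t$translation))
}

#' Compose rigid transforms (apply `b` first, then `a`)
#' @param a,b `rigid_transform` objects.
#' @return `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param t `rigid_transform`.
#' @return n x 3 matrix of x -> Rx + t.
#' @export
transform_coords <- function(xyz, t) {
  xyz <- rbind(xyz)
  sweep(xyz %*% t(t$rotation), 2, -t$translation)
}

#' Apply a rigid transform to a structure model
#' @param model [structure_model()].
#' @param t `rigid_transform`.
#' @return transformed [structure_model()].
#' @export
apply_transform <- function(model, t) {
  xyz <- transform_coords(coords(model), t)
  model$atom$x <- xyz[, 1]; model$atom$y <- xyz[, 2]; model$atom$z <- xyz[, 3]
  model
}

#' Cross-group neighbor pairs within a distance cutoff
#'
#' Exact search over a cell list: returns every pair (one atom from each
#' set) with Euclidean distance less than or equal to `cutoff` (inclusive
#' boundary, matching the "within" phrasing of contact rules).
#'
#' @param xyz_a,xyz_b coordinate matrices (n x 3) or atom data.frames.
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @return data.frame with columns `i` (row in a), `j` (row in b),
#'   `distance`; ordered by `i` then `j`.
#' @export
neighbor_pairs <- function(xyz_a, xyz_b, cutoff) {
  if (cutoff <= 0) stopf("cutoff must be positive")
  if (is.data.frame(xyz_a)) xyz_a <- coords(xyz_a)
  if (is.data.frame(xyz_b)) xyz_b <- coords(xyz_b)
  xyz_a <- rbind(xyz_a); xyz_b <- rbind(xyz_b)
  na <- nrow(xyz_a); nb <- nrow(xyz_b)
  empty <- data.frame(i = integer(), j = integer(), distance = numeric())
  if (na == 0L || nb == 0L) return(empty)
  # cell list over the b set
  cell <- function(m) {
    k <- floor(m / cutoff)
    paste(k[, 1], k[, 2], k[, 3], sep = ",")
  }
  kb <- floor(xyz_b / cutoff)
  keyb <- paste(kb[, 1], kb[, 2], kb[, 3], sep = ",")
  binb <- split(seq_len(nb), keyb)
  ka <- floor(xyz_a / cutoff)
  keya <- paste(ka[, 1], ka[, 2], ka[, 3], sep = ",")
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- list(); out_j <- list(); out_d <- list(); n_out <- 0L
  for (ck in unique(keya)) {
    ai <- which(keya == ck)
    base <- as.integer(strsplit(ck, ",", fixed = TRUE)[[1]])
    nb_keys <- paste(base[1] + off[, 1], base[2] + off[, 2],
                     base[3] + off[, 3], sep = ",")
    cand <- unlist(binb[nb_keys], use.names = FALSE)
    if (!length(cand)) next
    d2 <- outer(rowSums(xyz_a[ai, , drop = FALSE]^2), rep(1, length(cand))) +
      outer(rep(1, length(ai)), rowSums(xyz_b[cand, , drop = FALSE]^2)) -
      2 * xyz_a[ai, , drop = FALSE] %*% t(xyz_b[cand, , drop = FALSE])
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (!nrow(hit)) next
    n_out <- n_out + 1L
    out_i[[n_out]] <- ai[hit[, 1]]
    out_j[[n_out]] <- cand[hit[, 2]]
    out_d[[n_out]] <- sqrt(pmax(0, d2[hit]))
  }
  if (!n_out) return(empty)
  res <- data.frame(i = unlist(out_i), j = unlist(out_j),
                    distance = unlist(out_d))
  res <- res[order(res$i, res$j), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Kabsch superposition
#'
#' Least-squares rigid superposition of `mobile` onto `reference` (paired
#' coordinates, equal lengths).  Reflections are never returned: when the
#' optimal orthogonal matrix is improper the smallest singular direction is
#' flipped, yielding the best proper rotation.
#'
#' @param mobile,reference n x 3 matrices, n >= 3, not all collinear.
#' @return list with `transform` ([rigid_transform()]) and `rmsd` (Angstrom,
#'   after applying the transform to `mobile`).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- rbind(mobile); reference <- rbind(reference)
  if (nrow(mobile) != nrow(reference))
    stopf("point sets differ in length (%d vs %d)", nrow(mobile), nrow(reference))
  if (nrow(mobile) < 3) stopf("at least 3 paired points are required")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  tr <- rigid_transform(R, cr - as.numeric(R %*% cm))
  moved <- transform_coords(mobile, tr)
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  list(transform = tr, rmsd = rmsd)
}

#' Root-mean-square deviation of paired coordinates
#' @param a,b n x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_coords <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  if (nrow(a) != nrow(b)) stopf("point sets differ in length")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Aromatic ring descriptor
#'
#' Centroid and plane normal of an aromatic side-chain ring.  Tryptophan
#' uses its six-membered ring; histidine rings are flagged `tentative`
#' because protonation (and hence aromatic character for pi interactions)
#' cannot be read from heavy atoms.
#'
#' @param model [structure_model()].
#' @param chain,resnum,icode residue key.
#' @return list with `residue`, `resname`, `centroid`, `normal` (unit),
#'   `member_atoms`, `tentative`; class `ring_descriptor`.
#' @export
ring_descriptor <- function(model, chain, resnum, icode = "") {
  res <- residue_atoms(model, chain, resnum, icode)
  if (nrow(res) == 0L) stopf("residue %s:%s%s not found", chain, resnum, icode)
  rn <- res$resname[1]
  members <- .ring_atoms[[rn]]
  if (is.null(members))
    stopf("residue %s (%s:%s) has no aromatic ring", rn, chain, resnum)
  missing <- setdiff(members, res$name)
  if (length(missing))
    stopf("ring atoms missing for %s %s:%s: %s", rn, chain, resnum,
          paste(missing, collapse = ", "))
  xyz <- coords(res[match(members, res$name), , drop = FALSE])
  centroid <- colMeans(xyz)
  cc <- sweep(xyz, 2, centroid)
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  normal <- unit(ev$vectors[, 3])
  structure(list(residue = res_key(chain, resnum, icode), resname = rn,
                 centroid = centroid, normal = normal,
                 member_atoms = members, tentative = identical(rn, "HIS")),
            class = "ring_descriptor")
}
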