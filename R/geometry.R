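#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets (reflections are corrected by sign-flipping the
#' smallest singular vector).
#'
#' @param mobile n x 3 coordinate matrix to be moved.
#' @param target n x 3 coordinate matrix to fit onto.
#' @return A `cap_transform`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3) and `rmsd` over the fitted points. Apply with
#'   [apply_transform()].
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target) || ncol(mobile) != 3 || ncol(target) != 3)
    cap_stop("capscan_argument_error",
             "mobile and target must be equal-length n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3)
    cap_stop("capscan_degeneracy_error", "need at least 3 paired points, got %d", n)
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- crossprod(A, B)
  sv <- svd(H)
  if (sv$d[2] < 1e-10)
    cap_stop("capscan_degeneracy_error",
             "rank-deficient point sets (collinear or coincident)")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- ct - as.numeric(R %*% cm)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "cap_transform")
}

#' Apply a rigid transform to coordinates
#' @param transform a `cap_transform` from [superpose()].
#' @param xyz n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, xyz) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2, transform$translation, "+")
}

#' @export
print.cap_transform <- function(x, ...) {
  cat(sprintf("<cap_transform> rmsd %.4f A over fitted core\n", x$rmsd))
  invisible(x)
}

#' Displacement of a segment between two structures
#'
#' Superposes structure `b` onto structure `a` over a rigid core (by default
#' every position mapped in both structures outside the segment padded by
#' `core_pad` residues), then reports the mean and maximum paired C-alpha
#' distance over the segment positions modeled in both.
#'
#' @param struct_a,struct_b two [cap_structure] models of the same protein.
#' @param map_a,map_b their residue maps onto the common reference.
#' @param segment integer `c(a, b)` reference interval of interest.
#' @param chain_a,chain_b chain identifiers (default from the maps).
#' @param core reference positions used for superposition; `NULL` for the
#'   default rule.
#' @param core_pad residues excluded on each side of the segment when
#'   building the default core.
#' @return named numeric `c(mean, max)` in A; both `NA` (with a warning) if
#'   no segment position is modeled in both structures.
#' @export
segment_displacement <- function(struct_a, struct_b, map_a, map_b, segment,
                                 chain_a = map_a$chain_id,
                                 chain_b = map_b$chain_id,
                                 core = NULL, core_pad = 5L) {
  xa <- reference_ca(struct_a, chain_a, map_a)
  xb <- reference_ca(struct_b, chain_b, map_b)
  if (map_a$reference_length != map_b$reference_length)
    cap_stop("capscan_input_error", "maps disagree on reference length")
  seg <- segment[1]:segment[2]
  shared <- which(!is.na(xa[, 1]) & !is.na(xb[, 1]))
  if (is.null(core)) {
    excluded <- max(1, segment[1] - core_pad):min(nrow(xa), segment[2] + core_pad)
    core <- setdiff(shared, excluded)
  } else {
    core <- intersect(core, shared)
    if (length(intersect(core, seg)))
      cap_stop("capscan_argument_error", "core must be disjoint from segment")
  }
  if (length(core) < 3)
    cap_stop("capscan_degeneracy_error",
             "fewer than 3 shared core positions for superposition")
  tr <- superpose(xb[core, , drop = FALSE], xa[core, , drop = FALSE])
  seg_shared <- intersect(seg, shared)
  if (length(seg_shared) == 0L) {
    warning("no segment position modeled in both structures; displacement undefined")
    return(c(mean = NA_real_, max = NA_real_))
  }
  moved <- apply_transform(tr, xb[seg_shared, , drop = FALSE])
  d <- row_norms(moved - xa[seg_shared, , drop = FALSE])
  c(mean = mean(d), max = max(d))
}

#' Distance between two named atoms
#'
#' @param structure a [cap_structure].
#' @param selector_a,selector_b atom selectors: lists with any of `chain`,
#'   `resno`, `insert`, `resid`, `elety`; each must resolve to exactly one atom.
#' @return distance in A.
#' @export
named_distance <- function(structure, selector_a, selector_b) {
  ia <- resolve_selector(structure, selector_a, "first")
  ib <- resolve_selector(structure, selector_b, "second")
  a <- structure$atoms
  sqrt((a$x[ia] - a$x[ib])^2 + (a$y[ia] - a$y[ib])^2 + (a$z[ia] - a$z[ib])^2)
}

#' First coordination shell of an ion
#'
#' All candidate oxygen/nitrogen atoms (protein, waters, ligands) within
#' `cutoff` of the ion, sorted by distance.
#'
#' @param structure a [cap_structure].
#' @param ion_selector selector resolving to exactly one ion atom.
#' @param cutoff shell cutoff (A), default 3.5.
#' @param elements candidate coordinating elements.
#' @return data.frame `chain`, `resno`, `resid`, `elety`, `dist`, ascending
#'   by distance.
#' @export
coordination_shell <- function(structure, ion_selector, cutoff = 3.5,
                               elements = c("O", "N")) {
  idx <- resolve_selector(structure, ion_selector, "ion")
  a <- structure$atoms
  p <- c(a$x[idx], a$y[idx], a$z[idx])
  cand <- which(a$elesy %in% elements & seq_len(nrow(a)) != idx)
  d <- sqrt((a$x[cand] - p[1])^2 + (a$y[cand] - p[2])^2 + (a$z[cand] - p[3])^2)
  keep <- d <= cutoff
  out <- data.frame(chain = a$chain[cand[keep]], resno = a$resno[cand[keep]],
                    resid = a$resid[cand[keep]], elety = a$elety[cand[keep]],
                    dist = d[keep], stringsAsFactors = FALSE)
  out <- out[order(out$dist), , drop = FALSE]
  rownames(out) <- NULL
  out
}
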