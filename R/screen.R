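#' Build the residue-by-member order matrix
#'
#' Entry `H` where [assign_ss()] calls helix, `D` where the reference
#' position is unmapped or has no coordinates, `O` (ordered, non-helical)
#' otherwise.
#'
#' @param ensemble a `cap_ensemble` or plain list of [cap_structure] members.
#' @param maps list of `cap_residue_map`, one per member, all on the same
#'   reference.
#' @param chain_id chain identifier (used for every member).
#' @param config secondary-structure thresholds, see [ss_config()].
#' @return character matrix `reference_length x n_members` with values
#'   `H`/`O`/`D` (class `cap_order_matrix`).
#' @export
build_order_matrix <- function(ensemble, maps, chain_id = "A",
                               config = ss_config()) {
  members <- if (inherits(ensemble, "cap_ensemble")) ensemble$members else ensemble
  if (length(members) != length(maps))
    cap_stop("capscan_input_error", "%d members but %d maps",
             length(members), length(maps))
  lens <- vapply(maps, `[[`, integer(1), "reference_length")
  if (length(unique(lens)) != 1L)
    cap_stop("capscan_input_error", "maps disagree on reference length: %s",
             paste(unique(lens), collapse = ", "))
  L <- lens[1]
  out <- matrix("D", L, length(members))
  colnames(out) <- vapply(members, function(s) s$id, character(1))
  for (m in seq_along(members)) {
    ss <- assign_ss(members[[m]], chain_id, maps[[m]], config)
    col <- ifelse(ss == "H", "H", ifelse(ss == "D", "D", "O"))
    out[, m] <- col
  }
  class(out) <- c("cap_order_matrix", class(out))
  out
}

#' Default folding-event detection parameters
#'
#' A reference position is event-positive when the fraction of members in
#' which it is helical is at least `theta_h` (scaled by the best member
#' support anywhere on the chain) *and* the fraction in which it is
#' disordered is at least `theta_d`: the segment must demonstrably exist in
#' both an ordered-helical and a disordered form across the ensemble.
#'
#' @param theta_h minimum helical-member fraction (default 0.15).
#' @param theta_d minimum disordered-member fraction (default 0.15).
#' @param min_length minimum event length in residues (default 5).
#' @param merge_gap event-positive runs separated by at most this many
#'   non-positive positions are merged (default 2).
#' @param min_members minimum ensemble size for a meaningful screen
#'   (default 4: more than 3 structures).
#' @return named list of parameters.
#' @export
detect_params <- function(theta_h = 0.15, theta_d = 0.15, min_length = 5L,
                          merge_gap = 2L, min_members = 4L) {
  assert_scalar_number(theta_h, "theta_h", 1e-12, 1)
  assert_scalar_number(theta_d, "theta_d", 1e-12, 1)
  list(theta_h = theta_h, theta_d = theta_d,
       min_length = as.integer(min_length), merge_gap = as.integer(merge_gap),
       min_members = as.integer(min_members))
}

#' Detect disorder-to-order folding events
#'
#' Scans the order matrix for maximal runs of event-positive positions (see
#' [detect_params()]) of at least `min_length` residues, merging runs
#' separated by at most `merge_gap` positions.
#'
#' @param matrix a `cap_order_matrix` from [build_order_matrix()].
#' @param params detection parameters from [detect_params()].
#' @param allow_small override the minimum ensemble size with a warning.
#' @return data.frame of events (class `cap_events`): `start`, `end`,
#'   `length`, `helical_members`, `disordered_members` (mean fractions over
#'   the event), plus `mean_dip`, `p_value` columns filled by
#'   [plddt_dip_test()] downstream (`NA` here).
#' @export
detect_folding_events <- function(matrix, params = detect_params(),
                                  allow_small = FALSE) {
  n_members <- ncol(matrix)
  if (n_members < 2)
    cap_stop("capscan_detection_error",
             "folding-event detection needs at least 2 ensemble members, got %d",
             n_members)
  if (n_members < params$min_members) {
    if (!allow_small)
      cap_stop("capscan_detection_error",
               "ensemble has %d members; the screen requires >= %d (use allow_small to override)",
               n_members, params$min_members)
    warning(sprintf("screening a small ensemble (%d members)", n_members))
  }
  f_h <- rowMeans(matrix == "H")
  f_d <- rowMeans(matrix == "D")
  support <- 1 - f_d
  max_support <- max(support)
  positive <- f_h >= params$theta_h * max_support & f_d >= params$theta_d

  runs <- run_lengths(positive)
  runs <- runs[runs$value, , drop = FALSE]
  events <- list()
  if (nrow(runs)) {
    # merge runs separated by <= merge_gap non-positive positions
    cur <- c(runs$start[1], runs$end[1])
    for (k in seq_len(nrow(runs))[-1]) {
      if (runs$start[k] - cur[2] - 1 <= params$merge_gap) {
        cur[2] <- runs$end[k]
      } else {
        events[[length(events) + 1]] <- cur
        cur <- c(runs$start[k], runs$end[k])
      }
    }
    events[[length(events) + 1]] <- cur
  }
  events <- Filter(function(e) e[2] - e[1] + 1 >= params$min_length, events)
  out <- data.frame(
    start = vapply(events, `[`, numeric(1), 1),
    end = vapply(events, `[`, numeric(1), 2))
  out$length <- out$end - out$start + 1
  out$helical_members <- vapply(events, function(e)
    mean(f_h[e[1]:e[2]]), numeric(1))
  out$disordered_members <- vapply(events, function(e)
    mean(f_d[e[1]:e[2]]), numeric(1))
  out$mean_dip <- rep(NA_real_, nrow(out))
  out$p_value <- rep(NA_real_, nrow(out))
  class(out) <- c("cap_events", class(out))
  out
}

#' Assign ensemble members to conformational states
#'
#' For one folding event, each member is labeled `unfolded` when the event
#' segment's helicity is undefined or below `helicity_min`; otherwise
#' `folded` when the segment's mean C-alpha displacement from the consensus
#' folded position (the medoid helical member, after superposition on the
#' rigid core) is below `displacement_threshold`, else `alternative`.
#'
#' @param ensemble a `cap_ensemble` or list of [cap_structure].
#' @param maps list of `cap_residue_map`, one per member.
#' @param event one event row (data.frame with `start`, `end`) or integer
#'   `c(a, b)`.
#' @param chain_id chain identifier.
#' @param displacement_threshold folded/alternative boundary (A), default 4.
#' @param helicity_min minimum helicity for a folded segment, default 0.3.
#' @param config secondary-structure thresholds.
#' @return A `cap_states`: list with `labels` (per member), `fractions`
#'   (named `folded`, `unfolded`, `alternative`, summing to 1),
#'   `displacement` (per member, A; `NA` for unfolded members) and
#'   `displacement_threshold`.
#' @export
classify_states <- function(ensemble, maps, event, chain_id = "A",
                            displacement_threshold = 4, helicity_min = 0.3,
                            config = ss_config()) {
  members <- if (inherits(ensemble, "cap_ensemble")) ensemble$members else ensemble
  segment <- if (is.data.frame(event)) c(event$start[1], event$end[1])
             else as.integer(event[1:2])
  n <- length(members)
  helicity <- numeric(n)
  for (m in seq_len(n)) {
    ss <- assign_ss(members[[m]], chain_id, maps[[m]], config)
    helicity[m] <- segment_helicity(ss, segment)
  }
  labels <- rep(NA_character_, n)
  labels[is.na(helicity) | helicity < helicity_min] <- "unfolded"
  helical <- which(is.na(labels))
  if (length(helical) == 0L && all(labels == "unfolded")) {
    fractions <- c(folded = 0, unfolded = 1, alternative = 0)
    return(structure(list(labels = labels, fractions = fractions,
                          displacement = rep(NA_real_, n),
                          displacement_threshold = displacement_threshold),
                     class = "cap_states"))
  }
  if (length(helical) == 0L)
    cap_stop("capscan_classification_error", "no classifiable member")

  # consensus folded position: medoid of the helical members' segment
  # centroids after core superposition onto the first helical member
  frame <- helical[1]
  centroids <- matrix(NA_real_, length(helical), 3)
  for (k in seq_along(helical)) {
    m <- helical[k]
    if (m == frame) {
      xyz <- reference_ca(members[[m]], chain_id, maps[[m]])
      seg_pos <- segment[1]:segment[2]
      centroids[k, ] <- colMeans(xyz[seg_pos, , drop = FALSE], na.rm = TRUE)
    } else {
      centroids[k, ] <- superposed_segment_centroid(
        members[[frame]], members[[m]], maps[[frame]], maps[[m]], segment,
        chain_id)
    }
  }
  dmat <- as.matrix(stats::dist(centroids))
  medoid <- helical[which.min(rowSums(dmat))]

  displacement <- rep(NA_real_, n)
  for (m in helical) {
    displacement[m] <- if (m == medoid) 0 else
      segment_displacement(members[[medoid]], members[[m]],
                           maps[[medoid]], maps[[m]], segment,
                           chain_a = chain_id, chain_b = chain_id)[["mean"]]
    labels[m] <- if (displacement[m] < displacement_threshold) "folded"
                 else "alternative"
  }
  counts <- c(folded = sum(labels == "folded"),
              unfolded = sum(labels == "unfolded"),
              alternative = sum(labels == "alternative"))
  structure(list(labels = labels, fractions = counts / n,
                 displacement = displacement,
                 displacement_threshold = displacement_threshold),
            class = "cap_states")
}

superposed_segment_centroid <- function(sa, sb, ma, mb, segment, chain_id,
                                        core_pad = 5L) {
  xa <- reference_ca(sa, chain_id, ma)
  xb <- reference_ca(sb, chain_id, mb)
  shared <- which(!is.na(xa[, 1]) & !is.na(xb[, 1]))
  excluded <- max(1, segment[1] - core_pad):min(nrow(xa), segment[2] + core_pad)
  core <- setdiff(shared, excluded)
  tr <- superpose(xb[core, , drop = FALSE], xa[core, , drop = FALSE])
  seg_pos <- intersect(segment[1]:segment[2], which(!is.na(xb[, 1])))
  colMeans(apply_transform(tr, xb[seg_pos, , drop = FALSE]))
}

#' @export
print.cap_states <- function(x, ...) {
  cat(sprintf("<cap_states> %d members: folded %.3f / unfolded %.3f / alternative %.3f (threshold %.1f A)\n",
              length(x$labels), x$fractions["folded"], x$fractions["unfolded"],
              x$fractions["alternative"], x$displacement_threshold))
  invisible(x)
}

#' Permutation test for a local pLDDT dip at a folding event
#'
#' The dip statistic is `delta = mean pLDDT(segment) - mean pLDDT(flanks)`
#' with two flanks of `flank_width` residues truncated at the chain ends.
#' The null distribution is built by sliding the segment to `n_perm`
#' positions drawn uniformly from all valid placements that do not overlap
#' the true segment, recomputing the identical statistic each time. The
#' one-sided p-value for a *decrease* uses the add-one rule
#' `p = (1 + #(null <= delta)) / (n_perm + 1)`.
#'
#' @param profile a [cap_plddt] profile on the reference frame.
#' @param segment integer `c(a, b)` event interval.
#' @param flank_width flank width in residues (default 15).
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed (mandatory for reproducibility).
#' @return A `cap_dip`: list with `delta`, `p_value`, `n_perm`, `seed`,
#'   `flank_width`, `null` (the null deltas).
#' @export
plddt_dip_test <- function(profile, segment, flank_width = 15L,
                           n_perm = 999L, seed = 1L) {
  L <- length(profile)
  len <- segment[2] - segment[1] + 1L
  if (n_perm < 99)
    cap_stop("capscan_argument_error", "n_perm must be >= 99")
  if (len > L - 2L)
    cap_stop("capscan_argument_error",
             "segment of %d residues too long for a %d-residue chain", len, L)
  if (segment[1] < 1 || segment[2] > L)
    cap_stop("capscan_argument_error", "segment outside profile")
  v <- as.numeric(profile)

  stat_at <- function(s) {
    e <- s + len - 1L
    fl <- c(seq(max(1L, s - flank_width), s - 1L),
            seq(e + 1L, min(L, e + flank_width)))
    fl <- fl[fl >= 1 & fl <= L]
    mean(v[s:e], na.rm = TRUE) - mean(v[fl], na.rm = TRUE)
  }
  delta <- stat_at(segment[1])

  starts <- setdiff(seq_len(L - len + 1L),
                    seq(max(1L, segment[1] - len + 1L), segment[2]))
  if (length(starts) == 0L)
    cap_stop("capscan_argument_error", "no valid null placement for the segment")
  withr::local_seed(as.integer(seed))
  drawn <- starts[sample.int(length(starts), n_perm, replace = TRUE)]
  null <- vapply(drawn, stat_at, numeric(1))
  p <- (1 + sum(null <= delta)) / (n_perm + 1)
  structure(list(delta = delta, p_value = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), flank_width = as.integer(flank_width),
                 null = null),
            class = "cap_dip")
}

#' @export
print.cap_dip <- function(x, ...) {
  cat(sprintf("<cap_dip> delta %.3f pLDDT units, one-sided p = %.4g (%d permutations)\n",
              x$delta, x$p_value, x$n_perm))
  invisible(x)
}
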