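#' Default thresholds for C-alpha secondary-structure assignment
#'
#' P-SEA-style criteria on C-alpha distances and pseudo-angles. A residue
#' window seeds a helix when d(i,i+2) and d(i,i+3) fall in helical ranges, or
#' when the C-alpha pseudo-dihedral and pseudo-angle do; strand criteria are
#' the extended-geometry analogues. Runs shorter than the minimum run length
#' are demoted to coil.
#'
#' @return named list of thresholds (distances in A, angles in degrees).
#' @export
ss_config <- function() {
  list(helix_d13 = c(5.1, 6.4), helix_d14 = c(4.2, 5.5),
       helix_alpha = c(30, 80), helix_tau = c(85, 100),
       strand_d13 = c(6.7, 7.1), strand_d14 = c(9.9, 10.7),
       min_run_h = 5L, min_run_e = 3L, chain_break = 4.5)
}

in_range <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]

# raw per-window flags within one contiguous C-alpha stretch (m x 3 matrix)
stretch_flags <- function(xyz, cfg) {
  m <- nrow(xyz)
  d13 <- d14 <- alpha <- tau <- rep(NA_real_, m)
  if (m >= 3) {
    i <- seq_len(m - 2)
    d13[i] <- row_norms(xyz[i + 2, , drop = FALSE] - xyz[i, , drop = FALSE])
    it <- 2:(m - 1)
    tau[it] <- vapply(it, function(j)
      vec_angle(xyz[j - 1, ] - xyz[j, ], xyz[j + 1, ] - xyz[j, ]), numeric(1))
  }
  if (m >= 4) {
    i <- seq_len(m - 3)
    d14[i] <- row_norms(xyz[i + 3, , drop = FALSE] - xyz[i, , drop = FALSE])
    ia <- 2:(m - 2)
    alpha[ia] <- vapply(ia, function(j)
      dihedral4(xyz[j - 1, ], xyz[j, ], xyz[j + 1, ], xyz[j + 2, ]), numeric(1))
  }
  h <- (in_range(d13, cfg$helix_d13) & in_range(d14, cfg$helix_d14)) |
       (in_range(alpha, cfg$helix_alpha) & in_range(tau, cfg$helix_tau))
  e <- in_range(d13, cfg$strand_d13) & in_range(d14, cfg$strand_d14)
  list(h = h, e = e)
}

#' Assign secondary structure from C-alpha geometry
#'
#' Returns one code per reference position: `H` helix, `E` strand, `C` coil,
#' `D` disordered (position unmapped or without coordinates). Works on
#' C-alpha-only models, so deposited structures and backbone-only synthetic
#' fixtures are treated uniformly. Consecutive mapped residues more than
#' `chain_break` A apart split assignment windows.
#'
#' @param structure a [cap_structure].
#' @param chain_id chain identifier.
#' @param map a `cap_residue_map` from [map_to_reference()].
#' @param config thresholds from [ss_config()].
#' @return character vector of length `map$reference_length` (class `cap_ss`).
#' @export
assign_ss <- function(structure, chain_id, map, config = ss_config()) {
  xyz_ref <- reference_ca(structure, chain_id, map)
  L <- map$reference_length
  ss <- rep("D", L)
  modeled <- which(!is.na(xyz_ref[, 1]))
  if (length(modeled) == 0L) return(structure(ss, class = "cap_ss"))
  ss[modeled] <- "C"

  # contiguous stretches: consecutive reference positions, no geometric break
  gap <- diff(modeled) != 1L
  if (length(modeled) > 1) {
    step <- row_norms(xyz_ref[modeled[-1], , drop = FALSE] -
                      xyz_ref[modeled[-length(modeled)], , drop = FALSE])
    gap <- gap | step > config$chain_break
  }
  stretch_id <- cumsum(c(1L, as.integer(gap)))

  for (sid in unique(stretch_id)) {
    pos <- modeled[stretch_id == sid]
    m <- length(pos)
    if (m < 4) next
    fl <- stretch_flags(xyz_ref[pos, , drop = FALSE], config)
    hmask <- rep(FALSE, m); emask <- rep(FALSE, m)
    for (i in which(fl$h)) hmask[i:min(m, i + 3L)] <- TRUE
    for (i in which(fl$e)) emask[i:min(m, i + 3L)] <- TRUE
    ss[pos[emask]] <- "E"
    ss[pos[hmask]] <- "H"   # helix takes precedence
  }

  # demote runs below the minimum length to coil
  runs <- run_lengths(ss)
  for (k in seq_len(nrow(runs))) {
    v <- runs$value[k]
    if ((v == "H" && runs$length[k] < config$min_run_h) ||
        (v == "E" && runs$length[k] < config$min_run_e))
      ss[runs$start[k]:runs$end[k]] <- "C"
  }
  structure(ss, class = "cap_ss")
}

#' @export
print.cap_ss <- function(x, ...) {
  cat(sprintf("<cap_ss> %d positions: H %d, E %d, C %d, D %d\n", length(x),
              sum(x == "H"), sum(x == "E"), sum(x == "C"), sum(x == "D")))
  invisible(x)
}

#' Helical fraction of a segment
#'
#' Fraction of helical positions among the non-disordered positions of a
#' segment; `NA` (undefined) when every position is disordered.
#'
#' @param ss a `cap_ss` string from [assign_ss()].
#' @param segment integer `c(a, b)` reference interval.
#' @return fraction in `[0, 1]`, or `NA` if the whole segment is disordered.
#' @export
segment_helicity <- function(ss, segment) {
  if (length(segment) != 2L || segment[1] > segment[2])
    cap_stop("capscan_argument_error", "segment must be c(a, b) with a <= b")
  if (segment[1] < 1 || segment[2] > length(ss))
    cap_stop("capscan_argument_error",
             "segment [%d, %d] outside reference length %d",
             segment[1], segment[2], length(ss))
  s <- ss[segment[1]:segment[2]]
  n_obs <- sum(s != "D")
  if (n_obs == 0L) return(NA_real_)
  sum(s == "H") / n_obs
}
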