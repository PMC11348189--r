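#' Ideal alpha-helix C-alpha trace
#'
#' Parametric ideal helix: radius 2.3 A, rise 1.5 A per residue, twist 100
#' degrees per residue, giving the canonical ~3.8 A consecutive C-alpha
#' spacing.
#'
#' @param n number of residues.
#' @return n x 3 coordinate matrix.
#' @export
make_helix <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    cap_stop("capscan_argument_error", "`n` must be >= 1")
  t <- seq_len(n) - 1
  theta <- t * 100 * pi / 180
  cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * t)
}

#' Self-avoiding random-coil C-alpha trace
#'
#' Random chain with fixed 3.8 A bond length and uniformly random step
#' directions, subject to a minimum separation of `min_sep` between
#' non-adjacent residues. Reproducible from `seed`.
#'
#' @param n number of residues.
#' @param seed integer seed.
#' @param bond bond length (A).
#' @param min_sep self-avoidance minimum distance between non-adjacent
#'   C-alphas (A).
#' @param max_restarts chain restarts before giving up.
#' @return n x 3 coordinate matrix.
#' @export
make_coil <- function(n, seed = 1L, bond = 3.8, min_sep = 3.0,
                      max_restarts = 20L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    cap_stop("capscan_argument_error", "`n` must be >= 1")
  withr::local_seed(as.integer(seed))
  for (attempt in seq_len(max_restarts)) {
    xyz <- matrix(0, n, 3)
    ok <- TRUE
    i <- 2L
    while (i <= n) {
      placed <- FALSE
      for (try in 1:100) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u * u))
        cand <- xyz[i - 1L, ] + bond * u
        if (i > 2L) {
          d2 <- colSums((t(xyz[seq_len(i - 2L), , drop = FALSE]) - cand)^2)
          if (min(d2) < min_sep^2) next
        }
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
      i <- i + 1L
    }
    if (ok) return(xyz)
  }
  cap_stop("capscan_generation_error",
           "self-avoiding coil of length %d unsatisfiable after %d restarts",
           n, max_restarts)
}

#' Specification of a synthetic conformational ensemble
#'
#' Defines the study conditions for the planted-truth ensembles: a chain in
#' which one contiguous segment is helical in a `folded` fraction of members,
#' missing (disordered) in an `unfolded` fraction, and rigidly displaced
#' helical in an `alternative` fraction, mirroring a three-state
#' folded / unfolded / backfolded conformational equilibrium.
#'
#' @param n_members ensemble size.
#' @param chain_length residues in the full reference chain.
#' @param event_segment integer `c(a, b)`: the segment undergoing the
#'   disorder-to-order transition.
#' @param state_fractions numeric `c(folded, unfolded, alternative)`,
#'   non-negative, summing to 1.
#' @param displacement rigid translation (A) applied to the alternative
#'   state's segment.
#' @param missing_prefix number of N-terminal residues absent in all members
#'   (an unresolved flexible terminus).
#' @param noise_sigma isotropic Gaussian jitter (A) on every coordinate.
#' @param unfolded_as_coil if `TRUE`, unfolded members carry random-coil
#'   coordinates for the segment instead of missing residues.
#' @param seed integer seed.
#' @return validated `cap_ensemble_spec` list.
#' @export
ensemble_spec <- function(n_members = 100L, chain_length = 550L,
                          event_segment = c(385L, 400L),
                          state_fractions = c(0.23, 0.69, 0.08),
                          displacement = 8, missing_prefix = 39L,
                          noise_sigma = 0, unfolded_as_coil = FALSE,
                          seed = 1L) {
  assert_scalar_number(n_members, "n_members", 1)
  assert_scalar_number(chain_length, "chain_length", 2)
  if (length(event_segment) != 2L || event_segment[1] < 1 ||
      event_segment[1] > event_segment[2] || event_segment[2] > chain_length)
    cap_stop("capscan_validation_error",
             "event_segment must satisfy 1 <= a <= b <= chain_length")
  if (length(state_fractions) != 3L || any(state_fractions < 0) ||
      abs(sum(state_fractions) - 1) > 1e-9)
    cap_stop("capscan_validation_error",
             "state_fractions must be three non-negative values summing to 1 (got sum %.6f)",
             sum(state_fractions))
  assert_scalar_number(displacement, "displacement", 0)
  assert_scalar_number(missing_prefix, "missing_prefix", 0, chain_length - 1)
  assert_scalar_number(noise_sigma, "noise_sigma", 0)
  structure(list(n_members = as.integer(n_members),
                 chain_length = as.integer(chain_length),
                 event_segment = as.integer(event_segment),
                 state_fractions = as.numeric(state_fractions),
                 displacement = displacement,
                 missing_prefix = as.integer(missing_prefix),
                 noise_sigma = noise_sigma,
                 unfolded_as_coil = isTRUE(unfolded_as_coil),
                 seed = as.integer(seed)),
            class = "cap_ensemble_spec")
}

# largest-remainder apportionment of n among fractions
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

# build a CA-only cap_structure from coordinates + author numbering + sequence
ca_chain_structure <- function(xyz, resno, aa, id, chain = "A") {
  keep <- !is.na(xyz[, 1])
  atoms <- data.frame(
    chain = chain, resno = resno[keep], insert = "",
    resid = bio3d::aa123(aa[keep]), aa = aa[keep],
    elety = "CA", elesy = "C",
    x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3],
    o = 1, b = 0, het = FALSE, stringsAsFactors = FALSE)
  cap_structure(atoms, id = id, source_format = "synthetic")
}

#' Generate a synthetic conformational ensemble with known ground truth
#'
#' All members share one random-coil scaffold outside the event segment (up
#' to `noise_sigma` jitter). Folded members carry an ideal helix across the
#' segment; unfolded members lack the segment's residues entirely (or carry
#' coil coordinates if `unfolded_as_coil`); alternative members carry the
#' same helix rigidly translated by `displacement` A. State counts follow
#' largest-remainder rounding of the requested fractions.
#'
#' @param spec a [ensemble_spec].
#' @return A `cap_ensemble`: list with `members` (list of [cap_structure]),
#'   `labels` (ground-truth state per member), `reference` (amino-acid
#'   sequence), and `spec`.
#' @export
make_ensemble <- function(spec = ensemble_spec()) {
  if (!inherits(spec, "cap_ensemble_spec")) spec <- do.call(ensemble_spec, spec)
  L <- spec$chain_length
  a <- spec$event_segment[1]; b <- spec$event_segment[2]
  seg <- a:b
  withr::local_seed(spec$seed)
  aa_seq <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                   L, replace = TRUE)
  scaffold <- make_coil(L, seed = spec$seed + 104729L)

  helix <- make_helix(length(seg))
  anchor <- if (a >= 2) scaffold[a - 1L, ] else c(0, 0, 0)
  dir <- if (a >= 3) {
    d <- scaffold[a - 1L, ] - scaffold[a - 2L, ]; d / sqrt(sum(d * d))
  } else c(1, 0, 0)
  helix <- sweep(helix, 2, anchor + 3.8 * dir - helix[1, ], "+")
  helix_alt <- sweep(helix, 2, spec$displacement * c(0, 0, 1), "+")

  counts <- largest_remainder(spec$state_fractions, spec$n_members)
  if (any(abs(spec$state_fractions * spec$n_members - counts) > 1e-9))
    message(sprintf("state counts rounded to %s by largest remainder",
                    paste(counts, collapse = "/")))
  labels <- rep(c("folded", "unfolded", "alternative"), counts)

  member_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_members)
  prefix <- seq_len(spec$missing_prefix)
  members <- vector("list", spec$n_members)
  for (m in seq_len(spec$n_members)) {
    xyz <- scaffold
    xyz[seg, ] <- switch(labels[m],
      folded = helix,
      alternative = helix_alt,
      unfolded = if (spec$unfolded_as_coil)
        sweep(make_coil(length(seg), seed = member_seeds[m]), 2,
              anchor + 3.8 * dir, "+")
      else matrix(NA_real_, length(seg), 3))
    if (spec$missing_prefix > 0) xyz[prefix, ] <- NA_real_
    if (spec$noise_sigma > 0) {
      withr::with_seed(member_seeds[m] %% 2147483646L + 1L, {
        xyz <- xyz + rnorm(length(xyz), sd = spec$noise_sigma)
      })
    }
    members[[m]] <- ca_chain_structure(
      xyz, resno = seq_len(L), aa = aa_seq,
      id = sprintf("member_%03d_%s", m, labels[m]))
  }
  structure(list(members = members, labels = labels,
                 reference = paste(aa_seq, collapse = ""), spec = spec),
            class = "cap_ensemble")
}

#' @export
print.cap_ensemble <- function(x, ...) {
  cat(sprintf("<cap_ensemble> %d members (%s), chain length %d, event %d-%d\n",
              length(x$members),
              paste(names(table(x$labels)), table(x$labels), sep = ":",
                    collapse = " "),
              x$spec$chain_length, x$spec$event_segment[1],
              x$spec$event_segment[2]))
  invisible(x)
}

#' Generate a synthetic pLDDT profile with a localized dip
#'
#' Baseline plus Gaussian noise everywhere; `baseline - dip_depth` plus noise
#' inside `dip_segment`; clipped to `[0, 100]`.
#'
#' @param chain_length profile length.
#' @param baseline baseline pLDDT (0-100).
#' @param dip_depth depth of the dip (pLDDT units, `baseline - dip_depth >= 0`).
#' @param dip_segment integer `c(a, b)` interval of the dip.
#' @param noise_sigma Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return A [cap_plddt] profile.
#' @export
make_plddt <- function(chain_length, baseline = 90, dip_depth = 5,
                       dip_segment = c(385L, 400L), noise_sigma = 2,
                       seed = 1L) {
  assert_scalar_number(baseline, "baseline", 0, 100)
  assert_scalar_number(dip_depth, "dip_depth", 0, baseline)
  if (length(dip_segment) != 2L || dip_segment[1] < 1 ||
      dip_segment[1] > dip_segment[2] || dip_segment[2] > chain_length)
    cap_stop("capscan_validation_error", "invalid dip_segment")
  withr::local_seed(as.integer(seed))
  v <- baseline + rnorm(chain_length, sd = noise_sigma)
  v[dip_segment[1]:dip_segment[2]] <-
    v[dip_segment[1]:dip_segment[2]] - dip_depth
  cap_plddt(pmin(100, pmax(0, v)), source = "synthetic")
}

#' Hollow spherical shell fixture
#'
#' Dense shell of carbon pseudo-atoms whose van der Waals inner surface lies
#' at `inner_radius`, enclosing a spherical cavity of analytically known
#' volume -- the oracle fixture for pocket-volume estimation.
#'
#' @param inner_radius radius (A) of the cavity at the atom surfaces.
#' @param atom_radius van der Waals radius of the shell atoms (carbon, 1.7 A).
#' @param spacing approximate atom spacing on the shell (A); must be small
#'   enough that no probe can leak between atoms.
#' @return A [cap_structure] of het "DUM" carbon atoms.
#' @export
make_shell_fixture <- function(inner_radius = 6, atom_radius = 1.7,
                               spacing = 1.2) {
  rc <- inner_radius + atom_radius
  n <- max(12L, ceiling(4 * pi * rc^2 / spacing^2))
  pts <- fibonacci_sphere(n) * rc
  atoms <- data.frame(
    chain = "S", resno = seq_len(n), insert = "", resid = "DUM", aa = "X",
    elety = "C", elesy = "C", x = pts[, 1], y = pts[, 2], z = pts[, 3],
    o = 1, b = 0, het = TRUE, stringsAsFactors = FALSE)
  cap_structure(atoms, id = sprintf("shell_R%.1f", inner_radius),
                source_format = "synthetic")
}

#' Synthetic active-site fixture with planted geometry
#'
#' A cavity (hollow shell of dummy atoms) containing: a two-atom acyclic
#' ligand with C1 and C6 at a configurable separation; a monovalent ion with
#' coordinating oxygen atoms (structural waters and a cofactor-like oxygen)
#' at configurable distances. All planted values are recoverable by
#' [named_distance()], [coordination_shell()] and [pocket_volume()].
#'
#' @param c1_c6_sep planted C1-C6 distance (A).
#' @param coord_dists planted ion-coordination distances (A).
#' @param inner_radius cavity radius of the enclosing shell (A).
#' @param n_ions number of ion atoms (a second ion makes bare ion selectors
#'   ambiguous on purpose).
#' @return A [cap_structure].
#' @export
make_site_fixture <- function(c1_c6_sep = 3.4, coord_dists = c(2.4, 2.8, 3.2),
                              inner_radius = 7, n_ions = 1L) {
  shell <- make_shell_fixture(inner_radius = inner_radius)
  rowd <- function(chain, resno, resid, aa, elety, elesy, p, het = TRUE)
    data.frame(chain = chain, resno = resno, insert = "", resid = resid,
               aa = aa, elety = elety, elesy = elesy,
               x = p[1], y = p[2], z = p[3], o = 1, b = 0, het = het,
               stringsAsFactors = FALSE)
  lig <- rbind(
    rowd("L", 1L, "LIG", "X", "C1", "C", c(-c1_c6_sep / 2, -2.4, 0)),
    rowd("L", 1L, "LIG", "X", "C6", "C", c(+c1_c6_sep / 2, -2.4, 0)))
  ion <- rowd("L", 2L, "K", "X", "K", "K", c(0, 0.8, 0))
  dirs <- rbind(c(1, 0, 0), c(0, 0, 1), c(-0.6, 0.6, -0.529))
  dirs <- dirs / row_norms(dirs)
  waters <- do.call(rbind, lapply(seq_along(coord_dists), function(i) {
    p <- c(0, 0.8, 0) + coord_dists[i] * dirs[(i - 1) %% nrow(dirs) + 1, ]
    resid <- if (i == length(coord_dists)) "NAD" else "HOH"
    elety <- if (resid == "NAD") "O7N" else "O"
    rowd("L", 2L + i, resid, "X", elety, "O", p)
  }))
  extra_ion <- if (n_ions > 1L)
    do.call(rbind, lapply(seq_len(n_ions - 1L), function(i)
      rowd("L", 100L + i, "K", "X", "K", "K", c(0, -0.8 - i, 1.5))))
  else NULL
  cap_structure(rbind(shell$atoms, lig, ion, waters, extra_ion),
                id = "site_fixture", source_format = "synthetic")
}
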