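#' Van der Waals radii by element
#'
#' Defaults used by [sasa()], [buried_surface_area()] and [pocket_volume()];
#' override by passing a modified named vector.
#'
#' @return named numeric vector of radii (A).
#' @export
element_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    NA_ = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39, MN = 1.61,
    FE = 1.56)
}

atom_radii <- function(atoms, radii) {
  ele <- atoms$elesy
  ele[ele == "NA"] <- "NA_"
  r <- radii[ele]
  if (anyNA(r)) {
    offenders <- sort(unique(atoms$elesy[is.na(r)]))
    cap_stop("capscan_radius_error",
             "no van der Waals radius for element(s): %s",
             paste(offenders, collapse = ", "))
  }
  as.numeric(r)
}

select_atoms <- function(structure, chains = NULL, exclude_water = TRUE) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  if (exclude_water) keep <- keep & !(a$resid %in% c("HOH", "WAT", "DOD"))
  a[keep, , drop = FALSE]
}

sasa_atoms <- function(atoms, probe, n_points, radii) {
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  re <- atom_radii(atoms, radii) + probe   # expanded radii
  sphere <- fibonacci_sphere(n_points)
  out <- numeric(n)
  # neighbor lists via squared-distance threshold
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (re[i] + re)^2 & seq_len(n) != i)
    pts <- sweep(sphere * re[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- colSums((t(pts) - xyz[j, ])^2)
      exposed <- exposed & dj2 > re[j]^2
      if (!any(exposed)) break
    }
    out[i] <- 4 * pi * re[i]^2 * sum(exposed) / n_points
  }
  out
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Quasi-uniform points are placed on each atom's probe-expanded sphere; the
#' exposed fraction times the expanded-sphere area gives the per-atom SASA.
#'
#' @param structure a [cap_structure].
#' @param probe probe radius (A), default 1.4 (water).
#' @param n_sphere_points quadrature points per atom (default 960; error
#'   scales as 1/sqrt(n)).
#' @param radii named radii table, see [element_radii()].
#' @param chains restrict to these chains (`NULL` = all).
#' @param exclude_water drop waters before the calculation (deposited models
#'   differ widely in retained waters)?
#' @return numeric vector: SASA (A^2) per retained atom, with the retained
#'   atom table as attribute `atoms`.
#' @export
sasa <- function(structure, probe = 1.4, n_sphere_points = 960L,
                 radii = element_radii(), chains = NULL,
                 exclude_water = TRUE) {
  atoms <- select_atoms(structure, chains, exclude_water)
  if (nrow(atoms) == 0L)
    cap_stop("capscan_argument_error", "no atoms selected for SASA")
  out <- sasa_atoms(atoms, probe, n_sphere_points, radii)
  attr(out, "atoms") <- atoms
  out
}

#' Buried surface area between two chain sets
#'
#' `BSA = SASA(A alone) + SASA(B alone) - SASA(A and B together)`.
#'
#' @param structure a [cap_structure].
#' @param chain_set_a,chain_set_b disjoint, non-empty chain-id vectors.
#' @inheritParams sasa
#' @return buried area (A^2, non-negative up to quadrature error).
#' @export
buried_surface_area <- function(structure, chain_set_a, chain_set_b,
                                probe = 1.4, n_sphere_points = 960L,
                                radii = element_radii(),
                                exclude_water = TRUE) {
  if (length(chain_set_a) == 0L || length(chain_set_b) == 0L)
    cap_stop("capscan_argument_error", "chain sets must be non-empty")
  if (length(intersect(chain_set_a, chain_set_b)))
    cap_stop("capscan_argument_error", "chain sets overlap: %s",
             paste(intersect(chain_set_a, chain_set_b), collapse = ", "))
  s_a <- sum(sasa(structure, probe, n_sphere_points, radii,
                  chains = chain_set_a, exclude_water = exclude_water))
  s_b <- sum(sasa(structure, probe, n_sphere_points, radii,
                  chains = chain_set_b, exclude_water = exclude_water))
  s_ab <- sum(sasa(structure, probe, n_sphere_points, radii,
                   chains = c(chain_set_a, chain_set_b),
                   exclude_water = exclude_water))
  s_a + s_b - s_ab
}

#' Buried surface area for every chain pair of a multimer
#'
#' @param structure a [cap_structure].
#' @inheritParams buried_surface_area
#' @return data.frame `chain_a`, `chain_b`, `bsa` for all unordered pairs.
#' @export
interface_table <- function(structure, probe = 1.4, n_sphere_points = 960L,
                            radii = element_radii(), exclude_water = TRUE) {
  ch <- unique(select_atoms(structure, NULL, exclude_water)$chain)
  if (length(ch) < 2)
    cap_stop("capscan_argument_error", "need at least two chains")
  pairs <- utils::combn(ch, 2)
  data.frame(
    chain_a = pairs[1, ], chain_b = pairs[2, ],
    bsa = apply(pairs, 2, function(p)
      buried_surface_area(structure, p[1], p[2], probe, n_sphere_points,
                          radii, exclude_water)))
}
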