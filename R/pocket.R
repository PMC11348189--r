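# --- voxel-grid helpers -----------------------------------------------------

# zero-padded shift of a 3D logical array by integer offset d
shift3 <- function(mask, d) {
  dm <- dim(mask)
  out <- array(FALSE, dm)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (d[k] >= 0) {
      dst[[k]] <- (1 + d[k]):dm[k]; src[[k]] <- 1:(dm[k] - d[k])
    } else {
      dst[[k]] <- 1:(dm[k] + d[k]); src[[k]] <- (1 - d[k]):dm[k]
    }
    if (dm[k] <= abs(d[k])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

ball_offsets <- function(radius_cells) {
  r <- floor(radius_cells + 1e-9)
  g <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  g <- g[g$i^2 + g$j^2 + g$k^2 <= radius_cells^2 + 1e-9 &
           (g$i != 0 | g$j != 0 | g$k != 0), , drop = FALSE]
  as.matrix(g)
}

# morphological dilation by a Euclidean ball; large radii are realized as
# iterated dilations by smaller digitized balls (sub-voxel approximation)
dilate_mask <- function(mask, radius_cells, max_kernel = 500L) {
  if (radius_cells <= 0) return(mask)
  n_steps <- 1L
  while (nrow(ball_offsets(radius_cells / n_steps)) > max_kernel)
    n_steps <- n_steps + 1L
  off <- ball_offsets(radius_cells / n_steps)
  for (s in seq_len(n_steps)) {
    out <- mask
    for (k in seq_len(nrow(off))) out <- out | shift3(mask, off[k, ])
    mask <- out
  }
  mask
}

# 26-connected components of a voxel mask; returns per-voxel component label
# (aligned with which(mask)) using an igraph over voxel adjacencies
voxel_components <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L)
    return(list(idx = idx, labels = integer(0)))
  pos <- arrayInd(idx, dm)
  id_of <- array(0L, dm)
  id_of[idx] <- seq_along(idx)
  off <- ball_offsets(sqrt(3) + 1e-6)        # all 26 neighbors
  off <- off[off[, 1] > 0 | (off[, 1] == 0 & (off[, 2] > 0 |
              (off[, 2] == 0 & off[, 3] > 0))), , drop = FALSE]
  edges <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    np <- sweep(pos, 2, off[k, ], "+")
    ok <- np[, 1] >= 1 & np[, 1] <= dm[1] & np[, 2] >= 1 & np[, 2] <= dm[2] &
          np[, 3] >= 1 & np[, 3] <= dm[3]
    nid <- integer(nrow(pos))
    nid[ok] <- id_of[np[ok, , drop = FALSE]]
    hit <- nid > 0L
    if (any(hit)) edges[[k]] <- rbind(which(hit), nid[hit])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(em)) g <- igraph::add_edges(g, as.vector(em))
  list(idx = idx, labels = igraph::components(g)$membership)
}

# --- pocket volume ----------------------------------------------------------

#' Grid-based pocket (cavity) volume
#'
#' Two-probe cavity estimation: grid points farther than `atom radius +
#' probe_min` from every atom are empty; the bulk solvent is the empty region
#' reachable from the bounding-box faces by a sphere of radius `probe_max`
#' (flood fill of the large-probe-open region, then a `probe_max` rolling
#' sweep). Remaining empty points form cavities; the volume of the component
#' containing (or nearest to) `seed_point` is returned, or that of the
#' largest component when no seed is given.
#'
#' @param structure a [cap_structure].
#' @param seed_point optional length-3 coordinate inside the pocket of
#'   interest (e.g. the centroid of the catalytic atoms).
#' @param probe_min small probe radius (A) defining the molecular surface,
#'   default 1.4.
#' @param probe_max large probe radius (A) used to peel off bulk solvent,
#'   default 3.4.
#' @param grid_spacing voxel edge (A), default 0.5 (must be <= 1).
#' @param radii element radii table, see [element_radii()].
#' @param exclude_water drop waters before gridding?
#' @return cavity volume in A^3 (voxel count x spacing^3), with attributes
#'   `n_components` and `component_volumes`.
#' @export
pocket_volume <- function(structure, seed_point = NULL, probe_min = 1.4,
                          probe_max = 3.4, grid_spacing = 0.5,
                          radii = element_radii(), exclude_water = TRUE) {
  if (probe_min > probe_max)
    cap_stop("capscan_argument_error", "probe_min must be <= probe_max")
  if (grid_spacing > 1.0)
    cap_stop("capscan_argument_error", "grid_spacing must be <= 1.0 A")
  atoms <- select_atoms(structure, NULL, exclude_water)
  if (nrow(atoms) == 0L) {
    warning("no atoms: everything is bulk solvent, volume 0")
    return(0)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- atom_radii(atoms, radii)
  pad <- probe_max + max(r) + 2 * grid_spacing
  xs <- seq(min(xyz[, 1]) - pad, max(xyz[, 1]) + pad, by = grid_spacing)
  ys <- seq(min(xyz[, 2]) - pad, max(xyz[, 2]) + pad, by = grid_spacing)
  zs <- seq(min(xyz[, 3]) - pad, max(xyz[, 3]) + pad, by = grid_spacing)
  dm <- c(length(xs), length(ys), length(zs))

  # distance to the nearest atom surface, updated atom-by-atom in local boxes
  dmin <- array(Inf, dm)
  for (i in seq_len(nrow(xyz))) {
    reach <- r[i] + probe_max + 2 * grid_spacing
    ix <- which(abs(xs - xyz[i, 1]) <= reach)
    iy <- which(abs(ys - xyz[i, 2]) <= reach)
    iz <- which(abs(zs - xyz[i, 3]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer((xs[ix] - xyz[i, 1])^2, (ys[iy] - xyz[i, 2])^2, "+"),
                (zs[iz] - xyz[i, 3])^2, "+")
    dmin[ix, iy, iz] <- pmin(dmin[ix, iy, iz], sqrt(d2) - r[i])
  }

  if (!is.null(seed_point)) {
    d_seed <- min(row_norms(sweep(xyz, 2, seed_point)) - r)
    if (d_seed < 0)
      cap_stop("capscan_argument_error", "seed point lies inside an atom")
  }

  empty <- dmin > probe_min
  open_large <- dmin > probe_max

  # flood fill: large-probe-open components touching the box boundary
  comp <- voxel_components(open_large)
  pos <- arrayInd(comp$idx, dm)
  on_boundary <- pos[, 1] == 1 | pos[, 1] == dm[1] |
                 pos[, 2] == 1 | pos[, 2] == dm[2] |
                 pos[, 3] == 1 | pos[, 3] == dm[3]
  outside_labels <- unique(comp$labels[on_boundary])
  outside <- array(FALSE, dm)
  outside[comp$idx[comp$labels %in% outside_labels]] <- TRUE

  bulk <- empty & dilate_mask(outside, probe_max / grid_spacing)
  cavity <- empty & !bulk

  cav <- voxel_components(cavity)
  if (length(cav$idx) == 0L) {
    warning("no cavity found; volume 0")
    return(0)
  }
  vols <- tabulate(cav$labels) * grid_spacing^3
  if (is.null(seed_point)) {
    pick <- which.max(vols)
  } else {
    cav_pos <- arrayInd(cav$idx, dm)
    cav_xyz <- cbind(xs[cav_pos[, 1]], ys[cav_pos[, 2]], zs[cav_pos[, 3]])
    nearest <- which.min(row_norms(sweep(cav_xyz, 2, seed_point)))
    pick <- cav$labels[nearest]
  }
  structure(vols[pick], n_components = length(vols), component_volumes = vols)
}
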