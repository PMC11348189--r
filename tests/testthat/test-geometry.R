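test_that("Kabsch superposition recovers applied rigid transforms exactly", {
  set.seed(4)
  X <- matrix(rnorm(36), 12, 3)
  expect_equal(superpose(X, X)$rmsd, 0, tolerance = 1e-12)
  expect_equal(superpose(X, X)$rotation, diag(3), tolerance = 1e-9)
  R <- random_rotation(6); t_vec <- c(4, -2, 9)
  Y <- sweep(X %*% t(R), 2, t_vec, "+")
  tr <- superpose(X, Y)
  expect_lt(tr$rmsd, 1e-9)
  expect_equal(tr$rotation, R, tolerance = 1e-9)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  # applying the recovered transform and its inverse restores coordinates
  moved <- apply_transform(tr, X)
  back <- sweep(moved, 2, tr$translation) %*% tr$rotation
  expect_equal(back, X, tolerance = 1e-9)
})

test_that("superposition rmsd matches a brute-force rotation-grid oracle", {
  set.seed(9)
  A <- matrix(rnorm(30), 10, 3)
  B <- matrix(rnorm(30), 10, 3)
  fit <- superpose(A, B)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  grid_best <- Inf
  step <- pi / 36   # 5-degree grid over ZYZ Euler angles
  for (a1 in seq(0, 2 * pi - step, by = step))
    for (a2 in seq(0, pi, by = step))
      for (a3 in seq(0, 2 * pi - step, by = step)) {
        Rz1 <- rbind(c(cos(a1), -sin(a1), 0), c(sin(a1), cos(a1), 0), c(0, 0, 1))
        Ry <- rbind(c(cos(a2), 0, sin(a2)), c(0, 1, 0), c(-sin(a2), 0, cos(a2)))
        Rz2 <- rbind(c(cos(a3), -sin(a3), 0), c(sin(a3), cos(a3), 0), c(0, 0, 1))
        rmsd <- sqrt(mean(rowSums((Ac %*% t(Rz2 %*% Ry %*% Rz1) - Bc)^2)))
        if (rmsd < grid_best) grid_best <- rmsd
      }
  expect_lte(fit$rmsd, grid_best + 1e-9)    # least squares cannot lose
  expect_lt(grid_best - fit$rmsd, 0.05)     # and the grid gets this close
})

test_that("superposition agrees with an independent reference implementation", {
  set.seed(12)
  A <- matrix(rnorm(45), 15, 3)
  B <- A %*% t(random_rotation(3)) + matrix(rnorm(45, sd = 0.5), 15, 3)
  fit <- superpose(A, B)
  moved <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(B)), mobile = as.numeric(t(A))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(moved, ncol = 3, byrow = TRUE) - B)^2)))
  expect_equal(fit$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("degenerate point sets are refused", {
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               class = "capscan_degeneracy_error")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), class = "capscan_degeneracy_error")
})

test_that("segment displacement is zero against itself and recovers planted shifts", {
  ens <- small_ensemble(n_members = 8L, state_fractions = c(0.5, 0.25, 0.25),
                        displacement = 8)
  maps <- ensemble_maps(ens)
  seg <- ens$spec$event_segment
  d0 <- segment_displacement(ens$members[[1]], ens$members[[1]],
                             maps[[1]], maps[[1]], seg)
  expect_equal(unname(d0), c(0, 0), tolerance = 1e-9)
  i_a <- which(ens$labels == "alternative")[1]
  d <- segment_displacement(ens$members[[1]], ens$members[[i_a]],
                            maps[[1]], maps[[i_a]], seg)
  expect_equal(unname(d[["mean"]]), 8, tolerance = 1e-6)
  expect_equal(unname(d[["max"]]), 8, tolerance = 1e-6)
  # displacement against a member that lacks the segment entirely is
  # undefined, with a warning (sequence crafted so the alignment cannot
  # place any residue inside the deleted segment)
  aa <- rep("L", 120); aa[40:55] <- "W"
  xyz <- make_coil(120, seed = 31)
  full <- capscan:::ca_chain_structure(xyz, 1:120, aa, "full")
  keep <- setdiff(1:120, 40:55)
  gone <- capscan:::ca_chain_structure(xyz[keep, ], keep, aa[keep], "gone")
  m_full <- map_to_reference(full, "A", paste(aa, collapse = ""))
  m_gone <- map_to_reference(gone, "A", paste(aa, collapse = ""))
  expect_warning(
    du <- segment_displacement(full, gone, m_full, m_gone, c(40, 55)),
    "undefined")
  expect_true(all(is.na(du)))
})

test_that("named distances resolve selectors and measure Euclidean separation", {
  s <- make_site_fixture()
  expect_equal(named_distance(s, list(elety = "C1"), list(elety = "C6")), 3.4)
  a <- data.frame(chain = "A", resno = 1:2, insert = "", resid = "DUM", aa = "X",
                  elety = c("X1", "X2"), elesy = "C",
                  x = c(0, 1), y = 0, z = 0, o = 1, b = 0, het = TRUE)
  s2 <- cap_structure(a)
  expect_equal(named_distance(s2, list(elety = "X1"), list(elety = "X2")), 1.0)
  expect_error(named_distance(s2, list(elety = "NOPE"), list(elety = "X2")),
               class = "capscan_selection_error")
  expect_error(named_distance(s2, list(resid = "DUM"), list(elety = "X2")),
               class = "capscan_selection_error")
})

test_that("coordination shells honor the cutoff and demand unique ions", {
  s <- make_site_fixture()
  shell <- coordination_shell(s, list(elety = "K"))
  expect_equal(shell$dist, c(2.4, 2.8, 3.2), tolerance = 1e-9)
  expect_false(is.unsorted(shell$dist))
  expect_equal(nrow(coordination_shell(s, list(elety = "K"), cutoff = 2.0)), 0)
  two <- make_site_fixture(n_ions = 2L)
  expect_error(coordination_shell(two, list(elety = "K")),
               class = "capscan_selection_error")
  expect_equal(nrow(coordination_shell(two, list(elety = "K", resno = 2L))), 3)
})

test_that("pocket volume matches the analytic hollow-sphere value", {
  sh <- make_shell_fixture(inner_radius = 6)
  v <- pocket_volume(sh)
  analytic <- 4 / 3 * pi * (6 - 1.4)^3
  expect_lt(abs(v - analytic) / analytic, 0.10)
})

test_that("pocket volume converges as the grid is refined", {
  sh <- make_shell_fixture(inner_radius = 4.5)
  v1 <- pocket_volume(sh, grid_spacing = 0.5)
  v2 <- pocket_volume(sh, grid_spacing = 0.25)
  expect_lt(abs(v2 - v1) / v1, 0.03)
})

test_that("pocket volume handles degenerate inputs per contract", {
  sh <- make_shell_fixture(inner_radius = 5)
  expect_error(pocket_volume(sh, seed_point = as.numeric(sh$atoms[1, c("x", "y", "z")])),
               class = "capscan_argument_error")
  # a single atom has no cavity at all
  lone <- cap_structure(data.frame(chain = "A", resno = 1L, insert = "",
                                   resid = "DUM", aa = "X", elety = "C",
                                   elesy = "C", x = 0, y = 0, z = 0, o = 1,
                                   b = 0, het = TRUE))
  expect_warning(v <- pocket_volume(lone), "no cavity")
  expect_equal(as.numeric(v), 0)
  expect_error(pocket_volume(sh, grid_spacing = 1.5),
               class = "capscan_argument_error")
})

test_that("a seeded pocket query returns the component around the seed", {
  sh <- make_shell_fixture(inner_radius = 5)
  v_seeded <- pocket_volume(sh, seed_point = c(0, 0, 0))
  v_largest <- pocket_volume(sh)
  expect_equal(as.numeric(v_seeded), as.numeric(v_largest))
})

test_that("SASA matches the analytic sphere area for isolated and distant atoms", {
  mk <- function(x) data.frame(chain = "A", resno = seq_along(x), insert = "",
                               resid = "DUM", aa = "X", elety = "C", elesy = "C",
                               x = x, y = 0, z = 0, o = 1, b = 0, het = TRUE)
  one <- cap_structure(mk(0))
  analytic <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(sum(sasa(one)) - analytic) / analytic, 0.01)
  two <- cap_structure(mk(c(0, 100)))
  expect_equal(sum(sasa(two)), 2 * analytic, tolerance = 0.01)
  # an atom tightly caged by a shell has zero accessible surface
  caged <- cap_structure(rbind(make_shell_fixture(inner_radius = 2)$atoms, mk(0)))
  s <- sasa(caged)
  expect_equal(tail(s, 1), 0)
})

test_that("unknown elements are refused with the offenders listed", {
  a <- data.frame(chain = "A", resno = 1L, insert = "", resid = "UNK", aa = "X",
                  elety = "QQ", elesy = "QQ", x = 0, y = 0, z = 0, o = 1, b = 0,
                  het = TRUE)
  expect_error(sasa(cap_structure(a)), "QQ")
  expect_error(sasa(cap_structure(a)), class = "capscan_radius_error")
})

test_that("buried surface area is symmetric, near zero for distant chains, and refines stably", {
  slab <- function(chain, offset) {
    g <- expand.grid(x = seq(0, 6, by = 2), y = seq(0, 6, by = 2), z = offset)
    data.frame(chain = chain, resno = seq_len(nrow(g)), insert = "",
               resid = "DUM", aa = "X", elety = "C", elesy = "C",
               x = g$x, y = g$y, z = g$z, o = 1, b = 0, het = TRUE)
  }
  far <- cap_structure(rbind(slab("A", 0), slab("B", 100)))
  expect_equal(buried_surface_area(far, "A", "B"), 0, tolerance = 1)
  touching <- cap_structure(rbind(slab("A", 0), slab("B", 3.6)))
  b_ab <- buried_surface_area(touching, "A", "B")
  b_ba <- buried_surface_area(touching, "B", "A")
  expect_gt(b_ab, 0)
  expect_equal(b_ab, b_ba)
  refined <- buried_surface_area(touching, "A", "B", n_sphere_points = 1920L)
  expect_lt(abs(b_ab - refined) / refined, 0.02)
  expect_error(buried_surface_area(touching, "A", "A"),
               class = "capscan_argument_error")
  expect_error(buried_surface_area(touching, character(0), "B"),
               class = "capscan_argument_error")
})

test_that("all geometry is invariant under global rigid motion", {
  s <- make_site_fixture()
  R <- random_rotation(5); t_vec <- c(-7, 13, 4)
  moved <- rigid_move(s, R, t_vec)
  expect_equal(named_distance(moved, list(elety = "C1"), list(elety = "C6")),
               3.4, tolerance = 1e-9)
  expect_equal(coordination_shell(moved, list(elety = "K"))$dist,
               coordination_shell(s, list(elety = "K"))$dist, tolerance = 1e-9)
  expect_equal(sum(sasa(moved)), sum(sasa(s)), tolerance = 0.01 * sum(sasa(s)))
  sh <- make_shell_fixture(inner_radius = 5)
  sh_moved <- rigid_move(sh, R, t_vec)
  v0 <- as.numeric(pocket_volume(sh))
  v1 <- as.numeric(pocket_volume(sh_moved))
  expect_lt(abs(v1 - v0) / v0, 0.05)
})

test_that("the interface table covers every chain pair once", {
  tri <- do.call(rbind, lapply(seq_len(3), function(i) {
    g <- expand.grid(x = seq(0, 4, by = 2), y = seq(0, 4, by = 2),
                     z = (i - 1) * 3.6)
    data.frame(chain = LETTERS[i], resno = seq_len(nrow(g)), insert = "",
               resid = "DUM", aa = "X", elety = "C", elesy = "C",
               x = g$x, y = g$y, z = g$z, o = 1, b = 0, het = TRUE)
  }))
  tab <- interface_table(cap_structure(tri), n_sphere_points = 240L)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$bsa > -1))
  # adjacent layers bury surface; the distal pair buries much less
  ac <- tab$bsa[tab$chain_a == "A" & tab$chain_b == "C"]
  ab <- tab$bsa[tab$chain_a == "A" & tab$chain_b == "B"]
  expect_gt(ab, ac)
})
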