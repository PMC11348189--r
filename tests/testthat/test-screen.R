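# hand-built order matrix: L positions x n members
toy_matrix <- function(L, members, events) {
  m <- matrix("O", L, members)
  for (e in events) {
    pos <- e$segment[1]:e$segment[2]
    m[pos, seq_len(e$n_h)] <- "H"
    m[pos, e$n_h + seq_len(e$n_d)] <- "D"
  }
  class(m) <- c("cap_order_matrix", class(m))
  m
}

test_that("the order matrix reflects planted order states", {
  ens <- small_ensemble(n_members = 8L, chain_length = 80L,
                        event_segment = c(30L, 45L),
                        state_fractions = c(0.5, 0.5, 0), missing_prefix = 10L)
  maps <- ensemble_maps(ens)
  om <- build_order_matrix(ens, maps)
  expect_equal(dim(om), c(80L, 8L))
  seg <- 30:45
  for (m in seq_len(8)) {
    if (ens$labels[m] == "folded") expect_true(all(om[seg, m] == "H"))
    else expect_true(all(om[seg, m] == "D"))
    expect_true(all(om[1:10, m] == "D"))   # unresolved N terminus
  }
  # D exactly where coordinates are missing
  expect_true(all(om[11:29, ] != "D"))
})

test_that("a homogeneous ensemble yields zero folding events", {
  ens <- small_ensemble(n_members = 6L, state_fractions = c(1, 0, 0))
  om <- build_order_matrix(ens, ensemble_maps(ens))
  ev <- detect_folding_events(om)
  expect_equal(nrow(ev), 0)
})

test_that("a planted three-state event is recovered with tight bounds", {
  ens <- make_ensemble(ensemble_spec(
    n_members = 26L, chain_length = 150L, event_segment = c(60L, 75L),
    state_fractions = c(0.23, 0.69, 0.08), displacement = 8,
    missing_prefix = 0L, noise_sigma = 0, seed = 5))
  om <- build_order_matrix(ens, ensemble_maps(ens))
  ev <- detect_folding_events(om)
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$start - 60), 2)
  expect_lte(abs(ev$end - 75), 2)
  expect_gte(ev$helical_members, 0.15)
  expect_gte(ev$disordered_members, 0.15)
})

test_that("well-separated events stay separate; nearby runs merge", {
  m <- toy_matrix(120, 10, list(
    list(segment = c(20, 35), n_h = 3, n_d = 6),
    list(segment = c(66, 80), n_h = 4, n_d = 5)))
  ev <- detect_folding_events(m)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$start, c(20, 66))
  # two positive runs separated by a gap of 2 merge into one event
  m2 <- toy_matrix(120, 10, list(
    list(segment = c(20, 30), n_h = 3, n_d = 6),
    list(segment = c(33, 43), n_h = 3, n_d = 6)))
  expect_equal(nrow(detect_folding_events(m2)), 1)
})

test_that("detection is invariant under member reordering", {
  ens <- small_ensemble(n_members = 12L)
  om <- build_order_matrix(ens, ensemble_maps(ens))
  ev1 <- detect_folding_events(om)
  perm <- om[, sample(ncol(om))]
  class(perm) <- class(om)
  ev2 <- detect_folding_events(perm)
  expect_equal(as.data.frame(ev1), as.data.frame(ev2))
})

test_that("raising the disorder threshold never increases the event count", {
  ens <- small_ensemble(n_members = 15L, state_fractions = c(0.4, 0.4, 0.2))
  om <- build_order_matrix(ens, ensemble_maps(ens))
  counts <- vapply(c(0.05, 0.15, 0.3, 0.5, 0.8), function(td)
    nrow(detect_folding_events(om, detect_params(theta_d = td))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("tiny ensembles are refused unless explicitly allowed", {
  ens <- small_ensemble(n_members = 3L, state_fractions = c(0.4, 0.6, 0))
  om <- build_order_matrix(ens, ensemble_maps(ens))
  expect_error(detect_folding_events(om), class = "capscan_detection_error")
  expect_warning(ev <- detect_folding_events(om, allow_small = TRUE),
                 "small ensemble")
  expect_s3_class(ev, "cap_events")
  one <- om[, 1, drop = FALSE]
  class(one) <- class(om)
  expect_error(detect_folding_events(one, allow_small = TRUE),
               class = "capscan_detection_error")
})

test_that("state fractions are recovered exactly on a noise-free planted ensemble", {
  ens <- small_ensemble(n_members = 20L, state_fractions = c(0.25, 0.65, 0.10),
                        displacement = 8)
  maps <- ensemble_maps(ens)
  st <- classify_states(ens, maps, ens$spec$event_segment)
  expect_equal(unname(st$fractions), c(0.25, 0.65, 0.10))
  expect_identical(unname(st$labels), ens$labels)
  expect_equal(sum(st$fractions), 1, tolerance = 1e-12)
})

test_that("an all-folded ensemble classifies as (1, 0, 0)", {
  ens <- small_ensemble(n_members = 6L, state_fractions = c(1, 0, 0))
  st <- classify_states(ens, ensemble_maps(ens), ens$spec$event_segment)
  expect_equal(unname(st$fractions), c(1, 0, 0))
})

test_that("members displaced beyond the threshold are never labeled folded", {
  ens <- small_ensemble(n_members = 10L, state_fractions = c(0.5, 0.2, 0.3),
                        displacement = 8)
  st <- classify_states(ens, ensemble_maps(ens), ens$spec$event_segment,
                        displacement_threshold = 4)
  alt <- ens$labels == "alternative"
  expect_true(all(st$labels[alt] == "alternative"))
  expect_true(all(st$displacement[alt] > 4))
})

test_that("fraction recovery survives moderate coordinate noise", {
  ens <- make_ensemble(ensemble_spec(
    n_members = 20L, chain_length = 120L, event_segment = c(40L, 55L),
    state_fractions = c(0.25, 0.65, 0.10), displacement = 8,
    noise_sigma = 0.3, seed = 21))
  st <- classify_states(ens, ensemble_maps(ens), ens$spec$event_segment)
  accuracy <- mean(st$labels == ens$labels)
  expect_gte(accuracy, 0.95)
})

test_that("the dip statistic is exact arithmetic on noise-free profiles", {
  flat <- cap_plddt(rep(80, 200))
  r0 <- plddt_dip_test(flat, c(90, 105), seed = 1)
  expect_equal(r0$delta, 0)
  expect_gt(r0$p_value, 0.05)
  dipped <- make_plddt(200, baseline = 80, dip_depth = 10,
                       dip_segment = c(90, 105), noise_sigma = 0, seed = 1)
  r1 <- plddt_dip_test(dipped, c(90, 105), seed = 1)
  expect_equal(r1$delta, -10)
  expect_lte(r1$p_value, 0.01)
})

test_that("dip p-values respect the add-one permutation rule and bounds", {
  prof <- make_plddt(150, baseline = 85, dip_depth = 6, dip_segment = c(60, 75),
                     noise_sigma = 2, seed = 8)
  r <- plddt_dip_test(prof, c(60, 75), n_perm = 199, seed = 8)
  expect_gte(r$p_value, 1 / 200)
  expect_lte(r$p_value, 1)
  expect_equal(r$p_value, (1 + sum(r$null <= r$delta)) / (r$n_perm + 1))
  # determinism from the seed
  r2 <- plddt_dip_test(prof, c(60, 75), n_perm = 199, seed = 8)
  expect_identical(r$null, r2$null)
  expect_error(plddt_dip_test(prof, c(1, 149)), class = "capscan_argument_error")
  expect_error(plddt_dip_test(prof, c(60, 75), n_perm = 50),
               class = "capscan_argument_error")
})
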