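test_that("map functions convert distance to recombination fraction", {
  expect_equal(map_distance_to_r(0), 0)
  expect_equal(map_distance_to_r(0, "kosambi"), 0)
  expect_equal(map_distance_to_r(30), (1 - exp(-0.6)) / 2)
  expect_equal(map_distance_to_r(30), 0.2256, tolerance = 1e-4)
  expect_equal(map_distance_to_r(30, "kosambi"), tanh(0.6) / 2)
  expect_equal(map_distance_to_r(1e6), 0.5, tolerance = 1e-12)
  expect_error(map_distance_to_r(-1), "must be >= 0")
  d <- seq(0.5, 200, 0.5)
  rh <- map_distance_to_r(d)
  rk <- map_distance_to_r(d, "kosambi")
  expect_true(all(diff(rh) > 0))
  expect_true(all(rk > rh)) # Kosambi maps a given distance to more recombination
  expect_true(all(abs(rh[d <= 1] - rk[d <= 1]) <= 1e-4)) # agree to first order
})

test_that("coupling-phase diagonal proportions follow the worked 30 cM case", {
  pp <- expected_phase_proportions(map_distance_to_r(30))
  expect_equal(round(pp$p_parental, 4), 0.9218)
  expect_equal(round(pp$p_recombinant, 4), 0.0782)
  # Kosambi gives a different split for the same interval
  ppk <- expected_phase_proportions(map_distance_to_r(30, "kosambi"))
  expect_equal(round(ppk$p_parental, 4), 0.8812)
  expect_equal(expected_phase_proportions(0)$p_parental, 1)
  expect_equal(expected_phase_proportions(0.5)$p_parental, 0.5)
  expect_error(expected_phase_proportions(0.6), "0.5")
})

test_that("diagonal proportions normalize and decrease in r", {
  r <- seq(0, 0.5, length.out = 101)
  pp <- expected_phase_proportions(r)
  expect_equal(pp$p_parental + pp$p_recombinant, rep(1, length(r)))
  expect_true(all(diff(pp$p_parental) < 0))
  expect_true(all(pp$p_parental >= pp$p_recombinant))
})

test_that("pair counts tally the double-homozygote diagonal", {
  g <- cbind(
    m1 = c("A", "A", "B", "B"), m2 = c("A", "A", "B", "B"),
    m3 = c("B", "B", "A", "A"), m4 = c("A", "H", "B", "-"),
    m5 = c("A", "A", "A", "B")
  )
  rownames(g) <- paste0("i", 1:4)
  pop <- pop_data(g, coding = "ABH", generation = 8)
  expect_equal(
    unlist(pair_counts(pop, "m1", "m2")),
    c(n_parental = 4, n_recombinant = 0, n_uninformative = 0)
  )
  expect_equal(
    unlist(pair_counts(pop, "m1", "m3")),
    c(n_parental = 0, n_recombinant = 4, n_uninformative = 0)
  )
  expect_equal(
    unlist(pair_counts(pop, "m4", "m5")),
    c(n_parental = 1, n_recombinant = 1, n_uninformative = 2)
  )
  expect_error(pair_counts(pop, "m1", "nope"), "nope")
})

test_that("the worked 35-vs-15 pair is called coupling with a significant test", {
  call <- infer_pair_phase(35, 15, d = 30)
  expect_equal(call$phase, "coupling")
  expect_equal(call$statistic, 8)
  expect_lt(call$p_value, 0.05)
  expect_equal(call$p_value, 0.004678, tolerance = 1e-3)
  expect_equal(round(call$expected_p_parental, 4), 0.9218)
  expect_equal(infer_pair_phase(15, 35, d = 30)$phase, "repulsion")
  expect_equal(infer_pair_phase(20, 20, d = 30)$phase, "ambiguous")
  amb <- infer_pair_phase(0, 0, d = 30)
  expect_equal(amb$phase, "ambiguous")
  expect_true(is.na(amb$statistic))
})

test_that("a flipped marker inside a group is detected and recoded back", {
  pattern <- c("A", "A", "A", "B", "B", "B", "A", "B", "H", "-")
  pop <- toy_abh(n_markers = 3, pattern = pattern, parents = FALSE)
  flipped_geno <- pop$geno
  flipped_geno[, "m2"] <- crossphase:::.swap_ab(flipped_geno[, "m2"])
  flipped <- pop_data(flipped_geno, coding = "ABH", generation = 8)
  map <- toy_map(c("m1", "m2", "m3"), spacing = 5)

  ph <- phase_linkage_group(flipped, map)
  expect_equal(ph$phase, c("coupling", "repulsion", "coupling"))
  expect_equal(ph$flipped, c(FALSE, TRUE, FALSE))
  expect_true(all(ph$arbitrary)) # no anchors: group orientation is arbitrary
  restored <- recode_abh(flipped, ph)
  expect_identical(restored$geno, pop$geno)
})

test_that("gaps wider than max_gap start a new arbitrary segment", {
  pattern <- c("A", "A", "A", "B", "B", "B")
  pop <- toy_abh(n_markers = 3, pattern = pattern, parents = FALSE)
  map <- genetic_map(c("m1", "m2", "m3"), rep("LG1", 3), c(0, 10, 100))
  ph <- phase_linkage_group(pop, map, max_gap = 50)
  expect_equal(ph$segment, c(1L, 1L, 2L))
  expect_true(ph$arbitrary[3])
  expect_true(is.na(ph$anchor[3])) # new segment seeds itself
})

test_that("anchors orient a group and markers left of the first anchor", {
  pattern <- c("A", "A", "A", "B", "B", "B", "A", "B")
  pop <- toy_abh(n_markers = 4, pattern = pattern, parents = FALSE)
  map <- toy_map(paste0("m", 1:4), spacing = 5)
  ph <- phase_linkage_group(pop, map, anchors = c(m3 = TRUE))
  expect_equal(ph$phase[3], "anchor")
  expect_false(any(ph$arbitrary))
  # all markers agree with m3, whose labelling is declared flipped
  expect_true(all(ph$flipped))
  # m1 and m2 were oriented right-to-left from the anchor side
  expect_false(is.na(ph$flipped[1]))
})

test_that("map markers absent from the dataset error unless skipped", {
  pop <- toy_abh(n_markers = 2, parents = FALSE)
  map <- toy_map(c("m1", "m2", "ghost"))
  expect_error(phase_linkage_group(pop, map), "ghost")
  ph <- phase_linkage_group(pop, map, skip_missing = TRUE)
  expect_equal(nrow(ph), 2)
})

test_that("recoding is an involution and the identity without repulsion calls", {
  sim <- simulate_population(sim_config(
    n_ind = 60, generation = 8, markers_per_group = 20,
    missing_rate = 0.05, flip_rate = 0.3, parents_in_output = FALSE,
    seed = 77
  ))
  ph <- phase_linkage_group(sim$data, sim$map)
  once <- recode_abh(sim$data, ph)
  twice <- recode_abh(once, ph)
  expect_identical(twice$geno, sim$data$geno)
  no_flip <- ph
  no_flip$flipped[] <- FALSE
  expect_identical(recode_abh(sim$data, no_flip)$geno, sim$data$geno)
  acgt <- simulate_population(sim_config(
    n_ind = 10, generation = 8, markers_per_group = 3,
    coding = "ACGT", seed = 1
  ))
  expect_error(recode_abh(acgt$data, ph), "ABH")
})

test_that("phase recovery is near-perfect on a flip-injected RIL", {
  sim <- simulate_population(sim_config(
    n_ind = 150, generation = 8, markers_per_group = 100, spacing_cM = 2,
    flip_rate = 0.2, missing_rate = 0.05, parents_in_output = FALSE,
    seed = 2024
  ))
  ph <- phase_linkage_group(sim$data, sim$map)
  truth <- sim$truth$flipped[ph$marker]
  # group orientation is arbitrary without parental anchors: score modulo
  # the global flip
  agree <- mean(!is.na(ph$flipped) & ph$flipped == truth)
  agree_inv <- mean(!is.na(ph$flipped) & ph$flipped == !truth)
  expect_gte(max(agree, agree_inv), 0.99)
})
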