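test_that("selfing-series proportions reproduce the printed F1-F3 fractions", {
  # (hom1, het, hom2) per cross type and generation
  expect_equal(unname(expected_proportions("hom_hom", 1)), c(0, 1, 0))
  expect_equal(unname(expected_proportions("het_het", 1)), c(1 / 4, 1 / 2, 1 / 4))
  expect_equal(unname(expected_proportions("hom_het", 1)), c(1 / 2, 1 / 2, 0))
  expect_equal(unname(expected_proportions("hom_hom", 2)), c(1 / 4, 1 / 2, 1 / 4))
  expect_equal(unname(expected_proportions("het_het", 2)), c(3 / 8, 1 / 4, 3 / 8))
  expect_equal(unname(expected_proportions("hom_het", 2)), c(5 / 8, 1 / 4, 1 / 8))
  expect_equal(unname(expected_proportions("hom_hom", 3)), c(3 / 8, 1 / 4, 3 / 8))
  expect_equal(unname(expected_proportions("het_het", 3)), c(7 / 16, 1 / 8, 7 / 16))
  expect_equal(unname(expected_proportions("hom_het", 3)), c(11 / 16, 1 / 8, 3 / 16))
})

test_that("proportions approach the fixation limits as x grows", {
  expect_equal(unname(expected_proportions("hom_hom", 60)),
    c(1 / 2, 0, 1 / 2),
    tolerance = 1e-12
  )
  expect_equal(unname(expected_proportions("het_het", 60)),
    c(1 / 2, 0, 1 / 2),
    tolerance = 1e-12
  )
  expect_equal(unname(expected_proportions("hom_het", 60)),
    c(3 / 4, 0, 1 / 4),
    tolerance = 1e-12
  )
  expect_error(expected_proportions("hom_hom", 0), "generation")
})

test_that("each selfing generation halves the heterozygotes and splits the rest", {
  for (cross in c("hom_hom", "het_het", "hom_het")) {
    for (x in 1:30) {
      p <- expected_proportions(cross, x)
      q <- expected_proportions(cross, x + 1)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_equal(q[["p_het"]], p[["p_het"]] / 2)
      expect_equal(q[["p_hom1"]], p[["p_hom1"]] + p[["p_het"]] / 4)
      expect_equal(q[["p_hom2"]], p[["p_hom2"]] + p[["p_het"]] / 4)
    }
  }
})

test_that("homozygote x homozygote crosses always segregate 1:1", {
  for (x in 1:30) {
    p <- expected_proportions("hom_hom", x)
    expect_identical(p[["p_hom1"]], p[["p_hom2"]])
  }
})

test_that("the 1:1 homozygote test matches hand calculations", {
  expect_equal(chi_square_1to1(25, 25)$statistic, 0)
  expect_equal(chi_square_1to1(25, 25)$p_value, 1)
  r <- chi_square_1to1(35, 15)
  expect_equal(r$statistic, 8)
  expect_equal(r$p_value, 0.004678, tolerance = 1e-3)
  for (k in c(1, 7, 100)) expect_equal(chi_square_1to1(k, k)$statistic, 0)
  expect_equal(
    chi_square_1to1(12, 30)$statistic,
    chi_square_1to1(30, 12)$statistic
  )
  expect_error(chi_square_1to1(0, 0), "uninformative")
})

test_that("the major-vs-rest test evaluates the generation-x expectation", {
  r <- chi_square_major_vs_rest(20, 20, x = 6)
  # E_major = (3/4 - 1/2^7) * 40 = 29.6875, E_rest = 10.3125
  expect_equal(r$statistic, (20 - 29.6875)^2 / 29.6875 + (20 - 10.3125)^2 / 10.3125)
  expect_equal(r$statistic, 12.2616, tolerance = 1e-4)
  # observed equal to the expectation gives exactly zero: x = 1 expects 1:1
  expect_equal(chi_square_major_vs_rest(10, 10, x = 1)$statistic, 0)
  # near the 3:1 limit the statistic is tiny
  expect_lt(chi_square_major_vs_rest(30, 10, x = 40)$statistic, 1e-8)
  # maximal departure is decisive
  expect_lt(chi_square_major_vs_rest(0, 40, x = 8)$p_value, 1e-6)
  expect_error(chi_square_major_vs_rest(0, 0, x = 8), "uninformative")
})

test_that("closed-form statistics agree with a Pearson chi-square oracle", {
  for (n in c(4, 8, 12)) {
    for (o1 in 0:n) {
      o2 <- n - o1
      if (o1 > 0 && o2 > 0) {
        oracle <- suppressWarnings(
          stats::chisq.test(c(o1, o2), p = c(0.5, 0.5))
        )
        expect_equal(chi_square_1to1(o1, o2)$statistic,
          unname(oracle$statistic),
          tolerance = 1e-12
        )
      }
      p_major <- 0.75 - 0.5^(6 + 1)
      oracle2 <- suppressWarnings(
        stats::chisq.test(c(o1, o2), p = c(p_major, 1 - p_major))
      )
      expect_equal(chi_square_major_vs_rest(o1, o2, x = 6)$statistic,
        unname(oracle2$statistic),
        tolerance = 1e-12
      )
    }
  }
})

test_that("the 1-df survival function matches its erfc identity", {
  expect_equal(chi2_sf_1df(0), 1)
  expect_equal(chi2_sf_1df(3.841), 0.05, tolerance = 1e-3)
  expect_equal(chi2_sf_1df(8), 0.004678, tolerance = 1e-3)
  skip_if_not_installed("pracma")
  for (s in c(0.1, 1, 3.841, 8, 20)) {
    expect_equal(chi2_sf_1df(s), pracma::erfc(sqrt(s / 2)), tolerance = 1e-12)
  }
  expect_true(all(diff(chi2_sf_1df(seq(0, 10, 0.5))) < 0))
  expect_error(chi2_sf_1df(-1), "must be >= 0")
})

test_that("cross-type assignment picks the smaller statistic, ties to hom_hom", {
  expect_equal(infer_cross_type(48, 52, 0, x = 8)$cross_type, "hom_hom")
  r <- infer_cross_type(75, 25, 2, x = 8)
  expect_equal(r$cross_type, "hom_het")
  expect_equal(r$major_class, 1L)
  expect_gt(r$statistic_1to1, r$statistic_major)
  # x = 1: both tests expect 1:1, equal counts tie both at zero
  tie <- infer_cross_type(10, 10, 0, x = 1)
  expect_equal(tie$statistic_1to1, tie$statistic_major)
  expect_equal(tie$cross_type, "hom_hom")
  expect_error(infer_cross_type(0, 0, 5, x = 8), "uninformative")
})

test_that("cross types are recovered on simulated populations", {
  sim_hom <- simulate_population(sim_config(
    n_ind = 200, generation = 8, markers_per_group = 100,
    het_parent1 = 0, seed = 401
  ))
  cc <- call_cross_types(sim_hom$data)
  expect_gte(mean(cc$cross_type == "hom_hom"), 0.95)

  sim_het <- simulate_population(sim_config(
    n_ind = 200, generation = 8, markers_per_group = 100,
    het_parent1 = 1, seed = 402
  ))
  cc2 <- call_cross_types(sim_het$data)
  expect_gte(mean(cc2$cross_type == "hom_het"), 0.90)
})

test_that("the marker filter removes each class of incompetent marker", {
  n <- 100
  geno <- cbind(
    mono = rep("A", n),
    gappy = c(rep("A", 20), rep("B", 20), rep("-", 60)),
    hets = rep("H", n),
    distorted = c(rep("A", 50), rep("H", 50)),
    good = c(rep("A", 48), rep("B", 50), rep("H", 2)),
    skewed = c(rep("A", 70), rep("B", 30))
  )
  rownames(geno) <- paste0("i", 1:n)
  pop <- pop_data(geno, coding = "ABH", generation = 8)
  res <- segregation_filter(pop, alpha = 0.05, max_missing = 0.5)
  rep <- res$report
  expect_equal(rep$reason[rep$marker == "mono"], "monomorphic")
  expect_equal(rep$reason[rep$marker == "gappy"], "missing")
  expect_equal(rep$reason[rep$marker == "hets"], "uninformative")
  # 50 hom1 / 0 hom2 / 50 het at x = 8 fails both cross-type tests
  expect_equal(rep$reason[rep$marker == "distorted"], "distorted")
  expect_true("good" %in% colnames(res$data$geno))
  # a 70:30 homozygote split at x = 8 fits the hom x het expectation
  # (70 : 30 vs ~74.8 : 25.2) and is retained
  expect_true("skewed" %in% colnames(res$data$geno))
  expect_equal(
    call_cross_types(res$data)$cross_type[
      call_cross_types(res$data)$marker == "skewed"
    ],
    "hom_het"
  )
})
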