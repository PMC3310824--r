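make_parent_toy <- function() {
  # 8 individuals x 4 markers, clear 1:1 segregation everywhere;
  # m3's parent 1 call is missing, m4's parents are both "A" (off parent)
  pattern <- c("A", "A", "A", "A", "B", "B", "B", "B")
  geno <- matrix(rep(pattern, 4), 8, 4,
    dimnames = list(paste0("i", 1:8), paste0("m", 1:4))
  )
  parents <- rbind(
    P1 = c("A", "A", "-", "A"),
    P2 = c("B", "B", "B", "A")
  )
  pop_data(geno, coding = "ABH", generation = 8, parents = parents)
}

test_that("concordant observed parents pass through; missing and off parents are handled", {
  pop <- make_parent_toy()
  map <- toy_map(paste0("m", 1:4), spacing = 5)
  res <- infer_parent_genotypes(pop, map)
  expect_equal(res$source, c("observed", "observed", "inferred", "conflict"))
  # inference wins everywhere, and recovers the masked and off-parent calls
  expect_equal(res$p1_inferred, rep("A", 4))
  expect_equal(res$p2_inferred, rep("B", 4))
  # the observed off-parent value stays on record
  expect_equal(res$p2_observed[4], "A")
  gl <- generics::glance(res)
  expect_equal(gl$n_conflict, 1)
  expect_equal(gl$n_observed, 2)
})

test_that("unmapped markers are unresolved with a reason", {
  pop <- make_parent_toy()
  map <- toy_map(paste0("m", 1:3), spacing = 5)
  res <- infer_parent_genotypes(pop, map)
  expect_equal(res$source[res$marker == "m4"], "unresolved")
  expect_equal(res$reason[res$marker == "m4"], "unmapped")
})

test_that("swapping the parent labels swaps every assignment and nothing else", {
  pop <- make_parent_toy()
  map <- toy_map(paste0("m", 1:4), spacing = 5)
  swapped <- pop
  swapped$parents <- pop$parents[c(2, 1), ]
  rownames(swapped$parents) <- c("P1", "P2")
  swapped$parent_klass <- pop$parent_klass[c(2, 1), ]
  rownames(swapped$parent_klass) <- c("P1", "P2")
  a <- infer_parent_genotypes(pop, map)
  b <- infer_parent_genotypes(swapped, map)
  expect_equal(b$p1_inferred, a$p2_inferred)
  expect_equal(b$p2_inferred, a$p1_inferred)
  expect_equal(b$source, a$source)
})

test_that("inference is invariant to marker order in the input", {
  sim <- simulate_population(sim_config(
    n_ind = 80, generation = 8, markers_per_group = 20, spacing_cM = 5,
    coding = "ACGT", missing_rate = 0.05, seed = 31
  ))
  pop <- sim$data
  perm <- sample(seq_len(n_markers(pop)))
  shuffled <- pop_data(pop$geno[, perm],
    coding = "ACGT", generation = 8,
    parents = pop$parents[, perm]
  )
  a <- infer_parent_genotypes(pop, sim$map)
  b <- infer_parent_genotypes(shuffled, sim$map)
  b <- b[match(a$marker, b$marker), ]
  expect_equal(a$p1_inferred, b$p1_inferred)
  expect_equal(a$p2_inferred, b$p2_inferred)
  expect_equal(a$source, b$source)
})

test_that("masked parental calls are recovered from segregation and the map", {
  sim <- simulate_population(sim_config(
    n_ind = 150, generation = 8, markers_per_group = 50, spacing_cM = 2,
    coding = "ACGT", seed = 57
  ))
  pop <- sim$data
  set.seed(58)
  masked <- sort(sample(colnames(pop$geno), 10))
  pop$parents["P1", masked] <- "-"
  pop <- pop_data(pop$geno,
    coding = "ACGT", generation = 8,
    parents = pop$parents
  )
  res <- infer_parent_genotypes(pop, sim$map)
  got <- res$p1_inferred[match(masked, res$marker)]
  expect_equal(res$source[match(masked, res$marker)], rep("inferred", 10))
  expect_equal(got, unname(sim$truth$parent1[masked]))
})

test_that("heterozygous-parent markers are assigned by minor-allele phase", {
  sim <- simulate_population(sim_config(
    n_ind = 300, generation = 4, markers_per_group = 40, spacing_cM = 2,
    coding = "ACGT", het_parent1 = 0.25, seed = 91
  ))
  flt <- segregation_filter(sim$data)
  res <- infer_parent_genotypes(flt$data, sim$map)
  het_mk <- intersect(sim$truth$het_loci, res$marker)
  resolved <- res[res$marker %in% het_mk &
    res$source %in% c("observed", "inferred", "conflict"), ]
  expect_gt(nrow(resolved), 3)
  hits <- mean(resolved$p1_inferred ==
    unname(sim$truth$parent1[resolved$marker]))
  expect_gte(hits, 0.9)
})

test_that("ACGT to ABH conversion recodes relative to the parents", {
  parents <- tibble::tibble(
    marker = c("m1", "m2", "m3"),
    source = c("inferred", "inferred", "unresolved"),
    p1_inferred = c("G", "A", NA),
    p2_inferred = c("T", "A", NA)
  )
  geno <- cbind(
    m1 = c("G", "T", "GT", "-"),
    m2 = c("A", "A", "A", "A"),
    m3 = c("C", "G", "C", "C")
  )
  rownames(geno) <- paste0("i", 1:4)
  pop <- pop_data(geno, coding = "ACGT", generation = 8)
  out <- acgt_to_abh(pop, parents)
  expect_equal(unname(out$data$geno[, "m1"]), c("A", "B", "H", "-"))
  expect_false("m2" %in% colnames(out$data$geno)) # identical parents
  expect_setequal(out$excluded$marker, c("m2", "m3"))
  expect_equal(
    out$excluded$reason[out$excluded$marker == "m2"],
    "monomorphic_in_parents"
  )
})

test_that("ACGT -> ABH -> ACGT round-trips on a clean simulated population", {
  sim <- simulate_population(sim_config(
    n_ind = 80, generation = 8, markers_per_group = 25, spacing_cM = 4,
    coding = "ACGT", seed = 12
  ))
  flt <- segregation_filter(sim$data)
  parents <- infer_parent_genotypes(flt$data, sim$map)
  conv <- acgt_to_abh(flt$data, parents)
  kept <- colnames(conv$data$geno)
  # conversion reproduces the simulator's true ABH matrix
  expect_identical(conv$data$geno, sim$truth$abh_true[, kept])
  back <- abh_to_acgt(conv$data)
  expect_identical(back$geno, flt$data$geno[, kept])
  expect_error(acgt_to_abh(conv$data, parents), "ACGT")
})
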