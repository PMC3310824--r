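# Seeded simulator for biparental inbred populations with ground truth.
#
# Emulates the data-generating process the inference assumes: two (nearly)
# inbred parents are crossed, each progeny line descends from its own F1 and
# is selfed x - 1 times, and each meiosis recombines independently between
# adjacent markers with the recombination fraction implied by the interval's
# map length. Noise processes mirror the failure modes the tool exists to
# repair: residual parental heterozygosity, "off-parent" genotyping of a
# parent line that has since become fixed, missing calls, and phase flips
# injected into the emitted ABH matrix.

#' Simulation configuration
#'
#' @param n_ind Number of progeny individuals.
#' @param generation Selfing-generation index x (F_x; x = 1 is the F1).
#' @param n_groups Number of linkage groups.
#' @param markers_per_group Markers per linkage group.
#' @param spacing_cM Distance between adjacent markers, centimorgan.
#' @param map_function Map function used to turn spacing into a per-interval
#'   recombination fraction (`"haldane"` matches the no-interference meiosis
#'   model exactly; `"kosambi"` is applied per interval as an approximation).
#' @param coding Output coding, `"ABH"` or `"ACGT"`.
#' @param het_parent1 Fraction of loci at which parent 1 was still
#'   heterozygous at crossing time (true cross type hom x het there).
#' @param offparent_rate Probability that a heterozygous parent-1 locus is
#'   genotyped later as fixed for a random allele (the off-parent case).
#' @param missing_rate Per-cell missing probability in the progeny matrix.
#' @param flip_rate Per-marker probability of swapping A/B orientation in
#'   the emitted ABH matrix (phase-error injection; ABH coding only).
#' @param parents_in_output Include the (possibly off-parent) genotyped
#'   parental rows in the dataset.
#' @param seed Mandatory integer seed; runs are bit-reproducible.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_ind = 150, generation = 8, n_groups = 1,
                       markers_per_group = 100, spacing_cM = 2,
                       map_function = c("haldane", "kosambi"),
                       coding = c("ABH", "ACGT"),
                       het_parent1 = 0, offparent_rate = 0,
                       missing_rate = 0, flip_rate = 0,
                       parents_in_output = TRUE, seed) {
  map_function <- match.arg(map_function)
  coding <- match.arg(coding)
  stopifnot(
    n_ind >= 1, n_groups >= 1, markers_per_group >= 1, spacing_cM >= 0,
    het_parent1 >= 0, het_parent1 <= 1,
    offparent_rate >= 0, offparent_rate <= 1,
    missing_rate >= 0, missing_rate <= 1,
    flip_rate >= 0, flip_rate <= 1
  )
  if (missing(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a seed is mandatory for reproducible simulation", call. = FALSE)
  }
  if (coding == "ACGT" && flip_rate > 0) {
    stop("flip injection applies to ABH output only", call. = FALSE)
  }
  structure(
    list(
      n_ind = as.integer(n_ind),
      generation = .normalize_generation(generation),
      n_groups = as.integer(n_groups),
      markers_per_group = as.integer(markers_per_group),
      spacing_cM = as.numeric(spacing_cM),
      map_function = map_function, coding = coding,
      het_parent1 = het_parent1, offparent_rate = offparent_rate,
      missing_rate = missing_rate, flip_rate = flip_rate,
      parents_in_output = parents_in_output,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# one meiosis for all individuals of a group: hapA/hapB are n x m 0/1
# matrices; r is the length-(m-1) vector of interval recombination fractions
.meiosis <- function(hapA, hapB, r) {
  n <- nrow(hapA)
  m <- ncol(hapA)
  state <- matrix(0L, n, m)
  state[, 1] <- stats::rbinom(n, 1L, 0.5)
  if (m > 1L) {
    xo <- matrix(
      stats::rbinom(n * (m - 1L), 1L, rep(r, each = n)),
      n, m - 1L
    )
    for (j in 2:m) {
      state[, j] <- (state[, j - 1] + xo[, j - 1]) %% 2L
    }
  }
  ifelse(state == 0L, hapA, hapB)
}

#' Simulate a biparental inbred mapping population
#'
#' Generates a genotype matrix, its genetic map, and complete ground truth.
#' Each individual descends from its own F1 (so residual parental
#' heterozygosity segregates among lines, as in the selfing-series model)
#' and is selfed `generation - 1` times with independent per-interval
#' recombination. All randomness comes from one stream seeded by
#' `config$seed`; the same configuration always yields a bit-identical
#' result.
#'
#' @param config A [sim_config].
#'
#' @return A list:
#' \describe{
#'   \item{data}{[pop_data] with genotyped (possibly off-parent) parental
#'     rows if `parents_in_output`.}
#'   \item{map}{[genetic_map] of the simulated markers.}
#'   \item{truth}{list with `parent1`, `parent2` (true genotype tokens at
#'     crossing time), `alleles` (marker x 2 matrix: parent-1 side allele,
#'     parent-2 side allele), `cross_type`, `flipped` (named logical: marker
#'     emitted with inverted A/B orientation), `het_loci`, `offparent_loci`,
#'     `missing_cells` (tibble individual/marker), and `abh_true` (the
#'     noise-free ABH matrix before flips/missingness).}
#' }
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  m_per <- cfg$markers_per_group
  groups <- paste0("LG", seq_len(cfg$n_groups))
  marker <- as.vector(vapply(
    seq_len(cfg$n_groups),
    function(g) sprintf("M%d_%03d", g, seq_len(m_per)),
    character(m_per)
  ))
  map <- genetic_map(
    marker = marker,
    group = rep(groups, each = m_per),
    pos_cM = rep(cfg$spacing_cM * (seq_len(m_per) - 1), cfg$n_groups)
  )
  M <- length(marker)
  N <- cfg$n_ind

  # alleles: column 1 = parent-1 side, column 2 = parent-2 side
  if (cfg$coding == "ABH") {
    alleles <- cbind(rep("A", M), rep("B", M))
  } else {
    alleles <- t(vapply(
      seq_len(M),
      function(i) sample(c("A", "C", "G", "T"), 2L),
      character(2)
    ))
  }
  rownames(alleles) <- marker
  colnames(alleles) <- c("p1", "p2")

  het_loci <- marker[stats::runif(M) < cfg$het_parent1]
  is_het <- marker %in% het_loci

  # haplotypes as 0/1 allele-side indices
  p1_hapA <- rep(0L, M)
  p1_hapB <- ifelse(is_het, 1L, 0L)

  r <- map_distance_to_r(rep(cfg$spacing_cM, m_per - 1L), cfg$map_function)

  hapA <- matrix(0L, N, 0L)
  hapB <- matrix(0L, N, 0L)
  for (g in seq_len(cfg$n_groups)) {
    cols <- ((g - 1L) * m_per + 1L):(g * m_per)
    gA <- .meiosis(
      matrix(p1_hapA[cols], N, m_per, byrow = TRUE),
      matrix(p1_hapB[cols], N, m_per, byrow = TRUE), r
    )
    gB <- matrix(1L, N, m_per) # parent 2 fully inbred
    for (s in seq_len(cfg$generation - 1L)) {
      g1 <- .meiosis(gA, gB, r)
      g2 <- .meiosis(gA, gB, r)
      gA <- g1
      gB <- g2
    }
    hapA <- cbind(hapA, gA)
    hapB <- cbind(hapB, gB)
  }

  ids <- sprintf("RIL%03d", seq_len(N))
  abh_true <- matrix("H", N, M, dimnames = list(ids, marker))
  abh_true[hapA == 0L & hapB == 0L] <- "A"
  abh_true[hapA == 1L & hapB == 1L] <- "B"

  geno <- .tokens_from_haps(hapA, hapB, alleles, cfg$coding)
  dimnames(geno) <- list(ids, marker)

  # true parental genotypes at crossing time
  true_p1 <- ifelse(
    is_het,
    if (cfg$coding == "ABH") "H" else .het_pair(alleles),
    alleles[, "p1"]
  )
  true_p2 <- alleles[, "p2"]
  names(true_p1) <- names(true_p2) <- marker

  # genotyped parents: off-parent fixation at heterozygous parent-1 loci
  obs_p1 <- true_p1
  off_loci <- character(0)
  if (length(het_loci) > 0L && cfg$offparent_rate > 0) {
    off <- het_loci[stats::runif(length(het_loci)) < cfg$offparent_rate]
    if (length(off) > 0L) {
      pick <- sample(c("p1", "p2"), length(off), replace = TRUE)
      obs_p1[off] <- alleles[cbind(off, pick)]
      off_loci <- off
    }
  }

  # missing mask on progeny
  missing_cells <- tibble::tibble(individual = character(0), marker = character(0))
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(N * M) < cfg$missing_rate, N, M)
    geno[mask] <- "-"
    idx <- which(mask, arr.ind = TRUE)
    missing_cells <- tibble::tibble(
      individual = ids[idx[, 1]], marker = marker[idx[, 2]]
    )
  }

  # phase-flip injection (ABH only)
  flipped <- stats::setNames(rep(FALSE, M), marker)
  if (cfg$flip_rate > 0) {
    fl <- marker[stats::runif(M) < cfg$flip_rate]
    flipped[fl] <- TRUE
    for (m in fl) geno[, m] <- .swap_ab(geno[, m])
  }

  parents <- NULL
  if (cfg$parents_in_output) {
    parents <- rbind(P1 = obs_p1, P2 = true_p2)
    if (any(flipped)) {
      for (m in marker[flipped]) parents[, m] <- .swap_ab(parents[, m])
    }
  }

  data <- pop_data(geno,
    coding = cfg$coding, generation = cfg$generation,
    parents = parents
  )
  truth <- list(
    parent1 = true_p1, parent2 = true_p2, alleles = alleles,
    cross_type = stats::setNames(
      ifelse(is_het, "hom_het", "hom_hom"), marker
    ),
    flipped = flipped, het_loci = het_loci, offparent_loci = off_loci,
    missing_cells = missing_cells, abh_true = abh_true
  )
  list(data = data, map = map, truth = truth)
}

.het_pair <- function(alleles) {
  apply(alleles, 1, function(a) paste0(min(a), max(a)))
}

.tokens_from_haps <- function(hapA, hapB, alleles, coding) {
  N <- nrow(hapA)
  M <- ncol(hapA)
  out <- matrix("", N, M)
  for (j in seq_len(M)) {
    a <- alleles[j, ]
    c1 <- a[hapA[, j] + 1L]
    c2 <- a[hapB[, j] + 1L]
    if (coding == "ABH") {
      out[, j] <- ifelse(c1 == c2, c1, "H")
    } else {
      lo <- pmin(c1, c2)
      hi <- pmax(c1, c2)
      out[, j] <- ifelse(lo == hi, lo, paste0(lo, hi))
    }
  }
  out
}

#' Two-locus genotype distribution from one gamete union
#'
#' Probability of each of the nine two-locus genotype classes formed by the
#' union of two gametes from a double heterozygote AB/ab, with gamete
#' frequencies (1-r)/2, (1-r)/2, r/2, r/2 for AB, ab, Ab, aB under the
#' coupling hypothesis (repulsion swaps the B/b labels). In particular
#' P(AABB) = P(aabb) = (1-r)^2/4 and P(AAbb) = P(aaBB) = r^2/4, so among the
#' four double-homozygote classes the same-class proportion is
#' [expected_phase_proportions()]'s `p_parental`.
#'
#' @param r Recombination fraction in `[0, 0.5]`.
#' @param phase `"coupling"` or `"repulsion"`.
#' @return A tibble: `genotype` (e.g. `"AABb"`), `prob`, summing to 1.
#' @export
two_locus_genotype_distribution <- function(r, phase = c("coupling", "repulsion")) {
  phase <- match.arg(phase)
  if (length(r) != 1L || is.na(r) || r < 0 || r > 0.5) {
    stop("recombination fraction must be in [0, 0.5]", call. = FALSE)
  }
  gametes <- c("AB", "ab", "Ab", "aB")
  freq <- c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
  if (phase == "repulsion") {
    # parental gametes carry opposite-case alleles
    gametes <- c("Ab", "aB", "AB", "ab")
  }
  geno_of <- function(g1, g2) {
    l1 <- sort(c(substr(g1, 1, 1), substr(g2, 1, 1)),
      method = "radix"
    ) # "A" < "a" in C locale
    l2 <- sort(c(substr(g1, 2, 2), substr(g2, 2, 2)), method = "radix")
    paste0(paste(l1, collapse = ""), paste(l2, collapse = ""))
  }
  tab <- new.env()
  for (i in 1:4) {
    for (j in 1:4) {
      g <- geno_of(gametes[i], gametes[j])
      p <- freq[i] * freq[j]
      assign(g, p + (if (exists(g, tab)) get(g, tab) else 0), envir = tab)
    }
  }
  gg <- sort(ls(tab))
  out <- tibble::tibble(
    genotype = gg,
    prob = unname(vapply(gg, function(g) get(g, tab), numeric(1)))
  )
  out[order(-out$prob, out$genotype), ]
}
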