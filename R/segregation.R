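# Segregation model for selfing series and per-marker cross-type inference.
#
# A biparental inbred population is produced by an initial cross followed by
# x - 1 rounds of selfing (F_x; F_1 is the hybrid itself). When both parents
# were homozygous at a locus (AA x aa) the two progeny homozygote classes
# segregate 1:1 at every generation. When one parent was still heterozygous
# (AA x Aa), the expected split of the major homozygote against everything
# else is (3/4 - (1/2)^(x+1)) : (1/4 + (1/2)^(x+1)). Two 1-df chi-square
# tests against these expectations decide the cross type per marker.

#' Expected genotype proportions after x generations of selfing
#'
#' Closed-form genotype proportions (hom1, het, hom2) in generation F_x for
#' the three biparental cross types. Each additional selfing generation
#' halves the heterozygote proportion and adds a quarter of the previous
#' heterozygote proportion to each homozygote class.
#'
#' For `"hom_hom"` (AA x aa) the two homozygotes are always equal (1:1). For
#' `"hom_het"` (AA x Aa), `p_hom1` is the major homozygote.
#'
#' @param cross_type One of `"hom_hom"` (AA x aa), `"het_het"` (Aa x Aa),
#'   `"hom_het"` (AA x Aa).
#' @param x Selfing-generation index (integer >= 1; x = 1 is the F1).
#'
#' @return Named numeric vector `c(p_hom1, p_het, p_hom2)` summing to 1.
#'
#' @examples
#' expected_proportions("hom_hom", 2) # F2: 1/4, 1/2, 1/4
#' expected_proportions("hom_het", 3) # 11/16, 1/8, 3/16
#' @export
expected_proportions <- function(cross_type = c("hom_hom", "het_het", "hom_het"),
                                 x) {
  cross_type <- match.arg(cross_type)
  x <- .normalize_generation(x)
  h <- 0.5^x
  p <- switch(cross_type,
    hom_hom = c(0.5 - h, 2 * h, 0.5 - h),
    het_het = c(0.5 - h / 2, h, 0.5 - h / 2),
    hom_het = c(0.75 - h / 2, h, 0.25 - h / 2)
  )
  names(p) <- c("p_hom1", "p_het", "p_hom2")
  p
}

#' Survival function of the 1-df chi-square distribution
#'
#' Upper-tail probability of a chi-square variate with one degree of
#' freedom, the reference distribution of every test in the package.
#'
#' @param stat Non-negative chi-square statistic (vectorized).
#' @return p-value in `[0, 1]`.
#' @export
chi2_sf_1df <- function(stat) {
  if (any(is.na(stat)) || any(stat < 0)) {
    stop("chi-square statistic must be >= 0", call. = FALSE)
  }
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Chi-square test of a 1:1 homozygote ratio
#'
#' Pearson chi-square test of the two homozygote counts against the 1:1
#' ratio expected when both parents were homozygous: statistic
#' `(n_hom1 - n_hom2)^2 / (n_hom1 + n_hom2)` on 1 df. Heterozygotes are not
#' used. Symmetric in its arguments.
#'
#' @param n_hom1,n_hom2 Homozygote class counts (vectorized).
#' @return A tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_1to1 <- function(n_hom1, n_hom2) {
  if (any(n_hom1 < 0) || any(n_hom2 < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  n <- n_hom1 + n_hom2
  if (any(n == 0)) {
    stop("uninformative marker: no homozygous calls", call. = FALSE)
  }
  stat <- (n_hom1 - n_hom2)^2 / n
  tibble::tibble(statistic = stat, df = 1L, p_value = chi2_sf_1df(stat))
}

#' Chi-square test of the major homozygote against the rest
#'
#' Pearson chi-square test of the split (major homozygote) : (other
#' homozygote + heterozygotes) against the generation-x expectation for a
#' homozygote x heterozygote cross, `(3/4 - (1/2)^(x+1)) : (1/4 +
#' (1/2)^(x+1))`, on 1 df.
#'
#' @param n_major Count of the more frequent homozygote class.
#' @param n_rest Count of the other homozygote plus heterozygotes.
#' @param x Selfing-generation index (integer >= 1).
#' @return A tibble: `statistic`, `df`, `p_value`.
#'
#' @examples
#' chi_square_major_vs_rest(20, 20, x = 6) # statistic ~ 12.26
#' @export
chi_square_major_vs_rest <- function(n_major, n_rest, x) {
  x <- .normalize_generation(x)
  if (any(n_major < 0) || any(n_rest < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  n <- n_major + n_rest
  if (any(n == 0)) {
    stop("uninformative marker: no calls", call. = FALSE)
  }
  p_major <- 0.75 - 0.5^(x + 1)
  e_major <- p_major * n
  e_rest <- (1 - p_major) * n
  stat <- (n_major - e_major)^2 / e_major + (n_rest - e_rest)^2 / e_rest
  tibble::tibble(statistic = stat, df = 1L, p_value = chi2_sf_1df(stat))
}

#' Infer the parental cross type of a marker from progeny counts
#'
#' Compares two 1-df chi-square statistics: (a) the 1:1 test of the two
#' homozygote classes ([chi_square_1to1()], expected under a homozygote x
#' homozygote cross) and (b) the major-vs-rest test
#' ([chi_square_major_vs_rest()], expected under a homozygote x heterozygote
#' cross), and assigns the cross type with the smaller statistic. Ties go to
#' `"hom_hom"`, the default assumption for inbred parents. A heterozygote x
#' heterozygote cross segregates 1:1 between homozygotes too and is never
#' called: for nominally inbred, self-pollinated parents its prior
#' probability is negligible, and after selfing it is statistically
#' indistinguishable from a homozygote x homozygote cross.
#'
#' @param n_hom1,n_hom2 Homozygote class counts.
#' @param n_het Heterozygote count.
#' @param x Selfing-generation index.
#'
#' @return A one-row tibble: `cross_type` (`"hom_hom"` or `"hom_het"`),
#'   `major_class` (1 or 2: which homozygote was treated as the major one),
#'   `statistic_1to1`, `p_1to1`, `statistic_major`, `p_major`.
#' @export
infer_cross_type <- function(n_hom1, n_hom2, n_het, x) {
  if (n_hom1 + n_hom2 == 0) {
    stop("uninformative marker: no homozygous calls", call. = FALSE)
  }
  a <- chi_square_1to1(n_hom1, n_hom2)
  major_class <- if (n_hom2 > n_hom1) 2L else 1L
  n_major <- max(n_hom1, n_hom2)
  n_rest <- min(n_hom1, n_hom2) + n_het
  b <- chi_square_major_vs_rest(n_major, n_rest, x)
  cross <- if (a$statistic <= b$statistic) "hom_hom" else "hom_het"
  tibble::tibble(
    cross_type = cross,
    major_class = major_class,
    statistic_1to1 = a$statistic, p_1to1 = a$p_value,
    statistic_major = b$statistic, p_major = b$p_value
  )
}

#' Cross-type calls for every marker of a dataset
#'
#' Applies [infer_cross_type()] to every valid marker. Markers with no
#' homozygous call (or flagged non-biallelic) get `NA` calls instead of an
#' error.
#'
#' @param x A [pop_data] object.
#' @param generation Selfing-generation index; defaults to the dataset's.
#'
#' @return A tibble of class `crossphase_cross`: one row per marker with
#'   counts, both test statistics and p-values, `cross_type`, and
#'   `major_allele` (the allele of the major homozygote class).
#' @seealso [segregation_filter()], [autoplot.crossphase_cross()]
#' @export
call_cross_types <- function(x, generation = NULL) {
  stopifnot(inherits(x, "pop_data"))
  gen <- if (is.null(generation)) x$generation else .normalize_generation(generation)
  cnt <- marker_counts(x)
  res <- purrr::pmap_dfr(
    cnt[, c("n_hom1", "n_hom2", "n_het")],
    function(n_hom1, n_hom2, n_het) {
      if (n_hom1 + n_hom2 == 0) {
        tibble::tibble(
          cross_type = NA_character_, major_class = NA_integer_,
          statistic_1to1 = NA_real_, p_1to1 = NA_real_,
          statistic_major = NA_real_, p_major = NA_real_
        )
      } else {
        infer_cross_type(n_hom1, n_hom2, n_het, gen)
      }
    }
  )
  out <- dplyr::bind_cols(cnt, res)
  out$cross_type[!x$marker_ok[out$marker]] <- NA_character_
  out$major_allele <- dplyr::case_when(
    is.na(out$major_class) ~ NA_character_,
    out$major_class == 1L ~ out$allele1,
    TRUE ~ out$allele2
  )
  out$generation <- gen
  class(out) <- c("crossphase_cross", class(tibble::tibble()))
  out
}

#' Remove incompetent markers before inference
#'
#' Drops markers that are (i) non-biallelic, (ii) missing in more than
#' `max_missing` of individuals, (iii) monomorphic, (iv) without any
#' homozygous call (uninformative), or (v) distorted: the better-fitting of
#' the two cross-type tests is still rejected at `alpha`. Phase and parent
#' inference assume distorted markers have been removed.
#'
#' @param x A [pop_data] object.
#' @param generation Selfing-generation index; defaults to the dataset's.
#' @param alpha Significance level for the distortion test (default 0.05).
#' @param max_missing Maximum tolerated missing-call fraction (default 0.5).
#'
#' @return A list with `data` (the filtered [pop_data]) and `report` (a
#'   tibble: `marker`, `reason`, `statistic`, `p_value`; one row per removed
#'   marker).
#' @export
segregation_filter <- function(x, generation = NULL, alpha = 0.05,
                               max_missing = 0.5) {
  stopifnot(inherits(x, "pop_data"))
  stopifnot(alpha > 0, alpha < 1)
  gen <- if (is.null(generation)) x$generation else .normalize_generation(generation)
  cc <- call_cross_types(x, gen)
  n_ind <- n_individuals(x)

  reason <- rep(NA_character_, nrow(cc))
  stat <- rep(NA_real_, nrow(cc))
  pval <- rep(NA_real_, nrow(cc))

  nonbi <- !x$marker_ok[cc$marker]
  reason[nonbi] <- "non_biallelic"
  too_missing <- is.na(reason) & cc$n_missing / n_ind > max_missing
  reason[too_missing] <- "missing"
  mono <- is.na(reason) &
    purrr::map_lgl(x$alleles[cc$marker], ~ length(.x) < 2) &
    cc$n_het == 0
  reason[mono] <- "monomorphic"
  uninf <- is.na(reason) & cc$n_hom1 + cc$n_hom2 == 0
  reason[uninf] <- "uninformative"

  best_stat <- pmin(cc$statistic_1to1, cc$statistic_major)
  best_p <- pmax(cc$p_1to1, cc$p_major)
  distorted <- is.na(reason) & !is.na(best_p) & best_p < alpha
  reason[distorted] <- "distorted"
  stat[distorted] <- best_stat[distorted]
  pval[distorted] <- best_p[distorted]

  drop <- !is.na(reason)
  report <- tibble::tibble(
    marker = cc$marker[drop],
    reason = reason[drop],
    statistic = stat[drop],
    p_value = pval[drop]
  )
  keep <- cc$marker[!drop]
  if (length(keep) == 0L) {
    warning("all markers removed by segregation_filter", call. = FALSE)
  }
  out <- .subset_markers(x, keep)
  list(data = out, report = report)
}

# subset a pop_data to a set of markers (order preserved as given)
.subset_markers <- function(x, markers) {
  structure(
    list(
      geno = x$geno[, markers, drop = FALSE],
      klass = x$klass[, markers, drop = FALSE],
      alleles = x$alleles[markers],
      marker_ok = x$marker_ok[markers],
      marker_error = x$marker_error[markers],
      coding = x$coding, generation = x$generation,
      parents = if (is.null(x$parents)) NULL else x$parents[, markers, drop = FALSE],
      parent_klass = if (is.null(x$parent_klass)) NULL else x$parent_klass[, markers, drop = FALSE],
      missing_tokens = x$missing_tokens
    ),
    class = "pop_data"
  )
}
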