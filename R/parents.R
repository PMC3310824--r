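# Reconstruction of the actual parental genotypes from progeny segregation.
#
# Per marker: (1) the cross type fixes whether both parents were homozygous
# (hom x hom) or one was still heterozygous (hom x het); (2) linkage phase
# relative to markers with trustworthy observed parents assigns each progeny
# homozygote class to parent 1 or parent 2; (3) the parental genotypes
# follow. Observed parental calls that contradict the inference are the
# "off parent" cases the tool exists to detect: the inference wins in the
# exported genotypes, but both values are reported.

#' Infer parental genotypes from progeny segregation and a genetic map
#'
#' For every mapped marker, infers the genotypes of the two parents that
#' actually produced the population. Markers whose observed parental calls
#' are complete, homozygous for the two progeny alleles, and consistent with
#' a hom x hom cross serve as phase anchors; all other markers are oriented
#' relative to them along each linkage group (see [phase_linkage_group()]).
#'
#' Sources in the result: `observed` (input parents agree with the
#' inference), `inferred` (at least one parental call was missing),
#' `conflict` (observed parents contradict the inference — the off-parent
#' case; the inferred value is exported, the observed one kept alongside),
#' `unresolved` (unmapped, uninformative, ambiguous phase, or too few
#' informative individuals).
#'
#' For a hom x het cross the heterozygous parent is the one whose haplotype
#' carries the minor homozygote's allele; that assignment is only made when
#' at least `min_informative` individuals are double homozygous at the
#' marker and its anchor with the minor allele involved.
#'
#' @param x A [pop_data] object (run [segregation_filter()] first).
#' @param map A [genetic_map] covering the markers to infer.
#' @param map_function `"haldane"` or `"kosambi"`.
#' @param alpha Significance level used in reporting.
#' @param min_informative Minimum minor-allele double-homozygote count for
#'   calling the heterozygous parent of a hom x het marker (default 5).
#'
#' @return A tibble of class `crossphase_parents`: `marker`, `group`,
#'   `pos_cM`, `p1_observed`, `p2_observed`, `p1_inferred`, `p2_inferred`,
#'   `source`, `reason`, `cross_type`, `phase`, `flipped`, `p_1to1`,
#'   `p_major`, `phase_p`.
#' @export
infer_parent_genotypes <- function(x, map, map_function = c("haldane", "kosambi"),
                                   alpha = 0.05, min_informative = 5) {
  stopifnot(inherits(x, "pop_data"))
  map_function <- match.arg(map_function)

  cross <- call_cross_types(x)
  anchors <- .parent_anchors(x, cross)
  ph <- phase_linkage_group(x, map,
    anchors = anchors,
    map_function = map_function, skip_missing = TRUE
  )
  ph_by <- split(ph, ph$marker)

  mk <- colnames(x$geno)
  cross_by <- split(cross, cross$marker)

  rows <- purrr::map_dfr(mk, function(m) {
    cr <- cross_by[[m]]
    inv <- x$alleles[[m]]
    obs <- .observed_parent_tokens(x, m)
    base <- tibble::tibble(
      marker = m,
      group = NA_character_, pos_cM = NA_real_,
      p1_observed = obs[1], p2_observed = obs[2],
      p1_inferred = NA_character_, p2_inferred = NA_character_,
      source = "unresolved", reason = NA_character_,
      cross_type = cr$cross_type, phase = NA_character_,
      flipped = NA,
      p_1to1 = cr$p_1to1, p_major = cr$p_major, phase_p = NA_real_
    )
    pr <- ph_by[[m]]
    if (is.null(pr)) {
      base$reason <- "unmapped"
      return(base)
    }
    base$group <- pr$group
    base$pos_cM <- pr$pos_cM
    base$phase <- pr$phase
    base$flipped <- pr$flipped
    base$phase_p <- pr$p_value
    if (is.na(cr$cross_type) || length(inv) < 2L) {
      base$reason <- "uninformative"
      return(base)
    }
    if (is.na(pr$flipped)) {
      base$reason <- "ambiguous_phase"
      return(base)
    }
    # orientation: flipped == FALSE means hom1 (allele inv[1]) is parent 1's
    p1_allele <- if (pr$flipped) inv[2] else inv[1]
    p2_allele <- setdiff(inv, p1_allele)
    if (cr$cross_type == "hom_hom") {
      g1 <- .hom_token(p1_allele, x$coding)
      g2 <- .hom_token(p2_allele, x$coding)
    } else { # hom_het
      minor_allele <- setdiff(inv, cr$major_allele)
      n_minor <- .minor_informative_count(x, m, pr$anchor, cr$major_class)
      if (is.na(n_minor) || n_minor < min_informative) {
        base$reason <- "minor_count"
        return(base)
      }
      het <- .het_token(inv, x$coding)
      maj <- .hom_token(cr$major_allele, x$coding)
      if (p1_allele == minor_allele) {
        g1 <- het
        g2 <- maj
      } else {
        g1 <- maj
        g2 <- het
      }
    }
    base$p1_inferred <- g1
    base$p2_inferred <- g2
    obs_k <- .observed_parent_klass(x, m)
    if (all(!is.na(obs[1:2])) && !any(obs_k == .KLASS_MISSING)) {
      same <- .same_genotype(obs[1], g1, x) && .same_genotype(obs[2], g2, x)
      base$source <- if (same) "observed" else "conflict"
    } else {
      base$source <- "inferred"
    }
    base
  })
  class(rows) <- c("crossphase_parents", class(tibble::tibble()))
  rows
}

# anchors: markers whose observed parents are complete, homozygous for the
# two progeny alleles, and concordant with a hom x hom cross type.
# Returns a named logical vector: TRUE = parent 1 carries allele 2 (hom2).
.parent_anchors <- function(x, cross) {
  if (is.null(x$parents)) {
    return(stats::setNames(logical(0), character(0)))
  }
  out <- logical(0)
  for (i in seq_len(nrow(cross))) {
    m <- cross$marker[i]
    if (is.na(cross$cross_type[i]) || cross$cross_type[i] != "hom_hom") next
    pk <- x$parent_klass[, m]
    inv <- x$alleles[[m]]
    if (length(inv) != 2L) next
    hom <- c(.KLASS_HOM1, .KLASS_HOM2)
    if (!all(pk %in% hom) || pk[1] == pk[2]) next
    out <- c(out, stats::setNames(pk[1] == .KLASS_HOM2, m))
  }
  out
}

.observed_parent_tokens <- function(x, m) {
  if (is.null(x$parents)) {
    return(c(NA_character_, NA_character_))
  }
  unname(x$parents[, m])
}

.observed_parent_klass <- function(x, m) {
  if (is.null(x$parent_klass)) {
    return(c(.KLASS_MISSING, .KLASS_MISSING))
  }
  x$parent_klass[, m]
}

# count of individuals double homozygous at marker and anchor where the
# marker call is the minor homozygote class
.minor_informative_count <- function(x, m, anchor, major_class) {
  if (is.na(anchor) || !(anchor %in% colnames(x$klass))) {
    return(NA_integer_)
  }
  minor_class <- if (major_class == 1L) .KLASS_HOM2 else .KLASS_HOM1
  km <- x$klass[, m]
  ka <- x$klass[, anchor]
  sum(km == minor_class & (ka == .KLASS_HOM1 | ka == .KLASS_HOM2))
}

.hom_token <- function(allele, coding) {
  allele
}

.het_token <- function(inv, coding) {
  if (coding == "ABH") "H" else paste0(inv[1], inv[2])
}

# token equality up to classification (e.g. "GT" == "TG" == "K")
.same_genotype <- function(tok_a, tok_b, x) {
  pa <- .parse_tokens(c(tok_a, tok_b), x$coding, x$missing_tokens)
  identical(pa[1, ], pa[2, ])
}

#' Convert an ACGT dataset to ABH coding
#'
#' Recodes every progeny call relative to the inferred (or observed)
#' parental genotypes: homozygous for parent 1's allele becomes `A`, for
#' parent 2's allele `B`, heterozygotes `H`, missing stays missing. When one
#' parent is heterozygous (hom x het cross), the allele unique to that
#' parent defines its side. Markers whose parents are unresolved, in
#' conflict, or identical ("monomorphic in parents") are excluded and
#' listed.
#'
#' @param x A [pop_data] object in ACGT coding.
#' @param parents A `crossphase_parents` tibble from
#'   [infer_parent_genotypes()].
#' @param missing_token Output token for missing calls.
#'
#' @return A list with `data` (the ABH [pop_data], parental rows recoded
#'   too) and `excluded` (tibble: `marker`, `reason`).
#' @seealso [abh_to_acgt()] for the inverse.
#' @export
acgt_to_abh <- function(x, parents, missing_token = "-") {
  stopifnot(inherits(x, "pop_data"))
  if (x$coding != "ACGT") {
    stop("acgt_to_abh requires ACGT coding", call. = FALSE)
  }
  pt <- parents[match(colnames(x$geno), parents$marker), ]
  excluded <- tibble::tibble(marker = character(0), reason = character(0))
  keep <- character(0)
  p1a <- character(0)
  p2a <- character(0)
  for (i in seq_len(nrow(pt))) {
    m <- colnames(x$geno)[i]
    if (is.na(pt$marker[i]) || is.na(pt$source[i]) ||
      !(pt$source[i] %in% c("observed", "inferred"))) {
      excluded <- dplyr::add_row(excluded,
        marker = m,
        reason = if (identical(pt$source[i], "conflict")) "conflict" else "unresolved"
      )
      next
    }
    al <- .parent_side_alleles(pt$p1_inferred[i], pt$p2_inferred[i], x)
    if (is.null(al)) {
      excluded <- dplyr::add_row(excluded,
        marker = m,
        reason = "monomorphic_in_parents"
      )
      next
    }
    keep <- c(keep, m)
    p1a <- c(p1a, al[1])
    p2a <- c(p2a, al[2])
  }
  geno <- x$geno[, keep, drop = FALSE]
  out <- matrix(missing_token, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  pout <- if (is.null(x$parents)) {
    NULL
  } else {
    matrix(missing_token, 2L, length(keep),
      dimnames = list(rownames(x$parents), keep)
    )
  }
  for (j in seq_along(keep)) {
    out[, j] <- .abh_recode_column(geno[, j], p1a[j], p2a[j], x, missing_token)
    if (!is.null(pout)) {
      pout[, j] <- .abh_recode_column(
        x$parents[, keep[j]], p1a[j], p2a[j], x, missing_token
      )
    }
  }
  abh <- pop_data(out,
    coding = "ABH", generation = x$generation,
    parents = pout, missing_tokens = union(x$missing_tokens, missing_token)
  )
  attr(abh, "parent_alleles") <- tibble::tibble(
    marker = keep, p1_allele = p1a, p2_allele = p2a
  )
  list(data = abh, excluded = excluded)
}

# which single allele identifies each parent's side; NULL if unresolvable
.parent_side_alleles <- function(g1, g2, x) {
  if (is.na(g1) || is.na(g2)) {
    return(NULL)
  }
  a <- .parse_tokens(c(g1, g2), x$coding, x$missing_tokens)
  al1 <- unique(a[1, ])
  al2 <- unique(a[2, ])
  if (setequal(al1, al2)) {
    return(NULL)
  } # includes identical homozygotes
  u1 <- setdiff(al1, al2)
  u2 <- setdiff(al2, al1)
  s1 <- if (length(al1) == 1L) al1 else u1
  s2 <- if (length(al2) == 1L) al2 else u2
  if (length(s1) != 1L || length(s2) != 1L || s1 == s2) {
    return(NULL)
  }
  c(s1, s2)
}

.abh_recode_column <- function(tokens, p1_allele, p2_allele, x, missing_token) {
  al <- .parse_tokens(tokens, x$coding, x$missing_tokens)
  out <- rep(missing_token, length(tokens))
  hom1 <- !is.na(al[, 1]) & al[, 1] == p1_allele & al[, 2] == p1_allele
  hom2 <- !is.na(al[, 1]) & al[, 1] == p2_allele & al[, 2] == p2_allele
  het <- !is.na(al[, 1]) & al[, 1] != al[, 2]
  out[hom1] <- "A"
  out[hom2] <- "B"
  out[het] <- "H"
  out
}

#' Convert an ABH dataset back to ACGT calls
#'
#' Inverse of [acgt_to_abh()] given the per-marker parental side alleles
#' (the `parent_alleles` attribute of the converted dataset, or any tibble
#' with `marker`, `p1_allele`, `p2_allele`).
#'
#' @param x A [pop_data] in ABH coding.
#' @param parent_alleles Tibble mapping each marker to its parental alleles.
#' @param missing_token Output token for missing calls.
#' @return A [pop_data] in ACGT coding.
#' @export
abh_to_acgt <- function(x, parent_alleles = attr(x, "parent_alleles"),
                        missing_token = "-") {
  stopifnot(inherits(x, "pop_data"))
  if (x$coding != "ABH") {
    stop("abh_to_acgt requires ABH coding", call. = FALSE)
  }
  if (is.null(parent_alleles)) {
    stop("parent_alleles mapping is required", call. = FALSE)
  }
  pa <- parent_alleles[match(colnames(x$geno), parent_alleles$marker), ]
  if (any(is.na(pa$marker))) {
    stop("parent_alleles does not cover all markers", call. = FALSE)
  }
  decode <- function(kcol, a1, a2) {
    out <- rep(missing_token, length(kcol))
    out[kcol == .KLASS_HOM1] <- a1 # ABH: hom1 is always the A class
    out[kcol == .KLASS_HOM2] <- a2
    het <- kcol == .KLASS_HET
    out[het] <- paste0(min(a1, a2), max(a1, a2))
    out
  }
  geno <- x$geno
  for (j in seq_len(ncol(geno))) {
    # ABH inventory is c("A","B"); hom1 = A side = parent 1
    geno[, j] <- decode(x$klass[, j], pa$p1_allele[j], pa$p2_allele[j])
  }
  pop_data(geno,
    coding = "ACGT", generation = x$generation,
    missing_tokens = union(x$missing_tokens, missing_token)
  )
}
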