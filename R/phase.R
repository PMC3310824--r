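# Linkage phase inference for adjacent markers on a genetic map.
#
# For two linked markers, the parental haplotypes are either in coupling
# (AB/ab) or repulsion (Ab/aB) phase. Among the four double-homozygote
# classes, the same-class pairs (AABB + aabb) are parental under coupling
# and recombinant under repulsion, so comparing the two diagonal counts
# decides the phase. The expected proportions follow from the recombination
# fraction r of the interval, obtained from the map distance via Haldane's
# or Kosambi's map function:
#
#   P_p = (1-r)^2 / (1 - 2 r (1-r)),   P_r = r^2 / (1 - 2 r (1-r))
#
# Because crossovers in different intervals are assumed independent, phase
# propagates marker-to-marker along a linkage group as a left-to-right
# Markov walk, and markers called repulsion relative to the corrected chain
# are flipped when recoding ABH data.

#' Convert a map distance to a recombination fraction
#'
#' Haldane's map function (no crossover interference),
#' `r = (1 - exp(-2 d)) / 2`, or Kosambi's (partial interference),
#' `r = tanh(2 d) / 2`, with `d` in Morgan (input in centimorgan).
#'
#' @param d Map distance in centimorgan (vectorized, `>= 0`).
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return Recombination fraction in `[0, 0.5)`.
#'
#' @examples
#' map_distance_to_r(30) # ~0.2256
#' map_distance_to_r(30, "kosambi")
#' @export
map_distance_to_r <- function(d, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(is.na(d)) || any(d < 0)) {
    stop("map distance must be >= 0 cM", call. = FALSE)
  }
  morgan <- d / 100
  switch(map_function,
    haldane = (1 - exp(-2 * morgan)) / 2,
    kosambi = tanh(2 * morgan) / 2
  )
}

#' Expected diagonal-class proportions under coupling
#'
#' Among the four double-homozygote classes of a linked marker pair,
#' the expected proportion of same-class pairs (parental under coupling)
#' and opposite-class pairs (recombinant under coupling):
#' `P_p = (1-r)^2 / (1 - 2 r (1-r))` and `P_r = r^2 / (1 - 2 r (1-r))`.
#' They sum to 1, and `P_p >= P_r` with equality only at `r = 0.5`.
#'
#' @param r Recombination fraction in `[0, 0.5]` (vectorized).
#' @return A tibble: `p_parental`, `p_recombinant`.
#'
#' @examples
#' expected_phase_proportions(map_distance_to_r(30)) # 0.9218, 0.0782
#' @export
expected_phase_proportions <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r > 0.5)) {
    stop("recombination fraction must be in [0, 0.5]", call. = FALSE)
  }
  denom <- 1 - 2 * r * (1 - r)
  tibble::tibble(
    p_parental = (1 - r)^2 / denom,
    p_recombinant = r^2 / denom
  )
}

#' Diagonal-class counts for a marker pair
#'
#' Counts individuals that are double homozygous at two markers: in the same
#' class at both (`n_parental`: hom1/hom1 or hom2/hom2, the AABB + aabb
#' diagonal) or in opposite classes (`n_recombinant`: AAbb + aaBB).
#' Individuals heterozygous or missing at either marker are uninformative.
#' Class labels are relative to each column's current allele orientation.
#'
#' @param x A [pop_data] object.
#' @param marker_i,marker_j Marker names.
#' @return A one-row tibble: `n_parental`, `n_recombinant`,
#'   `n_uninformative` (summing to the number of individuals).
#' @export
pair_counts <- function(x, marker_i, marker_j) {
  stopifnot(inherits(x, "pop_data"))
  absent <- setdiff(c(marker_i, marker_j), colnames(x$geno))
  if (length(absent) > 0L) {
    stop("marker(s) not in dataset: ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  .pair_counts_klass(x$klass[, marker_i], x$klass[, marker_j])
}

.pair_counts_klass <- function(ki, kj) {
  if (length(ki) != length(kj)) {
    stop("marker columns have different lengths", call. = FALSE)
  }
  hom_i <- ki == .KLASS_HOM1 | ki == .KLASS_HOM2
  hom_j <- kj == .KLASS_HOM1 | kj == .KLASS_HOM2
  both <- hom_i & hom_j
  n_par <- sum(both & ki == kj)
  n_rec <- sum(both & ki != kj)
  tibble::tibble(
    n_parental = n_par,
    n_recombinant = n_rec,
    n_uninformative = length(ki) - n_par - n_rec
  )
}

#' Phase decision for one marker pair
#'
#' Decides coupling vs repulsion by direct comparison of the diagonal
#' counts: coupling if `n_parental > n_recombinant`, repulsion if smaller,
#' ambiguous on a tie (including both zero). The 1-df chi-square of the
#' counts against the 1:1 null, `(n_p - n_r)^2 / (n_p + n_r)`, and the
#' expected proportions for the interval are attached for audit only — the
#' count comparison alone decides, because for any interval short enough to
#' be mapped the expected parental proportion far exceeds 1/2.
#'
#' @param n_parental,n_recombinant Diagonal-class counts.
#' @param d Interval length in centimorgan.
#' @param map_function `"haldane"` or `"kosambi"`.
#' @return A one-row tibble: `phase` (`"coupling"`, `"repulsion"`,
#'   `"ambiguous"`), the counts, `distance_cM`, `expected_p_parental`,
#'   `expected_p_recombinant`, `statistic`, `p_value`.
#'
#' @examples
#' infer_pair_phase(35, 15, d = 30) # coupling, statistic 8, p ~ 0.0047
#' @export
infer_pair_phase <- function(n_parental, n_recombinant, d,
                             map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (n_parental < 0 || n_recombinant < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  exp_p <- expected_phase_proportions(map_distance_to_r(d, map_function))
  n <- n_parental + n_recombinant
  if (n > 0) {
    stat <- (n_parental - n_recombinant)^2 / n
    p <- chi2_sf_1df(stat)
  } else {
    stat <- NA_real_
    p <- NA_real_
  }
  phase <- if (n == 0 || n_parental == n_recombinant) {
    "ambiguous"
  } else if (n_parental > n_recombinant) {
    "coupling"
  } else {
    "repulsion"
  }
  tibble::tibble(
    phase = phase,
    n_parental = n_parental, n_recombinant = n_recombinant,
    distance_cM = d,
    expected_p_parental = exp_p$p_parental,
    expected_p_recombinant = exp_p$p_recombinant,
    statistic = stat, p_value = p
  )
}

#' Phase every marker of a genetic map relative to anchored neighbours
#'
#' Walks each linkage group in map order. Anchored markers (orientation
#' known, e.g. from observed parental genotypes) seed the walk; every other
#' marker is phased against the nearest already-oriented marker to its left
#' within `max_gap` centimorgan, with the diagonal counts taken against the
#' anchor's corrected orientation — so the reported phase is relative to the
#' reference and `flipped` is simply `phase == "repulsion"`. Ambiguous
#' markers stay
#' unoriented and never serve as anchors. Markers to the left of the first
#' anchor are phased right-to-left from it. If a group has no anchor, its
#' leftmost informative marker is fixed as the reference and the group is
#' flagged `arbitrary`: its overall orientation cannot be identified without
#' parental information. A gap wider than `max_gap` starts a new,
#' arbitrarily oriented segment — beyond ~50 cM the expected parental and
#' recombinant proportions approach 1/2 and the counts carry little
#' information.
#'
#' @param x A [pop_data] object.
#' @param map A [genetic_map]. Markers listed in the map but absent from the
#'   dataset raise an error unless `skip_missing = TRUE`.
#' @param anchors Markers with known orientation: either a character vector
#'   of marker names (orientation "as is") or a named logical vector
#'   (`TRUE` = the marker's current hom1/hom2 labelling is flipped relative
#'   to the reference orientation).
#' @param map_function `"haldane"` or `"kosambi"`.
#' @param max_gap Maximum anchoring distance in centimorgan (default 50).
#' @param skip_missing Silently drop map markers absent from the dataset.
#'
#' @return A tibble of class `crossphase_phase`: one row per mapped marker
#'   with `group`, `pos_cM`, `anchor`, `distance_cM`, the diagonal counts,
#'   expected proportions, `phase`, `statistic`, `p_value`, `flipped`
#'   (logical: orientation relative to the reference; `NA` if ambiguous),
#'   `segment`, and `arbitrary` (no anchored marker in the segment).
#' @seealso [recode_abh()], [infer_pair_phase()]
#' @export
phase_linkage_group <- function(x, map, anchors = NULL,
                                map_function = c("haldane", "kosambi"),
                                max_gap = 50, skip_missing = FALSE) {
  stopifnot(inherits(x, "pop_data"))
  map_function <- match.arg(map_function)
  if (!all(c("marker", "group", "pos_cM") %in% names(map))) {
    stop("map must have columns marker, group, pos_cM", call. = FALSE)
  }
  absent <- setdiff(map$marker, colnames(x$geno))
  if (length(absent) > 0L) {
    if (!skip_missing) {
      stop("map marker(s) absent from dataset: ",
        paste(utils::head(absent, 10), collapse = ", "),
        call. = FALSE
      )
    }
    map <- map[!(map$marker %in% absent), , drop = FALSE]
  }
  anchor_flip <- .normalize_anchors(anchors)
  anchor_flip <- anchor_flip[names(anchor_flip) %in% map$marker]

  out <- purrr::map_dfr(
    split(seq_len(nrow(map)), map$group)[unique(map$group)],
    function(idx) {
      .walk_group(
        x, map[idx, , drop = FALSE], anchor_flip,
        map_function, max_gap
      )
    }
  )
  class(out) <- c("crossphase_phase", class(tibble::tibble()))
  out
}

.normalize_anchors <- function(anchors) {
  if (is.null(anchors) || length(anchors) == 0L) {
    return(stats::setNames(logical(0), character(0)))
  }
  if (is.character(anchors)) {
    return(stats::setNames(rep(FALSE, length(anchors)), anchors))
  }
  if (is.logical(anchors) && !is.null(names(anchors))) {
    return(anchors[!is.na(anchors)])
  }
  stop("anchors must be a character vector or a named logical vector",
    call. = FALSE
  )
}

# Walk one linkage group. grp: map rows (ordered). anchor_flip: named logical.
.walk_group <- function(x, grp, anchor_flip, map_function, max_gap) {
  mk <- grp$marker
  pos <- grp$pos_cM
  n <- length(mk)

  flip <- rep(NA, n) # orientation relative to reference (NA = unoriented)
  phase <- rep("ambiguous", n)
  anchor <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  npar <- rep(NA_integer_, n)
  nrec <- rep(NA_integer_, n)
  ep <- rep(NA_real_, n)
  er <- rep(NA_real_, n)
  stat <- rep(NA_real_, n)
  pv <- rep(NA_real_, n)

  kl <- x$klass[, mk, drop = FALSE]
  informative <- colSums(kl == .KLASS_HOM1 | kl == .KLASS_HOM2) > 0
  is_anchor <- mk %in% names(anchor_flip)

  # segments: a gap wider than max_gap severs phase propagation
  segment <- cumsum(c(TRUE, diff(pos) > max_gap))
  arbitrary <- rep(FALSE, n)

  pair_against <- function(j, a) {
    # count against the anchor's corrected orientation, so the reported
    # phase is relative to the reference and flipped == (phase repulsion)
    ka <- kl[, a]
    if (isTRUE(flip[a])) ka <- .swap_klass(ka)
    pc <- .pair_counts_klass(ka, kl[, j])
    call <- infer_pair_phase(
      pc$n_parental, pc$n_recombinant,
      abs(pos[j] - pos[a]), map_function
    )
    anchor[j] <<- mk[a]
    dist[j] <<- call$distance_cM
    npar[j] <<- call$n_parental
    nrec[j] <<- call$n_recombinant
    ep[j] <<- call$expected_p_parental
    er[j] <<- call$expected_p_recombinant
    stat[j] <<- call$statistic
    pv[j] <<- call$p_value
    phase[j] <<- call$phase
    if (call$phase == "coupling") {
      flip[j] <<- FALSE
    } else if (call$phase == "repulsion") {
      flip[j] <<- TRUE
    }
  }

  for (s in unique(segment)) {
    idx <- which(segment == s)
    seg_anchors <- idx[is_anchor[idx]]
    if (length(seg_anchors) > 0L) {
      flip[seg_anchors] <- unname(anchor_flip[mk[seg_anchors]])
      phase[seg_anchors] <- "anchor"
    } else {
      arbitrary[idx] <- TRUE
      seed <- idx[informative[idx]]
      if (length(seed) > 0L) {
        # no anchored marker: fix the leftmost informative one as reference
        flip[seed[1]] <- FALSE
        phase[seed[1]] <- "coupling"
      }
    }
    # forward pass: orient from the nearest oriented marker on the left
    last <- NA_integer_
    for (j in idx) {
      if (!is.na(flip[j])) {
        last <- j
        next
      }
      if (!is.na(last) && phase[j] == "ambiguous" && is.na(anchor[j]) &&
        (pos[j] - pos[last]) <= max_gap) {
        pair_against(j, last)
        if (!is.na(flip[j])) last <- j
      }
    }
    # backward pass: markers left of the segment's first oriented marker
    last <- NA_integer_
    for (j in rev(idx)) {
      if (!is.na(flip[j])) {
        last <- j
        next
      }
      if (!is.na(last) && is.na(anchor[j]) &&
        (pos[last] - pos[j]) <= max_gap) {
        pair_against(j, last)
        if (!is.na(flip[j])) last <- j
      }
    }
  }

  tibble::tibble(
    marker = mk, group = grp$group, pos_cM = pos,
    anchor = anchor, distance_cM = dist,
    n_parental = npar, n_recombinant = nrec,
    expected_p_parental = ep, expected_p_recombinant = er,
    phase = phase, statistic = stat, p_value = pv,
    flipped = flip, segment = segment, arbitrary = arbitrary
  )
}

#' Recode an ABH dataset to a consistent parental phase
#'
#' Swaps A and B (in progeny and parental rows) at every marker whose
#' inferred orientation is flipped relative to the reference
#' (`flipped == TRUE` in the phase table). H and missing calls are
#' untouched; ambiguous markers are left unchanged. Applying the same phase
#' table twice restores the original dataset.
#'
#' @param x A [pop_data] object in ABH coding.
#' @param phase_calls A `crossphase_phase` tibble from
#'   [phase_linkage_group()] (any tibble with `marker` and `flipped`
#'   columns works).
#' @return A new [pop_data] with corrected orientations.
#' @export
recode_abh <- function(x, phase_calls) {
  stopifnot(inherits(x, "pop_data"))
  if (x$coding != "ABH") {
    stop("recode_abh requires ABH coding; convert with acgt_to_abh() first",
      call. = FALSE
    )
  }
  if (!all(c("marker", "flipped") %in% names(phase_calls))) {
    stop("phase_calls must have columns marker and flipped", call. = FALSE)
  }
  to_flip <- phase_calls$marker[!is.na(phase_calls$flipped) & phase_calls$flipped]
  to_flip <- intersect(to_flip, colnames(x$geno))
  geno <- x$geno
  parents <- x$parents
  for (m in to_flip) {
    geno[, m] <- .swap_ab(geno[, m])
    if (!is.null(parents)) parents[, m] <- .swap_ab(parents[, m])
  }
  pop_data(geno,
    coding = "ABH", generation = x$generation,
    parents = parents, missing_tokens = x$missing_tokens
  )
}

# swap the two homozygote class codes (relabel hom1 <-> hom2)
.swap_klass <- function(k) {
  out <- k
  out[k == .KLASS_HOM1] <- .KLASS_HOM2
  out[k == .KLASS_HOM2] <- .KLASS_HOM1
  out
}

.swap_ab <- function(tokens) {
  up <- toupper(tokens)
  out <- tokens
  out[up == "A"] <- "B"
  out[up == "B"] <- "A"
  out[up == "AA"] <- "BB"
  out[up == "BB"] <- "AA"
  out
}
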