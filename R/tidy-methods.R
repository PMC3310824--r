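# broom-style accessors and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a population dataset into a long tibble
#'
#' One row per (individual, marker) cell with the raw token and its
#' classification.
#'
#' @param x A [pop_data] object.
#' @param ... Unused.
#' @return A tibble: `individual`, `marker`, `call`, `klass`.
#' @exportS3Method generics::tidy
tidy.pop_data <- function(x, ...) {
  tibble::tibble(
    individual = rep(rownames(x$geno), times = ncol(x$geno)),
    marker = rep(colnames(x$geno), each = nrow(x$geno)),
    call = as.vector(x$geno),
    klass = .KLASS_LABELS[as.vector(x$klass) + 1L]
  )
}

#' One-row summary of a population dataset
#'
#' @param x A [pop_data] object.
#' @param ... Unused.
#' @return A one-row tibble: `n_individuals`, `n_markers`, `coding`,
#'   `generation`, `has_parents`, `prop_missing`, `prop_het`,
#'   `n_invalid_markers`.
#' @exportS3Method generics::glance
glance.pop_data <- function(x, ...) {
  tibble::tibble(
    n_individuals = nrow(x$geno),
    n_markers = ncol(x$geno),
    coding = x$coding,
    generation = x$generation,
    has_parents = !is.null(x$parents),
    prop_missing = mean(x$klass == .KLASS_MISSING),
    prop_het = mean(x$klass == .KLASS_HET),
    n_invalid_markers = sum(!x$marker_ok)
  )
}

#' Summarize an inferred-parents table
#'
#' @param x A `crossphase_parents` tibble from [infer_parent_genotypes()].
#' @param ... Unused.
#' @return A one-row tibble with marker counts by source.
#' @exportS3Method generics::glance
glance.crossphase_parents <- function(x, ...) {
  tibble::tibble(
    n_markers = nrow(x),
    n_observed = sum(x$source == "observed"),
    n_inferred = sum(x$source == "inferred"),
    n_conflict = sum(x$source == "conflict"),
    n_unresolved = sum(x$source == "unresolved")
  )
}

#' Plot phase calls along the genetic map
#'
#' One panel per linkage group; markers at their map position, coloured by
#' phase decision, with flipped markers drawn on the upper row.
#'
#' @param object A `crossphase_phase` tibble from [phase_linkage_group()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.crossphase_phase <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    orientation = dplyr::case_when(
      is.na(.data$flipped) ~ "unoriented",
      .data$flipped ~ "flipped",
      TRUE ~ "kept"
    )
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$pos_cM, y = .data$orientation,
      colour = .data$phase
    )
  ) +
    ggplot2::geom_point(shape = 124, size = 4) +
    ggplot2::facet_wrap(~ .data$group, ncol = 1) +
    ggplot2::labs(
      x = "map position (cM)", y = NULL, colour = "phase call",
      title = "Linkage phase along the map"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-marker segregation against the cross-type expectations
#'
#' Shows each marker's homozygote-1 fraction against its heterozygote
#' fraction, coloured by the inferred cross type, with the theoretical
#' points for the dataset's generation marked.
#'
#' @param object A `crossphase_cross` tibble from [call_cross_types()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.crossphase_cross <- function(object, ...) {
  n <- object$n_hom1 + object$n_hom2 + object$n_het
  df <- dplyr::mutate(object,
    f_hom1 = .data$n_hom1 / n, f_het = .data$n_het / n
  )
  gen <- object$generation[1]
  exp_pts <- tibble::tibble(
    cross_type = c("hom_hom", "hom_het"),
    f_hom1 = c(
      expected_proportions("hom_hom", gen)[["p_hom1"]],
      expected_proportions("hom_het", gen)[["p_hom1"]]
    ),
    f_het = c(
      expected_proportions("hom_hom", gen)[["p_het"]],
      expected_proportions("hom_het", gen)[["p_het"]]
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$f_hom1, y = .data$f_het,
    colour = .data$cross_type
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(
      data = exp_pts, shape = 4, size = 4, stroke = 1.5,
      show.legend = FALSE
    ) +
    ggplot2::labs(
      x = "fraction homozygote 1", y = "fraction heterozygous",
      colour = "cross type",
      title = sprintf("Marker segregation at generation F%d", gen)
    ) +
    ggplot2::theme_minimal()
}
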