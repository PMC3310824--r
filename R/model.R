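# Genotype call classification and the pop_data container.
#
# A biparental inbred population is an individuals x markers matrix of short
# genotype tokens, either in ACGT coding (SNP calls: "G", "GT", IUPAC "K",
# ...) or ABH coding (A = homozygous parent-1 allele, B = homozygous
# parent-2 allele, H = heterozygous). Every downstream test works on the
# classification of each call into homozygote-1 / homozygote-2 /
# heterozygote / missing relative to the <=2 alleles seen at that marker.

# Integer class codes used in the internal classification matrix.
.KLASS_MISSING <- 0L
.KLASS_HOM1 <- 1L
.KLASS_HOM2 <- 2L
.KLASS_HET <- 3L

.KLASS_LABELS <- c("missing", "hom1", "hom2", "het")

.IUPAC_HET <- list(
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C")
)

.default_missing_tokens <- function() c("-", ".", "N", "")

#' Default missing-call tokens
#'
#' Tokens treated as missing genotype calls. Matching is case-insensitive.
#'
#' @return Character vector of tokens.
#' @export
missing_tokens_default <- function() .default_missing_tokens()

# Parse raw tokens into a 2-column allele matrix (NA rows = missing).
# Unparseable tokens raise an error naming the token.
.parse_tokens <- function(tokens, coding, missing_tokens = missing_tokens_default()) {
  up <- toupper(trimws(tokens))
  miss <- up %in% toupper(missing_tokens)
  a1 <- rep(NA_character_, length(tokens))
  a2 <- rep(NA_character_, length(tokens))
  todo <- which(!miss)
  if (length(todo) == 0L) {
    return(cbind(a1, a2))
  }
  tok <- up[todo]
  if (coding == "ABH") {
    ok <- tok %in% c("A", "B", "H", "AA", "BB", "AB", "BA")
    if (!all(ok)) {
      bad <- tok[!ok][1]
      stop("unrecognized ABH genotype token: '", bad, "'", call. = FALSE)
    }
    one <- substr(tok, 1, 1)
    two <- ifelse(nchar(tok) == 2L, substr(tok, 2, 2), one)
    a1[todo] <- ifelse(one == "H", "A", one)
    a2[todo] <- ifelse(one == "H", "B", two)
  } else if (coding == "ACGT") {
    for (i in seq_along(todo)) {
      t <- tok[i]
      n <- nchar(t)
      if (n == 1L && t %in% c("A", "C", "G", "T")) {
        a1[todo[i]] <- t
        a2[todo[i]] <- t
      } else if (n == 1L && t %in% names(.IUPAC_HET)) {
        pr <- .IUPAC_HET[[t]]
        a1[todo[i]] <- pr[1]
        a2[todo[i]] <- pr[2]
      } else if (n == 2L) {
        l1 <- substr(t, 1, 1)
        l2 <- substr(t, 2, 2)
        if (!all(c(l1, l2) %in% c("A", "C", "G", "T"))) {
          stop("unrecognized ACGT genotype token: '", tokens[todo[i]], "'",
            call. = FALSE
          )
        }
        pr <- sort(c(l1, l2))
        a1[todo[i]] <- pr[1]
        a2[todo[i]] <- pr[2]
      } else {
        stop("unrecognized ACGT genotype token: '", tokens[todo[i]], "'",
          call. = FALSE
        )
      }
    }
  } else {
    stop("coding must be 'ACGT' or 'ABH'", call. = FALSE)
  }
  # canonical order within the pair
  swap <- !is.na(a1) & a1 > a2
  tmp <- a1[swap]
  a1[swap] <- a2[swap]
  a2[swap] <- tmp
  cbind(a1, a2)
}

#' Classify genotype call tokens
#'
#' Classifies raw genotype tokens into homozygote-1 / homozygote-2 /
#' heterozygote / missing, relative to a marker's (at most two) alleles.
#' Homozygote 1 is the homozygote of the lexicographically smaller allele;
#' the labelling is arbitrary and all downstream tests are symmetric in it.
#'
#' In ACGT coding a heterozygote may be written as a two-letter token
#' (order-insensitive, e.g. `"AG"` or `"GA"`) or as a single IUPAC ambiguity
#' letter (R, Y, S, W, K, M). In ABH coding, doubled tokens (`"AA"`, `"AB"`,
#' `"BB"`) are also accepted.
#'
#' @param raw Character vector of genotype tokens.
#' @param coding `"ACGT"` or `"ABH"`.
#' @param allele_inventory Optional character vector of the marker's alleles
#'   (at most 2). If `NULL`, derived from the non-missing calls in `raw`.
#' @param missing_tokens Tokens treated as missing (case-insensitive).
#'
#' @return A tibble with one row per token: `raw`, `klass` (one of
#'   `"hom1"`, `"hom2"`, `"het"`, `"missing"`), `allele1`, `allele2`.
#'
#' @examples
#' classify_calls(c("A", "H", "B", "-"), coding = "ABH")
#' classify_calls(c("G", "GT", "T", "K"), coding = "ACGT")
#' @export
classify_calls <- function(raw, coding = c("ACGT", "ABH"),
                           allele_inventory = NULL,
                           missing_tokens = missing_tokens_default()) {
  coding <- match.arg(coding)
  al <- .parse_tokens(raw, coding, missing_tokens)
  inv <- allele_inventory
  if (is.null(inv)) {
    inv <- sort(unique(stats::na.omit(c(al[, 1], al[, 2]))))
  } else {
    inv <- sort(unique(toupper(inv)))
  }
  if (length(inv) > 2L) {
    stop("non-biallelic marker: alleles {", paste(inv, collapse = ","), "}",
      call. = FALSE
    )
  }
  seen <- unique(stats::na.omit(c(al[, 1], al[, 2])))
  extra <- setdiff(seen, inv)
  if (length(extra) > 0L) {
    stop("non-biallelic marker: token introduces allele(s) ",
      paste(extra, collapse = ","),
      call. = FALSE
    )
  }
  klass <- .classify_alleles(al, inv)
  tibble::tibble(
    raw = as.character(raw),
    klass = .KLASS_LABELS[klass + 1L],
    allele1 = al[, 1],
    allele2 = al[, 2]
  )
}

# integer klass codes from a parsed allele matrix and a sorted inventory
.classify_alleles <- function(al, inv) {
  k <- rep(.KLASS_MISSING, nrow(al))
  nm <- !is.na(al[, 1])
  het <- nm & al[, 1] != al[, 2]
  k[het] <- .KLASS_HET
  hom <- nm & !het
  if (length(inv) >= 1L) k[hom & al[, 1] == inv[1]] <- .KLASS_HOM1
  if (length(inv) == 2L) k[hom & al[, 1] == inv[2]] <- .KLASS_HOM2
  k
}

#' Construct a biparental population dataset
#'
#' Bundles an individuals x markers genotype token matrix with its coding
#' scheme, selfing generation, and optional parental rows, and classifies
#' every call. Markers with more than two distinct alleles are flagged
#' invalid (with a warning) rather than rejected; `segregation_filter()`
#' removes them.
#'
#' @param geno Character matrix of genotype tokens, individuals in rows
#'   (rownames = individual identifiers), markers in columns (colnames =
#'   marker names). A data frame with an identifier first column is also
#'   accepted.
#' @param coding `"ACGT"`, `"ABH"`, or `NULL` to auto-detect (ABH iff every
#'   non-missing token is a valid ABH token).
#' @param generation Selfing-generation index `x` (F_x; x = 1 is the F1
#'   hybrid itself, x = 2 an F2, ...). `"RIL"` is accepted as an alias for
#'   `x = 10`, where residual heterozygosity (1/2)^9 is below 0.2%.
#' @param parents Optional 2 x markers character matrix of parental tokens
#'   (rows: parent 1, parent 2), same marker order as `geno`.
#' @param missing_tokens Tokens treated as missing (case-insensitive).
#'
#' @return An object of class `pop_data`: a list with the raw matrix
#'   (`geno`), the classification matrix (`klass`), per-marker allele
#'   inventories (`alleles`), per-marker validity (`marker_ok`, `marker_error`),
#'   plus `coding`, `generation`, `parents`, and `missing_tokens`.
#'
#' @seealso [marker_counts()], [segregation_filter()], [read_genotype_table()]
#' @export
pop_data <- function(geno, coding = NULL, generation = 10, parents = NULL,
                     missing_tokens = missing_tokens_default()) {
  if (is.data.frame(geno)) {
    ids <- as.character(geno[[1]])
    m <- as.matrix(geno[, -1, drop = FALSE])
    rownames(m) <- ids
    geno <- m
  }
  if (!is.matrix(geno) || !is.character(geno)) {
    storage.mode(geno) <- "character"
  }
  if (is.null(colnames(geno))) {
    stop("genotype matrix must have marker names as column names", call. = FALSE)
  }
  if (is.null(rownames(geno))) {
    rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  }
  if (anyDuplicated(colnames(geno))) {
    stop("duplicate marker names: ",
      paste(unique(colnames(geno)[duplicated(colnames(geno))]), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(rownames(geno))) {
    stop("duplicate individual identifiers", call. = FALSE)
  }
  generation <- .normalize_generation(generation)
  if (is.null(coding)) coding <- .detect_coding(geno, missing_tokens)
  coding <- match.arg(coding, c("ACGT", "ABH"))
  if (!is.null(parents)) {
    parents <- as.matrix(parents)
    storage.mode(parents) <- "character"
    if (nrow(parents) != 2L || ncol(parents) != ncol(geno)) {
      stop("parents must be a 2 x markers matrix matching the genotype matrix",
        call. = FALSE
      )
    }
    colnames(parents) <- colnames(geno)
    if (is.null(rownames(parents))) rownames(parents) <- c("P1", "P2")
  }

  nm <- ncol(geno)
  klass <- matrix(.KLASS_MISSING, nrow(geno), nm,
    dimnames = dimnames(geno)
  )
  pklass <- if (is.null(parents)) NULL else matrix(.KLASS_MISSING, 2L, nm, dimnames = dimnames(parents))
  alleles <- vector("list", nm)
  names(alleles) <- colnames(geno)
  marker_ok <- rep(TRUE, nm)
  marker_error <- rep(NA_character_, nm)
  names(marker_ok) <- names(marker_error) <- colnames(geno)

  for (j in seq_len(nm)) {
    toks <- geno[, j]
    ptoks <- if (is.null(parents)) character(0) else parents[, j]
    al <- tryCatch(
      .parse_tokens(c(toks, ptoks), coding, missing_tokens),
      error = function(e) e
    )
    if (inherits(al, "error")) {
      bad <- conditionMessage(al)
      stop(bad, " (marker '", colnames(geno)[j], "')", call. = FALSE)
    }
    inv <- sort(unique(stats::na.omit(c(al[, 1], al[, 2]))))
    alleles[[j]] <- inv
    if (length(inv) > 2L) {
      marker_ok[j] <- FALSE
      marker_error[j] <- "non_biallelic"
      next
    }
    k <- .classify_alleles(al, inv)
    klass[, j] <- k[seq_len(nrow(geno))]
    if (!is.null(parents)) pklass[, j] <- k[nrow(geno) + 1:2]
  }
  if (any(!marker_ok)) {
    warning(
      sum(!marker_ok), " non-biallelic marker(s) flagged invalid: ",
      paste(utils::head(colnames(geno)[!marker_ok], 5), collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      geno = geno, klass = klass, alleles = alleles,
      marker_ok = marker_ok, marker_error = marker_error,
      coding = coding, generation = generation,
      parents = parents, parent_klass = pklass,
      missing_tokens = missing_tokens
    ),
    class = "pop_data"
  )
}

.normalize_generation <- function(generation) {
  if (is.character(generation)) {
    if (toupper(generation) == "RIL") {
      return(10L)
    }
    generation <- suppressWarnings(as.numeric(generation))
  }
  if (length(generation) != 1L || is.na(generation) ||
    generation < 1 || generation != floor(generation)) {
    stop("generation must be an integer >= 1 (or \"RIL\")", call. = FALSE)
  }
  as.integer(generation)
}

.detect_coding <- function(geno, missing_tokens) {
  up <- toupper(trimws(as.vector(geno)))
  up <- up[!(up %in% toupper(missing_tokens))]
  if (length(up) > 0L && all(up %in% c("A", "B", "H", "AA", "AB", "BA", "BB"))) {
    "ABH"
  } else {
    "ACGT"
  }
}

#' @export
print.pop_data <- function(x, ...) {
  cat(
    "<pop_data> ", nrow(x$geno), " individuals x ", ncol(x$geno),
    " markers (", x$coding, " coding, generation F", x$generation, ")\n",
    sep = ""
  )
  if (!is.null(x$parents)) {
    cat("  parental rows: ", paste(rownames(x$parents), collapse = ", "), "\n", sep = "")
  }
  nbad <- sum(!x$marker_ok)
  if (nbad > 0) cat("  invalid (non-biallelic) markers: ", nbad, "\n", sep = "")
  miss <- mean(x$klass == .KLASS_MISSING)
  cat("  missing calls: ", sprintf("%.1f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' Number of individuals / markers in a population dataset
#'
#' @param x A [pop_data] object.
#' @return An integer count.
#' @export
n_individuals <- function(x) {
  stopifnot(inherits(x, "pop_data"))
  nrow(x$geno)
}

#' @rdname n_individuals
#' @export
n_markers <- function(x) {
  stopifnot(inherits(x, "pop_data"))
  ncol(x$geno)
}

#' Per-marker genotype class counts
#'
#' Counts homozygote-1 / homozygote-2 / heterozygote / missing calls for
#' every marker. Counts always sum to the number of individuals. Homozygote
#' 1 carries the lexicographically smaller allele; all downstream tests are
#' symmetric in the labelling.
#'
#' @param x A [pop_data] object.
#' @param markers Optional character vector restricting to these markers.
#'
#' @return A tibble: `marker`, `allele1`, `allele2`, `n_hom1`, `n_hom2`,
#'   `n_het`, `n_missing`.
#' @export
marker_counts <- function(x, markers = NULL) {
  stopifnot(inherits(x, "pop_data"))
  mk <- colnames(x$geno)
  if (!is.null(markers)) {
    absent <- setdiff(markers, mk)
    if (length(absent) > 0L) {
      stop("marker(s) not in dataset: ", paste(absent, collapse = ", "),
        call. = FALSE
      )
    }
    mk <- markers
  }
  k <- x$klass[, mk, drop = FALSE]
  inv <- x$alleles[mk]
  tibble::tibble(
    marker = mk,
    allele1 = purrr::map_chr(inv, ~ if (length(.x) >= 1) .x[1] else NA_character_),
    allele2 = purrr::map_chr(inv, ~ if (length(.x) >= 2) .x[2] else NA_character_),
    n_hom1 = unname(colSums(k == .KLASS_HOM1)),
    n_hom2 = unname(colSums(k == .KLASS_HOM2)),
    n_het = unname(colSums(k == .KLASS_HET)),
    n_missing = unname(colSums(k == .KLASS_MISSING))
  )
}

#' Build a genetic map
#'
#' A genetic map is an ordered set of linkage groups, each an ordered list
#' of (marker, position in centimorgan). Groups keep their order of first
#' appearance; markers are sorted by position within a group (stable on
#' ties).
#'
#' @param marker Character vector of marker names (unique across the map).
#' @param group Linkage-group identifiers (coerced to character).
#' @param pos_cM Numeric map positions in centimorgan.
#'
#' @return A tibble of class `genetic_map` with columns `marker`, `group`,
#'   `pos_cM`.
#' @seealso [read_map()]
#' @export
genetic_map <- function(marker, group, pos_cM) {
  marker <- as.character(marker)
  group <- as.character(group)
  pos_cM <- as.numeric(pos_cM)
  if (length(marker) != length(group) || length(marker) != length(pos_cM)) {
    stop("marker, group and pos_cM must have equal length", call. = FALSE)
  }
  if (anyDuplicated(marker)) {
    stop("duplicate marker name(s) in map: ",
      paste(unique(marker[duplicated(marker)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(is.na(pos_cM))) {
    stop("map positions must be numeric and non-missing", call. = FALSE)
  }
  grp_order <- unique(group)
  out <- tibble::tibble(marker = marker, group = group, pos_cM = pos_cM)
  out <- out[order(match(out$group, grp_order), out$pos_cM), ]
  class(out) <- c("genetic_map", class(tibble::tibble()))
  out
}
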