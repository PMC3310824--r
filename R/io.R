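# Tab-delimited readers/writers for genotype matrices and genetic maps,
# plus the MapQTL .loc exporter. The generic genotype table is: header row
# of marker names, first column of individual identifiers, parental rows
# identified by configurable identifiers. Marker order in the genotype file
# is independent of the map; files are matched by marker name.

#' File dialect for genotype tables
#'
#' @param missing_tokens Tokens treated as missing calls.
#' @param parent_ids Identifiers of the two parental rows (distinct).
#' @param orientation `"markers_as_columns"` (default: rows are individuals)
#'   or `"markers_as_rows"` (transposed input).
#' @return A list of class `file_dialect`.
#' @export
file_dialect <- function(missing_tokens = missing_tokens_default(),
                         parent_ids = c("P1", "P2"),
                         orientation = c("markers_as_columns", "markers_as_rows")) {
  orientation <- match.arg(orientation)
  if (length(parent_ids) != 2L || parent_ids[1] == parent_ids[2]) {
    stop("parent_ids must be two distinct identifiers", call. = FALSE)
  }
  structure(
    list(
      missing_tokens = missing_tokens, parent_ids = parent_ids,
      orientation = orientation
    ),
    class = "file_dialect"
  )
}

# split tab-delimited lines, enforcing a rectangular table
.read_tsv_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) {
    return(NULL)
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- lengths(cells)
  # trailing empty field after a final tab is legitimate (missing token "")
  if (length(unique(width)) > 1L) {
    bad <- which(width != width[1])[1]
    stop("ragged row in ", basename(path), ": line ", bad,
      " has ", width[bad], " fields, expected ", width[1],
      call. = FALSE
    )
  }
  do.call(rbind, cells)
}

#' Read a tab-delimited genotype table
#'
#' First row: marker names (first cell is an ignored corner label). First
#' column: individual identifiers. Rows whose identifier matches
#' `dialect$parent_ids` become the parental rows (excluded from the progeny
#' count). Coding is auto-detected: ABH iff every non-missing token is a
#' valid ABH token. With `orientation = "markers_as_rows"` the table is
#' transposed after reading.
#'
#' @param path File path.
#' @param generation Selfing-generation index of the population (or
#'   `"RIL"`).
#' @param dialect A [file_dialect()].
#' @param coding Force `"ACGT"`/`"ABH"` instead of auto-detecting.
#' @return A [pop_data] object.
#' @export
read_genotype_table <- function(path, generation = 10,
                                dialect = file_dialect(), coding = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  m <- .read_tsv_matrix(path)
  if (is.null(m) || nrow(m) < 2L || ncol(m) < 2L) {
    stop("genotype table needs a header row, an id column and data: ", path,
      call. = FALSE
    )
  }
  if (dialect$orientation == "markers_as_rows") m <- t(m)
  markers <- m[1, -1]
  ids <- m[-1, 1]
  geno <- m[-1, -1, drop = FALSE]
  if (anyDuplicated(markers)) {
    stop("duplicate marker name(s): ",
      paste(unique(markers[duplicated(markers)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(ids)) {
    stop("duplicate individual identifier(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  dimnames(geno) <- list(ids, markers)
  is_parent <- ids %in% dialect$parent_ids
  parents <- NULL
  if (any(is_parent)) {
    pr <- geno[is_parent, , drop = FALSE]
    # order P1 then P2; a single observed parent row gets a missing partner
    parents <- matrix(dialect$missing_tokens[1], 2L, ncol(geno),
      dimnames = list(dialect$parent_ids, markers)
    )
    parents[rownames(pr), ] <- pr
    geno <- geno[!is_parent, , drop = FALSE]
  }
  pop_data(geno,
    coding = coding, generation = generation, parents = parents,
    missing_tokens = dialect$missing_tokens
  )
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]: parental rows (if any) first, then
#' individuals, tokens exactly as stored, so read -> write round-trips
#' byte-identically.
#'
#' @param x A [pop_data] object.
#' @param path Output file path.
#' @param dialect A [file_dialect()] (controls orientation and the
#'   identifiers written for the parental rows).
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path, dialect = file_dialect()) {
  stopifnot(inherits(x, "pop_data"))
  geno <- x$geno
  if (!is.null(x$parents)) {
    pr <- x$parents
    rownames(pr) <- dialect$parent_ids
    geno <- rbind(pr, geno)
  }
  body <- cbind(rownames(geno), geno)
  tab <- rbind(c("id", colnames(x$geno)), body)
  if (dialect$orientation == "markers_as_rows") tab <- t(tab)
  writeLines(apply(tab, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a genetic map
#'
#' Three tab-delimited columns: marker, linkage group, position in
#' centimorgan. A header line is detected (and skipped) when its third field
#' is not numeric. Groups keep their order of first appearance; markers are
#' sorted by position within each group.
#'
#' @param path File path.
#' @return A [genetic_map] tibble (empty, with a warning, for an empty
#'   file).
#' @export
read_map <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  m <- .read_tsv_matrix(path)
  if (is.null(m)) {
    warning("empty map file: ", path, call. = FALSE)
    return(genetic_map(character(0), character(0), numeric(0)))
  }
  if (ncol(m) < 3L) {
    stop("map file needs 3 columns (marker, group, position): ", path,
      call. = FALSE
    )
  }
  first_data <- 1L
  if (is.na(suppressWarnings(as.numeric(m[1, 3])))) first_data <- 2L
  if (nrow(m) < first_data) {
    warning("empty map file: ", path, call. = FALSE)
    return(genetic_map(character(0), character(0), numeric(0)))
  }
  rows <- first_data:nrow(m)
  pos <- suppressWarnings(as.numeric(m[rows, 3]))
  if (any(is.na(pos))) {
    bad <- rows[which(is.na(pos))[1]]
    stop("non-numeric map position '", m[bad, 3], "' at line ", bad,
      " of ", basename(path),
      call. = FALSE
    )
  }
  genetic_map(marker = m[rows, 1], group = m[rows, 2], pos_cM = pos)
}

#' Write a genetic map
#'
#' @param map A [genetic_map].
#' @param path Output file path.
#' @param header Write a `marker group pos_cM` header line.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, header = TRUE) {
  lines <- paste(map$marker, map$group, format(map$pos_cM, trim = TRUE),
    sep = "\t"
  )
  if (header) lines <- c("marker\tgroup\tpos_cM", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Export an ABH dataset as a MapQTL .loc file
#'
#' Writes the standard `.loc` header (`name`, `popt`, `nloc`, `nind`)
#' followed by one row per marker with genotype codes `a`/`b`/`h`/`u`
#' (u = unknown). Markers not resolvable to a/b/h (e.g. flagged
#' non-biallelic) are omitted with a warning. Output is byte-stable for a
#' fixed input.
#'
#' @param x A [pop_data] in ABH coding.
#' @param path Output file path.
#' @param pop_name Population name for the header.
#' @param popt MapQTL population-type token; the default `"RIx"` substitutes
#'   the dataset's generation (e.g. `RI8`). Pass e.g. `"F2"` explicitly for
#'   early generations.
#' @param map Optional [genetic_map]; if given, markers are written in map
#'   order and restricted to mapped markers.
#' @return `path`, invisibly.
#' @export
export_mapqtl_loc <- function(x, path, pop_name = "population",
                              popt = NULL, map = NULL) {
  stopifnot(inherits(x, "pop_data"))
  if (x$coding != "ABH") {
    stop(".loc export requires ABH coding; convert with acgt_to_abh() first",
      call. = FALSE
    )
  }
  if (is.null(popt)) popt <- paste0("RI", x$generation)
  markers <- colnames(x$geno)
  if (!is.null(map)) {
    markers <- intersect(map$marker, markers)
  }
  ok <- x$marker_ok[markers]
  if (any(!ok)) {
    warning(sum(!ok), " marker(s) omitted from .loc export", call. = FALSE)
    markers <- markers[ok]
  }
  code <- c("u", "a", "b", "h") # indexed by klass code + 1
  lines <- c(
    paste0("name = ", pop_name),
    paste0("popt = ", popt),
    paste0("nloc = ", length(markers)),
    paste0("nind = ", nrow(x$geno)),
    ""
  )
  for (m in markers) {
    lines <- c(lines, paste0(
      m, "\t", paste(code[x$klass[, m] + 1L], collapse = " ")
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

# tab-delimited report writer shared by the CLI
.write_report <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA"
  )
  invisible(path)
}
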