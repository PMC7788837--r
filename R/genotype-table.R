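#' Build a genotype table from a data frame
#'
#' A genotype table is the package's central container: a tibble with a
#' `sample_id` column followed by one column per marker, each cell holding an
#' unordered diploid allele pair. Alleles are opaque labels ("A", "T", "12",
#' "9.3", ...), stored sorted and joined by `"/"`; missing genotypes are `NA`.
#' Because the pair is unordered, phase is deliberately discarded.
#'
#' @param df A data frame whose first column holds sample identifiers and
#'   whose remaining columns hold genotypes as `"allele1<sep>allele2"`
#'   strings (or `NA`).
#' @param allele_sep Separator between the two alleles, matched literally
#'   (default `"/"`). Regex metacharacters such as `"|"` need no escaping.
#' @param marker_types Optional character vector (one of `"SNP"`, `"STR"`,
#'   `"other"`) naming the type of each marker column; informational only,
#'   no computation branches on it.
#' @return A `genotype_tbl`: a tibble of `sample_id` plus one character
#'   column per marker with normalized `"a/b"` cells. The number of cells
#'   that failed to split into exactly two non-empty allele labels is kept
#'   in the `n_unparsed` attribute (they become `NA`, with a warning).
#' @examples
#' df <- tibble::tibble(
#'   id   = c("s1", "s2"),
#'   STR1 = c("12|13", "12|12"),
#'   SNP1 = c("A|T", "T|T")
#' )
#' genotype_table(df, allele_sep = "|")
#' @export
genotype_table <- function(df, allele_sep = "/", marker_types = NULL) {
  stopifnot(is.data.frame(df))
  if (ncol(df) < 2L) {
    stop("genotype table needs a sample-id column and at least one marker", call. = FALSE)
  }
  if (nrow(df) < 1L) {
    stop("genotype table needs at least one individual", call. = FALSE)
  }
  if (!nzchar(allele_sep)) {
    stop("`allele_sep` must be a non-empty string", call. = FALSE)
  }
  sample_id <- as.character(df[[1L]])
  markers <- names(df)[-1L]
  n_unparsed <- 0L
  cells <- lapply(df[-1L], function(col) {
    col <- as.character(col)
    col[!is.na(col) & col == ""] <- NA_character_
    parts <- strsplit(col, allele_sep, fixed = TRUE)
    norm <- vapply(parts, function(p) {
      if (length(p) == 2L && all(nzchar(p))) {
        paste(sort(p), collapse = "/")
      } else {
        NA_character_
      }
    }, character(1))
    n_unparsed <<- n_unparsed + sum(is.na(norm) & !is.na(col))
    norm
  })
  if (n_unparsed > 0L) {
    warning(n_unparsed, " cell(s) did not split into two alleles on '",
            allele_sep, "' and were set to missing", call. = FALSE)
  }
  out <- tibble::tibble(sample_id = sample_id, !!!cells)
  new_genotype_tbl(out, marker_types = marker_types, n_unparsed = n_unparsed)
}

new_genotype_tbl <- function(tbl, marker_types = NULL, n_unparsed = 0L) {
  markers <- setdiff(names(tbl), "sample_id")
  if (!is.null(marker_types)) {
    stopifnot(length(marker_types) == length(markers))
    marker_types <- stats::setNames(as.character(marker_types), markers)
  }
  structure(
    tbl,
    class = c("genotype_tbl", class(tibble::tibble())),
    marker_type = marker_types,
    n_unparsed = n_unparsed
  )
}

#' Marker names of a genotype table
#' @param gt A `genotype_tbl`.
#' @return Character vector of marker column names.
#' @export
gt_markers <- function(gt) setdiff(names(gt), "sample_id")

#' Split a genotype table into two allele matrices
#'
#' Internal workhorse representation: two character matrices (individuals x
#' markers) with the within-cell sorted first and second allele. All counting
#' routines run on this representation.
#'
#' @param gt A `genotype_tbl`.
#' @return A list with character matrices `a1` and `a2` (NA where missing),
#'   and `markers` / `sample_id` vectors.
#' @keywords internal
gt_split <- function(gt) {
  markers <- gt_markers(gt)
  n <- nrow(gt)
  a1 <- matrix(NA_character_, n, length(markers), dimnames = list(NULL, markers))
  a2 <- a1
  for (j in seq_along(markers)) {
    cell <- gt[[markers[j]]]
    ok <- !is.na(cell)
    if (any(ok)) {
      parts <- strsplit(cell[ok], "/", fixed = TRUE)
      a1[ok, j] <- vapply(parts, `[`, character(1), 1L)
      a2[ok, j] <- vapply(parts, `[`, character(1), 2L)
    }
  }
  list(a1 = a1, a2 = a2, markers = markers, sample_id = gt$sample_id)
}

# inverse of gt_split; allele order inside each cell is re-normalized
gt_from_split <- function(split, marker_types = NULL) {
  swap <- !is.na(split$a1) & split$a1 > split$a2
  if (any(swap)) {
    tmp <- split$a1[swap]
    split$a1[swap] <- split$a2[swap]
    split$a2[swap] <- tmp
  }
  cells <- lapply(seq_along(split$markers), function(j) {
    out <- paste(split$a1[, j], split$a2[, j], sep = "/")
    out[is.na(split$a1[, j])] <- NA_character_
    out
  })
  names(cells) <- split$markers
  tbl <- tibble::tibble(sample_id = split$sample_id, !!!cells)
  new_genotype_tbl(tbl, marker_types = marker_types)
}

validate_genotype_tbl <- function(gt) {
  if (!inherits(gt, "genotype_tbl")) {
    if (is.data.frame(gt) && "sample_id" %in% names(gt)) {
      gt <- new_genotype_tbl(tibble::as_tibble(gt))
    } else {
      stop("expected a `genotype_tbl` (see `genotype_table()`)", call. = FALSE)
    }
  }
  if (length(gt_markers(gt)) == 0L) stop("genotype table has zero markers", call. = FALSE)
  if (nrow(gt) == 0L) stop("genotype table has zero individuals", call. = FALSE)
  gt
}

#' @export
print.genotype_tbl <- function(x, ...) {
  cat("# Genotype table: ", nrow(x), " individuals x ", length(gt_markers(x)),
      " markers\n", sep = "")
  NextMethod()
}
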