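#' Read a genotype matrix from a CSV/TSV file
#'
#' The expected layout has marker names in the header row and sample IDs in
#' the first column; every other cell is a diploid genotype written as the
#' two allele labels joined by `allele_sep` (e.g. `"12|13"`, `"A|T"`).
#'
#' @param path Path to a `.csv`, `.tsv` or `.txt` file.
#' @param allele_sep Allele separator, matched literally (default `"|"`).
#' @param marker_types Optional per-marker type labels, see
#'   [genotype_table()].
#' @return A `genotype_tbl`.
#' @seealso [read_vcf_gt()], [write_genotypes()]
#' @export
read_genotypes <- function(path, allele_sep = "|", marker_types = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  genotype_table(raw, allele_sep = allele_sep, marker_types = marker_types)
}

#' Read diploid genotypes from the GT field of a VCF file
#'
#' Each VCF record becomes one marker; GT allele indices are resolved to the
#' REF/ALT strings. Phased (`0|1`) and unphased (`0/1`) genotypes are both
#' accepted and phase is discarded; `./.` (or `.`-containing) genotypes
#' become missing. The marker id is the ID field when present, otherwise
#' `CHROM:POS`. A marker type is inferred per record (SNP when REF and all
#' ALT alleles have length 1, otherwise "other") — informational only.
#'
#' @param path Path to a VCF 4.x file with a GT entry in FORMAT.
#' @return A `genotype_tbl`.
#' @export
read_vcf_gt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no records", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT entry in FORMAT", call. = FALSE)
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  ids <- make.unique(ids)
  samples <- colnames(gt)
  n <- length(samples)
  cells <- vector("list", nrow(fix))
  types <- character(nrow(fix))
  for (r in seq_len(nrow(fix))) {
    ref <- fix[r, "REF"]
    alt <- fix[r, "ALT"]
    alleles <- c(ref, if (!is.na(alt) && alt != ".") strsplit(alt, ",", fixed = TRUE)[[1]])
    types[r] <- if (all(nchar(alleles) == 1L)) "SNP" else "other"
    g <- gt[r, ]
    parts <- strsplit(ifelse(is.na(g), ".", g), "[/|]")
    ploidy_bad <- vapply(parts, length, integer(1)) > 2L |
      (vapply(parts, length, integer(1)) == 1L &
         vapply(parts, function(p) p[1] != ".", logical(1)))
    if (any(ploidy_bad)) {
      stop("record ", ids[r], ": GT is not diploid for sample(s) ",
           paste(samples[ploidy_bad], collapse = ", "), call. = FALSE)
    }
    cell <- vapply(parts, function(p) {
      if (length(p) != 2L || any(p == ".")) return(NA_character_)
      idx <- suppressWarnings(as.integer(p))
      if (any(is.na(idx)) || any(idx < 0L) || any(idx >= length(alleles))) {
        return(NA_character_)
      }
      paste(sort(alleles[idx + 1L]), collapse = "/")
    }, character(1))
    cells[[r]] <- unname(cell)
  }
  names(cells) <- ids
  tbl <- tibble::tibble(sample_id = samples, !!!cells)
  new_genotype_tbl(tbl, marker_types = types)
}

#' Write a genotype table to CSV
#'
#' Writes the tabular layout read by [read_genotypes()]: header of marker
#' names, first column of sample IDs, genotypes joined by `allele_sep`.
#' Missing genotypes are written as empty strings. `read_genotypes()` on the
#' output recovers the table exactly (allele order within a cell is
#' normalized).
#'
#' @param gt A `genotype_tbl`.
#' @param path Output file path.
#' @param allele_sep Separator to join the two alleles with (default `"|"`).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path, allele_sep = "|") {
  gt <- validate_genotype_tbl(gt)
  out <- tibble::as_tibble(gt)
  for (mk in gt_markers(gt)) {
    out[[mk]] <- gsub("/", allele_sep, out[[mk]], fixed = TRUE)
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}
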