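#' Codominant biallelic genotype matrix
#'
#' The central container of the package: an individuals x loci matrix of
#' alternate-allele dosages (0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing), together with a locus table
#' holding chromosome, 1-based position, reference and alternate allele, and a
#' locus identifier. Dosage counts the ALT allele; phase is ignored.
#'
#' @param calls integer matrix, individuals in rows, loci in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param individuals character vector of sample labels (defaults to
#'   `rownames(calls)`).
#' @param loci data frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `id`; one row per column of `calls`. If `NULL`, placeholder
#'   loci on a single chromosome are generated.
#' @return An object of class `geno_matrix`: a list with elements `calls`
#'   (integer matrix with dimnames) and `loci` (data frame).
#' @examples
#' gm <- geno_matrix(rbind(a = c(0L, 1L), b = c(2L, NA)))
#' n_loci(gm)
#' @export
geno_matrix <- function(calls, individuals = rownames(calls), loci = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(individuals)) {
    individuals <- paste0("ind", seq_len(nrow(calls)))
  }
  if (length(individuals) != nrow(calls)) {
    stop("length of 'individuals' must equal nrow(calls)")
  }
  if (anyDuplicated(individuals)) {
    stop("duplicated individual labels")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("non-missing calls must be alternate-allele dosages in {0, 1, 2}")
  }
  if (is.null(loci)) {
    loci <- data.frame(
      chrom = "ch01",
      pos = seq_len(ncol(calls)),
      ref = "A",
      alt = "T",
      stringsAsFactors = FALSE
    )
  }
  loci <- validate_loci(loci, ncol(calls))
  dimnames(calls) <- list(individuals, loci$id)
  structure(list(calls = calls, loci = loci), class = "geno_matrix")
}

validate_loci <- function(loci, n) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(loci))) {
    stop("locus table needs columns: ", paste(req, collapse = ", "))
  }
  if (nrow(loci) != n) {
    stop("locus table has ", nrow(loci), " rows but matrix has ", n, " loci")
  }
  if (any(loci$pos < 1)) stop("locus positions must be >= 1 (1-based)")
  if (any(loci$ref == loci$alt)) stop("ref and alt allele must differ")
  if (is.null(loci$id)) loci$id <- make_locus_ids(loci$chrom, loci$pos)
  if (anyDuplicated(loci$id)) stop("duplicated locus ids")
  rownames(loci) <- NULL
  loci
}

#' Build chromosome_position locus identifiers
#'
#' @param chrom,pos chromosome labels and 1-based positions.
#' @return character vector `"<chrom>_<pos>"`.
#' @export
make_locus_ids <- function(chrom, pos) paste(chrom, pos, sep = "_")

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$calls), "individuals x", ncol(x$calls), "loci\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of individuals / loci in a genotype matrix
#' @param x a `geno_matrix`.
#' @return integer count.
#' @export
n_individuals <- function(x) nrow(x$calls)

#' @rdname n_individuals
#' @export
n_loci <- function(x) ncol(x$calls)

#' Individual labels of a genotype container
#' @param x a `geno_matrix` or `allele_depth_set`.
#' @return character vector of sample labels.
#' @export
individuals <- function(x) {
  if (inherits(x, "allele_depth_set")) rownames(x$ref) else rownames(x$calls)
}

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param x a `geno_matrix`.
#' @param i individual selector (indices or labels); `j` locus selector.
#' @param j see `i`.
#' @param ... ignored.
#' @return a `geno_matrix`.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  calls <- x$calls[i, j, drop = FALSE]
  geno_matrix(calls, rownames(calls), x$loci[match(colnames(calls), x$loci$id), ])
}

#' Per-individual, per-locus allele read depths
#'
#' Holds reference and alternate read counts for every individual x locus
#' cell, the raw material for read-depth-fraction genotype calling.
#'
#' @param ref,alt non-negative integer matrices of identical dimension:
#'   reference- and alternate-allele read counts.
#' @param individuals sample labels; defaults to `rownames(ref)`.
#' @param loci locus table as in [geno_matrix()].
#' @return An object of class `allele_depth_set`.
#' @export
allele_depth_set <- function(ref, alt, individuals = rownames(ref), loci = NULL) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
  if (!identical(dim(ref), dim(alt))) stop("ref and alt dimensions differ")
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative")
  }
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(ref)))
  if (is.null(loci)) {
    loci <- data.frame(chrom = "ch01", pos = seq_len(ncol(ref)),
                       ref = "A", alt = "T", stringsAsFactors = FALSE)
  }
  loci <- validate_loci(loci, ncol(ref))
  dimnames(ref) <- dimnames(alt) <- list(individuals, loci$id)
  structure(list(ref = ref, alt = alt, loci = loci), class = "allele_depth_set")
}

#' @export
print.allele_depth_set <- function(x, ...) {
  cat("allele_depth_set:", nrow(x$ref), "individuals x", ncol(x$ref), "loci\n")
  cat(sprintf("  mean total depth: %.2f\n", mean(x$ref + x$alt)))
  invisible(x)
}
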