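#' Read a VCF file into a genotype matrix (and allele depths when present)
#'
#' GT fields map to alternate-allele dosage (`0/0` -> 0, `0/1` or `1|0` -> 1,
#' `1/1` -> 2, `./.` -> `NA`; phase separators are ignored). When an AD
#' (allelic depth) FORMAT field is present it populates an
#' [allele_depth_set()]. Multiallelic records (ALT containing a comma) are
#' dropped with a message reporting the count.
#'
#' @param path VCF 4.x file (plain text or gzipped).
#' @return list with elements `genotypes` (a [geno_matrix()]), `depths` (an
#'   [allele_depth_set()] or `NULL` when AD is absent) and
#'   `n_multiallelic_dropped`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) stop("no records in VCF: ", path)
  alt <- v@fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    message("dropping ", sum(multi), " multiallelic record(s)")
    v <- v[!multi, ]
  }
  if (nrow(v@fix) == 0) stop("no biallelic records in VCF: ", path)
  fix <- v@fix
  loci <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  id <- fix[, "ID"]
  if (!all(is.na(id) | id == ".")) loci$id <- id
  gt <- vcfR::extract.gt(v, element = "GT")
  # gt is loci x individuals; strip phase, map to dosage
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow = nrow(gt_clean), ncol = ncol(gt_clean))
  dosage[gt_clean %in% "0/0"] <- 0L
  dosage[gt_clean %in% c("0/1", "1/0")] <- 1L
  dosage[gt_clean %in% "1/1"] <- 2L
  unknown <- !is.na(gt_clean) & !(gt_clean %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(unknown)) {
    stop("unrecognised GT value(s), e.g. ", gt_clean[which(unknown)[1]])
  }
  gm <- geno_matrix(t(dosage), individuals = colnames(gt), loci = loci)

  depths <- NULL
  fmt <- v@gt[, 1]
  if (all(grepl("AD", fmt))) {
    ad <- vcfR::extract.gt(v, element = "AD")
    split_counts <- function(k) {
      out <- matrix(0L, nrow = nrow(ad), ncol = ncol(ad))
      ok <- !is.na(ad) & ad != "."
      parts <- strsplit(ad[ok], ",", fixed = TRUE)
      out[ok] <- vapply(parts, function(p) as.integer(p[k]), integer(1))
      out
    }
    depths <- allele_depth_set(t(split_counts(1)), t(split_counts(2)),
                               individuals = colnames(ad), loci = loci)
  }
  list(genotypes = gm, depths = depths, n_multiallelic_dropped = sum(multi))
}

#' Write a genotype matrix (and optional allele depths) as VCF 4.2
#'
#' Emits plain-text VCF with GT (and AD, when `depths` is supplied) so that
#' `read_vcf(write_vcf(m))` round-trips calls, sample order and coordinates
#' exactly. Missing calls are written as `./.`.
#'
#' @param gm a [geno_matrix()].
#' @param path output file path.
#' @param depths optional [allele_depth_set()] with matching dimensions.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, depths = NULL) {
  if (n_loci(gm) == 0 || n_individuals(gm) == 0) stop("empty genotype matrix")
  if (!is.null(depths) && !identical(dim(depths$ref), dim(gm$calls))) {
    stop("depths dimensions do not match genotype matrix")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=gbspop",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(depths))
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">'
  ), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", individuals(gm)), collapse = "\t"), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  fmt <- if (is.null(depths)) "GT" else "GT:AD"
  for (j in seq_len(n_loci(gm))) {
    d <- gm$calls[, j]
    g <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    if (!is.null(depths)) {
      g <- paste0(g, ":", depths$ref[, j], ",", depths$alt[, j])
    }
    lo <- gm$loci[j, ]
    writeLines(paste(c(lo$chrom, lo$pos, lo$id, lo$ref, lo$alt, ".", "PASS",
                       ".", fmt, g), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a genotype matrix as a tab-separated dosage table
#'
#' One row per individual, one column per locus id; missing as `NA`.
#'
#' @param gm a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geno_table <- function(gm, path) {
  utils::write.table(cbind(individual = individuals(gm), as.data.frame(gm$calls)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
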