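#' Population map: individual -> group assignment
#'
#' Assigns each individual to exactly one group (here, persimmon astringency
#' types such as PCNA/PCA/PVNA/PVA). Individuals labelled `"Unknown"` (case
#' insensitive) are retained for whole-collection analyses (trees, PCA,
#' total-population diversity) but excluded from group-wise statistics, AMOVA
#' and pairwise Fst.
#'
#' @param individual,group character vectors of equal length.
#' @return An object of class `popmap`: a data frame with columns
#'   `individual` and `group`.
#' @examples
#' pm <- popmap(c("a", "b", "c"), c("PCNA", "PCA", "Unknown"))
#' analyzable(pm)
#' @export
popmap <- function(individual, group) {
  individual <- as.character(individual)
  group <- as.character(group)
  if (length(individual) != length(group)) stop("lengths differ")
  if (anyDuplicated(individual)) {
    stop("duplicated individual in population map: ",
         paste(unique(individual[duplicated(individual)]), collapse = ", "))
  }
  structure(data.frame(individual = individual, group = group,
                       stringsAsFactors = FALSE),
            class = c("popmap", "data.frame"))
}

is_unknown_group <- function(x) tolower(x) %in% c("unknown", "na", "")

#' Subset of a population map with a known group assignment
#'
#' @param pm a `popmap`.
#' @return the `popmap` rows whose group is not `"Unknown"`.
#' @export
analyzable <- function(pm) {
  pm[!is_unknown_group(pm$group), , drop = FALSE]
}

#' Group labels present in a population map
#' @param pm a `popmap`.
#' @param drop_unknown drop the `"Unknown"` label (default `TRUE`).
#' @return character vector of group labels in order of first appearance.
#' @export
popmap_groups <- function(pm, drop_unknown = TRUE) {
  g <- unique(pm$group)
  if (drop_unknown) g <- g[!is_unknown_group(g)]
  g
}

#' Read a two-column population map file
#'
#' Expects a delimited text table whose first two columns are individual and
#' group label; a header line is detected automatically.
#'
#' @param path file path.
#' @param individuals optional character vector of individuals that must be
#'   covered (typically from the genotype matrix).
#' @param on_missing what to do when an individual in `individuals` is absent
#'   from the file: `"error"` (default) or `"unknown"` (assign `"Unknown"`).
#' @param sep field separator, default tab.
#' @return a [popmap()].
#' @export
read_popmap <- function(path, individuals = NULL,
                        on_missing = c("error", "unknown"), sep = "\t") {
  on_missing <- match.arg(on_missing)
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("population map needs two columns")
  # drop a header line if present
  if (tolower(tab[1, 1]) %in% c("individual", "sample", "id")) {
    tab <- tab[-1, , drop = FALSE]
  }
  pm <- popmap(tab[[1]], tab[[2]])
  if (!is.null(individuals)) {
    absent <- setdiff(individuals, pm$individual)
    if (length(absent)) {
      if (on_missing == "error") {
        stop("individuals missing from population map: ",
             paste(absent, collapse = ", "))
      }
      pm <- popmap(c(pm$individual, absent),
                   c(pm$group, rep("Unknown", length(absent))))
    }
  }
  pm
}

#' Write a population map as a tab-separated file
#' @param pm a `popmap`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path) {
  utils::write.table(pm, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
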