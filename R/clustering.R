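#' Nei's standard genetic distance between individuals
#'
#' Each individual's dosage at a locus is converted to a within-individual
#' allele-frequency vector (`0 -> (1, 0)`, `1 -> (0.5, 0.5)`, `2 -> (0, 1)`).
#' Over the loci typed in both members of a pair, `Jxy` is the mean of
#' `sum_a x_a y_a`, `Jx` and `Jy` the means of the squared own frequencies,
#' and `D = -log(Jxy / sqrt(Jx * Jy))`. Pairs whose genetic identity is zero
#' are clamped at a large finite ceiling. Missing loci are handled by
#' pairwise-complete deletion.
#'
#' @param gm a [geno_matrix()] with at least 2 individuals.
#' @param ceiling distance assigned when the identity underflows to zero
#'   (default `-log(1e-12)`, about 27.6).
#' @return a symmetric `matrix` of distances with zero diagonal, labelled by
#'   individual.
#' @export
nei_distance_matrix <- function(gm, ceiling = -log(1e-12)) {
  X <- gm$calls
  if (nrow(X) < 2) stop("need at least 2 individuals")
  M <- (!is.na(X)) * 1
  P <- X / 2           # within-individual ALT frequency
  P[is.na(P)] <- 0
  Q <- M - P           # REF frequency, zeroed where untyped
  shared <- tcrossprod(M)
  if (any(shared[upper.tri(shared)] == 0)) {
    idx <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
    stop("no shared typed loci between ", rownames(X)[idx[1]],
         " and ", rownames(X)[idx[2]])
  }
  jxy <- (tcrossprod(P) + tcrossprod(Q)) / shared
  B <- (P^2 + Q^2)
  jx <- tcrossprod(B, M) / shared     # [x, y] = mean of x's J over shared loci
  identity <- jxy / sqrt(jx * t(jx))
  D <- ifelse(identity > 0, -log(identity), ceiling)
  D <- pmin(D, ceiling)
  D[D < 0] <- 0                        # guard tiny negative rounding
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`), returning an unrooted tree.
#' Negative branch lengths, an artefact of non-additive distances, are
#' clamped to zero with the deficit transferred to the sibling branch at the
#' same node so that adjacent path lengths are preserved as far as possible.
#'
#' @param d symmetric distance matrix (or `dist`) over >= 3 labels.
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix is not symmetric")
  if (nrow(d) < 3) stop("need at least 3 labels")
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  if (length(neg)) {
    message("clamping ", length(neg), " negative branch length(s) to zero")
    for (e in neg) {
      len <- tr$edge.length[e]
      parent <- tr$edge[e, 1]
      sib <- which(tr$edge[, 1] == parent & seq_along(tr$edge.length) != e)
      tr$edge.length[e] <- 0
      if (length(sib)) {
        tr$edge.length[sib[1]] <- max(tr$edge.length[sib[1]] + len, 0)
      }
    }
  }
  tr
}

#' Locus-bootstrap support for a neighbor-joining tree
#'
#' Builds the full-data Nei-distance NJ tree, then resamples loci with
#' replacement `n_boot` times, rebuilding the distance matrix and tree for
#' each replicate, and maps bipartition frequencies (as percentages) onto the
#' internal nodes of the full-data tree. Deterministic given `seed`.
#'
#' @param gm a [geno_matrix()] with >= 3 individuals and >= 2 loci.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return an `ape::phylo` tree whose `node.label` holds percent support
#'   (the root label is empty).
#' @export
bootstrap_tree <- function(gm, n_boot = 1000, seed = 1L) {
  if (n_individuals(gm) < 3 || n_loci(gm) < 2) {
    stop("need >= 3 individuals and >= 2 loci")
  }
  full <- nj_tree(nei_distance_matrix(gm))
  set.seed(seed)
  L <- n_loci(gm)
  reps <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(L, L, replace = TRUE)
    sub <- geno_matrix(gm$calls[, idx, drop = FALSE],
                       individuals = individuals(gm))
    reps[[b]] <- suppressMessages(nj_tree(nei_distance_matrix(sub)))
  }
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_boot, 1)
  full$node.label <- as.character(support)
  full$node.label[1] <- ""   # root of the unrooted representation
  full
}

#' Principal component analysis of a genotype matrix
#'
#' Missing dosages are imputed with the locus mean; columns are centered and
#' optionally scaled by `sqrt(p (1 - p))` with `p` the locus allele
#' frequency. Coordinates are the left singular vectors scaled by the
#' singular values; explained-variance fractions are the normalised squared
#' singular values.
#'
#' @param gm a [geno_matrix()] with >= 2 individuals and >= 2 loci.
#' @param scale logical; apply `sqrt(p(1 - p))` scaling (default `FALSE`,
#'   i.e. unscaled centered dosages).
#' @param n_comp number of components to keep (default `min(10, n - 1)`).
#' @return object of class `snp_pca`: list with `scores` (individuals x
#'   components), `explained` (variance fractions) and `sdev`.
#' @export
snp_pca <- function(gm, scale = FALSE, n_comp = NULL) {
  X <- gm$calls
  if (nrow(X) < 2 || ncol(X) < 2) stop("need >= 2 individuals and >= 2 loci")
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  Xc <- sweep(X, 2, colMeans(X))
  if (scale) {
    p <- colMeans(X) / 2
    s <- sqrt(pmax(p * (1 - p), 0))
    ok <- s > 0
    Xc <- sweep(Xc[, ok, drop = FALSE], 2, s[ok], "/")
  }
  if (all(abs(Xc) < 1e-12)) stop("genotype matrix has zero variance")
  sv <- svd(Xc)
  if (is.null(n_comp)) n_comp <- min(10L, nrow(X) - 1L)
  n_comp <- min(n_comp, sum(sv$d > 1e-9))
  scores <- sv$u[, seq_len(n_comp), drop = FALSE] %*%
    diag(sv$d[seq_len(n_comp)], n_comp)
  rownames(scores) <- rownames(gm$calls)
  colnames(scores) <- paste0("PC", seq_len(n_comp))
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores, explained = ev[seq_len(n_comp)],
                 sdev = sv$d / sqrt(max(nrow(X) - 1, 1))),
            class = "snp_pca")
}

#' @export
print.snp_pca <- function(x, ...) {
  cat("snp_pca:", nrow(x$scores), "individuals,", ncol(x$scores), "components\n")
  cat("explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained), collapse = " "), "\n")
  invisible(x)
}

#' Evanno delta-K selection of the number of admixture clusters
#'
#' Post-processes replicate log-likelihoods of admixture runs over a
#' contiguous range of K. With `L(K)` the replicate mean:
#' `L'(K) = L(K) - L(K - 1)`, `|L''(K)| = |L'(K + 1) - L'(K)|`, and
#' `deltaK = |L''(K)| / sd(L(K))`, defined only for interior K. The optimal K
#' maximises deltaK.
#'
#' @param runs data frame with columns `K` (integer) and `logL` (one row per
#'   replicate run); >= 3 contiguous K values with >= 2 replicates each.
#' @return object of class `delta_k`: data frame with columns `K`, `n_rep`,
#'   `mean_L`, `sd_L`, `Lp` (L'(K)), `Lpp_abs` (|L''(K)|), `delta_K`, and
#'   attribute `optimal_k`.
#' @export
evanno_delta_k <- function(runs) {
  if (!all(c("K", "logL") %in% names(runs))) {
    stop("runs needs columns K and logL")
  }
  ks <- sort(unique(runs$K))
  if (length(ks) < 3) stop("need >= 3 K values")
  if (!all(diff(ks) == 1)) stop("K values must be contiguous")
  nrep <- tapply(runs$logL, factor(runs$K, levels = ks), length)
  if (any(nrep < 2)) stop("need >= 2 replicates per K for sd")
  mean_L <- as.numeric(tapply(runs$logL, factor(runs$K, levels = ks), mean))
  sd_L <- as.numeric(tapply(runs$logL, factor(runs$K, levels = ks), stats::sd))
  nk <- length(ks)
  Lp <- c(NA, diff(mean_L))                       # L'(K), defined for K >= ks[2]
  Lpp <- rep(NA_real_, nk)
  Lpp[2:(nk - 1)] <- abs(Lp[3:nk] - Lp[2:(nk - 1)])
  dk <- Lpp / sd_L
  if (any(sd_L == 0 & !is.na(Lpp))) {
    warning("sd(L) = 0 at some K; delta-K undefined there")
    dk[sd_L == 0] <- NA_real_
  }
  out <- data.frame(K = ks, n_rep = as.integer(nrep), mean_L = mean_L,
                    sd_L = sd_L, Lp = Lp, Lpp_abs = Lpp, delta_K = dk)
  opt <- if (all(is.na(dk))) NA_integer_ else ks[which.max(dk)]
  attr(out, "optimal_k") <- opt
  class(out) <- c("delta_k", "data.frame")
  out
}

#' @export
print.delta_k <- function(x, ...) {
  print.data.frame(x, digits = 5, row.names = FALSE)
  cat("optimal K:", attr(x, "optimal_k"), "\n")
  invisible(x)
}
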