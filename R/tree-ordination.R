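# run expr under a fixed seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Covariance-matrix PCA of a binary marker matrix
#'
#' Principal component analysis of the samples-by-markers matrix on the
#' variance--covariance matrix: columns are mean-centered but never scaled,
#' so common and rare markers contribute according to their variance.
#'
#' @param m a [MarkerMatrix-class] (>= 3 samples, >= 2 markers) or a numeric
#'   samples-x-markers matrix.
#' @return list of class \code{"tbpPca"}: \code{eigenvalues} (descending),
#'   \code{percentVar} (summing to 100 over all components),
#'   \code{scores} (samples x components) and \code{degenerate} (TRUE when
#'   total variance is zero; all rows identical).
#' @export
pcaCovariance <- function(m) {
  x <- .sampleRows(m)
  if (nrow(x) < 3L) stop("need >= 3 samples")
  if (ncol(x) < 2L) stop("need >= 2 markers")
  if (anyNA(x)) stop("NA cells present; combine with missing = 'drop'")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  total <- sum(ev)
  degenerate <- total < 1e-12
  structure(list(eigenvalues = ev,
                 percentVar = if (degenerate) rep(0, length(ev))
                              else 100 * ev / total,
                 scores = pr$x, degenerate = degenerate),
            class = "tbpPca")
}

#' @export
print.tbpPca <- function(x, ...) {
  cat("Covariance-matrix PCA:", nrow(x$scores), "samples\n")
  if (x$degenerate) {
    cat("  DEGENERATE: total variance is zero (all profiles identical)\n")
  } else {
    k <- min(4, length(x$percentVar))
    cat("  variance explained:",
        paste0("PC", seq_len(k), " ", sprintf("%.2f%%", x$percentVar[1:k]),
               collapse = ", "), "\n")
  }
  invisible(x)
}

.checkDistMatrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("need a square matrix")
  if (nrow(D) < 3L) stop("need >= 3 samples")
  if (any(!is.finite(D))) stop("distances must be finite (no NaN/NA)")
  if (any(D < 0)) stop("distances must be non-negative")
  if (max(abs(D - t(D))) > 1e-8) stop("matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("diagonal must be zero")
  invisible(TRUE)
}

#' Neighbor-joining tree
#'
#' Saitou--Nei agglomeration with the standard Q-criterion. Two choices are
#' pinned down for reproducibility: ties in the Q minimization are broken by
#' the lowest (i, j) index pair, and a negative branch length is clamped to
#' zero with the deficit moved to the adjacent (sister) branch, preserving
#' the path length between the joined nodes. For an additive distance matrix
#' the leaf-to-leaf path lengths of the result equal the input distances
#' exactly.
#'
#' @param d a \code{dist} or symmetric zero-diagonal matrix, n >= 3.
#' @return an unrooted \code{\link[ape]{phylo}} tree (basal trifurcation).
#' @export
njTree <- function(d) {
  D <- as.matrix(d)
  .checkDistMatrix(D)
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(D)))
  fmt <- function(z) sprintf("%.17g", z)
  nodes <- labs
  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newNode <- paste0("(", nodes[i], ":", fmt(li), ",",
                      nodes[j], ":", fmt(lj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], newNode)
    rownames(D2) <- colnames(D2) <- seq_len(r - 1)
    D <- D2
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- D[1, 2] - l1
  l3 <- D[1, 3] - l1
  if (l1 < 0) { l2 <- l2 + l1; l3 <- l3 + l1; l1 <- 0 }
  if (l2 < 0) { l2 <- 0 }
  if (l3 < 0) { l3 <- 0 }
  txt <- paste0("(", nodes[1], ":", fmt(l1), ",", nodes[2], ":", fmt(l2),
                ",", nodes[3], ":", fmt(l3), ");")
  ape::read.tree(text = txt)
}

# non-trivial leaf bipartitions of an unrooted tree as canonical keys:
# each internal edge splits the tips; the side NOT containing the reference
# tip, sorted and collapsed, identifies the split
.bipartitionKeys <- function(tree, refTip = NULL) {
  tips <- tree$tip.label
  if (is.null(refTip)) refTip <- sort(tips)[1]
  pp <- ape::prop.part(tree)
  n <- length(tips)
  keys <- character(0)
  nodeOf <- integer(0)
  for (k in seq_along(pp)) {
    clade <- tips[pp[[k]]]
    if (length(clade) >= n - 1L || length(clade) <= 1L) next  # trivial
    side <- if (refTip %in% clade) setdiff(tips, clade) else clade
    if (length(side) <= 1L || length(side) >= n - 1L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodeOf <- c(nodeOf, n + k)
  }
  list(keys = keys, nodes = nodeOf)
}

#' Bootstrap support for the neighbor-joining tree of a marker matrix
#'
#' Marker columns are the exchangeable unit of a binary marker matrix:
#' each replicate resamples markers with replacement (same marker count),
#' recomputes Whittaker distances and the NJ tree, and each internal edge of
#' the reference tree is scored by the percentage of replicates containing
#' the same leaf bipartition. A replicate that leaves some sample with an
#' all-zero profile is redrawn (counted in \code{nRedrawn}).
#'
#' @param m a [MarkerMatrix-class].
#' @param nReps number of bootstrap replicates (default 1000).
#' @param seed integer seed; the caller's RNG state is restored afterwards.
#' @return the reference \code{phylo} tree with \code{node.label} holding
#'   supports (0--100, root empty) and attributes \code{support}
#'   (named vector by bipartition) and \code{nRedrawn}.
#' @export
bootstrapSupport <- function(m, nReps = 1000, seed = NULL) {
  p <- if (is(m, "MarkerMatrix")) presence(m) else as.matrix(m)
  if (anyNA(p)) stop("NA cells present; combine with missing = 'drop'")
  # canonical sample order: supports must not depend on column order
  p <- p[, order(colnames(p)), drop = FALSE]
  ref <- njTree(whittakerDist(t(p)))
  bp <- .bipartitionKeys(ref)
  counts <- stats::setNames(numeric(length(bp$keys)), bp$keys)
  nRedrawn <- 0L
  .withSeed(seed, {
    for (rep in seq_len(nReps)) {
      for (try in seq_len(10000L)) {
        idx <- sample.int(nrow(p), replace = TRUE)
        b <- p[idx, , drop = FALSE]
        if (all(colSums(b) > 0)) break
        nRedrawn <- nRedrawn + 1L
        if (try == 10000L) stop("could not draw a valid bootstrap replicate")
      }
      tr <- njTree(whittakerDist(t(b)))
      kk <- .bipartitionKeys(tr, refTip = sort(ref$tip.label)[1])$keys
      hit <- bp$keys %in% kk
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / nReps
  nl <- rep("", ref$Nnode)
  nl[bp$nodes - length(ref$tip.label)] <-
    format(support, trim = TRUE, digits = 4)
  ref$node.label <- nl
  attr(ref, "support") <- support
  attr(ref, "nRedrawn") <- nRedrawn
  ref
}

.pairVector <- function(D, labs) {
  D <- as.matrix(D)
  D <- D[labs, labs]
  D[upper.tri(D)]
}

#' Cophenetic correlation between a tree and its source distances
#'
#' Pearson correlation, over all unordered sample pairs, between the input
#' dissimilarities and the path-length (cophenetic) distances implied by the
#' tree -- the usual degree-of-fit measure for a distance-based tree.
#'
#' @param tree a \code{phylo} whose tips are the samples of \code{d}.
#' @param d \code{dist} or symmetric matrix with matching labels.
#' @return list of class \code{"tbpCor"}: \code{r}, \code{p} (NA here),
#'   \code{method}.
#' @export
copheneticCorrelation <- function(tree, d) {
  D <- as.matrix(d)
  labs <- rownames(D)
  if (!setequal(tree$tip.label, labs))
    stop("tree tips and matrix samples differ: ",
         paste(c(setdiff(tree$tip.label, labs), setdiff(labs, tree$tip.label)),
               collapse = ", "))
  v1 <- .pairVector(D, labs)
  v2 <- .pairVector(ape::cophenetic.phylo(tree), labs)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero-variance distance vector: correlation undefined")
  structure(list(r = stats::cor(v1, v2), p = NA_real_,
                 nPermutations = 0L, seed = NULL, method = "cophenetic"),
            class = "tbpCor")
}

#' Correlation between two distance matrices (Mantel test)
#'
#' Pearson correlation of the off-diagonal upper triangles of two distance
#' matrices over the same samples, with a permutation p-value obtained by
#' permuting the sample labels of the second matrix (the Mantel procedure;
#' one-sided, p = (1 + #{r_perm >= r}) / (n_permutations + 1)).
#'
#' @param d1,d2 \code{dist} or symmetric matrices over the same sample set.
#' @param nPermutations number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list of class \code{"tbpCor"}: \code{r}, \code{p},
#'   \code{nPermutations}, \code{seed}.
#' @export
matrixCorrelation <- function(d1, d2, nPermutations = 999, seed = NULL) {
  D1 <- as.matrix(d1); D2 <- as.matrix(d2)
  labs <- rownames(D1)
  if (!setequal(labs, rownames(D2)))
    stop("sample sets differ: ",
         paste(c(setdiff(labs, rownames(D2)), setdiff(rownames(D2), labs)),
               collapse = ", "))
  v1 <- .pairVector(D1, labs)
  v2 <- .pairVector(D2, labs)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero-variance distance vector: correlation undefined")
  r <- stats::cor(v1, v2)
  p <- NA_real_
  if (nPermutations > 0) {
    D2o <- D2[labs, labs]
    n <- length(labs)
    hits <- .withSeed(seed, {
      sum(vapply(seq_len(nPermutations), function(k) {
        perm <- sample.int(n)
        stats::cor(v1, D2o[perm, perm][upper.tri(D2o)]) >= r
      }, logical(1)))
    })
    p <- (1 + hits) / (nPermutations + 1)
  }
  structure(list(r = r, p = p, nPermutations = nPermutations, seed = seed,
                 method = "mantel"),
            class = "tbpCor")
}

#' @export
print.tbpCor <- function(x, ...) {
  cat(sprintf("Matrix correlation (%s): r = %.4f", x$method, x$r))
  if (!is.na(x$p))
    cat(sprintf(", p = %.4g (%d permutations)", x$p, x$nPermutations))
  cat("\n")
  invisible(x)
}

#' Write a tree with bootstrap node labels as newick
#'
#' @param tree a \code{phylo} (e.g. from [bootstrapSupport()]).
#' @param path output file.
#' @return invisibly \code{path}.
#' @export
writeTbpTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
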