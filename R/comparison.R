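#' Euclidean distance between two usage vectors
#'
#' @param x,y `tud` objects sharing the same ordered word list.
#' @return Nonnegative scalar: sqrt of the summed squared per-word deviation
#'   differences.
#' @export
euclidean_distance <- function(x, y) {
  stopifnot(inherits(x, "tud"), inherits(y, "tud"))
  if (!identical(x$words, y$words)) {
    stop("usage vectors have different word lists; run filter_universal first")
  }
  sqrt(sum((x$deviation - y$deviation)^2))
}

#' Pairwise distance matrix over a collection of usage vectors
#'
#' @param vectors List of >= 2 `tud` objects with a common word list.
#' @return A [stats::dist] object labeled by genome ids, input order
#'   preserved.
#' @export
distance_matrix <- function(vectors) {
  if (length(vectors) < 2L) stop("need at least 2 usage vectors")
  stats::dist(tud_matrix(vectors), method = "euclidean")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei neighbor joining: iteratively selects the pair minimizing the
#' Q criterion, joins it with the standard branch-length formulas, and
#' reduces the matrix, finishing with the three-point formulas. Consistent
#' on tree-additive distances. A negative branch length is clamped to zero
#' and its deficit moved onto the sister branch, preserving the path length
#' through the join. Deterministic given input order (first minimal pair in
#' column-major order wins ties).
#'
#' @param dm A `dist` object or labeled symmetric matrix with >= 3 taxa.
#' @return Unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  # subtree Newick fragments for each active node
  frag <- labs
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  join2 <- function(fi, li, fj, lj) {
    # clamp negatives, moving the deficit to the sister branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    sprintf("(%s:%s,%s:%s)", fi, fmt(li), fj, fmt(lj))
  }
  while (n > 3L) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    ij <- arrayInd(which.min(q), dim(q))
    i <- min(ij); j <- max(ij)
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    newfrag <- join2(frag[i], li, frag[j], lj)
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    frag <- c(frag[keep], newfrag)
    n <- n - 1L
  }
  # three-point closed form
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(la), frag[2], fmt(lb),
                 frag[3], fmt(lc))
  ape::read.tree(text = nwk)
}

#' Average-linkage (UPGMA) dendrogram from a distance matrix
#'
#' Wraps [stats::hclust] with `method = "average"` and converts the result
#' to a rooted ultrametric `phylo` tree; cophenetic distances on the tree
#' equal the merge heights, so exactly ultrametric inputs are reproduced
#' as-is.
#'
#' @param dm A `dist` object or labeled symmetric matrix with >= 2 taxa.
#' @return Rooted `ape::phylo` dendrogram.
#' @export
average_linkage <- function(dm) {
  d <- stats::as.dist(dm)
  if (attr(d, "Size") < 2L) stop("average linkage needs at least 2 taxa")
  hc <- stats::hclust(d, method = "average")
  ape::as.phylo(hc)
}

#' Principal components analysis of usage deviation vectors
#'
#' Natural-log transforms the deviation matrix (all retained deviations must
#' be positive — run [filter_universal()] first), column-centers without
#' scaling, and decomposes with [stats::prcomp]. Component signs are fixed
#' so the largest-magnitude loading in each column is positive.
#'
#' @param vectors List of >= 2 `tud` objects with a common word list, or a
#'   genomes-by-words numeric matrix.
#' @param log_transform Apply `log()` before centering (default TRUE).
#' @return Object of class `tud_pca`: `scores` (genomes x components),
#'   `loadings` (words x components), `variance_fraction`, `sdev`,
#'   `center`, `log_transform`.
#' @export
tud_pca <- function(vectors, log_transform = TRUE) {
  m <- if (is.matrix(vectors)) vectors else tud_matrix(vectors)
  if (nrow(m) < 2L) stop("PCA needs at least 2 genomes")
  if (log_transform) {
    if (any(m <= 0)) {
      stop("log transform requires strictly positive deviations; ",
           "apply filter_universal() to remove zero-count words")
    }
    m <- log(m)
  }
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  flip <- apply(p$rotation, 2L, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2L, flip, `*`)
  loadings <- sweep(p$rotation, 2L, flip, `*`)
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(scores = scores, loadings = loadings, variance_fraction = vf,
         sdev = p$sdev, center = p$center, log_transform = log_transform),
    class = "tud_pca"
  )
}

#' @export
print.tud_pca <- function(x, ...) {
  cat(sprintf("PCA of %d usage deviation vectors (%d words%s)\n",
              nrow(x$scores), nrow(x$loadings),
              if (x$log_transform) ", log-transformed" else ""))
  vf <- utils::head(x$variance_fraction, 3L)
  cat("  variance captured: ",
      paste(sprintf("PC%d %.1f%%", seq_along(vf), 100 * vf), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.tud_pca <- function(x, components = c(1L, 2L), groups = NULL, ...) {
  s <- x$scores[, components, drop = FALSE]
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  vf <- x$variance_fraction[components]
  plot(s, col = col, pch = 19,
       xlab = sprintf("PC%d (%.1f%%)", components[1L], 100 * vf[1L]),
       ylab = sprintf("PC%d (%.1f%%)", components[2L], 100 * vf[2L]), ...)
  invisible(x)
}

# tip labels below each edge's child node, for split extraction
edge_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  # postorder guarantees children are filled before parents
  eo <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(eo$edge))) {
    par <- eo$edge[e, 1L]; chi <- eo$edge[e, 2L]
    desc[[par]] <- c(desc[[par]], desc[[chi]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) {
    sort(desc[[tree$edge[e, 2L]]])
  })
}

#' Check group monophyly on a tree
#'
#' A group is monophyletic when some edge of the (unrooted) tree separates
#' exactly that group's leaves from all others.
#'
#' @param tree An `ape::phylo` tree.
#' @param labels Named character vector mapping every tip label to a group.
#' @return Named logical vector, one entry per group.
#' @export
monophyly_check <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  missing <- setdiff(tips, names(labels))
  if (length(missing) > 0L) {
    stop("unlabeled leaves: ", paste(missing, collapse = ", "))
  }
  grp <- labels[tips]
  n_tip <- length(tips)
  sides <- edge_tip_sets(tree)
  groups <- unique(unname(grp))
  res <- vapply(groups, function(g) {
    members <- sort(unname(which(grp == g)))
    if (length(members) == n_tip) return(TRUE)
    comp <- setdiff(seq_len(n_tip), members)
    any(vapply(sides, function(s) {
      identical(s, members) || identical(s, comp)
    }, TRUE))
  }, TRUE)
  stats::setNames(res, groups)
}
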