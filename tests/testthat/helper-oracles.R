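# Independent oracles and fixture builders shared across the test files.

# brute-force word counting: take the substring at every start position of
# each strand, drop windows containing non-ACGT characters, and tabulate
naive_count_words <- function(seq, k) {
  pair <- extend_with_revcomp(seq)
  words <- enumerate_words(k)
  counts <- stats::setNames(integer(length(words)), words)
  for (s in c(pair$forward, pair$reverse)) {
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    subs <- substring(s, starts, starts + k - 1L)
    subs <- subs[!grepl("N", subs, fixed = TRUE)]
    tab <- table(subs)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts
}

rand_seq <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# random binary tree with positive branch lengths and the tree-additive
# distance matrix implied by its path lengths
random_additive_case <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.5, 3))
  list(tree = tr, dm = stats::as.dist(ape::cophenetic.phylo(tr)))
}

# unrooted Robinson-Foulds distance; 0 means identical topology
rf_dist <- function(t1, t2) {
  suppressMessages(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}

# mean silhouette width of a 2-D embedding under known group labels
mean_silhouette <- function(xy, groups) {
  d <- as.matrix(stats::dist(xy))
  g <- as.character(groups)
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- g == g[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(g), g[i]),
                    function(h) mean(d[i, g == h]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# does any called interval overlap the truth interval [start, end)?
overlaps_truth <- function(calls, start, end) {
  if (nrow(calls) == 0L) return(FALSE)
  any(calls$start < end & calls$end > start)
}
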