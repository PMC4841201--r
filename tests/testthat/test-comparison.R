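make_vec <- function(dev, id = "x") {
  words <- names(dev)
  structure(list(source_id = id, k = nchar(words[1]),
                 observed = stats::setNames(rep(1L, length(dev)), words),
                 expected = stats::setNames(rep(1, length(dev)), words),
                 deviation = dev, words = words, canonical = TRUE,
                 zero_expected = character(0)),
            class = "tud")
}

test_that("euclidean distance matches hand cases and metric axioms", {
  x <- make_vec(c(AA = 1, AC = 2, AG = 1), "x")
  expect_equal(euclidean_distance(x, x), 0)
  y <- make_vec(c(AA = 4, AC = 2, AG = 5), "y")  # differs by (3, 0, 4)
  expect_equal(euclidean_distance(x, y), 5)
  z <- make_vec(c(AA = 2, AC = 0, AG = 3), "z")
  dxy <- euclidean_distance(x, y)
  dxz <- euclidean_distance(x, z)
  dyz <- euclidean_distance(y, z)
  expect_lte(dxy, dxz + dyz)
  bad <- make_vec(c(AA = 1, AC = 2, AT = 1))
  expect_error(euclidean_distance(x, bad), "different word lists")
})

test_that("distance_matrix agrees with the pairwise oracle", {
  withr::local_seed(31)
  seqs <- stats::setNames(
    c(vapply(1:3, function(i) rand_seq(4000), "")), c("a", "b", "c"))
  seqs["a2"] <- seqs[["a"]]  # duplicated genome under a second id
  vecs <- usage_deviation_set(seqs, k = 4)
  dm <- as.matrix(distance_matrix(vecs))
  expect_identical(rownames(dm), c("a", "b", "c", "a2"))
  expect_equal(dm["a", "a2"], 0)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(dm[i, j], euclidean_distance(vecs[[i]], vecs[[j]]))
  }
  # permuting the input permutes rows/columns consistently
  dm2 <- as.matrix(distance_matrix(vecs[c(3, 1, 2, 4)]))
  expect_equal(dm2[rownames(dm), colnames(dm)], dm)
  expect_error(distance_matrix(vecs[1]), "at least 2")
})

test_that("three-taxon NJ uses the closed-form branch lengths", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  bl <- stats::setNames(tr$edge.length,
                        tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (3 + 5 - 6) / 2)  # 1
  expect_equal(bl[["b"]], (3 + 6 - 5) / 2)  # 2
  expect_equal(bl[["c"]], (5 + 6 - 3) / 2)  # 4
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers a known 4-taxon additive tree exactly", {
  # tree: (a:2,b:3) -- internal 1 -- (c:4,d:5); pairwise path sums
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 5
  d["a", "c"] <- d["c", "a"] <- 7
  d["a", "d"] <- d["d", "a"] <- 8
  d["b", "c"] <- d["c", "b"] <- 8
  d["b", "d"] <- d["d", "b"] <- 9
  d["c", "d"] <- d["d", "c"] <- 9
  tr <- neighbor_joining(d)
  truth <- ape::read.tree(text = "((a:2,b:3):1,c:4,d:5);")
  expect_equal(rf_dist(tr, truth), 0)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[letters[1:4], letters[1:4]],
               d)
})

test_that("NJ is consistent on random additive matrices", {
  withr::local_seed(55)
  recovered <- 0L
  for (i in 1:30) {
    case <- random_additive_case(sample(4:8, 1))
    tr <- neighbor_joining(case$dm)
    recovered <- recovered + (rf_dist(tr, case$tree) == 0)
    # path lengths reproduced (additivity)
    labs <- case$tree$tip.label
    expect_equal(as.matrix(ape::cophenetic.phylo(tr))[labs, labs],
                 as.matrix(case$dm)[labs, labs], tolerance = 1e-8)
  }
  expect_identical(recovered, 30L)
  # and it matches the independent ape implementation topologically
  withr::local_seed(56)
  for (i in 1:5) {
    case <- random_additive_case(7)
    expect_equal(rf_dist(neighbor_joining(case$dm), ape::nj(case$dm)), 0)
  }
})

test_that("NJ clamps negative branch lengths without losing path length", {
  # triangle-violating matrix drives the closed-form branch negative
  d <- matrix(c(0, 1, 1, 1, 0, 3, 1, 3, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
  # noisy near-additive matrices stay nonnegative too
  withr::local_seed(99)
  for (i in 1:10) {
    case <- random_additive_case(6)
    dd <- as.matrix(case$dm)
    noise <- matrix(stats::runif(36, 0, 0.4), 6, 6)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    expect_true(all(neighbor_joining(dd + noise)$edge.length >= 0))
  }
})

test_that("UPGMA merges two leaves at half their distance", {
  d <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- average_linkage(d)
  expect_identical(sort(tr$tip.label), c("a", "b"))
  expect_equal(unname(tr$edge.length), c(2, 2))
})

test_that("UPGMA is a fixed point on ultrametric matrices", {
  # build an exactly ultrametric matrix from a coalescent-style tree
  withr::local_seed(9)
  for (i in 1:5) {
    tr0 <- ape::rcoal(6)
    d0 <- ape::cophenetic.phylo(tr0)
    tr <- average_linkage(d0)
    d1 <- as.matrix(ape::cophenetic.phylo(tr))[rownames(d0), colnames(d0)]
    expect_equal(d1, d0, tolerance = 1e-9)
  }
})

test_that("NJ and UPGMA topologies coincide on ultrametric input", {
  withr::local_seed(14)
  tr0 <- ape::rcoal(5)
  d0 <- ape::cophenetic.phylo(tr0)
  expect_equal(rf_dist(neighbor_joining(d0), average_linkage(d0)), 0)
})

test_that("PCA satisfies variance and reconstruction invariants", {
  withr::local_seed(61)
  seqs <- stats::setNames(vapply(1:6, function(i) rand_seq(8000), ""),
                          paste0("g", 1:6))
  seqs["g6"] <- seqs[["g5"]]  # two identical genomes
  vecs <- usage_deviation_set(seqs, k = 4)
  p <- tud_pca(vecs)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  expect_equal(unname(p$scores["g5", ]), unname(p$scores["g6", ]))
  # centered data reconstructed from scores %*% t(loadings)
  centered <- sweep(log(tud_matrix(vecs)), 2, p$center)
  expect_equal(p$scores %*% t(p$loadings), centered,
               tolerance = 1e-9, ignore_attr = TRUE)
  # sign convention: dominant loading of each component positive
  for (j in seq_len(ncol(p$loadings))) {
    col <- p$loadings[, j]
    expect_gte(col[which.max(abs(col))], 0)
  }
})

test_that("PCA demands positive deviations before log transform", {
  v1 <- usage_deviation("AAAACCCC", k = 2, id = "g1")
  v2 <- usage_deviation("AAAATTTT", k = 2, id = "g2")
  expect_error(tud_pca(list(v1, v2)), "filter_universal")
  expect_silent(tud_pca(filter_universal(list(v1, v2))))
})

test_that("monophyly matches the stated examples", {
  lab <- c(a1 = "a", a2 = "a", b1 = "b", b2 = "b")
  tr1 <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  expect_identical(unname(monophyly_check(tr1, lab)), c(TRUE, TRUE))
  tr2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  expect_identical(unname(monophyly_check(tr2, lab)), c(FALSE, FALSE))
  expect_error(monophyly_check(tr1, lab[1:3]), "unlabeled")
})

test_that("monophyly agrees with brute-force bipartition enumeration", {
  withr::local_seed(71)
  for (i in 1:10) {
    tr <- ape::rtree(12, rooted = FALSE)
    groups <- stats::setNames(sample(c("x", "y", "z"), 12, replace = TRUE),
                              tr$tip.label)
    got <- monophyly_check(tr, groups)
    # oracle: enumerate every edge's bipartition via prop.part on all splits
    parts <- ape::prop.part(tr)
    all_splits <- lapply(seq_along(parts), function(j) sort(parts[[j]]))
    n <- 12L
    for (g in names(got)) {
      mem <- sort(unname(which(groups[tr$tip.label] == g)))
      comp <- setdiff(seq_len(n), mem)
      hit <- length(mem) %in% c(1L, n) ||
        any(vapply(all_splits, function(s) identical(s, mem) ||
                     identical(s, comp), TRUE))
      expect_identical(unname(got[g]), hit)
    }
  }
})
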