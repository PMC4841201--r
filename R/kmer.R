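#' Enumerate all words of length k
#'
#' Returns the 4^k words over `{A,C,G,T}` in lexicographic order (A < C < G
#' < T), the column order used by every counting function in the package.
#'
#' @param k Word length, between 1 and 8.
#' @return Character vector of length `4^k`.
#' @export
enumerate_words <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 || k > 8) {
    stop("k must be an integer between 1 and 8")
  }
  k <- as.integer(k)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic
  do.call(paste0, rev(grid))
}

#' Count word occurrences on an extended sequence
#'
#' Counts every k-word on the forward strand and on the reverse complement
#' separately and sums the two; no word spans the junction between strands.
#' Windows containing `N` contribute nothing. Every enumerated word gets an
#' entry, possibly zero.
#'
#' @param pair A `strand_pair` from [extend_with_revcomp()], or a single
#'   character string (extended automatically).
#' @param k Word length.
#' @return Named integer vector over [enumerate_words()] order.
#' @export
count_words <- function(pair, k) {
  if (is.character(pair)) pair <- extend_with_revcomp(pair)
  stopifnot(inherits(pair, "strand_pair"))
  if (k > nchar(pair$forward)) {
    stop("k (", k, ") exceeds sequence length (", nchar(pair$forward), ")")
  }
  words <- enumerate_words(k)
  cf <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(pair$forward), width = k)
  cr <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(pair$reverse), width = k)
  counts <- cf + cr
  counts[words]
}

#' Mononucleotide composition of an extended sequence
#'
#' Frequencies are computed over the ACGT characters of both strands;
#' `n_total` is the combined length of both strands (the genome-length term
#' of the expected-count formula applied to the extended sequence) and
#' `n_effective` the number of unambiguous characters. On an extended pair
#' A/T and C/G frequencies are equal by construction.
#'
#' @param pair A `strand_pair` or a single character string.
#' @return List with `freq` (named numeric over A,C,G,T), `n_effective`,
#'   `n_total`.
#' @export
composition <- function(pair) {
  if (is.character(pair)) pair <- extend_with_revcomp(pair)
  stopifnot(inherits(pair, "strand_pair"))
  tab <- Biostrings::alphabetFrequency(Biostrings::DNAString(pair$forward)) +
    Biostrings::alphabetFrequency(Biostrings::DNAString(pair$reverse))
  acgt <- tab[c("A", "C", "G", "T")]
  n_eff <- sum(acgt)
  if (n_eff == 0L) stop("sequence contains no unambiguous (ACGT) characters")
  list(freq = acgt / n_eff,
       n_effective = as.integer(n_eff),
       n_total = 2L * nchar(pair$forward))
}

#' Expected count of a word under the zero-order Markov model
#'
#' For a word with nucleotide counts (a, c, g, t) the expectation is
#' `fA^a * fC^c * fG^g * fT^t * N`, where the `f` are the mononucleotide
#' frequencies of the (extended) sequence and `N` its length. With
#' `denominator = "positions"` the number of word start positions
#' `2*(L - k + 1)` replaces the raw length; the two differ by O(k/L).
#'
#' @param word Character vector of words over `{A,C,G,T}`.
#' @param comp Composition list from [composition()].
#' @param denominator `"length"` (default) or `"positions"`.
#' @return Numeric vector of expected counts.
#' @export
expected_count <- function(word, comp, denominator = c("length", "positions")) {
  denominator <- match.arg(denominator)
  k <- nchar(word[1L])
  n <- if (denominator == "length") comp$n_total else
    comp$n_total - 2L * (k - 1L)
  cnt <- word_letter_counts(word)
  f <- pmax(comp$freq, 0)
  # 0^0 == 1 in R, so absent nucleotides zero the product only when used.
  # Grouping A with T and C with G keeps E(W) bit-identical to E(revcomp(W))
  # on extended sequences, where the paired frequencies are exactly equal.
  as.numeric((f["A"]^cnt[, "A"] * f["T"]^cnt[, "T"]) *
               (f["C"]^cnt[, "C"] * f["G"]^cnt[, "G"]) * n)
}

# per-word A/C/G/T counts, memoized on the full lexicographic word list per k
.word_count_cache <- new.env(parent = emptyenv())

word_letter_counts <- function(word) {
  k <- nchar(word[1L])
  key <- as.character(k)
  full <- get0(key, envir = .word_count_cache)
  if (is.null(full)) {
    all_w <- enumerate_words(k)
    chars <- matrix(unlist(strsplit(all_w, "", fixed = TRUE), use.names = FALSE),
                    ncol = k, byrow = TRUE)
    full <- cbind(A = rowSums(chars == "A"), C = rowSums(chars == "C"),
                  G = rowSums(chars == "G"), T = rowSums(chars == "T"))
    rownames(full) <- all_w
    assign(key, full, envir = .word_count_cache)
  }
  full[word, , drop = FALSE]
}

#' Oligonucleotide usage deviation of a genome
#'
#' The central statistic: for each word W of length k, the observed count
#' N(W) over the genome extended by its reverse complement, divided by its
#' expected count E(W) under the zero-order Markov model of the extended
#' sequence's mononucleotide composition. A deviation of 1 means the word is
#' used exactly as often as its composition predicts; 2 means twice as
#' often. At k = 4 this is tetranucleotide usage deviation (TUD). Words
#' never observed get deviation 0.
#'
#' @param seq Single character string (one genome sequence), or a
#'   `strand_pair`.
#' @param k Word length (default 4).
#' @param id Identifier recorded on the result (defaults to the pair's
#'   `source_id` or `"genome"`).
#' @param denominator Passed to [expected_count()].
#' @return Object of class `tud`: list with `source_id`, `k`, `observed`,
#'   `expected`, `deviation` (named numeric vectors over the current word
#'   list), `words`, `canonical` flag, `zero_expected` (words observed but
#'   with zero expectation, normally empty).
#' @examples
#' tv <- usage_deviation("AAAA", k = 2)
#' tv$deviation[["AA"]]  # 1.5
#' @export
usage_deviation <- function(seq, k = 4L, id = NULL,
                            denominator = c("length", "positions")) {
  denominator <- match.arg(denominator)
  pair <- if (inherits(seq, "strand_pair")) seq else extend_with_revcomp(seq)
  if (nchar(pair$forward) < k) {
    stop("genome shorter than k (", nchar(pair$forward), " < ", k, ")")
  }
  if (is.null(id)) {
    id <- if (!is.na(pair$source_id)) pair$source_id else "genome"
  }
  obs <- count_words(pair, k)
  comp <- composition(pair)
  words <- names(obs)
  exp_ <- stats::setNames(expected_count(words, comp, denominator), words)
  dev <- ifelse(exp_ > 0, obs / exp_, 0)
  dev[obs == 0L] <- 0
  zero_exp <- words[exp_ == 0 & obs > 0L]
  structure(
    list(source_id = id, k = as.integer(k), observed = obs, expected = exp_,
         deviation = stats::setNames(as.numeric(dev), words), words = words,
         canonical = FALSE, zero_expected = zero_exp),
    class = "tud"
  )
}

#' @export
print.tud <- function(x, ...) {
  cat(sprintf("Usage deviation vector (k = %d) for '%s'\n", x$k, x$source_id))
  cat(sprintf("  %d words%s; total observed count %d\n", length(x$words),
              if (x$canonical) " (canonical)" else "", sum(x$observed)))
  d <- sort(x$deviation, decreasing = TRUE)
  top <- utils::head(d, 3L)
  cat("  most over-represented: ",
      paste(sprintf("%s=%.2f", names(top), top), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.tud <- function(object, ...) {
  cat(sprintf("Usage deviation (k = %d), genome '%s'\n",
              object$k, object$source_id))
  print(summary(object$deviation))
  invisible(object)
}

# vectorized reverse complement for plain ACGT words
revcomp_words <- function(words) {
  rc <- chartr("ACGT", "TGCA", words)
  vapply(strsplit(rc, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), "")
}

#' Collapse reverse-complement redundancy in a usage vector
#'
#' Counting on the extended sequence makes deviation values of a word and
#' its reverse complement identical, so one of each pair is redundant. This
#' keeps the lexicographically smaller member of each pair (palindromes are
#' kept once), leaving `(4^k + 4^(k/2)) / 2` words for even k — 136 at
#' k = 4.
#'
#' @param x A `tud` object (not yet canonical).
#' @return The `tud` object restricted to canonical words, `canonical` set.
#' @export
canonicalize <- function(x) {
  stopifnot(inherits(x, "tud"))
  if (x$canonical) stop("usage vector is already canonicalized")
  keep <- x$words <= revcomp_words(x$words)
  x$observed <- x$observed[keep]
  x$expected <- x$expected[keep]
  x$deviation <- x$deviation[keep]
  x$words <- x$words[keep]
  x$canonical <- TRUE
  x
}

#' Remove words absent from any genome in a collection
#'
#' Cross-collection filter applied before distance calculations and PCA:
#' every word with observed count zero in at least one usage vector is
#' dropped from all of them, so all remaining deviations are strictly
#' positive and log-transformable.
#'
#' @param vectors List of `tud` objects sharing `k` and canonicalization
#'   state.
#' @return List of `tud` objects with a common, possibly shorter, word list;
#'   attribute `removed_words` lists what was dropped.
#' @export
filter_universal <- function(vectors) {
  if (!is.list(vectors) || length(vectors) == 0L ||
      !all(vapply(vectors, inherits, TRUE, "tud"))) {
    stop("'vectors' must be a non-empty list of tud objects")
  }
  ks <- vapply(vectors, `[[`, 1L, "k")
  if (length(unique(ks)) != 1L) stop("mixed k across usage vectors")
  canon <- vapply(vectors, `[[`, TRUE, "canonical")
  if (length(unique(canon)) != 1L) {
    stop("mixed canonicalization state across usage vectors")
  }
  w0 <- vectors[[1L]]$words
  for (v in vectors) {
    if (!identical(v$words, w0)) stop("usage vectors have different word lists")
  }
  obs <- do.call(rbind, lapply(vectors, `[[`, "observed"))
  keep <- colSums(obs == 0L) == 0L
  removed <- w0[!keep]
  out <- lapply(vectors, function(v) {
    v$observed <- v$observed[keep]
    v$expected <- v$expected[keep]
    v$deviation <- v$deviation[keep]
    v$words <- v$words[keep]
    v
  })
  attr(out, "removed_words") <- removed
  out
}

#' Assemble a genomes-by-words deviation matrix
#'
#' @param vectors List of `tud` objects sharing one word list.
#' @return Numeric matrix, rows = genome ids, columns = words.
#' @export
tud_matrix <- function(vectors) {
  w0 <- vectors[[1L]]$words
  for (v in vectors) {
    if (!identical(v$words, w0)) stop("usage vectors have different word lists")
  }
  m <- do.call(rbind, lapply(vectors, `[[`, "deviation"))
  rownames(m) <- vapply(vectors, `[[`, "", "source_id")
  m
}

#' Usage deviation vectors for a whole collection
#'
#' Convenience pipeline: [usage_deviation()] per genome, then optional
#' [canonicalize()] and [filter_universal()].
#'
#' @param seqs Named character vector of genome sequences.
#' @param k Word length.
#' @param canonical Collapse reverse-complement pairs (default TRUE).
#' @param filter Apply the cross-collection universality filter (default
#'   TRUE).
#' @param denominator Passed to [usage_deviation()].
#' @return List of `tud` objects.
#' @export
usage_deviation_set <- function(seqs, k = 4L, canonical = TRUE, filter = TRUE,
                                denominator = c("length", "positions")) {
  denominator <- match.arg(denominator)
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("'seqs' must be a named character vector")
  }
  vecs <- lapply(names(seqs), function(id) {
    usage_deviation(seqs[[id]], k = k, id = id, denominator = denominator)
  })
  if (canonical) vecs <- lapply(vecs, canonicalize)
  if (filter) vecs <- filter_universal(vecs)
  vecs
}
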