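#' Sliding-window intervals over a genome
#'
#' 0-based half-open intervals `[s, s + window_size)` for
#' `s = 0, step, 2*step, ...` while the window fits inside the sequence. A
#' final partial window is dropped rather than truncated, because a short
#' window under-samples the word space; if the whole genome is shorter than
#' one window, a single truncated interval `[0, L)` is returned and flagged.
#'
#' @param length_bp Genome length in bases (or a sequence string).
#' @param window_size Window width in bp (default 2000).
#' @param step Step size in bp (default 500).
#' @return Data frame with columns `start`, `end` (0-based half-open) and
#'   `truncated`.
#' @export
sliding_windows <- function(length_bp, window_size = 2000L, step = 500L) {
  if (is.character(length_bp)) length_bp <- nchar(length_bp)
  if (window_size < 1L || step < 1L) stop("window_size and step must be >= 1")
  L <- as.integer(length_bp)
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  if (L < window_size) {
    return(data.frame(start = 0L, end = L, truncated = TRUE))
  }
  starts <- seq.int(0L, L - window_size, by = step)
  data.frame(start = starts, end = starts + as.integer(window_size),
             truncated = FALSE)
}

#' Per-window usage deviation profile of one genome
#'
#' Each window is treated as an independent mini-genome: extended by its own
#' reverse complement, counted, and normalized to its own mononucleotide
#' composition. No cross-window filtering is applied; vectors are
#' canonicalized.
#'
#' @param seq Genome sequence (single character string).
#' @param k Word length (default 4).
#' @param window_size,step Window geometry in bp (defaults 2000 / 500).
#' @param id Genome identifier for labeling.
#' @return Object of class `window_profile`: `source_id`, `k`,
#'   `window_size`, `step`, `windows` (interval data frame), `vectors`
#'   (list of canonical `tud` objects, one per window).
#' @export
window_profile <- function(seq, k = 4L, window_size = 2000L, step = 500L,
                           id = "genome") {
  if (nchar(seq) < k) stop("genome shorter than k")
  win <- sliding_windows(nchar(seq), window_size, step)
  vecs <- lapply(seq_len(nrow(win)), function(i) {
    sub <- substring(seq, win$start[i] + 1L, win$end[i])
    canonicalize(usage_deviation(sub, k = k,
                                 id = sprintf("%s:%d-%d", id, win$start[i],
                                              win$end[i])))
  })
  structure(
    list(source_id = id, k = as.integer(k),
         window_size = as.integer(window_size), step = as.integer(step),
         windows = win, vectors = vecs),
    class = "window_profile"
  )
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf("Window profile of '%s': %d windows of %d bp (step %d), k = %d\n",
              x$source_id, nrow(x$windows), x$window_size, x$step, x$k))
  invisible(x)
}

#' Window-versus-window distance heatmap with overlap mask
#'
#' Pairwise Euclidean distances between all window usage vectors. For each
#' pair, words with zero expected count in either window are excluded, so
#' unattainable words in a window (an absent nucleotide) cannot inflate the
#' distance. The overlap mask marks pairs of windows whose intervals
#' overlap; masked entries are excluded from downstream statistics just as
#' they are blanked in heatmap figures.
#'
#' @param profile A `window_profile`.
#' @return Object of class `window_heatmap`: `source_id`, `windows`,
#'   `distances` (symmetric matrix), `overlap_mask` (logical matrix, TRUE
#'   where windows overlap), `window_size`.
#' @export
window_heatmap <- function(profile) {
  stopifnot(inherits(profile, "window_profile"))
  n <- length(profile$vectors)
  if (n < 2L) stop("heatmap needs at least 2 windows")
  dev <- do.call(rbind, lapply(profile$vectors, `[[`, "deviation"))
  expz <- do.call(rbind, lapply(profile$vectors, function(v) v$expected == 0))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      use <- !(expz[i, ] | expz[j, ])
      d[i, j] <- d[j, i] <- sqrt(sum((dev[i, use] - dev[j, use])^2))
    }
  }
  starts <- profile$windows$start
  mask <- abs(outer(starts, starts, "-")) < profile$window_size
  dimnames(d) <- dimnames(mask) <-
    list(sprintf("w%d", starts), sprintf("w%d", starts))
  structure(
    list(source_id = profile$source_id, windows = profile$windows,
         distances = d, overlap_mask = mask,
         window_size = profile$window_size),
    class = "window_heatmap"
  )
}

#' @export
print.window_heatmap <- function(x, ...) {
  um <- x$distances[!x$overlap_mask]
  cat(sprintf("Window heatmap of '%s': %d windows, median unmasked distance %.3f\n",
              x$source_id, nrow(x$distances), stats::median(um)))
  invisible(x)
}

#' Flag compositionally anomalous windows
#'
#' For each window, the mean of its unmasked distances to all other windows
#' is computed; windows whose mean reaches `median + z * MAD` of those means
#' are flagged, and runs of flagged windows are merged into intervals. The
#' robust threshold tolerates the heavy upper tail that repeat blocks
#' induce in window-mean distances.
#'
#' @param heatmap A `window_heatmap`.
#' @param z Robustified z-score threshold (default 3).
#' @return Data frame of flagged intervals with columns `start`, `end`
#'   (0-based half-open, merged over adjacent flagged windows); attribute
#'   `window_means` holds the per-window mean distances, `flagged` the
#'   per-window logical.
#' @export
call_outlier_windows <- function(heatmap, z = 3.0) {
  stopifnot(inherits(heatmap, "window_heatmap"))
  d <- heatmap$distances
  mask <- heatmap$overlap_mask
  n <- nrow(d)
  if (sum(!mask[upper.tri(mask)]) < 5L) {
    stop("fewer than 5 unmasked window pairs")
  }
  means <- vapply(seq_len(n), function(i) {
    use <- !mask[i, ]
    if (!any(use)) return(NA_real_)
    mean(d[i, use])
  }, 0)
  thr <- stats::median(means, na.rm = TRUE) +
    z * stats::mad(means, na.rm = TRUE)
  flagged <- !is.na(means) & means >= thr
  # merge adjacent flagged windows into intervals
  out <- data.frame(start = integer(0), end = integer(0))
  if (any(flagged)) {
    idx <- which(flagged)
    brk <- c(0L, which(diff(idx) != 1L), length(idx))
    for (b in seq_len(length(brk) - 1L)) {
      run <- idx[(brk[b] + 1L):brk[b + 1L]]
      out <- rbind(out, data.frame(start = heatmap$windows$start[run[1L]],
                                   end = heatmap$windows$end[run[length(run)]]))
    }
  }
  attr(out, "window_means") <- means
  attr(out, "flagged") <- flagged
  out
}

#' Single-word usage deviation track along a genome
#'
#' In each sliding window, the word's observed count over both strands is
#' divided by its expected count under the window's own mononucleotide
#' composition — the per-window deviation for one word rather than the full
#' vector. Useful for words tied to biological signals (e.g. the Dam
#' methylation site GATC or the BamHI site GGATCC).
#'
#' @param seq Genome sequence.
#' @param word Word over `{A,C,G,T}` (any length <= window_size).
#' @param window_size,step Window geometry in bp (defaults 5000 / 1000).
#' @param id Genome identifier.
#' @return Object of class `word_track`: `source_id`, `word`,
#'   `window_size`, `step`, `starts`, `deviation`.
#' @export
word_track <- function(seq, word, window_size = 5000L, step = 1000L,
                       id = "genome") {
  word <- toupper(word)
  if (grepl("[^ACGT]", word)) stop("word must be over {A,C,G,T}")
  if (nchar(word) > window_size) stop("word longer than window")
  win <- sliding_windows(nchar(seq), window_size, step)
  k <- nchar(word)
  dev <- vapply(seq_len(nrow(win)), function(i) {
    sub <- substring(seq, win$start[i] + 1L, win$end[i])
    pair <- extend_with_revcomp(sub)
    obs <- Biostrings::countPattern(word, Biostrings::DNAString(pair$forward)) +
      Biostrings::countPattern(word, Biostrings::DNAString(pair$reverse))
    comp <- composition(pair)
    e <- expected_count(word, comp)
    if (e > 0) obs / e else 0
  }, 0)
  structure(
    list(source_id = id, word = word, window_size = as.integer(window_size),
         step = as.integer(step), starts = win$start, deviation = dev),
    class = "word_track"
  )
}

#' @export
print.word_track <- function(x, ...) {
  cat(sprintf("%s usage track for '%s': %d windows (%d bp, step %d), mean %.2f\n",
              x$word, x$source_id, length(x$starts), x$window_size, x$step,
              mean(x$deviation)))
  invisible(x)
}

#' @export
plot.word_track <- function(x, ...) {
  plot(x$starts, x$deviation, type = "l",
       xlab = "window start (bp)",
       ylab = sprintf("%s usage deviation", x$word),
       main = x$source_id, ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Mean usage track over a group of genomes
#'
#' Averages several word tracks window-index by window-index, truncating at
#' the shortest track (genomes are unaligned, so only the shared leading
#' window indices are comparable).
#'
#' @param tracks List of `word_track` objects sharing word, window size and
#'   step.
#' @param group_id Identifier recorded on the mean track.
#' @return A `word_track` holding the per-index arithmetic mean.
#' @export
group_mean_track <- function(tracks, group_id = "group") {
  if (length(tracks) == 0L) stop("no tracks supplied")
  w <- tracks[[1L]]
  for (t in tracks) {
    if (!identical(t$word, w$word) ||
        !identical(t$window_size, w$window_size) ||
        !identical(t$step, w$step)) {
      stop("tracks differ in word, window size or step")
    }
  }
  n <- min(vapply(tracks, function(t) length(t$starts), 0L))
  m <- do.call(rbind, lapply(tracks, function(t) t$deviation[seq_len(n)]))
  structure(
    list(source_id = group_id, word = w$word, window_size = w$window_size,
         step = w$step, starts = w$starts[seq_len(n)],
         deviation = colMeans(m)),
    class = "word_track"
  )
}

#' Write flagged intervals as BED
#'
#' @param calls Data frame with `start`, `end` (0-based half-open).
#' @param chrom Sequence name for the first BED column.
#' @param path Output path.
#' @export
write_bed <- function(calls, chrom, path) {
  df <- data.frame(chrom = chrom, start = calls$start, end = calls$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
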