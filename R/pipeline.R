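#' Whole-collection comparison workflow
#'
#' End-to-end run: usage deviation vectors for every genome (canonicalized
#' and universality-filtered), pairwise Euclidean distance matrix,
#' neighbor-joining and average-linkage trees, PCA, and — when labels are
#' supplied — a per-group monophyly report for both trees. All artifacts
#' are written as TSV/Newick under `out_dir` together with the resolved
#' configuration, so a rerun with the same inputs is byte-identical. With
#' only 2 genomes the trees are skipped with a notice (NJ needs 3).
#'
#' @param fasta Path to a multi-record FASTA file, or a named character
#'   vector of sequences.
#' @param labels Optional path to a labels TSV or a named character vector
#'   (genome id -> group).
#' @param out_dir Output directory (created if needed).
#' @param k Word length (default 4).
#' @param canonical,filter Passed to [usage_deviation_set()].
#' @param pca_log Log-transform before PCA (default TRUE).
#' @param denominator Expected-count denominator convention.
#' @return Invisibly, a list with the in-memory results (`vectors`, `dist`,
#'   `nj`, `average`, `pca`, `monophyly`) and `files` (paths written).
#' @export
run_compare <- function(fasta, labels = NULL, out_dir, k = 4L,
                        canonical = TRUE, filter = TRUE, pca_log = TRUE,
                        denominator = "length") {
  t0 <- Sys.time()
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    read_fasta(fasta) else fasta
  if (length(seqs) < 2L) stop("run_compare needs at least 2 genomes")
  if (!is.null(labels) && is.character(labels) && length(labels) == 1L &&
      file.exists(labels)) {
    labels <- read_labels(labels)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name) {
    message(sprintf("[%s] %s (%.1fs elapsed)", "run_compare", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  stage("usage deviation")
  vecs <- usage_deviation_set(seqs, k = k, canonical = canonical,
                              filter = filter, denominator = denominator)
  removed <- attr(vecs, "removed_words")
  if (length(removed) > 0L) {
    message(sprintf("[run_compare] universality filter removed %d word(s): %s",
                    length(removed), paste(removed, collapse = ", ")))
  }
  m <- tud_matrix(vecs)
  files <- list(tud = file.path(out_dir, "tud.tsv"))
  utils::write.table(
    data.frame(id = rownames(m), format(m, digits = 15, trim = TRUE),
               check.names = FALSE),
    files$tud, sep = "\t", quote = FALSE, row.names = FALSE)

  stage("distance matrix")
  dm <- distance_matrix(vecs)
  files$dist <- write_matrix(dm, file.path(out_dir, "dist.tsv"))

  nj <- avg <- mono <- NULL
  if (length(vecs) >= 3L) {
    stage("trees")
    nj <- neighbor_joining(dm)
    avg <- average_linkage(dm)
    files$nj <- write_newick(nj, file.path(out_dir, "nj.nwk"))
    files$average <- write_newick(avg, file.path(out_dir, "average.nwk"))
  } else {
    message("[run_compare] fewer than 3 genomes: trees skipped")
  }

  stage("PCA")
  pca <- tud_pca(vecs, log_transform = pca_log)
  files$pca_scores <- file.path(out_dir, "pca_scores.tsv")
  utils::write.table(
    data.frame(id = rownames(pca$scores),
               format(pca$scores, digits = 15, trim = TRUE),
               check.names = FALSE),
    files$pca_scores, sep = "\t", quote = FALSE, row.names = FALSE)
  files$pca_variance <- file.path(out_dir, "pca_variance.tsv")
  utils::write.table(
    data.frame(component = seq_along(pca$variance_fraction),
               variance_fraction = format(pca$variance_fraction, digits = 15)),
    files$pca_variance, sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(labels) && !is.null(nj)) {
    stage("monophyly")
    mono <- data.frame(
      group = names(monophyly_check(nj, labels)),
      nj = unname(monophyly_check(nj, labels)),
      average = unname(monophyly_check(avg, labels)))
    files$monophyly <- file.path(out_dir, "monophyly.tsv")
    utils::write.table(mono, files$monophyly, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  config <- list(workflow = "compare", k = k, canonical = canonical,
                 universality_filter = filter, pca_log = pca_log,
                 denominator = denominator, n_genomes = length(seqs))
  files$config <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, files$config, auto_unbox = TRUE, pretty = TRUE)
  stage("done")
  invisible(list(vectors = vecs, dist = dm, nj = nj, average = avg, pca = pca,
                 monophyly = mono, files = files))
}

#' Within-genome window workflow
#'
#' Computes the sliding-window usage profile of one genome, the
#' window-versus-window distance heatmap with overlap mask, and outlier
#' window calls, writing profile/heatmap/mask TSVs and a BED of flagged
#' intervals under `out_dir`.
#'
#' @param fasta Path to a FASTA file or named character vector of
#'   sequences.
#' @param genome_id Which genome to analyse.
#' @param out_dir Output directory.
#' @param k Word length (default 4).
#' @param window_size,step Window geometry (defaults 2000 / 500).
#' @param z Outlier threshold for [call_outlier_windows()].
#' @return Invisibly, list with `profile`, `heatmap`, `calls`, `files`.
#' @export
run_windows <- function(fasta, genome_id, out_dir, k = 4L,
                        window_size = 2000L, step = 500L, z = 3.0) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    read_fasta(fasta) else fasta
  if (!genome_id %in% names(seqs)) {
    stop("genome '", genome_id, "' not found; available: ",
         paste(names(seqs), collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prof <- window_profile(seqs[[genome_id]], k = k, window_size = window_size,
                         step = step, id = genome_id)
  hm <- window_heatmap(prof)
  calls <- call_outlier_windows(hm, z = z)

  files <- list(profile = file.path(out_dir, "profile.tsv"))
  pm <- do.call(rbind, lapply(prof$vectors, `[[`, "deviation"))
  utils::write.table(
    data.frame(start = prof$windows$start, end = prof$windows$end,
               format(pm, digits = 15, trim = TRUE), check.names = FALSE),
    files$profile, sep = "\t", quote = FALSE, row.names = FALSE)
  files$heatmap <- write_matrix(hm$distances,
                                file.path(out_dir, "heatmap.tsv"))
  mask <- hm$overlap_mask
  storage.mode(mask) <- "integer"
  files$mask <- write_matrix(mask, file.path(out_dir, "mask.tsv"))
  files$calls <- write_bed(calls, genome_id, file.path(out_dir, "calls.bed"))
  config <- list(workflow = "windows", genome_id = genome_id, k = k,
                 window_size = window_size, step = step, z = z)
  files$config <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, files$config, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(profile = prof, heatmap = hm, calls = calls, files = files))
}
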