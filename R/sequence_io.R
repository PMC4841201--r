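#' Read a multi-record nucleotide FASTA file
#'
#' Reads a FASTA file into a named character vector of uppercase sequences.
#' The record identifier is the header token before the first whitespace; the
#' full header line is kept in the `"descriptions"` attribute. Characters
#' outside `{A,C,G,T,N}` (IUPAC ambiguity codes, gaps, ...) are mapped to `N`
#' and the number of replaced characters is reported with a warning.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return Named character vector of sequences, one element per record, in
#'   file order, with attribute `descriptions` (full header lines).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  n_bad <- sum(vapply(seqs, function(s) nchar(gsub("[ACGTN]", "", s)), 0L))
  cleaned <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), "")
  if (n_bad > 0L) {
    warning(sprintf("%d non-ACGTN character(s) replaced by N", n_bad))
  }
  names(cleaned) <- ids
  attr(cleaned, "descriptions") <- headers
  cleaned
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' `N` maps to `N`. Operates on plain character strings.
#'
#' @param seq Character string over `{A,C,G,T,N}`.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "", USE.NAMES = FALSE)
}

#' Extend a genome by its reverse complement
#'
#' Word counting treats the forward sequence and its reverse complement as two
#' separate strands: no word spans the junction between them. This extension
#' removes strand-of-deposit effects, making every usage statistic invariant
#' to which strand of the genome was sequenced.
#'
#' @param seq Character string over `{A,C,G,T,N}` (one genome).
#' @param id Optional identifier carried along for reporting.
#' @return A `strand_pair` list with elements `forward`, `reverse`,
#'   `source_id`.
#' @export
extend_with_revcomp <- function(seq, id = NA_character_) {
  seq <- toupper(seq)
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) < 1L) {
    stop("sequence must be a single non-empty string")
  }
  structure(
    list(forward = seq, reverse = revcomp(seq), source_id = id),
    class = "strand_pair"
  )
}

#' Read a genome label (cluster/subcluster) table
#'
#' Two-column TSV `genome_id<TAB>label`; lines starting with `#` are ignored;
#' no header expected.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping genome id to label.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stop("malformed label line(s): ", lines[which(bad)[1L]])
  stats::setNames(vapply(parts, `[[`, "", 2L), vapply(parts, `[[`, "", 1L))
}

#' Write a tree in Newick format
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write / read a labeled distance matrix as TSV
#'
#' The TSV carries a header row of genome ids and a first column of ids;
#' values are written with enough digits to round-trip.
#'
#' @param m A `dist` object or square symmetric numeric matrix with labels.
#' @param path File path.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("matrix must be labeled")
  df <- data.frame(id = rownames(m), format(m, digits = 15, trim = TRUE,
                                            scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = 1L)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  m
}
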