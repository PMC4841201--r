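# run code under a private, seeded RNG stream, restoring global state after
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483563) + 1L
}

#' Random biased Markov model for sequence generation
#'
#' Draws a transition probability vector over `{A,C,G,T}` for every context
#' of the given order from a symmetric Dirichlet with concentration
#' `1 / bias_strength` per component: strength 0 gives the uniform model,
#' larger strengths give stronger, more idiosyncratic word-usage biases.
#'
#' @param order Markov order (0 to 5); order 3 directly shapes 4-mer usage.
#' @param bias_strength Nonnegative distortion strength (default 0.5).
#' @param seed Integer seed; same seed, same model.
#' @param model_id Optional identifier.
#' @return Object of class `biased_model`: `order`, `prob` (4^order x 4
#'   matrix, rows = contexts in lexicographic order, columns A,C,G,T),
#'   `bias_strength`, `model_id`.
#' @export
random_biased_model <- function(order = 3L, bias_strength = 0.5, seed,
                                model_id = NULL) {
  if (order < 0L || order > 5L) stop("order must be between 0 and 5")
  if (bias_strength < 0) stop("bias_strength must be nonnegative")
  n_ctx <- 4L^order
  ctx <- if (order == 0L) "" else enumerate_words(order)
  if (bias_strength == 0) {
    prob <- matrix(0.25, n_ctx, 4L)
  } else {
    alpha <- 1 / bias_strength
    prob <- with_seed(seed, {
      g <- matrix(stats::rgamma(n_ctx * 4L, shape = alpha), n_ctx, 4L)
      g / rowSums(g)
    })
  }
  dimnames(prob) <- list(ctx, c("A", "C", "G", "T"))
  structure(
    list(order = as.integer(order), prob = prob,
         bias_strength = bias_strength,
         model_id = if (is.null(model_id)) sprintf("model_s%d", seed)
                    else model_id),
    class = "biased_model"
  )
}

# re-draw each context's probabilities around the parent model's, with high
# concentration, so sibling genomes share a signature but are not identical
jitter_model <- function(model, concentration = 200, seed) {
  prob <- with_seed(seed, {
    p <- model$prob
    g <- matrix(stats::rgamma(length(p), shape = concentration * pmax(p, 1e-6)),
                nrow(p), ncol(p))
    g / rowSums(g)
  })
  dimnames(prob) <- dimnames(model$prob)
  model$prob <- prob
  model
}

#' Generate a genome from a biased Markov model
#'
#' The initial context is drawn uniformly; each subsequent base is sampled
#' from the model's transition probabilities for the current context.
#'
#' @param model A `biased_model`.
#' @param length Genome length in bases (> model order).
#' @param seed Integer seed; same (model, length, seed), same sequence.
#' @return Single character string over `{A,C,G,T}`.
#' @export
generate_genome <- function(model, length, seed) {
  stopifnot(inherits(model, "biased_model"))
  len <- as.integer(length)
  if (len <= model$order) stop("length must exceed the model order")
  bases <- c("A", "C", "G", "T")
  p <- model$prob
  # cumulative thresholds per context, compared against one uniform draw
  c1 <- p[, 1L]; c2 <- c1 + p[, 2L]; c3 <- c2 + p[, 3L]
  n_ctx <- nrow(p)
  mod <- max(n_ctx %/% 4L, 1L)
  with_seed(seed, {
    ctx <- sample.int(n_ctx, 1L) - 1L
    u <- stats::runif(len)
    out <- integer(len)
    if (model$order == 0L) {
      out <- (u >= c1[1L]) + (u >= c2[1L]) + (u >= c3[1L])
    } else {
      for (i in seq_len(len)) {
        ui <- u[i]
        b <- (ui >= c1[ctx + 1L]) + (ui >= c2[ctx + 1L]) + (ui >= c3[ctx + 1L])
        out[i] <- b
        ctx <- (ctx %% mod) * 4L + b
      }
    }
    paste(bases[out + 1L], collapse = "")
  })
}

#' Generate a cluster-structured synthetic genome community
#'
#' One biased model per cluster (all derived from `seed`), with a small
#' per-genome jitter so within-cluster variance is nonzero. Optionally
#' plants a contiguous foreign segment generated from a donor cluster's
#' model into a fraction of one cluster's genomes (an HGT-like insertion),
#' and/or a tandem-repeat block. All planted coordinates are recorded as
#' ground truth.
#'
#' @param n_clusters Number of clusters.
#' @param genomes_per_cluster Genomes per cluster.
#' @param genome_length Length of each genome in bp (before insertions).
#' @param bias_strength Per-cluster Dirichlet distortion (default 0.5).
#' @param order Markov order of the generating models (default 3).
#' @param hgt Optional list `list(donor=, recipient=, length=, fraction=)`:
#'   insert a `length`-bp segment from the donor cluster's model into
#'   `round(fraction * genomes_per_cluster)` genomes of the recipient
#'   cluster, at a seeded random position.
#' @param repeats Optional list `list(unit=, copies=, recipient=)`: insert a
#'   tandem block `strrep(unit, copies)` into every genome of the recipient
#'   cluster (default cluster 1) at a seeded random position.
#' @param seed Top-level integer seed; all sub-seeds derive from it.
#' @return Object of class `synthetic_community`: `genomes` (named
#'   character vector), `labels` (named cluster labels), `truth` (data
#'   frame: genome_id, cluster, feature_type, start, end — 0-based
#'   half-open), `models`, `spec` (the resolved parameters).
#' @export
generate_community <- function(n_clusters = 3L, genomes_per_cluster = 5L,
                               genome_length = 50000L, bias_strength = 0.5,
                               order = 3L, hgt = NULL, repeats = NULL,
                               seed = 1L) {
  if (!is.null(hgt)) {
    stopifnot(all(c("donor", "recipient", "length", "fraction") %in% names(hgt)))
    if (hgt$donor > n_clusters || hgt$donor < 1 ||
        hgt$recipient > n_clusters || hgt$recipient < 1) {
      stop("hgt donor/recipient cluster out of range")
    }
  }
  models <- lapply(seq_len(n_clusters), function(cl) {
    random_biased_model(order = order, bias_strength = bias_strength,
                        seed = derive_seed(seed, cl),
                        model_id = sprintf("cluster%d", cl))
  })
  genomes <- character(0)
  labels <- character(0)
  truth <- data.frame(genome_id = character(0), cluster = character(0),
                      feature_type = character(0), start = integer(0),
                      end = integer(0))
  hgt_targets <- integer(0)
  if (!is.null(hgt)) {
    n_rec <- round(hgt$fraction * genomes_per_cluster)
    hgt_targets <- seq_len(n_rec)  # first genomes of the recipient cluster
  }
  idx <- 0L
  for (cl in seq_len(n_clusters)) {
    for (g in seq_len(genomes_per_cluster)) {
      idx <- idx + 1L
      gid <- sprintf("c%d_g%d", cl, g)
      gm <- jitter_model(models[[cl]], seed = derive_seed(seed, 1000L + idx))
      s <- generate_genome(gm, genome_length, derive_seed(seed, 2000L + idx))
      feat <- "none"; fstart <- NA_integer_; fend <- NA_integer_
      if (!is.null(hgt) && cl == hgt$recipient && g %in% hgt_targets) {
        seg <- generate_genome(models[[hgt$donor]], hgt$length,
                               derive_seed(seed, 3000L + idx))
        pos <- with_seed(derive_seed(seed, 4000L + idx), {
          sample.int(nchar(s) - 1L, 1L)
        })
        s <- paste0(substring(s, 1L, pos), seg, substring(s, pos + 1L))
        feat <- "hgt"; fstart <- pos; fend <- pos + as.integer(hgt$length)
      }
      if (!is.null(repeats) &&
          cl == (if (is.null(repeats$recipient)) 1L else repeats$recipient)) {
        block <- strrep(repeats$unit, repeats$copies)
        pos <- with_seed(derive_seed(seed, 5000L + idx), {
          sample.int(nchar(s) - 1L, 1L)
        })
        s <- paste0(substring(s, 1L, pos), block, substring(s, pos + 1L))
        truth <- rbind(truth, data.frame(
          genome_id = gid, cluster = sprintf("c%d", cl),
          feature_type = "repeat", start = pos,
          end = pos + nchar(block)))
      }
      genomes[gid] <- s
      labels[gid] <- sprintf("c%d", cl)
      truth <- rbind(truth, data.frame(
        genome_id = gid, cluster = sprintf("c%d", cl), feature_type = feat,
        start = fstart, end = fend))
    }
  }
  structure(
    list(genomes = genomes, labels = labels, truth = truth, models = models,
         spec = list(n_clusters = n_clusters,
                     genomes_per_cluster = genomes_per_cluster,
                     genome_length = genome_length,
                     bias_strength = bias_strength, order = order,
                     hgt = hgt, repeats = repeats, seed = seed)),
    class = "synthetic_community"
  )
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("Synthetic community: %d clusters x %d genomes of %d bp (seed %d)\n",
              x$spec$n_clusters, x$spec$genomes_per_cluster,
              x$spec$genome_length, x$spec$seed))
  planted <- x$truth[x$truth$feature_type != "none", , drop = FALSE]
  if (nrow(planted) > 0L) {
    cat(sprintf("  planted features: %s\n",
                paste(sprintf("%s[%s %d-%d]", planted$genome_id,
                              planted$feature_type, planted$start,
                              planted$end), collapse = ", ")))
  }
  invisible(x)
}
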