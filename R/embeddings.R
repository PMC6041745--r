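# Skip-gram embeddings with negative sampling, trained on the task corpus
# only. Words are replaced by their lemmas and every detected mention is
# treated as a single vocabulary unit (its lemmas joined by "_"), so a
# multi-word mention such as "the IL-6 kappa B motif" gets one vector.

sigmoid <- function(x) 1 / (1 + exp(-x))

# per-sentence unit sequences: lemmas with mention token runs collapsed
corpus_units <- function(corpus, mentions_list) {
  seqs <- list()
  for (d in seq_along(corpus)) {
    doc <- corpus[[d]]
    dt <- doc_tokens(doc)
    mn <- mentions_list[[d]]
    for (s in doc$sentences) {
      tk <- s$tokens
      ms <- mn[mn$sentence == s$index, , drop = FALSE]
      if (nrow(ms) > 0L) {
        ms <- ms[order(ms$tok_start, -ms$tok_end), , drop = FALSE]
        keep <- logical(nrow(ms)); frontier <- -1L
        for (k in seq_len(nrow(ms))) {
          if (ms$tok_start[k] > frontier) {
            keep[k] <- TRUE; frontier <- ms$tok_end[k]
          }
        }
        ms <- ms[keep, , drop = FALSE]
      }
      units <- character(); i <- 0L
      while (i <= max(tk$index)) {
        hit <- which(nrow(ms) > 0 & ms$tok_start == i)
        if (length(hit) == 1L) {
          units <- c(units,
                     mention_key(dt, s$index, ms$tok_start[hit],
                                 ms$tok_end[hit]))
          i <- ms$tok_end[hit] + 1L
        } else {
          units <- c(units, tk$lemma[tk$index == i])
          i <- i + 1L
        }
      }
      seqs[[length(seqs) + 1L]] <- units
    }
  }
  seqs
}

#' Train skip-gram embeddings on a document corpus
#'
#' Plain skip-gram with negative sampling over per-sentence unit
#' sequences in which every detected mention is a single unit. Fully
#' deterministic for a fixed seed. Out-of-vocabulary items map to a zero
#' vector at lookup time.
#'
#' @param corpus list of parsed \code{coref_document}
#' @param dim embedding dimensionality (50 by default)
#' @param seed RNG seed
#' @param window symmetric context window in units
#' @param negative negative samples per context pair
#' @param epochs passes over the corpus
#' @param lr initial learning rate (linearly decayed)
#' @param gazetteer optional bio-entity terms for mention detection
#' @param mentions optional list of precomputed mention frames, one per
#'   document
#' @return object of class \code{coref_embeddings}
#' @export
train_embeddings <- function(corpus, dim = 50L, seed = 1L, window = 2L,
                             negative = 5L, epochs = 5L, lr = 0.05,
                             gazetteer = NULL, mentions = NULL) {
  if (length(corpus) == 0L) stop("empty corpus")
  if (is.null(mentions))
    mentions <- lapply(corpus, function(d)
      rbind(detect_anaphors(d, gazetteer), detect_candidates(d, gazetteer)))
  seqs <- corpus_units(corpus, mentions)
  vocab <- sort(unique(unlist(seqs)))
  V <- length(vocab)
  if (V == 0L) stop("empty corpus")
  counts <- table(factor(unlist(seqs), levels = vocab))
  neg_prob <- as.numeric(counts)^0.75
  neg_prob <- neg_prob / sum(neg_prob)
  idx <- lapply(seqs, function(u) match(u, vocab))

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  W <- matrix(stats::runif(V * dim, -0.5 / dim, 0.5 / dim), nrow = V)
  C <- matrix(0, nrow = V, ncol = dim)

  pairs <- list()
  for (u in idx) {
    n <- length(u)
    if (n < 2L) next
    for (t in seq_len(n)) {
      lo <- max(1L, t - window); hi <- min(n, t + window)
      for (o in lo:hi) if (o != t)
        pairs[[length(pairs) + 1L]] <- c(u[t], u[o])
    }
  }
  if (length(pairs) == 0L) stop("corpus too small to form context pairs")
  pm <- do.call(rbind, pairs)

  total <- epochs * nrow(pm)
  step <- 0L
  for (ep in seq_len(epochs)) {
    for (r in seq_len(nrow(pm))) {
      step <- step + 1L
      eta <- lr * max(1e-4, 1 - step / total)
      ct <- pm[r, 1L]; ot <- pm[r, 2L]
      targets <- c(ot, sample.int(V, negative, replace = TRUE,
                                  prob = neg_prob))
      labels <- c(1, numeric(negative))
      h <- W[ct, ]
      scores <- sigmoid(C[targets, , drop = FALSE] %*% h)
      err <- as.numeric(scores) - labels
      gh <- crossprod(C[targets, , drop = FALSE], err)
      C[targets, ] <- C[targets, ] - eta * (err %o% h)
      W[ct, ] <- W[ct, ] - eta * as.numeric(gh)
    }
  }
  rownames(W) <- vocab
  structure(list(vectors = W, dim = dim, vocab = vocab),
            class = "coref_embeddings")
}

#' Look up an embedding vector; unknown keys map to zeros
#' @param emb a \code{coref_embeddings}
#' @param key unit key (lemma or mention key)
#' @return numeric vector of length \code{emb$dim}
#' @export
emb_lookup <- function(emb, key) {
  i <- match(key, emb$vocab)
  if (is.na(i)) numeric(emb$dim) else emb$vectors[i, ]
}

#' @export
print.coref_embeddings <- function(x, ...) {
  cat("<coref_embeddings>", length(x$vocab), "units, dim", x$dim, "\n")
  invisible(x)
}
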