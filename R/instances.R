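# Mention-pair sequence instances: the token/mention sequence running from
# a candidate antecedent (first item) to an anaphor (last item), with words
# sharing a mention index replaced by their common mention.

MENTION_TYPES <- c("np_candidate", "relative_pronoun", "personal_pronoun",
                   "definite_np")
NUMBER_LEVELS <- c("singular", "plural", "unknown")

default_windows <- function() {
  c(relative_pronoun = 0L, personal_pronoun = 1L, definite_np = 2L)
}

mention_key <- function(doc_toks, sentence, tok_start, tok_end) {
  lem <- doc_toks$lemma[doc_toks$sentence == sentence &
                          doc_toks$index >= tok_start &
                          doc_toks$index <= tok_end]
  paste(lem, collapse = "_")
}

word_item <- function(lemma) {
  list(kind = "word", key = lemma, mention_type = NA_character_,
       number = NA_character_, protein_count = NA_integer_,
       bioentity_count = NA_integer_)
}

mention_item <- function(m, doc_toks) {
  list(kind = "mention",
       key = mention_key(doc_toks, m$sentence, m$tok_start, m$tok_end),
       mention_type = m$mention_type, number = m$number,
       protein_count = m$protein_count, bioentity_count = m$bioentity_count)
}

#' Build mention-pair sequence instances for a document
#'
#' For each anaphor, one instance per candidate NP inside the anaphor
#' type's sentence window (0 for relative pronouns, 1 for personal
#' pronouns, 2 for definite NPs), the candidate preceding the anaphor.
#' The instance item list runs from the candidate (first item) to the
#' anaphor (last item); intervening tokens belonging to another detected
#' mention are replaced by that mention. Labels come from the document's
#' gold links when present (1/0), else NA. Instances longer than
#' \code{max_len} are truncated from the left keeping both endpoints and
#' flagged \code{truncated}.
#'
#' @param doc a parsed \code{coref_document}
#' @param mentions optional precomputed mention frame (anaphors and
#'   candidates together); detected when NULL
#' @param windows named sentence windows per anaphor type
#' @param max_len maximum items per instance (82 by default)
#' @param gazetteer optional bio-entity term vector
#' @return list of \code{seq_instance} objects
#' @export
build_instances <- function(doc, mentions = NULL,
                            windows = default_windows(), max_len = 82L,
                            gazetteer = NULL) {
  if (is.null(mentions))
    mentions <- rbind(detect_anaphors(doc, gazetteer),
                      detect_candidates(doc, gazetteer))
  dt <- doc_tokens(doc)
  g_of <- function(sentence, index)
    dt$gindex[dt$sentence == sentence & dt$index == index]
  mentions$g_start <- mapply(g_of, mentions$sentence, mentions$tok_start)
  mentions$g_end <- mapply(g_of, mentions$sentence, mentions$tok_end)

  anaphors <- mentions[mentions$mention_type != "np_candidate", ,
                       drop = FALSE]
  cands <- mentions[mentions$mention_type == "np_candidate", , drop = FALSE]
  out <- list()
  if (nrow(anaphors) == 0L) return(out)

  for (i in seq_len(nrow(anaphors))) {
    a <- anaphors[i, , drop = FALSE]
    w <- windows[[a$mention_type]]
    sel <- cands$sentence >= a$sentence - w &
      (cands$sentence < a$sentence | cands$tok_end < a$tok_start)
    for (j in which(sel)) {
      cand <- cands[j, , drop = FALSE]
      lo <- cand$g_start; hi <- a$g_end
      # mentions replacing word runs strictly between the endpoints
      mid <- mentions[mentions$g_start > cand$g_end &
                        mentions$g_end < a$g_start, , drop = FALSE]
      if (nrow(mid) > 1L) {
        mid <- mid[order(mid$g_start, -mid$g_end,
                         match(mid$mention_type, MENTION_TYPES)), ,
                   drop = FALSE]
        keep <- logical(nrow(mid))
        frontier <- -1L
        for (k in seq_len(nrow(mid))) {
          if (mid$g_start[k] > frontier) {
            keep[k] <- TRUE
            frontier <- mid$g_end[k]
          }
        }
        mid <- mid[keep, , drop = FALSE]
      }
      items <- list(mention_item(cand, dt))
      g <- cand$g_end + 1L
      while (g < a$g_start) {
        hit <- which(mid$g_start == g)
        if (length(hit) == 1L) {
          items[[length(items) + 1L]] <- mention_item(mid[hit, ], dt)
          g <- mid$g_end[hit] + 1L
        } else {
          items[[length(items) + 1L]] <- word_item(dt$lemma[dt$gindex == g])
          g <- g + 1L
        }
      }
      items[[length(items) + 1L]] <- mention_item(a, dt)

      truncated <- FALSE
      if (length(items) > max_len) {
        items <- c(items[1L],
                   items[(length(items) - max_len + 2L):length(items)])
        truncated <- TRUE
      }
      label <- NA_integer_
      if (!is.null(doc$gold_links)) {
        gl <- doc$gold_links
        label <- as.integer(any(gl$anaphor_start == a$start &
                                  gl$anaphor_end == a$end &
                                  gl$antecedent_start == cand$start &
                                  gl$antecedent_end == cand$end))
      }
      out[[length(out) + 1L]] <- structure(
        list(items = items, label = label, doc_id = doc$doc_id,
             anaphor = a, candidate = cand, truncated = truncated,
             distance = word_distance(cand$head_gindex, a$head_gindex)),
        class = "seq_instance")
    }
  }
  out
}

#' @export
print.seq_instance <- function(x, ...) {
  keys <- vapply(x$items, `[[`, character(1), "key")
  kinds <- vapply(x$items, `[[`, character(1), "kind")
  cat("<seq_instance> y=", x$label, " : ",
      paste(ifelse(kinds == "mention", paste0("[", keys, "]"), keys),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

# one-hot block: mention type (4) + number (3) + protein bucket (3) +
# bio-entity bucket (3); all-zero for plain words
encode_features <- function(item) {
  v <- numeric(13L)
  if (item$kind == "mention") {
    v[match(item$mention_type, MENTION_TYPES)] <- 1
    v[4L + match(item$number, NUMBER_LEVELS)] <- 1
    pb <- if (item$protein_count == 0L) 1L else
      if (item$protein_count == 1L) 2L else 3L
    bb <- if (item$bioentity_count == 0L) 1L else
      if (item$bioentity_count == 1L) 2L else 3L
    v[7L + pb] <- 1
    v[10L + bb] <- 1
  }
  v
}

#' Encode a sequence instance as a real-valued matrix
#'
#' Each row is the concatenation of the item's embedding vector (mention
#' or lemma; zero for out-of-vocabulary items) and the 13-dimensional
#' one-hot feature block.
#'
#' @param inst a \code{seq_instance}
#' @param emb a \code{coref_embeddings} object
#' @return numeric matrix, one row per item
#' @export
encode_sequence <- function(inst, emb) {
  t(vapply(inst$items, function(it)
    c(emb_lookup(emb, it$key), encode_features(it)),
    numeric(emb$dim + 13L)))
}
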