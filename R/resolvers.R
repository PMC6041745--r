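# Deterministic resolution procedures, one per anaphor type:
#   relative pronoun  -> shortest syntactic path, same sentence
#   personal pronoun  -> coordination-aware farthest candidate, window 1
#   definite NP       -> semantic constraints over bio-entity NPs, window 2

link_row <- function(doc, anaphor, cand) {
  data.frame(doc_id = doc$doc_id,
             anaphor_start = anaphor$start, anaphor_end = anaphor$end,
             anaphor_type = anaphor$mention_type,
             antecedent_start = cand$start, antecedent_end = cand$end,
             stringsAsFactors = FALSE)
}

# tokens strictly between the candidate head and the anaphor token
word_distance <- function(cand_head_g, anaphor_g) {
  abs(anaphor_g - cand_head_g) - 1L
}

number_agrees <- function(a, b) {
  a == "unknown" | b == "unknown" | a == b
}

# farthest candidate = maximal word distance; ties toward the leftmost
pick_farthest <- function(cands, anaphor_g) {
  d <- word_distance(cands$head_gindex, anaphor_g)
  cands[order(-d, cands$sentence, cands$tok_start), , drop = FALSE][1L, ]
}

# closest candidate = minimal word distance; ties toward the rightmost
pick_closest <- function(cands, anaphor_g) {
  d <- word_distance(cands$head_gindex, anaphor_g)
  cands[order(d, -cands$sentence, -cands$tok_start), , drop = FALSE][1L, ]
}

#' Resolve a relative pronoun anaphor
#'
#' Candidates are all candidate NPs strictly before the pronoun in the
#' same sentence; the one whose parse path to the pronoun leaf (edge
#' count through the lowest common ancestor) is shortest wins. Ties are
#' broken by smaller word distance, then by the leftmost candidate.
#'
#' @param anaphor one-row mention data.frame of type
#'   \code{relative_pronoun}
#' @param doc the containing document
#' @param candidates candidate mention frame from
#'   \code{\link{detect_candidates}} (recomputed when NULL)
#' @param gazetteer passed to \code{\link{detect_candidates}} when needed
#' @return one-row link data.frame, or NULL when no candidate precedes
#' @export
resolve_relative <- function(anaphor, doc, candidates = NULL,
                             gazetteer = NULL) {
  stopifnot(anaphor$mention_type == "relative_pronoun")
  if (is.null(candidates)) candidates <- detect_candidates(doc, gazetteer)
  cands <- candidates[candidates$sentence == anaphor$sentence &
                        candidates$tok_end < anaphor$tok_start, ,
                      drop = FALSE]
  if (nrow(cands) == 0L) return(NULL)
  tree <- doc$sentences[[anaphor$sentence + 1L]]$parse
  plen <- vapply(cands$node_id, function(id)
    pt_path_length(tree, anaphor$node_id, id), integer(1))
  d <- word_distance(cands$head_gindex, anaphor$head_gindex)
  best <- cands[order(plen, d, cands$tok_start), , drop = FALSE][1L, ]
  link_row(doc, anaphor, best)
}

#' Resolve a third-person personal pronoun anaphor
#'
#' Only bio-entity candidates (bioentity_count >= 1) are considered.
#' With same-sentence candidates present, the parse is walked bottom-up
#' from the pronoun: at the first coordinate structure (coordinate NP, VP
#' or clause) the farthest candidate inside the first conjunct is chosen;
#' otherwise the farthest candidate inside the closest containing clause
#' (S/SBAR). With none, number-agreeing bio-entity candidates of the
#' previous sentence are searched bottom-up from its last word for the
#' closest clause containing candidates, again taking the farthest.
#'
#' @inheritParams resolve_relative
#' @param anaphor one-row mention of type \code{personal_pronoun}
#' @return one-row link data.frame or NULL
#' @export
resolve_personal <- function(anaphor, doc, candidates = NULL,
                             gazetteer = NULL) {
  stopifnot(anaphor$mention_type == "personal_pronoun")
  if (is.null(candidates)) candidates <- detect_candidates(doc, gazetteer)
  bio <- candidates[candidates$bioentity_count >= 1L, , drop = FALSE]
  same <- bio[bio$sentence == anaphor$sentence &
                bio$tok_end < anaphor$tok_start, , drop = FALSE]
  ag <- anaphor$head_gindex
  if (nrow(same) > 0L) {
    tree <- doc$sentences[[anaphor$sentence + 1L]]$parse
    for (id in pt_ancestors(tree, anaphor$node_id)) {
      cat <- pt_coordination(tree, id)
      if (!is.na(cat)) {
        fc <- pt_first_conjunct(tree, id, cat)
        inside <- same[same$tok_start >= tree$nodes$tok_start[fc] &
                         same$tok_end <= tree$nodes$tok_end[fc], ,
                       drop = FALSE]
        if (nrow(inside) > 0L)
          return(link_row(doc, anaphor, pick_farthest(inside, ag)))
      } else if (tree$nodes$label[id] %in% CLAUSE_LABELS) {
        inside <- same[same$tok_start >= tree$nodes$tok_start[id] &
                         same$tok_end <= tree$nodes$tok_end[id], ,
                       drop = FALSE]
        if (nrow(inside) > 0L)
          return(link_row(doc, anaphor, pick_farthest(inside, ag)))
      }
    }
    return(link_row(doc, anaphor, pick_farthest(same, ag)))
  }
  if (anaphor$sentence == 0L) return(NULL)
  prev <- bio[bio$sentence == anaphor$sentence - 1L &
                number_agrees(bio$number, anaphor$number), , drop = FALSE]
  if (nrow(prev) == 0L) return(NULL)
  tree <- doc$sentences[[anaphor$sentence]]$parse
  last_leaf <- pt_leaf_of_token(tree, max(tree$nodes$token, na.rm = TRUE))
  for (id in pt_ancestors(tree, last_leaf)) {
    if (!tree$nodes$label[id] %in% CLAUSE_LABELS) next
    inside <- prev[prev$tok_start >= tree$nodes$tok_start[id] &
                     prev$tok_end <= tree$nodes$tok_end[id], , drop = FALSE]
    if (nrow(inside) > 0L)
      return(link_row(doc, anaphor, pick_farthest(inside, ag)))
  }
  link_row(doc, anaphor, pick_farthest(prev, ag))
}

#' Resolve a definite NP anaphor by semantic constraints
#'
#' Candidates are bio-entity NPs in a sentence window of 2 (same-sentence
#' candidates must precede the anaphor). Exactly one of four constraints
#' is selected by the anaphor's grammatical number and head word; its
#' sub-preferences are tried in order and the closest candidate of the
#' first non-empty one is returned. The winning branch is recorded in
#' \code{attr(, "fired")}.
#'
#' \itemize{
#' \item C1 plural protein/gene head; protein-bearing candidates only:
#'   (a) candidate head \emph{proteins}/\emph{genes}, (b) >1 protein.
#' \item C2 plural factor/element/receptor/complex/construct head:
#'   (a) same head word, (b) >1 bio-entity, (c) >1 protein.
#' \item C3 singular protein/gene head; protein-bearing candidates only:
#'   (a) candidate head \emph{protein}/\emph{gene}, (b) exactly 1 protein.
#' \item C4 singular other head: (a) same head word, (b) exactly 1
#'   bio-entity, (c) exactly 1 protein.
#' }
#'
#' @inheritParams resolve_relative
#' @param anaphor one-row mention of type \code{definite_np}
#' @param window sentence window (default 2)
#' @return one-row link data.frame or NULL
#' @export
resolve_definite <- function(anaphor, doc, candidates = NULL,
                             gazetteer = NULL, window = 2L) {
  stopifnot(anaphor$mention_type == "definite_np")
  if (is.null(candidates)) candidates <- detect_candidates(doc, gazetteer)
  bio <- candidates[candidates$bioentity_count >= 1L, , drop = FALSE]
  cands <- bio[bio$sentence >= anaphor$sentence - window &
                 (bio$sentence < anaphor$sentence |
                    bio$tok_end < anaphor$tok_start), , drop = FALSE]
  if (nrow(cands) == 0L) return(NULL)

  plural <- anaphor$number == "plural"
  pg_head <- anaphor$head_lemma %in% c("protein", "gene")
  head_lc <- tolower(anaphor$head_surface)

  if (plural && pg_head) {          # Constraint 1
    pool <- cands[cands$protein_count >= 1L, , drop = FALSE]
    prefs <- list(
      C1a = tolower(pool$head_surface) %in% c("proteins", "genes"),
      C1b = pool$protein_count > 1L)
  } else if (plural) {              # Constraint 2
    pool <- cands
    prefs <- list(
      C2a = tolower(pool$head_surface) == head_lc,
      C2b = pool$bioentity_count > 1L,
      C2c = pool$protein_count > 1L)
  } else if (pg_head) {             # Constraint 3
    pool <- cands[cands$protein_count >= 1L, , drop = FALSE]
    prefs <- list(
      C3a = tolower(pool$head_surface) %in% c("protein", "gene"),
      C3b = pool$protein_count == 1L)
  } else {                          # Constraint 4
    pool <- cands
    prefs <- list(
      C4a = tolower(pool$head_surface) == head_lc,
      C4b = pool$bioentity_count == 1L,
      C4c = pool$protein_count == 1L)
  }
  if (nrow(pool) == 0L) return(NULL)
  for (nm in names(prefs)) {
    sub <- pool[prefs[[nm]], , drop = FALSE]
    if (nrow(sub) > 0L) {
      out <- link_row(doc, anaphor, pick_closest(sub, anaphor$head_gindex))
      attr(out, "fired") <- nm
      return(out)
    }
  }
  NULL
}

#' Resolve every anaphor in a document with the rule system
#'
#' Detects anaphors and candidate NPs, dispatches each anaphor to its
#' type's resolver, and returns at most one link per anaphor. The
#' decision log (anaphor, candidate count, fired rule, antecedent) is
#' attached as \code{attr(, "log")}.
#'
#' @param doc a parsed \code{coref_document}
#' @param gazetteer optional bio-entity term vector
#' @param definite_window sentence window for definite NPs
#' @return link data.frame (possibly empty)
#' @export
resolve_all <- function(doc, gazetteer = NULL, definite_window = 2L) {
  anaphors <- detect_anaphors(doc, gazetteer)
  candidates <- detect_candidates(doc, gazetteer)
  links <- list()
  log <- list()
  if (nrow(anaphors) > 0L) for (i in seq_len(nrow(anaphors))) {
    a <- anaphors[i, , drop = FALSE]
    lk <- switch(a$mention_type,
      relative_pronoun = resolve_relative(a, doc, candidates, gazetteer),
      personal_pronoun = resolve_personal(a, doc, candidates, gazetteer),
      definite_np = resolve_definite(a, doc, candidates, gazetteer,
                                     definite_window))
    fired <- if (is.null(lk)) NA_character_ else
      attr(lk, "fired") %||% a$mention_type
    log[[i]] <- data.frame(
      doc_id = doc$doc_id, anaphor = a$text, anaphor_type = a$mention_type,
      sentence = a$sentence, fired = fired,
      antecedent = if (is.null(lk)) NA_character_ else
        substring(doc$text, lk$antecedent_start + 1L, lk$antecedent_end),
      stringsAsFactors = FALSE)
    if (!is.null(lk)) links[[length(links) + 1L]] <- lk
  }
  out <- if (length(links) == 0L) empty_links() else {
    res <- do.call(rbind, links)
    attr(res, "fired") <- NULL
    res
  }
  attr(out, "log") <- if (length(log) == 0L) NULL else do.call(rbind, log)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
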