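# Link-level evaluation: recall / precision / F1 with strict or
# protein-partial matching, and the five-category error audit
# (MGM / FL / OOR on the missing side, EL / FL / BMB on the spurious side).

ANAPHOR_TYPES <- c("relative_pronoun", "personal_pronoun", "definite_np")

f1_score <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0

# antecedent credit under the given mode; docs is a doc_id-keyed list
antecedent_matches <- function(g, p, docs, mode) {
  if (g$antecedent_start == p$antecedent_start &&
      g$antecedent_end == p$antecedent_end) return(TRUE)
  if (mode != "partial") return(FALSE)
  doc <- docs[[g$doc_id]]
  if (is.null(doc) || nrow(doc$proteins) == 0L) return(FALSE)
  pr <- doc$proteins
  inside_gold <- pr$start >= g$antecedent_start & pr$end <= g$antecedent_end
  covered <- pr$start >= p$antecedent_start & pr$end <= p$antecedent_end
  any(inside_gold & covered)
}

# greedy one-to-one matching; returns logical vectors over gold and pred
match_links <- function(gold, pred, docs = NULL, mode = "strict") {
  mg <- logical(nrow(gold))
  mp <- logical(nrow(pred))
  docs <- docs_by_id(docs)
  if (nrow(pred) > 0L) for (j in seq_len(nrow(pred))) {
    p <- pred[j, , drop = FALSE]
    if (nrow(gold) == 0L) break
    hit <- which(!mg & gold$doc_id == p$doc_id &
                   gold$anaphor_start == p$anaphor_start &
                   gold$anaphor_end == p$anaphor_end)
    for (i in hit) {
      if (antecedent_matches(gold[i, , drop = FALSE], p, docs, mode)) {
        mg[i] <- TRUE
        mp[j] <- TRUE
        break
      }
    }
  }
  list(gold = mg, pred = mp)
}

docs_by_id <- function(docs) {
  if (is.null(docs)) return(list())
  if (inherits(docs, "coref_document")) docs <- list(docs)
  stats::setNames(docs, vapply(docs, `[[`, character(1), "doc_id"))
}

link_types <- function(links) {
  ty <- links$anaphor_type
  ty[is.na(ty)] <- "unknown"
  ty
}

#' Score predicted coreference links against gold links
#'
#' Link-level recall (matched gold / total gold), precision (matched
#' predictions / total predictions) and F1, with a per-anaphor-type
#' breakdown. \code{strict} mode requires exact span equality on both
#' endpoints; \code{partial} mode additionally credits a predicted
#' antecedent that covers a protein annotation lying inside the gold
#' antecedent (the protein-mention criterion of the coreference task
#' tradition; requires \code{docs}).
#'
#' @param gold,pred link data.frames (see \code{\link{read_standoff}})
#' @param docs list of documents (needed for partial mode)
#' @param mode \code{"partial"} (default) or \code{"strict"}
#' @return object of class \code{coref_eval}
#' @export
score_links <- function(gold, pred, docs = NULL,
                        mode = c("partial", "strict")) {
  mode <- match.arg(mode)
  both <- intersect(unique(gold$doc_id), unique(pred$doc_id))
  known <- unique(c(gold$doc_id, pred$doc_id))
  if (!is.null(docs)) {
    ids <- names(docs_by_id(docs))
    if (length(setdiff(known, ids)) > 0L && length(ids) > 0L)
      stop("links reference documents outside the supplied set: ",
           paste(setdiff(known, ids), collapse = ", "))
  }
  m <- match_links(gold, pred, docs, mode)
  n_gold <- nrow(gold); n_pred <- nrow(pred); n_match <- sum(m$gold)
  recall <- if (n_gold > 0L) n_match / n_gold else 1
  precision <- if (n_pred > 0L) n_match / n_pred else if (n_gold > 0L) 0 else 1
  if (n_pred == 0L && n_gold > 0L) precision <- 0

  gty <- link_types(gold); pty <- link_types(pred)
  types <- unique(c(gty, pty))
  per_type <- do.call(rbind, lapply(types, function(tt) {
    ng <- sum(gty == tt); np <- sum(pty == tt)
    nm_g <- sum(m$gold & gty == tt)
    nm_p <- sum(m$pred & pty == tt)
    r <- if (ng > 0L) nm_g / ng else 1
    p <- if (np > 0L) nm_p / np else if (ng > 0L) 0 else 1
    data.frame(type = tt, n_gold = ng, n_pred = np, matched = nm_g,
               recall = r, precision = p, f1 = f1_score(p, r),
               stringsAsFactors = FALSE)
  }))
  structure(list(recall = recall, precision = precision,
                 f1 = f1_score(precision, recall),
                 n_gold = n_gold, n_pred = n_pred, n_matched = n_match,
                 per_type = per_type, mode = mode,
                 matched_gold = m$gold, matched_pred = m$pred),
            class = "coref_eval")
}

#' @export
print.coref_eval <- function(x, ...) {
  cat(sprintf("<coref_eval %s> R %.3f  P %.3f  F1 %.3f  (%d/%d gold, %d pred)\n",
              x$mode, x$recall, x$precision, x$f1, x$n_matched, x$n_gold,
              x$n_pred))
  invisible(x)
}

#' Classify unmatched links into the five error categories
#'
#' Each unmatched gold link becomes, in priority order, MGM (an endpoint
#' was not produced by mention detection, including antecedents detected
#' with missing words), OOR (the true antecedent lies beyond the anaphor
#' type's sentence window) or FL (a resolution error). Each unmatched
#' predicted link becomes EL (the predicted anaphor has no gold link at
#' all), BMB (the predicted antecedent strictly contains the gold one,
#' i.e. covers extra words) or FL.
#'
#' @param gold,pred link data.frames
#' @param mentions mention frame covering all documents (anaphors and
#'   candidates), used to decide MGM
#' @param docs list of documents (sentence spans are needed to locate
#'   gold antecedents for the window check)
#' @param windows named per-type sentence windows
#' @param mode matching mode passed to the link matcher
#' @return object of class \code{coref_error_audit}: per-type count
#'   matrices \code{missing} (MGM/FL/OOR) and \code{spurious}
#'   (EL/FL/BMB) plus reconciliation totals
#' @export
error_audit <- function(gold, pred, mentions, docs,
                        windows = default_windows(), mode = "strict") {
  docs <- docs_by_id(docs)
  m <- match_links(gold, pred, docs, mode)
  gty <- link_types(gold)
  # infer types for gold links lacking one: by detected anaphor span, else
  # "others" (anaphor kinds the system does not handle)
  for (i in which(gty == "unknown")) {
    hit <- mentions$doc_id == gold$doc_id[i] &
      mentions$mention_type %in% ANAPHOR_TYPES &
      mentions$start == gold$anaphor_start[i] &
      mentions$end == gold$anaphor_end[i]
    gty[i] <- if (any(hit)) mentions$mention_type[which(hit)[1L]] else
      "others"
  }
  types <- unique(c(ANAPHOR_TYPES, "others", gty, link_types(pred)))
  zero <- function(cats)
    matrix(0L, nrow = length(cats), ncol = length(types),
           dimnames = list(cats, types))
  missing <- zero(c("MGM", "FL", "OOR"))
  spurious <- zero(c("EL", "BMB", "FL"))

  for (i in which(!m$gold)) {
    g <- gold[i, , drop = FALSE]
    tt <- gty[i]
    ana_det <- any(mentions$doc_id == g$doc_id &
                     mentions$mention_type %in% ANAPHOR_TYPES &
                     mentions$start == g$anaphor_start &
                     mentions$end == g$anaphor_end)
    ant_det <- any(mentions$doc_id == g$doc_id &
                     mentions$mention_type == "np_candidate" &
                     mentions$start == g$antecedent_start &
                     mentions$end == g$antecedent_end)
    if (!ana_det || !ant_det) {
      missing["MGM", tt] <- missing["MGM", tt] + 1L
      next
    }
    oor <- FALSE
    doc <- docs[[g$doc_id]]
    if (!is.null(doc) && tt %in% names(windows)) {
      sa <- doc_sentence_of(doc, g$anaphor_start, g$anaphor_end)
      st <- doc_sentence_of(doc, g$antecedent_start, g$antecedent_end)
      if (!is.na(sa) && !is.na(st) && sa - st > windows[[tt]]) oor <- TRUE
    }
    if (oor) missing["OOR", tt] <- missing["OOR", tt] + 1L
    else missing["FL", tt] <- missing["FL", tt] + 1L
  }

  pty <- link_types(pred)
  for (j in which(!m$pred)) {
    p <- pred[j, , drop = FALSE]
    tt <- pty[j]
    g_same <- gold[gold$doc_id == p$doc_id &
                     gold$anaphor_start == p$anaphor_start &
                     gold$anaphor_end == p$anaphor_end, , drop = FALSE]
    if (nrow(g_same) == 0L) {
      spurious["EL", tt] <- spurious["EL", tt] + 1L
      next
    }
    bmb <- any(p$antecedent_start <= g_same$antecedent_start &
                 p$antecedent_end >= g_same$antecedent_end &
                 (p$antecedent_end - p$antecedent_start) >
                   (g_same$antecedent_end - g_same$antecedent_start))
    if (bmb) spurious["BMB", tt] <- spurious["BMB", tt] + 1L
    else spurious["FL", tt] <- spurious["FL", tt] + 1L
  }

  structure(list(missing = missing, spurious = spurious,
                 n_gold = nrow(gold), n_pred = nrow(pred),
                 n_matched = sum(m$gold),
                 missing_total = sum(missing),
                 spurious_total = sum(spurious)),
            class = "coref_error_audit")
}

#' @export
print.coref_error_audit <- function(x, ...) {
  cat("<coref_error_audit> missing", x$missing_total,
      "(of", x$n_gold, "gold), spurious", x$spurious_total,
      "(of", x$n_pred, "pred)\n")
  print(x$missing); print(x$spurious)
  invisible(x)
}

#' Fill in anaphor types on a link frame from detected mentions
#' @param links link data.frame
#' @param mentions mention frame (with doc_id)
#' @return links with \code{anaphor_type} populated where a detected
#'   anaphor has the same span
#' @export
attach_link_types <- function(links, mentions) {
  if (nrow(links) == 0L) return(links)
  for (i in seq_len(nrow(links))) {
    if (!is.na(links$anaphor_type[i])) next
    hit <- mentions$doc_id == links$doc_id[i] &
      mentions$mention_type %in% ANAPHOR_TYPES &
      mentions$start == links$anaphor_start[i] &
      mentions$end == links$anaphor_end[i]
    if (any(hit))
      links$anaphor_type[i] <- mentions$mention_type[which(hit)[1L]]
  }
  links
}
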