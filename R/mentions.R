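# Mention detection: the three anaphor types (relative pronoun, personal
# pronoun, definite NP) and candidate-antecedent NPs, extracted from the
# constituency parses with the heuristic filters described in the vignette.

DEFINITE_HEADS <- c("protein", "gene", "factor", "element", "receptor",
                    "complex", "construct")
THIRD_PERSON_PRONOUNS <- c("it", "its", "itself", "they", "them", "their",
                           "themselves")
PLURAL_PRONOUNS <- c("they", "them", "their", "themselves")
DEFINITE_DETERMINERS <- c("the", "this", "that", "these", "those")

default_pleonastic_patterns <- function() {
  list(c("^(has|have|had|is|was)$", "^been$"),
       c("^(seems|appears)$"),
       c("^(is|was)$", "^(possible|likely)$"))
}

#' Read a bio-entity gazetteer file
#'
#' One term per line; matching is case-insensitive. Lines that are empty
#' or start with \code{#} are ignored.
#' @param path file path
#' @return character vector of terms
#' @export
read_gazetteer <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Head word of a noun phrase
#'
#' Returns the rightmost noun-tagged leaf of the NP occurring before any
#' postmodifier boundary (a PP or SBAR child, or a comma/colon leaf). When
#' the bounded region has no noun leaf, the rightmost leaf is returned and
#' flagged via \code{attr(, "unknown_head")}.
#'
#' @param tree a \code{parse_tree}
#' @param node_id id of an NP node in \code{tree}
#' @param tokens the sentence token data.frame
#' @return one-row token data.frame with attribute \code{unknown_head}
#' @export
head_word <- function(tree, node_id, tokens) {
  cids <- tree$children[[node_id]]
  if (length(cids) == 0L) {           # NP written directly as a leaf
    idx <- tree$nodes$token[node_id]
    tok <- tokens[tokens$index == idx, , drop = FALSE]
    attr(tok, "unknown_head") <- !(tokens$pos[tokens$index == idx] %in%
                                     NOUN_TAGS)
    return(tok)
  }
  boundary <- vapply(cids, function(id) {
    lb <- tree$nodes$label[id]
    lb %in% c("PP", "SBAR") || (tree$nodes$leaf[id] && lb %in% c(",", ":"))
  }, logical(1))
  keep <- if (any(boundary)) cids[seq_len(which(boundary)[1L] - 1L)] else cids
  if (length(keep) == 0L) keep <- cids   # NP starting with a postmodifier
  lo <- min(tree$nodes$tok_start[keep])
  hi <- max(tree$nodes$tok_end[keep])
  lv <- tree$nodes[tree$nodes$leaf & tree$nodes$token >= lo &
                     tree$nodes$token <= hi, , drop = FALSE]
  nouns <- lv[lv$label %in% NOUN_TAGS, , drop = FALSE]
  unknown <- nrow(nouns) == 0L
  pick <- if (unknown) lv[which.max(lv$token), ] else
    nouns[which.max(nouns$token), ]
  tok <- tokens[tokens$index == pick$token, , drop = FALSE]
  attr(tok, "unknown_head") <- unknown
  tok
}

#' Grammatical number of a mention
#'
#' Plural for NNS/NNPS heads, plural third-person pronouns, and
#' coordinated NPs; singular for NN/NNP heads and it/its/itself;
#' unknown otherwise (e.g. a CD head).
#'
#' @param head_surface head token surface form
#' @param head_pos head token POS tag
#' @param coordinated is the mention a coordinate NP?
#' @return one of \code{"singular"}, \code{"plural"}, \code{"unknown"}
#' @export
grammatical_number <- function(head_surface, head_pos, coordinated = FALSE) {
  if (isTRUE(coordinated)) return("plural")
  s <- tolower(head_surface)
  if (head_pos %in% c("PRP", "PRP$")) {
    if (s %in% PLURAL_PRONOUNS) return("plural")
    if (s %in% c("it", "its", "itself")) return("singular")
    return("unknown")
  }
  if (head_pos %in% c("NNS", "NNPS")) return("plural")
  if (head_pos %in% c("NN", "NNP")) return("singular")
  "unknown"
}

#' Protein and bio-entity counts inside a mention span
#'
#' \code{protein_count} is the number of .a1 protein annotations whose
#' character span lies inside the mention; \code{bioentity_count} adds
#' case-insensitive whole-word matches of gazetteer terms (so with no
#' gazetteer the two counts coincide).
#'
#' @param m list or one-row data.frame with \code{start}/\code{end}
#'   character offsets
#' @param doc the containing \code{coref_document}
#' @param gazetteer character vector of non-protein bio-entity terms
#' @return named integer vector \code{c(protein_count, bioentity_count)}
#' @export
entity_counts <- function(m, doc, gazetteer = NULL) {
  pc <- 0L
  if (nrow(doc$proteins) > 0L)
    pc <- sum(doc$proteins$start >= m$start & doc$proteins$end <= m$end)
  gc <- 0L
  if (length(gazetteer) > 0L) {
    seg <- substring(doc$text, m$start + 1L, m$end)
    for (term in gazetteer) {
      pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term),
                    "\\b")
      hits <- gregexpr(pat, seg, ignore.case = TRUE)[[1]]
      if (hits[1L] > 0L) gc <- gc + length(hits)
    }
  }
  c(protein_count = pc, bioentity_count = pc + gc)
}

# Build one mention row for a parse node (NP) or leaf (pronoun).
mention_row <- function(doc, sent, node_id, type, gazetteer) {
  tree <- sent$parse
  toks <- sent$tokens
  nd <- tree$nodes[node_id, ]
  tok_start <- nd$tok_start
  tok_end <- nd$tok_end
  start <- toks$start[toks$index == tok_start]
  end <- toks$end[toks$index == tok_end]
  coord <- identical(pt_coordination(tree, node_id), "NP")
  if (nd$leaf) {
    head_tok <- toks[toks$index == nd$token, , drop = FALSE]
  } else {
    head_tok <- head_word(tree, node_id, toks)
  }
  m <- data.frame(
    doc_id = doc$doc_id, mention_type = type, sentence = sent$index,
    tok_start = tok_start, tok_end = tok_end, start = start, end = end,
    text = substring(doc$text, start + 1L, end),
    node_id = node_id,
    head_index = head_tok$index, head_surface = head_tok$surface,
    head_lemma = head_tok$lemma, head_pos = head_tok$pos,
    head_gindex = head_tok$gindex,
    stringsAsFactors = FALSE)
  m$number <- grammatical_number(head_tok$surface, head_tok$pos, coord)
  cnt <- entity_counts(m, doc, gazetteer)
  m$protein_count <- cnt[["protein_count"]]
  m$bioentity_count <- cnt[["bioentity_count"]]
  m
}

empty_mentions <- function() {
  data.frame(doc_id = character(), mention_type = character(),
             sentence = integer(), tok_start = integer(),
             tok_end = integer(), start = integer(), end = integer(),
             text = character(), node_id = integer(),
             head_index = integer(), head_surface = character(),
             head_lemma = character(), head_pos = character(),
             head_gindex = integer(), number = character(),
             protein_count = integer(), bioentity_count = integer(),
             stringsAsFactors = FALSE)
}

is_pleonastic_it <- function(sent, leaf_token, patterns) {
  toks <- sent$tokens
  after <- tolower(toks$surface[toks$index > leaf_token])
  for (pat in patterns) {
    if (length(after) < length(pat)) next
    if (all(mapply(grepl, pat, after[seq_along(pat)]))) return(TRUE)
  }
  FALSE
}

# NP nodes that pass the candidate filter: no clausal descendant and no
# NP ancestor within the same clause.
candidate_np_nodes <- function(tree) {
  nps <- which(tree$nodes$label == "NP" & !tree$nodes$leaf)
  nps[!vapply(nps, function(id) tree$nodes$clause_below[id] ||
                pt_surrounded_np(tree, id), logical(1))]
}

#' Detect anaphoric mentions
#'
#' Extracts relative pronouns (WDT/WP leaves), third-person personal
#' pronouns with pleonastic \emph{it} removed, and definite NPs with a
#' definite or demonstrative determiner whose head word is one of the
#' configured nouns (protein, gene, factor, element, receptor, complex,
#' construct; singular or plural).
#'
#' @param doc a parsed \code{coref_document}
#' @param gazetteer optional character vector of non-protein bio-entity
#'   terms (see \code{\link{entity_counts}})
#' @param heads head-word lemma list for definite-NP anaphors
#' @param pleonastic_patterns list of regex sequences matched against the
#'   tokens following \emph{it}
#' @return mention data.frame ordered by position
#' @export
detect_anaphors <- function(doc, gazetteer = NULL, heads = DEFINITE_HEADS,
                            pleonastic_patterns =
                              default_pleonastic_patterns()) {
  if (length(doc$sentences) == 0L)
    stop(doc$doc_id, ": document has no parsed sentences")
  out <- list()
  for (sent in doc$sentences) {
    tree <- sent$parse
    nodes <- tree$nodes
    # relative pronouns
    for (id in which(nodes$leaf & nodes$label %in% c("WDT", "WP")))
      out[[length(out) + 1L]] <-
        mention_row(doc, sent, id, "relative_pronoun", gazetteer)
    # personal pronouns
    for (id in which(nodes$leaf & nodes$label %in% c("PRP", "PRP$"))) {
      surf <- tolower(nodes$surface[id])
      if (!surf %in% THIRD_PERSON_PRONOUNS) next
      if (surf == "it" &&
          is_pleonastic_it(sent, nodes$token[id], pleonastic_patterns)) next
      out[[length(out) + 1L]] <-
        mention_row(doc, sent, id, "personal_pronoun", gazetteer)
    }
    # definite NPs
    for (id in candidate_np_nodes(tree)) {
      first_leaf <- tree$nodes[tree$nodes$leaf &
                                 tree$nodes$token == nodes$tok_start[id], ]
      if (!(first_leaf$label == "DT" &&
            tolower(first_leaf$surface) %in% DEFINITE_DETERMINERS)) next
      m <- mention_row(doc, sent, id, "definite_np", gazetteer)
      if (!(m$head_lemma %in% heads || tolower(m$head_surface) %in% heads))
        next
      out[[length(out) + 1L]] <- m
    }
  }
  if (length(out) == 0L) return(empty_mentions())
  res <- do.call(rbind, out)
  res[order(res$sentence, res$tok_start, res$tok_end), , drop = FALSE]
}

#' Detect candidate-antecedent noun phrases
#'
#' Candidates are NP nodes with no clausal (S/SBAR) descendant and no NP
#' ancestor within the same clause, i.e. the maximal clause-free NPs; each
#' is annotated with grammatical number and protein/bio-entity counts.
#'
#' @inheritParams detect_anaphors
#' @return mention data.frame of type \code{np_candidate}, ordered by
#'   position
#' @export
detect_candidates <- function(doc, gazetteer = NULL) {
  if (length(doc$sentences) == 0L)
    stop(doc$doc_id, ": document has no parsed sentences")
  out <- list()
  for (sent in doc$sentences)
    for (id in candidate_np_nodes(sent$parse))
      out[[length(out) + 1L]] <-
        mention_row(doc, sent, id, "np_candidate", gazetteer)
  if (length(out) == 0L) return(empty_mentions())
  res <- do.call(rbind, out)
  res[order(res$sentence, res$tok_start, res$tok_end), , drop = FALSE]
}
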