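# Document container: text + sentences (tokens, parse) + protein annotations
# + optional gold links. All character offsets are 0-based half-open,
# matching BioNLP-ST standoff convention.

empty_links <- function() {
  data.frame(doc_id = character(), anaphor_start = integer(),
             anaphor_end = integer(), anaphor_type = character(),
             antecedent_start = integer(), antecedent_end = integer(),
             stringsAsFactors = FALSE)
}

empty_proteins <- function() {
  data.frame(ann_id = character(), label = character(),
             start = integer(), end = integer(), text = character(),
             stringsAsFactors = FALSE)
}

#' Assemble a document from raw text and per-sentence parses
#'
#' Tokens are taken from the parse leaves and aligned to \code{text} by a
#' left-to-right greedy exact match, so the text may use any whitespace
#' layout. Sentence spans run from the first to the last token.
#'
#' @param doc_id document identifier
#' @param text full document text
#' @param ptb character vector of bracketed parse strings, one per sentence
#' @param proteins data.frame (ann_id, label, start, end, text) or NULL
#' @param gold_links data.frame as in \code{\link{read_standoff}} or NULL
#' @return object of class \code{coref_document}
#' @export
build_document <- function(doc_id, text, ptb, proteins = NULL,
                           gold_links = NULL) {
  sentences <- vector("list", length(ptb))
  cursor <- 1L
  gindex <- 0L
  for (i in seq_along(ptb)) {
    tree <- read_bracketed_parse(ptb[i])
    toks <- pt_tokens(tree)
    starts <- integer(nrow(toks)); ends <- integer(nrow(toks))
    for (j in seq_len(nrow(toks))) {
      hit <- regexpr(toks$surface[j], substring(text, cursor), fixed = TRUE)
      if (hit < 0L)
        stop("document ", doc_id, ": token '", toks$surface[j],
             "' (sentence ", i - 1L, ") not found in text")
      starts[j] <- cursor + hit - 2L          # 0-based
      ends[j] <- starts[j] + nchar(toks$surface[j])
      cursor <- ends[j] + 1L
    }
    toks$start <- starts
    toks$end <- ends
    toks$gindex <- gindex + seq_len(nrow(toks)) - 1L
    gindex <- gindex + nrow(toks)
    sentences[[i]] <- list(index = i - 1L, start = starts[1L],
                           end = ends[length(ends)], tokens = toks,
                           parse = tree)
  }
  doc <- structure(list(doc_id = doc_id, text = text, sentences = sentences,
                        proteins = if (is.null(proteins)) empty_proteins()
                                   else proteins,
                        gold_links = gold_links),
                   class = "coref_document")
  validate_document(doc)
  doc
}

#' Validate a document's structural invariants
#'
#' Checks that sentence spans are ordered, disjoint and within the text,
#' that token spans tile sentences and match their surfaces, that parse
#' leaves correspond one-to-one with tokens, and that every protein span
#' lies inside exactly one sentence.
#'
#' @param doc a \code{coref_document}
#' @return the document, invisibly; stops on violation
#' @export
validate_document <- function(doc) {
  n <- nchar(doc$text)
  last_end <- -1L
  for (s in doc$sentences) {
    if (s$start < 0L || s$end > n || s$start >= s$end)
      stop(doc$doc_id, ": sentence ", s$index, " span out of bounds")
    if (s$start < last_end)
      stop(doc$doc_id, ": sentence ", s$index, " overlaps previous")
    last_end <- s$end
    tk <- s$tokens
    if (any(tk$start < s$start | tk$end > s$end))
      stop(doc$doc_id, ": token outside sentence ", s$index)
    if (any(diff(tk$start) <= 0) || any(tk$end[-nrow(tk)] > tk$start[-1L]))
      stop(doc$doc_id, ": token spans overlap in sentence ", s$index)
    got <- substring(doc$text, tk$start + 1L, tk$end)
    if (any(got != tk$surface))
      stop(doc$doc_id, ": token surface/span mismatch in sentence ", s$index)
    nl <- sum(s$parse$nodes$leaf)
    if (nl != nrow(tk))
      stop(doc$doc_id, ": parse/token count mismatch in sentence ", s$index)
  }
  if (nrow(doc$proteins) > 0L) {
    for (k in seq_len(nrow(doc$proteins))) {
      p <- doc$proteins[k, ]
      if (p$start < 0L || p$end > n || p$start >= p$end)
        stop(doc$doc_id, ": protein ", p$ann_id, " span out of bounds")
      inside <- vapply(doc$sentences, function(s)
        p$start >= s$start && p$end <= s$end, logical(1))
      if (sum(inside) != 1L)
        stop(doc$doc_id, ": protein ", p$ann_id,
             " not inside exactly one sentence")
      if (substring(doc$text, p$start + 1L, p$end) != p$text)
        stop(doc$doc_id, ": protein ", p$ann_id, " text/span mismatch")
    }
    if (anyDuplicated(doc$proteins$ann_id))
      stop(doc$doc_id, ": duplicate protein annotation ids")
  }
  if (!is.null(doc$gold_links) && nrow(doc$gold_links) > 0L) {
    g <- doc$gold_links
    if (any(g$antecedent_start > g$anaphor_start))
      stop(doc$doc_id, ": gold antecedent begins after its anaphor")
    if (any(g$anaphor_start == g$antecedent_start &
            g$anaphor_end == g$antecedent_end))
      stop(doc$doc_id, ": gold link with identical anaphor/antecedent span")
  }
  invisible(doc)
}

#' @export
print.coref_document <- function(x, ...) {
  cat("<coref_document>", x$doc_id, "-", length(x$sentences), "sentences,",
      nrow(x$proteins), "proteins,",
      if (is.null(x$gold_links)) "no gold links"
      else paste(nrow(x$gold_links), "gold links"), "\n")
  invisible(x)
}

# flat token table across sentences: sentence, index, gindex, surface,
# lemma, pos, start, end
doc_tokens <- function(doc) {
  do.call(rbind, lapply(doc$sentences, function(s) {
    tk <- s$tokens
    tk$sentence <- s$index
    tk
  }))
}

# sentence index containing a character span, or NA
doc_sentence_of <- function(doc, start, end) {
  for (s in doc$sentences)
    if (start >= s$start && end <= s$end) return(s$index)
  NA_integer_
}
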