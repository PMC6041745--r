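# Constituent labels treated as clause boundaries throughout the package.
CLAUSE_LABELS <- c("S", "SBAR")
NOUN_TAGS <- c("NN", "NNS", "NNP", "NNPS")

IRREGULAR_LEMMA <- c(
  is = "be", was = "be", are = "be", were = "be", been = "be", being = "be",
  am = "be", has = "have", have = "have", had = "have", does = "do", did = "do"
)

#' Crude fallback lemmatizer
#'
#' Used only when the input bundle does not carry explicit lemmas
#' (leaves may be written as \code{surface|lemma}). Handles regular noun
#' plurals, third-person verb forms and a short irregular table; everything
#' else is lowercased.
#'
#' @param surface token surface form
#' @param pos Penn Treebank POS tag
#' @return lemma string
#' @export
simple_lemma <- function(surface, pos) {
  s <- tolower(surface)
  if (s %in% names(IRREGULAR_LEMMA)) return(unname(IRREGULAR_LEMMA[s]))
  if (pos %in% c("NNS", "NNPS", "VBZ")) {
    if (grepl("ies$", s) && nchar(s) > 4) {
      s <- sub("ies$", "y", s)
    } else if (grepl("(xes|ches|shes|sses|zes)$", s)) {
      s <- sub("es$", "", s)
    } else if (grepl("s$", s) && !grepl("ss$", s)) {
      s <- sub("s$", "", s)
    }
  }
  s
}

#' Read a Penn-style bracketed constituency parse
#'
#' Parses one bracketed tree string into a flat node table. Leaves are
#' written \code{(POS surface)} or \code{(POS surface|lemma)}; when no
#' explicit lemma is given, \code{\link{simple_lemma}} supplies one.
#'
#' Token and node spans are 0-based inclusive token-index intervals; a
#' node's span is the union of its children's spans and each leaf carries
#' exactly one token index.
#'
#' @param s bracketed tree string, balanced, one sentence
#' @param tokens optional data.frame with a \code{surface} column; when
#'   given, the leaf count and surfaces are validated against it
#' @return an object of class \code{parse_tree}: a list with \code{nodes}
#'   (data.frame: id, parent, label, leaf, token, tok_start, tok_end,
#'   surface, lemma, depth, clause_below) and \code{children} (list of
#'   integer child-id vectors, in surface order)
#' @export
read_bracketed_parse <- function(s, tokens = NULL) {
  raw <- regmatches(s, gregexpr("\\(|\\)|[^()[:space:]]+", s))[[1]]
  if (length(raw) == 0L) stop("empty parse string")

  # shift-reduce over the bracket stream
  stack <- list()
  expect_label <- FALSE
  root <- NULL
  for (tk in raw) {
    if (tk == "(") {
      stack[[length(stack) + 1L]] <- list(label = NA_character_,
                                          children = list(),
                                          words = character())
      expect_label <- TRUE
    } else if (tk == ")") {
      n <- length(stack)
      if (n == 0L) stop("unbalanced brackets: extra ')'")
      nd <- stack[[n]]
      stack[[n]] <- NULL
      if (is.na(nd$label)) stop("node without label")
      if (length(nd$words) > 1L)
        stop("leaf with multiple words: ", paste(nd$words, collapse = " "))
      if (length(nd$words) == 1L && length(nd$children) > 0L)
        stop("mixed leaf/constituent node at '", nd$label, "'")
      if (length(nd$words) == 0L && length(nd$children) == 0L)
        stop("empty constituent '", nd$label, "'")
      if (length(stack) == 0L) {
        if (!is.null(root)) stop("multiple root trees in one string")
        root <- nd
      } else {
        stack[[length(stack)]]$children <-
          c(stack[[length(stack)]]$children, list(nd))
      }
    } else if (expect_label) {
      stack[[length(stack)]]$label <- tk
      expect_label <- FALSE
    } else {
      if (length(stack) == 0L) stop("word outside brackets: '", tk, "'")
      stack[[length(stack)]]$words <- c(stack[[length(stack)]]$words, tk)
    }
  }
  if (length(stack) > 0L) stop("unbalanced brackets: ", length(stack),
                               " unclosed '('")
  if (is.null(root)) stop("no tree found")

  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$children <- list()
  env$leaf_i <- 0L

  flatten <- function(nd, parent, depth) {
    id <- length(env$rows) + 1L
    env$rows[[id]] <- list(id = id, parent = parent, label = nd$label,
                           leaf = FALSE, token = NA_integer_,
                           tok_start = NA_integer_, tok_end = NA_integer_,
                           surface = NA_character_, lemma = NA_character_,
                           depth = depth, clause_below = FALSE)
    env$children[[id]] <- integer()
    if (length(nd$words) == 1L) {
      w <- nd$words
      lemma <- NA_character_
      if (grepl("|", w, fixed = TRUE)) {
        parts <- strsplit(w, "|", fixed = TRUE)[[1]]
        if (length(parts) != 2L) stop("bad leaf annotation: '", w, "'")
        w <- parts[1L]; lemma <- parts[2L]
      }
      if (is.na(lemma)) lemma <- simple_lemma(w, nd$label)
      ti <- env$leaf_i
      env$leaf_i <- env$leaf_i + 1L
      env$rows[[id]]$leaf <- TRUE
      env$rows[[id]]$token <- ti
      env$rows[[id]]$tok_start <- ti
      env$rows[[id]]$tok_end <- ti
      env$rows[[id]]$surface <- w
      env$rows[[id]]$lemma <- lemma
      return(FALSE)
    }
    clause <- FALSE
    for (ch in nd$children) {
      cid <- length(env$rows) + 1L
      env$children[[id]] <- c(env$children[[id]], cid)
      sub_clause <- flatten(ch, id, depth + 1L)
      clause <- clause || sub_clause || ch$label %in% CLAUSE_LABELS
    }
    cids <- env$children[[id]]
    env$rows[[id]]$tok_start <-
      min(vapply(env$rows[cids], `[[`, integer(1), "tok_start"))
    env$rows[[id]]$tok_end <-
      max(vapply(env$rows[cids], `[[`, integer(1), "tok_end"))
    env$rows[[id]]$clause_below <- clause
    clause
  }
  flatten(root, NA_integer_, 0L)

  nodes <- do.call(rbind, lapply(env$rows, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  tree <- structure(list(nodes = nodes, children = env$children),
                    class = "parse_tree")

  if (!is.null(tokens)) {
    lv <- nodes[nodes$leaf, , drop = FALSE]
    lv <- lv[order(lv$token), , drop = FALSE]
    if (nrow(lv) != nrow(tokens))
      stop("leaf count (", nrow(lv), ") does not match token count (",
           nrow(tokens), ")")
    bad <- which(lv$surface != tokens$surface)
    if (length(bad) > 0L)
      stop("leaf surface mismatch at token ", bad[1L] - 1L, ": '",
           lv$surface[bad[1L]], "' vs '", tokens$surface[bad[1L]], "'")
  }
  tree
}

#' @export
print.parse_tree <- function(x, ...) {
  cat("<parse_tree>", sum(x$nodes$leaf), "tokens,",
      nrow(x$nodes), "nodes\n")
  invisible(x)
}

# ---- node utilities ---------------------------------------------------------

pt_root <- function(tree) which(is.na(tree$nodes$parent))[1L]

pt_leaf_of_token <- function(tree, token) {
  id <- which(tree$nodes$leaf & tree$nodes$token == token)
  if (length(id) != 1L) stop("no unique leaf for token ", token)
  id
}

# ancestor ids from immediate parent to root
pt_ancestors <- function(tree, id) {
  out <- integer()
  p <- tree$nodes$parent[id]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tree$nodes$parent[p]
  }
  out
}

#' Number of edges between two nodes through their lowest common ancestor
#' @param tree a \code{parse_tree}
#' @param id1,id2 node ids
#' @return integer edge count
#' @export
pt_path_length <- function(tree, id1, id2) {
  a1 <- c(id1, pt_ancestors(tree, id1))
  a2 <- c(id2, pt_ancestors(tree, id2))
  lca <- a1[a1 %in% a2][1L]
  d <- tree$nodes$depth
  (d[id1] - d[lca]) + (d[id2] - d[lca])
}

# NP nodes rejected as "surrounded" when an NP ancestor exists with no
# clause boundary (S/SBAR) strictly between the two NPs.
pt_surrounded_np <- function(tree, id) {
  p <- tree$nodes$parent[id]
  while (!is.na(p)) {
    lb <- tree$nodes$label[p]
    if (lb %in% "NP") return(TRUE)
    if (lb %in% CLAUSE_LABELS) return(FALSE)
    p <- tree$nodes$parent[p]
  }
  FALSE
}

# Coordinate structure: >= 2 same-category children (NP/VP/S) with a CC or
# comma leaf among the children. Returns the category or NA.
pt_coordination <- function(tree, id) {
  if (tree$nodes$leaf[id]) return(NA_character_)
  cids <- tree$children[[id]]
  labs <- tree$nodes$label[cids]
  if (!any(labs %in% c("CC", ","))) return(NA_character_)
  for (cat in c("NP", "VP", "S")) {
    if (sum(labs == cat) >= 2L) return(cat)
  }
  NA_character_
}

pt_first_conjunct <- function(tree, id, cat) {
  cids <- tree$children[[id]]
  cids[tree$nodes$label[cids] == cat][1L]
}

#' Serialize a parse tree back to a bracketed string
#'
#' Leaves whose lemma differs from the fallback lemmatizer's output are
#' written as \code{surface|lemma} so that a write/read cycle is exact.
#' @param tree a \code{parse_tree}
#' @return single bracketed string
#' @export
deparse_parse <- function(tree) {
  rec <- function(id) {
    nd <- tree$nodes[id, ]
    if (nd$leaf) {
      w <- nd$surface
      if (!identical(nd$lemma, simple_lemma(nd$surface, nd$label)))
        w <- paste0(w, "|", nd$lemma)
      return(paste0("(", nd$label, " ", w, ")"))
    }
    paste0("(", nd$label, " ",
           paste(vapply(tree$children[[id]], rec, character(1)),
                 collapse = " "), ")")
  }
  rec(pt_root(tree))
}

# token data.frame (index, surface, lemma, pos) from the tree's leaves
pt_tokens <- function(tree) {
  lv <- tree$nodes[tree$nodes$leaf, , drop = FALSE]
  lv <- lv[order(lv$token), , drop = FALSE]
  data.frame(index = lv$token, surface = lv$surface, lemma = lv$lemma,
             pos = lv$label, stringsAsFactors = FALSE)
}
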