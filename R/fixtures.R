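# Synthetic annotated-corpus generator. Documents are built from
# hand-written bracketed-tree templates with slot-filling (generic protein
# symbols, head nouns), so fixtures are deterministic and parser-free, and
# the correct resolution of every gold link is known by construction.

C1_HEADS <- c("proteins", "genes")
C2_HEADS <- c("factors", "elements", "receptors", "complexes", "constructs")
C3_HEADS <- c("protein", "gene")
C4_HEADS <- c("factor", "element", "receptor", "complex", "construct")

FILLER_SENTENCES <- c(
  "(S (NP (DT The) (NN experiment)) (VP (VBD was) (VP (VBN repeated))) (. .))",
  "(S (NP (DT The) (NNS results)) (VP (VBD were) (ADJP (JJ consistent))) (. .))",
  "(S (NP (DT The) (NN assay)) (VP (VBD was) (VP (VBN performed) (ADVP (RB twice)))) (. .))")

tpl_link <- function(a_sent, a_from, a_to, t_sent, t_from, t_to, type) {
  data.frame(a_sent = a_sent, a_from = a_from, a_to = a_to,
             t_sent = t_sent, t_from = t_from, t_to = t_to,
             type = type, stringsAsFactors = FALSE)
}

tpl_prot <- function(sentence, tok) {
  data.frame(sentence = sentence, tok_from = tok, tok_to = tok,
             stringsAsFactors = FALSE)
}

no_links <- function()
  tpl_link(integer(), integer(), integer(), integer(), integer(),
           integer(), character())

# Each template takes protein symbols p[1..3] and gazetteer terms g[1..]
# and returns ptb strings plus token-coordinate proteins and gold links.
fixture_templates <- function() {
  def_anaphor <- function(det, head_pl) {
    tag <- if (grepl("s$", head_pl) && !head_pl %in% C3_HEADS) "NNS" else "NN"
    vb <- if (tag == "NNS") "VBP" else "VBZ"
    sprintf("(S (NP (DT %s) (%s %s)) (VP (%s %s) (ADJP (JJ active))) (. .))",
            det, tag, head_pl, vb, if (tag == "NNS") "are" else "is")
  }
  list(
    relative = function(p, g) {
      if (stats::runif(1) < 0.5) {
        list(ptb = sprintf(
          "(S (NP (DT The) (NN %s) (NN gene)) (SBAR (WHNP (WDT that)) (S (VP (VBZ activates) (NP (NN %s))))) (VP (VBZ is) (ADJP (JJ active))) (. .))",
          p[1], p[2]),
          proteins = rbind(tpl_prot(0L, 1L), tpl_prot(0L, 5L)),
          links = tpl_link(0L, 3L, 3L, 0L, 0L, 2L, "relative_pronoun"))
      } else {
        list(ptb = sprintf(
          "(S (NP (NN %s)) (VP (VBZ encodes) (NP (DT the) (NN %s) (NN enzyme)) (SBAR (WHNP (WDT which)) (S (VP (VBZ binds) (NP (NN %s)))))) (. .))",
          p[1], p[2], p[3]),
          proteins = rbind(tpl_prot(0L, 0L), tpl_prot(0L, 3L),
                           tpl_prot(0L, 7L)),
          links = tpl_link(0L, 5L, 5L, 0L, 2L, 4L, "relative_pronoun"))
      }
    },
    personal_same_sentence = function(p, g) {
      list(ptb = sprintf(
        "(S (NP (DT The) (NN %s) (NN enzyme)) (VP (VBZ binds) (NP (NN %s)) (SBAR (IN because) (S (NP (PRP it)) (VP (VBZ activates) (NP (NN %s)))))) (. .))",
        p[1], p[2], p[3]),
        proteins = rbind(tpl_prot(0L, 1L), tpl_prot(0L, 4L),
                         tpl_prot(0L, 8L)),
        links = tpl_link(0L, 6L, 6L, 0L, 0L, 2L, "personal_pronoun"))
    },
    personal_coordination = function(p, g) {
      if (stats::runif(1) < 0.5) {
        list(ptb = sprintf(
          "(S (S (NP (NN %s)) (VP (VBZ binds) (NP (DT the) (NN %s) (NN enzyme)))) (CC and) (S (NP (PRP it)) (VP (VBZ activates) (NP (NN %s)))) (. .))",
          p[1], p[2], p[3]),
          proteins = rbind(tpl_prot(0L, 0L), tpl_prot(0L, 3L),
                           tpl_prot(0L, 8L)),
          links = tpl_link(0L, 6L, 6L, 0L, 0L, 0L, "personal_pronoun"))
      } else {
        list(ptb = sprintf(
          "(S (S (NP (NP (NN %s)) (CC and) (NP (NN %s))) (VP (VBP interact))) (CC and) (S (NP (PRP they)) (VP (VBP activate) (NP (NN %s)))) (. .))",
          p[1], p[2], p[3]),
          proteins = rbind(tpl_prot(0L, 0L), tpl_prot(0L, 2L),
                           tpl_prot(0L, 7L)),
          links = tpl_link(0L, 5L, 5L, 0L, 0L, 2L, "personal_pronoun"))
      }
    },
    personal_prev_sentence = function(p, g) {
      if (stats::runif(1) < 0.5) {
        list(ptb = c(sprintf(
          "(S (NP (DT The) (NN %s) (NN enzyme)) (VP (VBZ inhibits) (NP (NN %s))) (. .))",
          p[1], p[2]),
          sprintf(
            "(S (ADVP (RB Moreover)) (, ,) (NP (PRP it)) (VP (VBZ represses) (NP (NN %s))) (. .))",
            p[3])),
          proteins = rbind(tpl_prot(0L, 1L), tpl_prot(0L, 4L),
                           tpl_prot(1L, 4L)),
          links = tpl_link(1L, 2L, 2L, 0L, 0L, 2L, "personal_pronoun"))
      } else {
        list(ptb = c(sprintf(
          "(S (NP (NP (NN %s)) (CC and) (NP (NN %s))) (VP (VBP interact) (ADVP (RB strongly))) (. .))",
          p[1], p[2]),
          sprintf(
            "(S (ADVP (RB Moreover)) (, ,) (NP (PRP they)) (VP (VBP repress) (NP (NN %s))) (. .))",
            p[3])),
          proteins = rbind(tpl_prot(0L, 0L), tpl_prot(0L, 2L),
                           tpl_prot(1L, 4L)),
          links = tpl_link(1L, 2L, 2L, 0L, 0L, 2L, "personal_pronoun"))
      }
    },
    definite_1a = function(p, g) {
      head_pl <- sample(C1_HEADS, 1L)
      list(ptb = c(sprintf(
        "(S (NP (DT The) (NN %s) (NNS proteins)) (VP (VBP interact) (PP (IN with) (NP (NN %s)))) (. .))",
        p[1], p[2]),
        def_anaphor("These", head_pl)),
        proteins = rbind(tpl_prot(0L, 1L), tpl_prot(0L, 5L)),
        links = tpl_link(1L, 0L, 1L, 0L, 0L, 2L, "definite_np"))
    },
    definite_1b = function(p, g) {
      head_pl <- sample(C1_HEADS, 1L)
      list(ptb = c(sprintf(
        "(S (NP (NN %s)) (VP (VBZ recruits) (NP (NP (NN %s)) (CC and) (NP (NN %s)))) (. .))",
        p[3], p[1], p[2]),
        def_anaphor("These", head_pl)),
        proteins = rbind(tpl_prot(0L, 0L), tpl_prot(0L, 2L),
                         tpl_prot(0L, 4L)),
        links = tpl_link(1L, 0L, 1L, 0L, 2L, 4L, "definite_np"))
    },
    definite_2a = function(p, g) {
      head_pl <- sample(C2_HEADS, 1L)
      list(ptb = c(sprintf(
        "(S (NP (DT The) (NN %s) (NNS %s)) (VP (VBP bind) (NP (NN %s))) (. .))",
        p[1], head_pl, p[2]),
        def_anaphor("These", head_pl)),
        proteins = rbind(tpl_prot(0L, 1L), tpl_prot(0L, 4L)),
        links = tpl_link(1L, 0L, 1L, 0L, 0L, 2L, "definite_np"))
    },
    definite_2b = function(p, g) {
      head_pl <- sample(C2_HEADS, 1L)
      list(ptb = c(sprintf(
        "(S (NP (NN %s)) (VP (VBZ binds) (NP (NP (NN %s)) (CC and) (NP (NN %s)))) (. .))",
        p[1], p[2], g[1]),
        def_anaphor("These", head_pl)),
        proteins = rbind(tpl_prot(0L, 0L), tpl_prot(0L, 2L)),
        links = tpl_link(1L, 0L, 1L, 0L, 2L, 4L, "definite_np"))
    },
    definite_2c = function(p, g) {
      head_pl <- sample(C2_HEADS, 1L)
      list(ptb = c(sprintf(
        "(S (NP (NN %s)) (VP (VBZ binds) (NP (NP (NN %s)) (CC and) (NP (NN %s)))) (. .))",
        p[3], p[1], p[2]),
        def_anaphor("These", head_pl)),
        proteins = rbind(tpl_prot(0L, 0L), tpl_prot(0L, 2L),
                         tpl_prot(0L, 4L)),
        links = tpl_link(1L, 0L, 1L, 0L, 2L, 4L, "definite_np"))
    },
    definite_3a = function(p, g) {
      head_sg <- sample(C3_HEADS, 1L)
      list(ptb = c(sprintf(
        "(S (NP (DT The) (NN %s) (NN gene)) (VP (VBZ encodes) (NP (NN %s))) (. .))",
        p[1], p[2]),
        def_anaphor("This", head_sg)),
        proteins = rbind(tpl_prot(0L, 1L), tpl_prot(0L, 4L)),
        links = tpl_link(1L, 0L, 1L, 0L, 0L, 2L, "definite_np"))
    },
    definite_3b = function(p, g) {
      head_sg <- sample(C3_HEADS, 1L)
      list(ptb = c(sprintf(
        "(S (NP (NN %s)) (VP (VBZ interacts) (PP (IN with) (NP (NN %s)))) (. .))",
        p[1], p[2]),
        def_anaphor("This", head_sg)),
        proteins = rbind(tpl_prot(0L, 0L), tpl_prot(0L, 3L)),
        links = tpl_link(1L, 0L, 1L, 0L, 3L, 3L, "definite_np"))
    },
    definite_4a = function(p, g) {
      head_sg <- sample(C4_HEADS, 1L)
      list(ptb = c(sprintf(
        "(S (NP (DT The) (NN %s) (NN %s)) (VP (VBZ binds) (NP (NN %s))) (. .))",
        p[1], head_sg, p[2]),
        def_anaphor("This", head_sg)),
        proteins = rbind(tpl_prot(0L, 1L), tpl_prot(0L, 4L)),
        links = tpl_link(1L, 0L, 1L, 0L, 0L, 2L, "definite_np"))
    },
    definite_4b = function(p, g) {
      head_sg <- sample(C4_HEADS, 1L)
      list(ptb = c(sprintf(
        "(S (NP (NN %s)) (VP (VBZ binds) (NP (NP (NN %s)) (CC and) (NP (NN %s)))) (. .))",
        g[1], p[1], p[2]),
        def_anaphor("This", head_sg)),
        proteins = rbind(tpl_prot(0L, 2L), tpl_prot(0L, 4L)),
        links = tpl_link(1L, 0L, 1L, 0L, 0L, 0L, "definite_np"))
    },
    definite_4c = function(p, g) {
      head_sg <- sample(C4_HEADS, 1L)
      list(ptb = c(sprintf(
        "(S (NP (NP (NN %s)) (CC and) (NP (NN %s))) (VP (VBP bind) (NP (DT the) (NN domain))) (. .))",
        p[1], g[1]),
        def_anaphor("This", head_sg)),
        proteins = tpl_prot(0L, 0L),
        links = tpl_link(1L, 0L, 1L, 0L, 0L, 2L, "definite_np"))
    },
    pleonastic_it = function(p, g) {
      list(ptb = sprintf(
        "(S (NP (PRP It)) (VP (VBZ has) (VP (VBN been) (VP (VBN shown) (SBAR (IN that) (S (NP (NN %s)) (VP (VBZ activates) (NP (NN %s)))))))) (. .))",
        p[1], p[2]),
        proteins = rbind(tpl_prot(0L, 5L), tpl_prot(0L, 7L)),
        links = no_links())
    },
    out_of_window = function(p, g) {
      list(ptb = c(sprintf(
        "(S (NP (DT The) (NN %s) (NN gene)) (VP (VBZ encodes) (NP (NN %s))) (. .))",
        p[1], p[2]),
        FILLER_SENTENCES[1L], FILLER_SENTENCES[2L],
        def_anaphor("This", "gene")),
        proteins = rbind(tpl_prot(0L, 1L), tpl_prot(0L, 4L)),
        links = tpl_link(3L, 0L, 1L, 0L, 0L, 2L, "definite_np"))
    },
    no_antecedent = function(p, g) {
      list(ptb = c(
        "(S (NP (DT The) (NN complex)) (VP (VBZ dissociates)) (. .))",
        "(S (NP (PRP It)) (VP (VBZ is) (ADJP (JJ stable))) (. .))"),
        proteins = tpl_prot(integer(), integer()),
        links = no_links())
    }
  )
}

#' Names of templates whose gold links the rule system resolves exactly
#' @return character vector of template names
#' @export
closed_loop_templates <- function() {
  setdiff(names(fixture_templates()), "out_of_window")
}

#' Fixture-corpus configuration
#'
#' Generation is a pure function of the configuration (including the
#' seed).
#'
#' @param seed RNG seed
#' @param n_docs number of documents
#' @param templates template names to draw from (all by default)
#' @param protein_pool generic protein placeholder symbols
#' @param gazetteer non-protein bio-entity placeholder terms
#' @param distractor_rate probability of prefixing a document with a
#'   bio-entity-free filler sentence
#' @return list of class \code{fixture_config}
#' @export
fixture_config <- function(seed = 1L, n_docs = 100L,
                           templates = names(fixture_templates()),
                           protein_pool = sprintf("PRT%d", 1:24),
                           gazetteer = sprintf("BENT%d", 1:8),
                           distractor_rate = 0.3) {
  unknown <- setdiff(templates, names(fixture_templates()))
  if (length(unknown) > 0L)
    stop("unknown template name(s): ", paste(unknown, collapse = ", "))
  structure(list(seed = seed, n_docs = n_docs, templates = templates,
                 protein_pool = protein_pool, gazetteer = gazetteer,
                 distractor_rate = distractor_rate),
            class = "fixture_config")
}

# character layout of a sentence list: tokens joined by single spaces
layout_sentences <- function(ptb) {
  trees <- lapply(ptb, read_bracketed_parse)
  spans <- list()
  text_parts <- character(length(trees))
  offset <- 0L
  for (i in seq_along(trees)) {
    tk <- pt_tokens(trees[[i]])
    starts <- integer(nrow(tk)); ends <- integer(nrow(tk))
    pos <- offset
    for (j in seq_len(nrow(tk))) {
      starts[j] <- pos
      ends[j] <- pos + nchar(tk$surface[j])
      pos <- ends[j] + 1L
    }
    text_parts[i] <- paste(tk$surface, collapse = " ")
    spans[[i]] <- data.frame(index = tk$index, start = starts, end = ends)
    offset <- pos
  }
  list(text = paste(text_parts, collapse = " "), spans = spans)
}

build_fixture_doc <- function(doc_id, tpl_out, shift = 0L) {
  ptb <- tpl_out$ptb
  if (shift > 0L) {
    ptb <- c(sample(FILLER_SENTENCES, shift), ptb)
    if (nrow(tpl_out$proteins) > 0L)
      tpl_out$proteins$sentence <- tpl_out$proteins$sentence + shift
    if (nrow(tpl_out$links) > 0L) {
      tpl_out$links$a_sent <- tpl_out$links$a_sent + shift
      tpl_out$links$t_sent <- tpl_out$links$t_sent + shift
    }
  }
  lay <- layout_sentences(ptb)
  span_of <- function(sent, from, to) {
    sp <- lay$spans[[sent + 1L]]
    c(sp$start[sp$index == from], sp$end[sp$index == to])
  }
  proteins <- empty_proteins()
  if (nrow(tpl_out$proteins) > 0L) {
    pr <- tpl_out$proteins
    rows <- lapply(seq_len(nrow(pr)), function(k) {
      s <- span_of(pr$sentence[k], pr$tok_from[k], pr$tok_to[k])
      data.frame(ann_id = paste0("T", k), label = "Protein",
                 start = s[1L], end = s[2L],
                 text = substring(lay$text, s[1L] + 1L, s[2L]),
                 stringsAsFactors = FALSE)
    })
    proteins <- do.call(rbind, rows)
  }
  gold <- empty_links()
  if (nrow(tpl_out$links) > 0L) {
    lk <- tpl_out$links
    rows <- lapply(seq_len(nrow(lk)), function(k) {
      a <- span_of(lk$a_sent[k], lk$a_from[k], lk$a_to[k])
      t <- span_of(lk$t_sent[k], lk$t_from[k], lk$t_to[k])
      data.frame(doc_id = doc_id, anaphor_start = a[1L],
                 anaphor_end = a[2L], anaphor_type = lk$type[k],
                 antecedent_start = t[1L], antecedent_end = t[2L],
                 stringsAsFactors = FALSE)
    })
    gold <- do.call(rbind, rows)
  }
  build_document(doc_id, lay$text, ptb, proteins, gold)
}

#' Generate a synthetic annotated corpus
#'
#' Draws one phenomenon template per document, fills its protein and
#' bio-entity slots from the configured pools, and returns fully
#' validated documents whose gold links are correct by construction.
#' Identical corpora are produced for identical configurations.
#'
#' @param cfg a \code{\link{fixture_config}}
#' @return list of \code{coref_document}, with the gazetteer attached as
#'   \code{attr(, "gazetteer")}
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  tpls <- fixture_templates()
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)
  docs <- vector("list", cfg$n_docs)
  for (i in seq_len(cfg$n_docs)) {
    nm <- if (length(cfg$templates) == 1L) cfg$templates else
      sample(cfg$templates, 1L)
    p <- sample(cfg$protein_pool, 3L)
    g <- sample(cfg$gazetteer, 2L)
    shift <- if (stats::runif(1) < cfg$distractor_rate) 1L else 0L
    docs[[i]] <- build_fixture_doc(sprintf("synth%04d", i),
                                   tpls[[nm]](p, g), shift)
    attr(docs[[i]], "template") <- nm
  }
  attr(docs, "gazetteer") <- cfg$gazetteer
  docs
}

#' Generate labelled mention-pair instances from a planted rule
#'
#' Builds a fixture corpus, constructs every anaphor's candidate
#' instances, and relabels them so that exactly the candidate selected by
#' the planted rule is positive. The default rule plants the nearest
#' protein-bearing candidate NP.
#'
#' @param cfg a \code{\link{fixture_config}}
#' @param rule \code{"nearest_protein"} or a function taking the
#'   instance list of one anaphor and returning the index of the positive
#'   instance (or 0 for none)
#' @param windows,max_len passed to \code{\link{build_instances}}
#' @return list with \code{instances} (labelled), \code{planted} (the
#'   planted link frame), \code{docs}, and \code{balance} (class counts)
#' @export
generate_planted_pairs <- function(cfg, rule = "nearest_protein",
                                   windows = default_windows(),
                                   max_len = 82L) {
  if (is.character(rule)) {
    rule <- switch(rule,
      nearest_protein = function(grp) {
        pc <- vapply(grp, function(i) i$candidate$protein_count, integer(1))
        d <- vapply(grp, `[[`, integer(1), "distance")
        ok <- which(pc >= 1L)
        if (length(ok) == 0L) return(0L)
        ok[order(d[ok])][1L]
      },
      stop("unknown planted rule"))
  }
  docs <- generate_corpus(cfg)
  gaz <- attr(docs, "gazetteer")
  all_inst <- list()
  planted <- list()
  for (doc in docs) {
    inst <- build_instances(doc, windows = windows, max_len = max_len,
                            gazetteer = gaz)
    if (length(inst) == 0L) next
    akey <- vapply(inst, function(i)
      paste(i$anaphor$start, i$anaphor$end), character(1))
    for (k in unique(akey)) {
      grp <- inst[akey == k]
      pos <- rule(grp)
      for (j in seq_along(grp))
        grp[[j]]$label <- as.integer(j == pos)
      if (pos > 0L)
        planted[[length(planted) + 1L]] <-
          link_row(list(doc_id = doc$doc_id), grp[[pos]]$anaphor,
                   grp[[pos]]$candidate)
      all_inst <- c(all_inst, grp)
    }
  }
  y <- vapply(all_inst, `[[`, integer(1), "label")
  list(instances = all_inst,
       planted = if (length(planted) == 0L) empty_links() else
         do.call(rbind, planted),
       docs = docs,
       balance = c(pos = sum(y == 1L), neg = sum(y == 0L)))
}
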