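resolve_doc_links <- function(doc, gaz = NULL) {
  out <- resolve_all(doc, gazetteer = gaz)
  attr(out, "log") <- NULL
  out
}

test_that("relative pronouns link to the head NP of their clause", {
  doc <- make_doc(paste0(
    "(S (NP (DT the) (NN gene)) (SBAR (WHNP (WDT that)) (S (VP (VBZ encodes)",
    " (NP (NN PRT4))))) (VP (VBZ is) (ADJP (JJ active))) (. .))"))
  anas <- detect_anaphors(doc)
  lk <- resolve_relative(anas[anas$mention_type == "relative_pronoun", ],
                         doc)
  expect_equal(substring(doc$text, lk$antecedent_start + 1L,
                         lk$antecedent_end), "the gene")
})

test_that("a sentence-initial relative pronoun has no antecedent", {
  doc <- make_doc(
    "(S (WHNP (WDT Which)) (VP (VBZ binds) (NP (NN PRT1))) (. .))")
  anas <- detect_anaphors(doc)
  expect_null(resolve_relative(anas[1, ], doc))
})

test_that("shortest-path resolution matches exhaustive enumeration", {
  set.seed(101)
  checked <- 0L
  for (rep in 1:120) {
    doc <- make_doc(random_relative_ptb(),
                    doc_id = sprintf("rnd%03d", rep))
    anas <- detect_anaphors(doc)
    rel <- anas[anas$mention_type == "relative_pronoun", , drop = FALSE]
    if (nrow(rel) == 0L) next
    cands <- detect_candidates(doc)
    for (i in seq_len(nrow(rel))) {
      got <- resolve_relative(rel[i, ], doc, cands)
      want <- oracle_resolve_relative(rel[i, ], doc, cands)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(c(got$antecedent_start, got$antecedent_end),
                     c(want$start, want$end))
      }
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 100L)
})

test_that("coordination sends a pronoun to the farthest candidate of the first conjunct", {
  doc <- make_doc(paste0(
    "(S (S (NP (NN PRT1)) (VP (VBZ binds) (NP (DT the) (NN PRT2)",
    " (NN enzyme)))) (CC and) (S (NP (PRP it)) (VP (VBZ activates)",
    " (NP (NN PRT3)))) (. .))"),
    proteins = rbind(prot(0L, 0L), prot(0L, 3L), prot(0L, 8L)))
  anas <- detect_anaphors(doc)
  lk <- resolve_personal(anas[anas$mention_type == "personal_pronoun", ],
                         doc)
  expect_equal(substring(doc$text, lk$antecedent_start + 1L,
                         lk$antecedent_end), "PRT1")
})

test_that("without coordination the closest clause supplies the farthest candidate", {
  doc <- make_doc(paste0(
    "(S (NP (DT The) (NN PRT1) (NN enzyme)) (VP (VBZ binds) (NP (NN PRT2))",
    " (SBAR (IN because) (S (NP (PRP it)) (VP (VBZ activates)",
    " (NP (NN PRT3)))))) (. .))"),
    proteins = rbind(prot(0L, 1L), prot(0L, 4L), prot(0L, 8L)))
  anas <- detect_anaphors(doc)
  lk <- resolve_personal(anas[anas$mention_type == "personal_pronoun", ],
                         doc)
  expect_equal(substring(doc$text, lk$antecedent_start + 1L,
                         lk$antecedent_end), "The PRT1 enzyme")
})

test_that("the motif example resolves its pronoun to the protein-bearing NP", {
  doc <- il6_doc()
  pred <- resolve_doc_links(doc)
  expect_equal(nrow(pred), 1L)
  expect_equal(substring(doc$text, pred$antecedent_start + 1L,
                         pred$antecedent_end), "the IL-6 kappa B motif")
  expect_equal(pred[, names(biocoref:::empty_links())],
               doc$gold_links[, names(biocoref:::empty_links())])
})

test_that("previous-sentence fallback respects number agreement", {
  doc <- make_doc(c(paste0(
    "(S (NP (NP (NN PRT1)) (CC and) (NP (NN PRT2))) (VP (VBP interact)",
    " (PP (IN with) (NP (NN PRT3)))) (. .))"),
    "(S (ADVP (RB Moreover)) (, ,) (NP (PRP they)) (VP (VBP dissociate)) (. .))"),
    proteins = rbind(prot(0L, 0L), prot(0L, 2L), prot(0L, 5L)))
  anas <- detect_anaphors(doc)
  lk <- resolve_personal(anas[anas$mention_type == "personal_pronoun", ],
                         doc)
  # "PRT3" is singular and filtered; the coordinate NP is plural
  expect_equal(substring(doc$text, lk$antecedent_start + 1L,
                         lk$antecedent_end), "PRT1 and PRT2")
})

test_that("a pronoun with no bio-entity candidate anywhere gets none", {
  doc <- make_doc(c(
    "(S (NP (DT The) (NN buffer)) (VP (VBD was) (ADJP (JJ fresh))) (. .))",
    "(S (NP (PRP It)) (VP (VBZ looks) (ADJP (JJ stable))) (. .))"))
  anas <- detect_anaphors(doc)
  pp <- anas[anas$mention_type == "personal_pronoun", ]
  expect_equal(nrow(pp), 1L)
  expect_null(resolve_personal(pp, doc))
})

test_that("personal resolution never returns a candidate without bio-entities (property)", {
  docs <- generate_corpus(fixture_config(seed = 31, n_docs = 40))
  gaz <- attr(docs, "gazetteer")
  for (doc in docs) {
    cands <- detect_candidates(doc, gaz)
    anas <- detect_anaphors(doc, gaz)
    pp <- anas[anas$mention_type == "personal_pronoun", , drop = FALSE]
    if (nrow(pp) == 0L) next
    for (i in seq_len(nrow(pp))) {
      lk <- resolve_personal(pp[i, ], doc, cands, gaz)
      if (is.null(lk)) next
      hit <- cands[cands$start == lk$antecedent_start &
                     cands$end == lk$antecedent_end, ]
      expect_gte(hit$bioentity_count[1L], 1L)
      if (hit$sentence[1L] < pp$sentence[i])
        expect_true(biocoref:::number_agrees(hit$number[1L], pp$number[i]))
    }
  }
})

expected_branch <- c(definite_1a = "C1a", definite_1b = "C1b",
                     definite_2a = "C2a", definite_2b = "C2b",
                     definite_2c = "C2b",   # (c) is subsumed by (b)
                     definite_3a = "C3a", definite_3b = "C3b",
                     definite_4a = "C4a", definite_4b = "C4b",
                     definite_4c = "C4c")

test_that("each definite-NP constraint branch selects its constructed answer", {
  for (tpl in names(expected_branch)) {
    docs <- generate_corpus(fixture_config(seed = 37, n_docs = 4,
                                           templates = tpl,
                                           distractor_rate = 0))
    gaz <- attr(docs, "gazetteer")
    for (doc in docs) {
      anas <- detect_anaphors(doc, gaz)
      dn <- anas[anas$mention_type == "definite_np" &
                   anas$sentence > 0L, , drop = FALSE]
      expect_equal(nrow(dn), 1L)
      lk <- resolve_definite(dn, doc, gazetteer = gaz)
      expect_false(is.null(lk))
      expect_equal(attr(lk, "fired"), unname(expected_branch[tpl]),
                   info = tpl)
      g <- doc$gold_links
      expect_equal(c(lk$antecedent_start, lk$antecedent_end),
                   c(g$antecedent_start, g$antecedent_end), info = tpl)
    }
  }
})

test_that("definite resolution matches the enumerating constraint oracle", {
  docs <- generate_corpus(fixture_config(seed = 43, n_docs = 60))
  gaz <- attr(docs, "gazetteer")
  for (doc in docs) {
    cands <- detect_candidates(doc, gaz)
    anas <- detect_anaphors(doc, gaz)
    dn <- anas[anas$mention_type == "definite_np", , drop = FALSE]
    if (nrow(dn) == 0L) next
    for (i in seq_len(nrow(dn))) {
      got <- resolve_definite(dn[i, ], doc, cands, gaz)
      want <- oracle_resolve_definite(dn[i, ], cands)
      if (is.null(want)) expect_null(got)
      else expect_equal(c(got$antecedent_start, got$antecedent_end),
                        c(want$start, want$end))
    }
  }
})

test_that("antecedents outside the two-sentence window are not used", {
  docs <- generate_corpus(fixture_config(seed = 47, n_docs = 6,
                                         templates = "out_of_window",
                                         distractor_rate = 0))
  for (doc in docs) {
    pred <- resolve_doc_links(doc)
    expect_equal(nrow(pred), 0L)     # gold exists but lies out of range
    expect_equal(nrow(doc$gold_links), 1L)
  }
})

test_that("higher-priority sub-preferences always win over closer lower ones", {
  doc <- make_doc(c(
    paste0("(S (NP (DT The) (NN PRT7) (NNS proteins)) (VP (VBP interact)",
           " (ADVP (RB strongly))) (. .))"),
    paste0("(S (NP (NN PRT8)) (VP (VBZ recruits) (NP (NP (NN PRT1))",
           " (CC and) (NP (NN PRT2)))) (. .))"),
    "(S (NP (DT These) (NNS proteins)) (VP (VBP are) (ADJP (JJ active))) (. .))"),
    proteins = rbind(prot(0L, 1L), prot(1L, 0L), prot(1L, 2L),
                     prot(1L, 4L)))
  anas <- detect_anaphors(doc)
  dn <- anas[anas$mention_type == "definite_np" & anas$sentence == 2L, ]
  lk <- resolve_definite(dn, doc)
  # the head-word match (sub-preference a) beats the closer multi-protein
  # coordinate NP (sub-preference b)
  expect_equal(attr(lk, "fired"), "C1a")
  expect_equal(substring(doc$text, lk$antecedent_start + 1L,
                         lk$antecedent_end), "The PRT7 proteins")
})

test_that("resolve_all composes per-type resolvers deterministically", {
  docs <- generate_corpus(fixture_config(seed = 53, n_docs = 25))
  gaz <- attr(docs, "gazetteer")
  for (doc in docs) {
    cands <- detect_candidates(doc, gaz)
    anas <- detect_anaphors(doc, gaz)
    all1 <- resolve_all(doc, gazetteer = gaz)
    all2 <- resolve_all(doc, gazetteer = gaz)
    attr(all1, "log") <- attr(all2, "log") <- NULL
    expect_identical(all1, all2)
    expect_lte(nrow(all1), nrow(anas))
    # at most one link per anaphor
    expect_false(anyDuplicated(paste(all1$anaphor_start,
                                     all1$anaphor_end)) > 0)
    # composition: every link equals its per-type resolver's output
    if (nrow(all1) > 0L) for (k in seq_len(nrow(all1))) {
      a <- anas[anas$start == all1$anaphor_start[k] &
                  anas$end == all1$anaphor_end[k] &
                  anas$mention_type == all1$anaphor_type[k], , drop = FALSE]
      single <- switch(a$mention_type,
        relative_pronoun = resolve_relative(a, doc, cands, gaz),
        personal_pronoun = resolve_personal(a, doc, cands, gaz),
        definite_np = resolve_definite(a, doc, cands, gaz))
      expect_equal(c(single$antecedent_start, single$antecedent_end),
                   c(all1$antecedent_start[k], all1$antecedent_end[k]))
    }
  }
})

test_that("a document without anaphors yields no links", {
  doc <- make_doc("(S (NP (NN PRT1)) (VP (VBZ acts)) (. .))",
                  proteins = prot(0L, 0L))
  expect_equal(nrow(resolve_doc_links(doc)), 0L)
})
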