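test_that("anaphor detection finds the possessive pronoun, not pleonastic it", {
  doc <- il6_doc()
  anas <- detect_anaphors(doc)
  expect_true("its" %in% anas$text)
  expect_false("it" %in% anas$text)          # "it has been ..." filtered
  expect_equal(anas$mention_type[anas$text == "its"], "personal_pronoun")
})

test_that("pleonastic-it patterns and the third-person lexicon are applied", {
  doc <- make_doc(c(
    "(S (NP (PRP It)) (VP (VBZ has) (VP (VBN been) (VP (VBN shown)))) (. .))",
    "(S (NP (PRP It)) (VP (VBZ seems) (ADJP (JJ clear))) (. .))",
    "(S (NP (PRP We)) (VP (VBP study) (NP (PRP it))) (. .))"))
  anas <- detect_anaphors(doc)
  pp <- anas[anas$mention_type == "personal_pronoun", ]
  # only the genuinely referential "it" of sentence 3 survives; "We" is not
  # third person
  expect_equal(nrow(pp), 1L)
  expect_equal(pp$sentence, 2L)
  expect_equal(tolower(pp$text), "it")
})

test_that("definite-NP anaphors require a definite determiner and a listed head", {
  doc <- make_doc(c(
    "(S (NP (DT The) (NN enzyme)) (VP (VBD was) (ADJP (JJ active))) (. .))",
    "(S (NP (DT This) (NN protein)) (VP (VBZ binds)) (. .))",
    "(S (NP (DT A) (NN gene)) (VP (VBZ acts)) (. .))",
    "(S (NP (DT These) (NNS complexes)) (VP (VBP form)) (. .))"))
  anas <- detect_anaphors(doc)
  dn <- anas[anas$mention_type == "definite_np", ]
  expect_setequal(dn$text, c("This protein", "These complexes"))
  # "the enzyme": head not in the list; "a gene": indefinite determiner
})

test_that("candidate filter drops clause-containing and same-clause nested NPs", {
  doc <- make_doc(paste0(
    "(S (NP (NN PRT9)) (VP (VBZ studies) (NP (NP (DT the) (NN gene))",
    " (SBAR (WHNP (WDT which)) (S (VP (VBZ encodes)",
    " (NP (DT the) (NN protein))))))) (. .))"))
  cands <- detect_candidates(doc)
  # outer object NP contains a clause; its inner "the gene" is surrounded
  # by it within the same clause; "the protein" sits inside the relative
  # clause and survives
  expect_setequal(cands$text, c("PRT9", "the protein"))
})

test_that("a flat NP is a single candidate", {
  doc <- make_doc("(S (NP (DT the) (NN protein)) (VP (VBZ acts)) (. .))")
  cands <- detect_candidates(doc)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$text, "the protein")
})

test_that("candidates contain no clause and never nest (property)", {
  docs <- generate_corpus(fixture_config(seed = 19, n_docs = 30))
  for (doc in docs) {
    cands <- detect_candidates(doc, attr(docs, "gazetteer"))
    if (nrow(cands) < 1L) next
    for (i in seq_len(nrow(cands))) {
      tree <- doc$sentences[[cands$sentence[i] + 1L]]$parse
      expect_false(tree$nodes$clause_below[cands$node_id[i]])
    }
    if (nrow(cands) > 1L) for (i in seq_len(nrow(cands)))
      for (j in seq_len(nrow(cands))) {
        if (i == j || cands$sentence[i] != cands$sentence[j]) next
        nested <- cands$tok_start[j] >= cands$tok_start[i] &&
          cands$tok_end[j] <= cands$tok_end[i]
        expect_false(nested)
      }
  }
})

test_that("head finding stops at postmodifier boundaries", {
  doc <- make_doc(paste0(
    "(S (NP (DT the) (NN IL-6) (NN kappa) (NN B) (NN motif))",
    " (VP (VBZ acts)) (. .))"))
  sent <- doc$sentences[[1]]
  np <- which(sent$parse$nodes$label == "NP" & !sent$parse$nodes$leaf)[1]
  h <- head_word(sent$parse, np, sent$tokens)
  expect_equal(h$surface, "motif")
  expect_false(attr(h, "unknown_head"))

  doc2 <- make_doc(paste0(
    "(S (NP (NP (DT the) (NN receptor)) (PP (IN for) (NP (NN IL-2))))",
    " (VP (VBZ signals)) (. .))"))
  sent2 <- doc2$sentences[[1]]
  outer <- which(sent2$parse$nodes$label == "NP" & !sent2$parse$nodes$leaf &
                   sent2$parse$nodes$tok_start == 0L &
                   sent2$parse$nodes$tok_end == 3L)[1]
  expect_equal(head_word(sent2$parse, outer, sent2$tokens)$surface,
               "receptor")

  doc3 <- make_doc("(S (NP (DT these) (NNS proteins)) (VP (VBP act)) (. .))")
  sent3 <- doc3$sentences[[1]]
  np3 <- which(sent3$parse$nodes$label == "NP" & !sent3$parse$nodes$leaf)[1]
  expect_equal(head_word(sent3$parse, np3, sent3$tokens)$surface, "proteins")
})

test_that("NPs without a noun leaf get a flagged fallback head", {
  doc <- make_doc("(S (NP (DT the) (CD 42)) (VP (VBZ acts)) (. .))")
  sent <- doc$sentences[[1]]
  np <- which(sent$parse$nodes$label == "NP" & !sent$parse$nodes$leaf)[1]
  h <- head_word(sent$parse, np, sent$tokens)
  expect_true(attr(h, "unknown_head"))
  expect_equal(h$surface, "42")
})

test_that("grammatical number follows POS, pronoun lexicon and coordination", {
  expect_equal(grammatical_number("proteins", "NNS"), "plural")
  expect_equal(grammatical_number("its", "PRP$"), "singular")
  expect_equal(grammatical_number("they", "PRP"), "plural")
  expect_equal(grammatical_number("42", "CD"), "unknown")
  expect_equal(grammatical_number("PRT2", "NN", coordinated = TRUE),
               "plural")
})

test_that("entity counts use interval containment and the gazetteer", {
  doc <- make_doc(paste0(
    "(S (NP (NP (NN PRT1)) (CC and) (NP (NN SITE9))) (VP (VBP bind)",
    " (NP (NN PRT2))) (. .))"),
    proteins = rbind(prot(0L, 0L), prot(0L, 4L)))
  cands <- detect_candidates(doc, gazetteer = "SITE9")
  co <- cands[cands$text == "PRT1 and SITE9", ]
  expect_equal(co$protein_count, 1L)
  expect_equal(co$bioentity_count, 2L)
  single <- cands[cands$text == "PRT2", ]
  expect_equal(single$protein_count, 1L)
  expect_equal(single$bioentity_count, 1L)
  # a span covering no annotation counts zero
  none <- entity_counts(list(start = 0L, end = 4L),
                        make_doc("(S (NP (NN cell)) (VP (VBZ grows)) (. .))"))
  expect_equal(unname(none), c(0L, 0L))
})

test_that("detection covers every gold endpoint on generated corpora", {
  docs <- generate_corpus(fixture_config(seed = 23, n_docs = 40))
  gaz <- attr(docs, "gazetteer")
  for (doc in docs) {
    if (is.null(doc$gold_links) || nrow(doc$gold_links) == 0L) next
    mn <- rbind(detect_anaphors(doc, gaz), detect_candidates(doc, gaz))
    for (k in seq_len(nrow(doc$gold_links))) {
      g <- doc$gold_links[k, ]
      expect_true(any(mn$start == g$anaphor_start &
                        mn$end == g$anaphor_end &
                        mn$mention_type != "np_candidate"))
      expect_true(any(mn$start == g$antecedent_start &
                        mn$end == g$antecedent_end &
                        mn$mention_type == "np_candidate"))
    }
  }
})
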