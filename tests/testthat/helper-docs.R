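# Build small in-memory documents from bracketed trees and
# token-coordinate annotations, reusing the package's fixture plumbing.

make_doc <- function(ptb, proteins = NULL, links = NULL,
                     doc_id = "test0001") {
  if (is.null(proteins))
    proteins <- data.frame(sentence = integer(), tok_from = integer(),
                           tok_to = integer())
  if (is.null(links))
    links <- data.frame(a_sent = integer(), a_from = integer(),
                        a_to = integer(), t_sent = integer(),
                        t_from = integer(), t_to = integer(),
                        type = character(), stringsAsFactors = FALSE)
  biocoref:::build_fixture_doc(doc_id, list(ptb = ptb, proteins = proteins,
                                            links = links))
}

prot <- function(sentence, tok_from, tok_to = tok_from) {
  data.frame(sentence = sentence, tok_from = tok_from, tok_to = tok_to)
}

glink <- function(a_sent, a_from, a_to, t_sent, t_from, t_to, type) {
  data.frame(a_sent = a_sent, a_from = a_from, a_to = a_to,
             t_sent = t_sent, t_from = t_from, t_to = t_to, type = type,
             stringsAsFactors = FALSE)
}

# The motif/pronoun example: a multi-token protein-bearing NP antecedent
# and a possessive pronoun anaphor, with pleonastic "it" earlier in the
# sentence.
il6_doc <- function() {
  ptb <- paste0(
    "(S (SBAR (IN Although) (S (NP (PRP it)) (VP (VBZ has) (VP (VBN been)",
    " (ADVP (RB previously)) (VP (VBN shown) (SBAR (IN that)",
    " (S (NP (DT the) (NN IL-6) (NN kappa) (NN B) (NN motif))",
    " (VP (VBZ functions) (PP (IN as) (NP (DT a) (JJ potent)",
    " (NN element))))))))))) (, ,) (NP (PRP$ its) (NN activity))",
    " (VP (VBD was) (VP (VBN found) (S (VP (TO to) (VP (VB be)",
    " (VP (VBN repressed))))))) (. .))")
  make_doc(ptb,
           proteins = prot(0L, 8L, 10L),                 # IL-6 kappa B
           links = glink(0L, 18L, 18L, 0L, 7L, 11L,      # its -> the ... motif
                         "personal_pronoun"),
           doc_id = "il6")
}

# write a document's bundle to a fresh temporary directory
write_tmp_bundle <- function(doc) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_standoff(doc, dir)
  dir
}
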