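---
title: "Protein coreference resolution: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein coreference resolution: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biocoref)
```

## The task

Protein coreference resolution here is a *link-finding* task, not a
clustering one: for each anaphoric mention (a relative pronoun, a
third-person personal pronoun, or a definite NP such as *this protein*),
find the single earlier noun phrase it refers to — typically one
containing a protein name annotated in the document's `.a1` file. The
unit of evaluation is the directed (anaphor, antecedent) link.

The package assumes pre-processing has already happened: documents
arrive with sentence segmentation, tokens (surface, POS, lemma) and one
bracketed constituency parse per sentence, supplied as a `.ptb` sidecar
file next to the BioNLP-ST standoff bundle. No tagger or parser is run
internally; the resolution rules only need constituent labels, tree
paths and coordination, all of which Penn-style bracketed trees express.
Character offsets are 0-based half-open (standoff convention); token and
node spans are 0-based inclusive token indices.

## Mention detection

Anaphors are read off the parse:

* **Relative pronouns**: WDT/WP leaves.
* **Personal pronouns**: PRP/PRP$ leaves restricted to the third-person
  lexicon *it, its, itself, they, them, their, themselves* (first- and
  second-person forms never refer to proteins). Pleonastic *it* is
  removed by a small configurable pattern set matched against the
  following tokens: `it {has|have|had|is|was} been`,
  `it {seems|appears}`, `it {is|was} {possible|likely}`.
* **Definite NPs**: NPs starting with a definite or demonstrative
  determiner (*the, this, that, these, those*) whose head word is one of
  *protein, gene, factor, element, receptor, complex, construct*
  (singular or plural). This head list concentrates on nouns that
  actually corefer with protein entities in task data; widening it
  mostly adds spurious anaphors.

Candidate antecedents are NP nodes passing two filters: no clausal
(S/SBAR) descendant, and no NP ancestor *within the same clause* (no
clause boundary between the two NPs). The second filter is the
package's reading of "surrounded by a larger NP": it keeps exactly the
maximal clause-free NPs — in `the promoter of the gene` only the full NP
survives — while still admitting NPs that sit inside a relative clause
attached to some larger NP. Nested candidates therefore never occur,
matching the task convention that antecedent spans are full NPs.

Head finding takes the rightmost noun-tagged leaf before the first
postmodifier boundary (a PP or SBAR child, or a comma); an NP with no
noun leaf falls back to its rightmost leaf and is flagged. Grammatical
number comes from the head POS (NNS/NNPS plural, NN/NNP singular), the
pronoun lexicon, or coordination (a coordinate NP is plural regardless
of its head's tag); anything else is `unknown`, and `unknown` is treated
as agreeing with everything, since only clear disagreement should filter
a candidate.

Each mention carries two counts: `protein_count`, the number of `.a1`
protein spans inside it, and `bioentity_count`, which adds
case-insensitive whole-word matches from an optional gazetteer of
non-protein biological entities. With no gazetteer supplied (the
default) the two counts coincide; the fixture generator ships a small
placeholder gazetteer so that code paths distinguishing the two are
exercised. This is a documented limitation for real corpora, where
non-protein entity recognition would need an actual lexicon or NER
system.

## The rule resolvers

**Relative pronouns** (window 0). Candidates are the NPs strictly before
the pronoun in its sentence; the winner minimizes the parse-path length
(edge count through the lowest common ancestor) between the pronoun leaf
and the candidate's NP node. Path-length ties are broken by smaller word
distance, then leftmost candidate — both needed only in degenerate
trees, but fixed so output is deterministic.

**Personal pronouns** (window 1). Candidates must be bio-entity NPs
(`bioentity_count >= 1`). If any precede the pronoun in its sentence,
the parse is walked bottom-up from the pronoun leaf:

1. at the first *coordinate structure* — a node with two or more
   same-category children among NP/VP/S separated by a CC or comma — the
   farthest candidate (by word distance) inside the **first conjunct**
   wins;
2. otherwise, the farthest candidate inside the first containing S/SBAR
   that holds any.

The "farthest in the first conjunct" behaviour reflects how conjoined
clauses reuse their first clause's subject. With no same-sentence
candidate, number-agreeing bio-entity NPs of the previous sentence are
searched from its last word upward for the closest clause containing
candidates, again taking the farthest.

**Definite NPs** (window 2; same-sentence candidates must precede).
Exactly one of four constraints applies, selected by the anaphor's
number and head lemma; within it, sub-preferences are tried in order and
the *closest* candidate of the first non-empty one is returned:

| | head ∈ {protein, gene} | other listed head |
|---|---|---|
| plural | **C1** (protein-bearing only): (a) head *proteins*/*genes*; (b) >1 protein | **C2**: (a) same head word; (b) >1 bio-entity; (c) >1 protein |
| singular | **C3** (protein-bearing only): (a) head *protein*/*gene*; (b) exactly 1 protein | **C4**: (a) same head word; (b) exactly 1 bio-entity; (c) exactly 1 protein |

Two design notes. The C3(a)/C1(a) head tests use the number-appropriate
forms of the pair {protein, gene} on both sides; mixed-number head lists
would make the branch unreachable in one of the two constraints.
Second, because `bioentity_count >= protein_count` always holds, any
candidate satisfying C2(c) also satisfies C2(b); C2(c) is retained for
symmetry with C4 but can never be the uniquely deciding branch. In C4
the counts are exact, so C4(c) *is* reachable (one protein plus one
gazetteer entity fails C4(b) and passes C4(c)); the fixture suite covers
that branch explicitly.

## LSTM-Coref

The learned resolver is a mention-pair model: each (candidate, anaphor)
pair within the anaphor type's sentence window (0/1/2, as above) becomes
one binary-labelled sequence instance. The instance is the token run
from the candidate to the anaphor in which every token span belonging to
a detected mention is collapsed to a single mention unit, giving a mixed
sequence like `[m1] w3 w4 [m2] w8 [m3] w11 w12 [m4]` whose first item is
the candidate and last item the anaphor.

**Encoding.** Each unit maps to the concatenation of (i) a skip-gram
embedding (default 50 dimensions) trained on the task corpus itself with
lemmatized words and *whole mentions as single vocabulary units* — so
`the IL-6 kappa B motif` has one vector — and (ii) a 13-dimensional
one-hot block: mention type (4: NP candidate, relative, personal,
definite NP), number (3), protein count (3: 0/1/>1), bio-entity count
(3: 0/1/>1). Plain words carry an all-zero feature block.
Out-of-vocabulary units map to the zero vector. The skip-gram trainer
is deliberately minimal (window 2, 5 negative samples, unigram^0.75
negative distribution, linearly decayed learning rate) and fully
deterministic under its seed.

**Recurrence.** A single-layer LSTM with input, forget and output gates
acting on `[h_{t-1}, x_t]` runs from zero initial state; the last hidden
state feeds a dense sigmoid layer, `P(Y=1) = sigma(w·h_l + b)`. The
output map is a learned projection because `h_l` is a vector; a plain
elementwise squashing of `h_l` would not produce a scalar probability.

**Training.** Mean binary cross-entropy, minimized by mini-batch Adam
(default batch 80, learning rate 0.01, at most 50 epochs). Gate weights
are Glorot-uniform under a fixed seed, the forget bias starts at 1 (a
standard trainability device), and the output layer starts at zero — so
the initial prediction is exactly 0.5 and the initial loss on balanced
labels is exactly ln 2, which the tests assert analytically. Gradients
come from full backpropagation through time and are verified against
central finite differences. When a development set is supplied, the
checkpoint with the best dev F1 is kept; otherwise the final parameters
are returned. Training refuses single-class data.

**Decoding.** Among an anaphor's instances with probability above the
decision threshold (0.5), the candidate with maximal probability wins;
ties break toward the closer candidate. No positive instance means no
link — the model may abstain, like the rules.

**Sizes.** Package defaults follow corpus-scale practice (hidden 200,
embedding 50, maximum instance length 82 with left truncation that
always keeps both endpoints, since they define the pair). The test
suite and acceptance script run the same code at fixture scale — hidden
24, embedding 16, 25–50 epochs, a few hundred instances — chosen so the
whole suite runs in minutes while still exercising every code path;
parameter-recovery results at that scale say nothing about corpus-scale
accuracy.

## Scoring and error audit

`score_links` computes link-level recall (matched gold / gold),
precision (matched predictions / predictions) and F1 with greedy
one-to-one matching. Anaphor spans must match exactly in both modes.
`strict` requires exact antecedent spans too; `partial` (the default)
also credits a predicted antecedent that covers a protein annotation
lying inside the gold antecedent — the protein-mention criterion of the
shared-task tradition. Both modes ship because no single criterion is
canonical; closed-loop fixture tests use `strict`.

`error_audit` classifies each unmatched gold link as, in priority
order: **MGM** (an endpoint never produced by mention detection),
**OOR** (the true antecedent lies beyond the anaphor type's sentence
window), else **FL** (a resolution error); and each unmatched predicted
link as **EL** (the predicted anaphor has no gold link), **BMB** (the
predicted antecedent strictly contains the gold one), else **FL**. The
priority order is a package decision — the categories themselves do not
dictate one — and makes the audit counts reconcile exactly:
missing = gold − matched, spurious = predicted − matched, which is
asserted on every fixture run.

## The synthetic corpus generator

`generate_corpus` builds documents from hand-written bracketed-tree
templates with slot-filling from pools of generic placeholder symbols
(`PRT7`-style protein names, `BENT3`-style gazetteer entities), one
phenomenon per document: relative-pronoun attachment (two tree shapes),
same-sentence personal pronouns with and without coordination,
previous-sentence pronouns (singular and plural), one template per
definite-NP constraint sub-preference (1a–4c), pleonastic *it*, an
out-of-window antecedent, and a no-antecedent case. An optional filler
sentence (default rate 0.3) is prefixed as a distractor. Generation is
a pure function of the configuration: fixed seed, identical corpus.

Templates are trees, not free text, so no parser is needed and the
correct link is known by construction; `closed_loop_templates()` names
the subset on which the rule system is exact, which is what the
closed-loop recall/precision/F1 = 1 checks certify. What passing those
checks shows is *internal correctness* — each rule implements its
intended decision procedure and the pipeline composes them losslessly.
What it cannot show is robustness to real abstracts: genuine MEDLINE
text has parser errors, apposition, abbreviation aliases, anaphor types
outside the three handled here, and lexical variety the placeholder
pools do not emulate. The out-of-window template exists precisely to
keep one known-unresolvable phenomenon in the default mix so the audit
path is exercised.

## Numerical and degenerate-input choices

* Tie-breaks: shortest path → word distance → leftmost (relative);
  farthest → leftmost (personal); closest → rightmost (definite).
* Word distance is the count of tokens strictly between candidate head
  and anaphor token.
* Clause labels are {S, SBAR}; coordination requires ≥ 2 same-category
  children among NP/VP/S plus a CC or comma child.
* Empty candidate sets, anaphor-less documents, and empty corpora are
  ordinary non-error cases yielding empty outputs; unparsed documents,
  malformed standoff lines (reported with line numbers), spans outside
  the text, and single-class training sets are errors.
* Probabilities are clipped at 1e-12 inside the loss; hidden states are
  bounded by tanh, so forward passes cannot overflow.
* `.a2` output is byte-stable: mention lines numbered after the `.a1`
  annotations in span order, relation lines ordered by anaphor position.

## Known limitations

* The default gazetteer is empty, collapsing bio-entity counts onto
  protein counts; C2(b)/C4(b) then lose their discriminating power.
* Constraint C2(c) is subsumed by C2(b) (see above).
* The scorer's `partial` mode approximates the shared-task matcher; the
  official minimal/maximal-span semantics are not published in a
  machine-checkable form, so both modes are exposed instead.
* Resolution quality on real text is bounded by the supplied parses;
  the package never re-parses.
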