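# Independent oracles: graph-search path lengths, a scalar LSTM
# re-implementation, an enumerating definite-NP constraint table, and a
# random sentence generator for relative-pronoun resolution.

# shortest path between two tree nodes by breadth-first search over the
# undirected parent/child adjacency (independent of the depth arithmetic)
bfs_path_length <- function(tree, from, to) {
  n <- nrow(tree$nodes)
  adj <- vector("list", n)
  for (id in seq_len(n)) {
    for (ch in tree$children[[id]]) {
      adj[[id]] <- c(adj[[id]], ch)
      adj[[ch]] <- c(adj[[ch]], id)
    }
  }
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    if (cur == to) return(dist[cur])
    for (nb in adj[[cur]]) if (is.na(dist[nb])) {
      dist[nb] <- dist[cur] + 1L
      queue <- c(queue, nb)
    }
  }
  stop("nodes not connected")
}

# exhaustive relative-pronoun resolution: enumerate every candidate and
# its BFS path length, then apply the documented tie-breaks
oracle_resolve_relative <- function(anaphor, doc, candidates) {
  cands <- candidates[candidates$sentence == anaphor$sentence &
                        candidates$tok_end < anaphor$tok_start, ,
                      drop = FALSE]
  if (nrow(cands) == 0L) return(NULL)
  tree <- doc$sentences[[anaphor$sentence + 1L]]$parse
  plen <- vapply(cands$node_id, function(id)
    bfs_path_length(tree, anaphor$node_id, id), integer(1))
  d <- abs(anaphor$head_gindex - cands$head_gindex) - 1L
  cands[order(plen, d, cands$tok_start), , drop = FALSE][1L, ]
}

# plain scalar forward pass written with explicit per-unit loops
scalar_lstm_forward <- function(X, params) {
  sg <- function(x) 1 / (1 + exp(-x))
  H <- params$hidden
  h <- rep(0, H); cc <- rep(0, H)
  for (t in seq_len(nrow(X))) {
    z <- c(h, X[t, ])
    hn <- numeric(H); cn <- numeric(H)
    for (j in seq_len(H)) {
      ij <- sg(sum(params$Wi[j, ] * z) + params$bi[j])
      fj <- sg(sum(params$Wf[j, ] * z) + params$bf[j])
      oj <- sg(sum(params$Wo[j, ] * z) + params$bo[j])
      gj <- tanh(sum(params$Wc[j, ] * z) + params$bc[j])
      cn[j] <- fj * cc[j] + ij * gj
      hn[j] <- oj * tanh(cn[j])
    }
    h <- hn; cc <- cn
  }
  sg(sum(params$w_out * h) + params$b_out)
}

# enumerating re-implementation of the definite-NP constraint table
oracle_resolve_definite <- function(anaphor, cands, window = 2L) {
  cands <- cands[cands$bioentity_count >= 1L &
                   cands$sentence >= anaphor$sentence - window &
                   (cands$sentence < anaphor$sentence |
                      cands$tok_end < anaphor$tok_start), , drop = FALSE]
  if (nrow(cands) == 0L) return(NULL)
  plural <- anaphor$number == "plural"
  pg <- anaphor$head_lemma %in% c("protein", "gene")
  hs <- function(x) tolower(x$head_surface)
  if (pg) pool <- cands[cands$protein_count >= 1L, , drop = FALSE]
  else pool <- cands
  if (nrow(pool) == 0L) return(NULL)
  tests <- if (plural && pg) {
    list(function(p) hs(p) %in% c("proteins", "genes"),
         function(p) p$protein_count > 1L)
  } else if (plural) {
    list(function(p) hs(p) == tolower(anaphor$head_surface),
         function(p) p$bioentity_count > 1L,
         function(p) p$protein_count > 1L)
  } else if (pg) {
    list(function(p) hs(p) %in% c("protein", "gene"),
         function(p) p$protein_count == 1L)
  } else {
    list(function(p) hs(p) == tolower(anaphor$head_surface),
         function(p) p$bioentity_count == 1L,
         function(p) p$protein_count == 1L)
  }
  for (f in tests) {
    sub <- pool[f(pool), , drop = FALSE]
    if (nrow(sub) > 0L) {
      d <- abs(anaphor$head_gindex - sub$head_gindex) - 1L
      return(sub[order(d, -sub$sentence, -sub$tok_start), ,
                 drop = FALSE][1L, ])
    }
  }
  NULL
}

# random single-sentence trees containing one relative pronoun and a
# varying number of (possibly nested) candidate NPs
random_relative_ptb <- function() {
  nid <- 0L
  rand_np <- function(depth) {
    nid <<- nid + 1L
    noun <- paste0("gene", nid)
    base <- if (stats::runif(1) < 0.5)
      sprintf("(NP (DT the) (NN %s))", noun)
    else sprintf("(NP (NN %s))", noun)
    if (depth > 0L && stats::runif(1) < 0.4)
      sprintf("(NP %s (PP (IN of) %s))", base, rand_np(depth - 1L))
    else base
  }
  verb <- function() sample(c("binds", "activates", "inhibits"), 1L)
  rel <- sprintf("(SBAR (WHNP (WDT %s)) (S (VP (VBZ %s) %s)))",
                 sample(c("which", "that"), 1L), verb(), rand_np(1L))
  subj <- rand_np(2L)
  obj <- rand_np(2L)
  extra <- if (stats::runif(1) < 0.4)
    sprintf(" (PP (IN with) %s)", rand_np(1L)) else ""
  if (stats::runif(1) < 0.5)
    sprintf("(S %s (VP (VBZ %s) %s%s %s) (. .))", subj, verb(), obj,
            extra, rel)
  else
    sprintf("(S %s (VP (VBZ %s) %s%s) %s (. .))", subj, verb(), obj,
            extra, rel)
}

# expected instance count from the mention frames alone
oracle_instance_count <- function(doc, gazetteer = NULL,
                                  windows = biocoref:::default_windows()) {
  anas <- detect_anaphors(doc, gazetteer)
  cands <- detect_candidates(doc, gazetteer)
  total <- 0L
  if (nrow(anas) > 0L) for (i in seq_len(nrow(anas))) {
    a <- anas[i, ]
    w <- windows[[a$mention_type]]
    total <- total + sum(cands$sentence >= a$sentence - w &
                           (cands$sentence < a$sentence |
                              cands$tok_end < a$tok_start))
  }
  total
}
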