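random_params <- function(input_dim, hidden, seed) {
  p <- lstm_init(input_dim, hidden, seed = seed)
  set.seed(seed + 100)
  p$w_out <- stats::rnorm(hidden, sd = 0.5)
  p$b_out <- stats::rnorm(1, sd = 0.2)
  p
}

test_that("all-zero parameters give probability exactly 0.5", {
  set.seed(1)
  for (rep in 1:5) {
    X <- matrix(stats::rnorm(4 * 7), nrow = 4)
    expect_identical(lstm_forward(X, lstm_zero_params(7, 3)), 0.5)
  }
})

test_that("the forward pass matches a scalar re-implementation", {
  set.seed(2)
  for (rep in 1:30) {
    l <- sample(1:6, 1)
    d <- sample(2:5, 1)
    H <- sample(2:4, 1)
    X <- matrix(stats::rnorm(l * d), nrow = l)
    p <- random_params(d, H, seed = rep)
    expect_equal(lstm_forward(X, p), scalar_lstm_forward(X, p),
                 tolerance = 1e-10)
  }
})

test_that("a single-step 1-dimensional cell equals the closed form", {
  p <- lstm_zero_params(1, 1)
  p$Wi[] <- c(0, 1); p$Wf[] <- c(0, 1); p$Wo[] <- c(0, 1); p$Wc[] <- c(0, 1)
  p$bi <- 0.1; p$bf <- 0.2; p$bo <- 0.3; p$bc <- 0.4
  p$w_out <- 2; p$b_out <- -0.5
  x <- 0.7
  sg <- function(u) 1 / (1 + exp(-u))
  i1 <- sg(x + 0.1); o1 <- sg(x + 0.3); g1 <- tanh(x + 0.4)
  h1 <- o1 * tanh(i1 * g1)           # c0 = 0, so the forget path vanishes
  expect_equal(lstm_forward(matrix(x, 1, 1), p), sg(2 * h1 - 0.5),
               tolerance = 1e-12)
})

test_that("hidden states stay inside the tanh bound", {
  set.seed(3)
  X <- matrix(stats::rnorm(40), nrow = 8)
  p <- random_params(5, 6, seed = 4)
  fw <- lstm_forward(X, p, with_cache = TRUE)
  for (s in fw$cache) {
    expect_true(all(is.finite(s$c)))
    expect_true(all(abs(o <- s$o * s$tanh_c) < 1))
  }
  expect_true(all(abs(fw$h_last) < 1))
})

test_that("backpropagation matches central finite differences", {
  set.seed(5)
  X <- matrix(stats::rnorm(12), nrow = 3)
  p <- random_params(4, 3, seed = 6)
  for (y in c(0, 1)) {
    fw <- lstm_forward(X, p, with_cache = TRUE)
    gr <- biocoref:::lstm_backward(fw, p, y)
    for (nm in biocoref:::PARAM_NAMES) {
      idx <- seq_len(min(5, length(p[[nm]])))
      for (i in idx) {
        eps <- 1e-6
        p1 <- p; p2 <- p
        p1[[nm]][i] <- p1[[nm]][i] + eps
        p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (bce_loss(lstm_forward(X, p1), y) -
                  bce_loss(lstm_forward(X, p2), y)) / (2 * eps)
        expect_lt(abs(gr[[nm]][i] - num), 1e-5)
      }
    }
  }
})

test_that("the loss equals independently computed binary cross-entropy", {
  p <- c(0.9, 0.2, 0.5, 0.99)
  y <- c(1, 0, 1, 1)
  expect_equal(bce_loss(p, y),
               -mean(c(log(0.9), log(0.8), log(0.5), log(0.99))))
})

small_planted_set <- function(seed, n_docs) {
  cfg <- fixture_config(seed = seed, n_docs = n_docs)
  pp <- generate_planted_pairs(cfg)
  emb <- train_embeddings(pp$docs, dim = 10, seed = seed, epochs = 2,
                          gazetteer = attr(pp$docs, "gazetteer"))
  list(pp = pp, emb = emb)
}

test_that("initial loss on balanced labels is ln 2 and training separates a small set", {
  s <- small_planted_set(83, 12)
  inst <- s$pp$instances
  y <- vapply(inst, `[[`, integer(1), "label")
  # balance to 10 positives + 10 negatives
  sel <- c(which(y == 1L)[1:10], which(y == 0L)[1:10])
  sel <- sel[!is.na(sel)]
  inst <- inst[sel]
  y <- y[sel]
  p0 <- lstm_init(s$emb$dim + 13L, 8, seed = 1)
  probs0 <- vapply(inst, function(i)
    lstm_forward(encode_sequence(i, s$emb), p0), numeric(1))
  expect_equal(bce_loss(probs0, y), log(2), tolerance = 1e-3)

  model <- lstm_train(inst, s$emb, hidden = 8, epochs = 50,
                      batch_size = 10, lr = 0.05, seed = 2)
  probs <- predict_instances(model, inst)
  expect_equal(mean((probs > 0.5) == (y == 1L)), 1.0)
  # loss decreases overall
  expect_lt(utils::tail(model$losses, 1), model$losses[1])
})

test_that("training is deterministic and refuses single-class data", {
  s <- small_planted_set(89, 8)
  inst <- s$pp$instances
  m1 <- lstm_train(inst, s$emb, hidden = 6, epochs = 4, batch_size = 16,
                   seed = 7)
  m2 <- lstm_train(inst, s$emb, hidden = 6, epochs = 4, batch_size = 16,
                   seed = 7)
  expect_identical(m1$losses, m2$losses)
  expect_identical(m1$params$Wi, m2$params$Wi)
  y <- vapply(inst, `[[`, integer(1), "label")
  expect_error(lstm_train(inst[y == 1L], s$emb, hidden = 4, epochs = 1),
               "single class")
})

test_that("antecedent decoding takes the argmax over positive instances", {
  s <- small_planted_set(97, 6)
  inst <- s$pp$instances
  akey <- vapply(inst, function(i)
    paste(i$doc_id, i$anaphor$start), character(1))
  grp <- inst[akey == akey[1]]
  model <- lstm_train(s$pp$instances, s$emb, hidden = 6, epochs = 8,
                      batch_size = 16, seed = 3)
  p <- predict_instances(model, grp)
  lk <- predict_antecedent(grp[[1]]$anaphor, grp, model)
  if (any(p > 0.5)) {
    best <- which.max(ifelse(p > 0.5, p, -Inf))
    expect_equal(c(lk$antecedent_start, lk$antecedent_end),
                 c(grp[[best]]$candidate$start, grp[[best]]$candidate$end))
  } else {
    expect_null(lk)
  }
  # permuting the instance list leaves the decoded link unchanged
  perm <- rev(seq_along(grp))
  lk2 <- predict_antecedent(grp[[1]]$anaphor, grp[perm], model)
  expect_equal(lk, lk2, ignore_attr = TRUE)
  # mixing anaphors is an error
  other <- inst[akey != akey[1]]
  if (length(other) > 0)
    expect_error(predict_antecedent(grp[[1]]$anaphor,
                                    c(grp, other[1]), model),
                 "share")
})

test_that("argmax agrees with an exhaustive maximum over random score sets", {
  set.seed(11)
  for (rep in 1:200) {
    k <- sample(1:6, 1)
    probs <- stats::runif(k)
    dists <- sample(1:20, k)
    pos <- which(probs > 0.5)
    if (length(pos) == 0L) next
    ord <- pos[order(-probs[pos], dists[pos])][1]
    brute <- pos[probs[pos] == max(probs[pos])]
    if (length(brute) > 1L) brute <- brute[which.min(dists[brute])]
    expect_equal(ord, brute)
  }
})

test_that("models survive a save/load round trip", {
  s <- small_planted_set(101, 5)
  model <- lstm_train(s$pp$instances, s$emb, hidden = 4, epochs = 2,
                      batch_size = 8, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$params, model$params)
  expect_identical(predict_instances(back, s$pp$instances[1:3]),
                   predict_instances(model, s$pp$instances[1:3]))
})
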