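# Single-layer LSTM mention-pair classifier. Gates act on the
# concatenation (h_{t-1}, x_t); the last hidden state h_l feeds a dense
# sigmoid layer giving P(Y = 1). Training minimizes mean binary
# cross-entropy with Adam over mini-batches; gradients come from full
# backpropagation through time.

#' Initialize LSTM parameters
#'
#' Gate weights use Glorot-uniform initialization under a fixed seed; the
#' forget-gate bias starts at 1 and the output layer at zero, so the
#' initial prediction is exactly 0.5 for any input.
#'
#' @param input_dim per-step input dimensionality
#' @param hidden hidden state size H
#' @param seed RNG seed
#' @return object of class \code{lstm_params}
#' @export
lstm_init <- function(input_dim, hidden, seed = 1L) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  z <- hidden + input_dim
  lim <- sqrt(6 / (hidden + z))
  mk <- function() matrix(stats::runif(hidden * z, -lim, lim), nrow = hidden)
  structure(list(Wi = mk(), Wf = mk(), Wo = mk(), Wc = mk(),
                 bi = numeric(hidden), bf = rep(1, hidden),
                 bo = numeric(hidden), bc = numeric(hidden),
                 w_out = numeric(hidden), b_out = 0,
                 hidden = hidden, input_dim = input_dim),
            class = "lstm_params")
}

#' Zero-valued LSTM parameters (useful as an analytic reference point)
#' @inheritParams lstm_init
#' @return \code{lstm_params} with all weights and biases zero
#' @export
lstm_zero_params <- function(input_dim, hidden) {
  z <- hidden + input_dim
  mk <- function() matrix(0, nrow = hidden, ncol = z)
  structure(list(Wi = mk(), Wf = mk(), Wo = mk(), Wc = mk(),
                 bi = numeric(hidden), bf = numeric(hidden),
                 bo = numeric(hidden), bc = numeric(hidden),
                 w_out = numeric(hidden), b_out = 0,
                 hidden = hidden, input_dim = input_dim),
            class = "lstm_params")
}

#' LSTM forward pass over one encoded sequence
#'
#' Runs the gated recurrence from zero initial hidden and cell state and
#' returns the link probability \eqn{P(Y=1) = \sigma(w \cdot h_l + b)}.
#'
#' @param X numeric matrix, one row per step (from
#'   \code{\link{encode_sequence}})
#' @param params an \code{lstm_params}
#' @param with_cache keep per-step activations for backpropagation
#' @return probability in (0, 1); with \code{with_cache}, a list
#'   \code{(p, cache)}
#' @export
lstm_forward <- function(X, params, with_cache = FALSE) {
  if (!is.matrix(X) || nrow(X) == 0L) stop("non-empty matrix input required")
  H <- params$hidden
  if (ncol(X) != params$input_dim)
    stop("input dimension mismatch: got ", ncol(X), ", expected ",
         params$input_dim)
  h <- numeric(H)
  cc <- numeric(H)
  l <- nrow(X)
  cache <- if (with_cache) vector("list", l) else NULL
  for (t in seq_len(l)) {
    z <- c(h, X[t, ])
    i <- sigmoid(as.numeric(params$Wi %*% z) + params$bi)
    f <- sigmoid(as.numeric(params$Wf %*% z) + params$bf)
    o <- sigmoid(as.numeric(params$Wo %*% z) + params$bo)
    g <- tanh(as.numeric(params$Wc %*% z) + params$bc)
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    if (with_cache)
      cache[[t]] <- list(z = z, i = i, f = f, o = o, g = g,
                         c = cc, c_prev = c_prev, tanh_c = tc)
  }
  p <- sigmoid(sum(params$w_out * h) + params$b_out)
  if (!with_cache) return(p)
  list(p = p, h_last = h, cache = cache)
}

# BPTT gradients of the binary cross-entropy for one sequence
lstm_backward <- function(fw, params, y) {
  H <- params$hidden
  cache <- fw$cache
  l <- length(cache)
  g0 <- function() matrix(0, nrow = H, ncol = H + params$input_dim)
  gr <- list(Wi = g0(), Wf = g0(), Wo = g0(), Wc = g0(),
             bi = numeric(H), bf = numeric(H), bo = numeric(H),
             bc = numeric(H), w_out = numeric(H), b_out = 0)
  du <- fw$p - y                      # d loss / d output logit
  gr$w_out <- du * fw$h_last
  gr$b_out <- du
  dh <- du * params$w_out
  dc_next <- numeric(H)
  for (t in rev(seq_len(l))) {
    s <- cache[[t]]
    do <- dh * s$tanh_c
    dc <- dc_next + dh * s$o * (1 - s$tanh_c^2)
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dc_next <- dc * s$f
    dpi <- di * s$i * (1 - s$i)
    dpf <- df * s$f * (1 - s$f)
    dpo <- do * s$o * (1 - s$o)
    dpg <- dg * (1 - s$g^2)
    gr$Wi <- gr$Wi + dpi %o% s$z
    gr$Wf <- gr$Wf + dpf %o% s$z
    gr$Wo <- gr$Wo + dpo %o% s$z
    gr$Wc <- gr$Wc + dpg %o% s$z
    gr$bi <- gr$bi + dpi
    gr$bf <- gr$bf + dpf
    gr$bo <- gr$bo + dpo
    gr$bc <- gr$bc + dpg
    dz <- as.numeric(crossprod(params$Wi, dpi) + crossprod(params$Wf, dpf) +
                       crossprod(params$Wo, dpo) + crossprod(params$Wc, dpg))
    dh <- dz[seq_len(H)]
  }
  gr
}

#' Mean binary cross-entropy
#' @param p predicted probabilities
#' @param y binary labels
#' @return scalar loss
#' @export
bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

PARAM_NAMES <- c("Wi", "Wf", "Wo", "Wc", "bi", "bf", "bo", "bc",
                 "w_out", "b_out")

#' Train the LSTM mention-pair classifier
#'
#' Minimizes mean binary cross-entropy by mini-batch Adam over encoded
#' sequence instances. Requires at least one instance of each class.
#' When a \code{dev} set is supplied, the parameters with the best dev F1
#' (classification at \code{threshold}) are kept; otherwise the final
#' parameters are returned. Fully deterministic for fixed seed and data.
#'
#' @param instances list of labelled \code{seq_instance}
#' @param emb a \code{coref_embeddings} used to encode items
#' @param hidden hidden units (paper-scale default 200)
#' @param epochs maximum training epochs
#' @param batch_size mini-batch size
#' @param lr Adam learning rate
#' @param seed RNG seed for init and shuffling
#' @param dev optional held-out instance list for checkpoint selection
#' @param threshold decision threshold
#' @param verbose print per-epoch loss
#' @return object of class \code{lstm_coref_model}: params, embeddings,
#'   per-epoch training losses, and the configuration used
#' @export
lstm_train <- function(instances, emb, hidden = 200L, epochs = 50L,
                       batch_size = 80L, lr = 0.01, seed = 1L, dev = NULL,
                       threshold = 0.5, verbose = FALSE) {
  y <- vapply(instances, `[[`, integer(1), "label")
  if (anyNA(y)) stop("all training instances must be labelled")
  if (length(unique(y)) < 2L)
    stop("training set contains a single class")
  X <- lapply(instances, encode_sequence, emb = emb)
  n <- length(X)
  input_dim <- emb$dim + 13L
  params <- lstm_init(input_dim, hidden, seed = seed)

  m <- lapply(params[PARAM_NAMES], function(p) p * 0)
  v <- lapply(params[PARAM_NAMES], function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  tstep <- 0L

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed + 1L)

  dev_X <- if (!is.null(dev)) lapply(dev, encode_sequence, emb = emb)
  dev_y <- if (!is.null(dev)) vapply(dev, `[[`, integer(1), "label")
  best <- list(f1 = -1, params = NULL, epoch = NA_integer_)

  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    for (b_start in seq(1L, n, by = batch_size)) {
      idx <- perm[b_start:min(b_start + batch_size - 1L, n)]
      gsum <- NULL
      for (k in idx) {
        fw <- lstm_forward(X[[k]], params, with_cache = TRUE)
        ep_loss <- ep_loss + bce_loss(fw$p, y[k])
        g <- lstm_backward(fw, params, y[k])
        gsum <- if (is.null(gsum)) g else
          Map(`+`, gsum, g)
      }
      gsum <- lapply(gsum, `/`, length(idx))
      tstep <- tstep + 1L
      for (nm in PARAM_NAMES) {
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gsum[[nm]]
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gsum[[nm]]^2
        mhat <- m[[nm]] / (1 - b1^tstep)
        vhat <- v[[nm]] / (1 - b2^tstep)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    losses[ep] <- ep_loss / n
    if (verbose) message("epoch ", ep, " loss ", round(losses[ep], 5))
    if (!is.null(dev)) {
      dp <- vapply(dev_X, lstm_forward, numeric(1), params = params)
      pred <- as.integer(dp > threshold)
      tp <- sum(pred == 1L & dev_y == 1L)
      f1 <- if (sum(pred) + sum(dev_y) == 0L) 0 else
        2 * tp / (sum(pred) + sum(dev_y))
      if (f1 > best$f1) best <- list(f1 = f1, params = params, epoch = ep)
    }
  }
  if (!is.null(dev) && !is.null(best$params)) {
    params <- best$params
  }
  structure(list(params = params, emb = emb, hidden = hidden,
                 input_dim = input_dim, losses = losses,
                 threshold = threshold,
                 best_epoch = if (is.null(dev)) length(losses)
                              else best$epoch,
                 config = list(epochs = epochs, batch_size = batch_size,
                               lr = lr, seed = seed)),
            class = "lstm_coref_model")
}

#' @export
print.lstm_coref_model <- function(x, ...) {
  cat("<lstm_coref_model> hidden", x$hidden, "input_dim", x$input_dim,
      "- final loss", round(utils::tail(x$losses, 1), 4), "\n")
  invisible(x)
}

#' Predict link probabilities for a list of instances
#' @param model an \code{lstm_coref_model}
#' @param instances list of \code{seq_instance}
#' @return numeric vector of probabilities
#' @export
predict_instances <- function(model, instances) {
  vapply(instances, function(inst)
    lstm_forward(encode_sequence(inst, model$emb), model$params),
    numeric(1))
}

#' Decode the antecedent of one anaphor
#'
#' Among the anaphor's instances classified positive (probability above
#' the threshold), returns the candidate with maximal probability; ties
#' are broken toward the closer candidate. NULL when no instance is
#' positive.
#'
#' @param anaphor one-row anaphor mention frame (all instances must share
#'   this anaphor)
#' @param instances the anaphor's candidate instances
#' @param model an \code{lstm_coref_model}
#' @param threshold decision threshold (model default when NULL)
#' @return one-row link data.frame or NULL
#' @export
predict_antecedent <- function(anaphor, instances, model, threshold = NULL) {
  if (length(instances) == 0L) return(NULL)
  same <- vapply(instances, function(inst)
    inst$anaphor$start == anaphor$start && inst$anaphor$end == anaphor$end,
    logical(1))
  if (!all(same)) stop("instances do not all share the given anaphor")
  if (is.null(threshold)) threshold <- model$threshold
  p <- predict_instances(model, instances)
  pos <- which(p > threshold)
  if (length(pos) == 0L) return(NULL)
  d <- vapply(instances[pos], `[[`, integer(1), "distance")
  best <- pos[order(-p[pos], d)][1L]
  inst <- instances[[best]]
  lk <- link_row(list(doc_id = inst$doc_id), inst$anaphor, inst$candidate)
  attr(lk, "probability") <- p[best]
  lk
}

#' Resolve a whole document with a trained model
#'
#' Builds the document's instances, groups them by anaphor and decodes at
#' most one link per anaphor.
#'
#' @param doc a parsed \code{coref_document}
#' @param model an \code{lstm_coref_model}
#' @param windows sentence windows per anaphor type
#' @param max_len maximum instance length
#' @param gazetteer optional bio-entity terms
#' @return link data.frame
#' @export
lstm_resolve_all <- function(doc, model, windows = default_windows(),
                             max_len = 82L, gazetteer = NULL) {
  instances <- build_instances(doc, windows = windows, max_len = max_len,
                               gazetteer = gazetteer)
  if (length(instances) == 0L) return(empty_links())
  akey <- vapply(instances, function(i)
    paste(i$anaphor$start, i$anaphor$end), character(1))
  links <- list()
  for (k in unique(akey)) {
    grp <- instances[akey == k]
    lk <- predict_antecedent(grp[[1L]]$anaphor, grp, model)
    if (!is.null(lk)) links[[length(links) + 1L]] <- lk
  }
  if (length(links) == 0L) return(empty_links())
  out <- do.call(rbind, links)
  out[order(out$anaphor_start, out$anaphor_end), , drop = FALSE]
}

#' Save / load a trained model
#' @param model an \code{lstm_coref_model}
#' @param path file path
#' @return \code{path} (save) or the model (load)
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "lstm_coref_model")) stop("not an lstm_coref_model file")
  m
}
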