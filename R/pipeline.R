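# End-to-end orchestration: read standoff bundles -> detect mentions ->
# resolve (rules or LSTM) -> write predictions -> score against gold.

#' Assemble a pipeline configuration
#'
#' @param method \code{"rules"} or \code{"lstm"}
#' @param input_dir directory of standoff bundles (.txt/.a1/.ptb, optional
#'   .a2 gold)
#' @param out_dir optional directory for predicted .a2 files
#' @param gazetteer bio-entity terms: a character vector or a path to a
#'   one-term-per-line file
#' @param model_path trained model file (required for \code{lstm})
#' @param windows per-type sentence windows (defaults 0/1/2)
#' @param mode scoring mode when gold links are present
#' @param seed seed recorded in the report
#' @param verbose log every resolution decision to stderr
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(method = c("rules", "lstm"), input_dir = NULL,
                            out_dir = NULL, gazetteer = NULL,
                            model_path = NULL,
                            windows = default_windows(),
                            mode = c("partial", "strict"), seed = 1L,
                            verbose = FALSE) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (any(unlist(windows) < 0L)) stop("windows must be non-negative")
  if (method == "lstm" && is.null(model_path))
    stop("method 'lstm' requires model_path")
  structure(list(method = method, input_dir = input_dir, out_dir = out_dir,
                 gazetteer = gazetteer, model_path = model_path,
                 windows = windows, mode = mode, seed = seed,
                 verbose = verbose),
            class = "pipeline_config")
}

#' Read a YAML pipeline configuration file
#' @param path YAML file with keys matching \code{\link{pipeline_config}}
#' @return a \code{pipeline_config}
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  w <- default_windows()
  if (!is.null(y$windows)) for (nm in names(y$windows))
    w[[nm]] <- as.integer(y$windows[[nm]])
  pipeline_config(method = y$method %||% "rules",
                  input_dir = y$input_dir, out_dir = y$out_dir,
                  gazetteer = y$gazetteer, model_path = y$model_path,
                  windows = w, mode = y$mode %||% "partial",
                  seed = as.integer(y$seed %||% 1L),
                  verbose = isTRUE(y$verbose))
}

resolve_gazetteer <- function(gazetteer) {
  if (is.null(gazetteer)) return(NULL)
  if (length(gazetteer) == 1L && file.exists(gazetteer))
    return(read_gazetteer(gazetteer))
  gazetteer
}

#' Run the coreference pipeline over a corpus
#'
#' For every document: detect mentions, resolve each anaphor with the
#' configured method, optionally write predicted links as .a2 files, and
#' when gold links are present score them and run the error audit.
#'
#' @param cfg a \code{\link{pipeline_config}}
#' @param docs optional pre-loaded document list (bypasses
#'   \code{input_dir})
#' @return list of class \code{coref_report}: prediction counts per
#'   document, the pooled predicted links, and \code{eval}/\code{audit}
#'   when gold links exist
#' @export
run_pipeline <- function(cfg, docs = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(docs)) {
    if (is.null(cfg$input_dir)) stop("no input_dir and no docs supplied")
    docs <- read_corpus_dir(cfg$input_dir)
  }
  gaz <- resolve_gazetteer(cfg$gazetteer)
  model <- if (cfg$method == "lstm") load_model(cfg$model_path)

  preds <- list()
  mentions <- list()
  per_doc <- list()
  for (doc in docs) {
    if (length(doc$sentences) == 0L)
      stop("document ", doc$doc_id, " has no parses (missing .ptb sidecar?)")
    mn <- rbind(detect_anaphors(doc, gaz), detect_candidates(doc, gaz))
    links <- if (cfg$method == "rules") {
      resolve_all(doc, gazetteer = gaz,
                  definite_window = cfg$windows[["definite_np"]])
    } else {
      lstm_resolve_all(doc, model, windows = cfg$windows, gazetteer = gaz)
    }
    if (cfg$verbose && !is.null(attr(links, "log"))) {
      lg <- attr(links, "log")
      for (i in seq_len(nrow(lg)))
        message(sprintf("[%s] %s (%s) -> %s [%s]", lg$doc_id[i],
                        lg$anaphor[i], lg$anaphor_type[i],
                        lg$antecedent[i] %||% "none", lg$fired[i]))
    }
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_links(doc, links,
                  file.path(cfg$out_dir, paste0(doc$doc_id, ".a2")))
    }
    preds[[length(preds) + 1L]] <- links
    mentions[[length(mentions) + 1L]] <- mn
    per_doc[[length(per_doc) + 1L]] <- data.frame(
      doc_id = doc$doc_id,
      n_anaphors = sum(mn$mention_type != "np_candidate"),
      n_candidates = sum(mn$mention_type == "np_candidate"),
      n_links = nrow(links),
      n_gold = if (is.null(doc$gold_links)) 0L else nrow(doc$gold_links),
      stringsAsFactors = FALSE)
  }
  pred <- if (length(preds) == 0L) empty_links() else
    do.call(rbind, lapply(preds, function(x) { attr(x, "log") <- NULL; x }))
  all_mentions <- if (length(mentions) == 0L) empty_mentions() else
    do.call(rbind, mentions)

  gold_list <- Filter(Negate(is.null), lapply(docs, `[[`, "gold_links"))
  eval <- audit <- NULL
  if (length(gold_list) > 0L) {
    gold <- do.call(rbind, gold_list)
    gold <- attach_link_types(gold, all_mentions)
    eval <- score_links(gold, pred, docs, mode = cfg$mode)
    audit <- error_audit(gold, pred, all_mentions, docs,
                         windows = cfg$windows, mode = cfg$mode)
  }
  structure(list(method = cfg$method, seed = cfg$seed,
                 n_docs = length(docs),
                 per_doc = do.call(rbind, per_doc),
                 pred = pred, eval = eval, audit = audit),
            class = "coref_report")
}

#' @export
print.coref_report <- function(x, ...) {
  cat("<coref_report>", x$method, "over", x$n_docs, "documents,",
      nrow(x$pred), "predicted links\n")
  if (!is.null(x$eval)) print(x$eval)
  invisible(x)
}

#' Write a run report as JSON
#'
#' Mirrors the evaluation tables: overall and per-type recall/precision/
#' F1 plus the error-category counts.
#'
#' @param report a \code{coref_report}
#' @param path output JSON path
#' @return \code{path}, invisibly
#' @export
write_report <- function(report, path) {
  out <- list(method = report$method, n_docs = report$n_docs,
              n_pred_links = nrow(report$pred))
  if (!is.null(report$eval)) {
    e <- report$eval
    out$overall <- list(recall = e$recall, precision = e$precision,
                        f1 = e$f1, n_gold = e$n_gold, n_pred = e$n_pred)
    out$per_type <- e$per_type
  }
  if (!is.null(report$audit)) {
    a <- report$audit
    out$errors <- list(missing = as.data.frame(a$missing),
                       spurious = as.data.frame(a$spurious),
                       missing_total = a$missing_total,
                       spurious_total = a$spurious_total)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
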