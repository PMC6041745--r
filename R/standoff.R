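# BioNLP-ST standoff I/O (.txt / .a1 / .a2) plus the bracketed-parse
# sidecar (.ptb, one tree per line, aligned to sentences).

read_text_file <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop("file not found: ", path)
  txt <- readChar(path, sz, useBytes = TRUE)
  Encoding(txt) <- "UTF-8"
  txt
}

parse_standoff_t_line <- function(line, lineno, path) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 2L)
    stop("malformed standoff line ", lineno, " in ", path, ": '", line, "'")
  mid <- strsplit(parts[2L], " ", fixed = TRUE)[[1]]
  if (length(mid) != 3L)
    stop("malformed mention span at line ", lineno, " in ", path)
  start <- suppressWarnings(as.integer(mid[2L]))
  end <- suppressWarnings(as.integer(mid[3L]))
  if (is.na(start) || is.na(end))
    stop("non-numeric offsets at line ", lineno, " in ", path)
  list(ann_id = parts[1L], label = mid[1L], start = start, end = end,
       text = if (length(parts) >= 3L) parts[3L] else NA_character_)
}

#' Read a BioNLP-ST standoff document bundle
#'
#' Reads raw text, protein term annotations (.a1), optional gold
#' coreference links (.a2, \code{R} lines with \code{Anaphora}/
#' \code{Antecedent} roles) and the bracketed-parse sidecar (.ptb).
#'
#' @param txt_path path to the .txt file
#' @param a1_path path to the .a1 file (may be missing/empty)
#' @param a2_path optional path to a .a2 file; gold links are populated
#'   iff given
#' @param ptb_path optional path to the .ptb sidecar; defaults to the
#'   .txt path with extension replaced. Required for any downstream
#'   mention detection; pass \code{NA} to skip parses.
#' @param doc_id document id; defaults to the .txt basename
#' @return a \code{coref_document}
#' @export
read_standoff <- function(txt_path, a1_path = NULL, a2_path = NULL,
                          ptb_path = NULL, doc_id = NULL) {
  if (is.null(doc_id)) doc_id <- sub("\\.txt$", "", basename(txt_path))
  text <- read_text_file(txt_path)
  text <- sub("\n+$", "", text)

  proteins <- empty_proteins()
  if (!is.null(a1_path) && file.exists(a1_path)) {
    lines <- readLines(a1_path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) > 0L) {
      rows <- lapply(seq_along(lines), function(i) {
        r <- parse_standoff_t_line(lines[i], i, a1_path)
        as.data.frame(r, stringsAsFactors = FALSE)
      })
      proteins <- do.call(rbind, rows)
      got <- substring(text, proteins$start + 1L, proteins$end)
      bad <- which(!is.na(proteins$text) & got != proteins$text)
      if (length(bad) > 0L)
        stop(doc_id, ": a1 span/text mismatch for ", proteins$ann_id[bad[1L]])
      proteins$text <- got
    }
  }

  if (is.null(ptb_path)) {
    cand <- sub("\\.txt$", ".ptb", txt_path)
    ptb_path <- if (file.exists(cand)) cand else NA
  }
  if (!is.na(ptb_path) && !file.exists(ptb_path))
    stop(doc_id, ": parse sidecar not found: ", ptb_path)

  gold <- NULL
  if (!is.null(a2_path) && file.exists(a2_path)) {
    gold <- read_a2_links(a2_path, text, proteins, doc_id)
  }

  if (!is.na(ptb_path)) {
    ptb <- readLines(ptb_path, warn = FALSE)
    ptb <- ptb[nzchar(trimws(ptb))]
    doc <- build_document(doc_id, text, ptb, proteins, gold)
  } else {
    doc <- structure(list(doc_id = doc_id, text = text, sentences = list(),
                          proteins = proteins, gold_links = gold),
                     class = "coref_document")
  }
  doc
}

read_a2_links <- function(a2_path, text, proteins, doc_id) {
  lines <- readLines(a2_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  spans <- list()
  if (nrow(proteins) > 0L)
    for (k in seq_len(nrow(proteins)))
      spans[[proteins$ann_id[k]]] <- c(proteins$start[k], proteins$end[k])
  links <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "T")) {
      r <- parse_standoff_t_line(ln, i, a2_path)
      if (r$start < 0L || r$end > nchar(text) || r$start >= r$end)
        stop(doc_id, ": a2 mention ", r$ann_id, " span outside text")
      spans[[r$ann_id]] <- c(r$start, r$end)
    } else if (startsWith(ln, "R")) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L)
        stop("malformed relation line ", i, " in ", a2_path)
      fields <- strsplit(parts[2L], " ", fixed = TRUE)[[1]]
      args <- fields[-1L]
      kv <- strsplit(args, ":", fixed = TRUE)
      names(kv) <- vapply(kv, `[[`, character(1), 1L)
      ana <- kv[["Anaphora"]][2L]
      ant <- kv[["Antecedent"]][2L]
      if (is.null(spans[[ana]]) || is.null(spans[[ant]]))
        stop("dangling mention reference at line ", i, " in ", a2_path)
      links[[length(links) + 1L]] <- data.frame(
        doc_id = doc_id,
        anaphor_start = spans[[ana]][1L], anaphor_end = spans[[ana]][2L],
        anaphor_type = NA_character_,
        antecedent_start = spans[[ant]][1L], antecedent_end = spans[[ant]][2L],
        stringsAsFactors = FALSE)
    }
  }
  if (length(links) == 0L) return(empty_links())
  do.call(rbind, links)
}

#' Write coreference links in standoff .a2 form
#'
#' Emits one \code{T} line per distinct mention span (label \code{Exp},
#' numbered after the document's .a1 annotations, in span order) and one
#' \code{R} line per link (\code{Coref Anaphora:Tx Antecedent:Ty}, ordered
#' by anaphor position then antecedent position), so output is byte-stable
#' for a given link set and \code{\link{read_standoff}} inverts it.
#'
#' @param doc the \code{coref_document} the links belong to
#' @param links links data.frame (columns as in \code{empty} link frame)
#' @param out_path output file path
#' @return \code{out_path}, invisibly
#' @export
write_links <- function(doc, links, out_path) {
  n <- nchar(doc$text)
  if (nrow(links) > 0L) {
    bad <- links$anaphor_start < 0 | links$anaphor_end > n |
      links$antecedent_start < 0 | links$antecedent_end > n
    if (any(bad))
      stop(doc$doc_id, ": link span not resolvable to document offsets")
  }
  t_base <- 0L
  if (nrow(doc$proteins) > 0L) {
    ids <- suppressWarnings(as.integer(sub("^T", "", doc$proteins$ann_id)))
    if (!anyNA(ids)) t_base <- max(ids)
  }
  out <- character()
  span_id <- character()
  if (nrow(links) > 0L) {
    spans <- unique(rbind(
      data.frame(start = links$anaphor_start, end = links$anaphor_end),
      data.frame(start = links$antecedent_start, end = links$antecedent_end)))
    spans <- spans[order(spans$start, spans$end), , drop = FALSE]
    for (k in seq_len(nrow(spans))) {
      id <- paste0("T", t_base + k)
      span_id[paste(spans$start[k], spans$end[k])] <- id
      out <- c(out, paste0(id, "\tExp ", spans$start[k], " ", spans$end[k],
                           "\t", substring(doc$text, spans$start[k] + 1L,
                                           spans$end[k])))
    }
    lk <- links[order(links$anaphor_start, links$anaphor_end,
                      links$antecedent_start, links$antecedent_end), ,
                drop = FALSE]
    for (k in seq_len(nrow(lk))) {
      out <- c(out, paste0(
        "R", k, "\tCoref Anaphora:",
        span_id[paste(lk$anaphor_start[k], lk$anaphor_end[k])],
        " Antecedent:",
        span_id[paste(lk$antecedent_start[k], lk$antecedent_end[k])]))
    }
  }
  writeLines(out, out_path)
  invisible(out_path)
}

#' Write a document bundle (.txt/.a1/.ptb and .a2 when gold links exist)
#' @param doc a \code{coref_document}
#' @param dir output directory, created if needed
#' @return the directory, invisibly
#' @export
write_standoff <- function(doc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, doc$doc_id)
  con <- file(paste0(base, ".txt"), "wb")
  writeChar(doc$text, con, eos = NULL)
  close(con)
  a1 <- character()
  if (nrow(doc$proteins) > 0L)
    a1 <- paste0(doc$proteins$ann_id, "\t", doc$proteins$label, " ",
                 doc$proteins$start, " ", doc$proteins$end, "\t",
                 doc$proteins$text)
  writeLines(a1, paste0(base, ".a1"))
  writeLines(vapply(doc$sentences, function(s) deparse_parse(s$parse),
                    character(1)), paste0(base, ".ptb"))
  if (!is.null(doc$gold_links))
    write_links(doc, doc$gold_links, paste0(base, ".a2"))
  invisible(dir)
}

#' Read every standoff bundle in a directory
#' @param dir directory holding .txt/.a1/.ptb (and optionally .a2) files
#' @return list of \code{coref_document}
#' @export
read_corpus_dir <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  # a document bundle has at least an .a1 or .ptb mate; stray text files
  # (e.g. a gazetteer) are not documents
  has_mate <- vapply(txts, function(tp) {
    base <- sub("\\.txt$", "", tp)
    file.exists(paste0(base, ".a1")) || file.exists(paste0(base, ".ptb"))
  }, logical(1))
  txts <- txts[has_mate]
  if (length(txts) == 0L) return(list())
  lapply(txts, function(tp) {
    base <- sub("\\.txt$", "", tp)
    a2 <- paste0(base, ".a2")
    read_standoff(tp,
                  a1_path = paste0(base, ".a1"),
                  a2_path = if (file.exists(a2)) a2 else NULL,
                  ptb_path = paste0(base, ".ptb"))
  })
}

#' Write a corpus of documents as standoff bundles
#' @param docs list of \code{coref_document}
#' @param dir output directory
#' @return \code{dir}, invisibly
#' @export
write_corpus <- function(docs, dir) {
  for (d in docs) write_standoff(d, dir)
  invisible(dir)
}
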