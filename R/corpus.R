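#' Read a corpus of plain-text documents
#'
#' Two layouts are supported: a directory of UTF-8 \code{.txt} files (one
#' document per file, \code{doc_id} = file name without extension) or a
#' JSON-lines file with one \code{{"doc_id": ..., "text": ...}} record per
#' line. Empty documents are dropped with a warning.
#'
#' @param path directory (textdir) or file (jsonl).
#' @param format \code{"textdir"} or \code{"jsonl"}.
#' @return list of documents, each \code{list(doc_id=, text=)}, class
#'   \code{"corpus"}.
#' @export
read_corpus <- function(path, format = c("textdir", "jsonl")) {
  format <- match.arg(format)
  docs <- if (format == "textdir") {
    if (!dir.exists(path)) stop("no such directory: ", path)
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    lapply(files, function(f)
      list(doc_id = sub("\\.txt$", "", basename(f)),
           text = paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                        collapse = "\n")))
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e)
                        stop("malformed JSON-lines record at line ", i, ": ",
                             conditionMessage(e)))
      if (is.null(rec$doc_id) || is.null(rec$text))
        stop("malformed JSON-lines record at line ", i,
             ": needs doc_id and text")
      list(doc_id = as.character(rec$doc_id), text = as.character(rec$text))
    })
  }
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids))
    stop("integrity error: duplicate doc_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  empty <- !nzchar(trimws(vapply(docs, `[[`, character(1), "text")))
  if (any(empty)) {
    warning(sum(empty), " empty document(s) dropped")
    docs <- docs[!empty]
  }
  structure(docs, class = "corpus")
}

#' Tokenize, tag and lemmatize one document
#'
#' Applies a tagger honouring the contract of \code{\link{simple_tagger}}
#' and attaches the result as \code{sentences}: a list of data.frames with
#' columns \code{surface}, \code{base_form}, \code{pos}. Unknown tags map
#' to \code{OTHER}; empty sentences are dropped.
#'
#' @param doc a document (\code{list(doc_id=, text=)}).
#' @param tagger a tagger function; default \code{simple_tagger()}.
#' @return the document with a \code{sentences} element.
#' @export
analyze_document <- function(doc, tagger = simple_tagger()) {
  sents <- tryCatch(tagger(doc$text), error = function(e)
    stop("tagger failure on document '", doc$doc_id, "': ",
         conditionMessage(e)))
  ok_pos <- c("NOUN", "VERB", "ADJ", "ADV", "OTHER")
  sents <- lapply(sents, function(s) {
    s$pos[!(s$pos %in% ok_pos)] <- "OTHER"
    s
  })
  sents <- sents[vapply(sents, nrow, integer(1)) > 0]
  doc$sentences <- sents
  doc
}

#' @rdname analyze_document
#' @param corpus a \code{corpus}.
#' @return \code{analyze_corpus}: the corpus with every document analyzed.
#' @export
analyze_corpus <- function(corpus, tagger = simple_tagger()) {
  structure(lapply(corpus, analyze_document, tagger = tagger),
            class = "corpus")
}

content_pos <- c("NOUN", "VERB", "ADJ", "ADV")

rare_pseudo <- c(NOUN = "rare-noun", VERB = "rare-verb",
                 ADJ = "rare-adjective", ADV = "rare-adverb")

#' Build part-of-speech-filtered context windows
#'
#' For every content-word occurrence (noun, verb, adjective or adverb) the
#' context is the k nearest content words on each side within the same
#' sentence (2k = 4 by default), ignoring order. Base forms whose
#' corpus-wide frequency does not exceed \code{rare_threshold} are binned
#' into part-of-speech pseudo-words (\code{rare-noun}, \code{rare-verb},
#' \code{rare-adjective}, \code{rare-adverb}) to densify sparse contexts.
#' Windows at sentence boundaries are truncated, never padded.
#'
#' @param corpus an analyzed corpus (see \code{\link{analyze_corpus}}).
#' @param k half-window size in content words per side (default 2).
#' @param rare_threshold corpus-wide base-form frequency at or below which a
#'   context word is replaced by its POS pseudo-word (default 1: words
#'   appearing uniquely in the corpus).
#' @return data.frame with one row per content-word occurrence: columns
#'   \code{doc_id}, \code{base_form}, \code{pos}, \code{context} (canonical
#'   order-invariant key: sorted \code{base/pos} items joined by
#'   \code{"\\x1f"}).
#' @export
build_contexts <- function(corpus, k = 2, rare_threshold = 1) {
  stopifnot(k >= 1)
  # corpus-wide base-form counts over content words (drives rare binning)
  all_tok <- do.call(rbind, unlist(lapply(corpus, function(d) d$sentences),
                                   recursive = FALSE))
  if (is.null(all_tok) || !nrow(all_tok))
    return(data.frame(doc_id = character(), base_form = character(),
                      pos = character(), context = character(),
                      stringsAsFactors = FALSE))
  content <- all_tok[all_tok$pos %in% content_pos, , drop = FALSE]
  counts <- table(content$base_form)

  res <- lapply(corpus, function(d) {
    per_sent <- lapply(d$sentences, function(s) {
      cw <- s[s$pos %in% content_pos, , drop = FALSE]
      n <- nrow(cw)
      if (!n) return(NULL)
      # pre-bin the context representation of each content word
      ctx_item <- ifelse(as.vector(counts[cw$base_form]) <= rare_threshold,
                         paste0(rare_pseudo[cw$pos], "/", cw$pos),
                         paste0(cw$base_form, "/", cw$pos))
      keys <- vapply(seq_len(n), function(i) {
        lo <- max(1L, i - k); hi <- min(n, i + k)
        idx <- setdiff(lo:hi, i)
        paste(sort(ctx_item[idx]), collapse = "\x1f")
      }, character(1))
      data.frame(doc_id = d$doc_id, base_form = cw$base_form, pos = cw$pos,
                 context = keys, stringsAsFactors = FALSE)
    })
    do.call(rbind, per_sent)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

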