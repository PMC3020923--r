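#' Recognize ontology concepts in an analyzed corpus
#'
#' Dictionary-based concept recognition at the lemma level: each concept's
#' preferred name and synonyms are normalized to lemma-token sequences, and
#' every sentence is scanned left to right with longest-match-first
#' resolution (overlapping candidate spans go to the longest term, ties to
#' the leftmost). Matching is case-insensitive and never crosses sentence
#' boundaries.
#'
#' @param corpus an analyzed corpus (see \code{\link{analyze_corpus}}).
#' @param ontology an \code{ontology} (or any object with a
#'   \code{concepts} data.frame) acting as the recognition lexicon.
#' @param unit co-occurrence unit: \code{"document"} (default; the medical
#'   abstract in the reference setting) or \code{"sentence"}.
#' @return data.frame of mentions with columns \code{unit_id},
#'   \code{doc_id}, \code{concept_id}, \code{surface_span}.
#' @export
match_concepts <- function(corpus, ontology, unit = c("document", "sentence")) {
  unit <- match.arg(unit)
  cdf <- ontology$concepts
  dict <- new.env(parent = emptyenv())
  max_len <- 1L
  for (i in seq_len(nrow(cdf))) {
    terms <- c(cdf$preferred_name[i],
               strsplit(cdf$synonyms[i], "|", fixed = TRUE)[[1]])
    for (t in terms[nzchar(terms)]) {
      key <- normalize_term(t)
      if (!nzchar(key)) next
      nlen <- length(strsplit(key, " ", fixed = TRUE)[[1]])
      max_len <- max(max_len, nlen)
      prev <- get0(key, envir = dict)
      if (is.null(prev)) assign(key, cdf$id[i], envir = dict)
    }
  }
  out <- lapply(corpus, function(d) {
    mentions <- list()
    for (si in seq_along(d$sentences)) {
      s <- d$sentences[[si]]
      lem <- s$base_form
      n <- length(lem)
      i <- 1L
      while (i <= n) {
        hit <- NULL
        for (L in seq(min(max_len, n - i + 1L), 1L)) {
          key <- paste(lem[i:(i + L - 1L)], collapse = " ")
          cid <- get0(key, envir = dict)
          if (!is.null(cid)) { hit <- list(cid = cid, L = L); break }
        }
        if (!is.null(hit)) {
          mentions[[length(mentions) + 1L]] <- data.frame(
            unit_id = if (unit == "document") d$doc_id
                      else paste0(d$doc_id, "#", si),
            doc_id = d$doc_id, concept_id = hit$cid,
            surface_span = paste(s$surface[i:(i + hit$L - 1L)], collapse = " "),
            stringsAsFactors = FALSE)
          i <- i + hit$L
        } else i <- i + 1L
      }
    }
    do.call(rbind, mentions)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(unit_id = character(), doc_id = character(),
                      concept_id = character(), surface_span = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Concept usage frequencies from mentions
#'
#' Normalized mention counts: f_i = mentions(i) / total mentions, summing
#' to one over the concepts observed in the corpus.
#'
#' @param mentions mention data.frame from \code{\link{match_concepts}}.
#' @return named numeric vector of frequencies f, sorted by concept id.
#' @export
estimate_frequencies <- function(mentions) {
  if (!nrow(mentions)) stop("no mentions: cannot estimate frequencies")
  tb <- table(mentions$concept_id)
  f <- as.numeric(tb) / sum(tb)
  names(f) <- names(tb)
  f[order(names(f))]
}

#' Concept-pair association probabilities from unit co-occurrence
#'
#' n_ij counts the units of text (documents or sentences) in which concepts
#' i and j both occur (binary per unit, i != j; numerically symmetric).
#' p_ij = n_ij / sum_j' n_ij' row-normalizes these counts; concepts never
#' co-occurring (or absent from the corpus) get an all-zero row, the zero
#' policy that penalizes unobserved ontology content.
#'
#' @param mentions mention data.frame from \code{\link{match_concepts}}.
#' @return data.frame with columns \code{source}, \code{target}, \code{n},
#'   \code{p}, one row per directed pair with n > 0.
#' @export
estimate_relation_probs <- function(mentions) {
  units <- split(mentions$concept_id, mentions$unit_id)
  pair_rows <- lapply(units, function(cs) {
    cs <- sort(unique(cs))
    if (length(cs) < 2) return(NULL)
    cmb <- utils::combn(cs, 2)
    data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pair_rows)
  if (is.null(pairs) || !nrow(pairs))
    return(data.frame(source = character(), target = character(),
                      n = integer(), p = numeric(), stringsAsFactors = FALSE))
  key <- paste(pairs$a, pairs$b, sep = "\x1f")
  tb <- table(key)
  ab <- do.call(rbind, strsplit(names(tb), "\x1f", fixed = TRUE))
  # directed bookkeeping: emit both orientations with the same count
  cooc <- data.frame(source = c(ab[, 1], ab[, 2]),
                     target = c(ab[, 2], ab[, 1]),
                     n = rep(as.integer(tb), 2), stringsAsFactors = FALSE)
  row_tot <- tapply(cooc$n, cooc$source, sum)
  cooc$p <- cooc$n / as.numeric(row_tot[cooc$source])
  cooc <- cooc[order(cooc$source, cooc$target), ]
  rownames(cooc) <- NULL
  cooc
}

#' Smoothed association probabilities with a null-sink pseudo-concept
#'
#' Additive smoothing that keeps p a proper probability for every concept,
#' observed or not: each real target j receives pseudo-count alpha and a
#' reserved pseudo-concept (the null sink) receives
#' alpha * M * (1 - beta) / beta, where M is the number of real candidate
#' targets, so that
#' p_ij = (n_ij + alpha) / (n_i + alpha * M / beta) and the sink takes the
#' rest. Rows always sum to one; when concept i is unobserved the sink mass
#' is 1 - beta (close to 1 for small beta) and every real p_ij is beta / M
#' (close to 0); when alpha = 0 the observed rows reduce exactly to the
#' unsmoothed estimates with zero sink mass. beta is therefore the share of
#' smoothing pseudo-mass kept on real concepts.
#'
#' @param cooc co-occurrence data.frame from
#'   \code{\link{estimate_relation_probs}} (columns source, target, n).
#' @param concepts character vector: the full concept universe (rows are
#'   produced for every member, observed or not).
#' @param alpha pseudo-count on each real target, 0 <= alpha < beta.
#' @param beta share of smoothing mass on real targets, alpha < beta < 1.
#' @param null_id identifier for the pseudo-concept sink (must not collide
#'   with a real concept id).
#' @return data.frame with columns \code{source}, \code{target}, \code{p};
#'   every source row (incl. the sink column) sums to one. For alpha = 0
#'   only observed targets and the sink appear.
#' @export
smooth_relation_probs <- function(cooc, concepts, alpha = 0.01, beta = 0.1,
                                  null_id = "<null>") {
  if (!(alpha >= 0 && alpha < beta && beta < 1))
    stop("parameter error: need 0 <= alpha < beta < 1")
  if (null_id %in% concepts)
    stop("parameter error: null_id collides with a concept id")
  concepts <- sort(unique(concepts))
  M <- length(concepts) - 1L  # real candidate targets per source
  if (M < 1) stop("need at least two concepts to smooth over")
  sink_pc <- if (alpha > 0) alpha * M * (1 - beta) / beta else 0
  out <- lapply(concepts, function(i) {
    row <- cooc[cooc$source == i, , drop = FALSE]
    n_i <- sum(row$n)
    denom <- n_i + (if (alpha > 0) alpha * M / beta else 0)
    if (denom == 0) {
      # alpha = 0 and unobserved: all mass on the sink by the zero policy
      return(data.frame(source = i, target = null_id, p = 1,
                        stringsAsFactors = FALSE))
    }
    if (alpha > 0) {
      targets <- setdiff(concepts, i)
      n_vec <- stats::setNames(rep(0, length(targets)), targets)
      n_vec[row$target] <- row$n
      data.frame(source = i,
                 target = c(targets, null_id),
                 p = c((n_vec + alpha) / denom, sink_pc / denom),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(source = i, target = c(row$target, null_id),
                 p = c(row$n / denom, 0), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Relative weights of typed relations per concept pair
#'
#' Given counts of (source, predicate, target) mention triples, the weight
#' of predicate k for pair (i, j) is its share of all triple mentions for
#' that pair, so weights sum to one within each pair. Pairs with no triples
#' are omitted.
#'
#' @param triples data.frame with columns \code{source}, \code{predicate},
#'   \code{target} and optionally \code{count} (default 1 per row).
#' @return data.frame with columns \code{source}, \code{predicate},
#'   \code{target}, \code{weight}.
#' @export
estimate_typed_weights <- function(triples) {
  triples <- as.data.frame(triples, stringsAsFactors = FALSE)
  if (is.null(triples$count)) triples$count <- 1
  if (!nrow(triples))
    return(data.frame(source = character(), predicate = character(),
                      target = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(count ~ source + predicate + target, triples, sum)
  pair_tot <- stats::aggregate(count ~ source + target, agg, sum)
  names(pair_tot)[3] <- "tot"
  agg <- merge(agg, pair_tot, by = c("source", "target"))
  agg$weight <- agg$count / agg$tot
  agg <- agg[order(agg$source, agg$target, agg$predicate),
             c("source", "predicate", "target", "weight")]
  rownames(agg) <- NULL
  agg
}

#' Bundle corpus-derived statistics
#'
#' Container for the quantities the metric family consumes: concept
#' frequencies f, pair co-occurrence counts and probabilities p, and
#' optionally typed-relation weights.
#'
#' @param concept_freq named numeric vector from
#'   \code{\link{estimate_frequencies}}.
#' @param cooc data.frame from \code{\link{estimate_relation_probs}}.
#' @param typed_weight optional data.frame from
#'   \code{\link{estimate_typed_weights}}.
#' @param label corpus label.
#' @return object of class \code{"corpus_stats"}.
#' @export
corpus_stats <- function(concept_freq, cooc = NULL, typed_weight = NULL,
                         label = "corpus") {
  stopifnot(is.numeric(concept_freq), !is.null(names(concept_freq)))
  if (abs(sum(concept_freq) - 1) > 1e-9)
    stop("concept frequencies must sum to 1")
  if (is.null(cooc))
    cooc <- data.frame(source = character(), target = character(),
                       n = integer(), p = numeric(), stringsAsFactors = FALSE)
  structure(list(concept_freq = concept_freq, cooc = cooc,
                 typed_weight = typed_weight, label = label),
            class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("Corpus statistics '%s': %d concepts, %d directed co-occurring pairs\n",
              x$label, length(x$concept_freq), nrow(x$cooc)))
  invisible(x)
}

#' Estimate all corpus statistics for an ontology in one call
#'
#' Convenience wrapper: concept recognition, frequency estimation and
#' co-occurrence probability estimation.
#'
#' @inheritParams match_concepts
#' @return a \code{\link{corpus_stats}} object.
#' @export
estimate_corpus_stats <- function(corpus, ontology,
                                  unit = c("document", "sentence")) {
  unit <- match.arg(unit)
  mentions <- match_concepts(corpus, ontology, unit = unit)
  corpus_stats(estimate_frequencies(mentions),
               estimate_relation_probs(mentions),
               label = "corpus")
}
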