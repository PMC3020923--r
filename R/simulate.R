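# Synthetic corpora, ontologies and thesauri with known ground truth.
#
# The generator emulates the statistical structure the metrics rest on —
# skewed (Zipf) concept usage, planted concept co-occurrence and planted
# synonym substitution rates — using template sentences, not realistic
# English. Concept and filler tokens are opaque strings the rule
# lemmatizer leaves untouched, so dictionary matching recovers mentions
# exactly and every estimate can be checked against the planted truth.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for the synthetic concept-corpus generator
#'
#' @param seed integer seed; the same seed always yields a byte-identical
#'   corpus.
#' @param n_concepts number of concepts.
#' @param zipf_s Zipf skew exponent for concept frequencies
#'   (f_i proportional to i^-s; 0 gives uniform).
#' @param n_documents number of documents.
#' @param mentions_per_doc mean concept mentions per document in
#'   independent-mention mode (each document draws
#'   1 + Poisson(mentions_per_doc - 1) mentions).
#' @param cooccurrence optional row-stochastic n_concepts x n_concepts
#'   matrix of target association probabilities (zero diagonal). When
#'   given, each document carries one unordered concept pair drawn from
#'   the joint law implied by the matrix and the Zipf frequencies, and the
#'   emitted ground truth is exactly what unit-level co-occurrence
#'   estimation measures.
#' @param n_filler size of the filler vocabulary; a further
#'   \code{n_filler} singleton fillers are sprinkled so the rare-word
#'   binning path is exercised.
#' @return validated spec, class \code{"generator_spec"}.
#' @export
generator_spec <- function(seed = 1L, n_concepts = 50L, zipf_s = 1,
                           n_documents = 500L, mentions_per_doc = 3,
                           cooccurrence = NULL, n_filler = 20L) {
  stopifnot(n_concepts >= 2, n_documents >= 1, zipf_s >= 0,
            mentions_per_doc >= 1)
  if (!is.null(cooccurrence)) {
    cooccurrence <- as.matrix(cooccurrence)
    if (nrow(cooccurrence) != n_concepts || ncol(cooccurrence) != n_concepts)
      stop("infeasible spec: cooccurrence matrix must be n_concepts x n_concepts")
    if (any(diag(cooccurrence) != 0))
      stop("infeasible spec: cooccurrence diagonal must be zero")
    if (any(cooccurrence < 0) ||
        any(abs(rowSums(cooccurrence) - 1) > 1e-8))
      stop("infeasible spec: cooccurrence rows must be stochastic")
  }
  structure(list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
                 zipf_s = zipf_s, n_documents = as.integer(n_documents),
                 mentions_per_doc = mentions_per_doc,
                 cooccurrence = cooccurrence, n_filler = as.integer(n_filler)),
            class = "generator_spec")
}

zipf_weights <- function(n, s) {
  w <- (seq_len(n))^(-s)
  w / sum(w)
}

concept_token <- function(i) sprintf("cpt%04dx", i)
concept_id <- function(i) sprintf("C%04d", i)

#' Generate a concept-bearing corpus with known ground truth
#'
#' Two modes, chosen by whether the spec plants a co-occurrence matrix:
#' \describe{
#'   \item{independent mentions}{each document draws its mentions i.i.d.
#'     from the Zipf frequency law; ground truth is the frequency vector
#'     (no pair truth is emitted).}
#'   \item{planted pairs}{each document carries exactly one unordered
#'     concept pair drawn from the symmetrized joint law
#'     u_ij = f_i P_ij + f_j P_ji; the emitted truth is the implied mention
#'     frequency (row sums of the joint over 2) and the row-normalized
#'     joint, which is exactly the population value of the unit-level
#'     co-occurrence estimator.}
#' }
#'
#' @param spec a \code{\link{generator_spec}}.
#' @return list with \code{corpus} (unanalyzed \code{corpus}),
#'   \code{ontology} (the recognition lexicon: one single-token concept
#'   per id), \code{truth} (list \code{f} named vector and \code{p}
#'   data.frame source/target/p or NULL), \code{spec}.
#' @export
generate_concept_corpus <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_concepts
  f0 <- zipf_weights(n, spec$zipf_s)
  ids <- concept_id(seq_len(n))
  toks <- concept_token(seq_len(n))
  fillers <- sprintf("flb%03dq", seq_len(spec$n_filler))
  singletons <- sprintf("unq%05dq", seq_len(spec$n_documents))

  with_seed(spec$seed, {
    if (is.null(spec$cooccurrence)) {
      docs <- lapply(seq_len(spec$n_documents), function(d) {
        m <- 1L + stats::rpois(1, max(spec$mentions_per_doc - 1, 0))
        idx <- sample.int(n, m, replace = TRUE, prob = f0)
        idx
      })
      truth_f <- stats::setNames(f0, ids)
      truth_p <- NULL
    } else {
      P <- spec$cooccurrence
      U <- outer(f0, rep(1, n)) * P
      U <- U + t(U)            # symmetric joint, unordered weight U[i,j]
      ut <- which(upper.tri(U), arr.ind = TRUE)
      w <- U[ut]
      w <- w / sum(w)
      pick <- sample.int(nrow(ut), spec$n_documents, replace = TRUE, prob = w)
      docs <- lapply(pick, function(k) c(ut[k, 1], ut[k, 2]))
      # population values of the estimators on this scheme
      rs <- rowSums(U) / sum(U)
      truth_f <- stats::setNames(rs, ids)   # each doc mentions both members once
      Pn <- U / rowSums(U)
      nz <- which(Pn > 0 & row(Pn) != col(Pn), arr.ind = TRUE)
      truth_p <- data.frame(source = ids[nz[, 1]], target = ids[nz[, 2]],
                            p = Pn[nz], stringsAsFactors = FALSE)
      truth_p <- truth_p[order(truth_p$source, truth_p$target), ]
      rownames(truth_p) <- NULL
    }
    texts <- vapply(seq_along(docs), function(d) {
      mention_toks <- toks[docs[[d]]]
      fill <- c(sample(fillers, 2, replace = TRUE), singletons[d])
      words <- sample(c(mention_toks, fill))
      paste0(paste(words, collapse = " "), ".")
    }, character(1))
    corpus <- structure(lapply(seq_along(texts), function(d)
      list(doc_id = sprintf("doc%05d", d), text = texts[[d]])),
      class = "corpus")
    lexicon <- ontology(data.frame(id = ids, preferred_name = toks,
                                   stringsAsFactors = FALSE),
                        name = "synthetic-lexicon")
    list(corpus = corpus, ontology = lexicon,
         truth = list(f = truth_f, p = truth_p), spec = spec)
  })
}

#' Generate a corpus with planted synonym substitution rates
#'
#' Each thesaurus entry gets its own family of template contexts (shared
#' content words flanking a target slot); occurrence by occurrence the slot
#' is filled with the headword or one of its synonyms according to the
#' planted rates. The planted substitution table (including the headword's
#' self-substitution mass) is emitted alongside.
#'
#' @param entries list of entries, each
#'   \code{list(headword=, pos=, rates=)} where \code{rates} is a named
#'   numeric vector of per-synonym substitution rates summing to < 1 (the
#'   rest is headword self-mass).
#' @param occurrences_per_entry number of target-slot occurrences planted
#'   per entry.
#' @param templates_per_entry number of distinct context templates cycled
#'   through per entry.
#' @param seed integer seed.
#' @return list with \code{corpus}, \code{thesaurus} (data.frame),
#'   \code{lexicon} (tagger lexicon for the planted vocabulary),
#'   \code{truth} (planted substitution table incl. self rows).
#' @export
generate_substitution_corpus <- function(entries, occurrences_per_entry = 200,
                                         templates_per_entry = 3, seed = 1L) {
  stopifnot(length(entries) >= 1)
  texts <- character(0)
  lex <- list()
  truth <- list()
  thes <- list()
  with_seed(seed, {
    for (e in seq_along(entries)) {
      ent <- entries[[e]]
      stopifnot(!is.null(ent$headword), !is.null(ent$rates))
      pos <- ent$pos %||% "NOUN"
      rates <- ent$rates
      if (any(rates < 0) || sum(rates) > 1)
        stop("planted rates must be non-negative and sum to at most 1")
      cand <- c(ent$headword, names(rates))
      probs <- c(1 - sum(rates), as.numeric(rates))
      ctx <- sprintf("ctx%02d%02dw", e, seq_len(2 * templates_per_entry))
      lex[[length(lex) + 1L]] <- data.frame(
        surface = c(cand, ctx), base_form = c(cand, ctx),
        pos = c(rep(pos, length(cand)), rep("NOUN", length(ctx))),
        stringsAsFactors = FALSE)
      choice <- sample(cand, occurrences_per_entry, replace = TRUE,
                       prob = probs)
      tpl <- rep(seq_len(templates_per_entry),
                 length.out = occurrences_per_entry)
      texts <- c(texts, vapply(seq_len(occurrences_per_entry), function(o) {
        a <- ctx[2 * tpl[o] - 1]; b <- ctx[2 * tpl[o]]
        paste0(a, " ", choice[o], " ", b, ".")
      }, character(1)))
      truth[[length(truth) + 1L]] <- data.frame(
        headword = ent$headword, pos = pos, synonym = cand,
        probability = probs, stringsAsFactors = FALSE)
      thes[[length(thes) + 1L]] <- data.frame(
        headword = ent$headword, pos = pos,
        synonyms = paste(names(rates), collapse = "|"),
        stringsAsFactors = FALSE)
    }
    corpus <- structure(lapply(seq_along(texts), function(d)
      list(doc_id = sprintf("sdoc%05d", d), text = texts[[d]])),
      class = "corpus")
    list(corpus = corpus, thesaurus = do.call(rbind, thes),
         lexicon = do.call(rbind, lex), truth = do.call(rbind, truth))
  })
}

#' Generate a graded family of test ontologies
#'
#' From a generated concept corpus's ground truth, emits same-size
#' sub-ontologies sampling the top, a random stratum and the bottom of the
#' frequency law, so metric orderings (top beats random beats bottom in
#' Depth) are predictable. Relations are the truth pairs restricted to the
#' selected concepts.
#'
#' @param gen output of \code{\link{generate_concept_corpus}}.
#' @param size concepts per sub-ontology.
#' @param seed seed for the random stratum.
#' @return named list of \code{ontology} objects: \code{top},
#'   \code{random}, \code{bottom}.
#' @export
generate_ontology_family <- function(gen, size, seed = 1L) {
  f <- sort(gen$truth$f, decreasing = TRUE)
  ids <- names(f)
  stopifnot(size >= 1, size <= length(ids))
  sel <- list(top = ids[seq_len(size)],
              random = with_seed(seed, sample(ids, size)),
              bottom = ids[seq(length(ids) - size + 1L, length(ids))])
  lapply(stats::setNames(names(sel), names(sel)), function(nm) {
    keep <- sel[[nm]]
    cdf <- gen$ontology$concepts[gen$ontology$concepts$id %in% keep, ,
                                 drop = FALSE]
    rel <- NULL
    if (!is.null(gen$truth$p)) {
      tp <- gen$truth$p
      rel <- tp[tp$source %in% keep & tp$target %in% keep,
                c("source", "target"), drop = FALSE]
    }
    ontology(cdf, rel, name = nm)
  })
}

#' Write a generated fixture to disk through the standard interfaces
#'
#' Emits the corpus as JSON-lines, the recognition lexicon as ontology
#' TSVs, and the ground truth as TSVs, so generated fixtures round-trip
#' through the same readers real data would use.
#'
#' @param gen output of \code{\link{generate_concept_corpus}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_fixture <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "corpus.jsonl"), "w", encoding = "UTF-8")
  for (d in gen$corpus)
    writeLines(jsonlite::toJSON(list(doc_id = d$doc_id, text = d$text),
                                auto_unbox = TRUE), con)
  close(con)
  write_ontology(gen$ontology, file.path(dir, "lexicon"), format = "tsv")
  utils::write.table(data.frame(concept_id = names(gen$truth$f),
                                f = as.numeric(gen$truth$f)),
                     file.path(dir, "truth_f.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(gen$truth$p))
    utils::write.table(gen$truth$p, file.path(dir, "truth_p.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
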