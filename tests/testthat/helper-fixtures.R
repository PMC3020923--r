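# Shared fixtures and independent oracles.

toy_ontology <- function() {
  ontology(
    concepts = data.frame(
      id = c("a", "b", "c"),
      preferred_name = c("alphazor", "betazor", "gammazor"),
      synonyms = c("alephzor", "", ""),
      stringsAsFactors = FALSE),
    relations = data.frame(
      source = c("a", "a", "b"),
      predicate = c("is-a", "part-of", "is-a"),
      target = c("b", "b", "c"), stringsAsFactors = FALSE),
    name = "toy")
}

make_corpus <- function(texts, ids = sprintf("d%03d", seq_along(texts))) {
  structure(Map(function(i, t) list(doc_id = i, text = t), ids, texts),
            class = "corpus", names = NULL)
}

# ---- independent naive scanner oracle -------------------------------------
# Counts single-token concept mentions straight off the raw text with
# regex tokenization; no tagger, matcher or package estimator involved.
naive_scan <- function(corpus, concept_tokens) {
  # concept_tokens: named character (id -> token)
  stopifnot(!is.null(names(concept_tokens)))
  per_doc <- lapply(corpus, function(d) {
    toks <- tolower(regmatches(d$text,
                               gregexpr("[A-Za-z0-9'-]+", d$text))[[1]])
    hits <- names(concept_tokens)[match(toks, concept_tokens)]
    hits[!is.na(hits)]
  })
  counts <- table(factor(unlist(per_doc), levels = sort(names(concept_tokens))))
  counts <- counts[counts > 0]
  f <- as.numeric(counts) / sum(counts)
  names(f) <- names(counts)
  # unit-level co-occurrence by explicit double loop
  ids <- sort(names(concept_tokens))
  n <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (hits in per_doc) {
    u <- sort(unique(hits))
    if (length(u) < 2) next
    for (i in seq_along(u)) for (j in seq_along(u)) if (i != j)
      n[u[i], u[j]] <- n[u[i], u[j]] + 1L
  }
  p <- n / pmax(rowSums(n), 1)
  p[rowSums(n) == 0, ] <- 0
  list(f = f, n = n, p = p)
}

# ---- exhaustive fittest oracle --------------------------------------------
best_depth_exhaustive <- function(mass, k) {
  stopifnot(k >= 1, k <= length(mass))
  subsets <- utils::combn(length(mass), k)
  max(apply(subsets, 2, function(ix) sum(mass[ix]))) / k
}

# random corpus_stats fixture on m concepts
random_stats <- function(m = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("k%02d", seq_len(m))
  f <- stats::setNames(as.numeric(stats::rgamma(m, 1)), ids)
  f <- f / sum(f)
  # random symmetric co-occurrence counts
  n <- matrix(stats::rpois(m * m, 1), m, m)
  n <- n + t(n); diag(n) <- 0
  nz <- which(n > 0, arr.ind = TRUE)
  cooc <- if (nrow(nz)) {
    rt <- rowSums(n)
    data.frame(source = ids[nz[, 1]], target = ids[nz[, 2]],
               n = n[nz], p = n[nz] / rt[nz[, 1]], stringsAsFactors = FALSE)
  } else NULL
  corpus_stats(f, cooc, label = "random")
}

sub_ontology <- function(stats, concept_ids, pairs = NULL, name = "sub") {
  cdf <- data.frame(id = concept_ids,
                    preferred_name = paste0(concept_ids, "term"),
                    stringsAsFactors = FALSE)
  ontology(cdf, pairs, name = name)
}
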