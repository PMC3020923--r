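test_that("dictionary matching is longest-match, lemma-level and synonym-aware", {
  onto <- ontology(data.frame(
    id = c("hep", "cvh", "ha"),
    preferred_name = c("hepatitis", "chronic viral hepatitis C", "headache"),
    synonyms = c("", "", "migraine")))
  corp <- analyze_corpus(make_corpus(
    "Chronic viral hepatitis C was noted. Migraines and hepatitis persist."))
  m <- match_concepts(corp, onto)
  # the longer concept wins over its embedded substring
  expect_equal(sort(m$concept_id), c("cvh", "ha", "hep"))
  expect_equal(m$concept_id[m$surface_span == "chronic viral hepatitis c"],
               "cvh")
  # synonym mention maps to the canonical concept, via lemma (migraines)
  expect_equal(m$concept_id[m$surface_span == "migraines"], "ha")
})

test_that("frequencies normalize mention counts", {
  mentions <- data.frame(unit_id = c("u1", "u1", "u2", "u3"),
                         concept_id = c("a", "a", "a", "b"))
  f <- estimate_frequencies(mentions)
  expect_equal(f, c(a = 0.75, b = 0.25))
  expect_equal(sum(f), 1)
  single <- estimate_frequencies(data.frame(unit_id = "u", concept_id = "z"))
  expect_equal(unname(single), 1)
  expect_error(estimate_frequencies(data.frame(unit_id = character(),
                                               concept_id = character())),
               "no mentions")
})

test_that("co-occurrence probabilities follow unit-level counting", {
  mentions <- data.frame(
    unit_id = c("doc1", "doc1", "doc2", "doc2", "doc3", "doc3"),
    concept_id = c("a", "b", "a", "b", "a", "c"))
  cc <- estimate_relation_probs(mentions)
  expect_equal(cc$p[cc$source == "a" & cc$target == "b"], 2 / 3)
  expect_equal(cc$p[cc$source == "a" & cc$target == "c"], 1 / 3)
  expect_equal(cc$p[cc$source == "b" & cc$target == "a"], 1)
  # repeated mentions inside one unit count once
  rep_m <- data.frame(unit_id = c("u", "u", "u"), concept_id = c("a", "a", "b"))
  expect_equal(estimate_relation_probs(rep_m)$n, c(1L, 1L))
  # a concept never co-occurring has no row: zero policy
  expect_false("c" %in% cc$source[cc$target == "b"])
})

test_that("estimates match an independent naive scanner on small corpora", {
  for (seed in c(11, 23, 37)) {
    sp <- generator_spec(seed = seed, n_concepts = 8, zipf_s = 1,
                         n_documents = 40, mentions_per_doc = 3)
    gen <- generate_concept_corpus(sp)
    ac <- analyze_corpus(gen$corpus)
    mentions <- match_concepts(ac, gen$ontology)
    oracle <- naive_scan(gen$corpus,
                         stats::setNames(gen$ontology$concepts$preferred_name,
                                         gen$ontology$concepts$id))
    expect_equal(estimate_frequencies(mentions), oracle$f)
    cc <- estimate_relation_probs(mentions)
    for (r in seq_len(nrow(cc))) {
      expect_equal(cc$n[r], unname(oracle$n[cc$source[r], cc$target[r]]))
      expect_equal(cc$p[r], unname(oracle$p[cc$source[r], cc$target[r]]))
    }
    expect_equal(sum(oracle$n > 0), nrow(cc))
  }
})

test_that("estimates are invariant to document order and extra whitespace", {
  sp <- generator_spec(seed = 5, n_concepts = 6, n_documents = 30)
  gen <- generate_concept_corpus(sp)
  ac <- analyze_corpus(gen$corpus)
  st1 <- estimate_corpus_stats(ac, gen$ontology)
  perm <- structure(ac[rev(seq_along(ac))], class = "corpus")
  st2 <- estimate_corpus_stats(perm, gen$ontology)
  expect_equal(st1$concept_freq, st2$concept_freq)
  expect_equal(st1$cooc, st2$cooc)
  spaced <- structure(lapply(ac, function(d) {
    d$text <- gsub(" ", "   ", d$text)
    analyze_document(d)
  }), class = "corpus")
  st3 <- estimate_corpus_stats(spaced, gen$ontology)
  expect_equal(st1$cooc$p, st3$cooc$p)
})

test_that("smoothing keeps rows stochastic and honours its limits", {
  cooc <- data.frame(source = c("a", "a"), target = c("b", "c"),
                     n = c(3L, 1L))
  concepts <- c("a", "b", "c")
  # alpha = 0, observed: reduces exactly to the unsmoothed estimate
  sm0 <- smooth_relation_probs(cooc, concepts, alpha = 0, beta = 0.1)
  a0 <- sm0[sm0$source == "a", ]
  expect_equal(a0$p[a0$target == "b"], 0.75)
  expect_equal(a0$p[a0$target == "<null>"], 0)
  # unobserved concept: sink mass 1 - beta, real targets beta / M
  sm <- smooth_relation_probs(cooc, concepts, alpha = 0.01, beta = 0.02)
  b <- sm[sm$source == "b", ]
  expect_equal(b$p[b$target == "<null>"], 0.98)
  expect_equal(sum(b$p[b$target != "<null>"]), 0.02)
  # every row sums to one
  sums <- tapply(sm$p, sm$source, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(smooth_relation_probs(cooc, concepts, alpha = 0.2, beta = 0.1),
               "parameter error")
  expect_error(smooth_relation_probs(cooc, concepts, null_id = "a"),
               "parameter error")
})

test_that("smoothed rows sum to one across many random count matrices", {
  set.seed(404)
  for (i in 1:50) {
    m <- sample(3:10, 1)
    ids <- sprintf("c%02d", seq_len(m))
    n <- matrix(stats::rpois(m * m, 0.7), m, m); diag(n) <- 0
    nz <- which(n > 0, arr.ind = TRUE)
    cooc <- data.frame(source = ids[nz[, 1]], target = ids[nz[, 2]],
                       n = n[nz])
    beta <- stats::runif(1, 0.05, 0.9)
    alpha <- stats::runif(1, 0, beta * 0.9)
    sm <- smooth_relation_probs(cooc, ids, alpha = alpha, beta = beta)
    sums <- tapply(sm$p, sm$source, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(sm$p >= 0 & sm$p <= 1))
  }
})

test_that("smoothed and unsmoothed estimates agree in the alpha -> 0 limit", {
  cooc <- data.frame(source = c("a", "a", "b"), target = c("b", "c", "a"),
                     n = c(3L, 1L, 2L))
  raw <- estimate_relation_probs(data.frame(
    unit_id = c(rep(c("1", "2", "3"), each = 2), "4", "4"),
    concept_id = c("a", "b", "a", "b", "a", "b", "a", "c")))
  sm <- smooth_relation_probs(raw[, c("source", "target", "n")],
                              c("a", "b", "c"), alpha = 1e-10, beta = 0.5)
  for (r in seq_len(nrow(raw))) {
    p_sm <- sm$p[sm$source == raw$source[r] & sm$target == raw$target[r]]
    expect_equal(p_sm, raw$p[r], tolerance = 1e-6)
  }
})

test_that("typed weights are per-pair relative frequencies", {
  triples <- data.frame(
    source = c("a", "a", "a", "a", "b"),
    predicate = c("is-a", "is-a", "is-a", "part-of", "is-a"),
    target = c("b", "b", "b", "b", "c"))
  tw <- estimate_typed_weights(triples)
  expect_equal(tw$weight[tw$source == "a" & tw$predicate == "is-a"], 0.75)
  expect_equal(tw$weight[tw$source == "a" & tw$predicate == "part-of"], 0.25)
  expect_equal(tw$weight[tw$source == "b"], 1)
  sums <- tapply(tw$weight, paste(tw$source, tw$target), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # planted predicate mixture recovered within counting error
  set.seed(7)
  ks <- sample(c("is-a", "part-of"), 400, replace = TRUE, prob = c(0.7, 0.3))
  tw2 <- estimate_typed_weights(data.frame(source = "x", predicate = ks,
                                           target = "y"))
  w <- tw2$weight[tw2$predicate == "is-a"]
  expect_lt(abs(w - 0.7), 3 * sqrt(0.7 * 0.3 / 400))
})
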