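test_that("precision, recall and F follow their definitions and edge policy", {
  perfect <- ir_metrics(tp = 5, fp = 0, fn = 0)
  expect_equal(perfect, list(precision = 1, recall = 1, f_measure = 1))
  mid <- ir_metrics(tp = 1, fp = 1, fn = 3)
  expect_equal(mid$precision, 0.5)
  expect_equal(mid$recall, 0.25)
  expect_equal(mid$f_measure, 1 / 3)
  zero <- ir_metrics(tp = 0, fp = 2, fn = 2)
  expect_equal(zero$f_measure, 0)
  # undefined denominators are NA, never silently zero
  expect_true(is.na(ir_metrics(tp = 0, fp = 0, fn = 2)$precision))
  expect_true(is.na(ir_metrics(tp = 0, fp = 2, fn = 0)$recall))
})

test_that("confusion counts cross-tabulate ontology against corpus content", {
  st <- corpus_stats(c(a = 0.5, b = 0.3, c = 0.2),
                     data.frame(source = c("a", "b"), target = c("b", "a"),
                                n = c(2L, 2L), p = c(1, 1)))
  x <- sub_ontology(st, c("a", "b", "zzz"),
                    data.frame(source = c("a", "zzz"), target = c("b", "a")))
  cc1 <- confusion_counts(x, st, level = 1)
  expect_equal(cc1[c("tp", "fp", "fn")], list(tp = 2L, fp = 1L, fn = 1L))
  expect_equal(cc1$tp + cc1$fn, 3L)  # corpus-side positives
  cc2 <- confusion_counts(x, st, level = 2)
  expect_equal(cc2[c("tp", "fp", "fn")], list(tp = 1L, fp = 1L, fn = 1L))
})

test_that("level-1 breadth sums covered concept mass", {
  st <- corpus_stats(c(a = 0.2, b = 0.8))
  expect_equal(breadth1(sub_ontology(st, "a"), st), 0.2)
  expect_equal(breadth1(sub_ontology(st, c("a", "b")), st), 1.0)
  # concepts outside the corpus contribute nothing
  expect_equal(breadth1(sub_ontology(st, c("a", "q")), st), 0.2)
})

test_that("level-2 breadth weights covered pairs by f_i * p_ij", {
  st <- corpus_stats(c(a = 0.5, b = 0.3, c = 0.2),
                     data.frame(source = c("a", "a", "b", "c"),
                                target = c("b", "c", "a", "a"),
                                n = c(2L, 3L, 2L, 3L),
                                p = c(0.4, 0.6, 1, 1)))
  x1 <- sub_ontology(st, c("a", "b"),
                     data.frame(source = "a", target = "b"))
  expect_equal(breadth2(x1, st), 0.5 * 0.4)
  # covering every observed pair recovers the full conserved mass
  full <- sub_ontology(st, c("a", "b", "c"),
                       data.frame(source = c("a", "a", "b", "c"),
                                  target = c("b", "c", "a", "a")))
  expect_equal(breadth2(full, st), 1)
})

test_that("breadth equals a brute-force sum on random sub-ontologies", {
  set.seed(202)
  for (i in 1:20) {
    st <- random_stats(m = 10)
    ids <- names(st$concept_freq)
    keep <- sample(ids, sample(2:8, 1))
    pairs <- st$cooc[st$cooc$source %in% keep & st$cooc$target %in% keep,
                     c("source", "target")]
    x <- sub_ontology(st, keep, if (nrow(pairs)) pairs else NULL)
    expect_equal(breadth1(x, st), sum(st$concept_freq[keep]))
    oracle2 <- 0
    for (r in seq_len(nrow(st$cooc)))
      if (st$cooc$source[r] %in% keep && st$cooc$target[r] %in% keep)
        oracle2 <- oracle2 +
          st$concept_freq[[st$cooc$source[r]]] * st$cooc$p[r]
    expect_equal(breadth2(x, st), oracle2)
    expect_gte(breadth1(x, st), 0); expect_lte(breadth1(x, st), 1)
    expect_gte(breadth2(x, st), 0); expect_lte(breadth2(x, st), 1)
  }
})

test_that("depth divides breadth by the level's size denominator", {
  # published-scale examples: breadth over concept / pair counts
  expect_equal(ontology_depth(2.259e-2, size = 3500), 6.454e-6,
               tolerance = 1e-3)
  expect_equal(ontology_depth(1.405e-2, size = 12112), 1.160e-6,
               tolerance = 1e-3)
  expect_equal(ontology_depth(0, size = 10), 0)
  st <- corpus_stats(c(a = 1))
  expect_error(ontology_depth(0.5, size = 0), "empty")
})

test_that("typed breadth reduces to level 2 under a single predicate", {
  st <- corpus_stats(c(a = 0.6, b = 0.4),
                     data.frame(source = c("a", "b"), target = c("b", "a"),
                                n = c(1L, 1L), p = c(1, 1)))
  st$typed_weight <- data.frame(source = c("a", "b"), predicate = "is-a",
                                target = c("b", "a"), weight = c(1, 1))
  x <- sub_ontology(st, c("a", "b"),
                    data.frame(source = c("a", "b"), predicate = "is-a",
                               target = c("b", "a")))
  res <- breadth3_depth3(x, st)
  expect_equal(res$breadth3, breadth2(x, st))
  expect_equal(res$depth3 * n_relations(x),
               ontology_depth(breadth2(x, st), x, level = 2) * n_pairs(x))
})

test_that("typed breadth splits pair mass across equal-weight predicates", {
  st <- corpus_stats(c(a = 0.6, b = 0.4),
                     data.frame(source = "a", target = "b", n = 1L, p = 1))
  st$typed_weight <- data.frame(source = c("a", "a"),
                                predicate = c("is-a", "part-of"),
                                target = c("b", "b"), weight = c(0.5, 0.5))
  x <- sub_ontology(st, c("a", "b"),
                    data.frame(source = "a", predicate = "is-a", target = "b"))
  res <- breadth3_depth3(x, st)
  expect_equal(res$breadth3, 0.6 * 1 * 0.5)
  # a covered pair with no weight entry contributes zero, with a warning
  st$typed_weight <- st$typed_weight[0, ]
  expect_warning(res2 <- breadth3_depth3(x, st), "typed weights")
  expect_equal(res2$breadth3, 0)
})

test_that("typed breadth equals a brute-force triple sum on random fixtures", {
  set.seed(77)
  for (i in 1:10) {
    st <- random_stats(m = 6)
    cc <- st$cooc
    if (!nrow(cc)) next
    preds <- c("is-a", "part-of")
    tw <- do.call(rbind, lapply(seq_len(nrow(cc)), function(r) {
      w <- stats::runif(2); w <- w / sum(w)
      data.frame(source = cc$source[r], predicate = preds,
                 target = cc$target[r], weight = w)
    }))
    st$typed_weight <- tw
    take <- sample(nrow(tw), max(2, nrow(tw) %/% 2))
    rel <- tw[take, c("source", "predicate", "target")]
    ids <- unique(c(rel$source, rel$target))
    x <- sub_ontology(st, ids, rel)
    oracle <- 0
    for (r in seq_len(nrow(rel))) {
      pr <- cc$p[cc$source == rel$source[r] & cc$target == rel$target[r]]
      wr <- tw$weight[tw$source == rel$source[r] &
                      tw$target == rel$target[r] &
                      tw$predicate == rel$predicate[r]]
      oracle <- oracle + st$concept_freq[[rel$source[r]]] * pr * wr
    }
    res <- breadth3_depth3(x, st)
    expect_equal(res$breadth3, unname(oracle))
    expect_equal(res$depth3, unname(oracle) / nrow(rel))
  }
})

test_that("adding concepts or relations never decreases breadth", {
  set.seed(303)
  st <- random_stats(m = 10)
  ids <- names(st$concept_freq)
  x <- sub_ontology(st, ids[1:4])
  grown <- sub_ontology(st, ids[1:5])
  expect_gte(breadth1(grown, st), breadth1(x, st))
  cc <- st$cooc
  x2 <- sub_ontology(st, ids, cc[1:2, c("source", "target")])
  grown2 <- sub_ontology(st, ids, cc[1:3, c("source", "target")])
  expect_gte(breadth2(grown2, st), breadth2(x2, st))
})

test_that("padding with zero-frequency concepts strictly lowers depth, never breadth", {
  st <- corpus_stats(c(a = 0.5, b = 0.5))
  x <- sub_ontology(st, c("a", "b"))
  padded <- sub_ontology(st, c("a", "b", "pad1", "pad2"))
  expect_equal(breadth1(padded, st), breadth1(x, st))
  expect_lt(ontology_depth(breadth1(padded, st), padded, level = 1),
            ontology_depth(breadth1(x, st), x, level = 1))
})

test_that("equal precision/recall ontologies can differ in depth", {
  # two same-size ontologies covering the same number of observed concepts
  # (identical tp/fp/fn) but different probability mass
  st <- corpus_stats(c(a = 0.7, b = 0.1, c = 0.1, d = 0.1))
  x_heavy <- sub_ontology(st, c("a", "b"))
  x_light <- sub_ontology(st, c("c", "d"))
  r1 <- metric_report(x_heavy, st, level = 1)
  r2 <- metric_report(x_light, st, level = 1)
  expect_equal(r1$precision, r2$precision)
  expect_equal(r1$recall, r2$recall)
  expect_gt(r1$depth, r2$depth)
})
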