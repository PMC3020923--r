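# Breadth and Depth metric family.
#
# Breadth^1 is the total corpus probability mass covered by an ontology's
# concepts; Breadth^2 extends this to concept pairs, weighting each covered
# ordered pair (i, j) by f_i * p_ij; Breadth^3 further splits pair mass
# across relation types by their corpus prevalence weights. Depth divides
# Breadth by the number of constituents charged for it (concepts, ordered
# pairs, or typed relations), measuring coverage efficiency rather than
# coverage: national income versus income per capita. Concepts or pairs
# present in the ontology but unobserved in the corpus contribute zero mass
# rather than counting as false positives — corpus absence makes a relation
# improbable, not wrong.

#' Precision, recall and F-measure from confusion counts
#'
#' @param tp,fp,fn,tn non-negative counts. \code{tn} is accepted for
#'   completeness but unused by these three measures.
#' @return list with \code{precision}, \code{recall}, \code{f_measure}.
#'   An undefined ratio (zero denominator) is reported as \code{NA}, never
#'   silently 0; F is 0 when precision = recall = 0 and NA when either is
#'   NA.
#' @export
ir_metrics <- function(tp, fp, fn, tn = NA) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (is.na(precision) || is.na(recall)) NA_real_
       else if (precision + recall == 0) 0
       else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f_measure = f)
}

#' Cross-tabulate an ontology against corpus-observed content
#'
#' Concept level: tp = |C_X intersect C_T|, fp = |C_X - C_T|,
#' fn = |C_T - C_X|. Pair level analogously over ordered pairs. tn is not
#' defined without a closed universe and reported as NA.
#'
#' @param x an \code{ontology}.
#' @param stats a \code{corpus_stats}.
#' @param level 1 (concepts) or 2 (ordered pairs).
#' @return list with tp, fp, fn, tn.
#' @export
confusion_counts <- function(x, stats, level = 1) {
  if (level == 1) {
    cx <- x$concepts$id
    ct <- names(stats$concept_freq)
  } else {
    p <- pair_set(x)
    cx <- paste(p$source, p$target, sep = "\x1f")
    ct <- paste(stats$cooc$source, stats$cooc$target, sep = "\x1f")
  }
  list(tp = length(intersect(cx, ct)), fp = length(setdiff(cx, ct)),
       fn = length(setdiff(ct, cx)), tn = NA_integer_)
}

#' Concept-level Breadth
#'
#' Sum of corpus frequencies f_i over the ontology's concepts observed in
#' the corpus. Lies in [0, 1]; equals 1 when the ontology covers every
#' observed concept.
#'
#' @param x an \code{ontology}.
#' @param stats a \code{corpus_stats}.
#' @return numeric scalar.
#' @export
breadth1 <- function(x, stats) {
  f <- stats$concept_freq
  sum(f[names(f) %in% x$concepts$id])
}

#' Concept-and-relation Breadth
#'
#' Sum over the ontology's ordered pairs observed in the corpus of
#' f_i * p_ij. Bounded by 1 because each row of p sums to at most 1 and f
#' sums to 1.
#'
#' @inheritParams breadth1
#' @return numeric scalar.
#' @export
breadth2 <- function(x, stats) {
  p <- pair_set(x)
  if (!nrow(p) || !nrow(stats$cooc)) return(0)
  key_x <- paste(p$source, p$target, sep = "\x1f")
  cc <- stats$cooc
  key_t <- paste(cc$source, cc$target, sep = "\x1f")
  hit <- cc[key_t %in% key_x, , drop = FALSE]
  if (!nrow(hit)) return(0)
  f <- stats$concept_freq
  fsrc <- f[hit$source]
  fsrc[is.na(fsrc)] <- 0
  sum(fsrc * hit$p)
}

#' Depth at a given level
#'
#' Depth normalizes Breadth by ontology size: number of concepts at level
#' 1, number of ordered related pairs at level 2, number of relation
#' triples at level 3. The level-2 normalization deliberately ignores how
#' many distinct predicates the ontology catalogs per pair.
#'
#' @param breadth Breadth value at the chosen level.
#' @param x an \code{ontology} (supplies the size), or \code{NULL} if
#'   \code{size} is given directly.
#' @param level 1, 2 or 3.
#' @param size explicit size override (|C_X|, |pairs| or |R_X|).
#' @return numeric scalar Depth.
#' @export
ontology_depth <- function(breadth, x = NULL, level = 1, size = NULL) {
  if (is.null(size)) {
    stopifnot(inherits(x, "ontology"))
    size <- switch(as.character(level),
                   "1" = n_concepts(x), "2" = n_pairs(x), "3" = n_relations(x))
  }
  if (size <= 0) stop("empty ontology: Depth undefined")
  breadth / size
}

#' Typed-relation Breadth and Depth
#'
#' Splits each covered pair's f_i * p_ij mass across relation types in
#' proportion to their corpus prevalence weights, then sums over the typed
#' relations the ontology actually holds. Depth^3 divides by the total
#' relation count |R_X|. A covered pair lacking a weight entry contributes
#' zero, with a warning.
#'
#' @inheritParams breadth1
#' @return list with \code{breadth3} and \code{depth3}.
#' @export
breadth3_depth3 <- function(x, stats) {
  if (is.null(stats$typed_weight))
    stop("stats carries no typed-relation weights")
  rel <- x$relations
  if (!nrow(rel)) stop("empty ontology: Depth undefined")
  f <- stats$concept_freq
  cc <- stats$cooc
  pkey <- paste(cc$source, cc$target, sep = "\x1f")
  tw <- stats$typed_weight
  twkey <- paste(tw$source, tw$predicate, tw$target, sep = "\x1f")
  total <- 0
  missing_pi <- character()
  for (r in seq_len(nrow(rel))) {
    i <- rel$source[r]; j <- rel$target[r]; k <- rel$predicate[r]
    ci <- match(paste(i, j, sep = "\x1f"), pkey)
    if (is.na(ci) || is.na(f[i])) next        # pair unobserved: zero mass
    wi <- match(paste(i, k, j, sep = "\x1f"), twkey)
    if (is.na(wi)) {
      if (!any(tw$source == i & tw$target == j)) {
        missing_pi <- c(missing_pi, paste0(i, "->", j))
      }
      next                                     # predicate unobserved
    }
    total <- total + f[[i]] * cc$p[ci] * tw$weight[wi]
  }
  if (length(missing_pi))
    warning("no typed weights for covered pair(s): ",
            paste(unique(missing_pi), collapse = ", "),
            " — contributing 0")
  list(breadth3 = total, depth3 = total / nrow(rel))
}

#' Full metric report for an ontology against corpus statistics
#'
#' @inheritParams breadth1
#' @param level 1 or 2.
#' @return list of class \code{"metric_report"}: \code{level},
#'   \code{breadth}, \code{depth}, \code{size_used}, plus precision /
#'   recall / F at the same level.
#' @export
metric_report <- function(x, stats, level = 1) {
  stopifnot(level %in% 1:2)
  b <- if (level == 1) breadth1(x, stats) else breadth2(x, stats)
  size <- if (level == 1) n_concepts(x) else n_pairs(x)
  cc <- confusion_counts(x, stats, level = level)
  ir <- ir_metrics(cc$tp, cc$fp, cc$fn)
  structure(list(level = level, breadth = b,
                 depth = ontology_depth(b, size = size),
                 size_used = size,
                 precision = ir$precision, recall = ir$recall,
                 f_measure = ir$f_measure),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Level %d: Breadth = %.4g, Depth = %.4g (size %d); P = %.3g, R = %.3g, F = %.3g\n",
              x$level, x$breadth, x$depth, x$size_used,
              x$precision, x$recall, x$f_measure))
  invisible(x)
}
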