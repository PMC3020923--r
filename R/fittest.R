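# Complete ontology, fittest ontology of fixed size, and Depth Loss.

#' Complete ontology of a corpus
#'
#' The ontology holding every concept and every co-occurring concept pair
#' observed in the corpus, with their estimated probabilities attached.
#' It is the reference against which test ontologies are benchmarked and
#' the pool from which fittest ontologies are drawn.
#'
#' @param stats a \code{corpus_stats}.
#' @return list of class \code{"complete_ontology"}: \code{concepts}
#'   (data.frame id, f), \code{pairs} (data.frame source, target, p,
#'   weight = f_source * p), \code{label}.
#' @export
complete_ontology <- function(stats) {
  stopifnot(inherits(stats, "corpus_stats"))
  f <- stats$concept_freq
  if (!length(f)) stop("empty corpus statistics")
  concepts <- data.frame(id = names(f), f = as.numeric(f),
                         stringsAsFactors = FALSE)
  cc <- stats$cooc
  if (nrow(cc)) {
    fsrc <- f[cc$source]
    fsrc[is.na(fsrc)] <- 0
    pairs <- data.frame(source = cc$source, target = cc$target,
                        p = cc$p, weight = as.numeric(fsrc) * cc$p,
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(source = character(), target = character(),
                        p = numeric(), weight = numeric(),
                        stringsAsFactors = FALSE)
  }
  structure(list(concepts = concepts, pairs = pairs, label = stats$label),
            class = "complete_ontology")
}

#' @export
print.complete_ontology <- function(x, ...) {
  cat(sprintf("Complete ontology of '%s': %d concepts, %d ordered pairs\n",
              x$label, nrow(x$concepts), nrow(x$pairs)))
  invisible(x)
}

#' Fittest ontology of fixed size
#'
#' The size-constrained subset of the complete ontology that maximizes
#' Depth. Because Depth is an additive sum over selected items divided by
#' the fixed budget, the exact optimum is the top-\code{budget} items by
#' mass: concept frequency f_i at level 1, pair weight f_i * p_ij at level
#' 2. Ties are broken by identifier so selection is reproducible
#' bit-for-bit.
#'
#' @param complete a \code{\link{complete_ontology}}.
#' @param budget number of concepts (level 1) or ordered pairs (level 2)
#'   allowed; clamped to availability with a warning.
#' @param level 1 or 2.
#' @return list with \code{selection} (data.frame of chosen items with
#'   mass), \code{depth} (Depth of the fittest ontology), \code{breadth},
#'   \code{budget} (after clamping), \code{level}.
#' @export
fittest_of_size <- function(complete, budget, level = 1) {
  stopifnot(inherits(complete, "complete_ontology"), level %in% 1:2,
            budget >= 1)
  if (level == 1) {
    items <- complete$concepts
    items$mass <- items$f
    items$key <- items$id
  } else {
    items <- complete$pairs
    items$mass <- items$weight
    items$key <- paste(items$source, items$target, sep = "\x1f")
  }
  if (budget > nrow(items)) {
    warning("budget ", budget, " exceeds available items (", nrow(items),
            "); clamped")
    budget <- nrow(items)
  }
  ord <- order(-items$mass, items$key)
  sel <- items[ord[seq_len(budget)], , drop = FALSE]
  rownames(sel) <- NULL
  b <- sum(sel$mass)
  list(selection = sel[, setdiff(names(sel), "key"), drop = FALSE],
       breadth = b, depth = b / budget, budget = budget, level = level)
}

#' Depth Loss and its normalized variants
#'
#' Depth Loss is the Depth shortfall of a test ontology against the fittest
#' ontology of the same size: fittest depth minus test depth. Because Depth
#' is not naturally bounded, the normalized Relative Depth
#' (depth / fittest depth) and Relative Depth Loss (1 - Relative Depth) put
#' ontologies of any size on the [0, 1] scale; the two always sum to one.
#'
#' @param depth_x Depth of the test ontology.
#' @param fittest_depth Depth of the same-size fittest ontology (> 0).
#' @param tol slack for the optimality check.
#' @return list with \code{depth_loss}, \code{relative_depth},
#'   \code{relative_depth_loss}.
#' @export
loss_metrics <- function(depth_x, fittest_depth, tol = 1e-12) {
  if (fittest_depth <= 0) stop("fittest depth must be positive")
  if (depth_x > fittest_depth * (1 + tol) + tol)
    stop("internal consistency error: test depth ", depth_x,
         " exceeds fittest depth ", fittest_depth,
         " (optimality violated)")
  rd <- depth_x / fittest_depth
  list(depth_loss = fittest_depth - depth_x,
       relative_depth = rd,
       relative_depth_loss = 1 - rd)
}

#' Benchmark an ontology against a corpus end to end
#'
#' Computes the metric report at the requested level, the same-size fittest
#' ontology, and the loss metrics.
#'
#' @param x an \code{ontology}.
#' @param stats a \code{corpus_stats}.
#' @param level 1 or 2.
#' @return list with \code{report} (\code{\link{metric_report}}),
#'   \code{fittest} (\code{\link{fittest_of_size}} result) and the three
#'   loss metrics.
#' @export
benchmark_ontology <- function(x, stats, level = 1) {
  rep <- metric_report(x, stats, level = level)
  comp <- complete_ontology(stats)
  fit <- fittest_of_size(comp, budget = rep$size_used, level = level)
  c(list(report = rep, fittest = fit),
    loss_metrics(rep$depth, fit$depth))
}
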