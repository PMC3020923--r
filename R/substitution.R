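# Synonym substitution probabilities by conditioning on shared contexts.
#
# For a thesaurus headword w with synonyms s1..sM (same part of speech),
# the probability that w could be replaced by sj is estimated as
#   p(sj | w) = sum over contexts c of P(c | w) * P(sj | c),
# where P(c | w) is the share of w's occurrences carrying context c and
# P(x | c) is x's share of the candidate-set occurrences in context c, the
# candidate set being {w} union synonyms(w). Including the headword itself
# in the candidate set makes the row a proper conditional distribution
# (self-mass plus synonym mass equals one for any headword with context
# support) and prevents single-synonym entries from degenerating to
# certainty. Headwords absent from the corpus get all-zero rows.

#' Read a thesaurus from TSV
#'
#' Columns: \code{headword}, \code{pos} (coarse tag), \code{synonyms}
#' (pipe-separated).
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{headword}, \code{pos},
#'   \code{synonyms}.
#' @export
read_thesaurus <- function(path) {
  th <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  stopifnot(all(c("headword", "pos", "synonyms") %in% names(th)))
  th
}

#' Synonym substitution probabilities from context windows
#'
#' @param contexts context occurrence table from
#'   \code{\link{build_contexts}}.
#' @param thesaurus data.frame with columns \code{headword}, \code{pos},
#'   \code{synonyms} (pipe-separated). Synonyms are matched at the
#'   headword's part of speech; entries with no synonyms are skipped with a
#'   warning.
#' @return data.frame of class \code{"substitution_table"}: columns
#'   \code{headword}, \code{pos}, \code{synonym}, \code{probability},
#'   \code{headword_count} (corpus occurrences of the headword). The
#'   headword's own self-substitution row is included with
#'   \code{synonym == headword}.
#' @export
substitution_probs <- function(contexts, thesaurus) {
  thesaurus <- as.data.frame(thesaurus, stringsAsFactors = FALSE)
  occ_key <- paste(contexts$base_form, contexts$pos, sep = "\x1f")
  out <- vector("list", nrow(thesaurus))
  for (r in seq_len(nrow(thesaurus))) {
    hw <- thesaurus$headword[r]
    pos <- thesaurus$pos[r]
    syns <- strsplit(thesaurus$synonyms[r], "|", fixed = TRUE)[[1]]
    syns <- unique(syns[nzchar(syns) & syns != hw])
    if (!length(syns)) {
      warning("thesaurus entry '", hw, "' has no synonyms; skipped")
      next
    }
    cand <- c(hw, syns)
    hw_ctx <- contexts$context[occ_key == paste(hw, pos, sep = "\x1f")]
    n_hw <- length(hw_ctx)
    if (n_hw == 0) {
      out[[r]] <- data.frame(headword = hw, pos = pos, synonym = cand,
                             probability = 0, headword_count = 0L,
                             stringsAsFactors = FALSE)
      next
    }
    # occurrences of every candidate, by context
    cand_rows <- contexts[occ_key %in% paste(cand, pos, sep = "\x1f"), ,
                          drop = FALSE]
    ctx_word <- table(cand_rows$context, cand_rows$base_form)
    p_c_given_hw <- table(hw_ctx) / n_hw
    probs <- stats::setNames(numeric(length(cand)), cand)
    cols <- intersect(cand, colnames(ctx_word))
    for (cx in names(p_c_given_hw)) {
      cnt <- as.numeric(ctx_word[cx, cols, drop = FALSE])
      tot <- sum(cnt)
      if (tot == 0) next
      probs[cols] <- probs[cols] + as.numeric(p_c_given_hw[[cx]]) * cnt / tot
    }
    out[[r]] <- data.frame(headword = hw, pos = pos, synonym = cand,
                           probability = as.numeric(probs),
                           headword_count = n_hw, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(headword = character(), pos = character(),
                      synonym = character(), probability = numeric(),
                      headword_count = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("substitution_table", class(out))
  out
}

#' Rank a headword's synonyms by substitution probability
#'
#' Descending probability, ties broken lexicographically; the headword's
#' self-substitution row is excluded. Synonyms with zero probability are
#' dropped, so an all-zero row yields an empty ranking.
#'
#' @param table a \code{substitution_table}.
#' @param headword headword to rank.
#' @return character vector of synonyms, best first.
#' @export
rank_synonyms <- function(table, headword) {
  rows <- table[table$headword == headword & table$synonym != headword, ,
                drop = FALSE]
  if (!nrow(rows)) stop("unknown headword: ", headword)
  rows <- rows[rows$probability > 0, , drop = FALSE]
  rows <- rows[order(-rows$probability, rows$synonym), , drop = FALSE]
  rows$synonym
}

js_divergence <- function(p, q) {
  # base-2 Jensen-Shannon divergence on the simplex; max 1 on disjoint support
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Compare substitution tables across corpora
#'
#' For every headword present with non-zero support in at least two tables,
#' computes the mean pairwise Jensen-Shannon divergence (base 2, so 0 for
#' identical distributions and 1 for disjoint support) between its
#' candidate-set distributions, and ranks headwords from most to least
#' divergent. Headwords with an all-zero row in a corpus are excluded from
#' that corpus's comparisons; headwords missing everywhere are omitted.
#'
#' @param tables named list of \code{substitution_table}s over a shared
#'   thesaurus.
#' @return data.frame with columns \code{headword}, \code{pos},
#'   \code{divergence}, sorted most-divergent first.
#' @export
compare_corpora <- function(tables) {
  stopifnot(length(tables) >= 2)
  hw_all <- unique(do.call(rbind, lapply(tables, function(t)
    unique(t[, c("headword", "pos")]))))
  res <- lapply(seq_len(nrow(hw_all)), function(i) {
    hw <- hw_all$headword[i]; pos <- hw_all$pos[i]
    dists <- list()
    for (t in tables) {
      rows <- t[t$headword == hw & t$pos == pos, , drop = FALSE]
      if (!nrow(rows) || sum(rows$probability) <= 0) next
      v <- stats::setNames(rows$probability, rows$synonym)
      dists[[length(dists) + 1L]] <- v[order(names(v))]
    }
    if (length(dists) < 2) return(NULL)
    # align candidate supports by name before comparing
    support <- sort(unique(unlist(lapply(dists, names))))
    dists <- lapply(dists, function(v) {
      out <- stats::setNames(numeric(length(support)), support)
      out[names(v)] <- v
      out
    })
    pairs <- utils::combn(length(dists), 2)
    d <- mean(apply(pairs, 2, function(ij)
      js_divergence(dists[[ij[1]]], dists[[ij[2]]])))
    data.frame(headword = hw, pos = pos, divergence = d,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(headword = character(), pos = character(),
                      divergence = numeric(), stringsAsFactors = FALSE))
  res <- res[order(-res$divergence, res$headword), ]
  rownames(res) <- NULL
  res
}

#' Write a substitution table to TSV
#'
#' @param table a \code{substitution_table}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_substitution_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
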