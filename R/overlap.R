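# Venn-style overlap of ontologies at the concept and relation level.
#
# Concept identity across ontologies is established by case-folded,
# lemmatized exact string match over preferred names and synonyms. Concepts
# whose normalized key sets intersect are treated as the same union element
# (connected components over shared keys), so region counts always
# partition the union exactly.

concept_keys <- function(x) {
  lapply(seq_len(nrow(x$concepts)), function(i) {
    terms <- c(x$concepts$preferred_name[i],
               strsplit(x$concepts$synonyms[i], "|", fixed = TRUE)[[1]])
    unique(normalize_term(terms[nzchar(terms)]))
  })
}

# assign each concept of each ontology to a cross-ontology match class
match_classes <- function(ontologies, matcher = normalize_term) {
  nodes <- list()   # per node: keys
  for (oi in seq_along(ontologies)) {
    x <- ontologies[[oi]]
    ks <- lapply(seq_len(nrow(x$concepts)), function(i) {
      terms <- c(x$concepts$preferred_name[i],
                 strsplit(x$concepts$synonyms[i], "|", fixed = TRUE)[[1]])
      unique(matcher(terms[nzchar(terms)]))
    })
    for (ci in seq_along(ks))
      nodes[[length(nodes) + 1L]] <- list(onto = oi,
                                          id = x$concepts$id[ci],
                                          keys = ks[[ci]])
  }
  # union-find over shared keys
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  key_owner <- new.env(parent = emptyenv())
  for (i in seq_along(nodes)) {
    for (k in nodes[[i]]$keys) {
      j <- get0(k, envir = key_owner)
      if (is.null(j)) assign(k, i, envir = key_owner)
      else { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj }
    }
  }
  comp <- vapply(seq_along(nodes), find, integer(1))
  comp <- match(comp, unique(comp))
  data.frame(onto = vapply(nodes, `[[`, integer(1), "onto"),
             id = vapply(nodes, `[[`, character(1), "id"),
             class = comp, stringsAsFactors = FALSE)
}

region_labels <- function(n, names) {
  regs <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1, , drop = FALSE]
  apply(regs, 1, function(r) paste(names[as.logical(r)], collapse = "&"))
}

count_regions <- function(membership, names) {
  # membership: list per union element of integer vector of ontology indices
  lab <- vapply(membership, function(m)
    paste(names[sort(unique(m))], collapse = "&"), character(1))
  all_lab <- region_labels(length(names), names)
  counts <- stats::setNames(integer(length(all_lab)), all_lab)
  tb <- table(lab)
  counts[names(tb)] <- as.integer(tb)
  counts
}

#' Concept-level overlap of two or three ontologies
#'
#' Counts, for every intersection region of the Venn partition, the number
#' of distinct concepts (match classes). Two concepts from different
#' ontologies belong to the same class when any of their normalized names
#' or synonyms coincide.
#'
#' @param ontologies list of 2 or 3 \code{ontology} objects.
#' @param matcher function mapping term vectors to canonical keys
#'   (default \code{\link{normalize_term}}).
#' @return named integer vector of region counts (names like
#'   \code{"A"}, \code{"A&B"}, ...); counts sum to the union size.
#' @export
concept_overlap <- function(ontologies, matcher = normalize_term) {
  stopifnot(length(ontologies) %in% 2:3)
  nm <- vapply(ontologies, `[[`, character(1), "name")
  if (anyDuplicated(nm)) nm <- paste0(nm, ".", seq_along(nm))
  mc <- match_classes(ontologies, matcher)
  membership <- split(mc$onto, mc$class)
  count_regions(membership, nm)
}

#' Relation-level overlap of two or three ontologies
#'
#' As \code{\link{concept_overlap}} but over concept pairs with at least one
#' relation, with endpoints mapped through the cross-ontology match classes.
#'
#' @inheritParams concept_overlap
#' @param directed if \code{FALSE}, pairs are compared as unordered
#'   (symmetric comparison).
#' @return named integer vector of region counts.
#' @export
relation_overlap <- function(ontologies, matcher = normalize_term,
                             directed = TRUE) {
  stopifnot(length(ontologies) %in% 2:3)
  nm <- vapply(ontologies, `[[`, character(1), "name")
  if (anyDuplicated(nm)) nm <- paste0(nm, ".", seq_along(nm))
  mc <- match_classes(ontologies, matcher)
  pair_keys <- lapply(seq_along(ontologies), function(oi) {
    x <- ontologies[[oi]]
    cls <- mc$class[mc$onto == oi]
    names(cls) <- mc$id[mc$onto == oi]
    p <- pair_set(x)
    if (!nrow(p)) return(character())
    a <- cls[p$source]; b <- cls[p$target]
    if (directed) unique(paste(a, b, sep = ">"))
    else unique(paste(pmin(a, b), pmax(a, b), sep = "~"))
  })
  all_keys <- unique(unlist(pair_keys))
  membership <- lapply(all_keys, function(k)
    which(vapply(pair_keys, function(pk) k %in% pk, logical(1))))
  count_regions(membership, nm)
}
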