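#' Construct an ontology
#'
#' An ontology is modelled as a set of concepts and a set of directed,
#' optionally typed relations between them. Concepts carry a preferred name,
#' optional synonyms and an optional semantic type; relations carry a
#' predicate label (default \code{"related-to"}). Duplicate
#' (source, predicate, target) triples are collapsed, so a predicate-poor
#' ontology has exactly one relation per connected ordered pair, while a
#' predicate-rich one may have several.
#'
#' @param concepts data.frame with columns \code{id}, \code{preferred_name}
#'   and optionally \code{synonyms} (pipe-separated string or list column)
#'   and \code{semantic_type}.
#' @param relations data.frame with columns \code{source}, \code{target} and
#'   optionally \code{predicate}. May be empty.
#' @param name label for the ontology.
#' @return An object of class \code{"ontology"} with elements
#'   \code{concepts}, \code{relations}, \code{name}.
#' @examples
#' onto <- ontology(
#'   concepts  = data.frame(id = c("a", "b"), preferred_name = c("apple", "pear")),
#'   relations = data.frame(source = "a", target = "b"),
#'   name = "toy")
#' n_relations(onto)
#' @export
ontology <- function(concepts, relations = NULL, name = "ontology") {
  stopifnot(is.data.frame(concepts))
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  if (!all(c("id", "preferred_name") %in% names(concepts)))
    stop("concepts must have columns 'id' and 'preferred_name'")
  concepts$id <- as.character(concepts$id)
  concepts$preferred_name <- as.character(concepts$preferred_name)
  if (anyDuplicated(concepts$id))
    stop("integrity error: duplicate concept id(s): ",
         paste(unique(concepts$id[duplicated(concepts$id)]), collapse = ", "))
  if (any(!nzchar(concepts$preferred_name)))
    stop("integrity error: empty preferred_name")
  if (is.null(concepts$synonyms)) concepts$synonyms <- ""
  if (is.list(concepts$synonyms))
    concepts$synonyms <- vapply(concepts$synonyms,
                                function(s) paste(s, collapse = "|"), character(1))
  concepts$synonyms <- as.character(concepts$synonyms)
  concepts$synonyms[is.na(concepts$synonyms)] <- ""
  # drop synonyms that duplicate each other (or the preferred name) after
  # case/lemma normalization
  concepts$synonyms <- mapply(function(syn, pref) {
    if (!nzchar(syn)) return("")
    parts <- strsplit(syn, "|", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    keys <- vapply(parts, normalize_term, character(1))
    keep <- !duplicated(keys) & keys != normalize_term(pref)
    paste(parts[keep], collapse = "|")
  }, concepts$synonyms, concepts$preferred_name, USE.NAMES = FALSE)
  if (is.null(concepts$semantic_type)) concepts$semantic_type <- NA_character_

  if (is.null(relations))
    relations <- data.frame(source = character(), predicate = character(),
                            target = character(), stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (nrow(relations)) {
    if (!all(c("source", "target") %in% names(relations)))
      stop("relations must have columns 'source' and 'target'")
    if (is.null(relations$predicate)) relations$predicate <- "related-to"
    relations$source <- as.character(relations$source)
    relations$target <- as.character(relations$target)
    relations$predicate <- as.character(relations$predicate)
    dangling <- setdiff(unique(c(relations$source, relations$target)), concepts$id)
    if (length(dangling))
      stop("integrity error: relation endpoint(s) not in concept set: ",
           paste(dangling, collapse = ", "))
    relations <- unique(relations[, c("source", "predicate", "target")])
    relations <- relations[order(relations$source, relations$target,
                                 relations$predicate), , drop = FALSE]
    rownames(relations) <- NULL
  } else {
    relations <- data.frame(source = character(), predicate = character(),
                            target = character(), stringsAsFactors = FALSE)
  }
  concepts <- concepts[order(concepts$id),
                       c("id", "preferred_name", "synonyms", "semantic_type")]
  rownames(concepts) <- NULL
  structure(list(name = name, concepts = concepts, relations = relations),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("Ontology '%s': %d concepts, %d relations (%d ordered pairs)\n",
              x$name, nrow(x$concepts), nrow(x$relations), nrow(pair_set(x))))
  invisible(x)
}

#' Number of relations / concepts in an ontology
#'
#' \code{n_relations} counts relation triples (|R|); \code{n_concepts}
#' counts concepts (|C|); \code{n_pairs} counts ordered concept pairs with
#' at least one relation.
#' @param x an \code{ontology}.
#' @return integer count.
#' @export
n_relations <- function(x) nrow(x$relations)

#' @rdname n_relations
#' @export
n_concepts <- function(x) nrow(x$concepts)

#' @rdname n_relations
#' @export
n_pairs <- function(x) nrow(pair_set(x))

#' Ordered concept pairs with at least one relation
#'
#' Collapses relation triples to the set of distinct ordered
#' (source, target) pairs, ignoring predicate multiplicity. Direction is
#' preserved: (a, b) and (b, a) are distinct pairs.
#'
#' @param x an \code{ontology}.
#' @return data.frame with columns \code{source}, \code{target}, one row per
#'   ordered pair.
#' @export
pair_set <- function(x) {
  stopifnot(inherits(x, "ontology"))
  p <- unique(x$relations[, c("source", "target"), drop = FALSE])
  p <- p[order(p$source, p$target), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Read an ontology from disk
#'
#' Three interchange formats are supported:
#' \describe{
#'   \item{tsv}{\code{<path>} is a directory (or file stem) holding
#'     \code{concepts.tsv} (columns \code{id}, \code{preferred_name},
#'     \code{synonyms} pipe-separated, \code{semantic_type}) and
#'     \code{relations.tsv} (columns \code{source_id}, \code{predicate},
#'     \code{target_id}).}
#'   \item{json}{a single JSON file mirroring the same schema, with top-level
#'     \code{name}, \code{concepts}, \code{relations}.}
#'   \item{obo}{an OBO 1.2 flat file (read-only). \code{is_a} and
#'     \code{relationship:} lines become relations with the stated
#'     predicate; obsolete terms are skipped.}
#' }
#'
#' @param path file or directory path.
#' @param format one of \code{"tsv"}, \code{"json"}, \code{"obo"}.
#' @param name ontology label; defaults to the path's base name.
#' @return an \code{ontology}.
#' @export
load_ontology <- function(path, format = c("tsv", "json", "obo"),
                          name = NULL) {
  format <- match.arg(format)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  switch(format,
         tsv  = read_ontology_tsv(path, name),
         json = read_ontology_json(path, name),
         obo  = read_ontology_obo(path, name))
}

read_ontology_tsv <- function(path, name) {
  cfile <- if (dir.exists(path)) file.path(path, "concepts.tsv") else paste0(path, "_concepts.tsv")
  rfile <- if (dir.exists(path)) file.path(path, "relations.tsv") else paste0(path, "_relations.tsv")
  if (!file.exists(cfile)) stop("format error: missing ", cfile)
  concepts <- utils::read.delim(cfile, stringsAsFactors = FALSE,
                                colClasses = "character", quote = "")
  relations <- NULL
  if (file.exists(rfile) && length(readLines(rfile, n = 2)) > 1) {
    relations <- utils::read.delim(rfile, stringsAsFactors = FALSE,
                                   colClasses = "character", quote = "")
    names(relations)[names(relations) == "source_id"] <- "source"
    names(relations)[names(relations) == "target_id"] <- "target"
  }
  ontology(concepts, relations, name = name)
}

read_ontology_json <- function(path, name) {
  if (!file.exists(path)) stop("format error: missing ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  concepts <- as.data.frame(obj$concepts, stringsAsFactors = FALSE)
  relations <- if (!is.null(obj$relations) && length(obj$relations))
    as.data.frame(obj$relations, stringsAsFactors = FALSE) else NULL
  if (!is.null(relations)) {
    names(relations)[names(relations) == "source_id"] <- "source"
    names(relations)[names(relations) == "target_id"] <- "target"
  }
  ontology(concepts, relations, name = if (!is.null(obj$name)) obj$name else name)
}

# Minimal OBO 1.2 reader: [Term] stanzas with id, name, synonym, is_a,
# relationship and is_obsolete tags. Anything else is ignored.
read_ontology_obo <- function(path, name) {
  if (!file.exists(path)) stop("format error: missing ", path)
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  in_term <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "[Term]") { terms <- flush(cur, terms); cur <- list(rels = list(), syn = character()); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { terms <- flush(cur, terms); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (!grepl("^[A-Za-z_]+:", ln))
      stop("format error in OBO file at line ", i, ": ", ln)
    tag <- sub(":.*$", "", ln)
    val <- trimws(sub("^[A-Za-z_]+:", "", ln))
    val <- sub("\\s*!.*$", "", val)  # strip trailing comments
    if (tag == "id") cur$id <- val
    else if (tag == "name") cur$name <- val
    else if (tag == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    else if (tag == "synonym") {
      m <- regmatches(val, regexec('^"([^"]*)"', val))[[1]]
      if (length(m) == 2) cur$syn <- c(cur$syn, m[2])
    }
    else if (tag == "is_a") cur$rels[[length(cur$rels) + 1L]] <- c("is_a", val)
    else if (tag == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) >= 2) cur$rels[[length(cur$rels) + 1L]] <- c(parts[1], parts[2])
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop("format error: no [Term] stanzas in ", path)
  concepts <- data.frame(
    id = vapply(terms, `[[`, character(1), "id"),
    preferred_name = vapply(terms, function(t) t$name %||% t$id, character(1)),
    synonyms = vapply(terms, function(t) paste(t$syn, collapse = "|"), character(1)),
    stringsAsFactors = FALSE)
  rel <- do.call(rbind, unlist(lapply(terms, function(t) {
    lapply(t$rels, function(r) data.frame(source = t$id, predicate = r[1],
                                          target = r[2], stringsAsFactors = FALSE))
  }), recursive = FALSE))
  # drop relations pointing at obsolete/unknown terms rather than failing:
  # the OBO subset read here is intentionally minimal
  if (!is.null(rel)) rel <- rel[rel$target %in% concepts$id, , drop = FALSE]
  ontology(concepts, rel, name = name)
}

#' Write an ontology to disk
#'
#' Inverse of \code{\link{load_ontology}} for the tsv and json dialects.
#' Output is canonically ordered, so load-save-load round-trips are
#' identical.
#'
#' @param x an \code{ontology}.
#' @param path directory (tsv) or file path (json).
#' @param format \code{"tsv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_ontology <- function(x, path, format = c("tsv", "json")) {
  stopifnot(inherits(x, "ontology"))
  format <- match.arg(format)
  if (format == "tsv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(x$concepts, file.path(path, "concepts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    rel <- x$relations
    names(rel) <- c("source_id", "predicate", "target_id")
    utils::write.table(rel, file.path(path, "relations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(name = x$name, concepts = x$concepts,
                              relations = x$relations),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
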