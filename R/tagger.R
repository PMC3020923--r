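# Rule-based English morphology and part-of-speech assignment.
#
# The corpus pipeline only needs three things from a tagger: sentence
# splits, a coarse POS tag in {NOUN, VERB, ADJ, ADV, OTHER} and a base
# (lemmatized) form per token. Any function honouring that contract can be
# plugged in; the default below is a compact rule/lexicon tagger adequate
# for controlled and synthetic text.

.irregular_lemmas <- c(
  ran = "run", went = "go", ate = "eat", saw = "see", was = "be", were = "be",
  is = "be", are = "be", am = "be", been = "be", being = "be", has = "have",
  had = "have", did = "do", does = "do", done = "do", said = "say",
  made = "make", took = "take", taken = "take", came = "come", gave = "give",
  got = "get", found = "find", thought = "think", told = "tell", felt = "feel",
  left = "leave", kept = "keep", held = "hold", brought = "bring",
  wrote = "write", written = "write", stood = "stand", lay = "lie",
  knew = "know", known = "know", grew = "grow", drew = "draw", slept = "sleep",
  mice = "mouse", men = "man", women = "woman", children = "child",
  feet = "foot", teeth = "tooth", geese = "goose", people = "person",
  better = "good", best = "good", worse = "bad", worst = "bad")

.function_words <- c(
  "a", "an", "the", "this", "that", "these", "those", "some", "any", "no",
  "each", "every", "of", "in", "on", "at", "by", "for", "with", "from", "to",
  "into", "onto", "over", "under", "about", "after", "before", "between",
  "through", "during", "without", "within", "and", "or", "but", "nor", "so",
  "yet", "if", "because", "while", "although", "than", "as", "i", "you",
  "he", "she", "it", "we", "they", "him", "her", "them", "his", "its",
  "their", "our", "your", "my", "me", "us", "who", "whom", "which", "what",
  "when", "where", "why", "how", "not", "be", "been", "being", "is", "are",
  "was", "were", "am", "will", "would", "can", "could", "shall", "should",
  "may", "might", "must", "do", "does", "did", "have", "has", "had", "there",
  "here", "then", "too", "very", "also", "just", "only")

.common_verbs <- c(
  "sleep", "run", "eat", "go", "see", "say", "make", "take", "come", "give",
  "get", "find", "think", "tell", "feel", "leave", "keep", "hold", "bring",
  "write", "stand", "know", "grow", "draw", "walk", "jump", "play", "look",
  "want", "use", "work", "call", "try", "ask", "need", "become", "show",
  "hear", "let", "help", "talk", "turn", "start", "move", "live", "believe",
  "treat", "cause", "affect", "increase", "decrease", "reduce", "improve",
  "induce", "inhibit", "observe", "report", "suggest", "indicate", "occur",
  "develop", "associate", "compare", "measure", "study", "examine", "chase",
  "purr", "bark", "meow")

.common_adjectives <- c(
  "big", "small", "red", "blue", "green", "black", "white", "old", "new",
  "good", "bad", "high", "low", "long", "short", "great", "little", "large",
  "young", "early", "late", "chronic", "acute", "severe", "mild", "common",
  "rare", "clinical", "viral", "bacterial", "furry", "soft", "loud", "quiet",
  "fast", "slow", "happy", "sad", "warm", "cold")

.common_adverbs <- c(
  "fast", "well", "often", "never", "always", "soon", "again", "away",
  "almost", "quite", "rather", "really", "perhaps", "maybe", "together",
  "loudly", "quietly", "quickly", "slowly")

#' Lemmatize an English word with morphological rules
#'
#' Irregular forms come from a built-in table; regular inflections are
#' stripped by suffix rules (plural -s/-es/-ies, verbal -ing/-ed, adverbial
#' forms are left intact). Input is case-folded first. Words without an
#' applicable rule are returned unchanged, which keeps opaque identifiers
#' (codes, synthetic concept names) stable.
#'
#' @param word character vector of surface forms.
#' @return character vector of base forms.
#' @export
lemmatize <- function(word) {
  vapply(tolower(word), lemmatize1, character(1), USE.NAMES = FALSE)
}

lemmatize1 <- function(w) {
  if (w %in% names(.irregular_lemmas)) return(unname(.irregular_lemmas[[w]]))
  if (w %in% .function_words || w %in% .common_verbs ||
      w %in% .common_adjectives || w %in% .common_adverbs) return(w)
  n <- nchar(w)
  # -ies -> -y (bodies -> body)
  if (n > 4 && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3), "y"))
  # -sses/-shes/-ches/-xes/-zes -> strip es
  if (n > 4 && grepl("(ss|sh|ch|x|z)es$", w)) return(substr(w, 1, n - 2))
  # plain plural -s (not -ss, -us, -is)
  if (n > 3 && endsWith(w, "s") && !grepl("(ss|us|is)$", w))
    return(substr(w, 1, n - 1))
  # -ing (running -> run, making -> make heuristic: drop doubled consonant)
  if (n > 5 && endsWith(w, "ing")) {
    stem <- substr(w, 1, n - 3)
    if (nchar(stem) > 2 && substr(stem, nchar(stem), nchar(stem)) ==
        substr(stem, nchar(stem) - 1, nchar(stem) - 1))
      stem <- substr(stem, 1, nchar(stem) - 1)
    return(stem)
  }
  # -ed
  if (n > 4 && endsWith(w, "ed")) {
    stem <- substr(w, 1, n - 2)
    if (nchar(stem) > 2 && substr(stem, nchar(stem), nchar(stem)) ==
        substr(stem, nchar(stem) - 1, nchar(stem) - 1))
      stem <- substr(stem, 1, nchar(stem) - 1)
    return(stem)
  }
  w
}

#' Normalize a term to a canonical matching key
#'
#' Case-folds, tokenizes and lemmatizes each token, then rejoins with single
#' spaces. Used for establishing concept identity across ontologies and for
#' dictionary matching at the lemma level.
#'
#' @param term character vector of names/terms.
#' @return character vector of canonical keys.
#' @export
normalize_term <- function(term) {
  vapply(term, function(t) {
    toks <- tokenize_text(t)
    paste(lemmatize(toks), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

tokenize_text <- function(x) {
  toks <- regmatches(x, gregexpr("[A-Za-z0-9][A-Za-z0-9'-]*", x))[[1]]
  tolower(toks)
}

pos_tag1 <- function(base) {
  if (base %in% .function_words) return("OTHER")
  if (base %in% .common_adverbs) return("ADV")
  if (base %in% .common_verbs) return("VERB")
  if (base %in% .common_adjectives) return("ADJ")
  if (endsWith(base, "ly") && nchar(base) > 3) return("ADV")
  if (grepl("(ous|ful|ive|able|ible|al|ic)$", base) && nchar(base) > 4) return("ADJ")
  "NOUN"
}

#' Default sentence splitter / tagger / lemmatizer
#'
#' Returns a tagger function usable by \code{\link{analyze_document}}: it
#' takes raw text and returns a list of sentences, each a data.frame with
#' columns \code{surface}, \code{base_form}, \code{pos}. Tags are coarse
#' (\code{NOUN}, \code{VERB}, \code{ADJ}, \code{ADV}, \code{OTHER}).
#'
#' @param lexicon optional data.frame with columns \code{surface},
#'   \code{base_form}, \code{pos} overriding the built-in rules (used e.g.
#'   by the synthetic-corpus generator, whose vocabulary is known exactly).
#' @return a function \code{text -> list of sentence data.frames}.
#' @export
simple_tagger <- function(lexicon = NULL) {
  if (!is.null(lexicon)) {
    lexicon <- as.data.frame(lexicon, stringsAsFactors = FALSE)
    stopifnot(all(c("surface", "base_form", "pos") %in% names(lexicon)))
    lex_base <- stats::setNames(lexicon$base_form, tolower(lexicon$surface))
    lex_pos <- stats::setNames(lexicon$pos, tolower(lexicon$surface))
  }
  function(text) {
    sents <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
    sents <- sents[nzchar(trimws(sents))]
    out <- lapply(sents, function(s) {
      surf <- tokenize_text(s)
      if (!length(surf)) return(NULL)
      base <- character(length(surf))
      pos <- character(length(surf))
      for (i in seq_along(surf)) {
        w <- surf[i]
        if (!is.null(lexicon) && w %in% names(lex_base)) {
          base[i] <- lex_base[[w]]
          pos[i] <- lex_pos[[w]]
        } else {
          base[i] <- lemmatize1(w)
          pos[i] <- pos_tag1(base[i])
        }
      }
      data.frame(surface = surf, base_form = base, pos = pos,
                 stringsAsFactors = FALSE)
    })
    out[!vapply(out, is.null, logical(1))]
  }
}
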