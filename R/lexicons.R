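#' Load the feature lexicons
#'
#' Reads the seven lexicon families driving the pattern, window and negation
#' features: relational keywords, trigger words, action-verb phrases, genetic
#' phenomena, context-specific phrases, negation cues and stop words. Files
#' are plain text, one term or phrase per line, UTF-8, with `#` comments;
#' entries are lowercased on load. The package ships editable defaults under
#' `inst/extdata/lexicons/`.
#'
#' @param dir Directory containing the seven `*.txt` lexicon files; defaults
#'   to the lexicons shipped with the package.
#' @return An object of class `gdrex_lexicons`: a named list of character
#'   vectors.
#' @export
load_lexicons <- function(dir = default_lexicon_dir()) {
  if (!dir.exists(dir)) stopf("lexicon directory not found: %s", dir)
  fields <- c("relational_keywords", "trigger_words", "action_verbs",
              "genetic_phenomena", "context_specific", "negation_cues",
              "stop_words")
  lex <- lapply(fields, function(f)
    read_lexicon_file(file.path(dir, paste0(f, ".txt"))))
  names(lex) <- fields
  bad <- intersect(lex$negation_cues, lex$stop_words)
  if (length(bad))
    stopf("negation cues and stop words must be disjoint; shared: %s",
          paste(bad, collapse = ", "))
  structure(lex, class = "gdrex_lexicons")
}

#' @rdname load_lexicons
#' @export
default_lexicon_dir <- function() {
  system.file("extdata", "lexicons", package = "gdrex")
}
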