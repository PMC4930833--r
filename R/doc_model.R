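# Annotated-document data model. All offsets are 0-based, half-open character
# offsets into the *document* text (standoff convention); token/NP/mention
# spans therefore index doc$text directly via span_text().

#' Extract the text of a 0-based half-open span
#'
#' @param text A character scalar.
#' @param start,end Integer offsets, 0-based, half-open: the span covers
#'   characters `start` to `end - 1`.
#' @return The surface string at `[start, end)`.
#' @export
span_text <- function(text, start, end) {
  substring(text, start + 1L, end)
}

.num_levels <- c("singular", "plural", "unknown")

#' Construct a token
#'
#' @param start,end 0-based half-open character offsets into the document text.
#' @param number Grammatical number: `"singular"`, `"plural"` or `"unknown"`.
#' @param pronoun Logical; is the token a pronoun?
#' @param definite Logical; is the token a definite determiner?
#' @param pos Optional coarse category label (e.g. `"NOUN"`, `"DET"`, `"VERB"`),
#'   consumed only by [chunk_noun_phrases()].
#' @return A list of class `"belminer_token"`.
#' @export
token <- function(start, end, number = "unknown", pronoun = FALSE,
                  definite = FALSE, pos = NULL) {
  number <- match.arg(number, .num_levels)
  stopifnot(start >= 0, end > start)
  structure(list(start = as.integer(start), end = as.integer(end),
                 number = number, pronoun = isTRUE(pronoun),
                 definite = isTRUE(definite), pos = pos),
            class = "belminer_token")
}

#' Construct a noun phrase annotation
#'
#' @param start,end 0-based half-open offsets into the document text.
#' @param head 1-based index of the head token within the sentence token list.
#' @param number Grammatical number of the phrase.
#' @param definite Logical; does the phrase start with a definite determiner?
#' @return A list of class `"belminer_np"`.
#' @export
noun_phrase <- function(start, end, head, number = "unknown", definite = FALSE) {
  number <- match.arg(number, .num_levels)
  stopifnot(start >= 0, end > start, head >= 1)
  structure(list(start = as.integer(start), end = as.integer(end),
                 head = as.integer(head), number = number,
                 definite = isTRUE(definite)),
            class = "belminer_np")
}

#' Construct an entity mention annotation
#'
#' @param start,end 0-based half-open offsets into the document text.
#' @param category Mention category; only `"gene_or_protein"` is in scope.
#' @param source Where the mention came from (`"annotation"` or `"gazetteer"`).
#' @return A list of class `"belminer_mention"`.
#' @export
entity_mention <- function(start, end, category = "gene_or_protein",
                           source = "annotation") {
  category <- match.arg(category, "gene_or_protein")
  source <- match.arg(source, c("annotation", "gazetteer"))
  stopifnot(start >= 0, end > start)
  structure(list(start = as.integer(start), end = as.integer(end),
                 category = category, source = source),
            class = "belminer_mention")
}

#' Construct a sentence
#'
#' @param id Sentence identifier, e.g. `"SEN:10028008"`.
#' @param start,end 0-based half-open offsets of the sentence in the document.
#' @param tokens List of [token()] objects, ordered and non-overlapping.
#' @param noun_phrases List of [noun_phrase()] objects.
#' @param mentions List of [entity_mention()] objects.
#' @return A list of class `"belminer_sentence"`.
#' @export
sentence <- function(id, start, end, tokens = list(), noun_phrases = list(),
                     mentions = list()) {
  structure(list(id = as.character(id), start = as.integer(start),
                 end = as.integer(end), tokens = tokens,
                 noun_phrases = noun_phrases, mentions = mentions),
            class = "belminer_sentence")
}

#' Construct and validate an annotated document
#'
#' @param id Document identifier.
#' @param text Full document text.
#' @param sentences List of [sentence()] objects, ordered and non-overlapping.
#' @return A validated object of class `"annotated_document"`.
#' @export
annotated_document <- function(id, text, sentences = list()) {
  doc <- structure(list(id = as.character(id), text = text,
                        sentences = sentences),
                   class = "annotated_document")
  validate_document(doc)
}

#' Validate an annotated document against its structural invariants
#'
#' Checks that sentences are ordered and non-overlapping, that every child
#' span (token, noun phrase, mention) lies within its sentence, that tokens
#' are ordered and non-overlapping, and that every noun-phrase head token
#' lies inside the phrase span.
#'
#' @param doc An `"annotated_document"`.
#' @return `doc`, invisibly, if valid; otherwise an error naming the span.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "annotated_document"))
  n <- nchar(doc$text)
  prev_end <- -1L
  for (s in doc$sentences) {
    if (s$start < 0 || s$end > n || s$start >= s$end)
      stop(sprintf("sentence %s: span [%d,%d) outside text of length %d",
                   s$id, s$start, s$end, n))
    if (s$start < prev_end)
      stop(sprintf("sentence %s overlaps the preceding sentence", s$id))
    prev_end <- s$end
    tprev <- s$start - 1L
    for (tk in s$tokens) {
      if (tk$start < s$start || tk$end > s$end)
        stop(sprintf("sentence %s: token span [%d,%d) outside sentence span",
                     s$id, tk$start, tk$end))
      if (tk$start < tprev)
        stop(sprintf("sentence %s: tokens unordered or overlapping at %d",
                     s$id, tk$start))
      tprev <- tk$end
    }
    for (np in s$noun_phrases) {
      if (np$start < s$start || np$end > s$end)
        stop(sprintf("sentence %s: noun phrase span [%d,%d) outside sentence",
                     s$id, np$start, np$end))
      if (np$head > length(s$tokens))
        stop(sprintf("sentence %s: noun phrase head index %d out of range",
                     s$id, np$head))
      ht <- s$tokens[[np$head]]
      if (ht$start < np$start || ht$end > np$end)
        stop(sprintf("sentence %s: head token [%d,%d) outside NP [%d,%d)",
                     s$id, ht$start, ht$end, np$start, np$end))
    }
    for (m in s$mentions) {
      if (m$start < s$start || m$end > s$end)
        stop(sprintf("sentence %s: mention span [%d,%d) outside sentence",
                     s$id, m$start, m$end))
    }
  }
  invisible(doc)
}

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("<annotated_document %s: %d sentence(s), %d characters>\n",
              x$id, length(x$sentences), nchar(x$text)))
  for (s in x$sentences) {
    cat(sprintf("  %s [%d,%d) tokens=%d NPs=%d mentions=%d\n", s$id,
                s$start, s$end, length(s$tokens), length(s$noun_phrases),
                length(s$mentions)))
  }
  invisible(x)
}

.doc_to_list <- function(doc) {
  list(
    id = doc$id,
    text = doc$text,
    sentences = lapply(doc$sentences, function(s) {
      out <- list(
        id = s$id, start = s$start, end = s$end,
        tokens = lapply(s$tokens, function(tk) {
          t <- list(start = tk$start, end = tk$end, number = tk$number,
                    pronoun = tk$pronoun, definite = tk$definite)
          if (!is.null(tk$pos)) t$pos <- tk$pos
          t
        }),
        noun_phrases = lapply(s$noun_phrases, function(np) {
          list(start = np$start, end = np$end, head = np$head,
               number = np$number, definite = np$definite)
        }),
        mentions = lapply(s$mentions, function(m) {
          list(start = m$start, end = m$end, category = m$category)
        }))
      out
    }))
}

.doc_from_list <- function(x, path = "<memory>") {
  if (is.null(x$id) || is.null(x$text))
    stop(sprintf("%s: document JSON must carry 'id' and 'text'", path))
  sents <- lapply(x$sentences, function(s) {
    sentence(
      id = s$id, start = s$start, end = s$end,
      tokens = lapply(s$tokens, function(tk) {
        token(tk$start, tk$end,
              number = if (is.null(tk$number)) "unknown" else tk$number,
              pronoun = isTRUE(tk$pronoun), definite = isTRUE(tk$definite),
              pos = tk$pos)
      }),
      noun_phrases = lapply(s$noun_phrases, function(np) {
        noun_phrase(np$start, np$end, np$head,
                    number = if (is.null(np$number)) "unknown" else np$number,
                    definite = isTRUE(np$definite))
      }),
      mentions = lapply(s$mentions, function(m) {
        entity_mention(m$start, m$end,
                       category = if (is.null(m$category)) "gene_or_protein"
                                  else m$category)
      }))
  })
  annotated_document(x$id, x$text, sents)
}

#' Read an annotated document from JSON
#'
#' The JSON dialect mirrors the in-memory model:
#' `{"id", "text", "sentences":[{"id","start","end","tokens":[...],
#' "noun_phrases":[...], "mentions":[...]}]}` with 0-based half-open offsets
#' and 1-based noun-phrase head token indices.
#'
#' @param path Path to a JSON file.
#' @return A validated `"annotated_document"`.
#' @export
read_document <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e)
                  stop(sprintf("%s: malformed JSON: %s", path,
                               conditionMessage(e)), call. = FALSE))
  .doc_from_list(x, path)
}

#' Write an annotated document to JSON
#'
#' Inverse of [read_document()]: `read_document(write_document(doc, f))`
#' reproduces `doc` exactly.
#'
#' @param doc An `"annotated_document"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_document <- function(doc, path) {
  validate_document(doc)
  jsonlite::write_json(.doc_to_list(doc), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Default configuration for the pattern-based noun-phrase chunker
#'
#' @param determiners Surface forms treated as determiners.
#' @param definite_determiners Subset marking a phrase as definite.
#' @param noun_pos,adj_pos,det_pos Coarse category labels recognised as
#'   nouns, adjectives and determiners.
#' @return A list of chunking patterns.
#' @export
np_patterns <- function(determiners = c("the", "a", "an", "this", "that",
                                        "these", "those"),
                        definite_determiners = c("the", "this", "that",
                                                 "these", "those"),
                        noun_pos = c("NOUN", "NN", "NNS", "NNP"),
                        adj_pos = c("ADJ", "JJ"),
                        det_pos = c("DET", "DT")) {
  list(determiners = determiners,
       definite_determiners = definite_determiners,
       noun_pos = noun_pos, adj_pos = adj_pos, det_pos = det_pos)
}

# Number-feature resolution order: explicit annotation > closed-class lexicon >
# terminal-"s" morphology on common nouns > unknown. "unknown" never blocks
# agreement downstream.
.resolve_number <- function(tok, text) {
  if (tok$number != "unknown") return(tok$number)
  surf <- tolower(span_text(text, tok$start, tok$end))
  if (surf %in% c("it", "its", "this")) return("singular")
  if (surf %in% c("they", "their", "these", "those")) return("plural")
  if (!tok$pronoun && nchar(surf) > 2 &&
      grepl("s$", surf) && !grepl("ss$", surf)) return("plural")
  "unknown"
}

#' Chunk noun phrases from token annotations
#'
#' Fallback for documents whose input lacks noun-phrase annotations: a
#' pattern chunker matching an optional determiner followed by
#' adjective/noun modifiers ending at a noun head, leftmost-longest.
#' Tokens must carry coarse `pos` labels.
#'
#' @param sent A [sentence()].
#' @param text The document text the sentence indexes into.
#' @param patterns A [np_patterns()] configuration.
#' @return A list of [noun_phrase()] objects (possibly empty).
#' @export
chunk_noun_phrases <- function(sent, text, patterns = np_patterns()) {
  toks <- sent$tokens
  if (length(toks) == 0) return(list())
  pos <- vapply(toks, function(tk) {
    if (is.null(tk$pos))
      stop(sprintf("sentence %s: chunking requires 'pos' labels on tokens",
                   sent$id))
    tk$pos
  }, character(1))
  surf <- vapply(toks, function(tk) tolower(span_text(text, tk$start, tk$end)),
                 character(1))
  is_det <- pos %in% patterns$det_pos | surf %in% patterns$determiners
  is_adj <- pos %in% patterns$adj_pos
  is_noun <- pos %in% patterns$noun_pos
  nps <- list()
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    if (!(is_det[i] || is_adj[i] || is_noun[i])) { i <- i + 1L; next }
    start_i <- i
    j <- i
    if (is_det[j]) j <- j + 1L
    last_noun <- NA_integer_
    while (j <= n && (is_adj[j] || is_noun[j])) {
      if (is_noun[j]) last_noun <- j
      j <- j + 1L
    }
    if (!is.na(last_noun)) {
      head_tok <- toks[[last_noun]]
      num <- .resolve_number(head_tok, text)
      nps[[length(nps) + 1L]] <- noun_phrase(
        start = toks[[start_i]]$start, end = toks[[last_noun]]$end,
        head = last_noun, number = num,
        definite = is_det[start_i] &&
          surf[start_i] %in% patterns$definite_determiners)
      i <- last_noun + 1L
    } else {
      i <- j
    }
  }
  nps
}
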