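# Rule-based anaphora resolution over annotated documents, and coreference
# substitution with an offset map from resolved text back to the original.
#
# Antecedent selection uses three rules:
#   Rule 1: drop candidates that disagree in grammatical number with the
#           anaphor ("unknown" is compatible with everything);
#   Rule 2: for definite-NP anaphors only, keep candidates that overlap a
#           gene/protein mention;
#   Rule 3: among survivors, the textually closest candidate wins.

#' Configuration for anaphor detection and antecedent ranking
#'
#' @param personal Personal pronoun surface forms.
#' @param possessive Possessive pronoun surface forms.
#' @param relative Relative pronoun surface forms. Detection of relative
#'   pronouns is off by default: resolving them degrades event extraction.
#' @param domain_nouns Head nouns that license a definite-NP anaphor
#'   ("the protein", "these genes", ...).
#' @param window Number of preceding sentences searched for candidates, in
#'   addition to the text preceding the anaphor in its own sentence.
#' @param kinds Anaphor kinds enabled for detection.
#' @param genitive Genitive marker policy for possessive substitution:
#'   `"auto"` appends `'s`, or a bare `'` when the antecedent already ends
#'   in `s`/`S`.
#' @return A list of class `"coref_config"`.
#' @export
coref_config <- function(personal = c("it", "they"),
                         possessive = c("its", "their"),
                         relative = c("which", "that", "who", "whose"),
                         domain_nouns = c("gene", "genes", "protein",
                                          "proteins", "receptor", "receptors",
                                          "molecule", "molecules"),
                         window = 2L,
                         kinds = c("personal_pronoun", "possessive_pronoun",
                                   "definite_np"),
                         genitive = "auto") {
  stopifnot(window >= 0)
  kinds <- match.arg(kinds, c("personal_pronoun", "possessive_pronoun",
                              "definite_np", "relative_pronoun"),
                     several.ok = TRUE)
  structure(list(personal = tolower(personal),
                 possessive = tolower(possessive),
                 relative = tolower(relative),
                 domain_nouns = tolower(domain_nouns),
                 window = as.integer(window), kinds = kinds,
                 genitive = genitive),
            class = "coref_config")
}

.anaphor <- function(sentence_index, start, end, text, kind, number) {
  structure(list(sentence_index = sentence_index, start = start, end = end,
                 text = text, kind = kind, number = number),
            class = "belminer_anaphor")
}

#' Detect anaphoric mentions in a document
#'
#' Pronoun tokens are matched case-insensitively against the configured
#' lexicons. A noun phrase is a definite-NP anaphor when it is definite and
#' its head token is a configured domain noun; such an NP must not itself be
#' a gene/protein mention span.
#'
#' @param doc An `"annotated_document"`.
#' @param config A [coref_config()].
#' @return A list of anaphor objects in document order, each with fields
#'   `sentence_index`, `start`, `end`, `text`, `kind` and `number`.
#' @export
detect_anaphors <- function(doc, config = coref_config()) {
  validate_document(doc)
  out <- list()
  for (si in seq_along(doc$sentences)) {
    s <- doc$sentences[[si]]
    for (tk in s$tokens) {
      surf <- tolower(span_text(doc$text, tk$start, tk$end))
      kind <- if (surf %in% config$personal) "personal_pronoun"
      else if (surf %in% config$possessive) "possessive_pronoun"
      else if (surf %in% config$relative) "relative_pronoun"
      else NA_character_
      if (is.na(kind) || !(kind %in% config$kinds)) next
      out[[length(out) + 1L]] <- .anaphor(
        si, tk$start, tk$end, span_text(doc$text, tk$start, tk$end),
        kind, .resolve_number(tk, doc$text))
    }
    if ("definite_np" %in% config$kinds) {
      for (np in s$noun_phrases) {
        if (!np$definite || np$head > length(s$tokens)) next
        ht <- s$tokens[[np$head]]
        head_surf <- tolower(span_text(doc$text, ht$start, ht$end))
        if (!(head_surf %in% config$domain_nouns)) next
        num <- if (np$number != "unknown") np$number
               else .resolve_number(ht, doc$text)
        out[[length(out) + 1L]] <- .anaphor(
          si, np$start, np$end, span_text(doc$text, np$start, np$end),
          "definite_np", num)
      }
    }
  }
  ord <- order(vapply(out, `[[`, integer(1), "start"))
  out[ord]
}

.np_number <- function(np, sent, text) {
  if (np$number != "unknown") return(np$number)
  if (np$head <= length(sent$tokens))
    return(.resolve_number(sent$tokens[[np$head]], text))
  "unknown"
}

.overlaps_mention <- function(np, doc) {
  for (s in doc$sentences) {
    for (m in s$mentions) {
      if (m$category == "gene_or_protein" &&
          np$start < m$end && m$start < np$end) return(TRUE)
    }
  }
  FALSE
}

#' Rank antecedent candidates for one anaphor
#'
#' Candidates are all noun phrases that end before the anaphor starts, in
#' the anaphor's sentence or up to `config$window` preceding sentences.
#' Rule 1 filters by number agreement, Rule 2 (definite-NP anaphors only)
#' requires overlap with a gene/protein mention, and survivors are ordered
#' by increasing character distance (Rule 3), ties broken by the longer
#' candidate.
#'
#' @param anaphor An anaphor as returned by [detect_anaphors()].
#' @param doc The document it came from.
#' @param config A [coref_config()].
#' @return A data frame with one row per candidate: `start`, `end`, `text`,
#'   `sentence`, `number`, `ner_overlap`, `eliminated_by` (`NA`, `"rule1"`
#'   or `"rule2"`), `distance` and `rank` (`NA` for eliminated candidates).
#' @export
rank_candidates <- function(anaphor, doc, config = coref_config()) {
  rows <- list()
  lo <- max(1L, anaphor$sentence_index - config$window)
  for (si in lo:anaphor$sentence_index) {
    s <- doc$sentences[[si]]
    for (np in s$noun_phrases) {
      if (np$end > anaphor$start) next   # must fully precede the anaphor
      rows[[length(rows) + 1L]] <- data.frame(
        start = np$start, end = np$end,
        text = span_text(doc$text, np$start, np$end),
        sentence = si, number = .np_number(np, s, doc$text),
        ner_overlap = .overlaps_mention(np, doc),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0), sentence = integer(0),
                      number = character(0), ner_overlap = logical(0),
                      eliminated_by = character(0), distance = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, rows)
  cand$eliminated_by <- NA_character_
  disagree <- anaphor$number != "unknown" & cand$number != "unknown" &
    cand$number != anaphor$number
  cand$eliminated_by[disagree] <- "rule1"
  if (anaphor$kind == "definite_np") {
    r2 <- is.na(cand$eliminated_by) & !cand$ner_overlap
    cand$eliminated_by[r2] <- "rule2"
  }
  cand$distance <- anaphor$start - cand$end
  keep <- is.na(cand$eliminated_by)
  cand$rank <- NA_integer_
  if (any(keep)) {
    ord <- order(cand$distance[keep], -(cand$end[keep] - cand$start[keep]))
    cand$rank[keep][ord] <- seq_len(sum(keep))
  }
  cand[order(cand$distance, -(cand$end - cand$start)), , drop = FALSE]
}

#' Resolve coreference links in a document
#'
#' Applies [detect_anaphors()] and [rank_candidates()]; for each anaphor
#' with at least one surviving candidate, the top-ranked candidate becomes
#' the antecedent. Anaphors whose candidate set is fully filtered yield no
#' link and are recorded in the `"unresolved"` attribute. The procedure is
#' deterministic.
#'
#' @param doc An `"annotated_document"`.
#' @param config A [coref_config()].
#' @return A list of `"coreference_link"` objects, each with `anaphor`,
#'   `antecedent` (`start`, `end`, `text`) and `rule_trace` (the candidate
#'   table). Unresolved anaphors are attached as attribute `"unresolved"`.
#' @export
resolve_coreference <- function(doc, config = coref_config()) {
  anas <- detect_anaphors(doc, config)
  links <- list()
  unresolved <- list()
  for (a in anas) {
    cand <- rank_candidates(a, doc, config)
    top <- which(!is.na(cand$rank) & cand$rank == 1L)
    if (length(top) == 0) {
      unresolved[[length(unresolved) + 1L]] <- a
      next
    }
    links[[length(links) + 1L]] <- structure(
      list(anaphor = a,
           antecedent = list(start = cand$start[top], end = cand$end[top],
                             text = cand$text[top]),
           rule_trace = cand),
      class = "coreference_link")
  }
  attr(links, "unresolved") <- unresolved
  links
}

.genitive_form <- function(text, policy = "auto") {
  if (grepl("[sS]$", text)) paste0(text, "'") else paste0(text, "'s")
}

#' Substitute anaphors with their antecedents
#'
#' Each anaphor span is replaced by the antecedent's surface text
#' (possessive pronouns additionally receive a genitive marker).
#' Substitutions are applied right-to-left so earlier offsets stay valid.
#' The returned offset map is a segment table from resolved-text offsets to
#' original-text offsets: identity (shifted) on copied regions, and anchored
#' to the anaphor's original span on substituted regions, with the
#' antecedent's source span carried alongside for span projection.
#'
#' @param doc An `"annotated_document"`.
#' @param links Coreference links from [resolve_coreference()]. No two links
#'   may share or overlap anaphor spans.
#' @param config A [coref_config()] (genitive policy).
#' @return An object of class `"substitution_result"` with fields
#'   `resolved_text`, `offset_map` (a data frame of segments) and
#'   `applied_links`.
#' @export
substitute_coreferences <- function(doc, links, config = coref_config()) {
  if (length(links) > 0) {
    starts <- vapply(links, function(l) l$anaphor$start, integer(1))
    ends <- vapply(links, function(l) l$anaphor$end, integer(1))
    ord <- order(starts)
    links <- links[ord]; starts <- starts[ord]; ends <- ends[ord]
    if (any(starts[-1] < ends[-length(ends)]))
      stop("overlapping anaphor spans in substitution links")
  }
  text <- doc$text
  pieces <- character(0)
  map <- list()
  orig_cursor <- 0L
  res_cursor <- 0L
  add_copy <- function(from, to) {
    if (to > from) {
      pieces[[length(pieces) + 1L]] <<- span_text(text, from, to)
      map[[length(map) + 1L]] <<- data.frame(
        res_start = res_cursor, res_end = res_cursor + (to - from),
        orig_start = from, orig_end = to, kind = "copy",
        src_start = NA_integer_, src_end = NA_integer_,
        stringsAsFactors = FALSE)
      res_cursor <<- res_cursor + (to - from)
    }
  }
  for (l in links) {
    a <- l$anaphor
    add_copy(orig_cursor, a$start)
    repl <- l$antecedent$text
    if (a$kind == "possessive_pronoun")
      repl <- .genitive_form(repl, config$genitive)
    pieces[[length(pieces) + 1L]] <- repl
    map[[length(map) + 1L]] <- data.frame(
      res_start = res_cursor, res_end = res_cursor + nchar(repl),
      orig_start = a$start, orig_end = a$end, kind = "subst",
      src_start = l$antecedent$start, src_end = l$antecedent$end,
      stringsAsFactors = FALSE)
    res_cursor <- res_cursor + nchar(repl)
    orig_cursor <- a$end
  }
  add_copy(orig_cursor, nchar(text))
  offset_map <- if (length(map)) do.call(rbind, map) else
    data.frame(res_start = integer(0), res_end = integer(0),
               orig_start = integer(0), orig_end = integer(0),
               kind = character(0), src_start = integer(0),
               src_end = integer(0), stringsAsFactors = FALSE)
  structure(list(resolved_text = paste(pieces, collapse = ""),
                 offset_map = offset_map, applied_links = links),
            class = "substitution_result")
}

#' Project a resolved-text span back onto the original text
#'
#' Spans inside copied regions are shifted back identically. Spans falling
#' entirely inside one substituted region map, by default, to the
#' antecedent's source span in the original text (`inside = "antecedent"`),
#' or to the anaphor's original span (`inside = "anaphor"`). Spans crossing
#' a substitution boundary are unmappable and return `NULL`.
#'
#' @param subres A `"substitution_result"`.
#' @param start,end 0-based half-open offsets into the resolved text.
#' @param inside Target for spans inside substituted regions.
#' @return `list(start, end)` in original-text offsets, or `NULL`.
#' @export
project_span <- function(subres, start, end, inside = "antecedent") {
  inside <- match.arg(inside, c("antecedent", "anaphor"))
  m <- subres$offset_map
  if (nrow(m) == 0) return(list(start = start, end = end))
  row <- which(m$res_start <= start & end <= m$res_end)
  if (length(row) == 0) return(NULL)
  row <- row[1]
  if (m$kind[row] == "copy") {
    shift <- m$orig_start[row] - m$res_start[row]
    return(list(start = start + shift, end = end + shift))
  }
  if (inside == "antecedent")
    list(start = m$src_start[row], end = m$src_end[row])
  else
    list(start = m$orig_start[row], end = m$orig_end[row])
}

#' @export
print.substitution_result <- function(x, ...) {
  cat(sprintf("<substitution_result: %d substitution(s)>\n",
              sum(x$offset_map$kind == "subst")))
  cat(x$resolved_text, "\n")
  invisible(x)
}
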