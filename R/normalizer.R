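# Dictionary-based entity normalization: exact string matching of mention
# surfaces against lexicon fields (symbol > synonyms > alternative names >
# description), over an ordered list of lexicons (first lexicon with a hit
# wins). Statements containing any unmappable mention are dropped whole.

.norm_surface <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Build a lexicon from a data frame
#'
#' @param entries Data frame with columns `namespace`, `identifier`,
#'   `symbol`, `synonyms`, `alt_names` (both `|`-separated) and
#'   `description`.
#' @param name Optional lexicon name used in normalization results.
#' @return An indexed object of class `"bel_lexicon"`.
#' @export
bel_lexicon <- function(entries, name = "lexicon") {
  need <- c("namespace", "identifier", "symbol", "synonyms", "alt_names",
            "description")
  if (!all(need %in% names(entries)))
    stop(sprintf("lexicon must have columns: %s", paste(need, collapse = ", ")))
  if (any(!nzchar(trimws(entries$symbol))))
    stop("lexicon entries must have a non-empty symbol")
  key <- paste(entries$namespace, entries$identifier)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (namespace, identifier) pair: %s",
                 key[duplicated(key)][1]))
  index <- new.env(parent = emptyenv())
  add <- function(surface, row, field_rank) {
    if (!nzchar(trimws(surface))) return(invisible())
    k <- .norm_surface(surface)
    hit <- data.frame(namespace = entries$namespace[row],
                      identifier = entries$identifier[row],
                      symbol = entries$symbol[row],
                      field = c("symbol", "synonyms", "alt_names",
                                "description")[field_rank],
                      field_rank = field_rank, surface = surface,
                      stringsAsFactors = FALSE)
    index[[k]] <- rbind(index[[k]], hit)
  }
  for (r in seq_len(nrow(entries))) {
    add(entries$symbol[r], r, 1L)
    for (syn in strsplit(entries$synonyms[r], "|", fixed = TRUE)[[1]])
      add(syn, r, 2L)
    for (an in strsplit(entries$alt_names[r], "|", fixed = TRUE)[[1]])
      add(an, r, 3L)
    add(entries$description[r], r, 4L)
  }
  structure(list(name = name, entries = entries, index = index),
            class = "bel_lexicon")
}

#' Load a lexicon from a TSV file
#'
#' Expected tab-separated columns: `namespace`, `identifier`, `symbol`,
#' `synonyms` (`|`-separated), `alt_names` (`|`-separated), `description`.
#'
#' @param path Path to the TSV file.
#' @param name Lexicon name; defaults to the file name.
#' @return A `"bel_lexicon"`.
#' @export
load_lexicon <- function(path, name = basename(path)) {
  entries <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = "character", quote = "",
                               fileEncoding = "UTF-8")
  bel_lexicon(entries, name = name)
}

#' Normalize one mention against an ordered lexicon list
#'
#' The first lexicon containing an exact match wins; within a lexicon,
#' field priority is symbol > synonyms > alternative names > description,
#' and remaining ties break by lexicographic identifier. Surfaces are
#' compared after trimming, whitespace collapsing and case folding; with
#' `strict = TRUE` the raw surface must also match byte-for-byte.
#'
#' @param mention Mention string.
#' @param lexicons A `"bel_lexicon"` or list of them, in priority order.
#' @param strict Require byte-identical surfaces.
#' @return A list with `mention`, `dropped`, and on success `namespace`,
#'   `identifier`, `symbol`, `field` and `lexicon`.
#' @export
normalize_mention <- function(mention, lexicons, strict = FALSE) {
  if (inherits(lexicons, "bel_lexicon")) lexicons <- list(lexicons)
  k <- .norm_surface(mention)
  for (lex in lexicons) {
    hits <- lex$index[[k]]
    if (is.null(hits)) next
    if (strict) {
      hits <- hits[hits$surface == trimws(mention), , drop = FALSE]
      if (nrow(hits) == 0) next
    }
    hits <- hits[order(hits$field_rank, hits$identifier), , drop = FALSE]
    return(list(mention = mention, dropped = FALSE,
                namespace = hits$namespace[1], identifier = hits$identifier[1],
                symbol = hits$symbol[1], field = hits$field[1],
                lexicon = lex$name))
  }
  list(mention = mention, dropped = TRUE)
}

#' Normalize all entities of a statement list
#'
#' Fills the namespace and identifier (the lexicon symbol, as the BEL track
#' prints gene symbols) of every raw entity term. A statement survives only
#' if every entity in it normalizes; otherwise it is dropped whole and
#' logged.
#'
#' @param statements List of `"bel_statement"`s (or bare `"bel_term"`s)
#'   carrying raw mention strings.
#' @param lexicons A `"bel_lexicon"` or priority-ordered list of them.
#' @param sentence_ids Optional character vector parallel to `statements`,
#'   used in the drop log.
#' @param strict Passed to [normalize_mention()].
#' @return A list with `kept` (normalized statements), `kept_index`
#'   (positions into the input), and `log` (data frame `sentence_id`,
#'   `mention`, `stage`).
#' @export
normalize_statements <- function(statements, lexicons, sentence_ids = NULL,
                                 strict = FALSE) {
  if (is.null(sentence_ids)) sentence_ids <- rep(NA_character_,
                                                 length(statements))
  stopifnot(length(sentence_ids) == length(statements))
  log <- list()
  fill_term <- function(tm, sid) {
    if (tm$fn == "complex") {
      for (i in seq_along(tm$members)) {
        m <- fill_term(tm$members[[i]], sid)
        if (is.null(m)) return(NULL)
        tm$members[[i]] <- m
      }
      return(tm)
    }
    if (!is.na(tm$ns)) return(tm)
    res <- normalize_mention(tm$id, lexicons, strict = strict)
    if (res$dropped) {
      log[[length(log) + 1L]] <<- data.frame(
        sentence_id = sid, mention = tm$id, stage = "normalization",
        stringsAsFactors = FALSE)
      return(NULL)
    }
    tm$ns <- res$namespace
    tm$id <- res$symbol
    tm
  }
  kept <- list(); kept_index <- integer(0)
  for (i in seq_along(statements)) {
    st <- statements[[i]]
    if (inherits(st, "bel_statement")) {
      subj <- fill_term(st$subject, sentence_ids[i])
      obj <- if (!is.null(subj)) fill_term(st$object, sentence_ids[i]) else NULL
      if (is.null(subj) || is.null(obj)) next
      st$subject <- subj; st$object <- obj
    } else {
      tm <- fill_term(st, sentence_ids[i])
      if (is.null(tm)) next
      st <- tm
    }
    kept[[length(kept) + 1L]] <- st
    kept_index <- c(kept_index, i)
  }
  list(kept = kept, kept_index = kept_index,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(sentence_id = character(0), mention = character(0),
                    stage = character(0), stringsAsFactors = FALSE))
}
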