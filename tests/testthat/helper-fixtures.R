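# Shared fixtures and independent oracles, built in code.

# -- generic word-list document builder (independent of the package's
#    internal synthetic-corpus builder) ---------------------------------------

# words: list of lists with fields text, pos, num, pron, def, men
# nps: list of lists with fields from, to, head (token indices), num, def
wd <- function(text, pos = "NOUN", num = "unknown", pron = FALSE,
               def = FALSE, men = FALSE) {
  list(text = text, pos = pos, num = num, pron = pron, def = def, men = men)
}

mk_doc <- function(id, sentence_specs) {
  cursor <- 0L
  sents <- list()
  texts <- character(0)
  for (k in seq_along(sentence_specs)) {
    sp <- sentence_specs[[k]]
    words <- sp$words
    s_start <- cursor
    toks <- list()
    starts <- integer(0); ends <- integer(0)
    for (i in seq_along(words)) {
      w <- words[[i]]
      st <- cursor; en <- cursor + nchar(w$text)
      toks[[i]] <- token(st, en, number = w$num, pronoun = w$pron,
                         definite = w$def, pos = w$pos)
      starts <- c(starts, st); ends <- c(ends, en)
      cursor <- en + 1L
    }
    s_end <- cursor - 1L
    nps <- lapply(sp$nps, function(np)
      noun_phrase(starts[np$from], ends[np$to], head = np$head,
                  number = if (is.null(np$num)) "unknown" else np$num,
                  definite = isTRUE(np$def)))
    mentions <- list()
    for (i in seq_along(words))
      if (isTRUE(words[[i]]$men))
        mentions[[length(mentions) + 1L]] <- entity_mention(starts[i], ends[i])
    sents[[k]] <- sentence(sp$id, s_start, s_end, tokens = toks,
                           noun_phrases = nps, mentions = mentions)
    texts <- c(texts, paste(vapply(words, `[[`, character(1), "text"),
                            collapse = " "))
  }
  annotated_document(id, paste(texts, collapse = " "), sents)
}

# nth occurrence of `what` in `text` as a 0-based half-open span
span_of <- function(text, what, n = 1) {
  hits <- gregexpr(what, text, fixed = TRUE)[[1]]
  stopifnot(hits[1] > 0, length(hits) >= n)
  list(start = hits[n] - 1L, end = hits[n] - 1L + nchar(what))
}

# -- worked mdm2/p53 example --------------------------------------------------

mdm2_doc <- function() {
  words <- list(
    wd("mdm2", men = TRUE, num = "singular"), wd("directly", pos = "ADV"),
    wd("binds", pos = "VERB"), wd("to", pos = "ADP"),
    wd("the", pos = "DET", def = TRUE), wd("amino-terminal", pos = "ADJ"),
    wd("region"), wd("of", pos = "ADP"),
    wd("p53", men = TRUE, num = "singular"), wd("and", pos = "CONJ"),
    wd("targets", pos = "VERB"), wd("it", pos = "PRON", pron = TRUE),
    wd("for", pos = "ADP"), wd("degradation"), wd("through", pos = "ADP"),
    wd("the", pos = "DET", def = TRUE),
    wd("ubiquitin-proteasome", pos = "ADJ"), wd("pathway"))
  nps <- list(list(from = 1, to = 1, head = 1, num = "singular"),
              list(from = 5, to = 7, head = 7, num = "singular", def = TRUE),
              list(from = 9, to = 9, head = 9, num = "singular"))
  mk_doc("DOC-MDM2", list(list(id = "SEN:000101", words = words, nps = nps)))
}

# standoff over the coreference-resolved mdm2/p53 text
mdm2_resolved_standoff <- function(resolved_text) {
  tb <- function(id, label, span, text)
    textbound(id, label, span$start, span$end, text)
  s_mdm2 <- span_of(resolved_text, "mdm2")
  s_p53 <- span_of(resolved_text, "p53", n = 2)  # the substituted copy
  s_deg <- span_of(resolved_text, "degradation")
  s_tgt <- span_of(resolved_text, "targets")
  standoff_annotation(
    resolved_text,
    list(tb("T1", "Protein", s_mdm2, "mdm2"),
         tb("T2", "Protein", s_p53, "p53"),
         tb("T3", "Protein_catabolism", s_deg, "degradation"),
         tb("T4", "Positive_regulation", s_tgt, "targets")),
    list(bionlp_event("E1", "Protein_catabolism", "T3",
                      data.frame(role = "Theme", target = "T2",
                                 stringsAsFactors = FALSE)),
         bionlp_event("E2", "Positive_regulation", "T4",
                      data.frame(role = c("Theme", "Cause"),
                                 target = c("E1", "T1"),
                                 stringsAsFactors = FALSE))))
}

# -- worked IL-13 / TIMP-1 two-sentence passage -------------------------------

il13_doc <- function() {
  s1 <- list(
    id = "SEN:000201",
    words = list(wd("Interestingly", pos = "ADV"), wd(",", pos = "PUNCT"),
                 wd("IL-13", men = TRUE, num = "singular"),
                 wd("caused", pos = "VERB"), wd("a", pos = "DET"),
                 wd("significant", pos = "ADJ"), wd("decrease"),
                 wd("in", pos = "ADP"), wd("expression"),
                 wd("for", pos = "ADP"), wd("all", pos = "DET"),
                 wd("comparisons", num = "plural"), wd(".", pos = "PUNCT")),
    nps = list(list(from = 3, to = 3, head = 3, num = "singular"),
               list(from = 11, to = 12, head = 12, num = "plural")))
  s2 <- list(
    id = "SEN:000202",
    words = list(wd("It", pos = "PRON", pron = TRUE, num = "singular"),
                 wd("also", pos = "ADV"), wd("caused", pos = "VERB"),
                 wd("a", pos = "DET"), wd("significant", pos = "ADJ"),
                 wd("increase"), wd("in", pos = "ADP"),
                 wd("TIMP-1", men = TRUE, num = "singular"),
                 wd("expression"), wd(".", pos = "PUNCT")),
    nps = list())
  mk_doc("DOC-IL13", list(s1, s2))
}

il13_resolved_standoff <- function(resolved_text) {
  tb <- function(id, label, span, text)
    textbound(id, label, span$start, span$end, text)
  s_il13 <- span_of(resolved_text, "IL-13", n = 2)  # substituted copy in S2
  s_timp <- span_of(resolved_text, "TIMP-1")
  s_expr <- span_of(resolved_text, "expression", n = 2)
  s_caus <- span_of(resolved_text, "caused", n = 2)
  standoff_annotation(
    resolved_text,
    list(tb("T1", "Protein", s_il13, "IL-13"),
         tb("T2", "Protein", s_timp, "TIMP-1"),
         tb("T3", "Gene_expression", s_expr, "expression"),
         tb("T4", "Positive_regulation", s_caus, "caused")),
    list(bionlp_event("E1", "Gene_expression", "T3",
                      data.frame(role = "Theme", target = "T2",
                                 stringsAsFactors = FALSE)),
         bionlp_event("E2", "Positive_regulation", "T4",
                      data.frame(role = c("Theme", "Cause"),
                                 target = c("E1", "T1"),
                                 stringsAsFactors = FALSE))))
}

il13_original_standoff <- function(original_text) {
  tb <- function(id, label, span, text)
    textbound(id, label, span$start, span$end, text)
  s_timp <- span_of(original_text, "TIMP-1")
  s_expr <- span_of(original_text, "expression", n = 2)
  s_caus <- span_of(original_text, "caused", n = 2)
  standoff_annotation(
    original_text,
    list(tb("T1", "Protein", s_timp, "TIMP-1"),
         tb("T2", "Gene_expression", s_expr, "expression"),
         tb("T3", "Positive_regulation", s_caus, "caused")),
    list(bionlp_event("E1", "Gene_expression", "T2",
                      data.frame(role = "Theme", target = "T1",
                                 stringsAsFactors = FALSE)),
         bionlp_event("E2", "Positive_regulation", "T3",
                      data.frame(role = "Theme", target = "E1",
                                 stringsAsFactors = FALSE))))
}

# -- shared mini lexicon ------------------------------------------------------

mini_lexicon <- function() {
  bel_lexicon(data.frame(
    namespace = c("MGI", "MGI", "HGNC", "MGI", "HGNC", "HGNC"),
    identifier = c("Mdm2", "Trp53", "IL4", "C3ar1", "IL13", "TIMP1"),
    symbol = c("Mdm2", "Trp53", "IL4", "C3ar1", "IL13", "TIMP1"),
    synonyms = c("mdm2", "p53", "IL-4", "C3a", "IL-13", "TIMP-1"),
    alt_names = c("transformed mouse 3T3 cell double minute 2",
                  "tumor protein p53", "interleukin 4",
                  "complement component 3a receptor 1", "interleukin 13",
                  "TIMP metallopeptidase inhibitor 1"),
    description = c("E3 ubiquitin ligase", "tumor suppressor",
                    "cytokine", "receptor", "cytokine",
                    "protease inhibitor"),
    stringsAsFactors = FALSE), name = "mini")
}

# -- independent oracles ------------------------------------------------------

# brute-force application of the three antecedent rules, written as plain
# loops independent of rank_candidates()/resolve_coreference()
oracle_antecedent <- function(doc, ana, window = 2,
                              kind = ana$kind, number = ana$number) {
  best <- NULL
  for (si in seq_along(doc$sentences)) {
    if (si < ana$sentence_index - window || si > ana$sentence_index) next
    s <- doc$sentences[[si]]
    for (np in s$noun_phrases) {
      if (np$end > ana$start) next
      np_num <- np$number
      if (np_num == "unknown" && np$head <= length(s$tokens)) {
        ht <- s$tokens[[np$head]]
        surf <- tolower(substring(doc$text, ht$start + 1, ht$end))
        if (surf %in% c("it", "its", "this")) np_num <- "singular"
        else if (surf %in% c("they", "their", "these", "those"))
          np_num <- "plural"
        else if (!ht$pronoun && nchar(surf) > 2 && grepl("s$", surf) &&
                 !grepl("ss$", surf)) np_num <- "plural"
      }
      if (number != "unknown" && np_num != "unknown" && np_num != number)
        next  # rule 1
      if (kind == "definite_np") {
        has_ner <- FALSE
        for (s2 in doc$sentences) for (m in s2$mentions)
          if (np$start < m$end && m$start < np$end) has_ner <- TRUE
        if (!has_ner) next  # rule 2
      }
      d <- ana$start - np$end
      len <- np$end - np$start
      if (is.null(best) || d < best$d || (d == best$d && len > best$len))
        best <- list(start = np$start, end = np$end, d = d, len = len)
    }
  }
  best
}

# exhaustive maximum one-to-one matching over a logical match matrix
oracle_max_match <- function(M) {
  if (length(M) == 0 || nrow(M) == 0 || ncol(M) == 0) return(0L)
  rec <- function(i, used) {
    if (i > nrow(M)) return(0L)
    best <- rec(i + 1L, used)  # leave row i unmatched
    for (j in seq_len(ncol(M))) {
      if (!used[j] && M[i, j]) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, ncol(M)))
}
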