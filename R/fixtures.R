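# Deterministic synthetic corpus generator. Each unit plants one biological
# relation realized by a template sentence frame (degradation, expression,
# phosphorylation, binding, localization, inhibition, activation). A unit is
# either within-sentence (both entities mentioned locally) or cross-sentence:
# the causing entity appears only in a preceding sentence and the frame
# sentence reaches it through a planted anaphor (personal pronoun,
# possessive pronoun or definite NP) engineered so that exactly one
# candidate survives the resolution rules. Event standoffs are emitted for
# both extraction conditions: over the original text (what an extractor
# sees without coreference substitution: cross-sentence causes are absent)
# and over the resolved text (cross-sentence causes present).

.frames <- c("degradation", "expression", "phosphorylation", "binding",
             "localization", "inhibition", "activation")

#' Specification of a synthetic corpus
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_sentences Total number of sentences to generate.
#' @param anaphor_mix Named proportions over `personal_pronoun`,
#'   `possessive_pronoun`, `definite_np` (must sum to 1). Defaults follow
#'   the anaphor-type composition of the BEL-track training data
#'   (257:411:507, relative pronouns excluded).
#' @param event_mix Named proportions over the template frames.
#' @param cross_sentence_rate Fraction of units whose causing entity is
#'   reachable only through a planted anaphor.
#' @param n_genes Size of the synthetic gene-symbol pool (split between a
#'   human-style HGNC block and a mouse-style MGI block).
#' @param synonym_rate Fraction of mentions realized with the hyphenated
#'   synonym surface instead of the symbol.
#' @return A list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, n_sentences = 60L,
                         anaphor_mix = c(personal_pronoun = 257 / 1175,
                                         possessive_pronoun = 411 / 1175,
                                         definite_np = 507 / 1175),
                         event_mix = c(degradation = 0.2, expression = 0.2,
                                       phosphorylation = 0.15, binding = 0.1,
                                       localization = 0.1, inhibition = 0.15,
                                       activation = 0.1),
                         cross_sentence_rate = 0.5,
                         n_genes = 16L, synonym_rate = 0.2) {
  stopifnot(abs(sum(anaphor_mix) - 1) < 1e-8, abs(sum(event_mix) - 1) < 1e-8,
            cross_sentence_rate >= 0, cross_sentence_rate <= 1,
            all(names(event_mix) %in% .frames), n_genes >= 4)
  structure(list(seed = as.integer(seed), n_sentences = as.integer(n_sentences),
                 anaphor_mix = anaphor_mix, event_mix = event_mix,
                 cross_sentence_rate = cross_sentence_rate,
                 n_genes = as.integer(n_genes), synonym_rate = synonym_rate),
            class = "fixture_spec")
}

# word spec helper
.W <- function(text, pos = "NOUN", num = "unknown", pron = FALSE,
               def = FALSE, men = FALSE, men_len = NA_integer_,
               role = NA_character_) {
  list(text = text, pos = pos, num = num, pron = pron, def = def,
       men = men, men_len = men_len, role = role)
}

.gene_pool <- function(n) {
  n_h <- ceiling(n / 2); n_m <- n - n_h
  h <- sprintf("HSG%d", seq_len(n_h))
  m <- sprintf("Msg%d", seq_len(n_m))
  data.frame(
    namespace = c(rep("HGNC", n_h), rep("MGI", n_m)),
    identifier = c(h, m), symbol = c(h, m),
    synonyms = c(sprintf("HSG-%d", seq_len(n_h)),
                 sprintf("Msg-%d", seq_len(n_m))),
    alt_names = paste("synthetic gene", c(h, m)),
    description = paste("synthetic fixture gene", c(h, m), "for testing"),
    stringsAsFactors = FALSE)
}

# realize the frame sentence; subj_words is a list of word specs standing in
# for the causing entity (the entity itself, or an anaphoric stand-in)
.frame_words <- function(frame, subj_words, Yw, Zw = NULL) {
  V <- function(t, role = NA) .W(t, pos = "VERB", role = role)
  P <- function(t) .W(t, pos = "ADP")
  N <- function(t, role = NA) .W(t, pos = "NOUN", role = role)
  yw <- .W(Yw, num = "singular", men = TRUE, role = "Y")
  end <- list(.W(".", pos = "PUNCT"))
  body <- switch(frame,
    degradation = list(V("targets", "REG"), yw, P("for"),
                       N("degradation", "SIMPLE")),
    expression = list(V("induces", "REG"), yw, N("expression", "SIMPLE")),
    phosphorylation = list(V("promotes", "REG"),
                           N("phosphorylation", "SIMPLE"), P("of"), yw),
    binding = list(V("enhances", "REG"), N("binding", "SIMPLE"), P("of"), yw,
                   .W("and", pos = "CONJ"),
                   .W(Zw, num = "singular", men = TRUE, role = "Z")),
    localization = list(V("induces", "REG"), N("translocation", "SIMPLE"),
                        P("of"), yw),
    inhibition = list(V("inhibits", "REG"), yw),
    activation = list(V("causes"), N("activation", "REG"), P("of"), yw))
  c(subj_words, body, end)
}

# antecedent-introducing sentence: the gene plus a plural non-NER distractor
# NP, so the planted link survives Rule 1 (number) and Rule 2 (NER) uniquely
.intro_words <- function(Xw) {
  list(.W(Xw, num = "singular", men = TRUE, role = "X"),
       .W("was", pos = "VERB"), .W("studied", pos = "VERB"),
       .W("in", pos = "ADP"),
       .W("these", pos = "DET", def = TRUE, role = "DIST_FROM"),
       .W("cells", pos = "NOUN", num = "plural", role = "DIST_HEAD"),
       .W(".", pos = "PUNCT"))
}

.subject_stand_in <- function(kind, Xw) {
  switch(kind,
    entity = list(.W(Xw, num = "singular", men = TRUE, role = "X")),
    personal_pronoun = list(.W("It", pos = "PRON", num = "singular",
                               pron = TRUE, role = "ANA")),
    possessive_pronoun = list(.W("Its", pos = "PRON", num = "singular",
                                 pron = TRUE, role = "ANA"),
                              .W("overexpression", pos = "NOUN")),
    definite_np = list(.W("The", pos = "DET", def = TRUE, role = "ANA_FROM"),
                       .W("protein", pos = "NOUN", num = "singular",
                          role = "ANA_HEAD")))
}

# build one document from a list of sentence word lists; returns the
# annotated document plus per-sentence token offset tables
.build_doc <- function(doc_id, sent_ids, sent_word_lists) {
  cursor <- 0L
  sents <- list(); tok_tables <- list()
  texts <- character(0)
  for (k in seq_along(sent_word_lists)) {
    words <- sent_word_lists[[k]]
    s_start <- cursor
    toks <- list(); rows <- list()
    for (i in seq_along(words)) {
      w <- words[[i]]
      start <- cursor; end <- cursor + nchar(w$text)
      toks[[i]] <- token(start, end, number = w$num, pronoun = w$pron,
                         definite = w$def, pos = w$pos)
      rows[[i]] <- data.frame(i = i, start = start, end = end,
                              text = w$text, role = w$role,
                              men = w$men, men_len = w$men_len,
                              num = w$num, stringsAsFactors = FALSE)
      cursor <- end + 1L  # single space between tokens
    }
    s_end <- cursor - 1L
    tab <- do.call(rbind, rows)
    nps <- list(); mentions <- list()
    for (i in seq_along(words)) {
      w <- words[[i]]
      if (isTRUE(w$men)) {
        m_end <- if (!is.na(w$men_len)) tab$start[i] + w$men_len else tab$end[i]
        mentions[[length(mentions) + 1L]] <- entity_mention(tab$start[i], m_end)
        nps[[length(nps) + 1L]] <- noun_phrase(tab$start[i], tab$end[i],
                                               head = i, number = w$num)
      }
      if (identical(w$role, "ANA")) {
        # pronoun anaphors need no NP; tokens suffice
      }
    }
    # grouped NPs: distractor "these cells" and definite-NP anaphor spans
    grp <- function(from_role, head_role, def, num) {
      fi <- which(tab$role == from_role); hi <- which(tab$role == head_role)
      if (length(fi) && length(hi))
        nps[[length(nps) + 1L]] <<- noun_phrase(tab$start[fi], tab$end[hi],
                                                head = hi, number = num,
                                                definite = def)
    }
    grp("DIST_FROM", "DIST_HEAD", def = TRUE, num = "plural")
    grp("ANA_FROM", "ANA_HEAD", def = TRUE, num = "singular")
    texts <- c(texts, paste(vapply(words, `[[`, character(1), "text"),
                            collapse = " "))
    sents[[k]] <- sentence(sent_ids[k], s_start, s_end, tokens = toks,
                           noun_phrases = nps, mentions = mentions)
    tok_tables[[k]] <- tab
  }
  doc <- annotated_document(doc_id, paste(texts, collapse = " "), sents)
  list(doc = doc, tok = tok_tables)
}

# standoff events for one unit over a built document
.build_events <- function(frame, built, with_cause) {
  tab <- do.call(rbind, built$tok)
  find <- function(role)
    tab[!is.na(tab$role) & tab$role == role, , drop = FALSE]
  tbs <- list(); tid <- 0L
  add_tb <- function(row, label, men_len = NA) {
    tid <<- tid + 1L
    end <- if (!is.na(men_len)) row$start + men_len else row$end
    tbs[[length(tbs) + 1L]] <<- textbound(
      sprintf("T%d", tid), label, row$start, end,
      span_text(built$doc$text, row$start, end))
    sprintf("T%d", tid)
  }
  x <- find("X"); y <- find("Y"); z <- find("Z")
  reg <- find("REG"); simple <- find("SIMPLE")
  # when the subject occurs twice (antecedent + substituted copy), the
  # extractor's Cause is the local occurrence in the frame sentence
  x_id <- if (with_cause && nrow(x))
    add_tb(x[nrow(x), ], "Protein", x$men_len[nrow(x)])
  else NULL
  y_id <- add_tb(y[1, ], "Protein")
  z_id <- if (nrow(z)) add_tb(z[1, ], "Protein") else NULL
  evs <- list(); eid <- 0L
  add_ev <- function(type, trig_id, roles, targets) {
    eid <<- eid + 1L
    evs[[length(evs) + 1L]] <<- bionlp_event(
      sprintf("E%d", eid), type, trig_id,
      data.frame(role = roles, target = targets, stringsAsFactors = FALSE))
    sprintf("E%d", eid)
  }
  simple_type <- switch(frame, degradation = "Protein_catabolism",
                        expression = "Gene_expression",
                        phosphorylation = "Phosphorylation",
                        binding = "Binding", localization = "Localization",
                        NULL)
  reg_type <- if (frame == "inhibition") "Negative_regulation"
              else "Positive_regulation"
  if (!is.null(simple_type)) {
    st_id <- add_tb(simple[1, ], simple_type)
    inner_targets <- if (frame == "binding") c(y_id, z_id) else y_id
    inner <- add_ev(simple_type, st_id, rep("Theme", length(inner_targets)),
                    inner_targets)
    theme_target <- inner
  } else {
    theme_target <- y_id
  }
  rt_id <- add_tb(reg[1, ], reg_type)
  roles <- "Theme"; targets <- theme_target
  if (!is.null(x_id)) { roles <- c(roles, "Cause"); targets <- c(targets, x_id) }
  add_ev(reg_type, rt_id, roles, targets)
  standoff_annotation(built$doc$text, tbs, evs)
}

.gold_statement <- function(frame, gx, gy, gz, conversion) {
  p_of <- function(g) bel_term("p", ns = g$namespace, id = g$symbol)
  subj <- p_of(gx)
  obj <- switch(frame,
    degradation = { t <- p_of(gy); t$wrapper <- "deg"; t },
    expression = bel_term("r", ns = gy$namespace, id = gy$symbol),
    phosphorylation = bel_term("p", ns = gy$namespace, id = gy$symbol,
                               pmod = "P"),
    binding = bel_term("complex", members = list(p_of(gy), p_of(gz))),
    localization = { t <- p_of(gy); t$wrapper <- "tloc"; t },
    inhibition = p_of(gy),
    activation = {
      t <- p_of(gy)
      if (conversion$enable_act) t$wrapper <- "act"
      t
    })
  rel <- if (frame == "inhibition") "decreases" else "increases"
  serialize_bel(bel_statement(subj, rel, obj))
}

#' Generate a synthetic corpus with planted coreference links
#'
#' Output is fully determined by `spec$seed` (the caller's RNG state is
#' restored on exit). Gold BEL statements are written from the frame
#' templates themselves, independently of the conversion code, so that
#' recovering them through resolve/substitute/convert/normalize is a real
#' closure property of the pipeline.
#'
#' @param spec A [fixture_spec()].
#' @param conversion The [conversion_config()] the gold statements assume
#'   (relevant for the `act()` extension).
#' @return An object of class `"synthetic_corpus"`: `docs` (named list of
#'   annotated documents), `events` (per doc: `original` and `resolved`
#'   standoff annotations), `resolved_texts`, `links` (planted anaphor and
#'   antecedent spans per doc), `gold` (data frame `sentence_id`,
#'   `statement`, `doc_id`, `cross`), `lexicon` (lexicon data frame),
#'   `units` (per-unit metadata) and `spec`.
#' @export
generate_corpus <- function(spec = fixture_spec(),
                            conversion = conversion_config()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  pool <- .gene_pool(spec$n_genes)
  lex <- bel_lexicon(pool, name = "synthetic")
  surface_of <- function(g) {
    if (stats::runif(1) < spec$synonym_rate) g$synonyms else g$symbol
  }
  docs <- list(); events <- list(); links <- list()
  resolved_texts <- character(0)
  gold <- list(); units <- list()
  sent_counter <- 0L; doc_counter <- 0L
  next_sid <- function() {
    sent_counter <<- sent_counter + 1L
    sprintf("SEN:%06d", sent_counter)
  }
  used <- 0L
  while (used < spec$n_sentences) {
    frame <- sample(names(spec$event_mix), 1, prob = spec$event_mix)
    cross <- stats::runif(1) < spec$cross_sentence_rate &&
      used + 2L <= spec$n_sentences
    n_needed <- if (frame == "binding") 3L else 2L
    gs <- pool[sample(nrow(pool), n_needed), , drop = FALSE]
    gx <- gs[1, ]; gy <- gs[2, ]; gz <- if (n_needed == 3) gs[3, ] else NULL
    xs <- surface_of(gx); ys <- surface_of(gy)
    zs <- if (!is.null(gz)) surface_of(gz) else NULL
    doc_counter <- doc_counter + 1L
    doc_id <- sprintf("D%04d", doc_counter)
    if (!cross) {
      sid <- next_sid()
      wl <- list(.frame_words(frame, .subject_stand_in("entity", xs), ys, zs))
      built <- .build_doc(doc_id, sid, wl)
      sa <- .build_events(frame, built, with_cause = TRUE)
      docs[[doc_id]] <- built$doc
      events[[doc_id]] <- list(original = sa, resolved = sa)
      resolved_texts[doc_id] <- built$doc$text
      links[[doc_id]] <- list()
      kind <- NA_character_
      used <- used + 1L
    } else {
      kind <- sample(names(spec$anaphor_mix), 1, prob = spec$anaphor_mix)
      sid1 <- next_sid(); sid <- next_sid()
      wl_orig <- list(.intro_words(xs),
                      .frame_words(frame, .subject_stand_in(kind, xs), ys, zs))
      built_orig <- .build_doc(doc_id, c(sid1, sid), wl_orig)
      # resolved variant: the anaphor stand-in becomes the antecedent surface
      subst_surface <- if (kind == "possessive_pronoun")
        .genitive_form(xs) else xs
      resolved_subj <- list(.W(subst_surface, num = "singular", men = TRUE,
                               men_len = if (kind == "possessive_pronoun")
                                 nchar(xs) else NA_integer_,
                               role = "X"))
      if (kind == "possessive_pronoun")
        resolved_subj <- c(resolved_subj,
                           list(.W("overexpression", pos = "NOUN")))
      wl_res <- list(.intro_words(xs),
                     .frame_words(frame, resolved_subj, ys, zs))
      built_res <- .build_doc(doc_id, c(sid1, sid), wl_res)
      sa_res <- .build_events(frame, built_res, with_cause = TRUE)
      sa_orig <- .build_events(frame, built_orig, with_cause = FALSE)
      docs[[doc_id]] <- built_orig$doc
      events[[doc_id]] <- list(original = sa_orig, resolved = sa_res)
      resolved_texts[doc_id] <- built_res$doc$text
      tab <- do.call(rbind, built_orig$tok)
      ana_rows <- tab[!is.na(tab$role) &
                        tab$role %in% c("ANA", "ANA_FROM", "ANA_HEAD"), ,
                      drop = FALSE]
      x_row <- tab[!is.na(tab$role) & tab$role == "X", , drop = FALSE]
      links[[doc_id]] <- list(list(
        kind = kind,
        anaphor = list(start = min(ana_rows$start), end = max(ana_rows$end)),
        antecedent = list(start = x_row$start[1], end = x_row$end[1],
                          text = x_row$text[1])))
      used <- used + 2L
    }
    gold[[length(gold) + 1L]] <- data.frame(
      sentence_id = sid,
      statement = .gold_statement(frame, gx, gy, gz, conversion),
      doc_id = doc_id, cross = cross, stringsAsFactors = FALSE)
    units[[length(units) + 1L]] <- data.frame(
      doc_id = doc_id, frame = frame, cross = cross,
      anaphor_kind = kind, sentence_id = sid, stringsAsFactors = FALSE)
  }
  structure(list(spec = spec, docs = docs, events = events,
                 resolved_texts = resolved_texts, links = links,
                 gold = do.call(rbind, gold), lexicon = pool,
                 lexicon_index = lex, units = do.call(rbind, units)),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_corpus: %d document(s), %d gold ",
                     "statement(s), %d cross-sentence unit(s), seed %d>\n"),
              length(x$docs), nrow(x$gold), sum(x$units$cross), x$spec$seed))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Emits document JSON files, standoff triples for both extraction
#' conditions, the lexicon TSV, the gold BEL TSV and the planted links.
#'
#' @param corpus A `"synthetic_corpus"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  for (d in file.path(dir, c("docs", "events/original", "events/resolved")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (id in names(corpus$docs)) {
    write_document(corpus$docs[[id]], file.path(dir, "docs",
                                                paste0(id, ".json")))
    for (arm in c("original", "resolved")) {
      base <- file.path(dir, "events", arm, id)
      write_standoff(corpus$events[[id]][[arm]], paste0(base, ".txt"),
                     paste0(base, ".a1"), paste0(base, ".a2"))
    }
  }
  utils::write.table(corpus$lexicon, file.path(dir, "lexicon.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bel_tsv(corpus$gold[, c("sentence_id", "statement")],
                file.path(dir, "gold.tsv"))
  jsonlite::write_json(corpus$links, file.path(dir, "links.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Generate random BEL statements for grammar round-trip checks
#'
#' @param n Number of statements.
#' @param seed Integer seed (caller RNG state restored).
#' @return A list of `"bel_statement"` objects spanning the grammar:
#'   all abundance functions and namespaces, whitespace-bearing quoted
#'   identifiers, `pmod` codes, activity wrappers and `complex` members.
#' @export
random_bel_statements <- function(n = 100, seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  ids <- c("Mapk14", "Trp53", "IL4", "Stk16", "Cav1", "Itga8",
           "cell proliferation", "nitric oxide", "hyaluronic acid",
           "Hyperoxia", "GVX1", "response to stress")
  rand_simple <- function() {
    fn <- sample(c("p", "g", "r", "m", "bp", "path", "a"), 1)
    tm <- bel_term(fn, ns = sample(c("HGNC", "MGI", "EGID", "GOBP",
                                     "MESHD", "CHEBI"), 1),
                   id = sample(ids, 1),
                   pmod = if (fn == "p" && stats::runif(1) < 0.3)
                     sample(c("P", "S", "T"), 1) else NA_character_)
    if (stats::runif(1) < 0.35)
      tm$wrapper <- sample(c("deg", "tloc", "act", "kin", "tscript", "cat"), 1)
    tm
  }
  rand_term <- function() {
    if (stats::runif(1) < 0.2) {
      k <- sample(2:3, 1)
      members <- lapply(seq_len(k), function(i) {
        m <- rand_simple(); m$wrapper <- NA_character_; m
      })
      tm <- bel_term("complex", members = members)
      if (stats::runif(1) < 0.3) tm$wrapper <- "act"
      tm
    } else rand_simple()
  }
  lapply(seq_len(n), function(i)
    bel_statement(rand_term(), sample(c("increases", "decreases"), 1),
                  rand_term()))
}
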