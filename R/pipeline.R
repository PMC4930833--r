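# End-to-end orchestration: resolve -> substitute -> (externally extracted
# or fixture) events -> project -> convert -> normalize -> score. The
# pipeline never runs an event extractor itself; standoff events are an
# input artifact, supplied over the text matching the chosen condition
# (resolved text when coreference is on, original text otherwise).

#' Run the BEL extraction pipeline over annotated documents
#'
#' @param docs Named list of `"annotated_document"`s (names are doc ids).
#' @param events Named list (same names) of `"standoff_annotation"`s. With
#'   `coref = TRUE` these must annotate the coreference-resolved text that
#'   [substitute_coreferences()] produces for each document; otherwise the
#'   original text.
#' @param lexicons A `"bel_lexicon"` or priority-ordered list of them.
#' @param coref Enable coreference resolution and substitution.
#' @param coref_cfg A [coref_config()].
#' @param conversion A [conversion_config()].
#' @param gold Optional gold standard: a data frame with `sentence_id` and
#'   `statement` columns, or a named list of parsed statement lists.
#' @param tol A [tolerance_config()] used when `gold` is given.
#' @return A list of class `"pipeline_result"`: `predictions` (data frame
#'   `sentence_id`, `statement`, `confidence`, `doc_id`,
#'   `uses_substitution`), `statements` (parsed, grouped by sentence id),
#'   `report` (a `"bel_eval_report"` or `NULL`), and `manifest` (stage
#'   counts, per-stage timings, config snapshot).
#' @export
run_pipeline <- function(docs, events, lexicons, coref = TRUE,
                         coref_cfg = coref_config(),
                         conversion = conversion_config(),
                         gold = NULL, tol = tolerance_config()) {
  if (length(docs) > 0)
    stopifnot(!is.null(names(docs)), all(names(docs) %in% names(events)))
  counts <- c(anaphors = 0L, links = 0L, events = 0L, converted = 0L,
              emitted = 0L, dropped = 0L)
  timings <- c(coref = 0, convert = 0, normalize = 0, score = 0)
  pred_rows <- list()
  pred_map <- list()
  for (id in names(docs)) {
    doc <- docs[[id]]
    sa <- events[[id]]
    if (is.null(sa)) stop(sprintf("stage events: no standoff for doc %s", id))
    t0 <- proc.time()[["elapsed"]]
    if (coref) {
      links <- resolve_coreference(doc, coref_cfg)
      counts["anaphors"] <- counts["anaphors"] + length(links) +
        length(attr(links, "unresolved"))
      counts["links"] <- counts["links"] + length(links)
      subres <- substitute_coreferences(doc, links, coref_cfg)
      if (!identical(sa$text, subres$resolved_text))
        stop(sprintf(paste0("stage substitute: standoff text for doc %s does",
                            " not match the resolved text"), id))
    } else {
      subres <- substitute_coreferences(doc, list(), coref_cfg)
      if (!identical(sa$text, doc$text))
        stop(sprintf(paste0("stage events: standoff text for doc %s does not",
                            " match the document text"), id))
    }
    timings["coref"] <- timings["coref"] + proc.time()[["elapsed"]] - t0
    t0 <- proc.time()[["elapsed"]]
    counts["events"] <- counts["events"] + length(sa$events)
    conv <- convert_events(sa, conversion)
    counts["converted"] <- counts["converted"] + length(conv$statements)
    # attribute each statement to the original-text sentence of its trigger
    sids <- vapply(conv$provenance, function(pv) {
      pr <- project_span(subres, pv$trigger$start, pv$trigger$end,
                         inside = "anaphor")
      if (is.null(pr)) return(NA_character_)
      for (s in doc$sentences)
        if (s$start <= pr$start && pr$start < s$end) return(s$id)
      NA_character_
    }, character(1))
    uses_subst <- vapply(conv$provenance, function(pv) {
      spans <- sa$textbounds[pv$entity_ids]
      m <- subres$offset_map
      sub_rows <- m[m$kind == "subst", , drop = FALSE]
      any(vapply(spans, function(tb)
        any(tb$start < sub_rows$res_end & sub_rows$res_start < tb$end),
        logical(1)))
    }, logical(1))
    timings["convert"] <- timings["convert"] + proc.time()[["elapsed"]] - t0
    t0 <- proc.time()[["elapsed"]]
    norm <- normalize_statements(conv$statements, lexicons,
                                 sentence_ids = sids)
    timings["normalize"] <- timings["normalize"] + proc.time()[["elapsed"]] - t0
    counts["emitted"] <- counts["emitted"] + length(norm$kept)
    counts["dropped"] <- counts["dropped"] +
      length(conv$statements) - length(norm$kept)
    for (j in seq_along(norm$kept)) {
      i <- norm$kept_index[j]
      st <- norm$kept[[j]]
      pred_rows[[length(pred_rows) + 1L]] <- data.frame(
        sentence_id = sids[i], statement = serialize_bel(st),
        confidence = st$confidence, doc_id = id,
        uses_substitution = uses_subst[i], stringsAsFactors = FALSE)
      if (!is.na(sids[i]))
        pred_map[[sids[i]]] <- c(pred_map[[sids[i]]], list(st))
    }
  }
  predictions <- if (length(pred_rows)) do.call(rbind, pred_rows) else
    data.frame(sentence_id = character(0), statement = character(0),
               confidence = numeric(0), doc_id = character(0),
               uses_substitution = logical(0), stringsAsFactors = FALSE)
  report <- NULL
  if (!is.null(gold)) {
    t0 <- proc.time()[["elapsed"]]
    gold_map <- if (is.data.frame(gold)) {
      gm <- list()
      for (r in seq_len(nrow(gold)))
        gm[[gold$sentence_id[r]]] <- c(gm[[gold$sentence_id[r]]],
                                       list(parse_bel(gold$statement[r])))
      gm
    } else gold
    report <- score_corpus(gold_map, pred_map, tol)
    timings["score"] <- proc.time()[["elapsed"]] - t0
  }
  manifest <- structure(list(
    coref = coref, n_documents = length(docs), counts = counts,
    timings = timings,
    config = list(coref = coref_cfg, conversion = conversion)),
    class = "run_manifest")
  structure(list(predictions = predictions, statements = pred_map,
                 report = report, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest: %d document(s), coreference %s>\n",
              x$n_documents, if (x$coref) "on" else "off"))
  cat("  counts: ", paste(names(x$counts), x$counts, sep = "=",
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$manifest)
  cat(sprintf("  predictions: %d statement(s)\n", nrow(x$predictions)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Run the pipeline over a synthetic corpus
#'
#' Convenience wrapper selecting the event condition matching `coref`
#' (events over resolved text when on, over original text when off) and
#' scoring against the corpus' gold statements.
#'
#' @param corpus A `"synthetic_corpus"` from [generate_corpus()].
#' @param coref Enable coreference resolution.
#' @param conversion A [conversion_config()]; should match the one the
#'   corpus' gold statements were generated under.
#' @param ... Passed to [run_pipeline()].
#' @return A `"pipeline_result"`.
#' @export
run_corpus_pipeline <- function(corpus, coref = TRUE,
                                conversion = conversion_config(), ...) {
  arm <- if (coref) "resolved" else "original"
  events <- lapply(corpus$events, `[[`, arm)
  run_pipeline(corpus$docs, events, corpus$lexicon_index, coref = coref,
               conversion = conversion,
               gold = corpus$gold[, c("sentence_id", "statement")], ...)
}
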