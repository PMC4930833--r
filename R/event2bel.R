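# Translation of BioNLP GE events into BEL statements. Simple event types
# map to abundance/modifier terms (Protein_catabolism -> deg(p(X)),
# Gene_expression/Transcription -> r(X), Phosphorylation -> p(X,pmod(P)),
# Localization -> tloc(p(X)), Binding -> complex(...) or p(X)). Regulation
# events supply the statement skeleton: Positive_regulation -> increases
# (or the act() function when the trigger is an activation word and the
# extension is enabled), Negative_regulation -> decreases; the bare
# Regulation type is skipped as inherently ambiguous.

#' Trigger lexicons for regulation polarity and the act() extension
#'
#' Matching is case-insensitive on the trigger surface form; the three sets
#' must be disjoint. The attested seeds are "targets" (positive),
#' "down-regulator" (negative) and "activation"/"activated" (activation);
#' the remaining defaults are ordinary polarity verbs used by the synthetic
#' corpus templates.
#'
#' @param positive,negative,activation Character vectors of trigger surface
#'   forms.
#' @return A list of class `"trigger_lexicons"`.
#' @export
trigger_lexicons <- function(
    positive = c("targets", "induces", "increases", "enhances", "promotes",
                 "causes", "caused", "up-regulates", "stimulates"),
    negative = c("down-regulator", "inhibits", "suppresses", "decreases",
                 "reduces", "blocks", "represses"),
    activation = c("activation", "activated", "activates")) {
  positive <- tolower(positive); negative <- tolower(negative)
  activation <- tolower(activation)
  if (length(intersect(positive, negative)) ||
      length(intersect(positive, activation)) ||
      length(intersect(negative, activation)))
    stop("trigger lexicons must be disjoint")
  structure(list(positive = positive, negative = negative,
                 activation = activation),
            class = "trigger_lexicons")
}

#' Conversion configuration
#'
#' @param lexicons A [trigger_lexicons()] object.
#' @param enable_act Enable the extended `act()` BEL function for
#'   activation-triggered `Positive_regulation` events. Off by default.
#' @param confidence_threshold Statements scoring below this confidence are
#'   dropped (default 0: keep all, report scores).
#' @param drop_regulation Skip the ambiguous bare `Regulation` type.
#' @return A list of class `"conversion_config"`.
#' @export
conversion_config <- function(lexicons = trigger_lexicons(),
                              enable_act = FALSE,
                              confidence_threshold = 0,
                              drop_regulation = TRUE) {
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1)
  structure(list(lexicons = lexicons, enable_act = isTRUE(enable_act),
                 confidence_threshold = confidence_threshold,
                 drop_regulation = isTRUE(drop_regulation)),
            class = "conversion_config")
}

.entity_text <- function(sa, tid) sa$textbounds[[tid]]$text

#' Map a simple (non-regulation) event to a BEL term
#'
#' @param ev A [bionlp_event()] of a non-regulation type whose Theme
#'   arguments are entities.
#' @param sa The `"standoff_annotation"` the event belongs to.
#' @return A `"bel_term"` over raw mention strings (namespace `NA`), or
#'   `NULL` when the event has no Theme.
#' @export
map_simple_event <- function(ev, sa) {
  if (ev$type %in% .regulation_types)
    stop(sprintf("event %s: %s is not a simple event type", ev$id, ev$type))
  themes <- ev$args$target[ev$args$role == "Theme"]
  themes <- themes[grepl("^T", themes)]
  if (length(themes) == 0) return(NULL)
  mention <- function(tid) .entity_text(sa, tid)
  switch(ev$type,
    Binding = if (length(themes) >= 2)
      bel_term("complex",
               members = lapply(themes, function(t) bel_term("p", id = mention(t))))
    else bel_term("p", id = mention(themes[1])),
    Gene_expression = bel_term("r", id = mention(themes[1])),
    Transcription = bel_term("r", id = mention(themes[1])),
    Localization = bel_term("p", id = mention(themes[1]), wrapper = "tloc"),
    Phosphorylation = bel_term("p", id = mention(themes[1]), pmod = "P"),
    Protein_catabolism = bel_term("p", id = mention(themes[1]), wrapper = "deg"),
    stop(sprintf("event %s: unknown event type '%s'", ev$id, ev$type)))
}

#' Classify a regulation event's contribution to a statement
#'
#' @param ev A regulation-type [bionlp_event()].
#' @param sa The `"standoff_annotation"` (for the trigger surface form).
#' @param config A [conversion_config()].
#' @return One of `"increases"`, `"decreases"`, `"act_function"`, `"skip"`.
#' @export
classify_regulation <- function(ev, sa, config = conversion_config()) {
  stopifnot(ev$type %in% .regulation_types)
  if (ev$type == "Regulation")
    return(if (config$drop_regulation) "skip" else "increases")
  trig <- tolower(sa$textbounds[[ev$trigger]]$text)
  if (ev$type == "Positive_regulation") {
    if (config$enable_act && trig %in% config$lexicons$activation)
      return("act_function")
    return("increases")
  }
  "decreases"
}

# Term for an event used as a statement argument. Nested regulation events
# contribute their Theme's term (optionally act()-wrapped); only the
# outermost regulation yields a relationship.
.map_event_term <- function(ev, sa, config) {
  if (!(ev$type %in% .regulation_types)) return(map_simple_event(ev, sa))
  cls <- classify_regulation(ev, sa, config)
  themes <- ev$args$target[ev$args$role == "Theme"]
  if (length(themes) == 0) return(NULL)
  t1 <- themes[1]
  tm <- if (grepl("^T", t1)) bel_term("p", id = .entity_text(sa, t1))
        else .map_event_term(sa$events[[t1]], sa, config)
  if (is.null(tm)) return(NULL)
  if (cls == "act_function" && is.na(tm$wrapper)) tm$wrapper <- "act"
  tm
}

.collect_entity_ids <- function(ev, sa) {
  ids <- ev$args$target[grepl("^T", ev$args$target)]
  for (t in ev$args$target[grepl("^E", ev$args$target)])
    ids <- c(ids, .collect_entity_ids(sa$events[[t]], sa))
  unique(ids)
}

#' Confidence score of an event
#'
#' Geometric mean of the trigger probability and all argument probabilities
#' over the event and its transitively nested events. Equals 1 when all
#' probabilities are at their default of 1; adding any probability below 1
#' can only lower the score.
#'
#' @param ev A [bionlp_event()].
#' @param sa The `"standoff_annotation"` it belongs to.
#' @return A unit-interval score.
#' @export
score_confidence <- function(ev, sa) {
  probs <- function(e) {
    v <- c(e$trigger_prob, e$arg_probs)
    for (t in e$args$target[grepl("^E", e$args$target)])
      v <- c(v, probs(sa$events[[t]]))
    v
  }
  v <- probs(ev)
  exp(mean(log(pmax(v, .Machine$double.xmin))))
}

#' Convert BioNLP events to BEL statements
#'
#' Each `Positive_regulation`/`Negative_regulation` event carrying both a
#' Cause and a Theme yields one statement per (Cause, Theme) pair: the
#' subject maps the Cause (entity to `p(entity)`, event to its term), the
#' object maps the Theme likewise, and the relationship comes from
#' [classify_regulation()] (`act_function` wraps the object in `act()` and
#' relates with `increases`). Regulation events lacking a Cause, bare
#' `Regulation` events and statements below the confidence threshold
#' produce no output and are logged.
#'
#' @param sa A `"standoff_annotation"`.
#' @param config A [conversion_config()].
#' @return A list with `statements` (list of `"bel_statement"`s over raw
#'   mention strings), `provenance` (per statement: event id, trigger span,
#'   entity textbound ids) and `log` (a data frame of skipped/dropped
#'   events with reasons).
#' @export
convert_events <- function(sa, config = conversion_config()) {
  statements <- list(); provenance <- list()
  log <- list()
  note <- function(id, reason)
    log[[length(log) + 1L]] <<- data.frame(event = id, reason = reason,
                                           stringsAsFactors = FALSE)
  ids <- names(sa$events)[order(.id_num(names(sa$events)))]
  for (id in ids) {
    ev <- sa$events[[id]]
    if (!(ev$type %in% .regulation_types)) next
    cls <- classify_regulation(ev, sa, config)
    if (cls == "skip") { note(id, "regulation_skipped"); next }
    causes <- ev$args$target[ev$args$role == "Cause"]
    themes <- ev$args$target[ev$args$role == "Theme"]
    if (length(causes) == 0) { note(id, "no_cause"); next }
    if (length(themes) == 0) { note(id, "no_theme"); next }
    conf <- score_confidence(ev, sa)
    for (cz in causes) for (th in themes) {
      subj <- if (grepl("^T", cz)) bel_term("p", id = .entity_text(sa, cz))
              else .map_event_term(sa$events[[cz]], sa, config)
      obj <- if (grepl("^T", th)) bel_term("p", id = .entity_text(sa, th))
             else .map_event_term(sa$events[[th]], sa, config)
      if (is.null(subj) || is.null(obj)) { note(id, "unmappable_argument"); next }
      rel <- "increases"
      if (cls == "decreases") rel <- "decreases"
      if (cls == "act_function") {
        if (is.na(obj$wrapper)) obj$wrapper <- "act"
        else note(id, "act_superseded_by_inner_wrapper")
      }
      if (conf < config$confidence_threshold) {
        note(id, "below_threshold")
        next
      }
      statements[[length(statements) + 1L]] <-
        bel_statement(subj, rel, obj, confidence = conf)
      trig <- sa$textbounds[[ev$trigger]]
      provenance[[length(provenance) + 1L]] <- list(
        event = id, trigger = list(start = trig$start, end = trig$end,
                                   text = trig$text),
        entity_ids = .collect_entity_ids(ev, sa))
    }
  }
  list(statements = statements, provenance = provenance,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(event = character(0), reason = character(0),
                    stringsAsFactors = FALSE))
}
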