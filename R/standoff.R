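# BioNLP shared-task standoff I/O: T-lines (text-bound entities and event
# triggers) in .a1/.a2, E-lines (typed events with role:target arguments)
# in .a2. This is the contract between an external event extractor and the
# rest of the toolkit; event extraction itself is out of scope.

.event_types <- c("Binding", "Gene_expression", "Transcription",
                  "Localization", "Phosphorylation", "Protein_catabolism",
                  "Positive_regulation", "Negative_regulation", "Regulation")
.regulation_types <- c("Positive_regulation", "Negative_regulation",
                       "Regulation")

#' Construct a text-bound annotation (entity or event trigger)
#'
#' @param id Identifier of the form `"T<number>"`.
#' @param label Annotation label (`"Protein"`, or an event-type trigger
#'   label such as `"Protein_catabolism"`).
#' @param start,end 0-based half-open character offsets into the annotated
#'   text.
#' @param text Surface string at the span.
#' @return A list of class `"textbound"`.
#' @export
textbound <- function(id, label, start, end, text) {
  stopifnot(grepl("^T[0-9]+$", id), end > start)
  structure(list(id = id, label = label, start = as.integer(start),
                 end = as.integer(end), text = text),
            class = "textbound")
}

#' Construct a BioNLP event
#'
#' @param id Identifier of the form `"E<number>"`.
#' @param type Event type (GE repertoire: Binding, Gene_expression,
#'   Transcription, Localization, Phosphorylation, Protein_catabolism,
#'   Positive_regulation, Negative_regulation, Regulation).
#' @param trigger Id of the trigger [textbound()].
#' @param args Data frame with columns `role` (`"Theme"` or `"Cause"`) and
#'   `target` (a `T` or `E` id).
#' @param trigger_prob,arg_probs Optional extractor probabilities in
#'   `[0, 1]`; they default to 1 ("no confidence information").
#' @return A list of class `"bionlp_event"`.
#' @export
bionlp_event <- function(id, type, trigger, args,
                         trigger_prob = 1, arg_probs = NULL) {
  stopifnot(grepl("^E[0-9]+$", id))
  if (!(type %in% .event_types))
    stop(sprintf("event %s: unknown event type '%s'", id, type))
  if (is.null(arg_probs)) arg_probs <- rep(1, nrow(args))
  stopifnot(nrow(args) == length(arg_probs),
            all(args$role %in% c("Theme", "Cause")))
  structure(list(id = id, type = type, trigger = trigger, args = args,
                 trigger_prob = trigger_prob, arg_probs = arg_probs),
            class = "bionlp_event")
}

.check_event_graph <- function(events) {
  state <- new.env(parent = emptyenv())
  visit <- function(id, stack) {
    if (id %in% stack)
      stop(sprintf("cyclic event references: %s",
                   paste(c(stack, id), collapse = " -> ")))
    if (isTRUE(state[[id]])) return(invisible())
    ev <- events[[id]]
    for (t in ev$args$target) {
      if (grepl("^E", t)) {
        if (is.null(events[[t]]))
          stop(sprintf("event %s: dangling event reference %s", id, t))
        visit(t, c(stack, id))
      }
    }
    state[[id]] <- TRUE
    invisible()
  }
  for (id in names(events)) visit(id, character(0))
  invisible(TRUE)
}

#' Assemble and validate a standoff annotation set
#'
#' @param text The annotated text (original or coreference-resolved).
#' @param textbounds List of [textbound()] objects (entities and triggers).
#' @param events List of [bionlp_event()] objects.
#' @return A list of class `"standoff_annotation"` with named member lists.
#' @export
standoff_annotation <- function(text, textbounds = list(), events = list()) {
  names(textbounds) <- vapply(textbounds, `[[`, character(1), "id")
  names(events) <- vapply(events, `[[`, character(1), "id")
  if (anyDuplicated(names(textbounds)))
    stop("duplicate textbound ids")
  if (anyDuplicated(names(events)))
    stop("duplicate event ids")
  n <- nchar(text)
  for (tb in textbounds) {
    if (is.na(tb$start)) next  # unmappable after projection
    if (tb$start < 0 || tb$end > n)
      stop(sprintf("%s: span [%d,%d) outside text of length %d",
                   tb$id, tb$start, tb$end, n))
    actual <- span_text(text, tb$start, tb$end)
    if (!identical(actual, tb$text))
      stop(sprintf("%s: surface text '%s' does not match span text '%s'",
                   tb$id, tb$text, actual))
  }
  for (ev in events) {
    if (is.null(textbounds[[ev$trigger]]))
      stop(sprintf("event %s: dangling trigger reference %s",
                   ev$id, ev$trigger))
    if (!startsWith(textbounds[[ev$trigger]]$label, ev$type))
      stop(sprintf("event %s: trigger label '%s' does not match type '%s'",
                   ev$id, textbounds[[ev$trigger]]$label, ev$type))
    for (t in ev$args$target) {
      if (grepl("^T", t) && is.null(textbounds[[t]]))
        stop(sprintf("event %s: dangling reference %s", ev$id, t))
      if (grepl("^E", t) && is.null(events[[t]]))
        stop(sprintf("event %s: dangling event reference %s", ev$id, t))
    }
  }
  .check_event_graph(events)
  structure(list(text = text, textbounds = textbounds, events = events),
            class = "standoff_annotation")
}

.parse_t_line <- function(line, file) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 3)
    stop(sprintf("%s: malformed T line: %s", file, line))
  mid <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
  if (length(mid) != 3)
    stop(sprintf("%s: malformed span in line: %s", file, line))
  textbound(parts[1], mid[1], as.integer(mid[2]), as.integer(mid[3]),
            parts[3])
}

.parse_e_line <- function(line, file) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 2)
    stop(sprintf("%s: malformed E line: %s", file, line))
  fields <- strsplit(trimws(parts[2]), " +")[[1]]
  head <- strsplit(fields[1], ":", fixed = TRUE)[[1]]
  if (length(head) != 2)
    stop(sprintf("%s: malformed event head: %s", file, line))
  roles <- character(0); targets <- character(0)
  for (f in fields[-1]) {
    rt <- strsplit(f, ":", fixed = TRUE)[[1]]
    if (length(rt) != 2)
      stop(sprintf("%s: malformed argument '%s' in line: %s", file, f, line))
    role <- sub("^(Theme)[0-9]+$", "\\1", rt[1])  # Theme2... -> Theme
    if (!(role %in% c("Theme", "Cause")))
      stop(sprintf("%s: unsupported role '%s' in line: %s", file, rt[1], line))
    roles <- c(roles, role); targets <- c(targets, rt[2])
  }
  bionlp_event(parts[1], head[1], head[2],
               data.frame(role = roles, target = targets,
                          stringsAsFactors = FALSE))
}

#' Read BioNLP-ST standoff files
#'
#' @param txt_path Path to the `.txt` file with the annotated text.
#' @param a1_path Path to the `.a1` entity file (T lines).
#' @param a2_path Path to the `.a2` event file (trigger T lines and E
#'   lines). `Theme2`, `Theme3`, ... roles are normalized to repeated
#'   `Theme` entries.
#' @return A validated `"standoff_annotation"`.
#' @export
read_standoff <- function(txt_path, a1_path, a2_path) {
  text <- paste(readLines(txt_path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  tbs <- list(); evs <- list()
  for (path in c(a1_path, a2_path)) {
    if (is.na(path) || !file.exists(path)) next
    for (line in readLines(path, warn = FALSE, encoding = "UTF-8")) {
      if (!nzchar(trimws(line)) || startsWith(line, "#")) next
      if (startsWith(line, "T"))
        tbs[[length(tbs) + 1L]] <- .parse_t_line(line, path)
      else if (startsWith(line, "E"))
        evs[[length(evs) + 1L]] <- .parse_e_line(line, path)
      else stop(sprintf("%s: unsupported annotation line: %s", path, line))
    }
  }
  standoff_annotation(text, tbs, evs)
}

.id_num <- function(ids) as.integer(sub("^[TE]", "", ids))

.format_t_line <- function(tb) {
  sprintf("%s\t%s %d %d\t%s", tb$id, tb$label, tb$start, tb$end, tb$text)
}

.format_e_line <- function(ev) {
  args <- ev$args
  # re-emit repeated Themes as Theme, Theme2, ... for interoperability
  role_out <- args$role
  th <- which(args$role == "Theme")
  if (length(th) > 1)
    role_out[th[-1]] <- paste0("Theme", seq_along(th[-1]) + 1L)
  sprintf("%s\t%s:%s%s", ev$id, ev$type, ev$trigger,
          paste0(vapply(seq_len(nrow(args)), function(i)
            sprintf(" %s:%s", role_out[i], args$target[i]), character(1)),
            collapse = ""))
}

#' Write BioNLP-ST standoff files
#'
#' Inverse of [read_standoff()] up to whitespace normalization; output
#' ordering is canonical (by numeric id). Entity T-lines (label
#' `"Protein"`) go to `.a1`; trigger T-lines and E-lines go to `.a2`.
#'
#' @param sa A `"standoff_annotation"`.
#' @param txt_path,a1_path,a2_path Output paths.
#' @return `invisible(NULL)`.
#' @export
write_standoff <- function(sa, txt_path, a1_path, a2_path) {
  writeLines(sa$text, txt_path, useBytes = TRUE)
  tbs <- sa$textbounds[order(.id_num(names(sa$textbounds)))]
  is_entity <- vapply(tbs, function(tb) tb$label == "Protein", logical(1))
  writeLines(vapply(tbs[is_entity], .format_t_line, character(1)), a1_path,
             useBytes = TRUE)
  evs <- sa$events[order(.id_num(names(sa$events)))]
  a2 <- c(vapply(tbs[!is_entity], .format_t_line, character(1)),
          vapply(evs, .format_e_line, character(1)))
  writeLines(a2, a2_path, useBytes = TRUE)
  invisible(NULL)
}

#' Project standoff spans from resolved text back to the original text
#'
#' Needed because event extraction runs on coreference-substituted text
#' while gold offsets live on the original text. Spans outside any
#' substitution are shifted identically; spans entirely inside a
#' substituted region map to the antecedent's source span (whose surface
#' text equals the substituted surface). Unmappable spans (crossing a
#' substitution boundary) are kept with `NA` offsets and flagged.
#'
#' @param sa A `"standoff_annotation"` over the resolved text.
#' @param subres The `"substitution_result"` that produced that text.
#' @param original_text The original document text.
#' @return A `"standoff_annotation"` over `original_text`; textbounds gain
#'   a logical field `mapped`.
#' @export
project_events <- function(sa, subres, original_text) {
  tbs <- lapply(sa$textbounds, function(tb) {
    pr <- project_span(subres, tb$start, tb$end, inside = "antecedent")
    if (is.null(pr)) {
      tb$start <- NA_integer_; tb$end <- NA_integer_; tb$mapped <- FALSE
    } else {
      tb$start <- pr$start; tb$end <- pr$end
      tb$text <- span_text(original_text, pr$start, pr$end)
      tb$mapped <- TRUE
    }
    tb
  })
  standoff_annotation(original_text, tbs, unname(sa$events))
}

#' @export
print.standoff_annotation <- function(x, ...) {
  cat(sprintf("<standoff_annotation: %d textbound(s), %d event(s)>\n",
              length(x$textbounds), length(x$events)))
  invisible(x)
}
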