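# BEL term/statement abstract syntax, parser and canonical serializer for
# the BEL-track subset: abundance functions p/g/r/m/bp/path/a/complex, the
# pmod(code) modification, the deg/tloc/act (and, for evaluation tolerance,
# kin/tscript/cat) wrappers, and increases/decreases relationships. Long-form
# function names are accepted on input and always emitted short-form.

.namespaces <- c("HGNC", "MGI", "EGID", "GOBP", "MESHD", "CHEBI")
.abundance_fns <- c("p", "g", "r", "m", "bp", "path", "a")
.wrapper_fns <- c("deg", "tloc", "act", "kin", "tscript", "cat")
.long_forms <- c(
  proteinAbundance = "p", geneAbundance = "g", rnaAbundance = "r",
  microRNAAbundance = "m", biologicalProcess = "bp", pathology = "path",
  abundance = "a", complexAbundance = "complex",
  degradation = "deg", translocation = "tloc",
  molecularActivity = "act", kinaseActivity = "kin",
  transcriptionalActivity = "tscript", catalyticActivity = "cat",
  proteinModification = "pmod")

#' Construct a BEL term
#'
#' Non-complex terms carry a namespaced (or raw, pre-normalization) entity;
#' `complex` terms carry at least two member terms and no entity of their
#' own. At most one activity wrapper (`deg`, `tloc`, `act`, `kin`,
#' `tscript`, `cat`) may wrap a term; `pmod` carries a modification code.
#'
#' @param fn Abundance function: one of `p`, `g`, `r`, `m`, `bp`, `path`,
#'   `a`, `complex`.
#' @param ns Namespace (`HGNC`, `MGI`, `EGID`, `GOBP`, `MESHD`, `CHEBI`),
#'   or `NA` for a raw, not-yet-normalized mention.
#' @param id Entity identifier or raw mention string.
#' @param pmod Protein-modification code (e.g. `"P"`), or `NA`.
#' @param wrapper Activity/modifier wrapper name, or `NA`.
#' @param members List of member `bel_term`s (complex only).
#' @return A list of class `"bel_term"`.
#' @export
bel_term <- function(fn, ns = NA_character_, id = NULL, pmod = NA_character_,
                     wrapper = NA_character_, members = NULL) {
  if (fn == "complex") {
    if (is.null(members) || length(members) < 2)
      stop("complex() requires at least two member terms")
    if (!is.null(id)) stop("complex() carries members, not an entity")
    for (m in members)
      if (!inherits(m, "bel_term") || m$fn == "complex")
        stop("complex() members must be simple bel_term objects")
  } else {
    if (!(fn %in% .abundance_fns))
      stop(sprintf("unknown BEL function '%s'", fn))
    if (is.null(id) || !nzchar(id)) stop("entity identifier must be non-empty")
    if (!is.na(ns) && !(ns %in% .namespaces))
      stop(sprintf("unknown namespace '%s'", ns))
    if (!is.null(members)) stop("only complex() carries members")
  }
  if (!is.na(wrapper) && !(wrapper %in% .wrapper_fns))
    stop(sprintf("unknown wrapper function '%s'", wrapper))
  structure(list(fn = fn, ns = ns, id = id, pmod = pmod, wrapper = wrapper,
                 members = members),
            class = "bel_term")
}

#' Construct a BEL statement
#'
#' @param subject,object [bel_term()] objects.
#' @param relationship `"increases"` or `"decreases"`.
#' @param confidence Optional unit-interval score. Carried as a side
#'   channel; never serialized into BEL text.
#' @return A list of class `"bel_statement"`.
#' @export
bel_statement <- function(subject, relationship, object, confidence = NA_real_) {
  relationship <- match.arg(relationship, c("increases", "decreases"))
  stopifnot(inherits(subject, "bel_term"), inherits(object, "bel_term"))
  structure(list(subject = subject, relationship = relationship,
                 object = object, confidence = confidence),
            class = "bel_statement")
}

## ---- tokenizer -------------------------------------------------------------

.bel_tokenize <- function(s) {
  toks <- list()
  i <- 1L; n <- nchar(s)
  push <- function(type, value, pos)
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, pos = pos)
  while (i <= n) {
    ch <- substring(s, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")", ",", ":")) { push(ch, ch, i); i <- i + 1L; next }
    if (ch == "\"") {
      j <- regexpr("\"", substring(s, i + 1L))
      if (j < 0) stop(sprintf("unterminated quote at position %d", i))
      push("STRING", substring(s, i + 1L, i + j - 1L), i)
      i <- i + j + 1L
      next
    }
    if (ch == "-") {
      nxt <- substring(s, i + 1L, i + 1L)
      if (nxt == ">") { push("REL", "increases", i); i <- i + 2L; next }
      if (nxt == "|") { push("REL", "decreases", i); i <- i + 2L; next }
    }
    m <- regexpr("^[^\\s(),:\"]+", substring(s, i), perl = TRUE)
    len <- attr(m, "match.length")
    if (len <= 0) stop(sprintf("unexpected character '%s' at position %d", ch, i))
    word <- substring(s, i, i + len - 1L)
    if (word %in% c("increases", "decreases")) push("REL", word, i)
    else push("NAME", word, i)
    i <- i + len
  }
  toks
}

## ---- recursive-descent parser ---------------------------------------------

.parser_env <- function(toks) {
  e <- new.env(parent = emptyenv()); e$toks <- toks; e$i <- 1L; e
}
.peek <- function(p) if (p$i <= length(p$toks)) p$toks[[p$i]] else NULL
.next_tok <- function(p) { t <- .peek(p); p$i <- p$i + 1L; t }
.expect <- function(p, type) {
  t <- .next_tok(p)
  if (is.null(t))
    stop(sprintf("unexpected end of input; expected '%s'", type))
  if (t$type != type)
    stop(sprintf("expected '%s' at position %d, found '%s'",
                 type, t$pos, t$value))
  t
}

.canon_fn <- function(name, pos) {
  if (name %in% names(.long_forms)) return(unname(.long_forms[name]))
  if (name %in% c(.abundance_fns, "complex", .wrapper_fns, "pmod")) return(name)
  stop(sprintf("unknown function '%s' at position %d", name, pos))
}

.parse_value <- function(p) {
  t <- .next_tok(p)
  if (is.null(t) || !(t$type %in% c("NAME", "STRING")))
    stop(sprintf("expected an identifier%s",
                 if (is.null(t)) " at end of input"
                 else sprintf(" at position %d", t$pos)))
  t$value
}

.parse_term <- function(p) {
  t <- .expect(p, "NAME")
  fn <- .canon_fn(t$value, t$pos)
  .expect(p, "(")
  if (fn %in% .wrapper_fns) {
    inner <- .parse_term(p)
    .expect(p, ")")
    if (!is.na(inner$wrapper))
      stop(sprintf("at position %d: at most one activity wrapper per term",
                   t$pos))
    inner$wrapper <- fn
    return(inner)
  }
  if (fn == "pmod")
    stop(sprintf("pmod() at position %d must appear inside an abundance term",
                 t$pos))
  if (fn == "complex") {
    members <- list(.parse_term(p))
    while (!is.null(.peek(p)) && .peek(p)$type == ",") {
      .next_tok(p)
      members[[length(members) + 1L]] <- .parse_term(p)
    }
    .expect(p, ")")
    return(bel_term("complex", members = members))
  }
  # simple abundance: [NS ':'] value [',' pmod '(' code? ')']
  v <- .parse_value(p)
  ns <- NA_character_
  if (!is.null(.peek(p)) && .peek(p)$type == ":") {
    .next_tok(p)
    if (!(v %in% .namespaces))
      stop(sprintf("unknown namespace '%s' at position %d", v, t$pos))
    ns <- v
    v <- .parse_value(p)
  }
  pmod <- NA_character_
  if (!is.null(.peek(p)) && .peek(p)$type == ",") {
    .next_tok(p)
    pt <- .expect(p, "NAME")
    if (.canon_fn(pt$value, pt$pos) != "pmod")
      stop(sprintf("unexpected term argument '%s' at position %d",
                   pt$value, pt$pos))
    .expect(p, "(")
    if (!is.null(.peek(p)) && .peek(p)$type %in% c("NAME", "STRING"))
      pmod <- .next_tok(p)$value
    else pmod <- "P"
    .expect(p, ")")
  }
  .expect(p, ")")
  bel_term(fn, ns = ns, id = v, pmod = pmod)
}

#' Parse a BEL statement or bare term
#'
#' Accepts short-form function names, their long forms
#' (`proteinAbundance()`, ...), and `->` / `-|` / `increases` / `decreases`
#' relationship spellings. Errors report the failing position.
#'
#' @param s A BEL string, e.g.
#'   `'p(MGI:Lyve1) -> deg(a(CHEBI:"hyaluronic acid"))'`.
#' @return A `"bel_statement"`, or a bare `"bel_term"` when `s` has no
#'   relationship.
#' @export
parse_bel <- function(s) {
  p <- .parser_env(.bel_tokenize(s))
  subject <- .parse_term(p)
  t <- .peek(p)
  if (is.null(t)) return(subject)
  if (t$type != "REL")
    stop(sprintf("expected a relationship at position %d, found '%s'",
                 t$pos, t$value))
  .next_tok(p)
  object <- .parse_term(p)
  if (!is.null(.peek(p)))
    stop(sprintf("trailing input at position %d", .peek(p)$pos))
  bel_statement(subject, t$value, object)
}

## ---- canonical serializer --------------------------------------------------

.quote_value <- function(v) {
  if (grepl("\\s", v)) paste0("\"", v, "\"") else v
}

#' Serialize a BEL term or statement to canonical form
#'
#' Canonical form uses short-form function names, no space after commas,
#' double quotes only around identifiers containing whitespace,
#' lexicographically sorted `complex()` members, and `increases` /
#' `decreases` relationship spellings. `serialize_bel(parse_bel(s))` is the
#' canonicalization of `s` and is idempotent.
#'
#' @param x A `"bel_term"` or `"bel_statement"`.
#' @return A character scalar.
#' @export
serialize_bel <- function(x) {
  if (inherits(x, "bel_statement"))
    return(paste(serialize_bel(x$subject), x$relationship,
                 serialize_bel(x$object)))
  stopifnot(inherits(x, "bel_term"))
  if (x$fn == "complex") {
    inner <- sort(vapply(x$members, serialize_bel, character(1)),
                  method = "radix")
    base <- paste0("complex(", paste(inner, collapse = ","), ")")
  } else {
    ent <- if (is.na(x$ns)) .quote_value(x$id)
           else paste0(x$ns, ":", .quote_value(x$id))
    pm <- if (!is.na(x$pmod)) paste0(",pmod(", x$pmod, ")") else ""
    base <- paste0(x$fn, "(", ent, pm, ")")
  }
  if (!is.na(x$wrapper)) paste0(x$wrapper, "(", base, ")") else base
}

#' @export
print.bel_term <- function(x, ...) {
  cat(serialize_bel(x), "\n"); invisible(x)
}

#' @export
print.bel_statement <- function(x, ...) {
  cat(serialize_bel(x))
  if (!is.na(x$confidence)) cat(sprintf("  [confidence %.3f]", x$confidence))
  cat("\n"); invisible(x)
}

#' Decompose a statement into components and flattened entities
#'
#' @param x A `"bel_statement"` or bare `"bel_term"`.
#' @return A list with `subject`, `relationship`, `object` (all `NULL` but
#'   `subject` for a bare term) and `entities`: a data frame of the
#'   abundance function, namespace and identifier of every entity term,
#'   walking through wrappers and complex members.
#' @export
term_components <- function(x) {
  collect <- function(tm) {
    if (tm$fn == "complex")
      do.call(rbind, lapply(tm$members, collect))
    else
      data.frame(fn = tm$fn, ns = tm$ns, id = tm$id, stringsAsFactors = FALSE)
  }
  if (inherits(x, "bel_term"))
    return(list(subject = x, relationship = NULL, object = NULL,
                entities = collect(x)))
  list(subject = x$subject, relationship = x$relationship, object = x$object,
       entities = rbind(collect(x$subject), collect(x$object)))
}
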