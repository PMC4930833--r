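# Six-level scoring of predicted BEL statements against gold, with the
# shared-task tolerances (ortholog identifier equivalence across HGNC/MGI/
# EGID; act() accepted for kin()/tscript()/cat()), micro aggregation over
# sentences, and a paired t-test over contiguous sentence groups for
# comparing two systems.
#
# Levels: T (Term: abundance function + namespace + identifier of every
# entity), F (Function: a Table-2 function together with its abundance
# argument), Fs (Secondary Function: the function alone, namespace
# ignored), R (Relation: subject entities + relationship + object
# entities), Rs (Secondary Relation: at least two of the three components,
# full matches included), S (full Statement).

.levels <- c("T", "Fs", "F", "Rs", "R", "S")

#' True/false positive/negative counts
#' @param tp,fp,fn Non-negative integers.
#' @return A list of class `"eval_counts"`.
#' @export
eval_counts <- function(tp = 0, fp = 0, fn = 0) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)),
            class = "eval_counts")
}

.round1 <- function(x) floor(x * 10 + 0.5) / 10  # half-up, one decimal

.prf_raw <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f <- if (2 * tp + fp + fn > 0) 100 * 2 * tp / (2 * tp + fp + fn) else 0
  c(precision = p, recall = r, f = f)
}

#' Precision, recall and F-score from counts
#'
#' Precision = 100 tp/(tp+fp), recall = 100 tp/(tp+fn), and
#' F = 100 * 2tp/(2tp+fp+fn), the harmonic mean of precision and recall,
#' all on the 0-100 scale; empty denominators yield 0. Values are reported
#' to one decimal, rounding half up, matching how shared-task tables print.
#'
#' @param counts An [eval_counts()] (or a list with `tp`, `fp`, `fn`).
#' @param digits Decimal places for reporting, or `NULL` for unrounded.
#' @return A list with `precision`, `recall`, `f`.
#' @export
prf <- function(counts, digits = 1) {
  v <- .prf_raw(counts$tp, counts$fp, counts$fn)
  if (!is.null(digits)) {
    stopifnot(digits == 1)
    v <- .round1(v)
  }
  as.list(v)
}

#' Evaluation tolerance configuration
#'
#' @param ortholog_map Optional data frame of identifier equivalences with
#'   columns `ns_a`, `id_a`, `ns_b`, `id_b` (namespaces among HGNC, MGI,
#'   EGID). The symmetric/transitive closure is taken.
#' @param function_equivalence Named character vector mapping specialised
#'   activity functions onto the one the scorer accepts; the default folds
#'   `kin`, `tscript` and `cat` into `act`.
#' @return A list of class `"tolerance_config"`.
#' @export
tolerance_config <- function(ortholog_map = NULL,
                             function_equivalence = c(kin = "act",
                                                      tscript = "act",
                                                      cat = "act")) {
  classes <- new.env(parent = emptyenv())
  if (!is.null(ortholog_map) && nrow(ortholog_map) > 0) {
    # union-find over "NS:id" keys
    parent <- new.env(parent = emptyenv())
    find <- function(k) {
      while (!is.null(parent[[k]]) && parent[[k]] != k) k <- parent[[k]]
      k
    }
    keys_a <- paste0(ortholog_map$ns_a, ":", ortholog_map$id_a)
    keys_b <- paste0(ortholog_map$ns_b, ":", ortholog_map$id_b)
    for (k in unique(c(keys_a, keys_b))) parent[[k]] <- k
    for (i in seq_along(keys_a)) {
      ra <- find(keys_a[i]); rb <- find(keys_b[i])
      if (ra != rb) parent[[rb]] <- ra
    }
    for (k in ls(parent)) classes[[k]] <- find(k)
  }
  structure(list(entity_classes = classes,
                 function_equivalence = function_equivalence),
            class = "tolerance_config")
}

.ent_key <- function(ns, id, tol) {
  k <- if (is.na(ns)) id else paste0(ns, ":", id)
  rep <- tol$entity_classes[[k]]
  if (!is.null(rep)) rep else k
}

.fn_equiv <- function(w, tol) {
  if (!is.na(w) && w %in% names(tol$function_equivalence))
    unname(tol$function_equivalence[[w]])
  else w
}

# full canonical signature of a term under the tolerances (S level)
.sig_full <- function(tm, tol) {
  if (tm$fn == "complex") {
    inner <- sort(vapply(tm$members, .sig_full, character(1), tol = tol),
                  method = "radix")
    base <- paste0("complex(", paste(inner, collapse = ","), ")")
  } else {
    pm <- if (!is.na(tm$pmod)) paste0(",pmod(", tm$pmod, ")") else ""
    base <- paste0(tm$fn, "(", .ent_key(tm$ns, tm$id, tol), pm, ")")
  }
  w <- .fn_equiv(tm$wrapper, tol)
  if (!is.na(w)) paste0(w, "(", base, ")") else base
}

# entity-level items of a term: abundance function + entity class key,
# ignoring wrappers and pmod (T and R levels)
.entity_items <- function(tm, tol) {
  if (tm$fn == "complex")
    unlist(lapply(tm$members, .entity_items, tol = tol))
  else
    paste0(tm$fn, "|", .ent_key(tm$ns, tm$id, tol))
}

# Table-2 function occurrences of a term: (function, argument) pairs at
# F granularity and function-only at Fs granularity
.function_items <- function(tm, tol) {
  f <- character(0); fs <- character(0)
  if (tm$fn == "complex") {
    members <- sort(unlist(lapply(tm$members, .entity_items, tol = tol)),
                    method = "radix")
    f <- c(f, paste0("complex|", paste(members, collapse = ",")))
    fs <- c(fs, "complex")
    for (m in tm$members) {
      sub <- .function_items(m, tol)
      f <- c(f, sub$f); fs <- c(fs, sub$fs)
    }
    return(list(f = f, fs = fs))
  }
  ent <- .ent_key(tm$ns, tm$id, tol)
  w <- .fn_equiv(tm$wrapper, tol)
  if (!is.na(w)) {
    f <- c(f, paste0(w, "|", tm$fn, "|", ent))
    fs <- c(fs, paste0(w, "|", tm$fn))
  }
  if (!is.na(tm$pmod)) {
    f <- c(f, paste0("pmod(", tm$pmod, ")|", tm$fn, "|", ent))
    fs <- c(fs, paste0("pmod(", tm$pmod, ")|", tm$fn))
  }
  list(f = f, fs = fs)
}

.side_sig <- function(tm, tol)
  paste(sort(.entity_items(tm, tol), method = "radix"), collapse = "+")

.statement_features <- function(st, tol) {
  if (!inherits(st, "bel_statement")) {
    # bare term: contributes term/function items only
    return(list(terms = .entity_items(st, tol),
                funcs = .function_items(st, tol),
                subj = NA_character_, rel = NA_character_,
                obj = NA_character_, full = .sig_full(st, tol)))
  }
  list(terms = c(.entity_items(st$subject, tol),
                 .entity_items(st$object, tol)),
       funcs = list(
         f = c(.function_items(st$subject, tol)$f,
               .function_items(st$object, tol)$f),
         fs = c(.function_items(st$subject, tol)$fs,
                .function_items(st$object, tol)$fs)),
       subj = .side_sig(st$subject, tol), rel = st$relationship,
       obj = .side_sig(st$object, tol),
       full = paste(.sig_full(st$subject, tol), st$relationship,
                    .sig_full(st$object, tol)))
}

# multiset TP count between two item vectors
.multiset_tp <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0L)
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  as.integer(sum(pmin(ta[common], tb[common])))
}

# maximum bipartite matching size (Kuhn's augmenting paths); adj is a list
# over left vertices of integer vectors of right vertices
.max_matching <- function(adj, n_right) {
  match_r <- rep(NA_integer_, n_right)
  try_aug <- function(u, seen_env) {
    for (v in adj[[u]]) {
      if (seen_env$seen[v]) next
      seen_env$seen[v] <- TRUE
      if (is.na(match_r[v]) || try_aug(match_r[v], seen_env)) {
        match_r[v] <<- u
        return(TRUE)
      }
    }
    FALSE
  }
  size <- 0L
  for (u in seq_along(adj)) {
    seen_env <- new.env(parent = emptyenv())
    seen_env$seen <- rep(FALSE, n_right)
    if (try_aug(u, seen_env)) size <- size + 1L
  }
  size
}

#' Score one sentence's predictions against its gold statements
#'
#' Items are matched one-to-one per level; at every level the reported TP
#' equals the maximum one-to-one matching between gold and predicted items
#' (for the exact-equivalence levels this coincides with multiset
#' intersection). Unmatched predictions count as FP, unmatched gold as FN.
#'
#' @param gold,pred Lists of `"bel_statement"` (or bare `"bel_term"`)
#'   objects for one sentence.
#' @param tol A [tolerance_config()].
#' @return A data frame with one row per level (`T`, `Fs`, `F`, `Rs`, `R`,
#'   `S`) and columns `tp`, `fp`, `fn`.
#' @export
score_sentence <- function(gold, pred, tol = tolerance_config()) {
  fg <- lapply(gold, .statement_features, tol = tol)
  fp_ <- lapply(pred, .statement_features, tol = tol)
  items <- function(feats, what) unlist(lapply(feats, function(x)
    switch(what, terms = x$terms, f = x$funcs$f, fs = x$funcs$fs,
           full = if (!is.na(x$subj)) x$full else character(0))))
  counts <- function(g_items, p_items) {
    tp <- .multiset_tp(g_items, p_items)
    c(tp = tp, fp = length(p_items) - tp, fn = length(g_items) - tp)
  }
  ct_T <- counts(items(fg, "terms"), items(fp_, "terms"))
  ct_F <- counts(items(fg, "f"), items(fp_, "f"))
  ct_Fs <- counts(items(fg, "fs"), items(fp_, "fs"))
  ct_S <- counts(items(fg, "full"), items(fp_, "full"))
  # relation levels operate on full statements only
  gstat <- Filter(function(x) !is.na(x$subj), fg)
  pstat <- Filter(function(x) !is.na(x$subj), fp_)
  rsig <- function(x) paste(x$subj, x$rel, x$obj)
  ct_R <- counts(vapply(gstat, rsig, character(1)),
                 vapply(pstat, rsig, character(1)))
  # Rs: >= 2 of the three components agree (full matches included)
  adj <- lapply(gstat, function(g) {
    which(vapply(pstat, function(p)
      (g$subj == p$subj) + (g$rel == p$rel) + (g$obj == p$obj) >= 2,
      logical(1)))
  })
  tp_rs <- .max_matching(adj, length(pstat))
  ct_Rs <- c(tp = tp_rs, fp = length(pstat) - tp_rs,
             fn = length(gstat) - tp_rs)
  out <- rbind(T = ct_T, Fs = ct_Fs, F = ct_F, Rs = ct_Rs, R = ct_R, S = ct_S)
  data.frame(level = rownames(out), tp = out[, "tp"], fp = out[, "fp"],
             fn = out[, "fn"], row.names = NULL, stringsAsFactors = FALSE)
}

#' Score a whole corpus (micro aggregation)
#'
#' @param gold,pred Named lists mapping sentence id to a list of parsed
#'   statements (see [read_bel_tsv()]). Sentence id sets may differ:
#'   sentences missing on one side score against an empty list.
#' @param tol A [tolerance_config()].
#' @return An object of class `"bel_eval_report"`: `levels` (a data frame
#'   with summed `tp`, `fp`, `fn` and one-decimal `precision`, `recall`,
#'   `f` per level), `per_sentence` (per-sentence count tables) and
#'   `tolerance`.
#' @export
score_corpus <- function(gold, pred, tol = tolerance_config()) {
  if (anyDuplicated(names(gold)))
    stop(sprintf("duplicate sentence id in gold: %s",
                 names(gold)[duplicated(names(gold))][1]))
  if (anyDuplicated(names(pred)))
    stop(sprintf("duplicate sentence id in predictions: %s",
                 names(pred)[duplicated(names(pred))][1]))
  ids <- sort(union(names(gold), names(pred)))
  per_sentence <- list()
  total <- matrix(0L, nrow = length(.levels), ncol = 3,
                  dimnames = list(.levels, c("tp", "fp", "fn")))
  for (id in ids) {
    sc <- score_sentence(if (is.null(gold[[id]])) list() else gold[[id]],
                         if (is.null(pred[[id]])) list() else pred[[id]],
                         tol)
    per_sentence[[id]] <- sc
    total <- total + as.matrix(sc[, c("tp", "fp", "fn")])
  }
  lv <- data.frame(level = .levels, tp = total[, "tp"], fp = total[, "fp"],
                   fn = total[, "fn"], row.names = NULL,
                   stringsAsFactors = FALSE)
  pr <- t(apply(lv, 1, function(r)
    .prf_raw(as.integer(r["tp"]), as.integer(r["fp"]), as.integer(r["fn"]))))
  lv$precision <- .round1(pr[, "precision"])
  lv$recall <- .round1(pr[, "recall"])
  lv$f <- .round1(pr[, "f"])
  structure(list(levels = lv, per_sentence = per_sentence, tolerance = tol),
            class = "bel_eval_report")
}

#' @export
print.bel_eval_report <- function(x, ...) {
  cat("BEL evaluation (micro aggregation over",
      length(x$per_sentence), "sentence(s))\n")
  print(x$levels, row.names = FALSE)
  invisible(x)
}

#' Read a BEL-track TSV (sentence_id <TAB> statement)
#'
#' @param path Path to a tab-separated file, one statement per line.
#' @return A named list mapping sentence id to a list of parsed statements.
#' @export
read_bel_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (line in lines) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2)
      stop(sprintf("%s: expected 'sentence_id<TAB>statement': %s", path, line))
    sid <- parts[1]
    st <- parse_bel(parts[2])
    out[[sid]] <- c(out[[sid]], list(st))
  }
  out
}

#' Write a BEL-track TSV
#'
#' @param x Either a named list (sentence id to statement list) or a data
#'   frame with columns `sentence_id` and `statement`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bel_tsv <- function(x, path) {
  if (is.data.frame(x)) {
    lines <- sprintf("%s\t%s", x$sentence_id, x$statement)
  } else {
    lines <- unlist(lapply(names(x), function(sid)
      vapply(x[[sid]], function(st) sprintf("%s\t%s", sid, serialize_bel(st)),
             character(1))))
    if (is.null(lines)) lines <- character(0)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Per-group F-scores for one level
#'
#' Sentences (in sorted-id order) are partitioned into `groups` contiguous,
#' nearly equal groups; each group's F-score at `level` is computed from
#' its summed counts.
#'
#' @param report A `"bel_eval_report"`.
#' @param level One of `"T"`, `"Fs"`, `"F"`, `"Rs"`, `"R"`, `"S"`.
#' @param groups Number of groups (default 30).
#' @return Numeric vector of length `groups` (unrounded F on 0-100 scale).
#' @export
level_fscores <- function(report, level = "S", groups = 30) {
  level <- match.arg(level, .levels)
  ids <- sort(names(report$per_sentence))
  n <- length(ids)
  if (n < groups)
    stop(sprintf("cannot split %d sentences into %d groups", n, groups))
  grp <- ((seq_len(n) - 1L) * groups) %/% n + 1L
  vapply(seq_len(groups), function(g) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (id in ids[grp == g]) {
      sc <- report$per_sentence[[id]]
      row <- sc[sc$level == level, ]
      tp <- tp + row$tp; fp <- fp + row$fp; fn <- fn + row$fn
    }
    unname(.prf_raw(tp, fp, fn)["f"])
  }, numeric(1))
}

#' Paired t-test between two systems' per-group scores
#'
#' Computes t = mean(d) / (sd(d)/sqrt(n)) with d = a - b and df = n - 1.
#' The critical value defaults to the upper one-sided Student quantile at
#' `alpha` rounded to two decimals (1.70 at df = 29, alpha = 0.05; the
#' shared-task convention prints +/- 1.699); significance is declared when
#' |t| >= critical.
#'
#' @param a,b Equal-length numeric vectors of paired per-group scores
#'   (n >= 2).
#' @param alpha One-sided significance level.
#' @param critical Override the critical value.
#' @return A list of class `"paired_t_result"` with `t`, `df`, `critical`,
#'   `significant`, `mean_difference` and `zero_variance`.
#' @export
paired_ttest <- function(a, b, alpha = 0.05, critical = NULL) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  df <- n - 1L
  if (is.null(critical)) critical <- round(stats::qt(1 - alpha, df), 2)
  s <- stats::sd(d)
  zero_variance <- s == 0
  t_stat <- if (zero_variance) {
    if (mean(d) > 0) Inf else if (mean(d) < 0) -Inf else 0
  } else mean(d) / (s / sqrt(n))
  structure(list(t = t_stat, df = df, critical = critical,
                 significant = abs(t_stat) >= critical,
                 mean_difference = mean(d), zero_variance = zero_variance),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.2f (df = %d, critical = %.2f) -> %s\n",
              x$t, x$df, x$critical,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Compare two systems with a paired t-test at one evaluation level
#'
#' @param gold Gold standard (named list, sentence id to statements).
#' @param pred_a,pred_b Two systems' predictions in the same form.
#' @param level Evaluation level for the per-group F-scores.
#' @param groups Number of contiguous sentence groups (default 30, giving
#'   df = 29).
#' @param tol A [tolerance_config()].
#' @param ... Passed to [paired_ttest()].
#' @return A `"paired_t_result"` (positive t favours system A).
#' @export
compare_systems <- function(gold, pred_a, pred_b, level = "S", groups = 30,
                            tol = tolerance_config(), ...) {
  ra <- score_corpus(gold, pred_a, tol)
  rb <- score_corpus(gold, pred_b, tol)
  paired_ttest(level_fscores(ra, level, groups),
               level_fscores(rb, level, groups), ...)
}
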