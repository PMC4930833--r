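# in-memory standoff for mapping tests: entities A, B plus one trigger word
conv_standoff <- function(trigger_label, trigger_word = "regulates",
                          events = list()) {
  text <- paste("A", trigger_word, "B and C for degradation of expression")
  off <- function(w, n = 1) span_of(text, w, n)
  tb <- function(id, label, w, n = 1) {
    s <- off(w, n); textbound(id, label, s$start, s$end, w)
  }
  standoff_annotation(text, list(
    tb("T1", "Protein", "A"), tb("T2", "Protein", "B"),
    tb("T3", "Protein", "C"),
    tb("T4", trigger_label, trigger_word),
    tb("T5", "Protein_catabolism", "degradation"),
    tb("T6", "Gene_expression", "expression")), events)
}

ev <- function(id, type, trigger, roles, targets, trig_p = 1, arg_p = NULL)
  bionlp_event(id, type, trigger,
               data.frame(role = roles, target = targets,
                          stringsAsFactors = FALSE),
               trigger_prob = trig_p, arg_probs = arg_p)

test_that("simple event types map to their BEL functions", {
  sa <- conv_standoff("Positive_regulation")
  m <- function(type, roles, targets) {
    e <- ev("E1", type, switch(type, Protein_catabolism = "T5",
                               Gene_expression = "T6", Transcription = "T6",
                               "T5"),
            roles, targets)
    # bypass trigger-label consistency for type variety by rebuilding
    sa2 <- standoff_annotation(sa$text, unname(sa$textbounds), list())
    map_simple_event(e, sa2)
  }
  # table-lookup oracle: expected serialization per type
  expect_identical(serialize_bel(m("Protein_catabolism", "Theme", "T2")),
                   "deg(p(B))")
  expect_identical(serialize_bel(m("Gene_expression", "Theme", "T2")),
                   "r(B)")
  expect_identical(serialize_bel(m("Transcription", "Theme", "T2")), "r(B)")
  skip_mapping <- m("Gene_expression", "Cause", "T2")
  expect_null(skip_mapping)  # no Theme -> no term

  sa3 <- conv_standoff("Positive_regulation")
  loc <- ev("E1", "Localization", "T5", "Theme", "T2")
  expect_identical(serialize_bel(map_simple_event(loc, sa3)), "tloc(p(B))")
  ph <- ev("E1", "Phosphorylation", "T5", "Theme", "T2")
  expect_identical(serialize_bel(map_simple_event(ph, sa3)), "p(B,pmod(P))")
  # Binding: two Themes -> complex; one Theme -> plain protein abundance
  b2 <- ev("E1", "Binding", "T5", c("Theme", "Theme"), c("T2", "T3"))
  expect_identical(serialize_bel(map_simple_event(b2, sa3)),
                   "complex(p(B),p(C))")
  b1 <- ev("E1", "Binding", "T5", "Theme", "T2")
  expect_identical(serialize_bel(map_simple_event(b1, sa3)), "p(B)")
  # regulation types are rejected here
  expect_error(map_simple_event(ev("E1", "Regulation", "T4", "Theme", "T2"),
                                conv_standoff("Regulation")),
               "not a simple event type")
})

test_that("regulation classification follows trigger polarity lexicons", {
  pos <- conv_standoff("Positive_regulation", "targets")
  e <- ev("E1", "Positive_regulation", "T4", c("Cause", "Theme"),
          c("T1", "T2"))
  expect_identical(classify_regulation(e, pos), "increases")

  neg <- conv_standoff("Negative_regulation", "down-regulator")
  en <- ev("E1", "Negative_regulation", "T4", c("Cause", "Theme"),
           c("T1", "T2"))
  expect_identical(classify_regulation(en, neg), "decreases")

  act <- conv_standoff("Positive_regulation", "activation")
  ea <- ev("E1", "Positive_regulation", "T4", c("Cause", "Theme"),
           c("T1", "T2"))
  expect_identical(classify_regulation(ea, act), "increases")
  cfg <- conversion_config(enable_act = TRUE)
  expect_identical(classify_regulation(ea, act, cfg), "act_function")

  reg <- conv_standoff("Regulation")
  er <- ev("E1", "Regulation", "T4", c("Cause", "Theme"), c("T1", "T2"))
  expect_identical(classify_regulation(er, reg), "skip")
})

test_that("conversion nests simple events under regulation statements", {
  # worked degradation example: Cause mdm2-like entity, Theme a catabolism
  # event -> subject increases deg-wrapped object
  sa <- conv_standoff("Positive_regulation", "targets", list(
    ev("E1", "Protein_catabolism", "T5", "Theme", "T2"),
    ev("E2", "Positive_regulation", "T4", c("Theme", "Cause"),
       c("E1", "T1"))))
  out <- convert_events(sa)
  expect_length(out$statements, 1)
  expect_identical(serialize_bel(out$statements[[1]]),
                   "p(A) increases deg(p(B))")
  expect_setequal(out$provenance[[1]]$entity_ids, c("T1", "T2"))

  # regulation without a Cause yields nothing, logged
  sa_nc <- conv_standoff("Positive_regulation", "targets", list(
    ev("E1", "Protein_catabolism", "T5", "Theme", "T2"),
    ev("E2", "Positive_regulation", "T4", "Theme", "E1")))
  out_nc <- convert_events(sa_nc)
  expect_length(out_nc$statements, 0)
  expect_true("no_cause" %in% out_nc$log$reason)

  # bare Regulation events are skipped entirely
  sa_reg <- conv_standoff("Regulation", "modulates", list(
    ev("E1", "Regulation", "T4", c("Cause", "Theme"), c("T1", "T2"))))
  out_reg <- convert_events(sa_reg)
  expect_length(out_reg$statements, 0)
  expect_identical(out_reg$log$reason, "regulation_skipped")

  # act() appears only with the extension enabled
  sa_act <- conv_standoff("Positive_regulation", "activation", list(
    ev("E1", "Positive_regulation", "T4", c("Cause", "Theme"),
       c("T1", "T2"))))
  off <- convert_events(sa_act)
  expect_identical(serialize_bel(off$statements[[1]]), "p(A) increases p(B)")
  on <- convert_events(sa_act, conversion_config(enable_act = TRUE))
  expect_identical(serialize_bel(on$statements[[1]]),
                   "p(A) increases act(p(B))")
})

test_that("confidence is the geometric mean over the event tree", {
  sa <- conv_standoff("Positive_regulation", "targets", list(
    ev("E1", "Protein_catabolism", "T5", "Theme", "T2")))
  # all defaults -> 1
  expect_identical(score_confidence(sa$events[["E1"]], sa), 1)
  # trigger 0.9 and one argument 0.4 -> sqrt(0.36) = 0.6
  e2 <- ev("E1", "Protein_catabolism", "T5", "Theme", "T2",
           trig_p = 0.9, arg_p = 0.4)
  sa2 <- standoff_annotation(sa$text, unname(sa$textbounds), list(e2))
  expect_equal(score_confidence(sa2$events[["E1"]], sa2), 0.6)
  # nested: adding any probability < 1 never increases the score
  set.seed(5)
  for (i in 1:20) {
    p_in <- runif(2); p_out <- runif(2)
    inner1 <- ev("E1", "Protein_catabolism", "T5", "Theme", "T2")
    outer1 <- ev("E2", "Positive_regulation", "T4", c("Theme", "Cause"),
                 c("E1", "T1"))
    sa_a <- standoff_annotation(sa$text, unname(sa$textbounds),
                                list(inner1, outer1))
    inner2 <- ev("E1", "Protein_catabolism", "T5", "Theme", "T2",
                 trig_p = p_in[1], arg_p = p_in[2])
    outer2 <- ev("E2", "Positive_regulation", "T4", c("Theme", "Cause"),
                 c("E1", "T1"), trig_p = p_out[1],
                 arg_p = c(p_out[2], 1))
    sa_b <- standoff_annotation(sa$text, unname(sa$textbounds),
                                list(inner2, outer2))
    expect_lte(score_confidence(sa_b$events[["E2"]], sa_b),
               score_confidence(sa_a$events[["E2"]], sa_a))
  }
  # the threshold drops low-confidence statements
  inner <- ev("E1", "Protein_catabolism", "T5", "Theme", "T2",
              trig_p = 0.2, arg_p = 0.2)
  outer <- ev("E2", "Positive_regulation", "T4", c("Theme", "Cause"),
              c("E1", "T1"))
  sa_t <- standoff_annotation(sa$text, unname(sa$textbounds),
                              list(inner, outer))
  kept <- convert_events(sa_t, conversion_config(confidence_threshold = 0.1))
  expect_length(kept$statements, 1)
  dropped <- convert_events(sa_t,
                            conversion_config(confidence_threshold = 0.9))
  expect_length(dropped$statements, 0)
  expect_true("below_threshold" %in% dropped$log$reason)
})
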