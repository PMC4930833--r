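test_that("anaphor detection finds pronouns and definite domain NPs", {
  doc <- il13_doc()
  anas <- detect_anaphors(doc)
  expect_length(anas, 1)
  expect_identical(anas[[1]]$text, "It")
  expect_identical(anas[[1]]$kind, "personal_pronoun")
  expect_identical(anas[[1]]$number, "singular")

  # definite NP with a domain noun
  dn <- mk_doc("D", list(list(
    id = "S1",
    words = list(wd("mdm2", men = TRUE, num = "singular"),
                 wd("degrades", pos = "VERB"),
                 wd("the", pos = "DET", def = TRUE),
                 wd("protein", num = "singular")),
    nps = list(list(from = 1, to = 1, head = 1, num = "singular"),
               list(from = 3, to = 4, head = 4, num = "singular",
                    def = TRUE)))))
  anas <- detect_anaphors(dn)
  expect_length(anas, 1)
  expect_identical(anas[[1]]$kind, "definite_np")
  expect_identical(anas[[1]]$text, "the protein")

  # no pronouns, no definite NPs -> nothing
  plain <- mk_doc("D", list(list(
    id = "S1", words = list(wd("mdm2", men = TRUE),
                            wd("binds", pos = "VERB"),
                            wd("p53", men = TRUE)),
    nps = list(list(from = 1, to = 1, head = 1)))))
  expect_length(detect_anaphors(plain), 0)

  # relative pronouns only when explicitly enabled
  rel <- mk_doc("D", list(list(
    id = "S1", words = list(wd("p53", men = TRUE, num = "singular"),
                            wd(",", pos = "PUNCT"),
                            wd("which", pos = "PRON", pron = TRUE)),
    nps = list(list(from = 1, to = 1, head = 1, num = "singular")))))
  expect_length(detect_anaphors(rel), 0)
  cfg <- coref_config(kinds = c("personal_pronoun", "possessive_pronoun",
                                "definite_np", "relative_pronoun"))
  expect_length(detect_anaphors(rel, cfg), 1)
})

test_that("candidate ranking applies number, NER and distance rules", {
  # Rule 1: plural candidate removed for a singular anaphor; gene ranked first
  doc <- il13_doc()
  ana <- detect_anaphors(doc)[[1]]
  cand <- rank_candidates(ana, doc)
  il13 <- cand[cand$text == "IL-13", ]
  comp <- cand[cand$text == "all comparisons", ]
  expect_identical(comp$eliminated_by, "rule1")
  expect_identical(il13$rank, 1L)

  # Rule 2: non-NER candidate removed for a definite-NP anaphor
  doc2 <- mk_doc("D", list(
    list(id = "S1",
         words = list(wd("the", pos = "DET", def = TRUE),
                      wd("assay", num = "singular"),
                      wd("used", pos = "VERB"),
                      wd("mdm2", men = TRUE, num = "singular")),
         nps = list(list(from = 1, to = 2, head = 2, num = "singular",
                         def = TRUE),
                    list(from = 4, to = 4, head = 4, num = "singular"))),
    list(id = "S2",
         words = list(wd("the", pos = "DET", def = TRUE),
                      wd("protein", num = "singular"),
                      wd("was", pos = "VERB"),
                      wd("degraded", pos = "VERB")),
         nps = list(list(from = 1, to = 2, head = 2, num = "singular",
                         def = TRUE)))))
  ana2 <- detect_anaphors(doc2)
  kinds <- vapply(ana2, `[[`, character(1), "kind")
  target <- ana2[[which(vapply(ana2, `[[`, integer(1), "sentence_index") == 2)]]
  cand2 <- rank_candidates(target, doc2)
  expect_identical(cand2$eliminated_by[cand2$text == "the assay"], "rule2")
  expect_identical(cand2$rank[cand2$text == "mdm2"], 1L)

  # anaphor with nothing before it: empty candidate table
  solo <- mk_doc("D", list(list(
    id = "S1", words = list(wd("It", pos = "PRON", pron = TRUE,
                               num = "singular"),
                            wd("works", pos = "VERB")), nps = list())))
  expect_identical(nrow(rank_candidates(detect_anaphors(solo)[[1]], solo)), 0L)
})

test_that("resolution matches a brute-force application of the rules", {
  # a five-NP document mixing numbers and NER status
  doc <- mk_doc("D", list(
    list(id = "S1",
         words = list(wd("IL-13", men = TRUE, num = "singular"),
                      wd("and", pos = "CONJ"),
                      wd("receptors", num = "plural"),
                      wd("bind", pos = "VERB"),
                      wd("TIMP-1", men = TRUE, num = "singular")),
         nps = list(list(from = 1, to = 1, head = 1, num = "singular"),
                    list(from = 3, to = 3, head = 3, num = "plural"),
                    list(from = 5, to = 5, head = 5, num = "singular"))),
    list(id = "S2",
         words = list(wd("controls", num = "plural"),
                      wd("showed", pos = "VERB"),
                      wd("that", pos = "SCONJ"),
                      wd("it", pos = "PRON", pron = TRUE,
                         num = "singular"),
                      wd("degrades", pos = "VERB"),
                      wd("fast", pos = "ADV")),
         nps = list(list(from = 1, to = 1, head = 1, num = "plural")))))
  links <- resolve_coreference(doc)
  expect_length(links, 1)
  ana <- links[[1]]$anaphor
  expected <- oracle_antecedent(doc, ana)
  expect_identical(links[[1]]$antecedent$start, expected$start)
  expect_identical(links[[1]]$antecedent$end, expected$end)
  expect_identical(links[[1]]$antecedent$text, "TIMP-1")

  # property over generated corpora: package output equals the oracle
  # on every planted anaphor, and antecedents always precede anaphors
  cp <- generate_corpus(fixture_spec(seed = 11, n_sentences = 30,
                                     cross_sentence_rate = 1))
  for (id in names(cp$docs)) {
    links <- resolve_coreference(cp$docs[[id]])
    planted <- cp$links[[id]]
    expect_length(links, length(planted))
    for (k in seq_along(links)) {
      l <- links[[k]]
      expect_lt(l$antecedent$start, l$anaphor$start)
      o <- oracle_antecedent(cp$docs[[id]], l$anaphor)
      expect_identical(l$antecedent$start, o$start)
      expect_identical(l$antecedent$end, o$end)
    }
  }
  # determinism: identical inputs give identical links
  d1 <- resolve_coreference(cp$docs[[1]])
  d2 <- resolve_coreference(cp$docs[[1]])
  expect_identical(d1, d2)
})

test_that("substitution rewrites anaphors and keeps an exact offset map", {
  doc <- mdm2_doc()
  links <- resolve_coreference(doc)
  expect_length(links, 1)
  expect_identical(links[[1]]$antecedent$text, "p53")
  sub <- substitute_coreferences(doc, links)
  expect_match(sub$resolved_text, "targets p53 for degradation", fixed = TRUE)

  # identity on an empty link list
  idsub <- substitute_coreferences(doc, list())
  expect_identical(idsub$resolved_text, doc$text)
  expect_identical(project_span(idsub, 5, 9), list(start = 5, end = 9))

  # every non-substituted character projects back to itself
  m <- sub$offset_map
  for (r in which(m$kind == "copy")) {
    for (pos in seq(m$res_start[r], m$res_end[r] - 1L)) {
      pr <- project_span(sub, pos, pos + 1L)
      expect_identical(substring(doc$text, pr$start + 1, pr$end),
                       substring(sub$resolved_text, pos + 1, pos + 1))
    }
  }
  # the substituted region projects to the antecedent's source span
  srow <- m[m$kind == "subst", ]
  pr <- project_span(sub, srow$res_start, srow$res_end)
  expect_identical(substring(doc$text, pr$start + 1, pr$end), "p53")

  # possessive pronouns receive a genitive marker
  poss <- mk_doc("D", list(
    list(id = "S1",
         words = list(wd("IL-13", men = TRUE, num = "singular"),
                      wd("was", pos = "VERB"), wd("induced", pos = "VERB")),
         nps = list(list(from = 1, to = 1, head = 1, num = "singular"))),
    list(id = "S2",
         words = list(wd("its", pos = "PRON", pron = TRUE,
                         num = "singular"),
                      wd("expression"), wd("rose", pos = "VERB")),
         nps = list())))
  plinks <- resolve_coreference(poss)
  psub <- substitute_coreferences(poss, plinks)
  expect_match(psub$resolved_text, "IL-13's expression", fixed = TRUE)

  # overlapping anaphor spans are rejected
  bad <- c(plinks, plinks)
  expect_error(substitute_coreferences(poss, bad), "overlapping")
})
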