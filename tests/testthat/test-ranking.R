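test_that("per-term disease score is 1/N_t inside the closure, else 0", {
  idx <- toy$index
  expect_equal(term_disease_score(idx, "C", "d1"), 1)
  expect_equal(term_disease_score(idx, "A", "d1"), 0.5)
  expect_equal(term_disease_score(idx, "A", "d3"), 0)
  expect_equal(term_disease_score(idx, "R", "d4"), 0.25)

  # a term whose closure holds 150 diseases scores 1/150 for each of them
  ont <- parse_obo(c("[Term]", "id: ROOT",
                     "[Term]", "id: T", "is_a: ROOT"))
  direct <- c(setNames(rep("T", 150), sprintf("OMIM:%06d", 1:150)),
              setNames(rep("ROOT", 30), sprintf("OMIM:9%05d", 1:30)))
  idx150 <- build_index(ont, as.list(direct))
  expect_equal(unname(idx150$N_t["T"]), 150L)
  expect_equal(round(term_disease_score(idx150, "T", "OMIM:000001"), 4),
               0.0067)

  ann <- build_index(toy$ontology, list(d1 = "A"))
  expect_warning(s <- term_disease_score(ann, "B", "d1"), "no disease")
  expect_equal(s, 0)
})

test_that("the alpha cap rescues many weak agreements over one strong one", {
  # nine query terms each scoring 0.005 for disease D1 (N_t = 200) and one
  # term scoring 0.1 for disease D2 (N_t = 10): without the cap D2 wins
  # (0.1 > 0.045), with alpha = 0.01 the ordering reverses
  terms9 <- sprintf("T%02d", 1:9)
  obo <- c("[Term]", "id: ROOT",
           unlist(lapply(c(terms9, "T10"),
                         function(t) c("[Term]", paste0("id: ", t),
                                       "is_a: ROOT"))))
  ont <- parse_obo(obo)
  fillers <- sprintf("F:%03d", 1:199)
  direct <- c(list(D1 = terms9, D2 = "T10"),
              setNames(lapply(fillers, function(f) terms9), fillers),
              setNames(lapply(sprintf("G:%03d", 1:9), function(g) "T10"),
                       sprintf("G:%03d", 1:9)))
  idx <- build_index(ont, direct)
  expect_equal(unname(idx$N_t["T01"]), 200L)
  expect_equal(unname(idx$N_t["T10"]), 10L)
  q <- c(terms9, "T10")

  uncapped_d1 <- rbp_similarity(idx, q, "D1", alpha = 1)
  uncapped_d2 <- rbp_similarity(idx, q, "D2", alpha = 1)
  expect_equal(uncapped_d1, 9 * 0.005)
  expect_equal(uncapped_d2, 0.1)
  expect_lt(uncapped_d1, uncapped_d2)

  capped_d1 <- rbp_similarity(idx, q, "D1", alpha = 0.01)
  capped_d2 <- rbp_similarity(idx, q, "D2", alpha = 0.01)
  expect_equal(capped_d1, 0.045)
  expect_equal(capped_d2, 0.01)
  expect_gt(capped_d1, capped_d2)
})

test_that("RelativeBestPair sums capped per-term scores", {
  idx <- toy$index
  expect_equal(rbp_similarity(idx, c("C", "A"), "d1", alpha = 0.01), 0.02)
  expect_equal(rbp_similarity(idx, c("C", "A"), "d1", alpha = 1), 1.5)
  expect_equal(rbp_similarity(idx, c("B"), "d2"), 0)
  expect_error(rbp_similarity(idx, character(0), "d1"), "empty")
  expect_error(rbp_similarity(idx, "C", "d1", alpha = 0), "alpha")
})

test_that("score_all_diseases covers the corpus for every method", {
  idx <- toy$index
  ont <- toy$ontology
  s <- score_all_diseases(idx, ont, "C", method = "rbp", alpha = 1)
  expect_equal(s, c(d1 = 1, d2 = 0, d3 = 0, d4 = 0))

  r <- score_all_diseases(idx, ont, "C", method = "resnik")
  expect_equal(unname(r["d2"]), log(2), tolerance = 1e-12)
  expect_setequal(names(r), c("d1", "d2", "d3", "d4"))

  one <- build_index(ont, list(dx = "C"))
  expect_equal(names(score_all_diseases(one, ont, "C")), "dx")

  expect_error(score_all_diseases(idx, ont, "C", method = "bogus"),
               "valid methods")
})

test_that("tie-averaged ranking is deterministic and conserves rank sums", {
  r <- rank_with_ties(c(a = 5, b = 3, c = 3, d = 1))
  expect_equal(r$rank, c(1, 2.5, 2.5, 4))
  expect_equal(r$disease, c("a", "b", "c", "d"))

  all_tied <- rank_with_ties(c(w = 2, x = 2, y = 2, z = 2))
  expect_equal(all_tied$rank, rep(2.5, 4))
  expect_equal(all_tied$disease, c("w", "x", "y", "z"))  # id tiebreak

  distinct <- rank_with_ties(c(a = 3, b = 9, c = 1))
  expect_setequal(distinct$rank, 1:3)

  expect_equal(rank_of_disease(r, "a"), 1)
  expect_equal(rank_of_disease(r, "c"), 2.5)
  expect_error(rank_of_disease(r, "zz"), "not in ranking")

  for (seed in 1:20) {
    set.seed(seed)
    m <- sample(2:30, 1)
    scores <- setNames(sample(0:5, m, replace = TRUE) / 2,
                       paste0("d", 1:m))
    rk <- rank_with_ties(scores)
    expect_equal(sum(rk$rank), m * (m + 1) / 2)
  }
})

test_that("RBP scoring obeys normalisation, cap and monotonicity", {
  for (seed in 1:10) {
    cs <- random_case(seed)
    idx <- cs$index
    for (t in names(idx$closure)) {
      tot <- sum(vapply(idx$diseases, function(d) {
        term_disease_score(idx, t, d)
      }, numeric(1)))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
    ann <- names(idx$closure)
    q <- sample(ann, min(4L, length(ann)))
    for (d in idx$diseases) {
      s <- rbp_similarity(idx, q, d, alpha = 0.01)
      expect_lte(s, length(q) * 0.01 + 1e-15)
      extra <- setdiff(ann, q)
      if (length(extra)) {
        expect_gte(rbp_similarity(idx, c(q, extra[1]), d, alpha = 0.01),
                   s - 1e-15)
      }
      expect_equal(s, oracle_rbp(cs$ontology$parents, cs$direct, q, d),
                   tolerance = 1e-12)
    }
    # with alpha >= 1 a one-term query ranks by closure membership alone
    t1 <- sample(ann, 1)
    s1 <- score_all_diseases(idx, cs$ontology, t1, "rbp", alpha = 1)
    member <- names(s1)[s1 > 0]
    expect_setequal(member, idx$closure[[t1]])
  }
})

test_that("rank_diseases canonicalises queries end to end", {
  ont <- parse_obo(c("[Term]", "id: R",
                     "[Term]", "id: A", "is_a: R", "alt_id: A_alt",
                     "[Term]", "id: B", "is_a: R"))
  idx <- build_index(ont, list(d1 = "A", d2 = "B"))
  expect_warning(r <- rank_diseases(idx, ont, c("A_alt", "HP:404"),
                                    method = "rbp", alpha = 1),
                 "dropped")
  expect_equal(attr(r, "query"), "A")
  expect_equal(rank_of_disease(r, "d1"), 1)
})
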