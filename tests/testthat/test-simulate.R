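test_that("phenotype retention follows the profile frequencies", {
  prof_all <- list(disease = "OMIM:1", terms = paste0("t", 1:5),
                   freq = rep(1, 5))
  set.seed(1)
  p <- simulate_patient(prof_all)
  expect_s3_class(p, "phen_patient")
  expect_setequal(p$terms, prof_all$terms)
  expect_equal(p$variant, "clean")

  # a frequency-0 phenotype can never be kept; with only two live
  # phenotypes the three-term floor is unreachable
  prof_dead <- list(disease = "OMIM:2", terms = paste0("t", 1:3),
                    freq = c(1, 1, 0))
  set.seed(1)
  expect_error(simulate_patient(prof_dead, max_attempts = 50L),
               "within 50 attempts")

  # empirical keep rate within 3 binomial SE of the frequency
  # (unconditioned draws: floor disabled by min_terms = 0)
  prof <- list(disease = "OMIM:3", terms = paste0("t", 1:10),
               freq = rep(0.5, 10))
  set.seed(42)
  n_rep <- 2000L
  kept <- replicate(n_rep, {
    length(simulate_patient(prof, min_terms = 0L)$terms)
  })
  p_hat <- mean(kept) / 10
  se <- sqrt(0.5 * 0.5 / (n_rep * 10))
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("imprecision substitutes uniformly chosen non-root ancestors", {
  ont <- toy$ontology
  mk <- function(terms) {
    structure(list(patient_id = "p", true_disease = "d1", terms = terms,
                   variant = "clean"), class = "phen_patient")
  }
  set.seed(7)
  draws <- replicate(4000, add_imprecision(mk("C"), ont)$terms)
  expect_true(all(draws %in% c("A", "B")))   # root excluded
  tab <- table(factor(draws, levels = c("A", "B")))
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 1e-4)

  # a term whose only proper ancestor is the root is kept unchanged
  expect_equal(add_imprecision(mk("A"), ont)$terms, "A")
  # coinciding images collapse to a set
  set.seed(1)
  expect_equal(add_imprecision(mk(c("A", "B")), ont)$terms, c("A", "B"))
  expect_equal(add_imprecision(mk("C"), ont)$variant, "imprecise")
})

test_that("noise adds ceiling(n/2) unrelated annotated terms", {
  cs <- random_case(5, n_terms = 60L, n_diseases = 8L)
  mk <- function(terms, d) {
    structure(list(patient_id = "p", true_disease = d, terms = terms,
                   variant = "clean"), class = "phen_patient")
  }
  d <- names(cs$direct)[1]
  t4 <- cs$direct[[d]][1:3]
  set.seed(11)
  p3 <- add_noise(mk(t4, d), cs$ontology, cs$index)
  expect_length(p3$terms, 3 + 2)            # ceiling(3/2) = 2
  expect_equal(p3$variant, "noise")
  p3f <- add_noise(mk(t4, d), cs$ontology, cs$index, round_up = FALSE)
  expect_length(p3f$terms, 3 + 1)

  related <- unique(unlist(lapply(cs$direct[[d]], function(t) {
    c(t, cs$ontology$anc[[t]])
  })))
  for (rep in 1:200) {
    p <- add_noise(mk(t4, d), cs$ontology, cs$index)
    added <- setdiff(p$terms, t4)
    expect_length(added, 2L)
    expect_false(any(added %in% related))
    expect_true(all(cs$index$N_t[added] > 0L))
    expect_false(cs$ontology$root %in% added)
  }

  # pool exhaustion errors clearly on tiny fixtures
  expect_error(add_noise(mk("C", "d1"), toy$ontology, toy$index),
               "noise pool too small")
})

test_that("cohorts are reproducible and respect the corruption pipeline", {
  cs <- random_case(9, n_terms = 60L, n_diseases = 8L)
  profs <- lapply(cs$profiles, function(p) {
    p$freq <- rep(1, length(p$freq)); p
  })
  c1 <- generate_cohort(profs, cs$ontology, cs$index, per_disease = 3L,
                        variant = "noise+imprecise", seed = 123L)
  c2 <- generate_cohort(profs, cs$ontology, cs$index, per_disease = 3L,
                        variant = "noise+imprecise", seed = 123L)
  expect_identical(c1, c2)
  expect_length(c1, 8L * 3L)

  clean <- generate_cohort(profs, cs$ontology, per_disease = 3L,
                           variant = "clean", seed = 123L)
  for (i in seq_along(clean)) {
    p <- clean[[i]]
    expect_gte(length(p$terms), 3L)
    expect_true(all(p$terms %in% profs[[p$true_disease]]$terms))
    expect_equal(p$variant, "clean")
  }

  # imprecision precedes noise: every non-noise term is an ancestor-or-self
  # of a profile term, and the noise count matches the post-imprecision size
  imp <- generate_cohort(profs, cs$ontology, cs$index, per_disease = 3L,
                         variant = "imprecise", seed = 123L)
  for (p in imp) {
    prof_terms <- profs[[p$true_disease]]$terms
    anc_or_self <- unique(unlist(lapply(prof_terms, function(t) {
      c(t, cs$ontology$anc[[t]])
    })))
    expect_true(all(p$terms %in% anc_or_self))
  }
  both <- generate_cohort(profs, cs$ontology, cs$index, per_disease = 3L,
                          variant = "noise+imprecise", seed = 123L)
  for (i in seq_along(both)) {
    n_imp <- length(imp[[i]]$terms)  # same substream -> same imprecise set
    expect_length(both[[i]]$terms, n_imp + ceiling(n_imp / 2))
    expect_true(all(imp[[i]]$terms %in% both[[i]]$terms))
  }

  expect_error(generate_cohort(profs, cs$ontology, index = NULL,
                               variant = "noise", seed = 1L),
               "index is required")
})

test_that("profiles and cohorts round-trip through their TSV formats", {
  cs <- random_case(3)
  f_prof <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(cs$profiles, f_prof)
  back <- read_profiles(f_prof, cs$ontology)
  expect_setequal(names(back), names(cs$profiles))
  for (d in names(back)) {
    expect_equal(back[[d]]$terms, cs$profiles[[d]]$terms)
    expect_equal(back[[d]]$freq, cs$profiles[[d]]$freq, tolerance = 1e-6)
  }

  cohort <- generate_cohort(cs$profiles, cs$ontology, cs$index,
                            per_disease = 2L, variant = "clean", seed = 4L)
  f_pat <- withr::local_tempfile(fileext = ".tsv")
  write_patients(cohort, f_pat, metadata = c(seed = "4"))
  back2 <- read_patients(f_pat)
  expect_equal(length(back2), length(cohort))
  expect_identical(back2[[1]]$terms, cohort[[1]]$terms)
  expect_identical(back2[[1]]$true_disease, cohort[[1]]$true_disease)
  expect_true(any(startsWith(readLines(f_pat), "# seed: 4")))
})
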