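#' Simulate one clean patient from a disease frequency profile
#'
#' Each phenotype of the profile is kept independently according to its
#' population frequency: a random integer uniform on \{0, ..., 99\} is drawn
#' and the phenotype is kept iff the draw is smaller than frequency * 100,
#' so the keep probability equals the frequency exactly (when
#' frequency * 100 is an integer). The whole draw is repeated until at
#' least `min_terms` phenotypes survive, matching the requirement that
#' simulated patients present at least three phenotypes.
#'
#' @param profile A list with `disease` (disease id), `terms` (character)
#'   and `freq` (numeric in \[0, 1\], same length).
#' @param min_terms Minimum surviving phenotypes per patient (default 3).
#' @param max_attempts Retry budget before giving up (default 10000).
#' @param patient_id Identifier for the generated patient.
#' @return A `phen_patient`: list with `patient_id`, `true_disease`,
#'   `terms` (character set) and `variant = "clean"`.
#' @export
simulate_patient <- function(profile, min_terms = 3L, max_attempts = 10000L,
                             patient_id = "patient") {
  stopifnot(length(profile$terms) == length(profile$freq),
            all(profile$freq >= 0 & profile$freq <= 1))
  if (!length(profile$terms)) stop("empty disease profile")
  n <- length(profile$terms)
  for (attempt in seq_len(max_attempts)) {
    draws <- sample.int(100L, n, replace = TRUE) - 1L
    keep <- draws < profile$freq * 100
    if (sum(keep) >= min_terms) {
      return(structure(list(patient_id = patient_id,
                            true_disease = profile$disease,
                            terms = unique(profile$terms[keep]),
                            variant = "clean"),
                       class = "phen_patient"))
    }
  }
  stop("could not draw ", min_terms, " phenotypes for ", profile$disease,
       " within ", max_attempts, " attempts")
}

#' Make a patient's phenotypes less precise
#'
#' Replaces every present phenotype with one of its proper ancestors,
#' chosen uniformly, emulating a clinician who records a more general
#' abnormality than the patient actually shows. The ontology root is
#' excluded from the candidate pool (a term every patient trivially has
#' carries no signal); a phenotype whose only proper ancestor is the root
#' is kept unchanged. The resulting term set is deduplicated.
#'
#' @param patient A `phen_patient`.
#' @param ontology A `phen_ontology`.
#' @return A `phen_patient` with variant `"imprecise"` (or
#'   `"noise+imprecise"` if noise was already applied).
#' @export
add_imprecision <- function(patient, ontology) {
  new_terms <- vapply(patient$terms, function(t) {
    pool <- setdiff(ontology$anc[[t]], ontology$root)
    if (!length(pool)) t else pool[sample.int(length(pool), 1L)]
  }, character(1))
  patient$terms <- unique(unname(new_terms))
  patient$variant <- if (grepl("noise", patient$variant)) "noise+imprecise"
                     else "imprecise"
  patient
}

#' Add unrelated noise phenotypes to a patient
#'
#' Adds half as many noise terms as the patient presently has (rounded up
#' for odd counts by default), sampled uniformly without replacement from
#' terms unrelated to the underlying disease. The candidate pool contains
#' annotated, non-root terms that are not already present and that are not
#' related to the true disease, where "related" is controlled by
#' `unrelated_mode`:
#'
#' * `"closure"` (default): excludes the disease's direct annotation terms
#'   and all their ancestors (the closed annotation term set).
#' * `"strict"`: additionally excludes all ancestors of the patient's
#'   present terms.
#' * `"loose"`: excludes only the direct annotation terms.
#'
#' @param patient A `phen_patient`.
#' @param ontology A `phen_ontology`.
#' @param index A `phen_index` (defines which terms are annotated and the
#'   true disease's annotation set).
#' @param unrelated_mode How aggressively to exclude disease-related terms.
#' @param round_up Use ceiling(n/2) noise terms (default); `FALSE` uses
#'   floor(n/2).
#' @return A `phen_patient` with `"noise"` appended to its variant.
#' @export
add_noise <- function(patient, ontology, index,
                      unrelated_mode = c("closure", "strict", "loose"),
                      round_up = TRUE) {
  unrelated_mode <- match.arg(unrelated_mode)
  n <- length(patient$terms)
  stopifnot(n >= 1L)
  k <- if (round_up) ceiling(n / 2) else floor(n / 2)

  direct <- index$direct[[patient$true_disease]]
  related <- switch(unrelated_mode,
    loose = direct,
    closure = unique(unlist(lapply(direct, function(t) {
      c(t, ontology$anc[[t]])
    }), use.names = FALSE)),
    strict = unique(c(
      unlist(lapply(direct, function(t) c(t, ontology$anc[[t]])),
             use.names = FALSE),
      unlist(lapply(patient$terms, function(t) c(t, ontology$anc[[t]])),
             use.names = FALSE)))
  )
  pool <- names(index$closure)
  pool <- setdiff(pool, c(related, patient$terms, ontology$root))
  if (length(pool) < k) {
    stop("noise pool too small: need ", k, " unrelated terms, have ",
         length(pool))
  }
  noise <- pool[sample.int(length(pool), k)]
  patient$terms <- c(patient$terms, noise)
  patient$variant <- switch(patient$variant,
    clean = "noise",
    imprecise = "noise+imprecise",
    patient$variant)
  patient
}

#' Generate a reproducible cohort of simulated patients
#'
#' Draws `per_disease` patients from each frequency profile and applies the
#' requested corruption pipeline: clean -> imprecision (if any) -> noise
#' (if any). Imprecision is applied before noise, so the number of noise
#' terms is computed from the post-imprecision term count. Each patient is
#' generated under its own deterministically derived RNG substream, so
#' cohorts are reproducible byte-for-byte from `seed` and individual
#' patients do not depend on generation order.
#'
#' @param profiles List of disease profiles (see [simulate_patient()]).
#' @param ontology A `phen_ontology`.
#' @param index A `phen_index` (needed for the noise pool; may be `NULL`
#'   for clean or imprecise-only cohorts).
#' @param per_disease Patients per profile (default 25).
#' @param variant One of `"clean"`, `"noise"`, `"imprecise"`,
#'   `"noise+imprecise"`.
#' @param seed Integer seed for the cohort.
#' @param min_terms Minimum phenotypes per clean patient (default 3).
#' @param unrelated_mode Passed to [add_noise()].
#' @return List of `phen_patient` objects, length
#'   `length(profiles) * per_disease`.
#' @export
generate_cohort <- function(profiles, ontology, index = NULL,
                            per_disease = 25L,
                            variant = c("clean", "noise", "imprecise",
                                        "noise+imprecise"),
                            seed = 1L, min_terms = 3L,
                            unrelated_mode = "closure") {
  variant <- match.arg(variant)
  stopifnot(per_disease >= 1L)
  if (grepl("noise", variant) && is.null(index)) {
    stop("an annotation index is required to sample noise terms")
  }
  n_total <- length(profiles) * per_disease
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  substreams <- sample.int(.Machine$integer.max, n_total)

  cohort <- vector("list", n_total)
  i <- 0L
  for (profile in profiles) {
    for (j in seq_len(per_disease)) {
      i <- i + 1L
      set.seed(substreams[i])
      pid <- sprintf("%s_p%02d", profile$disease, j)
      p <- simulate_patient(profile, min_terms = min_terms, patient_id = pid)
      if (grepl("imprecise", variant)) p <- add_imprecision(p, ontology)
      if (grepl("noise", variant)) {
        p <- add_noise(p, ontology, index, unrelated_mode = unrelated_mode)
      }
      p$variant <- variant
      cohort[[i]] <- p
    }
  }
  cohort
}

#' @export
print.phen_patient <- function(x, ...) {
  cat("phen_patient ", x$patient_id, " [", x$variant, "] true disease ",
      x$true_disease, ": ", paste(x$terms, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read disease frequency profiles from TSV
#'
#' Expects tab-separated columns `disease_id`, `term_id`, `frequency`
#' (header optional; lines starting with `#` ignored). Term ids are
#' canonicalised if an ontology is supplied.
#'
#' @param file Path to the TSV file.
#' @param ontology Optional `phen_ontology` for canonicalisation.
#' @return List of profiles: each a list with `disease`, `terms`, `freq`.
#' @export
read_profiles <- function(file, ontology = NULL) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && grepl("^disease_id\t", lines[[1L]])) {
    lines <- lines[-1L]
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 3L, logical(1))
  if (any(bad)) warning(sum(bad), " malformed profile row(s) skipped")
  parts <- parts[!bad]
  if (!length(parts)) stop("no profile rows found")
  df <- data.frame(disease = vapply(parts, `[[`, character(1), 1L),
                   term = vapply(parts, `[[`, character(1), 2L),
                   freq = as.numeric(vapply(parts, `[[`, character(1), 3L)),
                   stringsAsFactors = FALSE)
  if (anyNA(df$freq) || any(df$freq < 0 | df$freq > 1)) {
    stop("frequencies must be numeric in [0, 1]")
  }
  if (!is.null(ontology)) df$term <- resolve_term(ontology, df$term)
  lapply(split(df, df$disease), function(g) {
    g <- g[!duplicated(g$term), ]
    list(disease = g$disease[[1L]], terms = g$term, freq = g$freq)
  })
}

#' Write disease frequency profiles to TSV
#'
#' @param profiles List of profiles.
#' @param file Output path.
#' @export
write_profiles <- function(profiles, file) {
  rows <- unlist(lapply(profiles, function(p) {
    paste(p$disease, p$terms, format(p$freq, trim = TRUE), sep = "\t")
  }), use.names = FALSE)
  writeLines(c("disease_id\tterm_id\tfrequency", rows), file)
}

#' Write a simulated cohort to TSV
#'
#' One row per patient: `patient_id`, `variant`, `true_disease`, then the
#' comma-separated term ids. Metadata (seed, parameters) can be recorded as
#' `#`-prefixed header lines.
#'
#' @param cohort List of `phen_patient`.
#' @param file Output path.
#' @param metadata Named character vector written as `# name: value` lines.
#' @export
write_patients <- function(cohort, file, metadata = NULL) {
  hdr <- character(0)
  if (!is.null(metadata)) {
    hdr <- paste0("# ", names(metadata), ": ", metadata)
  }
  rows <- vapply(cohort, function(p) {
    paste(p$patient_id, p$variant, p$true_disease,
          paste(p$terms, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(c(hdr, "patient_id\tvariant\ttrue_disease\tterms", rows), file)
}

#' Read a simulated cohort from TSV
#'
#' @param file Path written by [write_patients()].
#' @return List of `phen_patient`.
#' @export
read_patients <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) && startsWith(lines[[1L]], "patient_id\t")) {
    lines <- lines[-1L]
  }
  lapply(strsplit(lines, "\t", fixed = TRUE), function(p) {
    if (length(p) < 4L) stop("malformed patient row")
    structure(list(patient_id = p[[1L]], true_disease = p[[3L]],
                   terms = strsplit(p[[4L]], ",", fixed = TRUE)[[1L]],
                   variant = p[[2L]]),
              class = "phen_patient")
  })
}
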