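#' Random rooted DAG ontology generator
#'
#' Builds a random is_a DAG for testing: term 1 is the root, and every
#' later term i draws between 1 and `max_parents` parents uniformly from
#' the terms generated before it, which guarantees acyclicity and
#' reachability of the root. With `max_parents = 1` the result is a tree.
#' Term ids follow the `"T:%04d"` pattern.
#'
#' @param n_terms Number of terms (>= 2).
#' @param max_parents Maximum parents per non-root term (>= 1).
#' @param seed Optional integer seed.
#' @return A `phen_ontology`.
#' @export
gen_ontology <- function(n_terms, max_parents = 2L, seed = NULL) {
  stopifnot(n_terms >= 2L, max_parents >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("T:%04d", seq_len(n_terms))
  terms <- list()
  terms[[ids[1L]]] <- list(id = ids[1L], name = "root",
                           parent_ids = character(0),
                           alt_ids = character(0), obsolete = FALSE)
  for (i in seq.int(2L, n_terms)) {
    k <- sample.int(min(max_parents, i - 1L), 1L)
    parents <- ids[sample.int(i - 1L, k)]
    terms[[ids[i]]] <- list(id = ids[i], name = paste0("term ", i),
                            parent_ids = parents,
                            alt_ids = character(0), obsolete = FALSE)
  }
  build_ontology(terms)
}

#' Random annotation corpus and matching frequency profiles
#'
#' Annotates each synthetic disease to a uniform sample of non-root terms,
#' with per-phenotype frequencies drawn uniformly from `freq_range`. The
#' returned profiles mirror the annotations so the simulator and the
#' ranking corpus agree. Disease ids follow `"OMIM:6%05d"`.
#'
#' @param ontology A `phen_ontology`.
#' @param n_diseases Number of diseases (>= 1).
#' @param terms_per_disease Integer range `c(min, max)` of annotation-set
#'   sizes; the minimum must be >= 3 so the simulator's at-least-three
#'   floor is satisfiable at frequency 1.
#' @param freq_range Numeric interval in \[0, 1\] for phenotype frequencies.
#' @param seed Optional integer seed.
#' @param disjoint If `TRUE`, disease annotation sets are disjoint (used
#'   for planted-disease recovery checks); requires enough non-root terms.
#' @return A list with `direct` (annotation map for [build_index()]) and
#'   `profiles` (list for [generate_cohort()]).
#' @export
gen_annotations <- function(ontology, n_diseases = 5L,
                            terms_per_disease = c(3L, 6L),
                            freq_range = c(0.3, 1), seed = NULL,
                            disjoint = FALSE) {
  stopifnot(n_diseases >= 1L, length(terms_per_disease) == 2L,
            terms_per_disease[1L] >= 3L,
            terms_per_disease[2L] >= terms_per_disease[1L],
            all(freq_range >= 0 & freq_range <= 1))
  if (!is.null(seed)) set.seed(seed)
  pool <- setdiff(ontology$ids, ontology$root)
  if (disjoint && length(pool) < n_diseases * terms_per_disease[2L]) {
    stop("not enough non-root terms for disjoint annotation sets")
  }
  if (length(pool) < terms_per_disease[2L]) {
    stop("terms_per_disease exceeds available non-root terms")
  }
  direct <- list()
  profiles <- list()
  avail <- pool
  for (i in seq_len(n_diseases)) {
    d <- sprintf("OMIM:6%05d", i)
    k <- sample(seq.int(terms_per_disease[1L], terms_per_disease[2L]), 1L)
    src <- if (disjoint) avail else pool
    ts <- src[sample.int(length(src), k)]
    if (disjoint) avail <- setdiff(avail, ts)
    direct[[d]] <- ts
    profiles[[d]] <- list(disease = d, terms = ts,
                          freq = stats::runif(k, freq_range[1L], freq_range[2L]))
  }
  list(direct = direct, profiles = profiles)
}

#' Hand-verified four-term diamond fixture
#'
#' The smallest fixture on which every measure in the package has a
#' closed-form value: root R with children A and B, and C a child of both
#' (a diamond), annotated by four diseases d1 -> \{C\}, d2 -> \{A\},
#' d3 -> \{B\}, d4 -> \{R\}. With N = 4 this gives IC(R) = 0,
#' IC(A) = IC(B) = ln 2 and IC(C) = ln 4.
#'
#' @return A list with `ontology`, `direct`, `index`.
#' @export
toy_fixture <- function() {
  obo <- c(
    "[Term]", "id: R", "name: root", "",
    "[Term]", "id: A", "name: a", "is_a: R ! root", "",
    "[Term]", "id: B", "name: b", "is_a: R ! root", "",
    "[Term]", "id: C", "name: c", "is_a: A ! a", "is_a: B ! b")
  ont <- parse_obo(obo)
  direct <- list(d1 = "C", d2 = "A", d3 = "B", d4 = "R")
  list(ontology = ont, direct = direct, index = build_index(ont, direct))
}

#' Serialise an ontology to OBO flat-file text
#'
#' Writes `[Term]` stanzas with `id`, `name` and `is_a` lines that
#' round-trip through [parse_obo()].
#'
#' @param ontology A `phen_ontology`.
#' @param file Output path, or `NULL` to return the lines.
#' @return Invisibly (or visibly when `file` is `NULL`) the OBO text lines.
#' @export
write_obo <- function(ontology, file = NULL) {
  lines <- c("format-version: 1.2", "")
  for (id in ontology$ids) {
    ps <- ontology$parents[[id]]
    lines <- c(lines, "[Term]", paste0("id: ", id),
               paste0("name: ", ontology$name[[id]]),
               if (length(ps)) paste0("is_a: ", ps), "")
  }
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Serialise an annotation map to classic HPOA-dialect TSV
#'
#' One row per (disease, term) pair in the classic column-positional
#' dialect (DB, DB_Object_ID, DB_Name, Qualifier, HPO_ID, ...), consumable
#' by [parse_annotations()].
#'
#' @param direct Named list: disease id (`"DB:accession"`) -> term ids.
#' @param file Output path, or `NULL` to return the lines.
#' @return Invisibly (or visibly when `file` is `NULL`) the TSV lines.
#' @export
write_annotations <- function(direct, file = NULL) {
  rows <- unlist(lapply(names(direct), function(d) {
    db <- sub(":.*$", "", d)
    acc <- sub("^[^:]+:", "", d)
    paste(db, acc, paste0("disease ", acc), "", direct[[d]],
          "", "", "", sep = "\t")
  }), use.names = FALSE)
  if (is.null(file)) return(rows)
  writeLines(rows, file)
  invisible(rows)
}
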