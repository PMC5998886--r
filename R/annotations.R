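#' Parse a disease–phenotype annotation file
#'
#' Reads HPOA-style tab-separated annotations in either dialect:
#' the classic column-positional small file (DB, DB_Object_ID, DB_Name,
#' Qualifier, HPO_ID, ...) with no header, or the newer header-bearing file
#' (database_id, disease_name, qualifier, hpo_id, ...). The dialect is
#' auto-detected from the first non-comment line.
#'
#' Rows are filtered to one disease namespace (default `"OMIM"`), term ids
#' are canonicalised through alt_ids, rows with a `NOT` qualifier are
#' dropped, and duplicate (disease, term) pairs are collapsed. Rows whose
#' term id cannot be resolved (unknown or obsolete) are skipped with a
#' warning giving the count.
#'
#' @param file Path to the TSV file, or a character vector of its lines.
#' @param ontology A `phen_ontology` used to canonicalise term ids.
#' @param namespace_filter Database namespace to keep (matched against the
#'   prefix of the disease id); default `"OMIM"`.
#' @return Named list: disease id (`"OMIM:123456"`) -> character vector of
#'   canonical term ids directly annotated to that disease.
#' @export
parse_annotations <- function(file, ontology, namespace_filter = "OMIM") {
  if (length(file) == 1L && !grepl("[\n\t]", file)) {
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no annotation rows found")

  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  new_dialect <- any(tolower(header) %in% c("database_id", "hpo_id"))
  if (new_dialect) {
    cols <- tolower(header)
    rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
    i_db <- match("database_id", cols)
    i_qual <- match("qualifier", cols)
    i_term <- match("hpo_id", cols)
    if (is.na(i_db) || is.na(i_term)) stop("malformed annotation header")
    get <- function(r, i) if (!is.na(i) && length(r) >= i) r[[i]] else ""
    recs <- lapply(rows, function(r) {
      c(disease = get(r, i_db), qualifier = get(r, i_qual),
        term = get(r, i_term))
    })
  } else {
    rows <- strsplit(lines, "\t", fixed = TRUE)
    recs <- lapply(rows, function(r) {
      if (length(r) < 5L) return(NULL)
      c(disease = paste0(r[[1L]], ":", r[[2L]]), qualifier = r[[4L]],
        term = r[[5L]])
    })
  }
  malformed <- sum(vapply(recs, is.null, logical(1)))
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (malformed > 0L) warning(malformed, " malformed row(s) skipped")

  m <- do.call(rbind, recs)
  if (is.null(m) || nrow(m) == 0L) stop("no parsable annotation rows")
  keep <- startsWith(m[, "disease"], paste0(namespace_filter, ":"))
  m <- m[keep, , drop = FALSE]
  m <- m[toupper(trimws(m[, "qualifier"])) != "NOT", , drop = FALSE]

  # canonicalise; skip (with count) unknown/obsolete term ids
  ids <- m[, "term"]
  mapped <- ifelse(ids %in% names(ontology$alt), ontology$alt[ids], ids)
  ok <- mapped %in% ontology$ids & !(mapped %in% ontology$obsolete)
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with unresolvable term ids skipped")
  }
  m <- m[ok, , drop = FALSE]
  mapped <- mapped[ok]
  if (nrow(m) == 0L) stop("zero annotation rows survived filtering")

  direct <- split(mapped, m[, "disease"])
  lapply(direct, unique)
}

#' Build the annotation index: disease closures and information content
#'
#' Propagates each direct disease–term annotation up the ontology (the
#' true-path rule): a disease directly annotated to term t belongs to the
#' disease closure D(a) of every ancestor a of t. Equivalently, D(t) is the
#' union of direct annotations over t and all of its descendants. From the
#' closure sizes the information content of every term is computed as
#' IC(t) = -log(N_t / N) in natural log units (nats), where N is the number
#' of annotated diseases and N_t = |D(t)|.
#'
#' @param ontology A `phen_ontology`.
#' @param direct Named list: disease id -> character vector of canonical
#'   term ids (as returned by [parse_annotations()]).
#' @return An object of class `phen_index`: a list with `direct` (the input,
#'   deduplicated), `closure` (named list term -> disease ids D(t); terms
#'   with empty closure are absent), `diseases` (all disease ids), `N`,
#'   `N_t` (named integer per term, 0 for unannotated terms), and `ic`
#'   (named numeric per annotated term, in nats).
#' @export
build_index <- function(ontology, direct) {
  if (length(direct) == 0L) stop("empty annotation map")
  direct <- lapply(direct, unique)
  diseases <- names(direct)

  closure_env <- new.env(parent = emptyenv())
  for (d in diseases) {
    terms <- direct[[d]]
    up <- unique(unlist(lapply(terms, function(t) c(t, ontology$anc[[t]])),
                        use.names = FALSE))
    for (t in up) {
      closure_env[[t]] <- c(closure_env[[t]], d)
    }
  }
  closure <- as.list(closure_env)
  closure <- lapply(closure, unique)

  N <- length(diseases)
  N_t <- setNames(integer(length(ontology$ids)), ontology$ids)
  nn <- vapply(closure, length, integer(1))
  N_t[names(nn)] <- nn
  ic <- -log(nn / N)
  structure(list(direct = direct, closure = closure, diseases = diseases,
                 N = N, N_t = N_t, ic = ic, log_base = "e"),
            class = "phen_index")
}

#' @export
print.phen_index <- function(x, ...) {
  cat("phen_index: ", x$N, " diseases, ",
      sum(x$N_t > 0L), " annotated terms (natural-log IC)\n", sep = "")
  invisible(x)
}

#' Information content of a term
#'
#' IC(t) = -log(N_t / N) in nats; 0 for the root (whose closure contains
#' every annotated disease under true-path propagation).
#'
#' @param index A `phen_index`.
#' @param id Canonical term id.
#' @return Non-negative numeric scalar.
#' @export
information_content <- function(index, id) {
  nt <- index$N_t[id]
  if (is.na(nt)) stop("term not in index: ", id)
  if (nt == 0L) {
    stop("unannotated term (no annotated descendant): ", id)
  }
  unname(index$ic[id])
}

annotated_terms <- function(index) names(index$closure)

#' Most informative common ancestor of two terms
#'
#' Among the common ancestors of `t1` and `t2` (each taken inclusive of the
#' term itself), returns the one with maximal information content. Ties are
#' broken by lexicographically smallest term id so results are
#' deterministic. Both terms must be annotated (N_t > 0).
#'
#' @param index A `phen_index`.
#' @param ontology A `phen_ontology`.
#' @param t1,t2 Canonical term ids.
#' @return A term id.
#' @export
mica <- function(index, ontology, t1, t2) {
  for (t in c(t1, t2)) {
    if (is.na(index$N_t[t])) stop("term not in index: ", t)
    if (index$N_t[t] == 0L) stop("unannotated term: ", t)
  }
  common <- intersect(c(t1, ontology$anc[[t1]]), c(t2, ontology$anc[[t2]]))
  if (!length(common)) {
    stop("internal consistency error: no common ancestor in rooted DAG")
  }
  ics <- index$ic[common]
  best <- common[ics == max(ics)]
  sort(best)[1L]
}
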