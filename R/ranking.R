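#' Per-term disease score S(D|t)
#'
#' The building block of RelativeBestPair: given that a patient shows term
#' t, the score of disease D is 1/N_t if D lies in the annotation closure
#' D(t) (D is annotated by t or any descendant of t), and 0 otherwise. The
#' scores for a term thus form a probability-like distribution over
#' diseases: they sum to exactly 1 over the corpus.
#'
#' A term annotating no disease supports none; it scores 0 for every
#' disease, with a warning.
#'
#' @param index A `phen_index`.
#' @param t Canonical term id.
#' @param d Disease id.
#' @return Numeric scalar in \[0, 1\].
#' @export
term_disease_score <- function(index, t, d) {
  nt <- index$N_t[t]
  if (is.na(nt)) stop("term not in index: ", t)
  if (nt == 0L) {
    warning("term annotates no disease, scores 0 everywhere: ", t)
    return(0)
  }
  if (d %in% index$closure[[t]]) 1 / unname(nt) else 0
}

#' RelativeBestPair similarity from a query term set to one disease
#'
#' Sums, over the query terms, each term's per-disease score capped at the
#' threshold alpha:
#' Sim(D | t_1..t_n) = sum_i min(alpha, S(D | t_i)).
#' The cap stops a single very specific term (large 1/N_t) from dominating
#' the sum and drowning out the agreement of many other terms. The score is
#' bounded above by |Q| * alpha.
#'
#' @param index A `phen_index`.
#' @param query Nonempty character vector of canonical term ids.
#' @param d Disease id.
#' @param alpha Per-term contribution cap, in (0, 1]; default 0.01.
#' @return Numeric scalar in \[0, |Q| * alpha\].
#' @export
rbp_similarity <- function(index, query, d, alpha = 0.01) {
  query <- unique(query)
  if (!length(query)) stop("empty query term set")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must be a single number in (0, 1]")
  }
  s <- vapply(query, function(t) {
    nt <- index$N_t[t]
    if (is.na(nt) || nt == 0L) return(0)  # unannotated terms contribute 0
    if (d %in% index$closure[[t]]) min(alpha, 1 / unname(nt)) else 0
  }, numeric(1))
  sum(s)
}

#' Score every disease in the corpus against a query
#'
#' For `method = "rbp"` each disease receives its RelativeBestPair score;
#' for the seven classical measures each disease receives the one-sided
#' best-match similarity of the query against the disease's annotation
#' term set (its direct annotations by default; set `use_closure = TRUE`
#' to match against the closed set of the disease's terms and all their
#' ancestors).
#'
#' @param index A `phen_index`.
#' @param ontology A `phen_ontology`.
#' @param query Nonempty character vector of canonical term ids.
#' @param method `"rbp"` or one of `"resnik"`, `"lin"`, `"jc"`, `"rel"`,
#'   `"ic"`, `"graphic"`, `"wang"`.
#' @param alpha RelativeBestPair cap (used only by `"rbp"`).
#' @param w_e Wang edge weight (used only by `"wang"`).
#' @param use_closure Match disease term sets as closures rather than
#'   direct annotations (classical measures only).
#' @return Named numeric vector: disease id -> score, covering every
#'   disease in the corpus.
#' @export
score_all_diseases <- function(index, ontology, query, method = "rbp",
                               alpha = 0.01, w_e = 0.8,
                               use_closure = FALSE) {
  valid <- c("rbp", measure_names)
  if (!is.character(method) || length(method) != 1L || !method %in% valid) {
    stop("unknown method '", method, "'; valid methods: ",
         paste(valid, collapse = ", "))
  }
  query <- unique(query)
  if (!length(query)) stop("empty query term set")

  if (method == "rbp") {
    scores <- setNames(numeric(length(index$diseases)), index$diseases)
    for (t in query) {
      nt <- index$N_t[t]
      if (is.na(nt) || nt == 0L) next
      hit <- index$closure[[t]]
      scores[hit] <- scores[hit] + min(alpha, 1 / unname(nt))
    }
    return(scores)
  }

  dsets <- index$direct
  if (use_closure) {
    dsets <- lapply(dsets, function(ts) {
      unique(unlist(lapply(ts, function(t) c(t, ontology$anc[[t]])),
                    use.names = FALSE))
    })
  }
  if (method != "wang") {
    q_eff <- query[!is.na(index$N_t[query]) & index$N_t[query] > 0L]
    if (length(q_eff) < length(query)) {
      warning(length(query) - length(q_eff),
              " unannotated query term(s) skipped")
    }
    if (!length(q_eff)) {
      return(setNames(numeric(length(index$diseases)), index$diseases))
    }
  } else {
    q_eff <- query
  }

  # pairwise similarities are cached over the distinct disease terms so a
  # full-corpus scan costs |Q| x |distinct terms| evaluations, not
  # |Q| x sum of term-set sizes
  all_terms <- unique(unlist(dsets, use.names = FALSE))
  if (method != "wang") {
    all_terms <- all_terms[!is.na(index$N_t[all_terms]) &
                             index$N_t[all_terms] > 0L]
  }
  simmat <- matrix(0, nrow = length(q_eff), ncol = length(all_terms),
                   dimnames = list(q_eff, all_terms))
  for (q in q_eff) {
    for (t in all_terms) {
      simmat[q, t] <- term_similarity(index, ontology, q, t,
                                      measure = method, w_e = w_e)
    }
  }
  vapply(dsets[index$diseases], function(ts) {
    ts <- intersect(ts, all_terms)
    if (!length(ts)) return(0)
    mean(apply(simmat[, ts, drop = FALSE], 1L, max))
  }, numeric(1))
}

#' Rank diseases with tie-averaged ranks
#'
#' Orders diseases by score, largest first. Diseases sharing a score all
#' receive the mean of the integer ranks their block spans (so the ranks
#' over M diseases always sum to M(M+1)/2). Output order is deterministic:
#' score descending, then disease id ascending.
#'
#' @param scores Named numeric vector: disease id -> score.
#' @return A data.frame with columns `disease`, `score`, `rank`.
#' @export
rank_with_ties <- function(scores) {
  if (!length(scores)) stop("empty score map")
  rk <- rank(-scores, ties.method = "average")
  ord <- order(-scores, names(scores))
  data.frame(disease = names(scores)[ord],
             score = unname(scores[ord]),
             rank = unname(rk[ord]),
             stringsAsFactors = FALSE)
}

#' Rank of one disease in a ranking
#'
#' @param ranked A data.frame from [rank_with_ties()].
#' @param d Disease id.
#' @return Numeric rank (fractional under ties).
#' @export
rank_of_disease <- function(ranked, d) {
  i <- match(d, ranked$disease)
  if (is.na(i)) stop("disease not in ranking: ", d)
  ranked$rank[i]
}

#' Rank the disease corpus for a phenotype query
#'
#' One-call front end: canonicalises the query (alt ids replaced, unknown
#' and obsolete ids dropped with a warning), scores every disease with the
#' chosen method and returns the tie-averaged ranking.
#'
#' @inheritParams score_all_diseases
#' @param query Character vector of query term ids (alt ids accepted).
#' @return A data.frame as from [rank_with_ties()], with the canonicalised
#'   query attached as attribute `"query"`.
#' @export
rank_diseases <- function(index, ontology, query, method = "rbp",
                          alpha = 0.01, w_e = 0.8, use_closure = FALSE) {
  cq <- canonicalize_query(ontology, query)
  if (length(cq$dropped)) {
    warning("dropped unresolvable query term(s): ",
            paste(cq$dropped, collapse = ", "))
  }
  if (!length(cq$terms)) stop("no resolvable query terms")
  scores <- score_all_diseases(index, ontology, cq$terms, method = method,
                               alpha = alpha, w_e = w_e,
                               use_closure = use_closure)
  out <- rank_with_ties(scores)
  attr(out, "query") <- cq$terms
  out
}
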