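#' Classical pairwise term similarity measures
#'
#' Seven measures between two ontology terms, six based on information
#' content and the most informative common ancestor (MICA), and one (Wang)
#' based purely on graph structure:
#'
#' * `sim_resnik`: IC(MICA).
#' * `sim_lin`: 2 IC(MICA) / (IC(t1) + IC(t2)); defined as 0 when both
#'   terms are the root (0/0 convention).
#' * `sim_jc` (Jiang–Conrath, similarity transform):
#'   1 / (1 + IC(t1) + IC(t2) - 2 IC(MICA)).
#' * `sim_rel` (Relevance): Lin × (1 - p(MICA)), where p(MICA) is the
#'   proportion of diseases annotated by the MICA.
#' * `sim_infocoeff` (information coefficient):
#'   Lin × (1 - 1 / (1 + IC(MICA))).
#' * `sim_graphic` (graph IC / simGIC): sum of IC over the shared ancestors
#'   of the two terms divided by the sum over the union of their ancestors
#'   (both inclusive of the terms themselves); 0 when the union sum is 0.
#' * `sim_wang`: see [sim_wang()].
#'
#' All IC-based measures require both terms to be annotated (N_t > 0).
#'
#' @param index A `phen_index`.
#' @param ontology A `phen_ontology`.
#' @param t1,t2 Canonical term ids.
#' @return Numeric scalar. Lin, JC, Relevance, information coefficient and
#'   graph IC lie in \[0, 1\]; Resnik in \[0, max IC\].
#' @name pairwise_measures
NULL

#' @rdname pairwise_measures
#' @export
sim_resnik <- function(index, ontology, t1, t2) {
  unname(index$ic[mica(index, ontology, t1, t2)])
}

#' @rdname pairwise_measures
#' @export
sim_lin <- function(index, ontology, t1, t2) {
  denom <- information_content(index, t1) + information_content(index, t2)
  if (denom == 0) return(0)
  2 * unname(index$ic[mica(index, ontology, t1, t2)]) / denom
}

#' @rdname pairwise_measures
#' @export
sim_jc <- function(index, ontology, t1, t2) {
  dist <- information_content(index, t1) + information_content(index, t2) -
    2 * unname(index$ic[mica(index, ontology, t1, t2)])
  1 / (1 + dist)
}

#' @rdname pairwise_measures
#' @export
sim_rel <- function(index, ontology, t1, t2) {
  m <- mica(index, ontology, t1, t2)
  p <- unname(index$N_t[m]) / index$N
  sim_lin(index, ontology, t1, t2) * (1 - p)
}

#' @rdname pairwise_measures
#' @export
sim_infocoeff <- function(index, ontology, t1, t2) {
  icm <- unname(index$ic[mica(index, ontology, t1, t2)])
  sim_lin(index, ontology, t1, t2) * (1 - 1 / (1 + icm))
}

#' @rdname pairwise_measures
#' @export
sim_graphic <- function(index, ontology, t1, t2) {
  for (t in c(t1, t2)) information_content(index, t)  # annotation check
  a1 <- c(t1, ontology$anc[[t1]])
  a2 <- c(t2, ontology$anc[[t2]])
  ic_of <- function(ts) {
    v <- index$ic[ts]
    sum(v[!is.na(v)])
  }
  denom <- ic_of(union(a1, a2))
  if (denom == 0) return(0)
  ic_of(intersect(a1, a2)) / denom
}

#' Wang semantic-contribution S-values of a term
#'
#' On the ancestor subgraph DAG_t of a term t, the semantic contribution of
#' each node n is S_t(t) = 1 and, for every ancestor n,
#' S_t(n) = max over children n' of n inside DAG_t of w_e * S_t(n'),
#' with edge weight `w_e` (default 0.8).
#'
#' @param ontology A `phen_ontology`.
#' @param t Canonical term id.
#' @param w_e Edge contribution factor, in (0, 1).
#' @return A list with `anchor` (= `t`), `svalue` (named numeric over all
#'   nodes of DAG_t, anchor included) and `SV` (their sum).
#' @export
wang_svalues <- function(ontology, t, w_e = 0.8) {
  if (!is.numeric(w_e) || length(w_e) != 1L || w_e <= 0 || w_e >= 1) {
    stop("w_e must be a single number in (0, 1)")
  }
  check_term(ontology, t)
  nodes <- c(t, ontology$anc[[t]])
  sv <- setNames(rep(NA_real_, length(nodes)), nodes)
  sv[[t]] <- 1
  svalue <- function(n) {
    if (!is.na(sv[[n]])) return(sv[[n]])
    kids <- intersect(ontology$children[[n]], nodes)
    val <- max(vapply(kids, function(k) w_e * svalue(k), numeric(1)))
    sv[[n]] <<- val
    val
  }
  for (n in nodes) svalue(n)
  list(anchor = t, svalue = sv, SV = sum(sv))
}

#' Wang graph-based term similarity
#'
#' Ratio of the summed semantic contributions of the terms shared by the
#' two ancestor subgraphs to SV(t1) + SV(t2). The shared set is taken as
#' the intersection of the full subgraphs (anchors included) so that
#' sim(t, t) = 1; `strict = TRUE` restricts it to the proper-ancestor
#' intersection exactly as one literal reading has it, under which
#' self-similarity falls below 1.
#'
#' @inheritParams wang_svalues
#' @param t1,t2 Canonical term ids.
#' @param strict Use the proper-ancestor-only shared set.
#' @return Numeric scalar in (0, 1].
#' @export
sim_wang <- function(ontology, t1, t2, w_e = 0.8, strict = FALSE) {
  s1 <- wang_svalues(ontology, t1, w_e)
  s2 <- wang_svalues(ontology, t2, w_e)
  set1 <- if (strict) ontology$anc[[t1]] else names(s1$svalue)
  set2 <- if (strict) ontology$anc[[t2]] else names(s2$svalue)
  shared <- intersect(set1, set2)
  sum(s1$svalue[shared] + s2$svalue[shared]) / (s1$SV + s2$SV)
}

measure_names <- c("resnik", "lin", "jc", "rel", "ic", "graphic", "wang")

#' Pairwise similarity by measure name
#'
#' Dispatches to one of the seven pairwise measures by its short name:
#' `"resnik"`, `"lin"`, `"jc"`, `"rel"`, `"ic"`, `"graphic"` or `"wang"`.
#'
#' @inheritParams pairwise_measures
#' @param measure Measure name.
#' @param w_e Wang edge weight (used only by `"wang"`).
#' @return Numeric scalar.
#' @export
term_similarity <- function(index, ontology, t1, t2,
                            measure = c("resnik", "lin", "jc", "rel",
                                        "ic", "graphic", "wang"),
                            w_e = 0.8) {
  measure <- match.arg(measure)
  switch(measure,
    resnik  = sim_resnik(index, ontology, t1, t2),
    lin     = sim_lin(index, ontology, t1, t2),
    jc      = sim_jc(index, ontology, t1, t2),
    rel     = sim_rel(index, ontology, t1, t2),
    ic      = sim_infocoeff(index, ontology, t1, t2),
    graphic = sim_graphic(index, ontology, t1, t2),
    wang    = sim_wang(ontology, t1, t2, w_e = w_e)
  )
}

#' One-sided best-match set similarity
#'
#' Averages, over the query terms only, each query term's best pairwise
#' match against the disease's term set:
#' sim(Q -> D) = (1/|Q|) * sum over t1 in Q of max over t2 in D of
#' sim(t1, t2). This asymmetric form suits diagnosis: the patient's
#' observed phenotypes are matched against the disease, not vice versa.
#'
#' Query terms that are not annotated in the index cannot be scored by the
#' IC-based measures and are skipped with a warning (the average is over
#' the remaining terms). An empty disease term set scores 0 with a warning
#' rather than erroring, so full-corpus ranking never aborts.
#'
#' @param index A `phen_index`.
#' @param ontology A `phen_ontology`.
#' @param query Nonempty character vector of canonical query term ids.
#' @param disease_terms Character vector of the disease's term ids.
#' @param measure Pairwise measure name (see [term_similarity()]).
#' @param w_e Wang edge weight.
#' @return Numeric scalar.
#' @export
one_sided_similarity <- function(index, ontology, query, disease_terms,
                                 measure = "resnik", w_e = 0.8) {
  query <- unique(query)
  if (!length(query)) stop("empty query term set")
  disease_terms <- unique(disease_terms)
  if (!length(disease_terms)) {
    warning("empty disease term set scores 0")
    return(0)
  }
  if (measure != "wang") {
    ann <- query[index$N_t[query] > 0L]
    if (length(ann) < length(query)) {
      warning(length(query) - length(ann),
              " unannotated query term(s) skipped")
    }
    query <- ann
    if (!length(query)) return(0)
    disease_terms <- disease_terms[index$N_t[disease_terms] > 0L]
    if (!length(disease_terms)) {
      warning("no annotated disease terms; similarity 0")
      return(0)
    }
  }
  best <- vapply(query, function(q) {
    max(vapply(disease_terms, function(d) {
      term_similarity(index, ontology, q, d, measure = measure, w_e = w_e)
    }, numeric(1)))
  }, numeric(1))
  mean(best)
}
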