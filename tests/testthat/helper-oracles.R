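# Independent brute-force oracles: plain recursive graph walks and direct
# transcriptions of the formulas, sharing no code or caches with the
# package implementation. All take a parents list (named list id -> parent
# ids) and a direct annotation map, never a phen_ontology/phen_index.

oracle_ancestors <- function(parents, id, include_self = FALSE) {
  walk <- function(v) {
    out <- character(0)
    for (p in parents[[v]]) out <- union(out, c(p, walk(p)))
    out
  }
  a <- walk(id)
  if (include_self) union(id, a) else a
}

oracle_descendants <- function(parents, id, include_self = FALSE) {
  ids <- names(parents)
  d <- ids[vapply(ids, function(v) id %in% oracle_ancestors(parents, v),
                  logical(1))]
  if (include_self) union(id, d) else d
}

# D(t), N_t, IC via the descendant-union definition (the package propagates
# upward instead, so the two routes are independent)
oracle_closure <- function(parents, direct, t) {
  down <- oracle_descendants(parents, t, include_self = TRUE)
  ds <- names(direct)[vapply(names(direct), function(d) {
    length(intersect(direct[[d]], down)) > 0L
  }, logical(1))]
  sort(ds)
}

# memo: optional environment caching IC values within one (parents, direct)
# case — pure memoisation of the oracle's own arithmetic
oracle_ic <- function(parents, direct, t, memo = NULL) {
  if (!is.null(memo) && !is.null(memo[[t]])) return(memo[[t]])
  nt <- length(oracle_closure(parents, direct, t))
  v <- if (nt == 0L) NA_real_ else -log(nt / length(direct))
  if (!is.null(memo)) memo[[t]] <- v
  v
}

oracle_mica <- function(parents, direct, t1, t2, memo = NULL) {
  common <- intersect(oracle_ancestors(parents, t1, TRUE),
                      oracle_ancestors(parents, t2, TRUE))
  ics <- vapply(common, function(t) oracle_ic(parents, direct, t, memo),
                numeric(1))
  common <- common[!is.na(ics)]
  ics <- ics[!is.na(ics)]
  sort(common[ics == max(ics)])[1L]
}

oracle_measure <- function(parents, direct, t1, t2, measure, w_e = 0.8,
                           memo = NULL) {
  if (measure == "wang") return(oracle_wang(parents, t1, t2, w_e))
  m <- oracle_mica(parents, direct, t1, t2, memo)
  ic1 <- oracle_ic(parents, direct, t1, memo)
  ic2 <- oracle_ic(parents, direct, t2, memo)
  icm <- oracle_ic(parents, direct, m, memo)
  lin <- if (ic1 + ic2 == 0) 0 else 2 * icm / (ic1 + ic2)
  switch(measure,
    resnik = icm,
    lin = lin,
    jc = 1 / (1 + ic1 + ic2 - 2 * icm),
    rel = lin * (1 - length(oracle_closure(parents, direct, m)) /
                   length(direct)),
    ic = lin * (1 - 1 / (1 + icm)),
    graphic = {
      a1 <- oracle_ancestors(parents, t1, TRUE)
      a2 <- oracle_ancestors(parents, t2, TRUE)
      icsum <- function(ts) {
        v <- vapply(ts, function(t) oracle_ic(parents, direct, t, memo),
                    numeric(1))
        sum(v[!is.na(v)])
      }
      den <- icsum(union(a1, a2))
      if (den == 0) 0 else icsum(intersect(a1, a2)) / den
    })
}

# plain recursion, no memoisation
oracle_wang_svalue <- function(parents, anchor, n, w_e, nodes) {
  if (n == anchor) return(1)
  kids <- nodes[vapply(nodes, function(v) n %in% parents[[v]], logical(1))]
  max(vapply(kids, function(k) {
    w_e * oracle_wang_svalue(parents, anchor, k, w_e, nodes)
  }, numeric(1)))
}

oracle_wang <- function(parents, t1, t2, w_e = 0.8) {
  n1 <- oracle_ancestors(parents, t1, TRUE)
  n2 <- oracle_ancestors(parents, t2, TRUE)
  s1 <- vapply(n1, function(n) oracle_wang_svalue(parents, t1, n, w_e, n1),
               numeric(1))
  s2 <- vapply(n2, function(n) oracle_wang_svalue(parents, t2, n, w_e, n2),
               numeric(1))
  shared <- intersect(n1, n2)
  sum(s1[shared] + s2[shared]) / (sum(s1) + sum(s2))
}

oracle_one_sided <- function(parents, direct, query, dterms, measure,
                             w_e = 0.8, memo = NULL) {
  if (is.null(memo)) memo <- new.env(parent = emptyenv())
  ann <- function(t) !is.na(oracle_ic(parents, direct, t, memo))
  if (measure != "wang") {
    query <- query[vapply(query, ann, logical(1))]
    dterms <- dterms[vapply(dterms, ann, logical(1))]
  }
  if (!length(query) || !length(dterms)) return(0)
  mean(vapply(query, function(q) {
    max(vapply(dterms, function(d) {
      oracle_measure(parents, direct, q, d, measure, w_e, memo)
    }, numeric(1)))
  }, numeric(1)))
}

oracle_rbp <- function(parents, direct, query, d, alpha = 0.01) {
  sum(vapply(unique(query), function(t) {
    cl <- oracle_closure(parents, direct, t)
    if (!length(cl) || !d %in% cl) return(0)
    min(alpha, 1 / length(cl))
  }, numeric(1)))
}

# shared small fixture builders -------------------------------------------

toy <- phenorbp::toy_fixture()

# one chain-shaped branch per disease under a common root, each disease
# annotated only inside its own branch: recovery of the planted disease is
# then exact for every measure (cross-branch MICAs are all the root)
planted_case <- function(n_diseases = 5L, depth = 4L) {
  stopifnot(depth >= 3L)
  lines <- c("[Term]", "id: ROOT")
  direct <- list()
  profiles <- list()
  for (i in seq_len(n_diseases)) {
    ids <- sprintf("HP:%02d%02d", i, seq_len(depth))
    for (j in seq_len(depth)) {
      parent <- if (j == 1L) "ROOT" else ids[j - 1L]
      lines <- c(lines, "[Term]", paste0("id: ", ids[j]),
                 paste0("is_a: ", parent))
    }
    d <- sprintf("OMIM:7%05d", i)
    direct[[d]] <- ids[seq.int(depth - 2L, depth)]
    profiles[[d]] <- list(disease = d, terms = direct[[d]],
                          freq = rep(1, 3L))
  }
  ont <- parse_obo(lines)
  list(ontology = ont, direct = direct, index = build_index(ont, direct),
       profiles = profiles)
}

random_case <- function(seed, n_terms = 25L, n_diseases = 6L,
                        max_parents = 3L) {
  set.seed(seed)
  ont <- gen_ontology(n_terms, max_parents = max_parents)
  ann <- gen_annotations(ont, n_diseases = n_diseases,
                         terms_per_disease = c(3L, min(6L, n_terms - 1L)))
  list(ontology = ont, direct = ann$direct,
       index = build_index(ont, ann$direct), profiles = ann$profiles)
}
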