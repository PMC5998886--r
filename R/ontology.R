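#' @importFrom stats setNames
NULL

#' Parse an OBO flat file into a validated ontology DAG
#'
#' Reads an OBO 1.2/1.4 flat file (the format the Human Phenotype Ontology is
#' distributed in) and builds an immutable directed acyclic graph of terms
#' linked by `is_a` edges. Only `is_a` relationships define the hierarchy;
#' any other `relationship:` lines are ignored with a warning. Obsolete terms
#' are retained as metadata (so their ids can still be recognised and
#' reported) but are excluded from the DAG. `alt_id` lines are recorded so
#' that retired identifiers can be canonicalised with [resolve_term()].
#'
#' After parsing, the graph is validated: every `is_a` target must be a
#' defined term, the graph must be acyclic, and exactly one non-obsolete term
#' may lack parents (the root) unless `root` is supplied to override root
#' detection for nonstandard files. Ancestor and descendant closures are
#' precomputed so subsequent queries are pure lookups.
#'
#' @param file Path to an OBO file, or a character vector of OBO text lines
#'   (anything containing a newline is treated as literal text).
#' @param root Optional term id to force as root for files whose structure
#'   does not have a unique parentless term; declaring it also disables the
#'   unique-root and root-reachability validation.
#' @return An object of class `phen_ontology`: a list with elements `ids`
#'   (non-obsolete term ids), `name` (named character), `parents` and
#'   `children` (named lists of character vectors), `anc` and `desc`
#'   (precomputed proper ancestor/descendant closures), `root`,
#'   `edge_count`, `alt` (named character, alt id -> primary id) and
#'   `obsolete` (character vector of obsolete ids).
#' @examples
#' obo <- c("[Term]", "id: R", "name: root",
#'          "[Term]", "id: A", "is_a: R",
#'          "[Term]", "id: B", "is_a: R")
#' ont <- parse_obo(obo)
#' ont$root
#' ancestors(ont, "A")
#' @export
parse_obo <- function(file, root = NULL) {
  if (length(file) == 1L && !grepl("\n", file)) {
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- trimws(lines)

  # split into [Term] stanzas; header and non-term stanzas are skipped
  stanza_starts <- which(lines == "[Term]")
  other_stanzas <- grep("^\\[(?!Term\\])", lines, perl = TRUE)
  breaks <- sort(c(stanza_starts, other_stanzas, length(lines) + 1L))

  terms <- list()
  n_other_rel <- 0L
  for (s in stanza_starts) {
    end <- min(breaks[breaks > s]) - 1L
    body <- lines[seq.int(s + 1L, length.out = max(0L, end - s))]
    body <- body[nzchar(body)]
    tag <- sub(":.*$", "", body)
    val <- trimws(sub("^[^:]+:", "", body))
    # strip trailing "! comment" from id-valued tags
    strip_cmt <- function(x) trimws(sub("\\s*!.*$", "", x))

    id <- strip_cmt(val[tag == "id"][1L])
    if (is.na(id) || !nzchar(id)) next
    obsolete <- any(tag == "is_obsolete" & tolower(val) == "true")
    term <- list(
      id = id,
      name = if (any(tag == "name")) val[tag == "name"][1L] else id,
      parent_ids = unique(strip_cmt(val[tag == "is_a"])),
      alt_ids = unique(strip_cmt(val[tag == "alt_id"])),
      obsolete = obsolete
    )
    n_other_rel <- n_other_rel + sum(tag == "relationship")
    if (!is.null(terms[[id]])) {
      stop("duplicate term id in OBO input: ", id)
    }
    terms[[id]] <- term
  }
  if (n_other_rel > 0L) {
    warning(n_other_rel, " non-is_a relationship line(s) ignored; ",
            "only is_a edges build the DAG")
  }
  if (length(terms) == 0L) stop("no [Term] stanzas found in OBO input")
  build_ontology(terms, root = root)
}

# Validate term list and assemble the phen_ontology object.
build_ontology <- function(terms, root = NULL) {
  all_ids <- names(terms)
  obsolete <- all_ids[vapply(terms, `[[`, logical(1), "obsolete")]
  live_ids <- setdiff(all_ids, obsolete)
  if (length(live_ids) == 0L) stop("all terms are obsolete")

  alt <- character(0)
  for (tm in terms) {
    if (length(tm$alt_ids)) {
      alt <- c(alt, setNames(rep(tm$id, length(tm$alt_ids)), tm$alt_ids))
    }
  }
  clash <- intersect(names(alt), all_ids)
  if (length(clash)) {
    stop("alt_id collides with a primary term id: ",
         paste(clash, collapse = ", "))
  }
  if (anyDuplicated(names(alt))) {
    alt <- alt[!duplicated(names(alt))]
  }

  parents <- lapply(terms[live_ids], function(tm) {
    if (tm$obsolete) character(0) else tm$parent_ids
  })
  undef <- setdiff(unlist(parents, use.names = FALSE), live_ids)
  if (length(undef)) {
    bad <- intersect(undef, obsolete)
    stop("is_a target(s) undefined or obsolete: ",
         paste(utils::head(undef, 5), collapse = ", "),
         if (length(bad)) " (some point at obsolete terms)" else "")
  }

  children <- setNames(vector("list", length(live_ids)), live_ids)
  for (id in live_ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }

  # Kahn topological sort doubles as the cycle check
  indeg <- vapply(parents, length, integer(1))  # edges point child -> parent
  order <- character(0)
  queue <- live_ids[indeg == 0L]
  indeg_work <- indeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg_work[[ch]] <- indeg_work[[ch]] - 1L
      if (indeg_work[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < length(live_ids)) {
    member <- setdiff(live_ids, order)[1L]
    stop("cycle detected in is_a graph involving term: ", member)
  }

  roots <- live_ids[indeg == 0L]
  declared_root <- root
  if (!is.null(root)) {
    if (!root %in% live_ids) stop("declared root not a live term: ", root)
  } else if (length(roots) != 1L) {
    stop(length(roots), " parentless term(s) found, expected exactly 1: ",
         paste(utils::head(roots, 10), collapse = ", "),
         "; pass root= to override")
  } else {
    root <- roots
  }

  # proper ancestor closure, filled in topological order (parents first)
  anc <- setNames(vector("list", length(live_ids)), live_ids)
  for (id in order) {
    up <- unique(unlist(
      lapply(parents[[id]], function(p) c(p, anc[[p]])),
      use.names = FALSE))
    anc[id] <- list(if (is.null(up)) character(0) else up)
  }
  if (length(roots) == 1L && is.null(declared_root)) {
    unreachable <- live_ids[
      live_ids != root & !vapply(anc, function(a) root %in% a, logical(1))]
    if (length(unreachable)) {
      stop("term(s) cannot reach the root: ",
           paste(utils::head(unreachable, 5), collapse = ", "))
    }
  }
  desc <- setNames(vector("list", length(live_ids)), live_ids)
  for (id in rev(order)) {
    down <- unique(unlist(
      lapply(children[[id]], function(ch) c(ch, desc[[ch]])),
      use.names = FALSE))
    desc[id] <- list(if (is.null(down)) character(0) else down)
  }
  children <- lapply(children, function(x) if (is.null(x)) character(0) else x)

  structure(list(
    ids = live_ids,
    name = vapply(terms[live_ids], `[[`, character(1), "name"),
    parents = parents,
    children = children,
    anc = anc,
    desc = desc,
    topo = order,
    root = root,
    edge_count = sum(vapply(parents, length, integer(1))),
    alt = alt,
    obsolete = obsolete
  ), class = "phen_ontology")
}

#' @export
print.phen_ontology <- function(x, ...) {
  cat("phen_ontology: ", length(x$ids), " terms, ", x$edge_count,
      " is_a edges, root ", x$root,
      if (length(x$obsolete)) paste0(", ", length(x$obsolete), " obsolete"),
      "\n", sep = "")
  invisible(x)
}

#' Canonicalise term identifiers
#'
#' Maps each identifier to its primary term id: primary ids map to
#' themselves and `alt_id`s map to the term that owns them. Unknown ids are
#' an error; obsolete ids raise an error of class `phen_obsolete_error` so
#' callers can decide whether to drop them (see [canonicalize_query()]).
#'
#' @param ontology A `phen_ontology`.
#' @param ids Character vector of term identifiers.
#' @return Character vector of canonical ids, same length as `ids`.
#' @export
resolve_term <- function(ontology, ids) {
  out <- ids
  is_alt <- ids %in% names(ontology$alt)
  out[is_alt] <- ontology$alt[ids[is_alt]]
  obs <- out %in% ontology$obsolete
  if (any(obs)) {
    stop(structure(class = c("phen_obsolete_error", "error", "condition"),
                   list(message = paste0("obsolete term id(s): ",
                                         paste(unique(out[obs]), collapse = ", ")),
                        call = sys.call(-1))))
  }
  unknown <- !(out %in% ontology$ids)
  if (any(unknown)) {
    stop("unknown term id(s): ", paste(unique(ids[unknown]), collapse = ", "))
  }
  out
}

#' Canonicalise a query term set, reporting replacements
#'
#' Convenience wrapper around [resolve_term()] for user queries: alt ids are
#' replaced by their primary ids, obsolete and unknown ids are dropped, and
#' a report of every replacement and drop is attached.
#'
#' @param ontology A `phen_ontology`.
#' @param ids Character vector of query term identifiers.
#' @return A list with `terms` (canonical, deduplicated ids), `replaced`
#'   (named character: alt -> primary) and `dropped` (ids that are unknown
#'   or obsolete).
#' @export
canonicalize_query <- function(ontology, ids) {
  ids <- unique(ids)
  mapped <- ifelse(ids %in% names(ontology$alt), ontology$alt[ids], ids)
  keep <- mapped %in% ontology$ids & !(mapped %in% ontology$obsolete)
  replaced <- setNames(mapped[keep & mapped != ids], ids[keep & mapped != ids])
  list(terms = unique(mapped[keep]),
       replaced = replaced,
       dropped = ids[!keep])
}

check_term <- function(ontology, id) {
  if (length(id) != 1L || !id %in% ontology$ids) {
    stop("unknown term id: ", paste(id, collapse = ", "))
  }
  id
}

#' Ancestors of a term
#'
#' Transitive closure over `is_a` edges. For any non-root term the result
#' always contains the root.
#'
#' @param ontology A `phen_ontology`.
#' @param id Canonical term id.
#' @param include_self Include `id` itself in the returned set?
#' @return Character vector of term ids.
#' @export
ancestors <- function(ontology, id, include_self = FALSE) {
  check_term(ontology, id)
  if (include_self) c(id, ontology$anc[[id]]) else ontology$anc[[id]]
}

#' Descendants of a term
#'
#' @inheritParams ancestors
#' @return Character vector of term ids.
#' @export
descendants <- function(ontology, id, include_self = FALSE) {
  check_term(ontology, id)
  if (include_self) c(id, ontology$desc[[id]]) else ontology$desc[[id]]
}

#' Induced ancestor subgraph of a term
#'
#' Returns the subgraph DAG_t consisting of a term, its ancestors, and all
#' `is_a` edges among them — the structure the Wang similarity measure is
#' computed on. Following the convention that separates the anchor term from
#' its ancestor set, `terms` excludes `id` itself.
#'
#' @inheritParams ancestors
#' @return A list with `anchor` (= `id`), `terms` (proper ancestors T_t) and
#'   `edges` (two-column character matrix, child then parent).
#' @export
wang_subgraph <- function(ontology, id) {
  check_term(ontology, id)
  nodes <- c(id, ontology$anc[[id]])
  edges <- do.call(rbind, lapply(nodes, function(v) {
    ps <- intersect(ontology$parents[[v]], nodes)
    if (length(ps)) cbind(child = v, parent = ps) else NULL
  }))
  if (is.null(edges)) edges <- matrix(character(0), 0, 2,
                                      dimnames = list(NULL, c("child", "parent")))
  list(anchor = id, terms = ontology$anc[[id]], edges = edges)
}
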