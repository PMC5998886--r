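#' Evaluate a ranking method over a simulated cohort
#'
#' For each patient: score every disease in the corpus against the
#' patient's term set, rank with tie-averaged ranks, and record the rank of
#' the true disease. Patients whose true disease is absent from the corpus
#' are excluded and counted.
#'
#' @param cohort List of `phen_patient`.
#' @param index A `phen_index` (the disease corpus).
#' @param ontology A `phen_ontology`.
#' @param method `"rbp"` or a classical measure name.
#' @param alpha RelativeBestPair cap.
#' @param w_e Wang edge weight.
#' @param use_closure Match disease term sets as closures (classical
#'   measures only).
#' @param ks Thresholds for top-k counts.
#' @return A `phen_eval`: list with `method`, `variant`, `ranks` (numeric,
#'   one per evaluated patient), `topk` (named integer), `n_patients`, and
#'   `n_excluded`.
#' @export
evaluate_cohort <- function(cohort, index, ontology, method = "rbp",
                            alpha = 0.01, w_e = 0.8, use_closure = FALSE,
                            ks = c(1L, 5L, 10L, 20L)) {
  stopifnot(length(cohort) >= 1L)
  ranks <- numeric(0)
  n_excluded <- 0L
  for (p in cohort) {
    if (!p$true_disease %in% index$diseases) {
      n_excluded <- n_excluded + 1L
      warning("true disease not in corpus, patient excluded: ",
              p$patient_id)
      next
    }
    scores <- score_all_diseases(index, ontology, p$terms, method = method,
                                 alpha = alpha, w_e = w_e,
                                 use_closure = use_closure)
    ranked <- rank_with_ties(scores)
    ranks <- c(ranks, rank_of_disease(ranked, p$true_disease))
  }
  variant <- unique(vapply(cohort, `[[`, character(1), "variant"))
  structure(list(method = method,
                 variant = paste(variant, collapse = "/"),
                 ranks = ranks,
                 topk = topk_counts(ranks, ks),
                 n_patients = length(ranks),
                 n_excluded = n_excluded),
            class = "phen_eval")
}

#' @export
print.phen_eval <- function(x, ...) {
  cat("phen_eval: method ", x$method, ", variant ", x$variant, ", ",
      x$n_patients, " patients\n", sep = "")
  pct <- sprintf("%.2f%%", 100 * x$topk / x$n_patients)
  cat(paste0("  top-", names(x$topk), ": ", x$topk, " (", pct, ")",
             collapse = "\n"), "\n")
  invisible(x)
}

#' Top-k counts of true-disease ranks
#'
#' Counts, for each threshold k, how many ranks are <= k. Fractional
#' (tie-averaged) ranks are compared with <=, so a tied rank of 1.5 does
#' not count as top-1 but does count as top-5.
#'
#' @param ranks Numeric vector of true-disease ranks.
#' @param ks Integer thresholds, sorted ascending.
#' @return Named integer vector, one count per threshold.
#' @export
topk_counts <- function(ranks, ks = c(1L, 5L, 10L, 20L)) {
  stopifnot(length(ranks) >= 1L, !is.unsorted(ks))
  setNames(vapply(ks, function(k) sum(ranks <= k), integer(1)),
           as.character(ks))
}

#' Cumulative distribution of true-disease ranks
#'
#' For each threshold 1..max_rank, the proportion of patients whose true
#' disease is ranked at or below the threshold — the data behind
#' cumulative rank curves.
#'
#' @param ranks Numeric vector of true-disease ranks.
#' @param max_rank Largest threshold to evaluate (>= 1).
#' @return A data.frame with columns `threshold` and `proportion`
#'   (non-decreasing, in \[0, 1\]).
#' @export
cumulative_curve <- function(ranks, max_rank) {
  stopifnot(max_rank >= 1L)
  thresholds <- seq_len(max_rank)
  data.frame(threshold = thresholds,
             proportion = vapply(thresholds,
                                 function(k) mean(ranks <= k), numeric(1)))
}

#' Write an evaluation report to TSV
#'
#' @param eval_result A `phen_eval`.
#' @param file Output path.
#' @param metadata Named character vector of `# name: value` header lines.
#' @export
write_eval_report <- function(eval_result, file, metadata = NULL) {
  hdr <- c(paste0("# method: ", eval_result$method),
           paste0("# variant: ", eval_result$variant),
           paste0("# n_patients: ", eval_result$n_patients))
  if (!is.null(metadata)) {
    hdr <- c(hdr, paste0("# ", names(metadata), ": ", metadata))
  }
  rows <- paste(names(eval_result$topk), eval_result$topk,
                sprintf("%.2f", 100 * eval_result$topk /
                          eval_result$n_patients), sep = "\t")
  writeLines(c(hdr, "k\tcount\tpercent", rows), file)
}
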