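#' Construct a visit prediction record
#'
#' @param truth integer indices of the ground-truth medication set.
#' @param predicted integer indices of the recommended set.
#' @param o_hat probability vector over the medication vocabulary.
#' @param patient_id,t provenance.
#' @return object of class `visit_prediction`.
#' @export
visit_prediction <- function(truth, predicted, o_hat,
                             patient_id = NA_character_, t = NA_integer_) {
  structure(list(truth = sort(unique(as.integer(truth))),
                 predicted = sort(unique(as.integer(predicted))),
                 o_hat = o_hat, patient_id = patient_id, t = as.integer(t)),
            class = "visit_prediction")
}

#' DDI rate of predicted combinations
#'
#' Per visit: the fraction of unordered predicted-drug pairs that interact
#' according to `D`; visits with fewer than two predicted drugs contribute 0
#' (zero-denominator convention). Averaged over visits.
#'
#' @param predictions list of `visit_prediction`.
#' @param D binary symmetric DDI matrix.
#' @return scalar in `[0, 1]`.
#' @export
ddi_rate <- function(predictions, D) {
  if (length(predictions) == 0L) return(0)
  per_visit <- vapply(predictions, function(p) {
    s <- p$predicted
    n <- length(s)
    if (n < 2L) return(0)
    sub <- D[s, s, drop = FALSE]
    sum(sub[upper.tri(sub)]) / (n * (n - 1) / 2)
  }, numeric(1))
  mean(per_visit)
}

#' Mean per-visit Jaccard similarity
#'
#' `|truth intersect predicted| / |truth union predicted|` averaged over
#' visits; two empty sets count as identical (Jaccard 1).
#'
#' @param predictions list of `visit_prediction`.
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(predictions) {
  if (length(predictions) == 0L) return(0)
  mean(vapply(predictions, function(p) {
    u <- length(union(p$truth, p$predicted))
    if (u == 0L) return(1)
    length(intersect(p$truth, p$predicted)) / u
  }, numeric(1)))
}

#' Mean per-visit F1 score
#'
#' Per visit precision and recall, combined harmonically; an empty prediction
#' has precision 0 and `P + R = 0` yields F1 = 0.
#'
#' @param predictions list of `visit_prediction`.
#' @return scalar in `[0, 1]`.
#' @export
f1 <- function(predictions) {
  if (length(predictions) == 0L) return(0)
  mean(vapply(predictions, function(p) {
    tp <- length(intersect(p$truth, p$predicted))
    prec <- if (length(p$predicted) == 0L) 0 else tp / length(p$predicted)
    rec <- if (length(p$truth) == 0L) 0 else tp / length(p$truth)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1)))
}

#' Mean per-visit precision-recall AUC
#'
#' Per visit, drugs are ranked by descending probability and the step sum
#' `sum_k Precision(k) * DeltaRecall(k)` is accumulated over the full ranked
#' list. Visits with no true drug are skipped; their count is attached as the
#' `skipped` attribute.
#'
#' @param predictions list of `visit_prediction` (each needs `o_hat`).
#' @return scalar in `[0, 1]` with attribute `skipped`.
#' @export
prauc <- function(predictions) {
  vals <- numeric(0)
  skipped <- 0L
  for (p in predictions) {
    npos <- length(p$truth)
    if (npos == 0L) { skipped <- skipped + 1L; next }
    y <- numeric(length(p$o_hat)); y[p$truth] <- 1
    ord <- order(p$o_hat, decreasing = TRUE)
    ypos <- y[ord]
    tp <- cumsum(ypos)
    prec <- tp / seq_along(ypos)
    # DeltaRecall is 1/npos at each true drug's rank, 0 elsewhere
    vals <- c(vals, sum(prec[ypos == 1]) / npos)
  }
  out <- if (length(vals)) mean(vals) else 0
  attr(out, "skipped") <- skipped
  out
}

compute_metrics <- function(predictions, D) {
  pr <- prauc(predictions)
  list(ddi_rate = ddi_rate(predictions, D),
       jaccard = jaccard(predictions),
       f1 = f1(predictions),
       prauc = as.numeric(pr),
       prauc_skipped = attr(pr, "skipped"),
       avg_n_drugs = if (length(predictions) == 0L) 0 else
         mean(vapply(predictions, function(p) length(p$predicted), numeric(1))))
}

#' Bootstrap evaluation protocol
#'
#' Repeats `n_rounds` evaluation rounds; each round samples `frac` of the
#' test patients without replacement, predicts all their visits and computes
#' DDI rate, Jaccard, F1, PRAUC and the average number of recommended drugs.
#' Reports per-metric mean and standard deviation over rounds.
#'
#' @param model a `visitrx_model`.
#' @param cohort the held-out test `ehr_cohort`.
#' @param D binary symmetric DDI matrix.
#' @param n_rounds number of rounds (default 10).
#' @param frac fraction of patients sampled per round (default 0.8).
#' @param seed integer seed.
#' @return object of class `metrics_report`: `mean`, `sd` (named lists),
#'   `rounds` (data.frame of per-round values), `n_rounds`.
#' @export
bootstrap_evaluate <- function(model, cohort, D, n_rounds = 10L, frac = 0.8,
                               seed = 1L) {
  if (length(cohort$patients) == 0L) stop("empty test cohort")
  preds_by_patient <- split_predictions(predict_cohort(model, cohort))
  ids <- names(preds_by_patient)
  k <- max(1L, round(frac * length(ids)))
  rounds <- vector("list", n_rounds)
  local_rng(seed, {
    for (r in seq_len(n_rounds)) {
      take <- if (k >= length(ids)) ids else sample(ids, k)
      preds <- unlist(preds_by_patient[take], recursive = FALSE,
                      use.names = FALSE)
      m <- compute_metrics(preds, D)
      rounds[[r]] <- data.frame(round = r, ddi_rate = m$ddi_rate,
                                jaccard = m$jaccard, f1 = m$f1,
                                prauc = m$prauc,
                                avg_n_drugs = m$avg_n_drugs)
    }
  })
  rounds <- do.call(rbind, rounds)
  metrics <- c("ddi_rate", "jaccard", "f1", "prauc", "avg_n_drugs")
  structure(list(
    mean = as.list(vapply(rounds[metrics], mean, numeric(1))),
    sd = as.list(vapply(rounds[metrics], stats::sd, numeric(1))),
    rounds = rounds, n_rounds = n_rounds), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d rounds\n", x$n_rounds))
  for (nm in names(x$mean))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", nm, x$mean[[nm]], x$sd[[nm]]))
  invisible(x)
}

split_predictions <- function(predictions) {
  ids <- vapply(predictions, `[[`, character(1), "patient_id")
  split(predictions, ids)
}

#' Visit-count-stratified evaluation
#'
#' Partitions the test patients by their total number of visits and evaluates
#' each stratum separately. The `n = 1` stratum is the cold-start report.
#'
#' @param model a `visitrx_model`.
#' @param cohort the held-out test `ehr_cohort`.
#' @param D binary symmetric DDI matrix.
#' @return named list (names are visit counts) of per-stratum metric lists,
#'   each with an added `n_patients` field.
#' @export
stratify_by_visit_count <- function(model, cohort, D) {
  counts <- vapply(cohort$patients, function(p) length(p$visits), integer(1))
  preds_by_patient <- split_predictions(predict_cohort(model, cohort))
  out <- list()
  for (n in sort(unique(counts))) {
    pats <- vapply(cohort$patients[counts == n], `[[`, character(1),
                   "patient_id")
    preds <- unlist(preds_by_patient[intersect(pats, names(preds_by_patient))],
                    recursive = FALSE, use.names = FALSE)
    m <- compute_metrics(preds, D)
    m$n_patients <- length(pats)
    out[[as.character(n)]] <- m
  }
  out
}
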