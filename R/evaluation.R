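#' Turn a score matrix into a multi-label prediction
#'
#' Only suborganelle scores are compared with thresholds; a suborganelle
#' scoring at or above its threshold triggers the prediction of its
#' organelle, which
#' keeps the two levels consistent.  In strict mode a protein may receive
#' no label at all; the `top1` fallback adds the highest-scoring occupied
#' cell when nothing passes.
#'
#' @param scores A `loc_scores` prediction.
#' @param thresholds Threshold tibble from [tune_thresholds()] /
#'   [threshold_set()].
#' @param h A `loc_hierarchy`.
#' @param fallback `"none"` (strict) or `"top1"`.
#' @return A `loc_prediction`: list with `suborganelles`, `organelles`,
#'   `scores` (per-cell tibble), `accession`.
#' @export
decide <- function(scores, thresholds, h, fallback = c("none", "top1")) {
  fallback <- match.arg(fallback)
  occ <- h$cells
  th <- thresholds$threshold[match(occ$suborganelle, thresholds$suborganelle)]
  if (anyNA(th))
    .stopf("thresholds missing for cell '%s'",
           occ$suborganelle[which(is.na(th))[1]])
  s <- scores$sub[cbind(occ$row, occ$col)]
  hit <- s >= th
  if (!any(hit) && fallback == "top1") hit[which.max(s)] <- TRUE
  subs <- occ$suborganelle[hit]
  orgs <- unique(occ$organelle[hit])
  structure(list(suborganelles = subs, organelles = orgs,
                 scores = tibble(suborganelle = occ$suborganelle,
                                 organelle = occ$organelle,
                                 score = s, threshold = th, predicted = hit),
                 accession = scores$accession),
            class = "loc_prediction")
}

#' @export
print.loc_prediction <- function(x, ...) {
  cat(sprintf("<loc_prediction> %s: {%s} / {%s}\n", x$accession %||% "?",
              paste(x$organelles, collapse = ","),
              paste(x$suborganelles, collapse = ",")))
  invisible(x)
}

#' Predict localization for a table of records
#'
#' @param ens A `loc_ensemble`.
#' @param records Record tibble (sequences are encoded with the ensemble's
#'   configuration) or a pre-built list of `loc_encoded`.
#' @param fallback See [decide()].
#' @return Tibble: `accession`, list-columns `organelles` and
#'   `suborganelles`, and a `scores` list-column of per-cell tibbles.
#' @export
predict_localization <- function(ens, records, fallback = "none") {
  enc <- if (is.data.frame(records))
    encode_records(records, encode_len = ens$cfg$encode_len)
  else records
  rows <- lapply(enc, function(e) {
    pr <- decide(ensemble_predict(ens, e), ens$thresholds, ens$hierarchy,
                 fallback = fallback)
    tibble(accession = e$accession,
           organelles = list(pr$organelles),
           suborganelles = list(pr$suborganelles),
           scores = list(pr$scores))
  })
  dplyr::bind_rows(rows)
}

#' Confusion counts for a binary prediction
#' @param pred,truth Logical vectors of equal length.
#' @return List with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  list(TP = sum(pred & truth), FP = sum(pred & !truth),
       TN = sum(!pred & !truth), FN = sum(!pred & truth))
}

mcc_value <- function(c) {
  den <- (c$TP + c$FP) * (c$TP + c$FN) * (c$TN + c$FP) * (c$TN + c$FN)
  if (den == 0) return(NA_real_)
  (c$TP * c$TN - c$FP * c$FN) / sqrt(den)
}

#' Binary classification metrics
#'
#' Accuracy, Matthews correlation coefficient, recall and precision from a
#' confusion table.  A metric whose denominator is zero is undefined and
#' returned as `NA` (flagged), never silently zeroed.
#'
#' @param counts List with `TP`, `FP`, `TN`, `FN` (see
#'   [confusion_counts()]).
#' @return Tibble `metric, value, defined`.
#' @export
binary_metrics <- function(counts) {
  c <- counts
  n <- c$TP + c$TN + c$FP + c$FN
  acc <- if (n > 0) (c$TP + c$TN) / n else NA_real_
  rec <- if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_
  prec <- if (c$TP + c$FP > 0) c$TP / (c$TP + c$FP) else NA_real_
  mcc <- mcc_value(c)
  tibble(metric = c("ACC", "MCC", "recall", "precision"),
         value = c(acc, mcc, rec, prec),
         defined = !is.na(c(acc, mcc, rec, prec)))
}

#' Ranking metrics: ROC AUC and precision-recall AUC
#'
#' The ROC AUC is computed as the Mann-Whitney probability that a random
#' positive outranks a random negative (ties count one half).  The PR AUC
#' integrates the precision-recall curve over the distinct score cutoffs
#' with linear (trapezoidal) interpolation in recall.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical).
#' @return Tibble `metric, value, defined`; both metrics are `NA`-flagged
#'   when one class is absent.
#' @export
ranking_metrics <- function(scores, labels) {
  labels <- as.logical(labels > 0 | labels == TRUE)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    return(tibble(metric = c("ROC_auc", "PR_auc"),
                  value = c(NA_real_, NA_real_), defined = c(FALSE, FALSE)))
  r <- rank(scores, ties.method = "average")
  roc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(!l)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # one point per distinct cutoff
  tp <- tp[keep]; fp <- fp[keep]
  rec <- tp / n1
  prec <- tp / (tp + fp)
  rec <- c(0, rec); prec <- c(prec[1], prec)
  pr <- sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  tibble(metric = c("ROC_auc", "PR_auc"), value = c(roc, pr),
         defined = c(TRUE, TRUE))
}

#' Exact-match count for multi-label organelle predictions
#'
#' A sample matches exactly when its predicted organelle set equals the
#' annotated set with no difference.
#'
#' @param preds List of character vectors (predicted organelle sets) or a
#'   prediction tibble from [predict_localization()].
#' @param truths List of character vectors (annotated organelle sets).
#' @return List with `count` and `rate`.
#' @export
exact_match <- function(preds, truths) {
  if (is.data.frame(preds)) preds <- preds$organelles
  if (length(preds) != length(truths))
    .stopf("predictions (%d) and truths (%d) differ in length",
           length(preds), length(truths))
  hit <- mapply(function(p, t) setequal(p, t), preds, truths)
  list(count = sum(hit), rate = mean(hit))
}

#' Per-class one-vs-rest evaluation report
#'
#' Reduces the multi-label problem to one binary problem per organelle and
#' per suborganelle class, reporting confusion-based metrics at the
#' supplied thresholds and ranking metrics from the raw scores, plus the
#' overall organelle-level exact-match rate.
#'
#' @param predictions Prediction tibble from [predict_localization()].
#' @param records Record tibble with the true label list-columns.
#' @param h A `loc_hierarchy`.
#' @return List with `classes` (tibble: class, level, TP..FN, ACC, MCC,
#'   recall, precision, ROC_auc, PR_auc) and `exact_match`.
#' @export
evaluation_report <- function(predictions, records, h) {
  stopifnot(nrow(predictions) == nrow(records))
  truth_org <- lapply(seq_len(nrow(records)), function(i) {
    t <- labels_to_matrix(records[i, ], h = h)
    h$organelles[t$org > 0]
  })
  rows <- list()
  class_row <- function(cl, level, pred, truth, score) {
    cc <- confusion_counts(pred, truth)
    bm <- binary_metrics(cc)
    rm <- ranking_metrics(score, truth)
    tibble(class = cl, level = level,
           TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
           ACC = bm$value[1], MCC = bm$value[2], recall = bm$value[3],
           precision = bm$value[4],
           ROC_auc = rm$value[1], PR_auc = rm$value[2])
  }
  org_scores <- t(vapply(predictions$scores, function(s)
    vapply(h$organelles, function(o) max(s$score[s$organelle == o]),
           numeric(1)), numeric(length(h$organelles))))
  for (j in seq_along(h$organelles)) {
    o <- h$organelles[j]
    pred <- vapply(predictions$organelles, function(x) o %in% x, TRUE)
    truth <- vapply(truth_org, function(x) o %in% x, TRUE)
    rows[[length(rows) + 1L]] <- class_row(o, "organelle", pred, truth,
                                           org_scores[, j])
  }
  for (i in seq_len(nrow(h$cells))) {
    cl <- h$cells$suborganelle[i]
    pred <- vapply(predictions$suborganelles, function(x) cl %in% x, TRUE)
    truth <- vapply(records$suborganelles, function(x) cl %in% x, TRUE)
    score <- vapply(predictions$scores, function(s)
      s$score[s$suborganelle == cl], numeric(1))
    rows[[length(rows) + 1L]] <- class_row(cl, "suborganelle", pred, truth,
                                           score)
  }
  list(classes = dplyr::bind_rows(rows),
       exact_match = exact_match(predictions$organelles, truth_org))
}
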