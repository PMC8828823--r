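#' Confusion matrix
#'
#' Tally of true class (rows) against predicted class (columns).
#'
#' @param truth,predicted Equal-length vectors of class names (character or
#'   factor) or 1-based class indices.
#' @param labels Class names fixing row/column order; defaults to the sorted
#'   union of observed values, or [scinti_classes()] when all values belong
#'   to it.
#' @return A `scinti_confusion` integer matrix with dimnames.
#' @export
#' @examples
#' confusion_matrix(c("a", "a", "b", "b"), c("a", "b", "b", "b"),
#'                  labels = c("a", "b"))
confusion_matrix <- function(truth, predicted, labels = NULL) {
  if (length(truth) != length(predicted)) {
    abort(sprintf("Label vectors differ in length: %d vs %d",
                  length(truth), length(predicted)))
  }
  if (length(truth) == 0) abort("Cannot tabulate zero samples")
  if (is.numeric(truth)) {
    K <- max(truth, predicted)
    labels <- labels %||% as.character(seq_len(K))
    truth <- labels[truth]; predicted <- labels[predicted]
  }
  if (is.null(labels)) {
    obs <- unique(c(as.character(truth), as.character(predicted)))
    labels <- if (all(obs %in% scinti_classes())) {
      intersect(scinti_classes(), obs)
    } else {
      sort(obs)
    }
  }
  bad <- setdiff(unique(c(as.character(truth), as.character(predicted))), labels)
  if (length(bad) > 0) {
    abort(paste0("Labels outside the class set: ", paste(bad, collapse = ", ")))
  }
  tf <- factor(truth, levels = labels)
  pf <- factor(predicted, levels = labels)
  cm <- unclass(table(truth = tf, predicted = pf))
  structure(cm, class = c("scinti_confusion", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' Per-class metrics are computed one-vs-rest: with TP, TN, FP, FN counted
#' for class k against the rest,
#' accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), specificity = TN/(TN+FP) and F1 the harmonic mean of
#' precision and recall. Headline values are macro averages (unweighted
#' means over classes); micro averages (pooled counts) are also reported.
#' Any metric with a zero denominator is reported as 0 and flagged
#' `degenerate`.
#'
#' @param cm A [confusion_matrix()] (any square integer matrix with
#'   dimnames works).
#' @return A `scinti_metrics` list: `per_class` tibble, `overall_accuracy`,
#'   `macro` and `micro` one-row tibbles.
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || nrow(cm) == 0) {
    abort("Need a non-empty square confusion matrix")
  }
  total <- sum(cm)
  if (total == 0) abort("Confusion matrix is empty (no samples)")
  K <- nrow(cm)
  classes <- rownames(cm) %||% as.character(seq_len(K))
  safe_div <- function(num, den) if (den == 0) c(0, TRUE) else c(num / den, FALSE)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    TP <- cm[k, k]
    FN <- sum(cm[k, ]) - TP
    FP <- sum(cm[, k]) - TP
    TN <- total - TP - FN - FP
    pr <- safe_div(TP, TP + FP)
    rc <- safe_div(TP, TP + FN)
    sp <- safe_div(TN, TN + FP)
    f1 <- if (pr[1] + rc[1] == 0) c(0, TRUE) else
      c(2 * pr[1] * rc[1] / (pr[1] + rc[1]), FALSE)
    rows[[k]] <- tibble::tibble(
      class = classes[k],
      accuracy = (TP + TN) / total,
      precision = pr[1], recall = rc[1], specificity = sp[1], f1 = f1[1],
      support = TP + FN,
      degenerate = any(c(pr[2], rc[2], sp[2], f1[2]) == 1)
    )
  }
  per_class <- dplyr::bind_rows(rows)
  micro_tp <- sum(diag(cm))
  structure(
    list(
      per_class = per_class,
      overall_accuracy = micro_tp / total,
      macro = tibble::tibble(
        accuracy = mean(per_class$accuracy),
        precision = mean(per_class$precision),
        recall = mean(per_class$recall),
        specificity = mean(per_class$specificity),
        f1 = mean(per_class$f1)
      ),
      micro = tibble::tibble(
        precision = micro_tp / total, recall = micro_tp / total,
        f1 = micro_tp / total
      ),
      n = total
    ),
    class = "scinti_metrics"
  )
}

#' @export
print.scinti_metrics <- function(x, ...) {
  cat(sprintf("<scinti_metrics> %d samples, overall accuracy %.4f\n",
              x$n, x$overall_accuracy))
  print(x$per_class)
  cat("macro:\n"); print(x$macro)
  invisible(x)
}

# binary ROC by threshold sweep; scores higher => more positive
roc_binary <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NULL)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- positive[ord]
  # group tied scores so the curve steps once per distinct threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos, 1)
  fpr <- c(0, fp[last] / n_neg, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(curve = tibble::tibble(fpr = fpr, tpr = tpr), auc = auc)
}

#' ROC curves and AUC
#'
#' Binary problems get the standard threshold-sweep ROC with trapezoidal
#' area, which equals the rank (Mann-Whitney) probability that a random
#' positive is scored above a random negative (ties count one half).
#' Multiclass problems get one one-vs-rest curve per class, their unweighted
#' mean as the macro AUC (the headline number), and a micro-averaged pooled
#' curve for a single-curve presentation.
#'
#' @param truth Vector of true class names (or indices).
#' @param scores Matrix of per-class scores, one column per class
#'   (column names taken as class names; otherwise `labels`). A bare vector
#'   is treated as the positive-class score of a binary problem with
#'   `truth` logical or two-valued.
#' @param labels Optional class-name vector fixing column interpretation.
#' @return A `scinti_roc` list: `per_class` tibble (`class`, `auc`),
#'   `curves` tibble (`class`, `fpr`, `tpr`, including a `"micro"` curve),
#'   `macro_auc`, `micro_auc`.
#' @export
roc_auc <- function(truth, scores, labels = NULL) {
  if (is.null(dim(scores))) {
    pos <- if (is.logical(truth)) truth else truth == sort(unique(truth))[2]
    r <- roc_binary(scores, pos)
    if (is.null(r)) abort("Need at least one positive and one negative sample")
    r$curve$class <- "binary"
    return(structure(
      list(per_class = tibble::tibble(class = "binary", auc = r$auc),
           curves = r$curve[, c("class", "fpr", "tpr")],
           macro_auc = r$auc, micro_auc = r$auc),
      class = "scinti_roc"
    ))
  }
  labels <- labels %||% colnames(scores) %||%
    (if (ncol(scores) == 3) scinti_classes() else as.character(seq_len(ncol(scores))))
  truth <- as.character(truth)
  per <- list(); curves <- list()
  for (j in seq_along(labels)) {
    r <- roc_binary(scores[, j], truth == labels[j])
    if (is.null(r)) {
      warn(sprintf("Class %s has no positives or no negatives; excluded from AUC",
                   labels[j]))
      next
    }
    per[[length(per) + 1]] <- tibble::tibble(class = labels[j], auc = r$auc)
    r$curve$class <- labels[j]
    curves[[length(curves) + 1]] <- r$curve[, c("class", "fpr", "tpr")]
  }
  if (length(per) == 0) abort("No class had both positives and negatives")
  micro <- roc_binary(
    as.numeric(scores),
    as.logical(outer(truth, labels, `==`))
  )
  micro$curve$class <- "micro"
  per_class <- dplyr::bind_rows(per)
  structure(
    list(
      per_class = per_class,
      curves = dplyr::bind_rows(c(curves, list(micro$curve[, c("class", "fpr", "tpr")]))),
      macro_auc = mean(per_class$auc),
      micro_auc = micro$auc
    ),
    class = "scinti_roc"
  )
}

#' @export
print.scinti_roc <- function(x, ...) {
  cat(sprintf("<scinti_roc> macro AUC %.4f, micro AUC %.4f\n",
              x$macro_auc, x$micro_auc))
  print(x$per_class)
  invisible(x)
}

#' Merge the two metastatic classes of a label vector
#'
#' Maps `ADMet` and `nADMet` to `Met`, leaving `NoMet`; used for the
#' two-class (metastatic vs non-metastatic) evaluation.
#'
#' @param label Character vector of three-class labels.
#' @return Character vector over `{NoMet, Met}`.
#' @export
merge_metastatic <- function(label) {
  check_labels(label)
  ifelse(label == "NoMet", "NoMet", "Met")
}

#' Evaluate a trained classifier on held-out studies
#'
#' Predicts the manifest rows named by `split$test_ids` (or all rows) and
#' assembles the full report: confusion matrix, one-vs-rest metric suite and
#' ROC/AUC. With `merge_metastatic = TRUE` the three-class predictions are
#' collapsed to metastatic vs non-metastatic (probabilities of the two
#' metastatic classes are summed) before evaluation.
#'
#' @param model A trained `scinti_model`.
#' @param manifest Manifest with the model's image column.
#' @param split Optional [split_dataset()]; evaluation uses its test side.
#' @param image_col Image list-column name.
#' @param merge_metastatic Collapse to the two-class problem?
#' @return A `scinti_report` list: `confusion`, `metrics`, `roc`,
#'   `predictions` (tibble).
#' @export
evaluate_model <- function(model, manifest, split = NULL,
                           image_col = "composite", merge_metastatic = FALSE) {
  rows <- if (is.null(split)) manifest else
    manifest[manifest$study_id %in% split$test_ids, , drop = FALSE]
  if (nrow(rows) == 0) abort("No studies to evaluate")
  preds <- predict(model, rows, image_col = image_col)
  truth <- rows$label
  if (merge_metastatic && model$spec$num_classes == 3) {
    truth <- merge_metastatic(truth)
    probs <- cbind(
      NoMet = preds$.pred_NoMet,
      Met = preds$.pred_ADMet + preds$.pred_nADMet
    )
    hard <- c("NoMet", "Met")[max.col(probs, ties.method = "first")]
    labels <- c("NoMet", "Met")
  } else {
    labels <- if (model$spec$num_classes == 3) scinti_classes() else c("NoMet", "Met")
    probs <- as.matrix(preds[, paste0(".pred_", labels)])
    colnames(probs) <- labels
    hard <- preds$.pred_class
  }
  cm <- confusion_matrix(truth, hard, labels = labels)
  structure(
    list(
      confusion = cm,
      metrics = classification_metrics(cm),
      roc = roc_auc(truth, probs, labels = labels),
      predictions = tibble::tibble(study_id = rows$study_id, truth = truth,
                                   predicted = hard)
    ),
    class = "scinti_report"
  )
}

#' @export
print.scinti_report <- function(x, ...) {
  print(x$metrics)
  cat(sprintf("AUC: macro %.4f, micro %.4f\n",
              x$roc$macro_auc, x$roc$micro_auc))
  invisible(x)
}

#' One-row summary of an evaluation report
#'
#' @param x A `scinti_report` from [evaluate_model()].
#' @param ... Unused.
#' @return Tibble with overall accuracy, macro precision/recall/F1 and
#'   macro/micro AUC.
#' @export
glance.scinti_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$metrics$overall_accuracy,
    precision = x$metrics$macro$precision,
    recall = x$metrics$macro$recall,
    f1 = x$metrics$macro$f1,
    macro_auc = x$roc$macro_auc,
    micro_auc = x$roc$micro_auc,
    n = x$metrics$n
  )
}
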