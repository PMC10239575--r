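#' Confusion counts between predicted and ground-truth neighbor edges
#'
#' Classifies every unordered pair of cells: predicted edges present in the
#' ground truth are true positives (TP); predicted edges absent from the
#' truth are false positives (FP); true contacts the algorithm missed are
#' false negatives (FN); pairs connected in neither graph are true
#' negatives (TN). The four counts partition the `choose(n, 2)` pair
#' universe.
#'
#' @param predicted predicted edges: a `neighbor_graph` (its kept edges are
#'   used) or a 2-column matrix / data frame of id pairs.
#' @param truth ground-truth edges, same forms as `predicted`.
#' @param node_ids integer ids of all cells (defines the pair universe).
#' @return Object of class `confusion_counts`: list with `TP`, `FP`, `FN`,
#'   `TN`, `n_nodes`.
#' @examples
#' confusion_counts(rbind(c(0, 1), c(2, 3)), rbind(c(0, 1), c(1, 2)), 0:3)
#' @export
confusion_counts <- function(predicted, truth, node_ids) {
  pred <- as_edge_matrix(predicted)
  tru <- as_edge_matrix(truth)
  node_ids <- as.integer(node_ids)
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")
  check_members <- function(e, what) {
    bad <- setdiff(unique(as.vector(e)), node_ids)
    if (length(bad)) {
      stop(what, " edges reference unknown node id(s): ", paste(bad, collapse = ", "))
    }
  }
  check_members(pred, "predicted")
  check_members(tru, "truth")
  pk <- edge_key(pred[, 1], pred[, 2])
  tk <- edge_key(tru[, 1], tru[, 2])
  TP <- sum(pk %in% tk)
  FP <- nrow(pred) - TP
  FN <- nrow(tru) - TP
  n <- length(node_ids)
  TN <- as.integer(choose(n, 2)) - TP - FP - FN
  structure(
    list(TP = TP, FP = FP, FN = FN, TN = TN, n_nodes = n),
    class = "confusion_counts"
  )
}

as_edge_matrix <- function(x) {
  if (inherits(x, "neighbor_graph")) {
    return(kept_edges(x))
  }
  normalize_edges(x)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(
    sprintf(
      "Confusion counts over %d pairs (%d nodes): TP=%d FP=%d FN=%d TN=%d\n",
      x$TP + x$FP + x$FN + x$TN, x$n_nodes, x$TP, x$FP, x$FN, x$TN
    )
  )
  invisible(x)
}

#' Performance metrics of a predicted neighbor graph
#'
#' Computes the true positive rate `TPR = TP/(TP+FN)` (sensitivity: the
#' coverage of true contacts), positive predictive value
#' `PPV = TP/(TP+FP)` (precision: the fraction of predictions that are
#' real), Jaccard index `JI = TP/(TP+FN+FP)` (overlap of the two edge
#' sets), `F1 = 2 TP/(2 TP+FP+FN)` (harmonic mean of TPR and PPV), and the
#' Matthews correlation coefficient (MCC). TPR, PPV and JI do not involve
#' TN, which is deliberate: in a sparse contact graph negatives vastly
#' outnumber positives and TN-dependent scores are inflated. MCC, which
#' does use TN, is included for completeness.
#'
#' A metric whose denominator is zero is reported as `NaN` with a warning
#' rather than silently coerced to 0, so that averages over runs are not
#' biased.
#'
#' @param counts a [confusion_counts()] object.
#' @return Object of class `metrics_report`: list with `TPR`, `PPV`, `JI`,
#'   `F1`, `MCC`, and `counts`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- as.numeric(counts$TP)
  FP <- as.numeric(counts$FP)
  FN <- as.numeric(counts$FN)
  TN <- as.numeric(counts$TN)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      warning(name, " undefined (zero denominator); reported as NaN", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  TPR <- safe_div(TP, TP + FN, "TPR")
  PPV <- safe_div(TP, TP + FP, "PPV")
  JI <- safe_div(TP, TP + FN + FP, "JI")
  F1 <- safe_div(2 * TP, 2 * TP + FP + FN, "F1")
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  MCC <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator); reported as NaN", call. = FALSE)
    NaN
  } else {
    (TP * TN - FP * FN) / mcc_den
  }
  structure(
    list(TPR = TPR, PPV = PPV, JI = JI, F1 = F1, MCC = MCC, counts = counts),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(
    sprintf(
      "TPR = %.3f  PPV = %.3f  JI = %.3f  F1 = %.3f  MCC = %.3f\n",
      x$TPR, x$PPV, x$JI, x$F1, x$MCC
    )
  )
  invisible(x)
}

#' Evaluate a predicted neighbor graph against ground truth
#'
#' Convenience wrapper: [confusion_counts()] followed by
#' [compute_metrics()].
#'
#' @inheritParams confusion_counts
#' @return A `metrics_report`.
#' @export
evaluate_graph <- function(predicted, truth, node_ids) {
  compute_metrics(confusion_counts(predicted, truth, node_ids))
}

#' Jaccard index implied by sensitivity and precision
#'
#' For a single confusion table the three TN-free metrics are linked by the
#' identity `1/JI = 1/TPR + 1/PPV - 1` (valid when TP > 0), so the Jaccard
#' index is determined by TPR and PPV. Useful for consistency-checking
#' reported metric triples.
#'
#' @param tpr true positive rate in (0, 1].
#' @param ppv positive predictive value in (0, 1].
#' @return The implied Jaccard index.
#' @examples
#' implied_jaccard(0.902, 0.948)
#' @export
implied_jaccard <- function(tpr, ppv) {
  stopifnot(all(tpr > 0), all(ppv > 0))
  1 / (1 / tpr + 1 / ppv - 1)
}
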