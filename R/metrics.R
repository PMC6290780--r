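# Confusion-matrix evaluation of inferred networks over directed gene pairs.

#' Confusion counts of a predicted network against the truth
#'
#' Every ordered gene pair `(regulator j, target i)` with `j != i` (unless
#' `include_self`) is classified: TP if predicted and true, FN if true only,
#' FP if predicted only, TN otherwise. In `strict_delay` mode a pair only
#' counts as TP when the predicted delay class (instantaneous vs delayed)
#' matches the truth; a class mismatch scores both a FN and a FP.
#'
#' @param predicted,truth [edge_set()] objects (extra columns ignored).
#' @param n_genes total gene count N.
#' @param include_self evaluate self-pairs `(j, j)`?
#' @param strict_delay require matching delay class for a TP?
#' @return list of class `confusion_counts` with `TP`, `FN`, `FP`, `TN`.
#' @export
confusion <- function(predicted, truth, n_genes, include_self = FALSE,
                      strict_delay = FALSE) {
  check <- function(df, nm) {
    if (nrow(df) && (any(df$regulator < 1 | df$regulator > n_genes) ||
                     any(df$target < 1 | df$target > n_genes)))
      stop("index error: ", nm, " edge references a gene outside 1..", n_genes)
  }
  check(predicted, "predicted"); check(truth, "truth")
  pair_mat <- function(df) {
    m <- matrix(FALSE, n_genes, n_genes)
    if (nrow(df)) m[cbind(df$regulator, df$target)] <- TRUE
    m
  }
  P <- pair_mat(predicted)
  G <- pair_mat(truth)
  eval_mask <- matrix(TRUE, n_genes, n_genes)
  if (!include_self) diag(eval_mask) <- FALSE
  hit <- P & G
  if (strict_delay && any(hit)) {
    dmat <- function(df) {
      m <- matrix(NA_character_, n_genes, n_genes)
      if (nrow(df)) m[cbind(df$regulator, df$target)] <- df$class
      m
    }
    agree <- dmat(predicted) == dmat(truth)
    agree[is.na(agree)] <- FALSE
    mismatch <- hit & !agree
    # delay-class mismatch: the true edge is missed and a wrong edge asserted
    TP <- sum(hit & agree & eval_mask)
    FN <- sum(G & eval_mask) - TP
    FP <- sum(P & eval_mask) - TP
  } else {
    TP <- sum(hit & eval_mask)
    FN <- sum(G & !P & eval_mask)
    FP <- sum(P & !G & eval_mask)
  }
  total <- sum(eval_mask)
  structure(list(TP = TP, FN = FN, FP = FP, TN = total - TP - FN - FP),
            class = "confusion_counts")
}

#' Sensitivity Sn = TP / (TP + FN)
#' @param c a [confusion()] result.
#' @return sensitivity in `[0, 1]`.
#' @export
sensitivity <- function(c) {
  if (c$TP + c$FN == 0) stop("undefined metric: no true edges (TP + FN = 0)")
  c$TP / (c$TP + c$FN)
}

#' Specificity Sp = TN / (FP + TN)
#' @param c a [confusion()] result.
#' @return specificity in `[0, 1]`.
#' @export
specificity <- function(c) {
  if (c$FP + c$TN == 0) stop("undefined metric: no true non-edges (FP + TN = 0)")
  c$TN / (c$FP + c$TN)
}

#' Parallel speedup ratio
#'
#' @param runtime_single wall-clock seconds on one node.
#' @param runtime_cluster wall-clock seconds on the cluster.
#' @return `runtime_single / runtime_cluster` (informational only).
#' @export
speedup <- function(runtime_single, runtime_cluster) {
  if (runtime_single <= 0 || runtime_cluster <= 0)
    stop("invalid argument: runtimes must be positive")
  runtime_single / runtime_cluster
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FN=%d FP=%d TN=%d\n", x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}
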