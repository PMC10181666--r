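#' Semantic segmentation metrics
#'
#' Point-level precision, recall, F1 and IoU for the two semantic classes
#' (0 = branch, 1 = leaf), plus their unweighted two-class means.  For each
#' class: precision = TP / (TP + FP), recall = TP / (TP + FN),
#' F1 = 2 P R / (P + R), IoU = TP / (TP + FP + FN).  A ratio with a zero
#' denominator is reported as 0 and flagged in the `undefined` column.
#'
#' @param true_labels,pred_labels equal-length binary vectors in \{0, 1\}.
#' @return An object of class `semantic_report`: data frame with rows
#'   "branch", "leaf" and "mean" and columns `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `iou`, `undefined`.
#' @export
semantic_metrics <- function(true_labels, pred_labels) {
  true_labels <- as.integer(true_labels)
  pred_labels <- as.integer(pred_labels)
  if (length(true_labels) == 0L) stop("empty label vectors")
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have equal length")
  if (!all(c(true_labels, pred_labels) %in% c(0L, 1L)))
    stop("labels must be binary (0 = branch, 1 = leaf)")
  per_class <- lapply(c(0L, 1L), function(cl) {
    tp <- sum(true_labels == cl & pred_labels == cl)
    fp <- sum(true_labels != cl & pred_labels == cl)
    fn <- sum(true_labels == cl & pred_labels != cl)
    safe <- function(num, den) if (den > 0) num / den else 0
    pr <- safe(tp, tp + fp)
    rc <- safe(tp, tp + fn)
    f1 <- safe(2 * pr * rc, pr + rc)
    iou <- safe(tp, tp + fp + fn)
    undef <- (tp + fp) == 0L || (tp + fn) == 0L
    data.frame(tp = tp, fp = fp, fn = fn, precision = pr, recall = rc,
               f1 = f1, iou = iou, undefined = undef)
  })
  out <- do.call(rbind, per_class)
  means <- data.frame(tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
                      precision = mean(out$precision),
                      recall = mean(out$recall),
                      f1 = mean(out$f1), iou = mean(out$iou),
                      undefined = any(out$undefined))
  out <- rbind(out, means)
  rownames(out) <- c("branch", "leaf", "mean")
  class(out) <- c("semantic_report", "data.frame")
  out
}

#' @export
print.semantic_report <- function(x, digits = 4, ...) {
  cat("Semantic segmentation report (0 = branch, 1 = leaf)\n")
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}

#' Point-level IoU of two instances
#'
#' `|A intersect B| / |A union B|` for two point-index sets over the same
#' point universe.  If both sets are empty the IoU is reported as 0 with
#' attribute `undefined = TRUE`.
#'
#' @param set_a,set_b integer index vectors.
#' @return IoU in \[0, 1\].
#' @export
instance_iou <- function(set_a, set_b) {
  set_a <- unique(as.integer(set_a))
  set_b <- unique(as.integer(set_b))
  u <- length(union(set_a, set_b))
  if (u == 0L) return(structure(0, undefined = TRUE))
  length(intersect(set_a, set_b)) / u
}

iou_matrix <- function(true_instances, pred_instances) {
  outer(seq_along(true_instances), seq_along(pred_instances),
        Vectorize(function(i, j)
          instance_iou(true_instances[[i]], pred_instances[[j]])))
}

#' Mean coverage (mCov) of an instance prediction
#'
#' The average, over ground-truth instances, of the best point-level IoU
#' achieved by any predicted instance.  Each true instance takes its best
#' match independently (no one-to-one constraint).
#'
#' @param true_instances list of point-index sets (ground truth), length
#'   >= 1.
#' @param pred_instances list of point-index sets (prediction).
#' @return mCov in \[0, 1\]; 0 if the prediction list is empty.
#' @export
mcov <- function(true_instances, pred_instances) {
  if (length(true_instances) == 0L)
    stop("need at least one ground-truth instance")
  if (length(pred_instances) == 0L) return(0)
  M <- iou_matrix(true_instances, pred_instances)
  mean(apply(M, 1, max))
}

#' Instance-level precision and recall at an IoU threshold
#'
#' Greedy one-to-one matching by descending IoU; `T` is the number of
#' matched pairs with IoU strictly greater than `threshold`.
#' `precision = T / P` (predicted instance count), `recall = T / G`
#' (ground-truth instance count).  mCov is reported alongside.
#'
#' @inheritParams mcov
#' @param threshold IoU threshold (default 0.5, strict inequality).
#' @return An object of class `instance_report`: list with `t_matched`,
#'   `n_pred`, `n_true`, `precision`, `recall`, `mcov`, `undefined`
#'   (TRUE when there are no predicted instances) and `matches` (data
#'   frame of matched pairs with their IoU).
#' @export
instance_pr <- function(true_instances, pred_instances, threshold = 0.5) {
  if (length(true_instances) == 0L)
    stop("need at least one ground-truth instance")
  G <- length(true_instances)
  P <- length(pred_instances)
  if (P == 0L) {
    return(structure(list(t_matched = 0L, n_pred = 0L, n_true = G,
                          precision = 0, recall = 0, mcov = 0,
                          undefined = TRUE,
                          matches = data.frame(true = integer(0),
                                               pred = integer(0),
                                               iou = numeric(0))),
                     class = "instance_report"))
  }
  M <- iou_matrix(true_instances, pred_instances)
  ord <- order(-M)                        # pairs by descending IoU
  used_t <- logical(G)
  used_p <- logical(P)
  mt <- integer(0); mp <- integer(0); mi <- numeric(0)
  for (o in ord) {
    i <- (o - 1L) %% G + 1L
    j <- (o - 1L) %/% G + 1L
    if (M[i, j] <= threshold) break
    if (used_t[i] || used_p[j]) next
    used_t[i] <- TRUE
    used_p[j] <- TRUE
    mt <- c(mt, i); mp <- c(mp, j); mi <- c(mi, M[i, j])
  }
  t_matched <- length(mt)
  structure(list(t_matched = t_matched, n_pred = P, n_true = G,
                 precision = t_matched / P, recall = t_matched / G,
                 mcov = mean(apply(M, 1, max)), undefined = FALSE,
                 matches = data.frame(true = mt, pred = mp, iou = mi)),
            class = "instance_report")
}

#' @export
print.instance_report <- function(x, ...) {
  cat(sprintf(paste0("Instance segmentation report: %d true, %d predicted, ",
                     "%d matched\n"), x$n_true, x$n_pred, x$t_matched))
  cat(sprintf("  precision %.4f  recall %.4f  mCov %.4f%s\n",
              x$precision, x$recall, x$mcov,
              if (x$undefined) "  (precision undefined: no predictions)"
              else ""))
  invisible(x)
}

#' Instance index sets from an instance-labeled cloud
#'
#' @param cloud a [leaf_cloud()] with instance ids, or an integer instance
#'   vector.
#' @return Named list of point-index sets, one per instance id >= 0.
#' @export
instance_sets <- function(cloud) {
  inst <- if (inherits(cloud, "leaf_cloud")) cloud$instance else
    as.integer(cloud)
  if (is.null(inst)) stop("cloud has no instance ids")
  pos <- which(inst >= 0L)
  split(pos, inst[pos])
}
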