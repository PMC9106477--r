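#' One-vs-rest confusion counts
#'
#' Tallies tp/fp/tn/fn for one class treated as positive; the four counts
#' always sum to the number of evaluated samples.
#'
#' @param truth,pred label vectors of equal length.
#' @param positive the label counted as positive.
#' @return Named integer vector \code{c(tp, fp, tn, fn)}.
#' @export
confusionCounts <- function(truth, pred, positive) {
  stopifnot(length(truth) == length(pred))
  t <- truth == positive; p <- pred == positive
  c(tp = sum(t & p), fp = sum(!t & p), tn = sum(!t & !p), fn = sum(t & !p))
}

#' Classification accuracy (percent)
#'
#' For a counts vector, \code{100 (tp + tn) / total}; for two label vectors,
#' 100 times the fraction of exact matches (the multiclass form). Invariant
#' under consistent relabeling and sample reordering.
#'
#' @param counts counts from [confusionCounts()], or a truth vector when
#'   \code{pred} is given.
#' @param pred optional predicted labels.
#' @return Percentage in [0, 100].
#' @export
classificationAccuracy <- function(counts, pred = NULL) {
  if (!is.null(pred)) return(100 * mean(counts == pred))
  total <- sum(counts)
  if (total == 0) stop("classificationAccuracy: no samples")
  unname(100 * (counts["tp"] + counts["tn"]) / total)
}

#' Sensitivity / recall (percent)
#'
#' \code{100 tp / (tp + fn)} for a counts vector; for label vectors, the
#' macro (unweighted) average of the per-class one-vs-rest sensitivities.
#'
#' @inheritParams classificationAccuracy
#' @return Percentage in [0, 100].
#' @export
sensitivityPct <- function(counts, pred = NULL) {
  if (!is.null(pred)) {
    truth <- counts
    per <- vapply(sort(unique(as.character(truth))), function(cl)
      sensitivityPct(confusionCounts(truth, pred, cl)), numeric(1))
    return(mean(per))
  }
  denom <- counts["tp"] + counts["fn"]
  if (denom == 0) stop("sensitivityPct: no positive samples (tp + fn = 0)")
  unname(100 * counts["tp"] / denom)
}

#' Mean squared error between two images
#'
#' @param a,b numeric arrays (or [RawImage-class]) of identical shape.
#' @return Mean squared difference; symmetric in its arguments.
#' @export
imageMSE <- function(a, b) {
  x <- asImageArray(a); y <- asImageArray(b)
  if (!identical(dim(x), dim(y))) stop("imageMSE: shapes differ")
  mean((x - y)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' \code{10 log10(maxValue^2 / MSE)}; identical images (MSE 0) return the
#' documented cap of 99 dB rather than infinity.
#'
#' @inheritParams imageMSE
#' @param max_value peak intensity (default 255).
#' @param cap value returned when MSE is 0 (default 99).
#' @return PSNR in dB.
#' @examples
#' imagePSNR(matrix(0, 4, 4), matrix(2, 4, 4))  # 10*log10(255^2/4)
#' @export
imagePSNR <- function(a, b, max_value = 255, cap = 99) {
  m <- imageMSE(a, b)
  if (m == 0) return(cap)
  min(cap, 10 * log10(max_value^2 / m))
}

#' Signal-to-noise ratio (dB)
#'
#' \code{10 log10(sum(a^2) / sum((a - b)^2))} with the reference signal
#' first; not symmetric in its arguments. Zero error returns the cap.
#'
#' @param a reference image; \code{b} the degraded image.
#' @inheritParams imagePSNR
#' @return SNR in dB.
#' @export
imageSNR <- function(a, b, cap = 99) {
  x <- asImageArray(a); y <- asImageArray(b)
  if (!identical(dim(x), dim(y))) stop("imageSNR: shapes differ")
  err <- sum((x - y)^2)
  if (err == 0) return(cap)
  min(cap, 10 * log10(sum(x^2) / err))
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds to build the TPR-vs-FPR curve and integrates
#' it by the trapezoid rule; tied scores are grouped so the area equals the
#' rank form \eqn{P(s^+ > s^-) + \frac{1}{2} P(s^+ = s^-)}. Multiclass
#' labels are reduced by macro one-vs-rest averaging (with \code{scores}
#' given as a matrix, one column per class).
#'
#' @param scores numeric vector of classifier scores (higher = more
#'   positive), or a matrix for the multiclass case.
#' @param labels binary labels (logical, 0/1, or two-level), or multiclass
#'   labels matching the score-matrix columns.
#' @return A list of class \code{"ROCResult"}: \code{curve} (data frame
#'   threshold/fpr/tpr, binary case), \code{auc}, and per-class AUCs for
#'   multiclass input.
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc  # 1
#' @export
rocAuc <- function(scores, labels) {
  if (is.matrix(scores)) {
    classes <- colnames(scores)
    if (is.null(classes)) classes <- as.character(seq_len(ncol(scores)))
    labels <- as.character(labels)
    present <- intersect(classes, unique(labels))
    if (length(present) < 2L)
      stop("rocAuc: need at least two classes present")
    per <- vapply(present, function(cl)
      rocAuc(scores[, cl], labels == cl)$auc, numeric(1))
    return(structure(list(curve = NULL, auc = mean(per), perClass = per),
                     class = "ROCResult"))
  }
  y <- if (is.logical(labels)) labels else {
    lv <- sort(unique(labels))
    if (length(lv) == 1L) stop("rocAuc: both classes must be present")
    if (length(lv) != 2L) stop("rocAuc: labels must be binary")
    labels == lv[2]
  }
  nPos <- sum(y); nNeg <- sum(!y)
  if (nPos == 0 || nNeg == 0) stop("rocAuc: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yy <- y[o]
  grp <- cumsum(!duplicated(s))
  tpGrp <- tapply(yy, grp, sum)
  fpGrp <- tapply(!yy, grp, sum)
  tpr <- c(0, cumsum(tpGrp) / nPos)
  fpr <- c(0, cumsum(fpGrp) / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  curve <- data.frame(threshold = c(Inf, s[!duplicated(s)]),
                      fpr = fpr, tpr = tpr)
  structure(list(curve = curve, auc = unname(auc), perClass = NULL),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROCResult: AUC = %.4f%s\n", x$auc,
              if (!is.null(x$perClass))
                paste0(" (macro over ", length(x$perClass), " classes)")
              else ""))
  invisible(x)
}

#' Write an ROC curve as CSV
#'
#' @param roc a binary [rocAuc()] result.
#' @param path destination CSV (threshold, fpr, tpr).
#' @return \code{path}, invisibly.
#' @export
writeROC <- function(roc, path) {
  if (is.null(roc$curve)) stop("writeROC: no curve (multiclass result)")
  utils::write.csv(roc$curve, path, row.names = FALSE)
  invisible(path)
}

#' Assemble the standard metrics report
#'
#' Classification metrics (accuracy, macro sensitivity, macro AUC) from
#' labels and scores, and image-fidelity metrics (MSE, PSNR, SNR) from a
#' reference/degraded image pair.
#'
#' @param truth,pred label vectors.
#' @param scores score matrix (one column per class) for the AUC.
#' @param reference,degraded image pair for MSE/PSNR/SNR (optional; NA
#'   metrics when absent).
#' @param max_value peak intensity for PSNR (default 255).
#' @return A [MetricsReport-class].
#' @export
metricsReport <- function(truth, pred, scores = NULL, reference = NULL,
                          degraded = NULL, max_value = 255) {
  acc <- classificationAccuracy(truth, pred)
  sens <- sensitivityPct(truth, pred)
  auc <- if (!is.null(scores)) rocAuc(scores, truth)$auc else NA_real_
  if (!is.null(reference) && !is.null(degraded)) {
    m <- imageMSE(reference, degraded)
    p <- imagePSNR(reference, degraded, max_value)
    s <- imageSNR(reference, degraded)
  } else m <- p <- s <- NA_real_
  new("MetricsReport", accuracy = acc, sensitivity = sens, mse = m,
      psnr = p, snr = s, auc = auc)
}

#' Serialize a metrics report as JSON
#'
#' @param report a [MetricsReport-class].
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  jsonlite::write_json(
    list(accuracy = report@accuracy, sensitivity = report@sensitivity,
         mse = report@mse, psnr = report@psnr, snr = report@snr,
         auc = report@auc),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
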