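#' @title Performance metrics
#' @description Four-class accuracy and RMSE on the mMRC scale, plus binary
#'   screening metrics where class 0 is "healthy" and classes 1-3 are
#'   "dyspneic": false positive rate (healthy called dyspneic), false
#'   negative rate (dyspneic called healthy), and the area under the ROC
#'   curve of a continuous dyspnea score.
#' @name evaluation
NULL

#' Construct an evaluation set
#'
#' @param reference_mmrc integer reference labels in 0..3, one per
#'   participant.
#' @param estimated_mmrc integer estimated labels in 0..3.
#' @param dyspnea_score optional continuous score in `[0, 1]` (by
#'   convention `1 - p[mMRC = 0]` of the final fused vector) used for AUC.
#' @return object of class `evaluation_set`.
#' @export
evaluation_set <- function(reference_mmrc, estimated_mmrc,
                           dyspnea_score = NULL) {
  stopifnot(length(reference_mmrc) == length(estimated_mmrc),
            length(reference_mmrc) >= 1,
            all(reference_mmrc %in% 0:3), all(estimated_mmrc %in% 0:3))
  if (!is.null(dyspnea_score)) {
    stopifnot(length(dyspnea_score) == length(reference_mmrc),
              all(is.finite(dyspnea_score)))
  }
  structure(list(reference_mmrc = as.integer(reference_mmrc),
                 estimated_mmrc = as.integer(estimated_mmrc),
                 dyspnea_score = dyspnea_score,
                 n = length(reference_mmrc)),
            class = "evaluation_set")
}

#' Four-class mMRC accuracy
#'
#' @param es an [evaluation_set()].
#' @return fraction of participants with estimated == reference.
#' @export
accuracy <- function(es) {
  stopifnot(inherits(es, "evaluation_set"))
  mean(es$estimated_mmrc == es$reference_mmrc)
}

#' Root mean square error on the mMRC scale
#'
#' `sqrt(mean((estimated - reference)^2))` over participants.
#'
#' @param es an [evaluation_set()].
#' @return non-negative RMSE.
#' @export
rmse <- function(es) {
  stopifnot(inherits(es, "evaluation_set"))
  sqrt(mean((es$estimated_mmrc - es$reference_mmrc)^2))
}

#' Binary false positive and false negative rates
#'
#' A false positive is a participant with reference mMRC 0 estimated as
#' 1-3; a false negative is a participant with reference mMRC >= 1
#' estimated as 0. Rates use per-class denominators: FP over the
#' reference-healthy participants, FN over the reference-dyspneic ones. A
#' rate with an empty denominator is `NA`.
#'
#' @param es an [evaluation_set()].
#' @return named numeric vector `c(fp_rate, fn_rate)`.
#' @export
fp_fn_rates <- function(es) {
  stopifnot(inherits(es, "evaluation_set"))
  healthy <- es$reference_mmrc == 0
  fp <- if (any(healthy)) mean(es$estimated_mmrc[healthy] > 0) else NA_real_
  fn <- if (any(!healthy)) mean(es$estimated_mmrc[!healthy] == 0) else NA_real_
  c(fp_rate = fp, fn_rate = fn)
}

#' Binary AUC via the Mann-Whitney statistic
#'
#' Area under the ROC curve of `dyspnea_score` against the binarized
#' reference (0 vs 1-3), computed from ranks; tied scores count one half.
#' Equivalent to trapezoidal integration of the ROC curve and invariant
#' under strictly increasing transforms of the score.
#'
#' @param es an [evaluation_set()] with `dyspnea_score` populated.
#' @return AUC in `[0, 1]`.
#' @export
auc_binary <- function(es) {
  stopifnot(inherits(es, "evaluation_set"))
  if (is.null(es$dyspnea_score)) stop("dyspnea_score is not populated")
  pos <- es$reference_mmrc >= 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both binary classes must be present")
  r <- rank(es$dyspnea_score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metrics report
#'
#' Accuracy, RMSE, binary FP/FN rates, AUC (when a score is available),
#' participant count and the 4 x 4 confusion matrix (rows = reference,
#' columns = estimate), as a plain list serializable to JSON.
#'
#' @param es an [evaluation_set()].
#' @return list of metrics.
#' @export
metrics_report <- function(es) {
  stopifnot(inherits(es, "evaluation_set"))
  cm <- table(factor(es$reference_mmrc, levels = 0:3),
              factor(es$estimated_mmrc, levels = 0:3))
  rates <- fp_fn_rates(es)
  list(
    accuracy = accuracy(es),
    rmse = rmse(es),
    fp_rate = unname(rates["fp_rate"]),
    fn_rate = unname(rates["fn_rate"]),
    auc = if (!is.null(es$dyspnea_score) &&
              length(unique(es$reference_mmrc >= 1)) == 2) {
      auc_binary(es)
    } else NA_real_,
    n = es$n,
    confusion = matrix(as.integer(cm), 4, 4,
                       dimnames = list(reference = 0:3, estimated = 0:3))
  )
}
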