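#' @title Hierarchical score fusion
#' @description Classifier outputs (4-class probability vectors over mMRC
#'   0-3) are combined element-wise with five rules - minimum, maximum,
#'   mean, median, product - each renormalized to a probability vector, and
#'   the five results are averaged. The same combiner is applied at three
#'   levels: across the two repetitions of a vocalization, across the two
#'   feature kinds (by a simple average), and across the vocalization
#'   types.
#' @name fusion
NULL

check_prob_vector <- function(p, tol = 1e-6) {
  stopifnot(length(p) == 4, all(is.finite(p)), all(p >= -tol))
  if (abs(sum(p) - 1) > tol) stop("probability vector does not sum to 1")
  invisible(p)
}

#' Combine probability vectors with the five fusion rules
#'
#' Element-wise minimum, maximum, mean, median and product across the
#' inputs; each of the five resulting vectors is renormalized to sum 1
#' (raw minima and products do not), and their arithmetic mean is returned.
#' The median of an even number of inputs is the mean of the two central
#' order statistics. A rule whose vector sums to zero is excluded with a
#' warning.
#'
#' @param vectors list of one or more probability vectors (length 4).
#' @return fused probability vector of length 4.
#' @export
five_rule_combine <- function(vectors) {
  if (length(vectors) == 0) stop("no probability vectors to combine")
  for (v in vectors) check_prob_vector(v)
  M <- do.call(cbind, vectors) # 4 x m
  rules <- list(
    min = apply(M, 1, min),
    max = apply(M, 1, max),
    mean = rowMeans(M),
    median = apply(M, 1, stats::median),
    product = apply(M, 1, prod)
  )
  kept <- list()
  for (nm in names(rules)) {
    s <- sum(rules[[nm]])
    if (s <= 0) {
      warning("fusion rule '", nm, "' produced an all-zero vector; excluded")
    } else {
      kept[[nm]] <- rules[[nm]] / s
    }
  }
  if (length(kept) == 0) stop("all fusion rules degenerate")
  out <- rowMeans(do.call(cbind, kept))
  out / sum(out)
}

#' Fuse the two repetitions of one (vocalization, feature kind) slot
#'
#' Delegates to [five_rule_combine()]. A missing repetition (`NULL`) is
#' dropped; with a single available vector the fusion is a pass-through.
#'
#' @param rep1,rep2 probability vectors (either may be `NULL`).
#' @return fused probability vector.
#' @export
fuse_repetitions <- function(rep1, rep2) {
  vs <- Filter(Negate(is.null), list(rep1, rep2))
  if (length(vs) == 0) stop("both repetitions missing")
  five_rule_combine(vs)
}

#' Fuse the time-dependent and time-independent probability vectors
#'
#' Simple element-wise average of the two feature-kind vectors of one
#' vocalization. A missing kind (`NULL`) passes the other through.
#'
#' @param time_dep,time_indep probability vectors (either may be `NULL`).
#' @return fused probability vector.
#' @export
fuse_feature_types <- function(time_dep, time_indep) {
  vs <- Filter(Negate(is.null), list(time_dep, time_indep))
  if (length(vs) == 0) stop("both feature kinds missing")
  for (v in vs) check_prob_vector(v)
  out <- Reduce(`+`, vs) / length(vs)
  out / sum(out)
}

#' Fuse the vocalization-level probability vectors
#'
#' [five_rule_combine()] over whichever subset of the /ae-ae/, /sa-sa/ and
#' counting vectors is available (supports ablation subsets; a singleton
#' passes through unchanged).
#'
#' @param ae,sa,counting probability vectors (any may be `NULL`).
#' @return final fused probability vector.
#' @export
fuse_vocalizations <- function(ae = NULL, sa = NULL, counting = NULL) {
  vs <- Filter(Negate(is.null), list(ae, sa, counting))
  if (length(vs) == 0) stop("no vocalization vectors supplied")
  five_rule_combine(vs)
}

#' Final mMRC decision from a fused probability vector
#'
#' Argmax over the four classes; ties are broken toward the lower
#' (healthier) class to bias against false positives.
#'
#' @param final probability vector of length 4.
#' @return integer mMRC estimate in 0..3.
#' @export
predict_mmrc <- function(final) {
  check_prob_vector(final)
  which.max(final) - 1L
}
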