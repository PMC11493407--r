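# Linear radiomic signature evaluation and generic binary-classification
# metrics (ROC/AUC, confusion matrix).

#' Load a radiomic signature from JSON
#'
#' A signature is an intercept plus an ordered list of (feature name,
#' coefficient) terms. `"builtin:mc2"` loads the shipped five-feature
#' signature discriminating the MC-II subtype.
#'
#' @param source JSON file path, or `"builtin:mc2"`.
#' @return list with `name`, `intercept` and `terms` (named numeric vector).
#' @export
load_radscore_signature <- function(source = "builtin:mc2") {
  path <- if (identical(source, "builtin:mc2"))
    system.file("extdata", "radscore_mc2.json", package = "airomics",
                mustWork = TRUE)
  else source
  sig <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- unlist(sig$terms)
  if (anyDuplicated(names(terms))) stop("duplicate feature names in signature")
  if (!all(is.finite(c(sig$intercept, terms))))
    stop("non-finite signature coefficients")
  list(name = sig$name, intercept = sig$intercept, terms = terms)
}

#' Evaluate a linear radiomic signature on one feature map
#'
#' `intercept + sum(coefficient * value)` over the signature's terms, on
#' raw feature values (no scaling applied).
#'
#' @param features named numeric vector (or single-row data.frame) of
#'   radiomic feature values.
#' @param signature signature list from [load_radscore_signature()].
#' @return the radiomic score (real).
#' @export
evaluate_radscore <- function(features, signature = load_radscore_signature()) {
  if (is.data.frame(features)) features <- unlist(features[1L, ])
  missing_feats <- setdiff(names(signature$terms), names(features))
  if (length(missing_feats) > 0L)
    stop("missing signature feature(s): ",
         paste(missing_feats, collapse = ", "))
  unname(signature$intercept +
           sum(signature$terms * features[names(signature$terms)]))
}

#' Evaluate a radiomic signature over a feature table
#'
#' @param table data.frame with one row per patient and the signature's
#'   features as columns.
#' @param signature signature list from [load_radscore_signature()].
#' @return numeric vector of scores, one per row.
#' @export
evaluate_radscore_table <- function(table,
                                    signature = load_radscore_signature()) {
  missing_feats <- setdiff(names(signature$terms), names(table))
  if (length(missing_feats) > 0L)
    stop("missing signature feature(s): ",
         paste(missing_feats, collapse = ", "))
  m <- as.matrix(table[, names(signature$terms), drop = FALSE])
  unname(signature$intercept + drop(m %*% signature$terms))
}

#' ROC curve and AUC for binary discrimination scores
#'
#' AUC via the rank (Mann-Whitney) formulation with midrank tie handling;
#' the full sensitivity/specificity curve over all score thresholds is
#' returned for plotting.
#'
#' @param scores numeric vector.
#' @param labels binary vector (logical, 0/1, or two-level factor); the
#'   higher/TRUE level is the positive class.
#' @return list with `auc`, `thresholds`, `sensitivity`, `specificity`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("undefined AUC: both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1L) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & y == 0L) / n0, numeric(1))
  list(auc = auc, thresholds = thr, sensitivity = sens, specificity = spec)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(droplevels(labels)) > 2L) stop("labels must be binary")
    return(as.integer(labels == levels(droplevels(labels))[2L]))
  }
  u <- sort(unique(labels))
  if (length(u) > 2L) stop("labels must be binary")
  as.integer(labels == max(u))
}

#' Confusion matrix and accuracy at a score threshold
#'
#' Scores at or above the threshold are predicted positive.
#'
#' @param scores numeric vector.
#' @param labels binary truth vector.
#' @param threshold decision threshold (finite).
#' @return list with `confusion` (2x2 matrix: predicted x truth) and
#'   `accuracy`.
#' @export
confusion_accuracy <- function(scores, labels, threshold) {
  stopifnot(is.finite(threshold))
  y <- as_binary_labels(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  confusion <- matrix(c(tp, fp, fn, tn), 2L, byrow = TRUE,
                      dimnames = list(predicted = c("positive", "negative"),
                                      truth = c("positive", "negative")))
  list(confusion = confusion, accuracy = (tp + tn) / length(y))
}
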