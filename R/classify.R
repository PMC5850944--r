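#' Classify one patient against the two class families
#'
#' The patient's readouts are compared with the predictions of each class
#' family under the patient's own binarized input profile; the patient is
#' assigned to the class with the lower mean squared error. The confidence
#' score `mse_pr / (mse_cr + mse_pr)` lies in \[0,1\] and is oriented so that
#' 1 means complete confidence in remission (CR) and 0 complete confidence in
#' resistance (PR); an exact tie (including both errors 0) scores 0.5.
#'
#' @param cr_family,pr_family `bn_family` objects learned per class.
#' @param patient_inputs named 0/1 vector covering both families' clamped
#'   inputs.
#' @param patient_readouts named numeric vector in \[0,1\]; readouts missing
#'   from it are excluded pairwise with a warning.
#' @param tie what an exact MSE tie yields: `"CR"` (majority-class fallback,
#'   the default) or `"unknown"`.
#' @return one-row tibble: `mse_cr`, `mse_pr`, `label`, `confidence`, `tie`.
#' @export
classify_patient <- function(cr_family, pr_family, patient_inputs,
                             patient_readouts, tie = c("CR", "unknown")) {
  tie <- match.arg(tie)
  stopifnot(inherits(cr_family, "bn_family"), inherits(pr_family, "bn_family"))
  need <- union(cr_family$inputs, pr_family$inputs)
  missing <- setdiff(need, names(patient_inputs))
  if (length(missing) > 0L) {
    stop("missing input value(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rd <- union(cr_family$readouts, pr_family$readouts)
  have <- intersect(rd, names(patient_readouts))
  if (length(have) == 0L) stop("no overlapping readouts", call. = FALSE)
  if (length(have) < length(rd)) {
    warning("readout(s) not measured, excluded: ",
            paste(setdiff(rd, have), collapse = ", "), call. = FALSE)
  }
  one_mse <- function(family) {
    r <- intersect(family$readouts, have)
    if (length(r) == 0L) stop("no overlapping readouts", call. = FALSE)
    pred <- predict(family, patient_inputs[family$inputs], readouts = r)
    mean((pred - patient_readouts[r])^2)
  }
  mse_cr <- one_mse(cr_family)
  mse_pr <- one_mse(pr_family)
  is_tie <- mse_cr == mse_pr
  label <- if (is_tie) {
    if (tie == "unknown") "unknown" else "CR"
  } else if (mse_cr < mse_pr) "CR" else "PR"
  confidence <- if (mse_cr + mse_pr == 0) 0.5 else mse_pr / (mse_cr + mse_pr)
  tibble::tibble(mse_cr = mse_cr, mse_pr = mse_pr, label = label,
                 confidence = confidence, tie = is_tie)
}

#' Keep only patients whose readouts carry a significant signal
#'
#' A readout value is significant when it is close to a Boolean level:
#' below `low` or above `high`. Under `mode = "all"` (default, the strict
#' reading) every readout must be significant for the patient to be kept;
#' under `mode = "any"` one significant readout suffices.
#'
#' @param patient_readouts named numeric vector in \[0,1\].
#' @param low,high thresholds with `0 <= low < high <= 1` (defaults 0.25 and
#'   0.6).
#' @param mode `"all"` or `"any"`.
#' @return `TRUE` (keep) or `FALSE` (drop).
#' @export
filter_significant <- function(patient_readouts, low = 0.25, high = 0.6,
                               mode = c("all", "any")) {
  mode <- match.arg(mode)
  stopifnot(low >= 0, low < high, high <= 1)
  if (length(patient_readouts) == 0L) {
    warning("no readouts: patient dropped", call. = FALSE)
    return(FALSE)
  }
  sig <- patient_readouts < low | patient_readouts > high
  if (mode == "all") all(sig) else any(sig)
}

#' Classify a set of patients
#'
#' Applies [classify_patient()] to every row of a processed dataset.
#' `method = 1` classifies everyone; `method = 2` first drops patients whose
#' readouts lack a significant signal ([filter_significant()]) and labels
#' them `"excluded"`, and resolves MSE ties as `"unknown"`.
#'
#' @param cr_family,pr_family per-class `bn_family` objects.
#' @param proc a `processed_patients` object (its labels, when present, are
#'   carried into the output as `truth`).
#' @param method 1 or 2.
#' @param low,high,mode significance filter parameters (method 2).
#' @return tibble (class `bn_predictions`): `patient`, `truth`, `mse_cr`,
#'   `mse_pr`, `label`, `confidence`.
#' @export
classify_patients <- function(cr_family, pr_family, proc, method = 1,
                              low = 0.25, high = 0.6,
                              mode = c("all", "any")) {
  mode <- match.arg(mode)
  stopifnot(inherits(proc, "processed_patients"), method %in% c(1, 2))
  rows <- lapply(proc$patients, function(p) {
    inp <- stats::setNames(as.numeric(proc$inputs[p, , drop = FALSE]),
                           colnames(proc$inputs))
    ro <- stats::setNames(as.numeric(proc$readouts[p, , drop = FALSE]),
                          colnames(proc$readouts))
    if (method == 2 && !filter_significant(ro, low, high, mode)) {
      return(tibble::tibble(patient = p, mse_cr = NA_real_, mse_pr = NA_real_,
                            label = "excluded", confidence = NA_real_,
                            tie = FALSE))
    }
    res <- classify_patient(cr_family, pr_family, inp, ro,
                            tie = if (method == 2) "unknown" else "CR")
    dplyr::bind_cols(tibble::tibble(patient = p), res)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, truth = unname(proc$labels[.data$patient]),
                       .after = "patient")
  class(out) <- c("bn_predictions", class(out))
  out
}

#' Accuracy report for a set of predictions
#'
#' Per-class accuracy is computed over the classified patients of that class
#' (patients labelled `unknown` or `excluded` leave the denominators);
#' balanced accuracy is the unweighted mean of the two per-class accuracies.
#' All accuracies are percentages.
#'
#' @param predictions tibble from [classify_patients()] (columns `label` and,
#'   unless `truth` is given, `truth`).
#' @param truth optional named character vector of true labels overriding the
#'   `truth` column.
#' @return one-row tibble: `acc_cr`, `acc_pr`, `balanced` (percent; `NA` when
#'   a class has no classified patient), `n_cr`, `n_pr` (classified counts),
#'   `n_excluded`.
#' @export
evaluate_predictions <- function(predictions, truth = NULL) {
  stopifnot(is.data.frame(predictions), "label" %in% names(predictions))
  tr <- if (!is.null(truth)) {
    unname(truth[predictions$patient])
  } else predictions$truth
  if (anyNA(tr[!predictions$label %in% c("excluded")])) {
    stop("missing truth label for a classified patient", call. = FALSE)
  }
  classified <- predictions$label %in% c("CR", "PR")
  acc <- function(cl) {
    in_cl <- classified & tr == cl
    if (!any(in_cl)) return(NA_real_)
    100 * mean(predictions$label[in_cl] == cl)
  }
  acc_cr <- acc("CR")
  acc_pr <- acc("PR")
  tibble::tibble(
    acc_cr = acc_cr, acc_pr = acc_pr,
    balanced = (acc_cr + acc_pr) / 2,
    n_cr = sum(classified & tr == "CR"),
    n_pr = sum(classified & tr == "PR"),
    n_excluded = sum(!classified)
  )
}

#' @export
glance.bn_predictions <- function(x, ...) evaluate_predictions(x)
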