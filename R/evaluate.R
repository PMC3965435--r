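#' Cross-tabulate binary calls against gold labels
#'
#' Positive class is `"case"`. The two inputs must cover exactly the same
#' report ids.
#'
#' @param calls Tibble with `report_id` and logical `call` (or a
#'   `screening_result`).
#' @param labels Gold labels tibble (`report_id`, `label`).
#' @return A `confusion_counts` object with fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(calls, labels) {
  labels <- validate_labels(labels)
  if (!setequal(calls$report_id, labels$report_id) ||
      nrow(calls) != nrow(labels)) {
    stop("calls and labels must cover the same report ids", call. = FALSE)
  }
  lab <- labels$label[match(calls$report_id, labels$report_id)]
  is_case <- lab == "case"
  structure(
    list(
      tp = sum(calls$call & is_case),
      fp = sum(calls$call & !is_case),
      tn = sum(!calls$call & !is_case),
      fn = sum(!calls$call & is_case)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> tp:", x$tp, " fp:", x$fp,
      " tn:", x$tn, " fn:", x$fn, "\n")
  invisible(x)
}

#' Sensitivity and specificity with exact binomial confidence intervals
#'
#' Sensitivity is `tp / (tp + fn)`, specificity `tn / (tn + fp)`; interval
#' estimates are Clopper-Pearson exact binomial (conservative; the method
#' is recorded in the output so results are self-describing).
#'
#' @param counts A `confusion_counts` object.
#' @param level Confidence level (default 0.95).
#' @return Tibble with one row per metric: `metric`, `estimate`,
#'   `conf.low`, `conf.high`, `method`.
#' @export
sens_spec_ci <- function(counts, level = 0.95) {
  if (counts$tp + counts$fn == 0L) {
    stop("no positive-class reports: sensitivity undefined", call. = FALSE)
  }
  if (counts$tn + counts$fp == 0L) {
    stop("no negative-class reports: specificity undefined", call. = FALSE)
  }
  one <- function(metric, x, n) {
    ci <- stats::binom.test(x, n, conf.level = level)$conf.int
    tibble::tibble(metric = metric, estimate = x / n,
                   conf.low = ci[1L], conf.high = ci[2L],
                   method = "clopper-pearson")
  }
  dplyr::bind_rows(
    one("sensitivity", counts$tp, counts$tp + counts$fn),
    one("specificity", counts$tn, counts$tn + counts$fp)
  )
}

#' ROC curve and AUC with a DeLong confidence interval
#'
#' Sweeps the distinct scores as thresholds to build the ROC curve and
#' computes the area under it; the AUC equals the Mann-Whitney rank
#' statistic (ties counting one half). The interval is DeLong's. The
#' heavy lifting is delegated to pROC, the standard R implementation.
#'
#' @param scores Tibble with `report_id` and `score` (a
#'   `screening_result` works as is), or a bare numeric vector aligned
#'   with `labels`.
#' @param labels Gold labels tibble.
#' @param level Confidence level for the AUC interval.
#' @return An `aefi_roc` object: `curve` (tibble `threshold`, `fpr`,
#'   `tpr`), `auc`, `auc_ci`, class counts and the `pROC::roc` fit.
#' @export
roc_auc_ci <- function(scores, labels, level = 0.95) {
  labels <- validate_labels(labels)
  if (is.data.frame(scores)) {
    lab <- labels$label[match(scores$report_id, labels$report_id)]
    if (anyNA(lab)) stop("unlabeled reports in scores", call. = FALSE)
    s <- scores$score
  } else {
    if (length(scores) != nrow(labels)) {
      stop("scores and labels lengths differ", call. = FALSE)
    }
    lab <- labels$label
    s <- scores
  }
  if (length(unique(lab)) < 2L) {
    stop("both classes must be represented to compute a ROC curve",
         call. = FALSE)
  }
  fit <- pROC::roc(response = lab, predictor = s,
                   levels = c("non_case", "case"), direction = "<",
                   quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(fit, conf.level = level, method = "delong"))
  curve <- tibble::tibble(
    threshold = rev(fit$thresholds),
    fpr = rev(1 - fit$specificities),
    tpr = rev(fit$sensitivities)
  )
  structure(
    list(curve = curve, auc = as.numeric(pROC::auc(fit)),
         auc_ci = c(lower = ci[1L], upper = ci[3L]), level = level,
         n_case = sum(lab == "case"), n_non_case = sum(lab == "non_case"),
         roc = fit),
    class = "aefi_roc"
  )
}

#' @export
print.aefi_roc <- function(x, ...) {
  cat(sprintf(
    "<aefi_roc> AUC %.3f (%.0f%% CI %.3f-%.3f), %d cases / %d non-cases\n",
    x$auc, 100 * x$level, x$auc_ci[["lower"]], x$auc_ci[["upper"]],
    x$n_case, x$n_non_case))
  invisible(x)
}

#' Compare classification methods on one labeled corpus
#'
#' Builds the standard comparison table — one row per method with
#' sensitivity and specificity (Clopper-Pearson intervals) and, for
#' methods producing scores, the AUC with its DeLong interval. Each
#' method is given as a tibble of binary calls (`report_id`, `call`) or
#' of scores (`report_id`, `score`, and optionally `call`); scores
#' without calls are thresholded at the method's `"threshold"` attribute
#' when present.
#'
#' @param labels Gold labels tibble.
#' @param ... Named method results.
#' @param level Confidence level.
#' @return A tibble with one row per method.
#' @examples
#' \donttest{
#' sim <- simulate_corpus(sim_config(n_reports = 400, seed = 7))
#' eng <- classify_reports(sim$reports, build_catalog("updated"))
#' mod <- fit_screening(sim$reports, sim$labels)
#' compare_methods(sim$labels,
#'                 brighton_updated = brighton_calls(eng),
#'                 expanded_smq = screen(sim$reports, mod))
#' }
#' @export
compare_methods <- function(labels, ..., level = 0.95) {
  methods <- list(...)
  stopifnot(length(methods) > 0L, !is.null(names(methods)),
            all(nzchar(names(methods))))
  purrr::imap_dfr(methods, function(m, name) {
    has_score <- "score" %in% names(m)
    calls <- if ("call" %in% names(m)) {
      m[, c("report_id", "call")]
    } else if (has_score && !is.null(attr(m, "threshold"))) {
      tibble::tibble(report_id = m$report_id,
                     call = m$score >= attr(m, "threshold"))
    } else {
      stop("method '", name, "' provides neither calls nor a threshold",
           call. = FALSE)
    }
    ss <- sens_spec_ci(confusion(calls, labels), level = level)
    row <- tibble::tibble(
      method = name,
      sensitivity = ss$estimate[ss$metric == "sensitivity"],
      sens_low = ss$conf.low[ss$metric == "sensitivity"],
      sens_high = ss$conf.high[ss$metric == "sensitivity"],
      specificity = ss$estimate[ss$metric == "specificity"],
      spec_low = ss$conf.low[ss$metric == "specificity"],
      spec_high = ss$conf.high[ss$metric == "specificity"],
      auc = NA_real_, auc_low = NA_real_, auc_high = NA_real_
    )
    if (has_score) {
      roc <- roc_auc_ci(m[, c("report_id", "score")], labels, level = level)
      row$auc <- roc$auc
      row$auc_low <- roc$auc_ci[["lower"]]
      row$auc_high <- roc$auc_ci[["upper"]]
    }
    row
  })
}
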