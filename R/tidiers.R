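#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ROC fit into its curve points
#'
#' @param x An `aefi_roc` from [roc_auc_ci()].
#' @param ... Unused.
#' @return Tibble with `threshold`, `fpr`, `tpr`.
#' @method tidy aefi_roc
#' @export
tidy.aefi_roc <- function(x, ...) x$curve

#' One-row summary of a ROC fit
#'
#' @param x An `aefi_roc`.
#' @param ... Unused.
#' @return Tibble with `auc`, `auc_low`, `auc_high`, `conf.level`,
#'   `n_case`, `n_non_case`, `ci_method`.
#' @method glance aefi_roc
#' @export
glance.aefi_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, auc_low = x$auc_ci[["lower"]], auc_high = x$auc_ci[["upper"]],
    conf.level = x$level, n_case = x$n_case, n_non_case = x$n_non_case,
    ci_method = "delong"
  )
}

#' Plot a ROC curve
#'
#' @param object An `aefi_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot aefi_roc
#' @export
autoplot.aefi_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve, AUC %.3f (%.0f%% CI %.3f-%.3f)",
                      object$auc, 100 * object$level,
                      object$auc_ci[["lower"]], object$auc_ci[["upper"]])
    ) +
    ggplot2::theme_minimal()
}

#' Tidy a confusion-count object
#'
#' @param x A `confusion_counts`.
#' @param ... Unused.
#' @return Long tibble with `cell` and `n`.
#' @method tidy confusion_counts
#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble::tibble(cell = c("tp", "fp", "tn", "fn"),
                 n = c(x$tp, x$fp, x$tn, x$fn))
}

#' Summarise a confusion-count object
#'
#' @param x A `confusion_counts`.
#' @param level Confidence level passed to [sens_spec_ci()].
#' @param ... Unused.
#' @return One-row tibble with the counts, sensitivity and specificity
#'   and their exact binomial intervals.
#' @method glance confusion_counts
#' @export
glance.confusion_counts <- function(x, level = 0.95, ...) {
  ss <- sens_spec_ci(x, level = level)
  tibble::tibble(
    tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
    sensitivity = ss$estimate[1L], sens_low = ss$conf.low[1L],
    sens_high = ss$conf.high[1L],
    specificity = ss$estimate[2L], spec_low = ss$conf.low[2L],
    spec_high = ss$conf.high[2L]
  )
}

#' Tidy a screening model's term list
#'
#' @param x A `screening_model`.
#' @param ... Unused.
#' @return The expanded-SMQ tibble (`code`, `provenance`) joined with the
#'   model's idf weights where defined.
#' @method tidy screening_model
#' @export
tidy.screening_model <- function(x, ...) {
  dplyr::left_join(x$smq, x$idf, by = "code")
}

#' One-row summary of a screening model
#'
#' @param x A `screening_model`.
#' @param ... Unused.
#' @return Tibble with term counts by provenance, threshold and alpha.
#' @method glance screening_model
#' @export
glance.screening_model <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x$smq),
    n_base = sum(x$smq$provenance %in% c("base_smq", "both")),
    n_selected = sum(x$smq$provenance %in% c("chi2_selected", "both")),
    threshold = x$threshold,
    alpha = x$alpha,
    n_train = length(x$train_ids)
  )
}

#' Plot the score distribution of a screening result
#'
#' Histograms of cosine scores, faceted or coloured by gold label when
#' labels are supplied, with the decision threshold marked.
#'
#' @param object A `screening_result` from [screen()].
#' @param labels Optional gold labels tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot screening_result
#' @export
autoplot.screening_result <- function(object, labels = NULL, ...) {
  df <- tibble::as_tibble(object)
  thr <- attr(object, "threshold")
  if (!is.null(labels)) {
    labels <- validate_labels(labels)
    df$label <- labels$label[match(df$report_id, labels$report_id)]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$label)) +
      ggplot2::geom_histogram(bins = 40, alpha = 0.7, position = "identity") +
      ggplot2::scale_fill_manual(values = c(case = "#b2182b",
                                            non_case = "#2166ac"))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
      ggplot2::geom_histogram(bins = 40, fill = "#2166ac", alpha = 0.8)
  }
  p +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "Cosine similarity to SMQ query", y = "Reports") +
    ggplot2::theme_minimal()
}

#' Plot the category distribution of classification results
#'
#' @param object A `brighton_classifications` tibble.
#' @param ... Unused.
#' @return A ggplot bar chart over the six outcome categories.
#' @method autoplot brighton_classifications
#' @export
autoplot.brighton_classifications <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$category <- factor(df$category, levels = brighton_categories)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_bar(fill = "#2166ac") +
    ggplot2::labs(x = "Brighton outcome category", y = "Reports",
                  title = paste("Catalog variant:", df$variant[1L])) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
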