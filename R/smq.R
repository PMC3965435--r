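#' Chi-square scores for every reporting term against the gold label
#'
#' For each distinct raw term in the corpus, builds the 2x2 contingency
#' table of term presence against the expert gold label and computes the
#' uncorrected Pearson chi-square statistic
#' \deqn{\chi^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}
#' with `a` = term present & case, `b` = term present & non-case,
#' `c` = term absent & case, `d` = term absent & non-case, together with
#' its df = 1 p-value. A term with a degenerate marginal (present in every
#' report or correlated with a single-class corpus) scores 0. No
#' continuity correction is applied: the selection rule compares the raw
#' statistic against the uncorrected critical value (3.841 at alpha 0.05).
#'
#' @param corpus An `aefi_corpus`.
#' @param labels Gold labels tibble (`report_id`, `label`).
#' @return Tibble with one row per distinct term: `code`, `a`, `b`, `c`,
#'   `d`, `chi2`, `p_value`, sorted by decreasing `chi2`.
#' @export
chi2_scores <- function(corpus, labels) {
  if (nrow(corpus) == 0L) stop("empty corpus", call. = FALSE)
  labels <- validate_labels(labels)
  lab <- labels$label[match(corpus$report_id, labels$report_id)]
  if (anyNA(lab)) {
    stop("every report must be labeled; missing: ",
         paste(utils::head(corpus$report_id[is.na(lab)], 5L), collapse = ", "),
         call. = FALSE)
  }
  n_case <- sum(lab == "case")
  n_non <- sum(lab == "non_case")
  long <- tibble::tibble(
    is_case = rep(lab == "case", lengths(corpus$raw_terms)),
    code = unlist(corpus$raw_terms, use.names = FALSE) %||% character(0)
  )
  counts <- dplyr::summarise(
    dplyr::group_by(long, code),
    a = sum(is_case), b = sum(!is_case), .groups = "drop"
  )
  counts$a <- as.numeric(counts$a)
  counts$b <- as.numeric(counts$b)
  counts$c <- n_case - counts$a
  counts$d <- n_non - counts$b
  N <- n_case + n_non
  with(counts, {
    denom <- (a + b) * (c + d) * (a + c) * (b + d)
    chi2 <- ifelse(denom == 0, 0, N * (a * d - b * c)^2 / denom)
    out <- tibble::tibble(
      code = counts$code, a = a, b = b, c = c, d = d,
      chi2 = chi2,
      p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    )
    dplyr::arrange(out, dplyr::desc(chi2), code)
  })
}

#' Select terms significantly associated with the gold label
#'
#' Keeps the terms whose uncorrected chi-square statistic strictly exceeds
#' the df = 1 critical value at `alpha` (3.841 for alpha = 0.05). Smaller
#' `alpha` always selects a subset of a larger one.
#'
#' @inheritParams chi2_scores
#' @param alpha Significance level in (0, 1).
#' @return The selected subset of the [chi2_scores()] tibble.
#' @export
chi2_select <- function(corpus, labels, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  scores <- chi2_scores(corpus, labels)
  scores[scores$chi2 > stats::qchisq(1 - alpha, df = 1), ]
}

#' Read a base SMQ-style term list
#'
#' One code per line; blank lines ignored. The shipped
#' `smq_base_synthetic.txt` is a synthetic 77-term stand-in for a real
#' anaphylaxis SMQ (real SMQ term lists are licensed MedDRA content).
#'
#' @param path Path to the term list; default is the shipped synthetic one.
#' @return Character vector of codes.
#' @export
read_base_smq <- function(path = NULL) {
  path <- path %||% system.file("extdata", "smq_base_synthetic.txt",
                                package = "brightonaefi", mustWork = TRUE)
  x <- readr::read_lines(path)
  x <- stringr::str_trim(x)
  unique(x[nzchar(x)])
}

#' Expand a base SMQ with chi-square selected terms
#'
#' Union of the base term list and the selected terms, duplicates removed,
#' with per-term provenance (`base_smq`, `chi2_selected`, or `both`).
#'
#' @param base Character vector of base SMQ codes.
#' @param selected A [chi2_select()] tibble or a character vector of codes.
#' @return An `expanded_smq` tibble with columns `code`, `provenance`.
#' @export
expand_smq <- function(base, selected) {
  sel <- if (is.data.frame(selected)) selected$code else selected
  base <- unique(base)
  sel <- unique(sel)
  codes <- union(base, sel)
  out <- tibble::tibble(
    code = codes,
    provenance = dplyr::case_when(
      codes %in% base & codes %in% sel ~ "both",
      codes %in% base ~ "base_smq",
      TRUE ~ "chi2_selected"
    )
  )
  class(out) <- c("expanded_smq", class(out))
  out
}

#' Inverse document frequencies of a corpus
#'
#' `idf(t) = ln(N / df_t)` over the distinct raw terms of the corpus
#' (document frequency `df_t >= 1` by construction; no smoothing). Terms
#' never seen in the fitting corpus carry no weight and drop out of any
#' query vector.
#'
#' @param corpus An `aefi_corpus`.
#' @return Tibble with columns `code`, `df`, `idf`.
#' @export
fit_idf <- function(corpus) {
  if (nrow(corpus) == 0L) stop("empty corpus", call. = FALSE)
  N <- nrow(corpus)
  counts <- table(unlist(lapply(corpus$raw_terms, unique), use.names = FALSE))
  tibble::tibble(
    code = names(counts),
    df = as.integer(counts),
    idf = log(N / as.integer(counts))
  )
}

#' Fit a tf-idf cosine screening model
#'
#' Builds the expanded SMQ (chi-square selection over the training
#' reports, union with the base list), fits idf weights on the training
#' reports, and picks the default score threshold as the Youden-J
#' maximizer of the training ROC. With `split` in (0, 1) the corpus is
#' partitioned at random and only the training fraction is used for all
#' three steps, leaving the held-out reports for honest evaluation
#' (`model$test_ids`); with `split = NULL` the full corpus is used for
#' both (the primary-analysis mode).
#'
#' @param corpus An `aefi_corpus`.
#' @param labels Gold labels tibble.
#' @param base_smq Character vector of base SMQ codes; defaults to the
#'   shipped synthetic list.
#' @param alpha Chi-square selection significance level.
#' @param split Training fraction in (0, 1), or `NULL` for full-corpus
#'   fitting.
#' @param tf `"binary"` (term sets; the default, matching coded-report
#'   annotations) or `"count"` (raw occurrence counts).
#' @return A `screening_model` with the expanded SMQ, idf table,
#'   threshold, and the train/test partition.
#' @export
fit_screening <- function(corpus, labels, base_smq = read_base_smq(),
                          alpha = 0.05, split = NULL,
                          tf = c("binary", "count")) {
  tf <- match.arg(tf)
  labels <- validate_labels(labels)
  if (!is.null(split)) {
    stopifnot(split > 0, split < 1)
    idx <- sample.int(nrow(corpus), size = round(split * nrow(corpus)))
    train <- corpus[sort(idx), ]
    class(train) <- class(corpus)
    test_ids <- corpus$report_id[-sort(idx)]
  } else {
    train <- corpus
    test_ids <- corpus$report_id
  }
  selected <- chi2_select(train, labels[labels$report_id %in% train$report_id, ],
                          alpha = alpha)
  smq <- expand_smq(base_smq, selected)
  idf <- fit_idf(train)
  model <- structure(
    list(smq = smq, idf = idf, threshold = NA_real_, alpha = alpha,
         tf = tf, train_ids = train$report_id, test_ids = test_ids),
    class = "screening_model"
  )
  train_scores <- cosine_score(train, model)
  train_lab <- labels$label[match(train$report_id, labels$report_id)]
  roc <- pROC::roc(response = train_lab, predictor = train_scores,
                   levels = c("non_case", "case"), direction = "<",
                   quiet = TRUE)
  best <- pROC::coords(roc, "best", best.method = "youden",
                       ret = "threshold", transpose = FALSE)
  thr <- best$threshold[1L]
  if (!is.finite(thr)) thr <- 0.5  # degenerate ROC (e.g. all scores equal)
  model$threshold <- thr
  model
}

#' @export
print.screening_model <- function(x, ...) {
  cat("<screening_model> ", nrow(x$smq), " SMQ terms (",
      sum(x$smq$provenance != "base_smq"), " chi2-selected), ",
      nrow(x$idf), " idf weights, threshold ",
      formatC(x$threshold, digits = 4, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Cosine similarity of reports to the SMQ query
#'
#' Each report is a tf-idf weighted vector over its raw terms (binary tf
#' by default); the query is the SMQ term set with tf 1 and the same idf
#' weights. The score is the cosine of the angle between the two vectors:
#' 1 for identical term profiles, 0 for reports sharing no weighted term
#' with the query (including reports whose vector is all zero).
#'
#' @param corpus An `aefi_corpus` (any corpus, not only the fitting one).
#' @param model A `screening_model`.
#' @return Numeric vector of scores in `[0, 1]`, one per report.
#' @export
cosine_score <- function(corpus, model) {
  vocab <- model$idf$code
  w <- model$idf$idf
  q <- numeric(length(vocab))
  q[vocab %in% model$smq$code] <- w[vocab %in% model$smq$code]
  q_norm <- sqrt(sum(q^2))
  n <- nrow(corpus)
  if (n == 0L) return(numeric(0))

  terms <- corpus$raw_terms
  if (model$tf == "binary") terms <- lapply(terms, unique)
  rows <- rep(seq_len(n), lengths(terms))
  cols <- match(unlist(terms, use.names = FALSE), vocab)
  keep <- !is.na(cols)
  if (!any(keep) || q_norm == 0) return(numeric(n))
  X <- Matrix::sparseMatrix(
    i = rows[keep], j = cols[keep], x = w[cols[keep]],
    dims = c(n, length(vocab))
  )
  num <- as.numeric(X %*% q)
  r_norm <- sqrt(Matrix::rowSums(X^2))
  score <- ifelse(r_norm == 0, 0, num / (r_norm * q_norm))
  pmin(pmax(score, 0), 1)
}

#' Score and threshold a corpus with a screening model
#'
#' @inheritParams cosine_score
#' @param threshold Score cutoff; defaults to the model's fitted
#'   (training Youden) threshold. A report is called positive when its
#'   score is at or above the cutoff.
#' @return A `screening_result` tibble: `report_id`, `score`, `call`.
#' @export
screen <- function(corpus, model, threshold = NULL) {
  threshold <- threshold %||% model$threshold
  if (!is.finite(threshold)) stop("model has no threshold", call. = FALSE)
  out <- tibble::tibble(
    report_id = corpus$report_id,
    score = cosine_score(corpus, model)
  )
  out$call <- out$score >= threshold
  attr(out, "threshold") <- threshold
  class(out) <- c("screening_result", class(out))
  out
}
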