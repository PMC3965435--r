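test_that("confusion counts equal a brute-force tally", {
  set.seed(201)
  ids <- sprintf("r%03d", 1:100)
  is_case <- stats::runif(100) < 0.3
  call <- stats::runif(100) < 0.5
  counts <- confusion(tibble::tibble(report_id = ids, call = call),
                      labels_tbl(ids, is_case))
  expect_equal(counts$tp, sum(call & is_case))
  expect_equal(counts$fp, sum(call & !is_case))
  expect_equal(counts$tn, sum(!call & !is_case))
  expect_equal(counts$fn, sum(!call & is_case))
  expect_equal(counts$tp + counts$fp + counts$tn + counts$fn, 100)

  perfect <- confusion(tibble::tibble(report_id = ids, call = is_case),
                       labels_tbl(ids, is_case))
  expect_equal(c(perfect$fp, perfect$fn), c(0L, 0L))
  none <- confusion(tibble::tibble(report_id = ids, call = FALSE),
                    labels_tbl(ids, is_case))
  expect_equal(c(none$tp, none$fp), c(0L, 0L))

  expect_error(
    confusion(tibble::tibble(report_id = c(ids[-1], "zzz"), call = call),
              labels_tbl(ids, is_case)),
    "same report ids"
  )
})

test_that("sensitivity/specificity and exact intervals match the beta oracle", {
  counts <- structure(list(tp = 9L, fn = 1L, tn = 8L, fp = 2L),
                      class = "confusion_counts")
  ss <- sens_spec_ci(counts)
  expect_equal(ss$estimate, c(0.9, 0.8))
  # Clopper-Pearson endpoints straight from beta quantiles (x=9, n=10)
  expect_equal(ss$conf.low[1L], stats::qbeta(0.025, 9, 2))
  expect_equal(ss$conf.high[1L], stats::qbeta(0.975, 10, 1))
  # perfect sensitivity keeps the upper endpoint at 1
  all_found <- structure(list(tp = 10L, fn = 0L, tn = 5L, fp = 5L),
                         class = "confusion_counts")
  ss2 <- sens_spec_ci(all_found)
  expect_equal(ss2$estimate[1L], 1)
  expect_equal(ss2$conf.high[1L], 1)

  no_pos <- structure(list(tp = 0L, fn = 0L, tn = 5L, fp = 5L),
                      class = "confusion_counts")
  expect_error(sens_spec_ci(no_pos), "sensitivity")
  no_neg <- structure(list(tp = 5L, fn = 5L, tn = 0L, fp = 0L),
                      class = "confusion_counts")
  expect_error(sens_spec_ci(no_neg), "specificity")
})

test_that("AUC equals the pairwise rank statistic", {
  # closed-form corners
  ids4 <- c("a", "b", "c", "d")
  # (pROC warns that a CI on a perfect AUC is degenerate; the point
  # estimate is what the corner checks)
  perfect <- suppressWarnings(roc_auc_ci(
    tibble::tibble(report_id = ids4, score = c(0.9, 0.8, 0.1, 0.2)),
    labels_tbl(ids4, c(TRUE, TRUE, FALSE, FALSE))))
  expect_equal(perfect$auc, 1)
  ties <- roc_auc_ci(
    tibble::tibble(report_id = ids4, score = rep(0.4, 4)),
    labels_tbl(ids4, c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(ties$auc, 0.5)

  # brute-force pairwise oracle on a scored corpus with ties
  set.seed(202)
  ids <- sprintf("r%03d", 1:200)
  is_case <- stats::runif(200) < 0.4
  score <- round(stats::rnorm(200, mean = ifelse(is_case, 1, 0)), 1)
  roc <- roc_auc_ci(tibble::tibble(report_id = ids, score = score),
                    labels_tbl(ids, is_case))
  expect_equal(roc$auc, pairwise_auc(score, is_case), tolerance = 1e-12)

  expect_error(
    roc_auc_ci(tibble::tibble(report_id = ids4, score = c(1, 2, 3, 4)),
               labels_tbl(ids4, rep(TRUE, 4))),
    "both classes"
  )
})

test_that("the trapezoid under the swept curve equals the rank AUC", {
  set.seed(203)
  n <- 150
  ids <- sprintf("r%03d", seq_len(n))
  is_case <- rep(c(TRUE, FALSE), length.out = n)
  score <- stats::runif(n)  # continuous, tie-free almost surely
  roc <- roc_auc_ci(tibble::tibble(report_id = ids, score = score),
                    labels_tbl(ids, is_case))
  curve <- tidy(roc)
  expect_equal(curve$fpr[1L], 0)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$tpr) >= 0))
  trapezoid <- sum(diff(curve$fpr) *
                     (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  expect_equal(trapezoid, pairwise_auc(score, is_case), tolerance = 1e-12)
})

test_that("calls are threshold-sweep consistent under monotone transforms", {
  set.seed(204)
  ids <- sprintf("r%02d", 1:60)
  is_case <- rep(c(TRUE, FALSE), 30)
  score <- stats::runif(60)
  thr <- 0.5
  before <- confusion(tibble::tibble(report_id = ids, call = score >= thr),
                      labels_tbl(ids, is_case))
  mono <- function(x) exp(3 * x) - 0.5
  after <- confusion(tibble::tibble(report_id = ids, call = mono(score) >= mono(thr)),
                     labels_tbl(ids, is_case))
  expect_equal(tidy(before), tidy(after))
})

test_that("confidence intervals tighten with corpus size", {
  sens_width <- function(n, seed) {
    sim <- simulate_corpus(sim_config(n_reports = n, prevalence = 0.2,
                                      seed = seed))
    res <- classify_reports(sim$reports, build_catalog("updated"))
    ss <- sens_spec_ci(confusion(brighton_calls(res), sim$labels))
    diff(c(ss$conf.low[1L], ss$conf.high[1L]))
  }
  expect_lt(sens_width(5000, seed = 17), sens_width(50, seed = 17))
})

test_that("the method-comparison table has the documented layout", {
  sim <- simulate_corpus(sim_config(n_reports = 300, prevalence = 0.15,
                                    seed = 29))
  res <- classify_reports(sim$reports, build_catalog("updated"))
  set.seed(30)
  model <- fit_screening(sim$reports, sim$labels)
  tab <- compare_methods(
    sim$labels,
    brighton_updated = brighton_calls(res),
    expanded_smq = screen(sim$reports, model)
  )
  expect_equal(tab$method, c("brighton_updated", "expanded_smq"))
  # a calls-only method has no AUC; a scored method does
  expect_true(is.na(tab$auc[1L]))
  expect_false(is.na(tab$auc[2L]))
  expect_true(all(tab$sens_low <= tab$sensitivity &
                    tab$sensitivity <= tab$sens_high))
  # an engine given fully reported evidence finds nearly everything
  clean <- simulate_corpus(sim_config(n_reports = 300, prevalence = 0.15,
                                      p_omit_finding = 0, seed = 29))
  res_clean <- classify_reports(clean$reports, build_catalog("updated"))
  tab2 <- compare_methods(clean$labels, engine = brighton_calls(res_clean))
  expect_equal(tab2$sensitivity, 1)
})
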