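test_that("chi-square matches the closed-form table computation", {
  # corpus engineered to give the table (a,b,c,d) = (30,10,20,40):
  # term T present in 30 cases + 10 non-cases, absent in 20 + 40
  ids <- sprintf("r%03d", 1:100)
  is_case <- rep(c(TRUE, FALSE), c(50, 50))
  has_term <- c(rep(TRUE, 30), rep(FALSE, 20), rep(TRUE, 10), rep(FALSE, 40))
  corpus <- make_corpus(stats::setNames(
    lapply(has_term, function(h) if (h) "SYN:000001" else "SYN:000002"), ids))
  scores <- chi2_scores(corpus, labels_tbl(ids, is_case))
  row <- scores[scores$code == "SYN:000001", ]
  expect_equal(c(row$a, row$b, row$c, row$d), c(30, 10, 20, 40))
  # hand evaluation of N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  expect_equal(row$chi2, 100 * (30 * 40 - 10 * 20)^2 / (40 * 60 * 50 * 50))
  # independent textbook computation
  ref <- stats::chisq.test(matrix(c(30, 10, 20, 40), 2, byrow = TRUE),
                           correct = FALSE)
  expect_equal(row$chi2, unname(ref$statistic))
  expect_equal(row$p_value, ref$p.value)
})

test_that("balanced tables score zero and are never selected", {
  ids <- sprintf("r%02d", 1:40)
  is_case <- seq_along(ids) <= 20
  # term in half the cases and half the non-cases: (10,10,10,10)
  corpus <- make_corpus(stats::setNames(
    lapply(seq_along(ids), function(i) {
      if (i %% 2 == 0) "SYN:000001" else "SYN:000002"
    }), ids))
  scores <- chi2_scores(corpus, labels_tbl(ids, is_case))
  expect_equal(scores$chi2[scores$code == "SYN:000001"], 0)
  sel <- chi2_select(corpus, labels_tbl(ids, is_case))
  expect_false("SYN:000001" %in% sel$code)
  # a term present in every report has a zero marginal: defined as 0
  corpus2 <- make_corpus(stats::setNames(
    lapply(ids, function(i) "SYN:000009"), ids))
  expect_equal(chi2_scores(corpus2, labels_tbl(ids, is_case))$chi2, 0)
  expect_error(chi2_scores(corpus[0, ], labels_tbl(character(0), logical(0))),
               "empty")
})

test_that("selection threshold is the uncorrected critical value, strictly", {
  expect_equal(round(stats::qchisq(0.95, df = 1), 3), 3.841)
  sim <- simulate_corpus(sim_config(n_reports = 300, prevalence = 0.2, seed = 3))
  strict <- chi2_select(sim$reports, sim$labels, alpha = 0.05)
  expect_true(all(strict$chi2 > stats::qchisq(0.95, 1)))
  # monotone in alpha: tightening alpha can only drop terms
  tight <- chi2_select(sim$reports, sim$labels, alpha = 0.01)
  expect_true(all(tight$code %in% strict$code))
  expect_error(chi2_select(sim$reports, sim$labels, alpha = 1.2))
})

test_that("SMQ expansion is a union with provenance", {
  smq <- expand_smq(c("A", "B", "C"), c("D", "E"))
  expect_equal(nrow(smq), 5L)
  expect_setequal(smq$provenance[smq$code %in% c("A", "B", "C")], "base_smq")
  expect_setequal(smq$provenance[smq$code %in% c("D", "E")], "chi2_selected")

  # the union-cardinality identity |base| + |selected| - |overlap|
  base <- sprintf("B%02d", 1:77)
  selected <- c(sprintf("B%02d", 1:29), sprintf("S%02d", 1:91))  # overlap 29
  smq2 <- expand_smq(base, selected)
  expect_equal(nrow(smq2), 77 + 120 - 29)
  expect_equal(sum(smq2$provenance == "both"), 29L)

  # idempotent union
  smq3 <- expand_smq(c("A", "B"), c("A", "B"))
  expect_equal(nrow(smq3), 2L)
  expect_setequal(smq3$provenance, "both")
})

test_that("idf weights equal the per-term counting oracle", {
  set.seed(41)
  ids <- sprintf("r%02d", 1:20)
  vocab <- sprintf("SYN:%06d", 1:30)
  terms <- stats::setNames(
    lapply(ids, function(i) sample(vocab, sample(1:6, 1))), ids)
  corpus <- make_corpus(terms)
  idf <- fit_idf(corpus)
  for (k in seq_len(nrow(idf))) {
    df_brute <- sum(vapply(terms, function(t) idf$code[[k]] %in% t, logical(1)))
    expect_equal(idf$df[[k]], df_brute)
    expect_equal(idf$idf[[k]], log(20 / df_brute))
  }
  # a term in every report carries no weight; a term in one report ln(N)
  corpus2 <- make_corpus(list(a = c("X", "Y"), b = "X", c = "X"))
  idf2 <- fit_idf(corpus2)
  expect_equal(idf2$idf[idf2$code == "X"], 0)
  expect_equal(idf2$idf[idf2$code == "Y"], log(3))
})

unit_model <- function(vocab, smq_terms, threshold = 0.5) {
  structure(
    list(smq = expand_smq(smq_terms, character(0)),
         idf = tibble::tibble(code = vocab, df = 1L, idf = 1),
         threshold = threshold, alpha = 0.05, tf = "binary",
         train_ids = character(0), test_ids = character(0)),
    class = "screening_model"
  )
}

test_that("cosine score hits its closed-form endpoints", {
  m <- unit_model(c("t1", "t2", "t3"), c("t1", "t2"))
  identical_corpus <- make_corpus(list(r1 = c("t1", "t2")))
  expect_equal(cosine_score(identical_corpus, m), 1)
  disjoint <- make_corpus(list(r1 = "t3"))
  expect_equal(cosine_score(disjoint, m), 0)
  empty <- make_corpus(list(r1 = character(0)))
  expect_equal(cosine_score(empty, m), 0)
  # hand-computed overlap: {t1,t2} vs {t1,t3} = 1/(sqrt(2) sqrt(2))
  m2 <- unit_model(c("t1", "t2", "t3"), c("t1", "t3"))
  half <- make_corpus(list(r1 = c("t1", "t2")))
  expect_equal(cosine_score(half, m2), 0.5)
  # binary tf: duplicating a report's terms changes nothing
  expect_equal(cosine_score(make_corpus(list(r1 = c("t1", "t2", "t1"))), m2), 0.5)
})

test_that("cosine scores stay in [0,1] and rank-invariant under idf scaling", {
  sim <- simulate_corpus(sim_config(n_reports = 150, seed = 13))
  model <- structure(
    list(smq = expand_smq(read_base_smq(), character(0)),
         idf = fit_idf(sim$reports), threshold = 0.1, alpha = 0.05,
         tf = "binary", train_ids = character(0), test_ids = character(0)),
    class = "screening_model"
  )
  s1 <- cosine_score(sim$reports, model)
  expect_true(all(s1 >= 0 & s1 <= 1))
  scaled <- model
  scaled$idf$idf <- scaled$idf$idf * 7.3
  s2 <- cosine_score(sim$reports, scaled)
  expect_equal(order(s1), order(s2))
})

test_that("screening calls respect the threshold semantics", {
  m <- unit_model(c("t1", "t2", "t3"), c("t1", "t2"))
  corpus <- make_corpus(list(r1 = c("t1", "t3"), r2 = "t3",
                             r3 = character(0)))
  # at threshold 0 every report holding an SMQ term is called positive
  calls0 <- screen(corpus, m, threshold = 0)
  expect_true(all(calls0$call[calls0$score > 0]))
  expect_true(calls0$call[1L])
  # an unreachable threshold calls nothing
  expect_false(any(screen(corpus, m, threshold = 1.01)$call))
  m$threshold <- NA_real_
  expect_error(screen(corpus, m), "threshold")
})

test_that("the fitted screen recovers planted cases on a clean corpus", {
  sim <- simulate_corpus(sim_config(
    n_reports = 600, prevalence = 0.1, p_omit_finding = 0,
    p_spurious_brighton_term = 0, seed = 8
  ))
  set.seed(51)
  model <- fit_screening(sim$reports, sim$labels)
  result <- screen(sim$reports, model)
  counts <- confusion(result, sim$labels)
  ss <- sens_spec_ci(counts)
  # Youden threshold on noiseless planted evidence separates well
  expect_gt(ss$estimate[ss$metric == "sensitivity"], 0.9)
  expect_gt(ss$estimate[ss$metric == "specificity"], 0.8)
})

test_that("the train/test split fits only on the training half", {
  sim <- simulate_corpus(sim_config(n_reports = 400, prevalence = 0.15, seed = 6))
  set.seed(99)
  model <- fit_screening(sim$reports, sim$labels, split = 0.5)
  expect_equal(length(model$train_ids), 200L)
  expect_equal(length(model$test_ids), 200L)
  expect_length(intersect(model$train_ids, model$test_ids), 0L)
  # idf was fitted on the training half only: document frequencies are
  # bounded by the training size, and codes seen only in the held-out
  # half carry no weight
  expect_lte(max(model$idf$df), length(model$train_ids))
  train_codes <- unique(unlist(
    sim$reports$raw_terms[sim$reports$report_id %in% model$train_ids]))
  test_only <- setdiff(
    unlist(sim$reports$raw_terms[sim$reports$report_id %in% model$test_ids]),
    train_codes)
  expect_setequal(model$idf$code, train_codes)
  expect_length(intersect(test_only, model$idf$code), 0L)
  held <- sim$reports[sim$reports$report_id %in% model$test_ids, ]
  class(held) <- class(sim$reports)
  expect_length(screen(held, model)$score, 200L)
})
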