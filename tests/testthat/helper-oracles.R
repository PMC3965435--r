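# Independent oracles and small fixture builders used across the suite.

# Interval reformulation of the three-valued semantics: each subexpression
# is summarised by (lo, hi) = (certainly true, possibly true), computed
# compositionally. This is an independent scalar-recursive formulation of
# the same logic the package evaluates via vectorized min/max matrices.
oracle_eval <- function(e, statuses) {
  rec <- function(e) {
    op <- e[[1L]]
    if (op == "atom") {
      s <- if (e[[2L]] %in% names(statuses)) statuses[[e[[2L]]]] else "unknown"
      return(c(lo = s == "present", hi = s != "absent"))
    }
    if (op == "not") {
      v <- rec(e[[2L]])
      return(c(lo = !v[["hi"]], hi = !v[["lo"]]))
    }
    members <- if (op == "at_least") e[-(1:2)] else e[-1L]
    vs <- vapply(members, rec, logical(2))
    if (op == "and") return(c(lo = all(vs["lo", ]), hi = all(vs["hi", ])))
    if (op == "or") return(c(lo = any(vs["lo", ]), hi = any(vs["hi", ])))
    k <- e[[2L]]
    c(lo = sum(vs["lo", ]) >= k, hi = sum(vs["hi", ]) >= k)
  }
  v <- rec(e)
  if (v[["lo"]]) "present" else if (!v[["hi"]]) "absent" else "unknown"
}

# random expression of bounded depth over a small atom alphabet
random_expr <- function(depth, atoms) {
  if (depth == 0L || stats::runif(1) < 0.3) {
    return(atom(sample(atoms, 1L)))
  }
  op <- sample(c("not", "and", "or", "at_least"), 1L)
  if (op == "not") return(not_(random_expr(depth - 1L, atoms)))
  n <- sample(2:3, 1L)
  subs <- replicate(n, random_expr(depth - 1L, atoms), simplify = FALSE)
  switch(op,
    and = do.call(and_, subs),
    or = do.call(or_, subs),
    at_least = do.call(at_least, c(list(sample.int(n, 1L)), subs))
  )
}

# all 3^k status assignments over an atom alphabet
all_assignments <- function(atoms) {
  grid <- expand.grid(rep(list(finding_statuses), length(atoms)),
                      stringsAsFactors = FALSE)
  names(grid) <- atoms
  grid
}

# brute-force Mann-Whitney AUC: mean over all (case, non-case) pairs of
# [score_case > score_non] + 0.5 [tie]
pairwise_auc <- function(scores, is_case) {
  pos <- scores[is_case]
  neg <- scores[!is_case]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

# corpus built directly from a named list of term vectors
make_corpus <- function(terms, mapping = default_mapping()) {
  df <- tibble::tibble(
    report_id = names(terms),
    terms = vapply(terms, paste, "", collapse = "; ")
  )
  as_reports(df, mapping)
}

# category ordering used by the monotonicity / variant-dominance checks
cat_rank <- function(category) {
  unname(c(level_1 = 4L, level_2 = 3L, level_3 = 2L,
           insufficient_evidence = 1L, not_a_case = 1L,
           no_evidence = 0L)[category])
}

labels_tbl <- function(ids, is_case) {
  tibble::tibble(report_id = ids,
                 label = ifelse(is_case, "case", "non_case"))
}
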