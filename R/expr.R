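#' Criterion expressions
#'
#' A Brighton criterion is a boolean expression over finding atoms,
#' evaluated under strong-Kleene three-valued logic. Expressions are plain
#' nested lists (so catalogs can live in YAML files rather than code), with
#' five node types:
#'
#' * `atom(x)` — the status of atom `x` in the report;
#' * `not_(e)` — Kleene negation (`unknown` stays `unknown`);
#' * `and_(e1, e2, ...)` — conjunction (minimum over absent < unknown < present);
#' * `or_(e1, e2, ...)` — disjunction (maximum);
#' * `at_least(k, e1, e2, ...)` — `present` when at least `k` members are
#'   present, `absent` when so many members are absent that `k` presents
#'   are no longer attainable, `unknown` otherwise.
#'
#' @param x Atom name (single string).
#' @param e,... Sub-expressions.
#' @param k Minimum number of members that must be present.
#' @return An expression node (a list with class `criterion_expr`).
#' @examples
#' # minor respiratory criterion of the original encoding
#' ex <- and_(atom("difficulty_breathing"),
#'            not_(atom("bilateral_wheeze")),
#'            not_(atom("stridor")))
#' eval_expr(ex, c(difficulty_breathing = "present",
#'                 bilateral_wheeze = "absent", stridor = "absent"))
#' @name criterion_expr
NULL

new_expr <- function(x) structure(x, class = "criterion_expr")

#' @rdname criterion_expr
#' @export
atom <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  new_expr(list("atom", x))
}

#' @rdname criterion_expr
#' @export
not_ <- function(e) new_expr(list("not", e))

#' @rdname criterion_expr
#' @export
and_ <- function(...) new_expr(c(list("and"), list(...)))

#' @rdname criterion_expr
#' @export
or_ <- function(...) new_expr(c(list("or"), list(...)))

#' @rdname criterion_expr
#' @export
at_least <- function(k, ...) {
  members <- list(...)
  k <- as.integer(k)
  if (k < 1L || k > length(members)) {
    stop("at_least: k must satisfy 1 <= k <= number of members", call. = FALSE)
  }
  new_expr(c(list("at_least", k), members))
}

# Parse an expression from the nested-list form used in catalog YAML:
# ["atom", name] | ["not", e] | ["and", e...] | ["or", e...] | ["at_least", k, e...]
expr_from_list <- function(x) {
  # YAML gives homogeneous sequences (e.g. ["atom", "stridor"]) as atomic
  # vectors rather than lists
  if (is.atomic(x)) x <- as.list(x)
  if (!is.list(x) || length(x) < 2L) {
    stop("malformed criterion expression: ", deparse(x), call. = FALSE)
  }
  op <- x[[1L]]
  switch(op,
    atom = atom(x[[2L]]),
    not = not_(expr_from_list(x[[2L]])),
    and = do.call(and_, lapply(x[-1L], expr_from_list)),
    or = do.call(or_, lapply(x[-1L], expr_from_list)),
    at_least = do.call(
      at_least,
      c(list(x[[2L]]), lapply(x[-(1:2)], expr_from_list))
    ),
    stop("unknown expression operator: ", op, call. = FALSE)
  )
}

# All atom names referenced anywhere in an expression.
expr_atoms <- function(e) {
  op <- e[[1L]]
  if (op == "atom") return(e[[2L]])
  members <- if (op == "at_least") e[-(1:2)] else e[-1L]
  unique(unlist(lapply(members, expr_atoms)))
}

# Whether an expression contains a negation anywhere (the updated catalog
# is negation-free, which is what makes it monotone).
expr_has_negation <- function(e) {
  op <- e[[1L]]
  if (op == "atom") return(FALSE)
  if (op == "not") return(TRUE)
  members <- if (op == "at_least") e[-(1:2)] else e[-1L]
  any(vapply(members, expr_has_negation, logical(1)))
}

# Vectorized strong-Kleene evaluation over a reports x atoms status matrix
# (integer codes 0 absent / 1 unknown / 2 present). Returns an integer
# vector with one tri-state code per report row.
eval_expr_matrix <- function(e, status) {
  op <- e[[1L]]
  if (op == "atom") {
    a <- e[[2L]]
    if (!a %in% colnames(status)) {
      stop("unknown atom in criterion expression: ", a, call. = FALSE)
    }
    return(status[, a])
  }
  if (op == "not") {
    return(2L - eval_expr_matrix(e[[2L]], status))
  }
  if (op == "and" || op == "or") {
    vals <- lapply(e[-1L], eval_expr_matrix, status = status)
    return(as.integer(Reduce(if (op == "and") pmin else pmax, vals)))
  }
  if (op == "at_least") {
    k <- e[[2L]]
    vals <- lapply(e[-(1:2)], eval_expr_matrix, status = status)
    m <- length(vals)
    n_present <- Reduce(`+`, lapply(vals, function(v) as.integer(v == 2L)))
    n_absent <- Reduce(`+`, lapply(vals, function(v) as.integer(v == 0L)))
    out <- rep(1L, length(vals[[1L]]))
    out[n_absent > m - k] <- 0L
    out[n_present >= k] <- 2L
    return(out)
  }
  stop("unknown expression operator: ", op, call. = FALSE)
}

#' Evaluate a criterion expression on one report
#'
#' Applies strong-Kleene three-valued semantics: conjunction is the minimum
#' and disjunction the maximum over the order absent < unknown < present,
#' negation maps present to absent (and vice versa) and leaves unknown
#' unchanged, and `at_least(k, ...)` is present as soon as `k` members are
#' present, absent once more than `length - k` members are absent, and
#' unknown in between. Atoms not named in `findings` evaluate as unknown
#' (the open-world reading).
#'
#' @param expr A [criterion_expr] node.
#' @param findings Named character vector of statuses (names are atoms), or
#'   a findings tibble with columns `atom` and `status`.
#' @param atoms Optional character vector of legal atom names; when given,
#'   an expression referencing an atom outside it raises an error naming
#'   the atom.
#' @return A single status string.
#' @export
eval_expr <- function(expr, findings, atoms = NULL) {
  if (is.data.frame(findings)) {
    findings <- stats::setNames(findings$status, findings$atom)
  }
  used <- expr_atoms(expr)
  if (!is.null(atoms)) {
    bad <- setdiff(used, atoms)
    if (length(bad)) {
      stop("unknown atom in criterion expression: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  cols <- union(used, names(findings))
  status <- matrix(1L, nrow = 1L, ncol = length(cols),
                   dimnames = list(NULL, cols))
  if (length(findings)) {
    status[1L, names(findings)] <- status_to_int(unname(findings))
  }
  int_to_status(eval_expr_matrix(expr, status))
}
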