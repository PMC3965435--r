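#' Tri-state finding status
#'
#' Every clinical finding in a report carries one of three statuses:
#' `"present"`, `"absent"`, or `"unknown"`. Reports are open-world objects:
#' an atom a report does not mention has status `"unknown"`, and turning
#' those unknowns into explicit absences is a separate, deliberate step
#' ([closed_world_complete()]).
#'
#' Internally statuses map to the integers 0 (absent), 1 (unknown),
#' 2 (present), the total order used by the strong-Kleene connectives
#' (conjunction is `min`, disjunction is `max`, negation reflects).
#'
#' @format A character vector of the three legal status values.
#' @export
finding_statuses <- c("absent", "unknown", "present")

# status string <-> internal integer code (absent=0, unknown=1, present=2)
status_to_int <- function(status) {
  out <- match(status, finding_statuses) - 1L
  if (anyNA(out)) {
    bad <- unique(status[is.na(match(status, finding_statuses))])
    stop("invalid finding status: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

int_to_status <- function(x) finding_statuses[x + 1L]

#' Merge two statuses asserted for the same atom
#'
#' When several reporting-vocabulary codes on one report map to the same
#' criterion atom, their asserted statuses are merged under the lattice
#' present > absent > unknown: an explicit assertion always beats
#' no information, and a positive assertion beats a negative one. The
#' present-vs-absent conflict still resolves (to present) but is worth
#' surfacing; [read_reports()] records such conflicts in its diagnostics.
#'
#' The merge is associative and commutative, so the order in which a
#' report's codes are processed never changes the resulting findings.
#'
#' @param existing,incoming Status strings (vectorized, recycled).
#' @return A list with `status` (merged status vector) and `conflict`
#'   (logical vector, `TRUE` where one side asserted present and the other
#'   absent).
#' @examples
#' merge_status("unknown", "present")$status   # "present"
#' merge_status("absent", "present")$conflict  # TRUE
#' @export
merge_status <- function(existing, incoming) {
  a <- status_to_int(existing)
  b <- status_to_int(incoming)
  # lattice order for merging: unknown (1) < absent (0) < present (2)
  rank <- function(x) c(2L, 1L, 3L)[x + 1L]
  merged <- ifelse(rank(a) >= rank(b), a, b)
  list(
    status = int_to_status(merged),
    conflict = (a == 0L & b == 2L) | (a == 2L & b == 0L)
  )
}
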