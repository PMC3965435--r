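#' Read coded AEFI reports from a CSV file
#'
#' The file has one row per report with columns `report_id`, `terms`
#' (reporting-vocabulary codes separated by `";"`, surrounding whitespace
#' ignored; `";"` is the delimiter because clinical code labels routinely
#' contain commas) and an optional `statuses` column giving a positional
#' status (`present`/`absent`/`unknown`) for each term; terms without a
#' statuses column are taken as present.
#'
#' Each code is translated through `mapping` into Brighton criterion atom
#' assertions ([decompose_compound()] semantics). A term reported `absent`
#' flips the mapping's positively asserted atoms to absent and contributes
#' nothing for atoms the mapping already asserts absent; a term reported
#' `unknown` contributes no findings. When several codes on one report
#' assert the same atom, statuses are merged under the [merge_status()]
#' lattice, and a present-vs-absent clash is recorded as a `conflict`
#' diagnostic. Codes absent from the mapping are kept in `raw_terms` (they
#' still matter for screening) and reported as `unmapped` diagnostics,
#' never silently dropped.
#'
#' @param path CSV file path.
#' @param mapping A `term_mapping` tibble; defaults to the shipped
#'   synthetic mapping.
#' @return An `aefi_corpus` tibble with columns `report_id`, `raw_terms`
#'   (list of code vectors), `findings` (list of `atom`/`status` tibbles)
#'   and `has_reported_anaphylaxis`. Diagnostics are attached as the
#'   `"diagnostics"` attribute; see [report_diagnostics()].
#' @export
read_reports <- function(path, mapping = default_mapping()) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("report_id", "terms") %in% names(df))) {
    stop("reports file must have columns report_id and terms: ", path,
         call. = FALSE)
  }
  as_reports(df, mapping)
}

#' Build an AEFI corpus from a data frame of coded reports
#'
#' The in-memory counterpart of [read_reports()]: takes a data frame with
#' `report_id`, `terms` and optionally `statuses` columns (`";"`-separated
#' strings) and returns the corpus tibble every other verb in the package
#' consumes.
#'
#' @param df Data frame of reports.
#' @param mapping A `term_mapping` tibble.
#' @return An `aefi_corpus` tibble; see [read_reports()].
#' @export
as_reports <- function(df, mapping = default_mapping()) {
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$report_id)) {
    dup <- unique(df$report_id[duplicated(df$report_id)])
    stop("duplicate report_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  split_field <- function(x) {
    out <- stringr::str_split(dplyr::coalesce(x, ""), ";")
    lapply(out, function(v) {
      v <- stringr::str_trim(v)
      v[nzchar(v)]
    })
  }
  terms <- split_field(df$terms)
  if ("statuses" %in% names(df)) {
    statuses <- split_field(df$statuses)
    n_terms <- lengths(terms)
    n_stat <- lengths(statuses)
    bad <- which(n_stat != 0L & n_stat != n_terms)
    if (length(bad)) {
      stop("malformed row ", bad[1L] + 1L,
           ": statuses count does not match terms count", call. = FALSE)
    }
    statuses <- purrr::map2(statuses, n_terms, function(s, n) {
      if (length(s) == 0L) rep("present", n) else s
    })
    bad_status <- setdiff(unique(unlist(statuses)), finding_statuses)
    if (length(bad_status)) {
      stop("invalid finding status: ", paste(bad_status, collapse = ", "),
           call. = FALSE)
    }
  } else {
    statuses <- lapply(lengths(terms), function(n) rep("present", n))
  }

  long <- tibble::tibble(
    report_id = rep(df$report_id, lengths(terms)),
    code = unlist(terms, use.names = FALSE) %||% character(0),
    term_status = unlist(statuses, use.names = FALSE) %||% character(0)
  )

  map_atoms <- mapping[mapping$atom != "", c("code", "atom", "asserted_status")]
  joined <- dplyr::inner_join(long, map_atoms, by = "code",
                              relationship = "many-to-many")
  # a term reported absent flips the mapping's positive assertions and
  # silences its negative ones; unknown terms contribute nothing
  joined <- dplyr::mutate(
    joined,
    status = dplyr::case_when(
      term_status == "present" ~ asserted_status,
      term_status == "absent" & asserted_status == "present" ~ "absent",
      TRUE ~ NA_character_
    )
  )
  joined <- dplyr::filter(joined, !is.na(status))

  # merge multiple assertions per (report, atom) under the status lattice:
  # highest merge rank wins (unknown < absent < present)
  joined$merge_rank <- c(2L, 1L, 3L)[status_to_int(joined$status) + 1L]
  merged <- dplyr::group_by(joined, report_id, atom)
  merged <- dplyr::mutate(
    merged,
    conflict = any(status == "present") && any(status == "absent")
  )
  merged <- dplyr::ungroup(
    dplyr::slice_max(merged, merge_rank, n = 1L, with_ties = FALSE)
  )

  diagnostics <- list()
  unmapped <- dplyr::distinct(
    long[!long$code %in% mapping$code, c("report_id", "code")]
  )
  if (nrow(unmapped)) {
    diagnostics$unmapped <- tibble::tibble(
      report_id = unmapped$report_id, code = unmapped$code, issue = "unmapped"
    )
  }
  confl <- merged[merged$conflict, c("report_id", "atom")]
  if (nrow(confl)) {
    diagnostics$conflict <- tibble::tibble(
      report_id = confl$report_id, code = confl$atom, issue = "conflict"
    )
  }
  diagnostics <- if (length(diagnostics)) {
    dplyr::bind_rows(diagnostics)
  } else {
    tibble::tibble(report_id = character(), code = character(), issue = character())
  }

  findings_by_id <- split(
    tibble::tibble(atom = merged$atom, status = merged$status),
    factor(merged$report_id, levels = df$report_id)
  )
  empty_findings <- tibble::tibble(atom = character(), status = character())
  findings <- lapply(findings_by_id, function(f) {
    if (is.null(f) || nrow(f) == 0L) empty_findings else tibble::as_tibble(f)
  })

  ana_codes <- anaphylaxis_codes(mapping)
  has_ana <- dplyr::summarise(
    dplyr::group_by(long, report_id),
    flag = any(code %in% ana_codes & term_status == "present"),
    .groups = "drop"
  )
  flag <- stats::setNames(rep(FALSE, nrow(df)), df$report_id)
  flag[has_ana$report_id] <- has_ana$flag

  corpus <- tibble::tibble(
    report_id = df$report_id,
    raw_terms = terms,
    findings = unname(findings),
    has_reported_anaphylaxis = unname(flag)
  )
  attr(corpus, "diagnostics") <- diagnostics
  class(corpus) <- c("aefi_corpus", class(corpus))
  corpus
}

#' Diagnostics collected while building a corpus
#'
#' @param corpus An `aefi_corpus`.
#' @return A tibble with columns `report_id`, `code`, `issue`
#'   (`"unmapped"` or `"conflict"`).
#' @export
report_diagnostics <- function(corpus) {
  attr(corpus, "diagnostics") %||%
    tibble::tibble(report_id = character(), code = character(), issue = character())
}

#' Look up the status of one atom in one report
#'
#' Reports are open-world: an atom the report does not list is `"unknown"`.
#'
#' @param corpus An `aefi_corpus`.
#' @param report_id Report identifier.
#' @param atom Atom name.
#' @return A status string.
#' @export
finding_status <- function(corpus, report_id, atom) {
  i <- match(report_id, corpus$report_id)
  if (is.na(i)) stop("unknown report_id: ", report_id, call. = FALSE)
  f <- corpus$findings[[i]]
  j <- match(atom, f$atom)
  if (is.na(j)) "unknown" else f$status[[j]]
}

#' Write a corpus back to the reports CSV format
#'
#' Serializes `raw_terms` with the `";"` delimiter; findings are not
#' written because they are derived from the terms via the mapping.
#'
#' @param corpus An `aefi_corpus`.
#' @param path Output CSV path.
#' @param statuses Optional list of per-term status vectors to write as a
#'   `statuses` column (used by the simulator's fixtures).
#' @return `path`, invisibly.
#' @export
write_reports <- function(corpus, path, statuses = NULL) {
  out <- tibble::tibble(
    report_id = corpus$report_id,
    terms = vapply(corpus$raw_terms, paste, "", collapse = "; ")
  )
  if (!is.null(statuses)) {
    out$statuses <- vapply(statuses, paste, "", collapse = "; ")
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read expert gold labels
#'
#' @param path CSV with columns `report_id` and `label`
#'   (`case` / `non_case`).
#' @return A tibble with one row per report.
#' @export
read_labels <- function(path) {
  labs <- readr::read_csv(path, col_types = readr::cols(
    report_id = readr::col_character(), label = readr::col_character()
  ))
  validate_labels(labs)
}

validate_labels <- function(labs) {
  bad <- setdiff(unique(labs$label), c("case", "non_case"))
  if (length(bad)) {
    stop("labels must be 'case' or 'non_case', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(labs$report_id)) {
    stop("more than one label for report_id: ",
         paste(unique(labs$report_id[duplicated(labs$report_id)]), collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(labs[, c("report_id", "label")])
}

# reports x atoms tri-state integer matrix (0 absent / 1 unknown / 2 present)
findings_status_matrix <- function(corpus, atoms) {
  n <- nrow(corpus)
  status <- matrix(1L, nrow = n, ncol = length(atoms),
                   dimnames = list(corpus$report_id, atoms))
  f_atoms <- unlist(lapply(corpus$findings, `[[`, "atom"), use.names = FALSE)
  f_status <- unlist(lapply(corpus$findings, `[[`, "status"), use.names = FALSE)
  rows <- rep(seq_len(n), vapply(corpus$findings, nrow, 0L))
  cols <- match(f_atoms, atoms)
  keep <- !is.na(cols)
  status[cbind(rows[keep], cols[keep])] <- status_to_int(f_status[keep])
  status
}

`%||%` <- function(x, y) if (is.null(x)) y else x
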