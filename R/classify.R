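#' Outcome categories, from strongest to weakest evidence
#'
#' Levels 1-3 are the Brighton levels of diagnostic certainty (level 1
#' highest). Below them, a report carrying an anaphylaxis-like diagnosis
#' code but not meeting any level is "reported anaphylaxis with
#' insufficient evidence"; a report with at least one criterion atom
#' present but no level met is "not a case"; a report with no criterion
#' atom present at all is "no evidence".
#'
#' @format Character vector of the six category names.
#' @export
brighton_categories <- c("level_1", "level_2", "level_3",
                         "insufficient_evidence", "not_a_case", "no_evidence")

# ordering used by the monotonicity property and the variant-comparison
# checks: no_evidence < not_a_case = insufficient_evidence < L3 < L2 < L1
category_rank <- function(category) {
  c(level_1 = 4L, level_2 = 3L, level_3 = 2L,
    insufficient_evidence = 1L, not_a_case = 1L, no_evidence = 0L)[category]
}

#' Closed-world completion of a corpus
#'
#' Converts the open-world reading (unreported = unknown) into the
#' closed-world one (unreported = absent) with respect to a catalog's atom
#' vocabulary: every catalog atom whose status in a report is unknown
#' becomes an explicit absent finding. Present and absent findings are
#' untouched, so the operation is idempotent. Spontaneous reports rarely
#' record negative findings, and the original criteria encoding needs
#' those negatives before its "X without Y" minors can fire; completion
#' simulates the closed-world assumption the reporters implicitly made.
#'
#' @param corpus An `aefi_corpus`.
#' @param catalog A `brighton_catalog` supplying the atom vocabulary.
#' @return A new `aefi_corpus`; the input is not modified.
#' @export
closed_world_complete <- function(corpus, catalog) {
  status <- findings_status_matrix(corpus, catalog$atoms)
  status[status == 1L] <- 0L
  out <- corpus
  out$findings <- lapply(seq_len(nrow(corpus)), function(i) {
    extra <- corpus$findings[[i]][!corpus$findings[[i]]$atom %in% catalog$atoms, ]
    dplyr::bind_rows(
      tibble::tibble(atom = catalog$atoms,
                     status = int_to_status(status[i, ])),
      extra
    )
  })
  attr(out, "diagnostics") <- attr(corpus, "diagnostics")
  class(out) <- class(corpus)
  out
}

#' Classify reports against a Brighton criteria catalog
#'
#' Evaluates every criterion of the catalog on every report under
#' strong-Kleene three-valued logic, counts satisfied (i.e. present —
#' a criterion left unknown is not satisfied) major and minor criteria per
#' organ system, and assigns the highest level of diagnostic certainty
#' whose rule holds, with precedence level 1 > 2 > 3. When the catalog
#' demands the temporal gate, a positive level additionally requires the
#' sudden-onset and rapid-progression atoms to be present. Reports meeting
#' no level fall through to `insufficient_evidence` when they carry a
#' reported anaphylaxis diagnosis, `not_a_case` when at least one catalog
#' atom is present, and `no_evidence` otherwise.
#'
#' @param corpus An `aefi_corpus`.
#' @param catalog A `brighton_catalog` from [build_catalog()] or
#'   [read_catalog()].
#' @param closed_world Apply [closed_world_complete()] before evaluation?
#'   Defaults to the catalog's own policy (`TRUE` for the
#'   `original_closed_world` variant).
#' @return A `brighton_classifications` tibble: `report_id`, `category`,
#'   `level` (integer or `NA`), `satisfied` (list of satisfied criterion
#'   ids) and `variant`.
#' @examples
#' corpus <- as_reports(data.frame(
#'   report_id = "369695",
#'   terms = "Erythema, generalized; Urticaria, generalized; Difficulty breathing"
#' ))
#' classify_reports(corpus, build_catalog("original_closed_world"))
#' @export
classify_reports <- function(corpus, catalog, closed_world = NULL) {
  closed_world <- closed_world %||% catalog$closed_world
  status <- findings_status_matrix(corpus, catalog$atoms)
  if (isTRUE(closed_world)) {
    # equivalent to classifying closed_world_complete(corpus, catalog):
    # completion only turns unknown catalog atoms absent
    status[status == 1L] <- 0L
  }
  n <- nrow(corpus)
  crit <- catalog$criteria
  vals <- vapply(crit$expr, eval_expr_matrix, integer(n), status = status)
  vals <- matrix(vals, nrow = n,
                 dimnames = list(NULL, crit$criterion_id))
  satisfied <- vals == 2L

  count_for <- function(weight) {
    m <- vapply(criterion_systems, function(sys) {
      cols <- crit$criterion_id[crit$system == sys & crit$weight == weight]
      if (length(cols) == 0L) return(integer(n))
      as.integer(rowSums(satisfied[, cols, drop = FALSE]))
    }, integer(n))
    matrix(m, nrow = n, dimnames = list(NULL, criterion_systems))
  }
  major <- count_for("major")
  minor <- count_for("minor")

  positive_ok <- if (catalog$require_temporal) {
    status[, catalog$temporal_atoms[1L]] == 2L &
      status[, catalog$temporal_atoms[2L]] == 2L
  } else {
    rep(TRUE, n)
  }

  level <- rep(NA_integer_, n)
  for (lv in 3:1) {
    hold <- eval_level_rule(catalog$level_rules[[paste0("level_", lv)]],
                            major, minor)
    level[hold & positive_ok] <- lv
  }

  any_present <- rowSums(status == 2L) > 0L
  category <- dplyr::case_when(
    !is.na(level) ~ paste0("level_", level),
    corpus$has_reported_anaphylaxis ~ "insufficient_evidence",
    any_present ~ "not_a_case",
    TRUE ~ "no_evidence"
  )

  out <- tibble::tibble(
    report_id = corpus$report_id,
    category = category,
    level = level,
    satisfied = lapply(seq_len(n), function(i) crit$criterion_id[satisfied[i, ]]),
    variant = catalog$variant
  )
  class(out) <- c("brighton_classifications", class(out))
  out
}

#' Classify a single report given as findings
#'
#' Convenience wrapper for interactive use and worked examples: takes a
#' named status vector or findings tibble plus the report-level
#' anaphylaxis-diagnosis flag, and returns the one-row classification.
#'
#' @param findings Named status vector or tibble with `atom`, `status`.
#' @param catalog A `brighton_catalog`.
#' @param has_reported_anaphylaxis Does the report carry an
#'   anaphylaxis-like diagnosis code?
#' @param report_id Identifier used in the result.
#' @inheritParams classify_reports
#' @return A one-row `brighton_classifications` tibble.
#' @export
classify_findings <- function(findings, catalog,
                              has_reported_anaphylaxis = FALSE,
                              report_id = "report_1", closed_world = NULL) {
  if (!is.data.frame(findings)) {
    findings <- tibble::tibble(atom = names(findings), status = unname(findings))
  }
  corpus <- tibble::tibble(
    report_id = report_id,
    raw_terms = list(character(0)),
    findings = list(tibble::as_tibble(findings)),
    has_reported_anaphylaxis = has_reported_anaphylaxis
  )
  class(corpus) <- c("aefi_corpus", class(corpus))
  classify_reports(corpus, catalog, closed_world = closed_world)
}

#' Collapse Brighton categories to binary screening calls
#'
#' Levels 1-3 count as positive; by default "reported anaphylaxis with
#' insufficient evidence" counts as negative (it flags a reported
#' diagnosis lacking support, not evidence of a case), which can be
#' overridden.
#'
#' @param results A `brighton_classifications` tibble.
#' @param insufficient_positive Count `insufficient_evidence` as positive?
#' @return Tibble with `report_id` and logical `call`.
#' @export
brighton_calls <- function(results, insufficient_positive = FALSE) {
  pos <- c("level_1", "level_2", "level_3",
           if (insufficient_positive) "insufficient_evidence")
  tibble::tibble(report_id = results$report_id,
                 call = results$category %in% pos)
}

#' Write classification results to CSV
#'
#' One row per report with the satisfied criterion ids joined by `";"`;
#' [read_classifications()] restores the tibble losslessly.
#'
#' @param results A `brighton_classifications` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(results, path) {
  out <- tibble::tibble(
    report_id = results$report_id,
    category = results$category,
    variant = results$variant,
    satisfied = vapply(results$satisfied, paste, "", collapse = ";")
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_classifications
#' @export
read_classifications <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  bad <- setdiff(unique(df$category), brighton_categories)
  if (length(bad)) {
    stop("unknown category in file: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  level <- match(df$category, c("level_1", "level_2", "level_3"))
  out <- tibble::tibble(
    report_id = df$report_id,
    category = df$category,
    level = level,
    satisfied = lapply(dplyr::coalesce(df$satisfied, ""), function(s) {
      v <- strsplit(s, ";", fixed = TRUE)[[1L]]
      v[nzchar(v)]
    }),
    variant = df$variant
  )
  class(out) <- c("brighton_classifications", class(out))
  out
}
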