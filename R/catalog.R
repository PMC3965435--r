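catalog_variants <- c("original", "original_closed_world", "updated")
criterion_systems <- c("dermatologic_mucosal", "cardiovascular", "respiratory",
                       "gastrointestinal", "laboratory")
criterion_weights <- c("major", "minor")

#' Build a Brighton anaphylaxis criteria catalog
#'
#' A catalog bundles the case definition's criteria (each a weighted,
#' per-system [criterion_expr]), the rules mapping per-system counts of
#' satisfied major/minor criteria to levels 1-3 of diagnostic certainty,
#' and the evaluation policy (closed-world completion, temporal gating).
#' Three variants are shipped:
#'
#' * `"original"` — the literal encoding, in which minor criteria of the
#'   form "X without Y" carry an explicit negation of Y, and the Level 3
#'   "two other systems" clause excludes both the cardiovascular and the
#'   respiratory system. Evaluated open-world, unreported findings leave
#'   these negated criteria unknown, so such minors never fire.
#' * `"original_closed_world"` — the same criteria, but reports are
#'   closed-world completed before evaluation (every catalog atom not
#'   positively reported is taken as absent).
#' * `"updated"` — the negation-free encoding: "X without Y" minors are
#'   decomposed so X alone carries the minor criterion (the corresponding
#'   "X with Y" major still outranks it), and Level 3 excludes only the
#'   system supplying the qualifying minor criterion. All expressions are
#'   monotone, so no closed-world step is needed.
#'
#' The temporal atoms (sudden onset, rapid progression) gate every
#' positive level when `require_temporal = TRUE`. Coded report
#' vocabularies often cannot express them, so classification of
#' spontaneous-report data typically relaxes the gate (the default).
#'
#' Catalogs are data, not code: the shipped definitions live in YAML files
#' under `inst/extdata` and any other Brighton-style case definition in the
#' same format can be loaded with [read_catalog()].
#'
#' @param variant One of `"original"`, `"original_closed_world"`, `"updated"`.
#' @param require_temporal Gate positive levels on sudden onset AND rapid
#'   progression being present? Default `FALSE` (relaxed).
#' @return A `brighton_catalog` object.
#' @examples
#' cat_u <- build_catalog("updated")
#' cat_u
#' @export
build_catalog <- function(variant = c("updated", "original", "original_closed_world"),
                          require_temporal = FALSE) {
  variant <- match.arg(variant)
  file <- if (variant == "updated") "catalog_updated.yaml" else "catalog_original.yaml"
  path <- system.file("extdata", file, package = "brightonaefi", mustWork = TRUE)
  cat <- read_catalog(path, require_temporal = require_temporal)
  cat$variant <- variant
  cat$closed_world <- identical(variant, "original_closed_world")
  cat
}

#' Read a criteria catalog from a YAML file
#'
#' The file lists the atom vocabulary, the temporal atoms, the criteria
#' (id, system, weight, expression as a nested list), and the level rules
#' expressed over count predicates `[ge_major, system, k]`,
#' `[ge_minor, system, k]` and `[minor_systems_excluding, [systems], k]`
#' combined with `and`/`or`.
#'
#' @param path Path to a catalog YAML file.
#' @param require_temporal Gate positive levels on the temporal atoms?
#' @return A `brighton_catalog` object.
#' @export
read_catalog <- function(path, require_temporal = FALSE) {
  raw <- yaml::read_yaml(path)
  for (field in c("variant", "atoms", "criteria", "level_rules")) {
    if (is.null(raw[[field]])) {
      stop("catalog file is missing field '", field, "': ", path, call. = FALSE)
    }
  }
  atoms <- unlist(raw$atoms)
  criteria <- purrr::map_dfr(raw$criteria, function(cr) {
    tibble::tibble(
      criterion_id = cr$id,
      system = cr$system,
      weight = cr$weight,
      expr = list(expr_from_list(cr$expr))
    )
  })
  if (anyDuplicated(criteria$criterion_id)) {
    stop("duplicate criterion id in catalog", call. = FALSE)
  }
  bad_sys <- setdiff(criteria$system, criterion_systems)
  if (length(bad_sys)) stop("unknown system: ", paste(bad_sys, collapse = ", "), call. = FALSE)
  bad_w <- setdiff(criteria$weight, criterion_weights)
  if (length(bad_w)) stop("unknown weight: ", paste(bad_w, collapse = ", "), call. = FALSE)
  used <- unique(unlist(lapply(criteria$expr, expr_atoms)))
  missing_atoms <- setdiff(used, atoms)
  if (length(missing_atoms)) {
    stop("criterion references atoms outside the catalog vocabulary: ",
         paste(missing_atoms, collapse = ", "), call. = FALSE)
  }
  rules <- raw$level_rules
  if (!all(c("level_1", "level_2", "level_3") %in% names(rules))) {
    stop("catalog must declare level rules for levels 1-3", call. = FALSE)
  }
  rules <- lapply(rules[c("level_1", "level_2", "level_3")], validate_level_rule)
  structure(
    list(
      variant = raw$variant,
      atoms = atoms,
      temporal_atoms = unlist(raw$temporal_atoms),
      criteria = criteria,
      level_rules = rules,
      require_temporal = isTRUE(require_temporal),
      closed_world = FALSE
    ),
    class = "brighton_catalog"
  )
}

#' All Brighton criterion atoms of the shipped anaphylaxis catalogs
#'
#' @return Character vector of atom names (findings vocabulary).
#' @export
brighton_atoms <- function() build_catalog("updated")$atoms

#' @export
print.brighton_catalog <- function(x, ...) {
  n_maj <- sum(x$criteria$weight == "major")
  cat("<brighton_catalog> variant:", x$variant, "\n",
      " ", nrow(x$criteria), " criteria (", n_maj, " major, ",
      nrow(x$criteria) - n_maj, " minor) over ",
      length(unique(x$criteria$system)), " systems, ",
      length(x$atoms), " atoms\n",
      "  closed_world: ", x$closed_world,
      ", require_temporal: ", x$require_temporal, "\n", sep = "")
  invisible(x)
}

# -- level rules ------------------------------------------------------------

validate_level_rule <- function(rule) {
  if (is.atomic(rule)) rule <- as.list(rule)  # see expr_from_list
  if (!is.list(rule) || length(rule) < 2L) {
    stop("malformed level rule", call. = FALSE)
  }
  op <- rule[[1L]]
  if (op %in% c("and", "or")) {
    rule[-1L] <- lapply(rule[-1L], validate_level_rule)
  } else if (op %in% c("ge_major", "ge_minor")) {
    if (!rule[[2L]] %in% criterion_systems) {
      stop("level rule references unknown system: ", rule[[2L]], call. = FALSE)
    }
    stopifnot(rule[[3L]] >= 1)
  } else if (op == "minor_systems_excluding") {
    excl <- unlist(rule[[2L]])
    bad <- setdiff(excl, criterion_systems)
    if (length(bad)) {
      stop("level rule excludes unknown system: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    stopifnot(rule[[3L]] >= 1)
  } else {
    stop("unknown level-rule operator: ", op, call. = FALSE)
  }
  rule
}

# Evaluate a level rule to a logical vector over reports, given per-system
# counts of satisfied criteria: `major` and `minor` are reports x systems
# integer matrices.
eval_level_rule <- function(rule, major, minor) {
  op <- rule[[1L]]
  if (op == "and" || op == "or") {
    vals <- lapply(rule[-1L], eval_level_rule, major = major, minor = minor)
    return(Reduce(if (op == "and") `&` else `|`, vals))
  }
  if (op == "ge_major") return(major[, rule[[2L]]] >= rule[[3L]])
  if (op == "ge_minor") return(minor[, rule[[2L]]] >= rule[[3L]])
  if (op == "minor_systems_excluding") {
    keep <- setdiff(colnames(minor), unlist(rule[[2L]]))
    n_sys <- rowSums(minor[, keep, drop = FALSE] >= 1L)
    return(n_sys >= rule[[3L]])
  }
  stop("unknown level-rule operator: ", op, call. = FALSE)
}
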