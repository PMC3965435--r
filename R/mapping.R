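#' Read a reporting-vocabulary to Brighton-atom term mapping
#'
#' The mapping translates the codes used by a reporting system (MedDRA-like
#' preferred terms in real data; a synthetic stand-in vocabulary here) into
#' Brighton criterion atoms with asserted statuses. A single code may map
#' to several atoms: compound codes such as "capillary refill time > 3 sec
#' without hypotension" decompose into one present atom and one absent atom.
#' Codes flagged `is_anaphylaxis_diagnosis_term` carry a reported
#' anaphylaxis(-like) diagnosis rather than a finding; they set a report's
#' `has_reported_anaphylaxis` flag, which is what separates "reported
#' anaphylaxis with insufficient evidence" from "not a case".
#'
#' The file is tab-separated with columns `code`, `atom`, `asserted_status`,
#' `is_anaphylaxis_diagnosis_term`; diagnosis-only codes leave `atom` empty.
#'
#' @param path Path to a mapping TSV file.
#' @param atoms Atom vocabulary to validate the mapping targets against;
#'   defaults to the shipped Brighton anaphylaxis atoms.
#' @return A `term_mapping` tibble with one row per (code, atom) pair.
#' @seealso [default_mapping()], [decompose_compound()]
#' @export
read_mapping <- function(path, atoms = brighton_atoms()) {
  m <- readr::read_tsv(
    path,
    col_types = readr::cols(
      code = readr::col_character(),
      atom = readr::col_character(),
      asserted_status = readr::col_character(),
      is_anaphylaxis_diagnosis_term = readr::col_logical()
    )
  )
  m$atom[is.na(m$atom)] <- ""
  bad_status <- setdiff(m$asserted_status, finding_statuses)
  if (length(bad_status)) {
    stop("mapping asserts invalid status: ", paste(bad_status, collapse = ", "),
         call. = FALSE)
  }
  bad_atom <- setdiff(setdiff(unique(m$atom), ""), atoms)
  if (length(bad_atom)) {
    stop("mapping targets atoms outside the Brighton vocabulary: ",
         paste(bad_atom, collapse = ", "), call. = FALSE)
  }
  if (any(m$atom == "" & !m$is_anaphylaxis_diagnosis_term)) {
    stop("mapping rows without a target atom must be diagnosis terms",
         call. = FALSE)
  }
  class(m) <- c("term_mapping", class(m))
  m
}

#' The shipped synthetic term mapping
#'
#' A stand-in for a real MedDRA-to-Brighton mapping (such mappings are
#' licensed-terminology derivatives and cannot be shipped): one
#' human-readable code per Brighton atom, a handful of compound codes, and
#' the anaphylaxis-like diagnosis codes. Marked synthetic in its filename;
#' substitute your own via [read_mapping()] for real data.
#'
#' @return A `term_mapping` tibble.
#' @export
default_mapping <- function() {
  read_mapping(system.file("extdata", "mapping_synthetic.tsv",
                           package = "brightonaefi", mustWork = TRUE))
}

#' Decompose a (possibly compound) reporting code into atom assertions
#'
#' Compound codes bundle several clinical assertions in one term; correct
#' classification requires splitting them ("X without Y" asserts X present
#' and Y absent). A code not covered by the mapping's compound table is its
#' own single atom, asserted present.
#'
#' @param code A single reporting-vocabulary code.
#' @param mapping A `term_mapping` tibble.
#' @return A tibble with columns `atom`, `status`.
#' @examples
#' decompose_compound("Capillary refill time > 3 sec without hypotension",
#'                    default_mapping())
#' @export
decompose_compound <- function(code, mapping = default_mapping()) {
  stopifnot(is.character(code), length(code) == 1L)
  hit <- mapping[mapping$code == code & mapping$atom != "", ]
  if (nrow(hit) == 0L) {
    return(tibble::tibble(atom = code, status = "present"))
  }
  tibble::tibble(atom = hit$atom, status = hit$asserted_status)
}

# Codes flagged as carrying an anaphylaxis(-like) diagnosis.
anaphylaxis_codes <- function(mapping) {
  unique(mapping$code[mapping$is_anaphylaxis_diagnosis_term])
}
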