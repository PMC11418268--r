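#' Construct a visit
#'
#' A visit is the atomic clinical unit: one hospital encounter with its set of
#' diagnosis, procedure and medication codes. Code sets are deduplicated;
#' ordinals `t` are 1-based within a patient.
#'
#' @param patient_id character scalar.
#' @param t visit ordinal (>= 1).
#' @param diagnoses,procedures,medications character vectors of codes.
#' @return object of class `ehr_visit`.
#' @export
new_visit <- function(patient_id, t, diagnoses, procedures, medications) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L, t >= 1)
  structure(list(
    patient_id = patient_id,
    t = as.integer(t),
    diagnoses = sort(unique(as.character(diagnoses))),
    procedures = sort(unique(as.character(procedures))),
    medications = sort(unique(as.character(medications)))
  ), class = "ehr_visit")
}

#' Construct a patient record
#'
#' @param patient_id character scalar.
#' @param visits list of `ehr_visit` with consecutive ordinals 1..N.
#' @return object of class `ehr_patient`.
#' @export
new_patient <- function(patient_id, visits) {
  ords <- vapply(visits, `[[`, integer(1), "t")
  if (!identical(ords, seq_along(visits)))
    stop("patient ", patient_id, ": visit ordinals must be consecutive 1..N")
  ids <- vapply(visits, `[[`, character(1), "patient_id")
  if (!all(ids == patient_id))
    stop("patient ", patient_id, ": visits carry a different patient_id")
  structure(list(patient_id = patient_id, visits = visits), class = "ehr_patient")
}

#' Construct a cohort
#'
#' A cohort bundles a vocabulary with a list of patient records plus free-form
#' provenance metadata (generator seed/parameters or data source).
#'
#' @param vocabulary a `medical_vocabulary`.
#' @param patients list of `ehr_patient`.
#' @param metadata named list, free form.
#' @return object of class `ehr_cohort`.
#' @export
new_cohort <- function(vocabulary, patients, metadata = list()) {
  cohort <- structure(list(vocabulary = vocabulary, patients = patients,
                           metadata = metadata), class = "ehr_cohort")
  validate_cohort(cohort)
  cohort
}

#' Validate cohort invariants
#'
#' Checks that every code of every visit resolves through the cohort
#' vocabulary. Called by [new_cohort()] and [read_cohort()].
#'
#' @param cohort an `ehr_cohort`.
#' @return the cohort, invisibly; errors on violation.
#' @export
validate_cohort <- function(cohort) {
  for (p in cohort$patients) {
    for (v in p$visits) {
      code_index(cohort$vocabulary, v$diagnoses, "diagnosis")
      code_index(cohort$vocabulary, v$procedures, "procedure")
      code_index(cohort$vocabulary, v$medications, "medication")
    }
  }
  invisible(cohort)
}

#' @export
print.ehr_cohort <- function(x, ...) {
  nv <- sum(vapply(x$patients, function(p) length(p$visits), integer(1)))
  cat(sprintf("<ehr_cohort> %d patients, %d visits, |D|=%d |P|=%d |M|=%d\n",
              length(x$patients), nv,
              length(x$vocabulary$diagnosis), length(x$vocabulary$procedure),
              length(x$vocabulary$medication)))
  invisible(x)
}

#' Total number of visits in a cohort
#' @param cohort an `ehr_cohort`.
#' @return integer.
#' @export
n_visits <- function(cohort) {
  sum(vapply(cohort$patients, function(p) length(p$visits), integer(1)))
}

# JSONL schema, version 1:
#   line 1: {"schema_version":1,"record":"header","vocabulary":{...},"metadata":{...}}
#   line 2+: {"record":"patient","patient_id":"...",
#             "visits":[{"t":1,"diagnoses":[...],"procedures":[...],"medications":[...]}]}

#' Write a cohort to JSONL
#'
#' One header record with the vocabulary and metadata, then one line per
#' patient. Key ordering is fixed so that round trips are byte-stable.
#'
#' @param cohort an `ehr_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  to_json <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  header <- list(schema_version = 1L, record = "header",
                 vocabulary = list(diagnosis = cohort$vocabulary$diagnosis,
                                   procedure = cohort$vocabulary$procedure,
                                   medication = cohort$vocabulary$medication),
                 metadata = cohort$metadata)
  lines <- character(1L + length(cohort$patients))
  lines[1] <- to_json(header)
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    lines[i + 1L] <- to_json(list(
      record = "patient", patient_id = p$patient_id,
      visits = lapply(p$visits, function(v) list(
        t = v$t, diagnoses = as.list(v$diagnoses),
        procedures = as.list(v$procedures),
        medications = as.list(v$medications)))))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a cohort from JSONL
#'
#' @param path path to a file written by [write_cohort()] (schema above).
#' @return an `ehr_cohort`.
#' @export
read_cohort <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty cohort file: ", path)
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
             error = function(e) stop("malformed JSONL at line ", i, " of ",
                                      path, ": ", conditionMessage(e)))
  }
  header <- parse_line(1L)
  if (!identical(header$record, "header"))
    stop("line 1 of ", path, " is not a header record")
  vocab <- new_vocabulary(unlist(header$vocabulary$diagnosis),
                          unlist(header$vocabulary$procedure),
                          unlist(header$vocabulary$medication))
  patients <- vector("list", length(lines) - 1L)
  for (i in seq_along(patients)) {
    rec <- parse_line(i + 1L)
    if (!identical(rec$record, "patient"))
      stop("line ", i + 1L, " of ", path, " is not a patient record")
    visits <- lapply(rec$visits, function(v)
      new_visit(rec$patient_id, v$t,
                unlist(v$diagnoses, use.names = FALSE) %||% character(0),
                unlist(v$procedures, use.names = FALSE) %||% character(0),
                unlist(v$medications, use.names = FALSE) %||% character(0)))
    patients[[i]] <- new_patient(rec$patient_id, visits)
  }
  meta <- header$metadata
  if (is.null(meta) || length(meta) == 0L) meta <- list()
  new_cohort(vocab, patients, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a drug-drug interaction matrix from a TSV edge list
#'
#' The file has two tab-separated columns of medication codes; `#` starts a
#' comment line. Pairs with codes outside the vocabulary are skipped with a
#' single warning reporting the count, so a generic interaction list can be
#' paired with a reduced vocabulary. The result is symmetric with a zero
#' diagonal.
#'
#' @param path path to the TSV edge list.
#' @param vocab a `medical_vocabulary`.
#' @return `|M| x |M|` binary matrix of class `ddi_matrix`.
#' @export
read_ddi <- function(path, vocab) {
  if (!file.exists(path)) stop("cannot read DDI file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- vocab_size(vocab, "medication")
  mat <- matrix(0L, m, m, dimnames = list(vocab$medication, vocab$medication))
  skipped <- 0L
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("malformed DDI line (need 2 columns): ", ln)
    a <- vocab$index$medication[parts[1]]
    b <- vocab$index$medication[parts[2]]
    if (is.na(a) || is.na(b)) { skipped <- skipped + 1L; next }
    if (a == b) next
    mat[a, b] <- 1L
    mat[b, a] <- 1L
  }
  if (skipped > 0L)
    warning(skipped, " DDI pair(s) skipped: code(s) not in the medication vocabulary")
  structure(mat, class = c("ddi_matrix", class(mat)))
}

#' Write a DDI matrix as a TSV edge list
#'
#' @param ddi binary symmetric matrix with medication-code dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ddi <- function(ddi, path) {
  idx <- which(upper.tri(ddi) & ddi == 1L, arr.ind = TRUE)
  lines <- c("# medication DDI edge list (tab-separated)",
             if (nrow(idx)) paste(rownames(ddi)[idx[, 1]],
                                  colnames(ddi)[idx[, 2]], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Split a cohort into train / validation / test by patient
#'
#' Patients (never individual visits) are randomly partitioned so held-out
#' patients are fully unseen — required for a meaningful cold-start
#' evaluation. Sizes are proportional to `ratios` (largest-remainder
#' rounding); the split is reproducible for a fixed seed.
#'
#' @param cohort an `ehr_cohort`.
#' @param ratios numeric length-3 vector, default `c(4, 1, 1)`.
#' @param seed integer seed.
#' @return named list of cohorts: `train`, `validation`, `test`.
#' @export
split_cohort <- function(cohort, ratios = c(4, 1, 1), seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  n <- length(cohort$patients)
  if (n < 3L) stop("need at least 3 patients to split, got ", n)
  props <- ratios / sum(ratios)
  sizes <- floor(props * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- props * n - sizes
    for (k in order(frac, decreasing = TRUE)[seq_len(rem)])
      sizes[k] <- sizes[k] + 1L
  }
  perm <- local_rng(seed, sample.int(n))
  bounds <- cumsum(sizes)
  take <- list(perm[seq_len(bounds[1])],
               perm[seq.int(bounds[1] + 1L, bounds[2])],
               perm[seq.int(bounds[2] + 1L, bounds[3])])
  out <- lapply(take, function(ix) {
    meta <- cohort$metadata
    meta$split_of <- NULL
    new_cohort(cohort$vocabulary, cohort$patients[sort(ix)], meta)
  })
  names(out) <- c("train", "validation", "test")
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
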