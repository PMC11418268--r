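#' Medical code vocabulary
#'
#' A vocabulary holds the three ordered code spaces used throughout the
#' package: diagnoses (D), procedures (P) and medications (M). Each space maps
#' codes to 1-based integer indices and back; multi-hot vectors are defined
#' relative to these index maps.
#'
#' @param diagnosis_codes character vector of unique diagnosis codes.
#' @param procedure_codes character vector of unique procedure codes.
#' @param medication_codes character vector of unique medication codes.
#' @return An object of class `medical_vocabulary`.
#' @export
new_vocabulary <- function(diagnosis_codes, procedure_codes, medication_codes) {
  spaces <- list(diagnosis = as.character(diagnosis_codes),
                 procedure = as.character(procedure_codes),
                 medication = as.character(medication_codes))
  for (nm in names(spaces)) {
    codes <- spaces[[nm]]
    if (length(codes) == 0L)
      stop("vocabulary space '", nm, "' must be non-empty")
    if (anyDuplicated(codes))
      stop("duplicate codes in vocabulary space '", nm, "'")
  }
  structure(list(
    diagnosis = spaces$diagnosis,
    procedure = spaces$procedure,
    medication = spaces$medication,
    index = lapply(spaces, function(codes) stats::setNames(seq_along(codes), codes))
  ), class = "medical_vocabulary")
}

#' @export
print.medical_vocabulary <- function(x, ...) {
  cat(sprintf("<medical_vocabulary> |D|=%d |P|=%d |M|=%d\n",
              length(x$diagnosis), length(x$procedure), length(x$medication)))
  invisible(x)
}

#' Size of a vocabulary space
#' @param vocab a `medical_vocabulary`.
#' @param space one of `"diagnosis"`, `"procedure"`, `"medication"`.
#' @return integer size.
#' @export
vocab_size <- function(vocab, space) {
  space <- match.arg(space, c("diagnosis", "procedure", "medication"))
  length(vocab[[space]])
}

#' Map codes to integer indices
#'
#' @inheritParams vocab_size
#' @param codes character vector of codes, all of which must exist in `space`.
#' @return integer indices (1-based) in the order of `codes`.
#' @export
code_index <- function(vocab, codes, space) {
  space <- match.arg(space, c("diagnosis", "procedure", "medication"))
  if (length(codes) == 0L) return(integer(0))
  idx <- vocab$index[[space]][as.character(codes)]
  if (anyNA(idx)) {
    bad <- as.character(codes)[is.na(idx)]
    stop("unknown ", space, " code(s): ", paste(bad, collapse = ", "))
  }
  unname(idx)
}

#' Encode a code set as a multi-hot vector
#'
#' Produces a binary indicator vector over one vocabulary space with ones
#' exactly at the indices of the given codes.
#'
#' @inheritParams code_index
#' @return an integer vector of class `multi_hot` with attribute `space`.
#' @export
encode_multi_hot <- function(codes, vocab, space) {
  space <- match.arg(space, c("diagnosis", "procedure", "medication"))
  v <- integer(vocab_size(vocab, space))
  v[code_index(vocab, codes, space)] <- 1L
  structure(v, space = space, class = "multi_hot")
}

#' Decode a multi-hot vector back to a code set
#'
#' Inverse of [encode_multi_hot()].
#'
#' @param vector a `multi_hot` (or plain binary vector, with `space` given).
#' @param vocab a `medical_vocabulary`.
#' @param space vocabulary space; defaults to the vector's `space` attribute.
#' @return character vector of codes (vocabulary order).
#' @export
decode_multi_hot <- function(vector, vocab, space = attr(vector, "space")) {
  if (is.null(space)) stop("space must be supplied for a plain vector")
  space <- match.arg(space, c("diagnosis", "procedure", "medication"))
  n <- vocab_size(vocab, space)
  if (length(vector) != n)
    stop("multi-hot length ", length(vector), " does not match |", space, "| = ", n)
  if (!all(vector %in% c(0L, 1L)))
    stop("multi-hot entries must be 0/1")
  vocab[[space]][which(vector == 1L)]
}
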