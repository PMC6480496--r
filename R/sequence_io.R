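# Standard one-letter amino-acid alphabet. Ambiguity codes (B, J, O, U, X, Z)
# and stop (*) are rejected: exact-match scanning and mass computation are
# undefined on them.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Validate and canonicalise a protein or peptide sequence
#'
#' Uppercases the input, strips all whitespace, and checks that every residue
#' is one of the 20 standard one-letter amino-acid codes.
#'
#' @param raw A character scalar.
#' @param what Label used in error messages (e.g. a record id).
#' @return The canonical sequence (uppercase, no whitespace).
#' @examples
#' validate_sequence("mkv")        # "MKV"
#' validate_sequence("MK V\n")     # "MKV"
#' @export
validate_sequence <- function(raw, what = "sequence") {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop(what, ": input must be a single character string", call. = FALSE)
  }
  s <- toupper(gsub("[[:space:]]+", "", raw))
  if (nchar(s) == 0L) {
    stop(what, ": sequence is empty after removing whitespace", call. = FALSE)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf(
      "%s: non-standard residue '%s' at position %d", what, chars[bad[1L]], bad[1L]
    ), call. = FALSE)
  }
  s
}

#' Construct a protein record
#'
#' @param id Accession or free-text label.
#' @param sequence Amino-acid sequence; validated with [validate_sequence()].
#' @param description Optional free-text description.
#' @return A list of class `protein_record` with fields `id`, `description`,
#'   `sequence` and `length` (the residue count N).
#' @export
protein_record <- function(id, sequence, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- validate_sequence(sequence, what = paste0("record '", id, "'"))
  structure(
    list(id = id, description = description, sequence = seq,
         length = nchar(seq)),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s  (%d aa)\n", x$id, x$length))
  if (nzchar(x$description)) cat("  ", x$description, "\n", sep = "")
  s <- x$sequence
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat("  ", s, "\n", sep = "")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines). Headers are
#' split into an id (first whitespace-delimited token) and a description
#' (remainder). Sequences are uppercased, whitespace-stripped and validated
#' against the standard 20-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @param on_invalid `"error"` (default) stops on the first record with a
#'   non-standard residue; `"drop"` warns and drops such records instead.
#' @return A list of [protein_record()] objects, in file order.
#' @export
read_fasta <- function(path, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  aas <- Biostrings::readBStringSet(path)
  if (length(aas) == 0L) stop("FASTA file contains no records: ", path, call. = FALSE)
  headers <- names(aas)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- vector("list", length(aas))
  keep <- logical(length(aas))
  for (i in seq_along(aas)) {
    rec <- tryCatch(
      protein_record(ids[i], as.character(aas[[i]]), descs[i]),
      error = function(e) e
    )
    if (inherits(rec, "error")) {
      if (on_invalid == "error") stop(conditionMessage(rec), call. = FALSE)
      warning("dropping record: ", conditionMessage(rec), call. = FALSE)
    } else {
      out[[i]] <- rec
      keep[i] <- TRUE
    }
  }
  out[keep]
}

#' Write protein records to a FASTA file
#'
#' @param records A list of [protein_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "protein_record")) records <- list(records)
  stopifnot(length(records) > 0L,
            all(vapply(records, inherits, logical(1), "protein_record")))
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1))
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}
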