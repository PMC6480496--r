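# Controlled activity vocabulary. Open-ended classes are allowed with an
# "other:" prefix (e.g. "other:anti-inflammatory").
ACTIVITY_CODES <- c(
  AC  = "ACE inhibitory",
  AO  = "antioxidant",
  AA  = "anti-amnestic",
  AT  = "antithrombotic",
  S   = "stimulating",
  R   = "regulating",
  DPP = "DPP-IV inhibitory"
)

.check_activity <- function(code) {
  ok <- code %in% names(ACTIVITY_CODES) | grepl("^other:.+", code)
  if (!all(ok)) {
    stop("unknown activity code(s): ", paste(unique(code[!ok]), collapse = ", "),
         " (use one of ", paste(names(ACTIVITY_CODES), collapse = "/"),
         " or an 'other:<label>' code)", call. = FALSE)
  }
  invisible(code)
}

#' Build an activity dictionary from peptide entries
#'
#' An activity dictionary is the searchable collection of known bioactive
#' peptides against which proteins are profiled and digestion fragments
#' matched. Each entry is a (sequence, activity) pair, optionally carrying an
#' IC50 and a source tag. Duplicate (sequence, activity) pairs are collapsed
#' with a warning; the same sequence may appear under several activities.
#'
#' @param entries A data.frame with columns `sequence` and `activity`, and
#'   optionally `ic50_value`, `ic50_units` and `source`.
#' @param name Dictionary name/version label.
#' @return An object of class `activity_dictionary`.
#' @export
activity_dictionary <- function(entries, name = "unnamed") {
  stopifnot(is.data.frame(entries),
            all(c("sequence", "activity") %in% names(entries)))
  entries$sequence <- vapply(as.character(entries$sequence), validate_sequence,
                             character(1), USE.NAMES = FALSE)
  entries$activity <- as.character(entries$activity)
  .check_activity(entries$activity)
  n <- nrow(entries)
  if (is.null(entries$ic50_value)) entries$ic50_value <- rep(NA_real_, n)
  if (is.null(entries$ic50_units)) entries$ic50_units <- rep(NA_character_, n)
  if (is.null(entries$source))     entries$source     <- rep(NA_character_, n)
  bad_units <- !is.na(entries$ic50_units) &
    !entries$ic50_units %in% c("uM", "mM")
  if (any(bad_units)) {
    stop("ic50_units must be 'uM' or 'mM' (got: ",
         paste(unique(entries$ic50_units[bad_units]), collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(!is.na(entries$ic50_value) & entries$ic50_value <= 0)) {
    stop("ic50_value must be positive", call. = FALSE)
  }
  key <- paste(entries$sequence, entries$activity, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate (sequence, activity) row(s) collapsed",
            call. = FALSE)
    entries <- entries[!duplicated(key), , drop = FALSE]
  }
  entries <- entries[order(entries$sequence, entries$activity),
                     c("sequence", "activity", "ic50_value", "ic50_units", "source")]
  rownames(entries) <- NULL
  structure(list(entries = entries, name = name),
            class = "activity_dictionary")
}

#' @export
print.activity_dictionary <- function(x, ...) {
  cat(sprintf("<activity_dictionary> %s: %d entries, %d distinct peptides\n",
              x$name, nrow(x$entries), length(unique(x$entries$sequence))))
  tab <- table(x$entries$activity)
  cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Load an activity dictionary from a tab-separated file
#'
#' Expected columns: `sequence`, `activity`, `ic50_value`, `ic50_units`,
#' `source` (UTF-8, "." for a missing IC50 field).
#'
#' @param path Path to the TSV file.
#' @param name Dictionary label; defaults to the file name.
#' @return An [activity_dictionary()].
#' @export
load_dictionary <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("dictionary file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".",
                          colClasses = "character", fileEncoding = "UTF-8")
  required <- c("sequence", "activity", "ic50_value", "ic50_units", "source")
  if (!all(required %in% names(df))) {
    stop("dictionary file must have header columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(activity_dictionary(
      data.frame(sequence = character(), activity = character()), name = name))
  }
  bad_row <- which(is.na(df$sequence) | !nzchar(df$sequence) |
                   is.na(df$activity) | !nzchar(df$activity))
  if (length(bad_row) > 0L) {
    stop("malformed dictionary row at line ", bad_row[1L] + 1L,
         " (missing sequence or activity)", call. = FALSE)
  }
  df$ic50_value <- suppressWarnings(as.numeric(df$ic50_value))
  activity_dictionary(df, name = name)
}

#' Write an activity dictionary to a tab-separated file
#'
#' Inverse of [load_dictionary()]: missing IC50 fields are written as ".".
#'
#' @param dict An [activity_dictionary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "activity_dictionary"))
  df <- dict$entries
  df$ic50_value <- ifelse(is.na(df$ic50_value), ".",
                          format(df$ic50_value, trim = TRUE, scientific = FALSE))
  df$ic50_units[is.na(df$ic50_units)] <- "."
  df$source[is.na(df$source)] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Look up a peptide in the dictionary
#'
#' Exact-equality matching only: the query must equal an entry's full
#' sequence (no substring semantics). A peptide present under several
#' activities returns one row per activity.
#'
#' @param dict An [activity_dictionary()].
#' @param peptide Peptide sequence.
#' @return The matching rows of the entry table (zero rows when absent).
#' @export
lookup <- function(dict, peptide) {
  stopifnot(inherits(dict, "activity_dictionary"))
  peptide <- validate_sequence(peptide)
  hits <- dict$entries[dict$entries$sequence == peptide, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' The bundled bioactive-peptide dictionary
#'
#' Loads the dictionary fixture shipped with the package: experimentally
#' characterised ACE-inhibitory peptides from microalgal studies (with
#' published IC50 values), the antioxidant peptide LNGDVW, two
#' anti-inflammatory peptides, a set of multifunctional di-/tripeptides
#' recorded under both ACE-inhibitory and DPP-IV-inhibitory activities, and a
#' documented synthetic set so that every activity class has at least five
#' entries. It is a small, versioned stand-in for a full bioactive-peptide
#' database, not a mirror of one.
#'
#' @return An [activity_dictionary()].
#' @export
bundled_dictionary <- function() {
  load_dictionary(
    system.file("extdata", "bioactive_peptides.tsv", package = "biopepsim",
                mustWork = TRUE),
    name = "biopepsim-bundled-0.1.0"
  )
}
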