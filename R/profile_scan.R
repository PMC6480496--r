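# Fixed activity-column order used in profile reports.
PROFILE_ACTIVITY_ORDER <- c("AC", "AO", "AA", "AT", "S", "R", "DPP")

# Round half away from zero to `digits` decimals (the convention that
# reproduces the published occurrence frequencies from their own counts;
# base round() rounds half to even).
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Locate every dictionary peptide inside a protein
#'
#' Scans a protein for exact occurrences of every dictionary peptide of
#' length >= `min_len`. Every occurrence of every entry is reported:
#' overlapping and nested matches are all counted, and a peptide recorded
#' under several activities yields one occurrence row per activity.
#' Coordinates are 1-based and inclusive.
#'
#' @param protein A [protein_record()] (or a plain sequence string).
#' @param dict An [activity_dictionary()].
#' @param min_len Minimum dictionary-peptide length to scan for (default 2;
#'   single-residue entries otherwise dominate the counts).
#' @return A data.frame with columns `protein_id`, `peptide`, `activity`,
#'   `start`, `end`, sorted by (start, end, activity).
#' @examples
#' d <- activity_dictionary(data.frame(
#'   sequence = c("VY", "VPL", "VPL"), activity = c("AC", "AC", "DPP")))
#' scan_protein(protein_record("p", "AVYVPLK"), d)
#' @export
scan_protein <- function(protein, dict, min_len = 2L) {
  if (is.character(protein)) protein <- protein_record("protein", protein)
  stopifnot(inherits(protein, "protein_record"),
            inherits(dict, "activity_dictionary"),
            min_len >= 1L)
  seq <- protein$sequence
  ent <- dict$entries
  ent <- ent[nchar(ent$sequence) >= min_len, , drop = FALSE]
  peptides <- unique(ent$sequence)
  rows <- vector("list", length(peptides))
  for (i in seq_along(peptides)) {
    pep <- peptides[i]
    # lookahead so overlapping occurrences are all found
    hits <- gregexpr(paste0("(?=", pep, ")"), seq, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    acts <- ent$activity[ent$sequence == pep]
    rows[[i]] <- data.frame(
      protein_id = protein$id,
      peptide = pep,
      activity = rep(acts, each = length(hits)),
      start = rep(as.integer(hits), times = length(acts)),
      end = rep(as.integer(hits) + nchar(pep) - 1L, times = length(acts)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), peptide = character(),
                      activity = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$end, out$activity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-activity occurrence counts
#'
#' Tabulates the occurrence count a for each activity class from a scan of a
#' single protein. Activities absent from the occurrences are reported as 0.
#'
#' @param occurrences Output of [scan_protein()] for one protein.
#' @param activities Activity codes to report (default: the seven standard
#'   classes plus any "other:" codes present).
#' @return A named integer vector of counts.
#' @export
activity_counts <- function(occurrences, activities = NULL) {
  stopifnot(is.data.frame(occurrences), "activity" %in% names(occurrences))
  if (length(unique(occurrences$protein_id)) > 1L) {
    stop("occurrences mix several proteins; count one protein at a time",
         call. = FALSE)
  }
  if (is.null(activities)) {
    extra <- setdiff(unique(occurrences$activity), PROFILE_ACTIVITY_ORDER)
    activities <- c(PROFILE_ACTIVITY_ORDER, sort(extra))
  }
  counts <- vapply(activities, function(a) sum(occurrences$activity == a),
                   integer(1))
  counts
}

#' Occurrence frequency A = a / N
#'
#' The occurrence frequency of an activity class in a protein: the number of
#' bioactive-peptide occurrences a divided by the protein's residue count N,
#' rounded half away from zero to three decimals.
#'
#' @param a Non-negative occurrence count.
#' @param N Protein length in residues (>= 1).
#' @return Frequency rounded to 3 decimals.
#' @examples
#' occurrence_frequency(250, 567)  # 0.441
#' @export
occurrence_frequency <- function(a, N) {
  stopifnot(is.numeric(a), all(a >= 0))
  if (!is.numeric(N) || length(N) != 1L || N < 1) {
    stop("protein length N must be >= 1", call. = FALSE)
  }
  round_half_up(a / N, 3L)
}

#' Activity profile of one protein
#'
#' Combines [scan_protein()], [activity_counts()] and
#' [occurrence_frequency()] into the per-protein profile: for each activity
#' class, the occurrence count a and frequency A = a/N.
#'
#' @inheritParams scan_protein
#' @return A list of class `activity_profile` with fields `protein_id`, `N`,
#'   `counts` (named integer vector) and `frequencies` (named numeric
#'   vector).
#' @export
activity_profile <- function(protein, dict, min_len = 2L) {
  if (is.character(protein)) protein <- protein_record("protein", protein)
  occ <- scan_protein(protein, dict, min_len = min_len)
  counts <- activity_counts(occ)
  structure(
    list(protein_id = protein$id, N = protein$length, counts = counts,
         frequencies = occurrence_frequency(counts, protein$length)),
    class = "activity_profile"
  )
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("<activity_profile> %s  (N = %d)\n", x$protein_id, x$N))
  for (a in names(x$counts)) {
    cat(sprintf("  %-24s %s\n", a, format_count_cell(x$counts[[a]], x$frequencies[[a]])))
  }
  invisible(x)
}

# "a (A)" cell, A printed to 3 decimals; "-" for empty cells when dashed.
format_count_cell <- function(a, A, dash_zeros = FALSE) {
  if (dash_zeros && a == 0L) return("-")
  sprintf("%d (%.3f)", a, A)
}

#' Profile report for a set of proteins
#'
#' One row per protein with, for each of the seven standard activity classes
#' (ACE inhibitory, antioxidant, anti-amnestic, antithrombotic, stimulating,
#' regulating, DPP-IV inhibitory, in that fixed order), the occurrence count
#' `a_<code>` and frequency `A_<code>`.
#'
#' @param proteins A list of [protein_record()] objects (or one record).
#' @param dict An [activity_dictionary()].
#' @param min_len Minimum dictionary-peptide length (default 2).
#' @return A data.frame with columns `protein_id`, `N`, then `a_AC`, `A_AC`,
#'   ..., `a_DPP`, `A_DPP`.
#' @export
profile_report <- function(proteins, dict, min_len = 2L) {
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  stopifnot(length(proteins) > 0L)
  rows <- lapply(proteins, function(p) {
    prof <- activity_profile(p, dict, min_len = min_len)
    row <- data.frame(protein_id = prof$protein_id, N = prof$N,
                      stringsAsFactors = FALSE)
    for (a in PROFILE_ACTIVITY_ORDER) {
      row[[paste0("a_", a)]] <- unname(prof$counts[a])
      row[[paste0("A_", a)]] <- unname(prof$frequencies[a])
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
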