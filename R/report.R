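#' Format a profile report with "a (A)" cells
#'
#' Renders the numeric profile table of [profile_report()] as one
#' publication-style cell per activity: the count followed by the frequency
#' in parentheses to three decimals, e.g. `"59 (0.454)"`. Zero cells can be
#' rendered as `"-"`.
#'
#' @param report Output of [profile_report()].
#' @param dash_zeros Render zero-count cells as `"-"` (default `FALSE`).
#' @return A character data.frame with columns `protein_id`, `N` and one
#'   column per activity class.
#' @export
format_profile_report <- function(report, dash_zeros = FALSE) {
  stopifnot(is.data.frame(report), "protein_id" %in% names(report))
  out <- report[, c("protein_id", "N"), drop = FALSE]
  for (a in PROFILE_ACTIVITY_ORDER) {
    out[[a]] <- mapply(format_count_cell, report[[paste0("a_", a)]],
                       report[[paste0("A_", a)]],
                       MoreArgs = list(dash_zeros = dash_zeros))
  }
  out
}

# Write a data.frame as TSV and its numbers as a JSON mirror.
write_tsv_json <- function(df, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(df, json, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' Profile a FASTA file and write the activity-profile report
#'
#' End-to-end "profile" command: read proteins, scan against the dictionary,
#' and write the per-protein activity profile as TSV and JSON (identical
#' numbers in both).
#'
#' @param fasta Path to a FASTA file of proteins.
#' @param dict An [activity_dictionary()], or a path to a dictionary TSV;
#'   default: the bundled dictionary.
#' @param out_prefix Output path prefix (writes `<prefix>.tsv` and
#'   `<prefix>.json`); `NULL` writes nothing.
#' @param min_len Minimum dictionary-peptide length (default 2).
#' @return The numeric report data.frame, invisibly when writing.
#' @export
cmd_profile <- function(fasta, dict = bundled_dictionary(), out_prefix = NULL,
                        min_len = 2L) {
  if (is.character(dict)) dict <- load_dictionary(dict)
  proteins <- read_fasta(fasta)
  rep <- profile_report(proteins, dict, min_len = min_len)
  if (!is.null(out_prefix)) {
    write_tsv_json(rep, out_prefix)
    return(invisible(rep))
  }
  rep
}

#' Digest a FASTA file under the default battery and write the report
#'
#' End-to-end "battery" command: for each protein, run the battery of
#' digestion schemes and write per-scheme released bioactive-peptide counts
#' as TSV and JSON.
#'
#' @inheritParams cmd_profile
#' @param schemes List of [digestion_scheme()] objects; default the
#'   15-scheme [default_battery()].
#' @param missed Missed cleavages per digestion (default 0).
#' @return The combined report data.frame (one block of rows per protein),
#'   invisibly when writing.
#' @export
cmd_battery <- function(fasta, dict = bundled_dictionary(),
                        schemes = default_battery(), out_prefix = NULL,
                        missed = 0L, min_len = 2L) {
  if (is.character(dict)) dict <- load_dictionary(dict)
  proteins <- read_fasta(fasta)
  blocks <- lapply(proteins, function(p) {
    b <- run_battery(p, dict, schemes = schemes, missed = missed,
                     min_len = min_len)
    cbind(protein_id = p$id, b, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, blocks)
  rownames(rep) <- NULL
  if (!is.null(out_prefix)) {
    write_tsv_json(rep, out_prefix)
    return(invisible(rep))
  }
  rep
}

#' Peptide mass and charge-state report
#'
#' Monoisotopic mass of a peptide (2 dp, presentation rounding only) and the
#' m/z of its protonated ions at the requested charges.
#'
#' @param peptide Peptide sequence.
#' @param charges Integer charges to report (default 1:3).
#' @param modifications Optional per-residue mass deltas, as in
#'   [monoisotopic_mass()].
#' @return A list with `sequence`, `mass` (unrounded), `mass_2dp`, and a
#'   data.frame `ions` of (z, mz).
#' @examples
#' cmd_mass("NFNNIEDGFYISPAFLDK")$mass_2dp  # 2102.99
#' @export
cmd_mass <- function(peptide, charges = 1:3, modifications = NULL) {
  m <- monoisotopic_mass(peptide, modifications = modifications)
  ions <- data.frame(z = as.integer(charges),
                     mz = vapply(charges, function(z) mz(m, z), numeric(1)))
  list(sequence = validate_sequence(peptide), mass = m,
       mass_2dp = round_half_up(m, 2L), ions = ions)
}
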