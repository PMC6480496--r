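# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate a random protein sequence
#'
#' Draws residues i.i.d. from a composition over the 20-letter alphabet
#' (uniform by default). Bit-reproducible given a seed.
#'
#' @param length Residue count (>= 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param composition Named numeric vector of per-residue probabilities over
#'   the 20 standard residues (need not be normalised); default uniform. Use
#'   [empirical_composition()] to mimic a real proteome.
#' @param id Record id.
#' @return A [protein_record()].
#' @export
random_protein <- function(length, seed = NULL, composition = NULL,
                           id = "synthetic") {
  stopifnot(is.numeric(length), length >= 1)
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  if (is.null(names(composition)) ||
      !setequal(names(composition), AA_ALPHABET) ||
      any(composition < 0) || sum(composition) <= 0) {
    stop("composition must be a non-negative vector named by the 20 standard residues",
         call. = FALSE)
  }
  composition <- composition[AA_ALPHABET] / sum(composition)
  seq <- with_seed(seed, paste(
    sample(AA_ALPHABET, length, replace = TRUE, prob = composition),
    collapse = ""))
  protein_record(id, seq)
}

#' Residue composition of a set of proteins
#'
#' @param records List of [protein_record()] objects (e.g. from
#'   [read_fasta()]).
#' @return Named numeric vector of residue frequencies summing to 1,
#'   suitable as `composition` for [random_protein()].
#' @export
empirical_composition <- function(records) {
  if (inherits(records, "protein_record")) records <- list(records)
  chars <- unlist(strsplit(vapply(records, `[[`, character(1), "sequence"),
                           "", fixed = TRUE))
  counts <- vapply(AA_ALPHABET, function(a) sum(chars == a), numeric(1))
  counts / sum(counts)
}

# Brute-force count of (possibly overlapping) occurrences of `motif`.
count_occurrences <- function(sequence, motif) {
  n <- nchar(sequence); m <- nchar(motif)
  if (m > n) return(0L)
  sum(vapply(seq_len(n - m + 1L),
             function(i) substr(sequence, i, i + m - 1L) == motif,
             logical(1)))
}

#' Plant motif copies into a random background with exact ground truth
#'
#' Builds a protein of the given length containing exactly `k`
#' non-overlapping copies of each motif at recorded positions and, crucially,
#' no accidental occurrence of any motif elsewhere: whole candidates failing
#' the exact-count check are rejected and resampled (up to `max_tries`), so
#' the recorded ground truth is exact, not approximate.
#'
#' @param length Total protein length.
#' @param motifs A data.frame with columns `peptide`, `activity`, `k`
#'   (copies to plant, >= 0).
#' @param seed Integer seed.
#' @param composition Background residue composition (default uniform).
#' @param max_tries Rejection-sampling retry cap (default 1000).
#' @param id Record id.
#' @return A list with `protein` (a [protein_record()]) and `planted` (a
#'   data.frame of `peptide`, `activity`, `start`, `end`).
#' @export
plant_motifs <- function(length, motifs, seed = NULL, composition = NULL,
                         max_tries = 1000L, id = "synthetic") {
  stopifnot(is.data.frame(motifs),
            all(c("peptide", "activity", "k") %in% names(motifs)))
  motifs$peptide <- vapply(as.character(motifs$peptide), validate_sequence,
                           character(1), USE.NAMES = FALSE)
  motifs$k <- as.integer(motifs$k)
  stopifnot(all(motifs$k >= 0))
  if (sum(nchar(motifs$peptide) * motifs$k) > length) {
    stop("total motif length exceeds protein length", call. = FALSE)
  }
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  composition <- composition[AA_ALPHABET] / sum(composition)

  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      chars <- sample(AA_ALPHABET, length, replace = TRUE, prob = composition)
      taken <- logical(length)
      placed <- list()
      ok <- TRUE
      for (j in seq_len(nrow(motifs))) {
        pep <- motifs$peptide[j]; k <- motifs$k[j]
        if (k == 0L) next
        m <- nchar(pep)
        pep_chars <- strsplit(pep, "", fixed = TRUE)[[1L]]
        for (copy in seq_len(k)) {
          free <- which(vapply(seq_len(length - m + 1L), function(s) {
            !any(taken[s:(s + m - 1L)])
          }, logical(1)))
          if (length(free) == 0L) { ok <- FALSE; break }
          s <- if (length(free) == 1L) free else sample(free, 1L)
          chars[s:(s + m - 1L)] <- pep_chars
          taken[s:(s + m - 1L)] <- TRUE
          placed[[length(placed) + 1L]] <- data.frame(
            peptide = pep, activity = motifs$activity[j],
            start = s, end = s + m - 1L, stringsAsFactors = FALSE)
        }
        if (!ok) break
      }
      if (!ok) next
      seq <- paste(chars, collapse = "")
      # exact-count check: each motif occurs exactly k times in the result
      counts_ok <- all(vapply(seq_len(nrow(motifs)), function(j) {
        count_occurrences(seq, motifs$peptide[j]) == motifs$k[j]
      }, logical(1)))
      if (counts_ok) {
        planted <- if (length(placed) > 0L) do.call(rbind, placed) else
          data.frame(peptide = character(), activity = character(),
                     start = integer(), end = integer(),
                     stringsAsFactors = FALSE)
        planted <- planted[order(planted$start), , drop = FALSE]
        rownames(planted) <- NULL
        return(list(protein = protein_record(id, seq), planted = planted))
      }
    }
    stop("could not satisfy non-overlap/exact-count constraints in ",
         max_tries, " tries", call. = FALSE)
  })
}

#' Construct a protein whose digestion yields prescribed fragments
#'
#' Concatenates the wanted fragments so that digesting the result under the
#' given rule returns exactly those fragments in order. Each fragment must be
#' free of internal cleavage sites under the rule, and each junction must be
#' cleavable; violations are errors.
#'
#' @param rule A [protease_rule()].
#' @param fragments_wanted Character vector of fragment sequences, in order.
#' @return A [protein_record()] whose zero-missed digestion under `rule`
#'   equals `fragments_wanted`.
#' @examples
#' after_k <- protease_rule("after_k", p1 = "K")
#' synthetic_rule_protein(after_k, c("AVK", "GGK", "WF"))  # "AVKGGKWF"
#' @export
synthetic_rule_protein <- function(rule, fragments_wanted, id = "synthetic") {
  stopifnot(inherits(rule, "protease_rule"), length(fragments_wanted) >= 1L)
  frags <- vapply(as.character(fragments_wanted), validate_sequence,
                  character(1), USE.NAMES = FALSE)
  for (f in frags) {
    if (length(cleavage_sites(f, rule)) > 0L) {
      stop("fragment '", f, "' contains an internal cleavage site under rule '",
           rule$name, "'", call. = FALSE)
    }
  }
  seq <- paste(frags, collapse = "")
  got <- digest(seq, rule)$sequence
  if (!identical(got, unname(frags))) {
    stop("junctions are not all cleavable under rule '", rule$name,
         "': digestion yields [", paste(got, collapse = ", "),
         "] instead of the requested fragments", call. = FALSE)
  }
  protein_record(id, seq)
}
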