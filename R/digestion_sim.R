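#' Declarative protease cleavage rule
#'
#' A protease rule states, for the scissile bond between residue i (P1) and
#' residue i+1 (P1'), which residues are accepted on each side and which
#' (P1, P1') pairs block cleavage. An empty set on either side means "any
#' residue". Trypsin, for example, cleaves C-terminal to K or R but poorly
#' when they are followed by proline: `p1 = c("K","R")`, empty `p1_prime`,
#' exceptions `K:P` and `R:P`.
#'
#' @param name Rule name (used as scheme label component).
#' @param p1 Character vector of residues accepted at P1 (empty = any).
#' @param p1_prime Character vector of residues accepted at P1' (empty = any).
#' @param exceptions Character vector of blocking pairs, each written
#'   `"X:Y"` (P1 residue X followed by P1' residue Y blocks the cut).
#' @param ec EC number string (optional).
#' @param notes Free text.
#' @return An object of class `protease_rule`.
#' @export
protease_rule <- function(name, p1 = character(), p1_prime = character(),
                          exceptions = character(), ec = NA_character_,
                          notes = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  p1 <- toupper(as.character(p1)); p1_prime <- toupper(as.character(p1_prime))
  if (length(p1) == 0L && length(p1_prime) == 0L) {
    stop("rule '", name, "': at least one of p1/p1_prime must be non-empty",
         call. = FALSE)
  }
  if (!all(p1 %in% AA_ALPHABET) || !all(p1_prime %in% AA_ALPHABET)) {
    stop("rule '", name, "': p1/p1_prime must be standard residues", call. = FALSE)
  }
  exceptions <- as.character(exceptions)
  exc <- lapply(exceptions, function(e) {
    parts <- strsplit(toupper(e), ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !all(nchar(parts) == 1L) ||
        !all(parts %in% AA_ALPHABET)) {
      stop("rule '", name, "': malformed exception pair '", e,
           "' (expected 'X:Y' with standard residues)", call. = FALSE)
    }
    parts
  })
  structure(
    list(name = name, ec = ec, p1 = unique(p1), p1_prime = unique(p1_prime),
         exceptions = exc, notes = notes),
    class = "protease_rule"
  )
}

#' @export
print.protease_rule <- function(x, ...) {
  fmt_set <- function(s) if (length(s) == 0L) "any" else paste(s, collapse = "")
  exc <- if (length(x$exceptions) == 0L) "none" else
    paste(vapply(x$exceptions, paste, character(1), collapse = ":"), collapse = ",")
  cat(sprintf("<protease_rule> %s (EC %s)  P1:{%s}  P1':{%s}  blocked:%s\n",
              x$name, ifelse(is.na(x$ec), "?", x$ec),
              fmt_set(x$p1), fmt_set(x$p1_prime), exc))
  invisible(x)
}

#' Cleavage sites of a rule on a sequence
#'
#' Position i (1 <= i < N) is a cleavage site iff residue i is accepted at
#' P1, residue i+1 at P1', and the (P1, P1') pair is not an exception. A cut
#' at i severs the bond between residues i and i+1.
#'
#' @param sequence Protein sequence (string or [protein_record()]).
#' @param rule A [protease_rule()].
#' @return Sorted integer vector of cut positions.
#' @examples
#' tr <- protease_rule("trypsin", p1 = c("K", "R"),
#'                     exceptions = c("K:P", "R:P"))
#' cleavage_sites("AKRPAR", tr)  # 2
#' @export
cleavage_sites <- function(sequence, rule) {
  if (inherits(sequence, "protein_record")) sequence <- sequence$sequence
  stopifnot(inherits(rule, "protease_rule"))
  seq <- validate_sequence(sequence)
  n <- nchar(seq)
  if (n < 2L) return(integer())
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  i <- seq_len(n - 1L)
  ok <- (length(rule$p1) == 0L | chars[i] %in% rule$p1) &
        (length(rule$p1_prime) == 0L | chars[i + 1L] %in% rule$p1_prime)
  for (exc in rule$exceptions) {
    ok <- ok & !(chars[i] == exc[1L] & chars[i + 1L] == exc[2L])
  }
  which(ok)
}

#' Digestion scheme: one to three proteases acting simultaneously
#'
#' Combined schemes pool their cleavage sites (union semantics, a single
#' simultaneous digestion), mirroring combined "enzyme action" of up to three
#' proteases.
#'
#' @param rules A [protease_rule()] or list of up to three of them.
#' @param label Scheme label; defaults to rule names joined with `+`.
#' @return An object of class `digestion_scheme`.
#' @export
digestion_scheme <- function(rules, label = NULL) {
  if (inherits(rules, "protease_rule")) rules <- list(rules)
  stopifnot(length(rules) >= 1L, length(rules) <= 3L,
            all(vapply(rules, inherits, logical(1), "protease_rule")))
  if (is.null(label)) {
    label <- paste(vapply(rules, `[[`, character(1), "name"), collapse = "+")
  }
  structure(list(label = label, rules = rules), class = "digestion_scheme")
}

#' @export
print.digestion_scheme <- function(x, ...) {
  cat(sprintf("<digestion_scheme> %s  (%d enzyme%s)\n", x$label,
              length(x$rules), if (length(x$rules) > 1L) "s" else ""))
  invisible(x)
}

#' In silico digestion of a protein
#'
#' Cuts the sequence at the union of the scheme's cleavage sites. With
#' `missed = 0` the fragments are the maximal runs between consecutive sites
#' (they tile the protein exactly); with `missed = m`, every concatenation of
#' up to m+1 adjacent zero-missed fragments is additionally reported, with
#' its missed-cleavage count.
#'
#' @param sequence Protein sequence (string or [protein_record()]).
#' @param scheme A [digestion_scheme()] or single [protease_rule()].
#' @param missed Maximum number of missed cleavages (default 0).
#' @return A data.frame with columns `sequence`, `start`, `end`, `n_missed`,
#'   sorted by (start, end).
#' @examples
#' tr <- protease_rule("trypsin", p1 = c("K", "R"),
#'                     exceptions = c("K:P", "R:P"))
#' digest("AKRPAR", tr)              # AK | RPAR
#' digest("AKGK", tr, missed = 1)    # AK, GK, AKGK
#' @export
digest <- function(sequence, scheme, missed = 0L) {
  if (inherits(scheme, "protease_rule")) scheme <- digestion_scheme(scheme)
  stopifnot(inherits(scheme, "digestion_scheme"),
            is.numeric(missed), length(missed) == 1L, missed >= 0)
  if (inherits(sequence, "protein_record")) sequence <- sequence$sequence
  seq <- validate_sequence(sequence)
  n <- nchar(seq)
  sites <- sort(unique(unlist(lapply(scheme$rules, cleavage_sites, sequence = seq))))
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  frags <- list()
  k <- length(starts)  # zero-missed fragment count
  for (m in 0:missed) {
    if (m >= k) break
    i <- seq_len(k - m)
    frags[[m + 1L]] <- data.frame(
      start = starts[i], end = ends[i + m], n_missed = m,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, frags)
  out$sequence <- substring(seq, out$start, out$end)
  out <- out[order(out$start, out$end), c("sequence", "start", "end", "n_missed")]
  rownames(out) <- NULL
  out
}

#' Released bioactive fragments
#'
#' A digestion fragment is "released bioactive" iff its full sequence exactly
#' equals a dictionary peptide (of length >= `min_len`). Counts are per
#' fragment occurrence and per matching activity: the same released sequence
#' appearing twice counts twice, and a peptide with two recorded activities
#' counts once under each.
#'
#' @param fragments Output of [digest()].
#' @param dict An [activity_dictionary()].
#' @param min_len Minimum fragment length considered (default 2, matching
#'   the profiler's filter).
#' @return A list with `counts` (named integer vector over activity classes)
#'   and `matches` (data.frame of matched fragments with their activities).
#' @export
released_bioactive <- function(fragments, dict, min_len = 2L) {
  stopifnot(is.data.frame(fragments), "sequence" %in% names(fragments),
            inherits(dict, "activity_dictionary"))
  frag <- fragments[nchar(fragments$sequence) >= min_len, , drop = FALSE]
  ent <- dict$entries[nchar(dict$entries$sequence) >= min_len, , drop = FALSE]
  rows <- list()
  if (nrow(frag) > 0L && nrow(ent) > 0L) {
    for (i in seq_len(nrow(frag))) {
      acts <- ent$activity[ent$sequence == frag$sequence[i]]
      if (length(acts) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = frag$sequence[i], start = frag$start[i],
          end = frag$end[i], activity = acts, stringsAsFactors = FALSE
        )
      }
    }
  }
  matches <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(sequence = character(), start = integer(), end = integer(),
               activity = character(), stringsAsFactors = FALSE)
  extra <- setdiff(unique(matches$activity), PROFILE_ACTIVITY_ORDER)
  classes <- c(PROFILE_ACTIVITY_ORDER, sort(extra))
  counts <- vapply(classes, function(a) sum(matches$activity == a), integer(1))
  list(counts = counts, matches = matches)
}

#' Run a battery of digestion schemes
#'
#' Digests a protein under each scheme (zero missed cleavages by default, the
#' convention for release simulations) and tabulates per-activity released
#' bioactive-peptide counts: one row per scheme.
#'
#' @param protein A [protein_record()] or sequence string.
#' @param dict An [activity_dictionary()].
#' @param schemes List of [digestion_scheme()] objects; default
#'   [default_battery()].
#' @param missed Missed cleavages allowed in each digestion (default 0).
#' @param min_len Minimum fragment length matched (default 2).
#' @return A data.frame with columns `scheme`, `n_enzymes`, `n_fragments`,
#'   then one count column per standard activity class.
#' @export
run_battery <- function(protein, dict, schemes = default_battery(),
                        missed = 0L, min_len = 2L) {
  if (is.character(protein)) protein <- protein_record("protein", protein)
  stopifnot(inherits(protein, "protein_record"),
            all(vapply(schemes, inherits, logical(1), "digestion_scheme")))
  rows <- lapply(schemes, function(sc) {
    frags <- digest(protein$sequence, sc, missed = missed)
    rel <- released_bioactive(frags, dict, min_len = min_len)
    row <- data.frame(scheme = sc$label, n_enzymes = length(sc$rules),
                      n_fragments = nrow(frags), stringsAsFactors = FALSE)
    for (a in PROFILE_ACTIVITY_ORDER) row[[a]] <- unname(rel$counts[a])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
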