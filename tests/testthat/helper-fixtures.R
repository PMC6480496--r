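# Shared fixtures and independent oracles used across the suite.

# Brute-force substring scan: the oracle scan_protein() must match exactly.
oracle_scan <- function(sequence, entries, min_len = 2L) {
  rows <- list()
  n <- nchar(sequence)
  ent <- entries[nchar(entries$sequence) >= min_len, , drop = FALSE]
  for (j in seq_len(nrow(ent))) {
    pep <- ent$sequence[j]
    m <- nchar(pep)
    if (m > n) next
    for (i in seq_len(n - m + 1L)) {
      if (substr(sequence, i, i + m - 1L) == pep) {
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = pep, activity = ent$activity[j],
          start = i, end = i + m - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(peptide = character(), activity = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end, out$activity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# Random protease rule (P1 set of 1-4 residues, sometimes an exception pair).
random_rule <- function() {
  p1 <- sample(AA20, sample(1:4, 1))
  exc <- character()
  if (runif(1) < 0.5) exc <- paste0(sample(p1, 1), ":", sample(AA20, 1))
  protease_rule(paste0("rnd_", paste(p1, collapse = "")), p1 = p1,
                exceptions = exc)
}

# Random sequence over the standard alphabet.
random_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Temporary FASTA file helper.
write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# Dictionary from a compact spec like c(VY = "AC", VPL = "AC,DPP").
mini_dict <- function(spec) {
  seqs <- character(); acts <- character()
  for (s in names(spec)) {
    for (a in strsplit(spec[[s]], ",", fixed = TRUE)[[1L]]) {
      seqs <- c(seqs, s); acts <- c(acts, a)
    }
  }
  activity_dictionary(data.frame(sequence = seqs, activity = acts,
                                 stringsAsFactors = FALSE), name = "mini")
}
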