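# Frozen residue-mass tables (Da). Monoisotopic values are the standard
# residue masses used throughout MS-based proteomics; the table is versioned
# with the package so computed masses are bit-reproducible.
MONOISOTOPIC_RESIDUE_MASS <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276, V =  99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

AVERAGE_RESIDUE_MASS <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167, V =  99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

MASS_WATER  <- 18.010565   # monoisotopic H2O
MASS_PROTON <- 1.007276    # mass of a proton (H+)

.residue_table <- function(type = c("monoisotopic", "average")) {
  type <- match.arg(type)
  if (type == "monoisotopic") MONOISOTOPIC_RESIDUE_MASS else AVERAGE_RESIDUE_MASS
}

#' Neutral peptide mass
#'
#' Computes the neutral mass of a peptide as the sum of its residue masses
#' plus one water. Monoisotopic masses are the default, matching
#' Orbitrap-style high-resolution data; average masses are available via
#' `type = "average"`. Fixed or variable modifications (e.g.
#' carbamidomethyl-C +57.02146, oxidised-M +15.994915) can be applied as
#' per-residue mass deltas.
#'
#' @param sequence Peptide sequence (validated with [validate_sequence()]).
#' @param type `"monoisotopic"` (default) or `"average"`.
#' @param modifications Optional named numeric vector of per-residue mass
#'   deltas, e.g. `c(C = 57.02146)`; applied to every occurrence of the
#'   named residue.
#' @return Neutral mass in Da (unrounded).
#' @examples
#' monoisotopic_mass("NFNNIEDGFYISPAFLDK")  # 2102.995
#' monoisotopic_mass("G")                   # 75.03203
#' @export
monoisotopic_mass <- function(sequence, type = c("monoisotopic", "average"),
                              modifications = NULL) {
  tab <- .residue_table(type)
  seq <- validate_sequence(sequence)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  m <- sum(tab[chars]) + if (identical(match.arg(type), "average")) 18.01528 else MASS_WATER
  if (!is.null(modifications)) {
    stopifnot(is.numeric(modifications), !is.null(names(modifications)),
              all(names(modifications) %in% AA_ALPHABET))
    for (res in names(modifications)) {
      m <- m + modifications[[res]] * sum(chars == res)
    }
  }
  unname(m)
}

#' Mass-to-charge ratio of a protonated peptide
#'
#' m/z of the `[M + zH]^(z+)` ion: `(mass + z * proton) / z`.
#'
#' @param mass Neutral mass in Da (> 0).
#' @param z Positive integer charge.
#' @return m/z in Da per unit charge.
#' @examples
#' mz(2102.99489, 2)  # 1052.50 at 2 dp
#' @export
mz <- function(mass, z) {
  stopifnot(is.numeric(mass), length(mass) == 1L, mass > 0)
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != as.integer(z)) {
    stop("charge z must be a positive integer", call. = FALSE)
  }
  (mass + z * MASS_PROTON) / z
}

#' Charged-peptide descriptor
#'
#' Bundles a peptide with its neutral monoisotopic mass, charge state, and
#' m/z of the protonated ion.
#'
#' @inheritParams monoisotopic_mass
#' @param z Positive integer charge.
#' @return A list of class `charged_peptide` with fields `sequence`, `mass`,
#'   `z` and `mz`.
#' @export
charged_peptide <- function(sequence, z = 1L, type = "monoisotopic",
                            modifications = NULL) {
  m <- monoisotopic_mass(sequence, type = type, modifications = modifications)
  structure(
    list(sequence = validate_sequence(sequence), mass = m, z = as.integer(z),
         mz = mz(m, z)),
    class = "charged_peptide"
  )
}

#' @export
print.charged_peptide <- function(x, ...) {
  cat(sprintf("<charged_peptide> %s  M = %.5f Da  [M+%dH]%d+ m/z = %.4f\n",
              x$sequence, x$mass, x$z, x$z, x$mz))
  invisible(x)
}

#' Infer charge state from isotope spacing
#'
#' In an isotope envelope, adjacent signals of a z-charged ion are separated
#' by 1/z m/z units: a spacing of 0.50 indicates a doubly charged ion, 0.33 a
#' triply charged one. Returns `z = round(1 / delta_mz)` together with the
#' residual `|1/delta_mz - z|`; a residual above `tolerance` means the
#' spacing is not a clean 1/z and is rejected.
#'
#' @param delta_mz Observed spacing between adjacent isotope signals (> 0).
#' @param tolerance Maximum accepted residual (default 0.1).
#' @return A list with integer `z` and numeric `residual`.
#' @examples
#' charge_from_isotope_spacing(0.50)$z  # 2
#' charge_from_isotope_spacing(0.33)$z  # 3
#' @export
charge_from_isotope_spacing <- function(delta_mz, tolerance = 0.1) {
  stopifnot(is.numeric(delta_mz), length(delta_mz) == 1L, delta_mz > 0)
  inv <- 1 / delta_mz
  z <- as.integer(round(inv))
  residual <- abs(inv - z)
  if (z < 1L || residual > tolerance) {
    stop(sprintf(
      "not a clean isotope spacing: 1/%g = %.4f (residual %.4f > tolerance %g)",
      delta_mz, inv, residual, tolerance), call. = FALSE)
  }
  list(z = z, residual = residual)
}

#' Theoretical b/y fragment-ion ladder
#'
#' Computes the theoretical b- or y-series fragment ions of a peptide at a
#' given charge: neutral b_i is the sum of residues 1..i, neutral y_j the sum
#' of the last j residues plus one water; each is protonated per [mz()].
#' Indices run 1..(n-1), so at every i the b_i / y_(n-i) pair partitions the
#' residue masses.
#'
#' @param sequence Peptide of length >= 2.
#' @param series `"b"` or `"y"`.
#' @param z Charge applied to each fragment ion (default 1).
#' @param type Residue-mass table, as in [monoisotopic_mass()].
#' @return A data.frame with columns `ion` (e.g. `"b1"`), `index`,
#'   `neutral_mass` and `mz`, ordered by index.
#' @export
fragment_ions <- function(sequence, series = c("b", "y"), z = 1L,
                          type = "monoisotopic") {
  series <- match.arg(series)
  seq <- validate_sequence(sequence)
  n <- nchar(seq)
  if (n < 2L) stop("fragment ions require a peptide of length >= 2", call. = FALSE)
  tab <- .residue_table(type)
  res <- tab[strsplit(seq, "", fixed = TRUE)[[1L]]]
  idx <- seq_len(n - 1L)
  neutral <- if (series == "b") {
    cumsum(res)[idx]
  } else {
    rev(cumsum(rev(res)))[2L:n] + MASS_WATER  # y_j = last j residues + water
  }
  if (series == "y") neutral <- rev(neutral)  # order y1, y2, ...
  data.frame(
    ion = paste0(series, idx),
    index = idx,
    neutral_mass = unname(neutral),
    mz = vapply(neutral, mz, numeric(1), z = z),
    stringsAsFactors = FALSE
  )
}

#' Sequence coverage from matched peptide intervals
#'
#' Percentage of a protein's residues covered by the union of matched peptide
#' intervals (1-based, inclusive). Overlapping intervals are counted once;
#' the result is rounded to the nearest integer percent.
#'
#' @param matched A data.frame or matrix with two columns (start, end), or a
#'   list of length-2 vectors.
#' @param N Protein length (residues).
#' @return Integer percentage in \[0, 100\].
#' @examples
#' coverage(list(c(1, 10), c(5, 14)), N = 100)  # 14
#' @export
coverage <- function(matched, N) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1)
  if (is.list(matched) && !is.data.frame(matched)) {
    if (length(matched) == 0L) return(0L)
    matched <- do.call(rbind, matched)
  }
  matched <- as.matrix(matched)
  if (nrow(matched) == 0L) return(0L)
  stopifnot(ncol(matched) == 2L)
  start <- matched[, 1L]; end <- matched[, 2L]
  if (any(start > end)) stop("interval with start > end", call. = FALSE)
  if (any(start < 1) || any(end > N)) {
    stop("interval outside [1, N]", call. = FALSE)
  }
  covered <- logical(N)
  for (i in seq_along(start)) covered[start[i]:end[i]] <- TRUE
  as.integer(round(sum(covered) / N * 100))
}
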