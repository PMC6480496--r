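---
title: "Profiling and releasing bioactive peptides in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling and releasing bioactive peptides in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biopepsim)
```

## The problem

Dietary and microalgal proteins encrypt many short peptides — mostly di- and
tripeptides — that are biologically active only after release from the
parent chain: ACE inhibitors (antihypertensive), DPP-IV inhibitors
(antidiabetic), antioxidants, and related classes. Two questions recur in
this literature:

1. **Profiling.** How rich is a given protein in known bioactive peptides,
   per activity class?
2. **Release.** Which proteases, alone or combined, would actually liberate
   those peptides on hydrolysis?

`biopepsim` answers both with fully local, versioned data: a
peptide-activity dictionary (tab-separated, one `(sequence, activity)` entry
per row with optional IC50 metadata) and a protease rules file. No web
database is queried; swapping either file changes the analysis data, not
the code.

## The profiling model

A protein of length $N$ is scanned for exact substring occurrences of every
dictionary peptide. Counting semantics are deliberately simple and
oracle-checkable:

- every occurrence of every entry counts — overlapping and nested matches
  included;
- a peptide recorded under $m$ activities contributes one count to each of
  the $m$ classes per occurrence;
- duplicate dictionary rows are collapsed at load time.

For each activity class the count $a$ yields the occurrence frequency

$$A = \frac{a}{N},$$

reported half-away-from-zero rounded to three decimals. That rounding rule
is not cosmetic: it is the convention under which published profile tables
can be regenerated from their own printed $(a, N)$ pairs, and base R's
round-half-to-even would disagree on boundary cases.

The profiler's `min_len` filter (default 2) excludes single-residue
dictionary "peptides", which otherwise dominate every count; the filter is a
visible argument, not hidden behaviour, because curated databases do contain
single-residue entries.

The scanner uses a zero-width lookahead regular expression so that
overlapping matches are all found; the test suite holds it bit-identical to
a naive brute-force substring oracle on randomised instances, so the
implementation is free to change without changing the statistic.

## The digestion model

A protease rule is declarative: a set of residues accepted at P1
(immediately N-terminal of the scissile bond), a set at P1′ (immediately
C-terminal; empty means any), and a list of blocking (P1, P1′) pairs.
Trypsin is the canonical example — cleaves after K or R, poorly when
followed by proline — and is pinned to exactly that rule in the bundled
file. Position $i$ is a cut site when residue $i$ passes P1, residue $i+1$
passes P1′, and the pair is not an exception.

Design choices that were genuinely open:

- **Combined schemes act simultaneously**, pooling the union of their cut
  sites in a single digestion, rather than sequentially re-digesting
  fragments. This matches the "enzyme action" semantics of release
  screening, and it is what makes the tiling invariant hold: zero-missed
  fragments always concatenate back to the protein.
- **Missed cleavages** with budget $m$ add every concatenation of up to
  $m+1$ adjacent zero-missed fragments, labelled by the number of internal
  sites spanned. With $F$ zero-missed fragments and $F > m$ this yields
  exactly $\sum_{j=0}^{m}(F-j)$ fragments — a property the suite checks on
  random sequences. The release battery uses $m = 0$ (the screening
  convention); proteomics-style tryptic digestion typically uses $m = 2$.
- **Release is exact-match**: a fragment counts iff its entire sequence
  equals a dictionary entry, once per matching activity per fragment
  occurrence. Duplicated released sequences therefore count per occurrence,
  and fragments shorter than `min_len` (default 2) are listed but not
  matched. Both switches are exposed because curated tools leave this
  undocumented.
- **Enzyme transcriptions are data.** Screening batteries conventionally
  name enzymes by EC number only, and published specificity tables are
  richer than a P1/P1′-plus-exceptions grammar can express (e.g. extended
  subsites).
  The bundled `protease_rules.tsv` is therefore a documented, simplified
  transcription in that grammar — reviewable and swappable — and the
  EC 3.4.21.20 entry is resolved to cathepsin G. "Pepsin (pH > 2)" is a
  distinct rule (`pepsin_ph_gt2`); the pH is part of the rule identity, not
  a runtime parameter. Engine correctness is established with synthetic
  rules, so it does not depend on any particular transcription.

The default battery is the 15-scheme screening layout: 12 single proteases,
pepsin + trypsin, and the two triples adding chymotrypsin A or C. A
structural consequence of union semantics — checked explicitly in the
suite — is that a combined scheme never yields fewer zero-missed fragments
than any of its component enzymes alone. That is the engine-level form of
the common observation that multi-enzyme hydrolysis tends to release more
peptides; note it is guaranteed for fragment counts, not for matched counts,
since finer fragmentation can also destroy a matching fragment.

Absolute released-peptide counts from any particular published screen are
**not** a reproduction target: they depend on the exact dictionary snapshot
and cleavage-rule table of the tool used at the time, neither of which is
published. The package reproduces the structure and the statistic, and
verifies the engine by construction instead.

## Mass and charge arithmetic

Peptide masses are monoisotopic by default — residue masses summed plus one
water (18.010565 Da), proton 1.007276 Da, from a 20-entry table frozen in
the source so results are bit-reproducible. Monoisotopic is the right
default for high-resolution (Orbitrap-class) data and is what matches
published "calculated MW" values; an average-mass table sits behind
`type = "average"`. Fixed or variable modifications (e.g.
carbamidomethyl-C +57.02146 Da, oxidised-M +15.994915 Da) are optional
per-residue deltas; the default is none, since the reference peptides used
in tests contain neither C nor M.

Charge states are read from isotope spacing as $z = \mathrm{round}(1/\Delta
m/z)$ with the residual reported; a residual above the tolerance (default
0.1, generous enough for caption-precision spacings like 0.33) is an error
rather than a guess. Theoretical b/y ladders use the usual neutral-mass
recurrences, with the complementarity identity
$b_i + y_{n-i} = \text{residue sum} + \text{water} + 2\,\text{protons}$ (on
the singly protonated scale) checked at every index on random peptides.
Observed spectra routinely deviate from calculated values by instrument
calibration; the package computes calculated values only and does not parse
spectra.

Sequence coverage is the size of the union of matched 1-based inclusive
peptide intervals over $N$, as an integer percent. Coordinates everywhere in
the package are 1-based and inclusive.

## Synthetic data: what it does and does not emulate

The generators exist to give every stage an exact ground truth:

- `random_protein()` draws i.i.d. residues (uniform by default;
  `empirical_composition()` mimics a real proteome's composition);
- `plant_motifs()` places exactly $k$ non-overlapping copies of each motif
  and rejection-samples the whole candidate until no motif occurs anywhere
  else (retry cap 1000, an error beyond that rather than a silent
  approximation) — so recovered counts can be asserted equal, not close;
- `synthetic_rule_protein()` concatenates wanted fragments under a rule,
  erroring if a fragment contains an internal cut site or a junction is not
  cleavable.

All generators are bit-reproducible under a seed, with the caller's RNG
state restored. I.i.d. residue strings lack the homology, domain structure
and compositional autocorrelation of real proteins, so passing
planted-motif tests demonstrates correctness of the counting and digestion
machinery — not that any real proteome has a particular peptide content.
Sizes used in the shipped suite (proteins of 150–200 residues, batteries on
a 567-residue scale, ~1000 randomised rule/sequence instances) were chosen
as comfortably representative of the real use case while keeping the suite
quick to run.

## Numerical choices and degenerate inputs

- Rounding: half-away-from-zero for reported frequencies (3 dp) and masses
  at presentation time (2 dp); all internal arithmetic is unrounded.
- Validation is strict: ambiguous residues (B, J, O, U, X, Z) and `*` are
  rejected with the offending position, because both scanning and mass
  arithmetic are undefined on them; `read_fasta(on_invalid = "drop")`
  downgrades to warn-and-drop per record.
- A protein with no cut sites digests to itself (one fragment); an empty
  dictionary profiles to all-zero counts; zero-length inputs are errors,
  not zeros.
- Ties never arise in scan ordering: output is sorted by (start, end,
  activity), and two distinct peptides cannot share both endpoints.

## Known limitations

- The P1/P1′ + exceptions grammar cannot express extended-subsite
  preferences (P2, P2′ and beyond) or partial/kinetic digestion; rules are
  all-or-nothing per bond.
- Exact-match release ignores in vivo realities — gastrointestinal
  stability, absorption, and activity of near-miss fragments that contain a
  bioactive core with extra flanking residues.
- The bundled dictionary is a small curated fixture (every activity class
  populated, IC50s where published); it is a stand-in for, not a mirror of,
  the large curated databases, so absolute profile counts on real proteins
  will be smaller than database-backed ones.
- IC50 values are stored metadata only; no potency modelling or QSAR is
  attempted.
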