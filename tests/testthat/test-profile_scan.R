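test_that("scan_protein locates dictionary peptides with coordinates", {
  d <- mini_dict(c(VY = "AC", VPL = "AC,DPP"))
  occ <- scan_protein(protein_record("p", "AVYVPLK"), d)
  expect_identical(occ$peptide, c("VY", "VPL", "VPL"))
  expect_identical(occ$activity, c("AC", "AC", "DPP"))
  expect_identical(occ$start, c(2L, 4L, 4L))
  expect_identical(occ$end, c(3L, 6L, 6L))
})

test_that("overlapping and nested occurrences are all counted", {
  d <- mini_dict(c(AA = "AO"))
  occ <- scan_protein("AAAA", d)
  expect_identical(occ$start, 1:3)
  expect_identical(occ$end, 2:4)

  # empty dictionary -> empty scan
  d0 <- activity_dictionary(data.frame(sequence = character(),
                                       activity = character()))
  expect_identical(nrow(scan_protein("AAAA", d0)), 0L)
})

test_that("scan_protein equals the brute-force substring oracle", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(20:200, 1)
    seq <- random_seq(n)
    n_ent <- sample(1:50, 1)
    ent <- data.frame(
      sequence = unique(vapply(seq_len(n_ent), function(j) {
        if (runif(1) < 0.6) {
          # draw from the sequence itself so matches actually happen
          L <- sample(2:4, 1); s <- sample(n - L + 1, 1)
          substr(seq, s, s + L - 1)
        } else random_seq(sample(2:4, 1))
      }, character(1))),
      stringsAsFactors = FALSE)
    ent$activity <- sample(c("AC", "AO", "DPP"), nrow(ent), replace = TRUE)
    d <- suppressWarnings(activity_dictionary(ent))
    got <- scan_protein(protein_record("p", seq), d)
    want <- oracle_scan(seq, d$entries)
    expect_identical(got[, c("peptide", "activity", "start", "end")], want)
  }
})

test_that("min_len filter excludes short dictionary entries", {
  d <- mini_dict(c(A = "AC", AV = "AC"))
  expect_identical(scan_protein("AVA", d, min_len = 2)$peptide, "AV")
  expect_identical(nrow(scan_protein("AVA", d, min_len = 3)), 0L)
  expect_identical(sum(scan_protein("AVA", d, min_len = 1)$peptide == "A"), 2L)
})

test_that("activity_counts tabulates per activity and rejects mixed proteins", {
  d <- mini_dict(c(VY = "AC", VPL = "AC,DPP"))
  occ <- scan_protein("AVYVPLK", d)
  counts <- activity_counts(occ)
  expect_identical(unname(counts[c("AC", "DPP")]), c(2L, 1L))
  expect_identical(unname(counts["AO"]), 0L)
  expect_true(all(activity_counts(occ[0, ]) == 0L))
  occ2 <- occ; occ2$protein_id[1] <- "other"
  expect_error(activity_counts(occ2), "mix")
})

test_that("occurrence_frequency reproduces published roundings", {
  expect_equal(occurrence_frequency(250, 567), 0.441)
  expect_equal(occurrence_frequency(224, 465), 0.482)
  expect_equal(occurrence_frequency(0, 567), 0)
  expect_error(occurrence_frequency(1, 0), "N must be >= 1")
  # half-away-from-zero at the boundary: 0.0005 -> 0.001 (base round gives 0)
  expect_equal(occurrence_frequency(1, 2000), 0.001)
})

test_that("monotonicity: adding a dictionary entry never decreases counts", {
  set.seed(33)
  for (i in 1:20) {
    seq <- random_seq(150)
    d1 <- mini_dict(c(VY = "AC", LA = "DPP"))
    extra <- substr(seq, 5, 6)
    ent2 <- rbind(d1$entries[, c("sequence", "activity")],
                  data.frame(sequence = extra, activity = "AC"))
    d2 <- suppressWarnings(activity_dictionary(ent2))
    c1 <- activity_counts(scan_protein(seq, d1))
    c2 <- activity_counts(scan_protein(seq, d2))
    expect_true(all(c2[names(c1)] >= c1))
  }
})

test_that("profile_report has one row per protein and fixed column order", {
  d <- bundled_dictionary()
  ps <- list(random_protein(120, seed = 1, id = "s1"),
             random_protein(80, seed = 2, id = "s2"))
  rep <- profile_report(ps, d)
  expect_identical(nrow(rep), 2L)
  expect_identical(names(rep)[1:2], c("protein_id", "N"))
  expect_identical(names(rep)[seq(3, 16, by = 2)],
                   paste0("a_", c("AC", "AO", "AA", "AT", "S", "R", "DPP")))
  expect_equal(rep$A_AC, mapply(occurrence_frequency, rep$a_AC, rep$N),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("formatted report renders 'a (A)' cells and optional dashes", {
  d <- mini_dict(c(VY = "AC"))
  p <- protein_record("p", paste(c("VY", rep("G", 128)), collapse = ""))
  rep <- profile_report(p, d)
  fmt <- format_profile_report(rep)
  expect_identical(fmt$AC, "1 (0.008)")
  expect_identical(fmt$AO, "0 (0.000)")
  fmt2 <- format_profile_report(rep, dash_zeros = TRUE)
  expect_identical(fmt2$AO, "-")
  # the published style: a = 59 occurrences in a 130-residue protein
  expect_identical(sprintf("%d (%.3f)", 59L, occurrence_frequency(59, 130)),
                   "59 (0.454)")
})
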