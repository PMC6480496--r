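trypsin <- protease_rule("trypsin", p1 = c("K", "R"),
                         exceptions = c("K:P", "R:P"), ec = "3.4.21.4")

test_that("cleavage_sites applies P1/P1' sets and exception pairs", {
  # after K2; R3 blocked by P4; R6 is terminal (no bond to cut)
  expect_identical(cleavage_sites("AKRPAR", trypsin), 2L)
  expect_identical(cleavage_sites("AAAA", protease_rule("g", p1 = "G")),
                   integer())
  expect_identical(cleavage_sites("AAAA", protease_rule("a", p1 = "A")), 1:3)
  # P1' specificity: cut N-terminal to L
  nterm <- protease_rule("pre_l", p1_prime = "L")
  expect_identical(cleavage_sites("GLAL", nterm), c(1L, 3L))
})

test_that("digest produces tiling fragments and missed-cleavage joins", {
  expect_identical(digest("AKRPAR", trypsin)$sequence, c("AK", "RPAR"))
  f <- digest("AKGK", trypsin, missed = 1)
  expect_identical(f$sequence, c("AK", "AKGK", "GK"))
  expect_identical(f$n_missed[f$sequence == "AKGK"], 1L)
  # zero-site protein: the whole chain is the single fragment
  expect_identical(digest("GGGG", trypsin)$sequence, "GGGG")
})

test_that("combined schemes pool cleavage sites (union semantics)", {
  after_a <- protease_rule("after_a", p1 = "A")
  after_g <- protease_rule("after_g", p1 = "G")
  expect_identical(digest("AAGG", after_a)$sequence, c("A", "A", "GG"))
  expect_identical(digest("AAGG", after_g)$sequence, c("AAG", "G"))
  both <- digestion_scheme(list(after_a, after_g))
  expect_identical(digest("AAGG", both)$sequence, c("A", "A", "G", "G"))
})

test_that("tiling and fragment-count invariants hold on random instances", {
  set.seed(55)
  for (i in 1:300) {
    seq <- random_seq(sample(2:120, 1))
    rule <- random_rule()
    frags <- digest(seq, rule)
    expect_identical(paste(frags$sequence, collapse = ""), seq)
    expect_identical(nrow(frags), length(cleavage_sites(seq, rule)) + 1L)
  }
})

test_that("missed-cleavage fragment count follows sum_{j<=m} (F - j)", {
  set.seed(56)
  for (i in 1:60) {
    seq <- random_seq(sample(10:150, 1))
    m <- sample(0:3, 1)
    F <- nrow(digest(seq, trypsin))
    got <- nrow(digest(seq, trypsin, missed = m))
    if (F > m) {
      expect_identical(got, sum(F - 0:m))
    } else {
      expect_identical(got, sum(F - 0:(F - 1L)))
    }
  }
})

test_that("released_bioactive is exact full-sequence matching per occurrence", {
  d <- mini_dict(c(AK = "DPP", VW = "AC"))
  frags <- digest("AKRPAR", trypsin)
  rel <- released_bioactive(frags, d)
  expect_identical(unname(rel$counts["DPP"]), 1L)
  expect_identical(unname(rel$counts["AC"]), 0L)

  # per-occurrence counting: VW released twice counts twice
  after_k <- protease_rule("after_k", p1 = "K")
  p <- synthetic_rule_protein(after_k, c("VWK", "GGK", "VW"))
  d2 <- mini_dict(c(VW = "AC", VWK = "AC"))
  rel2 <- released_bioactive(digest(p$sequence, after_k), d2)
  expect_identical(unname(rel2$counts["AC"]), 2L)  # VWK + terminal VW

  # empty dictionary -> all zeros
  d0 <- activity_dictionary(data.frame(sequence = character(),
                                       activity = character()))
  expect_true(all(released_bioactive(frags, d0)$counts == 0L))

  # min-length filter excludes single-residue fragments
  dA <- mini_dict(c(A = "AC"))
  fr <- digest("AAA", protease_rule("after_a", p1 = "A"))
  expect_identical(unname(released_bioactive(fr, dA, min_len = 2)$counts["AC"]), 0L)
  expect_identical(unname(released_bioactive(fr, dA, min_len = 1)$counts["AC"]), 3L)
})

test_that("released_bioactive equals brute-force fragment-vs-entry check", {
  set.seed(57)
  d <- bundled_dictionary()
  for (i in 1:20) {
    seq <- random_seq(sample(50:200, 1))
    frags <- digest(seq, random_rule())
    rel <- released_bioactive(frags, d)
    brute <- 0L
    for (f in frags$sequence) {
      if (nchar(f) >= 2) brute <- brute + sum(d$entries$sequence == f)
    }
    expect_identical(sum(rel$counts), brute)
  }
})

test_that("default battery has 15 schemes: 12 single, 1 double, 2 triple", {
  schemes <- default_battery()
  expect_length(schemes, 15L)
  sizes <- vapply(schemes, function(s) length(s$rules), integer(1))
  expect_identical(sum(sizes == 1L), 12L)
  expect_identical(sum(sizes == 2L), 1L)
  expect_identical(sum(sizes == 3L), 2L)
  labels <- vapply(schemes, `[[`, character(1), "label")
  expect_true(all(c("trypsin", "pepsin_ph_gt2", "pepsin_ph_gt2+trypsin",
                    "pepsin_ph_gt2+trypsin+chymotrypsin_a",
                    "pepsin_ph_gt2+trypsin+chymotrypsin_c") %in% labels))
})

test_that("bundled trypsin rule reproduces the K/R-not-before-P specificity", {
  tr <- load_protease_rules()[["trypsin"]]
  expect_setequal(tr$p1, c("K", "R"))
  expect_identical(cleavage_sites("AKRPAR", tr), 2L)
  expect_identical(digest("AKRPAR", tr)$sequence, c("AK", "RPAR"))
})

test_that("run_battery counts planted released peptides exactly", {
  # protein built so one synthetic enzyme releases the dictionary peptides
  after_w <- protease_rule("after_w", p1 = "W")
  d <- mini_dict(c(AFL = "AC", GPA = "AA"))
  p <- synthetic_rule_protein(after_w, c("AFLW", "GGGW", "AFL"))
  rel <- released_bioactive(digest(p$sequence, after_w), d)
  expect_identical(unname(rel$counts["AC"]), 1L)  # terminal AFL only
  b <- run_battery(p, d, schemes = list(digestion_scheme(after_w)))
  expect_identical(nrow(b), 1L)
  expect_identical(b$AC, 1L)
  expect_identical(b$AA, 0L)
})

test_that("battery on a zero-site protein matches whole-protein lookup", {
  d <- mini_dict(c(GGGG = "AC"))
  no_cut <- protease_rule("after_w", p1 = "W")
  b <- run_battery("GGGG", d, schemes = list(digestion_scheme(no_cut)))
  expect_identical(b$n_fragments, 1L)
  expect_identical(b$AC, 1L)
})
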