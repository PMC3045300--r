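test_that("the default PCR error model has the expected structure", {
  tm <- transition_model()
  p <- tm$probs
  # transitions (A<->G, C<->T) cost less than transversions
  expect_lt(tm$sub_neg_log["A", "G"], tm$sub_neg_log["A", "C"])
  expect_lt(tm$sub_neg_log["A", "G"], tm$sub_neg_log["A", "T"])
  expect_lt(tm$sub_neg_log["C", "T"], tm$sub_neg_log["C", "A"])
  expect_lt(tm$sub_neg_log["C", "T"], tm$sub_neg_log["C", "G"])
  expect_lt(tm$sub_neg_log["G", "A"], tm$sub_neg_log["G", "C"])
  expect_lt(tm$sub_neg_log["T", "C"], tm$sub_neg_log["T", "G"])
  # rows normalised to exact unit sums
  expect_equal(unname(rowSums(p)), rep(1, 4), tolerance = 1e-12)
  expect_error(transition_model(matrix(0.3, 4, 4)), "sum to 1")
  bad <- pcr_transition_default()
  bad[1, 1] <- 0.0001
  bad[1, 2] <- 0.9999 - sum(bad[1, 3:4])
  expect_error(transition_model(bad), "diagonal")
})

test_that("transition models round-trip through the editable TSV", {
  tm <- transition_model()
  path <- tempfile(fileext = ".tsv")
  write_transition_model(tm, path)
  back <- read_transition_model(path)
  expect_equal(back$probs, tm$probs, tolerance = 1e-8)
  expect_equal(back$gap_penalty, 15)
  expect_equal(back$homopolymer_gap_penalty, 4)
})

test_that("homopolymer gaps are distinguished from standard gaps", {
  tm <- transition_model()
  mcost <- function(s) sum(diag(tm$sub_neg_log)[match(strsplit(s, "")[[1]],
                                                      c("A", "C", "G", "T"))])
  # identical sequences: no gaps, cost = sum of diagonal terms
  aln <- align_homopolymer_nw("ACGT", "ACGT", tm)
  expect_equal(aln$a, "ACGT")
  expect_equal(aln$b, "ACGT")
  expect_equal(aln$cost, mcost("ACGT"), tolerance = 1e-12)

  # run contraction: homopolymer gap at 4.0
  aln <- align_homopolymer_nw("AAAT", "AAT", tm)
  expect_equal(aln$cost, 4 + mcost("AAT"), tolerance = 1e-9)
  expect_equal(aln$ncols, 4)

  # deletion not flanked by a matching base: standard gap at 15.0
  aln <- align_homopolymer_nw("ACGT", "AGT", tm)
  expect_equal(aln$cost, 15 + mcost("AGT"), tolerance = 1e-9)
})

test_that("alignment cost equals the exhaustive minimum on short sequences", {
  tm <- transition_model()
  set.seed(41)
  cases <- list(c("AAAT", "AAT"), c("ACGT", "AGT"), c("ACACAC", "ACAC"),
                c("GGGGG", "GG"), c("ACGTACG", "TACGT"))
  for (i in 1:8) {
    cases[[length(cases) + 1]] <- c(random_seq(sample(3:7, 1)),
                                    random_seq(sample(3:7, 1)))
  }
  cases[[length(cases) + 1]] <- c(random_seq(8), random_seq(8))
  for (cs in cases) {
    aln <- align_homopolymer_nw(cs[1], cs[2], tm)
    expect_equal(aln$cost, brute_force_align(cs[1], cs[2], tm),
                 tolerance = 1e-9, label = paste(cs, collapse = " vs "))
  }
})

test_that("the read is the first argument: asymmetric models break symmetry", {
  probs <- pcr_transition_default()
  probs["A", "G"] <- 5e-3                      # exaggerate A->G read errors
  probs["A", "A"] <- 1 - sum(probs["A", c("C", "G", "T")])
  tm <- transition_model(probs)
  r <- "GGTT"
  s <- "AGTT"                                  # read G where truth is A
  e_rs <- seq_distance(r, s, tm)               # uses P(G | A): likely
  e_sr <- seq_distance(s, r, tm)               # uses P(A | G): rare
  expect_lt(e_rs, e_sr)
  # and the brute-force oracle agrees under the asymmetric model too
  expect_equal(align_homopolymer_nw(r, s, tm)$cost,
               brute_force_align(r, s, tm), tolerance = 1e-9)
})

test_that("sequence distance anchors match direct evaluation", {
  tm <- transition_model()
  # one standard gap in a 100-column alignment contributes 15/100 = 0.15;
  # TAG-periodic template with C inserted between A and G: every alternative
  # alignment pays a transversion plus a gap, so the single standard gap is
  # provably optimal
  b <- paste(rep(c("T", "A", "G"), length.out = 99), collapse = "")
  ins <- "C"
  a <- paste0(substr(b, 1, 50), ins, substr(b, 51, 99))
  aln <- align_homopolymer_nw(a, b, tm)
  expect_equal(aln$ncols, 100)
  match_cost <- sum(diag(tm$sub_neg_log)[match(strsplit(b, "")[[1]],
                                               c("A", "C", "G", "T"))])
  expect_equal(seq_distance(a, b, tm), (match_cost + 15) / 100,
               tolerance = 1e-9)
  expect_equal(seq_distance(a, b, tm) - match_cost / 100, 0.15,
               tolerance = 1e-9)

  # 100 identical A's: e = -ln P(A|A)
  # (row renormalisation shifts the printed 0.9995 by ~2.5e-5)
  eAA <- seq_distance(strrep("A", 100), strrep("A", 100), tm)
  expect_equal(eAA, -log(0.9995), tolerance = 0.06)

  # a single A->G among 100 bases
  s <- strrep("A", 100)
  r <- paste0(strrep("A", 49), "G", strrep("A", 50))
  expect_equal(seq_distance(r, s, tm),
               (99 * (-log(0.9995)) + (-log(5.1e-4))) / 100,
               tolerance = 2e-3)
})

test_that("weighted sequence clustering merges satellites and keeps weight", {
  set.seed(43)
  s <- random_seq(150)
  sat <- s
  substr(sat, 70, 70) <- if (substr(s, 70, 70) == "A") "G" else "A"
  seqs <- data.frame(id = c("true", "sat"), seq = c(s, sat),
                     weight = c(100, 2))
  fit <- seqnoise(seqs, truncate_len = 150)
  expect_equal(nrow(fit$components), 1)
  expect_equal(fit$components$sequence, s)
  expect_equal(fit$components$frequency, 102)
  expect_equal(fit$mapping$component, rep(fit$components$id, 2))

  # one unique sequence maps to itself with its total weight
  fit1 <- seqnoise(data.frame(id = "x", seq = s, weight = 7))
  expect_equal(fit1$components$frequency, 7)
  expect_equal(fit1$components$sequence, s)
})

test_that("sequences at 8% divergence with equal weights stay separate", {
  set.seed(44)
  a <- strsplit(random_seq(150), "")[[1]]
  b <- a
  pos <- sample(150, 12)                          # 8% substitutions
  b[pos] <- vapply(b[pos], function(x) {
    sample(setdiff(c("A", "C", "G", "T"), x), 1)
  }, character(1))
  seqs <- data.frame(id = c("a", "b"),
                     seq = c(paste(a, collapse = ""), paste(b, collapse = "")),
                     weight = c(50, 50))
  fit <- seqnoise(seqs, truncate_len = 150)
  expect_equal(nrow(fit$components), 2)
  expect_equal(sort(fit$components$frequency), c(50, 50))
  expect_equal(sum(fit$components$frequency), 100)
  expect_true(all(diff(fit$loglik) >= -1e-8))
})
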