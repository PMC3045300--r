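test_that("flow encoding matches the canonical example and inverts", {
  expect_equal(sequence_to_flows("CAAAGTGGG", "TACG"),
               c(0, 0, 1, 0, 0, 3, 0, 1, 1, 0, 0, 3))
  expect_equal(flows_to_sequence(c(0, 0, 1, 0, 0, 3, 0, 1, 1, 0, 0, 3), "TACG"),
               "CAAAGTGGG")
  expect_equal(sequence_to_flows("T", "TACG"), c(1, 0, 0, 0))
  expect_equal(sequence_to_flows("", "TACG"), integer(0))
  expect_equal(flows_to_sequence(integer(0)), "")
  expect_equal(flows_to_sequence(c(0, 0, 0, 0)), "")
  expect_equal(flows_to_sequence(c(2, 0, 0, 1), "TACG"), "TTG")
  expect_error(sequence_to_flows("ACGN"), "ambiguity")
})

test_that("flow encoding round-trips on random sequences", {
  set.seed(11)
  for (i in 1:25) {
    s <- random_seq(sample(1:80, 1))
    runs <- sequence_to_flows(s)
    expect_equal(length(runs) %% 4, 0)
    expect_equal(flows_to_sequence(runs), s)
    # every complete frame before sequence end has a signal
    nz <- which(runs > 0)
    if (length(nz)) {
      frames <- split(runs[1:max(nz)],
                      (seq_len(max(nz)) - 1) %/% 4)[seq_len(max(nz) %/% 4)]
      expect_true(all(vapply(frames, function(f) any(f > 0), logical(1))))
    }
  }
})

test_that("flowtable round-trips and rejects malformed records", {
  fgs <- list(flowgram("a", c(1.02, 0.03, 2.41, 0.08)),
              flowgram("b", c(0.01, 1.11, 0.95, 3.07)))
  path <- tempfile(fileext = ".tsv")
  write_flowtable(fgs, path)
  back <- read_flowgrams(path, "flowtable")
  expect_length(back, 2)
  expect_equal(back[[1]]$id, "a")
  expect_equal(back[[2]]$values, c(0.01, 1.11, 0.95, 3.07))

  empty <- tempfile()
  writeLines(character(0), empty)
  expect_length(read_flowgrams(empty, "flowtable"), 0)

  bad <- tempfile()
  writeLines(c("a\t1.0\t0.5", "b\t-0.2\t1.0"), bad)
  expect_error(read_flowgrams(bad, "flowtable"), "record 2")
  expect_error(read_flowgrams(tempfile(), "flowtable"), "no such file")
  expect_error(read_flowgrams(path, "fastq"), "unknown")
})

test_that("SFF reader recovers flow values written by an independent writer", {
  path <- tempfile(fileext = ".sff")
  flows <- list(c(1.01, 0.05, 2.03, 0.11, 0.98, 0.02, 0.04, 1.12),
                c(0.03, 1.04, 1.02, 0.07, 2.96, 0.08, 1.01, 0.05))
  write_sff_fixture(path, c("read1", "longer_name_2"), flows)
  fgs <- read_flowgrams(path, "sff")
  expect_length(fgs, 2)
  expect_equal(fgs[[1]]$id, "read1")
  expect_equal(fgs[[2]]$id, "longer_name_2")
  expect_equal(fgs[[1]]$values, flows[[1]])
  expect_equal(fgs[[2]]$values, flows[[2]])
  expect_error(read_flowgrams(tempfile(fileext = ".sff")), "no such file")
  notsff <- tempfile(fileext = ".sff")
  writeBin(as.raw(1:32), notsff)
  expect_error(read_flowgrams(notsff), "not an SFF")
})

test_that("filtering applies the noise-window, frame and truncation rules", {
  set.seed(3)
  clean <- runif(400, 0.9, 1.1)
  pol <- filter_policy("FLX")

  res <- filter_and_truncate(flowgram("r", clean), pol)
  expect_true(res$accepted)
  expect_length(res$flowgram$values, 360)

  noisy <- clean
  noisy[300] <- 0.6
  res <- filter_and_truncate(flowgram("r", noisy), pol)
  expect_false(res$accepted)
  expect_match(res$reason, "noisy before")

  # noisy-window boundaries: 0.5 is noisy, 0.7 is not
  v <- clean; v[100] <- 0.70
  expect_true(filter_and_truncate(flowgram("r", v), pol)$accepted)
  v[100] <- 0.50
  expect_false(filter_and_truncate(flowgram("r", v), pol)$accepted)

  dead <- clean
  dead[381:384] <- 0.1
  res <- filter_and_truncate(flowgram("r", dead), pol)
  expect_true(res$accepted)
  expect_length(res$flowgram$values, 360)

  # dead frame at 365-368: clean length 364, frame-rounded 364, capped at 360
  dead2 <- clean
  dead2[365:368] <- 0.1
  res <- filter_and_truncate(flowgram("r", dead2), pol)
  expect_true(res$accepted)
  expect_length(res$flowgram$values, 360)

  expect_false(filter_and_truncate(flowgram("r", clean[1:100]), pol)$accepted)
})

test_that("filtering is idempotent and never exceeds the end truncation", {
  set.seed(4)
  pol <- filter_policy("FLX")
  for (i in 1:10) {
    # clean up to flow 360, with assorted late noise that truncation absorbs
    v <- runif(400, 0.9, 1.1)
    if (i %% 2 == 0) {
      s <- sample(seq(361, 397, by = 4), 1)
      v[s:(s + 3)] <- 0.1
    }
    if (i %% 3 == 0) v[sample(361:400, 1)] <- 0.6
    res <- filter_and_truncate(flowgram("r", v), pol)
    expect_true(res$accepted)
    kept <- res$flowgram
    expect_lte(length(kept$values), pol$end_truncation_flow)
    expect_equal(length(kept$values) %% 4, 0)
    again <- filter_and_truncate(kept, pol)
    expect_true(again$accepted)
    expect_identical(again$flowgram$values, kept$values)
  }
})

test_that("primer and tag are checked IUPAC-exactly at the read start", {
  primer <- "GTGNCAGCMGCCGCGGTAA"
  seqs <- list(ok = "AGTGCGTAGTGACAGCAGCCGCGGTAACCTT",
               bad_primer = "AGTGCGTAGTGACAGCTGCCGCGGTAACCTT",
               bad_tag = "TTTTCGTAGTGACAGCAGCCGCGGTAACCTT")
  pol <- filter_policy("FLX", primer = primer, tag = "AGTGCGTA")
  vals <- runif(400, 0.9, 1.1)
  fg <- flowgram("r", vals)
  expect_true(filter_and_truncate(fg, pol, seq = seqs$ok)$accepted)
  r <- filter_and_truncate(fg, pol, seq = seqs$bad_primer)
  expect_false(r$accepted)
  expect_equal(r$reason, "no primer")
  r <- filter_and_truncate(fg, pol, seq = seqs$bad_tag)
  expect_false(r$accepted)
  expect_equal(r$reason, "no tag")
  expect_error(filter_policy("FLX", min_clean_flow = 500,
                             end_truncation_flow = 360))
})

test_that("batch filtering produces a rejection log and conserves reads", {
  set.seed(5)
  fgs <- lapply(1:20, function(i) {
    v <- runif(400, 0.9, 1.1)
    if (i %% 4 == 0) v[sample(50:300, 1)] <- 0.6
    flowgram(paste0("r", i), v)
  })
  out <- filter_flowgrams(fgs, filter_policy("FLX"))
  expect_equal(length(out$kept) + nrow(out$rejections), 20)
  expect_equal(sum(grepl("noisy", out$rejections$reason)), 5)
  log <- tempfile()
  write_rejection_log(out$rejections, log)
  expect_equal(nrow(read.table(log, header = TRUE, sep = "\t")),
               nrow(out$rejections))
})

test_that("abundance-annotated FASTA round-trips", {
  path <- tempfile(fileext = ".fasta")
  write_weighted_fasta(c("x", "y"), c("ACGT", "GGTTAA"), c(120, 3), path)
  df <- read_weighted_fasta(path)
  expect_equal(df$id, c("x", "y"))
  expect_equal(df$seq, c("ACGT", "GGTTAA"))
  expect_equal(df$weight, c(120, 3))
})
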