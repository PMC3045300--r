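test_that("the chimera index equals exhaustive binomial enumeration", {
  set.seed(51)
  for (i in 1:40) {
    y <- sample(0:12, 1)
    x <- sample(0:12, 1)
    y_A <- if (y > 0) sample(0:y, 1) else 0L
    x_B <- if (x > 0) sample(0:x, 1) else 0L
    len_a <- sample(1:80, 1)
    len_b <- sample(1:80, 1)
    cnt <- list(x_A = x - x_B, x_B = x_B, y_A = y_A, y_B = y - y_A)
    p_a <- len_a / (len_a + len_b)
    expected <- -(log(binom_tail_enum(y_A, y, p_a)) +
                    log(binom_tail_enum(x_B, x, 1 - p_a)))
    expect_lt(abs(chimera_index(cnt, len_a, len_b) - expected),
              1e-12 * max(1, abs(expected)))
  }
  # hand-checked values
  expect_equal(chimera_index(list(x_A = 0, x_B = 0, y_A = 0, y_B = 0), 10, 10),
               0)
  expect_equal(chimera_index(list(x_A = 0, x_B = 4, y_A = 6, y_B = 0), 50, 50),
               10 * log(2), tolerance = 1e-12)
  expect_equal(chimera_index(list(x_A = 0, x_B = 0, y_A = 2, y_B = 1), 30, 30),
               -log(0.5), tolerance = 1e-12)
})

test_that("the index is monotone in the bias of the change partition", {
  for (y_A in 0:5) {
    i1 <- chimera_index(list(x_A = 0, x_B = 0, y_A = y_A, y_B = 6 - y_A),
                        40, 40)
    i2 <- chimera_index(list(x_A = 0, x_B = 0, y_A = y_A + 1,
                             y_B = 5 - y_A), 40, 40)
    expect_gte(i2, i1)
  }
  for (x_B in 0:5) {
    i1 <- chimera_index(list(x_A = 6 - x_B, x_B = x_B, y_A = 0, y_B = 0),
                        40, 40)
    i2 <- chimera_index(list(x_A = 5 - x_B, x_B = x_B + 1, y_A = 0, y_B = 0),
                        40, 40)
    expect_gte(i2, i1)
  }
})

test_that("parsimony change counts resolve majority ancestors per column", {
  # identical rows: no changes anywhere
  cnt <- parsimony_change_counts("ACGT", "ACGT", "ACGT", 2)
  expect_equal(unlist(cnt[c("x_A", "x_B", "y_A", "y_B", "z_A", "z_B")]),
               c(x_A = 0, x_B = 0, y_A = 0, y_B = 0, z_A = 0, z_B = 0))

  # perfect bimera: C matches A left of the break, B right of it;
  # A/B differ at 6 left and 4 right columns
  set.seed(52)
  a <- strsplit(random_seq(40), "")[[1]]
  b <- a
  left_pos <- sample(1:20, 6)
  right_pos <- sample(21:40, 4)
  for (p in c(left_pos, right_pos)) {
    b[p] <- sample(setdiff(c("A", "C", "G", "T"), a[p]), 1)
  }
  cc <- c(a[1:20], b[21:40])
  cnt <- parsimony_change_counts(paste(a, collapse = ""),
                                 paste(b, collapse = ""),
                                 paste(cc, collapse = ""), 20,
                                 a_is_prefix = TRUE)
  expect_equal(cnt$y_A, 6)   # changes to distant parent sit in A's part
  expect_equal(cnt$y_B, 0)
  expect_equal(cnt$x_A, 0)
  expect_equal(cnt$x_B, 4)   # changes to close parent sit in B's part
  expect_equal(cnt$z_A + cnt$z_B, 0)
  expect_equal(cnt$len_a, 20)
  expect_equal(cnt$len_b, 20)

  # a column where only C differs increments z on C's side of the break only
  cc2 <- cc
  cc2[5] <- setdiff(c("A", "C", "G", "T"), c(a[5], b[5]))[1]
  cnt2 <- parsimony_change_counts(paste(a, collapse = ""),
                                  paste(b, collapse = ""),
                                  paste(cc2, collapse = ""), 20)
  expect_equal(cnt2$z_A, 1)
  expect_equal(cnt2$z_B, 0)

  # three distinct states attribute no change
  cnt3 <- parsimony_change_counts("A", "C", "G", 1)
  expect_equal(cnt3$x_A + cnt3$y_A + cnt3$z_A, 0)
})

test_that("the logistic classifier evaluates and inverts exactly", {
  m <- logistic_model(-183.25, 10.56)
  expect_equal(logistic_predict(decision_point(m), m), 0.5, tolerance = 1e-12)
  expect_equal(decision_point(m), 183.25 / 10.56, tolerance = 1e-12)
  m2 <- logistic_model(-7.5, 0.5)
  expect_equal(logistic_predict(20, m2), 1 / (1 + exp(-2.5)),
               tolerance = 1e-12)
  expect_equal(decision_point(m2), 15)
  expect_error(decision_point(logistic_model(1, 0)), "beta = 0")
})

test_that("logistic training recovers parameters and flags separation", {
  set.seed(53)
  alpha <- -6
  beta <- 0.8
  I <- runif(5000, 0, 20)
  lab <- runif(5000) < 1 / (1 + exp(-(alpha + beta * I)))
  fit <- logistic_train(I, lab)
  se <- sqrt(diag(vcov(glm(lab ~ I, family = binomial()))))
  expect_lt(abs(fit$alpha - alpha), 2 * se[1])
  expect_lt(abs(fit$beta - beta), 2 * se[2])
  expect_true(fit$converged)

  # complete separation: non-convergence flagged, decision point between
  # the classes
  I2 <- c(1, 2, 3, 10, 11, 12)
  lab2 <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  fit2 <- logistic_train(I2, lab2)
  expect_false(fit2$converged)
  expect_true(fit2$separated)
  expect_gt(fit2$decision_point, 3)
  expect_lt(fit2$decision_point, 10)

  # inverted labels give a negative slope with a warning
  expect_warning(logistic_train(c(1, 2, 9, 10), c(TRUE, TRUE, FALSE, FALSE)),
                 "negative coefficient")
  expect_error(logistic_train(c(1, 2), c(TRUE, TRUE)), "both")
})

test_that("parent search matches brute-force pair x breakpoint enumeration", {
  tm <- transition_model()
  set.seed(54)
  for (rep in 1:5) {
    parents <- make_parents(5, 60, div = 0.25)
    pool <- data.frame(id = paste0("p", 1:5), seq = parents,
                       weight = 100:96)
    b_true <- sample(20:40, 1)
    pair <- sample(5, 2)
    query <- paste0(substr(parents[pair[1]], 1, b_true),
                    substr(parents[pair[2]], b_true + 1, 60))
    q <- list(id = "q", seq = query, weight = 5)
    hit <- find_best_parents(q, pool, tm)
    expect_equal(hit$dist_chimera, 0, tolerance = 1e-3)
    expect_setequal(c(hit$prefix_parent, hit$suffix_parent),
                    paste0("p", pair))

    # brute force: recompute every parent's per-position mismatch profile
    # from its own alignment and scan all ordered pairs and breakpoints
    mism <- unname(vapply(unname(parents), function(p) {
      pr <- pyroclean:::parent_profile(query, p, tm)
      cumsum(pr$mism)
    }, numeric(nchar(query))))
    best <- Inf
    for (p1 in 1:5) for (p2 in 1:5) for (b in 1:(nchar(query) - 1)) {
      cost <- mism[b, p1] + (mism[nchar(query), p2] - mism[b, p2])
      if (cost < best) best <- cost
    }
    got <- min(vapply(1:(nchar(query) - 1), function(b) {
      min(mism[b, ]) + min(mism[nchar(query), ] - mism[b, ])
    }, numeric(1)))
    expect_equal(got, best)
    expect_equal(best, 0)
  }
})

test_that("parent search degenerates gracefully", {
  tm <- transition_model()
  set.seed(55)
  s <- random_seq(50)
  pool <- data.frame(id = c("big", "same"), seq = c(random_seq(50), s),
                     weight = c(100, 50))
  # query identical to a candidate: chimera and parent distances coincide
  hit <- find_best_parents(list(id = "q", seq = s, weight = 10), pool, tm)
  expect_equal(hit$dist_chimera, hit$dist_parent, tolerance = 1e-9)
  # most-abundant query: no candidate
  expect_null(find_best_parents(list(id = "q", seq = s, weight = 1000),
                                pool, tm))
})

test_that("the full classifier calls constructed bimeras and spares parents", {
  set.seed(56)
  parents <- make_parents(4, 120, div = 0.2)
  bim <- paste0(substr(parents[1], 1, 60), substr(parents[2], 61, 120))
  seqs <- data.frame(id = c(paste0("p", 1:4), "chi"),
                     seq = c(parents, bim), weight = c(90, 80, 70, 60, 5))
  rep <- perseus(seqs)
  expect_s3_class(rep, "perseus")
  calls <- setNames(rep$chimeric, rep$id)
  expect_true(calls[["chi"]])
  expect_false(any(calls[paste0("p", 1:4)]))
  # the most abundant sequence has no candidate parents: probability 0
  expect_equal(rep$prob[rep$id == "p1"], 0)
  expect_true(is.na(rep$parent_a[rep$id == "p1"]))
  # a sequence far from every reconstruction stays good regardless of I
  far <- data.frame(id = c("p1", "p2", "odd"),
                    seq = c(parents[1:2], random_seq(120)),
                    weight = c(90, 80, 5))
  rep2 <- perseus(far)
  expect_false(rep2$chimeric[rep2$id == "odd"])
  expect_equal(rep2$prob[rep2$id == "odd"], 0)
  expect_gte(rep2$dist_chimera[rep2$id == "odd"], 0.15)
})

test_that("sensitivity: generated bimeras are flagged, parents never", {
  set.seed(57)
  parents <- make_parents(20, 150, div = 0.2)
  pool <- data.frame(id = sprintf("p%02d", 1:20), seq = parents,
                     weight = rep(100, 20))
  n_bim <- 200
  pair <- t(replicate(n_bim, sample(20, 2)))
  bp <- sample(45:105, n_bim, replace = TRUE)
  bims <- vapply(seq_len(n_bim), function(i) {
    paste0(substr(parents[pair[i, 1]], 1, bp[i]),
           substr(parents[pair[i, 2]], bp[i] + 1, 150))
  }, character(1))
  keep <- !duplicated(bims) & !bims %in% parents
  all_seqs <- rbind(pool, data.frame(id = sprintf("b%03d", which(keep)),
                                     seq = bims[keep], weight = 2))
  rep <- perseus(all_seqs)
  is_bim <- grepl("^b", rep$id)
  expect_gte(mean(rep$chimeric[is_bim]), 0.95)
  expect_equal(sum(rep$chimeric[!is_bim]), 0)
  # reported parents always respect the abundance constraint
  w <- setNames(all_seqs$weight, all_seqs$id)
  ok <- is.na(rep$parent_a) | w[rep$parent_a] >= rep$weight
  expect_true(all(ok))
})

test_that("chimera reports serialise to TSV", {
  set.seed(58)
  parents <- make_parents(3, 80, div = 0.2)
  seqs <- data.frame(id = paste0("p", 1:3), seq = parents,
                     weight = c(30, 20, 10))
  rep <- perseus(seqs)
  path <- tempfile(fileext = ".tsv")
  write_perseus_report(rep, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 3)
  expect_true(all(back$call %in% c("good", "chimeric")))
})
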