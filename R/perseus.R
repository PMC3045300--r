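# Abundance-aware chimera detection. A PCR chimera must have experienced at
# least one fewer amplification cycle than either parent, so both parents are
# present at equal or greater abundance: the candidate-parent pool of a query
# is every sequence at least as abundant. The best two-parent splice is found
# from per-parent prefix/suffix mismatch arrays, its plausibility quantified
# by the binomial "chimera index", and the final call made by a logistic
# classifier on that index.

# Align a candidate parent to the query and project onto query coordinates.
# For query position p: `mism[p]` counts the columns attributed to p in which
# the parent differs from the query (substitutions, parent gaps, and parent
# insertions attributed to the following query base; trailing insertions to
# the last base); `ins[p]` and `base[p]` hold the parent's characters so any
# prefix/suffix splice can be reconstructed, and `cost`/`ncols` give e(query,
# parent) for free.
parent_profile <- function(query, parent, tm) {
  aln <- align_homopolymer_nw(query, parent, tm)
  qc <- strsplit(aln$a, "")[[1]]
  pc <- strsplit(aln$b, "")[[1]]
  n <- sum(qc != "-")
  mism <- integer(n)
  ins <- character(n)
  base <- character(n)
  pos <- 0L
  pending <- ""
  pending_m <- 0L
  for (k in seq_along(qc)) {
    if (qc[k] == "-") {
      pending <- paste0(pending, pc[k])
      pending_m <- pending_m + 1L
    } else {
      pos <- pos + 1L
      ins[pos] <- pending
      mism[pos] <- pending_m + (pc[k] != qc[k])
      base[pos] <- pc[k]
      pending <- ""
      pending_m <- 0L
    }
  }
  if (nzchar(pending)) {          # trailing insertions attach to the last base
    ins_extra <- pending
    mism[n] <- mism[n] + pending_m
    base[n] <- paste0(base[n], ins_extra)
  }
  list(mism = mism, ins = ins, base = base, e = aln$cost / aln$ncols)
}

splice_from_profiles <- function(prof_pre, prof_suf, b, n) {
  pre <- paste0(prof_pre$ins[seq_len(b)], prof_pre$base[seq_len(b)],
                collapse = "")
  suf <- paste0(prof_suf$ins[(b + 1L):n], prof_suf$base[(b + 1L):n],
                collapse = "")
  gsub("-", "", paste0(pre, suf), fixed = TRUE)
}

#' Find the best chimeric parent pair for a query sequence
#'
#' Aligns the query to every candidate parent (sequences of equal or greater
#' abundance), builds per-parent prefix- and suffix-mismatch arrays in query
#' coordinates, and minimises, over all breakpoints, the best-prefix plus
#' best-suffix mismatch count -- finding the optimal parent pair and
#' breakpoint without enumerating pairs. The spliced reconstruction is then
#' rebuilt and its PCR-error-corrected distance to the query returned,
#' together with the distance to the closest of the two chosen parents.
#'
#' @param query a single-row data frame (`id`, `seq`, `weight`) or a list
#'   with those elements.
#' @param pool data frame of candidate parents (`id`, `seq`, `weight`),
#'   excluding the query itself; only rows with `weight >= query weight` are
#'   considered.
#' @param tm a [transition_model].
#' @return `NULL` when no candidate parent exists (the query is the most
#'   abundant sequence); otherwise a list with `parent_a` (closest parent
#'   id), `parent_b`, `breakpoint` (the prefix covers query positions
#'   `1..breakpoint`), `dist_chimera`, `dist_parent`, `a_is_prefix`, and the
#'   internal profiles used by [parsimony_change_counts()].
#' @export
find_best_parents <- function(query, pool, tm = transition_model()) {
  qseq <- toupper(query$seq)
  pool <- pool[pool$weight >= query$weight & pool$id != query$id, ,
               drop = FALSE]
  pool <- pool[order(-pool$weight, pool$id), , drop = FALSE]
  if (nrow(pool) == 0) return(NULL)
  n <- nchar(qseq)
  profs <- lapply(pool$seq, function(p) parent_profile(qseq, toupper(p), tm))
  pref <- vapply(profs, function(pr) cumsum(pr$mism), numeric(n))  # n x P
  if (is.null(dim(pref))) pref <- matrix(pref, nrow = n)
  total <- pref[n, ]
  if (n < 2) {
    k <- which.min(total)
    pr <- profs[[k]]
    return(list(parent_a = pool$id[k], parent_b = pool$id[k], breakpoint = 0L,
                dist_chimera = pr$e, dist_parent = pr$e, a_is_prefix = TRUE,
                prefix_parent = pool$id[k], suffix_parent = pool$id[k],
                prof_a = pr, prof_b = pr, n = n))
  }
  suf <- sweep(-pref, 2, total, "+")                               # n x P
  bp_range <- seq_len(n - 1L)
  best_pre <- apply(pref[bp_range, , drop = FALSE], 1, which.min)
  best_suf <- apply(suf[bp_range, , drop = FALSE], 1, which.min)
  cost_b <- pref[cbind(bp_range, best_pre)] + suf[cbind(bp_range, best_suf)]
  b <- which.min(cost_b)
  p1 <- best_pre[b]
  p2 <- best_suf[b]
  splice <- splice_from_profiles(profs[[p1]], profs[[p2]], b, n)
  dist_chimera <- seq_distance(qseq, splice, tm)
  e1 <- profs[[p1]]$e
  e2 <- profs[[p2]]$e
  a_is_prefix <- e1 <= e2
  list(parent_a = if (a_is_prefix) pool$id[p1] else pool$id[p2],
       parent_b = if (a_is_prefix) pool$id[p2] else pool$id[p1],
       breakpoint = as.integer(b),
       dist_chimera = dist_chimera,
       dist_parent = min(e1, e2),
       a_is_prefix = a_is_prefix,
       prefix_parent = pool$id[p1], suffix_parent = pool$id[p2],
       prof_a = if (a_is_prefix) profs[[p1]] else profs[[p2]],
       prof_b = if (a_is_prefix) profs[[p2]] else profs[[p1]],
       n = n)
}

# Three-row alignment of parents A and B against query C in common (query)
# coordinates: per query position, insertion columns from each parent precede
# the base column. Built by projecting the two pairwise alignments; replaces
# an external three-way aligner.
tri_alignment <- function(prof_a, prof_b, qseq) {
  qc <- strsplit(toupper(qseq), "")[[1]]
  n <- length(qc)
  rows_a <- character(0); rows_b <- character(0); rows_c <- character(0)
  part_col <- integer(0)
  for (p in seq_len(n)) {
    ia <- strsplit(prof_a$ins[p], "")[[1]]
    ib <- strsplit(prof_b$ins[p], "")[[1]]
    if (length(ia)) {
      rows_a <- c(rows_a, ia)
      rows_b <- c(rows_b, rep("-", length(ia)))
      rows_c <- c(rows_c, rep("-", length(ia)))
      part_col <- c(part_col, rep(p, length(ia)))
    }
    if (length(ib)) {
      rows_a <- c(rows_a, rep("-", length(ib)))
      rows_b <- c(rows_b, ib)
      rows_c <- c(rows_c, rep("-", length(ib)))
      part_col <- c(part_col, rep(p, length(ib)))
    }
    ba <- strsplit(prof_a$base[p], "")[[1]]
    bb <- strsplit(prof_b$base[p], "")[[1]]
    len <- max(length(ba), length(bb), 1L)
    ba <- c(ba, rep("-", len - length(ba)))
    bb <- c(bb, rep("-", len - length(bb)))
    cc <- c(qc[p], rep("-", len - 1L))
    rows_a <- c(rows_a, ba)
    rows_b <- c(rows_b, bb)
    rows_c <- c(rows_c, cc)
    part_col <- c(part_col, rep(p, len))
  }
  list(a = rows_a, b = rows_b, c = rows_c, qpos = part_col)
}

#' Parsimony change counts across a chimera breakpoint
#'
#' For a three-row alignment of the closest parent `A`, the distant parent
#' `B` and the query `C`, computes the per-column parsimony ancestor (the
#' majority state of the three rows; columns with three distinct states
#' attribute no change) and counts the base changes along each branch, split
#' into the part of the alignment where the chimera matches `A` and the part
#' where it matches `B`.
#'
#' @param a,b,c aligned rows (equal-length character strings, `-` for gaps)
#'   for parent A, parent B and the query.
#' @param breakpoint last alignment column of the first part.
#' @param a_is_prefix does parent A (the closest parent) match the part
#'   left of the breakpoint?
#' @return list with `x_A`, `x_B` (changes to A in the part matching A / B),
#'   `y_A`, `y_B` (changes to B), `z_A`, `z_B` (changes to C), and `len_a`,
#'   `len_b` (ungapped query columns in the part matching A / B).
#' @export
parsimony_change_counts <- function(a, b, c, breakpoint,
                                    a_is_prefix = TRUE) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  cc <- strsplit(c, "")[[1]]
  stopifnot(length(ca) == length(cb), length(cb) == length(cc),
            breakpoint >= 0, breakpoint <= length(ca))
  ncols <- length(ca)
  left <- seq_len(ncols) <= breakpoint
  in_a_part <- if (a_is_prefix) left else !left
  ab <- ca == cb
  ac <- ca == cc
  bc <- cb == cc
  chg_a <- !ab & !ac & bc      # A is the odd one out
  chg_b <- !ab & ac & !bc
  chg_c <- ab & !ac
  ungapped <- cc != "-"
  list(x_A = sum(chg_a & in_a_part), x_B = sum(chg_a & !in_a_part),
       y_A = sum(chg_b & in_a_part), y_B = sum(chg_b & !in_a_part),
       z_A = sum(chg_c & in_a_part), z_B = sum(chg_c & !in_a_part),
       len_a = sum(ungapped & in_a_part), len_b = sum(ungapped & !in_a_part))
}

#' Chimera index
#'
#' For a true chimera, the changes along the branch to the distant parent B
#' should all fall in the part of the alignment matching the close parent A,
#' and vice versa. Under the null (changes scattered at random), each set of
#' changes is binomially distributed across the two parts with probability
#' proportional to part size. The index is the negative log of the product of
#' the two tail probabilities of a split as biased or more than observed:
#' `I = -ln( Pr[Bin(y, len_a/(len_a+len_b)) >= y_A] * Pr[Bin(x,
#' len_b/(len_a+len_b)) >= x_B] )`. Larger values mean the pattern is less
#' likely to have evolved without recombination.
#'
#' @param counts list from [parsimony_change_counts()] (fields `x_A`, `x_B`,
#'   `y_A`, `y_B`).
#' @param len_a,len_b column counts of the parts matching parents A and B.
#' @return non-negative scalar (nats); zero when `x = y = 0`.
#' @export
chimera_index <- function(counts, len_a, len_b) {
  stopifnot(len_a >= 1, len_b >= 1)
  p_a <- len_a / (len_a + len_b)
  y <- counts$y_A + counts$y_B
  x <- counts$x_A + counts$x_B
  tail_b <- if (y == 0) 1 else pbinom(counts$y_A - 1L, y, p_a,
                                      lower.tail = FALSE)
  tail_a <- if (x == 0) 1 else pbinom(counts$x_B - 1L, x, 1 - p_a,
                                      lower.tail = FALSE)
  -(log(tail_b) + log(tail_a))
}

#' Logistic chimera classifier
#'
#' `P(chimeric | I) = 1 / (1 + exp(-(alpha + beta * I)))`. The default
#' `alpha = -7.5`, `beta = 0.5` performs well across data sets; train
#' data-set-specific values with [logistic_train()].
#'
#' @param alpha intercept.
#' @param beta coefficient on the chimera index.
#' @return an object of class `"logistic_model"`.
#' @export
logistic_model <- function(alpha = -7.5, beta = 0.5) {
  stopifnot(is.finite(alpha), is.finite(beta))
  structure(list(alpha = alpha, beta = beta), class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("<logistic_model> alpha =", x$alpha, " beta =", x$beta)
  if (x$beta != 0) cat("  (P50 at I =", format(-x$alpha / x$beta), ")")
  cat("\n")
  invisible(x)
}

#' @rdname logistic_model
#' @param I chimera index value(s).
#' @param model a `"logistic_model"`.
#' @return `logistic_predict`: probabilities in `[0, 1]`.
#' @export
logistic_predict <- function(I, model = logistic_model()) {
  1 / (1 + exp(-(model$alpha + model$beta * I)))
}

#' @rdname logistic_model
#' @return `decision_point`: the index value classified chimeric with
#'   probability exactly 0.5 (`-alpha / beta`).
#' @export
decision_point <- function(model) {
  if (model$beta == 0) stop("decision point undefined for beta = 0")
  -model$alpha / model$beta
}

#' Train the logistic chimera classifier
#'
#' One-dimensional maximum-likelihood logistic regression of chimeric status
#' on the chimera index, via iteratively reweighted least squares
#' (`glm(family = binomial)`). On completely separated training data the
#' likelihood has no finite maximiser; the fit is flagged non-converged but
#' the separating decision point is still reported.
#'
#' @param I numeric chimera indices.
#' @param chimeric logical (or 0/1) labels; both classes must be present.
#' @return a `"logistic_model"` with extra fields `converged`, `separated`,
#'   `null_deviance`, `deviance`, `decision_point`.
#' @export
logistic_train <- function(I, chimeric) {
  chimeric <- as.logical(chimeric)
  stopifnot(length(I) == length(chimeric), length(I) >= 2)
  if (length(unique(chimeric)) < 2) {
    stop("training data must contain both good and chimeric examples")
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(chimeric ~ I, family = binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  cf <- coef(fit)
  separated <- warned && fit$deviance < 1e-6
  if (cf[2] < 0) {
    warning("negative coefficient: larger indices predict non-chimeric")
  }
  m <- logistic_model(unname(cf[1]), unname(cf[2]))
  m$converged <- fit$converged && !separated
  m$separated <- separated
  m$null_deviance <- fit$null.deviance
  m$deviance <- fit$deviance
  m$decision_point <- if (cf[2] != 0) -cf[1] / cf[2] else NA_real_
  m
}

#' Classify chimeras in an abundance-annotated sequence set
#'
#' Processes sequences in decreasing abundance. For each query, the candidate
#' parents are all other sequences of equal or greater abundance; the best
#' spliced reconstruction is found with [find_best_parents()]. A query is a
#' chimera candidate only if its distance to that reconstruction is below
#' `dist_threshold` (default 0.15, one standard gap per 100 nucleotides) and
#' no greater than its distance to the closest single parent. Candidates are
#' scored by [chimera_index()] and [logistic_predict()]; all other sequences
#' get probability 0. The call is chimeric when the probability exceeds 0.5.
#'
#' @param seqs data frame `id`, `seq`, `weight` (e.g. from
#'   [denoised_sequences()]).
#' @param tm a [transition_model].
#' @param model a [logistic_model()].
#' @param dist_threshold maximum `dist_chimera` for a candidate.
#' @return an object of class `"perseus"`: a data frame with one row per
#'   input sequence (`id`, `weight`, `parent_a`, `parent_b`, `breakpoint`,
#'   `dist_chimera`, `dist_parent`, `index`, `prob`, `chimeric`).
#' @export
perseus <- function(seqs, tm = transition_model(), model = logistic_model(),
                    dist_threshold = 0.15) {
  stopifnot(all(c("id", "seq", "weight") %in% names(seqs)))
  seqs <- seqs[order(-seqs$weight, seqs$id), , drop = FALSE]
  n <- nrow(seqs)
  out <- data.frame(
    id = seqs$id, weight = seqs$weight, parent_a = NA_character_,
    parent_b = NA_character_, breakpoint = NA_integer_,
    dist_chimera = NA_real_, dist_parent = NA_real_, index = NA_real_,
    prob = 0, chimeric = FALSE, stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    query <- seqs[i, ]
    pool <- seqs[-i, , drop = FALSE]
    hit <- find_best_parents(query, pool, tm)
    if (is.null(hit)) next
    out$parent_a[i] <- hit$parent_a
    out$parent_b[i] <- hit$parent_b
    out$breakpoint[i] <- hit$breakpoint
    out$dist_chimera[i] <- hit$dist_chimera
    out$dist_parent[i] <- hit$dist_parent
    if (hit$dist_chimera < dist_threshold &&
        hit$dist_chimera <= hit$dist_parent && hit$breakpoint > 0) {
      tri <- tri_alignment(hit$prof_a, hit$prof_b, query$seq)
      bp_col <- max(which(tri$qpos <= hit$breakpoint))
      cnt <- parsimony_change_counts(paste(tri$a, collapse = ""),
                                     paste(tri$b, collapse = ""),
                                     paste(tri$c, collapse = ""),
                                     bp_col, a_is_prefix = hit$a_is_prefix)
      if (cnt$len_a >= 1 && cnt$len_b >= 1) {
        out$index[i] <- chimera_index(cnt, cnt$len_a, cnt$len_b)
        out$prob[i] <- logistic_predict(out$index[i], model)
      }
    }
  }
  out$chimeric <- out$prob > 0.5
  structure(out, class = c("perseus", "data.frame"),
            model = model, dist_threshold = dist_threshold)
}

#' @export
print.perseus <- function(x, ...) {
  cat("Chimera classification of", nrow(x), "sequences:",
      sum(x$chimeric), "chimeric /", sum(!x$chimeric), "good\n")
  m <- attr(x, "model")
  cat("  classifier: alpha =", m$alpha, " beta =", m$beta,
      " (P50 at I =", format(decision_point(m), digits = 4), ")\n")
  NextMethod()
}

#' Write a chimera report as TSV
#'
#' @param report a `"perseus"` object.
#' @param path output file.
#' @export
write_perseus_report <- function(report, path) {
  df <- as.data.frame(report)
  df$call <- ifelse(df$chimeric, "chimeric", "good")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
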