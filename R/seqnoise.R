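#' PCR substitution/indel error model
#'
#' Holds the 4x4 matrix of substitution probabilities `P(m | n)` (observed
#' base `m` given true base `n`) as negative logs, together with the alignment
#' gap penalties. Rows are normalised to exact unit sums at load time (the
#' printed defaults are rounded). The default matrix is the empirical PCR
#' error table measured on even mock communities; transitions (A<->G, C<->T)
#' are an order of magnitude more likely than transversions.
#'
#' @param probs 4x4 matrix of substitution probabilities, rows = true base,
#'   columns = observed base, in A, C, G, T order; row sums must be within
#'   1e-3 of 1.
#' @param gap_penalty cost of a standard gap column (default 15.0).
#' @param homopolymer_gap_penalty cost of a gap column whose inserted/deleted
#'   base matches an adjacent base of the other sequence (default 4.0).
#' @return an object of class `"transition_model"`.
#' @export
transition_model <- function(probs = pcr_transition_default(),
                             gap_penalty = 15.0,
                             homopolymer_gap_penalty = 4.0) {
  probs <- as.matrix(probs)
  stopifnot(all(dim(probs) == c(4, 4)), gap_penalty > 0,
            homopolymer_gap_penalty > 0)
  if (any(abs(rowSums(probs) - 1) > 1e-3)) {
    stop("substitution probability rows must sum to 1 (within 1e-3)")
  }
  if (any(probs <= 0)) stop("substitution probabilities must be positive")
  probs <- probs / rowSums(probs)
  if (!all(apply(probs, 1, which.max) == 1:4)) {
    stop("diagonal must be the row maximum")
  }
  dimnames(probs) <- list(true = c("A", "C", "G", "T"),
                          observed = c("A", "C", "G", "T"))
  structure(
    list(probs = probs, sub_neg_log = -log(probs), gap_penalty = gap_penalty,
         homopolymer_gap_penalty = homopolymer_gap_penalty),
    class = "transition_model"
  )
}

#' Default PCR per-base substitution probabilities
#'
#' Empirical per-base substitution frequencies of a standard Taq PCR measured
#' against known template mixtures (rows = true base, columns = observed
#' base, A/C/G/T order).
#'
#' @return a 4x4 probability matrix.
#' @export
pcr_transition_default <- function() {
  m <- matrix(c(
    0.9995, 7.2e-6, 5.1e-4, 7.7e-6,
    1.1e-5, 0.9996, 2.1e-6, 4.1e-4,
    3.5e-4, 3.2e-6, 0.9996, 2.1e-5,
    9.0e-6, 5.7e-4, 1.4e-5, 0.9994
  ), nrow = 4, byrow = TRUE)
  dimnames(m) <- list(true = c("A", "C", "G", "T"),
                      observed = c("A", "C", "G", "T"))
  m
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model> gap", x$gap_penalty, "/ homopolymer gap",
      x$homopolymer_gap_penalty, "\n")
  print(signif(x$probs, 4))
  invisible(x)
}

#' Write / read a transition model as an editable TSV
#'
#' The TSV holds the 4x4 probability matrix with row/column names plus two
#' header comment lines carrying the gap penalties.
#'
#' @param tm a [transition_model].
#' @param path file path.
#' @export
write_transition_model <- function(tm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# gap_penalty", tm$gap_penalty),
               paste("# homopolymer_gap_penalty", tm$homopolymer_gap_penalty)),
             con)
  write.table(format(tm$probs, digits = 10), con, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_transition_model
#' @export
read_transition_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  gv <- function(key, default) {
    hit <- grep(key, hdr, value = TRUE)
    if (length(hit)) as.numeric(strsplit(hit[1], " ")[[1]][3]) else default
  }
  mat <- as.matrix(read.table(text = lines[!startsWith(lines, "#")],
                              sep = "\t", header = TRUE, row.names = 1))
  transition_model(mat, gv("^# gap_penalty", 15),
                   gv("^# homopolymer_gap_penalty", 4))
}

#' Homopolymer-aware global alignment
#'
#' Needleman-Wunsch global alignment minimising total cost: substitution
#' columns cost `-log P(m | n)` under the transition model and gap columns
#' cost the homopolymer gap penalty when the inserted/deleted base equals an
#' adjacent base of the other sequence at that point (a homopolymer run
#' extension or contraction), else the standard gap penalty. Traceback is
#' deterministic (ties prefer substitution, then a gap in `b`, then a gap in
#' `a`).
#'
#' @param a the noisy read sequence.
#' @param b the hypothesised true sequence.
#' @param tm a [transition_model].
#' @return list with `a`, `b` (aligned strings with `-` gaps), `cost`, and
#'   `ncols` (alignment columns).
#' @export
align_homopolymer_nw <- function(a, b, tm = transition_model()) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  nw_align_pair(toupper(a), toupper(b), tm$sub_neg_log, tm$gap_penalty,
                tm$homopolymer_gap_penalty)
}

#' PCR-error-corrected sequence distance
#'
#' `e(r, S)`: the total cost of the optimal homopolymer-aware global
#' alignment of read `r` against hypothesis `S` (substitution negative log
#' probabilities plus gap penalties), normalised by the alignment length `A`
#' (all columns, terminal gaps included). One standard gap per 100 aligned
#' columns contributes 15/100 = 0.15.
#'
#' @inheritParams align_homopolymer_nw
#' @param r the noisy read sequence.
#' @param s the hypothesised true sequence.
#' @return non-negative scalar.
#' @export
seq_distance <- function(r, s, tm = transition_model()) {
  aln <- align_homopolymer_nw(r, s, tm)
  aln$cost / aln$ncols
}

#' Matrix of sequence distances
#'
#' `e(r, S)` for every read (rows) against every hypothesis (columns).
#'
#' @param reads,hyps character vectors of sequences.
#' @param tm a [transition_model].
#' @return numeric matrix.
#' @export
seq_distance_matrix <- function(reads, hyps = reads, tm = transition_model()) {
  seq_edist_mat(toupper(reads), toupper(hyps), tm$sub_neg_log, tm$gap_penalty,
                tm$homopolymer_gap_penalty)
}

#' Remove PCR point errors by EM clustering of denoised sequences
#'
#' Second-stage denoising: clusters abundance-weighted sequences (typically
#' the output of [pyronoise()]) with the same exponential-kernel EM as the
#' flowgram stage, but using the PCR-error-corrected sequence distance `e`.
#' Sequence weights enter both the component weights and the effective read
#' multiplicities, so abundant sequences anchor the clusters. Candidate
#' centres are restricted to the observed unique sequences. Sequences are
#' truncated to `truncate_len` before clustering (error rates rise towards
#' read ends).
#'
#' @param seqs data frame with columns `id`, `seq`, `weight` (see
#'   [denoised_sequences()]), or a character vector of sequences (unit
#'   weights).
#' @param tm a [transition_model].
#' @param sigma_s cluster scale (0.033 suits GS FLX; 0.04 and 0.1 are the
#'   documented Titanium presets).
#' @param cut_s complete-linkage initialisation cut-off (default 0.08).
#' @param truncate_len truncation length in bases (220 GS FLX, 400 Titanium).
#' @param max_iter,tol convergence control.
#' @return an object of class `"seqnoise"`: `components` (data frame `id`,
#'   `sequence`, `frequency`, `tau`; frequencies sum to the total input
#'   weight), `mapping` (data frame `input_id`, `component`), `loglik`,
#'   `converged`.
#' @export
seqnoise <- function(seqs, tm = transition_model(), sigma_s = 0.033,
                     cut_s = 0.08, truncate_len = 220L, max_iter = 1000,
                     tol = 1e-6) {
  if (is.character(seqs)) {
    seqs <- data.frame(id = paste0("s", seq_along(seqs)), seq = seqs,
                       weight = 1, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "seq", "weight") %in% names(seqs)),
            all(seqs$weight > 0), nrow(seqs) >= 1)
  seqs$seq <- substr(toupper(seqs$seq), 1L, truncate_len)

  uniq <- sort(unique(seqs$seq))
  w <- vapply(uniq, function(s) sum(seqs$weight[seqs$seq == s]), numeric(1))
  ord <- order(-w, uniq)
  uniq <- uniq[ord]
  w <- unname(w[ord])
  read_of_input <- match(seqs$seq, uniq)

  E <- seq_distance_matrix(uniq, uniq, tm)
  init <- init_complete_linkage((E + t(E)) / 2, cut_s)
  fit <- run_em(E, init, sigma_s, weights = w, max_iter = max_iter, tol = tol)

  centre_of_read <- fit$centre[fit$mapping]
  used <- sort(unique(centre_of_read))
  freq <- vapply(used, function(k) sum(w[centre_of_read == k]), numeric(1))
  tau_by_centre <- vapply(used, function(k) sum(fit$tau[fit$centre == k]),
                          numeric(1))
  ids <- sprintf("seq_%03d", seq_along(used))
  structure(
    list(
      components = data.frame(id = ids, sequence = uniq[used],
                              frequency = freq, tau = tau_by_centre,
                              stringsAsFactors = FALSE),
      mapping = data.frame(
        input_id = seqs$id,
        component = ids[match(centre_of_read[read_of_input], used)],
        stringsAsFactors = FALSE),
      loglik = fit$loglik, converged = fit$converged,
      iterations = fit$iterations, sigma_s = sigma_s, cut_s = cut_s,
      truncate_len = truncate_len, total_weight = sum(seqs$weight)
    ),
    class = "seqnoise"
  )
}

#' @export
print.seqnoise <- function(x, ...) {
  cat("Sequence EM denoising (total weight ", format(x$total_weight),
      ", truncated at ", x$truncate_len, " bp)\n", sep = "")
  cat("  components: ", nrow(x$components), "  sigma_s = ", x$sigma_s,
      "  cut_s = ", x$cut_s, "\n", sep = "")
  cat("  ", if (x$converged) "converged" else "NOT converged", " in ",
      x$iterations, " iterations, log-likelihood ",
      format(x$loglik[length(x$loglik)], digits = 8), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method summary seqnoise
summary.seqnoise <- function(object, ...) {
  print(object)
  ord <- order(-object$components$frequency)
  print(head(object$components[ord, c("id", "frequency", "tau")], 10),
        row.names = FALSE)
  invisible(object)
}

#' @export
#' @method logLik seqnoise
logLik.seqnoise <- function(object, ...) {
  structure(object$loglik[length(object$loglik)],
            df = 2 * nrow(object$components), class = "logLik")
}
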