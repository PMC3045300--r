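# Seeded generator of mock amplicon communities: known references, PCR point
# errors accumulated over amplification cycles, spliced chimeras respecting
# the parent-abundance constraint, and flowgrams drawn from an intensity
# model. Ground truth travels with every read so each pipeline stage can be
# scored without external data.

#' Per-cycle PCR substitution rate from a total error frequency
#'
#' Under ideal doubling, a random final molecule's lineage contains on
#' average `cycles / 2` strand-synthesis events (the number of copy events on
#' a random root-to-leaf path is Binomial(cycles, 1/2)), so an observed total
#' per-base substitution frequency `f` corresponds to a per-cycle rate
#' `p = 2 f / cycles`.
#'
#' @param total_f observed per-base substitution frequency.
#' @param cycles number of PCR cycles (default 30).
#' @return per-cycle substitution probability.
#' @export
per_cycle_rate <- function(total_f, cycles = 30) {
  2 * total_f / cycles
}

#' Per-cycle substitution probability matrix
#'
#' Converts a matrix of total observed substitution frequencies (e.g.
#' [pcr_transition_default()]) into per-cycle probabilities via
#' [per_cycle_rate()]; the diagonal is set to keep unit row sums.
#'
#' @param probs 4x4 total substitution probability matrix (rows = true base).
#' @param cycles number of PCR cycles.
#' @return 4x4 per-cycle probability matrix.
#' @export
per_cycle_rate_matrix <- function(probs = pcr_transition_default(),
                                  cycles = 30) {
  p <- per_cycle_rate(probs, cycles)
  diag(p) <- 0
  diag(p) <- 1 - rowSums(p)
  p
}

#' Define a mock community
#'
#' A set of reference sequences with known relative abundances plus the PCR
#' parameters used to generate reads from them. References can be supplied or
#' generated: generated references descend from a common random root with a
#' fixed per-sequence divergence, re-drawn until all pairwise divergences
#' reach `min_divergence` (the design of a clone mixture whose members are
#' unambiguously distinguishable).
#'
#' @param references optional named character vector of reference sequences.
#' @param n_refs,ref_length used when generating references.
#' @param divergence per-reference fraction of positions mutated away from
#'   the common root.
#' @param min_divergence minimum pairwise divergence between references.
#' @param abundances `"even"`, `"uneven"` (geometric, ratio 0.8) or a numeric
#'   vector; normalised to sum to 1.
#' @param cycles number of PCR cycles.
#' @param per_cycle_rates 4x4 per-cycle substitution matrix
#'   ([per_cycle_rate_matrix()] by default).
#' @param chimera_rate fraction of reads that are chimeric, in `[0, 1)`.
#' @param breakpoint_range chimera breakpoints are drawn uniformly over this
#'   fraction of the reference length (incomplete extension is a mid-molecule
#'   event, and both fragments must fall inside the sequenced window to be
#'   observable).
#' @param seed integer seed; generation is fully reproducible.
#' @return an object of class `"mock_community"`.
#' @export
mock_community <- function(references = NULL, n_refs = 20, ref_length = 300,
                           divergence = 0.12, min_divergence = 0.07,
                           abundances = "even", cycles = 30,
                           per_cycle_rates = per_cycle_rate_matrix(cycles = cycles),
                           chimera_rate = 0.05,
                           breakpoint_range = c(0.2, 0.5), seed = 1) {
  set.seed(seed)
  if (is.null(references)) {
    references <- generate_references(n_refs, ref_length, divergence,
                                      min_divergence)
  }
  if (is.null(names(references))) {
    names(references) <- sprintf("ref_%02d", seq_along(references))
  }
  n <- length(references)
  ab <- if (identical(abundances, "even")) {
    rep(1, n)
  } else if (identical(abundances, "uneven")) {
    0.8^(seq_len(n) - 1)
  } else {
    stopifnot(is.numeric(abundances), length(abundances) == n,
              all(abundances > 0))
    abundances
  }
  stopifnot(chimera_rate >= 0, chimera_rate < 1,
            all(dim(per_cycle_rates) == c(4, 4)))
  structure(
    list(references = references, abundances = ab / sum(ab),
         cycles = as.integer(cycles), per_cycle_rates = per_cycle_rates,
         chimera_rate = chimera_rate, breakpoint_range = breakpoint_range,
         seed = seed),
    class = "mock_community"
  )
}

generate_references <- function(n, len, divergence, min_divergence,
                                max_tries = 200) {
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, len, replace = TRUE)
  n_mut <- round(divergence * len)
  refs <- matrix("", n, len)
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      s <- root
      pos <- sample.int(len, n_mut)
      s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1),
                       character(1))
      if (i == 1 ||
          all(rowMeans(refs[seq_len(i - 1), , drop = FALSE] !=
                         matrix(s, i - 1, len, byrow = TRUE)) >=
              min_divergence)) {
        refs[i, ] <- s
        break
      }
      if (try == max_tries) stop("could not satisfy min_divergence")
    }
  }
  apply(refs, 1, paste, collapse = "")
}

#' @export
print.mock_community <- function(x, ...) {
  cat("<mock_community> ", length(x$references), " references (",
      nchar(x$references[1]), " nt), ", x$cycles, " PCR cycles, chimera rate ",
      x$chimera_rate, "\n", sep = "")
  invisible(x)
}

#' Simulate the amplified molecule pool of a mock community
#'
#' Draws read counts from the community abundances, injects chimeras by
#' splicing two references at a uniformly drawn breakpoint (chimera type
#' counts never exceed either parent's count, as PCR mechanics require), and
#' applies per-cycle point substitutions: each read's lineage length is
#' Binomial(cycles, 1/2) and each base substitutes per synthesis event
#' according to the per-cycle rate matrix.
#'
#' @param mc a [mock_community].
#' @param n_reads number of reads to generate.
#' @param seed integer seed.
#' @return data frame with one row per read: `read_id`, `seq`, `origin` (the
#'   generating reference or chimera type), `is_chimera`, `parent_a`,
#'   `parent_b`, `breakpoint`, `n_subs`.
#' @export
simulate_amplicon_pool <- function(mc, n_reads = 2000, seed = mc$seed) {
  set.seed(seed)
  refs <- mc$references
  len <- nchar(refs[1])
  n_chim <- round(mc$chimera_rate * n_reads)
  n_good <- n_reads - n_chim
  good_counts <- as.integer(rmultinom(1, n_good, mc$abundances))
  names(good_counts) <- names(refs)

  chim <- NULL
  if (n_chim > 0) {
    n_types <- max(1L, ceiling(n_chim / 8))
    pair <- t(vapply(seq_len(n_types),
                     function(i) sample.int(length(refs), 2), integer(2)))
    lo <- ceiling(mc$breakpoint_range[1] * len)
    hi <- floor(mc$breakpoint_range[2] * len)
    bp <- sample(lo:hi, n_types, replace = TRUE)
    counts <- as.integer(rmultinom(1, n_chim, rep(1, n_types)))
    chim <- data.frame(
      origin = sprintf("chim_%02d", seq_len(n_types)),
      parent_a = names(refs)[pair[, 1]], parent_b = names(refs)[pair[, 2]],
      breakpoint = bp, count = counts, stringsAsFactors = FALSE
    )
    chim$seq <- paste0(substr(refs[pair[, 1]], 1, bp),
                       substr(refs[pair[, 2]], bp + 1, len))
    bad <- chim$count > pmin(good_counts[chim$parent_a],
                             good_counts[chim$parent_b])
    if (any(bad)) {
      stop("chimera_rate too high: chimera type count would exceed a ",
           "parent's abundance")
    }
  }

  origin <- c(rep(names(refs), good_counts),
              if (!is.null(chim)) rep(chim$origin, chim$count))
  seqs <- c(rep(unname(refs), good_counts),
            if (!is.null(chim)) rep(chim$seq, chim$count))
  is_chim <- c(rep(FALSE, sum(good_counts)),
               if (!is.null(chim)) rep(TRUE, sum(chim$count)))
  n <- length(seqs)

  # per-cycle substitutions along each read's lineage
  reps <- rbinom(n, mc$cycles, 0.5)
  p_off <- mc$per_cycle_rates
  diag(p_off) <- 0
  p_tot <- rowSums(p_off)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seqs, "")
  n_subs <- integer(n)
  for (r in seq_len(n)) {
    s <- chars[[r]]
    bi <- match(s, bases)
    k <- rbinom(length(s), reps[r], p_tot[bi])
    hit <- which(k > 0)
    for (h in hit) {
      for (j in seq_len(k[h])) {
        cur <- match(s[h], bases)
        s[h] <- sample(bases, 1, prob = p_off[cur, ])
      }
    }
    n_subs[r] <- sum(s != chars[[r]])
    if (n_subs[r] > 0) seqs[r] <- paste(s, collapse = "")
  }

  idx <- if (!is.null(chim)) match(origin, chim$origin) else rep(NA_integer_, n)
  data.frame(
    read_id = sprintf("read_%04d", seq_len(n)),
    seq = seqs, origin = origin, is_chimera = is_chim,
    parent_a = ifelse(is_chim, chim$parent_a[idx], NA_character_),
    parent_b = ifelse(is_chim, chim$parent_b[idx], NA_character_),
    breakpoint = ifelse(is_chim, chim$breakpoint[idx], NA_integer_),
    n_subs = n_subs, stringsAsFactors = FALSE
  )
}

#' Simulate flowgrams from sequences under an intensity model
#'
#' Each read's perfect flowgram is computed, padded or cut to `n_flows`, and
#' every flow's intensity is drawn from the model's binned distribution
#' `P(f | n)` for that flow's true run length.
#'
#' @param seqs character vector of read sequences.
#' @param model an [intensity_model].
#' @param n_flows raw flow count (400 GS FLX, 800 Titanium).
#' @param flow_order flow cycle.
#' @param ids read identifiers.
#' @param seed integer seed.
#' @return list of [flowgram] objects.
#' @export
simulate_flowgrams <- function(seqs, model = default_intensity_model(),
                               n_flows = 400, flow_order = "TACG",
                               ids = sprintf("read_%04d", seq_along(seqs)),
                               seed = 1) {
  set.seed(seed)
  n <- length(seqs)
  runs <- matrix(0L, n, n_flows)
  for (i in seq_len(n)) {
    r <- sequence_to_flows(seqs[i], flow_order)
    m <- min(length(r), n_flows)
    runs[i, seq_len(m)] <- r[seq_len(m)]
  }
  probs <- exp(-model$neg_log_prob)
  nbins <- nrow(probs)
  vals <- matrix(0, n, n_flows)
  for (nn in 0:model$max_run) {
    idx <- which(pmin(runs, model$max_run) == nn)
    if (!length(idx)) next
    b <- sample.int(nbins, length(idx), replace = TRUE, prob = probs[, nn + 1])
    vals[idx] <- (b - 1L) * model$bin_width
  }
  platform <- if (n_flows >= 800) "TITANIUM" else "FLX"
  lapply(seq_len(n), function(i) {
    flowgram(ids[i], vals[i, ], flow_order, platform)
  })
}

#' Write per-read ground truth as TSV
#'
#' @param pool data frame from [simulate_amplicon_pool()].
#' @param path output file.
#' @export
write_ground_truth <- function(pool, path) {
  write.table(pool[, setdiff(names(pool), "seq")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standard synthetic benchmark inputs
#'
#' The package's reference study conditions: 20 references (300 nt, common
#' root, ~12% divergence, pairwise >= 7%), even abundances, 2000 reads,
#' 30 PCR cycles at the default per-cycle substitution rates, 5% chimeras
#' with mid-molecule breakpoints, GS FLX flowgrams (400 raw flows) under the
#' default intensity model. Analysis truncation is 200 bp: a random sequence
#' consumes about 1.5 flows per base, so the 360-flow window calls about
#' 240 nt and 200 bp lies safely inside every filtered read.
#'
#' @param seed integer seed driving all randomness.
#' @param n_reads number of reads.
#' @return list with `mc`, `pool`, `flowgrams`, `model`, `policy`,
#'   `truncate_bases`, and `ref_windows` (the references as called over the
#'   360-flow window and truncated to the analysis length -- the ground-truth
#'   sequences the pipeline should recover).
#' @export
synthetic_benchmark <- function(seed = 1, n_reads = 2000) {
  mc <- mock_community(seed = seed)
  pool <- simulate_amplicon_pool(mc, n_reads = n_reads, seed = seed + 1)
  model <- default_intensity_model()
  fgs <- simulate_flowgrams(pool$seq, model, n_flows = 400,
                            ids = pool$read_id, seed = seed + 2)
  policy <- filter_policy("FLX")
  truncate_bases <- 200L
  ref_windows <- vapply(mc$references, function(s) {
    runs <- sequence_to_flows(s)
    keep <- min(360L, length(runs))
    substr(flows_to_sequence(runs[seq_len(keep)]), 1L, truncate_bases)
  }, character(1))
  list(mc = mc, pool = pool, flowgrams = fgs, model = model, policy = policy,
       truncate_bases = truncate_bases, ref_windows = ref_windows)
}
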