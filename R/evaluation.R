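# Reference-based assessment machinery: per base error rates, chimera
# labelling against known references, and OTU construction accuracy.

#' Percent-difference matrix from exact pairwise global alignment
#'
#' Needleman-Wunsch with unit costs (match 0, mismatch 1, gap 1); percent
#' difference is differences (mismatches plus gap columns) over alignment
#' columns, times 100.
#'
#' @param seqs_a,seqs_b character vectors of sequences.
#' @return list with matrices `diffs`, `cols`, `percent`.
#' @export
percent_difference <- function(seqs_a, seqs_b = seqs_a) {
  res <- nw_unit_mat(toupper(seqs_a), toupper(seqs_b))
  res$percent <- 100 * res$diffs / res$cols
  res
}

#' Per base error rate against reference sequences
#'
#' Each read is aligned to its closest reference (fewest differences under
#' unit-cost global alignment) and the rate is the summed differences over
#' the summed alignment lengths, as a percentage. For denoised data, pass the
#' denoised sequence each read maps to via `mapped`: differences are then
#' counted between the denoised sequence and the closest reference of the
#' original, undenoised read -- so misassignments during denoising are
#' charged as errors.
#'
#' @param reads character vector of (original) read sequences.
#' @param refs character vector of reference sequences.
#' @param weights optional read multiplicities.
#' @param mapped optional character vector, parallel to `reads`, of the
#'   denoised sequence each read was mapped to.
#' @return error rate in percent.
#' @export
per_base_error_rate <- function(reads, refs, weights = NULL, mapped = NULL) {
  stopifnot(length(refs) >= 1, length(reads) >= 1)
  if (is.null(weights)) weights <- rep(1, length(reads))
  uniq <- unique(reads)
  pd <- percent_difference(uniq, refs)
  closest <- apply(pd$diffs, 1, which.min)
  iu <- match(reads, uniq)
  if (is.null(mapped)) {
    diffs <- pd$diffs[cbind(iu, closest[iu])]
    cols <- pd$cols[cbind(iu, closest[iu])]
  } else {
    stopifnot(length(mapped) == length(reads))
    key <- paste(mapped, closest[iu])
    fu <- !duplicated(key)
    pu <- percent_difference(mapped[fu], refs)
    rows <- match(key, key[fu])
    refi <- closest[iu]
    diffs <- pu$diffs[cbind(rows, refi)]
    cols <- pu$cols[cbind(rows, refi)]
  }
  100 * sum(weights * diffs) / sum(weights * cols)
}

# Prefix-mismatch arrays of a query against every reference, in query
# coordinates, plus the per-reference e distances (reuses the chimera-search
# projection).
reference_profiles <- function(seq, refs, tm) {
  profs <- lapply(refs, function(r) parent_profile(toupper(seq), toupper(r), tm))
  n <- nchar(seq)
  pref <- vapply(profs, function(pr) cumsum(pr$mism), numeric(n))
  list(profs = profs, pref = rbind(0, pref), n = n,
       e = vapply(profs, `[[`, numeric(1), "e"))
}

# Best k-segment reconstruction by dynamic programming over the
# prefix-mismatch arrays: exhaustive over breakpoints, each segment copied
# from a single reference.
best_segmentation <- function(pref, n, k) {
  R <- ncol(pref)
  # C[j, v]: best mismatches covering 1..v with j segments
  C <- matrix(Inf, k, n + 1)
  arg_u <- vector("list", k)
  arg_r <- vector("list", k)
  C[1, ] <- apply(pref, 1, min)
  arg_r[[1]] <- apply(pref, 1, which.min)
  if (k > 1) {
    for (j in 2:k) {
      arg_u[[j]] <- integer(n + 1)
      arg_r[[j]] <- integer(n + 1)
      for (v in j:n) {
        us <- (j - 1):(v - 1)
        seg <- pref[v + 1, , drop = FALSE][rep(1, length(us)), , drop = FALSE] -
          pref[us + 1, , drop = FALSE]
        segmin <- apply(seg, 1, min)
        tot <- C[j - 1, us + 1] + segmin
        b <- which.min(tot)
        C[j, v + 1] <- tot[b]
        arg_u[[j]][v + 1] <- us[b]
        arg_r[[j]][v + 1] <- which.min(seg[b, ])
      }
    }
  }
  # backtrack segment references and boundaries for the full cover 1..n
  segs <- integer(0)
  bounds <- integer(0)
  v <- n
  for (j in k:1) {
    if (j == 1) {
      segs <- c(arg_r[[1]][v + 1], segs)
      bounds <- c(0L, bounds)
    } else {
      segs <- c(arg_r[[j]][v + 1], segs)
      u <- arg_u[[j]][v + 1]
      bounds <- c(u, bounds)
      v <- u
    }
  }
  list(cost = C[k, n + 1], refs = segs, starts = bounds)
}

reconstruct_segments <- function(profs, refs_idx, starts, n) {
  pieces <- character(length(refs_idx))
  ends <- c(starts[-1], n)
  for (s in seq_along(refs_idx)) {
    pr <- profs[[refs_idx[s]]]
    pos <- (starts[s] + 1L):ends[s]
    pieces[s] <- paste0(pr$ins[pos], pr$base[pos], collapse = "")
  }
  gsub("-", "", paste(pieces, collapse = ""), fixed = TRUE)
}

#' Label a sequence against known references
#'
#' Finds the best single-reference match, then the best reconstructions with
#' one, two and three breakpoints (spliced from two, three, four
#' references). The label is promoted from Good to Bimera, Trimera,
#' Quadramera while each extra breakpoint improves the match by at least
#' `improvement` nucleotides. The final label additionally requires the
#' PCR-error-corrected distance to the chosen reconstruction to be below
#' `dist_threshold`; otherwise the sequence is Unclassified.
#'
#' @param seq query sequence.
#' @param refs character vector of reference sequences.
#' @param tm a [transition_model].
#' @param improvement minimum nucleotide improvement per extra breakpoint
#'   (default 3).
#' @param dist_threshold maximum `e` for any classified label (default 0.15).
#' @return list with `label` (factor level among Good, Bimera, Trimera,
#'   Quadramera, Unclassified), `best_distance` (e to the chosen
#'   reconstruction), `improvement_chain` (nucleotide improvements at 1, 2, 3
#'   breakpoints) and `mismatches` (by number of segments).
#' @export
classify_vs_reference <- function(seq, refs, tm = transition_model(),
                                  improvement = 3, dist_threshold = 0.15) {
  stopifnot(length(refs) >= 1)
  rp <- reference_profiles(seq, refs, tm)
  labels <- c("Good", "Bimera", "Trimera", "Quadramera")
  segfits <- lapply(1:4, function(k) best_segmentation(rp$pref, rp$n, k))
  mism <- vapply(segfits, `[[`, numeric(1), "cost")
  chain <- -diff(mism)
  level <- 1L
  while (level < 4L && chain[level] >= improvement) level <- level + 1L
  if (level == 1L) {
    best_idx <- which.min(rp$e)
    best_distance <- rp$e[best_idx]
  } else {
    fit <- segfits[[level]]
    recon <- reconstruct_segments(rp$profs, fit$refs, fit$starts, rp$n)
    best_distance <- seq_distance(seq, recon, tm)
  }
  label <- if (best_distance < dist_threshold) labels[level] else "Unclassified"
  list(label = label, best_distance = best_distance,
       improvement_chain = chain, mismatches = mism)
}

#' Cluster sequences into OTUs
#'
#' Builds the exact pairwise percent-difference matrix (unit-cost global
#' alignment), clusters hierarchically, and cuts the tree at each requested
#' cut-off.
#'
#' @param seqs character vector of sequences; names are used as ids.
#' @param linkage `"complete"` or `"average"`.
#' @param cutoffs percent-difference cut-offs (e.g. `seq(0, 5, by = 0.1)`).
#' @return list of OTU partitions, one per cutoff: each has `cutoff`,
#'   `linkage`, `clusters` (list of id vectors) and `n_otus`.
#' @export
cluster_otus <- function(seqs, linkage = c("complete", "average"),
                         cutoffs = 3) {
  linkage <- match.arg(linkage)
  stopifnot(length(seqs) >= 1)
  ids <- if (is.null(names(seqs))) paste0("s", seq_along(seqs)) else names(seqs)
  pct <- percent_difference(seqs)$percent
  memberships <- if (length(seqs) == 1) {
    matrix(1L, 1, length(cutoffs))
  } else {
    tree <- hclust(as.dist((pct + t(pct)) / 2), method = linkage)
    vapply(cutoffs, function(h) cutree(tree, h = h), integer(length(seqs)))
  }
  lapply(seq_along(cutoffs), function(j) {
    m <- memberships[, j]
    list(cutoff = cutoffs[j], linkage = linkage,
         clusters = split(ids, m), n_otus = max(m))
  })
}

#' OTU construction accuracy against references
#'
#' Clusters the denoised sequences jointly with the reference sequences and
#' labels every OTU: Good (contains both), Missed (references only -- true
#' diversity the pipeline lost), Noise (denoised only -- spurious diversity).
#'
#' @param denoised character vector of denoised sequences.
#' @param refs character vector of reference sequences.
#' @param cutoff percent-difference cut-off (default 3).
#' @param linkage clustering linkage.
#' @return named integer vector `good`, `missed`, `noise`.
#' @export
otu_accuracy <- function(denoised, refs, cutoff = 3, linkage = "complete") {
  stopifnot(length(denoised) >= 1, length(refs) >= 1)
  seqs <- unique(c(denoised, refs))
  is_den <- seqs %in% denoised
  is_ref <- seqs %in% refs
  names(seqs) <- paste0("u", seq_along(seqs))
  part <- cluster_otus(seqs, linkage = linkage, cutoffs = cutoff)[[1]]
  good <- missed <- noise <- 0L
  for (cl in part$clusters) {
    idx <- match(cl, names(seqs))
    has_d <- any(is_den[idx])
    has_r <- any(is_ref[idx])
    if (has_d && has_r) good <- good + 1L
    else if (has_r) missed <- missed + 1L
    else noise <- noise + 1L
  }
  c(good = good, missed = missed, noise = noise)
}

#' Write OTU partitions as one-cluster-per-line text
#'
#' @param partitions output of [cluster_otus()].
#' @param path output file.
#' @export
write_otu_lists <- function(partitions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in partitions) {
    writeLines(sprintf("# cutoff %.3f%% (%s linkage): %d OTUs", p$cutoff,
                       p$linkage, p$n_otus), con)
    for (cl in p$clusters) writeLines(paste(cl, collapse = "\t"), con)
  }
  invisible(path)
}
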