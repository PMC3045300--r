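#' Construct an intensity model
#'
#' An intensity model holds the binned distributions `P(f | n)` of observed
#' flow signal intensities `f` given true homopolymer run lengths `n`, stored
#' as per-signal distances `d(f | n) = -log P(f | n)`. Bins with no probability
#' mass hold `distance_cap`.
#'
#' @param neg_log_prob numeric matrix of `-log P(f | n)`, rows indexing
#'   intensity bins (bin `b` covers `[(b-1) * bin_width, b * bin_width)`),
#'   columns indexing run lengths `0..max_run`.
#' @param bin_width intensity bin width (flow units).
#' @param max_run largest modelled homopolymer length; longer runs reuse the
#'   last column.
#' @param distance_cap distance assigned to empty bins.
#' @return an object of class `"intensity_model"`.
#' @export
intensity_model <- function(neg_log_prob, bin_width = 0.01, max_run = 9L,
                            distance_cap = 100) {
  neg_log_prob <- as.matrix(neg_log_prob)
  stopifnot(ncol(neg_log_prob) == max_run + 1L,
            nrow(neg_log_prob) == round((max_run + 1) / bin_width))
  if (any(neg_log_prob < 0)) stop("negative per-signal distance")
  mass <- colSums(exp(-neg_log_prob))
  if (any(mass > 1 + 1e-6)) {
    stop("P(f | n) sums above 1 for run(s) ",
         paste(which(mass > 1 + 1e-6) - 1L, collapse = ", "))
  }
  structure(
    list(neg_log_prob = unname(neg_log_prob), bin_width = bin_width,
         max_run = as.integer(max_run), distance_cap = distance_cap),
    class = "intensity_model"
  )
}

#' @export
print.intensity_model <- function(x, ...) {
  cat("<intensity_model> bins of", x$bin_width, "flow units, runs 0-",
      x$max_run, ", cap", x$distance_cap, "\n")
  invisible(x)
}

#' Default intensity model
#'
#' A deterministic, parametric stand-in for an empirically calibrated model:
#' each run length `n` gets a discretised normal intensity distribution
#' centred on `n` whose spread grows linearly with `n` (`sd = sd0 +
#' sd_slope * n`), truncated to non-negative intensities. This mirrors the
#' qualitative structure of 454 signal distributions (unimodal at the run
#' length, variance increasing with length) and is the noise model used by the
#' synthetic-data generator. Regenerate with other parameters or replace by a
#' calibrated model via [calibrate_intensity_model()].
#'
#' @param bin_width,max_run,distance_cap see [intensity_model()].
#' @param sd0 intensity standard deviation at run length 0.
#' @param sd_slope increase in standard deviation per unit of run length.
#' @return an `"intensity_model"`.
#' @export
default_intensity_model <- function(bin_width = 0.01, max_run = 9L,
                                    distance_cap = 100, sd0 = 0.05,
                                    sd_slope = 0.035) {
  nbins <- round((max_run + 1) / bin_width)
  centres <- (seq_len(nbins) - 0.5) * bin_width
  mat <- matrix(distance_cap, nbins, max_run + 1L)
  for (n in 0:max_run) {
    dens <- dnorm(centres, mean = n, sd = sd0 + sd_slope * n)
    p <- dens / sum(dens)
    d <- -log(p)
    d[!is.finite(d) | d > distance_cap] <- distance_cap
    mat[, n + 1L] <- d
  }
  intensity_model(mat, bin_width, max_run, distance_cap)
}

#' Calibrate an intensity model from flowgrams with known truth
#'
#' Tabulates the empirical frequency of each binned intensity for each true
#' run length over all flow positions, takes the negative logarithm, and fills
#' empty bins with the distance cap.
#'
#' @param flowgrams list of [flowgram] objects.
#' @param truth list of perfect flowgrams (integer run-length vectors), one
#'   per flowgram, from the reads' generating references. Each pair is
#'   compared over their common truncated length.
#' @param bin_width,max_run,distance_cap see [intensity_model()].
#' @return an `"intensity_model"`.
#' @export
calibrate_intensity_model <- function(flowgrams, truth, bin_width = 0.01,
                                      max_run = 9L, distance_cap = 100) {
  stopifnot(length(flowgrams) == length(truth), length(flowgrams) > 0)
  nbins <- round((max_run + 1) / bin_width)
  counts <- matrix(0, nbins, max_run + 1L)
  for (i in seq_along(flowgrams)) {
    vals <- flowgrams[[i]]$values
    runs <- truth[[i]]
    m <- min(length(vals), length(runs))
    b <- bin_index(vals[seq_len(m)], bin_width, nbins)
    n <- pmin(runs[seq_len(m)], max_run) + 1L
    for (j in seq_len(m)) counts[b[j], n[j]] <- counts[b[j], n[j]] + 1
  }
  tot <- colSums(counts)
  if (any(tot == 0)) {
    warning("no observations for run length(s) ",
            paste(which(tot == 0) - 1L, collapse = ", "),
            "; filled with distance cap")
  }
  mat <- matrix(distance_cap, nbins, max_run + 1L)
  for (n in which(tot > 0)) {
    d <- -log(counts[, n] / tot[n])
    d[!is.finite(d) | d > distance_cap] <- distance_cap
    mat[, n] <- d
  }
  intensity_model(mat, bin_width, max_run, distance_cap)
}

bin_index <- function(values, bin_width, nbins) {
  pmin(pmax(floor(values / bin_width), 0), nbins - 1L) + 1L
}

# Per-flow likelihood-ratio distance table: d*(f | n) = d(f | n) - min_n'
# d(f | n'), zero when n is the most likely run for the observed intensity.
# Subtracting a per-intensity constant leaves EM responsibilities, M-step
# argmins and likelihood monotonicity untouched, but puts distances on the
# mismatch scale that the clustering cut-offs (c_p, sigma_p) refer to.
normalized_dist_table <- function(model) {
  m <- model$neg_log_prob
  m - apply(m, 1, min)
}

#' Flowgram distance
#'
#' The per-signal distance between an observed flowgram and a hypothesised
#' perfect flowgram, summed over flows and normalised by the number of flows
#' `M`: `d'(f, U) = sum_i d(f_i | u_i) / M`. The observed flowgram carries the
#' data; the perfect flowgram is the hypothesis (the distance is not
#' symmetric in its arguments).
#'
#' @param fg a [flowgram] or numeric intensity vector.
#' @param pf integer run-length vector of the same length.
#' @param model an [intensity_model].
#' @param normalize if `TRUE`, use the per-flow likelihood-ratio form
#'   `d(f | n) - min_n' d(f | n')`, which is zero for every flow whose most
#'   likely run length equals the hypothesis. This is the scale the EM
#'   clustering operates on; responsibilities are identical either way.
#' @return a non-negative scalar.
#' @export
flowgram_distance <- function(fg, pf, model, normalize = FALSE) {
  vals <- if (inherits(fg, "flowgram")) fg$values else as.numeric(fg)
  if (length(vals) != length(pf)) {
    stop("flowgram and perfect flowgram lengths differ (", length(vals),
         " vs ", length(pf), ")")
  }
  dm <- if (normalize) normalized_dist_table(model) else model$neg_log_prob
  b <- bin_index(vals, model$bin_width, nrow(dm))
  n <- pmin(pf, model$max_run) + 1L
  mean(dm[cbind(b, n)])
}

#' Write an intensity model as a plain-text table
#'
#' Header lines give `bin_width`, `max_run` and `distance_cap`; the remainder
#' is the distance matrix, one intensity bin per line.
#'
#' @param model an [intensity_model].
#' @param path output file.
#' @export
write_intensity_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("bin_width", model$bin_width),
               paste("max_run", model$max_run),
               paste("distance_cap", model$distance_cap)), con)
  write.table(format(model$neg_log_prob, digits = 10), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an intensity model written by [write_intensity_model()]
#'
#' @param path input file.
#' @return an `"intensity_model"`.
#' @export
read_intensity_model <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:3], " ", fixed = TRUE)
  vals <- setNames(vapply(hdr, function(x) as.numeric(x[2]), numeric(1)),
                   vapply(hdr, `[`, character(1), 1))
  mat <- as.matrix(read.table(text = lines[-(1:3)], sep = "\t"))
  intensity_model(mat, vals[["bin_width"]], as.integer(vals[["max_run"]]),
                  vals[["distance_cap"]])
}
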