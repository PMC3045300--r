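#' Construct a flowgram
#'
#' A flowgram is one read's ordered vector of light intensities, one value per
#' nucleotide flow, as produced by 454-style pyrosequencing. Intensities are
#' kept at two-decimal precision (hundredths of a flow unit).
#'
#' @param id read identifier.
#' @param values numeric vector of non-negative flow intensities.
#' @param flow_order the four-nucleotide flow cycle (default `"TACG"`).
#' @param platform `"FLX"` (400 raw flows) or `"TITANIUM"` (800 raw flows).
#' @return an object of class `"flowgram"`.
#' @export
flowgram <- function(id, values, flow_order = "TACG", platform = "FLX") {
  values <- as.numeric(values)
  if (any(is.na(values))) stop("flowgram '", id, "': non-numeric intensity")
  if (any(values < 0)) stop("flowgram '", id, "': negative intensity")
  structure(
    list(id = as.character(id), values = round(values, 2),
         flow_order = flow_order, platform = match.arg(platform, c("FLX", "TITANIUM"))),
    class = "flowgram"
  )
}

#' @export
print.flowgram <- function(x, ...) {
  cat("<flowgram> ", x$id, ": ", length(x$values), " flows (", x$platform,
      ", order ", x$flow_order, ")\n", sep = "")
  invisible(x)
}

#' Read flowgrams from disk
#'
#' Supports two formats: the plain-text FLOWTABLE interchange format (TSV, one
#' record per line: read id followed by the flow intensities) and the binary
#' SFF format produced by 454 instruments (read-only).
#'
#' @param path input file.
#' @param format `"flowtable"` or `"sff"`; case-insensitive. Defaults to the
#'   file extension.
#' @param flow_order flow cycle used for FLOWTABLE input (SFF stores its own).
#' @return a list of [flowgram] objects (empty list for an empty file).
#' @export
read_flowgrams <- function(path, format = NULL, flow_order = "TACG") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.sff$", path, ignore.case = TRUE)) "sff" else "flowtable"
  }
  format <- tolower(format)
  switch(format,
    flowtable = read_flowtable(path, flow_order),
    sff = read_sff(path),
    stop("unknown flowgram format: ", format)
  )
}

read_flowtable <- function(path, flow_order = "TACG") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("flowtable record ", i, ": no flow values")
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (any(is.na(vals))) stop("flowtable record ", i, ": non-numeric intensity")
    if (any(vals < 0)) stop("flowtable record ", i, ": negative intensity")
    platform <- if (length(vals) >= 800) "TITANIUM" else "FLX"
    out[[i]] <- flowgram(parts[[1]], vals, flow_order, platform)
  }
  out
}

#' Write flowgrams as a FLOWTABLE TSV
#'
#' @param fgs list of [flowgram] objects.
#' @param path output file.
#' @export
write_flowtable <- function(fgs, path) {
  lines <- vapply(fgs, function(fg) {
    paste(c(fg$id, sprintf("%.2f", fg$values)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Minimal big-endian SFF reader (common header + per-read flow values).
read_sff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  u8 <- function(n) readBin(con, "integer", n = n, size = 1, signed = FALSE)
  u16 <- function(n = 1) readBin(con, "integer", n = n, size = 2,
                                 signed = FALSE, endian = "big")
  u32 <- function(n = 1) readBin(con, "integer", n = n, size = 4, endian = "big")
  magic <- u32()
  if (length(magic) == 0 || magic != 0x2E736666) stop("not an SFF file: ", path)
  version <- u8(4)
  if (!identical(version, c(0L, 0L, 0L, 1L))) stop("unsupported SFF version")
  u32(2)                                   # index offset (uint64), skipped
  index_length <- u32()
  n_reads <- u32()
  header_length <- u16()
  key_length <- u16()
  n_flows <- u16()
  fmt <- u8(1)
  if (fmt != 1L) stop("unsupported SFF flowgram format code: ", fmt)
  flow_chars <- rawToChar(readBin(con, "raw", n = n_flows))
  readBin(con, "raw", n = key_length)
  pad <- header_length - (31 + n_flows + key_length)
  if (pad > 0) readBin(con, "raw", n = pad)
  flow_order <- substr(flow_chars, 1, 4)
  platform <- if (n_flows >= 800) "TITANIUM" else "FLX"
  out <- vector("list", n_reads)
  for (r in seq_len(n_reads)) {
    rh_len <- u16()
    name_len <- u16()
    n_bases <- u32()
    u16(4)                                 # clip points
    name <- rawToChar(readBin(con, "raw", n = name_len))
    pad <- rh_len - (16 + name_len)
    if (pad > 0) readBin(con, "raw", n = pad)
    vals <- u16(n_flows) / 100
    data_len <- 2 * n_flows + 3 * n_bases
    readBin(con, "raw", n = n_bases * 3)   # flow index, bases, qualities
    pad <- (8 - data_len %% 8) %% 8
    if (pad > 0) readBin(con, "raw", n = pad)
    if (length(vals) < n_flows) stop("SFF record ", r, ": truncated flowgram")
    out[[r]] <- flowgram(name, vals, flow_order, platform)
  }
  out
}

#' Encode a nucleotide sequence as a perfect flowgram
#'
#' The perfect flowgram of a sequence is the integer flowgram it would produce
#' with zero noise: flows are revealed in `flow_order` cycles and each flow
#' records the length of the homopolymer it incorporates (greedy
#' left-to-right). The output is zero-padded to a whole frame of four flows.
#'
#' @param seq an unambiguous A/C/G/T string.
#' @param flow_order the flow cycle.
#' @return integer vector of run lengths (possibly empty).
#' @export
sequence_to_flows <- function(seq, flow_order = "TACG") {
  if (nchar(seq) == 0) return(integer(0))
  chars <- strsplit(toupper(seq), "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("sequence contains ambiguity codes; perfect flowgrams require A/C/G/T")
  }
  order_chars <- strsplit(flow_order, "")[[1]]
  runs <- integer(0)
  pos <- 1L
  flow <- 0L
  n <- length(chars)
  while (pos <= n) {
    base <- order_chars[flow %% 4L + 1L]
    flow <- flow + 1L
    k <- 0L
    while (pos <= n && chars[pos] == base) {
      k <- k + 1L
      pos <- pos + 1L
    }
    runs <- c(runs, k)
  }
  length(runs) <- 4L * ceiling(length(runs) / 4L)
  runs[is.na(runs)] <- 0L
  runs
}

#' Decode a perfect flowgram back to its nucleotide sequence
#'
#' Inverse of [sequence_to_flows()] (up to trailing zero flows).
#'
#' @param runs integer vector of non-negative run lengths.
#' @param flow_order the flow cycle.
#' @return a nucleotide string.
#' @export
flows_to_sequence <- function(runs, flow_order = "TACG") {
  if (length(runs) == 0) return("")
  if (any(runs < 0)) stop("negative run length")
  order_chars <- strsplit(flow_order, "")[[1]]
  bases <- order_chars[(seq_along(runs) - 1L) %% 4L + 1L]
  paste(rep(bases, runs), collapse = "")
}

#' Quality-filter policy for flowgrams
#'
#' Encodes the read-filtering rules: reads must carry the expected tag and
#' primer at their start; the first flow with intensity inside `noise_window`
#' (noisy signals) or the first frame of four flows with no intensity at or
#' above `min_signal` marks the end of the clean part of the read; reads whose
#' clean part is shorter than `min_clean_flow` flows are discarded and the
#' rest are truncated at `end_truncation_flow` flows (dropping the noisy final
#' 10% of the run).
#'
#' @param platform `"FLX"` or `"TITANIUM"`; sets `end_truncation_flow` to 360
#'   or 720.
#' @param noise_window half-open intensity interval associated with noisy
#'   reads, default `[0.5, 0.7)`.
#' @param min_signal minimum intensity counted as a real signal in a frame.
#' @param min_clean_flow minimum clean length in flows.
#' @param end_truncation_flow final truncation point in flows.
#' @param primer IUPAC primer expected at the read start (after the tag); `""`
#'   disables the check.
#' @param tag exact tag expected at the very start; `""` disables the check.
#' @return an object of class `"filter_policy"`.
#' @export
filter_policy <- function(platform = c("FLX", "TITANIUM"),
                          noise_window = c(0.5, 0.7), min_signal = 0.5,
                          min_clean_flow = 360L,
                          end_truncation_flow = NULL,
                          primer = "", tag = "") {
  platform <- match.arg(platform)
  if (is.null(end_truncation_flow)) {
    end_truncation_flow <- if (platform == "FLX") 360L else 720L
  }
  stopifnot(min_clean_flow <= end_truncation_flow)
  structure(
    list(platform = platform, noise_window = noise_window,
         min_signal = min_signal, min_clean_flow = as.integer(min_clean_flow),
         end_truncation_flow = as.integer(end_truncation_flow),
         primer = toupper(primer), tag = toupper(tag)),
    class = "filter_policy"
  )
}

iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]",
           M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
           N = "[ACGT]")
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(map))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  paste(map[chars], collapse = "")
}

#' Filter and truncate one flowgram
#'
#' Applies a [filter_policy()]: (1) reject reads whose called sequence does not
#' start with the tag and an IUPAC-exact match to the primer; (2) locate the
#' first noisy-window signal and the first signal-free frame of four flows;
#' the clean length is whichever comes first; (3) reject reads whose clean
#' length is below `min_clean_flow`; (4) truncate survivors at the clean
#' length rounded down to a whole frame, capped at `end_truncation_flow`.
#'
#' @param fg a [flowgram].
#' @param policy a [filter_policy].
#' @param seq the read's called sequence; derived from the rounded flowgram if
#'   omitted.
#' @return a list with elements `accepted` (logical), `flowgram` (the
#'   truncated flowgram, when accepted) and `reason` (rejection reason, when
#'   not).
#' @export
filter_and_truncate <- function(fg, policy, seq = NULL) {
  stopifnot(inherits(fg, "flowgram"), inherits(policy, "filter_policy"))
  vals <- fg$values
  len <- length(vals)
  if (len < policy$min_clean_flow) {
    return(list(accepted = FALSE, reason = "too short"))
  }
  if (nzchar(policy$tag) || nzchar(policy$primer)) {
    if (is.null(seq)) {
      seq <- flows_to_sequence(pmax(0L, as.integer(round(vals))), fg$flow_order)
    }
    pattern <- paste0("^", policy$tag, iupac_regex(policy$primer))
    if (!grepl(pattern, toupper(seq))) {
      reason <- if (nzchar(policy$tag) &&
                    !startsWith(toupper(seq), policy$tag)) "no tag" else "no primer"
      return(list(accepted = FALSE, reason = reason))
    }
  }
  clean <- len
  lo <- policy$noise_window[1]
  hi <- policy$noise_window[2]
  noisy <- which(vals >= lo & vals < hi)
  if (length(noisy)) clean <- min(clean, noisy[1] - 1L)
  frame_starts <- seq.int(1L, len - len %% 4L, by = 4L)
  if (length(frame_starts)) {
    dead <- frame_starts[vapply(frame_starts, function(s) {
      all(vals[s:(s + 3L)] < policy$min_signal)
    }, logical(1))]
    if (length(dead)) clean <- min(clean, dead[1] - 1L)
  }
  if (clean < policy$min_clean_flow) {
    return(list(accepted = FALSE,
                reason = sprintf("noisy before flow %d", policy$min_clean_flow)))
  }
  keep <- min(clean - clean %% 4L, policy$end_truncation_flow)
  out <- fg
  out$values <- vals[seq_len(keep)]
  list(accepted = TRUE, flowgram = out)
}

#' Filter a set of flowgrams
#'
#' Vectorised wrapper around [filter_and_truncate()].
#'
#' @param fgs list of [flowgram] objects.
#' @param policy a [filter_policy].
#' @return a list with `kept` (list of truncated flowgrams) and `rejections`
#'   (data frame `read_id`, `reason`).
#' @export
filter_flowgrams <- function(fgs, policy) {
  kept <- list()
  rej_id <- character(0)
  rej_reason <- character(0)
  for (fg in fgs) {
    res <- filter_and_truncate(fg, policy)
    if (res$accepted) {
      kept[[length(kept) + 1L]] <- res$flowgram
    } else {
      rej_id <- c(rej_id, fg$id)
      rej_reason <- c(rej_reason, res$reason)
    }
  }
  list(kept = kept,
       rejections = data.frame(read_id = rej_id, reason = rej_reason,
                               stringsAsFactors = FALSE))
}

#' Write a rejection log
#'
#' @param rejections data frame from [filter_flowgrams()].
#' @param path output TSV.
#' @export
write_rejection_log <- function(rejections, path) {
  write.table(rejections, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file with abundance-annotated headers
#'
#' Headers of the form `>id_count` carry the sequence abundance as a suffix;
#' headers without a numeric suffix get weight 1.
#'
#' @param path FASTA file.
#' @return data frame with columns `id`, `seq`, `weight`.
#' @export
read_weighted_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- names(ss)
  m <- regmatches(ids, regexec("^(.*)_([0-9]+(?:\\.[0-9]+)?)$", ids))
  weight <- vapply(m, function(x) if (length(x) == 3) as.numeric(x[3]) else 1,
                   numeric(1))
  id <- vapply(seq_along(m), function(i) {
    if (length(m[[i]]) == 3) m[[i]][2] else ids[i]
  }, character(1))
  data.frame(id = id, seq = as.character(ss), weight = weight,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences as FASTA with abundance-annotated headers
#'
#' @param ids sequence identifiers.
#' @param seqs nucleotide strings.
#' @param weights abundances appended to the header as `_count`.
#' @param path output file.
#' @export
write_weighted_fasta <- function(ids, seqs, weights, path) {
  w <- ifelse(weights == round(weights), format(round(weights), scientific = FALSE,
                                                trim = TRUE),
              format(weights, trim = TRUE))
  ss <- Biostrings::DNAStringSet(setNames(seqs, paste0(ids, "_", w)))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
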