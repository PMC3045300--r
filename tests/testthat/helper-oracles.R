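# Independent oracles and fixture builders used across the suite.

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Exhaustive global-alignment oracle: recursive enumeration of every
# alignment, scoring with the same cost definitions as the package but none
# of its code. State (i, j) = next unconsumed 1-based positions.
brute_force_align <- function(a, b, tm) {
  ac <- strsplit(toupper(a), "")[[1]]
  bc <- strsplit(toupper(b), "")[[1]]
  n <- length(ac)
  m <- length(bc)
  snl <- tm$sub_neg_log
  gp <- tm$gap_penalty
  hp <- tm$homopolymer_gap_penalty
  gap_cost <- function(base, other, consumed) {
    prev <- if (consumed >= 1) other[consumed] else ""
    nxt <- if (consumed < length(other)) other[consumed + 1] else ""
    if (identical(base, prev) || identical(base, nxt)) hp else gp
  }
  rec <- function(i, j) {
    if (i > n && j > m) return(0)
    best <- Inf
    if (i <= n && j <= m) {
      best <- min(best, snl[bc[j], ac[i]] + rec(i + 1, j + 1))
    }
    if (i <= n) best <- min(best, gap_cost(ac[i], bc, j - 1) + rec(i + 1, j))
    if (j <= m) best <- min(best, gap_cost(bc[j], ac, i - 1) + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Binomial upper-tail probability by explicit enumeration (factorials), not
# distribution functions.
binom_tail_enum <- function(kmin, size, prob) {
  if (kmin <= 0) return(1)
  ks <- kmin:size
  sum(vapply(ks, function(k) {
    factorial(size) / (factorial(k) * factorial(size - k)) *
      prob^k * (1 - prob)^(size - k)
  }, numeric(1)))
}

# Intensity model putting probability 1 on the bin containing each integer
# run length: simulated flowgrams equal perfect flowgrams.
point_mass_model <- function(bin_width = 0.01, max_run = 9L, cap = 100) {
  nbins <- round((max_run + 1) / bin_width)
  mat <- matrix(cap, nbins, max_run + 1L)
  for (n in 0:max_run) {
    b <- min(max(floor(n / bin_width), 0), nbins - 1L) + 1L
    mat[b, n + 1L] <- 0
  }
  intensity_model(mat, bin_width, max_run, cap)
}

# Divergent parent sequences from a shared root.
make_parents <- function(n, len, div = 0.2) {
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, len, replace = TRUE)
  vapply(seq_len(n), function(i) {
    s <- root
    pos <- sample.int(len, round(div * len))
    s[pos] <- vapply(s[pos], function(x) sample(setdiff(bases, x), 1),
                     character(1))
    paste(s, collapse = "")
  }, character(1))
}

# Minimal big-endian SFF writer (fixture generator for the reader).
write_sff_fixture <- function(path, ids, flows_list, flow_chars = "TACG",
                              key = "TCAG") {
  stopifnot(length(ids) == length(flows_list))
  con <- file(path, "wb")
  on.exit(close(con))
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "big")
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "big")
  u8 <- function(x) writeBin(as.integer(x), con, size = 1)
  pad8 <- function(k) if (k %% 8 != 0) writeBin(raw(8 - k %% 8), con)
  n_flows <- length(flows_list[[1]])
  hdr_len_raw <- 31 + n_flows + nchar(key)
  hdr_len <- 8 * ceiling(hdr_len_raw / 8)
  u32(0x2E736666)
  u8(c(0, 0, 0, 1))
  u32(c(0, 0))                       # index offset (uint64)
  u32(0)                             # index length
  u32(length(ids))                   # number of reads
  u16(hdr_len)
  u16(nchar(key))
  u16(n_flows)
  u8(1)                              # flowgram format
  writeChar(strrep(flow_chars, n_flows / 4), con, eos = NULL)
  writeChar(key, con, eos = NULL)
  pad8(hdr_len_raw)
  for (r in seq_along(ids)) {
    name <- ids[r]
    n_bases <- 4L                    # minimal placeholder calls
    rh_raw <- 16 + nchar(name)
    u16(8 * ceiling(rh_raw / 8))
    u16(nchar(name))
    u32(n_bases)
    u16(c(0, 0, 0, 0))               # clip points
    writeChar(name, con, eos = NULL)
    pad8(rh_raw)
    u16(round(flows_list[[r]] * 100))
    u8(rep(1L, n_bases))             # flow index per base
    writeChar("ACGT", con, eos = NULL)
    u8(rep(30L, n_bases))            # qualities
    pad8(2 * n_flows + 3 * n_bases)
  }
  path
}
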