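# Independent pure-R oracles: position-by-position scans on plain character
# vectors, no Biostrings, no package internals.

rc_chr <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

random_dna <- function(n, gc = 0.5, n_prob = 0) {
  p <- c((1 - gc) / 2 * (1 - n_prob), gc / 2 * (1 - n_prob),
         gc / 2 * (1 - n_prob), (1 - gc) / 2 * (1 - n_prob), n_prob)
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE, prob = p),
        collapse = "")
}

# all 1-based start positions of motif in seq by direct window comparison
oracle_match <- function(seq, motif) {
  ch <- strsplit(seq, "")[[1L]]
  m <- strsplit(motif, "")[[1L]]
  L <- length(m); n <- length(ch)
  if (n < L) return(integer(0))
  ok <- ch[seq_len(n - L + 1L)] == m[1L]
  if (L > 1L) for (k in 2:L) ok <- ok & ch[k:(n - L + k)] == m[k]
  which(ok)
}

# sorted unique 0-based cut points of one enzyme (both strands), exactly the
# documented convention: forward cut = start0 + offset, reverse-strand cut =
# start0 + (L - offset); palindromic enzymes scan the top strand only
oracle_cuts <- function(seq, site, offset) {
  L <- nchar(site)
  cuts <- oracle_match(seq, site) - 1L + offset
  rc <- rc_chr(site)
  if (!identical(rc, site))
    cuts <- c(cuts, oracle_match(seq, rc) - 1L + (L - offset))
  sort(unique(cuts))
}

# every fragment between adjacent merged cut points, typed by flanking
# enzymes; returns the full tiling (pre type filter)
oracle_all_fragments <- function(seq, rare_site, rare_off, freq_site, freq_off) {
  cr <- oracle_cuts(seq, rare_site, rare_off)
  cf <- oracle_cuts(seq, freq_site, freq_off)
  pos <- sort(unique(c(cr, cf)))
  if (length(pos) < 2L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), left_rare = logical(0),
                      left_freq = logical(0), right_rare = logical(0),
                      right_freq = logical(0)))
  a <- pos[-length(pos)]; b <- pos[-1L]
  data.frame(start = a + 1L, end = b, length = b - a,
             left_rare = a %in% cr, left_freq = a %in% cf,
             right_rare = b %in% cr, right_freq = b %in% cf)
}

# the AFLP subset (one rare + one frequent end, either orientation),
# fragments containing non-ACGT bases dropped
oracle_aflp_fragments <- function(seq, rare_site, rare_off, freq_site, freq_off) {
  fr <- oracle_all_fragments(seq, rare_site, rare_off, freq_site, freq_off)
  keep <- (fr$left_rare & fr$right_freq) | (fr$left_freq & fr$right_rare)
  fr <- fr[keep & fr$length >= 1L, , drop = FALSE]
  if (nrow(fr)) {
    ch <- strsplit(seq, "")[[1L]]
    pure <- vapply(seq_len(nrow(fr)), function(i)
      all(ch[fr$start[i]:fr$end[i]] %in% c("A", "C", "G", "T")), logical(1))
    fr <- fr[pure, , drop = FALSE]
  }
  fr[, c("start", "end", "length")]
}

# all-pairs minimum gap between a marker interval and gene intervals on the
# same chromosome (1-based closed coordinates); Inf when no gene shares the
# chromosome; 0 on >= 1 bp overlap
oracle_min_distance <- function(m_chrom, m_start, m_end,
                                g_chrom, g_start, g_end) {
  vapply(seq_along(m_chrom), function(i) {
    j <- which(g_chrom == m_chrom[i])
    if (!length(j)) return(Inf)
    d <- vapply(j, function(k) {
      if (m_start[i] <= g_end[k] && g_start[k] <= m_end[i]) return(0)
      if (m_end[i] < g_start[k]) return(g_start[k] - m_end[i] - 1)
      m_start[i] - g_end[k] - 1
    }, numeric(1))
    min(d)
  }, numeric(1))
}

# catalogue the tests need, independent of aflp_enzymes()
oracle_enzyme_table <- function() {
  data.frame(
    name   = c("EcoRI", "MseI", "BsmI", "TaqI", "SacI", "HpaII"),
    site   = c("GAATTC", "TTAA", "GAATGC", "TCGA", "GAGCTC", "CCGG"),
    offset = c(1L, 1L, 6L, 1L, 5L, 1L)
  )
}

make_genome <- function(...) read_genome(c(...))
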