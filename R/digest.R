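#' Find all cut sites of one enzyme
#'
#' Scans every chromosome for the recognition sequence on the top strand
#' and, for non-palindromic enzymes, for its reverse complement (physical
#' digestion is strand-symmetric). Occurrences containing any non-ACGT base
#' never match. Overlapping occurrences are all reported; duplicate cut
#' positions are collapsed.
#'
#' Cut positions are reported as 0-based cut points: the number of bases of
#' the chromosome 5' of the cut, so a fragment bounded by cuts \code{a < b}
#' occupies 1-based bases \code{[a+1, b]} and has length \code{b - a}.
#'
#' @param genome an \code{aflp_genome}.
#' @param enzyme an \code{\link{enzyme}}.
#' @return a \code{data.table} with columns \code{chrom}, \code{cut}
#'   (0-based cut point), \code{enzyme}, \code{strand} (strand of the
#'   matched occurrence), \code{left_len}/\code{right_len} (recognition
#'   bases left/right of the cut), sorted by chromosome and position.
#' @export
find_cut_sites <- function(genome, enzyme) {
  stopifnot(inherits(genome, "aflp_genome"), inherits(enzyme, "aflp_enzyme"))
  L <- nchar(enzyme$site)
  off <- enzyme$cut_offset
  motifs <- list(list(pat = enzyme$site, strand = "+",
                      cut_shift = off, left_len = off, right_len = L - off))
  if (!enzyme$palindromic)
    motifs <- c(motifs, list(list(pat = revcomp_chr(enzyme$site), strand = "-",
                                  cut_shift = L - off,
                                  left_len = L - off, right_len = off)))
  res <- lapply(seq_along(genome$seqs), function(i) {
    hits <- lapply(motifs, function(m) {
      s <- start(Biostrings::matchPattern(m$pat, genome$seqs[[i]], fixed = TRUE))
      if (!length(s)) return(NULL)
      data.table(cut = s - 1L + m$cut_shift, strand = m$strand,
                 left_len = m$left_len, right_len = m$right_len)
    })
    dt <- rbindlist(hits)
    if (!nrow(dt)) return(NULL)
    dt[, chrom := names(genome$seqs)[i]]
    dt
  })
  dt <- rbindlist(res)
  if (!nrow(dt))
    return(data.table(chrom = character(), cut = integer(),
                      enzyme = character(), strand = character(),
                      left_len = integer(), right_len = integer()))
  dt[, enzyme := enzyme$name]
  dt[, chrom := factor(chrom, levels = names(genome$seqs))]
  setorder(dt, chrom, cut, strand)
  dt <- unique(dt, by = c("chrom", "cut"))
  dt[, chrom := as.character(chrom)]
  dt[, .(chrom, cut, enzyme, strand, left_len, right_len)]
}

#' Complete double digestion with an enzyme pair
#'
#' Merges the two enzymes' cut positions per chromosome; each pair of
#' adjacent cuts bounds one restriction fragment labelled by its flanking
#' enzymes. Only AFLP-type fragments (one rare end, one frequent end, in
#' either orientation) are returned; fragments containing any non-ACGT base
#' are discarded (digestion is undefined across un-sequenced bases), and
#' chromosome-terminal segments, bounded by only one cut, are discarded
#' (they could never be amplified). If both enzymes cut at the same
#' coordinate the point carries both labels and satisfies either end of
#' the type rule.
#'
#' @param genome an \code{aflp_genome}.
#' @param pair an \code{\link{enzyme_pair}}.
#' @return a \code{data.table} of fragments with columns \code{chrom},
#'   \code{start}, \code{end} (1-based, closed), \code{length},
#'   \code{left_enzyme}, \code{right_enzyme}, \code{left_is_rare}, and
#'   \code{left_inner}/\code{right_inner}: the 1-based position of the base
#'   immediately interior to the left/right recognition remnant (\code{NA}
#'   when the fragment is too short to have one).
#' @export
double_digest <- function(genome, pair) {
  stopifnot(inherits(genome, "aflp_genome"), inherits(pair, "aflp_pair"))
  sr <- find_cut_sites(genome, pair$rare)
  sf <- find_cut_sites(genome, pair$frequent)
  sr[, is_rare := TRUE]
  sf[, is_rare := FALSE]
  cuts <- rbind(sr, sf)
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      length = integer(), left_enzyme = character(),
                      right_enzyme = character(), left_is_rare = logical(),
                      left_inner = integer(), right_inner = integer())
  if (!nrow(cuts)) return(empty)
  cuts[, chrom := factor(chrom, levels = names(genome$seqs))]
  setorder(cuts, chrom, cut)
  frags <- cuts[, frags_one_chrom(.SD, pair), by = chrom]
  if (!nrow(frags)) return(empty)
  frags[, chrom := as.character(chrom)]
  # discard fragments containing any non-ACGT base
  keep <- acgt_only(genome, frags$chrom, frags$start, frags$end)
  frags <- frags[keep]
  frags[]
}

# fragments between adjacent cut points of one chromosome (cuts sorted)
frags_one_chrom <- function(cuts, pair) {
  # collapse coordinate ties between the two enzymes into one cut point
  # carrying both labels (remnant geometry per enzyme kept)
  agg <- cuts[, .(
    rare = any(is_rare), freq = any(!is_rare),
    rl_left = left_len[is_rare][1], rl_right = right_len[is_rare][1],
    fl_left = left_len[!is_rare][1], fl_right = right_len[!is_rare][1]
  ), by = cut]
  n <- nrow(agg)
  if (n < 2L)
    return(data.table(start = integer(), end = integer(), length = integer(),
                      left_enzyme = character(), right_enzyme = character(),
                      left_is_rare = logical(),
                      left_inner = integer(), right_inner = integer()))
  li <- seq_len(n - 1L); ri <- li + 1L
  rf <- agg$rare[li] & agg$freq[ri]   # rare left, frequent right
  fr <- agg$freq[li] & agg$rare[ri]   # frequent left, rare right
  is_aflp <- rf | fr
  left_is_rare <- rf                  # rare-left preferred on double ties
  li <- li[is_aflp]; ri <- ri[is_aflp]; left_is_rare <- left_is_rare[is_aflp]
  a <- agg$cut[li]; b <- agg$cut[ri]
  # remnant lengths of the enzyme assigned to each end (zero-length-safe)
  l_right_len <- agg$fl_right[li]; l_right_len[left_is_rare] <- agg$rl_right[li][left_is_rare]
  r_left_len <- agg$rl_left[ri]; r_left_len[left_is_rare] <- agg$fl_left[ri][left_is_rare]
  left_inner  <- a + l_right_len + 1L
  right_inner <- b - r_left_len
  bad <- left_inner > right_inner | left_inner > b | right_inner < a + 1L
  left_inner[bad] <- NA_integer_
  right_inner[bad] <- NA_integer_
  left_enzyme <- rep(pair$frequent$name, length(a))
  left_enzyme[left_is_rare] <- pair$rare$name
  right_enzyme <- rep(pair$rare$name, length(a))
  right_enzyme[left_is_rare] <- pair$frequent$name
  data.table(
    start = a + 1L, end = b, length = b - a,
    left_enzyme = left_enzyme, right_enzyme = right_enzyme,
    left_is_rare = left_is_rare,
    left_inner = as.integer(left_inner), right_inner = as.integer(right_inner)
  )[length >= 1L]
}

# TRUE where genome[chrom, start:end] is pure ACGT
acgt_only <- function(genome, chrom, start, end) {
  out <- logical(length(chrom))
  for (cn in unique(chrom)) {
    i <- chrom == cn
    v <- IRanges::Views(genome$seqs[[cn]], start = start[i], end = end[i])
    out[i] <- Biostrings::letterFrequency(v, letters = "ACGT")[, 1L] == width(v)
  }
  out
}

#' Size selection of restriction fragments
#'
#' Keeps fragments with \code{min_len <= length <= max_len} (inclusive
#' bounds, mimicking the 40-440 nt experimental window); order preserved.
#'
#' @param fragments fragment \code{data.table} from \code{\link{double_digest}}.
#' @param min_len,max_len inclusive bounds in nt; defaults 40 and 440.
#' @return the surviving fragments.
#' @export
size_select <- function(fragments, min_len = 40L, max_len = 440L) {
  if (min_len < 1L || min_len > max_len)
    stop("require 1 <= min_len <= max_len")
  fragments[fragments$length >= min_len & fragments$length <= max_len]
}

#' Restriction-fragment length to PCR-product length
#'
#' Adds the 32 nt contributed by the standard AFLP adapters/primers, so the
#' 40-440 nt restriction window corresponds to 72-472 nt PCR products.
#' Reporting helper only.
#'
#' @param restriction_fragment_length length(s) in nt, >= 1.
#' @return amplified length(s) in nt.
#' @examples
#' pcr_length(c(40, 440))  # 72 472
#' @export
pcr_length <- function(restriction_fragment_length) {
  stopifnot(all(restriction_fragment_length >= 1))
  restriction_fragment_length + 32L
}

#' Selective-nucleotide filter
#'
#' Keeps a fragment iff the base immediately interior to the rare-enzyme
#' recognition remnant is in the rare-end allowed set AND the base
#' immediately interior to the frequent-enzyme remnant is in the
#' frequent-end allowed set. The interior base at the right-hand end of the
#' fragment is read as its complement (the selective primer anneals on the
#' opposite strand). An empty allowed set on an end places no constraint.
#' Fragments too short to expose an interior base beyond both remnants fail
#' the filter.
#'
#' @param fragments fragment \code{data.table} from \code{\link{double_digest}}.
#' @param pair the \code{\link{enzyme_pair}}, whose \code{selective_rare} /
#'   \code{selective_frequent} sets define the filter (at least one must be
#'   non-empty).
#' @param genome the \code{aflp_genome} the fragments came from.
#' @return the surviving fragments.
#' @export
apply_selective <- function(fragments, pair, genome) {
  stopifnot(inherits(pair, "aflp_pair"))
  if (!length(pair$selective_rare) && !length(pair$selective_frequent))
    stop("selective spec empty on both ends; nothing to filter")
  # an allowed set containing all four bases constrains nothing; with no
  # real constraint on either end the filter is the identity
  sel_r <- if (length(pair$selective_rare) == 4L) character(0)
           else pair$selective_rare
  sel_f <- if (length(pair$selective_frequent) == 4L) character(0)
           else pair$selective_frequent
  if (!length(sel_r) && !length(sel_f)) return(fragments)
  if (!nrow(fragments)) return(fragments)
  ok <- !is.na(fragments$left_inner)
  base_at <- function(chrom, pos) {
    out <- rep(NA_character_, length(pos))
    for (cn in unique(chrom[!is.na(pos)])) {
      i <- which(chrom == cn & !is.na(pos))
      out[i] <- as.character(IRanges::Views(genome$seqs[[cn]],
                                            start = pos[i], width = 1L))
    }
    out
  }
  lb <- base_at(fragments$chrom, ifelse(ok, fragments$left_inner, NA))
  rb <- base_at(fragments$chrom, ifelse(ok, fragments$right_inner, NA))
  rb <- chartr("ACGT", "TGCA", rb)          # read on the opposite strand
  rare_base <- ifelse(fragments$left_is_rare, lb, rb)
  freq_base <- ifelse(fragments$left_is_rare, rb, lb)
  pass_rare <- if (length(sel_r)) rare_base %in% sel_r
               else rep(TRUE, nrow(fragments))
  pass_freq <- if (length(sel_f)) freq_base %in% sel_f
               else rep(TRUE, nrow(fragments))
  fragments[ok & pass_rare & pass_freq]
}

#' Collapse fragments into electrophoretic bands
#'
#' Groups fragments whose materialised sequences are identical (exact
#' string equality, orientation as stored): repeated genomic sequence
#' produces identical fragments that co-migrate as one band. Collapse by
#' identical length only (size homoplasy studies) is available via
#' \code{by = "length"}.
#'
#' @param fragments fragment \code{data.table}.
#' @param genome the \code{aflp_genome} the fragments came from.
#' @param by \code{"sequence"} (default) or \code{"length"}.
#' @return a \code{data.table} of bands: the representative fragment (the
#'   member with lowest chromosome order then lowest start) with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{length},
#'   \code{left_enzyme}, \code{right_enzyme}, \code{multiplicity}; sorted
#'   by representative position. Band multiplicities sum to the fragment
#'   count.
#' @export
collapse_bands <- function(fragments, genome, by = c("sequence", "length")) {
  by <- match.arg(by)
  if (!nrow(fragments)) {
    out <- copy(fragments)
    out[, multiplicity := integer(0)]
    return(out[, .(chrom, start, end, length, left_enzyme, right_enzyme,
                   multiplicity)])
  }
  f <- copy(fragments)
  key <- if (by == "sequence") {
    ks <- character(nrow(f))
    for (cn in unique(f$chrom)) {
      i <- which(f$chrom == cn)
      ks[i] <- as.character(IRanges::Views(genome$seqs[[cn]],
                                           start = f$start[i], end = f$end[i]))
    }
    ks
  } else as.character(f$length)
  f[, seqstr := key]
  f[, chrom := factor(chrom, levels = names(genome$seqs))]
  setorder(f, chrom, start)
  bands <- f[, c(.SD[1L], .(multiplicity = .N)), by = seqstr,
             .SDcols = c("chrom", "start", "end", "length",
                         "left_enzyme", "right_enzyme")]
  setorder(bands, chrom, start)
  bands[, seqstr := NULL]
  bands[, chrom := as.character(chrom)]
  bands[]
}

#' Fragments or bands as a GRanges of markers
#'
#' @param x a fragment/band \code{data.table}, or already a \code{GRanges}.
#' @param genome the companion \code{aflp_genome} (sets chromosome order and
#'   lengths).
#' @return an unstranded \code{GRanges}.
#' @export
markers_as_granges <- function(x, genome) {
  if (methods::is(x, "GRanges")) {
    gr <- x
  } else {
    gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
  }
  len <- chrom_lengths(genome)
  GenomeInfoDb::seqlevels(gr) <- names(len)
  GenomeInfoDb::seqlengths(gr) <- unname(len)
  gr
}

#' Materialise fragment sequences
#'
#' @param fragments fragment \code{data.table}.
#' @param genome the \code{aflp_genome}.
#' @return character vector of fragment sequences.
#' @export
fragment_sequences <- function(fragments, genome) {
  out <- character(nrow(fragments))
  for (cn in unique(fragments$chrom)) {
    i <- which(fragments$chrom == cn)
    out[i] <- as.character(IRanges::Views(genome$seqs[[cn]],
                                          start = fragments$start[i],
                                          end = fragments$end[i]))
  }
  out
}

#' Run the standard AFLP marker pipeline
#'
#' \code{double_digest} + \code{size_select} (+ optional selective filter),
#' the composite most analyses start from.
#'
#' @param genome an \code{aflp_genome}.
#' @param pair an \code{\link{enzyme_pair}}.
#' @param min_len,max_len size-selection bounds (nt).
#' @param selective apply the pair's selective-nucleotide spec if non-empty.
#' @return fragment \code{data.table} of AFLP markers.
#' @export
aflp_markers <- function(genome, pair, min_len = 40L, max_len = 440L,
                         selective = TRUE) {
  fr <- size_select(double_digest(genome, pair), min_len, max_len)
  if (selective &&
      (length(pair$selective_rare) || length(pair$selective_frequent)))
    fr <- apply_selective(fr, pair, genome)
  fr
}

#' Write fragments or bands as BED6
#'
#' Name column is \code{leftEnzyme-rightEnzyme:length}; score is the band
#' multiplicity (1 for plain fragments). Coordinates are BED 0-based
#' half-open.
#'
#' @param x fragment or band \code{data.table}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fragments_bed <- function(x, path) {
  score <- if ("multiplicity" %in% names(x)) x$multiplicity else rep(1L, nrow(x))
  df <- data.frame(x$chrom, x$start - 1L, x$end,
                   sprintf("%s-%s:%d", x$left_enzyme, x$right_enzyme, x$length),
                   score, ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
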