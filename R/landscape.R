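#' Non-overlapping window tiling of a genome
#'
#' @param genome an \code{aflp_genome}.
#' @param window_size window size in bp (default 200 kb; 100 kb is the
#'   other size commonly used). The final window of each chromosome may be
#'   shorter.
#' @return \code{data.table} with \code{chrom}, \code{wstart}, \code{wend}
#'   (1-based closed), tiling each chromosome exactly.
#' @export
genome_windows <- function(genome, window_size = 200000L) {
  stopifnot(window_size >= 1L)
  len <- chrom_lengths(genome)
  rbindlist(lapply(names(len), function(cn) {
    ws <- seq.int(1L, len[[cn]], by = window_size)
    data.table(chrom = cn, wstart = ws,
               wend = pmin(ws + window_size - 1L, len[[cn]]))
  }))
}

#' Per-window feature counts
#'
#' Assigns each feature to exactly one window by its start coordinate
#' (interval features: left end; point features: position) and counts per
#' window.
#'
#' @param features a \code{data.table}/\code{data.frame} with \code{chrom}
#'   and \code{start} (1-based) columns — fragment and band tables qualify —
#'   or a \code{GRanges}, or a cut-site table (its \code{cut} column, a
#'   0-based cut point, is used as position \code{cut + 1}).
#' @param genome an \code{aflp_genome}.
#' @param window_size window size in bp.
#' @return the window table from \code{\link{genome_windows}} with a
#'   \code{count} column; counts sum to the number of features.
#' @export
window_counts <- function(features, genome, window_size = 200000L) {
  win <- genome_windows(genome, window_size)
  if (methods::is(features, "GRanges")) {
    chrom <- as.character(seqnames(features))
    pos <- start(features)
  } else if (!is.null(features$start)) {
    chrom <- as.character(features$chrom)
    pos <- features$start
  } else if (!is.null(features$cut)) {
    chrom <- as.character(features$chrom)
    pos <- features$cut + 1L
  } else stop("features must carry start or cut positions")
  len <- chrom_lengths(genome)
  if (length(pos)) {
    if (!all(chrom %in% names(len))) stop("feature on unknown chromosome")
    if (any(pos < 1L | pos > len[chrom]))
      stop("feature position beyond chromosome end")
  }
  win[, count := 0L]
  if (length(pos)) {
    idx <- (pos - 1L) %/% window_size + 1L
    tab <- data.table(chrom = chrom, idx = idx)[, .(count = .N),
                                                by = c("chrom", "idx")]
    wi <- win[, .(chrom, idx = (wstart - 1L) %/% window_size + 1L)]
    m <- match(paste(wi$chrom, wi$idx), paste(tab$chrom, tab$idx))
    win[!is.na(m), count := tab$count[m[!is.na(m)]]]
  }
  win[]
}

#' Per-window GC content
#'
#' GC fraction (G+C)/(A+C+G+T) per window, ignoring N and other ambiguity
#' codes; windows with no ACGT base report \code{NA}.
#'
#' @param genome an \code{aflp_genome}.
#' @param window_size window size in bp.
#' @return window table with \code{gc} and \code{acgt_bases} columns.
#' @export
window_gc <- function(genome, window_size = 200000L) {
  win <- genome_windows(genome, window_size)
  gc <- numeric(nrow(win)); acgt <- integer(nrow(win))
  for (cn in unique(win$chrom)) {
    i <- which(win$chrom == cn)
    v <- IRanges::Views(genome$seqs[[cn]], start = win$wstart[i],
                        end = win$wend[i])
    lf <- Biostrings::letterFrequency(v, letters = c("CG", "AT"))
    acgt[i] <- lf[, 1L] + lf[, 2L]
    gc[i] <- ifelse(acgt[i] > 0L, lf[, 1L] / acgt[i], NA_real_)
  }
  win[, `:=`(gc = gc, acgt_bases = acgt)]
  win[]
}

#' Combined windowed landscape track
#'
#' One row per window with counts of AFLP fragments, bands, genes, rare and
#' frequent cut sites, plus mean GC — the layers plotted in marker
#' landscape figures.
#'
#' @param genome an \code{aflp_genome}.
#' @param geneset gene set \code{GRanges} (may be empty).
#' @param pair an \code{\link{enzyme_pair}}.
#' @param window_size window size in bp.
#' @param min_len,max_len size-selection bounds for the markers.
#' @param bands also collapse to bands and count them (default TRUE).
#' @return \code{data.table} with one row per window: \code{chrom},
#'   \code{wstart}, \code{wend}, \code{fragments}, \code{bands},
#'   \code{genes}, \code{rare_sites}, \code{frequent_sites}, \code{gc},
#'   \code{acgt_bases}.
#' @export
window_track <- function(genome, geneset, pair, window_size = 200000L,
                         min_len = 40L, max_len = 440L, bands = TRUE) {
  fr <- size_select(double_digest(genome, pair), min_len, max_len)
  out <- window_gc(genome, window_size)
  out[, fragments := window_counts(fr, genome, window_size)$count]
  if (bands) {
    bd <- collapse_bands(fr, genome)
    out[, bands := window_counts(bd, genome, window_size)$count]
  }
  out[, genes := window_counts(geneset, genome, window_size)$count]
  out[, rare_sites := window_counts(find_cut_sites(genome, pair$rare),
                                    genome, window_size)$count]
  out[, frequent_sites := window_counts(find_cut_sites(genome, pair$frequent),
                                        genome, window_size)$count]
  data.table::setcolorder(out, c("chrom", "wstart", "wend"))
  out[]
}

#' Genic vs intergenic GC content
#'
#' GC fraction over the union of gene intervals and over its complement,
#' each base classified exactly once; N and other ambiguity codes excluded
#' from both numerator and denominator. An empty stratum reports \code{NA}.
#'
#' @param genome an \code{aflp_genome}.
#' @param geneset non-empty gene set \code{GRanges}.
#' @return list with \code{genic_gc} and \code{intergenic_gc}.
#' @export
genic_intergenic_gc <- function(genome, geneset) {
  stopifnot(length(geneset) >= 1L)
  g <- GenomicRanges::reduce(markers_as_granges(geneset, genome),
                             ignore.strand = TRUE)
  gc_gen <- 0; acgt_gen <- 0; gc_tot <- 0; acgt_tot <- 0
  for (cn in names(genome$seqs)) {
    lf <- Biostrings::letterFrequency(genome$seqs[[cn]], letters = c("CG", "AT"))
    gc_tot <- gc_tot + lf[1L]; acgt_tot <- acgt_tot + lf[1L] + lf[2L]
    r <- IRanges::ranges(g[seqnames(g) == cn])
    if (length(r)) {
      v <- IRanges::Views(genome$seqs[[cn]], r)
      lfg <- Biostrings::letterFrequency(v, letters = c("CG", "AT"))
      gc_gen <- gc_gen + sum(lfg[, 1L])
      acgt_gen <- acgt_gen + sum(lfg[, 1L] + lfg[, 2L])
    }
  }
  gc_int <- gc_tot - gc_gen; acgt_int <- acgt_tot - acgt_gen
  list(genic_gc = if (acgt_gen > 0) unname(gc_gen / acgt_gen) else NA_real_,
       intergenic_gc = if (acgt_int > 0) unname(gc_int / acgt_int) else NA_real_)
}

#' Mean and population SD of gene lengths
#'
#' @param geneset non-empty gene set \code{GRanges}.
#' @return list with \code{mean} and \code{sd} in bp (population SD,
#'   denominator n).
#' @export
gene_length_stats <- function(geneset) {
  if (!length(geneset)) stop("empty gene set")
  w <- width(geneset)
  list(mean = mean(w), sd = sqrt(mean((w - mean(w))^2)))
}

#' Mean distance between consecutive markers
#'
#' Mean of start-to-start gaps between consecutive markers within each
#' chromosome, pooled over chromosomes. The coarser alternative
#' genome size / marker count is returned alongside.
#'
#' @param markers fragment/band \code{data.table} or \code{GRanges}.
#' @param genome an \code{aflp_genome}.
#' @return list with \code{mean_gap} (bp; \code{NA} with a warning when no
#'   chromosome carries two markers) and \code{per_marker}
#'   (genome size / marker count).
#' @export
mean_intermarker_distance <- function(markers, genome) {
  m <- markers_as_granges(markers, genome)
  gaps <- unlist(lapply(names(genome$seqs), function(cn) {
    s <- sort(start(m[seqnames(m) == cn]))
    if (length(s) >= 2L) diff(s) else numeric(0)
  }))
  if (!length(gaps)) {
    warning("fewer than 2 markers on every chromosome; mean gap undefined")
    mg <- NA_real_
  } else mg <- mean(gaps)
  list(mean_gap = mg,
       per_marker = if (length(m)) sum(chrom_lengths(genome)) / length(m)
                    else NA_real_)
}

#' Compositional summary of a genome + gene set + marker set
#'
#' @param genome an \code{aflp_genome}.
#' @param geneset gene set \code{GRanges}.
#' @param markers fragment/band table or \code{GRanges}.
#' @return list mirroring the per-species composition rows of a species
#'   table: genome size, genic/intergenic GC, gene count, gene length
#'   mean/SD, marker count, mean inter-marker distance.
#' @export
composition_summary <- function(genome, geneset, markers) {
  gc <- if (length(geneset)) genic_intergenic_gc(genome, geneset)
        else list(genic_gc = NA_real_, intergenic_gc = NA_real_)
  gl <- if (length(geneset)) gene_length_stats(geneset)
        else list(mean = NA_real_, sd = NA_real_)
  imd <- mean_intermarker_distance(markers, genome)
  n_markers <- if (methods::is(markers, "GRanges")) length(markers)
               else nrow(markers)
  list(genome_size = sum(chrom_lengths(genome)),
       unsequenced_pct = unsequenced_percentage(genome),
       genic_gc = gc$genic_gc, intergenic_gc = gc$intergenic_gc,
       n_genes = length(geneset),
       gene_len_mean = gl$mean, gene_len_sd = gl$sd,
       n_markers = n_markers,
       mean_intermarker = imd$mean_gap,
       genome_per_marker = imd$per_marker)
}

#' Write one window-track layer as bedGraph
#'
#' @param track a window track from \code{\link{window_track}},
#'   \code{\link{window_counts}} or \code{\link{window_gc}}.
#' @param layer column name to write (e.g. \code{"fragments"}, \code{"gc"}).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(track, layer, path) {
  stopifnot(layer %in% names(track))
  df <- data.frame(track$chrom, track$wstart - 1L, track$wend, track[[layer]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
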