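#' Distance from each marker to its nearest gene
#'
#' Gap distance in bp between intervals: 0 when the marker shares at least
#' one base with (or is contained in) a gene, otherwise the number of bases
#' strictly between the marker and the closest gene on the same chromosome.
#' Markers on chromosomes carrying no gene get \code{Inf}.
#'
#' @param markers fragment/band \code{data.table} or \code{GRanges}.
#' @param geneset gene set \code{GRanges}.
#' @param genome the companion \code{aflp_genome}.
#' @return numeric vector of distances, one per marker.
#' @export
distance_to_nearest_gene <- function(markers, geneset, genome) {
  m <- markers_as_granges(markers, genome)
  g <- markers_as_granges(geneset, genome)
  d <- rep(Inf, length(m))
  if (length(g)) {
    hits <- GenomicRanges::distanceToNearest(m, g, ignore.strand = TRUE)
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  }
  d
}

# overlap indicator used for the d = 0 statistics ("within the gene
# sequence or overlapping it" = >= 1 shared bp; touching intervals with a
# zero-length gap do not count)
overlaps_any <- function(x, y) {
  GenomicRanges::countOverlaps(x, y, minoverlap = 1L, ignore.strand = TRUE) > 0L
}

#' Percentage of markers within given distances of genes
#'
#' For each threshold d, 100 x |markers at distance <= d from the nearest
#' gene| / |markers|. The d = 0 class means overlap (>= 1 shared bp); the
#' classes are cumulative by construction.
#'
#' @param markers fragment/band \code{data.table} or \code{GRanges}.
#' @param geneset gene set \code{GRanges}.
#' @param genome the companion \code{aflp_genome}.
#' @param thresholds distances in bp; default \code{c(0, 1000, 10000)}.
#' @return named numeric vector of percentages (names = thresholds in bp).
#' @export
pct_markers_within <- function(markers, geneset, genome,
                               thresholds = c(0, 1000, 10000)) {
  m <- markers_as_granges(markers, genome)
  if (!length(m)) {
    warning("no markers; percentages undefined")
    return(stats::setNames(rep(NA_real_, length(thresholds)), thresholds))
  }
  g <- markers_as_granges(geneset, genome)
  d <- distance_to_nearest_gene(m, g, genome)
  ov <- overlaps_any(m, g)
  pct <- vapply(thresholds, function(th) {
    100 * sum(if (th == 0) ov else d <= th) / length(m)
  }, numeric(1))
  stats::setNames(pct, thresholds)
}

#' Random-placement expectation of the d = 0 marker percentage
#'
#' The percentage of the sequenced genome covered by the union of gene
#' intervals: the chance a uniformly placed marker overlaps a gene. N bases
#' are excluded from both numerator and denominator.
#'
#' @param geneset gene set \code{GRanges}.
#' @param genome an \code{aflp_genome}.
#' @return percentage in \code{[0, 100]}.
#' @export
expected_pct_markers_random <- function(geneset, genome) {
  seqd <- sum(sequenced_length(genome))
  if (seqd <= 0) stop("genome has no sequenced bases")
  g <- GenomicRanges::reduce(markers_as_granges(geneset, genome),
                             ignore.strand = TRUE)
  cov <- 0L
  for (cn in unique(as.character(seqnames(g)))) {
    r <- IRanges::ranges(g[seqnames(g) == cn])
    cov <- cov + sum(width(r)) -
      sum(width(IRanges::intersect(r, genome$n_runs[[cn]])))
  }
  100 * cov / seqd
}

#' Percentage of genes with a marker within given distances
#'
#' For each threshold d, 100 x |genes whose nearest marker is within d| /
#' |genes|; d = 0 means at least one marker overlapping the gene sequence.
#'
#' @inheritParams pct_markers_within
#' @return named numeric vector of percentages.
#' @export
pct_genes_with_marker_within <- function(markers, geneset, genome,
                                         thresholds = c(0, 1000, 10000)) {
  g <- markers_as_granges(geneset, genome)
  if (!length(g)) {
    warning("empty gene set; percentages undefined")
    return(stats::setNames(rep(NA_real_, length(thresholds)), thresholds))
  }
  m <- markers_as_granges(markers, genome)
  d <- distance_to_nearest_gene(g, m, genome)  # symmetric metric
  ov <- overlaps_any(g, m)
  pct <- vapply(thresholds, function(th) {
    100 * sum(if (th == 0) ov else d <= th) / length(g)
  }, numeric(1))
  stats::setNames(pct, thresholds)
}

#' Poisson expectation of the percentage of genes containing a marker
#'
#' lambda is the observed mean number of overlapping markers per gene
#' (total gene-marker overlap pairs / gene count); under a Poisson model of
#' marker placement with equal gene lengths, the expected percentage of
#' genes with at least one marker is 100(1 - exp(-lambda)).
#'
#' @inheritParams pct_markers_within
#' @return list with \code{lambda} and \code{expected_pct}.
#' @export
poisson_expected_pct_genes <- function(markers, geneset, genome) {
  g <- markers_as_granges(geneset, genome)
  stopifnot(length(g) >= 1L)
  m <- markers_as_granges(markers, genome)
  lambda <- sum(GenomicRanges::countOverlaps(g, m, minoverlap = 1L,
                                             ignore.strand = TRUE)) / length(g)
  list(lambda = lambda, expected_pct = 100 * (1 - exp(-lambda)))
}

#' Per-gene marker-count histogram with its Poisson expectation
#'
#' Observed number of genes with exactly k overlapping markers
#' (k = 0, 1, 2, ...) next to the Poisson(lambda) pmf, lambda being the
#' observed mean count. With strongly unequal gene lengths the observed
#' k = 0 class exceeds the Poisson prediction (over-dispersion).
#'
#' @inheritParams pct_markers_within
#' @return \code{data.frame} with columns \code{k}, \code{observed}
#'   (gene count), \code{observed_pct}, \code{poisson_pct}.
#' @export
gene_fragment_histogram <- function(markers, geneset, genome) {
  g <- markers_as_granges(geneset, genome)
  stopifnot(length(g) >= 1L)
  m <- markers_as_granges(markers, genome)
  k <- GenomicRanges::countOverlaps(g, m, minoverlap = 1L, ignore.strand = TRUE)
  lambda <- mean(k)
  kk <- 0:max(k, 0L)
  obs <- vapply(kk, function(x) sum(k == x), integer(1))
  data.frame(k = kk, observed = obs,
             observed_pct = 100 * obs / length(g),
             poisson_pct = 100 * stats::dpois(kk, lambda))
}

#' Marker-to-gene distance summary
#'
#' The full observed/expected distance block for one marker set against one
#' gene set: cumulative percentages of markers within each threshold of the
#' nearest gene, percentages of genes with a marker within each threshold,
#' the random-placement expectation of the d = 0 marker percentage (gene
#' union coverage of the sequenced genome) and the Poisson expectation of
#' the d = 0 gene percentage.
#'
#' @inheritParams pct_markers_within
#' @return object of class \code{aflp_distance_summary}: a list with
#'   \code{thresholds}, \code{pct_markers_within},
#'   \code{pct_genes_with_marker_within}, \code{expected_pct_markers_at_0},
#'   \code{expected_pct_genes_at_0}, \code{lambda}, \code{n_markers},
#'   \code{n_genes}.
#' @export
distance_summary <- function(markers, geneset, genome,
                             thresholds = c(0, 1000, 10000)) {
  m <- markers_as_granges(markers, genome)
  g <- markers_as_granges(geneset, genome)
  pois <- if (length(g)) poisson_expected_pct_genes(m, geneset, genome)
          else list(lambda = NA_real_, expected_pct = NA_real_)
  structure(list(
    thresholds = thresholds,
    pct_markers_within = pct_markers_within(m, geneset, genome, thresholds),
    pct_genes_with_marker_within =
      pct_genes_with_marker_within(m, geneset, genome, thresholds),
    expected_pct_markers_at_0 =
      if (length(g)) expected_pct_markers_random(geneset, genome) else NA_real_,
    expected_pct_genes_at_0 = pois$expected_pct,
    lambda = pois$lambda,
    n_markers = length(m), n_genes = length(g)
  ), class = "aflp_distance_summary")
}

#' @export
print.aflp_distance_summary <- function(x, digits = 2, ...) {
  cat(sprintf("<distance summary> %d markers vs %d genes\n",
              x$n_markers, x$n_genes))
  th <- paste0(format(x$thresholds / 1000, trim = TRUE), " kb")
  cat("  % markers within: ",
      paste(sprintf("%s=%s", th, round(x$pct_markers_within, digits)),
            collapse = "  "), "\n")
  cat(sprintf("    expected at 0 kb (random placement): %s\n",
              round(x$expected_pct_markers_at_0, digits)))
  cat("  % genes with marker within: ",
      paste(sprintf("%s=%s", th, round(x$pct_genes_with_marker_within, digits)),
            collapse = "  "), "\n")
  cat(sprintf("    expected at 0 kb (Poisson, lambda=%.3f): %s\n",
              x$lambda, round(x$expected_pct_genes_at_0, digits)))
  invisible(x)
}

#' Candidate-gene subset distance summary
#'
#' The same statistics as \code{\link{distance_summary}}, computed against a
#' candidate subset of the genes, with the extended default thresholds
#' 0 / 1 kb / 10 kb / 100 kb used for trait-specific gene sets. The
#' expected d = 0 marker percentage uses the candidates' union coverage.
#'
#' @param markers fragment/band \code{data.table} or \code{GRanges}.
#' @param candidate_geneset candidate gene set \code{GRanges} (non-empty),
#'   e.g. from \code{\link{select_genes}}.
#' @param genome the companion \code{aflp_genome}.
#' @param thresholds distances in bp.
#' @return an \code{aflp_distance_summary}.
#' @export
candidate_subset_summary <- function(markers, candidate_geneset, genome,
                                     thresholds = c(0, 1000, 10000, 100000)) {
  if (!length(candidate_geneset)) stop("candidate gene set is empty")
  distance_summary(markers, candidate_geneset, genome, thresholds)
}

#' Per-marker nearest gene table
#'
#' @inheritParams pct_markers_within
#' @return \code{data.frame}: marker coordinates, nearest gene ID
#'   (\code{NA} when the chromosome has no gene) and gap distance in bp.
#' @export
nearest_gene_table <- function(markers, geneset, genome) {
  m <- markers_as_granges(markers, genome)
  g <- markers_as_granges(geneset, genome)
  id <- rep(NA_character_, length(m))
  d <- rep(Inf, length(m))
  if (length(g)) {
    hits <- GenomicRanges::distanceToNearest(m, g, ignore.strand = TRUE)
    id[S4Vectors::queryHits(hits)] <-
      geneset$gene_id[S4Vectors::subjectHits(hits)]
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  }
  data.frame(chrom = as.character(seqnames(m)), start = start(m),
             end = end(m), nearest_gene = id, distance = d)
}
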