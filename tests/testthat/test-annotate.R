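# small fixed world reused across blocks
ann_world <- local({
  set.seed(53)
  g <- read_genome(c(c1 = random_dna(50000), c2 = random_dna(20000)))
  list(genome = g)
})

mk_genes <- function(genome, chrom, start, end, ids = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  gr$gene_id <- if (is.null(ids)) paste0("g", seq_along(start)) else ids
  as_gene_set(gr, genome = genome)
}

mk_markers <- function(chrom, start, end) {
  data.table::data.table(chrom = chrom, start = start, end = end,
                         length = end - start + 1L)
}

test_that("marker-to-gene distance is the interval gap, 0 on overlap", {
  g <- ann_world$genome
  genes <- mk_genes(g, "c1", c(51, 701), c(500, 900))
  # marker inside a gene
  expect_identical(distance_to_nearest_gene(mk_markers("c1", 101, 200), genes, g), 0)
  # marker touching the gene start: zero gap (but not an overlap)
  expect_identical(distance_to_nearest_gene(mk_markers("c1", 601, 700), genes, g), 0)
  # 0-based [100,200) vs nearest gene [700,900): gap of 500 bases
  m <- mk_markers("c1", 101, 200)
  genes2 <- mk_genes(g, "c1", 701, 900)
  expect_identical(distance_to_nearest_gene(m, genes2, g), 500)
  # chromosome without genes: Inf
  expect_identical(distance_to_nearest_gene(mk_markers("c2", 11, 20), genes, g), Inf)
})

test_that("distances match the all-pairs brute-force oracle", {
  set.seed(61)
  g <- ann_world$genome
  for (rep in 1:5) {
    ng <- sample(0:20, 1)
    gchrom <- sample(c("c1", "c2"), ng, replace = TRUE)
    gstart <- ifelse(gchrom == "c1", sample(45000, ng, TRUE), sample(18000, ng, TRUE))
    gend <- pmin(gstart + sample(50:2000, ng, TRUE),
                 ifelse(gchrom == "c1", 50000, 20000))
    genes <- mk_genes(g, gchrom, gstart, gend)
    nm <- 200
    mchrom <- sample(c("c1", "c2"), nm, replace = TRUE)
    mstart <- ifelse(mchrom == "c1", sample(49000, nm, TRUE), sample(19000, nm, TRUE))
    mend <- pmin(mstart + sample(40:440, nm, TRUE),
                 ifelse(mchrom == "c1", 50000, 20000))
    markers <- mk_markers(mchrom, mstart, mend)
    expect_equal(distance_to_nearest_gene(markers, genes, g),
                 oracle_min_distance(mchrom, mstart, mend, gchrom, gstart, gend))
  }
})

test_that("pct_markers_within handles the degenerate layouts", {
  g <- ann_world$genome
  genes <- mk_genes(g, "c1", 1, 50000)
  inside <- mk_markers(rep("c1", 5), seq(100, 500, 100), seq(150, 550, 100))
  expect_equal(unname(pct_markers_within(inside, genes, g)), c(100, 100, 100))
  nogenes <- as_gene_set(GenomicRanges::GRanges(), genome = g)
  expect_equal(unname(pct_markers_within(inside, nogenes, g)), c(0, 0, 0))
  expect_warning(p <- pct_markers_within(inside[0], genes, g))
  expect_true(all(is.na(p)))
})

test_that("percentage curves are cumulative and match oracle counting", {
  set.seed(67)
  g <- ann_world$genome
  genes <- mk_genes(g, rep("c1", 10), seq(1000, 46000, 5000),
                    seq(1000, 46000, 5000) + 800)
  m <- place_random_markers(g, 300, width = 60)
  th <- c(0, 1000, 10000, 100000)
  pm <- pct_markers_within(m, genes, g, th)
  pg <- pct_genes_with_marker_within(m, genes, g, th)
  expect_true(all(diff(pm) >= 0))
  expect_true(all(diff(pg) >= 0))
  # with a threshold beyond the longest chromosome every same-chromosome
  # marker/gene is within range; c2 has no genes here
  on_c1 <- sum(as.character(GenomicRanges::seqnames(m)) == "c1")
  expect_equal(unname(pm[4]), 100 * on_c1 / 300)
  expect_equal(unname(pg[4]), 100)
  # oracle cross-check at 1 kb
  d <- oracle_min_distance(as.character(GenomicRanges::seqnames(m)),
                           GenomicRanges::start(m), GenomicRanges::end(m),
                           rep("c1", 10), seq(1000, 46000, 5000),
                           seq(1000, 46000, 5000) + 800)
  expect_equal(unname(pm[2]), 100 * sum(d <= 1000) / 300)
})

test_that("random expectation is the union coverage of sequenced bases", {
  g <- read_genome(c(c1 = strrep("ACGT", 250)))   # 1000 bp, N-free
  genes <- mk_genes(g, "c1", 1, 590)
  expect_equal(expected_pct_markers_random(genes, g), 59)
  # overlapping genes: union semantics
  genes2 <- mk_genes(g, c("c1", "c1"), c(1, 1), c(590, 590))
  expect_equal(expected_pct_markers_random(genes2, g), 59)

  # with Ns: per-base classification oracle
  set.seed(71)
  seq <- random_dna(2000, n_prob = 0.05)
  g2 <- read_genome(c(c1 = seq))
  genes3 <- mk_genes(g2, rep("c1", 3), c(101, 501, 1501), c(300, 900, 1900))
  ch <- strsplit(seq, "")[[1]]
  in_gene <- rep(FALSE, 2000)
  in_gene[c(101:300, 501:900, 1501:1900)] <- TRUE
  seqd <- ch != "N"
  expect_equal(expected_pct_markers_random(genes3, g2),
               100 * sum(in_gene & seqd) / sum(seqd))
})

test_that("Poisson expectation follows the closed form", {
  g <- ann_world$genome
  genes <- mk_genes(g, c("c1", "c1"), c(1001, 5001), c(2000, 6000))
  # no overlaps: lambda 0, expectation 0
  po0 <- poisson_expected_pct_genes(mk_markers("c1", 30001, 30100), genes, g)
  expect_equal(po0$lambda, 0)
  expect_equal(po0$expected_pct, 0)
  # one marker in one of two genes: lambda = 0.5
  po <- poisson_expected_pct_genes(mk_markers("c1", 1101, 1200), genes, g)
  expect_equal(po$lambda, 0.5)
  expect_equal(po$expected_pct, 100 * (1 - exp(-0.5)))
})

test_that("gene-marker histogram sums and degenerates correctly", {
  g <- ann_world$genome
  genes <- mk_genes(g, rep("c1", 4), c(1, 1001, 2001, 3001), c(500, 1500, 2500, 3500))
  h0 <- gene_fragment_histogram(mk_markers(character(0), integer(0), integer(0)),
                                genes, g)
  expect_identical(h0$observed[h0$k == 0], 4L)
  m <- mk_markers(c("c1", "c1", "c1"), c(101, 201, 1101), c(150, 250, 1200))
  h <- gene_fragment_histogram(m, genes, g)
  expect_identical(sum(h$observed), 4L)
  expect_identical(h$observed, c(2L, 1L, 1L))   # genes with 0, 1, 2 markers
  expect_equal(h$poisson_pct, 100 * dpois(0:2, mean(c(2, 1, 0, 0))))
})

test_that("candidate subset equals the genome-wide summary when candidates = all", {
  set.seed(73)
  g <- ann_world$genome
  genes <- mk_genes(g, rep("c1", 8), seq(2001, 37001, 5000),
                    seq(2001, 37001, 5000) + 1200)
  m <- place_random_markers(g, 200, width = 80)
  whole <- distance_summary(m, genes, g)
  cand <- candidate_subset_summary(m, genes, g)
  expect_equal(cand$pct_markers_within[1:3], whole$pct_markers_within)
  expect_equal(cand$pct_genes_with_marker_within[1:3],
               whole$pct_genes_with_marker_within)
  expect_equal(cand$expected_pct_markers_at_0, whole$expected_pct_markers_at_0)
  expect_equal(cand$lambda, whole$lambda)
  expect_identical(cand$thresholds, c(0, 1000, 10000, 100000))
  expect_error(candidate_subset_summary(m, genes[0], g), "empty")
  # empty marker set: 0 observed everywhere, with a warning
  expect_warning(z <- candidate_subset_summary(m[0], genes, g))
  expect_true(all(is.na(z$pct_markers_within)))
  expect_equal(unname(z$pct_genes_with_marker_within), rep(0, 4))
})

test_that("nearest_gene_table reports IDs and distances", {
  g <- ann_world$genome
  genes <- mk_genes(g, "c1", 701, 900, ids = "target")
  tab <- nearest_gene_table(mk_markers(c("c1", "c2"), c(101, 11), c(200, 20)),
                            genes, g)
  expect_identical(tab$nearest_gene, c("target", NA))
  expect_equal(tab$distance, c(500, Inf))
})
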