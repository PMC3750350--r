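em_pair <- enzyme_pair("EcoRI", "MseI")

test_that("find_cut_sites handles the documented motifs", {
  # EcoRI's own motif: exactly one site, cut G^AATTC
  g <- make_genome(c1 = "TTTGAATTCTTT")
  s <- find_cut_sites(g, aflp_enzymes("EcoRI"))
  expect_identical(nrow(s), 1L)
  expect_identical(s$cut, 3L + 1L)   # motif starts at 0-based 3, offset 1

  # N never matches
  expect_identical(nrow(find_cut_sites(make_genome(c1 = "NNNNNN"),
                                       aflp_enzymes("EcoRI"))), 0L)

  # non-palindromic BsmI: forward GAATGC cut at its 3' boundary, reverse
  # occurrence GCATTC cut mirrored at its 5' boundary (hand-frozen)
  g2 <- make_genome(c1 = "TTTGAATGCTTTGCATTCTTT")
  s2 <- find_cut_sites(g2, aflp_enzymes("BsmI"))
  expect_identical(s2$cut, c(9L, 12L))
  expect_identical(s2$strand, c("+", "-"))
})

test_that("cut sites match the brute-force oracle on random sequence", {
  set.seed(31)
  cat <- oracle_enzyme_table()
  seqs <- stats::setNames(replicate(25, random_dna(2000, gc = runif(1, .3, .7),
                                                   n_prob = 0.01)),
                          paste0("s", 1:25))
  g <- read_genome(seqs)
  for (i in seq_len(nrow(cat))) {
    got <- find_cut_sites(g, enzyme(cat$name[i], cat$site[i], cat$offset[i]))
    for (cn in names(seqs)) {
      expect_identical(got$cut[got$chrom == cn],
                       oracle_cuts(seqs[[cn]], cat$site[i], cat$offset[i]),
                       label = paste(cat$name[i], cn))
    }
  }
})

test_that("double_digest produces the hand-computed fragment", {
  # one EcoRI site then one MseI site: exactly one rare-frequent fragment
  seq <- paste0("TTT", "GAATTC", strrep("C", 40), "TTAA", "GGG")
  g <- make_genome(c1 = seq)
  fr <- double_digest(g, em_pair)
  expect_identical(nrow(fr), 1L)
  # EcoRI cut 0-based 4, MseI cut 0-based 50 -> bases [5, 50], length 46
  expect_identical(fr$start, 5L)
  expect_identical(fr$end, 50L)
  expect_identical(fr$length, 46L)
  expect_identical(fr$left_enzyme, "EcoRI")
  expect_identical(fr$right_enzyme, "MseI")

  # only rare sites: no AFLP fragment
  g2 <- make_genome(c1 = paste0("T", "GAATTC", strrep("A", 30), "GAATTC", "T"))
  expect_identical(nrow(double_digest(g2, em_pair)), 0L)
})

test_that("double digestion matches the exhaustive oracle on random sequence", {
  set.seed(17)
  cat <- oracle_enzyme_table()
  pairs <- list(c("EcoRI", "MseI"), c("BsmI", "TaqI"), c("SacI", "HpaII"))
  seqs <- stats::setNames(replicate(20, random_dna(3000, gc = runif(1, .3, .7),
                                                   n_prob = 0.01)),
                          paste0("s", 1:20))
  g <- read_genome(seqs)
  for (p in pairs) {
    r <- cat[cat$name == p[1], ]; f <- cat[cat$name == p[2], ]
    got <- double_digest(g, enzyme_pair(p[1], p[2]))
    for (cn in names(seqs)) {
      want <- oracle_aflp_fragments(seqs[[cn]], r$site, r$offset, f$site, f$offset)
      have <- got[got$chrom == cn]
      expect_identical(have$start, want$start, label = paste(p[1], cn))
      expect_identical(have$end, want$end, label = paste(p[1], cn))
    }
  }
})

test_that("fragments tile the cut span exactly (partition invariant)", {
  set.seed(23)
  for (rep in 1:10) {
    seq <- random_dna(5000, gc = runif(1, .35, .65))
    full <- oracle_all_fragments(seq, "GAATTC", 1L, "TTAA", 1L)
    if (nrow(full) < 2) next
    # no gaps, no overlaps between the first and last cut
    expect_identical(full$start[-1], full$end[-nrow(full)] + 1L)
    expect_identical(sum(full$length),
                     full$end[nrow(full)] - full$start[1] + 1L)
    # the package's AFLP set is exactly the typed subset of the tiling
    g <- read_genome(c(c1 = seq))
    got <- double_digest(g, em_pair)
    want <- full[(full$left_rare & full$right_freq) |
                 (full$left_freq & full$right_rare), ]
    expect_identical(got$start, want$start)
  }
})

test_that("size selection is an inclusive, idempotent filter", {
  fr <- data.table::data.table(chrom = "c1", start = 1L,
                               end = c(39L, 40L, 440L, 441L),
                               length = c(39L, 40L, 440L, 441L))
  kept <- size_select(fr)
  expect_identical(kept$length, c(40L, 440L))
  expect_identical(nrow(size_select(fr[0])), 0L)
  expect_error(size_select(fr, 100, 50))

  set.seed(5)
  lens <- sample(1:1000, 1000, replace = TRUE)
  fr2 <- data.table::data.table(chrom = "c1", start = 1L, end = lens, length = lens)
  expect_identical(size_select(fr2, 40, 440)$length, lens[lens >= 40 & lens <= 440])
  expect_identical(size_select(size_select(fr2, 40, 440), 40, 440),
                   size_select(fr2, 40, 440))
})

test_that("pcr_length maps the size-selection window to PCR products", {
  expect_identical(pcr_length(40L), 72L)
  expect_identical(pcr_length(440L), 472L)
  expect_identical(pcr_length(100L), 132L)   # same affine map
  expect_error(pcr_length(0))
})

test_that("selective nucleotides read interior bases, right end complemented", {
  # TT GAATTC G AAAA C TTAA TT: fragment [4,15], interior left G (pos 9),
  # interior right C (pos 14) read as complement G
  g <- make_genome(c1 = "TTGAATTCGAAAACTTAATT")
  fr <- double_digest(g, em_pair)
  expect_identical(nrow(fr), 1L)
  expect_identical(fr$left_inner, 9L)
  expect_identical(fr$right_inner, 14L)

  gc_pair <- enzyme_pair("EcoRI", "MseI",
                         selective_rare = c("G", "C"),
                         selective_frequent = c("G", "C"))
  expect_identical(nrow(apply_selective(fr, gc_pair, g)), 1L)
  a_pair <- enzyme_pair("EcoRI", "MseI", selective_rare = "A",
                        selective_frequent = c("G", "C"))
  expect_identical(nrow(apply_selective(fr, a_pair, g)), 0L)

  # full allowed sets are vacuous: identity
  full <- enzyme_pair("EcoRI", "MseI",
                      selective_rare = c("A", "C", "G", "T"),
                      selective_frequent = c("A", "C", "G", "T"))
  expect_identical(apply_selective(fr, full, g), fr)
})

test_that("selective filtering is monotone in the allowed sets", {
  set.seed(12)
  g <- read_genome(c(c1 = random_dna(100000, gc = 0.45)))
  fr <- size_select(double_digest(g, em_pair))
  sel <- function(r, f) apply_selective(fr, enzyme_pair("EcoRI", "MseI",
                                                        selective_rare = r,
                                                        selective_frequent = f), g)
  n_gc <- nrow(sel(c("G", "C"), c("G", "C")))
  n_g <- nrow(sel("G", c("G", "C")))
  expect_lte(n_g, n_gc)
  expect_lte(n_gc, nrow(fr))
  # the survivors of the narrower set are a subset of the wider set's
  expect_true(all(sel("G", c("G", "C"))$start %in% sel(c("G", "C"), c("G", "C"))$start))
})

test_that("band collapse groups by sequence, not length", {
  # two fragments of the same length but different sequence: 2 bands
  seq1 <- paste0("T", "GAATTC", strrep("A", 40), "TTAA",
                 strrep("C", 20), "GAATTC", strrep("T", 39), "A", "TTAA", "G")
  g <- make_genome(c1 = seq1)
  fr <- double_digest(g, em_pair)
  f46 <- fr[fr$length == 46L]
  expect_identical(nrow(f46), 2L)   # same length, different sequences
  expect_false(fragment_sequences(f46, g)[1] == fragment_sequences(f46, g)[2])
  bd <- collapse_bands(fr, g)
  expect_identical(nrow(bd), nrow(fr))   # all distinct: no collapse

  # band count equals the number of distinct sequences (hash oracle)
  set.seed(19)
  g2 <- read_genome(c(c1 = random_dna(200000, gc = 0.5)))
  fr2 <- size_select(double_digest(g2, em_pair))
  bd2 <- collapse_bands(fr2, g2)
  expect_identical(nrow(bd2), length(unique(fragment_sequences(fr2, g2))))
  expect_identical(sum(bd2$multiplicity), nrow(fr2))
  expect_lte(nrow(bd2), nrow(fr2))
  # length-class collapse is the optional alternative
  bd_len <- collapse_bands(fr2, g2, by = "length")
  expect_identical(nrow(bd_len), length(unique(fr2$length)))
})

test_that("a tandem repeat array collapses to one band", {
  # 50 copies of a unit yielding one 104-bp fragment each (the classic
  # centromeric scenario); junction fragments fall below size selection
  pr <- em_pair
  cfg <- synthetic_genome_config(
    chrom_lengths = c(chr1 = 60000L), n_genes = 0,
    centromeres = list(list(chrom = "chr1", position = 20001L,
                            unit_length = 141L, copies = 50L, unit_gc = 0.6,
                            pair = pr, fragment_length = 104L)))
  res <- generate_genome(cfg, seed = 401)
  fr <- size_select(double_digest(res$genome, pr))
  rep_fr <- fr[fr$length == 104L &
               fr$start %in% res$truth$centromeres[[1]]$fragment_starts]
  expect_identical(nrow(rep_fr), 50L)
  bd <- collapse_bands(fr, res$genome)
  b104 <- bd[bd$length == 104L & bd$multiplicity >= 50L]
  expect_identical(nrow(b104), 1L)
  expect_gte(b104$multiplicity, 50L)
})

test_that("reverse-complementing a chromosome preserves the physical fragments", {
  # the same double-stranded molecules are produced from either strand; the
  # strand-invariant quantity is the site-to-site span (fragment plus both
  # recognition remnants) — cut-to-cut lengths shift by the cut-offset
  # asymmetry when the fragment's orientation flips
  canon <- function(fr, p) {
    enz <- list(p$rare, p$frequent)
    names(enz) <- c(p$rare$name, p$frequent$name)
    lo <- vapply(fr$left_enzyme, function(e) enz[[e]]$cut_offset, integer(1),
                 USE.NAMES = FALSE)
    rr <- vapply(fr$right_enzyme, function(e)
      nchar(enz[[e]]$site) - enz[[e]]$cut_offset, integer(1),
      USE.NAMES = FALSE)
    sort(fr$length + lo + rr)
  }
  set.seed(29)
  for (p in list(em_pair, enzyme_pair("SacI", "HpaII"))) {
    seq <- random_dna(30000, gc = 0.5)
    g_f <- read_genome(c(c1 = seq))
    g_r <- read_genome(c(c1 = rc_chr(seq)))
    f_f <- double_digest(g_f, p)
    f_r <- double_digest(g_r, p)
    expect_identical(nrow(f_f), nrow(f_r))
    expect_identical(canon(f_f, p), canon(f_r, p))
  }
})

test_that("pair_gc_fraction reproduces the catalogue values", {
  expect_equal(pair_gc_fraction(enzyme_pair("EcoRI", "MseI")), 0.2)
  expect_equal(pair_gc_fraction(enzyme_pair("BsmI", "TaqI")), 0.5)
  expect_equal(pair_gc_fraction(enzyme_pair("SacI", "HpaII")), 0.8)
})

test_that("enzyme config files round-trip the catalogue", {
  tf <- tempfile()
  writeLines(c("# name site offset", "EcoRI GAATTC 1", "MseI TTAA 1"), tf)
  cat <- read_enzyme_config(tf)
  expect_identical(names(cat), c("EcoRI", "MseI"))
  expect_identical(cat$EcoRI$site, "GAATTC")
  expect_true(cat$EcoRI$palindromic)
  expect_error(enzyme("Bad", "GAXTTC", 1))
  expect_error(enzyme("Bad", "GAATTC", 7))
})
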