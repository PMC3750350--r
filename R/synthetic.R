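#' Configuration for the synthetic genome generator
#'
#' Describes an annotated genome with the statistical structure the AFLP
#' analyses assume: higher GC in genic than intergenic sequence, gene
#' lengths drawn from a log-normal distribution, optional pericentromeric
#' tandem repeat arrays whose unit yields one AFLP fragment per copy,
#' optional N runs, and optional planted AFLP cassettes at explicit
#' positions for deterministic tests.
#'
#' Defaults emulate a small Arabidopsis-like genome: genic GC 0.393 vs
#' intergenic 0.313, mean (SD) gene length 2.1 (1.6) kb, roughly 280 genes
#' per Mb.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param n_genes total gene count; default ~280 genes/Mb.
#' @param gene_len_mean,gene_len_sd target mean and SD of gene length in bp
#'   (log-normal; \code{gene_len_sd = 0} gives constant lengths).
#' @param genic_gc,intergenic_gc GC fractions of genic / intergenic bases.
#' @param centromeres optional list of centromere specs, each a list with
#'   \code{chrom}, \code{position} (1-based start), \code{unit_length},
#'   \code{copies}, \code{unit_gc}, and — to make each copy yield one AFLP
#'   fragment — \code{pair} (an \code{\link{enzyme_pair}}) and
#'   \code{fragment_length} (cut-to-cut bp, must be < unit_length).
#' @param n_runs optional list \code{list(count =, length =)} of N runs to
#'   plant per genome (fixed length, random non-genic positions).
#' @param planted optional planted-cassette spec for deterministic tests: a
#'   list with \code{pair}, \code{fragment_length} and \code{positions}, a
#'   data.frame of \code{chrom}, \code{start}; each cassette is
#'   rare-site + scrubbed filler + frequent-site yielding exactly one AFLP
#'   fragment of the given length.
#' @param scrub optional \code{\link{enzyme_pair}}: every accidental
#'   occurrence of either recognition site (both strands) outside planted
#'   cassettes/repeat units is mutated away, so cut-site positions are
#'   exactly the planted truth.
#' @return object of class \code{aflp_syn_config}.
#' @export
synthetic_genome_config <- function(chrom_lengths = c(chr1 = 2000000L, chr2 = 1000000L),
                                    n_genes = NULL,
                                    gene_len_mean = 2100, gene_len_sd = 1600,
                                    genic_gc = 0.393, intergenic_gc = 0.313,
                                    centromeres = NULL, n_runs = NULL,
                                    planted = NULL, scrub = NULL) {
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  chrom_lengths <- stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
  stopifnot(all(chrom_lengths >= 1L),
            genic_gc >= 0, genic_gc <= 1,
            intergenic_gc >= 0, intergenic_gc <= 1,
            gene_len_mean > 0, gene_len_sd >= 0)
  if (is.null(n_genes))
    n_genes <- as.integer(round(sum(as.numeric(chrom_lengths)) * 280e-6))
  for (cm in centromeres) {
    stopifnot(cm$chrom %in% names(chrom_lengths),
              cm$unit_length >= 8L, cm$copies >= 1L)
    if (cm$position + cm$unit_length * cm$copies - 1L > chrom_lengths[[cm$chrom]])
      stop("centromere array does not fit on ", cm$chrom)
    if (!is.null(cm$pair) && cm$fragment_length >= cm$unit_length)
      stop("unit fragment length must be smaller than the unit length")
  }
  structure(list(chrom_lengths = chrom_lengths, n_genes = n_genes,
                 gene_len_mean = gene_len_mean, gene_len_sd = gene_len_sd,
                 genic_gc = genic_gc, intergenic_gc = intergenic_gc,
                 centromeres = centromeres, n_runs = n_runs,
                 planted = planted, scrub = scrub),
            class = "aflp_syn_config")
}

#' Generate a synthetic annotated genome
#'
#' Deterministic for a fixed seed. Intergenic bases are drawn i.i.d. at the
#' intergenic GC, genic bases at the genic GC; centromeres are exact tandem
#' copies of a repeat unit (with one rare and one frequent cut site spaced
#' to yield one AFLP fragment per copy when a pair is flagged); planted
#' cassettes and N runs are written afterwards; a post-write scan removes
#' accidental site creations inside flagged repeat units, planted cassettes
#' and (when \code{scrub} is set) the whole genome, so planted copy numbers
#' are exact.
#'
#' @param config an \code{\link{synthetic_genome_config}}.
#' @param seed integer seed.
#' @return list with \code{genome} (\code{aflp_genome}), \code{genes}
#'   (gene set \code{GRanges}) and \code{truth}: every planted quantity
#'   (gene intervals, per-centromere repeat fragment starts/length/copies,
#'   planted cassette fragment coordinates, N-run intervals).
#' @export
generate_genome <- function(config, seed = 1L) {
  stopifnot(inherits(config, "aflp_syn_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  lens <- config$chrom_lengths
  bases <- c("A", "C", "G", "T")
  probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

  chrs <- lapply(lens, function(n) sample(bases, n, replace = TRUE,
                                          prob = probs(config$intergenic_gc)))

  # reserved intervals per chromosome (centromere arrays + planted cassettes)
  reserved <- lapply(lens, function(n) IRanges::IRanges())
  note_reserved <- function(cn, s, e) {
    reserved[[cn]] <<- c(reserved[[cn]], IRanges::IRanges(s, e))
  }
  for (cm in config$centromeres)
    note_reserved(cm$chrom, cm$position,
                  cm$position + cm$unit_length * cm$copies - 1L)
  cassette_specs <- list()
  if (!is.null(config$planted)) {
    pl <- config$planted
    for (i in seq_len(nrow(pl$positions))) {
      # independent filler per cassette: planted fragments are identical in
      # length but distinct in sequence, so they stay separate bands
      cas <- build_cassette(pl$pair, pl$fragment_length, config$intergenic_gc)
      cn <- pl$positions$chrom[i]; s <- pl$positions$start[i]
      e <- s + length(cas$seq) - 1L
      if (e > lens[[cn]]) stop("planted cassette beyond chromosome end")
      note_reserved(cn, s, e)
      cassette_specs[[length(cassette_specs) + 1L]] <-
        list(chrom = cn, start = s, cassette = cas)
    }
  }

  # gene placement: lengths log-normal, uniform non-overlapping placement by
  # rejection, avoiding reserved intervals
  widths <- gene_lengths(config$n_genes, config$gene_len_mean, config$gene_len_sd)
  gene_chrom <- sample(names(lens), config$n_genes, replace = TRUE,
                       prob = as.numeric(lens) / sum(as.numeric(lens)))
  gene_rows <- rbindlist(lapply(names(lens), function(cn) {
    w <- widths[gene_chrom == cn]
    if (!length(w)) return(NULL)
    pl <- place_intervals(lens[[cn]], w, reserved[[cn]])
    data.table(chrom = cn, start = pl, width = w)
  }))
  genes <- if (nrow(gene_rows))
    GRanges(gene_rows$chrom,
            IRanges::IRanges(gene_rows$start, width = gene_rows$width))
  else GRanges()
  if (length(genes)) {
    genes$gene_id <- sprintf("SYNG%05d", seq_len(length(genes)))
    for (i in seq_len(length(genes))) {
      cn <- as.character(seqnames(genes)[i])
      idx <- start(genes)[i]:end(genes)[i]
      chrs[[cn]][idx] <- sample(bases, length(idx), replace = TRUE,
                                prob = probs(config$genic_gc))
    }
  }

  truth <- list(genes = genes, centromeres = list(), planted = NULL,
                n_runs = list())

  # motifs that must occur only where planted; immutable spans protect the
  # planted recognition occurrences from the scrubber
  allowed <- list()   # per motif string: integer vector of allowed starts per chrom
  immutable <- lapply(lens, function(n) IRanges::IRanges())
  add_allowed <- function(cn, motif, s) {
    key <- paste0(cn, "\r", motif)
    allowed[[key]] <<- c(allowed[[key]], s)
    immutable[[cn]] <<- c(immutable[[cn]],
                          IRanges::IRanges(s, s + nchar(motif) - 1L))
  }

  # centromere arrays
  for (cm in config$centromeres) {
    cn <- cm$chrom
    unit <- if (!is.null(cm$pair)) {
      cas <- build_cassette(cm$pair, cm$fragment_length,
                            if (is.null(cm$unit_gc)) 0.6 else cm$unit_gc,
                            total_length = cm$unit_length)
      cas
    } else {
      list(seq = sample(bases, cm$unit_length, replace = TRUE,
                        prob = probs(if (is.null(cm$unit_gc)) 0.6 else cm$unit_gc)),
           rare_motif_at = NA, freq_motif_at = NA)
    }
    arr_start <- cm$position
    for (k in seq_len(cm$copies)) {
      s <- arr_start + (k - 1L) * cm$unit_length
      chrs[[cn]][s:(s + cm$unit_length - 1L)] <- unit$seq
      if (!is.null(cm$pair)) {
        add_allowed(cn, cm$pair$rare$site, s + unit$rare_motif_at - 1L)
        add_allowed(cn, cm$pair$frequent$site, s + unit$freq_motif_at - 1L)
      }
    }
    frag_starts <- if (!is.null(cm$pair)) {
      cutR <- (arr_start - 1L) + (seq_len(cm$copies) - 1L) * cm$unit_length +
        unit$rare_cut
      cutR + 1L
    } else integer(0)
    truth$centromeres[[length(truth$centromeres) + 1L]] <- list(
      chrom = cn, start = arr_start,
      end = arr_start + cm$unit_length * cm$copies - 1L,
      unit_length = cm$unit_length, copies = cm$copies,
      fragment_length = if (!is.null(cm$pair)) cm$fragment_length else NA,
      fragment_starts = frag_starts)
  }

  # planted cassettes
  if (length(cassette_specs)) {
    pf <- lapply(cassette_specs, function(sp) {
      cn <- sp$chrom; s <- sp$start; cas <- sp$cassette
      chrs[[cn]][s:(s + length(cas$seq) - 1L)] <<- cas$seq
      add_allowed(cn, config$planted$pair$rare$site, s + cas$rare_motif_at - 1L)
      add_allowed(cn, config$planted$pair$frequent$site, s + cas$freq_motif_at - 1L)
      # global rare cut point (0-based) = (s - 1) + rel cut; the fragment's
      # first base is the next one
      data.frame(chrom = cn, start = s + cas$rare_cut,
                 end = s + cas$rare_cut + config$planted$fragment_length - 1L)
    })
    truth$planted <- do.call(rbind, pf)
    truth$planted$length <- config$planted$fragment_length
  }

  # scrub accidental occurrences so planted sites are the only ones: always
  # around planted/centromeric material for the flagged pair; genome-wide
  # when config$scrub is set
  scrub_pairs <- list()
  if (!is.null(config$scrub)) scrub_pairs <- c(scrub_pairs, list(config$scrub))
  if (!is.null(config$planted) && is.null(config$scrub))
    scrub_pairs <- c(scrub_pairs, list(config$planted$pair))
  for (cm in config$centromeres)
    if (!is.null(cm$pair) && is.null(config$scrub)) {
      # protect the array and its flanks only
      scrub_pairs <- c(scrub_pairs, list(structure(cm$pair, scope = list(
        chrom = cm$chrom,
        from = max(1L, cm$position - 2L * cm$unit_length),
        to = min(lens[[cm$chrom]],
                 cm$position + cm$unit_length * (cm$copies + 2L))))))
    }
  # collect one task per (chromosome, motif, window), then scrub all motifs
  # of a chromosome jointly: fixing one motif can create another, so the
  # loop has to be global per chromosome
  tasks <- lapply(lens, function(x) list())
  for (sp in scrub_pairs) {
    scope <- attr(sp, "scope")
    for (enz in list(sp$rare, sp$frequent)) {
      motifs <- unique(c(enz$site, revcomp_chr(enz$site)))
      for (cn in names(lens)) {
        if (!is.null(scope) && scope$chrom != cn) next
        win <- if (is.null(scope)) c(1L, lens[[cn]]) else c(scope$from, scope$to)
        for (m in motifs) {
          key <- paste0(cn, "\r", m)
          tasks[[cn]][[length(tasks[[cn]]) + 1L]] <-
            list(motif = m, allowed = allowed[[key]], win = win)
        }
      }
    }
  }
  for (cn in names(lens))
    if (length(tasks[[cn]]))
      chrs[[cn]] <- scrub_all(chrs[[cn]], tasks[[cn]], immutable[[cn]])

  # N runs (avoid genes and reserved material)
  if (!is.null(config$n_runs) && config$n_runs$count > 0L) {
    avoid <- reserved
    for (cn in names(lens)) {
      gi <- IRanges::ranges(genes[seqnames(genes) == cn])
      avoid[[cn]] <- IRanges::reduce(c(avoid[[cn]], gi))
    }
    run_chrom <- sample(names(lens), config$n_runs$count, replace = TRUE,
                        prob = as.numeric(lens) / sum(as.numeric(lens)))
    for (cn in unique(run_chrom)) {
      k <- sum(run_chrom == cn)
      s <- place_intervals(lens[[cn]], rep(config$n_runs$length, k), avoid[[cn]])
      for (x in s) {
        chrs[[cn]][x:(x + config$n_runs$length - 1L)] <- "N"
        truth$n_runs[[length(truth$n_runs) + 1L]] <-
          list(chrom = cn, start = x, end = x + config$n_runs$length - 1L)
      }
    }
  }

  seqs <- Biostrings::DNAStringSet(vapply(chrs, paste, "", collapse = ""))
  names(seqs) <- names(lens)
  genome <- structure(list(
    seqs = seqs,
    n_runs = stats::setNames(lapply(seqs, n_run_ranges), names(lens))
  ), class = "aflp_genome")
  genes <- as_gene_set(genes, genome = genome)
  list(genome = genome, genes = genes, truth = truth, config = config)
}

# log-normal gene lengths with target arithmetic mean/SD (in bp)
gene_lengths <- function(n, mean, sd) {
  if (!n) return(integer(0))
  if (sd == 0) return(rep(as.integer(round(mean)), n))
  sdlog2 <- log(1 + (sd / mean)^2)
  w <- stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
  pmax(1L, as.integer(round(w)))
}

# uniform non-overlapping placement by rejection sampling; errors out when
# the density is infeasible
place_intervals <- function(chrom_len, widths, reserved,
                            max_attempts = 1000L) {
  if (!length(widths)) return(integer(0))
  if (sum(as.numeric(widths)) + sum(as.numeric(width(reserved))) >
      0.98 * chrom_len)
    stop("infeasible placement: features exceed chromosome capacity")
  occupied <- IRanges::reduce(reserved)
  out <- integer(length(widths))
  ord <- order(widths, decreasing = TRUE)   # big intervals first
  for (j in ord) {
    w <- widths[j]
    if (w > chrom_len) stop("infeasible placement: feature longer than chromosome")
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      s <- sample.int(chrom_len - w + 1L, 1L)
      cand <- IRanges::IRanges(s, s + w - 1L)
      if (!IRanges::overlapsAny(cand, occupied)) {
        occupied <- c(occupied, cand)
        out[j] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("infeasible placement: rejection sampling exhausted")
  }
  out
}

# a cassette yielding exactly one AFLP fragment of `fragment_length` between
# the rare and the frequent cut: [pad][rare site][filler][frequent site][pad].
# Returned relative coordinates are 1-based within the cassette; rare_cut is
# the 0-based cut point relative to the cassette start.
build_cassette <- function(pair, fragment_length, gc, total_length = NULL) {
  r <- pair$rare; f <- pair$frequent
  lr <- nchar(r$site); lf <- nchar(f$site)
  fill <- fragment_length - (lr - r$cut_offset) - f$cut_offset
  if (fill < 0)
    stop("fragment_length too short for the recognition remnants of the pair")
  core_len <- lr + fill + lf
  pad_left <- 2L
  if (is.null(total_length)) total_length <- core_len + 2L * pad_left
  if (total_length < core_len + pad_left)
    stop("unit too short for its cassette")
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seq <- sample(bases, total_length, replace = TRUE, prob = probs)
  rare_at <- pad_left + 1L
  freq_at <- rare_at + lr + fill
  seq[rare_at:(rare_at + lr - 1L)] <- strsplit(r$site, "")[[1L]]
  seq[freq_at:(freq_at + lf - 1L)] <- strsplit(f$site, "")[[1L]]
  immutable <- IRanges::IRanges(c(rare_at, freq_at), width = c(lr, lf))
  # remove accidental occurrences inside the cassette *and* across a tandem
  # junction of two copies
  for (enz in list(r, f)) for (m in unique(c(enz$site, revcomp_chr(enz$site)))) {
    for (it in 1:25) {
      dbl <- c(seq, seq)
      hits <- match_positions(dbl, m)
      hits <- hits[hits <= total_length]   # each junction hit appears in copy 1
      exp_at <- c(if (m == r$site) rare_at, if (m == f$site) freq_at)
      bad <- setdiff(hits, exp_at)
      if (!length(bad)) break
      for (s in bad) {
        span <- s:(min(s + nchar(m) - 1L, total_length))
        mut <- setdiff(span, unlist(lapply(seq_len(length(immutable)), function(i)
          start(immutable)[i]:end(immutable)[i])))
        if (!length(mut)) stop("cannot scrub cassette without touching a planted site")
        p <- sample(mut, 1L)
        seq[p] <- sample(setdiff(bases, seq[p]), 1L)
      }
    }
  }
  list(seq = seq, rare_motif_at = rare_at, freq_motif_at = freq_at,
       rare_cut = rare_at - 1L + r$cut_offset)
}

# positions (1-based starts) of a motif in a character-per-base vector
match_positions <- function(ch, motif) {
  m <- strsplit(motif, "")[[1L]]
  L <- length(m); n <- length(ch)
  if (n < L) return(integer(0))
  ok <- ch[seq_len(n - L + 1L)] == m[1L]
  if (L > 1L) for (k in 2:L) ok <- ok & ch[k:(n - L + k)] == m[k]
  which(ok)
}

# mutate away every occurrence of every task motif inside its window whose
# start is not in that task's allowed set, never touching `immutable`
# positions; loops over all motifs jointly until no occurrence remains
# (mutating one motif away can create another)
scrub_all <- function(ch, tasks, immutable, max_iter = 40L) {
  bases <- c("A", "C", "G", "T")
  imm <- sort(unique(unlist(lapply(seq_len(length(immutable)), function(i)
    start(immutable)[i]:end(immutable)[i]))))
  for (it in seq_len(max_iter)) {
    dirty <- FALSE
    for (tk in tasks) {
      L <- nchar(tk$motif)
      seg <- ch[tk$win[1L]:tk$win[2L]]
      hits <- match_positions(seg, tk$motif) + tk$win[1L] - 1L
      bad <- setdiff(hits, tk$allowed)
      if (!length(bad)) next
      dirty <- TRUE
      for (s in bad) {
        span <- setdiff(s:(s + L - 1L), imm)
        if (!length(span)) next
        p <- span[ceiling(length(span) / 2)]
        ch[p] <- sample(setdiff(bases, ch[p]), 1L)
      }
    }
    if (!dirty) return(ch)
  }
  warning("site scrubbing did not fully converge")
  ch
}

#' Uniformly placed random markers
#'
#' Places n marker intervals uniformly on the genome (chromosome chosen
#' proportionally to its length, start uniform). Used to test the
#' random-placement expectations.
#'
#' @param genome an \code{aflp_genome}.
#' @param n marker count.
#' @param width marker width in bp (default 1).
#' @return an unstranded \code{GRanges}.
#' @export
place_random_markers <- function(genome, n, width = 1L) {
  lens <- chrom_lengths(genome)
  avail <- stats::setNames(pmax(0L, lens - width + 1L), names(lens))
  cn <- sample(names(lens), n, replace = TRUE, prob = avail / sum(avail))
  s <- vapply(cn, function(x) sample.int(avail[[x]], 1L), integer(1))
  markers_as_granges(GRanges(cn, IRanges::IRanges(s, width = width)), genome)
}

#' Synthetic cross-species marker panel
#'
#' Marker counts on a straight line through the origin (density x genome
#' size) plus multiplicative Gaussian noise, used to test parameter
#' recovery of the density regression.
#'
#' @param genome_sizes_mb genome sizes in Mb (>= 3 values).
#' @param density_per_mb true marker density (markers/Mb).
#' @param noise_frac SD of the multiplicative noise (0 = exact line).
#' @param labels optional species labels.
#' @return \code{data.frame} with \code{label}, \code{size_mb},
#'   \code{markers}.
#' @export
generate_species_panel <- function(genome_sizes_mb, density_per_mb = 152,
                                   noise_frac = 0.02, labels = NULL) {
  stopifnot(length(genome_sizes_mb) >= 3L, density_per_mb > 0, noise_frac >= 0)
  if (is.null(labels)) labels <- paste0("sp", seq_along(genome_sizes_mb))
  mu <- density_per_mb * genome_sizes_mb
  counts <- round(mu * (1 + stats::rnorm(length(mu), 0, noise_frac)))
  data.frame(label = labels, size_mb = genome_sizes_mb,
             markers = pmax(0, counts))
}

#' Generate a synthetic genome and write it to standard files
#'
#' Emits \code{genome.fa}, \code{genes.gff3} and \code{truth.tsv} under
#' \code{dir}.
#'
#' @param config an \code{\link{synthetic_genome_config}}.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return the \code{\link{generate_genome}} result, invisibly, with
#'   \code{$paths} added.
#' @export
generate_to_dir <- function(config, seed, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res <- generate_genome(config, seed)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "genes.gff3")
  tru <- file.path(dir, "truth.tsv")
  write_genome_fasta(res$genome, fa)
  write_genes_gff3(res$genes, gff)
  rows <- data.frame(kind = "gene",
                     chrom = as.character(seqnames(res$truth$genes)),
                     start = start(res$truth$genes),
                     end = end(res$truth$genes),
                     id = res$truth$genes$gene_id)
  for (cm in res$truth$centromeres)
    rows <- rbind(rows, data.frame(kind = "centromere_fragment",
                                   chrom = cm$chrom, start = cm$fragment_starts,
                                   end = cm$fragment_starts + cm$fragment_length - 1L,
                                   id = sprintf("rep_u%d_x%d", cm$unit_length,
                                                cm$copies)))
  if (!is.null(res$truth$planted))
    rows <- rbind(rows, data.frame(kind = "planted_fragment",
                                   chrom = res$truth$planted$chrom,
                                   start = res$truth$planted$start,
                                   end = res$truth$planted$end,
                                   id = "cassette"))
  utils::write.table(rows, tru, sep = "\t", quote = FALSE, row.names = FALSE)
  res$paths <- c(fasta = fa, gff3 = gff, truth = tru)
  invisible(res)
}
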