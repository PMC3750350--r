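#' Read a genome from FASTA
#'
#' Reads a multi-record FASTA (one record per chromosome, wrapped lines
#' allowed), uppercases the sequences, validates the alphabet (ACGT plus
#' IUPAC ambiguity codes) and indexes runs of N as un-sequenced intervals.
#'
#' @param fasta_source path to a FASTA file, or a named character vector of
#'   sequences (useful in tests).
#' @return an object of class \code{aflp_genome}: a list with
#'   \itemize{
#'     \item \code{seqs}: a \code{DNAStringSet}, record order preserved;
#'     \item \code{n_runs}: per-chromosome \code{IRanges} of maximal N runs
#'       (1-based, closed).
#'   }
#' @examples
#' g <- read_genome(c(c1 = "ACGTNNNACGT"))
#' sequenced_length(g)
#' @export
read_genome <- function(fasta_source) {
  if (is.character(fasta_source) && length(fasta_source) == 1L &&
      !grepl("[>\n]", fasta_source) && file.exists(fasta_source)) {
    seqs <- Biostrings::readDNAStringSet(fasta_source)
    if (!length(seqs)) stop("empty FASTA: ", fasta_source)
    # FASTA description lines may carry comments after the record name
    names(seqs) <- sub("[ \t].*$", "", names(seqs))
  } else {
    if (!is.character(fasta_source) || is.null(names(fasta_source)))
      stop("fasta_source must be a file path or a named character vector")
    seqs <- Biostrings::DNAStringSet(toupper(fasta_source))
  }
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every chromosome must have a non-empty name")
  if (anyDuplicated(nm))
    stop("duplicate chromosome names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(width(seqs) == 0L))
    stop("empty sequence for record(s): ",
         paste(nm[width(seqs) == 0L], collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  # DNAStringSet construction already rejects non-IUPAC characters, but give
  # a named error for anything outside the IUPAC set that slipped through as
  # '-' or '+' gap codes.
  bad <- vapply(seq_along(seqs), function(i) {
    lf <- Biostrings::letterFrequency(seqs[[i]], letters = "ACGTRYSWKMBDHVN")
    sum(lf) != length(seqs[[i]])
  }, logical(1))
  if (any(bad))
    stop("non-IUPAC nucleotide characters in record(s): ",
         paste(nm[bad], collapse = ", "))
  n_runs <- lapply(seq_along(seqs), function(i) n_run_ranges(seqs[[i]]))
  names(n_runs) <- nm
  structure(list(seqs = seqs, n_runs = n_runs), class = "aflp_genome")
}

# maximal runs of N in one DNAString, as an IRanges (1-based closed)
n_run_ranges <- function(seq) {
  m <- Biostrings::matchPattern("N", seq, fixed = TRUE)
  IRanges::reduce(IRanges::IRanges(start(m), end(m)))
}

#' @export
print.aflp_genome <- function(x, ...) {
  cat(sprintf("<genome> %d chromosome(s), %s bp (%.3f%% un-sequenced)\n",
              length(x$seqs), format(sum(chrom_lengths(x)), big.mark = ","),
              unsequenced_percentage(x)))
  invisible(x)
}

#' Chromosome names and lengths of a genome
#' @param genome an \code{aflp_genome}.
#' @return named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "aflp_genome"))
  stats::setNames(width(genome$seqs), names(genome$seqs))
}

#' Sequenced length per chromosome
#'
#' Chromosome length minus the total length of its N runs.
#'
#' @param genome an \code{aflp_genome}.
#' @param chrom optional chromosome name(s); default all.
#' @return named integer vector of sequenced lengths in bp.
#' @export
sequenced_length <- function(genome, chrom = NULL) {
  len <- chrom_lengths(genome)
  if (is.null(chrom)) chrom <- names(len)
  stopifnot(all(chrom %in% names(len)))
  nlen <- vapply(genome$n_runs[chrom], function(r) sum(width(r)), integer(1))
  len[chrom] - nlen
}

#' Percentage of un-sequenced (N) nucleotides
#'
#' @param genome an \code{aflp_genome}.
#' @return percentage in \code{[0, 100]}.
#' @export
unsequenced_percentage <- function(genome) {
  len <- sum(chrom_lengths(genome))
  100 * (len - sum(sequenced_length(genome))) / len
}

#' Read gene annotations into a gene set
#'
#' Reads gene intervals from GFF3 (features with type \code{gene};
#' 1-based inclusive coordinates, native) or BED (0-based half-open,
#' converted on read). Gene IDs come from the GFF3 \code{ID=} attribute or
#' the BED name column; absent IDs are auto-numbered \code{gene_<k>}.
#'
#' @param annotation_source file path.
#' @param format \code{"gff3"} or \code{"bed"}; default guessed from the
#'   file extension.
#' @param genome optional \code{aflp_genome} used to validate coordinates.
#'   Genes on chromosomes absent from the genome are dropped with a warning
#'   and recorded in \code{metadata()$unplaced_ids}; a gene extending
#'   beyond its chromosome is an error.
#' @return a \code{GRanges} with a \code{gene_id} metadata column; gene IDs
#'   are unique.
#' @export
read_genes <- function(annotation_source, format = NULL, genome = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(annotation_source))
    format <- switch(ext, gff = , gff3 = "gff3", bed = "bed",
                     stop("cannot guess annotation format from extension: ", ext))
  }
  format <- match.arg(format, c("gff3", "bed"))
  gr <- switch(format,
    gff3 = {
      g <- rtracklayer::import(annotation_source, format = "gff3")
      g <- g[tolower(as.character(g$type)) == "gene"]
      ids <- if (!is.null(g$ID)) as.character(g$ID) else rep(NA_character_, length(g))
      GenomicRanges::GRanges(seqnames(g), IRanges::ranges(g),
                             strand = BiocGenerics::strand(g), gene_id = ids)
    },
    bed = {
      g <- rtracklayer::import(annotation_source, format = "bed")
      ids <- if (!is.null(g$name)) as.character(g$name) else rep(NA_character_, length(g))
      GenomicRanges::GRanges(seqnames(g), IRanges::ranges(g),
                             strand = BiocGenerics::strand(g), gene_id = ids)
    }
  )
  if (any(width(gr) < 1L)) stop("gene with start >= end in ", annotation_source)
  nas <- is.na(gr$gene_id) | !nzchar(gr$gene_id)
  if (any(nas)) gr$gene_id[nas] <- paste0("gene_", seq_len(sum(nas)))
  if (anyDuplicated(gr$gene_id))
    gr$gene_id <- make.unique(gr$gene_id, sep = "_")
  as_gene_set(gr, genome = genome)
}

#' Coerce a GRanges to a validated gene set
#'
#' @param gr a \code{GRanges} with a \code{gene_id} column.
#' @param genome optional \code{aflp_genome} for coordinate validation and
#'   chromosome ordering (see \code{\link{read_genes}}).
#' @return a validated \code{GRanges} gene set.
#' @export
as_gene_set <- function(gr, genome = NULL) {
  stopifnot(methods::is(gr, "GRanges"))
  if (is.null(gr$gene_id))
    gr$gene_id <- if (length(gr)) paste0("gene_", seq_len(length(gr)))
                  else character(0)
  if (anyDuplicated(gr$gene_id)) stop("gene IDs must be unique")
  if (!is.null(genome)) {
    len <- chrom_lengths(genome)
    chr <- as.character(seqnames(gr))
    off <- !chr %in% names(len)
    unplaced <- character(0)
    if (any(off)) {
      unplaced <- gr$gene_id[off]
      warning(sum(off), " gene(s) on chromosomes absent from the genome ",
              "were dropped: ", paste(utils::head(unplaced, 5), collapse = ", "),
              if (sum(off) > 5) ", ..." else "")
      gr <- gr[!off]
      chr <- chr[!off]
    }
    if (length(gr) && any(start(gr) < 1L | end(gr) > len[chr]))
      stop("gene coordinates outside chromosome bounds")
    GenomeInfoDb::seqlevels(gr) <- names(len)
    GenomeInfoDb::seqlengths(gr) <- unname(len)
    S4Vectors::metadata(gr)$unplaced_ids <- unplaced
  }
  gr
}

#' Write a gene set as GFF3
#'
#' Emits one \code{gene} feature per record with an \code{ID=} attribute;
#' coordinates are the native GFF3 1-based inclusive convention.
#'
#' @param genes a gene set \code{GRanges}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  strand <- as.character(BiocGenerics::strand(genes))
  strand[strand == "*"] <- "."
  ln <- sprintf("%s\taflpscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                as.character(seqnames(genes)), start(genes), end(genes),
                strand, genes$gene_id)
  writeLines(c("##gff-version 3", ln), path)
  invisible(path)
}

#' Write a genome as FASTA
#' @param genome an \code{aflp_genome}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path, width = 70L)
  invisible(path)
}

#' Subset a gene set by candidate IDs
#'
#' @param geneset a gene set \code{GRanges}.
#' @param id_list character vector of gene IDs (non-empty), or a path to a
#'   plain-text file with one ID per line (\code{#} comments allowed).
#' @return the matching subset, with the unmatched IDs stored in
#'   \code{metadata()$unmatched_ids} and reported via \code{message()}.
#' @export
select_genes <- function(geneset, id_list) {
  if (length(id_list) == 1L && file.exists(id_list)) {
    id_list <- trimws(sub("#.*$", "", readLines(id_list)))
    id_list <- id_list[nzchar(id_list)]
  }
  if (!length(id_list)) stop("id_list must be non-empty")
  id_list <- unique(as.character(id_list))
  hit <- geneset$gene_id %in% id_list
  out <- geneset[hit]
  unmatched <- setdiff(id_list, geneset$gene_id)
  if (length(unmatched))
    message(length(out), "/", length(id_list), " candidate gene(s) localised; ",
            length(unmatched), " ID(s) unmatched")
  S4Vectors::metadata(out)$unmatched_ids <- unmatched
  out
}

#' Gene counts per chromosome, in a given order
#'
#' @param geneset a gene set \code{GRanges}.
#' @param chromosome_order character vector covering every chromosome that
#'   carries a gene; a gene on a chromosome not listed is an error.
#' @return named integer vector of counts, summing to \code{length(geneset)}.
#' @export
genes_per_chromosome <- function(geneset, chromosome_order) {
  chr <- as.character(seqnames(geneset))
  extra <- setdiff(unique(chr), chromosome_order)
  if (length(extra))
    stop("genes on chromosome(s) missing from chromosome_order: ",
         paste(extra, collapse = ", "))
  vapply(stats::setNames(chromosome_order, chromosome_order),
         function(cn) sum(chr == cn), integer(1))
}

#' Read a candidate-gene ID list
#'
#' One ID per line; \code{#} starts a comment.
#'
#' @param path file path.
#' @return character vector of IDs.
#' @export
read_id_list <- function(path) {
  ids <- trimws(sub("#.*$", "", readLines(path)))
  ids[nzchar(ids)]
}
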