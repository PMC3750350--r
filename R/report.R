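#' Marker-count-on-genome-size regression
#'
#' Ordinary least squares of marker count on genome size (Mb). The slope is
#' the marker density in markers per Mb; across eukaryotes the EcoRI/MseI
#' system sits near 152 markers/Mb (about one AFLP per 7 kb).
#'
#' @param points \code{data.frame} with columns \code{size_mb},
#'   \code{markers} and optionally \code{label}.
#' @param exclude labels to drop before fitting (e.g. an outlying species).
#' @param through_origin fit without intercept.
#' @return object of class \code{aflp_regression}: list with \code{slope}
#'   (markers/Mb), \code{intercept}, \code{r_squared} (squared correlation),
#'   \code{n}, \code{excluded}.
#' @export
density_regression <- function(points, exclude = character(0),
                               through_origin = FALSE) {
  stopifnot(all(c("size_mb", "markers") %in% names(points)))
  if (length(exclude)) {
    if (is.null(points$label)) stop("exclusions need a label column")
    points <- points[!points$label %in% exclude, , drop = FALSE]
  }
  if (nrow(points) < 3L) stop("need >= 3 points after exclusion")
  fit <- if (through_origin) stats::lm(markers ~ 0 + size_mb, data = points)
         else stats::lm(markers ~ size_mb, data = points)
  co <- stats::coef(fit)
  r2 <- if (through_origin) {
    # uncentered R^2, computed directly (summary.lm warns on perfect fits)
    1 - sum(stats::residuals(fit)^2) / sum(points$markers^2)
  } else if (stats::var(points$markers) == 0) 0
  else stats::cor(points$size_mb, points$markers)^2
  structure(list(slope = unname(co[["size_mb"]]),
                 intercept = if (through_origin) 0 else unname(co[["(Intercept)"]]),
                 r_squared = r2, n = nrow(points),
                 excluded = exclude),
            class = "aflp_regression")
}

#' @export
print.aflp_regression <- function(x, ...) {
  cat(sprintf("<density regression> slope %.1f markers/Mb, intercept %.1f, R^2 = %.3f (n = %d%s)\n",
              x$slope, x$intercept, x$r_squared, x$n,
              if (length(x$excluded))
                paste0("; excluded: ", paste(x$excluded, collapse = ", "))
              else ""))
  invisible(x)
}

#' Physical marker density to markers per centimorgan
#'
#' Pure unit conversion: markers/kb times kb/cM. A density of one marker
#' per 7 kb with 210 kb/cM gives ~30 markers per cM; with 700 kb/cM, ~100.
#'
#' @param density_per_kb markers per kb (> 0).
#' @param kb_per_cM physical size of one centimorgan in kb (> 0).
#' @return expected markers per cM.
#' @export
markers_per_cM <- function(density_per_kb, kb_per_cM) {
  if (!is.numeric(density_per_kb) || any(density_per_kb <= 0))
    stop("density_per_kb must be > 0")
  if (!is.numeric(kb_per_cM) || any(kb_per_cM <= 0))
    stop("kb_per_cM must be > 0")
  density_per_kb * kb_per_cM
}

#' Whole-genome species summary (Table-1-style)
#'
#' Runs digestion, distance annotation and composition for one genome and
#' one or more enzyme pairs. The first pair gets the full block (marker
#' count, mean inter-marker distance, both distance percentage blocks with
#' their expectations); the remaining pairs get marker count and the d = 0
#' marker percentage, as in comparative enzyme-system tables.
#'
#' @param genome an \code{aflp_genome}.
#' @param geneset gene set \code{GRanges}.
#' @param pairs a single \code{\link{enzyme_pair}} or a (named) list of
#'   them; the first is the main system.
#' @param min_len,max_len size-selection bounds (nt).
#' @param thresholds distance thresholds in bp for the main block.
#' @param label species label.
#' @return object of class \code{aflp_species_summary}: list with
#'   \code{label}, \code{composition} (see
#'   \code{\link{composition_summary}}), \code{main} (pair name, marker
#'   count, \code{aflp_distance_summary}), \code{extra} (per further pair:
#'   name, marker count, d = 0 marker percentage).
#' @export
build_table1 <- function(genome, geneset, pairs, min_len = 40L, max_len = 440L,
                         thresholds = c(0, 1000, 10000), label = "species") {
  if (inherits(pairs, "aflp_pair")) pairs <- list(pairs)
  stopifnot(length(pairs) >= 1L)
  pair_name <- function(p) paste0(p$rare$name, "/", p$frequent$name)
  if (is.null(names(pairs)) || any(!nzchar(names(pairs))))
    names(pairs) <- vapply(pairs, pair_name, "")
  main_pair <- pairs[[1L]]
  mk <- aflp_markers(genome, main_pair, min_len, max_len)
  main <- list(pair = names(pairs)[1L], n_markers = nrow(mk),
               distances = distance_summary(mk, geneset, genome, thresholds))
  extra <- lapply(seq_along(pairs)[-1L], function(i) {
    m <- aflp_markers(genome, pairs[[i]], min_len, max_len)
    list(pair = names(pairs)[i], n_markers = nrow(m),
         pct_at_0 = unname(pct_markers_within(m, geneset, genome, 0)))
  })
  structure(list(label = label,
                 composition = composition_summary(genome, geneset, mk),
                 main = main, extra = extra),
            class = "aflp_species_summary")
}

#' @export
print.aflp_species_summary <- function(x, ...) {
  co <- x$composition
  cat(sprintf("<species summary> %s\n", x$label))
  cat(sprintf("  genome %.1f Mb (%.2f%% un-sequenced), %d genes, gene length %.1f (%.1f) kb\n",
              co$genome_size / 1e6, co$unsequenced_pct, co$n_genes,
              co$gene_len_mean / 1000, co$gene_len_sd / 1000))
  cat(sprintf("  GC genic %.3f / intergenic %.3f\n", co$genic_gc, co$intergenic_gc))
  cat(sprintf("  %s: %d markers, mean spacing %.1f kb\n", x$main$pair,
              x$main$n_markers, co$mean_intermarker / 1000))
  print(x$main$distances)
  for (e in x$extra)
    cat(sprintf("  %s: %d markers, %%markers at 0 kb = %.0f\n",
                e$pair, e$n_markers, e$pct_at_0))
  invisible(x)
}

#' Flatten a species summary to a two-column TSV table
#'
#' One row per table cell (\code{row}, \code{value}), with the report
#' precisions of comparative tables: counts as integers, genome-wide
#' percentages as integers, kb to one decimal, GC to three decimals.
#'
#' @param x an \code{aflp_species_summary}.
#' @param path optional output file; when given, written as TSV.
#' @return \code{data.frame} of rows, invisibly when \code{path} is given.
#' @export
format_table1 <- function(x, path = NULL) {
  co <- x$composition
  d <- x$main$distances
  th_lab <- paste0(format(d$thresholds / 1000, trim = TRUE), " kb")
  rows <- data.frame(row = character(0), value = character(0))
  add <- function(row, value) rows <<- rbind(rows, data.frame(row = row, value = value))
  add("Genome size (Mb)", sprintf("%.0f", co$genome_size / 1e6))
  add("GC% (gene sequences)", sprintf("%.3f", co$genic_gc))
  add("GC% (intergenic sequences)", sprintf("%.3f", co$intergenic_gc))
  add("Number of genes", sprintf("%d", co$n_genes))
  add("Mean (stand. dev.) gene length (kb)",
      sprintf("%.1f (%.1f)", co$gene_len_mean / 1000, co$gene_len_sd / 1000))
  add(sprintf("[%s] Number of AFLPs", x$main$pair), sprintf("%d", x$main$n_markers))
  add("Mean distance between AFLPs (kb)", sprintf("%.1f", co$mean_intermarker / 1000))
  for (i in seq_along(d$thresholds)) {
    v <- sprintf("%.0f", d$pct_markers_within[i])
    if (d$thresholds[i] == 0)
      v <- sprintf("%s (%.0f)", v, d$expected_pct_markers_at_0)
    add(sprintf("%% AFLPs at %s from genes", th_lab[i]), v)
  }
  for (i in seq_along(d$thresholds)) {
    v <- sprintf("%.0f", d$pct_genes_with_marker_within[i])
    if (d$thresholds[i] == 0)
      v <- sprintf("%s (%.0f)", v, d$expected_pct_genes_at_0)
    add(sprintf("%% Genes with AFLPs at %s", th_lab[i]), v)
  }
  for (e in x$extra) {
    add(sprintf("[%s] Number of AFLPs", e$pair), sprintf("%d", e$n_markers))
    add(sprintf("[%s] %% AFLPs at 0 kb from genes", e$pair),
        sprintf("%.0f", e$pct_at_0))
  }
  if (!is.null(path)) {
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rows))
  }
  rows
}

#' Candidate-gene report (Table-2-style)
#'
#' Resolves candidate IDs against the gene set, reports per-chromosome
#' candidate counts, candidate gene-length statistics and the candidate
#' distance summary with thresholds 0 / 1 / 10 / 100 kb.
#'
#' @param genome an \code{aflp_genome}.
#' @param geneset full gene set \code{GRanges}.
#' @param candidate_ids character vector of candidate gene IDs (or a file
#'   path readable by \code{\link{read_id_list}}).
#' @param pair an \code{\link{enzyme_pair}}.
#' @param min_len,max_len size-selection bounds (nt).
#' @param label trait label.
#' @return object of class \code{aflp_candidate_summary}: list with
#'   \code{label}, \code{n_candidates}, \code{unmatched_ids},
#'   \code{per_chromosome}, \code{gene_len_mean}, \code{gene_len_sd},
#'   \code{distances} (an \code{aflp_distance_summary}).
#' @export
build_table2 <- function(genome, geneset, candidate_ids, pair,
                         min_len = 40L, max_len = 440L, label = "trait") {
  cand <- select_genes(geneset, candidate_ids)
  if (!length(cand)) stop("zero candidate IDs resolved against the gene set")
  mk <- aflp_markers(genome, pair, min_len, max_len)
  gl <- gene_length_stats(cand)
  structure(list(
    label = label,
    n_candidates = length(cand),
    unmatched_ids = S4Vectors::metadata(cand)$unmatched_ids,
    per_chromosome = genes_per_chromosome(cand, names(chrom_lengths(genome))),
    gene_len_mean = gl$mean, gene_len_sd = gl$sd,
    distances = candidate_subset_summary(mk, cand, genome)
  ), class = "aflp_candidate_summary")
}

#' @export
print.aflp_candidate_summary <- function(x, ...) {
  cat(sprintf("<candidate summary> %s: %d candidate genes (%d ID(s) unmatched)\n",
              x$label, x$n_candidates, length(x$unmatched_ids)))
  cat("  per chromosome:", paste(x$per_chromosome, collapse = ", "), "\n")
  cat(sprintf("  gene length %.1f (%.1f) kb\n",
              x$gene_len_mean / 1000, x$gene_len_sd / 1000))
  print(x$distances, digits = 2)
  invisible(x)
}

#' Flatten a candidate summary to a two-column TSV table
#'
#' Candidate-subset percentages are printed to two decimals.
#'
#' @param x an \code{aflp_candidate_summary}.
#' @param path optional output TSV.
#' @return \code{data.frame} of rows.
#' @export
format_table2 <- function(x, path = NULL) {
  d <- x$distances
  th_lab <- paste0(format(d$thresholds / 1000, trim = TRUE), " kb")
  rows <- data.frame(row = character(0), value = character(0))
  add <- function(row, value) rows <<- rbind(rows, data.frame(row = row, value = value))
  add("Number of candidate genes", sprintf("%d", x$n_candidates))
  add("Mean (stand. dev.) gene length (kb)",
      sprintf("%.1f (%.1f)", x$gene_len_mean / 1000, x$gene_len_sd / 1000))
  for (i in seq_along(d$thresholds)) {
    v <- sprintf("%.2f", d$pct_markers_within[i])
    if (d$thresholds[i] == 0)
      v <- sprintf("%s (%.2f)", v, d$expected_pct_markers_at_0)
    add(sprintf("%% AFLPs at %s from genes", th_lab[i]), v)
  }
  for (i in seq_along(d$thresholds)) {
    v <- sprintf("%.0f", d$pct_genes_with_marker_within[i])
    if (d$thresholds[i] == 0)
      v <- sprintf("%s (%.0f)", v, d$expected_pct_genes_at_0)
    add(sprintf("%% Genes with AFLPs at %s", th_lab[i]), v)
  }
  if (!is.null(path)) {
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rows))
  }
  rows
}
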