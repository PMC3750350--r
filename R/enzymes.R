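#' Restriction enzyme definition
#'
#' An enzyme is described by its recognition sequence (4-6 bp, ACGT only)
#' and the cut offset: the number of bases of the recognition occurrence
#' that lie 5' of the cut on the top strand. Palindromy (recognition equal
#' to its reverse complement) is derived, and determines whether the
#' reverse strand must be scanned separately.
#'
#' @param name enzyme name, e.g. \code{"EcoRI"}.
#' @param site recognition sequence, ACGT string.
#' @param cut_offset integer in \code{[0, nchar(site)]}; bases of the
#'   recognition occurrence left of the cut point (top strand).
#' @return an object of class \code{aflp_enzyme}.
#' @examples
#' enzyme("EcoRI", "GAATTC", 1)
#' @export
enzyme <- function(name, site, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site))
    stop("recognition sequence must be a non-empty ACGT string: ", site)
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(site))
    stop("cut offset must lie within [0, ", nchar(site), "] for ", name)
  structure(
    list(name = name, site = site, cut_offset = cut_offset,
         palindromic = identical(site, revcomp_chr(site))),
    class = "aflp_enzyme"
  )
}

#' @export
print.aflp_enzyme <- function(x, ...) {
  cat(sprintf("<enzyme> %s  %s^%s  (%s)\n", x$name,
              substr(x$site, 1, x$cut_offset),
              substr(x$site, x$cut_offset + 1L, nchar(x$site)),
              if (x$palindromic) "palindromic" else "non-palindromic"))
  invisible(x)
}

#' Built-in enzyme catalogue
#'
#' The six enzymes of the three classic AFLP systems. Cut offsets follow
#' the documented conventions EcoRI G^AATTC, MseI T^TAA, TaqI T^CGA,
#' SacI GAGCT^C, HpaII C^CGG; the non-palindromic BsmI is modelled as
#' cutting at the 3' boundary of its recognition occurrence. Offsets shift
#' fragment lengths by at most a few bp and are freely overridable via
#' \code{\link{enzyme}}.
#'
#' @param name optional single enzyme name to extract.
#' @return a named list of \code{aflp_enzyme} objects, or one enzyme.
#' @examples
#' aflp_enzymes("MseI")
#' @export
aflp_enzymes <- function(name = NULL) {
  cat <- list(
    EcoRI = enzyme("EcoRI", "GAATTC", 1L),
    MseI  = enzyme("MseI",  "TTAA",   1L),
    BsmI  = enzyme("BsmI",  "GAATGC", 6L),
    TaqI  = enzyme("TaqI",  "TCGA",   1L),
    SacI  = enzyme("SacI",  "GAGCTC", 5L),
    HpaII = enzyme("HpaII", "CCGG",   1L)
  )
  if (is.null(name)) return(cat)
  if (!name %in% names(cat)) stop("unknown enzyme: ", name)
  cat[[name]]
}

#' Read an enzyme catalogue from a plain-text config
#'
#' Three whitespace-separated columns: name, recognition site, cut offset.
#' Lines starting with \code{#} are comments.
#'
#' @param path config file path.
#' @return named list of \code{aflp_enzyme}.
#' @export
read_enzyme_config <- function(path) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  if (!length(ln)) stop("empty enzyme config: ", path)
  out <- lapply(strsplit(ln, "[ \t]+"), function(f) {
    if (length(f) != 3L) stop("malformed enzyme config line: ", paste(f, collapse = " "))
    enzyme(f[1L], f[2L], as.integer(f[3L]))
  })
  names(out) <- vapply(out, `[[`, "", "name")
  if (anyDuplicated(names(out))) stop("duplicate enzyme names in config")
  out
}

#' AFLP enzyme pair
#'
#' The rare (long recognition site) and frequent (short site) cutter that
#' define an AFLP system, plus an optional selective-nucleotide
#' specification: the set of bases allowed immediately interior to each
#' recognition remnant (an empty set places no constraint on that end).
#'
#' @param rare,frequent \code{aflp_enzyme} objects or catalogue names.
#' @param selective_rare,selective_frequent character vectors of allowed
#'   interior bases (subsets of ACGT); \code{character(0)} disables
#'   selection on that end.
#' @return an object of class \code{aflp_pair}.
#' @examples
#' enzyme_pair("EcoRI", "MseI")
#' enzyme_pair("EcoRI", "MseI",
#'             selective_rare = c("G", "C"), selective_frequent = c("G", "C"))
#' @export
enzyme_pair <- function(rare, frequent,
                        selective_rare = character(0),
                        selective_frequent = character(0)) {
  if (is.character(rare)) rare <- aflp_enzymes(rare)
  if (is.character(frequent)) frequent <- aflp_enzymes(frequent)
  stopifnot(inherits(rare, "aflp_enzyme"), inherits(frequent, "aflp_enzyme"))
  if (identical(rare$site, frequent$site))
    stop("the two enzymes of a pair must have distinct recognition sequences")
  chk_sel <- function(s) {
    s <- toupper(as.character(s))
    if (length(s) && !all(s %in% c("A", "C", "G", "T")))
      stop("selective bases must be in ACGT")
    unique(s)
  }
  structure(
    list(rare = rare, frequent = frequent,
         selective_rare = chk_sel(selective_rare),
         selective_frequent = chk_sel(selective_frequent)),
    class = "aflp_pair"
  )
}

#' @export
print.aflp_pair <- function(x, ...) {
  sel <- function(s) if (length(s)) paste(s, collapse = "/") else "-"
  cat(sprintf("<enzyme pair> %s (%s) / %s (%s)  selective: %s | %s\n",
              x$rare$name, x$rare$site, x$frequent$name, x$frequent$site,
              sel(x$selective_rare), sel(x$selective_frequent)))
  invisible(x)
}

#' GC fraction of an enzyme pair's recognition sequences
#'
#' The fraction of G+C bases pooled over the two recognition sequences:
#' 2/10 for EcoRI/MseI, 5/10 for BsmI/TaqI, 8/10 for SacI/HpaII. A higher
#' value biases the pair's cut sites towards GC-rich (typically genic)
#' sequence.
#'
#' @param pair an \code{\link{enzyme_pair}}.
#' @return GC fraction in \code{[0, 1]}.
#' @examples
#' pair_gc_fraction(enzyme_pair("SacI", "HpaII"))  # 0.8
#' @export
pair_gc_fraction <- function(pair) {
  stopifnot(inherits(pair, "aflp_pair"))
  s <- paste0(pair$rare$site, pair$frequent$site)
  ch <- strsplit(s, "")[[1L]]
  sum(ch %in% c("G", "C")) / length(ch)
}

# reverse complement of a plain character string (ACGT + IUPAC)
revcomp_chr <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}
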