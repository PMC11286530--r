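#' Genome assembly description
#'
#' A genome assembly is the ordered set of chromosome names and lengths that
#' every coordinate in a run is validated against. The assembly is always a
#' runtime input (read from a `chrom.sizes` file or built by
#' [make_genome()]); no reference genome is hard-coded.
#'
#' @param chrom_names Character vector of unique chromosome identifiers.
#' @param chrom_lengths Positive integer vector of chromosome lengths in
#'   bases, parallel to `chrom_names`.
#'
#' @return An object of class `genome_assembly`: a list with elements
#'   `chrom_names` and `chrom_lengths` (named by chromosome).
#' @examples
#' asm <- genome_assembly(c("chr1", "chr2"), c(1e6, 8e5))
#' asm
#' @export
genome_assembly <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths)) {
    stop("chrom_names and chrom_lengths must have equal length")
  }
  if (anyDuplicated(chrom_names)) {
    stop("chromosome names must be unique")
  }
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0) ||
      any(chrom_lengths != floor(chrom_lengths))) {
    stop("chromosome lengths must be positive integers")
  }
  names(chrom_lengths) <- chrom_names
  structure(
    list(chrom_names = chrom_names, chrom_lengths = chrom_lengths),
    class = "genome_assembly"
  )
}

#' Read a chrom.sizes file
#'
#' Two-column tab-separated file: chromosome name, length in bases
#' (the UCSC `chrom.sizes` convention).
#'
#' @param path Path to the file (plain or gzip).
#' @return A [genome_assembly()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) stop("empty chrom.sizes file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    stop("chrom.sizes parse error at line ", which(nf < 2L)[1L],
         ": expected 2 tab-separated fields")
  }
  genome_assembly(
    vapply(parts, `[[`, "", 1L),
    as.numeric(vapply(parts, `[[`, "", 2L))
  )
}

#' Write a chrom.sizes file
#' @param assembly A [genome_assembly()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(assembly, path) {
  stopifnot(inherits(assembly, "genome_assembly"))
  writeLines(
    paste(assembly$chrom_names,
          format(assembly$chrom_lengths, scientific = FALSE, trim = TRUE),
          sep = "\t"),
    path
  )
  invisible(path)
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("genome_assembly:", length(x$chrom_names), "chromosomes,",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total\n")
  n <- min(length(x$chrom_names), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  %-12s %s bp\n", x$chrom_names[i],
                format(x$chrom_lengths[i], big.mark = ",")))
  }
  if (length(x$chrom_names) > n) cat("  ...\n")
  invisible(x)
}

# Read all lines from a plain or gzip text file. gzfile() transparently
# handles both, so a single connection type covers every reader.
read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# 0-based half-open -> 1-based inclusive (and back). All internal
# coordinates are 0-based half-open; conversion happens only in parsers
# and writers.
zero_to_one_based <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}

one_to_zero_based <- function(start1, end1) {
  list(start = start1 - 1L, end = end1)
}

# Validate interval vectors against an assembly. Returns logical vector of
# records whose chromosome is known; stops on out-of-bounds coordinates for
# known chromosomes when check_bounds is TRUE.
chrom_known <- function(chrom, assembly) {
  chrom %in% assembly$chrom_names
}

check_intervals <- function(chrom, start0, end0, assembly, what = "interval") {
  if (any(start0 < 0)) stop(what, " with negative start")
  if (any(start0 >= end0)) stop(what, " with start >= end")
  len <- assembly$chrom_lengths[chrom]
  bad <- which(end0 > len)
  if (length(bad)) {
    stop(what, " beyond chromosome end: ", chrom[bad[1L]], ":",
         start0[bad[1L]], "-", end0[bad[1L]])
  }
  invisible(TRUE)
}

# GRanges helper: internal 0-based half-open table -> GRanges (1-based).
# '.' (unstranded in BED/pairs dialects) maps to GRanges '*'.
to_granges <- function(chrom, start0, end0, strand = "*") {
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand
  )
}
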