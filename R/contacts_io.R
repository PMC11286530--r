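#' RNA class vocabulary
#'
#' The closed vocabulary of RNA classes used throughout the package. Raw
#' annotation biotypes are mapped into this vocabulary by a biotype map
#' (see [default_biotype_map()]); anything unmapped becomes `other_ncRNA`.
#'
#' @return Character vector of the seven class names.
#' @export
rna_classes <- function() {
  c("protein_coding", "lncRNA", "snoRNA", "snRNA", "miRNA", "rRNA",
    "other_ncRNA")
}

#' Default biotype-to-class map
#'
#' Maps common GENCODE/Ensembl gene biotypes onto the package's closed RNA
#' class vocabulary. scaRNAs are grouped with snoRNAs (they carry snoRNA box
#' elements and behave as small chromatin-contacting ncRNAs in this
#' analysis). Biotypes absent from the map fall through to `other_ncRNA`.
#'
#' @return Named character vector: raw biotype -> rna_class.
#' @export
default_biotype_map <- function() {
  c(protein_coding = "protein_coding",
    lncRNA = "lncRNA", lincRNA = "lncRNA", antisense = "lncRNA",
    snoRNA = "snoRNA", scaRNA = "snoRNA",
    snRNA = "snRNA",
    miRNA = "miRNA",
    rRNA = "rRNA", Mt_rRNA = "rRNA", rRNA_pseudogene = "rRNA",
    misc_RNA = "other_ncRNA")
}

new_contact_pairs <- function(df, assembly, skipped = 0L) {
  rownames(df) <- NULL
  structure(df,
            class = c("contact_pairs", "data.frame"),
            assembly = assembly,
            skipped = as.integer(skipped))
}

#' Read RNA-DNA contact pairs
#'
#' Parses the pairs-dialect TSV produced by upstream iMARGI-style
#' processing: comment lines start with `#`; data columns are
#' `readID chrom1 pos1 chrom2 pos2 strand1 strand2` with 1-based single
#' positions. Side 1 is the RNA end and side 2 the DNA end (use
#' `swap_sides = TRUE` for the opposite dialect). Positions are converted to
#' the package-internal 0-based half-open convention as 1 bp intervals.
#'
#' Records on chromosomes absent from `assembly` (scaffolds, alt contigs)
#' are skipped and counted, not fatal; the count is available as
#' `attr(x, "skipped")` and shown by `print()`.
#'
#' @param path Pairs file (plain or gzip).
#' @param assembly A [genome_assembly()].
#' @param swap_sides If `TRUE`, side 2 is the RNA end.
#' @return A `contact_pairs` data frame with columns `read_id`, `rna_chrom`,
#'   `rna_start`, `rna_end`, `rna_strand`, `dna_chrom`, `dna_start`,
#'   `dna_end`, `dna_strand` (coordinates 0-based half-open).
#' @seealso [write_pairs()], [annotate_contacts()]
#' @export
read_pairs <- function(path, assembly, swap_sides = FALSE) {
  stopifnot(inherits(assembly, "genome_assembly"))
  lines <- read_text_lines(path)
  is_body <- !startsWith(lines, "#") & nzchar(lines)
  body <- lines[is_body]
  if (length(body) == 0L) {
    return(new_contact_pairs(empty_pairs_df(), assembly, skipped = 0L))
  }
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nf != 7L)) {
    bad <- which(is_body)[which(nf != 7L)[1L]]
    stop("pairs parse error at line ", bad, " of ", path,
         ": expected 7 tab-separated fields, got ", nf[nf != 7L][1L])
  }
  dt <- data.table::fread(
    text = body, header = FALSE, sep = "\t",
    colClasses = list(character = c(1L, 2L, 4L, 6L, 7L),
                      numeric = c(3L, 5L)),
    showProgress = FALSE
  )
  data.table::setnames(dt, c("read_id", "chrom1", "pos1", "chrom2", "pos2",
                             "strand1", "strand2"))
  if (swap_sides) {
    data.table::setnames(dt,
      c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2"),
      c("chrom2", "pos2", "strand2", "chrom1", "pos1", "strand1"))
  }
  ok_strand <- dt$strand1 %in% c("+", "-", ".") &
    dt$strand2 %in% c("+", "-", ".")
  if (!all(ok_strand)) {
    stop("pairs parse error: invalid strand in record ",
         which(!ok_strand)[1L])
  }
  keep <- chrom_known(dt$chrom1, assembly) & chrom_known(dt$chrom2, assembly)
  skipped <- sum(!keep)
  dt <- dt[keep, ]
  df <- data.frame(
    read_id = dt$read_id,
    rna_chrom = dt$chrom1,
    rna_start = dt$pos1 - 1,
    rna_end = dt$pos1,
    rna_strand = dt$strand1,
    dna_chrom = dt$chrom2,
    dna_start = dt$pos2 - 1,
    dna_end = dt$pos2,
    dna_strand = dt$strand2,
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    check_intervals(df$rna_chrom, df$rna_start, df$rna_end, assembly,
                    "RNA end")
    check_intervals(df$dna_chrom, df$dna_start, df$dna_end, assembly,
                    "DNA end")
  }
  new_contact_pairs(df, assembly, skipped)
}

empty_pairs_df <- function() {
  data.frame(read_id = character(), rna_chrom = character(),
             rna_start = numeric(), rna_end = numeric(),
             rna_strand = character(), dna_chrom = character(),
             dna_start = numeric(), dna_end = numeric(),
             dna_strand = character(), stringsAsFactors = FALSE)
}

#' Write contact pairs in the pairs dialect
#'
#' Inverse of [read_pairs()]: re-emits 1-based single positions so that
#' `read_pairs(write_pairs(x))` round-trips record for record.
#'
#' @param pairs A `contact_pairs` object.
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(inherits(pairs, "contact_pairs"))
  header <- c("## pairs format v1.0",
              "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2")
  body <- if (nrow(pairs)) {
    paste(pairs$read_id, pairs$rna_chrom,
          format(pairs$rna_start + 1, scientific = FALSE, trim = TRUE, digits = 15),
          pairs$dna_chrom,
          format(pairs$dna_start + 1, scientific = FALSE, trim = TRUE, digits = 15),
          pairs$rna_strand, pairs$dna_strand, sep = "\t")
  } else character()
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' @export
print.contact_pairs <- function(x, ...) {
  cat("contact_pairs:", nrow(x), "RNA-DNA pairs",
      sprintf("(%d records skipped on unknown chromosomes)\n",
              attr(x, "skipped") %||% 0L))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5L), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_gene_models <- function(df, skipped = 0L) {
  bad <- setdiff(unique(df$rna_class), rna_classes())
  if (length(bad)) stop("unknown rna_class: ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1L])
  }
  if (nrow(df) && !all(df$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  rownames(df) <- NULL
  structure(df, class = c("gene_models", "data.frame"),
            skipped = as.integer(skipped))
}

#' Read gene annotation from GTF/GFF
#'
#' Imports records of feature type `gene`, keeping the gene id, display
#' name, span and RNA class. The raw biotype attribute (`gene_biotype`,
#' `gene_type` or `biotype`, whichever the file carries) is mapped through
#' `biotype_map`; unmapped biotypes become `other_ncRNA`. GTF 1-based
#' inclusive coordinates are converted to 0-based half-open. Genes on
#' chromosomes absent from the assembly are skipped and counted.
#'
#' @param path GTF/GFF file (plain or gzip).
#' @param assembly A [genome_assembly()].
#' @param biotype_map Named character vector raw biotype -> rna_class;
#'   defaults to [default_biotype_map()].
#' @return A `gene_models` data frame with columns `gene_id`, `gene_name`,
#'   `rna_class`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path, assembly,
                                 biotype_map = default_biotype_map()) {
  stopifnot(inherits(assembly, "genome_assembly"))
  gr <- rtracklayer::import(path)
  meta <- S4Vectors::mcols(gr)
  if ("type" %in% names(meta)) {
    gr <- gr[as.character(meta$type) == "gene"]
    meta <- S4Vectors::mcols(gr)
  }
  if (length(gr) == 0L) {
    return(new_gene_models(empty_genes_df(), skipped = 0L))
  }
  if (!"gene_id" %in% names(meta)) {
    stop("annotation has no gene_id attribute")
  }
  gene_id <- as.character(meta$gene_id)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id in annotation: ",
         gene_id[duplicated(gene_id)][1L])
  }
  bio_col <- intersect(c("gene_biotype", "gene_type", "biotype"),
                       names(meta))[1]
  raw_bio <- if (!is.na(bio_col)) as.character(meta[[bio_col]]) else
    rep(NA_character_, length(gr))
  cls <- unname(biotype_map[raw_bio])
  cls[is.na(cls)] <- "other_ncRNA"
  name <- if ("gene_name" %in% names(meta)) {
    nm <- as.character(meta$gene_name)
    ifelse(is.na(nm), gene_id, nm)
  } else gene_id
  df <- data.frame(
    gene_id = gene_id,
    gene_name = name,
    rna_class = cls,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  keep <- chrom_known(df$chrom, assembly)
  skipped <- sum(!keep)
  df <- df[keep, ]
  if (nrow(df)) {
    check_intervals(df$chrom, df$start, df$end, assembly, "gene span")
  }
  new_gene_models(df, skipped)
}

empty_genes_df <- function() {
  data.frame(gene_id = character(), gene_name = character(),
             rna_class = character(), chrom = character(),
             start = numeric(), end = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Write gene models as GTF
#' @param genes A `gene_models` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_gtf <- function(genes, path) {
  stopifnot(inherits(genes, "gene_models"))
  attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                   genes$gene_id, genes$gene_name, genes$rna_class)
  lines <- paste(genes$chrom, "carna", "gene",
                 format(genes$start + 1, scientific = FALSE, trim = TRUE, digits = 15),
                 format(genes$end, scientific = FALSE, trim = TRUE, digits = 15),
                 ".", genes$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x), "genes\n")
  if (nrow(x)) {
    print(table(rna_class = x$rna_class))
  }
  invisible(x)
}

new_genomic_regions <- function(df) {
  rownames(df) <- NULL
  structure(df, class = c("genomic_regions", "data.frame"))
}

#' Read a BED region set
#'
#' BED3+ (0-based half-open). Columns beyond the first three are read as
#' `name`, `score`, `strand` when present; missing strand defaults to `.`.
#' Input order is preserved.
#'
#' @param path BED file (plain or gzip).
#' @param assembly A [genome_assembly()] the intervals are validated against.
#' @return A `genomic_regions` data frame with columns `chrom`, `start`,
#'   `end`, `name`, `strand`.
#' @export
read_bed <- function(path, assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  lines <- read_text_lines(path)
  is_body <- !startsWith(lines, "#") & !startsWith(lines, "track") &
    nzchar(lines)
  body <- lines[is_body]
  if (length(body) == 0L) {
    return(new_genomic_regions(empty_regions_df()))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop("BED parse error at line ", which(is_body)[which(nf < 3L)[1L]],
         ": fewer than 3 fields")
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.numeric(vapply(parts, `[[`, "", 2L))
  end <- as.numeric(vapply(parts, `[[`, "", 3L))
  if (any(is.na(start)) || any(is.na(end))) {
    stop("BED parse error: non-numeric coordinate at line ",
         which(is_body)[which(is.na(start) | is.na(end))[1L]])
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("BED parse error at line ", which(is_body)[bad[1L]],
         ": start >= end")
  }
  name <- ifelse(nf >= 4L, vapply(parts, function(p) p[min(4L, length(p))],
                                  ""), ".")
  strand <- ifelse(nf >= 6L, vapply(parts, function(p)
    p[min(6L, length(p))], ""), ".")
  strand[!strand %in% c("+", "-")] <- "."
  unknown <- !chrom_known(chrom, assembly)
  if (any(unknown)) {
    stop("BED region on unknown chromosome: ", chrom[unknown][1L])
  }
  check_intervals(chrom, start, end, assembly, "BED region")
  new_genomic_regions(data.frame(
    chrom = chrom, start = start, end = end, name = name, strand = strand,
    stringsAsFactors = FALSE
  ))
}

empty_regions_df <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Write regions as BED6
#' @param regions A `genomic_regions` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  lines <- paste(regions$chrom,
                 format(regions$start, scientific = FALSE, trim = TRUE, digits = 15),
                 format(regions$end, scientific = FALSE, trim = TRUE, digits = 15),
                 regions$name %||% ".", 0, regions$strand %||% ".",
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

new_signal_track <- function(values, assembly, bin_size,
                             normalization = "raw") {
  expected <- ceiling(assembly$chrom_lengths / bin_size)
  stopifnot(identical(sort(names(values)), sort(assembly$chrom_names)))
  for (chr in assembly$chrom_names) {
    v <- values[[chr]]
    if (length(v) != expected[[chr]]) {
      stop("signal vector length mismatch on ", chr)
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("signal values must be finite and >= 0")
    }
  }
  structure(list(values = values[assembly$chrom_names],
                 assembly = assembly, bin_size = bin_size,
                 normalization = normalization),
            class = "signal_track")
}

#' Read a bedGraph signal track into genome-wide bins
#'
#' Records are 0-based half-open and must be non-overlapping. Each bin's
#' value is the coverage-weighted mean of overlapping record values, with
#' uncovered bases contributing 0 (so a record of value 4 covering half a
#' bin yields bin value 2). The trailing partial bin of a chromosome is
#' averaged over its actual width.
#'
#' @param path bedGraph file (plain or gzip).
#' @param assembly A [genome_assembly()].
#' @param bin_size Bases per bin (>= 1).
#' @return A `signal_track` with `normalization = "raw"`; CPM scaling is a
#'   separate step ([cpm_normalize()]).
#' @export
read_signal_bedgraph <- function(path, assembly, bin_size) {
  stopifnot(inherits(assembly, "genome_assembly"), bin_size >= 1)
  lines <- read_text_lines(path)
  is_body <- !startsWith(lines, "#") & !startsWith(lines, "track") &
    nzchar(lines)
  body <- lines[is_body]
  if (length(body) == 0L) {
    return(zero_track(assembly, bin_size))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L)) {
    stop("bedGraph parse error at line ", which(is_body)[which(nf != 4L)[1L]],
         ": expected 4 fields")
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.numeric(vapply(parts, `[[`, "", 2L))
  end <- as.numeric(vapply(parts, `[[`, "", 3L))
  value <- as.numeric(vapply(parts, `[[`, "", 4L))
  if (any(is.na(start) | is.na(end) | is.na(value))) {
    stop("bedGraph parse error: non-numeric field")
  }
  if (any(start >= end)) stop("bedGraph record with start >= end")
  if (any(value < 0)) stop("bedGraph record with negative value")
  unknown <- !chrom_known(chrom, assembly)
  if (any(unknown)) {
    stop("bedGraph record on unknown chromosome: ", chrom[unknown][1L])
  }
  check_intervals(chrom, start, end, assembly, "bedGraph record")
  bin_records(chrom, start, end, value, assembly, bin_size)
}

zero_track <- function(assembly, bin_size, normalization = "raw") {
  values <- lapply(assembly$chrom_lengths,
                   function(L) numeric(ceiling(L / bin_size)))
  names(values) <- assembly$chrom_names
  new_signal_track(values, assembly, bin_size, normalization)
}

# Shared binning core: non-overlapping interval records -> per-bin
# coverage-weighted values. Also used by simulate_tracks().
bin_records <- function(chrom, start, end, value, assembly, bin_size) {
  track <- zero_track(assembly, bin_size)
  ord <- order(chrom, start)
  chrom <- chrom[ord]; start <- start[ord]; end <- end[ord]
  value <- value[ord]
  same <- chrom[-1] == chrom[-length(chrom)]
  if (length(chrom) > 1L && any(same & start[-1] < end[-length(end)])) {
    i <- which(same & start[-1] < end[-length(end)])[1L]
    stop("overlapping bedGraph records on ", chrom[i + 1L],
         " near position ",
         format(start[i + 1L], scientific = FALSE))
  }
  k0 <- floor(start / bin_size)
  k1 <- floor((end - 1) / bin_size)
  nb <- k1 - k0 + 1
  rec <- rep.int(seq_along(start), nb)
  bin <- k0[rec] + sequence(nb) - 1
  ov <- pmin(end[rec], (bin + 1) * bin_size) - pmax(start[rec],
                                                    bin * bin_size)
  wsum <- ov * value[rec]
  for (chr in unique(chrom)) {
    sel <- chrom[rec] == chr
    if (!any(sel)) next
    L <- track$assembly$chrom_lengths[[chr]]
    nbin <- length(track$values[[chr]])
    width <- pmin(bin_size, L - (seq_len(nbin) - 1) * bin_size)
    acc <- rowsum(wsum[sel], bin[sel])
    idx <- as.integer(rownames(acc)) + 1L
    track$values[[chr]][idx] <- acc[, 1L] / width[idx]
  }
  track
}

#' Write a signal track as bedGraph
#'
#' Emits one record per run of equal-valued bins; zero bins are omitted.
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  out <- character(0)
  bs <- track$bin_size
  for (chr in track$assembly$chrom_names) {
    v <- track$values[[chr]]
    if (!length(v)) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    L <- track$assembly$chrom_lengths[[chr]]
    s <- starts_bin[keep] * bs
    e <- pmin(ends_bin[keep] * bs, L)
    out <- c(out, paste(chr,
                        format(s, scientific = FALSE, trim = TRUE),
                        format(e, scientific = FALSE, trim = TRUE),
                        format(r$values[keep], scientific = FALSE,
                               trim = TRUE, digits = 15),
                        sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosomes, bin_size %d, %s\n",
              length(x$values), as.integer(x$bin_size), x$normalization))
  tot <- sum(vapply(x$values, sum, 0))
  cat("  total signal:", format(tot), "\n")
  invisible(x)
}
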