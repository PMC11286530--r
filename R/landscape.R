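#' Class-level interaction landscape
#'
#' Tabulates cis/trans contact counts per RNA class and derives three views
#' of the landscape: each class's share of all annotated cis contacts, its
#' share of all annotated trans contacts, and the trans fraction within the
#' class. The global cis fraction is computed over all contacts including
#' unannotated ones (locality needs no gene), whereas class shares are over
#' annotated contacts only — `unannotated` is not an RNA class.
#'
#' @param contacts An `annotated_contacts` data frame.
#' @return A `class_landscape` object: per-class table plus globals
#'   `n_total`, `n_cis`, `n_trans`, `n_unannotated`, `global_cis_fraction`.
#'   With no contacts, counts are 0 and every fraction is `NA`.
#' @export
class_landscape <- function(contacts) {
  n_total <- nrow(contacts)
  n_cis <- sum(contacts$locality == "cis")
  n_trans <- n_total - n_cis
  ann <- contacts[contacts$rna_class != "unannotated", , drop = FALSE]
  classes <- rna_classes()
  tab <- data.frame(rna_class = classes,
                    n_cis = 0L, n_trans = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(ann)) {
    agg <- table(factor(ann$rna_class, levels = classes), ann$locality)
    tab$n_cis <- as.integer(if ("cis" %in% colnames(agg)) agg[, "cis"]
                            else 0L)
    tab$n_trans <- as.integer(if ("trans" %in% colnames(agg))
      agg[, "trans"] else 0L)
  }
  ann_cis <- sum(tab$n_cis)
  ann_trans <- sum(tab$n_trans)
  tab$share_of_cis <- if (ann_cis > 0) tab$n_cis / ann_cis else NA_real_
  tab$share_of_trans <- if (ann_trans > 0) tab$n_trans / ann_trans else
    NA_real_
  within <- tab$n_cis + tab$n_trans
  tab$trans_fraction_within_class <- ifelse(within > 0,
                                            tab$n_trans / within, NA_real_)
  structure(list(
    classes = tab,
    n_total = n_total,
    n_cis = n_cis,
    n_trans = n_trans,
    n_unannotated = n_total - nrow(ann),
    global_cis_fraction = if (n_total > 0) n_cis / n_total else NA_real_
  ), class = "class_landscape")
}

#' @export
print.class_landscape <- function(x, digits = 3, ...) {
  cat("RNA-chromatin interaction landscape\n")
  cat(sprintf("  %d contacts: %d cis, %d trans (global cis fraction %s)\n",
              x$n_total, x$n_cis, x$n_trans,
              ifelse(is.na(x$global_cis_fraction), "NA",
                     format(round(x$global_cis_fraction, digits)))))
  cat(sprintf("  %d unannotated contacts excluded from class shares\n",
              x$n_unannotated))
  print(format(x$classes, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Summarise per-gene contact profiles
#'
#' One profile per gene with at least one annotated contact: total
#' contacts, trans contacts, and the trans fraction
#' `n_trans / n_total`. Unannotated contacts are excluded.
#'
#' @param contacts An `annotated_contacts` data frame.
#' @return A `gene_profiles` data frame with columns `gene_id`,
#'   `rna_class`, `n_total`, `n_trans`, `trans_fraction`.
#' @export
gene_profiles <- function(contacts) {
  ann <- contacts[contacts$rna_class != "unannotated", , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(structure(
      data.frame(gene_id = character(), rna_class = character(),
                 n_total = integer(), n_trans = integer(),
                 trans_fraction = numeric(), stringsAsFactors = FALSE),
      class = c("gene_profiles", "data.frame")))
  }
  ids <- ann$gene_id
  n_total <- rowsum(rep(1L, length(ids)), ids)
  n_trans <- rowsum(as.integer(ann$locality == "trans"), ids)
  gene_id <- rownames(n_total)
  prof <- data.frame(
    gene_id = gene_id,
    rna_class = ann$rna_class[match(gene_id, ids)],
    n_total = as.integer(n_total[, 1L]),
    n_trans = as.integer(n_trans[, 1L]),
    stringsAsFactors = FALSE
  )
  prof$trans_fraction <- prof$n_trans / prof$n_total
  structure(prof, class = c("gene_profiles", "data.frame"))
}

#' Call trans-acting RNAs by dual threshold
#'
#' A gene is called trans-acting when it shows frequent chromatin
#' association (`n_total >= min_contacts`) and a substantial proportion of
#' trans contacts (`trans_fraction >= min_trans_fraction`). Both thresholds
#' are inclusive. The defaults — at least 10 contacts of which at least 20%
#' are trans — are the operational definition this analysis uses for
#' trans-acting RNAs. The denominator of the trans fraction is all of the
#' gene's annotated contacts, cis plus trans.
#'
#' @param profiles A [gene_profiles()] data frame.
#' @param min_contacts Minimum total contacts (inclusive). Default 10.
#' @param min_trans_fraction Minimum trans proportion (inclusive).
#'   Default 0.20.
#' @return The called subset of `profiles`, sorted by `n_trans` descending
#'   (ties: `trans_fraction` descending, then `gene_id`), with class
#'   `trans_acting_calls`.
#' @export
call_trans_acting <- function(profiles, min_contacts = 10,
                              min_trans_fraction = 0.20) {
  if (min_contacts < 1) stop("min_contacts must be >= 1")
  if (min_trans_fraction < 0 || min_trans_fraction > 1) {
    stop("min_trans_fraction must be in [0, 1]")
  }
  called <- profiles$n_total >= min_contacts &
    profiles$trans_fraction >= min_trans_fraction
  out <- as.data.frame(profiles)[called, , drop = FALSE]
  out <- out[order(-out$n_trans, -out$trans_fraction, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("trans_acting_calls", "data.frame"),
            min_contacts = min_contacts,
            min_trans_fraction = min_trans_fraction)
}

#' @export
print.trans_acting_calls <- function(x, ...) {
  cat(sprintf("trans-acting RNAs: %d called (>= %s contacts, >= %s%% trans)\n",
              nrow(x), format(attr(x, "min_contacts")),
              format(100 * attr(x, "min_trans_fraction"))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Genome-wide interaction map of one RNA
#'
#' Bins the DNA ends of all contacts attributed to `gene_id` into
#' fixed-width genome-wide bins and emits one arc per non-empty bin from
#' the gene span to the bin, labelled cis or trans — the data behind a
#' circos-style plot (red trans arcs, green cis arcs, frequency track).
#' Bin frequencies sum exactly to the gene's total contact count.
#'
#' @param gene_id Focal gene (must have >= 1 annotated contact).
#' @param contacts An `annotated_contacts` data frame.
#' @param genes The `gene_models` used for annotation (provides the arc
#'   source span).
#' @param assembly A [genome_assembly()].
#' @param bin_size Bases per genome-wide bin (default 1e6).
#' @return An `interaction_map`: `gene` (one-row gene model), `bin_size`,
#'   `bins` (chrom, bin_start, bin_end, count, locality) and `n_total`.
#' @export
interaction_map <- function(gene_id, contacts, genes, assembly,
                            bin_size = 1e6) {
  sel <- !is.na(contacts$gene_id) & contacts$gene_id == gene_id
  if (!any(sel)) stop("gene has no annotated contacts: ", gene_id)
  g <- genes[genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1L) stop("unknown gene_id: ", gene_id)
  cc <- contacts[sel, , drop = FALSE]
  bin <- floor(cc$dna_start / bin_size)
  key <- paste(cc$dna_chrom, bin, cc$locality, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  chrom <- vapply(parts, `[[`, "", 1L)
  b <- as.numeric(vapply(parts, `[[`, "", 2L))
  bins <- data.frame(
    chrom = chrom,
    bin_start = b * bin_size,
    bin_end = pmin((b + 1) * bin_size, assembly$chrom_lengths[chrom]),
    locality = vapply(parts, `[[`, "", 3L),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  bins <- bins[order(match(bins$chrom, assembly$chrom_names),
                     bins$bin_start), , drop = FALSE]
  rownames(bins) <- NULL
  structure(list(gene = as.data.frame(g), bin_size = bin_size,
                 bins = bins, n_total = nrow(cc)),
            class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf("interaction_map for %s (%s): %d contacts in %d bins (bin %s bp)\n",
              x$gene$gene_id, x$gene$rna_class, x$n_total, nrow(x$bins),
              format(x$bin_size, scientific = FALSE)))
  invisible(x)
}

#' Export an interaction map as an arc table
#'
#' Writes one arc per non-empty bin: source span (the gene), target bin,
#' locality and contact count — a TSV consumable by circos-style plotters.
#'
#' @param map An [interaction_map()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_interaction_map <- function(map, path) {
  arcs <- data.frame(
    gene_id = map$gene$gene_id,
    source_chrom = map$gene$chrom,
    source_start = map$gene$start,
    source_end = map$gene$end,
    target_chrom = map$bins$chrom,
    target_start = map$bins$bin_start,
    target_end = map$bins$bin_end,
    locality = map$bins$locality,
    count = map$bins$count,
    stringsAsFactors = FALSE
  )
  utils::write.table(arcs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' qPCR enrichment ratio of an RNA-DNA interaction
#'
#' Interaction frequency enrichment measured on the sequencing library by
#' qPCR: the ratio of amplification of the chimeric RNA-DNA product to
#' amplification of the candidate RNA alone,
#' `efficiency^(ct_rna - ct_pair)`. With perfect doubling per cycle
#' (`efficiency = 2`) each cycle-threshold difference of 1 doubles the
#' ratio.
#'
#' @param ct_pair Cycle threshold of the RNA-DNA product.
#' @param ct_rna Cycle threshold of the candidate RNA.
#' @param efficiency Amplification base per cycle, > 1. Default 2.
#' @return Numeric enrichment ratio(s).
#' @export
qpcr_enrichment <- function(ct_pair, ct_rna, efficiency = 2.0) {
  if (any(!is.finite(ct_pair)) || any(!is.finite(ct_rna))) {
    stop("cycle thresholds must be finite")
  }
  if (!is.finite(efficiency) || efficiency <= 1) {
    stop("efficiency must be > 1")
  }
  efficiency^(ct_rna - ct_pair)
}
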