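#' CPM-normalize a signal track
#'
#' Scales every bin by `1e6 / library_size` so tracks from libraries of
#' different depth are comparable (counts per million). Normalizing an
#' already CPM-scaled track is refused.
#'
#' @param track A raw `signal_track`.
#' @param library_size Total raw signal units in the library (> 0).
#' @return The track with values scaled and `normalization = "CPM"`.
#' @export
cpm_normalize <- function(track, library_size) {
  stopifnot(inherits(track, "signal_track"))
  if (track$normalization != "raw") {
    stop("track is already normalized (", track$normalization, ")")
  }
  if (!is.finite(library_size) || library_size <= 0) {
    stop("library_size must be > 0")
  }
  track$values <- lapply(track$values, function(v) v * 1e6 / library_size)
  track$normalization <- "CPM"
  track
}

# Length-weighted mean of track bins over one interval [s, e).
# Uses the per-chromosome cumulative integral of the piecewise-constant
# track: F(x) = integral of bin values over [0, x).
track_integral <- function(track, chrom, x) {
  bs <- track$bin_size
  v <- track$values[[chrom]]
  csum <- c(0, cumsum(v * bs))
  # correct the last (possibly partial) bin: its stored value already
  # averages over the true width, so integrate with true width
  L <- track$assembly$chrom_lengths[[chrom]]
  nbin <- length(v)
  if (nbin >= 1) {
    last_w <- L - (nbin - 1) * bs
    csum[nbin + 1] <- csum[nbin] + v[nbin] * last_w
  }
  k <- pmin(floor(x / bs), nbin - 1)
  k <- pmax(k, 0)
  csum[k + 1] + v[k + 1] * (x - k * bs)
}

region_mean_signal <- function(track, chrom, start, end) {
  (track_integral(track, chrom, end) -
     track_integral(track, chrom, start)) / (end - start)
}

#' Score regions against chromatin-mark tracks
#'
#' Builds the regions-by-marks enrichment matrix: each entry is the
#' length-weighted mean signal of one track over one region (the
#' computeMatrix-style score underlying mark-enrichment heatmaps).
#'
#' @param regions A `genomic_regions` data frame.
#' @param tracks Named list of `signal_track`s sharing assembly and
#'   normalization; names are the mark labels (e.g. H3K27ac).
#' @return An `enrichment_matrix`: `scores` (|regions| x |marks|),
#'   `regions`, `marks`, `normalization`.
#' @export
score_regions <- function(regions, tracks) {
  if (!length(tracks)) stop("no tracks given")
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    stop("tracks must be a named list")
  }
  norms <- unique(vapply(tracks, function(t) t$normalization, ""))
  if (length(norms) != 1L) stop("tracks have mixed normalizations")
  asm <- tracks[[1L]]$assembly
  for (t in tracks) {
    if (!identical(t$assembly$chrom_names, asm$chrom_names)) {
      stop("tracks do not share an assembly")
    }
  }
  n <- nrow(regions)
  unknown <- !chrom_known(regions$chrom, asm)
  if (any(unknown)) {
    stop("region outside assembly: ", regions$chrom[unknown][1L])
  }
  if (n) check_intervals(regions$chrom, regions$start, regions$end, asm,
                         "region")
  scores <- matrix(0, nrow = n, ncol = length(tracks),
                   dimnames = list(NULL, names(tracks)))
  for (j in seq_along(tracks)) {
    tr <- tracks[[j]]
    for (chr in unique(regions$chrom)) {
      idx <- which(regions$chrom == chr)
      scores[idx, j] <- region_mean_signal(tr, chr, regions$start[idx],
                                           regions$end[idx])
    }
  }
  structure(list(scores = scores, regions = as.data.frame(regions),
                 marks = names(tracks), normalization = norms),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix: %d regions x %d marks (%s)\n",
              nrow(x$scores), ncol(x$scores), x$normalization))
  if (nrow(x$scores)) {
    cat("  column means:\n")
    print(round(colMeans(x$scores), 3))
  }
  invisible(x)
}

#' Average signal profile over a region set
#'
#' Each region, extended by `flank` bases on both sides (clipped at
#' chromosome ends), is rescaled to `n_bins` equal sub-intervals; the
#' profile is the across-region mean of the per-sub-interval mean signal.
#' Minus-strand regions are reversed so the profile reads 5' to 3'
#' (plotProfile-style metaregion curve).
#'
#' @param track A `signal_track`.
#' @param regions A `genomic_regions` data frame (strand column used).
#' @param flank Bases added on each side. Default 0.
#' @param n_bins Number of profile bins (>= 1).
#' @return Numeric vector of length `n_bins`.
#' @export
average_profile <- function(track, regions, flank = 0, n_bins = 50) {
  stopifnot(inherits(track, "signal_track"), n_bins >= 1)
  n <- nrow(regions)
  if (n == 0L) return(rep(NA_real_, n_bins))
  acc <- matrix(0, nrow = n, ncol = n_bins)
  for (i in seq_len(n)) {
    chr <- regions$chrom[i]
    L <- track$assembly$chrom_lengths[[chr]]
    s <- max(0, regions$start[i] - flank)
    e <- min(L, regions$end[i] + flank)
    edges <- s + (e - s) * (0:n_bins) / n_bins
    vals <- (track_integral(track, chr, edges[-1L]) -
               track_integral(track, chr, edges[-(n_bins + 1L)])) /
      diff(edges)
    if (identical(regions$strand[i], "-")) vals <- rev(vals)
    acc[i, ] <- vals
  }
  colMeans(acc)
}

#' Cluster regions by chromatin-mark enrichment
#'
#' Groups contact regions into k activity states C1..Ck: k-means on the
#' column-z-scored enrichment matrix, best of `n_restarts` random starts,
#' deterministic for a given seed. Clusters are then relabelled so C1 has
#' the highest mean raw signal of `labeling_mark` — with the default
#' H3K27ac, C1 is the transcriptionally active cluster.
#'
#' @param matrix An [score_regions()] `enrichment_matrix`.
#' @param k Number of clusters (default 4, i.e. C1-C4).
#' @param seed Integer RNG seed.
#' @param labeling_mark Mark whose descending mean orders the labels.
#' @param n_restarts Random restarts for k-means (default 50; with few,
#'   widely separated tight clusters a single random start is often stuck
#'   in a local optimum, so restarts are cheap insurance).
#' @return A `cluster_assignment`: `labels` (factor C1..Ck per region),
#'   `k`, `seed`, `labeling_mark`, `centers` (z-space), `tot_withinss`.
#' @export
cluster_regions <- function(matrix, k = 4, seed = 1,
                            labeling_mark = "H3K27ac", n_restarts = 50) {
  stopifnot(inherits(matrix, "enrichment_matrix"))
  x <- matrix$scores
  if (k > nrow(x)) stop("k exceeds the number of regions")
  if (!labeling_mark %in% colnames(x)) {
    stop("labeling mark not in matrix: ", labeling_mark)
  }
  sds <- apply(x, 2L, stats::sd)
  if (all(sds == 0 | is.na(sds))) {
    stop("every mark is constant across regions; no structure to cluster",
         " (use k = 1)")
  }
  z <- scale(x)
  z[, sds == 0] <- 0
  if (k == 1L) {
    labels <- factor(rep("C1", nrow(x)), levels = "C1")
    return(structure(list(labels = labels, k = 1L, seed = seed,
                          labeling_mark = labeling_mark,
                          centers = t(colMeans(z)),
                          tot_withinss = sum(scale(z, scale = FALSE)^2)),
                     class = "cluster_assignment"))
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = n_restarts, iter.max = 100)
  # relabel by descending mean raw labeling mark
  mark_mean <- tapply(x[, labeling_mark], km$cluster, mean)
  ord <- order(-mark_mean)
  relab <- integer(k)
  relab[as.integer(names(mark_mean))[ord]] <- seq_len(k)
  labels <- factor(paste0("C", relab[km$cluster]),
                   levels = paste0("C", seq_len(k)))
  structure(list(labels = labels, k = as.integer(k), seed = seed,
                 labeling_mark = labeling_mark,
                 centers = km$centers[as.integer(names(mark_mean))[ord], ,
                                      drop = FALSE],
                 tot_withinss = km$tot.withinss),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d regions in %d clusters (C1 = highest %s)\n",
              length(x$labels), x$k, x$labeling_mark))
  print(table(x$labels))
  invisible(x)
}

#' Compare signal between two conditions over a region set
#'
#' Per-region log2 ratio of mean CPM signal, condition B over condition A,
#' with a pseudocount guarding unmarked regions:
#' `log2((score_b + pc) / (score_a + pc))`. Both tracks must be
#' CPM-normalized on the same assembly.
#'
#' @param regions A `genomic_regions` data frame.
#' @param track_a,track_b CPM `signal_track`s (A = reference/control).
#' @param pseudocount Added to both scores. Default 1 CPM.
#' @return A `signal_comparison`: per-region `score_a`, `score_b`,
#'   `log2_ratio`, plus `mean_log2_ratio` and `median_log2_ratio`.
#' @export
compare_conditions <- function(regions, track_a, track_b,
                               pseudocount = 1.0) {
  stopifnot(inherits(track_a, "signal_track"),
            inherits(track_b, "signal_track"))
  if (track_a$normalization != "CPM" || track_b$normalization != "CPM") {
    stop("both tracks must be CPM-normalized")
  }
  if (!identical(track_a$assembly$chrom_names,
                 track_b$assembly$chrom_names)) {
    stop("tracks do not share an assembly")
  }
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  a <- score_regions(regions, list(A = track_a))$scores[, 1L]
  b <- score_regions(regions, list(B = track_b))$scores[, 1L]
  ratio <- log2((b + pseudocount) / (a + pseudocount))
  structure(list(
    regions = as.data.frame(regions),
    score_a = a, score_b = b, log2_ratio = ratio,
    pseudocount = pseudocount,
    mean_log2_ratio = if (length(ratio)) mean(ratio) else NA_real_,
    median_log2_ratio = if (length(ratio)) stats::median(ratio) else
      NA_real_
  ), class = "signal_comparison")
}

#' @export
print.signal_comparison <- function(x, ...) {
  cat(sprintf("signal_comparison over %d regions: mean log2(B/A) = %.4f, median = %.4f\n",
              length(x$log2_ratio), x$mean_log2_ratio,
              x$median_log2_ratio))
  invisible(x)
}
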