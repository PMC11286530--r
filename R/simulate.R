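#' Build a synthetic genome assembly
#'
#' At least two chromosomes are required: inter-chromosomal (trans)
#' contacts need somewhere to go.
#'
#' @param n_chroms Number of chromosomes (>= 2).
#' @param lengths Chromosome lengths in bases; recycled to `n_chroms`.
#' @param seed Unused for the deterministic default naming; kept so every
#'   generator op shares the same signature style.
#' @return A [genome_assembly()] with chromosomes `chrS1..chrSn`.
#' @export
make_genome <- function(n_chroms = 4, lengths = 2e6, seed = NULL) {
  if (n_chroms < 2) stop("need at least 2 chromosomes to allow trans contacts")
  lengths <- rep_len(as.numeric(lengths), n_chroms)
  genome_assembly(paste0("chrS", seq_len(n_chroms)), lengths)
}

default_length_ranges <- function() {
  list(protein_coding = c(5e3, 5e4),
       lncRNA = c(5e3, 2e4),
       snoRNA = c(70, 200),
       snRNA = c(100, 200),
       miRNA = c(60, 120),
       rRNA = c(100, 2000),
       other_ncRNA = c(200, 2000))
}

#' Generate a synthetic gene annotation
#'
#' Places the requested number of genes per RNA class on the assembly.
#' Non-host genes are mutually non-overlapping; a configurable fraction of
#' snoRNAs is instead nested strictly inside a same-strand lncRNA span,
#' emulating the snoRNA-in-host-gene arrangement (SNHG-type hosts) that
#' makes class-priority attribution necessary.
#'
#' @param assembly A [genome_assembly()].
#' @param class_counts Named integer vector, genes per RNA class.
#' @param length_ranges Named list of `c(min, max)` gene lengths per class.
#' @param nest_snorna_in_hosts Fraction of snoRNAs nested in lncRNA hosts
#'   (requires at least one lncRNA when > 0). Default 0.
#' @param seed Integer RNG seed.
#' @param max_tries Placement retries per gene before giving up.
#' @return A `gene_models` data frame.
#' @export
make_annotation <- function(assembly, class_counts,
                            length_ranges = default_length_ranges(),
                            nest_snorna_in_hosts = 0, seed = 1,
                            max_tries = 1000L) {
  stopifnot(inherits(assembly, "genome_assembly"))
  bad <- setdiff(names(class_counts), rna_classes())
  if (length(bad)) stop("unknown class in class_counts: ", bad[1L])
  if (nest_snorna_in_hosts < 0 || nest_snorna_in_hosts > 1) {
    stop("nest_snorna_in_hosts must be in [0, 1]")
  }
  count_of <- function(cls) {
    if (cls %in% names(class_counts)) class_counts[[cls]] else 0L
  }
  n_sno <- count_of("snoRNA")
  if (nest_snorna_in_hosts > 0 && n_sno > 0 && count_of("lncRNA") == 0L) {
    stop("snoRNA nesting requires lncRNA host genes")
  }
  set.seed(seed)
  placed <- list()   # per-chromosome matrix of occupied [start, end)
  rows <- list()
  counter <- 0L
  overlaps_any <- function(chr, s, e) {
    occ <- placed[[chr]]
    !is.null(occ) && any(s < occ[, 2L] & occ[, 1L] < e)
  }
  place_free <- function(len) {
    for (i in seq_len(max_tries)) {
      chr <- sample(assembly$chrom_names, 1L)
      L <- assembly$chrom_lengths[[chr]]
      if (L <= len) next
      s <- floor(stats::runif(1L, 0, L - len))
      if (!overlaps_any(chr, s, s + len)) {
        placed[[chr]] <<- rbind(placed[[chr]], c(s, s + len))
        return(list(chrom = chr, start = s, end = s + len))
      }
    }
    stop("could not place a gene of length ", len,
         " without overlap after ", max_tries, " tries")
  }
  add_gene <- function(cls, chrom, start, end, strand) {
    counter <<- counter + 1L
    id <- sprintf("%s_%03d", cls, sum(vapply(rows, function(r)
      r$rna_class == cls, TRUE)) + 1L)
    rows[[counter]] <<- data.frame(
      gene_id = id, gene_name = id, rna_class = cls, chrom = chrom,
      start = start, end = end, strand = strand, stringsAsFactors = FALSE)
  }
  # hosts (lncRNA) and all other non-snoRNA genes first, non-overlapping
  classes <- names(class_counts)
  for (cls in setdiff(classes, "snoRNA")) {
    rng <- length_ranges[[cls]]
    if (is.null(rng)) stop("no length range for class ", cls)
    for (i in seq_len(class_counts[[cls]])) {
      len <- floor(stats::runif(1L, rng[1L], rng[2L] + 1))
      pos <- place_free(len)
      add_gene(cls, pos$chrom, pos$start, pos$end,
               sample(c("+", "-"), 1L))
    }
  }
  # snoRNAs: a fraction nested strictly inside same-strand lncRNA hosts
  if (n_sno > 0) {
    genes_so_far <- do.call(rbind, rows)
    hosts <- genes_so_far[genes_so_far$rna_class == "lncRNA", ,
                          drop = FALSE]
    n_nested <- round(nest_snorna_in_hosts * n_sno)
    rng <- length_ranges[["snoRNA"]]
    for (i in seq_len(n_sno)) {
      len <- floor(stats::runif(1L, rng[1L], rng[2L] + 1))
      if (i <= n_nested) {
        h <- hosts[sample(nrow(hosts), 1L), ]
        if (h$end - h$start <= len + 2) stop("host too short for snoRNA")
        s <- floor(stats::runif(1L, h$start + 1, h$end - len - 1))
        add_gene("snoRNA", h$chrom, s, s + len, h$strand)
      } else {
        pos <- place_free(len)
        add_gene("snoRNA", pos$chrom, pos$start, pos$end,
                 sample(c("+", "-"), 1L))
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else empty_genes_df()
  new_gene_models(df)
}

#' Contact-simulation configuration
#'
#' Defines the statistical structure of a simulated RNA-chromatin contact
#' library. The default per-class trans rates encode the landscape this
#' package is built to detect: mRNAs and lncRNAs contact chromatin almost
#' exclusively near their transcription site (trans rate 0.02/0.03), while
#' snoRNAs and snRNAs contact chromatin predominantly in trans (rate 0.8).
#' Cis DNA ends decay exponentially with distance from the gene
#' (single-scale kernel, default 50 kb); trans DNA ends are uniform on a
#' uniformly chosen other chromosome.
#'
#' @param n_pairs Number of contact pairs to draw.
#' @param trans_rates Named per-class probability that a contact is
#'   inter-chromosomal.
#' @param expression_weights Named per-class relative expression weight
#'   (all genes of a class share it unless overridden).
#' @param gene_weights Optional named per-gene weight multipliers
#'   (e.g. to give hotspot genes high coverage).
#' @param hotspot_genes Optional named numeric: gene_id -> elevated trans
#'   rate overriding the class rate.
#' @param decay_scale Mean of the exponential cis-distance kernel, bases.
#' @param seed Integer RNG seed.
#' @return A `contact_sim_config` list.
#' @export
contact_sim_config <- function(n_pairs,
                               trans_rates = c(protein_coding = 0.02,
                                               lncRNA = 0.03,
                                               snoRNA = 0.80,
                                               snRNA = 0.80,
                                               miRNA = 0.05,
                                               rRNA = 0.30,
                                               other_ncRNA = 0.05),
                               expression_weights = c(protein_coding = 1.0,
                                                      lncRNA = 0.4,
                                                      snoRNA = 0.2,
                                                      snRNA = 0.2,
                                                      miRNA = 0.05,
                                                      rRNA = 0.1,
                                                      other_ncRNA = 0.05),
                               gene_weights = NULL,
                               hotspot_genes = NULL,
                               decay_scale = 5e4,
                               seed = 1) {
  if (n_pairs < 0) stop("n_pairs must be >= 0")
  if (any(trans_rates < 0 | trans_rates > 1)) {
    stop("trans_rates must be in [0, 1]")
  }
  if (any(expression_weights <= 0)) {
    stop("expression_weights must be > 0")
  }
  if (decay_scale <= 0) stop("decay_scale must be > 0")
  if (!is.null(hotspot_genes) &&
      any(hotspot_genes < 0 | hotspot_genes > 1)) {
    stop("hotspot trans rates must be in [0, 1]")
  }
  structure(list(n_pairs = as.integer(n_pairs), trans_rates = trans_rates,
                 expression_weights = expression_weights,
                 gene_weights = gene_weights,
                 hotspot_genes = hotspot_genes,
                 decay_scale = decay_scale, seed = seed),
            class = "contact_sim_config")
}

#' Simulate RNA-chromatin contact pairs with known truth
#'
#' Draws each pair as: source gene ~ expression weights; RNA end uniform
#' within the gene span, on the gene strand; locality ~
#' Bernoulli(trans rate of the gene, hotspot-overridden); cis DNA ends at
#' an exponentially distributed distance from the gene midpoint on the same
#' chromosome (clipped to bounds), trans DNA ends uniform on a uniformly
#' chosen other chromosome. Deterministic given the config seed.
#'
#' @param genes A `gene_models` data frame.
#' @param assembly A [genome_assembly()].
#' @param config A [contact_sim_config()].
#' @return List with `pairs` (a `contact_pairs` data frame) and `truth`
#'   (per-pair `read_id`, `gene_id`, `rna_class`, `locality` as drawn,
#'   plus per-gene expected rates as attribute `gene_rates`).
#' @export
simulate_contacts <- function(genes, assembly, config) {
  stopifnot(inherits(genes, "gene_models"),
            inherits(assembly, "genome_assembly"),
            inherits(config, "contact_sim_config"))
  if (nrow(genes) == 0L && config$n_pairs > 0L) {
    stop("cannot simulate contacts without genes")
  }
  rate <- unname(config$trans_rates[genes$rna_class])
  rate[is.na(rate)] <- 0
  if (!is.null(config$hotspot_genes)) {
    hs <- match(names(config$hotspot_genes), genes$gene_id)
    if (anyNA(hs)) {
      stop("hotspot gene not in annotation: ",
           names(config$hotspot_genes)[is.na(hs)][1L])
    }
    rate[hs] <- unname(config$hotspot_genes)
  }
  if (length(assembly$chrom_names) < 2L && any(rate > 0)) {
    stop("trans contacts require at least 2 chromosomes")
  }
  n <- config$n_pairs
  if (n == 0L) {
    return(list(pairs = new_contact_pairs(empty_pairs_df(), assembly),
                truth = empty_truth(genes, rate)))
  }
  w <- unname(config$expression_weights[genes$rna_class])
  w[is.na(w)] <- min(config$expression_weights)
  if (!is.null(config$gene_weights)) {
    gw <- match(names(config$gene_weights), genes$gene_id)
    if (anyNA(gw)) stop("gene_weights name not in annotation")
    w[gw] <- w[gw] * unname(config$gene_weights)
  }
  set.seed(config$seed)
  gi <- sample.int(nrow(genes), n, replace = TRUE, prob = w)
  rna_pos <- genes$start[gi] +
    floor(stats::runif(n) * (genes$end[gi] - genes$start[gi]))
  is_trans <- stats::runif(n) < rate[gi]
  chrom_len <- assembly$chrom_lengths
  dna_chrom <- genes$chrom[gi]
  dna_pos <- numeric(n)
  # cis: exponential decay from the gene midpoint, reflected sign
  ci <- which(!is_trans)
  if (length(ci)) {
    mid <- floor((genes$start[gi[ci]] + genes$end[gi[ci]]) / 2)
    off <- stats::rexp(length(ci), rate = 1 / config$decay_scale) *
      sample(c(-1, 1), length(ci), replace = TRUE)
    L <- chrom_len[dna_chrom[ci]]
    dna_pos[ci] <- pmin(pmax(floor(mid + off), 0), L - 1)
  }
  # trans: uniform position on a uniformly chosen other chromosome
  ti <- which(is_trans)
  if (length(ti)) {
    nc <- length(assembly$chrom_names)
    src <- match(dna_chrom[ti], assembly$chrom_names)
    pick <- floor(stats::runif(length(ti)) * (nc - 1)) + 1L
    pick <- ifelse(pick >= src, pick + 1L, pick)
    dna_chrom[ti] <- assembly$chrom_names[pick]
    dna_pos[ti] <- floor(stats::runif(length(ti)) *
                           chrom_len[dna_chrom[ti]])
  }
  read_id <- sprintf("p%07d", seq_len(n))
  pairs <- new_contact_pairs(data.frame(
    read_id = read_id,
    rna_chrom = genes$chrom[gi],
    rna_start = rna_pos, rna_end = rna_pos + 1,
    rna_strand = genes$strand[gi],
    dna_chrom = dna_chrom,
    dna_start = dna_pos, dna_end = dna_pos + 1,
    dna_strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ), assembly)
  truth <- data.frame(
    read_id = read_id,
    gene_id = genes$gene_id[gi],
    rna_class = genes$rna_class[gi],
    locality = ifelse(is_trans, "trans", "cis"),
    stringsAsFactors = FALSE
  )
  attr(truth, "gene_rates") <- data.frame(
    gene_id = genes$gene_id, rna_class = genes$rna_class,
    trans_rate = rate, weight = w, stringsAsFactors = FALSE)
  list(pairs = pairs, truth = truth)
}

empty_truth <- function(genes, rate) {
  truth <- data.frame(read_id = character(), gene_id = character(),
                      rna_class = character(), locality = character(),
                      stringsAsFactors = FALSE)
  attr(truth, "gene_rates") <- data.frame(
    gene_id = genes$gene_id, rna_class = genes$rna_class,
    trans_rate = rate, stringsAsFactors = FALSE)
  truth
}

#' Generate non-overlapping bin-aligned regions
#'
#' Helper for track simulations: `n` regions of `width` bases, aligned to
#' `align` boundaries so that region means recover planted signals exactly,
#' spread round-robin across chromosomes.
#'
#' @param assembly A [genome_assembly()].
#' @param n Number of regions.
#' @param width Region width, bases.
#' @param align Alignment grid, bases (use the track bin size).
#' @param seed Integer RNG seed (strand assignment).
#' @return A `genomic_regions` data frame.
#' @export
make_regions <- function(assembly, n, width = 1000, align = width,
                         seed = 1) {
  stopifnot(inherits(assembly, "genome_assembly"))
  set.seed(seed)
  nc <- length(assembly$chrom_names)
  chrom <- assembly$chrom_names[(seq_len(n) - 1L) %% nc + 1L]
  slot <- (seq_len(n) - 1L) %/% nc
  stride <- 2 * ceiling(width / align) * align  # aligned, gap >= width
  start <- slot * stride
  end <- start + width
  L <- assembly$chrom_lengths[chrom]
  if (any(end > L)) {
    stop("assembly too small for ", n, " regions of width ", width)
  }
  new_genomic_regions(data.frame(
    chrom = chrom, start = start, end = end,
    name = sprintf("region_%03d", seq_len(n)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

#' Default planted mark signatures
#'
#' A k x 6 matrix of per-cluster mean CPM signals over the six core marks,
#' with cluster 1 the active state (high H3K27ac/H3K36me3) and cluster k
#' the repressed state, mirroring the C1..C4 interpretation.
#'
#' @param k Number of clusters (<= 4 uses the built-in states).
#' @return Numeric matrix, rows = clusters, columns = marks.
#' @export
default_mark_signatures <- function(k = 4) {
  marks <- c("H3K4me3", "H3K27ac", "H3K9ac", "H3K36me3", "H3K27me3",
             "RNAPol2")
  sig <- rbind(
    c(40, 50, 35, 30, 2, 25),   # active promoter/transcribed
    c(25, 20, 20, 8, 5, 30),    # moderately active
    c(8, 6, 5, 4, 10, 5),       # weak
    c(2, 1, 1, 1, 35, 1)        # polycomb-repressed
  )
  colnames(sig) <- marks
  if (k > nrow(sig)) stop("default signatures support k <= 4")
  sig[seq_len(k), , drop = FALSE]
}

#' Simulate chromatin-mark tracks with planted region clusters
#'
#' Each region is assigned a cluster; its per-mark signal is the cluster
#' signature plus Gaussian noise (truncated at 0), rendered into
#' bedGraph-backed binned tracks over a zero background. The returned
#' truth labels let downstream clustering be scored against ground truth.
#'
#' @param assembly A [genome_assembly()].
#' @param regions A `genomic_regions` data frame (bin-aligned regions from
#'   [make_regions()] give exact signal recovery at `noise_sd = 0`).
#' @param k_clusters Number of planted clusters.
#' @param mark_signatures k x n_marks matrix of per-cluster means;
#'   defaults to [default_mark_signatures()].
#' @param noise_sd Gaussian noise SD added per region x mark.
#' @param bin_size Track bin size, bases.
#' @param seed Integer RNG seed.
#' @return List with `tracks` (named list of raw `signal_track`s) and
#'   `labels` (integer cluster per region).
#' @export
simulate_tracks <- function(assembly, regions, k_clusters = 4,
                            mark_signatures = default_mark_signatures(k_clusters),
                            noise_sd = 1, bin_size = 100, seed = 1) {
  stopifnot(inherits(assembly, "genome_assembly"), noise_sd >= 0)
  if (nrow(mark_signatures) != k_clusters) {
    stop("mark_signatures must have k_clusters rows")
  }
  if (is.null(colnames(mark_signatures))) {
    stop("mark_signatures must have mark names as columns")
  }
  set.seed(seed)
  n <- nrow(regions)
  labels <- sample(rep_len(seq_len(k_clusters), n))
  marks <- colnames(mark_signatures)
  signal <- mark_signatures[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * length(marks), sd = noise_sd), n)
  signal[signal < 0] <- 0
  tracks <- lapply(seq_along(marks), function(j) {
    bin_records(regions$chrom, regions$start, regions$end, signal[, j],
                assembly, bin_size)
  })
  names(tracks) <- marks
  list(tracks = tracks, labels = labels)
}
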