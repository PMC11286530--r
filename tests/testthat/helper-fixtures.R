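# Shared fixtures and independent brute-force oracles.
# Oracles are deliberately naive (per-base accumulation, linear scans)
# so they stay independent of the vectorized implementation paths.

tiny_assembly <- function() genome_assembly(c("chr1", "chr2"), c(1e4, 8e3))

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Arbitrary (possibly overlapping) gene models for oracle comparisons.
random_genes <- function(assembly, n, seed) {
  set.seed(seed)
  chrom <- sample(assembly$chrom_names, n, replace = TRUE)
  L <- assembly$chrom_lengths[chrom]
  start <- floor(runif(n, 0, L * 0.8))
  len <- pmax(50, floor(runif(n, 50, L * 0.2)))
  end <- pmin(start + len, L)
  carna:::new_gene_models(data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    gene_name = sprintf("g%03d", seq_len(n)),
    rna_class = sample(rna_classes(), n, replace = TRUE),
    chrom = chrom, start = start, end = end,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

# Linear-scan gene assignment: same contract as assign_rna_end, O(n*m).
oracle_assign <- function(chrom, start, end, strand, genes,
                          priority = class_priority(),
                          allow_antisense = FALSE) {
  n <- length(chrom)
  gene_id <- rep(NA_character_, n)
  cls <- rep("unannotated", n)
  for (i in seq_len(n)) {
    same_strand <- if (allow_antisense) TRUE else
      genes$strand == strand[i]
    cand <- which(genes$chrom == chrom[i] & same_strand &
                    genes$start < end[i] & start[i] < genes$end)
    if (!length(cand)) next
    ov <- pmin(genes$end[cand], end[i]) - pmax(genes$start[cand], start[i])
    pr <- match(genes$rna_class[cand], priority)
    w <- cand[order(pr, -ov, genes$gene_id[cand])][1L]
    gene_id[i] <- genes$gene_id[w]
    cls[i] <- genes$rna_class[w]
  }
  data.frame(gene_id = gene_id, rna_class = cls, stringsAsFactors = FALSE)
}

# Per-base accumulation oracle for bedGraph binning: expand every record
# to individual bases, then average bases per bin (uncovered bases = 0).
oracle_bin_track <- function(chrom, start, end, value, assembly,
                             bin_size) {
  out <- list()
  for (chr in assembly$chrom_names) {
    L <- assembly$chrom_lengths[[chr]]
    base <- numeric(L)
    idx <- which(chrom == chr)
    for (i in idx) {
      base[(start[i] + 1):end[i]] <- base[(start[i] + 1):end[i]] + value[i]
    }
    nbin <- ceiling(L / bin_size)
    v <- numeric(nbin)
    for (b in seq_len(nbin)) {
      lo <- (b - 1) * bin_size + 1
      hi <- min(b * bin_size, L)
      v[b] <- mean(base[lo:hi])
    }
    out[[chr]] <- v
  }
  out
}

# Per-base oracle for region scoring over a signal_track.
oracle_region_score <- function(track, chrom, start, end) {
  bs <- track$bin_size
  v <- track$values[[chrom]]
  bases <- start:(end - 1)
  mean(v[floor(bases / bs) + 1])
}

# Minimal annotated-contacts fixture builder (plain data frame; the
# landscape functions operate on columns, not class attributes).
ann_fixture <- function(gene_id, rna_class, locality) {
  data.frame(gene_id = gene_id, rna_class = rna_class,
             locality = locality, stringsAsFactors = FALSE)
}

# Standard small simulated study shared by several tests.
small_study <- function(n_pairs = 2000, seed = 11,
                        nest = 0.5, sim_seed = 13) {
  assembly <- make_genome(3, 2e6)
  genes <- make_annotation(
    assembly,
    c(protein_coding = 20, lncRNA = 10, snoRNA = 8, snRNA = 4),
    nest_snorna_in_hosts = nest, seed = seed)
  cfg <- contact_sim_config(n_pairs, seed = sim_seed)
  sim <- simulate_contacts(genes, assembly, cfg)
  list(assembly = assembly, genes = genes, sim = sim,
       annotated = annotate_contacts(sim$pairs, genes))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Write a complete small study (pairs, GTF, chrom.sizes, regions, tracks)
# to disk and return a run_full() config list.
write_study_dir <- function(dir, n_pairs = 1000, seed = 17) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- small_study(n_pairs = n_pairs, seed = seed,
                       sim_seed = seed + 1)
  write_pairs(study$sim$pairs, file.path(dir, "pairs.tsv"))
  write_gene_gtf(study$genes, file.path(dir, "genes.gtf"))
  write_chrom_sizes(study$assembly, file.path(dir, "chrom.sizes"))
  regions <- make_regions(study$assembly, 40, width = 1000, align = 100,
                          seed = seed + 2)
  write_bed(regions, file.path(dir, "regions.bed"))
  tracks <- simulate_tracks(study$assembly, regions, 4, noise_sd = 1,
                            bin_size = 100, seed = seed + 3)$tracks
  paths <- list()
  for (m in names(tracks)) {
    p <- file.path(dir, paste0(m, ".bedgraph"))
    write_signal_bedgraph(tracks[[m]], p)
    paths[[m]] <- p
  }
  list(pairs = file.path(dir, "pairs.tsv"),
       gtf = file.path(dir, "genes.gtf"),
       chrom_sizes = file.path(dir, "chrom.sizes"),
       regions = file.path(dir, "regions.bed"),
       tracks = paths,
       track_bin_size = 100,
       out_dir = file.path(dir, "out"))
}
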