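test_that("pairs parser converts 1-based positions to 0-based intervals", {
  asm <- tiny_assembly()
  path <- write_lines_tmp(c("## pairs format v1.0",
                            "r1\tchr1\t100\tchr2\t5000\t+\t-"))
  p <- read_pairs(path, asm)
  expect_equal(nrow(p), 1L)
  expect_equal(p$rna_chrom, "chr1")
  expect_equal(p$rna_start, 99)
  expect_equal(p$rna_end, 100)
  expect_equal(p$rna_strand, "+")
  expect_equal(p$dna_chrom, "chr2")
  expect_equal(p$dna_start, 4999)
  expect_equal(p$dna_end, 5000)
  expect_equal(p$dna_strand, "-")
  expect_equal(attr(p, "skipped"), 0L)
})

test_that("header-only pairs file yields an empty stream", {
  p <- read_pairs(write_lines_tmp("## pairs format v1.0"),
                  tiny_assembly())
  expect_equal(nrow(p), 0L)
  expect_equal(attr(p, "skipped"), 0L)
})

test_that("records on unknown chromosomes are skipped and counted", {
  path <- write_lines_tmp(c("## pairs format v1.0",
                            "r1\tchrUn\t10\tchr1\t20\t+\t+"))
  p <- read_pairs(path, tiny_assembly())
  expect_equal(nrow(p), 0L)
  expect_equal(attr(p, "skipped"), 1L)
})

test_that("malformed pairs records raise line-numbered parse errors", {
  path <- write_lines_tmp(c("## pairs format v1.0",
                            "r1\tchr1\t10\tchr1\t20\t+\t+",
                            "r2\tchr1\t10\tchr1\t20\t+"))
  expect_error(read_pairs(path, tiny_assembly()), "line 3")
})

test_that("pairs round-trip record-for-record, including gzip", {
  study <- small_study(n_pairs = 500)
  plain <- tempfile(fileext = ".tsv")
  gz <- tempfile(fileext = ".tsv.gz")
  write_pairs(study$sim$pairs, plain)
  write_pairs(study$sim$pairs, gz)
  for (path in c(plain, gz)) {
    back <- read_pairs(path, study$assembly)
    expect_identical(as.data.frame(back), as.data.frame(study$sim$pairs))
  }
})

test_that("coordinate conversion is an involution on random intervals", {
  set.seed(42)
  start0 <- floor(runif(1000, 0, 1e6))
  end0 <- start0 + floor(runif(1000, 1, 1e4))
  one <- carna:::zero_to_one_based(start0, end0)
  back <- carna:::one_to_zero_based(one$start, one$end)
  expect_identical(back$start, start0)
  expect_identical(back$end, end0)
  # 1-based inclusive width and 0-based half-open width agree
  expect_true(all(one$end - one$start + 1 == end0 - start0))
})

test_that("GTF genes convert coordinates and map biotypes", {
  asm <- tiny_assembly()
  gtf <- write_lines_tmp(c(
    'chr1\tx\tgene\t1001\t1100\t.\t+\t.\tgene_id "G1"; gene_biotype "snoRNA";',
    'chr1\tx\tgene\t2001\t2500\t.\t-\t.\tgene_id "G2"; gene_biotype "weird_biotype";'
  ), ext = ".gtf")
  g <- read_gene_annotation(gtf, asm)
  expect_equal(g$start, c(1000, 2000))
  expect_equal(g$end, c(1100, 2500))
  expect_equal(g$rna_class, c("snoRNA", "other_ncRNA"))
})

test_that("duplicate gene ids are rejected; unknown chromosomes counted", {
  asm <- tiny_assembly()
  dup <- write_lines_tmp(c(
    'chr1\tx\tgene\t1\t100\t.\t+\t.\tgene_id "G1"; gene_biotype "snRNA";',
    'chr2\tx\tgene\t1\t100\t.\t+\t.\tgene_id "G1"; gene_biotype "snRNA";'
  ), ext = ".gtf")
  expect_error(read_gene_annotation(dup, asm), "duplicate gene_id")
  off <- write_lines_tmp(c(
    'chr1\tx\tgene\t1\t100\t.\t+\t.\tgene_id "G1"; gene_biotype "snRNA";',
    'chrUn\tx\tgene\t1\t100\t.\t+\t.\tgene_id "G2"; gene_biotype "snRNA";'
  ), ext = ".gtf")
  g <- read_gene_annotation(off, asm)
  expect_equal(g$gene_id, "G1")
  expect_equal(attr(g, "skipped"), 1L)
})

test_that("gene models survive a GTF write/read round trip", {
  study <- small_study(n_pairs = 0)
  path <- tempfile(fileext = ".gtf")
  write_gene_gtf(study$genes, path)
  back <- read_gene_annotation(path, study$assembly)
  a <- as.data.frame(study$genes)[order(study$genes$gene_id), ]
  b <- as.data.frame(back)[order(back$gene_id), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("BED reading validates coordinates with line numbers", {
  asm <- tiny_assembly()
  r <- read_bed(write_lines_tmp("chr1\t0\t10"), asm)
  expect_equal(r$start, 0)
  expect_equal(r$end, 10)
  expect_equal(r$strand, ".")
  expect_equal(nrow(read_bed(write_lines_tmp(character()), asm)), 0L)
  expect_error(read_bed(write_lines_tmp("chr1\t10\t10"), asm), "line 1")
  expect_error(read_bed(write_lines_tmp("chrUn\t0\t10"), asm),
               "unknown chromosome")
  r6 <- read_bed(write_lines_tmp("chr2\t5\t25\tpeak1\t0\t-"), asm)
  expect_equal(r6$name, "peak1")
  expect_equal(r6$strand, "-")
})

test_that("bedGraph binning matches hand-derived weighted means", {
  asm <- tiny_assembly()
  t1 <- read_signal_bedgraph(write_lines_tmp("chr1\t0\t100\t2.0"),
                             asm, bin_size = 50)
  expect_equal(t1$values$chr1[1:2], c(2, 2))
  t2 <- read_signal_bedgraph(write_lines_tmp("chr1\t0\t25\t4.0"),
                             asm, bin_size = 50)
  expect_equal(t2$values$chr1[1], 2.0)  # 25/50 of the bin at value 4
  t3 <- read_signal_bedgraph(write_lines_tmp(character()), asm, 50)
  expect_true(all(unlist(t3$values) == 0))
  expect_error(
    read_signal_bedgraph(write_lines_tmp(c("chr1\t0\t100\t1",
                                           "chr1\t50\t150\t2")), asm, 50),
    "overlapping")
})

test_that("bedGraph binning equals per-base accumulation on random tracks", {
  asm <- genome_assembly(c("cA", "cB"), c(7300, 4100))
  for (case_seed in 1:5) {
    set.seed(case_seed)
    n <- sample(10:50, 1)
    chrom <- sample(asm$chrom_names, n, replace = TRUE)
    # non-overlapping records per chromosome: partition fixed slots
    start <- numeric(n); end <- numeric(n)
    for (chr in unique(chrom)) {
      idx <- which(chrom == chr)
      slots <- sort(sample(seq(0, asm$chrom_lengths[[chr]] - 60, by = 60),
                           length(idx)))
      start[idx] <- slots
      end[idx] <- slots + sample(10:60, length(idx), replace = TRUE)
    }
    value <- round(runif(n, 0, 10), 3)
    lines <- paste(chrom, start, end, value, sep = "\t")
    bs <- sample(c(37, 100, 250), 1)
    track <- read_signal_bedgraph(write_lines_tmp(lines), asm, bs)
    oracle <- oracle_bin_track(chrom, start, end, value, asm, bs)
    expect_equal(track$values$cA, oracle$cA, tolerance = 1e-9)
    expect_equal(track$values$cB, oracle$cB, tolerance = 1e-9)
  }
})

test_that("signal tracks survive a bedGraph write/read round trip", {
  asm <- tiny_assembly()
  sim <- simulate_tracks(asm, make_regions(asm, 10, width = 200,
                                           align = 100, seed = 1),
                         k_clusters = 2,
                         mark_signatures = default_mark_signatures(2),
                         noise_sd = 0.5, bin_size = 100, seed = 2)
  tr <- sim$tracks[[1L]]
  path <- tempfile(fileext = ".bedgraph")
  write_signal_bedgraph(tr, path)
  back <- read_signal_bedgraph(path, asm, 100)
  expect_equal(back$values, tr$values, tolerance = 1e-12)
})

test_that("chrom.sizes files round trip", {
  asm <- tiny_assembly()
  path <- tempfile()
  write_chrom_sizes(asm, path)
  back <- read_chrom_sizes(path)
  expect_equal(back$chrom_names, asm$chrom_names)
  expect_equal(back$chrom_lengths, asm$chrom_lengths)
})
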