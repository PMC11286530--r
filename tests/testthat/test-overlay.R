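uniform_track <- function(assembly, value, bin_size = 100,
                          normalization = "raw") {
  tr <- carna:::zero_track(assembly, bin_size, normalization)
  tr$values <- lapply(tr$values, function(v) rep(value, length(v)))
  tr
}

planted_fixture <- function(n_regions = 200, noise_sd = 1, seed = 21) {
  asm <- make_genome(4, 2e6)
  regions <- make_regions(asm, n_regions, width = 1000, align = 100,
                          seed = seed)
  sim <- simulate_tracks(asm, regions, k_clusters = 4,
                         noise_sd = noise_sd, bin_size = 100,
                         seed = seed + 1)
  list(assembly = asm, regions = regions, tracks = sim$tracks,
       labels = sim$labels)
}

test_that("CPM normalization scales by library size once", {
  asm <- tiny_assembly()
  tr <- uniform_track(asm, 5)
  expect_equal(cpm_normalize(tr, 1e6)$values$chr1[1], 5)
  tr10 <- uniform_track(asm, 10)
  norm <- cpm_normalize(tr10, 2e6)
  expect_equal(norm$values$chr1[1], 5)
  expect_equal(norm$normalization, "CPM")
  expect_error(cpm_normalize(norm, 1e6), "already normalized")
  zero <- cpm_normalize(uniform_track(asm, 0), 1e6)
  expect_true(all(unlist(zero$values) == 0))
})

test_that("region scores are exact on uniform tracks", {
  asm <- tiny_assembly()
  regions <- make_regions(asm, 6, width = 500, align = 100, seed = 3)
  em <- score_regions(regions, list(m1 = uniform_track(asm, 7),
                                    m2 = uniform_track(asm, 2)))
  expect_equal(dim(em$scores), c(6L, 2L))
  expect_true(all(em$scores[, "m1"] == 7))
  expect_true(all(em$scores[, "m2"] == 2))
  empty <- regions[integer(), ]
  expect_equal(nrow(score_regions(empty,
                                  list(m1 = uniform_track(asm, 7)))$scores),
               0L)
})

test_that("region scores equal the per-base oracle on random tracks", {
  asm <- genome_assembly(c("cA", "cB"), c(5300, 4100))
  set.seed(7)
  for (rep in 1:5) {
    tr <- carna:::zero_track(asm, 100)
    tr$values <- lapply(tr$values, function(v) round(runif(length(v), 0,
                                                           10), 3))
    n <- 20
    chrom <- sample(asm$chrom_names, n, replace = TRUE)
    start <- floor(runif(n, 0, asm$chrom_lengths[chrom] - 150))
    end <- start + sample(10:150, n, replace = TRUE)
    regions <- data.frame(chrom = chrom, start = start, end = end,
                          name = ".", strand = "+")
    em <- score_regions(regions, list(m = tr))
    for (i in seq_len(n)) {
      expect_equal(unname(em$scores[i, "m"]),
                   oracle_region_score(tr, chrom[i], start[i], end[i]),
                   tolerance = 1e-9)
    }
  }
})

test_that("average profile is flat on uniform tracks and recovers bins", {
  asm <- tiny_assembly()
  regions <- make_regions(asm, 4, width = 600, align = 100, seed = 5)
  prof <- average_profile(uniform_track(asm, 3), regions, flank = 100,
                          n_bins = 20)
  expect_equal(prof, rep(3, 20))
  # single region, no flank, n_bins = region bins -> the region's values
  tr <- carna:::zero_track(asm, 100)
  tr$values$chr1[1:4] <- c(1, 5, 2, 8)
  one <- data.frame(chrom = "chr1", start = 0, end = 400, name = ".",
                    strand = "+")
  expect_equal(average_profile(tr, one, flank = 0, n_bins = 4),
               c(1, 5, 2, 8))
})

test_that("profiles are strand-aware and symmetric on symmetric peaks", {
  asm <- genome_assembly("chr1", 1000)
  tr <- carna:::zero_track(asm, 100)
  tr$values$chr1 <- c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1)
  plus <- data.frame(chrom = "chr1", start = 0, end = 1000, name = ".",
                     strand = "+")
  prof <- average_profile(tr, plus, n_bins = 10)
  expect_equal(prof, rev(prof))  # symmetric fixture, symmetric profile
  minus <- plus
  minus$strand <- "-"
  asym <- carna:::zero_track(asm, 100)
  asym$values$chr1 <- 1:10
  expect_equal(average_profile(asym, minus, n_bins = 10),
               rev(average_profile(asym, plus, n_bins = 10)))
})

test_that("k-means recovers planted clusters exactly and stably", {
  fx <- planted_fixture()
  em <- score_regions(fx$regions, fx$tracks)
  cl <- cluster_regions(em, k = 4, seed = 7)
  expect_equal(adjusted_rand(cl$labels, fx$labels), 1.0)
  # bit-stable for a fixed seed
  cl2 <- cluster_regions(em, k = 4, seed = 7)
  expect_identical(cl$labels, cl2$labels)
  # stable across seeds on a well-separated fixture
  for (s in c(1, 99, 1234)) {
    expect_gte(adjusted_rand(cluster_regions(em, k = 4, seed = s)$labels,
                             fx$labels), 0.95)
  }
  # C1 carries the highest mean of the labeling mark
  means <- tapply(em$scores[, "H3K27ac"], cl$labels, mean)
  expect_equal(names(which.max(means)), "C1")
  expect_true(all(diff(means[paste0("C", 1:4)]) <= 0))
})

test_that("clustering is equivariant under region permutation", {
  fx <- planted_fixture(n_regions = 80)
  em <- score_regions(fx$regions, fx$tracks)
  cl <- cluster_regions(em, k = 4, seed = 3)
  set.seed(1)
  perm <- sample(nrow(fx$regions))
  em_p <- score_regions(fx$regions[perm, ], fx$tracks)
  cl_p <- cluster_regions(em_p, k = 4, seed = 3)
  expect_identical(as.character(cl_p$labels),
                   as.character(cl$labels)[perm])
})

test_that("duplicate regions get identical labels; degenerate input errors", {
  fx <- planted_fixture(n_regions = 40)
  dup <- rbind(fx$regions, fx$regions)
  em <- score_regions(dup, fx$tracks)
  cl <- cluster_regions(em, k = 4, seed = 2)
  expect_identical(cl$labels[1:40], cl$labels[41:80])
  # k = 1 trivially assigns everything to C1
  em1 <- score_regions(fx$regions, fx$tracks)
  expect_true(all(cluster_regions(em1, k = 1)$labels == "C1"))
  # constant matrix has no structure
  asm <- tiny_assembly()
  regions <- make_regions(asm, 5, width = 200, align = 100, seed = 1)
  flat <- score_regions(regions, list(H3K27ac = uniform_track(asm, 3)))
  expect_error(cluster_regions(flat, k = 2), "constant")
  expect_error(cluster_regions(em1, k = 50), "exceeds")
})

test_that("condition comparison is zero on identical tracks", {
  asm <- tiny_assembly()
  regions <- make_regions(asm, 8, width = 300, align = 100, seed = 4)
  a <- cpm_normalize(uniform_track(asm, 4), 1e6)
  for (pc in c(0.1, 1, 5)) {
    cmp <- compare_conditions(regions, a, a, pseudocount = pc)
    expect_true(all(cmp$log2_ratio == 0))
  }
})

test_that("condition comparison follows the pseudocount closed form", {
  asm <- tiny_assembly()
  regions <- make_regions(asm, 8, width = 300, align = 100, seed = 4)
  set.seed(8)
  a <- carna:::zero_track(asm, 100, "CPM")
  b <- carna:::zero_track(asm, 100, "CPM")
  a$values <- lapply(a$values, function(v) runif(length(v), 0, 20))
  b$values <- lapply(b$values, function(v) runif(length(v), 0, 20))
  cmp <- compare_conditions(regions, a, b, pseudocount = 1)
  sa <- score_regions(regions, list(x = a))$scores[, 1]
  sb <- score_regions(regions, list(x = b))$scores[, 1]
  expect_equal(cmp$log2_ratio, unname(log2((sb + 1) / (sa + 1))))
  expect_equal(cmp$mean_log2_ratio, mean(cmp$log2_ratio))
  # doubling the signal pushes ratios toward 1 as scores dominate the
  # pseudocount
  b2 <- a
  b2$values <- lapply(a$values, function(v) v * 2)
  lo <- compare_conditions(regions, a, b2, pseudocount = 1)
  hi_a <- a
  hi_a$values <- lapply(a$values, function(v) v * 100)
  hi_b <- b2
  hi_b$values <- lapply(b2$values, function(v) v * 100)
  hi <- compare_conditions(regions, hi_a, hi_b, pseudocount = 1)
  expect_true(all(hi$log2_ratio > lo$log2_ratio))
  expect_true(all(abs(hi$log2_ratio - 1) < 0.05))
  # raw tracks are refused
  expect_error(compare_conditions(regions, uniform_track(asm, 1),
                                  uniform_track(asm, 1)),
               "CPM")
})
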