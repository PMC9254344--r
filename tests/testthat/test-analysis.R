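test_that("size classification splits exactly at the published boundaries", {
  fr <- make_fragments(c(24, 25, 50, 100, 101, 250, 251))
  p <- size_filter_classify(fr)
  expect_setequal(fragment_lengths(p$uscf), c(25, 50, 100))
  expect_setequal(fragment_lengths(p$mncf), c(101, 250))
  expect_setequal(fragment_lengths(p$excluded), c(24, 251))
})

test_that("classification is an exhaustive disjoint partition", {
  fr <- make_fragments(1:300)
  p <- size_filter_classify(fr)
  expect_equal(nrow(p$uscf), 76L)      # 25..100
  expect_equal(nrow(p$mncf), 150L)     # 101..250
  expect_equal(nrow(p$excluded), 74L)  # 1..24 and 251..300
  expect_equal(nrow(p$uscf) + nrow(p$mncf) + nrow(p$excluded), nrow(fr))
  empty <- size_filter_classify(make_fragments(numeric(0)))
  expect_true(all(vapply(empty, nrow, 1L) == 0L))
})

test_that("deduplication keeps one representative per coordinate+UMI key", {
  fr <- make_fragments(c(50, 50), umi = c("AAAAAAAA", "AAAAAAAA"))
  expect_equal(nrow(deduplicate(fr)), 1L)
  fr2 <- make_fragments(c(50, 50), umi = c("AAAAAAAA", "CCCCCCCC"))
  expect_equal(nrow(deduplicate(fr2)), 2L)
  bad <- make_fragments(50); bad$umi <- ""
  expect_error(deduplicate(bad), "UMI")
})

test_that("deduplication equals the brute-force key-set oracle", {
  set.seed(31)
  n <- 10000
  base <- make_fragments(sample(25:250, n, TRUE),
                         start = sample(1:5000, n, TRUE),
                         umi = sample(replicate(50, paste(
                           sample(c("A", "C", "G", "T"), 8, TRUE),
                           collapse = "")), n, TRUE))
  dup <- base[sample(n, 2000, TRUE), ]   # plant exact duplicates
  fr <- fragment_set(rbind(as.data.frame(base), as.data.frame(dup)))
  oracle <- nrow(unique(data.frame(fr$contig, fr$start, fr$end, fr$strand,
                                   fr$umi)))
  expect_equal(nrow(deduplicate(fr)), oracle)
})

test_that("modal length takes the argmax with smallest-length tie-break", {
  h <- length_histogram(rep(c(49, 50, 51), c(3, 10, 2)))
  expect_equal(modal_length(h), 50L)
  tie <- length_histogram(rep(c(50, 60), c(5, 5)))
  expect_equal(modal_length(tie), 50L)
  expect_error(modal_length(length_histogram(numeric(0))), "empty")
})

test_that("histogram counts conserve fragments over a dense grid", {
  x <- c(25, 25, 30, 100)
  h <- length_histogram(x)
  expect_equal(sum(h$count), length(x))
  expect_equal(h$length, 25:100)
  expect_equal(h$count[h$length == 25], 2L)
})

test_that("periodicity finds constructed comb spacings", {
  mk_comb <- function(spacing) {
    counts <- rep(10, 61)
    counts[seq(1, 61, spacing)] <- 110
    length_histogram(rep(100:160, times = counts))
  }
  expect_equal(periodicity(mk_comb(10))$period, 10L)
  expect_equal(periodicity(mk_comb(7))$period, 7L)
  expect_error(periodicity(mk_comb(10), window = c(100, 130)),
               "window")
})

test_that("chromosome distribution validates contigs and normalizes", {
  gm <- toy_genome()
  fr <- make_fragments(rep(50, 10))
  cd <- chrom_distribution(fr, gm)
  expect_equal(cd$fraction[cd$contig == "chrA"], 1.0)
  expect_equal(sum(cd$count), 10L)
  alien <- make_fragments(50, contig = "chrZ")
  expect_error(chrom_distribution(alien, gm), "chrZ")
})

test_that("uniform placement gives equal per-Mb density on equal contigs", {
  gm <- default_genome(); ann <- default_annotation()
  fr <- cached("sim_uniform",
               simulate_population(gm, ann, uniform_config(), seed = 5))
  cd <- chrom_distribution(fr, gm)
  pa <- cd$fraction[cd$contig == "chrA"]
  pb <- cd$fraction[cd$contig == "chrB"]
  se <- sqrt(0.5 * 0.5 / nrow(fr))
  expect_lt(abs(pa - pb), 3 * 2 * se)
})

test_that("binned coverage assigns by midpoint and conserves counts", {
  gm <- toy_genome()
  fr <- make_fragments(50, start = 0)          # [0, 50): midpoint 25
  bc <- bin_coverage(fr, gm)
  expect_equal(bc$counts[1], 1L)
  fr2 <- make_fragments(100, start = 50)       # [50, 150): midpoint 100
  bc2 <- bin_coverage(fr2, gm)
  expect_equal(bc2$counts[2], 1L)              # half-open bins: bin index 1
  expect_equal(length(bc$counts),
               sum(ceiling(gm$contigs$length / 100)))
  sim <- simulate_population(gm, toy_annotation(),
                             population_config(n_total = 5000), seed = 17)
  expect_equal(sum(bin_coverage(sim, gm)$counts), 5000L)
})

test_that("Pearson matrix is symmetric with unit diagonal", {
  v <- c(1, 4, 2, 8, 5, 7)
  m <- pearson_matrix(list(a = v, b = v))
  expect_equal(unname(m["a", "b"]), 1.0)
  m2 <- pearson_matrix(list(a = v, b = 2 * mean(v) - v))  # reflect about mean
  expect_equal(unname(m2["a", "b"]), -1.0)
  expect_equal(diag(m2), c(a = 1, b = 1))
  expect_equal(m2, t(m2))
  expect_error(pearson_matrix(list(good = v, flat = rep(3, 6))), "flat")
  expect_error(pearson_matrix(list(a = v, b = v[-1])), "equal length")
})

test_that("replicate simulations correlate above a shuffled control", {
  gm <- toy_genome(); ann <- toy_annotation()
  cfg <- population_config(n_total = 8000)
  for (s in 1:10) {
    a <- bin_coverage(simulate_population(gm, ann, cfg, seed = s), gm,
                      bin_size = 1000)$counts
    b <- bin_coverage(simulate_population(gm, ann, cfg, seed = s + 500), gm,
                      bin_size = 1000)$counts
    set.seed(s)
    shuffled <- sample(b)
    m <- pearson_matrix(list(a = a, b = b, shuf = shuffled))
    expect_gt(m["a", "b"], m["a", "shuf"])
  }
})

test_that("fragment annotation is the midpoint bp class", {
  ann <- toy_annotation(n_genes = 4L, seed = 12L)
  oracle <- brute_force_classes(ann, "chrA")
  set.seed(41)
  fr <- make_fragments(sample(25:250, 2000, TRUE),
                       start = sample(0:40000, 2000, TRUE))
  got <- annotate_fragments(fr, ann)
  expect_identical(got, oracle[fragment_midpoints(fr) + 1])
  out_of_range <- make_fragments(100, start = 199990)
  expect_error(annotate_fragments(out_of_range, ann), "outside")
})

test_that("element profiles normalize and ratio against the baseline", {
  base <- c(promoter = 0.1, TTS = 0.1, exon = 0.2, intron = 0.2,
            intergenic = 0.4)
  prof <- element_profile(rep("exon", 50), base)
  expect_equal(prof$proportion[prof$class == "exon"], 1.0)
  expect_equal(sum(prof$proportion), 1.0)
  expect_equal(prof$ratio_to_baseline[prof$class == "exon"], 5.0)
  expect_error(element_profile(character(0), base), "no fragments")
})

test_that("default enrichment points uscf toward genes and mncf away", {
  gm <- default_genome(); ann <- default_annotation()
  fr <- default_simulation()
  p <- size_filter_classify(fr)
  us <- element_profile(annotate_fragments(p$uscf, ann), ann$baseline)
  mn <- element_profile(annotate_fragments(p$mncf, ann), ann$baseline)
  ratio <- function(pr, cls) pr$ratio_to_baseline[pr$class == cls]
  expect_gt(ratio(us, "promoter"), 1); expect_gt(ratio(us, "exon"), 1)
  expect_gt(ratio(us, "intron"), 1); expect_lt(ratio(us, "intergenic"), 1)
  expect_lt(ratio(mn, "promoter"), 1); expect_lt(ratio(mn, "exon"), 1)
  expect_lt(ratio(mn, "intron"), 1); expect_gt(ratio(mn, "intergenic"), 1)
})

test_that("size-binned profiles localize mass and flag empty bins", {
  ann <- toy_annotation()
  fr <- make_fragments(rep(47, 200), start = sample(0:40000, 200, TRUE))
  sbp <- size_binned_profile(fr, ann)
  in_bin <- sbp[sbp$bin_lo == 45, ]
  expect_true(all(in_bin$n == 200))
  expect_equal(sum(in_bin$proportion), 1.0)
  expect_true(all(is.na(sbp$proportion[sbp$bin_lo != 45])))
})

test_that("uniform placement keeps every size bin's ratios near 1", {
  gm <- default_genome(); ann <- default_annotation()
  fr <- cached("sim_uniform",
               simulate_population(gm, ann, uniform_config(), seed = 5))
  us <- size_filter_classify(fr)$uscf
  sbp <- size_binned_profile(us, ann)
  sbp <- sbp[!is.na(sbp$proportion), ]
  for (i in seq_len(nrow(sbp))) {
    b <- ann$baseline[[sbp$class[i]]]
    se <- sqrt(b * (1 - b) / sbp$n[i])
    expect_lt(abs(sbp$proportion[i] - b), 4 * se)
  }
})

test_that("size-conditioned enrichment peaks promoters at 45-55 nt", {
  gm <- default_genome(); ann <- default_annotation()
  fr <- cached("sim_sizecond",
               simulate_population(gm, ann,
                                   population_config(n_total = 50000,
                                                     frac_uscf = 1),
                                   seed = 19))
  sbp <- size_binned_profile(fr, ann)
  prom <- sbp[sbp$class == "promoter", ]
  expect_equal(prom$bin_lo[which.max(prom$ratio_to_baseline)], 45)
  inter <- sbp[sbp$class == "intergenic", ]
  expect_gt(inter$ratio_to_baseline[inter$bin_lo == 95],
            inter$ratio_to_baseline[inter$bin_lo == 55])
})
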