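mixed_set <- function(n = 4000, seed = 21) {
  simulate_population(toy_genome(), toy_annotation(),
                      population_config(n_total = n), seed = seed)
}

test_that("dsDNase at full efficiency removes exactly the duplex states", {
  fr <- mixed_set()
  out <- digest(fr, treatment_spec("dsDNase", efficiency = 1), seed = 1)
  expect_true(all(out$state == "ss"))
  expect_equal(nrow(out), sum(fr$state == "ss"))
})

test_that("single-strand nucleases empty a pure-ss set at full efficiency", {
  fr <- make_fragments(rep(50, 500))
  for (enz in c("S1", "P1", "ExoI"))
    expect_equal(nrow(digest(fr, treatment_spec(enz, efficiency = 1),
                             seed = 1)), 0L)
})

test_that("DNaseI at full efficiency empties any fragment set", {
  for (fr in list(mixed_set(1000, seed = 3), make_fragments(rep(160, 50))))
    expect_equal(nrow(digest(fr, treatment_spec("DNaseI", efficiency = 1),
                             seed = 1)), 0L)
})

test_that("RNase is the identity on DNA fragments", {
  fr <- mixed_set(1000, seed = 4)
  out <- digest(fr, treatment_spec("RNase"), seed = 1)
  expect_equal(nrow(out), nrow(fr))
  expect_equal(out$start, fr$start)
  expect_true(all(grepl("digest:RNase", out$treatment_history)))
})

test_that("unknown enzymes are a configuration error", {
  expect_error(treatment_spec("EcoRI"), "unknown enzyme")
})

test_that("partial dsDNase reduces mncf by ~efficiency and leaves uscf alone", {
  fr <- default_simulation()
  eff <- 0.6
  out <- digest(fr, treatment_spec("dsDNase", efficiency = eff), seed = 8)
  pre <- size_filter_classify(fr); post <- size_filter_classify(out)
  # ss molecules are untouched, deterministically
  expect_equal(nrow(post$uscf), nrow(pre$uscf))
  n_ds <- nrow(pre$mncf)
  surv <- nrow(post$mncf) / n_ds
  se <- sqrt(eff * (1 - eff) / n_ds)
  expect_lt(abs(surv - (1 - eff)), 3 * se)
})

test_that("no treatment increases length or total bp; only S1 adds molecules", {
  fr <- mixed_set(3000, seed = 6)
  max_len <- max(fragment_lengths(fr))
  # duplex restoration can exceed the observed ladder piece, so compare
  # against the stored duplex lengths for nick repair
  max_dup <- max(max_len, fr$duplex_length, na.rm = TRUE)
  total_bp <- sum(fragment_lengths(fr))
  total_dup_bp <- sum(ifelse(is.na(fr$duplex_length),
                             fragment_lengths(fr), fr$duplex_length))
  for (enz in c("dsDNase", "S1", "P1", "ExoI", "DNaseI", "nick_repair",
                "RNase")) {
    out <- digest(fr, treatment_spec(enz), seed = 7,
                  genome = toy_genome())
    expect_lte(max(fragment_lengths(out), -Inf), max_dup)
    expect_lte(sum(fragment_lengths(out)), total_dup_bp)
    if (enz != "S1") expect_lte(nrow(out), nrow(fr))
  }
  s1 <- digest(fr, treatment_spec("S1", efficiency = 1), seed = 7)
  expect_lte(sum(fragment_lengths(s1)), total_bp)
})

test_that("S1 shifts the mononucleosomal mode down 10 bp and flattens the ladder", {
  fr <- default_simulation()
  pre <- size_filter_classify(fr)
  per_pre <- periodicity(length_histogram(pre$mncf))
  out <- digest(fr, treatment_spec("S1"), seed = 9, genome = default_genome())
  post <- size_filter_classify(out)
  expect_equal(modal_length(length_histogram(pre$mncf)), 160L)
  expect_equal(modal_length(length_histogram(post$mncf)), 150L)
  per_post <- periodicity(length_histogram(post$mncf))
  expect_lt(per_post$contrast, per_pre$contrast)
})

test_that("nick repair restores duplex lengths and flattens the ladder", {
  fr <- default_simulation()
  per_pre <- periodicity(length_histogram(size_filter_classify(fr)$mncf))
  out <- digest(fr, treatment_spec("nick_repair", efficiency = 1), seed = 10,
                genome = default_genome())
  expect_false(any(out$state == "ds_nicked"))
  expect_true(all(out$nicks == ""))
  expect_equal(nrow(out), nrow(fr))
  per_post <- periodicity(length_histogram(size_filter_classify(out)$mncf))
  expect_lt(per_post$contrast, per_pre$contrast)
  # repaired molecules sit at their full duplex length
  nk <- fr$state == "ds_nicked"
  expect_equal(sort(fragment_lengths(out[nk, ])),
               sort(as.integer(fr$duplex_length[nk])))
})

test_that("ds-kit libraries reject single strands; ss-kit sizes add adapters", {
  ss_only <- make_fragments(rep(50, 200))
  expect_equal(nrow(prepare_library(ss_only, library_prep(kit = "ds"))), 0L)
  lib <- prepare_library(make_fragments(50), library_prep(kit = "ss"))
  expect_equal(lib$library_size, 200)
  expect_equal(library_to_insert(lib$library_size), 50)
})

test_that("ds-kit admits nicked duplexes at duplex length only when enabled", {
  fr <- mixed_set(4000, seed = 13)
  with_nick <- prepare_library(fr, library_prep(kit = "ds"))
  expect_setequal(unique(with_nick$state), c("ds_intact", "ds_nicked"))
  nk <- with_nick$state == "ds_nicked"
  expect_equal(with_nick$library_size[nk],
               with_nick$duplex_length[nk] + 150)
  without <- prepare_library(fr, library_prep(kit = "ds",
                                              include_nicked_in_ds = FALSE))
  expect_true(all(without$state == "ds_intact"))
})

test_that("skipping heat denaturation admits few duplexes but keeps ss", {
  ds_only <- make_fragments(rep(160, 1000), state = "ds_intact",
                            population = "mncf")
  n_heat <- nrow(prepare_library(ds_only, library_prep(kit = "ss",
                                                       heat_denaturation = TRUE)))
  expect_equal(n_heat, 1000L)
  tot <- 0
  for (s in 1:10)
    tot <- tot + nrow(prepare_library(ds_only,
                                      library_prep(kit = "ss",
                                                   heat_denaturation = FALSE),
                                      seed = s))
  # expected leak 5%; allow 3 binomial SE above it
  expect_lt(tot / (10 * 1000), 0.05 + 3 * sqrt(0.05 * 0.95 / 10000))
  # the ultrashort single strands always remain
  mix <- mixed_set(2000, seed = 14)
  noheat <- prepare_library(mix, library_prep(kit = "ss",
                                              heat_denaturation = FALSE),
                            seed = 2)
  expect_equal(sum(noheat$state == "ss"), sum(mix$state == "ss"))
})

test_that("treatment direction: ds-nucleases enrich uscf share, ss-nucleases mncf", {
  fr <- default_simulation()
  share_us <- function(x) {
    p <- size_filter_classify(x)
    nrow(p$uscf) / (nrow(p$uscf) + nrow(p$mncf))
  }
  base <- share_us(fr)
  expect_gt(share_us(digest(fr, treatment_spec("dsDNase"), seed = 1)), base)
  for (enz in c("S1", "P1", "ExoI"))
    expect_lt(share_us(digest(fr, treatment_spec(enz), seed = 2)), base)
  expect_lt(share_us(prepare_library(fr, library_prep(kit = "ds"))), base)
})
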