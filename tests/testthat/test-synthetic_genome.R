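gc_of <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  mean(ch %in% c("C", "G"))
}

test_that("background generation hits the requested composition and is deterministic", {
  asm <- generate_background(1, 10000, gc = 0.5, seed = 3)
  # binomial 3 s.d. band around 0.5 at n = 10 kb
  expect_lt(abs(gc_of(asm$seq[[1]]) - 0.5), 3 * sqrt(0.25 / 10000))
  asm2 <- generate_background(1, 10000, gc = 0.5, seed = 3)
  expect_identical(asm$seq, asm2$seq)
  asm3 <- generate_background(1, 10000, gc = 0.5, seed = 4)
  expect_false(identical(asm$seq, asm3$seq))
  expect_error(generate_background(2, function(n) rep(0L, n)),
               "non-positive")
})

test_that("hotspot blocks shift mixture GC to the closed-form mean", {
  asm <- generate_background(
    1, 50000, gc = 0.37,
    hotspot_model = list(fraction = 0.2, gc = 0.19, block_bp = 2000),
    seed = 11)
  hot <- attr(asm, "hotspots")
  expect_identical(sum(hot$end - hot$start), 10000L)
  mix_mean <- 0.8 * 0.37 + 0.2 * 0.19
  expect_lt(abs(gc_of(asm$seq[[1]]) - mix_mean), 3 * sqrt(0.25 / 50000))
  # hotspot segments themselves are AT-rich
  hot_gc <- gc_of(substr(asm$seq[[1]], hot$start[1] + 1, hot$end[1]))
  expect_lt(abs(hot_gc - 0.19), 3 * sqrt(0.19 * 0.81 / 2000))
})

test_that("LTR divergence is calibrated: E[K] = 2 r T", {
  ltr <- make_ltr(200L)
  dv <- diverge_ltr_pair(ltr, 0, seed = 1)
  expect_identical(dv$ltr5, dv$ltr3)
  expect_identical(dv$realized_K, 0)
  expect_error(diverge_ltr_pair(ltr, 7e7), "saturated")
  set.seed(5)
  ks <- replicate(2000, diverge_ltr_pair(ltr, 1e6)$realized_K)
  se <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - 0.0108), 3 * se)
  # calibration holds across the observed age range
  for (age in c(0.5e6, 6e6, 12e6)) {
    ks <- replicate(400, diverge_ltr_pair(ltr, age)$realized_K)
    expect_lt(abs(mean(ks) - 2 * 0.54e-8 * age),
              3 * sd(ks) / sqrt(length(ks)) + 1e-4)
  }
})

test_that("planting follows the TSD duplication convention and bookkeeping", {
  asm <- generate_background(1, 5000, seed = 21)
  ltr <- make_ltr(160L)
  internal <- random_dna(300L)
  sp <- plant_spec(ltr, internal, age_years = 0, category = "complete",
                   scaffold = "scaf001", position = 1000L)
  res <- plant_elements(asm, list(sp), seed = 1)
  # 620 bp element + one extra TSD copy
  expect_identical(total_length(res$assembly), total_length(asm) + 624L)
  reg <- res$registry
  expect_identical(reg$start, 1004L)
  expect_identical(reg$end, 1624L)
  # identical flanking 4-mers, host-derived
  seq <- res$assembly$seq[[1]]
  expect_identical(substr(seq, 1001, 1004), substr(seq, 1625, 1628))
  expect_identical(substr(seq, 1001, 1004), reg$tsd)
  # zero specs: unchanged assembly, empty registry
  res0 <- plant_elements(asm, list())
  expect_identical(res0$assembly$seq, asm$seq)
  expect_identical(nrow(res0$registry), 0L)
})

test_that("solo specs write their TSD and truncation keeps a fragment", {
  asm <- generate_background(1, 5000, seed = 22)
  ltr <- make_ltr(150L)
  solo <- plant_spec(ltr, tsd = "ATAT", age_years = 0,
                     category = "solo_ltr", scaffold = "scaf001",
                     position = 2000L)
  res <- plant_elements(asm, list(solo), seed = 2)
  seq <- res$assembly$seq[[1]]
  reg <- res$registry
  inserted <- substr(seq, reg$start - 3, reg$end + 4)
  expect_identical(substr(inserted, 1, 4), "ATAT")
  expect_identical(substr(inserted, nchar(inserted) - 3, nchar(inserted)),
                   "ATAT")
  expect_identical(reg$seq, ltr)
  tr <- plant_spec(ltr, random_dna(200L), age_years = 0,
                   category = "truncated", scaffold = "scaf001",
                   position = 3000L, truncate_frac = 0.6,
                   truncate_side = "3p")
  res2 <- plant_elements(asm, list(tr), seed = 3)
  full_len <- 2L * 150L + 200L
  expect_identical(res2$registry$end - res2$registry$start,
                   as.integer(round(0.6 * full_len)))
  # colliding positions are rejected
  expect_error(
    plant_elements(asm, list(solo,
                             plant_spec(ltr, tsd = "ACGT", age_years = 0,
                                        category = "solo_ltr",
                                        scaffold = "scaf001",
                                        position = 2002L))),
    "colliding")
})

test_that("registry completeness: every planted copy is recoverable exactly", {
  res <- planted_genome(seed = 301L)
  reg <- res$registry
  expect_identical(nrow(reg), 4L)
  for (i in seq_len(nrow(reg))) {
    extracted <- substr(res$assembly$seq[[reg$scaffold[i]]],
                        reg$start[i] + 1L, reg$end[i])
    expect_identical(extracted, reg$seq[i])
    seqfull <- res$assembly$seq[[reg$scaffold[i]]]
    expect_identical(substr(seqfull, reg$start[i] - 3L, reg$start[i]),
                     reg$tsd[i])
    expect_identical(substr(seqfull, reg$end[i] + 1L, reg$end[i] + 4L),
                     reg$tsd[i])
  }
})

test_that("homolog simulation separates species and exposes HT pairs", {
  tr <- ape::read.tree(
    text = "((A1:0.01,A2:0.01):0.2,((B1:0.01,B2:0.01):0.2,(C1:0.01,C2:0.01):0.2):0.05);")
  cons <- random_dna(400, 0.4)
  seqs <- simulate_homolog_set(cons, tr, rate = 1, seed = 7)
  expect_identical(unname(nchar(seqs)), rep(400L, 6))
  ident <- function(S, x, y)
    mean(strsplit(S[[x]], "")[[1]] == strsplit(S[[y]], "")[[1]])
  expect_gt(ident(seqs, "A1", "A2"), ident(seqs, "A1", "B1"))
  expect_gt(ident(seqs, "B1", "B2"), ident(seqs, "B1", "C1"))
  # rate 0: all identical
  seqs0 <- simulate_homolog_set(cons, tr, rate = 0, seed = 8)
  expect_true(all(seqs0 == cons))
  # HT between the two most distant species gives the top-identity pair
  seqs_ht <- simulate_homolog_set(
    cons, tr, ht_events = list(list(donor = "A1", recipient = "C2",
                                    divergence = 0.005)),
    rate = 1, seed = 9)
  pairs <- combn(names(seqs_ht), 2)
  idents <- apply(pairs, 2, function(p) ident(seqs_ht, p[1], p[2]))
  top <- pairs[, which.max(idents)]
  expect_setequal(top, c("A1", "C2"))
  expect_error(
    simulate_homolog_set(cons, tr,
                         ht_events = list(list(donor = "A1",
                                               recipient = "ZZ"))),
    "unknown")
})
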