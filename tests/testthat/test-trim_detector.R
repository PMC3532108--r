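# ungapped enumeration oracle: best repeat pair over all (start, offset,
# length) triples, scored by identity then length
ungapped_pair_oracle <- function(seq, lmin, lmax, dmin, dmax, min_ident) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  best <- NULL
  for (d in dmin:dmax) {
    n <- L - d
    if (n < lmin) next
    eq <- ch[1:n] == ch[(1 + d):L]
    cs <- cumsum(c(0L, eq))
    for (l in lmin:min(lmax, n)) {
      starts <- 1:(n - l + 1L)
      idents <- (cs[starts + l] - cs[starts]) / l
      for (s in which(idents >= min_ident)) {
        cand <- list(start = s, d = d, len = l, ident = idents[s])
        if (is.null(best) || cand$ident > best$ident ||
            (cand$ident == best$ident && cand$len > best$len))
          best <- cand
      }
    }
  }
  best
}

build_element_scaffold <- function(ltr5, ltr3, internal, tsd = "ATAT",
                                   pre = 300L, post = 300L, gc = 0.37) {
  list(seq = paste0(random_dna(pre, gc), tsd, ltr5, internal, ltr3, tsd,
                    random_dna(post, gc)),
       start = pre + 4L,
       end = pre + 4L + nchar(ltr5) + nchar(internal) + nchar(ltr3))
}

test_that("a perfect planted pair is recovered coordinate-exactly", {
  set.seed(51)
  ltr <- make_ltr(160L)
  internal <- random_dna(300L, 0.37)
  sc <- build_element_scaffold(ltr, ltr, internal)
  hits <- find_ltr_pairs(sc$seq)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, sc$start)
  expect_identical(hits$end, sc$end)
  expect_identical(hits$ltr5_end - hits$ltr5_start, 160L)
  expect_identical(hits$ltr3_end - hits$ltr3_start, 160L)
  expect_identical(hits$ltr_identity, 1)
  expect_identical(hits$tsd, "ATAT")
  expect_true(hits$termini5_ok && hits$termini3_ok)
})

test_that("a random scaffold with no planted repeats yields no candidates", {
  set.seed(52)
  seq <- random_dna(50000, 0.37)
  expect_identical(nrow(find_ltr_pairs(seq)), 0L)
})

test_that("the identity threshold is monotone on a 75%-identity pair", {
  set.seed(53)
  ltr5 <- make_ltr(160L)
  # 40 mutations clustered away from the termini: ~75% ungapped identity
  ltr3 <- mutate_positions(ltr5, 40L, protect = c(1:20, 121:160))
  sc <- build_element_scaffold(ltr5, ltr3, random_dna(300L, 0.37))
  strict <- find_ltr_pairs(sc$seq, trim_config(min_ltr_identity = 0.80))
  expect_identical(nrow(strict), 0L)
  loose <- find_ltr_pairs(sc$seq, trim_config(min_ltr_identity = 0.70))
  expect_identical(nrow(loose), 1L)
  expect_lt(loose$ltr_identity, 0.80)
  expect_gte(loose$ltr_identity, 0.70)
})

test_that("detector agrees with the all-substring-pairs oracle on small scaffolds", {
  set.seed(54)
  for (trial in 1:5) {
    ltr <- paste0("TG", random_dna(106, 0.37), "CA")
    # pin the internal-region ends so the maximal exact repeat run is
    # exactly the planted LTR (no chance extension into the flanks)
    internal <- paste0("C", random_dna(58, 0.37), "G")
    sc <- build_element_scaffold(ltr, ltr, internal,
                                 pre = 200L, post = 200L)
    hits <- find_ltr_pairs(sc$seq, trim_config(min_internal = 50L))
    oracle <- ungapped_pair_oracle(sc$seq, 100L, 120L, 150L, 400L, 0.999)
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$ltr5_start, oracle$start - 1L)
    expect_identical(hits$ltr5_end - hits$ltr5_start, oracle$len)
    expect_identical(hits$ltr3_start - hits$ltr5_start, oracle$d)
  }
})

test_that("PBS detection honors the reverse-complement rule and tie order", {
  set.seed(55)
  trna <- random_dna(15, 0.5)
  internal <- paste0(revcomp(trna), strrep("C", 40))
  hit <- detect_pbs(internal, c(leu = trna))
  expect_identical(hit$start, 0L)
  expect_identical(hit$end, 15L)
  expect_identical(hit$score, 15L)
  expect_identical(hit$trna, "leu")
  # poly-C internal region finds nothing in an A-rich tRNA set
  expect_null(detect_pbs(strrep("C", 40), c(x = strrep("A", 20))))
  expect_error(detect_pbs(internal, character(0)), "empty")
  # two tRNAs sharing a 12-bp 3' terminus tie: first by input order wins
  shared <- random_dna(12, 0.5)
  trnaA <- paste0(random_dna(8, 0.5), "AA", shared)
  trnaB <- paste0(random_dna(8, 0.5), "CC", shared)
  internal2 <- paste0(revcomp(shared), strrep("C", 30))
  hit <- detect_pbs(internal2, c(second = trnaB, first = trnaA))
  expect_identical(hit$trna, "second")
  expect_identical(hit$score, 12L)
})

test_that("PPT detection picks the qualifying window nearest the 3' LTR", {
  internal <- paste0(strrep("C", 45), "AAGGGAGGGAAGGAG")
  hit <- detect_ppt(internal)
  expect_identical(hit$start, 45L)
  expect_identical(hit$purine_frac, 1)
  expect_null(detect_ppt(paste0(random_dna(40, 0.5), strrep("CT", 15))))
  # a perfect early window loses to a qualifying window closer to the LTR
  internal2 <- paste0(strrep("C", 30), strrep("A", 15), "CC",
                      strrep("G", 13))
  hit2 <- detect_ppt(internal2)
  expect_identical(hit2$start, 45L)
  expect_equal(hit2$purine_frac, 13 / 15)
})

test_that("library scanning classifies solo and truncated copies from truth", {
  res <- planted_genome(seed = 61L)
  el <- detect_trims(res$assembly)
  reg <- res$registry
  for (cat in c("solo_ltr", "truncated")) {
    want <- reg[reg$category == cat, ]
    got <- el[el$category == cat, ]
    expect_identical(nrow(got), nrow(want))
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
  }
  solo <- el[el$category == "solo_ltr", ]
  expect_identical(solo$tsd, "ATAT")
  # no duplicate solo call inside a reported complete element
  comp <- el[el$category == "complete", ]
  others <- el[el$category != "complete", ]
  for (i in seq_len(nrow(comp))) {
    same <- others$scaffold == comp$scaffold[i]
    expect_false(any(same & others$start < comp$end[i] &
                       others$end > comp$start[i]))
  }
  expect_error(scan_solo_and_truncated(res$assembly, character(0)),
               "empty")
})

test_that("a sub-coverage LTR fragment is called truncated", {
  set.seed(62)
  ltr <- make_ltr(200L)
  frag <- substr(ltr, 1, 120)  # 60% of the library LTR
  seq <- paste0(random_dna(1000, 0.37), frag, random_dna(1000, 0.37))
  asm <- genome_assembly(c(s1 = seq))
  el <- scan_solo_and_truncated(asm, c(lib = ltr))
  expect_identical(nrow(el), 1L)
  expect_identical(el$category, "truncated")
  expect_identical(el$subtype, "solo")
})

test_that("detection is invariant to scaffold order", {
  res <- planted_genome(seed = 63L)
  el1 <- detect_trims(res$assembly)
  rev_asm <- genome_assembly(rev(res$assembly$seq))
  el2 <- detect_trims(rev_asm)
  key <- function(e) {
    k <- paste(e$scaffold, e$start, e$end, e$category)
    sort(k)
  }
  expect_identical(key(el1), key(el2))
})

test_that("full detection recovers every planted copy with motifs annotated", {
  res <- planted_genome(seed = 64L)
  el <- detect_trims(res$assembly)
  reg <- res$registry
  expect_identical(nrow(el), nrow(reg))
  m <- merge(reg, el, by = c("scaffold", "start", "end"))
  expect_identical(nrow(m), nrow(reg))
  expect_identical(m$category.x, m$category.y)
  # PPT annotation runs on complete elements (motif present by chance or
  # not, the coordinates must stay inside the internal region when called)
  comp <- el[el$category == "complete", ]
  has_ppt <- !is.na(comp$ppt_start)
  if (any(has_ppt)) {
    expect_true(all(comp$ppt_start[has_ppt] >= comp$ltr5_end[has_ppt]))
    expect_true(all(comp$ppt_end[has_ppt] <= comp$ltr3_start[has_ppt]))
  }
})
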