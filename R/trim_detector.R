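# Structural detection of complete TRIM candidates (paired co-oriented
# LTRs with TSD/termini refinement, PBS and PPT motifs) and
# similarity-based recovery of solo-LTRs and truncated copies.

# +2/-3 local-alignment scoring; N never matches anything
detect_submat <- function(match = 2, mismatch = -3) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

# positions (1-based) of all k-mers; k-mers containing N are unmatchable
kmer_vector <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  km <- substring(seq, 1:(L - k + 1L), k:L)
  km[grepl("N", km, fixed = TRUE)] <- NA_character_
  km
}

# greedy clustering of seed pairs on (diagonal, position)
cluster_seeds <- function(p1, d, band = 20L, max_gap = 400L) {
  o <- order(d, p1)
  p1 <- p1[o]; d <- d[o]
  grp <- integer(length(p1))
  g <- 0L
  for (i in seq_along(p1)) {
    if (i == 1L || d[i] - d[i - 1L] > band ||
        (d[i] == d[i - 1L] && p1[i] - p1[i - 1L] > max_gap) ||
        (d[i] != d[i - 1L] && abs(p1[i] - p1[i - 1L]) > max_gap)) {
      g <- g + 1L
    }
    grp[i] <- g
  }
  split(data.frame(p1 = p1, d = d), grp)
}

local_align <- function(s1, s2, cfg) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s1), Biostrings::DNAString(s2), type = "local",
    substitutionMatrix = detect_submat(cfg$match, cfg$mismatch),
    gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend)
}

# joint TSD/termini boundary refinement of a putative element [s, e) whose
# flanks should carry identical 4-mers and whose termini should read
# TG ... CA; returns the refined 0-based boundaries and their evidence
refine_boundaries <- function(seq, s, e, refine_bp, L = nchar(seq),
                              want_tg = TRUE, want_ca = TRUE) {
  search <- function(R) {
    best <- list(score = -Inf, s = s, e = e)
    for (da in -R:R) {
      a <- s + da
      if (a < 0L || a >= e) next
      tg <- want_tg && subseq0(seq, a, min(a + 2L, L)) == "TG"
      for (dd in -R:R) {
        b <- e + dd
        if (b > L || b <= a) next
        ca <- want_ca && b >= 2L && subseq0(seq, b - 2L, b) == "CA"
        tsd_ok <- a >= 4L && b + 4L <= L &&
          subseq0(seq, a - 4L, a) == subseq0(seq, b, b + 4L)
        sc <- 4 * tsd_ok + tg + ca - 0.01 * (abs(da) + abs(dd))
        if (sc > best$score)
          best <- list(score = sc, s = a, e = b, tsd_ok = tsd_ok,
                       tg = tg, ca = ca)
      }
    }
    best
  }
  best <- search(refine_bp)
  # alignment extension can overshoot a boundary by more than the refine
  # window; when no placement with full TSD + termini evidence is found
  # nearby, widen the search before settling for a weaker placement
  if (best$score < 4 + want_tg + want_ca - 0.5) {
    wide <- search(3L * refine_bp)
    if (wide$score > best$score) best <- wide
  }
  best$tsd <- if (isTRUE(best$tsd_ok))
    subseq0(seq, best$s - 4L, best$s) else NA_character_
  best
}

# refine a single internal boundary to the nearest expected terminus motif
refine_terminus <- function(seq, pos, motif_at, refine_bp) {
  # motif_at(p) returns TRUE if the terminus motif sits at boundary p
  best <- list(score = -Inf, pos = pos)
  for (dp in -refine_bp:refine_bp) {
    p <- pos + dp
    if (p < 0L || p > nchar(seq)) next
    sc <- motif_at(p) - 0.01 * abs(dp)
    if (sc > best$score) best <- list(score = sc, pos = p,
                                      ok = motif_at(p) > 0)
  }
  best
}

#' Find paired-LTR (complete TRIM) candidates on one scaffold
#'
#' Exact k-mer seeds shared at two positions within the element-size
#' window are chained by diagonal, extended by banded local alignment
#' (match +2, mismatch -3, gap open -5, extend -2), and refined within
#' +/- `refine_bp` bp to the boundary placement best supported by an
#' identical flanking 4-mer pair (the TSD) and TG ... CA termini on both
#' LTR copies. Candidates failing the termini at both ends are kept but
#' flagged. Overlapping candidates are resolved in favor of the higher
#' alignment score.
#'
#' @param seq Scaffold DNA string (or a 1-scaffold `genome_assembly`).
#' @param config A [trim_config()].
#' @param scaffold_id Id recorded in the output.
#' @return Candidate table: one row per retained LTR pair with element and
#'   LTR intervals (0-based half-open), `ltr_identity`, termini flags,
#'   `tsd` (or NA) and alignment `score`.
#' @export
find_ltr_pairs <- function(seq, config = trim_config(),
                           scaffold_id = "scaffold") {
  if (inherits(seq, "genome_assembly")) {
    scaffold_id <- names(seq$seq)[1L]
    seq <- seq$seq[[1L]]
  }
  cfg <- config
  empty <- data.frame(
    scaffold = character(), ltr5_start = integer(), ltr5_end = integer(),
    ltr3_start = integer(), ltr3_end = integer(), start = integer(),
    end = integer(), ltr_identity = numeric(), termini5_ok = logical(),
    termini3_ok = logical(), tsd = character(), score = numeric(),
    stringsAsFactors = FALSE)
  L <- nchar(seq)
  min_span <- 2L * cfg$min_ltr + cfg$min_internal
  if (L < min_span) return(empty)
  k <- cfg$seed_k
  km <- kmer_vector(seq, k)
  dup <- !is.na(km) & (duplicated(km) | duplicated(km, fromLast = TRUE))
  if (!any(dup)) return(empty)
  pos_by_kmer <- split(which(dup), km[dup])
  d_lo <- cfg$min_ltr + cfg$min_internal
  d_hi <- cfg$max_element - cfg$min_ltr
  seeds_p1 <- integer(0); seeds_d <- integer(0)
  for (p in pos_by_kmer) {
    if (length(p) > 12L) next  # low-complexity guard
    pr <- utils::combn(p, 2L)
    dd <- pr[2L, ] - pr[1L, ]
    keep <- dd >= d_lo & dd <= d_hi
    seeds_p1 <- c(seeds_p1, pr[1L, keep])
    seeds_d <- c(seeds_d, dd[keep])
  }
  if (!length(seeds_p1)) return(empty)
  clusters <- cluster_seeds(seeds_p1, seeds_d)
  # each window must cover its full LTR copy even when divergence leaves a
  # single seed, yet the two windows must stay disjoint (split at the
  # midpoint between the seed blocks), or the local alignment would lock
  # onto the trivial self-match of a shared span
  pad <- cfg$max_ltr
  cands <- empty
  for (cl in clusters) {
    d_med <- as.integer(round(stats::median(cl$d)))
    p1min <- min(cl$p1) - 1L
    p1max <- max(cl$p1) + k - 1L
    p2min <- p1min + d_med
    p2max <- p1max + d_med
    mid <- max((p1max + p2min) %/% 2L, p1max + 1L)
    w1s <- max(0L, p1min - pad)
    w1e <- min(L, mid)
    w2s <- min(L - 1L, mid)
    w2e <- min(L, p2max + pad)
    if (w2e <= w2s || w1e <= w1s) next
    aln <- local_align(subseq0(seq, w1s, w1e), subseq0(seq, w2s, w2e), cfg)
    pr <- Biostrings::pattern(aln); sb <- Biostrings::subject(aln)
    s5 <- w1s + Biostrings::start(pr) - 1L
    e5 <- w1s + Biostrings::end(pr)
    s3 <- w2s + Biostrings::start(sb) - 1L
    e3 <- w2s + Biostrings::end(sb)
    if (e5 - s5 < cfg$hard_min_ltr) next
    # refine the outer boundaries jointly (TSD couples them), then the
    # inner LTR5 end / LTR3 start to the nearest CA / TG
    outer <- refine_boundaries(seq, s5, e3, cfg$refine_bp)
    s5r <- outer$s; e3r <- outer$e
    inner_b <- refine_terminus(seq, e5, function(p)
      p >= 2L && subseq0(seq, p - 2L, p) == "CA", cfg$refine_bp)
    inner_c <- refine_terminus(seq, s3, function(p)
      p + 2L <= L && subseq0(seq, p, p + 2L) == "TG", cfg$refine_bp)
    e5r <- inner_b$pos; s3r <- inner_c$pos
    len5 <- e5r - s5r; len3 <- e3r - s3r
    internal_len <- s3r - e5r
    if (len5 < cfg$min_ltr || len5 > cfg$max_ltr) next
    if (len3 < cfg$min_ltr || len3 > cfg$max_ltr) next
    if (internal_len < cfg$min_internal ||
        internal_len > cfg$max_internal) next
    if (e3r - s5r > cfg$max_element) next
    gal <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(subseq0(seq, s5r, e5r)),
      Biostrings::DNAString(subseq0(seq, s3r, e3r)),
      type = "global",
      substitutionMatrix = detect_submat(cfg$match, cfg$mismatch),
      gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend)
    ident <- Biostrings::nmatch(gal) /
      nchar(as.character(Biostrings::alignedPattern(gal)))
    if (ident < cfg$min_ltr_identity) next
    t5 <- subseq0(seq, s5r, s5r + 2L) == "TG" &&
      subseq0(seq, e5r - 2L, e5r) == "CA"
    t3 <- subseq0(seq, s3r, s3r + 2L) == "TG" &&
      subseq0(seq, e3r - 2L, e3r) == "CA"
    cands <- rbind(cands, data.frame(
      scaffold = scaffold_id, ltr5_start = s5r, ltr5_end = e5r,
      ltr3_start = s3r, ltr3_end = e3r, start = s5r, end = e3r,
      ltr_identity = ident, termini5_ok = t5, termini3_ok = t3,
      tsd = outer$tsd, score = Biostrings::score(gal),
      stringsAsFactors = FALSE))
  }
  if (!nrow(cands)) return(empty)
  # overlap resolution: keep the higher-scoring candidate
  cands <- cands[order(-cands$score, cands$start), ]
  keep <- rep(TRUE, nrow(cands))
  for (i in seq_len(nrow(cands))) {
    if (!keep[i]) next
    if (i < nrow(cands)) {
      j <- (i + 1L):nrow(cands)
      ov <- keep[j] & cands$start[j] < cands$end[i] &
        cands$end[j] > cands$start[i]
      keep[j][ov] <- FALSE
    }
  }
  cands <- cands[keep, ]
  cands <- cands[order(cands$start), ]
  rownames(cands) <- NULL
  cands
}

#' Detect the primer binding site (PBS) in an internal region
#'
#' Searches the first `pbs_window` bp of the internal region for the
#' longest match (allowing up to `pbs_max_mismatch` mismatches, minimum
#' `pbs_min_match` bp) to the reverse complement of the 3' terminal
#' segment of any supplied tRNA. Ties go to the longer match, then the
#' earlier start, then tRNA input order.
#'
#' @param internal_seq Internal-region DNA string (5' LTR boundary first).
#' @param trna_set Named character vector of tRNA sequences.
#' @param config A [trim_config()].
#' @return `list(kind="PBS", start=, end=, trna=, score=)` with 0-based
#'   offsets into `internal_seq`, or `NULL`.
#' @export
detect_pbs <- function(internal_seq, trna_set, config = trim_config()) {
  if (length(trna_set) == 0L) stop("empty tRNA set")
  if (is.null(names(trna_set)))
    names(trna_set) <- paste0("trna", seq_along(trna_set))
  cfg <- config
  win <- substr(toupper(internal_seq), 1L, cfg$pbs_window)
  wl <- nchar(win)
  trna_set <- toupper(trna_set)
  if (min(wl, max(nchar(trna_set))) < cfg$pbs_min_match) return(NULL)
  for (m in seq(min(wl, max(nchar(trna_set))), cfg$pbs_min_match)) {
    for (s in seq_len(wl - m + 1L)) {
      frag <- substr(win, s, s + m - 1L)
      for (ti in seq_along(trna_set)) {
        tr <- trna_set[[ti]]
        if (nchar(tr) < m) next
        probe <- revcomp(substr(tr, nchar(tr) - m + 1L, nchar(tr)))
        mm <- sum(strsplit(frag, "")[[1]] != strsplit(probe, "")[[1]])
        if (mm <= cfg$pbs_max_mismatch)
          return(list(kind = "PBS", start = s - 1L, end = s - 1L + m,
                      trna = names(trna_set)[ti],
                      score = as.integer(m - mm)))
      }
    }
  }
  NULL
}

#' Detect the polypurine tract (PPT) upstream of the 3' LTR
#'
#' Scans `ppt_window`-bp windows within the last `ppt_region` bp of the
#' internal region and returns the purine-rich window (purine fraction >=
#' `ppt_min_purine`) closest to the 3' LTR.
#'
#' @param internal_seq Internal-region DNA string.
#' @param config A [trim_config()].
#' @return `list(kind="PPT", start=, end=, purine_frac=)` with 0-based
#'   offsets into `internal_seq`, or `NULL`.
#' @export
detect_ppt <- function(internal_seq, config = trim_config()) {
  cfg <- config
  seq <- toupper(internal_seq)
  n <- nchar(seq)
  w <- cfg$ppt_window
  if (n < w) return(NULL)
  lo <- max(1L, n - cfg$ppt_region + 1L)
  starts <- seq(lo, n - w + 1L)
  best <- NULL
  for (s in starts) {  # ascending: the last qualifying window wins
    frag <- strsplit(substr(seq, s, s + w - 1L), "")[[1]]
    pf <- mean(frag %in% c("A", "G"))
    if (pf >= cfg$ppt_min_purine)
      best <- list(kind = "PPT", start = s - 1L, end = s - 1L + w,
                   purine_frac = pf)
  }
  best
}

# merge a hit list by interval overlap on one scaffold; returns group ids
overlap_groups <- function(start, end) {
  o <- order(start)
  grp <- integer(length(start))
  g <- 0L
  max_end <- -1L
  for (i in o) {
    if (start[i] >= max_end) g <- g + 1L
    grp[i] <- g
    max_end <- max(max_end, end[i])
  }
  grp
}

#' Recover solo-LTRs and truncated copies by library scanning
#'
#' Local alignment (match +2, mismatch -3, affine gaps) of each library
#' sequence against both strands of every scaffold, seeded by shared
#' k-mers. Hits overlapping a detected complete element are absorbed into
#' it; remaining hits from LTR-sized library entries covering at least
#' `solo_min_coverage` of the library LTR are called `solo_ltr`, all other
#' hits `truncated` (subtype `"solo"` for partial-LTR hits, `"element"`
#' for hits from element-length library entries). Boundaries are refined
#' against flanking identical 4-mers and TG/CA termini, and a TSD is
#' called when the refined flanks match exactly.
#'
#' @param assembly A `genome_assembly`.
#' @param ltr_library Named character vector of representative LTR (and
#'   optionally full-element) sequences; entries longer than `max_ltr` are
#'   treated as full elements.
#' @param complete_hits Candidate table from [find_ltr_pairs()] (or any
#'   element table) whose intervals absorb overlapping hits; may be NULL.
#' @param config A [trim_config()].
#' @return Element table of `solo_ltr` / `truncated` calls.
#' @export
scan_solo_and_truncated <- function(assembly, ltr_library,
                                    complete_hits = NULL,
                                    config = trim_config()) {
  if (length(ltr_library) == 0L) stop("empty LTR library")
  if (is.null(names(ltr_library)))
    names(ltr_library) <- paste0("lib", seq_along(ltr_library))
  cfg <- config
  k <- 12L
  ltr_library <- toupper(ltr_library)
  lib_is_ltr <- nchar(ltr_library) <= cfg$max_ltr
  # phase 1: seed every library entry against every scaffold/strand and
  # record candidate regions (no alignment yet)
  regions <- list()
  for (sc in names(assembly$seq)) {
    seq <- assembly$seq[[sc]]
    L <- nchar(seq)
    if (L < k) next
    scaf_km <- kmer_vector(seq, k)
    for (li in seq_along(ltr_library)) {
      for (strand in c("+", "-")) {
        lib <- if (strand == "+") ltr_library[[li]]
        else revcomp(ltr_library[[li]])
        nlib <- nchar(lib)
        if (nlib < k) next
        lib_km <- kmer_vector(lib, k)
        hit_idx <- which(!is.na(scaf_km) & scaf_km %in% lib_km)
        if (!length(hit_idx)) next
        libpos <- match(scaf_km[hit_idx], lib_km)
        diag <- hit_idx - libpos
        cl <- cluster_seeds(hit_idx, diag, band = 20L, max_gap = 400L)
        for (group in cl) {
          d0 <- as.integer(round(stats::median(group$d)))
          rs <- max(0L, d0 - 30L)
          re <- min(L, d0 + nlib + 30L)
          if (re - rs < cfg$hard_min_ltr) next
          regions[[length(regions) + 1L]] <- data.frame(
            scaffold = sc, rs = rs, re = re, strand = strand, li = li,
            n_seeds = nrow(group), stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- empty_elements()
  if (!length(regions)) return(out)
  regions <- do.call(rbind, regions)
  # absorb regions that overlap a complete candidate (footprint includes
  # the flanking TSD copies) before any alignment work
  if (!is.null(complete_hits) && nrow(complete_hits)) {
    drop <- vapply(seq_len(nrow(regions)), function(i) {
      ch <- complete_hits[complete_hits$scaffold == regions$scaffold[i], ,
                          drop = FALSE]
      any(regions$rs[i] < ch$end + 4L & regions$re[i] > ch$start - 4L)
    }, TRUE)
    regions <- regions[!drop, , drop = FALSE]
  }
  if (!nrow(regions)) return(out)
  # phase 2: merge overlapping regions into loci; per locus align only the
  # best-seeded LTR-type and element-type library entries
  align_region <- function(seq, locus, cand) {
    lib <- if (cand$strand == "+") ltr_library[[cand$li]]
    else revcomp(ltr_library[[cand$li]])
    aln <- local_align(lib, subseq0(seq, locus$rs, locus$re), cfg)
    pr <- Biostrings::pattern(aln); sb <- Biostrings::subject(aln)
    alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
    nlib <- nchar(lib)
    ps <- Biostrings::start(pr); pe <- Biostrings::end(pr)
    # a genomic end matching an interior library position is a cut end:
    # no terminus motif is expected there (an LTR's reverse complement
    # still reads TG ... CA, so strand only swaps which library end maps
    # to which genomic end)
    lib_left <- ps <= 3L
    lib_right <- pe >= nlib - 2L
    list(start = locus$rs + Biostrings::start(sb) - 1L,
         end = locus$rs + Biostrings::end(sb),
         identity = Biostrings::nmatch(aln) / alen,
         coverage = (pe - ps + 1L) / nlib,
         score = Biostrings::score(aln),
         want_tg = if (cand$strand == "+") lib_left else lib_right,
         want_ca = if (cand$strand == "+") lib_right else lib_left,
         is_ltr = lib_is_ltr[cand$li], strand = cand$strand)
  }
  rows <- list()
  n_id <- 0L
  for (sc in unique(regions$scaffold)) {
    rg <- regions[regions$scaffold == sc, , drop = FALSE]
    grp <- overlap_groups(rg$rs, rg$re)
    seq <- assembly$seq[[sc]]
    for (g in unique(grp)) {
      cands <- rg[grp == g, , drop = FALSE]
      locus <- list(rs = min(cands$rs), re = max(cands$re))
      hits <- list()
      for (type_ltr in c(TRUE, FALSE)) {
        sub <- cands[lib_is_ltr[cands$li] == type_ltr, , drop = FALSE]
        if (!nrow(sub)) next
        best_cand <- sub[order(-sub$n_seeds), ][1L, ]
        h <- align_region(seq, locus, best_cand)
        if (h$end - h$start >= cfg$hard_min_ltr &&
            h$identity >= cfg$scan_min_identity)
          hits[[length(hits) + 1L]] <- h
      }
      if (!length(hits)) next
      best <- hits[[order(-vapply(hits, `[[`, 0, "score"))[1L]]]
      span <- best$end - best$start
      ltr_cov <- any(vapply(hits, function(h)
        h$is_ltr && h$coverage >= cfg$solo_min_coverage, TRUE))
      solo_ok <- ltr_cov && span <= cfg$max_ltr + 20L
      any_element_lib <- any(!vapply(hits, `[[`, TRUE, "is_ltr"))
      ref <- refine_boundaries(seq, best$start, best$end, cfg$refine_bp,
                               want_tg = best$want_tg,
                               want_ca = best$want_ca)
      n_id <- n_id + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("hit%03d", n_id), scaffold = sc,
        start = ref$s, end = ref$e, strand = best$strand,
        category = if (solo_ok) "solo_ltr" else "truncated",
        subtype = if (solo_ok) NA_character_
        else if (any_element_lib && span > cfg$max_ltr) "element"
        else "solo",
        tsd = ref$tsd, ltr_identity = best$identity,
        termini5_ok = isTRUE(ref$tg), termini3_ok = isTRUE(ref$ca),
        family = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(out)
  as_elements(do.call(rbind, rows))
}

#' Run the full structural detection pipeline on an assembly
#'
#' Finds paired-LTR candidates on every scaffold, annotates PBS/PPT motifs
#' in their internal regions, then scans for solo-LTRs and truncated
#' copies with a library built from the detected complete elements (their
#' 5' LTRs and full sequences) unless one is supplied.
#'
#' @param assembly A `genome_assembly`.
#' @param trna_set Optional named tRNA sequences for PBS calling.
#' @param ltr_library Optional scan library; defaults to the detected
#'   complete elements.
#' @param config A [trim_config()].
#' @return Element table over all categories.
#' @export
detect_trims <- function(assembly, trna_set = NULL, ltr_library = NULL,
                         config = trim_config()) {
  cfg <- config
  completes <- list()
  for (sc in names(assembly$seq)) {
    cands <- find_ltr_pairs(assembly$seq[[sc]], cfg, scaffold_id = sc)
    if (nrow(cands)) completes[[length(completes) + 1L]] <- cands
  }
  completes <- if (length(completes)) do.call(rbind, completes)
  else NULL
  rows <- list()
  if (!is.null(completes)) {
    for (i in seq_len(nrow(completes))) {
      e <- completes[i, ]
      seq <- assembly$seq[[e$scaffold]]
      internal <- subseq0(seq, e$ltr5_end, e$ltr3_start)
      pbs <- if (!is.null(trna_set))
        detect_pbs(internal, trna_set, cfg) else NULL
      ppt <- detect_ppt(internal, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("trim%03d", i), scaffold = e$scaffold,
        start = e$start, end = e$end, strand = "+",
        category = "complete",
        ltr5_start = e$ltr5_start, ltr5_end = e$ltr5_end,
        ltr3_start = e$ltr3_start, ltr3_end = e$ltr3_end,
        tsd = e$tsd, ltr_identity = e$ltr_identity,
        termini5_ok = e$termini5_ok, termini3_ok = e$termini3_ok,
        pbs_start = if (is.null(pbs)) NA_integer_ else
          e$ltr5_end + pbs$start,
        pbs_end = if (is.null(pbs)) NA_integer_ else e$ltr5_end + pbs$end,
        pbs_trna = if (is.null(pbs)) NA_character_ else pbs$trna,
        pbs_score = if (is.null(pbs)) NA_integer_ else pbs$score,
        ppt_start = if (is.null(ppt)) NA_integer_ else
          e$ltr5_end + ppt$start,
        ppt_end = if (is.null(ppt)) NA_integer_ else e$ltr5_end + ppt$end,
        stringsAsFactors = FALSE)
    }
  }
  complete_el <- if (length(rows)) as_elements(do.call(rbind, rows))
  else empty_elements()
  if (is.null(ltr_library) && nrow(complete_el)) {
    lib <- character(0)
    for (i in seq_len(nrow(complete_el))) {
      e <- complete_el[i, ]
      seq <- assembly$seq[[e$scaffold]]
      lib[paste0(e$id, ".ltr")] <- subseq0(seq, e$ltr5_start, e$ltr5_end)
      lib[paste0(e$id, ".full")] <- subseq0(seq, e$start, e$end)
    }
    ltr_library <- lib
  }
  others <- if (!is.null(ltr_library) && length(ltr_library))
    scan_solo_and_truncated(assembly, ltr_library, complete_el, cfg)
  else empty_elements()
  res <- rbind(complete_el, others)
  res <- res[order(res$scaffold, res$start), ]
  rownames(res) <- NULL
  res
}
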