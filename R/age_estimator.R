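# Insertion-age dating from LTR-pair divergence: global alignment of the
# two LTRs, Kimura two-parameter distance K, and T = K / (2 r).

# +1/-1 nucleotide scoring with N neutral (0 against everything)
ltr_submat <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Globally align the two LTRs of an element
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gaps -2 per
#' gapped position, end gaps penalized) via [Biostrings::pairwiseAlignment].
#'
#' @param ltr5_seq,ltr3_seq DNA strings.
#' @return `list(aln5=, aln3=, score=)` with equal-length gapped strings.
#' @export
align_ltr_pair <- function(ltr5_seq, ltr3_seq) {
  stopifnot(nchar(ltr5_seq) > 0, nchar(ltr3_seq) > 0)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(ltr5_seq)),
    Biostrings::DNAString(toupper(ltr3_seq)),
    type = "global", substitutionMatrix = ltr_submat(),
    gapOpening = 0, gapExtension = 2)
  list(aln5 = as.character(Biostrings::alignedPattern(aln)),
       aln3 = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

PURINES <- c("A", "G")
is_transition <- function(a, b)
  (a %in% PURINES) == (b %in% PURINES) & a != b

#' Kimura two-parameter distance between two aligned sequences
#'
#' Columns containing gaps or N are excluded from the site counts. With
#' transition proportion P and transversion proportion Q over the
#' comparable sites, `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`.
#' Saturated pairs (arguments of the logs non-positive) raise an error
#' rather than returning a clamped value.
#'
#' @param aligned `list(aln5=, aln3=)` as from [align_ltr_pair()], or a
#'   character vector of the two gapped rows.
#' @return Named numeric: `P`, `Q`, `K`, `sites`.
#' @export
k2p_distance <- function(aligned) {
  if (is.list(aligned)) aligned <- c(aligned$aln5, aligned$aln3)
  stopifnot(length(aligned) == 2L,
            nchar(aligned[1]) == nchar(aligned[2]))
  a <- strsplit(toupper(aligned[1]), "")[[1]]
  b <- strsplit(toupper(aligned[2]), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 1L) stop("no comparable (gap/N-free) sites in the alignment")
  ts <- sum(is_transition(a, b))
  tv <- sum(a != b) - ts
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("saturated LTR pair: K2P distance undefined (P=",
         signif(P, 3), ", Q=", signif(Q, 3), ")")
  K <- -0.5 * log(w1 * sqrt(w2))
  c(P = P, Q = Q, K = K, sites = n)
}

#' Insertion age from LTR divergence
#'
#' `T = K / (2 r)` years: the two LTRs were identical at integration, so
#' their divergence K, accumulated at rate r per site per year on each
#' copy, dates the insertion.
#'
#' @param K Substitutions per site between the two LTRs (vectorized).
#' @param r Substitution rate per site per year.
#' @return Age(s) in years.
#' @export
insertion_age <- function(K, r = 0.54e-8) {
  stopifnot(all(K >= 0), r > 0)
  K / (2 * r)
}

#' Date a cohort of complete elements
#'
#' Aligns each LTR pair, computes the K2P distance and converts it to an
#' age. LTR sequences are taken from `assembly` at the element's annotated
#' LTR intervals.
#'
#' @param elements Element table (only `category == "complete"` rows with
#'   both LTR intervals are dated).
#' @param assembly `genome_assembly` the coordinates refer to.
#' @param r Substitution rate per site per year.
#' @return Data frame: `element_id`, `aligned_sites`, `P`, `Q`, `K`, `r`,
#'   `T_years`, `T_my`.
#' @export
estimate_ages <- function(elements, assembly, r = 0.54e-8) {
  el <- elements[elements$category == "complete" &
                   !is.na(elements$ltr5_start) &
                   !is.na(elements$ltr3_start), , drop = FALSE]
  out <- lapply(seq_len(nrow(el)), function(i) {
    e <- el[i, ]
    seq <- assembly$seq[[e$scaffold]]
    aln <- align_ltr_pair(subseq0(seq, e$ltr5_start, e$ltr5_end),
                          subseq0(seq, e$ltr3_start, e$ltr3_end))
    k <- k2p_distance(aln)
    data.frame(element_id = e$id, aligned_sites = unname(k["sites"]),
               P = unname(k["P"]), Q = unname(k["Q"]), K = unname(k["K"]),
               r = r, T_years = insertion_age(k[["K"]], r),
               stringsAsFactors = FALSE)
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(element_id = character(), aligned_sites = numeric(),
               P = numeric(), Q = numeric(), K = numeric(), r = numeric(),
               T_years = numeric(), stringsAsFactors = FALSE)
  res$T_my <- res$T_years / 1e6
  res
}

#' Histogram of insertion ages
#'
#' @param ages Ages in years, or the data frame from [estimate_ages()].
#' @param bin_width_my Bin width in million years.
#' @param subfamily Optional per-element subfamily labels; adds a
#'   per-subfamily mean-age table.
#' @return `list(histogram=, subfamily_means=)`; histogram bins are
#'   `[lo, hi)` in My.
#' @export
age_distribution <- function(ages, bin_width_my = 1, subfamily = NULL) {
  if (is.data.frame(ages)) ages <- ages$T_years
  stopifnot(all(ages >= 0), bin_width_my > 0)
  my <- ages / 1e6
  nbin <- max(1L, ceiling(max(my, 0) / bin_width_my + 1e-9))
  idx <- pmin(nbin, floor(my / bin_width_my) + 1L)
  hist <- data.frame(bin_lo = (seq_len(nbin) - 1L) * bin_width_my,
                     bin_hi = seq_len(nbin) * bin_width_my,
                     count = as.integer(tabulate(idx, nbins = nbin)))
  means <- NULL
  if (!is.null(subfamily)) {
    stopifnot(length(subfamily) == length(my))
    means <- aggregate(list(mean_age_my = my),
                       by = list(subfamily = subfamily), FUN = mean)
  }
  list(histogram = hist, subfamily_means = means)
}
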