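# Spatial statistics and insertion-site profiling: the randomization test
# of scaffold occupancy, regional densities and clusters, and the TSD /
# flank position-frequency machinery behind sequence logos.

#' Randomization test of scaffold occupancy
#'
#' Tests whether elements occupy fewer distinct scaffolds than expected if
#' they were placed uniformly over the concatenated genome. Each replicate
#' re-assigns `n_elements` positions at random (scaffold chosen with
#' probability proportional to its length) and records how many distinct
#' scaffolds receive at least one element; the p-value is the
#' finite-sample-corrected lower tail
#' `(1 + #\{replicates <= observed\}) / (n_reps + 1)`.
#'
#' @param scaffold_lengths Positive scaffold lengths in bp.
#' @param n_elements Number of elements re-assigned per replicate.
#' @param observed_scaffolds Observed number of distinct occupied scaffolds.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @return A `randomization_result` list: `observed_scaffolds`,
#'   `n_elements`, `n_reps`, `null_counts`, `p_value`, `seed`.
#' @export
randomization_test <- function(scaffold_lengths, n_elements,
                               observed_scaffolds, n_reps = 5000L,
                               seed = 1L) {
  stopifnot(length(scaffold_lengths) >= 1, all(scaffold_lengths > 0),
            n_elements >= 1, n_reps >= 1)
  upper <- min(n_elements, length(scaffold_lengths))
  if (observed_scaffolds < 1 || observed_scaffolds > upper)
    stop("observed_scaffolds must be in [1, ", upper, "]")
  set.seed(seed)
  draws <- sample.int(length(scaffold_lengths), n_reps * n_elements,
                      replace = TRUE,
                      prob = scaffold_lengths / sum(scaffold_lengths))
  m <- matrix(draws, nrow = n_reps)
  null_counts <- vapply(seq_len(n_reps),
                        function(i) length(unique(m[i, ])), 0L)
  p <- (1 + sum(null_counts <= observed_scaffolds)) / (n_reps + 1)
  structure(list(observed_scaffolds = as.integer(observed_scaffolds),
                 n_elements = as.integer(n_elements),
                 n_reps = as.integer(n_reps),
                 null_counts = null_counts, p_value = p,
                 seed = as.integer(seed)),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "randomization test: %d elements on %d scaffolds observed; null mean %.1f; p = %.4g (%d reps)\n",
    x$n_elements, x$observed_scaffolds, mean(x$null_counts), x$p_value,
    x$n_reps))
  invisible(x)
}

#' Element density in a genomic region
#'
#' Elements are assigned to the region by interval midpoint; density is
#' elements per Mb (report at one decimal).
#'
#' @param elements Element table.
#' @param region `list(scaffold=, start=, end=)`, 0-based half-open.
#' @return Density in elements/Mb (unrounded).
#' @export
region_density <- function(elements, region) {
  stopifnot(region$end > region$start)
  mid <- (elements$start + elements$end) %/% 2
  n <- sum(elements$scaffold == region$scaffold &
             mid >= region$start & mid < region$end)
  n / ((region$end - region$start) / 1e6)
}

#' Single-linkage clusters of elements along scaffolds
#'
#' Elements on the same scaffold whose gap (start of next minus end of
#' previous) is at most `max_gap_bp` are merged.
#'
#' @param elements Element table.
#' @param max_gap_bp Maximum gap in bp.
#' @return Data frame: `scaffold`, `start`, `end`, `n`, `members`
#'   (comma-separated ids), `density_per_mb` over the cluster span.
#' @export
find_clusters <- function(elements, max_gap_bp) {
  out <- list()
  for (sc in unique(elements$scaffold)) {
    e <- elements[elements$scaffold == sc, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      e$start[-1L] - e$end[-nrow(e)] > max_gap_bp)))
    for (g in unique(grp)) {
      m <- e[grp == g, , drop = FALSE]
      span <- max(m$end) - min(m$start)
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, start = min(m$start), end = max(m$end),
        n = nrow(m), members = paste(m$id, collapse = ","),
        density_per_mb = nrow(m) / (span / 1e6),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), n = integer(), members = character(),
                      density_per_mb = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

PFT_POSITIONS <- c("-5", "-4", "-3", "-2", "-1", "T1", "T2", "T3", "T4",
                   "+1", "+2", "+3", "+4", "+5")

#' Position frequency table of nucleotide counts
#'
#' @param counts 4 x P integer matrix with rownames A, C, G, T; columns
#'   are ordered positions (for TSD contexts: -5..-1, T1..T4, +1..+5).
#'   Every column must sum to the same record count n.
#' @return A `position_frequency_table` list: `counts`, `positions`, `n`.
#' @export
position_frequency_table <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L)
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  stopifnot(identical(sort(rownames(counts)), c("A", "C", "G", "T")))
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  sums <- colSums(counts)
  if (length(unique(sums)) != 1L)
    stop("per-position counts must all sum to the same n (got ",
         paste(unique(sums), collapse = ", "), ")")
  structure(list(counts = counts, positions = colnames(counts),
                 n = as.integer(sums[1L])),
            class = "position_frequency_table")
}

#' Tabulate TSD contexts (5-bp flank + 4-bp TSD + 5-bp flank)
#'
#' Includes every element with a called TSD and full 5-bp flanks on both
#' sides; the context is read around the upstream TSD copy and after the
#' downstream copy, i.e. the 14-mer the insertion site presented before
#' integration.
#'
#' @param elements Element table.
#' @param assembly `genome_assembly` the coordinates refer to.
#' @return A `position_frequency_table` over positions -5..-1, T1..T4,
#'   +1..+5.
#' @export
tsd_context_table <- function(elements, assembly) {
  len <- scaffold_lengths(assembly)
  keep <- !is.na(elements$tsd) &
    elements$start - 9L >= 0L &
    elements$end + 9L <= len[elements$scaffold]
  el <- elements[keep, , drop = FALSE]
  counts <- matrix(0L, 4L, 14L,
                   dimnames = list(c("A", "C", "G", "T"), PFT_POSITIONS))
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    seq <- assembly$seq[[e$scaffold]]
    ctx <- paste0(subseq0(seq, e$start - 9L, e$start - 4L),
                  subseq0(seq, e$start - 4L, e$start),
                  subseq0(seq, e$end + 4L, e$end + 9L))
    ch <- strsplit(ctx, "")[[1]]
    ok <- ch %in% rownames(counts)
    if (!all(ok)) next  # N in the context: record excluded
    for (j in seq_len(14L))
      counts[ch[j], j] <- counts[ch[j], j] + 1L
  }
  position_frequency_table(counts)
}

#' GC content and modal nucleotides over a position subset
#'
#' @param table A `position_frequency_table`.
#' @param position_subset Column names to pool (e.g. `c("T1","T2","T3","T4")`).
#' @return `list(gc=, at=, modal=)`; `modal` is a data frame of the most
#'   frequent nucleotide and its frequency (percent of n) per position.
#' @export
composition_stats <- function(table, position_subset) {
  stopifnot(inherits(table, "position_frequency_table"))
  missing <- setdiff(position_subset, table$positions)
  if (length(missing))
    stop("unknown positions: ", paste(missing, collapse = ", "))
  sub <- table$counts[, position_subset, drop = FALSE]
  gc <- sum(sub[c("C", "G"), ]) / (table$n * ncol(sub))
  modal <- data.frame(
    position = colnames(sub),
    nucleotide = rownames(sub)[apply(sub, 2L, which.max)],
    freq_pct = 100 * apply(sub, 2L, max) / table$n,
    stringsAsFactors = FALSE)
  rownames(modal) <- NULL
  list(gc = gc, at = 1 - gc, modal = modal)
}

#' Per-position information content (sequence-logo heights)
#'
#' `R = 2 - H [- e_n]` bits per position, with `H` the Shannon entropy of
#' the column frequencies and `e_n = 3 / (2 ln(2) n)` the small-sample
#' correction when enabled. Letter heights for rendering are `p * R`,
#' returned as an attribute.
#'
#' @param table A `position_frequency_table`.
#' @param small_sample_correction Apply the `e_n` correction?
#' @return Named numeric vector of bits per position, with a `heights`
#'   attribute (4 x P matrix).
#' @export
logo_information <- function(table, small_sample_correction = FALSE) {
  stopifnot(inherits(table, "position_frequency_table"))
  p <- sweep(table$counts, 2L, colSums(table$counts), "/")
  plogp <- ifelse(p > 0, p * log2(p), 0)
  H <- -colSums(plogp)
  en <- if (small_sample_correction) 3 / (2 * log(2) * table$n) else 0
  R <- pmax(0, 2 - H - en)
  names(R) <- table$positions
  attr(R, "heights") <- sweep(p, 2L, R, "*")
  R
}

#' TSD position counts of the PbTRIM family
#'
#' The published nucleotide counts at the 4-bp TSD and its 5-bp flanks for
#' the 171 PbTRIM insertion sites (59 complete elements and 112 solo-LTRs)
#' characterized in the red harvester ant genome, shipped as package data.
#'
#' @return A `position_frequency_table` (n = 171).
#' @export
pbtrim_tsd_counts <- function() {
  path <- system.file("extdata", "pbtrim_tsd_counts.tsv",
                      package = "trimscan", mustWork = TRUE)
  tab <- read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1L])
  rownames(m) <- tab[[1L]]
  position_frequency_table(m)
}
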