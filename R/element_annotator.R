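# Copy classification support: LTR substructure (U3 / TATA / R / U5),
# identity-based family grouping (the 80/80 rule), and interval overlap of
# elements with user-supplied gene models.

#' Annotate the U3 / R / U5 substructure of an LTR
#'
#' The first exact TATAAA within the first `tata_search` bp marks the U3
#' promoter; the R region starts at the first G found `r_offset` bp after
#' the TATA hexamer (within +/- `r_offset_slack` bp) and ends at the last
#' CA dinucleotide whose implied R length falls inside `r_len_range`. U3
#' is the prefix before R and U5 the suffix after it, so the three regions
#' partition the LTR exactly. Without a TATAAA the LTR is partitioned at
#' the configured default lengths and flagged low-confidence.
#'
#' @param ltr_seq LTR DNA string (>= 100 bp).
#' @param config A [trim_config()].
#' @return `list(u3=, r=, u5=, tata_pos=, r_offset_used=, low_confidence=)`;
#'   intervals are 0-based half-open within the LTR, `tata_pos` the 0-based
#'   start of the hexamer or `NA`.
#' @export
annotate_ltr_substructure <- function(ltr_seq, config = trim_config()) {
  cfg <- config
  seq <- toupper(ltr_seq)
  n <- nchar(seq)
  min_needed <- cfg$r_len_range[1L] + 2L
  if (n < max(100L, min_needed))
    stop("LTR too short to partition (", n, " bp)")
  default_partition <- function() {
    u3e <- min(cfg$default_u3, n - 2L)
    re <- min(u3e + cfg$default_r, n)
    list(u3 = c(0L, u3e), r = c(u3e, re), u5 = c(re, n),
         tata_pos = NA_integer_, r_offset_used = NA_integer_,
         low_confidence = TRUE)
  }
  tata <- regexpr("TATAAA", substr(seq, 1L, cfg$tata_search), fixed = TRUE)
  if (tata == -1L) return(default_partition())
  tata_pos <- as.integer(tata) - 1L           # 0-based hexamer start
  tata_end <- tata_pos + 6L
  # first G at tata_end + r_offset, within the slack window
  target <- tata_end + cfg$r_offset
  r_start <- NA_integer_
  off_used <- NA_integer_
  for (dp in order(abs(seq(-cfg$r_offset_slack, cfg$r_offset_slack)))) {
    cand <- target + seq(-cfg$r_offset_slack, cfg$r_offset_slack)[dp]
    if (cand < tata_end || cand + 1L > n) next
    if (substr(seq, cand + 1L, cand + 1L) == "G") {
      r_start <- cand
      off_used <- cand - tata_end
      break
    }
  }
  if (is.na(r_start)) return(default_partition())
  # last CA whose implied R length is inside the configured range
  r_end <- NA_integer_
  for (e in seq(min(n, r_start + cfg$r_len_range[2L]),
                r_start + cfg$r_len_range[1L])) {
    if (e < 2L) break
    if (substr(seq, e - 1L, e) == "CA") {
      r_end <- e
      break
    }
  }
  if (is.na(r_end)) return(default_partition())
  list(u3 = c(0L, r_start), r = c(r_start, r_end), u5 = c(r_end, n),
       tata_pos = tata_pos, r_offset_used = off_used,
       low_confidence = FALSE)
}

# identity and coverage of two sequences under global alignment:
# identity over aligned columns, coverage relative to the shorter input
pair_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L)
    return(c(identity = 0, coverage = 0))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = ltr_submat(), gapOpening = 0, gapExtension = 2)
  acols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  if (acols == 0L) return(c(identity = 0, coverage = 0))
  c(identity = Biostrings::nmatch(aln) / acols,
    coverage = acols / min(nchar(a), nchar(b)))
}

#' Group elements into families by the 80/80 identity rule
#'
#' Two elements are linked when they share at least
#' `family_min_identity` sequence identity over at least
#' `family_min_coverage` of their internal domain or of their LTR
#' (either suffices); families are the connected components under single
#' linkage. Labels are deterministic: each family is named after its
#' lexicographically smallest member id.
#'
#' @param ids Element ids.
#' @param ltr_seqs Named (or parallel) LTR sequences; `NA`/"" allowed.
#' @param internal_seqs Internal-domain sequences; `NA`/"" allowed.
#' @param config A [trim_config()].
#' @return Named character vector: id -> family label.
#' @export
group_families <- function(ids, ltr_seqs, internal_seqs = NULL,
                           config = trim_config()) {
  cfg <- config
  n <- length(ids)
  stopifnot(length(ltr_seqs) == n,
            is.null(internal_seqs) || length(internal_seqs) == n)
  if (is.null(internal_seqs)) internal_seqs <- rep(NA_character_, n)
  ltr_seqs[is.na(ltr_seqs)] <- ""
  internal_seqs[is.na(internal_seqs)] <- ""
  linked <- function(i, j) {
    for (pair in list(c(ltr_seqs[i], ltr_seqs[j]),
                      c(internal_seqs[i], internal_seqs[j]))) {
      pc <- pair_identity(pair[1L], pair[2L])
      if (pc["identity"] >= cfg$family_min_identity &&
          pc["coverage"] >= cfg$family_min_coverage)
        return(TRUE)
    }
    FALSE
  }
  edges <- matrix(integer(0), ncol = 2L)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (linked(i, j)) edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  labels <- vapply(seq_len(n), function(i)
    min(ids[comp == comp[i]]), "")
  setNames(labels, ids)
}

#' Classify elements by proximity to gene models
#'
#' For each element: `overlaps_exon` if its interval intersects an exon,
#' else `overlaps_intron` if it lies inside a gene body without touching
#' an exon, else `within_window` if it sits within `window_bp` of a gene,
#' else `none`.
#'
#' @param elements Element table.
#' @param gene_models Path to a GFF3 file, or a `GRanges` of gene/exon
#'   features (1-based; `type` column used).
#' @param window_bp Proximity window in bp.
#' @return `list(table=, fraction_associated=)`; `table` adds an
#'   `association` column to the element ids.
#' @export
overlap_with_genes <- function(elements, gene_models, window_bp = 1000L) {
  gr <- if (is.character(gene_models))
    rtracklayer::import(gene_models, format = "gff3") else gene_models
  el <- GenomicRanges::GRanges(
    seqnames = elements$scaffold,
    ranges = IRanges::IRanges(start = elements$start + 1L,
                              end = pmax(elements$end,
                                         elements$start + 1L)))
  types <- if (length(gr)) as.character(gr$type) else character(0)
  genes <- gr[types %in% c("gene", "mRNA")]
  exons <- gr[types %in% c("exon", "CDS")]
  assoc <- rep("none", nrow(elements))
  if (length(exons)) {
    hit <- GenomicRanges::countOverlaps(el, exons,
                                        ignore.strand = TRUE) > 0
    assoc[hit] <- "overlaps_exon"
  }
  if (length(genes)) {
    in_gene <- GenomicRanges::countOverlaps(el, genes,
                                            ignore.strand = TRUE) > 0
    assoc[in_gene & assoc == "none"] <- "overlaps_intron"
    near <- GenomicRanges::countOverlaps(
      el, GenomicRanges::resize(genes,
                                GenomicRanges::width(genes) +
                                  2L * window_bp, fix = "center"),
      ignore.strand = TRUE) > 0
    assoc[near & assoc == "none"] <- "within_window"
  }
  tab <- data.frame(id = elements$id, association = assoc,
                    stringsAsFactors = FALSE)
  list(table = tab,
       fraction_associated = if (nrow(tab)) mean(assoc != "none") else 0)
}
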