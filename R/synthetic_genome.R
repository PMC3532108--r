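# Synthetic assemblies with planted TRIM copies and a truth registry.
# Every downstream stage (detection, dating, distribution, phylogeny) is
# validated against genomes produced here, so the generator is first-class,
# tested code.

#' Random DNA at a given GC content
#'
#' @param n Sequence length in bp.
#' @param gc GC fraction in (0,1); A/T and C/G are split evenly.
#' @return A single DNA string.
#' @export
random_dna <- function(n, gc = 0.37) {
  stopifnot(n >= 0, gc > 0, gc < 1)
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a background assembly with optional AT-rich hotspots
#'
#' Scaffolds are i.i.d. nucleotides at composition `gc` outside hotspots;
#' hotspot blocks (fixed length, lower GC) are placed at recorded positions
#' so insertion-preference analyses have ground truth. The defaults mirror
#' the ant genome this pipeline was developed on: 37% background GC, with
#' hotspots at 19% GC matching the composition observed around real
#' insertion sites.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param length_law Scaffold lengths: a single length, a `c(min, max)`
#'   range (uniform), or a `function(n)` returning `n` lengths.
#' @param gc Background GC fraction.
#' @param hotspot_model `NULL`, or `list(fraction=, gc=, block_bp=)` giving
#'   the approximate genome fraction covered by AT-rich blocks, their GC,
#'   and the block length.
#' @param seed Integer seed; the same seed yields the identical assembly.
#' @return A `genome_assembly`; hotspot coordinates (0-based half-open) are
#'   attached as `attr(, "hotspots")`.
#' @export
generate_background <- function(n_scaffolds, length_law, gc = 0.37,
                                hotspot_model = NULL, seed = 1L) {
  stopifnot(n_scaffolds >= 1, gc > 0, gc < 1)
  set.seed(seed)
  lens <- if (is.function(length_law)) length_law(n_scaffolds)
  else if (length(length_law) == 2L)
    round(runif(n_scaffolds, length_law[1], length_law[2]))
  else rep(round(length_law[1]), n_scaffolds)
  lens <- as.integer(lens)
  if (any(lens <= 0)) stop("length_law produced a non-positive length")
  ids <- sprintf("scaf%03d", seq_len(n_scaffolds))
  seqs <- vapply(lens, random_dna, "", gc = gc)
  hot <- data.frame(scaffold = character(), start = integer(),
                    end = integer(), stringsAsFactors = FALSE)
  if (!is.null(hotspot_model)) {
    frac <- hotspot_model$fraction
    hgc <- if (is.null(hotspot_model$gc)) 0.19 else hotspot_model$gc
    blk <- if (is.null(hotspot_model$block_bp)) 2000L
    else as.integer(hotspot_model$block_bp)
    stopifnot(frac > 0, frac < 1, blk > 0)
    for (i in seq_len(n_scaffolds)) {
      n_blk <- floor(frac * lens[i] / blk)
      if (n_blk < 1L) next
      # non-overlapping starts on a blk-grid, then jittered placement
      slots <- seq(0L, lens[i] - blk, by = blk)
      starts <- sort(sample(slots, min(n_blk, length(slots))))
      for (s in starts) {
        substr(seqs[i], s + 1L, s + blk) <- random_dna(blk, hgc)
        hot <- rbind(hot, data.frame(scaffold = ids[i], start = s,
                                     end = s + blk,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  asm <- genome_assembly(setNames(seqs, ids))
  attr(asm, "hotspots") <- hot
  asm
}

# K2P per-site change-category probabilities after divergence d (expected
# substitutions/site), with transition:transversion event ratio ts_tv.
# Rate matrix: transitions at rate a (one target), transversions at rate b
# per target; ts_tv = a/(2b); d = (a + 2b)t.
k2p_change_probs <- function(d, ts_tv) {
  bt <- d / (2 * ts_tv + 2)
  at <- 2 * ts_tv * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.5 - 0.5 * exp(-4 * bt)
  c(same = 1 - p_ts - p_tv, ts = p_ts, tv = p_tv)
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

# evolve one sequence along a branch of length d under K2P
mutate_k2p <- function(seq, d, ts_tv = 2) {
  if (d == 0) return(seq)
  p <- k2p_change_probs(d, ts_tv)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  cat_draw <- sample.int(3L, n, replace = TRUE, prob = p)
  ts_i <- which(cat_draw == 2L & chars %in% names(TRANSITION))
  tv_i <- which(cat_draw == 3L & chars %in% names(TRANSITION))
  if (length(ts_i)) chars[ts_i] <- TRANSITION[chars[ts_i]]
  if (length(tv_i)) {
    pick <- sample.int(2L, length(tv_i), replace = TRUE)
    chars[tv_i] <- vapply(seq_along(tv_i), function(j)
      TRANSVERSIONS[[substr(seq, tv_i[j], tv_i[j])]][pick[j]], "")
  }
  paste(chars, collapse = "")
}

#' Diverge an LTR template into an aged 5'/3' pair
#'
#' Emulates the dating model's premise: the two LTRs are identical at
#' integration and accumulate substitutions independently afterwards. Each
#' copy receives K2P-process substitutions on a branch of length
#' `r * age_years`, so the expected pairwise divergence is `2 * r *
#' age_years`.
#'
#' @param ltr_template Template DNA string.
#' @param age_years Age in years (>= 0).
#' @param r Substitution rate per site per year.
#' @param ts_tv Transition:transversion event ratio.
#' @param seed Optional integer seed.
#' @return `list(ltr5=, ltr3=, realized_K=)`; `realized_K` is the K2P
#'   estimate computed from the planted differences.
#' @export
diverge_ltr_pair <- function(ltr_template, age_years, r = 0.54e-8,
                             ts_tv = 2, seed = NULL) {
  stopifnot(age_years >= 0, r > 0)
  d <- 2 * r * age_years
  if (d >= 0.7)
    stop("requested expected divergence ", signif(d, 3),
         " is in the saturated region of the K2P formula (>= 0.7)")
  if (!is.null(seed)) set.seed(seed)
  ltr5 <- mutate_k2p(ltr_template, d / 2, ts_tv)
  ltr3 <- mutate_k2p(ltr_template, d / 2, ts_tv)
  k <- k2p_distance(list(aln5 = ltr5, aln3 = ltr3))
  list(ltr5 = ltr5, ltr3 = ltr3, realized_K = k[["K"]])
}

#' Specification of one copy to plant
#'
#' @param ltr_template LTR DNA string, 100-350 bp, beginning `TG` and
#'   ending `CA`.
#' @param internal_template Internal-region DNA string (ignored for
#'   `solo_ltr`).
#' @param tsd 4-bp TSD to write at the insertion site, or `NA` to duplicate
#'   the host 4-mer already present there.
#' @param age_years Insertion age in years.
#' @param category `"complete"`, `"truncated"` or `"solo_ltr"`.
#' @param scaffold,position Target scaffold id and 0-based insertion
#'   position (the 4-mer at `[position, position+4)` becomes the TSD).
#' @param truncate_frac,truncate_side For `truncated`: fraction of the
#'   complete element kept and which side survives (`"5p"` keeps the
#'   prefix, `"3p"` the suffix).
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(ltr_template, internal_template = "", tsd = NA,
                       age_years = 0, category = c("complete", "truncated",
                                                   "solo_ltr"),
                       scaffold, position, truncate_frac = 0.6,
                       truncate_side = c("5p", "3p")) {
  category <- match.arg(category)
  truncate_side <- match.arg(truncate_side)
  ltr_template <- toupper(ltr_template)
  internal_template <- toupper(internal_template)
  nl <- nchar(ltr_template)
  if (nl < 100L || nl > 350L)
    stop("LTR template must be 100-350 bp (got ", nl, ")")
  if (substr(ltr_template, 1L, 2L) != "TG" ||
      substr(ltr_template, nl - 1L, nl) != "CA")
    stop("LTR template must begin TG and end CA")
  if (category == "complete" &&
      2L * nl + nchar(internal_template) >= 1000L)
    stop("complete element would be >= 1000 bp")
  if (!is.na(tsd) && nchar(tsd) != 4L)
    stop("tsd must be a 4-bp string or NA")
  structure(list(ltr_template = ltr_template,
                 internal_template = internal_template,
                 tsd = if (is.na(tsd)) NA_character_ else toupper(tsd),
                 age_years = age_years, category = category,
                 scaffold = scaffold, position = as.integer(position),
                 truncate_frac = truncate_frac,
                 truncate_side = truncate_side),
            class = "plant_spec")
}

#' Plant TRIM copies into an assembly
#'
#' Insertion at site `s` duplicates the 4-mer at `[s, s+4)` (the integrase
#' staggered-cut convention): a complete copy becomes
#' `TSD + LTR5 + internal + LTR3 + TSD`, a solo-LTR `TSD + LTR + TSD`, and
#' a truncated copy a prefix/suffix of the complete sequence, so each
#' insertion grows the scaffold by the element length plus 4 bp. When a
#' spec supplies its own `tsd`, the host 4-mer at the site is overwritten
#' with it before duplication.
#'
#' @param assembly A `genome_assembly`.
#' @param specs List of [plant_spec()] objects; insertion positions on one
#'   scaffold must be at least 4 bp apart.
#' @param seed Integer seed for the divergence draws.
#' @param r,ts_tv Substitution rate and transition:transversion ratio used
#'   to realize LTR-pair divergence from `age_years`.
#' @return `list(assembly=, registry=)`; the registry records, per planted
#'   copy, its realized 0-based coordinates (element and LTR intervals,
#'   post-insertion), TSD, age and realized K.
#' @export
plant_elements <- function(assembly, specs, seed = 1L, r = 0.54e-8,
                           ts_tv = 2) {
  set.seed(seed)
  reg <- data.frame(
    id = character(), scaffold = character(), category = character(),
    subtype = character(), start = integer(), end = integer(),
    ltr5_start = integer(), ltr5_end = integer(),
    ltr3_start = integer(), ltr3_end = integer(),
    tsd = character(), age_years = numeric(), realized_K = numeric(),
    seq = character(), stringsAsFactors = FALSE)
  if (length(specs) == 0L) return(list(assembly = assembly, registry = reg))
  stopifnot(all(vapply(specs, inherits, TRUE, "plant_spec")))
  scafs <- vapply(specs, `[[`, "", "scaffold")
  pos <- vapply(specs, `[[`, 0L, "position")
  lens <- scaffold_lengths(assembly)
  unknown <- setdiff(scafs, names(lens))
  if (length(unknown)) stop("unknown target scaffold: ", unknown[1L])
  if (any(pos < 0L) || any(pos + 4L > lens[scafs]))
    stop("insertion position out of scaffold bounds")
  for (sc in unique(scafs)) {
    p <- sort(pos[scafs == sc])
    if (length(p) > 1L && any(diff(p) < 4L))
      stop("colliding insertion positions on ", sc,
           " (closer than the 4-bp TSD site): ",
           paste(p[c(which(diff(p) < 4L))], collapse = ", "))
  }
  seqs <- assembly$seq
  ord <- order(scafs, pos)
  k <- 0L
  offset <- setNames(rep(0L, length(seqs)), names(seqs))
  for (i in ord) {
    sp <- specs[[i]]
    k <- k + 1L
    id <- sprintf("planted%03d", i)
    # realize the element sequence
    realized_K <- NA_real_
    ltr5_len <- ltr3_len <- NA_integer_
    if (sp$category == "complete") {
      dv <- diverge_ltr_pair(sp$ltr_template, sp$age_years, r, ts_tv)
      eseq <- paste0(dv$ltr5, sp$internal_template, dv$ltr3)
      realized_K <- dv$realized_K
      ltr5_len <- nchar(dv$ltr5); ltr3_len <- nchar(dv$ltr3)
      subtype <- NA_character_
    } else if (sp$category == "solo_ltr") {
      eseq <- mutate_k2p(sp$ltr_template, r * sp$age_years, ts_tv)
      ltr5_len <- nchar(eseq)
      subtype <- NA_character_
    } else {
      dv <- diverge_ltr_pair(sp$ltr_template, sp$age_years, r, ts_tv)
      full <- paste0(dv$ltr5, sp$internal_template, dv$ltr3)
      keep <- max(20L, round(sp$truncate_frac * nchar(full)))
      eseq <- if (sp$truncate_side == "5p") substr(full, 1L, keep)
      else substr(full, nchar(full) - keep + 1L, nchar(full))
      subtype <- if (nchar(sp$internal_template) == 0L) "solo" else "element"
    }
    elen <- nchar(eseq)
    s <- sp$position + offset[sp$scaffold]
    seq <- seqs[[sp$scaffold]]
    site <- if (is.na(sp$tsd)) substr(seq, s + 1L, s + 4L) else sp$tsd
    seqs[[sp$scaffold]] <- paste0(substr(seq, 1L, s), site, eseq, site,
                                  substr(seq, s + 5L, nchar(seq)))
    # replaced the 4-mer at [s, s+4) with site + eseq + site
    e_start <- s + 4L
    e_end <- e_start + elen
    reg <- rbind(reg, data.frame(
      id = id, scaffold = sp$scaffold, category = sp$category,
      subtype = subtype, start = e_start, end = e_end,
      ltr5_start = if (!is.na(ltr5_len)) e_start else NA_integer_,
      ltr5_end = if (!is.na(ltr5_len)) e_start + ltr5_len else NA_integer_,
      ltr3_start = if (!is.na(ltr3_len)) e_end - ltr3_len else NA_integer_,
      ltr3_end = if (!is.na(ltr3_len)) e_end else NA_integer_,
      tsd = site, age_years = sp$age_years, realized_K = realized_K,
      seq = eseq, stringsAsFactors = FALSE))
    offset[sp$scaffold] <- offset[sp$scaffold] + elen + 4L
  }
  out <- genome_assembly(seqs)
  attr(out, "hotspots") <- attr(assembly, "hotspots")
  reg <- reg[order(reg$scaffold, reg$start), ]
  rownames(reg) <- NULL
  list(assembly = out, registry = reg)
}

#' Simulate homologous element sequences along a host species tree
#'
#' Evolves a subfamily consensus down `species_tree` (branch lengths x
#' `rate` = expected substitutions/site per branch, K2P process), then
#' applies optional horizontal-transfer events that overwrite a recipient
#' tip with a near-identical copy of the donor's sequence. Because the
#' model is substitution-only the output is a ready-aligned set.
#'
#' @param consensus Root DNA string.
#' @param species_tree [ape::phylo] with branch lengths; tip labels are the
#'   species names.
#' @param ht_events List of `list(donor=, recipient=, divergence=)` events.
#' @param rate Multiplier applied to branch lengths.
#' @param ts_tv Transition:transversion event ratio.
#' @param seed Integer seed.
#' @return Named character vector of aligned sequences (one per tip).
#' @export
simulate_homolog_set <- function(consensus, species_tree, ht_events = NULL,
                                 rate = 1, ts_tv = 2, seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"),
            !is.null(species_tree$edge.length))
  set.seed(seed)
  tr <- species_tree
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  node_seq <- vector("list", ntip + tr$Nnode)
  node_seq[[root]] <- toupper(consensus)
  # walk edges parents-first (topological over the edge list)
  todo <- seq_len(nrow(tr$edge))
  while (length(todo)) {
    ready <- todo[vapply(todo, function(e)
      !is.null(node_seq[[tr$edge[e, 1L]]]), TRUE)]
    if (!length(ready)) stop("malformed tree: unreachable edges")
    for (e in ready) {
      par <- tr$edge[e, 1L]; chl <- tr$edge[e, 2L]
      node_seq[[chl]] <- mutate_k2p(node_seq[[par]],
                                    tr$edge.length[e] * rate, ts_tv)
    }
    todo <- setdiff(todo, ready)
  }
  out <- setNames(unlist(node_seq[seq_len(ntip)]), tr$tip.label)
  for (ev in ht_events) {
    if (!all(c(ev$donor, ev$recipient) %in% tr$tip.label))
      stop("horizontal-transfer event names unknown species: ",
           ev$donor, " -> ", ev$recipient)
    dvg <- if (is.null(ev$divergence)) 0.01 else ev$divergence
    out[[ev$recipient]] <- mutate_k2p(out[[ev$donor]], dvg, ts_tv)
  }
  out
}
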