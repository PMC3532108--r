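#' @import methods
#' @importFrom stats setNames runif median aggregate as.dist
#' @importFrom utils modifyList read.delim combn
NULL

# Internal coordinate convention: 0-based, half-open [start, end).
# GFF3 output converts to 1-based inclusive (start + 1, end); reading
# converts back. Converting twice is the identity.

#' Construct a genome assembly from named sequences
#'
#' An assembly is an ordered set of scaffolds: named, uppercase DNA
#' sequences over the alphabet A, C, G, T, N.
#'
#' @param seqs Named character vector of DNA sequences.
#' @return An object of class `genome_assembly` with elements `seq`
#'   (named uppercase character vector) and `length` (named integer vector).
#' @export
genome_assembly <- function(seqs) {
  if (length(seqs) == 0L)
    stop("assembly must contain at least one scaffold")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every scaffold must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate scaffold ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L))
    stop("empty scaffold sequence: ", names(seqs)[nchar(seqs) == 0L][1L])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in scaffold: ", names(seqs)[bad][1L])
  structure(list(seq = seqs, length = setNames(nchar(seqs), names(seqs))),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("genome_assembly: %d scaffolds, %d bp total\n",
              length(x$seq), total_length(x)))
  invisible(x)
}

#' Total assembly length in bp
#' @param assembly A `genome_assembly`.
#' @return Integer total length.
#' @export
total_length <- function(assembly) sum(assembly$length)

#' Scaffold lengths
#' @param assembly A `genome_assembly`.
#' @return Named integer vector of per-scaffold lengths.
#' @export
scaffold_lengths <- function(assembly) assembly$length

#' Read a multi-FASTA file into a genome assembly
#'
#' Sequences are uppercased. Characters outside A/C/G/T/N are rejected
#' (`on_invalid = "error"`) or masked to N (`on_invalid = "mask"`).
#'
#' @param path Path to a FASTA file.
#' @param on_invalid `"error"` (strict, default) or `"mask"`.
#' @return A `genome_assembly`; record order is preserved.
#' @export
read_fasta <- function(path, on_invalid = c("error", "mask")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(set))
  # FASTA ids: first whitespace-delimited token of the header
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop("malformed FASTA header (empty id) at record ",
         which(!nzchar(ids))[1L])
  if (any(nchar(seqs) == 0L))
    stop("empty FASTA record: ", ids[nchar(seqs) == 0L][1L])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (on_invalid == "error")
      stop("record '", ids[bad][1L],
           "' contains characters outside {A,C,G,T,N}")
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  genome_assembly(setNames(seqs, ids))
}

#' Write an assembly (or any named sequences) to FASTA
#' @param assembly A `genome_assembly` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(assembly, path) {
  seqs <- if (inherits(assembly, "genome_assembly")) assembly$seq else assembly
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# canonical 0-row element table; every detector/annotator output binds to this
empty_elements <- function() {
  data.frame(
    id = character(), scaffold = character(),
    start = integer(), end = integer(), strand = character(),
    category = character(), subtype = character(),
    ltr5_start = integer(), ltr5_end = integer(),
    ltr3_start = integer(), ltr3_end = integer(),
    tsd = character(), ltr_identity = numeric(),
    termini5_ok = logical(), termini3_ok = logical(),
    pbs_start = integer(), pbs_end = integer(),
    pbs_trna = character(), pbs_score = integer(),
    ppt_start = integer(), ppt_end = integer(),
    family = character(), subfamily = character(),
    stringsAsFactors = FALSE)
}

# coerce a partial element data.frame onto the canonical column set,
# padding missing columns with NA of the right type
as_elements <- function(df) {
  tmpl <- empty_elements()
  n <- nrow(df)
  for (cn in names(tmpl)) {
    if (is.null(df[[cn]])) {
      v <- tmpl[[cn]]
      length(v) <- n
      df[[cn]] <- v
    }
  }
  df <- df[names(tmpl)]
  rownames(df) <- NULL
  df
}

validate_elements <- function(elements, assembly = NULL) {
  stopifnot(is.data.frame(elements))
  if (nrow(elements) == 0L) return(invisible(elements))
  if (any(elements$start < 0L) || any(elements$end <= elements$start))
    stop("invalid element interval (need 0 <= start < end)")
  if (!is.null(assembly)) {
    len <- scaffold_lengths(assembly)
    unknown <- setdiff(elements$scaffold, names(len))
    if (length(unknown))
      stop("element on unknown scaffold: ", unknown[1L])
    over <- elements$end > len[elements$scaffold]
    if (any(over))
      stop("element interval out of scaffold bounds: ",
           elements$id[over][1L])
  }
  invisible(elements)
}

#' Write annotated elements to GFF3
#'
#' One `repeat_region` feature per element (attributes: `category`,
#' `subtype`, `tsd`, `ltr_identity`, termini flags, family/subfamily),
#' with child `long_terminal_repeat`, `primer_binding_site` and
#' `polypurine_tract` features where annotated. Internal 0-based half-open
#' coordinates are emitted 1-based inclusive per the GFF3 standard.
#'
#' @param elements Element table as produced by the detector/annotator.
#' @param path Output path.
#' @param assembly Optional `genome_assembly` used to validate intervals.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(elements, path, assembly = NULL) {
  validate_elements(elements, assembly)
  elements <- as_elements(elements)
  gr_list <- list()
  n <- nrow(elements)
  mk <- function(scaffold, start0, end0, strand, type, id, parent = NA,
                 extra = list()) {
    md <- c(list(type = type, ID = id), extra)
    if (!is.na(parent)) md$Parent <- parent
    gr <- GenomicRanges::GRanges(
      seqnames = scaffold,
      ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
      strand = if (is.na(strand)) "*" else strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(md)
    gr
  }
  if (n > 0L) {
    for (i in seq_len(n)) {
      e <- elements[i, ]
      gr_list[[length(gr_list) + 1L]] <- mk(
        e$scaffold, e$start, e$end, e$strand, "repeat_region", e$id,
        extra = list(category = e$category, subtype = e$subtype,
                     tsd = e$tsd, ltr_identity = e$ltr_identity,
                     termini5_ok = e$termini5_ok, termini3_ok = e$termini3_ok,
                     family = e$family, subfamily = e$subfamily))
      if (!is.na(e$ltr5_start))
        gr_list[[length(gr_list) + 1L]] <- mk(
          e$scaffold, e$ltr5_start, e$ltr5_end, e$strand,
          "long_terminal_repeat", paste0(e$id, ".ltr5"), parent = e$id)
      if (!is.na(e$ltr3_start))
        gr_list[[length(gr_list) + 1L]] <- mk(
          e$scaffold, e$ltr3_start, e$ltr3_end, e$strand,
          "long_terminal_repeat", paste0(e$id, ".ltr3"), parent = e$id)
      if (!is.na(e$pbs_start))
        gr_list[[length(gr_list) + 1L]] <- mk(
          e$scaffold, e$pbs_start, e$pbs_end, e$strand,
          "primer_binding_site", paste0(e$id, ".pbs"), parent = e$id,
          extra = list(trna = e$pbs_trna, score = e$pbs_score))
      if (!is.na(e$ppt_start))
        gr_list[[length(gr_list) + 1L]] <- mk(
          e$scaffold, e$ppt_start, e$ppt_end, e$strand,
          "polypurine_tract", paste0(e$id, ".ppt"), parent = e$id)
    }
  }
  if (length(gr_list) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  all_cols <- unique(unlist(lapply(gr_list, function(g)
    names(S4Vectors::mcols(g)))))
  gr_list <- lapply(gr_list, function(g) {
    md <- S4Vectors::mcols(g)
    for (cn in setdiff(all_cols, names(md))) md[[cn]] <- NA
    S4Vectors::mcols(g) <- md[all_cols]
    g
  })
  gr <- do.call(c, gr_list)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read elements back from a GFF3 file written by [write_gff3()]
#'
#' @param path GFF3 path.
#' @return Element table with internal 0-based half-open coordinates.
#' @export
read_gff3_elements <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_elements())
  md <- S4Vectors::mcols(gr)
  is_parent <- md$type == "repeat_region"
  pgr <- gr[is_parent]
  pmd <- md[is_parent, , drop = FALSE]
  get_chr <- function(col) {
    v <- if (col %in% names(pmd)) as.character(pmd[[col]]) else
      rep(NA_character_, length(pgr))
    v[v %in% c("NA", "")] <- NA_character_
    v
  }
  out <- data.frame(
    id = as.character(pmd$ID),
    scaffold = as.character(GenomicRanges::seqnames(pgr)),
    start = GenomicRanges::start(pgr) - 1L,
    end = GenomicRanges::end(pgr),
    strand = as.character(GenomicRanges::strand(pgr)),
    category = get_chr("category"), subtype = get_chr("subtype"),
    tsd = get_chr("tsd"),
    ltr_identity = suppressWarnings(as.numeric(get_chr("ltr_identity"))),
    termini5_ok = as.logical(get_chr("termini5_ok")),
    termini3_ok = as.logical(get_chr("termini3_ok")),
    family = get_chr("family"), subfamily = get_chr("subfamily"),
    stringsAsFactors = FALSE)
  out$strand[out$strand == "*"] <- NA_character_
  # attach child features by Parent attribute
  add_child <- function(out, type, s_col, e_col, suffix) {
    ch <- gr[md$type == type &
               grepl(paste0("\\.", suffix, "$"),
                     as.character(S4Vectors::mcols(gr)$ID))]
    if (length(ch) == 0L) return(out)
    pid <- sub(paste0("\\.", suffix, "$"), "",
               as.character(S4Vectors::mcols(ch)$ID))
    i <- match(pid, out$id)
    out[[s_col]][i] <- GenomicRanges::start(ch) - 1L
    out[[e_col]][i] <- GenomicRanges::end(ch)
    out
  }
  out$ltr5_start <- out$ltr5_end <- out$ltr3_start <- out$ltr3_end <-
    out$pbs_start <- out$pbs_end <- out$ppt_start <- out$ppt_end <-
    NA_integer_
  out$pbs_trna <- NA_character_
  out$pbs_score <- NA_integer_
  out <- add_child(out, "long_terminal_repeat", "ltr5_start", "ltr5_end",
                   "ltr5")
  out <- add_child(out, "long_terminal_repeat", "ltr3_start", "ltr3_end",
                   "ltr3")
  out <- add_child(out, "primer_binding_site", "pbs_start", "pbs_end", "pbs")
  out <- add_child(out, "polypurine_tract", "ppt_start", "ppt_end", "ppt")
  pbs <- gr[md$type == "primer_binding_site"]
  if (length(pbs)) {
    pid <- sub("\\.pbs$", "", as.character(S4Vectors::mcols(pbs)$ID))
    i <- match(pid, out$id)
    if ("trna" %in% names(S4Vectors::mcols(pbs)))
      out$pbs_trna[i] <- as.character(S4Vectors::mcols(pbs)$trna)
    if ("score" %in% names(S4Vectors::mcols(pbs)))
      out$pbs_score[i] <-
        suppressWarnings(as.integer(S4Vectors::mcols(pbs)$score))
  }
  as_elements(out)
}

#' Read a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]: rejects unparsable
#' strings and duplicate tip labels. Internal node labels (bootstrap
#' supports) and branch lengths are preserved.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("could not parse Newick file: ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels in tree: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  tr
}

#' Write a tree to Newick
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Run configuration with the package defaults for every stage
#'
#' All tunable parameters of the pipeline in one (validated) list; pass
#' individual overrides as named arguments. A serialized config plus the
#' seeds it carries fully determines a run.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `trim_config`.
#' @export
trim_config <- function(...) {
  defaults <- list(
    # detector
    seed_k = 15L, min_ltr = 100L, max_ltr = 350L, hard_min_ltr = 50L,
    min_internal = 50L, max_internal = 700L, max_element = 1000L,
    min_ltr_identity = 0.80, refine_bp = 10L,
    match = 2, mismatch = -3, gap_open = 5, gap_extend = 2,
    # PBS / PPT
    pbs_window = 25L, pbs_min_match = 10L, pbs_max_mismatch = 1L,
    ppt_window = 15L, ppt_region = 30L, ppt_min_purine = 0.8,
    # library scan
    scan_min_identity = 0.80, solo_min_coverage = 0.80,
    # substructure
    tata_search = 70L, r_offset = 11L, r_offset_slack = 3L,
    r_len_range = c(60L, 80L), default_u3 = 62L, default_r = 69L,
    # families
    family_min_identity = 0.80, family_min_coverage = 0.80,
    # dating
    rate = 0.54e-8, ts_tv = 2, count_indel_sites = FALSE,
    # distribution stats
    n_reps = 5000L, max_gap_bp = 50000L,
    # simulator
    background_gc = 0.37, hotspot_gc = 0.19,
    # phylo
    bootstrap_reps = 1000L, tn93_frequencies = "pairwise",
    seed = 1L)
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all config overrides must be named")
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      stop("unknown config parameter: ", paste(unknown, collapse = ", "))
    defaults <- modifyList(defaults, over)
  }
  with(defaults, {
    if (min_ltr > max_ltr) stop("min_ltr > max_ltr")
    if (min_internal > max_internal) stop("min_internal > max_internal")
    if (min_ltr < hard_min_ltr)
      stop("min_ltr below the hard floor of ", hard_min_ltr, " bp")
  })
  structure(defaults, class = c("trim_config", "list"))
}

#' @export
print.trim_config <- function(x, ...) {
  cat(sprintf("trim_config (digest %s):\n", config_digest(x)))
  for (nm in names(x))
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

# short content digest used in log lines (FNV-1a over the serialized object)
config_digest <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(h, b) * 16777619) %% 2^32)
  sprintf("%08x", h)
}

log_msg <- function(...) message(format(Sys.time(), "[%H:%M:%S] "), ...)

# sequence helpers ----------------------------------------------------------

subseq0 <- function(seq, start, end) substr(seq, start + 1L, end)

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""), ""))
}
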