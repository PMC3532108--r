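# Element and host phylogenetics: Tamura-Nei (1993) distances with
# pairwise deletion, neighbor-joining with bootstrap supports, subfamily
# clade cutting, and Fitch parsimony reconstruction of presence/absence
# histories with exhaustive MPR enumeration and ACCTRAN/DELTRAN tracings.

aln_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    stopifnot(!is.null(names(alignment)))
    w <- nchar(alignment)
    if (length(unique(w)) != 1L)
      stop("alignment rows differ in length")
    m <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(m) <- names(alignment)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate sequence labels")
  m
}

# TN93 distance for one pair of residue vectors (comparable sites only)
tn93_pair <- function(a, b, freqs) {
  n <- length(a)
  gA <- freqs["A"]; gC <- freqs["C"]; gG <- freqs["G"]; gT <- freqs["T"]
  gR <- gA + gG; gY <- gC + gT
  diff <- a != b
  purA <- a %in% c("A", "G"); purB <- b %in% c("A", "G")
  P1 <- sum(diff & purA & purB) / n          # A <-> G
  P2 <- sum(diff & !purA & !purB) / n        # C <-> T
  Q <- sum(diff & (purA != purB)) / n
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  term <- function(k, P, g) {
    if (k <= 0) {
      if (P > 0) return(NA_real_)  # impossible composition
      return(0)
    }
    w <- 1 - P / k - Q / (2 * g)
    if (w <= 0) return(NA_real_)
    -k * log(w)
  }
  t1 <- term(k1, P1, gR)
  t2 <- term(k2, P2, gY)
  w3 <- 1 - Q / (2 * gR * gY)
  t3 <- if (Q == 0) 0 else if (w3 <= 0) NA_real_ else -k3 * log(w3)
  unname(t1 + t2 + t3)
}

#' Tamura-Nei (1993) distance matrix with pairwise deletion
#'
#' For each sequence pair, columns containing gaps or N in either row are
#' dropped (pairwise deletion) and the TN93 distance is computed from the
#' pair's transition proportions (A<->G and C<->T separately) and
#' transversion proportion. Base frequencies are per-pair empirical
#' (default) or pooled over the whole alignment.
#'
#' @param alignment Named character vector of equal-length aligned rows
#'   (characters A,C,G,T,N,-) or an equivalent character matrix.
#' @param frequencies `"pairwise"` (default) or `"global"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
tamura_nei_distance <- function(alignment,
                                frequencies = c("pairwise", "global")) {
  frequencies <- match.arg(frequencies)
  m <- aln_matrix(alignment)
  labs <- rownames(m)
  nt <- c("A", "C", "G", "T")
  gfreq <- NULL
  if (frequencies == "global") {
    tab <- table(factor(m[m %in% nt], levels = nt))
    gfreq <- as.numeric(tab) / sum(tab)
    names(gfreq) <- nt
  }
  ns <- length(labs)
  d <- matrix(0, ns, ns, dimnames = list(labs, labs))
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      ok <- m[i, ] %in% nt & m[j, ] %in% nt
      if (!any(ok))
        stop("no comparable sites for pair ", labs[i], " / ", labs[j])
      a <- m[i, ok]; b <- m[j, ok]
      fr <- if (frequencies == "pairwise") {
        tab <- table(factor(c(a, b), levels = nt))
        f <- as.numeric(tab) / sum(tab); names(f) <- nt; f
      } else gfreq
      if (any(fr[c("A", "G")] == 0) && any(fr[c("C", "T")] == 0))
        stop("degenerate base composition for pair ", labs[i], " / ",
             labs[j])
      dij <- tn93_pair(a, b, fr)
      if (is.na(dij))
        stop("saturated pair (TN93 undefined): ", labs[i], " / ", labs[j])
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration via [ape::nj()]; negative branch lengths
#' (a known NJ artifact) are clamped to zero and the total clamped
#' deficit recorded as an attribute.
#'
#' @param d Symmetric distance matrix (labels as dimnames) or `dist`.
#' @return Unrooted [ape::phylo] tree; `attr(, "clamped")` is the summed
#'   negative length removed.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 3L)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(as.dist(d))
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- deficit
  tr
}

#' Bootstrap supports for the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the TN93/NJ tree
#' per replicate, and reports bipartition frequencies (percent) on the
#' full-data tree as internal node labels. Replicates whose resampled
#' distances are undefined (saturation) are skipped and excluded from the
#' denominator.
#'
#' @param alignment As in [tamura_nei_distance()].
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param frequencies Passed to [tamura_nei_distance()].
#' @return The full-data NJ tree with `node.label` percent supports (the
#'   root label is `NA`).
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = 1L,
                              frequencies = c("pairwise", "global")) {
  frequencies <- match.arg(frequencies)
  m <- aln_matrix(alignment)
  main <- neighbor_joining(tamura_nei_distance(m, frequencies))
  set.seed(seed)
  boots <- vector("list", n_reps)
  ok <- 0L
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    tr <- tryCatch(
      neighbor_joining(tamura_nei_distance(m[, cols, drop = FALSE],
                                           frequencies)),
      error = function(e) NULL)
    if (!is.null(tr)) {
      ok <- ok + 1L
      boots[[ok]] <- tr
    }
  }
  if (ok == 0L) stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(main, boots[seq_len(ok)], rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / ok
  support[1L] <- NA  # root of the unrooted representation
  main$node.label <- round(support, 1)
  attr(main, "n_boot") <- ok
  main
}

#' Cut well-supported, compact clades into subfamily labels
#'
#' Walks the tree from the root and labels each maximal clade whose
#' bootstrap support is at least `min_support` and whose mean within-clade
#' patristic distance is at most `max_within_distance`. Tips outside every
#' qualifying clade are labeled `"unassigned"`.
#'
#' @param tree [ape::phylo] with numeric `node.label` supports (as from
#'   [bootstrap_support()]).
#' @param min_support Minimum percent support.
#' @param max_within_distance Maximum mean pairwise distance within a clade.
#' @param d Optional distance matrix to measure within-clade divergence;
#'   defaults to the tree's patristic (cophenetic) distances.
#' @return Named character vector: tip label -> subfamily (`"S1"`, `"S2"`,
#'   ... or `"unassigned"`).
#' @export
cut_subfamilies <- function(tree, min_support, max_within_distance,
                            d = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(d)) d <- ape::cophenetic.phylo(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  supports <- suppressWarnings(as.numeric(tree$node.label))
  labels <- setNames(rep("unassigned", ntip), tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  tips_under <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(kids[[as.character(node)]], tips_under))
  }
  counter <- 0L
  visit <- function(node) {
    if (node <= ntip) return(invisible())
    qualifies <- FALSE
    if (node != root) {
      sup <- supports[node - ntip]
      tps <- tips_under(node)
      if (length(tps) >= 2L && !is.na(sup) && sup >= min_support) {
        dd <- d[tree$tip.label[tps], tree$tip.label[tps]]
        if (mean(dd[upper.tri(dd)]) <= max_within_distance)
          qualifies <- TRUE
      }
    }
    if (qualifies) {
      counter <<- counter + 1L
      labels[tree$tip.label[tips_under(node)]] <<-
        paste0("S", counter)
    } else {
      for (ch in kids[[as.character(node)]]) visit(ch)
    }
    invisible()
  }
  visit(root)
  labels
}

# normalize a presence/absence character to integer 0/1 named by taxon
as_binary_states <- function(character_map, tree) {
  x <- character_map
  if (is.character(x))
    x <- setNames(as.integer(tolower(x) %in% c("present", "1", "yes")),
                  names(x))
  if (is.logical(x)) x <- setNames(as.integer(x), names(x))
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss))
    stop("no state for tree leaves: ", paste(miss, collapse = ", "))
  stopifnot(all(x[tree$tip.label] %in% c(0L, 1L)))
  setNames(as.integer(x[tree$tip.label]), tree$tip.label)
}

#' Fitch parsimony for a binary character on a rooted binary tree
#'
#' Bottom-up (downpass) state sets give the minimal number of changes;
#' per-node MPR state sets (the states each node takes in at least one
#' most-parsimonious reconstruction) are derived by exhaustive enumeration
#' on trees of tractable size.
#'
#' @param tree Rooted, binary [ape::phylo].
#' @param character_map Named vector over the tips: 0/1, logical, or
#'   `"present"`/`"absent"`.
#' @return `list(steps=, downpass=, mpr_sets=)`; `downpass` and `mpr_sets`
#'   are lists of state sets indexed by ape node number (tips first).
#' @export
fitch_parsimony <- function(tree, character_map) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree))
    stop("tree must be binary: resolve polytomies upstream")
  states <- as_binary_states(character_map, tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- states[[i]]
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  steps <- 0L
  # postorder: process internal nodes children-first
  todo <- (ntip + 1L):(ntip + nnode)
  done <- rep(FALSE, ntip + nnode)
  done[seq_len(ntip)] <- TRUE
  while (length(todo)) {
    ready <- todo[vapply(todo, function(v)
      all(done[kids[[as.character(v)]]]), TRUE)]
    for (v in ready) {
      cs <- lapply(kids[[as.character(v)]], function(ch) sets[[ch]])
      inter <- Reduce(intersect, cs)
      if (length(inter)) {
        sets[[v]] <- inter
      } else {
        sets[[v]] <- Reduce(union, cs)
        steps <- steps + 1L
      }
      done[v] <- TRUE
    }
    todo <- setdiff(todo, ready)
  }
  mpr_sets <- NULL
  if (nnode <= 16L) {
    rec <- enumerate_mprs(tree, character_map, root_state = "free")
    mpr_sets <- rec$node_state_sets
  }
  list(steps = steps, downpass = sets, mpr_sets = mpr_sets)
}

#' Enumerate all most-parsimonious reconstructions of a binary character
#'
#' Exhaustively searches internal-node state assignments on a rooted binary
#' tree, keeping those that realize the minimal change count. Each MPR is
#' annotated with its gains (absent -> present) and losses; ACCTRAN is the
#' MPR that pushes changes rootward (maximal number of internal nodes in
#' the derived, non-root state) and DELTRAN the one that delays them
#' tipward (minimal number), ties broken deterministically by enumeration
#' order.
#'
#' @param tree Rooted, binary [ape::phylo] with at most 16 internal nodes.
#' @param character_map Named tip states (see [fitch_parsimony()]).
#' @param root_state `"outgroup"` (default): the root is fixed to the
#'   observed state of a leaf attached directly to the root (the outgroup),
#'   matching ancestral-state practice when an outgroup anchors the
#'   analysis; `"free"`: the root state is unconstrained.
#' @return An `ancestral_reconstruction` list: `steps`, `mprs` (list of
#'   full node-state vectors, tips included), `gains`, `losses`,
#'   `acctran`, `deltran` (indices into `mprs`), `node_state_sets`.
#' @export
enumerate_mprs <- function(tree, character_map,
                           root_state = c("outgroup", "free")) {
  root_state <- match.arg(root_state)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree))
    stop("tree must be binary: resolve polytomies upstream")
  states <- as_binary_states(character_map, tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  if (nnode > 16L)
    stop("exhaustive MPR enumeration is limited to 16 internal nodes")
  root <- ntip + 1L
  anchored <- NA_integer_
  if (root_state == "outgroup") {
    root_kids <- tree$edge[tree$edge[, 1L] == root, 2L]
    leaf_kid <- root_kids[root_kids <= ntip]
    if (length(leaf_kid))
      anchored <- states[[leaf_kid[1L]]]
    # no leaf child at the root: fall back to a free root
  }
  edges <- tree$edge
  node_state <- integer(ntip + nnode)
  node_state[seq_len(ntip)] <- states
  internal <- root:(ntip + nnode)
  best <- Inf
  mprs <- list()
  for (code in 0:(2L^nnode - 1L)) {
    assign <- as.integer(intToBits(code)[seq_len(nnode)])
    if (!is.na(anchored) && assign[1L] != anchored) next
    node_state[internal] <- assign
    cost <- sum(node_state[edges[, 1L]] != node_state[edges[, 2L]])
    if (cost < best) {
      best <- cost
      mprs <- list(node_state)
    } else if (cost == best) {
      mprs[[length(mprs) + 1L]] <- node_state
    }
  }
  node_names <- c(tree$tip.label,
                  if (!is.null(tree$node.label) &&
                      length(tree$node.label) == nnode) tree$node.label
                  else paste0("node", root:(ntip + nnode)))
  mprs <- lapply(mprs, function(v) setNames(v, node_names))
  gains <- vapply(mprs, function(v)
    sum(v[edges[, 1L]] == 0L & v[edges[, 2L]] == 1L), 0L)
  losses <- vapply(mprs, function(v)
    sum(v[edges[, 1L]] == 1L & v[edges[, 2L]] == 0L), 0L)
  rs <- if (!is.na(anchored)) anchored else NA_integer_
  derived_count <- vapply(mprs, function(v) {
    base <- if (is.na(rs)) v[[root]] else rs
    sum(v[internal] != base)
  }, 0L)
  acctran <- which.max(derived_count)
  deltran <- which.min(derived_count)
  node_state_sets <- lapply(seq_len(ntip + nnode), function(v)
    sort(unique(vapply(mprs, `[[`, 0L, v))))
  structure(list(steps = as.integer(best), mprs = mprs, gains = gains,
                 losses = losses, acctran = acctran, deltran = deltran,
                 node_state_sets = node_state_sets,
                 root_state = rs, tree = tree),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat(sprintf(
    "parsimony reconstruction: %d steps, %d MPR(s); gains %s, losses %s\n",
    x$steps, length(x$mprs),
    paste(range(x$gains), collapse = "-"),
    paste(range(x$losses), collapse = "-")))
  cat(sprintf("ACCTRAN: %d gain(s) + %d loss(es); DELTRAN: %d gain(s) + %d loss(es)\n",
              x$gains[x$acctran], x$losses[x$acctran],
              x$gains[x$deltran], x$losses[x$deltran]))
  invisible(x)
}

#' Host phylogeny of the 13 taxa scored for PbTRIM presence
#'
#' The genus-level ant phylogeny (with the honey bee as outgroup) used for
#' ancestral-state reconstruction of PbTRIM presence/absence, assembled
#' from the standard molecular phylogenies of the ant subfamilies:
#' Myrmicinae (Pogonomyrmex, Aphaenogaster+Messor,
#' Crematogaster+Solenopsis, Pheidole), Formicinae (Camponotus, Lasius)
#' and Dolichoderinae (Linepithema) as successive outgroups, Apis rooting
#' the tree.
#'
#' @return Rooted binary [ape::phylo] with 13 tips.
#' @export
pbtrim_host_tree <- function() {
  ape::read.tree(text = paste0(
    "(Apis_mellifera,(Linepithema_humile,((Camponotus_pennsylvanicus,",
    "(Lasius_alienus,Lasius_neoniger)),((Pogonomyrmex_barbatus,",
    "Pogonomyrmex_rugosus),((Aphaenogaster_rudis,Messor_pergandei),",
    "((Crematogaster_sp,Solenopsis_xyloni),(Pheidole_desertorum,",
    "Pheidole_hyatti)))))));"))
}

#' PbTRIM presence/absence states for the host phylogeny
#'
#' Presence in both Pogonomyrmex species, both Pheidole species, both
#' Lasius species and Linepithema humile; absence in Aphaenogaster,
#' Camponotus, Crematogaster, Messor, Solenopsis and the Apis outgroup.
#'
#' @return Named integer vector (1 = present, 0 = absent) over the tips of
#'   [pbtrim_host_tree()].
#' @export
pbtrim_host_presence <- function() {
  present <- c("Pogonomyrmex_barbatus", "Pogonomyrmex_rugosus",
               "Pheidole_desertorum", "Pheidole_hyatti",
               "Lasius_alienus", "Lasius_neoniger", "Linepithema_humile")
  tips <- pbtrim_host_tree()$tip.label
  setNames(as.integer(tips %in% present), tips)
}

#' Simple center-star multiple alignment
#'
#' Pairwise global alignment of every sequence to the longest one, with
#' gap columns merged on the center's coordinates. A convenience for
#' synthetic data; real datasets should be aligned with a dedicated MSA
#' tool and supplied pre-aligned.
#'
#' @param seqs Named character vector of DNA sequences.
#' @return Named character vector of equal-length aligned rows.
#' @export
align_star <- function(seqs) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  center_i <- which.max(nchar(seqs))
  center <- seqs[[center_i]]
  nc <- nchar(center)
  others <- seq_along(seqs)[-center_i]
  alns <- lapply(others, function(i) {
    a <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(center), Biostrings::DNAString(seqs[[i]]),
      type = "global", substitutionMatrix = ltr_submat(),
      gapOpening = 0, gapExtension = 2)
    list(c = strsplit(as.character(Biostrings::alignedPattern(a)), "")[[1]],
         s = strsplit(as.character(Biostrings::alignedSubject(a)), "")[[1]])
  })
  # gaps inserted into the center before center position p (1..nc+1)
  ins_counts <- lapply(alns, function(al) {
    pos <- 1L
    ins <- integer(nc + 1L)
    run <- 0L
    for (ch in al$c) {
      if (ch == "-") run <- run + 1L
      else {
        ins[pos] <- ins[pos] + run
        run <- 0L
        pos <- pos + 1L
      }
    }
    ins[nc + 1L] <- ins[nc + 1L] + run
    ins
  })
  master <- Reduce(pmax, ins_counts, integer(nc + 1L))
  project <- function(row_c, row_s) {
    out <- character(0)
    pos <- 1L
    i <- 1L
    nal <- length(row_c)
    while (pos <= nc + 1L) {
      # consume this alignment's gap run before center position pos
      run <- 0L
      while (i <= nal && row_c[i] == "-") {
        out <- c(out, row_s[i])
        run <- run + 1L
        i <- i + 1L
      }
      if (master[pos] > run)
        out <- c(out, rep("-", master[pos] - run))
      if (pos <= nc) {
        out <- c(out, row_s[i])
        i <- i + 1L
      }
      pos <- pos + 1L
    }
    paste(out, collapse = "")
  }
  res <- character(length(seqs))
  center_chars <- strsplit(center, "")[[1]]
  res[center_i] <- project(center_chars, center_chars)
  for (k in seq_along(others))
    res[others[k]] <- project(alns[[k]]$c, alns[[k]]$s)
  names(res) <- names(seqs)
  res
}
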