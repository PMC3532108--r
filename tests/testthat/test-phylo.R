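test_that("TN93 distances match hand evaluation, ape, and pairwise deletion", {
  rows <- c(s1 = strrep("ACGT", 25), s2 = strrep("ACGT", 25))
  expect_identical(tamura_nei_distance(rows)[1, 2], 0)
  set.seed(81)
  for (i in 1:20) {
    pr <- aligned_pair(200, sample(1:20, 1), sample(0:10, 1), gc = 0.45)
    rows <- c(s1 = pr[["a"]], s2 = pr[["b"]])
    d <- tamura_nei_distance(rows)[1, 2]
    expect_equal(d, tn93_hand(pr[["a"]], pr[["b"]]), tolerance = 1e-10)
    bin <- ape::as.DNAbin(t(sapply(rows, function(s)
      strsplit(tolower(s), "")[[1]])))
    d_ape <- ape::dist.dna(bin, model = "TN93",
                           pairwise.deletion = TRUE)[1]
    expect_equal(d, unname(d_ape), tolerance = 1e-10)
  }
  # pairwise deletion: an all-gap column changes nothing
  pr <- aligned_pair(100, 5, 2)
  rows <- c(a = pr[["a"]], b = pr[["b"]])
  rows_gap <- c(a = paste0(pr[["a"]], "-"), b = paste0(pr[["b"]], "-"))
  expect_identical(tamura_nei_distance(rows), tamura_nei_distance(rows_gap))
  # saturation is an explicit error naming the pair
  sat <- aligned_pair(100, 48, 30)
  expect_error(tamura_nei_distance(c(x = sat[["a"]], y = sat[["b"]])),
               "saturated.*x.*y")
})

test_that("neighbor joining solves the 3-taxon equations and additive matrices", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 2)
  expect_equal(bl[["C"]], 3)
  # additive 4-taxon case: exact topology and branch lengths
  tr0 <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.5,D:3):1);")
  d4 <- ape::cophenetic.phylo(tr0)
  tr4 <- neighbor_joining(d4)
  expect_identical(ape::dist.topo(ape::unroot(tr0), tr4)[1], 0)
  expect_equal(sum(tr4$edge.length), sum(ape::unroot(tr0)$edge.length))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric|nrow")
})

test_that("bootstrap supports are deterministic and saturate on diagnostic columns", {
  set.seed(82)
  base <- random_dna(150, 0.45)
  # two 3-taxon clades separated by 50 fixed diagnostic columns
  diag_cols <- sample(150, 50)
  other <- base
  for (i in diag_cols) {
    substr(other, i, i) <-
      c(A = "G", G = "A", C = "T", T = "C")[[substr(base, i, i)]]
  }
  jitter1 <- function(s, k) mutate_positions(s, k)
  aln <- c(a1 = base, a2 = jitter1(base, 2), a3 = jitter1(base, 2),
           b1 = other, b2 = jitter1(other, 2), b3 = jitter1(other, 2))
  tr <- bootstrap_support(aln, n_reps = 100, seed = 5)
  # support of a bipartition can be labelled on either side of the split
  split_support <- function(tree, tips) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    vals <- numeric(0)
    for (side in list(tips, setdiff(tree$tip.label, tips))) {
      if (ape::is.monophyletic(tree, side)) {
        anc <- ape::getMRCA(tree, side)
        vals <- c(vals, sup[anc - length(tree$tip.label)])
      }
    }
    max(vals, na.rm = TRUE)
  }
  expect_true(ape::is.monophyletic(tr, c("a1", "a2", "a3")))
  expect_gte(split_support(tr, c("a1", "a2", "a3")), 99)
  tr_again <- bootstrap_support(aln, n_reps = 100, seed = 5)
  expect_identical(tr$node.label, tr_again$node.label)
})

test_that("subfamily cutting finds planted clusters and leaves outliers out", {
  set.seed(83)
  cons <- random_dna(300, 0.45)
  subcons <- lapply(1:4, function(i) mutate_positions(cons, 60L))
  seqs <- character(0)
  for (i in 1:4) {
    for (j in 1:4) {
      seqs[sprintf("f%d_%d", i, j)] <- mutate_positions(subcons[[i]], 8L)
    }
  }
  seqs["outlier"] <- mutate_positions(cons, 130L)
  tr <- bootstrap_support(seqs, n_reps = 100, seed = 6)
  # root on the divergent sequence so the clusters are proper clades
  tr <- ape::root(tr, outgroup = "outlier", resolve.root = TRUE,
                  edgelabel = TRUE)
  labs <- cut_subfamilies(tr, min_support = 70, max_within_distance = 0.12)
  for (i in 1:4) {
    members <- labs[grep(sprintf("^f%d_", i), names(labs))]
    expect_identical(length(unique(members)), 1L)
    expect_false(unique(members) == "unassigned")
  }
  expect_identical(length(setdiff(unique(labs), "unassigned")), 4L)
  expect_identical(unname(labs["outlier"]), "unassigned")
  # a star tree (no support labels, all equidistant) assigns nothing
  star_d <- matrix(0.3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(star_d) <- 0
  star <- neighbor_joining(star_d)
  expect_true(all(cut_subfamilies(star, 50, 0.5) == "unassigned"))
})

test_that("Fitch parsimony matches exhaustive counts and the phangorn oracle", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  states <- c(A = 1, B = 1, C = 0, D = 0)
  fp <- fitch_parsimony(tr, states)
  expect_identical(fp$steps, 1L)
  expect_identical(fitch_parsimony(tr, c(A = 1, B = 1, C = 1, D = 1))$steps,
                   0L)
  skip_if_not_installed("phangorn")
  set.seed(84)
  for (i in 1:15) {
    rt <- ape::rtree(sample(5:10, 1))
    st <- setNames(sample(0:1, length(rt$tip.label), replace = TRUE),
                   rt$tip.label)
    if (length(unique(st)) == 1L) st[1] <- 1 - st[1]
    dat <- phangorn::phyDat(matrix(as.character(st), ncol = 1,
                                   dimnames = list(names(st), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_identical(fitch_parsimony(rt, st)$steps,
                     as.integer(phangorn::parsimony(rt, dat)))
  }
})

test_that("MPR enumeration is exhaustive and consistent with the step count", {
  # outgroup-rooted quartet: the single MPR is one gain on the (A,B) stem
  tr <- ape::read.tree(text = "(O,((A,B),(C,D)));")
  states <- c(O = 0, A = 1, B = 1, C = 0, D = 0)
  rec <- enumerate_mprs(tr, states)
  expect_identical(rec$steps, 1L)
  expect_identical(length(rec$mprs), 1L)
  expect_identical(rec$gains, 1L)
  expect_identical(rec$losses, 0L)
  # constant character: one MPR, zero steps
  rec0 <- enumerate_mprs(tr, c(O = 1, A = 1, B = 1, C = 1, D = 1))
  expect_identical(rec0$steps, 0L)
  expect_identical(length(rec0$mprs), 1L)
  # every MPR realizes exactly `steps` changes; tracings are MPR members
  set.seed(85)
  for (i in 1:10) {
    rt <- ape::rtree(7)
    st <- setNames(sample(0:1, 7, replace = TRUE), rt$tip.label)
    if (length(unique(st)) == 1L) st[1] <- 1 - st[1]
    rec <- enumerate_mprs(rt, st, root_state = "free")
    expect_identical(rec$steps, fitch_parsimony(rt, st)$steps)
    expect_true(all(rec$gains + rec$losses == rec$steps))
    expect_true(rec$acctran %in% seq_along(rec$mprs))
    expect_true(rec$deltran %in% seq_along(rec$mprs))
  }
})

test_that("the host fixture reproduces the published reconstruction exactly", {
  tr <- pbtrim_host_tree()
  expect_identical(length(tr$tip.label), 13L)
  expect_true(ape::is.rooted(tr) && ape::is.binary(tr))
  states <- pbtrim_host_presence()
  expect_identical(sum(states), 7L)
  rec <- enumerate_mprs(tr, states)
  expect_identical(rec$steps, 4L)
  expect_identical(length(rec$mprs), 3L)
  expect_identical(range(rec$gains), c(1L, 4L))
  expect_identical(range(rec$losses), c(0L, 3L))
  expect_identical(rec$gains[rec$acctran], 1L)
  expect_identical(rec$losses[rec$acctran], 3L)
  expect_identical(rec$gains[rec$deltran], 4L)
  expect_identical(rec$losses[rec$deltran], 0L)
})

test_that("the center-star aligner reproduces simple indel structures", {
  set.seed(86)
  s <- random_dna(60, 0.5)
  del <- paste0(substr(s, 1, 29), substr(s, 33, 60))
  aln <- align_star(c(full = s, gapped = del, other = s))
  expect_identical(length(unique(nchar(aln))), 1L)
  expect_identical(gsub("-", "", aln[["gapped"]]), del)
  expect_identical(aln[["full"]], s)
  expect_identical(sum(strsplit(aln[["gapped"]], "")[[1]] == "-"), 3L)
})
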