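# Shared fixtures and independent oracles. The oracles deliberately use
# naive per-column loops / full DP so they share no code path with the
# package implementations they check.

make_ltr <- function(len = 160L, gc = 0.37) {
  paste0("TG", random_dna(len - 4L, gc), "CA")
}

# exhaustive Needleman-Wunsch score (linear gaps, end gaps penalized)
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(
        S[i, j] + if (A[i] == B[j]) match else mismatch,
        S[i, j + 1L] + gap,
        S[i + 1L, j] + gap)
    }
  }
  S[n + 1L, m + 1L]
}

# direct K2P formula evaluation with an explicit per-column loop
k2p_hand <- function(a, b) {
  nt <- c("A", "C", "G", "T")
  pur <- c("A", "G")
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_len(nchar(a))) {
    x <- substr(a, i, i); y <- substr(b, i, i)
    if (!(x %in% nt) || !(y %in% nt)) next
    n <- n + 1L
    if (x != y) {
      if ((x %in% pur) == (y %in% pur)) ts <- ts + 1L else tv <- tv + 1L
    }
  }
  P <- ts / n; Q <- tv / n
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# direct TN93 formula evaluation (per-pair empirical frequencies)
tn93_hand <- function(a, b) {
  nt <- c("A", "C", "G", "T")
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  ok <- A %in% nt & B %in% nt
  A <- A[ok]; B <- B[ok]
  n <- length(A)
  f <- table(factor(c(A, B), levels = nt)) / (2 * n)
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  P1 <- sum(A != B & A %in% pur_set & B %in% pur_set) / n
  P2 <- sum(A != B & !(A %in% pur_set) & !(B %in% pur_set)) / n
  Q  <- sum((A %in% pur_set) != (B %in% pur_set)) / n
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  t1 <- if (k1 > 0) -k1 * log(1 - P1 / k1 - Q / (2 * gR)) else 0
  t2 <- if (k2 > 0) -k2 * log(1 - P2 / k2 - Q / (2 * gY)) else 0
  t3 <- if (Q > 0) -k3 * log(1 - Q / (2 * gR * gY)) else 0
  t1 + t2 + t3
}
pur_set <- c("A", "G")

# mutate an exact set of positions to a different random base, never
# touching `protect` (1-based positions)
mutate_positions <- function(seq, n_mut, protect = integer(0)) {
  chars <- strsplit(seq, "")[[1]]
  avail <- setdiff(seq_along(chars), protect)
  idx <- sample(avail, n_mut)
  for (i in idx) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# a random aligned pair with controlled numbers of transitions and
# transversions at distinct sites (for K2P/TN93 formula checks)
aligned_pair <- function(n_sites, n_ts, n_tv, gc = 0.5) {
  a <- random_dna(n_sites, gc)
  b <- a
  idx <- sample(n_sites, n_ts + n_tv)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in idx[seq_len(n_ts)]) {
    substr(b, i, i) <- transition[[substr(a, i, i)]]
  }
  if (n_tv > 0) {
    for (i in idx[n_ts + seq_len(n_tv)]) {
      x <- substr(a, i, i)
      tv <- if (x %in% c("A", "G")) c("C", "T") else c("A", "G")
      substr(b, i, i) <- sample(tv, 1L)
    }
  }
  c(a = a, b = b)
}

# standard planted genome used by detector tests: background scaffolds
# plus complete / solo / truncated copies from a shared family template
planted_genome <- function(n_scaffolds = 4L, scaf_len = c(8000, 12000),
                           seed = 101L) {
  asm <- generate_background(n_scaffolds, scaf_len, gc = 0.37, seed = seed)
  set.seed(seed + 1L)
  ltr <- make_ltr(160L)
  internal <- random_dna(300L, 0.37)
  specs <- list(
    plant_spec(ltr, internal, tsd = "ATAT", age_years = 0,
               category = "complete", scaffold = "scaf001",
               position = 2000L),
    plant_spec(ltr, internal, age_years = 2e6, category = "complete",
               scaffold = "scaf002", position = 5000L),
    plant_spec(ltr, tsd = "ATAT", age_years = 1e6, category = "solo_ltr",
               scaffold = "scaf003", position = 3000L),
    plant_spec(ltr, internal, age_years = 0, category = "truncated",
               scaffold = "scaf004", position = 4000L,
               truncate_frac = 0.7))
  res <- plant_elements(asm, specs, seed = seed + 2L)
  res$ltr <- ltr
  res$internal <- internal
  res
}

# element-table construction helpers over the package's internal canon
empty_elements_fixture <- function() trimscan:::empty_elements()

as_elements_fixture <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (is.null(df$id)) df$id <- sprintf("el%03d", seq_len(nrow(df)))
  if (is.null(df$strand)) df$strand <- "+"
  if (is.null(df$category)) df$category <- "complete"
  trimscan:::as_elements(df)
}
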