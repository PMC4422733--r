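# Independent oracles used to check the package's alignment and metric
# code.  These are deliberately naive re-implementations (plain dynamic
# programming and per-column loops) kept free of any package internals.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                  collapse = "")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Affine-gap pairwise alignment score by explicit Gotoh DP.  A gap of
# length k costs gap_open + k * gap_ext.
oracle_align_score <- function(a, b, type = c("global", "local"),
                               mat = blosum62, gap_open = 11, gap_ext = 1) {
  type <- match.arg(type)
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes x)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes y)
  M[1, 1] <- 0
  if (type == "global") {
    for (i in 2:(n + 1)) Ix[i, 1] <- -(gap_open + (i - 1) * gap_ext)
    for (j in 2:(m + 1)) Iy[1, j] <- -(gap_open + (j - 1) * gap_ext)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  best_local <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[x[i - 1], y[j - 1]]
      diag_best <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      M[i, j] <- s + if (type == "local") max(0, diag_best) else diag_best
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                      Ix[i - 1, j] - gap_ext,
                      Iy[i - 1, j] - gap_open - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                      Iy[i, j - 1] - gap_ext,
                      Ix[i, j - 1] - gap_open - gap_ext)
      if (type == "local") best_local <- max(best_local, M[i, j])
    }
  }
  if (type == "local") best_local
  else max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Clustal groups restated independently for the metric oracle.
ORACLE_STRONG <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF",
                   "HY", "FYW")
ORACLE_WEAK <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SNDEQK",
                 "NDEQHK", "NEQHRK", "FVLIM", "HFY")

.in_any_group <- function(p, q, groups) {
  for (g in groups) {
    gs <- strsplit(g, "")[[1]]
    if (p %in% gs && q %in% gs) return(TRUE)
  }
  FALSE
}

# Column-by-column identity/similarity with the longest-sequence
# denominator and optional region-of-overlap restriction.
oracle_identity <- function(row_a, row_b, partial_mode = FALSE) {
  a <- strsplit(row_a, "")[[1]]; b <- strsplit(row_b, "")[[1]]
  cols <- seq_along(a)
  if (partial_mode) {
    both <- cols[a != "-" & b != "-"]
    stopifnot(length(both) > 0)
    cols <- seq(min(both), max(both))
  }
  n_id <- 0; n_sim <- 0; res_a <- 0; res_b <- 0
  for (k in cols) {
    p <- a[k]; q <- b[k]
    if (p != "-") res_a <- res_a + 1
    if (q != "-") res_b <- res_b + 1
    if (p == "-" || q == "-" || p == "X" || q == "X") next
    if (p == q) n_id <- n_id + 1
    else if (.in_any_group(p, q, ORACLE_STRONG) ||
             .in_any_group(p, q, ORACLE_WEAK)) n_sim <- n_sim + 1
  }
  denom <- max(res_a, res_b)
  list(pct_identity = 100 * n_id / denom,
       pct_similarity = 100 * (n_id + n_sim) / denom)
}

# Random plausible alignment rows: aligned residue pairs with gap columns
# sprinkled in (never gap-on-gap).
rand_alignment <- function(len = 40) {
  a <- character(len); b <- character(len)
  for (k in seq_len(len)) {
    r <- runif(1)
    if (r < 0.12) { a[k] <- "-"; b[k] <- sample(AA20, 1) }
    else if (r < 0.24) { a[k] <- sample(AA20, 1); b[k] <- "-" }
    else if (r < 0.5) { a[k] <- b[k] <- sample(AA20, 1) }
    else { a[k] <- sample(AA20, 1); b[k] <- sample(AA20, 1) }
  }
  list(row_a = paste(a, collapse = ""), row_b = paste(b, collapse = ""))
}

# Exhaustive sliding-window motif scan.
oracle_motif_scan <- function(aa_seq, pattern, max_mismatches = 0) {
  aa <- strsplit(toupper(aa_seq), "")[[1]]
  pat <- strsplit(toupper(pattern), "")[[1]]
  w <- length(pat)
  hits <- integer(0)
  if (length(aa) >= w) {
    for (s in seq_len(length(aa) - w + 1)) {
      mm <- 0
      for (k in seq_len(w)) {
        if (pat[k] != "X" && aa[s + k - 1] != pat[k]) mm <- mm + 1
      }
      if (mm <= max_mismatches) hits <- c(hits, s)
    }
  }
  hits
}
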