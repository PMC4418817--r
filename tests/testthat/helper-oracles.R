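# Independent brute-force oracles used only by the tests. They share the
# package's mathematical contracts (recurrences, tie-breaks) but none of
# its code paths.

blosum62_oracle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Full-matrix affine-gap Smith-Waterman with explicit traceback.
# States: M (pair), X (gap in subject), Y (gap in query); a gap of
# length L costs gap_open + L * gap_ext; alignments start and end in M.
# Best cell: max M, ties to smallest (row, col); traceback prefers
# M > X > Y > fresh start at equal score.
oracle_sw <- function(a, b, S = blosum62_oracle(), gap_open = 11,
                      gap_ext = 1) {
  qa <- match(strsplit(a, "")[[1]], rownames(S))
  sa <- match(strsplit(b, "")[[1]], rownames(S))
  n <- length(qa); m <- length(sa)
  oe <- gap_open + gap_ext
  M <- matrix(-Inf, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- S[qa[i], sa[j]] + max(0, M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - oe, X[i, j + 1] - gap_ext,
                             Y[i, j + 1] - oe)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - oe, X[i + 1, j] - oe,
                             Y[i + 1, j] - gap_ext)
    }
  }
  best <- 0; bi <- 0; bj <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]; bi <- i; bj <- j
      }
    }
  }
  if (best <= 0) {
    return(list(score = 0, identity = 0, coverage = 0, nmatch = 0,
                ncol = 0, qstart = 0, qend = 0, sstart = 0, send = 0))
  }
  feq <- function(x, y) is.finite(x) && abs(x - y) < 1e-9
  i <- bi; j <- bj; st <- "M"; ncols <- 0L; nmatch <- 0L
  repeat {
    if (st == "M") {
      ncols <- ncols + 1L
      if (qa[i] == sa[j]) nmatch <- nmatch + 1L
      need <- M[i + 1, j + 1] - S[qa[i], sa[j]]
      pm <- M[i, j]; px <- X[i, j]; py <- Y[i, j]
      i <- i - 1; j <- j - 1
      if (feq(pm, need)) st <- "M"
      else if (feq(px, need)) st <- "X"
      else if (feq(py, need)) st <- "Y"
      else break
    } else if (st == "X") {
      ncols <- ncols + 1L
      v <- X[i + 1, j + 1]
      pm <- M[i, j + 1]; px <- X[i, j + 1]
      i <- i - 1
      if (feq(pm - oe, v)) st <- "M"
      else if (feq(px - gap_ext, v)) st <- "X"
      else st <- "Y"
    } else {
      ncols <- ncols + 1L
      v <- Y[i + 1, j + 1]
      pm <- M[i + 1, j]; px <- X[i + 1, j]
      j <- j - 1
      if (feq(pm - oe, v)) st <- "M"
      else if (feq(px - oe, v)) st <- "X"
      else st <- "Y"
    }
  }
  list(score = best, identity = nmatch / ncols,
       coverage = (bj - j) / m,  # send - sstart + 1 = bj - (j+1) + 1
       nmatch = nmatch, ncol = ncols,
       qstart = i + 1, qend = bi, sstart = j + 1, send = bj)
}

# Exhaustive per-placement, per-position profile scoring.
oracle_profile_score <- function(profile, seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  if (n == 0) return(list(score = 0, start = 0L))
  L <- profile$length
  lo <- profile$log_odds
  one <- function(off) {
    s <- 0
    for (p in seq_len(min(L, n - off + 1))) {
      b <- ch[off + p - 1]
      if (b %in% colnames(lo)) s <- s + lo[p, b]
    }
    s
  }
  offs <- seq_len(max(1L, n - L + 1L))
  sc <- vapply(offs, one, numeric(1))
  list(score = max(sc), start = offs[which.max(sc)])
}

oracle_revcomp <- function(x) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
}

random_aa <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

# Global (full-length) identity between two unaligned same-length
# proteins, by exhaustive Needleman-Wunsch on match/mismatch counts is
# overkill for the generator's substitution-only mutants; position-wise
# comparison is the exact answer there.
oracle_global_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}
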