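test_that("profile building matches closed forms and a count oracle", {
  # two identical ungapped sequences, pseudocount 0: consensus base gets
  # log2(1/background), absent bases are floored (finite, very negative)
  p0 <- build_profile(c("ACGT", "ACGT"), pseudocount = 0)
  expect_equal(unname(p0$log_odds[1, "A"]), 2)  # log2(1 / 0.25)
  expect_true(all(is.finite(p0$log_odds)))
  expect_true(all(p0$log_odds[1, c("C", "G", "T")] < -10))

  # uniform column frequencies: 0 bits everywhere in that column
  pu <- build_profile(c("A", "C", "G", "T"), pseudocount = 0)
  expect_equal(unname(pu$log_odds[1, ]), rep(0, 4), tolerance = 1e-12)

  # 4-sequence toy alignment, pseudocount 1: (counts + 1) / (n + 4)
  aln <- c("ACG", "ACG", "ATG", "CTG")
  p1 <- build_profile(aln, pseudocount = 1)
  counts_col1 <- c(A = 3, C = 1, G = 0, T = 0)
  expect_equal(unname(p1$log_odds[1, ]),
               unname(log2(((counts_col1 + 1) / 8) / 0.25)),
               tolerance = 1e-12)

  # gap-majority columns are dropped
  pg <- build_profile(c("A-G", "A-G", "ACG", "A--"))
  expect_equal(pg$length, 2)

  expect_error(build_profile(character(0)), "at least 2")
})

test_that("sequence scoring equals the exhaustive placement oracle", {
  prof <- build_profile(fmn_training_alignment(8, seed = 2), name = "toy")
  small <- build_profile(c("ACGTA", "ACGTA", "ACCTA", "TCGTA"))
  set.seed(77)
  for (k in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), sample(3:16, 1),
                        replace = TRUE, prob = c(rep(0.24, 4), 0.04)),
                 collapse = "")
    got <- score_sequence(small, seq)
    want <- oracle_profile_score(small, seq)
    expect_equal(got$score, want$score, info = seq)
    expect_equal(got$start, want$start, info = seq)
  }
  # consensus scores the per-position maxima sum
  expect_equal(score_sequence(prof, prof$consensus)$score, prof$max_score)
  # empty sequence
  expect_equal(score_sequence(prof, ""), list(score = 0, start = 0L))
  # shorter than the profile: single truncated placement
  half <- substr(small$consensus, 1, 3)
  expect_equal(score_sequence(small, half)$score,
               sum(small$log_odds[cbind(1:3, match(strsplit(half, "")[[1]],
                                                   c("A", "C", "G", "T")))]))
  # ambiguity codes contribute 0 bits
  expect_equal(score_sequence(small, "NNNNN")$score, 0)
})

test_that("half-profile scores add up at the consensus placement", {
  prof <- fmn_profile()
  cons <- prof$consensus
  sub_profile <- function(rows) {
    lo <- prof$log_odds[rows, , drop = FALSE]
    structure(list(log_odds = lo, background = prof$background,
                   length = nrow(lo), name = "half",
                   max_score = sum(apply(lo, 1, max)),
                   consensus = paste(c("A", "C", "G", "T")[
                     apply(lo, 1, which.max)], collapse = "")),
              class = "riboswitch_profile")
  }
  s_full <- score_sequence(prof, cons)$score
  s1 <- score_sequence(sub_profile(1:60), substr(cons, 1, 60))$score
  s2 <- score_sequence(sub_profile(61:120), substr(cons, 61, 120))$score
  expect_equal(s1 + s2, s_full, tolerance = 1e-9)
})

test_that("sampled motifs land within 2 bits of their target", {
  prof <- fmn_profile()
  for (target in c(51.34, 56.34, 70, 0)) {
    m <- sample_motif(prof, target, seed = round(target * 10) + 1)
    expect_equal(nchar(m), prof$length)
    sc <- oracle_profile_score(prof, m)$score
    expect_lt(abs(sc - target), 2, label = sprintf("score at target %.2f", target))
  }
  # consensus is returned for the maximum target
  expect_equal(sample_motif(prof, prof$max_score, seed = 1), prof$consensus)
  expect_error(sample_motif(prof, prof$max_score + 5), "exceeds")
})

test_that("random background DNA scores far below the operating cutoff", {
  prof <- fmn_profile()
  set.seed(1234)
  n_below <- 0L
  for (k in 1:1000) {
    seq <- paste(sample(c("A", "C", "G", "T"), prof$length, replace = TRUE),
                 collapse = "")
    if (score_sequence(prof, seq)$score <= 51.34 - 10) n_below <- n_below + 1L
  }
  expect_gte(n_below / 1000, 0.99)
})

test_that("the cutoff is the minimum over the anchor set", {
  expect_identical(calibrate_cutoff(c(53.1, 51.34, 60.2)), 51.34)
  expect_identical(calibrate_cutoff(40.0), 40.0)
  set.seed(8)
  anchors <- runif(100, 51, 90)
  expect_identical(calibrate_cutoff(anchors), min(anchors))
  expect_error(calibrate_cutoff(numeric(0)), "non-empty")
})

test_that("scanning is strand symmetric and monotone in the cutoff", {
  prof <- fmn_profile()
  motif <- sample_motif(prof, 60, seed = 5)
  spacer <- strrep("A", 30)
  gene <- strrep("G", 90)
  pad <- strrep("T", 200)
  fwd <- paste0(pad, motif, spacer, gene, pad)
  tu_fwd <- data.frame(tu_id = "t", replicon = "chr", strand = "+",
                       start = 201 + 120 + 30, end = 200 + 120 + 30 + 90,
                       n_genes = 1, stringsAsFactors = FALSE)
  # mirror genome: reverse complement, gene on the minus strand
  rc <- oracle_revcomp(fwd)
  L <- nchar(fwd)
  tu_rev <- data.frame(tu_id = "t", replicon = "chr", strand = "-",
                       start = L - tu_fwd$end + 1, end = L - tu_fwd$start + 1,
                       n_genes = 1, stringsAsFactors = FALSE)
  h_fwd <- call_riboswitches(c(chr = fwd), tu_fwd, prof)
  h_rev <- call_riboswitches(c(chr = rc), tu_rev, prof)
  expect_equal(nrow(h_fwd), 1)
  expect_equal(nrow(h_rev), 1)
  expect_equal(h_fwd$score, h_rev$score)
  # hit coordinates mirror each other
  expect_equal(h_rev$start, L - h_fwd$end + 1)
  expect_equal(h_rev$end, L - h_fwd$start + 1)
  # raising the cutoff can only lose hits
  n_at <- function(cut) nrow(call_riboswitches(c(chr = fwd), tu_fwd, prof,
                                               cutoff = cut))
  counts <- vapply(c(10, 51.34, 59, 61, 100), n_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(n_at(61), 0)  # motif at ~60 bits suppressed above it
})

test_that("profiles round-trip through their TSV serialisation", {
  prof <- build_profile(fmn_training_alignment(6, seed = 4),
                        background = c(0.2, 0.3, 0.3, 0.2), name = "rt")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, f)
  back <- read_profile(f)
  expect_equal(back$log_odds, prof$log_odds, tolerance = 1e-8)
  expect_equal(back$background, prof$background)
  expect_equal(back$name, prof$name)
})
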