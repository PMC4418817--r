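#' Build a position-wise log-odds profile from an alignment
#'
#' Turns a training alignment into a `riboswitch_profile`: per-position
#' base frequencies with additive pseudocounts, expressed as log2 odds
#' (bits) against a background composition. Columns in which more than
#' half the sequences are gapped are dropped, so the profile models the
#' well-occupied core of the motif. This ungapped profile preserves the
#' bit-score-plus-cutoff contract of a covariance-model search without
#' modelling secondary structure.
#'
#' @param training Aligned nucleotide sequences of equal length
#'   (character vector or `DNAStringSet`); gaps as `-` or `.`.
#' @param background Background base probabilities over A,C,G,T
#'   (default uniform).
#' @param pseudocount Additive pseudocount per base (default 1, Laplace).
#' @param max_gap_frac Columns with gap fraction strictly above this are
#'   dropped (default 0.5).
#' @param name Profile name.
#' @return A `riboswitch_profile`: list with `log_odds` (L x 4 matrix in
#'   bits, columns A,C,G,T), `background`, `length`, `name`,
#'   `max_score` (sum of per-position maxima) and `consensus`.
#' @export
build_profile <- function(training, background = rep(0.25, 4),
                          pseudocount = 1, max_gap_frac = 0.5,
                          name = "profile") {
  training <- as.character(training)
  if (length(training) < 2) stop("need at least 2 aligned training sequences")
  if (length(unique(nchar(training))) != 1)
    stop("training sequences must have equal aligned length")
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-6)
  m <- do.call(rbind, strsplit(toupper(training), ""))
  m[m == "U"] <- "T"
  m[m == "."] <- "-"
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= max_gap_frac)
  if (length(keep) == 0) stop("no columns survive the gap filter")
  lo <- matrix(NA_real_, length(keep), 4,
               dimnames = list(NULL, DNA_BASES))
  for (k in seq_along(keep)) {
    col <- m[, keep[k]]
    col <- col[col %in% DNA_BASES]
    cnt <- vapply(DNA_BASES, function(b) sum(col == b), numeric(1))
    freq <- (cnt + pseudocount) / (length(col) + 4 * pseudocount)
    freq <- pmax(freq, 1e-9)  # floor guards log2(0) when pseudocount = 0
    lo[k, ] <- log2(freq / background)
  }
  new_profile(lo, background, name)
}

new_profile <- function(log_odds, background = rep(0.25, 4),
                        name = "profile") {
  stopifnot(ncol(log_odds) == 4)
  colnames(log_odds) <- DNA_BASES
  consensus <- paste(DNA_BASES[apply(log_odds, 1, which.max)], collapse = "")
  structure(list(log_odds = log_odds, background = background,
                 length = nrow(log_odds), name = name,
                 max_score = sum(apply(log_odds, 1, max)),
                 consensus = consensus),
            class = "riboswitch_profile")
}

#' @export
print.riboswitch_profile <- function(x, ...) {
  cat(sprintf("riboswitch profile '%s': %d positions, max score %.2f bits\n",
              x$name, x$length, x$max_score))
  invisible(x)
}

#' Packaged FMN riboswitch profile ("fmn-lite")
#'
#' A deterministic, synthetic stand-in for the FMN riboswitch covariance
#' model: a 120-position log-odds profile over a fixed consensus with
#' 85% per-position consensus probability and uniform background. Its
#' maximum attainable score (~212 bits) leaves generous headroom above
#' the 51.34-bit operating cutoff, so cutoff-straddling instances can be
#' sampled at any realistic level. It is not derived from Rfam data.
#'
#' @param match_prob Per-position probability of the consensus base.
#' @return A `riboswitch_profile`.
#' @export
fmn_profile <- function(match_prob = 0.85) {
  consensus <- fmn_consensus()
  bases <- strsplit(consensus, "")[[1]]
  lo <- matrix(log2((1 - match_prob) / 3 / 0.25), length(bases), 4,
               dimnames = list(NULL, DNA_BASES))
  lo[cbind(seq_along(bases), match(bases, DNA_BASES))] <- log2(match_prob / 0.25)
  new_profile(lo, rep(0.25, 4), "fmn-lite")
}

fmn_consensus <- function() {
  with_seed(50L, random_dna(120))
}

#' Training-alignment emulator for the packaged profile
#'
#' Samples aligned sequences from the `fmn-lite` position distributions;
#' useful as a worked input to [build_profile()].
#'
#' @param n Number of sequences.
#' @param seed RNG seed.
#' @param match_prob Per-position consensus probability.
#' @return Character vector of aligned sequences.
#' @export
fmn_training_alignment <- function(n = 20, seed = 1, match_prob = 0.85) {
  profile <- fmn_profile(match_prob)
  bases <- strsplit(profile$consensus, "")[[1]]
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(vapply(bases, function(b) {
        if (runif(1) < match_prob) b
        else sample(setdiff(DNA_BASES, b), 1)
      }, character(1)), collapse = "")
    }, character(1))
  })
}

#' Score a sequence against a riboswitch profile
#'
#' Best ungapped placement of the profile within the sequence: at each
#' offset the per-position bit contributions are summed; the maximum over
#' offsets is returned, ties resolved to the smallest offset. Non-ACGT
#' positions contribute 0 bits (the background expectation). A sequence
#' shorter than the profile is scored over the single truncated placement
#' with unmatched profile positions contributing 0.
#'
#' @param profile A `riboswitch_profile`.
#' @param seq Nucleotide sequence (character).
#' @return List with `score` (bits) and `start` (1-based offset of the
#'   best placement; 0 for an empty sequence).
#' @export
score_sequence <- function(profile, seq) {
  stopifnot(inherits(profile, "riboswitch_profile"))
  seq <- chartr("u", "T", chartr("U", "T", toupper(seq)))
  n <- nchar(seq)
  if (n == 0) return(list(score = 0, start = 0L))
  idx <- match(strsplit(seq, "")[[1]], DNA_BASES)  # NA for ambiguity codes
  L <- profile$length
  lo <- profile$log_odds
  contrib_at <- function(p, i) {  # profile position p against seq position i
    v <- lo[cbind(p, idx[i])]
    v[is.na(v)] <- 0
    v
  }
  if (n < L) {
    return(list(score = sum(contrib_at(seq_len(n), seq_len(n))), start = 1L))
  }
  n_off <- n - L + 1L
  scores <- vapply(seq_len(n_off), function(o) {
    sum(contrib_at(seq_len(L), o:(o + L - 1L)))
  }, numeric(1))
  best <- which.max(scores)  # first maximum = smallest offset
  list(score = scores[[best]], start = as.integer(best))
}

#' Sample a motif instance at a target bit score
#'
#' Starts from the profile consensus (the maximum-scoring string) and
#' degrades randomly chosen positions, greedily choosing base changes
#' that move the score toward `target_bits`, followed by local refinement
#' until the score is within tolerance. Used by the synthetic-data
#' generator to plant riboswitches at controlled score levels, including
#' instances straddling the 51.34-bit cutoff.
#'
#' @param profile A `riboswitch_profile`.
#' @param target_bits Desired score; must not exceed the profile maximum.
#' @param seed RNG seed.
#' @param tol Acceptable deviation in bits (default 0.5; the generator
#'   contract is +/- 2).
#' @return A nucleotide sequence of the profile's length.
#' @export
sample_motif <- function(profile, target_bits, seed = 1, tol = 0.5) {
  stopifnot(inherits(profile, "riboswitch_profile"))
  if (target_bits > profile$max_score + 1e-9)
    stop(sprintf("target %.2f bits exceeds profile maximum %.2f bits",
                 target_bits, profile$max_score))
  lo <- profile$log_odds
  L <- profile$length
  with_seed(seed, {
    cur <- apply(lo, 1, which.max)  # consensus, as column indices
    score <- sum(lo[cbind(seq_len(L), cur)])
    for (p in sample.int(L)) {  # greedy degradation pass
      resid <- score - target_bits
      if (resid <= tol) break
      drops <- lo[p, cur[p]] - lo[p, ]
      drops[drops > resid] <- -Inf  # never overshoot below target
      if (all(!is.finite(drops)) || max(drops) <= 0) next
      b <- which.max(drops)
      score <- score - drops[b]
      cur[p] <- b
    }
    repeat {  # refinement: single-base moves toward the target
      if (abs(score - target_bits) <= tol) break
      improved <- FALSE
      for (p in sample.int(L)) {
        deltas <- lo[p, ] - lo[p, cur[p]]
        gain <- abs(score + deltas - target_bits)
        b <- which.min(gain)
        if (gain[b] < abs(score - target_bits) - 1e-12) {
          score <- score + deltas[b]
          cur[p] <- b
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    paste(DNA_BASES[cur], collapse = "")
  })
}

#' Scan transcriptional-unit upstream regions for riboswitch hits
#'
#' Extracts the strand-aware upstream window of every TU, scores it with
#' the profile, and reports at most one hit per TU (the best placement),
#' suppressing scores below the cutoff. Hit coordinates are mapped back
#' to replicon coordinates (1-based inclusive), strand-aware.
#'
#' @param replicons Named character vector of replicon sequences for one
#'   genome, or a named list of such vectors for several genomes (then
#'   `tus` must carry a `genome` column).
#' @param tus TU table from [predict_tus()].
#' @param profile A `riboswitch_profile`.
#' @param cutoff Bit-score cutoff; hits with `score < cutoff` are
#'   suppressed. Default 51.34, the operating point calibrated as the
#'   lowest score observed on riboswitches of riboflavin biosynthetic
#'   operons (see [calibrate_cutoff()]).
#' @param window Upstream window length in nt (default 350).
#' @param circular Treat replicons as circular (default FALSE).
#' @param keep_all Report sub-cutoff scores too (default FALSE).
#' @return Data frame of hits: `genome`, `tu_id`, `replicon`, `start`,
#'   `end`, `strand`, `score`, `offset`.
#' @export
call_riboswitches <- function(replicons, tus, profile, cutoff = 51.34,
                              window = 350, circular = FALSE,
                              keep_all = FALSE) {
  if (!is.list(replicons)) {
    replicons <- list(genome = replicons)
    if (is.null(tus$genome)) tus$genome <- "genome"
  }
  out <- list()
  for (i in seq_len(nrow(tus))) {
    tu <- tus[i, ]
    g <- if (!is.null(tu$genome)) tu$genome else names(replicons)[[1]]
    seqs <- replicons[[g]]
    repseq <- seqs[[tu$replicon]]
    up <- upstream_region(tu, repseq, window = window, circular = circular)
    if (nchar(up) == 0) next
    sc <- score_sequence(profile, up)
    if (!keep_all && sc$score < cutoff) next
    coords <- hit_coords(tu, nchar(repseq), sc$start, profile$length,
                         nchar(up), window, circular)
    out[[length(out) + 1L]] <- data.frame(
      genome = g, tu_id = tu$tu_id, replicon = tu$replicon,
      start = coords[1], end = coords[2], strand = tu$strand,
      score = sc$score, offset = sc$start, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(genome = character(0), tu_id = character(0),
                      replicon = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), offset = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Map a placement offset inside the (possibly truncated) upstream window
# back to replicon coordinates, 1-based inclusive.
hit_coords <- function(tu, replicon_len, offset, profile_len, win_len,
                       window, circular) {
  hit_len <- min(profile_len, win_len - offset + 1L)
  if (tu$strand == "+") {
    wstart <- tu$start - win_len  # window ends immediately before the TU
    s <- wstart + offset - 1L
    e <- s + hit_len - 1L
  } else {
    wend <- tu$end + win_len  # scanned sequence is the revcomp, pos 1 = wend
    e <- wend - offset + 1L
    s <- e - hit_len + 1L
  }
  if (circular) {
    s <- ((s - 1L) %% replicon_len) + 1L
    e <- ((e - 1L) %% replicon_len) + 1L
  }
  c(s, e)
}

#' Calibrate the bit cutoff from anchor riboswitches
#'
#' The operating cutoff is defined as the lowest score observed among a
#' trusted anchor set — riboswitches sitting on known riboflavin
#' biosynthetic operons. With the published anchors this minimum is
#' 51.34 bits.
#'
#' @param anchor_scores Numeric vector of anchor bit scores.
#' @return The minimum anchor score.
#' @examples
#' calibrate_cutoff(c(53.1, 51.34, 60.2))
#' @export
calibrate_cutoff <- function(anchor_scores) {
  anchor_scores <- as.numeric(anchor_scores)
  if (length(anchor_scores) == 0 || any(is.na(anchor_scores)))
    stop("anchor set must be non-empty and free of NA")
  min(anchor_scores)
}

#' Serialize a riboswitch profile to TSV
#'
#' Header lines (`# name=`, `# background=`) followed by a
#' position-by-base matrix of log-odds in bits.
#'
#' @param profile A `riboswitch_profile`.
#' @param path Output file.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# name=%s", profile$name),
               sprintf("# background=%s",
                       paste(format(profile$background, digits = 10),
                             collapse = ","))), con)
  df <- data.frame(pos = seq_len(profile$length), profile$log_odds,
                   check.names = FALSE)
  write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a riboswitch profile from TSV
#' @param path File written by [write_profile()].
#' @return A `riboswitch_profile`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  name <- sub("^# name=", "", grep("^# name=", hdr, value = TRUE))
  bg <- as.numeric(strsplit(sub("^# background=", "",
                                grep("^# background=", hdr, value = TRUE)),
                            ",")[[1]])
  tab <- read.table(text = lines[!grepl("^# ", lines)], header = TRUE,
                    sep = "\t", check.names = FALSE)
  new_profile(as.matrix(tab[, DNA_BASES]), bg, name)
}
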