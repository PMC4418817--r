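#' Predict transcriptional units from gene order and intergenic distance
#'
#' Partitions the genes of each replicon into transcriptional units
#' (monocistrons and operons). Two adjacent same-strand genes share a TU
#' iff their intergenic distance is at most `d_max` *or* their
#' functional-linkage score is at least `link_min`; a strand change
#' always breaks a TU. Overlapping same-strand genes have negative
#' intergenic distance and therefore merge. Gene lists inside a TU are
#' reported in transcription order (right to left on the minus strand).
#'
#' @param genes Data frame with columns `gene_id`, `replicon`, `start`,
#'   `end` (1-based inclusive), `strand` (`+`/`-`), optional `family`.
#'   Must be sorted by `start` within each replicon.
#' @param linkage Optional functional-linkage table: data frame with
#'   columns `gene1`, `gene2`, `score` in \[0,1\] (symmetric; STRING-like).
#'   Pairs naming unknown genes are ignored with a warning.
#' @param d_max Maximum intergenic distance (bp) for a same-TU merge
#'   (default 50).
#' @param link_min Minimum linkage score for a distance-independent merge
#'   (default 0.8).
#' @return Data frame of TUs: `tu_id`, `replicon`, `strand`, `start`,
#'   `end`, `n_genes`, and list-column `gene_ids` (transcription order).
#' @export
predict_tus <- function(genes, linkage = NULL, d_max = 50, link_min = 0.8) {
  stopifnot(all(c("gene_id", "replicon", "start", "end", "strand") %in%
                  names(genes)))
  if (any(genes$start > genes$end)) stop("gene start must not exceed end")
  link <- linkage_lookup(linkage, genes$gene_id)
  out <- list()
  for (rep_id in unique(genes$replicon)) {
    g <- genes[genes$replicon == rep_id, , drop = FALSE]
    if (is.unsorted(g$start)) stop(sprintf(
      "genes on replicon '%s' are not sorted by start", rep_id))
    n <- nrow(g)
    brk <- logical(n - 1)
    for (i in seq_len(max(0, n - 1))) {
      gap <- g$start[i + 1] - g$end[i] - 1L
      same <- g$strand[i + 1] == g$strand[i]
      merged <- same && (gap <= d_max ||
                           link(g$gene_id[i], g$gene_id[i + 1]) >= link_min)
      brk[i] <- !merged
    }
    tu_idx <- cumsum(c(1L, as.integer(brk)))
    for (t in unique(tu_idx)) {
      memb <- g[tu_idx == t, , drop = FALSE]
      ids <- memb$gene_id
      if (memb$strand[1] == "-") ids <- rev(ids)
      out[[length(out) + 1L]] <- data.frame(
        tu_id = sprintf("%s_TU%03d", rep_id, t),
        replicon = rep_id, strand = memb$strand[1],
        start = min(memb$start), end = max(memb$end),
        n_genes = nrow(memb), stringsAsFactors = FALSE)
      out[[length(out)]]$gene_ids <- I(list(ids))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

linkage_lookup <- function(linkage, known_ids) {
  if (is.null(linkage) || nrow(linkage) == 0)
    return(function(a, b) -Inf)
  stopifnot(all(c("gene1", "gene2", "score") %in% names(linkage)))
  if (any(linkage$score < 0 | linkage$score > 1))
    stop("linkage scores must lie in [0, 1]")
  unknown <- setdiff(unique(c(linkage$gene1, linkage$gene2)), known_ids)
  if (length(unknown) > 0) {
    warning(sprintf("linkage table names %d unknown gene id(s); ignored",
                    length(unknown)))
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  tab <- setNames(linkage$score, key(linkage$gene1, linkage$gene2))
  function(a, b) {
    v <- tab[key(a, b)]
    if (is.na(v)) -Inf else v
  }
}

#' Extract the upstream region of a transcriptional unit
#'
#' Returns up to `window` nt ending immediately before the TU's first
#' gene in transcription order: the region 5' of `start` for a plus
#' strand TU, and the reverse complement of the region 3' of `end` for a
#' minus strand TU. Truncated at the replicon edge for linear replicons
#' (an empty string for a TU at position 1 is not an error); wrapped
#' around the origin for circular ones.
#'
#' @param tu One TU row (from [predict_tus()]) or any list with
#'   `start`, `end`, `strand`.
#' @param replicon_seq Replicon sequence (character).
#' @param window Window length in nt (default 350).
#' @param circular Wrap around the origin (default FALSE).
#' @return Nucleotide sequence, 5'->3' relative to transcription.
#' @export
upstream_region <- function(tu, replicon_seq, window = 350,
                            circular = FALSE) {
  stopifnot(window > 0)
  L <- nchar(replicon_seq)
  if (tu$strand == "+") {
    e <- tu$start - 1L
    s <- tu$start - window
    if (e < 1L) return("")
    if (s >= 1L || !circular) {
      substr(replicon_seq, max(1L, s), e)
    } else {
      paste0(substr(replicon_seq, L + s, L), substr(replicon_seq, 1L, e))
    }
  } else {
    s <- tu$end + 1L
    e <- tu$end + window
    if (s > L) {
      if (!circular) return("")
      # entire window lies past the origin
    }
    seq <- if (e <= L || !circular) {
      if (s > L) "" else substr(replicon_seq, s, min(L, e))
    } else {
      paste0(substr(replicon_seq, s, L), substr(replicon_seq, 1L, e - L))
    }
    if (nchar(seq) == 0) return("")
    revcomp(seq)
  }
}

#' Write predicted TUs to TSV
#'
#' One row per TU; member genes joined by commas in transcription order.
#'
#' @param tus TU table from [predict_tus()].
#' @param path Output file.
#' @export
write_tus <- function(tus, path) {
  flat <- tus
  flat$gene_ids <- vapply(tus$gene_ids, paste, character(1), collapse = ",")
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TU table written by [write_tus()]
#' @param path TSV file.
#' @return TU table with list-column `gene_ids`.
#' @export
read_tus <- function(path) {
  flat <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  flat$gene_ids <- I(strsplit(flat$gene_ids, ","))
  flat
}

#' Read gene annotations from GFF3
#'
#' Imports features of type `gene` with their `ID` and `family`
#' attributes into the package's gene table (1-based inclusive
#' coordinates).
#'
#' @param path GFF3 file.
#' @return Gene table: `gene_id`, `replicon`, `start`, `end`, `strand`,
#'   `family`.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  fam <- if ("family" %in% names(S4Vectors::mcols(gr))) gr$family
         else rep(NA_character_, length(gr))
  df <- data.frame(
    gene_id = gr$ID,
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    family = as.character(fam), stringsAsFactors = FALSE)
  df[order(df$replicon, df$start), , drop = FALSE]
}

#' Write gene annotations to GFF3
#'
#' @param genes Gene table (see [read_genes_gff3()]).
#' @param path Output GFF3 file.
#' @param source Value of the GFF3 source column.
#' @export
write_genes_gff3 <- function(genes, path, source = "riboscout") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$source <- source
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  if (!is.null(genes$family)) gr$family <- genes$family
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
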