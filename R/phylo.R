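#' Mask gap-heavy alignment columns
#'
#' Removes the columns in which the gap fraction is `max_gap_frac` or
#' more (default: columns that are 75% or more gaps are removed, so a
#' 4-taxon column with 3 gaps goes, one with 2 stays).
#'
#' @param alignment Named character vector of equal-length aligned rows
#'   (or an `AAStringSet`); gaps as `-` or `.`.
#' @param max_gap_frac Removal boundary (default 0.75); a column is kept
#'   iff its gap fraction is strictly below this.
#' @return A `masked_alignment`: list with `alignment` (masked rows),
#'   `kept` (1-based indices of retained columns), `taxa`.
#' @export
mask_columns <- function(alignment, max_gap_frac = 0.75) {
  alignment <- as_named_rows(alignment)
  if (length(alignment) == 0) stop("alignment is empty")
  if (length(unique(nchar(alignment))) != 1)
    stop("alignment rows must have equal length")
  m <- do.call(rbind, strsplit(alignment, ""))
  gap_frac <- colMeans(m == "-" | m == ".")
  kept <- which(gap_frac < max_gap_frac)
  masked <- apply(m[, kept, drop = FALSE], 1, paste, collapse = "")
  structure(list(alignment = setNames(masked, names(alignment)),
                 kept = kept, taxa = names(alignment)),
            class = "masked_alignment")
}

# as.character() drops names on plain character vectors; keep them.
as_named_rows <- function(x) {
  nm <- names(x)
  x <- as.character(x)
  if (!is.null(nm)) names(x) <- nm
  x
}

#' @export
print.masked_alignment <- function(x, ...) {
  cat(sprintf("masked alignment: %d taxa, %d columns kept\n",
              length(x$alignment), length(x$kept)))
  invisible(x)
}

#' Kimura-corrected protein distance between two aligned rows
#'
#' From the mismatch fraction p over mutually ungapped columns,
#' d = -ln(1 - p - 0.2 p^2), a closed-form correction for multiple
#' substitutions. Saturated pairs (argument of the log non-positive)
#' are capped at `cap` and flagged via the `"capped"` attribute.
#'
#' @param a,b Aligned rows of equal length.
#' @param cap Distance assigned at saturation (default 5).
#' @return Numeric distance (>= 0).
#' @export
protein_distance <- function(a, b, cap = 5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  ok <- !(ca %in% c("-", ".")) & !(cb %in% c("-", "."))
  if (!any(ok)) stop("no mutually ungapped columns to compare")
  p <- mean(ca[ok] != cb[ok])
  arg <- 1 - p - 0.2 * p^2
  if (arg <= 0) return(structure(cap, capped = TRUE))
  -log(arg)
}

#' Pairwise distance matrix from a (masked) alignment
#'
#' @param alignment Named character vector of aligned rows, or a
#'   `masked_alignment`.
#' @param cap Saturation cap passed to [protein_distance()].
#' @return Symmetric matrix with zero diagonal, taxa as dimnames.
#' @export
alignment_distances <- function(alignment, cap = 5) {
  if (inherits(alignment, "masked_alignment"))
    alignment <- alignment$alignment
  alignment <- as_named_rows(alignment)
  taxa <- names(alignment)
  n <- length(alignment)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- protein_distance(alignment[[i]], alignment[[j]], cap = cap)
      D[i, j] <- D[j, i] <- as.numeric(d)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (exact on additive matrices), with
#' negative branch lengths clamped to zero (flagged via the
#' `"clamped_edges"` attribute and a warning).
#'
#' @param D Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An `ape` `phylo` tree (unrooted).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("neighbor joining requires at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8)
    warning("distance matrix is not symmetric; using (D + t(D))/2")
  tree <- ape::nj(stats::as.dist((D + t(D)) / 2))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    warning(sprintf("%d negative NJ branch length(s) clamped to 0", sum(neg)))
    tree$edge.length[neg] <- 0
  }
  attr(tree, "clamped_edges") <- sum(neg)
  tree
}

#' Bootstrap supports for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the
#' distance+NJ tree per replicate, and maps bipartition frequencies
#' (percent) onto the full-data tree's internal nodes. Deterministic
#' under a fixed seed.
#'
#' @param alignment Named character vector of aligned rows (or a
#'   `masked_alignment`).
#' @param n_reps Number of replicates (>= 1).
#' @param seed RNG seed.
#' @param cap Saturation cap for distances.
#' @return The full-data `phylo` tree with `node.label` set to percent
#'   supports.
#' @export
bootstrap_support <- function(alignment, n_reps = 100, seed = 1, cap = 5) {
  stopifnot(n_reps >= 1)
  if (inherits(alignment, "masked_alignment"))
    alignment <- alignment$alignment
  alignment <- as_named_rows(alignment)
  m <- do.call(rbind, strsplit(alignment, ""))
  rownames(m) <- names(alignment)
  build <- function(mat) {
    rows <- setNames(apply(mat, 1, paste, collapse = ""), rownames(mat))
    nj_tree(alignment_distances(rows, cap = cap))
  }
  full <- build(m)
  counts <- with_seed(seed, {
    suppressWarnings(ape::boot.phylo(full, m, build, B = n_reps,
                                     quiet = TRUE, rooted = FALSE))
  })
  # the trivial all-taxa clade is reported NA by the bipartition counter
  # but is present in every replicate by construction
  counts[is.na(counts)] <- n_reps
  full$node.label <- round(100 * counts / n_reps)
  full
}

#' Write a tree to Newick
#' @param tree A `phylo` tree.
#' @param path Output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as TSV (or PHYLIP square format)
#' @param D Distance matrix.
#' @param path Output file.
#' @param format `"tsv"` or `"phylip"`.
#' @export
write_distances <- function(D, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(data.frame(taxon = rownames(D), D, check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(D)), con)
    for (i in seq_len(nrow(D))) {
      writeLines(paste(c(sprintf("%-10s", rownames(D)[i]),
                         sprintf("%.6f", D[i, ])), collapse = " "), con)
    }
  }
  invisible(path)
}
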