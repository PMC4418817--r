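#' Detect the riboflavin biosynthetic pathway from annotations
#'
#' A genome is scored RBP-positive iff it carries *both* marker families
#' encoding the last two steps of the pathway: the lumazine-synthase
#' family (COG0054-like) and the riboflavin-synthase family
#' (COG0307-like). A single marker does not qualify; use
#' [rbp_status_table()] to see partial states.
#'
#' @param genes Gene table with a `family` column (as from
#'   [read_genes_gff3()] or the synthetic generator).
#' @param markers The two marker family labels.
#' @return Logical scalar.
#' @export
detect_rbp <- function(genes, markers = c("COG0054", "COG0307")) {
  stopifnot(length(markers) == 2)
  fam <- genes$family
  all(markers %in% fam[!is.na(fam)])
}

#' Per-genome RBP status with partial-marker transparency
#'
#' @param genomes Named list of gene tables (one per genome).
#' @param markers The two marker family labels.
#' @return Data frame: `genome`, `rbp`, `partial_rbp` (exactly one
#'   marker present), `n_markers`.
#' @export
rbp_status_table <- function(genomes, markers = c("COG0054", "COG0307")) {
  rows <- lapply(names(genomes), function(g) {
    fam <- genomes[[g]]$family
    n <- sum(markers %in% fam[!is.na(fam)])
    data.frame(genome = g, rbp = n == 2, partial_rbp = n == 1,
               n_markers = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

CATEGORY_LEVELS <- c("RBP+transporter", "transporter-only", "RBP-only",
                     "neither")

#' Classify genomes by transporter/RBP co-occurrence
#'
#' Combines per-genome RBP flags with transporter-family ortholog calls
#' into one of four mutually exclusive categories: both RBP and at least
#' one transporter, transporter only (import is the sole riboflavin
#' source), RBP only, or neither (candidates for unknown transporter
#' families). Genomes missing from the taxonomy table are placed in
#' phylum "unknown" with a warning.
#'
#' @param rbp Named logical vector (genome -> RBP present), e.g. from
#'   [rbp_status_table()].
#' @param calls Ortholog-call table from [call_orthologs()].
#' @param taxonomy Named character vector (genome -> phylum).
#' @return List with `records` (data frame: `genome`, `phylum`, `rbp`,
#'   `n_families`, `category`, list-columns `families` and
#'   `riboswitch_on_transporter`) and `tallies` (named list: `both`,
#'   `transporter_only`, `rbp_only`, `neither`, `transporter_total`,
#'   `genomes_total`).
#' @export
classify_genomes <- function(rbp, calls, taxonomy = NULL) {
  genomes <- names(rbp)
  stopifnot(!is.null(genomes))
  missing_tax <- setdiff(genomes, names(taxonomy))
  if (length(missing_tax) > 0 && !is.null(taxonomy))
    warning(sprintf("%d genome(s) missing from taxonomy; phylum set to 'unknown'",
                    length(missing_tax)))
  rows <- lapply(genomes, function(g) {
    fams <- sort(unique(calls$family[calls$genome == g]))
    ribo <- vapply(fams, function(f)
      any(calls$riboswitch_linked[calls$genome == g & calls$family == f]),
      logical(1))
    has_t <- length(fams) > 0
    category <- if (rbp[[g]] && has_t) "RBP+transporter"
      else if (has_t) "transporter-only"
      else if (rbp[[g]]) "RBP-only"
      else "neither"
    phylum <- if (!is.null(taxonomy) && g %in% names(taxonomy))
      taxonomy[[g]] else "unknown"
    r <- data.frame(genome = g, phylum = phylum, rbp = rbp[[g]],
                    n_families = length(fams), category = category,
                    stringsAsFactors = FALSE)
    r$families <- I(list(fams))
    r$riboswitch_on_transporter <- I(list(ribo))
    r
  })
  records <- do.call(rbind, rows)
  if (is.null(records)) {
    records <- data.frame(genome = character(0), phylum = character(0),
                          rbp = logical(0), n_families = integer(0),
                          category = character(0), stringsAsFactors = FALSE)
    records$families <- I(list())
    records$riboswitch_on_transporter <- I(list())
  }
  tal <- function(cat) sum(records$category == cat)
  tallies <- list(
    both = tal("RBP+transporter"),
    transporter_only = tal("transporter-only"),
    rbp_only = tal("RBP-only"),
    neither = tal("neither"))
  tallies$transporter_total <- tallies$both + tallies$transporter_only
  tallies$genomes_total <- nrow(records)
  list(records = records, tallies = tallies)
}

#' Phylum-level distribution matrix of transporter families
#'
#' One row per phylum; for each transporter family two columns, counting
#' genomes of that phylum carrying the family with (`RBP+`) and without
#' (`RBP-`) the biosynthetic pathway. The presence variant marks cells
#' with `o` as in a distribution table.
#'
#' @param records Record table from [classify_genomes()].
#' @param families Column families (default: all packaged families).
#' @param counts Return counts (TRUE, default) or presence marks.
#' @return Matrix: phyla x (family:RBP+/RBP-).
#' @export
distribution_matrix <- function(records, families = names(family_prototypes()),
                                counts = TRUE) {
  phyla <- sort(unique(records$phylum))
  cols <- as.vector(t(outer(families, c("RBP+", "RBP-"), paste, sep = ":")))
  M <- matrix(0L, length(phyla), length(cols),
              dimnames = list(phyla, cols))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    for (f in r$families[[1]]) {
      if (!f %in% families) next
      col <- paste(f, if (r$rbp) "RBP+" else "RBP-", sep = ":")
      M[r$phylum, col] <- M[r$phylum, col] + 1L
    }
  }
  if (counts) return(M)
  marks <- ifelse(M > 0, "o", "")
  dimnames(marks) <- dimnames(M)
  marks
}

#' Genomes encoding two or more transporter families
#'
#' Lists genomes carrying orthologs of at least two distinct transporter
#' families (as observed for some alpha-Proteobacteria encoding both
#' RibN and RfnT), sorted by genome id.
#'
#' @param records Record table from [classify_genomes()].
#' @return Data frame: `genome`, `phylum`, `n_families`, `families`
#'   (comma-joined).
#' @export
multi_transporter_report <- function(records) {
  sel <- records[records$n_families >= 2, , drop = FALSE]
  sel <- sel[order(sel$genome), , drop = FALSE]
  data.frame(genome = sel$genome, phylum = sel$phylum,
             n_families = sel$n_families,
             families = vapply(sel$families, paste, character(1),
                               collapse = ","),
             stringsAsFactors = FALSE)
}

#' Write co-occurrence records to TSV (list columns flattened)
#' @param records Record table from [classify_genomes()].
#' @param path Output file.
#' @export
write_records <- function(records, path) {
  flat <- records
  flat$families <- vapply(records$families, paste, character(1),
                          collapse = ",")
  flat$riboswitch_on_transporter <- vapply(
    records$riboswitch_on_transporter,
    function(x) paste(sprintf("%s=%s", names(x), x), collapse = ","),
    character(1))
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
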