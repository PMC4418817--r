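#' Configure a synthetic genome cohort
#'
#' Describes a cohort of synthetic annotated genomes carrying planted
#' signals with known ground truth: transporter genes mutated to target
#' identities against the family prototypes, FMN riboswitch instances
#' sampled at target bit scores upstream of chosen transcriptional
#' units, riboflavin-biosynthetic-pathway (RBP) marker genes, and operon
#' structure with controlled intra- versus inter-operon intergenic
#' distances. Every downstream stage of the pipeline can then be scored
#' against the truth table the generator emits.
#'
#' @param n_genomes Number of genomes.
#' @param seed Master seed; one child stream per genome is derived from
#'   it, so generation is deterministic and genome-parallelisable.
#' @param genes_per_genome Total annotated genes per genome (planted
#'   genes included; default 8).
#' @param families_present Named list: genome id -> character vector of
#'   transporter families planted there (subset of
#'   `names(family_prototypes())`).
#' @param family_identity Named list: genome id -> named numeric of
#'   target global identities in \[0,1\] per planted family (default 0.6).
#' @param transporter_riboswitch_bits Named list: genome id -> named
#'   numeric of riboswitch target bit scores per planted family
#'   (`NA` = no riboswitch on that transporter's TU; default 62).
#' @param rbp_truth Named logical: genome id -> whether the genome
#'   carries both RBP marker genes (COG0054-like and COG0307-like).
#' @param rbp_riboswitch_bits Named numeric: genome id -> bit score of a
#'   riboswitch planted on the RBP operon (`NA` = none). These hits are
#'   the natural anchor set for [calibrate_cutoff()].
#' @param partial_rbp Named logical: genome id -> if TRUE and the genome
#'   is RBP-negative, plant a single marker gene (COG0054-like only), to
#'   exercise the dual-marker criterion. Default all FALSE.
#' @param taxonomy Named character: genome id -> phylum label.
#' @param same_operon_gap_mean,between_operon_gap_mean Mean intergenic
#'   distances (bp) inside and between operons (defaults 20 and 250;
#'   draws are uniform within +/-40% of the mean).
#' @param operon_size_range Filler-operon sizes (default 1..3 genes).
#' @param gene_length_range Filler/marker protein lengths in aa
#'   (default 150..250).
#' @param genome_length Optional fixed replicon length (bp); the genome
#'   is padded with background DNA to reach it, and generation fails
#'   with an explicit error if the annotated span does not fit.
#' @param gc Background GC fraction (default 0.5, i.i.d. bases).
#' @param spacer Distance (bp) between a planted riboswitch and the
#'   start of its TU (default 30).
#' @param profile Riboswitch profile motifs are sampled from
#'   (default [fmn_profile()]).
#' @param marker_length Length (aa) of the concatenated phylogenetic
#'   marker alignment emitted for the display tree (default 120).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_genomes, seed = 1,
                          genes_per_genome = 8,
                          families_present = NULL,
                          family_identity = NULL,
                          transporter_riboswitch_bits = NULL,
                          rbp_truth = NULL,
                          rbp_riboswitch_bits = NULL,
                          partial_rbp = NULL,
                          taxonomy = NULL,
                          same_operon_gap_mean = 20,
                          between_operon_gap_mean = 250,
                          operon_size_range = c(1, 3),
                          gene_length_range = c(150, 250),
                          genome_length = NULL,
                          gc = 0.5,
                          spacer = 30,
                          profile = fmn_profile(),
                          marker_length = 120) {
  stopifnot(n_genomes >= 0, genes_per_genome >= 1, gc > 0, gc < 1,
            spacer >= 0)
  ids <- if (n_genomes > 0) sprintf("G%03d", seq_len(n_genomes)) else character(0)
  fill_named <- function(x, default) {
    out <- setNames(rep(list(default), n_genomes), ids)
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  cfg <- list(
    n_genomes = n_genomes, seed = as.integer(seed),
    genome_ids = ids,
    genes_per_genome = genes_per_genome,
    families_present = fill_named(families_present, character(0)),
    family_identity = fill_named(family_identity, numeric(0)),
    transporter_riboswitch_bits =
      fill_named(transporter_riboswitch_bits, numeric(0)),
    rbp_truth = fill_scalar(rbp_truth, TRUE, ids),
    rbp_riboswitch_bits = fill_scalar(rbp_riboswitch_bits, NA_real_, ids),
    partial_rbp = fill_scalar(partial_rbp, FALSE, ids),
    taxonomy = fill_scalar(taxonomy, "PhylumA", ids),
    same_operon_gap_mean = same_operon_gap_mean,
    between_operon_gap_mean = between_operon_gap_mean,
    operon_size_range = operon_size_range,
    gene_length_range = gene_length_range,
    genome_length = genome_length,
    gc = gc, spacer = spacer, profile = profile,
    marker_length = marker_length)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Named per-genome scalar vector, defaulted then overridden by `x`.
fill_scalar <- function(x, default, ids) {
  out <- setNames(rep(default, length(ids)), ids)
  if (!is.null(x)) out[names(x)] <- x
  out
}

validate_cohort_config <- function(cfg) {
  known <- names(family_prototypes())
  for (g in cfg$genome_ids) {
    fams <- cfg$families_present[[g]]
    if (length(setdiff(fams, known)) > 0)
      stop(sprintf("genome %s: unknown family %s", g,
                   paste(setdiff(fams, known), collapse = ", ")))
    idt <- cfg$family_identity[[g]]
    if (length(idt) > 0 && any(idt < 0 | idt > 1))
      stop(sprintf("genome %s: identity targets must lie in [0, 1]", g))
    bits <- cfg$transporter_riboswitch_bits[[g]]
    ok <- bits[!is.na(bits)]
    if (length(ok) > 0 && any(ok > cfg$profile$max_score))
      stop(sprintf("genome %s: riboswitch bit target exceeds profile maximum",
                   g))
  }
  invisible(cfg)
}

#' Mutate a protein to a target global identity
#'
#' Substitutes `round((1 - target) * length)` randomly chosen positions,
#' each to a residue drawn uniformly from the 19 alternatives, optionally
#' followed by a small number of single-residue indels (capped at 5% of
#' the length). Used to plant transporter genes straddling the
#' identity-threshold decision boundary.
#'
#' @param prototype Protein sequence.
#' @param target Target identity in \[0, 1\].
#' @param seed RNG seed.
#' @param indels Number of single-residue indels to apply (default 0;
#'   capped at 5% of the prototype length).
#' @return Mutated protein sequence.
#' @export
mutate_to_identity <- function(prototype, target, seed = 1, indels = 0) {
  stopifnot(nzchar(prototype), target >= 0, target <= 1)
  n <- nchar(prototype)
  indels <- min(indels, floor(0.05 * n))
  with_seed(seed, {
    aa <- strsplit(prototype, "")[[1]]
    k <- round((1 - target) * n)
    if (k > 0) {
      pos <- sample.int(n, k)
      aa[pos] <- vapply(aa[pos], function(x) {
        sample(setdiff(AA_ALPHABET20, x), 1)
      }, character(1))
    }
    if (indels > 0) {
      for (i in seq_len(indels)) {
        if (runif(1) < 0.5 && length(aa) > 1) {
          aa <- aa[-sample.int(length(aa), 1)]
        } else {
          at <- sample.int(length(aa) + 1, 1)
          aa <- append(aa, sample(AA_ALPHABET20, 1), after = at - 1)
        }
      }
    }
    paste(aa, collapse = "")
  })
}

#' Generate a synthetic cohort with ground truth
#'
#' Builds every genome of the configured cohort: replicon sequence,
#' gene annotations, proteome, planted riboswitches and a concatenated
#' marker alignment for the display phylogeny, together with a truth
#' table recording what was planted where. Deterministic under a fixed
#' config (including seed): regenerating yields byte-identical files.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, files are written via
#'   [write_cohort()].
#' @return An `rf_cohort`: list with `genomes` (per genome: `replicons`
#'   named character, `genes` table, `proteins` named character),
#'   `truth` (list of `planted_riboswitches`, `planted_orthologs`,
#'   `rbp_status`, `tu_truth`), `taxonomy`, `marker_alignment`, `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  genomes <- list()
  ribo_truth <- list()
  orth_truth <- list()
  tu_truth <- list()
  for (i in seq_along(config$genome_ids)) {
    g <- config$genome_ids[[i]]
    built <- with_seed(derive_seed(config$seed, i),
                       build_genome(g, i, config))
    genomes[[g]] <- built$genome
    ribo_truth[[g]] <- built$riboswitches
    orth_truth[[g]] <- built$orthologs
    tu_truth[[g]] <- built$tus
  }
  truth <- list(
    planted_riboswitches = rbind_or_empty(ribo_truth, riboswitch_truth_cols),
    planted_orthologs = rbind_or_empty(orth_truth, ortholog_truth_cols),
    rbp_status = config$rbp_truth,
    tu_truth = rbind_or_empty(tu_truth, tu_truth_cols))
  cohort <- structure(list(
    genomes = genomes, truth = truth, taxonomy = config$taxonomy,
    marker_alignment = marker_alignment(config), config = config),
    class = "rf_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.rf_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d genome(s), %d planted riboswitch(es), %d planted ortholog(s)\n",
              length(x$genomes), nrow(x$truth$planted_riboswitches),
              nrow(x$truth$planted_orthologs)))
  invisible(x)
}

riboswitch_truth_cols <- c(genome = "character", replicon = "character",
                           start = "integer", end = "integer",
                           strand = "character", tu_index = "integer",
                           first_gene = "character", target_bits = "numeric")
ortholog_truth_cols <- c(genome = "character", gene_id = "character",
                         family = "character", target_identity = "numeric",
                         realized_identity = "numeric",
                         realized_coverage = "numeric")
tu_truth_cols <- c(genome = "character", replicon = "character",
                   tu_index = "integer", strand = "character",
                   gene_ids = "character")

rbind_or_empty <- function(parts, cols) {
  parts <- Filter(function(p) !is.null(p) && nrow(p) > 0, parts)
  if (length(parts) == 0) {
    df <- lapply(cols, function(ty) vector(ty, 0))
    return(as.data.frame(df, stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# Lay out one genome: plan TUs, build plus-strand blocks, flip blocks on
# the minus strand, and record absolute coordinates and truth.
build_genome <- function(g, genome_index, cfg) {
  protos <- family_prototypes()
  fams <- cfg$families_present[[g]]
  plan <- list()
  for (fam in fams) {
    target <- cfg$family_identity[[g]][fam]
    if (is.na(target) || is.null(target)) target <- 0.6
    bits_map <- cfg$transporter_riboswitch_bits[[g]]
    bits <- if (fam %in% names(bits_map)) bits_map[[fam]] else 62
    prot <- mutate_to_identity(protos[[fam]], target,
                               seed = derive_seed(cfg$seed,
                                                  genome_index * 1000 +
                                                    match(fam, names(protos))))
    plan[[length(plan) + 1L]] <- list(
      genes = list(list(protein = prot, family = fam)),
      rs_bits = bits, fam_target = setNames(target, fam))
  }
  rand_len <- function() sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], 1)
  if (isTRUE(cfg$rbp_truth[[g]])) {
    plan[[length(plan) + 1L]] <- list(
      genes = list(list(protein = random_protein(rand_len()), family = "COG0054"),
                   list(protein = random_protein(rand_len()), family = "COG0307")),
      rs_bits = cfg$rbp_riboswitch_bits[[g]])
  } else if (isTRUE(cfg$partial_rbp[[g]])) {
    plan[[length(plan) + 1L]] <- list(
      genes = list(list(protein = random_protein(rand_len()), family = "COG0054")),
      rs_bits = NA_real_)
  }
  n_planted <- sum(vapply(plan, function(p) length(p$genes), integer(1)))
  n_filler <- max(0L, cfg$genes_per_genome - n_planted)
  while (n_filler > 0L) {
    sz <- min(n_filler, sample(cfg$operon_size_range[1]:cfg$operon_size_range[2], 1))
    plan[[length(plan) + 1L]] <- list(
      genes = lapply(seq_len(sz), function(k)
        list(protein = random_protein(rand_len()), family = NA_character_)),
      rs_bits = NA_real_)
    n_filler <- n_filler - sz
  }
  plan <- plan[sample.int(length(plan))]

  replicon <- paste0(g, "_chr")
  gap_draw <- function(mean) {
    lo <- max(0L, as.integer(round(mean * 0.6)))
    hi <- as.integer(round(mean * 1.4))
    sample(lo:hi, 1)
  }
  chunks <- character(0)
  pos <- 0L  # last filled position (1-based inclusive coordinates)
  gene_rows <- list()
  ribo_rows <- list()
  tu_rows <- list()
  gene_counter <- 0L
  for (t in seq_along(plan)) {
    tu <- plan[[t]]
    strand <- sample(c("+", "-"), 1)
    gap <- gap_draw(cfg$between_operon_gap_mean)
    chunks <- c(chunks, random_dna(gap, cfg$gc))
    pos <- pos + gap
    blk <- build_block(tu, cfg, genome_index, t)
    B <- nchar(blk$seq)
    if (strand == "-") {
      blk_seq <- revcomp(blk$seq)
      flip <- function(s, e) c(B - e + 1L, B - s + 1L)
    } else {
      blk_seq <- blk$seq
      flip <- function(s, e) c(s, e)
    }
    chunks <- c(chunks, blk_seq)
    # genes of this TU in genomic (left-to-right) order
    rel <- lapply(seq_along(blk$gene_rel), function(k) {
      fe <- flip(blk$gene_rel[[k]][1], blk$gene_rel[[k]][2])
      list(k = k, start = pos + fe[1], end = pos + fe[2])
    })
    rel <- rel[order(vapply(rel, function(r) r$start, numeric(1)))]
    ids_in_tx_order <- character(length(rel))
    for (r in rel) {
      gene_counter <- gene_counter + 1L
      id <- sprintf("%s_g%03d", g, gene_counter)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = id, replicon = replicon,
        start = r$start, end = r$end, strand = strand,
        family = tu$genes[[r$k]]$family, protein = tu$genes[[r$k]]$protein,
        stringsAsFactors = FALSE)
      ids_in_tx_order[r$k] <- id
    }
    tu_rows[[length(tu_rows) + 1L]] <- data.frame(
      genome = g, replicon = replicon, tu_index = t, strand = strand,
      gene_ids = paste(ids_in_tx_order, collapse = ","),
      stringsAsFactors = FALSE)
    if (!is.null(blk$motif_rel)) {
      fe <- flip(blk$motif_rel[1], blk$motif_rel[2])
      ribo_rows[[length(ribo_rows) + 1L]] <- data.frame(
        genome = g, replicon = replicon,
        start = pos + fe[1], end = pos + fe[2], strand = strand,
        tu_index = t, first_gene = ids_in_tx_order[1],
        target_bits = tu$rs_bits, stringsAsFactors = FALSE)
    }
    pos <- pos + B
  }
  tail_gap <- gap_draw(cfg$between_operon_gap_mean)
  chunks <- c(chunks, random_dna(tail_gap, cfg$gc))
  pos <- pos + tail_gap
  seq <- paste(chunks, collapse = "")
  if (!is.null(cfg$genome_length)) {
    if (cfg$genome_length < pos)
      stop(sprintf(
        "genome %s: annotated span (%d bp) exceeds configured genome_length (%d bp)",
        g, pos, cfg$genome_length))
    seq <- paste0(seq, random_dna(cfg$genome_length - pos, cfg$gc))
  }
  genes <- do.call(rbind, gene_rows)
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  proteins <- setNames(genes$protein, genes$gene_id)
  genes$protein <- NULL
  # realized identity/coverage of planted transporter genes vs prototype
  orth <- list()
  planted <- genes$gene_id[!is.na(genes$family) &
                             genes$family %in% names(protos)]
  for (id in planted) {
    fam <- genes$family[genes$gene_id == id]
    aln <- align_local(proteins[[id]], protos[[fam]])
    tgt <- cfg$family_identity[[g]][fam]
    if (is.null(tgt) || is.na(tgt)) tgt <- 0.6
    orth[[length(orth) + 1L]] <- data.frame(
      genome = g, gene_id = id, family = fam, target_identity = tgt,
      realized_identity = aln$identity, realized_coverage = aln$coverage,
      stringsAsFactors = FALSE)
  }
  list(
    genome = list(replicons = setNames(seq, replicon), genes = genes,
                  proteins = proteins),
    riboswitches = if (length(ribo_rows)) do.call(rbind, ribo_rows) else NULL,
    orthologs = if (length(orth)) do.call(rbind, orth) else NULL,
    tus = if (length(tu_rows)) do.call(rbind, tu_rows) else NULL)
}

# Assemble one TU as a plus-strand block: [motif][spacer] gene1 [gap]
# gene2 ... ; returns the sequence plus relative 1-based coordinates.
build_block <- function(tu, cfg, genome_index, tu_index) {
  chunks <- character(0)
  pos <- 0L
  motif_rel <- NULL
  if (!is.null(tu$rs_bits) && length(tu$rs_bits) == 1 && !is.na(tu$rs_bits)) {
    motif <- sample_motif(cfg$profile, tu$rs_bits,
                          seed = derive_seed(cfg$seed,
                                             genome_index * 100000 + tu_index))
    chunks <- c(chunks, motif)
    motif_rel <- c(pos + 1L, pos + nchar(motif))
    pos <- pos + nchar(motif)
    chunks <- c(chunks, random_dna(cfg$spacer, cfg$gc))
    pos <- pos + cfg$spacer
  }
  gene_rel <- list()
  for (k in seq_along(tu$genes)) {
    if (k > 1) {
      gap <- {
        m <- cfg$same_operon_gap_mean
        sample(max(0L, as.integer(round(m * 0.6))):as.integer(round(m * 1.4)), 1)
      }
      chunks <- c(chunks, random_dna(gap, cfg$gc))
      pos <- pos + gap
    }
    nt <- reverse_translate(tu$genes[[k]]$protein)
    chunks <- c(chunks, nt)
    gene_rel[[k]] <- c(pos + 1L, pos + nchar(nt))
    pos <- pos + nchar(nt)
  }
  list(seq = paste(chunks, collapse = ""), gene_rel = gene_rel,
       motif_rel = motif_rel)
}

# Concatenated marker alignment for the display phylogeny: a shared
# ancestor diverged per phylum then per genome, plus a block of
# gap-heavy columns to exercise the 75% gap mask.
marker_alignment <- function(cfg) {
  if (cfg$n_genomes == 0) return(setNames(character(0), character(0)))
  with_seed(derive_seed(cfg$seed, 999983L), {
    anc <- random_protein(cfg$marker_length)
    phyla <- unique(cfg$taxonomy)
    phy_seq <- setNames(vapply(phyla, function(p)
      mutate_protein(anc, 0.10), character(1)), phyla)
    rows <- vapply(cfg$genome_ids, function(g)
      mutate_protein(phy_seq[[cfg$taxonomy[[g]]]], 0.06), character(1))
    n_gapcol <- 8L
    gap_block <- vapply(seq_along(rows), function(i)
      paste(sample(c("-", "A"), n_gapcol, replace = TRUE,
                   prob = c(0.8, 0.2)), collapse = ""), character(1))
    setNames(paste0(rows, gap_block), cfg$genome_ids)
  })
}

mutate_protein <- function(seq, frac) {
  aa <- strsplit(seq, "")[[1]]
  k <- round(frac * length(aa))
  if (k > 0) {
    pos <- sample.int(length(aa), k)
    aa[pos] <- vapply(aa[pos], function(x)
      sample(setdiff(AA_ALPHABET20, x), 1), character(1))
  }
  paste(aa, collapse = "")
}

#' Write a cohort to disk
#'
#' Per genome: `<id>.fna` (replicon FASTA), `<id>.gff3` (gene features
#' with `ID` and `family` attributes), `<id>.faa` (protein FASTA). Plus
#' `taxonomy.tsv`, `markers.afa` (aligned marker FASTA) and the truth
#' tables (`truth_riboswitches.tsv`, `truth_orthologs.tsv`,
#' `truth_rbp.tsv`, `truth_tus.tsv`).
#'
#' @param cohort An `rf_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(cohort$genomes)) {
    gen <- cohort$genomes[[g]]
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(gen$replicons),
      file.path(dir, paste0(g, ".fna")))
    write_genes_gff3(gen$genes, file.path(dir, paste0(g, ".gff3")))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(gen$proteins),
      file.path(dir, paste0(g, ".faa")))
  }
  tsv <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  tsv(data.frame(genome = names(cohort$taxonomy),
                 phylum = unname(cohort$taxonomy)), "taxonomy.tsv")
  tsv(cohort$truth$planted_riboswitches, "truth_riboswitches.tsv")
  tsv(cohort$truth$planted_orthologs, "truth_orthologs.tsv")
  tsv(data.frame(genome = names(cohort$truth$rbp_status),
                 rbp = unname(cohort$truth$rbp_status)), "truth_rbp.tsv")
  tsv(cohort$truth$tu_truth, "truth_tus.tsv")
  if (length(cohort$marker_alignment) > 0) {
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(cohort$marker_alignment),
      file.path(dir, "markers.afa"))
  }
  invisible(dir)
}

#' Read a cohort configuration from a YAML file
#'
#' The YAML fields mirror the arguments of [cohort_config()]; per-genome
#' maps (`families_present`, `family_identity`,
#' `transporter_riboswitch_bits`, `rbp_truth`, `rbp_riboswitch_bits`,
#' `partial_rbp`, `taxonomy`) are YAML mappings keyed by genome id.
#'
#' @param path YAML file.
#' @return A `cohort_config`.
#' @export
cohort_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(is.list(y), !is.null(y$n_genomes))
  per_genome_numeric <- function(x) {
    if (is.null(x)) return(NULL)
    lapply(x, function(v) {
      v <- unlist(v)
      storage.mode(v) <- "double"  # YAML integers stay numeric targets
      v
    })
  }
  per_genome_character <- function(x)
    if (is.null(x)) NULL else lapply(x, as.character)
  scalar_map <- function(x) if (is.null(x)) NULL else unlist(x)
  args <- list(
    n_genomes = y$n_genomes,
    families_present = per_genome_character(y$families_present),
    family_identity = per_genome_numeric(y$family_identity),
    transporter_riboswitch_bits =
      per_genome_numeric(y$transporter_riboswitch_bits),
    rbp_truth = scalar_map(y$rbp_truth),
    rbp_riboswitch_bits = {
      v <- scalar_map(y$rbp_riboswitch_bits)
      if (!is.null(v)) storage.mode(v) <- "double"
      v
    },
    partial_rbp = scalar_map(y$partial_rbp),
    taxonomy = scalar_map(y$taxonomy))
  for (f in c("seed", "genes_per_genome", "same_operon_gap_mean",
              "between_operon_gap_mean", "genome_length", "gc",
              "spacer", "marker_length")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(cohort_config, args)
}

#' Randomised cohort configuration at the study's operating conditions
#'
#' A convenience constructor for test and evaluation cohorts: each
#' genome draws 0-2 transporter families, planted at identities clearly
#' above threshold (0.55-0.70) with riboswitches well above the cutoff
#' (>= 60 bits), an RBP status with probability `p_rbp`, an anchor
#' riboswitch on the RBP operon, and a phylum from `phyla`.
#'
#' @param n_genomes Number of genomes.
#' @param seed Master seed.
#' @param p_rbp Probability a genome carries the RBP (default 0.7).
#' @param p_family Per-genome probability of carrying at least one
#'   transporter family (default 0.75).
#' @param identity_levels Pool of planted identity targets.
#' @param bits_levels Pool of planted riboswitch bit scores.
#' @param anchor_bits Pool of RBP-operon riboswitch scores.
#' @param phyla Phylum labels to draw from.
#' @param ... Passed through to [cohort_config()].
#' @return A `cohort_config`.
#' @export
random_cohort_config <- function(n_genomes, seed = 1, p_rbp = 0.7,
                                 p_family = 0.75,
                                 identity_levels = c(0.55, 0.6, 0.65, 0.7),
                                 bits_levels = c(60, 65, 70),
                                 anchor_bits = c(55, 58, 62),
                                 phyla = c("Firmicutes", "Proteobacteria",
                                           "Actinobacteria", "Spirochaetes"),
                                 ...) {
  fams <- names(family_prototypes())
  with_seed(derive_seed(seed, 424243L), {
    ids <- sprintf("G%03d", seq_len(n_genomes))
    families <- list()
    idents <- list()
    bits <- list()
    for (g in ids) {
      k <- if (runif(1) < p_family) sample(1:2, 1) else 0
      f <- if (k > 0) sample(fams, k) else character(0)
      families[[g]] <- f
      idents[[g]] <- setNames(sample(identity_levels, length(f),
                                     replace = TRUE), f)
      bits[[g]] <- setNames(sample(bits_levels, length(f),
                                   replace = TRUE), f)
    }
    rbp <- setNames(runif(n_genomes) < p_rbp, ids)
    # ensure at least one anchor genome so the cutoff stays calibratable
    if (n_genomes > 0 && !any(rbp)) rbp[sample(ids, 1)] <- TRUE
    anchors <- setNames(ifelse(rbp, sample(anchor_bits, n_genomes,
                                           replace = TRUE), NA_real_), ids)
    tax <- setNames(sample(phyla, n_genomes, replace = TRUE), ids)
    cohort_config(n_genomes, seed = seed, families_present = families,
                  family_identity = idents,
                  transporter_riboswitch_bits = bits,
                  rbp_truth = rbp, rbp_riboswitch_bits = anchors,
                  taxonomy = tax, ...)
  })
}
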