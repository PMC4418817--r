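#' Run the full discovery pipeline on a synthetic cohort
#'
#' Orchestrates generation, TU prediction, riboswitch scanning,
#' prototype-anchored ortholog calling, co-occurrence classification and
#' the display phylogeny as one reproducible run. All stage outputs are
#' written under `out_dir` together with a manifest (parameter values,
#' seeds, per-file checksums); rerunning with an identical config
#' reproduces identical stage-output checksums.
#'
#' @param config A [cohort_config()] (e.g. from
#'   [random_cohort_config()]).
#' @param out_dir Output directory.
#' @param d_max,link_min TU-prediction parameters (see [predict_tus()]).
#' @param window Upstream scan window (nt).
#' @param cutoff Riboswitch bit cutoff (default 51.34).
#' @param margin Borderline-identity rescue margin (see
#'   [call_orthologs()]).
#' @param inflation MCL inflation recorded for the similarity-graph
#'   stage.
#' @param bootstrap Bootstrap replicates for the tree (0 = none).
#' @return An `rf_run`: list with `cohort`, `tus`, `hits`, `calls`,
#'   `classification`, `matrix`, `tree`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, d_max = 50, link_min = 0.8,
                         window = 350, cutoff = 51.34, margin = 0.03,
                         inflation = 2, bootstrap = 0) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config, file.path(out_dir, "cohort"))

  tus <- cohort_tus(cohort, d_max = d_max, link_min = link_min)
  write_tus(tus, file.path(out_dir, "tus.tsv"))

  replicons <- lapply(cohort$genomes, `[[`, "replicons")
  hits <- call_riboswitches(replicons, tus, config$profile,
                            cutoff = cutoff, window = window)
  write.table(hits, file.path(out_dir, "riboswitch_hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_hits_bed(hits, file.path(out_dir, "riboswitch_hits.bed"))

  proteomes <- lapply(cohort$genomes, `[[`, "proteins")
  calls <- call_orthologs(proteomes, riboswitch_hits = hits, tus = tus,
                          margin = margin)
  write.table(calls, file.path(out_dir, "ortholog_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  rbp_tab <- rbp_status_table(lapply(cohort$genomes, `[[`, "genes"))
  classification <- classify_genomes(setNames(rbp_tab$rbp, rbp_tab$genome),
                                     calls, cohort$taxonomy)
  write_records(classification$records, file.path(out_dir, "records.tsv"))
  M <- distribution_matrix(classification$records)
  write.table(data.frame(phylum = rownames(M), M, check.names = FALSE),
              file.path(out_dir, "distribution_matrix.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(classification$tallies,
                       file.path(out_dir, "tallies.json"), auto_unbox = TRUE)

  tree <- NULL
  if (length(cohort$marker_alignment) >= 3) {
    masked <- mask_columns(cohort$marker_alignment)
    if (bootstrap > 0) {
      tree <- bootstrap_support(masked, n_reps = bootstrap,
                                seed = derive_seed(config$seed, 777L))
    } else {
      tree <- nj_tree(alignment_distances(masked))
    }
    write_tree_newick(tree, file.path(out_dir, "tree.nwk"))
  }

  params <- list(d_max = d_max, link_min = link_min, window = window,
                 cutoff = cutoff, margin = margin, inflation = inflation,
                 bootstrap = bootstrap, seed = config$seed)
  manifest <- run_manifest(out_dir, params)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(cohort = cohort, tus = tus, hits = hits, calls = calls,
                 classification = classification, matrix = M, tree = tree,
                 manifest = manifest, out_dir = out_dir),
            class = "rf_run")
}

#' @export
print.rf_run <- function(x, ...) {
  t <- x$classification$tallies
  cat(sprintf(paste0(
    "pipeline run: %d genome(s), %d riboswitch hit(s), %d ortholog call(s)\n",
    "categories: both=%d transporter-only=%d RBP-only=%d neither=%d\n"),
    length(x$cohort$genomes), nrow(x$hits), nrow(x$calls),
    t$both, t$transporter_only, t$rbp_only, t$neither))
  invisible(x)
}

# Predict TUs for every genome of a cohort; adds a `genome` column.
cohort_tus <- function(cohort, d_max = 50, link_min = 0.8) {
  parts <- lapply(names(cohort$genomes), function(g) {
    tu <- predict_tus(cohort$genomes[[g]]$genes, d_max = d_max,
                      link_min = link_min)
    tu$genome <- g
    tu
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# Stage-output checksums + parameters; timestamps are informational and
# excluded from any determinism comparison.
run_manifest <- function(out_dir, params) {
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  list(parameters = params,
       checksums = setNames(as.list(unname(sums)), files),
       generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write riboswitch hits as BED (0-based half-open, score in bits)
#' @param hits Hit table from [call_riboswitches()].
#' @param path Output BED file.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$replicon, start = hits$start - 1L,
                    end = hits$end, name = hits$tu_id,
                    score = hits$score, strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Score a pipeline run against the generator's ground truth
#'
#' Computes riboswitch recall and precision (a planted riboswitch is
#' recovered iff a hit is reported for the transcriptional unit
#' containing its first gene), ortholog-call accuracy (planted genes
#' whose accept/reject decision and family agree with the thresholds
#' applied to the *realized* identity and coverage, with false calls on
#' unplanted genes counted against), and category accuracy against the
#' truth-derived co-occurrence categories.
#'
#' @param run An `rf_run` from [run_pipeline()].
#' @param truth A truth table (default: the run's own cohort truth).
#' @param thresholds Family thresholds used for the expected decisions.
#' @return List of metrics in \[0,1\]: `riboswitch_recall`,
#'   `riboswitch_precision`, `ortholog_accuracy`, `category_accuracy`,
#'   plus a `detail` list with per-genome confusion tables.
#' @export
evaluate_against_truth <- function(run, truth = run$cohort$truth,
                                   thresholds = family_thresholds()) {
  if (!setequal(names(run$cohort$genomes),
                names(truth$rbp_status)))
    stop("truth table and run outputs cover different genomes")
  gene2tu <- setNames(
    rep(run$tus$tu_id, lengths(run$tus$gene_ids)),
    paste(rep(run$tus$genome, lengths(run$tus$gene_ids)),
          unlist(run$tus$gene_ids)))
  # riboswitches
  rtruth <- truth$planted_riboswitches
  hit_keys <- paste(run$hits$genome, run$hits$tu_id)
  truth_keys <- paste(rtruth$genome,
                      gene2tu[paste(rtruth$genome, rtruth$first_gene)])
  recovered <- truth_keys %in% hit_keys
  ribo_recall <- if (nrow(rtruth) == 0) 1 else mean(recovered)
  ribo_precision <- if (nrow(run$hits) == 0) 1
    else mean(hit_keys %in% truth_keys)
  # orthologs
  ot <- truth$planted_orthologs
  thr <- thresholds
  expected <- vapply(seq_len(nrow(ot)), function(i) {
    t <- thr[thr$family == ot$family[i], ]
    ot$realized_identity[i] > t$identity_min &&
      ot$realized_coverage[i] >= t$coverage_min
  }, logical(1))
  call_key <- paste(run$calls$genome, run$calls$gene_id)
  planted_key <- paste(ot$genome, ot$gene_id)
  got <- planted_key %in% call_key
  fam_ok <- vapply(seq_len(nrow(ot)), function(i) {
    if (!got[i]) return(TRUE)  # family only judged on accepted genes
    run$calls$family[call_key == planted_key[i]] == ot$family[i]
  }, logical(1))
  correct <- (got == expected) & fam_ok
  false_extra <- sum(!(call_key %in% planted_key))
  denom <- nrow(ot) + false_extra
  orth_acc <- if (denom == 0) 1 else sum(correct) / denom
  # categories
  exp_fams <- tapply(ot$family[expected], ot$genome[expected],
                     function(x) unique(x), simplify = FALSE)
  truth_cat <- vapply(names(truth$rbp_status), function(g) {
    has_t <- g %in% names(exp_fams) && length(exp_fams[[g]]) > 0
    rbp <- truth$rbp_status[[g]]
    if (rbp && has_t) "RBP+transporter"
    else if (has_t) "transporter-only"
    else if (rbp) "RBP-only"
    else "neither"
  }, character(1))
  rec <- run$classification$records
  obs_cat <- setNames(rec$category, rec$genome)
  cat_acc <- mean(obs_cat[names(truth_cat)] == truth_cat)
  list(riboswitch_recall = ribo_recall,
       riboswitch_precision = ribo_precision,
       ortholog_accuracy = orth_acc,
       category_accuracy = cat_acc,
       detail = list(
         riboswitch = data.frame(genome = rtruth$genome,
                                 first_gene = rtruth$first_gene,
                                 recovered = recovered,
                                 stringsAsFactors = FALSE),
         ortholog = data.frame(genome = ot$genome, gene_id = ot$gene_id,
                               family = ot$family, expected = expected,
                               called = got, correct = correct,
                               stringsAsFactors = FALSE),
         category = data.frame(genome = names(truth_cat),
                               truth = unname(truth_cat),
                               observed = unname(obs_cat[names(truth_cat)]),
                               stringsAsFactors = FALSE)))
}
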