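mk_calls <- function(genome, families, linked = TRUE) {
  if (length(families) == 0) {
    return(data.frame(genome = character(0), gene_id = character(0),
                      family = character(0), riboswitch_linked = logical(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(genome = genome, gene_id = paste0(genome, "_", families),
             family = families,
             riboswitch_linked = rep_len(linked, length(families)),
             stringsAsFactors = FALSE)
}

test_that("RBP detection requires both marker families", {
  both <- data.frame(gene_id = c("a", "b"), family = c("COG0054", "COG0307"))
  one <- data.frame(gene_id = "a", family = "COG0054")
  none <- data.frame(gene_id = "a", family = NA_character_)
  expect_true(detect_rbp(both))
  expect_false(detect_rbp(one))
  expect_false(detect_rbp(none))
  tab <- rbp_status_table(list(g1 = both, g2 = one, g3 = none))
  expect_equal(tab$rbp, c(TRUE, FALSE, FALSE))
  expect_equal(tab$partial_rbp, c(FALSE, TRUE, FALSE))
})

test_that("classification recovers the four categories and their algebra", {
  calls <- rbind(mk_calls("gBoth", "RibN"),
                 mk_calls("gOnly", c("RibN", "RfnT")))
  rbp <- c(gBoth = TRUE, gOnly = FALSE, gRbp = TRUE, gNone = FALSE)
  tax <- c(gBoth = "Proteobacteria", gOnly = "Proteobacteria",
           gRbp = "Firmicutes", gNone = "Firmicutes")
  cls <- classify_genomes(rbp, calls, tax)
  cats <- setNames(cls$records$category, cls$records$genome)
  expect_equal(unname(cats[c("gBoth", "gOnly", "gRbp", "gNone")]),
               c("RBP+transporter", "transporter-only", "RBP-only",
                 "neither"))
  expect_equal(cls$tallies$transporter_total,
               cls$tallies$both + cls$tallies$transporter_only)
  expect_equal(cls$tallies$genomes_total, 4)
  # missing taxonomy goes to "unknown" with a warning
  expect_warning(cls2 <- classify_genomes(rbp, calls, tax[1:2]), "taxonomy")
  expect_equal(cls2$records$phylum[cls2$records$genome == "gNone"],
               "unknown")
  # empty cohort: all tallies zero
  cls0 <- classify_genomes(setNames(logical(0), character(0)), calls[0, ])
  expect_equal(unlist(cls0$tallies), c(both = 0, transporter_only = 0,
                                       rbp_only = 0, neither = 0,
                                       transporter_total = 0,
                                       genomes_total = 0))
})

test_that("the published tally structure is internally consistent", {
  # a cohort with the headline structure: 341 transporter genomes of
  # which 253 also carry the RBP leaves 88 transporter-only genomes
  n <- 450
  ids <- sprintf("g%03d", 1:n)
  with_t <- ids[1:341]
  rbp <- setNames(c(rep(TRUE, 253), rep(FALSE, 88), rep(TRUE, 37),
                    rep(FALSE, 72)), ids)
  calls <- do.call(rbind, lapply(with_t, mk_calls, families = "RibU"))
  cls <- classify_genomes(rbp, calls)
  expect_equal(cls$tallies$transporter_total, 341)
  expect_equal(cls$tallies$both, 253)
  expect_equal(cls$tallies$transporter_only, 341 - 253)
  expect_equal(cls$tallies$neither, 72)
  expect_equal(with(cls$tallies, both + transporter_only + rbp_only +
                      neither), n)
})

test_that("category bookkeeping holds over random cohorts", {
  set.seed(90)
  fams <- names(family_prototypes())
  for (rep in 1:50) {
    n <- sample(1:25, 1)
    ids <- sprintf("g%02d", seq_len(n))
    rbp <- setNames(runif(n) < 0.5, ids)
    calls <- do.call(rbind, lapply(ids, function(g) {
      k <- sample(0:3, 1)
      mk_calls(g, if (k > 0) sample(fams, k) else character(0),
               linked = runif(1) < 0.5)
    }))
    cls <- classify_genomes(rbp, calls)
    t <- cls$tallies
    expect_equal(t$both + t$transporter_only + t$rbp_only + t$neither, n)
    n_with_family <- length(unique(calls$genome))
    expect_equal(t$transporter_total, n_with_family)
    # every genome lands in exactly one category
    expect_equal(nrow(cls$records), n)
    expect_true(all(cls$records$category %in%
                      c("RBP+transporter", "transporter-only",
                        "RBP-only", "neither")))
  }
})

test_that("the distribution matrix marks exactly the supported cells", {
  calls <- mk_calls("fuso1", "ImpX")
  rbp <- c(fuso1 = TRUE, firm1 = TRUE)
  tax <- c(fuso1 = "Fusobacteria", firm1 = "Firmicutes")
  cls <- classify_genomes(rbp, calls, tax)
  M <- distribution_matrix(cls$records)
  expect_equal(sum(M), 1)
  expect_equal(M["Fusobacteria", "ImpX:RBP+"], 1L)
  marks <- distribution_matrix(cls$records, counts = FALSE)
  expect_equal(marks["Fusobacteria", "ImpX:RBP+"], "o")
  expect_true(all(marks[marks != "o"] == ""))
  # no records: empty matrix
  M0 <- distribution_matrix(cls$records[0, ])
  expect_equal(nrow(M0), 0)
  # faithfulness on a synthetic classification
  set.seed(17)
  fams <- names(family_prototypes())
  ids <- sprintf("g%02d", 1:12)
  rbp2 <- setNames(runif(12) < 0.5, ids)
  calls2 <- do.call(rbind, lapply(ids, function(g)
    mk_calls(g, sample(fams, sample(0:2, 1)))))
  tax2 <- setNames(sample(c("P1", "P2", "P3"), 12, replace = TRUE), ids)
  cls2 <- classify_genomes(rbp2, calls2, tax2)
  M2 <- distribution_matrix(cls2$records)
  for (ph in rownames(M2)) {
    for (cn in colnames(M2)) {
      fam <- sub(":.*", "", cn)
      want_rbp <- grepl("RBP\\+", cn)
      support <- sum(vapply(seq_len(nrow(cls2$records)), function(i) {
        r <- cls2$records[i, ]
        r$phylum == ph && r$rbp == want_rbp && fam %in% r$families[[1]]
      }, logical(1)))
      expect_equal(M2[ph, cn], support)
    }
  }
})

test_that("multi-transporter genomes are listed sorted, singletons absent", {
  calls <- rbind(mk_calls("oant", c("RibN", "RfnT")),
                 mk_calls("rleg", c("RibN", "RfnT")),
                 mk_calls("bsub", "RibU"))
  rbp <- c(oant = TRUE, rleg = TRUE, bsub = TRUE)
  cls <- classify_genomes(rbp, calls)
  rep <- multi_transporter_report(cls$records)
  expect_equal(rep$genome, c("oant", "rleg"))
  expect_true(all(rep$n_families == 2))
  expect_false("bsub" %in% rep$genome)
})
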