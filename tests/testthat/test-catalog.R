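test_that("mature-peptide extraction follows the family rules", {
  prec <- paste0(random_protein(40), "RH", "HEVPSGPNPISN")
  iv <- c(40L, 54L)
  expect_equal(extract_mature_peptide(prec, iv, "CLE"), "HEVPSGPNPISN")
  expect_error(extract_mature_peptide(prec, c(40L, 52L), "CLE"),
               "shorter than 14")
  clel <- paste0(random_protein(30), "DYNNAGRKHRP")
  expect_equal(extract_mature_peptide(clel, c(30L, 41L), "CLEL"),
               "DYNNAGRKHRP")
  expect_match(extract_mature_peptide(clel, c(30L, 41L), "CLEL"), "^DY")
  bad <- paste0(random_protein(30), "NNAGRKHRP")
  expect_error(extract_mature_peptide(bad, c(30L, 39L), "CLEL"),
               "Asp/Glu-Tyr")
})

test_that("deduplication groups exactly and partitions the input", {
  entries <- data.frame(
    peptide = rep("HEVPSGPNPISN", 5L), family = "CLE",
    gene_id = paste0("g", 1:5),
    species = c("A", "A", "B", "C", "C"), stringsAsFactors = FALSE)
  u <- dedup_and_group(entries)
  expect_equal(nrow(u), 1L)
  expect_equal(u$n_species, 3L)
  expect_equal(u$n_genes, 5L)
  expect_equal(nrow(dedup_and_group(entries[0, ])), 0L)

  d <- fixture_dataset("clean")
  man <- d$manifest
  man_entries <- data.frame(
    peptide = man$transcripts$peptide,
    family = man$genes$family[match(man$transcripts$gene_id,
                                    man$genes$gene_id)],
    gene_id = man$transcripts$gene_id,
    species = man$genes$species[match(man$transcripts$gene_id,
                                      man$genes$gene_id)],
    stringsAsFactors = FALSE)
  u2 <- dedup_and_group(man_entries)
  expect_equal(nrow(u2), length(unique(man$transcripts$peptide)))
  # partition property: gene lists cover all entries
  expect_equal(sum(u2$n_genes),
               nrow(unique(man_entries[, c("peptide", "gene_id")])))
})

test_that("reference comparison reproduces the worked peptide distances", {
  ref <- load_reference_peptides()
  expect_length(ref, 32L)
  u <- data.frame(peptide = c("HEVPSGPNPISN", "RLVPSGPNPLHH"),
                  stringsAsFactors = FALSE)
  cmp <- compare_to_reference(u, ref)
  expect_equal(cmp$distance[1L], 0L)
  expect_equal(cmp$best_match[1L], "CLE41_44")
  # CLE13 vs CLE41: positions 1,2,10,11,12 differ (verified independently)
  a <- strsplit("RLVPSGPNPLHH", "")[[1L]]
  b <- strsplit("HEVPSGPNPISN", "")[[1L]]
  expect_equal(which(a != b), c(1L, 2L, 10L, 11L, 12L))
  d41 <- compare_to_reference(data.frame(peptide = "RLVPSGPNPLHH"),
                              ref[names(ref) == "CLE41_44"])
  expect_equal(d41$distance, 5L)
  expect_equal(d41$mismatch_positions, "1;2;10;11;12")
  expect_error(compare_to_reference(u, character()), "empty")
})

test_that("the ungapped peptide distance is a metric on equal lengths", {
  set.seed(41)
  peps <- replicate(12, random_protein(12))
  pd <- function(a, b) clemine:::peptide_distance(a, b)$distance
  for (i in 1:12) expect_equal(pd(peps[i], peps[i]), 0L)
  for (k in 1:30) {
    idx <- sample(12, 3)
    a <- peps[idx[1]]; b <- peps[idx[2]]; c0 <- peps[idx[3]]
    expect_equal(pd(a, b), pd(b, a))
    expect_lte(pd(a, c0), pd(a, b) + pd(b, c0))
  }
})

test_that("expression tallies match manifest labels and report the
           xylem/bark overlap", {
  d <- fixture_dataset("clean")
  man <- d$manifest
  tl <- expression_tally(man$ests[, c("gene_id", "library")])
  truth <- table(man$ests$gene_id, man$ests$library)
  for (i in seq_len(nrow(tl$tally))) {
    expect_equal(tl$tally$count[i],
                 unname(truth[tl$tally$gene_id[i], tl$tally$library[i]]))
  }
  # the planted cross-tissue gene shows up in the xylem/bark intersection
  overlap_gene <- man$genes$gene_id[man$genes$family == "CLE" &
                                      grepl("^CLE02_spA", man$genes$gene_id)]
  expect_true(overlap_gene %in% tl$xylem_bark_overlap)
  expect_true(overlap_gene %in% tl$multi_tissue)

  one <- data.frame(gene_id = "g1", library = "root")
  t1 <- expression_tally(one)
  expect_equal(t1$tally$count, 1L)
  expect_warning(expression_tally(data.frame(gene_id = "g1",
                                             library = "petal")),
                 "unknown")
})
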