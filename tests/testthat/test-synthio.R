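test_that("contradictory configs are rejected", {
  expect_error(synth_config(gc_content = 1.4), "\\[0, 1\\]")
  expect_error(synth_config(intron_length_range = c(10, 100)), "40")
  expect_error(synth_config(n_cle_genes = -1), ">= 0")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synth_config(seed = 7L, n_species = 2L, n_cle_genes = 2L,
                      n_clel_genes = 1L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
})

test_that("manifest exon chains translate to the stored precursors and all
           introns are canonical", {
  d <- fixture_dataset("clean")
  expect_true(validate_manifest(d))
})

test_that("planted gene architecture matches the family envelopes", {
  d <- fixture_dataset("clean")
  genes <- d$manifest$genes
  cle <- genes[genes$family == "CLE", ]
  # coding length 240-300 nt (80-100 aa), intronless
  expect_true(all(3L * nchar(cle$precursor) >= 240L &
                    3L * nchar(cle$precursor) <= 300L))
  expect_true(all(cle$n_introns == 0L))
  # signal peptide 15-30 aa (45-90 nt)
  expect_true(all(genes$sp_cleavage >= 15L & genes$sp_cleavage <= 30L))
  clel <- genes[genes$family == "CLEL", ]
  expect_true(all(clel$n_introns >= 1L))
  # alternative-variant peptide pairs are never identical
  for (gid in clel$gene_id[clel$alt]) {
    peps <- d$manifest$transcripts$peptide[
      d$manifest$transcripts$gene_id == gid]
    expect_equal(length(peps), 2L)
    expect_false(peps[1L] == peps[2L])
    expect_match(peps, "^[DE]Y", all = TRUE)
  }
})

test_that("error-free ESTs are exact transcript substrings and species
           labels partition as configured", {
  d <- fixture_dataset("clean")
  man <- d$manifest
  tx <- stats::setNames(man$transcripts$sequence,
                        man$transcripts$transcript_id)
  for (i in seq_len(nrow(man$ests))) {
    expect_true(grepl(man$ests$sequence[i], tx[[man$ests$transcript_id[i]]],
                      fixed = TRUE))
  }
  per_species <- table(man$ests$species)
  expect_equal(length(per_species), man$config$n_species)
  expect_true(all(per_species == per_species[1L]))
})

test_that("mutate_orthologue honours divergence and the conserved window", {
  p <- random_protein(60)
  expect_identical(mutate_orthologue(p, 0), p)
  m <- mutate_orthologue(p, 1, conserve_motif = TRUE,
                         motif_window = c(10L, 22L))
  expect_identical(substr(m, 11L, 22L), substr(p, 11L, 22L))
  out <- strsplit(m, "")[[1L]]
  ref <- strsplit(p, "")[[1L]]
  expect_true(all(out[-(11:22)] != ref[-(11:22)]))
  # binomial sampling: 0.15 over 10,000 sites within 3 SE
  set.seed(5)
  big <- random_protein(10000)
  mm <- mutate_orthologue(big, 0.15, conserve_motif = FALSE)
  frac <- mean(strsplit(mm, "")[[1L]] != strsplit(big, "")[[1L]])
  se <- sqrt(0.15 * 0.85 / 10000)
  expect_lt(abs(frac - 0.15), 3 * se)
})

test_that("dataset files round-trip through write_dataset", {
  d <- fixture_dataset("clean")
  dir <- tempfile()
  write_dataset(d, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "scaffolds.fasta", "ests.fasta", "manifest_genes.tsv",
    "manifest.gff3", "config.yaml")))))
  scf <- read_fasta(file.path(dir, "scaffolds.fasta"))
  expect_equal(scf$sequence, d$scaffolds$sequence)
  ests <- read_fasta(file.path(dir, "ests.fasta"))
  expect_equal(ests$species, d$ests$species)
  gff <- readLines(file.path(dir, "manifest.gff3"))
  expect_equal(gff[1L], "##gff-version 3")
})
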