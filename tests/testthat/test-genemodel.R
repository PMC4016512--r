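test_that("a transcript equal to a scaffold substring aligns as a single
           exon at identity 1.0, with strand symmetry", {
  set.seed(31)
  scaffold <- random_dna(2000, 0.45)
  tx <- substr(scaffold, 501, 900)
  sa <- spliced_align(tx, scaffold)
  expect_equal(nrow(sa$exons), 1L)
  expect_equal(sa$identity, 1.0)
  expect_equal(c(sa$exons$start, sa$exons$end), c(500L, 900L))
  expect_equal(sa$strand, "+")
  sar <- spliced_align(tx, reverse_complement(scaffold))
  expect_equal(sar$strand, "-")
  expect_equal(c(sar$exons$start, sar$exons$end),
               c(2000L - 900L, 2000L - 500L))
})

test_that("planted multi-exon transcripts are recovered with exact
           junction coordinates", {
  d <- fixture_dataset("clean")
  man <- d$manifest
  scf <- stats::setNames(d$scaffolds$sequence, d$scaffolds$id)
  for (i in seq_len(nrow(man$transcripts))) {
    tx <- man$transcripts[i, ]
    g <- man$genes[man$genes$gene_id == tx$gene_id, ]
    sa <- spliced_align(tx$sequence, scf[[g$scaffold]])
    expect_false(is.null(sa))
    ex_true <- man$exons[man$exons$transcript_id == tx$transcript_id &
                           man$exons$type == "exon", ]
    ex_true <- ex_true[order(ex_true$rank), ]
    expect_equal(sa$strand, g$strand)
    expect_equal(sa$exons$start, ex_true$start)
    expect_equal(sa$exons$end, ex_true$end)
  }
})

test_that("alternative 3'-terminal acceptor exons are recovered exactly on
           planted genes and absent elsewhere", {
  d <- fixture_dataset("clean")
  man <- d$manifest
  scf <- stats::setNames(d$scaffolds$sequence, d$scaffolds$id)
  for (gid in man$genes$gene_id[man$genes$family == "CLEL"]) {
    g <- man$genes[man$genes$gene_id == gid, ]
    txp <- man$transcripts[man$transcripts$gene_id == gid &
                             man$transcripts$variant == "primary", ]
    cds <- man$exons[man$exons$transcript_id == txp$transcript_id &
                       man$exons$type == "CDS", c("rank", "start", "end")]
    mdl <- clemine:::new_gene_model("m", g$scaffold, g$strand, "CLEL",
                                    cds, cds, txp$protein)
    vv <- find_alt_terminal_exons(mdl, scf[[g$scaffold]])
    expected <- man$transcripts$peptide[man$transcripts$gene_id == gid]
    expect_setequal(vv$peptide, expected)
    if (g$alt) {
      expect_equal(nrow(vv), 2L)
      txa <- man$transcripts[man$transcripts$gene_id == gid &
                               man$transcripts$variant == "alt", ]
      expect_equal(vv$donor[2L], txa$donor)
      expect_equal(vv$protein[2L], txa$protein)
    } else {
      expect_equal(nrow(vv), 1L)
    }
  }
})

test_that("a donor context whose downstream exon is frame-shifted yields
           the primary transcript only", {
  set.seed(32)
  # hand-built single-exon CLEL-like gene: CDS with an AG^GTA donor, then
  # an acceptor whose exon would encode a peptide only in the wrong frame
  prefix <- paste0("M", random_protein(20, c("L", "I", "V", "F")),
                   random_protein(10, c("N", "Q", "R")))
  donor_aa <- "K"                                 # AAG
  pep <- "DYRKSNHGQLSTP"                          # 13 aa
  cds <- paste0(back_translate(prefix, 0.5), "AAG", "GTA",
                back_translate(paste0(random_protein(6, c("S", "N")), pep),
                               0.5), "TAA")
  # alternative exon placed downstream but shifted by +1 nt so the reading
  # frame breaks; preceded by a valid pyrimidine tract + AG
  alt_exon <- paste0("T", back_translate(paste0("NNS", pep), 0.5), "TAA")
  scaffold <- paste0(random_dna(100, 0.45), cds,
                     random_dna(80, 0.45), "TTTTTTTTTT", "AG", alt_exon,
                     random_dna(100, 0.45))
  cds_iv <- data.frame(rank = 1L, start = 100L, end = 100L + nchar(cds))
  protein <- clemine:::translate_frame1(substr(scaffold, 101L,
                                               100L + nchar(cds) - 3L))
  mdl <- clemine:::new_gene_model("m", "s1", "+", "CLEL", cds_iv, cds_iv,
                                  protein)
  vv <- find_alt_terminal_exons(mdl, scaffold)
  expect_equal(vv$variant, "primary")
})

test_that("intronless calling finds genes on both strands, rejects
           stop-riddled hits, and reports tandem duplicates separately", {
  d <- fixture_dataset("multi")
  man <- d$manifest
  q <- motif_queries(stats::setNames(d$queries$peptide, d$queries$name),
                     d$queries$family)
  hits <- scan_motifs(d$scaffolds, q)
  models <- list()
  for (i in seq_len(nrow(d$scaffolds))) {
    models <- c(models, call_intronless_genes(as.list(d$scaffolds[i, ]),
                                              hits))
  }
  cle <- man$genes[man$genes$family == "CLE", ]
  expect_length(models, nrow(cle))
  got_strands <- vapply(models, `[[`, "", "strand")
  expect_setequal(unique(got_strands), unique(cle$strand))
  # every model's re-extracted CDS translates to its protein
  scf <- stats::setNames(d$scaffolds$sequence, d$scaffolds$id)
  for (m in models) {
    expect_equal(clemine:::translate_frame1(model_cds_seq(m, scf[[m$scaffold]])),
                 paste0(m$protein, "*"))
    expect_true(m$protein %in% cle$precursor)
  }
  # the planted duplicate pair produces two distinct models on one scaffold
  dup_gene <- cle[grepl("d_", cle$gene_id), ]
  expect_equal(nrow(dup_gene), 1L)
  dup_models <- Filter(function(m) m$protein == dup_gene$precursor, models)
  expect_equal(length(dup_models), 2L)

  # a motif hit planted inside a stop-riddled frame yields no model
  stopper <- paste0(strrep("TAA", 15), back_translate("HEVPSGPNPISN", 0.5),
                    strrep("TAA", 15))
  shits <- scan_motifs(c(sx = stopper),
                       motif_queries(c(t = "HEVPSGPNPISN"), "CLE"))
  expect_gt(nrow(shits), 0L)
  expect_length(call_intronless_genes(list(id = "sx", sequence = stopper),
                                      shits), 0L)
})
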