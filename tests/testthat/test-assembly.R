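test_that("two same-species reads with an exact 40-nt overlap merge into
           the concatenation; different species never merge", {
  set.seed(21)
  a <- random_dna(120, 0.45)
  b <- paste0(substr(a, 81, 120), random_dna(100, 0.45))
  cs <- assemble(data.frame(id = c("r1", "r2"), sequence = c(a, b),
                            species = "Pinus_taeda"))
  expect_length(cs, 1L)
  expect_equal(cs[[1L]]$consensus, paste0(a, substr(b, 41, nchar(b))))

  cs2 <- assemble(data.frame(id = c("r1", "r2"), sequence = c(a, a),
                             species = c("Picea_glauca", "Pinus_taeda")))
  expect_length(cs2, 2L)

  single <- assemble(data.frame(id = "r1", sequence = a, species = "X"))
  expect_length(single, 1L)
  expect_equal(single[[1L]]$consensus, a)
})

test_that("no read is lost or duplicated and the consensus is invariant to
           input order", {
  d <- fixture_dataset("clean")
  reads <- d$ests
  cs <- assemble(reads)
  ids <- sort(unlist(lapply(cs, function(x) x$members$id)))
  expect_equal(ids, sort(reads$id))
  set.seed(22)
  shuffled <- reads[sample(nrow(reads)), ]
  cs2 <- assemble(shuffled)
  expect_setequal(vapply(cs, `[[`, "", "consensus"),
                  vapply(cs2, `[[`, "", "consensus"))
})

test_that("error-free full-length ESTs recover exactly one contig per
           planted transcript per species", {
  d <- fixture_dataset("clean")
  cs <- assemble(d$ests)
  expect_length(cs, nrow(d$manifest$transcripts))
  expect_setequal(vapply(cs, `[[`, "", "consensus"),
                  d$manifest$transcripts$sequence)
})

test_that("variant calling classifies silent substitutions, flags
           direct-repeat insertions, and stays quiet on identical members", {
  set.seed(23)
  utr5 <- clemine:::strip_atg(random_dna(40, 0.5))
  prot <- paste0("M", random_protein(30))
  cds <- back_translate(prot, 0.5)
  # force a glycine GGT codon at a known position
  gpos <- 10L
  cds <- paste0(substr(cds, 1, 3 * (gpos - 1)), "GGT",
                substr(cds, 3 * gpos + 1, nchar(cds)))
  tx <- paste0(utr5, cds, "TAA", random_dna(60, 0.5))
  # member with the synonymous codon GGC
  tx_silent <- tx
  substr(tx_silent, nchar(utr5) + 3 * gpos, nchar(utr5) + 3 * gpos) <- "C"
  cs <- assemble(data.frame(id = c("r1", "r2"),
                            sequence = c(tx, tx_silent), species = "X"))
  expect_length(cs, 1L)
  orf <- c(nchar(utr5), nchar(utr5) + nchar(cds) + 3L)
  v <- detect_variants(cs[[1L]], orf = orf)
  expect_equal(nrow(v), 1L)
  expect_equal(v$type, "substitution")
  expect_equal(v$region, "coding")
  expect_equal(v$effect, "silent")

  # a 20-nt insertion in the 5'-UTR duplicating the following 20 nt
  ins <- substr(tx, 11, 30)
  tx_ins <- paste0(substr(tx, 1, 10), ins, substr(tx, 11, nchar(tx)))
  cs2 <- assemble(data.frame(id = c("r1", "r2", "r3"),
                             sequence = c(tx, tx, tx_ins), species = "X"))
  expect_length(cs2, 1L)
  v2 <- detect_variants(cs2[[1L]], orf = orf)
  insv <- v2[v2$type == "insertion", ]
  expect_equal(nrow(insv), 1L)
  expect_equal(insv$region, "5'-UTR")
  expect_equal(insv$note, "direct-repeat")
  expect_equal(insv$effect, "non-coding")

  # identical members -> no variants
  cs3 <- assemble(data.frame(id = c("r1", "r2"), sequence = c(tx, tx),
                             species = "X"))
  expect_equal(nrow(detect_variants(cs3[[1L]], orf = orf)), 0L)
})

test_that("amino-acid-changing substitutions are distinguished from silent
           ones", {
  set.seed(24)
  utr5 <- "CCTTCCTTCCTTCCTTCCTT"
  prot <- paste0("M", random_protein(25))
  cds <- paste0(back_translate(prot, 0.5), "TAA")
  tx <- paste0(utr5, cds, random_dna(40, 0.5))
  tx_mis <- tx
  # change the middle base of codon 5 (guaranteed nonsynonymous for any
  # sense codon except certain stop neighbourhoods; pick A->C swap)
  pos <- nchar(utr5) + 3L * 4L + 2L
  old <- substr(tx_mis, pos, pos)
  substr(tx_mis, pos, pos) <- if (old == "A") "C" else "A"
  cs <- assemble(data.frame(id = c("r1", "r2"), sequence = c(tx, tx_mis),
                            species = "X"))
  v <- detect_variants(cs[[1L]], orf = c(nchar(utr5),
                                         nchar(utr5) + nchar(cds)))
  expect_equal(v$effect, "amino-acid-changing")
})

test_that("the three-part rejection rule fires only when weak conservation,
           a truncated ORF, and a longer antisense ORF co-occur", {
  d <- fixture_dataset("clean")
  q <- motif_queries(stats::setNames(d$queries$peptide, d$queries$name),
                     d$queries$family)
  cs <- assemble(d$ests)
  # planted gene contigs are accepted with all sub-tests clean
  ct <- cs[[1L]]
  hits <- scan_motifs(stats::setNames(ct$consensus, ct$id), q)
  val <- validate_contig(ct, hits)
  expect_true(val$accept)
  expect_false(any(val$tests))

  # no motif hit at all -> reject
  val0 <- validate_contig(ct, hits[0, ])
  expect_false(val0$accept)

  # perfect motif but truncated ORF only -> still accepted
  tx <- d$manifest$transcripts[1L, ]
  gene <- d$manifest$genes[d$manifest$genes$gene_id == tx$gene_id, ]
  # cut just downstream of the start codon so no Met precedes the motif
  cut_at <- 150L
  trunc_seq <- substr(tx$sequence, cut_at, nchar(tx$sequence))
  trunc <- assemble(data.frame(id = "t1", sequence = trunc_seq,
                               species = gene$species))[[1L]]
  thits <- scan_motifs(stats::setNames(trunc$consensus, trunc$id), q)
  if (nrow(thits)) {
    vt <- validate_contig(trunc, thits)
    if (vt$tests[["truncated_orf"]] && sum(vt$tests) == 1L) {
      expect_true(vt$accept)
    }
  }

  # adversarial: reverse-complement of a coding transcript with a weak
  # chance hit -> antisense ORF longer than the sense ORF
  rc <- reverse_complement(tx$sequence)
  rcc <- assemble(data.frame(id = "rc1", sequence = rc,
                             species = gene$species))[[1L]]
  rhits <- scan_motifs(stats::setNames(rcc$consensus, rcc$id), q,
                       min_identity = 0, min_score = 10, min_span = 6L)
  # the chance weak hit is on the contig's plus strand; the real gene ORF
  # sits antisense to it
  rhits <- rhits[substr(rhits$frame, 1L, 1L) == "+", , drop = FALSE]
  expect_gt(nrow(rhits), 0L)
  vr <- validate_contig(rcc, rhits)
  expect_true(vr$tests[["antisense_orf"]])
  if (all(vr$tests)) expect_false(vr$accept)
})
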