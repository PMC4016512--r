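test_that("a lysine-rich N-terminus is not a signal peptide but a
           constructed h/c-region is, with the right cleavage site", {
  no_sp <- paste0("M", strrep("K", 40))
  expect_false(predict_signal_peptide(no_sp)$is_signal)

  sp <- paste0("M", "K", strrep("L", 12), "ASA")   # cleavage after 17 aa
  prot <- paste0(sp, "KR", random_protein(50))
  call <- predict_signal_peptide(prot)
  expect_true(call$is_signal)
  expect_equal(call$cleavage_pos, nchar(sp))
  expect_error(predict_signal_peptide("KLLLLLLLLLLLLLASAKRNQS"), "Met")
})

test_that("grammar-generated signal peptides and decoys are separated at
           >= 95% each over 500 samples", {
  set.seed(11)
  n <- 500L
  tp <- tn <- 0L
  for (i in seq_len(n)) {
    sp <- make_signal_peptide()
    mature <- paste0(random_protein(2, clemine:::mature_start_pool),
                     random_protein(58))
    if (predict_signal_peptide(paste0(sp$seq, mature))$is_signal) {
      tp <- tp + 1L
    }
    if (!predict_signal_peptide(paste0("M", random_protein(79)))$is_signal) {
      tn <- tn + 1L
    }
  }
  expect_gte(tp / n, 0.95)
  expect_gte(tn / n, 0.95)
})

test_that("raising the threshold never converts partial to full-length", {
  set.seed(12)
  for (i in 1:40) {
    sp <- make_signal_peptide()
    prot <- paste0(sp$seq, random_protein(2, clemine:::mature_start_pool),
                   random_protein(40))
    lo <- full_length_gate(prot, threshold = 0.4)$status
    hi <- full_length_gate(prot, threshold = 0.8)$status
    expect_false(lo == "partial" && hi == "full-length")
  }
})

test_that("the EST gate consults only the 5'-most in-frame Met", {
  d <- fixture_dataset("clean")
  man <- d$manifest
  # full-length synthetic transcripts pass with the manifest Met
  tx <- man$transcripts[man$transcripts$variant == "primary", ][1L, ]
  gene <- man$genes[man$genes$gene_id == tx$gene_id, ]
  frames <- translate_six_frames(tx$sequence)
  fl <- lapply(paste0("+", 1:3), function(f) full_length_gate(frames[[f]]))
  ok <- vapply(fl, function(g) g$status == "full-length", logical(1))
  expect_equal(sum(ok), 1L)
  expect_equal(fl[[which(ok)]]$protein, gene$precursor)

  # truncation 5' of the signal peptide -> partial
  cut <- substr(tx$sequence, 120L, nchar(tx$sequence))
  frames_cut <- translate_six_frames(cut)
  status_cut <- vapply(paste0("+", 1:3), function(f)
    full_length_gate(frames_cut[[f]])$status, character(1))
  expect_false(any(status_cut == "full-length" & vapply(
    paste0("+", 1:3), function(f) {
      p <- full_length_gate(frames_cut[[f]])$protein
      !is.na(p) && p == gene$precursor
    }, logical(1))))

  # an upstream in-frame Met without a signal peptide blocks the gate even
  # though the true downstream Met would pass (strict 5'-most rule)
  good <- fl[[which(ok)]]
  translation_good <- frames[[paste0("+", which(ok))]]
  poisoned <- paste0("M", strrep("DE", 15L), translation_good)
  expect_equal(full_length_gate(poisoned)$status, "partial")
  expect_equal(full_length_gate("GGGGG")$reason, "no-start")
})

test_that("the genomic rule accepts any Met with a signal peptide upstream
           of the motif and rejects otherwise", {
  set.seed(13)
  sp <- make_signal_peptide()
  ncs <- paste0(random_protein(2, clemine:::mature_start_pool),
                random_protein(40))
  motif <- "RHEVPSGPNPISN"
  orf <- paste0("E", sp$seq, ncs, motif)     # leading junk before the Met
  motif_start <- nchar(orf) - nchar(motif)   # 0-based
  acc <- call_genomic_candidate(orf, motif_start)
  expect_true(acc$accept)
  expect_equal(acc$met_index, 1L)

  # no signal peptide downstream of any Met
  orf2 <- paste0("M", strrep("K", 50), motif)
  expect_false(call_genomic_candidate(orf2, 51L)$accept)

  # signal peptide present but motif upstream of it
  orf3 <- paste0("M", motif, substr(sp$seq, 2L, nchar(sp$seq)), ncs)
  expect_false(call_genomic_candidate(orf3, 1L)$accept)

  # no motif hit at all
  expect_false(call_genomic_candidate(orf, NA)$accept)
})
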