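test_that("six-frame translation handles the worked examples", {
  expect_equal(translate_six_frames("ATGGCA")[["+1"]], "MA")
  set.seed(2)
  s <- random_dna(100, 0.5)
  fr <- translate_six_frames(s)
  expect_equal(nchar(fr[c("+1", "+2", "+3")]),
               c(`+1` = 33L, `+2` = 33L, `+3` = 32L))
  expect_warning(translate_six_frames("AT"), "shorter")
})

test_that("six-frame translation agrees with an independent translator on
           random sequences", {
  set.seed(3)
  for (i in 1:100) {
    s <- random_dna(sample(30:200, 1L), runif(1, 0.3, 0.7))
    expect_identical(translate_six_frames(s), translate_oracle(s))
  }
})

test_that("an exact back-translated motif is found at identity 1.0 and a
           stop-only subject yields nothing", {
  set.seed(4)
  pep <- "HEVPSGPNPISN"
  subject <- paste0(random_dna(30, 0.5), back_translate(pep, 0.5),
                    random_dna(30, 0.5))
  q <- motif_queries(c(TDIF = pep), "CLE")
  hits <- scan_motifs(c(s1 = subject), q)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1.0)
  expect_equal(gsub("-", "", hits$peptide), pep)
  stops <- paste(rep("TAA", 30), collapse = "")
  expect_equal(nrow(scan_motifs(c(s1 = stops), q)), 0L)
})

test_that("reported local-alignment scores equal a full-DP oracle", {
  set.seed(6)
  n_checked <- 0L
  for (i in 1:50) {
    pep <- random_protein(sample(12:16, 1L))
    subject <- paste0(random_dna(24, 0.5), back_translate(pep, 0.5),
                      random_dna(24, 0.5))
    q <- motif_queries(c(q1 = pep), "CLE")
    hits <- scan_motifs(c(s1 = subject), q, min_identity = 0, min_score = 1)
    frames <- translate_six_frames(subject)
    oracle <- max(vapply(frames, function(f) {
      if (nchar(f) < 1L) return(0)
      sw_oracle_score(pep, f)
    }, numeric(1)))
    if (nrow(hits)) {
      expect_equal(max(hits$score), oracle)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 45L)
})

test_that("hit intervals reproduce the aligned peptide on both strands and
           lowering min_score never removes hits", {
  d <- fixture_dataset("clean")
  q <- motif_queries(stats::setNames(d$queries$peptide, d$queries$name),
                     d$queries$family)
  hits <- scan_motifs(d$scaffolds, q)
  expect_gt(nrow(hits), 0L)
  expect_true(any(substr(hits$frame, 1L, 1L) == "-"))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    s <- d$scaffolds$sequence[d$scaffolds$id == h$subject]
    expect_equal((h$end - h$start) %% 3L, 0L)
    nt <- substr(s, h$start + 1L, h$end)
    if (substr(h$frame, 1L, 1L) == "-") nt <- reverse_complement(nt)
    expect_equal(clemine:::translate_frame1(nt), gsub("-", "", h$peptide))
  }
  lower <- scan_motifs(d$scaffolds, q, min_score = 20)
  key <- function(h) sprintf("%s:%s:%d-%d:%s", h$subject, h$frame, h$start,
                             h$end, h$query)
  expect_true(all(key(hits) %in% key(lower)))
})

test_that("second-round search is idempotent and only grows the hit set", {
  d <- fixture_dataset("clean")
  q <- motif_queries(stats::setNames(d$queries$peptide, d$queries$name),
                     d$queries$family)
  subjects <- stats::setNames(d$ests$sequence, d$ests$id)[1:10]
  h1 <- scan_motifs(subjects, q)
  h_same <- iterate_search(subjects, q, q[0, ])
  expect_equal(h1, h_same)
  disc <- motif_queries(c(disc1 = "DYQRSNPKHGNWL"), "CLEL")
  h2 <- iterate_search(subjects, q, disc)
  key <- function(h) sprintf("%s:%s:%d-%d:%s", h$subject, h$frame, h$start,
                             h$end, h$query)
  expect_true(all(key(h1) %in% key(h2)))
  expect_equal(nrow(scan_motifs(data.frame(id = character(),
                                           sequence = character()), q)), 0L)
})

test_that("a motif diverged beyond reach of the first-round queries is
           recovered in round two with a discovered conifer motif", {
  set.seed(8)
  planted <- "RLVPSGPDPQHH"
  subject <- paste0(random_dna(30, 0.5), back_translate(planted, 0.5),
                    random_dna(30, 0.5))
  # first-round query too diverged to pass the score threshold
  far_query <- motif_queries(c(q1 = "WWQMCFEAWWCM"), "CLE")
  h1 <- scan_motifs(c(s1 = subject), far_query)
  expect_equal(nrow(h1), 0L)
  disc <- motif_queries(c(conifer1 = "RLVPSGPDPQHY"), "CLE")
  h2 <- iterate_search(c(s1 = subject), far_query, disc)
  expect_equal(nrow(h2), 1L)
})
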