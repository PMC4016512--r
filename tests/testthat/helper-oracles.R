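# Independent brute-force oracles and shared fixtures for the test suite.
# Oracles are deliberately naive re-derivations, not calls into the code
# paths they check.

# --- naive Smith-Waterman (Gotoh affine) on BLOSUM62, local score only
sw_oracle_score <- function(query, subject, gap_open = 11, gap_extend = 1) {
  B <- clemine:::get_blosum62()
  q <- strsplit(query, "")[[1L]]
  s <- strsplit(subject, "")[[1L]]
  n <- length(q); m <- length(s)
  M <- X <- Y <- matrix(0, n + 1L, m + 1L)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      sub <- B[q[i - 1L], s[j - 1L]]
      M[i, j] <- max(0, M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + sub
      X[i, j] <- max(M[i - 1L, j] - gap_open, X[i - 1L, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1L] - gap_open, Y[i, j - 1L] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- independent six-frame translation via Biostrings
translate_oracle <- function(seq) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  one <- function(s, k) {
    n <- nchar(s) - k + 1L
    n <- n - n %% 3L
    if (n < 3L) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, k, k + n - 1L)),
      no.init.codon = TRUE, if.fuzzy.codon = "X"))
  }
  stats::setNames(c(one(seq, 1), one(seq, 2), one(seq, 3),
                    one(rc, 1), one(rc, 2), one(rc, 3)),
                  c("+1", "+2", "+3", "-1", "-2", "-3"))
}

# --- score a 2-row gapped alignment under BLOSUM62 + affine gaps
score_alignment_rows <- function(r1, r2, gap_open = 11, gap_extend = 1) {
  B <- clemine:::get_blosum62()
  a <- strsplit(r1, "")[[1L]]
  b <- strsplit(r2, "")[[1L]]
  # gap of length L costs gap_open + L * gap_extend (Biostrings convention)
  sc <- 0
  in_gap <- FALSE
  for (i in seq_along(a)) {
    if (a[i] == "-" || b[i] == "-") {
      sc <- sc - gap_extend - if (in_gap) 0 else gap_open
      in_gap <- TRUE
    } else {
      sc <- sc + B[a[i], b[i]]
      in_gap <- FALSE
    }
  }
  sc
}

# --- shared generated datasets (built once per test session)
.fixtures <- new.env(parent = emptyenv())

fixture_dataset <- function(name) {
  if (!is.null(.fixtures[[name]])) return(.fixtures[[name]])
  ref <- load_reference_peptides()
  d <- switch(name,
    clean = generate_dataset(synth_config(
      seed = 101L, n_species = 2L, n_cle_genes = 3L, n_clel_genes = 2L,
      est_error_rate = 0, est_indel_rate = 0, est_full_length = TRUE,
      exclude_peptides = unname(ref))),
    multi = generate_dataset(synth_config(
      seed = 103L, n_species = 3L, n_cle_genes = 2L, n_clel_genes = 2L,
      est_error_rate = 0, est_indel_rate = 0, est_full_length = TRUE,
      plant_duplicate_pair = TRUE, exclude_peptides = unname(ref))),
    stop("unknown fixture: ", name))
  .fixtures[[name]] <- d
  d
}

fixture_pipeline <- function() {
  if (!is.null(.fixtures$pipeline)) return(.fixtures$pipeline)
  ref <- load_reference_peptides()
  res <- run_pipeline(dataset = fixture_dataset("clean"), reference = ref)
  .fixtures$pipeline <- res
  res
}
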