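test_that("progressive alignment handles identical sequences, single
           indels, and keeps enough columns", {
  pa <- progressive_align(c(a = "MKLLVFDSTW", b = "MKLLVFDSTW"))
  expect_equal(pa$rows, c("MKLLVFDSTW", "MKLLVFDSTW"))
  p1 <- "MKLSTDQRSVWFY"
  p2 <- "MKLSTQRSVWFY"                # one deletion
  pa2 <- progressive_align(c(a = p1, b = p2))
  expect_equal(nchar(pa2$rows[1L]), nchar(pa2$rows[2L]))
  gaps <- gregexpr("-", pa2$rows[2L], fixed = TRUE)[[1L]]
  expect_equal(length(gaps[gaps > 0]), 1L)     # single contiguous gap
  # optimality: our pairwise alignment scores equal Biostrings' optimum
  set.seed(51)
  for (i in 1:15) {
    a <- random_protein(sample(20:40, 1))
    b <- mutate_orthologue(a, 0.1, conserve_motif = FALSE)
    if (runif(1) < 0.5) b <- paste0(substr(b, 1, 10), substr(b, 14, nchar(b)))
    ours <- progressive_align(c(a = a, b = b))
    my_score <- score_alignment_rows(ours$rows[1L], ours$rows[2L])
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = clemine:::get_blosum62(), gapOpening = 11,
      gapExtension = 1)
    expect_equal(my_score, Biostrings::score(ref))
    expect_gte(nchar(ours$rows[1L]), max(nchar(a), nchar(b)))
  }
  one <- progressive_align(c(solo = "MKWLY"))
  expect_equal(one$rows, "MKWLY")
})

test_that("Poisson distances follow the closed form under pairwise
           deletion", {
  msa <- as_msa(c(a = "AAAA", b = "AATT"))
  dm <- poisson_distances(msa)
  expect_equal(dm$p["a", "b"], 0.5)
  expect_equal(dm$d["a", "b"], -log(0.5))
  expect_equal(round(dm$d["a", "b"], 4), 0.6931)
  ident <- poisson_distances(as_msa(c(a = "MKLV", b = "MKLV")))
  expect_equal(ident$d["a", "b"], 0)

  # gapped rows: n_effective equals an exhaustive column count per pair
  set.seed(52)
  core <- random_protein(60)
  rows <- vapply(1:5, function(i) {
    x <- strsplit(mutate_orthologue(core, 0.3, conserve_motif = FALSE),
                  "")[[1L]]
    x[sample(60, 12)] <- "-"
    paste(x, collapse = "")
  }, character(1))
  names(rows) <- paste0("s", 1:5)
  dm2 <- poisson_distances(as_msa(rows))
  mat <- do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1L]]))
  for (i in 1:4) for (j in (i + 1):5) {
    both <- sum(mat[i, ] != "-" & mat[j, ] != "-")
    expect_equal(unname(dm2$n_effective[i, j]), both)
  }
  # d >= p >= 0 everywhere
  expect_true(all(dm2$d >= dm2$p))
  expect_error(poisson_distances(as_msa(c(a = "AAAA", b = "TTTT"))),
               "p = 1")
})

test_that("NJ recovers a 4-taxon additive matrix exactly, solves 3 taxa in
           closed form, and matches clustering on ultrametric input", {
  # additive matrix from branch lengths A:0.1 B:0.2 | 0.15 | C:0.3 D:0.1
  D <- matrix(c(0, 0.3, 0.55, 0.35,
                0.3, 0, 0.65, 0.45,
                0.55, 0.65, 0, 0.4,
                0.35, 0.45, 0.4, 0),
              4, 4, dimnames = list(c("A", "B", "C", "D"),
                                    c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  co <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(co, D, tolerance = 1e-8)
  ref <- ape::read.tree(text = "((A:0.1,B:0.2):0.15,C:0.3,D:0.1);")
  expect_equal(as.numeric(ape::dist.topo(tr, ref)), 0)

  D3 <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.4, 0.5, 0.4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(D3)
  co3 <- ape::cophenetic.phylo(t3)[rownames(D3), colnames(D3)]
  expect_equal(co3, D3, tolerance = 1e-8)
  expect_error(neighbor_joining(D3[1:2, 1:2]), "at least 3")

  # ultrametric distances: NJ topology equals single-linkage topology
  set.seed(53)
  for (k in 1:5) {
    coal <- ape::rcoal(8)
    DU <- ape::cophenetic.phylo(coal)
    nj_t <- neighbor_joining(DU)
    sl <- ape::as.phylo(stats::hclust(stats::as.dist(DU),
                                      method = "single"))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj_t),
                                       ape::unroot(sl))), 0)
  }
})

test_that("NJ returns the generating topology for random additive trees up
           to 12 taxa, agreeing with an independent implementation", {
  set.seed(54)
  for (k in 1:25) {
    nt <- sample(4:12, 1L)
    tr <- ape::rtree(nt, rooted = FALSE)
    tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 0.5)
    D <- ape::cophenetic.phylo(tr)
    mine <- neighbor_joining(D)
    expect_equal(as.numeric(ape::dist.topo(mine, ape::unroot(tr))), 0)
    cross <- ape::nj(D)
    expect_equal(as.numeric(ape::dist.topo(mine, ape::unroot(cross))), 0)
  }
})

test_that("bootstrap consensus is deterministic under a seed and a single
           replicate reproduces the plain NJ tree with full support", {
  set.seed(55)
  base <- random_protein(80)
  rows <- vapply(1:6, function(i)
    mutate_orthologue(base, 0.15, conserve_motif = FALSE), character(1))
  names(rows) <- paste0("t", 1:6)
  msa <- as_msa(rows)
  b1 <- bootstrap_consensus(msa, replicates = 50, seed = 9)
  b2 <- bootstrap_consensus(msa, replicates = 50, seed = 9)
  expect_identical(b1$tree$node.label, b2$tree$node.label)
  expect_true(all(b1$tree$node.label[-1L] > 50))

  single <- bootstrap_consensus(msa, replicates = 1, seed = 3)
  expect_true(all(single$tree$node.label == 100))
  expect_equal(single$n_retained, 1L)
})
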