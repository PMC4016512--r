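# Protein phylogenetics: progressive multiple alignment, Poisson-corrected
# distances with pairwise deletion, Neighbour-Joining with deterministic
# tie-breaks, and majority-rule bootstrap consensus with support values.
# Trees are ape "phylo" objects throughout.

#' Progressive multiple alignment of proteins
#'
#' Guide order from k-mer (k = 3) composition distances clustered by
#' average linkage; profiles are merged by profile-profile
#' Needleman-Wunsch over BLOSUM62 expected scores with affine gaps.
#' Deterministic for a fixed input order.
#'
#' @param proteins Named character vector (>= 1 sequence).
#' @param gap_open,gap_extend Affine gap penalties (positive).
#' @return An `msa` object: list with `names` and `rows` (equal-length
#'   aligned strings, gap character `-`).
#' @export
progressive_align <- function(proteins, gap_open = 11, gap_extend = 1) {
  stopifnot(length(proteins) >= 1L, !is.null(names(proteins)))
  if (length(proteins) == 1L) {
    return(structure(list(names = names(proteins),
                          rows = unname(proteins)), class = "msa"))
  }
  # guide tree from 3-mer composition distance
  kmer_profile <- function(s) {
    if (nchar(s) < 3L) return(table(character()))
    table(substring(s, 1:(nchar(s) - 2L), 3:nchar(s)))
  }
  profs <- lapply(proteins, kmer_profile)
  n <- length(proteins)
  dm <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ks <- union(names(profs[[i]]), names(profs[[j]]))
      a <- as.numeric(profs[[i]][ks]); a[is.na(a)] <- 0
      b <- as.numeric(profs[[j]][ks]); b[is.na(b)] <- 0
      dm[i, j] <- dm[j, i] <- sum(abs(a - b)) /
        (nchar(proteins[i]) + nchar(proteins[j]))
    }
  }
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  # merge following the dendrogram
  groups <- lapply(seq_len(n), function(i) {
    list(idx = i, rows = unname(proteins[i]))
  })
  for (m in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0L) groups[[-x]] else merged[[x]]
    if (m == 1L) merged <- list()
    g1 <- pick(hc$merge[m, 1L]); g2 <- pick(hc$merge[m, 2L])
    merged[[m]] <- list(idx = c(g1$idx, g2$idx),
                        rows = align_profiles(g1$rows, g2$rows,
                                              gap_open, gap_extend))
  }
  final <- merged[[nrow(hc$merge)]]
  ord <- order(final$idx)
  structure(list(names = names(proteins)[final$idx[ord]],
                 rows = final$rows[ord]), class = "msa")
}

# profile-profile global alignment with affine gaps (Gotoh), vectorized
# expected-score matrix; ties resolved diagonal > up > left
align_profiles <- function(rows1, rows2, gap_open = 11, gap_extend = 1) {
  B <- get_blosum62()
  alpha <- rownames(B)
  prof <- function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1L]]))
    L <- ncol(m)
    p <- matrix(0, L, length(alpha), dimnames = list(NULL, alpha))
    for (a in alpha) p[, a] <- colMeans(m == a)
    # gaps carry no residue mass
    p
  }
  p1 <- prof(rows1); p2 <- prof(rows2)
  S <- p1 %*% B[alpha, alpha] %*% t(p2)
  n <- nrow(S); m <- ncol(S)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in profile2 (consume profile1)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in profile1
  # gap of length L costs gap_open + L * gap_extend
  M[1L, 1L] <- 0
  for (i in 2L:(n + 1L)) X[i, 1L] <- -gap_open - gap_extend * (i - 1L)
  for (j in 2L:(m + 1L)) Y[1L, j] <- -gap_open - gap_extend * (j - 1L)
  tbM <- matrix(0L, n + 1L, m + 1L)
  tbX <- matrix(0L, n + 1L, m + 1L)
  tbY <- matrix(0L, n + 1L, m + 1L)
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      k <- which.max(prev)
      M[i, j] <- prev[k] + S[i - 1L, j - 1L]
      tbM[i, j] <- k
      op <- c(M[i - 1L, j] - gap_open - gap_extend,
              X[i - 1L, j] - gap_extend)
      k <- which.max(op)
      X[i, j] <- op[k]; tbX[i, j] <- k
      op <- c(M[i, j - 1L] - gap_open - gap_extend,
              Y[i, j - 1L] - gap_extend)
      k <- which.max(op)
      Y[i, j] <- op[k]; tbY[i, j] <- k
    }
  }
  # traceback
  i <- n + 1L; j <- m + 1L
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  path <- list()
  while (i > 1L || j > 1L) {
    if (state == 1L && i > 1L && j > 1L) {
      path[[length(path) + 1L]] <- "D"
      state <- tbM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L || (j == 1L && i > 1L)) {
      path[[length(path) + 1L]] <- "U"
      ns <- if (i > 1L && tbX[i, j] == 1L) 1L else 2L
      i <- i - 1L
      state <- if (j == 1L) 2L else ns
    } else {
      path[[length(path) + 1L]] <- "L"
      ns <- if (j > 1L && tbY[i, j] == 1L) 1L else 2L
      j <- j - 1L
      state <- if (i == 1L) 3L else if (ns == 1L) 1L else 3L
    }
  }
  ops <- rev(unlist(path))
  gap_line <- function(rows, take) {
    # build aligned rows: take[c]=TRUE means consume a column
    chars <- lapply(rows, function(r) strsplit(r, "")[[1L]])
    idx <- cumsum(take)
    vapply(chars, function(ch) {
      out <- ifelse(take, ch[pmax(idx, 1L)], "-")
      paste(out, collapse = "")
    }, character(1))
  }
  take1 <- ops %in% c("D", "U")
  take2 <- ops %in% c("D", "L")
  c(gap_line(rows1, take1), gap_line(rows2, take2))
}

#' Construct an msa object from pre-aligned rows
#' @param rows Named character vector of equal-length aligned sequences.
#' @return An `msa` object.
#' @export
as_msa <- function(rows) {
  stopifnot(!is.null(names(rows)), length(unique(nchar(rows))) == 1L)
  structure(list(names = names(rows), rows = unname(rows)), class = "msa")
}

#' Poisson-corrected distance matrix with pairwise deletion
#'
#' For each sequence pair only columns where both rows are ungapped are
#' used (pairwise deletion). p is the proportion of differing sites and
#' the corrected distance is d = -ln(1 - p).
#'
#' @param msa An `msa` object.
#' @return List of class `poisson_dm`: `names`, `d`, `p`, `n_effective`
#'   (symmetric matrices).
#' @export
poisson_distances <- function(msa) {
  n <- length(msa$rows)
  stopifnot(n >= 2L)
  m <- do.call(rbind, lapply(msa$rows, function(r) strsplit(r, "")[[1L]]))
  gap <- m == "-"
  p <- d <- ne <- matrix(0, n, n, dimnames = list(msa$names, msa$names))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- !gap[i, ] & !gap[j, ]
      k <- sum(use)
      if (k == 0L) {
        stop("poisson_distances: no shared ungapped columns for pair ",
             msa$names[i], " / ", msa$names[j])
      }
      pij <- sum(m[i, use] != m[j, use]) / k
      if (pij >= 1) {
        stop("poisson_distances: p = 1 for pair ", msa$names[i], " / ",
             msa$names[j], "; Poisson distance undefined")
      }
      p[i, j] <- p[j, i] <- pij
      ne[i, j] <- ne[j, i] <- k
      d[i, j] <- d[j, i] <- -log(1 - pij)
    }
  }
  diag(ne) <- nchar(msa$rows[1L])
  structure(list(names = msa$names, d = d, p = p, n_effective = ne),
            class = "poisson_dm")
}

#' Neighbour-Joining tree
#'
#' Saitou-Nei Q-criterion agglomeration with the standard branch-length
#' formulas; ties are broken toward the lexicographically smallest label
#' pair so the result is deterministic. Negative branch lengths are
#' clamped to zero. Returns an unrooted `phylo` tree.
#'
#' @param dm A `poisson_dm` object, or a symmetric numeric matrix with
#'   dimnames.
#' @return An [ape] `phylo` object.
#' @export
neighbor_joining <- function(dm) {
  D <- if (inherits(dm, "poisson_dm")) dm$d else dm
  labs <- rownames(D)
  n <- length(labs)
  if (n < 3L) stop("neighbor_joining: need at least 3 taxa")
  frag <- stats::setNames(labs, labs)           # newick fragments
  repeat {
    n <- nrow(D)
    if (n == 3L) break
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pair_lab <- apply(cand, 1L, function(ij) {
      paste(sort(rownames(D)[ij]), collapse = "\r")
    })
    sel <- cand[order(pair_lab)[1L], ]
    i <- sel[1L]; j <- sel[2L]
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    new_lab <- paste0("(", frag[rownames(D)[i]], ":", format(li, digits = 10),
                      ",", frag[rownames(D)[j]], ":",
                      format(lj, digits = 10), ")")
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nm <- c(rownames(D)[keep], paste0("node", n))
    rownames(D2) <- colnames(D2) <- nm
    frag <- c(frag[rownames(D)[keep]],
              stats::setNames(new_lab, paste0("node", n)))
    D <- D2
  }
  # resolve the final three nodes with the three-point formulas
  a <- rownames(D)[1L]; b <- rownames(D)[2L]; c0 <- rownames(D)[3L]
  la <- max(0, (D[a, b] + D[a, c0] - D[b, c0]) / 2)
  lb <- max(0, (D[a, b] + D[b, c0] - D[a, c0]) / 2)
  lc <- max(0, (D[a, c0] + D[b, c0] - D[a, b]) / 2)
  txt <- paste0("(", frag[a], ":", format(la, digits = 10), ",",
                frag[b], ":", format(lb, digits = 10), ",",
                frag[c0], ":", format(lc, digits = 10), ");")
  ape::read.tree(text = txt)
}

#' Bootstrap majority-rule consensus tree with support
#'
#' Alignment columns are resampled with replacement for each replicate; a
#' Neighbour-Joining tree is built per replicate on Poisson-corrected
#' pairwise-deletion distances. Replicates in which any pair has p = 1
#' (or no shared columns) are discarded and counted. Support is the
#' percentage of retained replicates containing each bipartition of the
#' majority-rule (>50%) consensus.
#'
#' @param msa An `msa` object.
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed (a single RNG stream drives all replicates).
#' @return List: `tree` (consensus `phylo` with `node.label` giving
#'   support in 0-100, `edge.length` dropped), `n_retained`,
#'   `n_discarded`.
#' @export
bootstrap_consensus <- function(msa, replicates = 1000L, seed = 1L) {
  stopifnot(replicates >= 1L)
  n <- length(msa$rows)
  m <- do.call(rbind, lapply(msa$rows, function(r) strsplit(r, "")[[1L]]))
  rownames(m) <- msa$names
  L <- ncol(m)
  gap <- m == "-"
  set.seed(seed)
  trees <- list()
  n_disc <- 0L
  for (rep in seq_len(replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    mm <- m[, idx, drop = FALSE]
    gg <- gap[, idx, drop = FALSE]
    D <- matrix(0, n, n, dimnames = list(msa$names, msa$names))
    bad <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        use <- !gg[i, ] & !gg[j, ]
        k <- sum(use)
        if (k == 0L) { bad <- TRUE; break }
        pij <- sum(mm[i, use] != mm[j, use]) / k
        if (pij >= 1) { bad <- TRUE; break }
        D[i, j] <- D[j, i] <- -log(1 - pij)
      }
      if (bad) break
    }
    if (bad) { n_disc <- n_disc + 1L; next }
    trees[[length(trees) + 1L]] <- neighbor_joining(D)
  }
  if (!length(trees)) {
    stop("bootstrap_consensus: all replicates discarded (p = 1 pairs)")
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  cons$node.label <- round(100 * counts / length(trees), 1)
  list(tree = cons, n_retained = length(trees), n_discarded = n_disc)
}

#' Write a tree with support labels to Newick
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
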