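# Gene-model construction: spliced alignment of transcripts/contigs to
# genomic scaffolds (k-mer anchors, colinear chaining, GT..AG boundary
# refinement), direct calling of intronless genes from genomic motif hits,
# and detection of alternative 3'-terminal acceptor exons downstream of an
# AG^GTA donor context.

# anchor blocks of exact k-mer matches grouped by diagonal
anchor_blocks <- function(transcript, genomic, k = 16L) {
  lt <- nchar(transcript)
  lg <- nchar(genomic)
  if (lt < k || lg < k) return(NULL)
  g_kmers <- substring(genomic, seq_len(lg - k + 1L), seq_len(lg - k + 1L) +
                         k - 1L)
  gmap <- split(seq_along(g_kmers) - 1L, g_kmers)      # 0-based positions
  t_pos <- seq_len(lt - k + 1L) - 1L
  t_kmers <- substring(transcript, t_pos + 1L, t_pos + k)
  anchors <- list()
  for (i in seq_along(t_pos)) {
    g <- gmap[[t_kmers[i]]]
    if (!is.null(g)) {
      anchors[[length(anchors) + 1L]] <- cbind(ti = t_pos[i], gi = g)
    }
  }
  if (!length(anchors)) return(NULL)
  a <- do.call(rbind, anchors)
  d <- a[, "gi"] - a[, "ti"]
  blocks <- lapply(split(seq_len(nrow(a)), d), function(idx) {
    ti <- a[idx, "ti"]
    list(diag = d[idx[1L]], t_start = min(ti), t_end = max(ti) + k,
         n = length(idx))
  })
  blocks[order(vapply(blocks, `[[`, 0, "t_start"))]
}

# chain blocks colinearly; consecutive diagonal increases within
# [min_intron, max_intron] are introns
chain_blocks <- function(blocks, min_intron, max_intron) {
  n <- length(blocks)
  cov <- vapply(blocks, function(b) b$t_end - b$t_start, 0)
  best <- cov
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(max(0L, j - 1L))) {
      dd <- blocks[[j]]$diag - blocks[[i]]$diag
      if (dd < min_intron || dd > max_intron) next
      if (blocks[[j]]$t_start < blocks[[i]]$t_end - 10L) next
      cand <- best[i] + cov[j]
      if (cand > best[j]) { best[j] <- cand; prev[j] <- i }
    }
  }
  j <- which.max(best)
  chain <- integer()
  while (!is.na(j)) { chain <- c(j, chain); j <- prev[j] }
  blocks[chain]
}

# choose the junction point between two chained blocks: maximize sequence
# agreement on both sides with a strong bonus for a canonical GT..AG intron
refine_junction <- function(transcript, genomic, b1, b2, slack = 6L) {
  lo <- max(0L, b1$t_end - 2L * slack)
  hi <- min(nchar(transcript), b2$t_start + 2L * slack)
  best <- NULL
  for (j in seq.int(lo, hi)) {
    g_donor <- j + b1$diag                  # 0-based intron start
    g_acc <- j + b2$diag                    # 0-based exon2 start
    if (g_donor < 0L || g_acc + 1L > nchar(genomic)) next
    canonical <- substr(genomic, g_donor + 1L, g_donor + 2L) == "GT" &&
      substr(genomic, g_acc - 1L, g_acc) == "AG"
    m <- 0L
    if (j > lo) {
      m <- m + sum(strsplit(substr(transcript, lo + 1L, j), "")[[1L]] ==
                     strsplit(substr(genomic, lo + b1$diag + 1L,
                                     j + b1$diag), "")[[1L]])
    }
    if (hi > j) {
      m <- m + sum(strsplit(substr(transcript, j + 1L, hi), "")[[1L]] ==
                     strsplit(substr(genomic, j + b2$diag + 1L,
                                     hi + b2$diag), "")[[1L]])
    }
    sc <- m + if (canonical) 1000L else 0L
    if (is.null(best) || sc > best$score) best <- list(j = j, score = sc)
  }
  best$j
}

#' Spliced alignment of a transcript to a genomic scaffold
#'
#' Exact k-mer anchors are grouped into diagonals, chained colinearly
#' (scaffold gaps within the intron length bounds become introns), and
#' junctions are refined to canonical GT..AG boundaries where a shift of a
#' few nt permits. Both strands are tried; the chain covering more of the
#' transcript at higher identity wins. Substitution errors are tolerated;
#' transcript indels are not modelled.
#'
#' @param transcript Transcript/contig sequence (sense strand).
#' @param scaffold Scaffold sequence (forward strand).
#' @param min_intron,max_intron Intron length bounds (nt).
#' @param k Anchor k-mer length.
#' @param min_coverage Minimum transcript fraction covered by the chain.
#' @return `NULL` (with attribute `reason`) if no acceptable chain, else a
#'   list: `strand`, `exons` (`data.frame` rank/t_start/t_end/start/end;
#'   genomic coordinates 0-based half-open on the forward strand, ranks in
#'   transcript 5'->3' order), `identity`, `coverage`, `n_introns`.
#' @export
spliced_align <- function(transcript, scaffold, min_intron = 40L,
                          max_intron = 10000L, k = 16L,
                          min_coverage = 0.8) {
  lt <- nchar(transcript)
  lg <- nchar(scaffold)
  try_strand <- function(gseq) {
    blocks <- anchor_blocks(transcript, gseq, k)
    if (is.null(blocks)) return(NULL)
    chain <- chain_blocks(blocks, min_intron, max_intron)
    if (!length(chain)) return(NULL)
    # junction points between consecutive blocks
    cuts <- integer()
    if (length(chain) > 1L) {
      for (i in seq_len(length(chain) - 1L)) {
        j <- refine_junction(transcript, gseq, chain[[i]], chain[[i + 1L]])
        if (is.null(j)) return(NULL)
        cuts <- c(cuts, j)
      }
    }
    starts_t <- c(0L, cuts)
    ends_t <- c(cuts, lt)
    ex <- list()
    for (i in seq_along(chain)) {
      d <- chain[[i]]$diag
      ts <- starts_t[i]; te <- ends_t[i]
      gs <- ts + d; ge <- te + d
      if (gs < 0L) { ts <- ts - gs; gs <- 0L }
      if (ge > nchar(gseq)) { te <- te - (ge - nchar(gseq))
                              ge <- nchar(gseq) }
      if (te <= ts) return(NULL)
      ex[[i]] <- data.frame(rank = i, t_start = ts, t_end = te,
                            start = gs, end = ge, stringsAsFactors = FALSE)
    }
    ex <- do.call(rbind, ex)
    spliced <- paste(substring(gseq, ex$start + 1L, ex$end), collapse = "")
    tpart <- paste(substring(transcript, ex$t_start + 1L, ex$t_end),
                   collapse = "")
    ident <- hamming_identity(tpart, spliced)
    cover <- sum(ex$t_end - ex$t_start) / lt
    list(exons = ex, identity = ident, coverage = cover,
         n_introns = nrow(ex) - 1L)
  }
  plus <- try_strand(scaffold)
  minus <- try_strand(reverse_complement(scaffold))
  score <- function(r) if (is.null(r)) -Inf else r$coverage * r$identity
  use_minus <- score(minus) > score(plus)
  res <- if (use_minus) minus else plus
  if (is.null(res) || res$coverage < min_coverage ||
      res$identity < 0.8) {
    reason <- if (is.null(res)) "no anchor chain" else
      sprintf("coverage %.2f or identity %.2f below threshold",
              res$coverage, res$identity)
    if (getOption("clemine.verbose", FALSE)) {
      message("spliced_align: no model (", reason, ")")
    }
    return(NULL)
  }
  if (use_minus) {
    ex <- res$exons
    new_start <- lg - ex$end
    ex$end <- lg - ex$start
    ex$start <- new_start
    res$exons <- ex
    res$strand <- "-"
  } else {
    res$strand <- "+"
  }
  res
}

## ---- gene models ------------------------------------------------------

new_gene_model <- function(id, scaffold, strand, family, exons, cds,
                           protein, motif_aa = NULL, source = "est") {
  structure(list(id = id, scaffold = scaffold, strand = strand,
                 family = family, exons = exons, cds = cds,
                 protein = protein, motif_aa = motif_aa, source = source),
            class = "gene_model")
}

# gene-space <-> forward-strand coordinate transforms for an interval
to_gene_space <- function(iv, strand, L) {
  if (strand == "+") iv else c(L - iv[2L], L - iv[1L])
}

#' Extract and splice a gene model's CDS from its scaffold
#'
#' @param model A `gene_model`.
#' @param scaffold_seq Forward-strand scaffold sequence.
#' @return The spliced CDS (sense strand).
#' @export
model_cds_seq <- function(model, scaffold_seq) {
  rr <- model$cds[order(model$cds$rank), , drop = FALSE]
  splice_exons(scaffold_seq, rr$start, rr$end, model$strand)
}

#' Call intronless genes from genomic motif hits
#'
#' Each motif hit is extended to its enclosing stop-to-stop open reading
#' frame in the hit frame; candidate Met initiators are screened with the
#' genomic selection rule (any Met with a predicted signal peptide between
#' the Met and the motif). Accepted ORFs become single-exon gene models.
#'
#' @param scaffold `list`/`data.frame` row with `id` and `sequence`.
#' @param hits Motif hits on this scaffold from [scan_motifs()].
#' @param threshold Signal-peptide decision threshold.
#' @return List of `gene_model` objects (possibly empty).
#' @export
call_intronless_genes <- function(scaffold, hits, threshold = 0.58) {
  sseq <- scaffold$sequence
  L <- nchar(sseq)
  hits <- hits[hits$subject == scaffold$id, , drop = FALSE]
  if (!nrow(hits)) return(list())
  frames <- translate_six_frames(sseq)
  out <- list()
  seen <- character()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    fp <- frames[[h$frame]]
    k <- as.integer(substr(h$frame, 2L, 2L))
    plus <- substr(h$frame, 1L, 1L) == "+"
    aa_start <- if (plus) (h$start - (k - 1L)) %/% 3L + 1L else
      ((L - h$end) - (k - 1L)) %/% 3L + 1L
    # enclosing ORF (stop-to-stop)
    ups <- gregexpr("*", substr(fp, 1L, aa_start - 1L), fixed = TRUE)[[1L]]
    orf_a <- if (ups[1L] == -1L) 1L else max(ups) + 1L
    dn <- regexpr("*", substr(fp, aa_start, nchar(fp)), fixed = TRUE)
    orf_b <- if (dn < 0L) nchar(fp) else aa_start + dn - 2L
    has_stop <- dn > 0L
    orf <- substr(fp, orf_a, orf_b)
    motif_rel <- aa_start - orf_a                    # 0-based in ORF
    call <- call_genomic_candidate(orf, motif_rel, threshold)
    if (!call$accept) next
    met <- call$met_index                            # 0-based in ORF
    # CDS in frame space: from the Met codon through the stop codon
    aa_from <- orf_a + met                           # 1-based aa
    aa_to <- orf_b + if (has_stop) 1L else 0L        # include stop codon
    fs <- (k - 1L) + 3L * (aa_from - 1L)             # 0-based frame-space nt
    fe <- (k - 1L) + 3L * aa_to
    iv <- if (plus) c(fs, fe) else c(L - fe, L - fs)
    key <- sprintf("%s:%s:%d-%d", scaffold$id, h$frame, iv[1L], iv[2L])
    if (key %in% seen) next
    seen <- c(key, seen)
    protein <- substr(orf, met + 1L, nchar(orf))
    cds <- data.frame(rank = 1L, start = iv[1L], end = iv[2L],
                      stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- new_gene_model(
      id = sprintf("%s_g%d", scaffold$id, length(out) + 1L),
      scaffold = scaffold$id, strand = if (plus) "+" else "-",
      family = h$family, exons = cds, cds = cds, protein = protein,
      motif_aa = c(motif_rel - met, motif_rel - met +
                     nchar(gsub("-", "", h$peptide))),
      source = "genomic")
  }
  out
}

#' Detect alternative 3'-terminal acceptor exons
#'
#' Scans the interior of the terminal coding exon for AG^GTA donor
#' contexts (exon ends ...AG, genomic continuation begins GTA). For each
#' donor, acceptor AG dinucleotides preceded by a polypyrimidine tract
#' (>= 6 pyrimidines in the preceding 8 nt) within `window` nt downstream
#' are examined: the candidate terminal exon must continue the reading
#' frame, reach a stop codon, and end with a 13-16 aa Asp/Glu-Tyr peptide
#' immediately before the stop. Candidate variants encoding the primary
#' transcript's own peptide, or a peptide already emitted (5'-most
#' acceptor wins), are discarded, so every reported variant carries a
#' distinct peptide.
#'
#' @param model A `gene_model` (CLEL family) with CDS rows.
#' @param scaffold_seq Forward-strand scaffold sequence.
#' @param window Maximum donor-to-acceptor search distance (nt).
#' @param min_intron Minimum alternative intron length (nt).
#' @return `data.frame` of transcript variants, the primary transcript
#'   first: `variant`, `donor`, `acceptor` (forward-strand boundary
#'   coordinates, NA for the primary), `peptide`, `protein`.
#' @export
find_alt_terminal_exons <- function(model, scaffold_seq, window = 5000L,
                                    min_intron = 40L) {
  L <- nchar(scaffold_seq)
  gseq <- if (model$strand == "+") scaffold_seq else
    reverse_complement(scaffold_seq)
  primary_pep <- clel_peptide_of(model$protein)
  prim <- data.frame(variant = "primary", donor = NA_integer_,
                     acceptor = NA_integer_, peptide = primary_pep,
                     protein = model$protein, stringsAsFactors = FALSE)
  cds <- model$cds[order(model$cds$rank), , drop = FALSE]
  gs_cds <- t(vapply(seq_len(nrow(cds)), function(i) {
    to_gene_space(c(cds$start[i], cds$end[i]), model$strand, L)
  }, numeric(2)))
  # in gene space rank order must be ascending
  if (nrow(gs_cds) > 1L && gs_cds[1L, 1L] > gs_cds[2L, 1L]) {
    stop("find_alt_terminal_exons: inconsistent CDS ranks")
  }
  term <- gs_cds[nrow(gs_cds), ]
  prefix_before_term <- if (nrow(gs_cds) > 1L) {
    sum(gs_cds[-nrow(gs_cds), 2L] - gs_cds[-nrow(gs_cds), 1L])
  } else 0
  prefix_seq_before <- if (nrow(gs_cds) > 1L) {
    paste(substring(gseq, gs_cds[-nrow(gs_cds), 1L] + 1L,
                    gs_cds[-nrow(gs_cds), 2L]), collapse = "")
  } else ""
  out <- list(prim)
  seen <- primary_pep
  # donors strictly inside the terminal coding exon
  term_seq <- substr(gseq, term[1L] + 1L, term[2L])
  dh <- gregexpr("AGGTA", term_seq, fixed = TRUE)[[1L]]
  if (dh[1L] == -1L) return(do.call(rbind, out))
  donors <- dh + term[1L] + 1L                       # 0-based intron starts
  donors <- donors[donors > term[1L] + 1L & donors < term[2L] - 3L]
  for (p in donors) {
    prefix_nt <- paste0(prefix_seq_before,
                        substr(gseq, term[1L] + 1L, p))
    lim <- min(nchar(gseq), p + window)
    region <- substr(gseq, p + 1L, lim)
    ags <- gregexpr("AG", region, fixed = TRUE)[[1L]]
    if (ags[1L] == -1L) next
    accs <- ags + p + 1L                             # 0-based exon starts
    accs <- accs[accs - p >= min_intron & accs - 10L >= 0L]
    for (q in accs) {
      tract <- substr(gseq, q - 9L, q - 2L)
      if (nchar(gsub("[CT]", "", tract)) > 2L) next
      tail_seq <- substr(gseq, q + 1L, min(nchar(gseq), q + 3L * 120L + 2L))
      aa_all <- translate_frame1(paste0(prefix_nt, tail_seq))
      st <- regexpr("*", aa_all, fixed = TRUE)
      if (st < 0L) next
      pep_region <- substr(aa_all, 1L, st - 1L)
      n_aa <- nchar(pep_region)
      pep <- NA_character_
      for (kk in 16:13) {
        if (n_aa >= kk &&
            substr(pep_region, n_aa - kk + 1L, n_aa - kk + 1L) %in%
              c("D", "E") &&
            substr(pep_region, n_aa - kk + 2L, n_aa - kk + 2L) == "Y") {
          pep <- substr(pep_region, n_aa - kk + 1L, n_aa)
          break
        }
      }
      if (is.na(pep) || pep %in% seen) next
      seen <- c(seen, pep)
      donor_fwd <- if (model$strand == "+") p else L - p
      acc_fwd <- if (model$strand == "+") q else L - q
      out[[length(out) + 1L]] <- data.frame(
        variant = sprintf("alt%d", length(out)), donor = donor_fwd,
        acceptor = acc_fwd, peptide = pep, protein = pep_region,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# trailing Asp/Glu-Tyr peptide (13-16 aa) of a CLEL precursor, NA if none
clel_peptide_of <- function(protein) {
  n <- nchar(protein)
  for (k in 16:13) {
    if (n >= k && substr(protein, n - k + 1L, n - k + 1L) %in% c("D", "E") &&
        substr(protein, n - k + 2L, n - k + 2L) == "Y") {
      return(substr(protein, n - k + 1L, n))
    }
  }
  NA_character_
}

#' Write gene models to GFF3
#'
#' @param models List of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
models_to_gff3 <- function(models, path) {
  rows <- list()
  for (m in models) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = m$scaffold, source = "clemine", type = "gene",
      start = min(m$exons$start), end = max(m$exons$end), score = ".",
      strand = m$strand, phase = ".",
      attributes = sprintf("ID=%s;family=%s", m$id, m$family),
      stringsAsFactors = FALSE)
    for (tt in c("exon", "CDS")) {
      src <- if (tt == "exon") m$exons else m$cds
      for (i in seq_len(nrow(src))) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = m$scaffold, source = "clemine", type = tt,
          start = src$start[i], end = src$end[i], score = ".",
          strand = m$strand, phase = ".",
          attributes = sprintf("Parent=%s", m$id),
          stringsAsFactors = FALSE)
      }
    }
  }
  write_gff3(do.call(rbind, rows), path)
}
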