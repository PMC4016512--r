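# generate_dataset(): assemble planted loci into scaffolds, derive
# transcripts and ESTs, and record the ground-truth manifest.

flip_iv <- function(iv, L) c(L - iv[2L], L - iv[1L])

# splice exon rows (already in 5'->3' transcript order) out of a scaffold
splice_exons <- function(scaffold_seq, starts, ends, strand) {
  segs <- substring(scaffold_seq, starts + 1L, ends)
  if (strand == "-") segs <- reverse_complement(segs)
  paste(segs, collapse = "")
}

apply_est_errors <- function(seq, sub_rate, indel_rate) {
  b <- strsplit(seq, "")[[1L]]
  n_sub <- 0L
  if (sub_rate > 0) {
    hit <- which(stats::runif(length(b)) < sub_rate)
    for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
    n_sub <- length(hit)
  }
  n_ind <- 0L
  if (indel_rate > 0) {
    hit <- which(stats::runif(length(b)) < indel_rate)
    for (i in rev(hit)) {            # right-to-left so indices stay valid
      if (stats::runif(1L) < 0.5) {
        b <- append(b, sample(c("A", "C", "G", "T"), 1L), after = i)
      } else {
        b <- b[-i]
      }
    }
    n_ind <- length(hit)
  }
  list(seq = paste(b, collapse = ""), n_sub = n_sub, n_indel = n_ind)
}

#' Generate a synthetic scaffold/EST dataset with ground truth
#'
#' Plants CLE and CLEL gene loci on random scaffolds for each species,
#' derives mature transcripts (including alternative 3'-terminal-exon
#' variants for flagged CLEL genes) and error-bearing ESTs, and returns a
#' manifest recording every planted feature. Deterministic for a fixed
#' config (the config's `seed` is applied on entry).
#'
#' @param config A [synth_config()] object.
#' @return A list of class `synth_dataset` with elements `scaffolds` (id,
#'   sequence, species), `ests` (ESTRecord data frame), and `manifest`
#'   (class `truth_manifest`: `genes`, `transcripts`, `exons`, `ests`
#'   data frames plus the config).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_species > 26L) stop("generate_dataset: at most 26 species")
  set.seed(config$seed)
  cfg <- config
  species <- sprintf("Pinopsida_synthetica_%s", LETTERS[seq_len(cfg$n_species)])
  sp_abbr <- sprintf("sp%s", LETTERS[seq_len(cfg$n_species)])

  used_peps <- cfg$exclude_peptides
  n_alt <- round(cfg$clel_alt_fraction * cfg$n_clel_genes)

  # ancestral archetypes, shared across species
  cle_arch <- vector("list", cfg$n_cle_genes)
  for (g in seq_len(cfg$n_cle_genes)) {
    pep <- if (g == 1L) TDIF_PEPTIDE else
      sample_cle_peptide(exclude = c(used_peps, TDIF_PEPTIDE))
    used_peps <- c(used_peps, pep)
    spp <- make_signal_peptide()
    sp_len <- nchar(spp$seq)
    ncs2_len <- if (stats::runif(1L) < cfg$cle_ncs2_prob)
      sample(1:12, 1L) else 0L
    lo <- max(40L, 80L - sp_len - 14L - ncs2_len)
    hi <- 100L - sp_len - 14L - ncs2_len
    if (hi < lo) { ncs2_len <- 0L; lo <- max(40L, 80L - sp_len - 14L)
                   hi <- 100L - sp_len - 14L }
    ncs1_len <- sample(seq.int(lo, hi), 1L)
    ncs1 <- paste0(random_protein(2L, mature_start_pool),
                   random_protein(ncs1_len - 2L))
    motif <- paste0(random_protein(2L, c("R", "K", "H")), pep)
    ncs2 <- random_protein(ncs2_len)
    precursor <- paste0(spp$seq, ncs1, motif, ncs2)
    cle_arch[[g]] <- list(precursor = precursor, sp_len = sp_len,
                          peptide = pep,
                          motif_window = c(sp_len + ncs1_len,
                                           sp_len + ncs1_len + 14L))
  }
  clel_arch <- vector("list", cfg$n_clel_genes)
  for (g in seq_len(cfg$n_clel_genes)) {
    alt_flag <- g <= n_alt
    spp <- make_signal_peptide()
    sp_len <- nchar(spp$seq)
    ncs1_len <- sample(seq.int(cfg$clel_ncs1_range[1L],
                               cfg$clel_ncs1_range[2L]), 1L)
    p1 <- sample_clel_peptide(exclude = used_peps)
    used_peps <- c(used_peps, p1)
    ncs1 <- paste0(random_protein(2L, mature_start_pool),
                   random_protein(ncs1_len - 2L))
    e1_aa <- sp_len + max(3L, round(ncs1_len / 3))
    d_aa <- sp_len + max(e1_aa - sp_len + 3L, round(2 * ncs1_len / 3))
    alt <- NULL
    if (alt_flag) {
      # donor codon ends AG, next codon is GTA(Val)
      substr(ncs1, d_aa - sp_len, d_aa - sp_len) <-
        sample(c("K", "E", "Q"), 1L)
      substr(ncs1, d_aa - sp_len + 1L, d_aa - sp_len + 1L) <- "V"
      p2 <- sample_clel_peptide(exclude = used_peps)
      used_peps <- c(used_peps, p2)
      alt <- list(linker = random_protein(sample(3:8, 1L),
                                          c("S", "N", "T", "Q", "R", "K",
                                            "H", "L", "P")),
                  peptide = p2)
    }
    precursor <- paste0(spp$seq, ncs1, p1)
    clel_arch[[g]] <- list(precursor = precursor, sp_len = sp_len,
                           peptide = p1, e1_aa = e1_aa, d_aa = d_aa,
                           alt = alt,
                           motif_window = c(sp_len + ncs1_len,
                                            nchar(precursor)))
  }

  # per-gene home tissue
  cle_tissue <- c("bark/phloem",
                  sample(TISSUE_VOCAB, max(0L, cfg$n_cle_genes - 1L),
                         replace = TRUE))
  clel_tissue <- sample(setdiff(TISSUE_VOCAB, "xylem"),
                        max(1L, cfg$n_clel_genes), replace = TRUE)

  genes <- list(); txs <- list(); exon_rows <- list(); est_rows <- list()
  scaff <- list()
  est_counter <- 0L

  for (s in seq_len(cfg$n_species)) {
    plan <- list()
    for (g in seq_len(cfg$n_cle_genes)) {
      arch <- cle_arch[[g]]
      prec <- if (s == 1L || (s == 2L && g == 1L)) arch$precursor else
        mutate_orthologue(arch$precursor, cfg$orthologue_divergence,
                          conserve_motif = TRUE,
                          motif_window = arch$motif_window,
                          protect = seq_len(arch$sp_len + 2L))
      plan[[length(plan) + 1L]] <-
        list(family = "CLE", g = g, precursor = prec, arch = arch,
             tissue = cle_tissue[g])
    }
    for (g in seq_len(cfg$n_clel_genes)) {
      arch <- clel_arch[[g]]
      protect <- c(seq_len(arch$sp_len + 2L),
                   if (!is.null(arch$alt)) c(arch$d_aa, arch$d_aa + 1L))
      prec <- if (s == 1L) arch$precursor else
        mutate_orthologue(arch$precursor, cfg$orthologue_divergence,
                          conserve_motif = TRUE,
                          motif_window = arch$motif_window,
                          protect = protect)
      alt <- arch$alt
      if (!is.null(alt) && s > 1L) {
        tail_s <- mutate_orthologue(paste0(alt$linker, alt$peptide),
                                    cfg$orthologue_divergence,
                                    conserve_motif = TRUE,
                                    motif_window = c(nchar(alt$linker),
                                                     nchar(alt$linker) +
                                                       nchar(alt$peptide)))
        alt <- list(linker = substr(tail_s, 1L, nchar(alt$linker)),
                    peptide = alt$peptide)
      }
      plan[[length(plan) + 1L]] <-
        list(family = "CLEL", g = g, precursor = prec, arch = arch,
             alt = alt, tissue = clel_tissue[g])
    }
    if (cfg$plant_duplicate_pair && s == 1L && cfg$n_cle_genes >= 2L) {
      dup <- plan[[2L]]
      dup$dup_of <- 2L
      plan[[length(plan) + 1L]] <- dup
    }

    # pack loci into scaffolds, two per scaffold
    order_idx <- sample(seq_along(plan))
    scf_of <- ceiling(seq_along(order_idx) / 2)
    for (k in unique(scf_of)) {
      scf_id <- sprintf("scf_%s_%02d", sp_abbr[s], k)
      seq_acc <- random_dna(sample(80:200, 1L), cfg$gc_content)
      for (idx in order_idx[scf_of == k]) {
        item <- plan[[idx]]
        strand <- sample(c("+", "-"), 1L)
        loc <- if (item$family == "CLE") {
          build_cle_locus(item$precursor, item$arch$sp_len, cfg$gc_content)
        } else {
          build_clel_locus(item$precursor, item$arch$sp_len,
                           item$arch$e1_aa, item$arch$d_aa, item$alt, cfg,
                           primary_peptide = item$arch$peptide)
        }
        L <- nchar(loc$seq)
        off <- nchar(seq_acc)
        gene_id <- if (!is.null(item$dup_of)) {
          sprintf("%s%02dd_%s", item$family, item$g, sp_abbr[s])
        } else sprintf("%s%02d_%s", item$family, item$g, sp_abbr[s])
        gseq <- if (strand == "+") loc$seq else reverse_complement(loc$seq)
        tx_names <- names(loc$transcripts)
        pep_all <- character()
        for (ti in seq_along(loc$transcripts)) {
          tr <- loc$transcripts[[ti]]
          tx_id <- sprintf("%s.t%d", gene_id, ti)
          tx_seq <- paste(substring(loc$seq,
                                    vapply(tr$tx_exons, `[`, 0, 1L) + 1L,
                                    vapply(tr$tx_exons, `[`, 0, 2L)),
                          collapse = "")
          # transform exon coords to scaffold forward strand
          mk_rows <- function(ivs, type) {
            n <- length(ivs)
            out <- lapply(seq_len(n), function(r) {
              iv <- ivs[[r]]
              if (strand == "-") iv <- flip_iv(iv, L)
              data.frame(transcript_id = tx_id, gene_id = gene_id,
                         scaffold = scf_id, strand = strand, type = type,
                         rank = r, start = iv[1L] + off, end = iv[2L] + off,
                         stringsAsFactors = FALSE)
            })
            do.call(rbind, out)
          }
          exon_rows[[length(exon_rows) + 1L]] <- mk_rows(tr$tx_exons, "exon")
          exon_rows[[length(exon_rows) + 1L]] <- mk_rows(tr$cds_exons, "CDS")
          pep <- if (item$family == "CLE") item$arch$peptide else
            if (tx_names[ti] == "primary") item$arch$peptide else
              item$alt$peptide
          pep_all <- c(pep_all, pep)
          donor_fwd <- NA_integer_
          if (!is.null(tr$donor)) {
            donor_fwd <- if (strand == "+") tr$donor + off else
              off + (L - tr$donor)
          }
          txs[[length(txs) + 1L]] <- data.frame(
            transcript_id = tx_id, gene_id = gene_id,
            variant = tx_names[ti], protein = tr$protein, peptide = pep,
            n_exons = length(tr$tx_exons), donor = donor_fwd,
            sequence = tx_seq, stringsAsFactors = FALSE)
          # ESTs
          for (e in seq_len(cfg$ests_per_transcript)) {
            est_counter <- est_counter + 1L
            if (cfg$est_full_length) {
              a <- 0L; b <- nchar(tx_seq)
            } else {
              len <- min(nchar(tx_seq),
                         sample(seq.int(cfg$est_length_range[1L],
                                        cfg$est_length_range[2L]), 1L))
              a <- sample.int(nchar(tx_seq) - len + 1L, 1L) - 1L
              b <- a + len
            }
            err <- apply_est_errors(substr(tx_seq, a + 1L, b),
                                    cfg$est_error_rate, cfg$est_indel_rate)
            lib <- item$tissue
            if (cfg$plant_tissue_overlap && s == 1L &&
                item$family == "CLE" && item$g == 2L &&
                is.null(item$dup_of)) {
              lib <- if (e %% 2L == 0L) "xylem" else "bark/phloem"
            }
            est_rows[[length(est_rows) + 1L]] <- data.frame(
              est_id = sprintf("SYNEST%05d", est_counter),
              transcript_id = tx_id, gene_id = gene_id,
              species = species[s], library = lib,
              tx_start = a, tx_end = b, n_sub = err$n_sub,
              n_indel = err$n_indel, sequence = err$seq,
              stringsAsFactors = FALSE)
          }
        }
        gene_iv <- range(unlist(lapply(loc$tx_exons, function(iv) {
          if (strand == "-") flip_iv(iv, L) else iv
        }))) + off
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gene_id, family = item$family, species = species[s],
          scaffold = scf_id, strand = strand,
          gene_start = gene_iv[1L], gene_end = gene_iv[2L],
          sp_cleavage = item$arch$sp_len, precursor = item$precursor,
          peptides = paste(unique(pep_all), collapse = ";"),
          n_introns = length(loc$tx_exons) - 1L,
          alt = length(loc$transcripts) > 1L, tissue = item$tissue,
          stringsAsFactors = FALSE)
        seq_acc <- paste0(seq_acc, gseq,
                          random_dna(sample(80:200, 1L), cfg$gc_content))
      }
      scaff[[length(scaff) + 1L]] <- data.frame(
        id = scf_id, sequence = seq_acc, species = species[s],
        assembly = "synthetic", stringsAsFactors = FALSE)
    }
  }

  # query set emulating known homologous motifs from a reference flora:
  # each archetype's motif diverged at the configured query divergence
  qrows <- list()
  for (g in seq_len(cfg$n_cle_genes)) {
    mw <- cle_arch[[g]]$motif_window
    motif <- substr(cle_arch[[g]]$precursor, mw[1L] + 1L, mw[2L])
    qrows[[length(qrows) + 1L]] <- data.frame(
      name = sprintf("QRY_CLE%02d", g),
      peptide = mutate_orthologue(motif, cfg$query_divergence,
                                  conserve_motif = FALSE),
      family = "CLE", stringsAsFactors = FALSE)
  }
  for (g in seq_len(cfg$n_clel_genes)) {
    qrows[[length(qrows) + 1L]] <- data.frame(
      name = sprintf("QRY_CLEL%02d", g),
      peptide = mutate_orthologue(clel_arch[[g]]$peptide,
                                  cfg$query_divergence,
                                  conserve_motif = FALSE),
      family = "CLEL", stringsAsFactors = FALSE)
    if (!is.null(clel_arch[[g]]$alt)) {
      qrows[[length(qrows) + 1L]] <- data.frame(
        name = sprintf("QRY_CLEL%02da", g),
        peptide = mutate_orthologue(clel_arch[[g]]$alt$peptide,
                                    cfg$query_divergence,
                                    conserve_motif = FALSE),
        family = "CLEL", stringsAsFactors = FALSE)
    }
  }
  queries <- if (length(qrows)) do.call(rbind, qrows) else
    data.frame(name = character(), peptide = character(),
               family = character(), stringsAsFactors = FALSE)

  manifest <- list(genes = do.call(rbind, genes),
                   transcripts = do.call(rbind, txs),
                   exons = do.call(rbind, exon_rows),
                   ests = do.call(rbind, est_rows),
                   queries = queries,
                   config = cfg)
  class(manifest) <- "truth_manifest"
  ests <- manifest$ests[, c("est_id", "species", "library", "sequence")]
  names(ests)[1L] <- "id"
  ests$source <- "synthetic"
  out <- list(scaffolds = do.call(rbind, scaff), ests = ests,
              queries = queries, manifest = manifest)
  class(out) <- "synth_dataset"
  out
}

#' Check internal consistency of a truth manifest
#'
#' Verifies, for every transcript: spliced CDS exons translate to the
#' stored protein (plus terminal stop); every planted intron begins GT and
#' ends AG; exon coordinates are ordered and non-overlapping.
#'
#' @param dataset A `synth_dataset`.
#' @return Invisibly TRUE; stops with a message on any violation.
#' @export
validate_manifest <- function(dataset) {
  man <- dataset$manifest
  scf <- stats::setNames(dataset$scaffolds$sequence, dataset$scaffolds$id)
  for (tx in man$transcripts$transcript_id) {
    rows <- man$exons[man$exons$transcript_id == tx, ]
    strand <- rows$strand[1L]
    sseq <- scf[[rows$scaffold[1L]]]
    for (type in c("exon", "CDS")) {
      rr <- rows[rows$type == type, ]
      rr <- rr[order(rr$rank), ]
      fwd <- rr[order(rr$start), ]
      if (any(fwd$start[-1L] < fwd$end[-nrow(fwd)])) {
        stop("manifest: overlapping ", type, " intervals in ", tx)
      }
      if (type == "CDS") {
        cds <- splice_exons(sseq, rr$start, rr$end, strand)
        prot <- man$transcripts$protein[man$transcripts$transcript_id == tx]
        got <- translate_frame1(cds)
        if (got != paste0(prot, "*")) {
          stop("manifest: CDS of ", tx, " does not translate to its protein")
        }
      }
      if (type == "exon" && nrow(rr) > 1L) {
        for (i in seq_len(nrow(rr) - 1L)) {
          a <- rr[i, ]; b <- rr[i + 1L, ]
          intron <- if (strand == "+") {
            substr(sseq, a$end + 1L, b$start)
          } else {
            reverse_complement(substr(sseq, b$end + 1L, a$start))
          }
          if (substr(intron, 1L, 2L) != "GT" ||
              substr(intron, nchar(intron) - 1L, nchar(intron)) != "AG") {
            stop("manifest: non-canonical intron in ", tx)
          }
        }
      }
    }
  }
  invisible(TRUE)
}

#' Write a synthetic dataset to disk
#'
#' Emits scaffolds and ESTs as FASTA (EST headers carry `species=` and
#' `library=` tags), the manifest tables as TSV, gene models as GFF3
#' (1-based inclusive), and the config as YAML.
#'
#' @param dataset A `synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$scaffolds, file.path(dir, "scaffolds.fasta"))
  write_fasta(dataset$ests, file.path(dir, "ests.fasta"))
  man <- dataset$manifest
  for (nm in c("genes", "transcripts", "exons", "ests")) {
    utils::write.table(man[[nm]], file.path(dir, paste0("manifest_", nm,
                                                        ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ex <- man$exons
  gff <- rbind(
    data.frame(seqid = man$genes$scaffold, source = "clemine",
               type = "gene", start = man$genes$gene_start,
               end = man$genes$gene_end, score = ".",
               strand = man$genes$strand, phase = ".",
               attributes = paste0("ID=", man$genes$gene_id),
               stringsAsFactors = FALSE),
    data.frame(seqid = ex$scaffold, source = "clemine",
               type = ifelse(ex$type == "CDS", "CDS", "exon"),
               start = ex$start, end = ex$end, score = ".",
               strand = ex$strand, phase = ".",
               attributes = paste0("Parent=", ex$transcript_id),
               stringsAsFactors = FALSE))
  write_gff3(gff, file.path(dir, "manifest.gff3"))
  cfg <- unclass(man$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
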