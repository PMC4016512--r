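# End-to-end orchestration: simulate -> translated motif scan -> contig
# assembly -> signal-peptide gate -> gene models (genomic intronless calls
# and spliced EST alignment, with alternative terminal-exon detection) ->
# mature-peptide catalog -> phylogenetics, plus a recovery report scoring
# every stage against the ground-truth manifest.

# cheap k-mer vote: which transcript does a contig consensus derive from?
best_transcript_match <- function(consensus, transcripts, k = 21L) {
  if (nchar(consensus) < k) return(NA_integer_)
  pos <- seq.int(1L, nchar(consensus) - k + 1L,
                 by = max(1L, (nchar(consensus) - k) %/% 20L))
  kmers <- substring(consensus, pos, pos + k - 1L)
  votes <- vapply(transcripts, function(tx) {
    sum(vapply(kmers, function(km) grepl(km, tx, fixed = TRUE), logical(1)))
  }, numeric(1))
  if (max(votes) == 0) NA_integer_ else which.max(votes)
}

# forward-strand intron intervals of an exon table (rank-ordered rows)
intron_set <- function(exons, scaffold, strand) {
  if (nrow(exons) < 2L) return(character())
  ex <- exons[order(exons$rank), , drop = FALSE]
  out <- character()
  for (i in seq_len(nrow(ex) - 1L)) {
    a <- ex[i, ]; b <- ex[i + 1L, ]
    iv <- if (strand == "+") c(a$end, b$start) else c(b$end, a$start)
    out <- c(out, sprintf("%s:%d-%d", scaffold, iv[1L], iv[2L]))
  }
  out
}

#' Run the full discovery pipeline on a synthetic dataset
#'
#' Stages, in fixed order: translated motif scan of the ESTs;
#' species-partitioned assembly of motif-positive ESTs; contig validation
#' and the full-length signal-peptide gate; a second-round scan with
#' discovered contig motifs; genomic intronless gene calling; spliced
#' alignment of contigs to scaffolds with alternative terminal-exon
#' detection; mature-peptide cataloguing; and (optionally) a bootstrap
#' Neighbour-Joining tree of the discovered precursors. Every stage's
#' record counts are logged in a funnel table and the outputs are scored
#' against the manifest.
#'
#' @param dataset A `synth_dataset` from [generate_dataset()], or `NULL`
#'   to generate one from `config`.
#' @param config A [synth_config()] (used when `dataset` is NULL).
#' @param min_identity,min_score Motif-scan thresholds.
#' @param bootstrap Bootstrap replicates for the phylogeny stage (0 skips
#'   the stage).
#' @param out_dir Optional directory for stage outputs (FASTA/TSV/GFF3/
#'   Newick).
#' @param reference Optional named vector of reference peptides for the
#'   conservation comparison.
#' @return List with stage outputs (`hits`, `contigs`, `gate`, `models`,
#'   `variants`, `catalog`, `compare`, `tally`, `tree`), the `funnel`
#'   count table, and `report` (precision/recall per category).
#' @export
run_pipeline <- function(dataset = NULL, config = NULL,
                         min_identity = 0.5, min_score = 40,
                         bootstrap = 0L, out_dir = NULL,
                         reference = NULL) {
  if (is.null(dataset)) {
    stopifnot(!is.null(config))
    dataset <- generate_dataset(config)
  }
  man <- dataset$manifest
  queries <- dataset$queries
  scaffolds <- dataset$scaffolds
  funnel <- list(n_ests = nrow(dataset$ests),
                 n_scaffolds = nrow(scaffolds))

  ## stage 1: translated motif scan of the ESTs
  hits1 <- scan_motifs(stats::setNames(dataset$ests$sequence,
                                       dataset$ests$id),
                       queries, min_identity, min_score)
  funnel$n_est_hits_round1 <- length(unique(hits1$subject))

  ## stage 2: assemble motif-positive ESTs by species
  positive <- dataset$ests[dataset$ests$id %in% hits1$subject, ,
                           drop = FALSE]
  contigs <- if (nrow(positive)) assemble(positive) else list()
  funnel$n_contigs <- length(contigs)

  ## stage 3: per-contig motif confirmation, validation, full-length gate
  gate <- list()
  discovered <- list()
  kept <- list()
  for (ct in contigs) {
    chits <- scan_motifs(stats::setNames(ct$consensus, ct$id), queries,
                         min_identity, min_score)
    val <- validate_contig(ct, chits)
    if (!val$accept) next
    best <- chits[which.max(chits$score), ]
    frames <- translate_six_frames(ct$consensus)
    g <- full_length_gate(frames[[best$frame]])
    kept[[length(kept) + 1L]] <- ct
    gate[[ct$id]] <- list(contig = ct$id, species = ct$species,
                          frame = best$frame, family = best$family,
                          status = g$status, reason = g$reason,
                          protein = g$protein)
    pep <- gsub("-", "", best$peptide)
    if (nchar(pep) >= 10L) {
      discovered[[length(discovered) + 1L]] <- data.frame(
        name = paste0("DISC_", ct$id), peptide = pep,
        family = best$family, stringsAsFactors = FALSE)
    }
  }
  contigs <- kept
  funnel$n_validated_contigs <- length(contigs)
  funnel$n_full_length <- sum(vapply(gate, function(g)
    g$status == "full-length", logical(1)))
  discovered <- if (length(discovered)) do.call(rbind, discovered) else
    queries[0, ]

  ## stage 4: second-round scan (original + discovered motifs), re-assemble
  hits2 <- iterate_search(stats::setNames(dataset$ests$sequence,
                                          dataset$ests$id),
                          queries, discovered, min_identity, min_score)
  funnel$n_est_hits_round2 <- length(unique(hits2$subject))
  if (length(setdiff(unique(hits2$subject), unique(hits1$subject))) > 0L) {
    positive <- dataset$ests[dataset$ests$id %in% hits2$subject, ,
                             drop = FALSE]
    contigs <- assemble(positive)
    gate <- list()
    kept <- list()
    for (ct in contigs) {
      chits <- scan_motifs(stats::setNames(ct$consensus, ct$id),
                           rbind(queries, discovered), min_identity,
                           min_score)
      val <- validate_contig(ct, chits)
      if (!val$accept) next
      best <- chits[which.max(chits$score), ]
      frames <- translate_six_frames(ct$consensus)
      g <- full_length_gate(frames[[best$frame]])
      kept[[length(kept) + 1L]] <- ct
      gate[[ct$id]] <- list(contig = ct$id, species = ct$species,
                            frame = best$frame, family = best$family,
                            status = g$status, reason = g$reason,
                            protein = g$protein)
    }
    contigs <- kept
    funnel$n_validated_contigs <- length(contigs)
  }

  ## stage 5: genomic intronless gene calling (CLE route)
  all_queries <- rbind(queries, discovered)
  ghits <- scan_motifs(scaffolds, all_queries, min_identity, min_score)
  models <- list()
  for (i in seq_len(nrow(scaffolds))) {
    models <- c(models, call_intronless_genes(as.list(scaffolds[i, ]),
                                              ghits))
  }
  funnel$n_genomic_models <- length(models)

  ## stage 6: spliced alignment of contigs -> models; alt terminal exons
  scf_seq <- stats::setNames(scaffolds$sequence, scaffolds$id)
  scf_species <- stats::setNames(scaffolds$species, scaffolds$id)
  est_models <- list()
  variants <- list()
  for (ct in contigs) {
    info <- gate[[ct$id]]
    if (is.null(info)) next
    cand <- names(scf_seq)[scf_species == ct$species]
    best <- NULL
    for (sid in cand) {
      sa <- spliced_align(ct$consensus, scf_seq[[sid]])
      if (!is.null(sa)) {
        sc <- sa$coverage * sa$identity
        if (is.null(best) || sc > best$sc) best <- list(sa = sa, sid = sid,
                                                        sc = sc)
      }
    }
    if (is.null(best)) next
    sa <- best$sa
    # CDS: map the gate's Met..stop interval from transcript to genome
    if (info$status != "full-length") next
    prot <- info$protein
    cds_tx <- locate_cds_in_transcript(ct$consensus, prot, info$frame)
    if (is.null(cds_tx)) next
    cds_rows <- map_tx_interval(sa$exons, cds_tx, sa$strand,
                                nchar(scf_seq[[best$sid]]))
    if (is.null(cds_rows)) next
    mdl <- new_gene_model(
      id = paste0(ct$id, "_m"), scaffold = best$sid, strand = sa$strand,
      family = info$family,
      exons = sa$exons[, c("rank", "start", "end")], cds = cds_rows,
      protein = prot, source = "est")
    est_models[[length(est_models) + 1L]] <- mdl
    if (info$family == "CLEL") {
      vv <- find_alt_terminal_exons(mdl, scf_seq[[best$sid]])
      vv$gene <- mdl$id
      vv$scaffold <- best$sid
      variants[[length(variants) + 1L]] <- vv
    }
  }
  variants <- if (length(variants)) do.call(rbind, variants) else NULL
  funnel$n_est_models <- length(est_models)
  funnel$n_alt_variants <- if (is.null(variants)) 0L else
    sum(variants$variant != "primary")

  ## stage 7: mature-peptide catalog
  entries <- list()
  for (m in models) {                                # genomic CLE models
    pep <- cle_peptide_from_protein(m$protein, all_queries)
    if (is.na(pep)) next
    entries[[length(entries) + 1L]] <- data.frame(
      peptide = pep, family = m$family, gene_id = m$id,
      species = scf_species[[m$scaffold]], stringsAsFactors = FALSE)
  }
  if (!is.null(variants)) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      if (is.na(v$peptide)) next
      entries[[length(entries) + 1L]] <- data.frame(
        peptide = v$peptide, family = "CLEL",
        gene_id = paste0(v$gene, ".", v$variant),
        species = scf_species[[v$scaffold]], stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(entries)) do.call(rbind, entries) else
    data.frame(peptide = character(), family = character(),
               gene_id = character(), species = character(),
               stringsAsFactors = FALSE)
  catalog <- dedup_and_group(entries)
  funnel$n_unique_peptides <- nrow(catalog)
  compare <- if (!is.null(reference) && nrow(catalog)) {
    compare_to_reference(catalog, reference)
  } else NULL

  ## stage 8: expression tally over motif-positive ESTs via their contigs
  est_gene <- assign_ests_to_genes(contigs, est_models, models)
  tally <- if (nrow(est_gene)) {
    lib <- dataset$ests$library[match(est_gene$est_id, dataset$ests$id)]
    expression_tally(data.frame(gene_id = est_gene$gene_id, library = lib,
                                stringsAsFactors = FALSE))
  } else NULL

  ## stage 9: phylogeny of discovered precursors
  tree <- NULL
  if (bootstrap > 0L) {
    prots <- unique(vapply(c(models, est_models), `[[`, "", "protein"))
    names(prots) <- sprintf("prot%02d", seq_along(prots))
    if (length(prots) >= 4L) {
      msa <- progressive_align(prots)
      tree <- bootstrap_consensus(msa, replicates = bootstrap,
                                  seed = man$config$seed)
    }
  }

  report <- recovery_report(man, models, est_models, variants, catalog,
                            gate, scf_seq)
  out <- list(dataset = dataset, hits = hits2, contigs = contigs,
              gate = gate, models = models, est_models = est_models,
              variants = variants, catalog = catalog, compare = compare,
              tally = tally, tree = tree,
              funnel = as.data.frame(funnel), report = report)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  invisible(out)
}

# transcript-space CDS interval of the gated protein (0-based half-open),
# from the frame label of the gate and the Met index
locate_cds_in_transcript <- function(consensus, protein, frame) {
  k <- as.integer(substr(frame, 2L, 2L))
  seq_use <- if (substr(frame, 1L, 1L) == "+") consensus else
    reverse_complement(consensus)
  fp <- translate_frame1(substr(seq_use, k, nchar(seq_use)))
  hit <- regexpr(protein, fp, fixed = TRUE)
  if (hit < 0L) return(NULL)
  s <- (k - 1L) + 3L * (hit - 1L)
  e <- s + 3L * (nchar(protein) + 1L)                # include stop codon
  e <- min(e, nchar(consensus))
  if (substr(frame, 1L, 1L) == "+") c(s, e) else
    c(nchar(consensus) - e, nchar(consensus) - s)
}

# map a transcript interval through the exon chain to genomic CDS rows.
# Exon table rows carry transcript (t_start/t_end) and forward-strand
# genomic (start/end) coordinates.
map_tx_interval <- function(exons, iv, strand, scaffold_len) {
  rows <- list()
  for (i in seq_len(nrow(exons))) {
    ex <- exons[i, ]
    a <- max(iv[1L], ex$t_start)
    b <- min(iv[2L], ex$t_end)
    if (b <= a) next
    if (strand == "+") {
      gs <- ex$start + (a - ex$t_start)
      ge <- ex$start + (b - ex$t_start)
    } else {
      ge <- ex$end - (a - ex$t_start)
      gs <- ex$end - (b - ex$t_start)
    }
    rows[[length(rows) + 1L]] <- data.frame(rank = ex$rank, start = gs,
                                            end = ge,
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# the mature CLE dodecapeptide: family motifs are ungapped, so the 14-aa
# motif window is located by the best-scoring ungapped placement of any
# CLE query (BLOSUM62), and its final 12 aa are the peptide
cle_peptide_from_protein <- function(protein, queries) {
  qq <- queries[queries$family == "CLE", , drop = FALSE]
  # the CLE motif is 14 aa by definition; partial (trimmed) discovered
  # motifs would misplace the window end
  if (any(nchar(qq$peptide) == 14L)) {
    qq <- qq[nchar(qq$peptide) == 14L, , drop = FALSE]
  }
  if (!nrow(qq)) return(NA_character_)
  B <- get_blosum62()
  p <- strsplit(protein, "")[[1L]]
  best_sc <- -Inf
  best_end <- NA_integer_
  for (i in seq_len(nrow(qq))) {
    q <- strsplit(qq$peptide[i], "")[[1L]]
    L <- length(q)
    if (length(p) < L) next
    for (off in 0:(length(p) - L)) {
      sc <- sum(B[cbind(q, p[off + seq_len(L)])])
      if (sc > best_sc) { best_sc <- sc; best_end <- off + L }
    }
  }
  if (is.na(best_end) || best_end < 12L) return(NA_character_)
  substr(protein, best_end - 11L, best_end)
}

# EST -> predicted gene locus, via contig membership and the contig model
assign_ests_to_genes <- function(contigs, est_models, genomic_models) {
  rows <- list()
  model_by_contig <- stats::setNames(
    vapply(est_models, `[[`, "", "id"),
    vapply(est_models, function(m) sub("_m$", "", m$id), character(1)))
  for (ct in contigs) {
    gid <- model_by_contig[ct$id]
    if (is.na(gid)) next
    for (e in ct$members$id) {
      rows[[length(rows) + 1L]] <- data.frame(est_id = e, gene_id = gid,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(est_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# score pipeline outputs against the manifest
recovery_report <- function(man, models, est_models, variants, catalog,
                            gate, scf_seq) {
  genes <- man$genes
  # --- gene discovery (locus level): predicted loci vs manifest genes
  pred <- lapply(c(models, est_models), function(m) {
    list(scaffold = m$scaffold, strand = m$strand,
         lo = min(m$cds$start), hi = max(m$cds$end), family = m$family)
  })
  # deduplicate predicted loci (genomic + EST routes find the same gene)
  key <- vapply(pred, function(p) sprintf("%s:%s:%d-%d", p$scaffold,
                                          p$strand, p$lo, p$hi), "")
  pred <- pred[!duplicated(key)]
  # manifest CDS span per gene (primary transcript)
  gspan <- lapply(seq_len(nrow(genes)), function(i) {
    rows <- man$exons[man$exons$gene_id == genes$gene_id[i] &
                        man$exons$type == "CDS", ]
    list(scaffold = genes$scaffold[i], strand = genes$strand[i],
         lo = min(rows$start), hi = max(rows$end))
  })
  hit_gene <- rep(FALSE, nrow(genes))
  pred_ok <- rep(FALSE, length(pred))
  for (k in seq_along(pred)) {
    p <- pred[[k]]
    for (i in seq_len(nrow(genes))) {
      g <- gspan[[i]]
      if (p$scaffold == g$scaffold && p$strand == g$strand &&
          p$lo < g$hi && p$hi > g$lo) {
        hit_gene[i] <- TRUE
        pred_ok[k] <- TRUE
      }
    }
  }
  gene_recall <- mean(hit_gene)
  gene_precision <- if (length(pred)) mean(pred_ok) else NA_real_

  # --- full-length gate: recall = manifest precursors recovered verbatim
  # by a full-length call; precision = full-length calls whose protein is
  # a manifest precursor
  fl_prot <- unlist(lapply(gate, function(g) {
    if (g$status == "full-length") g$protein else character()
  }))
  fl_recall <- mean(unique(man$transcripts$protein) %in% fl_prot)
  fl_precision <- if (length(fl_prot))
    mean(fl_prot %in% man$transcripts$protein) else NA_real_

  # --- exon junctions (introns, exact coordinates)
  true_introns <- character()
  for (tx in unique(man$exons$transcript_id)) {
    rows <- man$exons[man$exons$transcript_id == tx &
                        man$exons$type == "exon", ]
    true_introns <- c(true_introns,
                      intron_set(rows, rows$scaffold[1L], rows$strand[1L]))
  }
  true_introns <- unique(true_introns)
  pred_introns <- character()
  for (m in est_models) {
    pred_introns <- c(pred_introns,
                      intron_set(m$exons, m$scaffold, m$strand))
  }
  if (!is.null(variants)) {
    av <- variants[variants$variant != "primary", , drop = FALSE]
    for (i in seq_len(nrow(av))) {
      iv <- sort(c(av$donor[i], av$acceptor[i]))
      pred_introns <- c(pred_introns,
                        sprintf("%s:%d-%d", av$scaffold[i], iv[1L], iv[2L]))
    }
  }
  pred_introns <- unique(pred_introns)
  junction_recall <- if (length(true_introns))
    mean(true_introns %in% pred_introns) else NA_real_
  junction_precision <- if (length(pred_introns))
    mean(pred_introns %in% true_introns) else NA_real_

  # --- alternative splice variants (by distinct non-primary peptide)
  true_alt <- unique(man$transcripts$peptide[man$transcripts$variant ==
                                               "alt"])
  pred_alt <- if (is.null(variants)) character() else
    unique(variants$peptide[variants$variant != "primary"])
  variant_recall <- if (length(true_alt))
    mean(true_alt %in% pred_alt) else NA_real_
  variant_precision <- if (length(pred_alt))
    mean(pred_alt %in% true_alt) else NA_real_

  # --- unique peptides
  true_peps <- unique(man$transcripts$peptide)
  got_peps <- unique(catalog$peptide)
  peptide_recall <- if (length(true_peps))
    mean(true_peps %in% got_peps) else NA_real_
  peptide_precision <- if (length(got_peps))
    mean(got_peps %in% true_peps) else NA_real_

  data.frame(
    category = c("gene_discovery", "full_length_gate", "exon_junctions",
                 "splice_variants", "unique_peptides"),
    recall = c(gene_recall, fl_recall, junction_recall,
               variant_recall, peptide_recall),
    precision = c(gene_precision, fl_precision,
                  junction_precision, variant_precision,
                  peptide_precision),
    stringsAsFactors = FALSE)
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(out$hits)) {
    utils::write.table(out$hits, file.path(dir, "hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (length(out$contigs)) {
    write_fasta(data.frame(
      id = vapply(out$contigs, `[[`, "", "id"),
      sequence = vapply(out$contigs, `[[`, "", "consensus"),
      species = vapply(out$contigs, `[[`, "", "species"),
      stringsAsFactors = FALSE), file.path(dir, "contigs.fasta"))
  }
  all_models <- c(out$models, out$est_models)
  if (length(all_models)) {
    models_to_gff3(all_models, file.path(dir, "models.gff3"))
  }
  if (nrow(out$catalog)) {
    utils::write.table(out$catalog, file.path(dir, "catalog.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$tally)) {
    utils::write.table(out$tally$tally, file.path(dir, "tally.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$tree)) {
    write_tree_newick(out$tree$tree, file.path(dir, "tree.nwk"))
  }
  utils::write.table(out$funnel, file.path(dir, "funnel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(out$report, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
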