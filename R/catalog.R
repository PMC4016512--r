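# Mature-peptide catalog: extraction from precursors, cross-species
# deduplication, comparison against a reference peptide set, and EST
# tissue-library expression tallies.

#' Extract the mature peptide from a precursor
#'
#' CLE: the mature dodecapeptide is the final 12 aa of the 14-aa motif
#' (the two N-terminal motif residues are part of the protease recognition
#' context, not the peptide). CLEL: the peptide starts at the Asp/Glu-Tyr
#' pair inside the motif window and runs to the precursor C-terminus,
#' capped at 16 aa.
#'
#' @param precursor Precursor protein sequence.
#' @param motif_aa 0-based half-open residue interval of the motif.
#' @param family `"CLE"` or `"CLEL"`.
#' @param max_len Length cap for CLEL peptides.
#' @return The mature peptide string.
#' @export
extract_mature_peptide <- function(precursor, motif_aa, family,
                                   max_len = 16L) {
  stopifnot(motif_aa[1L] >= 0L, motif_aa[2L] <= nchar(precursor))
  if (family == "CLE") {
    if (motif_aa[2L] - motif_aa[1L] < 14L) {
      stop("extract_mature_peptide: CLE motif interval shorter than 14 aa")
    }
    return(substr(precursor, motif_aa[1L] + 3L, motif_aa[1L] + 14L))
  }
  win <- substr(precursor, motif_aa[1L] + 1L, motif_aa[2L])
  m <- regexpr("[DE]Y", win)
  if (m < 0L) {
    stop("extract_mature_peptide: CLEL motif lacks an Asp/Glu-Tyr start")
  }
  start <- motif_aa[1L] + m                          # 1-based in precursor
  substr(precursor, start, min(nchar(precursor), start + max_len - 1L))
}

#' Deduplicate peptides across genes and species
#'
#' Exact-string grouping; each unique peptide lists its source genes and
#' species. Output ordering is stable: family, then peptide.
#'
#' @param entries `data.frame` with `peptide`, `family`, `gene_id`,
#'   `species` columns (one row per gene/peptide occurrence).
#' @return `data.frame`: `peptide`, `family`, `n_genes`, `n_species`,
#'   `gene_ids`, `species` (semicolon-joined, sorted).
#' @export
dedup_and_group <- function(entries) {
  if (nrow(entries) == 0L) {
    return(data.frame(peptide = character(), family = character(),
                      n_genes = integer(), n_species = integer(),
                      gene_ids = character(), species = character(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(entries$family, entries$peptide, sep = "|")
  out <- lapply(sort(unique(key)), function(kk) {
    rr <- entries[key == kk, , drop = FALSE]
    data.frame(peptide = rr$peptide[1L], family = rr$family[1L],
               n_genes = length(unique(rr$gene_id)),
               n_species = length(unique(rr$species)),
               gene_ids = paste(sort(unique(rr$gene_id)), collapse = ";"),
               species = paste(sort(unique(rr$species)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$family, out$peptide), , drop = FALSE]
}

# ungapped distance between two peptides: equal length -> Hamming;
# unequal -> best sliding offset, 1 penalty per overhang residue
peptide_distance <- function(a, b) {
  xa <- strsplit(a, "")[[1L]]
  xb <- strsplit(b, "")[[1L]]
  if (length(xa) == length(xb)) {
    return(list(distance = sum(xa != xb),
                mismatches = which(xa != xb)))
  }
  if (length(xa) > length(xb)) { tmp <- xa; xa <- xb; xb <- tmp }
  n <- length(xa); m <- length(xb)
  best <- Inf; best_mm <- integer()
  for (off in 0:(m - n)) {
    seg <- xb[(off + 1L):(off + n)]
    dd <- sum(xa != seg) + (m - n)
    if (dd < best) { best <- dd; best_mm <- which(xa != seg) + off }
  }
  list(distance = best, mismatches = best_mm)
}

#' Compare a unique-peptide table against a reference set
#'
#' Each catalog peptide is matched to its closest reference peptide by
#' minimum ungapped distance (Hamming for equal lengths; for unequal
#' lengths the best ungapped offset, with one penalty per overhang
#' residue). Mismatch positions are reported relative to the reference.
#'
#' @param uniques Output of [dedup_and_group()] (or any `data.frame` with
#'   a `peptide` column).
#' @param reference Named character vector of reference peptides.
#' @return `data.frame`: `peptide`, `best_match`, `distance`,
#'   `mismatch_positions` (semicolon-joined), `perfect`. The number of
#'   perfectly conserved peptides is attached as attribute
#'   `n_perfect`.
#' @export
compare_to_reference <- function(uniques, reference) {
  if (length(reference) == 0L) {
    stop("compare_to_reference: empty reference set")
  }
  if (is.null(names(reference))) stop("reference peptides must be named")
  rows <- lapply(seq_len(nrow(uniques)), function(i) {
    p <- uniques$peptide[i]
    dd <- lapply(reference, function(r) peptide_distance(p, r))
    dist <- vapply(dd, `[[`, 0, "distance")
    j <- which.min(dist)
    data.frame(peptide = p, best_match = names(reference)[j],
               distance = dist[j],
               mismatch_positions = paste(dd[[j]]$mismatches,
                                          collapse = ";"),
               perfect = dist[j] == 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_perfect") <- sum(out$perfect)
  out
}

#' Load the bundled reference CLE dodecapeptide set
#'
#' A 32-entry Arabidopsis-style reference. The CLV3, CLE13 and CLE41/44
#' (TDIF) dodecapeptides are the real published sequences; the remaining
#' entries are synthetic CLE-like stand-ins (the full published set is not
#' redistributed here), which is sufficient for conservation screening
#' against catalogs whose planted peptides avoid the synthetic entries.
#'
#' @return Named character vector of 32 dodecapeptides.
#' @export
load_reference_peptides <- function() {
  path <- system.file("extdata", "athaliana_cle_reference_synthetic.fasta",
                      package = "clemine")
  df <- read_fasta(path, kind = "protein")
  stats::setNames(df$sequence, df$id)
}

#' Tally EST tissue-library evidence per gene
#'
#' @param ests `data.frame` with `gene_id` and `library` columns (one row
#'   per EST); unknown labels are tallied under `"other"` with a warning.
#' @param vocabulary Controlled tissue vocabulary.
#' @return List: `tally` (`data.frame` gene_id/library/count),
#'   `multi_tissue` (genes seen in >= 2 distinct tissue classes),
#'   `xylem_bark_overlap` (genes seen in both xylem and bark/phloem).
#' @export
expression_tally <- function(ests, vocabulary = TISSUE_VOCAB) {
  lib <- ests$library
  unknown <- !(lib %in% vocabulary)
  if (any(unknown)) {
    warning(sum(unknown), " EST(s) with unknown tissue label tallied as ",
            "'other'")
    lib[unknown] <- "other"
  }
  tab <- as.data.frame(table(gene_id = ests$gene_id, library = lib),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[3L] <- "count"
  tab <- tab[order(tab$gene_id, tab$library), , drop = FALSE]
  rownames(tab) <- NULL
  per_gene <- split(tab$library, tab$gene_id)
  multi <- names(per_gene)[vapply(per_gene, function(x)
    length(unique(x)) >= 2L, logical(1))]
  xb <- names(per_gene)[vapply(per_gene, function(x)
    all(c("xylem", "bark/phloem") %in% x), logical(1))]
  list(tally = tab, multi_tissue = multi, xylem_bark_overlap = xb)
}
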