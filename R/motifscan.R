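# Translated six-frame motif scanning: a desk-scale stand-in for TBLASTN.
# Queries (14-aa CLE motifs, 13-16 aa CLEL motifs) are Smith-Waterman
# aligned (BLOSUM62, affine gaps, BLAST default penalties) against all six
# translated frames of each subject, and hits are mapped back to
# forward-strand nucleotide coordinates.

FRAMES <- c("+1", "+2", "+3", "-1", "-2", "-3")

#' Translate a nucleotide sequence in all six reading frames
#'
#' Standard genetic code; stop codons are rendered `*`, codons containing
#' ambiguity codes as `X`; trailing partial codons are dropped.
#'
#' @param seq A single nucleotide string.
#' @return Named character vector of six peptides (`+1`,`+2`,`+3`,
#'   `-1`,`-2`,`-3`). For sequences shorter than 3 nt a warning is issued
#'   and all six entries are empty strings.
#' @examples
#' translate_six_frames("ATGGCA")[["+1"]]  # "MA"
#' @export
translate_six_frames <- function(seq) {
  if (nchar(seq) < 3L) {
    warning("translate_six_frames: sequence shorter than one codon")
    return(stats::setNames(rep("", 6L), FRAMES))
  }
  rc <- reverse_complement(seq)
  out <- c(vapply(1:3, function(k) {
    translate_frame1(substr(seq, k, nchar(seq)))
  }, character(1)),
  vapply(1:3, function(k) {
    translate_frame1(substr(rc, k, nchar(rc)))
  }, character(1)))
  stats::setNames(out, FRAMES)
}

#' Build a motif query table
#'
#' @param peptides Named character vector of query peptides (names become
#'   query names), standard 20-letter alphabet; hydroxyproline in published
#'   peptides must be given as `P`.
#' @param family `"CLE"` or `"CLEL"` (recycled).
#' @return `data.frame` with columns `name`, `peptide`, `family`.
#' @export
motif_queries <- function(peptides, family) {
  if (is.null(names(peptides)) || any(!nzchar(names(peptides)))) {
    stop("motif_queries: peptides must be named")
  }
  if (any(nchar(peptides) < 10L)) {
    stop("motif_queries: query peptides must be >= 10 aa")
  }
  data.frame(name = names(peptides), peptide = unname(peptides),
             family = rep(family, length.out = length(peptides)),
             stringsAsFactors = FALSE)
}

# local alignment of one query against one peptide string; returns all
# non-overlapping hits above thresholds via iterative masking
local_hits_one <- function(query, frame_pep, min_identity, min_score,
                           min_span, max_hits = 25L) {
  mat <- get_blosum62()
  out <- list()
  masked <- frame_pep
  for (i in seq_len(max_hits)) {
    if (nchar(masked) < min_span) break
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(masked),
      type = "local", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(aln)
    if (sc < min_score) break
    sub_aln <- Biostrings::subject(aln)
    a <- Biostrings::start(sub_aln)
    b <- Biostrings::end(sub_aln)
    width <- nchar(gsub("-", "", as.character(sub_aln)))
    ident <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    if (width >= min_span && ident >= min_identity) {
      out[[length(out) + 1L]] <- list(aa_start = a, aa_end = b,
                                      peptide = as.character(sub_aln),
                                      score = sc, identity = ident)
    }
    # mask the matched span so further hits elsewhere can surface
    substr(masked, a, b) <- paste(rep("*", b - a + 1L), collapse = "")
  }
  out
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# aa interval (1-based, within a frame translation) -> forward-strand
# 0-based half-open nt interval
frame_to_nt <- function(frame, aa_start, aa_end, seq_len) {
  k <- as.integer(substr(frame, 2L, 2L))
  s <- (k - 1L) + 3L * (aa_start - 1L)
  e <- (k - 1L) + 3L * aa_end
  if (substr(frame, 1L, 1L) == "+") c(s, e) else c(seq_len - e, seq_len - s)
}

#' Scan nucleotide subjects for translated peptide-motif hits
#'
#' Smith-Waterman local alignment (BLOSUM62, gap open 11 / extend 1) of
#' every query against all six translated frames of every subject. Hits
#' passing both thresholds over a minimum aligned span are mapped back to
#' forward-strand nucleotide coordinates; overlapping hits from the same
#' query on one subject are merged keeping the best score.
#'
#' @param subjects `data.frame` with `id` and `sequence` (nucleotide), or a
#'   named character vector.
#' @param queries A query table from [motif_queries()].
#' @param min_identity Minimum identity fraction over aligned columns.
#' @param min_score Minimum alignment score.
#' @param min_span Minimum aligned subject span (aa).
#' @return `data.frame` of hits: `subject`, `frame`, `start`, `end`
#'   (0-based half-open, forward strand), `peptide` (aligned subject
#'   peptide), `query`, `family`, `score`, `identity`.
#' @export
scan_motifs <- function(subjects, queries, min_identity = 0.5,
                        min_score = 40, min_span = 12L) {
  if (is.character(subjects)) {
    subjects <- data.frame(id = names(subjects), sequence = unname(subjects),
                           stringsAsFactors = FALSE)
  }
  stopifnot(nrow(queries) > 0L)
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    sseq <- subjects$sequence[i]
    if (nchar(sseq) < 3L) next
    frames <- translate_six_frames(sseq)
    for (f in FRAMES) {
      fp <- frames[[f]]
      if (nchar(fp) < min_span) next
      for (q in seq_len(nrow(queries))) {
        hits <- local_hits_one(queries$peptide[q], fp, min_identity,
                               min_score, min_span)
        for (h in hits) {
          iv <- frame_to_nt(f, h$aa_start, h$aa_end, nchar(sseq))
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subjects$id[i], frame = f,
            start = iv[1L], end = iv[2L], peptide = h$peptide,
            query = queries$name[q], family = queries$family[q],
            score = h$score, identity = h$identity,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(subject = character(), frame = character(),
                      start = integer(), end = integer(),
                      peptide = character(), query = character(),
                      family = character(), score = numeric(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, rows)
  merge_same_query_hits(hits)
}

# drop hits that overlap a better-scoring hit from the same query on the
# same subject (strand-agnostic interval overlap)
merge_same_query_hits <- function(hits) {
  hits <- hits[order(-hits$score, hits$subject, hits$start), ]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(hits)) > i &
                 hits$subject == hits$subject[i] &
                 hits$query == hits$query[i] &
                 hits$start < hits$end[i] & hits$end > hits$start[i])
    keep[j] <- FALSE
  }
  out <- hits[keep, ]
  rownames(out) <- NULL
  out
}

#' Second-round search with discovered motifs
#'
#' Re-scans the subjects with the original queries plus motifs discovered
#' in a first round (e.g. consensus motifs from validated contigs). With
#' identical thresholds the result always contains the first-round hits.
#'
#' @param subjects As in [scan_motifs()].
#' @param queries First-round query table.
#' @param discovered Additional query table of discovered motifs (may have
#'   zero rows).
#' @inheritParams scan_motifs
#' @return Combined hit table (same columns as [scan_motifs()]).
#' @export
iterate_search <- function(subjects, queries, discovered,
                           min_identity = 0.5, min_score = 40,
                           min_span = 12L) {
  all_q <- rbind(queries, discovered)
  all_q <- all_q[!duplicated(all_q$peptide), , drop = FALSE]
  scan_motifs(subjects, all_q, min_identity, min_score, min_span)
}
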