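# Signal-peptide prediction and the full-length gate.
#
# The predictor is an explicit, self-contained model sharing its grammar
# with the synthetic generator: (i) the h-region is scored as the maximum
# mean Kyte-Doolittle hydropathy over a 7-15 residue window within
# residues 2-30; (ii) candidate cleavage sites shortly after the h-region
# are scored by the von Heijne (-3,-1) small-residue rule; (iii) acidic
# residues (Asp/Glu) in the first 30 residues are penalized. It returns the
# same contract a black-box predictor would: a boolean call, a score, and
# the cleavage position.

# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

SMALL_RESIDUES <- c("A", "G", "S", "C", "T")

#' Predict a signal peptide on a precursor protein
#'
#' @param protein Amino-acid string starting with Met, length >= 20.
#' @param threshold Decision threshold on the combined score.
#' @return List of class `sp_call`: `is_signal`, `cleavage_pos` (0-based
#'   index of the first mature residue; NA when no candidate site exists),
#'   `score`, and `components` (h-region hydropathy, c-region site weight,
#'   acidic-residue penalty).
#' @export
predict_signal_peptide <- function(protein, threshold = 0.58) {
  aa <- strsplit(protein, "")[[1L]]
  if (length(aa) < 20L) {
    stop("predict_signal_peptide: protein shorter than 20 residues")
  }
  if (aa[1L] != "M") {
    stop("predict_signal_peptide: protein must start with Met")
  }
  kd <- unname(KD_SCALE[aa])
  kd[is.na(kd)] <- 0
  lim <- min(30L, length(aa))
  # h-region: best mean hydropathy over 7-15 residue windows in 2..lim
  h_best <- -Inf
  h_end <- NA_integer_
  for (w in 7:15) {
    if (lim - w < 1L) break
    for (s in 2:(lim - w + 1L)) {
      m <- mean(kd[s:(s + w - 1L)])
      if (m > h_best) { h_best <- m; h_end <- s + w - 1L }
    }
  }
  # candidate cleavage sites: just downstream of the h-region, within the
  # 15-45 window; site s = last residue of the signal peptide
  sites <- seq.int(max(15L, h_end + 2L), min(45L, h_end + 14L,
                                             length(aa) - 1L))
  c_best <- 0
  cleave <- NA_integer_
  for (s in sites) {
    cw <- (aa[s - 2L] %in% SMALL_RESIDUES) + (aa[s] %in% SMALL_RESIDUES)
    if (cw > c_best) { c_best <- cw; cleave <- s }
  }
  if (is.na(cleave) && length(sites)) cleave <- sites[1L]
  acid <- sum(aa[seq_len(lim)] %in% c("D", "E"))
  score <- 0.5 * min(max(h_best, 0) / 4, 1) + 0.175 * c_best - 0.04 * acid
  out <- list(is_signal = score >= threshold && !is.na(cleave),
              cleavage_pos = cleave, score = score,
              components = list(h_region = h_best, c_region = c_best,
                                acid_penalty = 0.04 * acid))
  class(out) <- "sp_call"
  out
}

#' Full-length gate for EST contig precursors
#'
#' A contig's predicted protein is assumed full-length if, and only if,
#' taking the 5'-most in-frame Met as initiator yields a predicted signal
#' peptide. Downstream Met residues are deliberately not consulted: a
#' 5'-most Met that fails the predictor leaves the contig classified
#' partial even if a later Met would pass.
#'
#' @param translation In-frame translation of the contig (may contain
#'   upstream residues and `*` stops).
#' @param threshold Passed to [predict_signal_peptide()].
#' @return List: `status` (`"full-length"`/`"partial"`), `reason`,
#'   `met_index` (0-based position of the 5'-most Met in `translation`, NA
#'   if none), `protein` (Met-to-stop candidate, NA if none), `sp_call`.
#' @export
full_length_gate <- function(translation, threshold = 0.58) {
  m <- regexpr("M", translation, fixed = TRUE)
  if (m < 0L) {
    return(list(status = "partial", reason = "no-start",
                met_index = NA_integer_, protein = NA_character_,
                sp_call = NULL))
  }
  cand <- substr(translation, m, nchar(translation))
  stop_at <- regexpr("*", cand, fixed = TRUE)
  if (stop_at > 0L) cand <- substr(cand, 1L, stop_at - 1L)
  if (nchar(cand) < 20L) {
    return(list(status = "partial", reason = "orf-too-short",
                met_index = m - 1L, protein = cand, sp_call = NULL))
  }
  call <- predict_signal_peptide(cand, threshold)
  if (call$is_signal) {
    list(status = "full-length", reason = "signal-peptide-at-5'-most-met",
         met_index = m - 1L, protein = cand, sp_call = call)
  } else {
    list(status = "partial", reason = "no-signal-peptide-at-5'-most-met",
         met_index = m - 1L, protein = cand, sp_call = call)
  }
}

#' Validate a genomic motif-hit candidate
#'
#' Genomic candidates are accepted when the open reading frame containing
#' the motif hit has at least one Met initiator whose downstream sequence
#' is predicted to carry a signal peptide lying upstream of the motif.
#' Unlike the EST gate, any in-frame Met may serve (the genomic rule), and
#' absence of a signal peptide marks the motif hit as spurious. Two
#' family-architecture constraints are also enforced: the precursor must
#' be at least `min_precursor` residues (real precursors are ~64-100 aa)
#' and the motif must begin at least `min_ncs` residues downstream of the
#' predicted cleavage site (every real precursor carries a non-conserved
#' NCS1 region there); chance open reading frames around spurious motif
#' hits rarely satisfy both.
#'
#' @param orf_protein ORF translation (stop-to-stop, no `*`).
#' @param motif_start 0-based residue index of the motif within the ORF;
#'   `NA` means no motif hit and the candidate is rejected.
#' @param threshold Passed to [predict_signal_peptide()].
#' @param min_ncs Minimum cleavage-to-motif spacing (aa).
#' @param min_precursor Minimum Met-to-stop precursor length (aa).
#' @return List: `accept`, `met_index` (0-based index in the ORF of the
#'   chosen initiator, NA on reject), `sp_call`, `reason`.
#' @export
call_genomic_candidate <- function(orf_protein, motif_start,
                                   threshold = 0.58, min_ncs = 20L,
                                   min_precursor = 60L) {
  if (is.na(motif_start)) {
    return(list(accept = FALSE, met_index = NA_integer_, sp_call = NULL,
                reason = "no-motif-hit"))
  }
  aa <- strsplit(orf_protein, "")[[1L]]
  mets <- which(aa == "M") - 1L                      # 0-based
  mets <- mets[mets < motif_start]
  for (m in mets) {
    cand <- substr(orf_protein, m + 1L, nchar(orf_protein))
    if (nchar(cand) < max(20L, min_precursor)) next
    call <- predict_signal_peptide(cand, threshold)
    # signal peptide must end well upstream of the motif (NCS1 spacing)
    if (call$is_signal && !is.na(call$cleavage_pos) &&
        m + call$cleavage_pos + min_ncs <= motif_start) {
      return(list(accept = TRUE, met_index = m, sp_call = call,
                  reason = "met-sp-motif-order-satisfied"))
    }
  }
  list(accept = FALSE, met_index = NA_integer_, sp_call = NULL,
       reason = if (!length(mets)) "no-met-initiator" else
         "no-signal-peptide-downstream-of-met")
}
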