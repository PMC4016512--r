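# Species-partitioned greedy overlap-layout-consensus assembly of
# motif-positive ESTs, with per-column variant calling and a three-part
# manual-validation rule. Reads from different species are never merged,
# mirroring hand curation with attention to species of origin.

# best suffix(a)-prefix(b) placement of b inside/after a; seed-and-verify.
# Returns NULL or list(shift, olen, identity, contained).
find_overlap <- function(a, b, min_overlap, min_identity, k = 14L) {
  la <- nchar(a); lb <- nchar(b)
  if (lb < k) return(NULL)
  seed_pos <- unique(pmin(c(1L, 9L, 17L, 25L, 33L), lb - k + 1L))
  shifts <- integer()
  for (sp in seed_pos) {
    seed <- substr(b, sp, sp + k - 1L)
    m <- gregexpr(seed, a, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    shifts <- c(shifts, m - sp)                      # 0-based placement of b
  }
  shifts <- sort(unique(shifts[shifts >= 0L & shifts <= la - min_overlap]))
  best <- NULL
  for (s in shifts) {
    olen <- min(la - s, lb)
    if (olen < min_overlap) next
    av <- substr(a, s + 1L, s + olen)
    bv <- substr(b, 1L, olen)
    ident <- hamming_identity(av, bv)
    contained <- s + lb <= la
    b_tail_start <- olen + 1L                 # first b base beyond overlap
    if (ident < min_identity) {
      # indel-tolerant fallback: ends-free alignment of all of b against
      # the a-suffix; identity over substitution columns only (indels are
      # separate events, recorded later as variants)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(b), Biostrings::DNAString(substr(a, s + 1L, la)),
        type = "overlap")
      nm <- Biostrings::nmatch(aln)
      nmm <- Biostrings::nmismatch(aln)
      if (nm + nmm >= min_overlap) {
        ident <- nm / (nm + nmm)
        pend <- Biostrings::end(Biostrings::pattern(aln))
        contained <- pend >= lb
        b_tail_start <- pend + 1L
        olen <- nm + nmm
      }
    }
    if (ident >= min_identity) {
      # containment is preferred over extension at equal overlap quality
      cand <- list(shift = s, olen = olen, identity = ident,
                   contained = contained, b_tail_start = b_tail_start,
                   score = olen * ident + 0.5 * contained)
      if (is.null(best) || cand$score > best$score) best <- cand
    }
  }
  best
}

hamming_identity <- function(x, y) {
  xs <- strsplit(x, "")[[1L]]
  ys <- strsplit(y, "")[[1L]]
  n <- min(length(xs), length(ys))
  if (n == 0L) return(0)
  sum(xs[seq_len(n)] == ys[seq_len(n)]) / n
}

#' Assemble ESTs into species-partitioned contigs
#'
#' Greedy overlap-layout-consensus: the best remaining suffix-prefix
#' overlap (by overlap length times identity) is merged first; reads
#' carrying different species labels are never placed in one contig;
#' unmerged reads become single-read contigs. The consensus is a
#' per-column majority with ties broken toward the read with the
#' lexicographically earliest id, which makes the result independent of
#' input order.
#'
#' @param reads `data.frame` with `id`, `sequence`, `species` columns.
#' @param min_overlap Minimum overlap length (nt).
#' @param min_identity Minimum identity within the overlap.
#' @return List of `contig` objects: `id`, `species`, `members`
#'   (`data.frame` id/offset/sequence), `consensus`, `rows` (per-member
#'   alignment strings padded to consensus length), `insertions`
#'   (`data.frame` member/pos/seq of member bases absent from the
#'   consensus).
#' @export
assemble <- function(reads, min_overlap = 40L, min_identity = 0.95) {
  stopifnot(nrow(reads) > 0L,
            all(c("id", "sequence", "species") %in% names(reads)))
  out <- list()
  for (sp in sort(unique(reads$species))) {
    rr <- reads[reads$species == sp, , drop = FALSE]
    rr <- rr[order(rr$id), , drop = FALSE]
    units <- lapply(seq_len(nrow(rr)), function(i) {
      list(backbone = rr$sequence[i],
           members = data.frame(id = rr$id[i], offset = 0L,
                                sequence = rr$sequence[i],
                                stringsAsFactors = FALSE))
    })
    repeat {
      best <- NULL
      for (i in seq_along(units)) {
        for (j in seq_along(units)) {
          if (i == j) next
          ov <- find_overlap(units[[i]]$backbone, units[[j]]$backbone,
                             min_overlap, min_identity)
          if (!is.null(ov)) {
            if (is.null(best) || ov$score > best$score) {
              best <- list(i = i, j = j, ov = ov, score = ov$score)
            }
          }
        }
      }
      if (is.null(best)) break
      a <- units[[best$i]]; b <- units[[best$j]]
      s <- best$ov$shift
      backbone <- if (best$ov$contained) a$backbone else
        paste0(a$backbone, substr(b$backbone, best$ov$b_tail_start,
                                  nchar(b$backbone)))
      b$members$offset <- b$members$offset + s
      merged <- list(backbone = backbone,
                     members = rbind(a$members, b$members))
      units[[best$i]] <- merged
      units <- units[-best$j]
    }
    for (u in units) {
      out[[length(out) + 1L]] <- finalize_contig(u, sp)
    }
  }
  for (i in seq_along(out)) out[[i]]$id <- sprintf("contig%03d", i)
  out
}

# layout -> per-member alignment rows, majority consensus, insertions
finalize_contig <- function(unit, species) {
  bb <- unit$backbone
  L <- nchar(bb)
  mem <- unit$members[order(unit$members$id), , drop = FALSE]
  rows <- character(nrow(mem))
  ins <- list()
  for (i in seq_len(nrow(mem))) {
    seq_i <- mem$sequence[i]
    off <- mem$offset[i]
    direct_end <- min(off + nchar(seq_i), L)
    ident <- hamming_identity(substr(bb, off + 1L, direct_end),
                              substr(seq_i, 1L, direct_end - off))
    if (ident >= 0.8 && off + nchar(seq_i) <= L) {
      rows[i] <- paste0(strrep(" ", off), seq_i,
                        strrep(" ", L - off - nchar(seq_i)))
    } else {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seq_i), Biostrings::DNAString(bb),
        type = "global-local")
      pat <- as.character(Biostrings::alignedPattern(aln))
      sub <- as.character(Biostrings::alignedSubject(aln))
      st <- Biostrings::start(Biostrings::subject(aln))
      en <- Biostrings::end(Biostrings::subject(aln))
      # columns where the subject (backbone) has a gap are member insertions
      sub_chars <- strsplit(sub, "")[[1L]]
      pat_chars <- strsplit(pat, "")[[1L]]
      keep <- sub_chars != "-"
      if (any(!keep)) {
        idx <- which(!keep)
        grp <- cumsum(c(TRUE, diff(idx) > 1L))   # consecutive gap columns
        for (g in unique(grp)) {
          cols <- idx[grp == g]
          ins[[length(ins) + 1L]] <- data.frame(
            member = mem$id[i],
            pos = st - 1L + sum(keep[seq_len(cols[1L] - 1L)]),
            seq = paste(pat_chars[cols], collapse = ""),
            stringsAsFactors = FALSE)
        }
      }
      aligned_to_bb <- paste(pat_chars[keep], collapse = "")
      rows[i] <- paste0(strrep(" ", st - 1L), aligned_to_bb,
                        strrep(" ", L - en))
    }
  }
  cons <- consensus_majority(rows, bb)
  structure(list(id = NA_character_, species = species,
                 members = mem, consensus = cons, rows = rows,
                 insertions = if (length(ins)) do.call(rbind, ins) else
                   data.frame(member = character(), pos = integer(),
                              seq = character(), stringsAsFactors = FALSE)),
            class = "contig")
}

# per-column majority over member rows; tie -> earliest-id member's base
# (rows are already ordered by member id); columns covered by no member
# fall back to the backbone base
consensus_majority <- function(rows, backbone) {
  L <- nchar(backbone)
  m <- do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1L]]))
  bb <- strsplit(backbone, "")[[1L]]
  out <- vapply(seq_len(L), function(c0) {
    col <- m[, c0]
    col <- col[col != " "]
    if (!length(col)) return(bb[c0])
    tab <- table(col)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) return(winners)
    first <- m[, c0][m[, c0] != " "][1L]
    if (first %in% winners) first else winners[1L]
  }, character(1))
  paste(out, collapse = "")
}

#' Call sequence variants among a contig's members
#'
#' Reports substitution/insertion/deletion columns relative to the
#' consensus. When an ORF annotation is supplied, positions are classified
#' as 5'-UTR, coding, or 3'-UTR; coding substitutions are classified
#' silent vs amino-acid-changing by codon comparison, and an insertion
#' that exactly duplicates the adjacent equal-length consensus segment is
#' flagged as a direct repeat.
#'
#' @param contig A `contig` object from [assemble()].
#' @param orf Optional `c(start, end)` 0-based half-open CDS interval on
#'   the consensus. Without it, variants get `region = "unknown"` and no
#'   effect classification.
#' @return `data.frame`: `contig`, `pos` (0-based consensus coordinate),
#'   `type`, `member`, `ref`, `alt`, `region`, `effect`, `note`.
#' @export
detect_variants <- function(contig, orf = NULL) {
  cons <- strsplit(contig$consensus, "")[[1L]]
  out <- list()
  emit <- function(pos, type, member, ref, alt) {
    region <- "unknown"; effect <- NA_character_; note <- ""
    if (!is.null(orf)) {
      region <- if (pos < orf[1L]) "5'-UTR" else
        if (pos >= orf[2L]) "3'-UTR" else "coding"
      if (region != "coding") {
        effect <- "non-coding"
      } else if (type == "substitution") {
        ci <- (pos - orf[1L]) %/% 3L
        cod_s <- orf[1L] + 3L * ci
        ref_cod <- paste(cons[(cod_s + 1L):(cod_s + 3L)], collapse = "")
        alt_cod <- ref_cod
        substr(alt_cod, pos - cod_s + 1L, pos - cod_s + 1L) <- alt
        effect <- if (translate_frame1(ref_cod) == translate_frame1(alt_cod))
          "silent" else "amino-acid-changing"
      } else {
        effect <- "amino-acid-changing"   # coding indel: frameshift
      }
    }
    if (type == "insertion") {
      len <- nchar(alt)
      follow <- substr(contig$consensus, pos + 1L, pos + len)
      precede <- if (pos - len >= 0L)
        substr(contig$consensus, pos - len + 1L, pos) else ""
      if (nzchar(alt) && (alt == follow || alt == precede)) {
        note <- "direct-repeat"
      }
    }
    out[[length(out) + 1L]] <<- data.frame(
      contig = contig$id, pos = pos, type = type, member = member,
      ref = ref, alt = alt, region = region, effect = effect, note = note,
      stringsAsFactors = FALSE)
  }
  if (nrow(contig$members) >= 2L) {
    for (i in seq_len(nrow(contig$members))) {
      row <- strsplit(contig$rows[i], "")[[1L]]
      diffs <- which(row != " " & row != cons)
      for (p in diffs) {
        if (row[p] == "-") {
          emit(p - 1L, "deletion", contig$members$id[i], cons[p], "-")
        } else {
          emit(p - 1L, "substitution", contig$members$id[i], cons[p], row[p])
        }
      }
    }
    if (nrow(contig$insertions)) {
      for (i in seq_len(nrow(contig$insertions))) {
        r <- contig$insertions[i, ]
        emit(r$pos, "insertion", r$member, "", r$seq)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(), pos = integer(),
                      type = character(), member = character(),
                      ref = character(), alt = character(),
                      region = character(), effect = character(),
                      note = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Validate a contig against the three-part manual-curation rule
#'
#' A contig is rejected only when all three symptoms co-occur: (i) weak
#' motif conservation (best hit identity below the conservation floor),
#' (ii) a truncated open reading frame in the motif frame (stop-interrupted
#' or lacking an upstream Met), and (iii) a clear antisense ORF longer than
#' the sense ORF overlapping the hit. Any single symptom is insufficient.
#'
#' @param contig A `contig` object.
#' @param hits Motif hits on the contig consensus (from [scan_motifs()]
#'   with the consensus as subject; `subject` must equal the contig id or
#'   be the only subject present).
#' @param conservation_floor Identity below which conservation is "weak".
#' @return List: `accept` (logical), `tests` (named logical vector of the
#'   three symptoms), `reasons` (character).
#' @export
validate_contig <- function(contig, hits, conservation_floor = 0.6) {
  if (nrow(hits) == 0L) {
    return(list(accept = FALSE,
                tests = c(weak_conservation = TRUE, truncated_orf = TRUE,
                          antisense_orf = TRUE),
                reasons = "no motif hit on contig"))
  }
  best <- hits[which.max(hits$score), ]
  weak <- best$identity < conservation_floor

  frames <- translate_six_frames(contig$consensus)
  fp <- frames[[best$frame]]
  # motif position within the frame translation
  L <- nchar(contig$consensus)
  k <- as.integer(substr(best$frame, 2L, 2L))
  if (substr(best$frame, 1L, 1L) == "+") {
    aa_start <- (best$start - (k - 1L)) %/% 3L + 1L
  } else {
    aa_start <- ((L - best$end) - (k - 1L)) %/% 3L + 1L
  }
  seg_start <- max(1L, gregexpr("\\*", substr(fp, 1L, aa_start))[[1L]])
  seg_start <- if (seg_start[1L] == -1L) 1L else max(seg_start) + 1L
  seg_end_rel <- regexpr("*", substr(fp, aa_start, nchar(fp)), fixed = TRUE)
  seg_end <- if (seg_end_rel < 0L) nchar(fp) else aa_start + seg_end_rel - 2L
  orf <- substr(fp, seg_start, seg_end)
  has_met_upstream <- grepl("M", substr(fp, seg_start, aa_start))
  truncated <- !has_met_upstream
  sense_len <- nchar(orf)

  anti_frames <- if (substr(best$frame, 1L, 1L) == "+")
    c("-1", "-2", "-3") else c("+1", "+2", "+3")
  anti_max <- 0L
  for (f in anti_frames) {
    segs <- strsplit(frames[[f]], "*", fixed = TRUE)[[1L]]
    if (length(segs)) anti_max <- max(anti_max, nchar(segs))
  }
  antisense <- anti_max > sense_len

  tests <- c(weak_conservation = weak, truncated_orf = truncated,
             antisense_orf = antisense)
  list(accept = !all(tests), tests = tests,
       reasons = names(tests)[tests])
}
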