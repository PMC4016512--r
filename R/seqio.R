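# Sequence IO and the core record model.
#
# Internal coordinate convention, used by every module in this package:
# 0-based half-open intervals on the forward strand of the sequence they
# refer to. GFF3 emission converts to 1-based inclusive at the boundary.

IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a FASTA file into a record data frame
#'
#' Reads nucleotide or protein FASTA and parses `key=value` tokens in the
#' header into metadata columns (e.g. `species=`, `library=` tags on EST
#' records). Sequences are uppercased on read; the number of records that
#' contained lowercase letters is reported via a message.
#'
#' @param path Path to a FASTA file.
#' @param kind `"nucleotide"` or `"protein"`; controls alphabet validation.
#' @return A `data.frame` with columns `id`, `sequence`, `desc`, one column
#'   per header tag found in the file, and a `source` column holding the
#'   file path. Record order is preserved.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">e1 species=Pinus_radiata library=xylem", "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  seqs <- as.character(set)
  n_lower <- sum(grepl("[a-z]", seqs))
  if (n_lower > 0L) {
    message(n_lower, " record(s) contained lowercase bases; uppercased")
    seqs <- toupper(seqs)
  }
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) {
    stop("malformed FASTA: empty header for record #", which(!nzchar(ids))[1L])
  }
  if (any(!nzchar(seqs))) {
    stop("malformed FASTA: empty sequence for record '",
         ids[which(!nzchar(seqs))[1L]], "'")
  }
  alphabet <- if (kind == "nucleotide") IUPAC_NT else c(AA20, "X", "*", "-")
  ok <- !grepl(sprintf("[^%s]", paste(alphabet, collapse = "")), seqs)
  if (any(!ok)) {
    stop("malformed FASTA: illegal ", kind, " characters in record '",
         ids[which(!ok)[1L]], "'")
  }
  desc <- sub("^\\S+\\s*", "", headers)
  df <- data.frame(id = ids, sequence = seqs, desc = desc,
                   stringsAsFactors = FALSE)
  tags <- parse_header_tags(desc)
  for (nm in names(tags)) df[[nm]] <- tags[[nm]]
  df$source <- path
  df
}

# key=value tokens in FASTA descriptions -> named list of columns
parse_header_tags <- function(desc) {
  toks <- strsplit(desc, "\\s+")
  keys <- unique(unlist(lapply(toks, function(tt) {
    kv <- grep("=", tt, fixed = TRUE, value = TRUE)
    sub("=.*$", "", kv)
  })))
  keys <- keys[nzchar(keys)]
  out <- list()
  for (k in keys) {
    out[[k]] <- vapply(toks, function(tt) {
      hit <- grep(paste0("^", k, "="), tt, value = TRUE)
      if (length(hit)) sub("^[^=]*=", "", hit[1L]) else NA_character_
    }, character(1))
  }
  out
}

#' Write records to FASTA
#'
#' @param records A `data.frame` with `id` and `sequence` columns (extra
#'   metadata columns among `species`, `library` are emitted as `key=value`
#'   header tags), or a named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(records)))
  headers <- records$id
  for (tag in intersect(c("species", "library"), names(records))) {
    val <- records[[tag]]
    keep <- !is.na(val) & nzchar(val)
    headers[keep] <- paste0(headers[keep], " ", tag, "=", val[keep])
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement nucleotide sequences
#'
#' Complements all IUPAC ambiguity codes and reverses. An involution:
#' `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
#' @export
reverse_complement <- function(seq) {
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_NT, collapse = "")), seq)
  if (any(bad)) {
    stop("reverse_complement: non-nucleotide characters in input (",
         "is this a protein sequence?)")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Write features to GFF3
#'
#' Converts the package's internal 0-based half-open intervals to the
#' 1-based inclusive coordinates GFF3 requires.
#'
#' @param features `data.frame` with columns `seqid`, `source`, `type`,
#'   `start` (0-based), `end` (half-open), `score`, `strand`, `phase`,
#'   `attributes` (preformatted `key=value;...` strings).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  need <- c("seqid", "source", "type", "start", "end", "score", "strand",
            "phase", "attributes")
  stopifnot(all(need %in% names(features)))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                   features$seqid, features$source, features$type,
                   features$start + 1L, features$end,
                   as.character(features$score), features$strand,
                   as.character(features$phase), features$attributes)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
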