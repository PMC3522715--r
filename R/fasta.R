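#' Read a FASTA file into a tibble of sequence records
#'
#' Sequences are uppercased and restricted to the A/C/G/T/N alphabet.  If a
#' header carries Ensembl-style coordinates as `chrom:start-end` (1-based
#' inclusive) in its first token, they are parsed into the `chrom`, `start`
#' and `end` columns and checked against the sequence length.
#'
#' @param path Path to a FASTA file (multi-line wrapping accepted).
#' @return A tibble with one row per record: `id`, `seq`, `chrom`, `start`,
#'   `end` (coordinates are `NA` when the header carries none; `start`/`end`
#'   are kept 1-based inclusive exactly as entered).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("cannot read FASTA '%s': %s", path, conditionMessage(e)))
  )
  if (length(set) == 0L) abort(sprintf("FASTA file '%s' contains no records", path))
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA ids: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- as.character(set)
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    abort(sprintf("FASTA record '%s' has an empty sequence (header-only record)",
                  ids[which(widths == 0L)[1]]))
  }
  seqs <- vapply(seq_along(seqs), function(i) {
    normalize_seq(seqs[[i]], sprintf("FASTA record '%s'", ids[i]))
  }, character(1))
  coord <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  chrom <- rep(NA_character_, length(ids))
  start1 <- end1 <- rep(NA_integer_, length(ids))
  for (i in seq_along(coord)) {
    if (length(coord[[i]]) == 4L) {
      chrom[i] <- coord[[i]][2]
      start1[i] <- as.integer(coord[[i]][3])
      end1[i] <- as.integer(coord[[i]][4])
      if (end1[i] - start1[i] + 1L != nchar(seqs[i])) {
        abort(sprintf(
          "record '%s': header coordinates span %d bp but sequence is %d bp",
          ids[i], end1[i] - start1[i] + 1L, nchar(seqs[i])))
      }
    }
  }
  tibble(id = ids, seq = seqs, chrom = chrom, start = start1, end = end1)
}

#' Write sequence records to a FASTA file
#'
#' @param records A data frame with `id` and `seq` columns (as returned by
#'   [read_fasta()]), or a named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- tibble(id = names(records), seq = unname(records))
  }
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# single-record accessor used throughout the pipeline
one_record <- function(records, what = "query") {
  records <- as_tibble(records)
  if (nrow(records) != 1L) {
    abort(sprintf("expected exactly one %s record, got %d", what, nrow(records)))
  }
  records
}
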