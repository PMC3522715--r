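# Internal helpers shared across modules.  All intervals in the package are
# 0-based half-open on the query (or genome) forward strand unless a function
# documents otherwise; reports convert to 1-based inclusive at the boundary.

DNA_BASES <- c("A", "C", "G", "T")

# data.table subsetting semantics inside this package
.datatable.aware <- TRUE

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper around [Biostrings::reverseComplement()].
#' IUPAC ambiguity codes are supported.
#'
#' @param seq A single DNA string.
#' @return The reverse-complemented string, same case as stored (uppercase).
#' @export
#' @examples
#' revcomp("ATCGAT")  # the ClaI site is its own reverse complement
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

normalize_seq <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  if (!nzchar(seq)) abort(paste0(what, " is empty"))
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    abort(sprintf("%s contains non-ACGTN characters: %s",
                  what, paste(unique(strsplit(bad, "")[[1]]), collapse = "")))
  }
  seq
}

# Integer encoding used by the C++ kernels: A=0 C=1 G=2 T=3, N/other = -1.
seq_to_int <- function(seq) {
  x <- utf8ToInt(seq)
  code <- rep_len(-1L, 256L)
  code[utf8ToInt("A")] <- 0L
  code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L
  code[utf8ToInt("T")] <- 3L
  code[x]
}

# --- interval algebra on 0-based half-open tibbles(start, end) ----------------

new_intervals <- function(start = integer(), end = integer()) {
  tibble(start = as.integer(start), end = as.integer(end))
}

#' Merge overlapping or bookended intervals
#'
#' @param x A data frame with integer `start`/`end` columns (0-based half-open).
#' @param gap Merge intervals separated by at most `gap` bases (default 0:
#'   merge only overlapping or directly adjacent intervals).
#' @return A tibble of disjoint intervals sorted by `start`.
#' @export
merge_intervals <- function(x, gap = 0L) {
  if (nrow(x) == 0L) return(new_intervals())
  x <- arrange(as_tibble(x)[c("start", "end")], .data$start, .data$end)
  s <- x$start; e <- x$end
  out_s <- s[1]; out_e <- e[1]; k <- 1L
  if (nrow(x) > 1L) {
    for (i in 2:nrow(x)) {
      if (s[i] <= out_e[k] + gap) {
        out_e[k] <- max(out_e[k], e[i])
      } else {
        k <- k + 1L
        out_s[k] <- s[i]; out_e[k] <- e[i]
      }
    }
  }
  new_intervals(out_s[seq_len(k)], out_e[seq_len(k)])
}

interval_union_length <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

overlap_length <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# intersect one interval set with another; returns merged pieces
intersect_intervals <- function(x, y) {
  if (nrow(x) == 0L || nrow(y) == 0L) return(new_intervals())
  xr <- IRanges::IRanges(x$start + 1L, x$end)
  yr <- IRanges::IRanges(y$start + 1L, y$end)
  z <- IRanges::intersect(xr, yr)
  new_intervals(IRanges::start(z) - 1L, IRanges::end(z))
}

fmt_bp <- function(n) format(n, big.mark = ",", trim = TRUE)

# 0-based half-open -> 1-based inclusive printing
fmt_interval_1based <- function(start, end) sprintf("%d-%d", start + 1L, end)
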