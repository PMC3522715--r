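# Local alignment of the query against the genome.  Either an external
# megablast-style aligner's 12-column tabular output is parsed, or the
# built-in seed-and-extend aligner is used.  The built-in aligner is ungapped:
# exact-word seeding on both strands, X-drop extension along the diagonal,
# and word-anchored end trimming, which keeps hit boundaries at exact-match
# anchors the way seeded aligners do.

#' Local-alignment scoring scheme
#'
#' Match/mismatch rewards plus the Karlin–Altschul parameters `lambda` and
#' `K` that convert raw scores to bit scores.  The defaults mirror
#' megablast-style nucleotide scoring (+1/−2) with the published ungapped
#' Karlin–Altschul values for that matrix.
#'
#' @param match Match reward (positive integer).
#' @param mismatch Mismatch penalty (negative integer).
#' @param gap_open,gap_extend Gap penalties, kept for score bookkeeping of
#'   externally parsed gapped hits; the built-in aligner is ungapped.
#' @param lambda,K Karlin–Altschul statistical parameters (positive).
#' @param word_size Exact-match seed length in bp (>= 8).
#' @param xdrop Extension termination: stop once the running score drops
#'   `xdrop` below its maximum, then trim back to the maximum.
#' @return A `scoring_scheme` object (a validated list).
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L,
                           gap_open = -5L, gap_extend = -2L,
                           lambda = 1.28, K = 0.46,
                           word_size = 16L, xdrop = 20) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  word_size <- as.integer(word_size)
  if (!(mismatch < 0L) || !(match >= 0L)) {
    abort("scoring scheme requires mismatch < 0 <= match")
  }
  if (lambda <= 0 || K <= 0) abort("lambda and K must be positive")
  if (word_size < 8L) abort("word_size must be >= 8")
  structure(
    list(match = match, mismatch = mismatch,
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         lambda = lambda, K = K, word_size = word_size, xdrop = xdrop),
    class = "scoring_scheme")
}

#' Convert a raw alignment score to bits
#'
#' Standard Karlin–Altschul normalisation:
#' \eqn{S' = (\lambda S - \ln K)/\ln 2}.
#'
#' @param raw_score Raw alignment score(s).
#' @param scheme A [scoring_scheme()].
#' @return Bit score(s).
#' @export
#' @examples
#' bit_score(100, scoring_scheme())
bit_score <- function(raw_score, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

# Smallest exact-match length whose all-match raw score reaches `min_bits`.
min_alignment_length <- function(min_bits, scheme = scoring_scheme()) {
  as.integer(ceiling((min_bits * log(2) + log(scheme$K)) /
                       (scheme$lambda * scheme$match)))
}

hit_columns <- function() {
  tibble(query_id = character(), q_start = integer(), q_end = integer(),
         subject_id = character(), s_start = integer(), s_end = integer(),
         strand = character(), raw_score = integer(), bit_score = double(),
         identity = double())
}

#' Parse BLAST-style 12-column tabular alignment output
#'
#' Accepts the standard tabular dialect (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore) with
#' `#`-prefixed comment lines.  Input coordinates are 1-based inclusive with
#' the subject interval reversed for minus-strand hits; output intervals are
#' 0-based half-open on the forward strand with the strand made explicit.
#'
#' @param x Either a character vector of lines or the path of a file.
#' @param query_id Hits whose qseqid differs are skipped (a message reports
#'   the skipped count).
#' @return A hit tibble (`query_id`, `q_start`, `q_end`, `subject_id`,
#'   `s_start`, `s_end`, `strand`, `raw_score` (NA for parsed hits),
#'   `bit_score`, `identity`).
#' @export
parse_tabular_hits <- function(x, query_id) {
  lines <- if (length(x) == 1L && !grepl("\t", x) && file.exists(x)) {
    readLines(x)
  } else {
    x
  }
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(hit_columns())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- idx[which(nf < 12L)[1]]
    abort(sprintf("malformed tabular hit at line %d: expected >= 12 tab-separated fields, got %d",
                  bad, nf[which(nf < 12L)[1]]))
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  num_cols <- c(3:12)
  nums <- suppressWarnings(apply(m[, num_cols, drop = FALSE], 2, as.numeric))
  nums <- matrix(nums, ncol = length(num_cols))
  if (anyNA(nums)) {
    bad_row <- which(apply(nums, 1, anyNA))[1]
    abort(sprintf("malformed tabular hit at line %d: non-numeric field", idx[bad_row]))
  }
  qsel <- m[, 1] == query_id
  n_skipped <- sum(!qsel)
  if (n_skipped > 0L) {
    inform(sprintf("parse_tabular_hits: skipped %d line(s) with qseqid != '%s'",
                   n_skipped, query_id))
  }
  m <- m[qsel, , drop = FALSE]
  nums <- nums[qsel, , drop = FALSE]
  if (nrow(m) == 0L) return(hit_columns())
  qstart <- as.integer(nums[, 5]); qend <- as.integer(nums[, 6])
  sstart <- as.integer(nums[, 7]); send <- as.integer(nums[, 8])
  minus <- sstart > send
  tibble(
    query_id = m[, 1],
    q_start = qstart - 1L, q_end = qend,
    subject_id = m[, 2],
    s_start = ifelse(minus, send - 1L, sstart - 1L),
    s_end = ifelse(minus, sstart, send),
    strand = ifelse(minus, "-", "+"),
    raw_score = NA_integer_,
    bit_score = nums[, 10],
    identity = nums[, 1] / 100
  )
}

#' Write hits in the 12-column tabular dialect
#'
#' Inverse of [parse_tabular_hits()]: intervals are converted back to 1-based
#' inclusive coordinates with the subject interval reversed on minus-strand
#' hits.  pident and bitscore are printed losslessly (`%.17g`) so round-trips
#' preserve them exactly.
#'
#' @param hits A hit tibble.
#' @param path Output file path (or "" for stdout).
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  len <- hits$q_end - hits$q_start
  mism <- as.integer(round((1 - hits$identity) * len))
  minus <- hits$strand == "-"
  sstart <- ifelse(minus, hits$s_end, hits$s_start + 1L)
  send <- ifelse(minus, hits$s_start + 1L, hits$s_end)
  lines <- sprintf("%s\t%s\t%.17g\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.17g",
                   hits$query_id, hits$subject_id, hits$identity * 100,
                   len, mism, 0L,
                   hits$q_start + 1L, hits$q_end, sstart, send,
                   0, hits$bit_score)
  writeLines(lines, path)
  invisible(path)
}

#' Filter hits on a minimum bit score
#'
#' Keeps hits whose bit score is at least `min_bits` (inclusive: a hit at
#' exactly the threshold is kept).  Order is preserved.
#'
#' @param hits A hit tibble.
#' @param min_bits Minimum bit score (default 200, the screening default).
#' @return The filtered hit tibble.
#' @export
filter_hits <- function(hits, min_bits = 200) {
  stopifnot(min_bits >= 0)
  hits[hits$bit_score >= min_bits, , drop = FALSE]
}

#' Align a query against a genome by exact-word seeding and ungapped extension
#'
#' Finds local similarities between the query and every genome record on both
#' strands: exact `word_size`-mers seed candidate diagonals, seeds are
#' extended without gaps under an X-drop rule, trimmed back to the
#' maximum-score extent, and finally anchored so that both hit ends terminate
#' in an exact match of at least `word_size` bases.  Runs of N are never
#' seeded and score as mismatches during extension.
#'
#' @param query A single sequence record (one-row tibble with `id`, `seq`).
#' @param genome A tibble of genome records (`id`, `seq`).
#' @param scheme A [scoring_scheme()].
#' @return A hit tibble sorted by (subject_id, s_start, strand); every hit's
#'   `raw_score` and `identity` are recomputable from the two sequences.
#' @export
align_seed_extend <- function(query, genome, scheme = scoring_scheme()) {
  query <- one_record(query)
  genome <- as_tibble(genome)
  w <- scheme$word_size
  nq <- nchar(query$seq)
  if (nq < w) abort(sprintf("query (%d bp) is shorter than word_size (%d)", nq, w))
  qint <- seq_to_int(query$seq)
  qkmers <- kmer_table(query$seq, w)
  if (nrow(qkmers) == 0L) {
    inform("align_seed_extend: query contains no seedable words (N runs are never seeded)")
    return(hit_columns())
  }
  out <- vector("list", 2L * nrow(genome))
  k <- 0L
  for (gi in seq_len(nrow(genome))) {
    gseq <- genome$seq[gi]
    ns <- nchar(gseq)
    for (str in c("+", "-")) {
      sseq <- if (str == "+") gseq else revcomp(gseq)
      hits <- extend_on_subject(qint, qkmers, sseq, scheme)
      if (nrow(hits) == 0L) next
      if (str == "-") {
        tmp <- hits$s_start
        hits$s_start <- ns - hits$s_end
        hits$s_end <- ns - tmp
      }
      hits$subject_id <- genome$id[gi]
      hits$strand <- str
      k <- k + 1L
      out[[k]] <- hits
    }
  }
  if (k == 0L) return(hit_columns())
  hits <- bind_rows(out[seq_len(k)])
  hits$query_id <- query$id
  hits$bit_score <- bit_score(hits$raw_score, scheme)
  hits <- hits[!duplicated(hits[c("subject_id", "strand", "q_start", "q_end", "s_start", "s_end")]), ]
  hits <- arrange(hits, .data$subject_id, .data$s_start, .data$strand)
  hits[names(hit_columns())]
}

# k-mer position table (0-based positions), N-containing words excluded
kmer_table <- function(seq, w) {
  n <- nchar(seq)
  if (n < w) return(data.table::data.table(kmer = character(), pos = integer()))
  pos <- 0:(n - w)
  kmer <- substring(seq, pos + 1L, pos + w)
  keep <- !grepl("N", kmer, fixed = TRUE)
  data.table::data.table(kmer = kmer[keep], pos = pos[keep])
}

# Seed + extend the (already oriented) subject sequence.  Returns a tibble
# with q_start/q_end/s_start/s_end/raw_score/identity in subject-local
# coordinates on the strand supplied.
extend_on_subject <- function(qint, qkmers, sseq, scheme) {
  w <- scheme$word_size
  skmers <- kmer_table(sseq, w)
  if (nrow(skmers) == 0L) return(tibble())
  seeds <- merge(qkmers, skmers, by = "kmer", allow.cartesian = TRUE,
                 suffixes = c("_q", "_s"))
  if (nrow(seeds) == 0L) return(tibble())
  sint <- seq_to_int(sseq)
  nq <- length(qint); ns <- length(sint)
  diags <- sort(unique(seeds$pos_s - seeds$pos_q))
  acc <- vector("list", length(diags))
  for (i in seq_along(diags)) {
    d <- diags[i]
    # overlap of query/subject along this diagonal, in query coordinates
    lo <- max(0L, -d); hi <- min(nq, ns - d)   # [lo, hi)
    if (hi - lo < w) next
    m <- qint[(lo + 1L):hi] == sint[(lo + d + 1L):(hi + d)] &
      qint[(lo + 1L):hi] >= 0L
    segs <- extend_diagonal(m, w, scheme$match, scheme$mismatch, scheme$xdrop)
    if (nrow(segs) == 0L) next
    acc[[i]] <- tibble(
      q_start = lo + segs$start, q_end = lo + segs$end,
      s_start = lo + d + segs$start, s_end = lo + d + segs$end,
      raw_score = segs$raw, identity = segs$identity)
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (length(acc) == 0L) return(tibble())
  bind_rows(acc)
}

# X-drop extension of all maximal exact runs >= w along one diagonal.
# `m` is the per-position match vector; returns 0-based [start, end)
# segments local to `m`, with raw score and identity, trimmed so both ends
# sit on an exact run of >= w matches.
extend_diagonal <- function(m, w, match, mismatch, xdrop) {
  r <- rle(m)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths            # 0-based starts
  core <- which(r$values & r$lengths >= w)
  if (length(core) == 0L) {
    return(tibble(start = integer(), end = integer(),
                  raw = integer(), identity = double()))
  }
  sc <- ifelse(m, match, mismatch)
  n <- length(m)
  out_s <- out_e <- out_raw <- integer(0)
  out_id <- double(0)
  prev_end <- -1L
  for (ci in core) {
    a <- run_start[ci]; b <- run_end[ci]      # exact run [a, b)
    if (a < prev_end) next                    # already inside previous hit
    # rightward: scores of positions b..n-1
    e <- b
    if (b < n) {
      cs <- cumsum(sc[(b + 1L):n])
      drop_at <- which(cummax(cs) - cs >= xdrop)
      lim <- if (length(drop_at)) drop_at[1] else length(cs)
      best <- which.max(cs[seq_len(lim)])
      if (cs[best] > 0) e <- b + best
    }
    # leftward: scores of positions a-1..0
    s <- a
    if (a > 0L) {
      cs <- cumsum(sc[a:1])
      drop_at <- which(cummax(cs) - cs >= xdrop)
      lim <- if (length(drop_at)) drop_at[1] else length(cs)
      best <- which.max(cs[seq_len(lim)])
      if (cs[best] > 0) s <- a - best
    }
    # anchor both ends on an exact >= w run inside [s, e)
    anchors <- which(r$values & r$lengths >= w &
                       run_start >= s & run_end <= e)
    s <- run_start[anchors[1]]
    e <- run_end[anchors[length(anchors)]]
    seg <- m[(s + 1L):e]
    out_s <- c(out_s, s); out_e <- c(out_e, e)
    out_raw <- c(out_raw, sum(seg) * match + sum(!seg) * mismatch)
    out_id <- c(out_id, mean(seg))
    prev_end <- e
  }
  tibble(start = out_s, end = out_e, raw = as.integer(out_raw), identity = out_id)
}
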