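# Per-base similarity classification of the query.  Every query position is
# mapped through the thresholded hits into genomic loci; a position with no
# genomic copy beyond its own is UNIQUE, one with extra copies confined to
# the query's own locus is SIMILAR_LOCAL, and one with any copy elsewhere in
# the genome is SIMILAR_GLOBAL (the white / cyan / gray classes of the
# original track figure).

MASK_LEVELS <- c("UNIQUE", "SIMILAR_GLOBAL", "SIMILAR_LOCAL")

new_similarity_mask <- function(query_id, labels, min_bits) {
  stopifnot(all(labels %in% 1:3))
  structure(list(query_id = query_id, labels = as.integer(labels),
                 min_bits = min_bits),
            class = "similarity_mask")
}

#' @export
print.similarity_mask <- function(x, ...) {
  n <- length(x$labels)
  counts <- tabulate(x$labels, 3L)
  cat(sprintf("<similarity_mask> %s: %s bp at min_bits = %g\n",
              x$query_id, fmt_bp(n), x$min_bits))
  for (i in 1:3) {
    cat(sprintf("  %-14s %10s bp (%5.1f%%)\n", MASK_LEVELS[i],
                fmt_bp(counts[i]), 100 * counts[i] / n))
  }
  invisible(x)
}

#' Per-label base counts of a similarity mask
#' @param x A `similarity_mask`.
#' @param ... Unused.
#' @return A one-row tibble with query id, length, and per-label base counts.
#' @export
glance.similarity_mask <- function(x, ...) {
  counts <- tabulate(x$labels, 3L)
  tibble(query_id = x$query_id, length = length(x$labels),
         min_bits = x$min_bits,
         unique = counts[1], similar_global = counts[2],
         similar_local = counts[3])
}

#' Maximal same-label regions of a similarity mask
#' @param x A `similarity_mask`.
#' @param ... Unused.
#' @return A region tibble (`label`, `start`, `end`), 0-based half-open,
#'   tiling the query exactly.
#' @export
tidy.similarity_mask <- function(x, ...) {
  r <- rle(x$labels)
  end <- cumsum(r$lengths)
  tibble(label = MASK_LEVELS[r$values],
         start = as.integer(end - r$lengths), end = as.integer(end))
}

mask_labels <- function(mask) MASK_LEVELS[mask$labels]

#' Locate the query's own copy in the genome (the self locus)
#'
#' The self locus is the genomic interval the query itself derives from; it
#' is the reference against which "locally repetitive" is judged.  Declared
#' coordinates win; otherwise the near-identity hit covering (almost) the
#' whole query with the highest bit score is taken.
#'
#' @param hits Bit-score-filtered hit tibble.
#' @param query The query record.
#' @param declared Optional declared origin: a list/one-row data frame with
#'   `chrom`, `start`, `end` (1-based inclusive, Ensembl style), e.g. from a
#'   `chrom:start-end` FASTA header.
#' @param min_identity,min_coverage Detection thresholds for the self hit.
#' @return A `self_locus` object: `subject_id`, `start`, `end` (0-based
#'   half-open) and `source` ("declared" or "detected").
#' @export
locate_self <- function(hits, query, declared = NULL,
                        min_identity = 0.99, min_coverage = 0.95) {
  query <- one_record(query)
  if (!is.null(declared) && !all(is.na(unlist(declared[c("chrom", "start", "end")])))) {
    declared <- as.list(declared)
    return(structure(list(subject_id = declared$chrom,
                          start = as.integer(declared$start) - 1L,
                          end = as.integer(declared$end),
                          source = "declared"),
                     class = "self_locus"))
  }
  nq <- nchar(query$seq)
  cand <- hits[hits$identity >= min_identity &
                 (hits$q_end - hits$q_start) >= min_coverage * nq, , drop = FALSE]
  if (nrow(cand) == 0L) {
    abort("self locus not found: no near-identity hit covers the query (is the query part of this genome build?)")
  }
  cand <- arrange(cand, desc(.data$bit_score), .data$subject_id, .data$s_start)
  structure(list(subject_id = cand$subject_id[1],
                 start = cand$s_start[1], end = cand$s_end[1],
                 source = "detected"),
            class = "self_locus")
}

#' @export
print.self_locus <- function(x, ...) {
  cat(sprintf("<self_locus> %s:%s (%s, %s bp)\n", x$subject_id,
              fmt_interval_1based(x$start, x$end), x$source,
              fmt_bp(x$end - x$start)))
  invisible(x)
}

#' Classify every query base as unique, globally similar, or locally repetitive
#'
#' For each query position the covering hits map it into genomic loci;
#' mapped positions closer than `tol` bases are counted as one locus.  The
#' query's own locus always counts once.  A position with no additional
#' locus is UNIQUE; with additional loci all confined to the self locus,
#' SIMILAR_LOCAL; with any additional locus elsewhere (including a locus
#' only partially inside the self interval), SIMILAR_GLOBAL.  Minus-strand
#' hits count like plus-strand ones.
#'
#' @param query The query record.
#' @param hits Bit-score-filtered hit tibble.
#' @param self_locus A [locate_self()] result.
#' @param min_bits The threshold the hits were filtered at (recorded in the
#'   mask).
#' @param tol Locus-merging and self-recognition tolerance in bp; defaults
#'   to the seed word size, below which seeded alignment cannot resolve
#'   boundaries anyway.
#' @return A `similarity_mask`.
#' @export
classify <- function(query, hits, self_locus, min_bits = 200, tol = 16L) {
  query <- one_record(query)
  nq <- nchar(query$seq)
  if (nrow(hits) > 0 && (any(hits$q_start < 0L) || any(hits$q_end > nq))) {
    abort("corrupt input: hit query interval outside the query sequence")
  }
  labels <- rep(1L, nq)                       # UNIQUE
  if (nrow(hits) == 0L) {
    return(new_similarity_mask(query$id, labels, min_bits))
  }
  bp <- sort(unique(c(0L, nq, hits$q_start, hits$q_end)))
  seg_s <- bp[-length(bp)]; seg_e <- bp[-1]
  hr <- IRanges::IRanges(hits$q_start + 1L, hits$q_end)
  sr <- IRanges::IRanges(seg_s + 1L, seg_e)
  ov <- IRanges::findOverlaps(sr, hr)
  cover <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  inside_self <- hits$subject_id == self_locus$subject_id &
    hits$s_start >= self_locus$start & hits$s_end <= self_locus$end
  for (si in names(cover)) {
    i <- as.integer(si)
    hh <- cover[[si]]
    p <- (seg_s[i] + seg_e[i]) %/% 2L         # segment midpoint
    mapped <- ifelse(hits$strand[hh] == "+",
                     hits$s_start[hh] + (p - hits$q_start[hh]),
                     hits$s_end[hh] - 1L - (p - hits$q_start[hh]))
    self_point <- self_locus$start + p
    is_self <- hits$subject_id[hh] == self_locus$subject_id &
      abs(mapped - self_point) <= tol
    if (!any(!is_self)) next                  # only the self copy
    ns_subj <- hits$subject_id[hh][!is_self]
    ns_map <- mapped[!is_self]
    ns_inside <- inside_self[hh][!is_self]
    # cluster mapped points within tol on the same subject -> distinct loci
    ord <- order(ns_subj, ns_map)
    ns_subj <- ns_subj[ord]; ns_map <- ns_map[ord]; ns_inside <- ns_inside[ord]
    new_cluster <- c(TRUE, ns_subj[-1] != ns_subj[-length(ns_subj)] |
                       diff(ns_map) > tol)
    cl <- cumsum(new_cluster)
    # a locus is external if any supporting hit is not fully inside the self
    # locus interval (border-straddling loci count as external)
    cluster_external <- tapply(!ns_inside, cl, any)
    labels[(seg_s[i] + 1L):seg_e[i]] <-
      if (any(cluster_external)) 2L else 3L
  }
  new_similarity_mask(query$id, labels, min_bits)
}

#' Extract maximal regions of one mask label
#'
#' @param mask A `similarity_mask`.
#' @param label One of `"UNIQUE"`, `"SIMILAR_GLOBAL"`, `"SIMILAR_LOCAL"`.
#' @return A region tibble sorted by `start`; regions are maximal runs of
#'   the label and non-overlapping.
#' @export
extract_regions <- function(mask, label) {
  label <- match.arg(label, MASK_LEVELS)
  regions <- tidy.similarity_mask(mask)
  out <- regions[regions$label == label, , drop = FALSE]
  arrange(out, .data$start)
}

#' Unique blocks long enough for single-copy probe design
#'
#' Contiguous UNIQUE stretches strictly exceeding `min_len` (default 4 kb:
#' a 4000 bp block is excluded, a 4001 bp block included).
#'
#' @param mask A `similarity_mask`.
#' @param min_len Minimum block length in bp (strict inequality).
#' @return A region tibble of qualifying UNIQUE blocks sorted by `start`.
#' @export
unique_blocks <- function(mask, min_len = 4000L) {
  stopifnot(min_len >= 0)
  u <- extract_regions(mask, "UNIQUE")
  u[(u$end - u$start) > min_len, , drop = FALSE]
}

#' Nearly contiguous similar blocks
#'
#' Merges SIMILAR_GLOBAL / SIMILAR_LOCAL runs separated by at most
#' `max_gap` bases of other labels into blocks; block boundaries always lie
#' on similar-labelled bases.
#'
#' @param mask A `similarity_mask`.
#' @param max_gap Permissible gap in bp (default 500).
#' @return A region tibble (`label` = `"SIMILAR"`) sorted by `start`.
#' @export
similar_blocks <- function(mask, max_gap = 500L) {
  stopifnot(max_gap >= 0)
  regions <- tidy.similarity_mask(mask)
  sim <- regions[regions$label != "UNIQUE", c("start", "end")]
  if (nrow(sim) == 0L) {
    return(tibble(label = character(), start = integer(), end = integer()))
  }
  merged <- merge_intervals(sim, gap = max_gap)
  tibble(label = "SIMILAR", start = merged$start, end = merged$end)
}
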