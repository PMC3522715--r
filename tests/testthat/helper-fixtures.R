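# Fixtures are generated in code; nothing is stored on disk.

# Small deterministic random DNA string.
rand_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# A tiny planted genome: query duplicated verbatim, plus optional extra
# copies of a marked segment.  Returns record tibbles.
plant_genome <- function(query_seq, before = 500L, after = 500L, seed = 1L,
                         extra = character()) {
  left <- rand_dna(before, seed)
  right <- rand_dna(after, seed + 1L)
  genome <- paste0(left, query_seq, paste(extra, collapse = ""), right)
  list(
    query = tibble::tibble(id = "q", seq = query_seq,
                           chrom = NA_character_, start = NA_integer_,
                           end = NA_integer_),
    genome = tibble::tibble(id = "g", seq = genome,
                            chrom = NA_character_, start = NA_integer_,
                            end = NA_integer_),
    locus = list(start = before, end = before + nchar(query_seq)))
}

# Construct a similarity mask from a compact label string:
# U = UNIQUE, G = SIMILAR_GLOBAL, L = SIMILAR_LOCAL.
mask_from_string <- function(s, query_id = "q", min_bits = 200) {
  code <- c(U = 1L, G = 2L, L = 3L)
  fishprobes:::new_similarity_mask(
    query_id, unname(code[strsplit(s, "")[[1]]]), min_bits)
}

# Positions within `collar` bases of a truth label change (both sides),
# as a logical vector over the mask length.
collar_positions <- function(truth_mask, collar = 16L) {
  lab <- truth_mask$labels
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  boundaries <- ends[-length(ends)]           # 0-based boundary positions
  out <- logical(length(lab))
  for (b in boundaries) {
    lo <- max(1L, b - collar + 1L); hi <- min(length(lab), b + collar)
    out[lo:hi] <- TRUE
  }
  out
}

# Random candidate-target instances for selection tests: n candidate
# windows on a line, each binding its own interval plus 0-2 extra sites.
random_candidates <- function(n, seed, span = 20000L) {
  withr::with_seed(seed, {
    starts <- sort(sample.int(span - 1500L, n))
    lens <- sample(seq(500L, 1500L, by = 100L), n, replace = TRUE)
    binding <- lapply(seq_len(n), function(i) {
      own <- tibble::tibble(start = starts[i], end = starts[i] + lens[i])
      k <- sample(0:2, 1)
      if (k > 0) {
        es <- sample.int(span, k)
        el <- sample(seq(400L, 1200L, by = 100L), k, replace = TRUE)
        own <- dplyr::bind_rows(own, tibble::tibble(start = es, end = es + el))
      }
      fishprobes::merge_intervals(own)
    })
    tibble::tibble(kind = "repetitive", label = NA_character_,
                   start = starts, end = starts + lens,
                   binding = binding,
                   cumulative_binding = vapply(binding,
                                               fishprobes::cumulative_binding,
                                               integer(1)))
  })
}

# Greedy/oracle pair on one instance; returns c(greedy, optimal).
selection_values <- function(cand) {
  sel <- fishprobes::select_repeat_targets(cand, min_gain = 1L)
  greedy <- fishprobes:::interval_union_length(dplyr::bind_rows(sel$binding))
  opt <- fishprobes::brute_force_select(cand)$value
  c(greedy = greedy, optimal = opt)
}

expect_masks_equal_outside_collars <- function(mask, ref, collar = 16L) {
  stopifnot(length(mask$labels) == length(ref$labels))
  keep <- !collar_positions(ref, collar)
  expect_identical(mask$labels[keep], ref$labels[keep])
}
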