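make_hit <- function(q_start, q_end, s_start, s_end, strand = "+",
                     subject = "g", bits = 500, identity = 1) {
  tibble::tibble(query_id = "q", q_start = q_start, q_end = q_end,
                 subject_id = subject, s_start = s_start, s_end = s_end,
                 strand = strand, raw_score = NA_integer_,
                 bit_score = bits, identity = identity)
}

test_that("declared coordinates define the self locus verbatim", {
  q <- tibble::tibble(id = "q", seq = rand_dna(200, 1))
  self <- locate_self(make_hit(0, 200, 900, 1100),
                      q, declared = list(chrom = "chr14", start = 501, end = 700))
  expect_equal(self$subject_id, "chr14")
  expect_equal(self$start, 500L)
  expect_equal(self$end, 700L)
  expect_equal(self$source, "declared")
})

test_that("the self locus is detected from the dominant near-identity hit", {
  q <- tibble::tibble(id = "q", seq = rand_dna(1000, 2))
  hits <- dplyr::bind_rows(
    make_hit(0, 1000, 5000, 6000, bits = 1800),
    make_hit(100, 400, 9000, 9300, bits = 500))
  self <- locate_self(hits, q)
  expect_equal(self$start, 5000L)
  expect_equal(self$source, "detected")
  # a duplicated locus: the higher bit score wins, ties break
  # lexicographically on (subject, start)
  dup <- dplyr::bind_rows(
    make_hit(0, 1000, 5000, 6000, bits = 1800),
    make_hit(0, 1000, 9000, 10000, bits = 1900))
  expect_equal(locate_self(dup, q)$start, 9000L)
  tie <- dplyr::bind_rows(
    make_hit(0, 1000, 9000, 10000, bits = 1800),
    make_hit(0, 1000, 5000, 6000, bits = 1800))
  expect_equal(locate_self(tie, q)$start, 5000L)
  expect_error(locate_self(make_hit(0, 100, 0, 100, bits = 10), q),
               "self locus not found")
})

test_that("a lone-copy query is entirely unique", {
  q <- tibble::tibble(id = "q", seq = rand_dna(500, 3))
  self <- structure(list(subject_id = "g", start = 100L, end = 600L,
                         source = "declared"), class = "self_locus")
  mask <- classify(q, make_hit(0, 500, 100, 600), self, tol = 10)
  expect_true(all(mask$labels == 1L))
  expect_equal(length(mask$labels), 500L)
})

test_that("hits outside the query bounds are rejected as corrupt", {
  q <- tibble::tibble(id = "q", seq = rand_dna(100, 4))
  self <- structure(list(subject_id = "g", start = 0L, end = 100L,
                         source = "declared"), class = "self_locus")
  expect_error(classify(q, make_hit(50, 150, 0, 100), self), "corrupt")
})

test_that("within-locus and global repeats are classified per base", {
  # locus with a 500 bp segment R twice inside, once (optionally) outside
  seg <- tibble::tibble(
    kind = c("unique", "unique", "local_repeat", "unique", "local_repeat",
             "unique", "global_repeat", "unique", "global_repeat", "unique"),
    family = c(NA, NA, 1, NA, 1, NA, 1, NA, 1, NA),
    length = c(3000, 2000, 500, 2000, 500, 2000, 500, 1500, 500, 3000),
    divergence = 0,
    in_locus = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  sim <- generate_genome(genome_spec(seg, seed = 5))
  scheme <- scoring_scheme()
  hits <- filter_hits(align_seed_extend(sim$query, sim$genome, scheme), 200)
  self <- locate_self(hits, sim$query)
  mask <- classify(sim$query, hits, self, tol = scheme$word_size)
  expect_masks_equal_outside_collars(mask, sim$truth, collar = scheme$word_size)
  # and agreement with the independent per-position multiplicity oracle
  oracle <- brute_force_mask(sim$query, sim$genome, scheme, 200,
                             self = sim$locus)
  expect_masks_equal_outside_collars(mask, oracle, collar = scheme$word_size)
})

test_that("mask labels partition the query", {
  for (s in c(6, 7)) {
    sim <- generate_genome(random_locus_spec(s, divergence = 0.02))
    scheme <- scoring_scheme()
    hits <- filter_hits(align_seed_extend(sim$query, sim$genome, scheme), 200)
    mask <- classify(sim$query, hits, locate_self(hits, sim$query),
                     tol = scheme$word_size)
    counts <- tabulate(mask$labels, 3L)
    expect_equal(sum(counts), nchar(sim$query$seq))
    regions <- tidy(mask)
    expect_equal(regions$start[1], 0L)
    expect_equal(regions$end[nrow(regions)], nchar(sim$query$seq))
    expect_true(all(regions$start[-1] == regions$end[-nrow(regions)]))
  }
})

test_that("maximal regions are extracted per label", {
  mask <- mask_from_string("UUGGUU")
  u <- extract_regions(mask, "UNIQUE")
  expect_equal(u$start, c(0L, 4L))
  expect_equal(u$end, c(2L, 6L))
  uniform <- extract_regions(mask_from_string(strrep("L", 7)), "SIMILAR_LOCAL")
  expect_equal(as.data.frame(uniform[c("start", "end")]),
               data.frame(start = 0L, end = 7L))
  # alternating labels: singleton regions, and all labels together tile the
  # query exactly (checked against a naive run-length scan)
  s <- paste(rep(c("U", "G"), 10), collapse = "")
  mask <- mask_from_string(s)
  all_regions <- dplyr::arrange(dplyr::bind_rows(
    extract_regions(mask, "UNIQUE"),
    extract_regions(mask, "SIMILAR_GLOBAL"),
    extract_regions(mask, "SIMILAR_LOCAL")), start)
  expect_equal(nrow(all_regions), 20L)
  expect_true(all(all_regions$end - all_regions$start == 1L))
  expect_equal(all_regions$start, 0:19)
})

test_that("unique blocks must strictly exceed the length cutoff", {
  mask <- mask_from_string(paste0(strrep("U", 4000), "G",
                                  strrep("U", 4001), "G"))
  blocks <- unique_blocks(mask, min_len = 4000)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$end - blocks$start, 4001L)
  expect_equal(nrow(unique_blocks(mask, min_len = 0)), 2L)
})

test_that("similar blocks merge across gaps up to the configured size", {
  mask <- mask_from_string("GGUUGG")
  one <- similar_blocks(mask, max_gap = 2)
  expect_equal(as.data.frame(one[c("start", "end")]),
               data.frame(start = 0L, end = 6L))
  two <- similar_blocks(mask, max_gap = 1)
  expect_equal(two$start, c(0L, 4L))
  expect_equal(two$end, c(2L, 6L))
  # max_gap 0: equal to directly adjacent merges of a naive scanner
  withr::with_seed(8, {
    for (i in 1:5) {
      s <- paste(sample(c("U", "G", "L"), 60, replace = TRUE), collapse = "")
      mask <- mask_from_string(s)
      got <- similar_blocks(mask, max_gap = 0)
      lab <- strsplit(s, "")[[1]] != "U"
      r <- rle(lab)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths
      want <- tibble::tibble(start = starts[r$values], end = ends[r$values])
      expect_equal(as.data.frame(got[c("start", "end")]),
                   as.data.frame(want))
    }
  })
})

test_that("raising the bit threshold never shrinks the unique set", {
  sim <- generate_genome(random_locus_spec(9, divergence = 0))
  scheme <- scoring_scheme()
  hits <- align_seed_extend(sim$query, sim$genome, scheme)
  prev_unique <- -1L
  for (th in c(100, 200, 400)) {
    th_hits <- filter_hits(hits, th)
    mask <- classify(sim$query, th_hits, locate_self(th_hits, sim$query),
                     min_bits = th, tol = scheme$word_size)
    n_unique <- sum(mask$labels == 1L)
    expect_gte(n_unique, prev_unique)
    prev_unique <- n_unique
  }
})
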