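self_at <- function(start, end, subject = "g") {
  structure(list(subject_id = subject, start = start, end = end,
                 source = "declared"), class = "self_locus")
}

local_hit <- function(q_start, q_end, s_start, s_end, self) {
  tibble::tibble(query_id = "q", q_start = q_start, q_end = q_end,
                 subject_id = self$subject_id,
                 s_start = self$start + s_start, s_end = self$start + s_end,
                 strand = "+", raw_score = NA_integer_, bit_score = 500,
                 identity = 0.99)
}

test_that("repeat families form by transitive closure of alignment links", {
  self <- self_at(0L, 10000L)
  mask <- mask_from_string(strrep("L", 10000))
  # R1 <-> R2 and R2 <-> R3, but no direct R1 <-> R3 hit
  hits <- dplyr::bind_rows(
    local_hit(1000, 1500, 4000, 4500, self),
    local_hit(4000, 4500, 7000, 7500, self))
  fams <- build_repeat_families(hits, self, mask)
  expect_equal(length(unique(fams$family)), 1L)
  expect_equal(nrow(fams), 3L)
  expect_equal(sort(fams$start), c(1000L, 4000L, 7000L))
  # two unrelated repeat pairs give two families
  hits2 <- dplyr::bind_rows(
    local_hit(1000, 1500, 4000, 4500, self),
    local_hit(6000, 6400, 8000, 8400, self))
  fams2 <- build_repeat_families(hits2, self, mask)
  expect_equal(length(unique(fams2$family)), 2L)
  # a single linked pair is one family of two members
  fams3 <- build_repeat_families(hits, self, mask)[1:2, ]
  expect_equal(nrow(fams3), 2L)
})

test_that("family members are trimmed to locally repetitive bases", {
  self <- self_at(0L, 4000L)
  mask <- mask_from_string(paste0(strrep("U", 1000), strrep("L", 500),
                                  strrep("U", 1500), strrep("L", 500),
                                  strrep("U", 500)))
  hits <- local_hit(1000, 1500, 3000, 3500, self)
  fams <- build_repeat_families(hits, self, mask)
  expect_equal(nrow(fams), 2L)
  expect_true(all(fams$start %in% c(1000L, 3000L)))
  expect_true(all(fams$end - fams$start == 500L))
})

test_that("self hits and outside hits never seed repeat families", {
  self <- self_at(100L, 5100L)
  mask <- mask_from_string(strrep("L", 5000))
  selfish <- local_hit(0, 5000, 0, 5000, self)
  outside <- tibble::tibble(query_id = "q", q_start = 0L, q_end = 500L,
                            subject_id = "g", s_start = 20000L, s_end = 20500L,
                            strand = "+", raw_score = NA_integer_,
                            bit_score = 500, identity = 1)
  expect_equal(nrow(build_repeat_families(
    dplyr::bind_rows(selfish, outside), self, mask)), 0L)
})

test_that("tiling maximises covered bases within the length limits", {
  cfg <- design_config()
  blk <- function(len) tibble::tibble(label = "UNIQUE", start = 0L,
                                      end = as.integer(len))
  one <- tile_single_copy(blk(10000), cfg)
  expect_equal(nrow(one), 1L)
  expect_equal(one$end - one$start, 10000L)
  two <- tile_single_copy(blk(10500), cfg)
  expect_equal(nrow(two), 2L)
  expect_equal(sum(two$end - two$start), 10500L)
  expect_true(all(two$end - two$start >= 1000L & two$end - two$start <= 10000L))
  expect_equal(two$start[2], two$end[1])      # consecutive tiling
  none <- tile_single_copy(blk(999), cfg)
  expect_equal(nrow(none), 0L)
  expect_equal(nrow(attr(none, "skipped")), 1L)
  # coverage equals the integer-partition optimum over k parts in [min, max]
  partition_optimum <- function(B, m, M) {
    best <- 0L
    for (k in seq_len(B %/% m)) {
      if (k * m > B) break
      best <- max(best, min(B, k * M))
    }
    best
  }
  withr::with_seed(10, {
    for (i in 1:20) {
      B <- sample.int(30000L, 1)
      tiles <- tile_single_copy(blk(B), cfg)
      expect_equal(sum(tiles$end - tiles$start),
                   partition_optimum(B, 1000L, 10000L))
    }
  })
})

test_that("candidate windows demand local purity and carry family binding", {
  n <- 4000L
  mask <- mask_from_string(paste0(strrep("L", 1500), strrep("U", 1000),
                                  strrep("G", 500), strrep("L", 1000)))
  fams <- tibble::tibble(family = c(1L, 1L), start = c(0L, 6000L),
                         end = c(1500L, 7500L))
  cfg <- design_config()
  block <- tibble::tibble(start = 0L, end = 1500L)
  cand <- candidate_repeat_windows(block, fams, mask, cfg)
  expect_gt(nrow(cand), 0L)
  full <- cand[cand$start == 0 & cand$end == 1500, ]
  expect_equal(nrow(full), 1L)
  sites <- full$binding[[1]]
  expect_true(any(sites$start == 6000L))      # other family copy included
  expect_equal(full$cumulative_binding, 3000L)
  # a window overlapping SIMILAR_GLOBAL bases is always rejected
  block2 <- tibble::tibble(start = 2500L, end = 4000L)
  cand2 <- candidate_repeat_windows(block2, fams, mask, cfg)
  expect_true(all(cand2$start >= 3000L))
  # exhaustive scan oracle: every returned window is >= 90% local, 0% global
  lab <- strsplit(paste0(strrep("L", 1500), strrep("U", 1000),
                         strrep("G", 500), strrep("L", 1000)), "")[[1]]
  for (i in seq_len(nrow(cand2))) {
    win <- lab[(cand2$start[i] + 1):cand2$end[i]]
    expect_gte(mean(win == "L"), 0.9)
    expect_equal(sum(win == "G"), 0L)
  }
})

test_that("greedy selection maximises marginal binding gain deterministically", {
  iv <- function(s, e) tibble::tibble(start = as.integer(s), end = as.integer(e))
  cand <- tibble::tibble(
    kind = "repetitive", label = NA_character_,
    start = c(0L, 2000L, 4000L), end = c(1000L, 3000L, 5000L),
    binding = list(
      dplyr::bind_rows(iv(0, 1000), iv(4000, 5000), iv(10000, 18000)), # A: 10 kb
      dplyr::bind_rows(iv(2000, 3000), iv(30000, 37000)),   # B: 8 kb disjoint
      dplyr::bind_rows(iv(4000, 5000), iv(10000, 18000))),  # C: 9 kb inside A
    cumulative_binding = c(10000L, 8000L, 9000L))
  sel <- select_repeat_targets(cand, min_gain = 500)
  expect_equal(sel$start, c(0L, 2000L))
  union_len <- fishprobes:::interval_union_length(dplyr::bind_rows(sel$binding))
  expect_equal(union_len, 18000L)
  expect_equal(union_len, brute_force_select(cand)$value)
  # single candidate above the gain floor is selected; below it, nothing is
  one <- cand[1, ]
  expect_equal(nrow(select_repeat_targets(one, min_gain = 500)), 1L)
  expect_equal(nrow(select_repeat_targets(one, min_gain = 20000)), 0L)
})

test_that("restriction sites are scanned on both strands with overlaps", {
  expect_equal(scan_restriction_sites("GGATCGATGG", "ATCGAT")$pos, 2L)
  expect_equal(nrow(scan_restriction_sites(rand_dna(50, 1), "AAAAAAAAAA")), 0L)
  expect_equal(scan_restriction_sites("ATCGATCGAT", "ATCGAT")$pos, c(0L, 4L))
  # non-palindromic site: the reverse complement is reported too
  hits <- scan_restriction_sites("GGTCTCAAGAGACC", "GGTCTC")
  expect_equal(hits$pos, c(0L, 8L))
  # IUPAC ambiguity codes are honoured (GGWCC matches GGACC and GGTCC)
  expect_equal(scan_restriction_sites("GGACCGGTCC", "GGWCC")$pos, c(0L, 5L))
})

test_that("verify mode annotates and enforce mode clears all sites", {
  cfg <- design_config()
  site <- "ATCGAT"
  # template: 3000 bp block with one site 50 bp into the first amplicon
  tpl <- rand_dna(3000, 20)
  tpl <- gsub("ATCGAT", "ATCGTT", tpl)        # clear chance occurrences
  substring(tpl, 51, 56) <- site
  blocks <- tibble::tibble(label = "UNIQUE", start = 0L, end = 3000L)
  targets <- tile_single_copy(blocks, cfg)
  targets <- fishprobes:::assign_labels(targets)
  ver <- enforce_restriction_free(targets, tpl, cfg, blocks = blocks,
                                  mode = "verify")
  expect_equal(ver$start, targets$start)      # intervals untouched
  expect_equal(ver$sites[[1]], 50L)
  enf <- enforce_restriction_free(targets, tpl, cfg, blocks = blocks,
                                  mode = "enforce")
  expect_gt(nrow(enf), 0L)
  for (i in seq_len(nrow(enf))) {
    amp <- substring(tpl, enf$start[i] + 1L, enf$end[i])
    expect_equal(nrow(scan_restriction_sites(amp, site)), 0L)
  }
  # the shifted amplicon starts past the site
  expect_gte(enf$start[1], 53L)
})

test_that("a centered site in a minimal block splits into two minimal amplicons", {
  cfg <- design_config()
  tpl <- gsub("ATCGAT", "ATCGTT", rand_dna(2000, 21))
  substring(tpl, 998, 1003) <- "ATCGAT"       # centered occurrence
  blocks <- tibble::tibble(label = "UNIQUE", start = 0L, end = 2000L)
  targets <- fishprobes:::assign_labels(tile_single_copy(blocks, cfg))
  enf <- enforce_restriction_free(targets, tpl, cfg, blocks = blocks,
                                  mode = "enforce")
  expect_equal(nrow(enf), 2L)
  expect_equal(enf$end - enf$start, c(1000L, 1000L))
  for (i in 1:2) {
    amp <- substring(tpl, enf$start[i] + 1L, enf$end[i])
    expect_equal(nrow(scan_restriction_sites(amp, "ATCGAT")), 0L)
  }
})

test_that("cumulative binding is the union length of the binding sites", {
  iv <- function(s, e) tibble::tibble(start = as.integer(s), end = as.integer(e))
  expect_equal(cumulative_binding(dplyr::bind_rows(iv(0, 100), iv(200, 350))), 250L)
  expect_equal(cumulative_binding(dplyr::bind_rows(iv(0, 100), iv(50, 150))), 150L)
  withr::with_seed(11, {
    for (i in 1:10) {
      s <- sample.int(500L, 8)
      b <- iv(s, s + sample.int(100L, 8))
      per_base <- sum(Reduce(`|`, lapply(seq_len(nrow(b)), function(j) {
        x <- logical(700); x[(b$start[j] + 1):b$end[j]] <- TRUE; x
      })))
      expect_equal(cumulative_binding(b), per_base)
    }
  })
})
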