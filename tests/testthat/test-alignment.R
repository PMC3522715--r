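test_that("tabular hits map fields and coordinate conventions correctly", {
  lines <- c(
    "# comment line",
    "q\tch14\t100.00\t500\t0\t0\t1\t500\t1001\t1500\t0.0\t924",
    "q\tch14\t98.00\t500\t10\t0\t1\t500\t1500\t1001\t0.0\t800")
  hits <- parse_tabular_hits(lines, "q")
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$q_start[1], 0L)
  expect_equal(hits$q_end[1], 500L)
  expect_equal(hits$s_start[1], 1000L)
  expect_equal(hits$s_end[1], 1500L)
  expect_equal(hits$strand[1], "+")
  expect_equal(hits$bit_score[1], 924)
  expect_equal(hits$identity[1], 1)
  # reversed subject coordinates signal the minus strand, stored forward
  expect_equal(hits$strand[2], "-")
  expect_equal(hits$s_start[2], 1000L)
  expect_equal(hits$s_end[2], 1500L)
})

test_that("tabular parsing rejects malformed lines and skips foreign queries", {
  expect_error(parse_tabular_hits(c("a\tb\t1"), "q"), "line 1")
  expect_error(
    parse_tabular_hits("q\tch\tx\t500\t0\t0\t1\t500\t1\t500\t0\t900", "q"),
    "non-numeric")
  expect_equal(nrow(parse_tabular_hits(character(), "q")), 0L)
  expect_message(
    hits <- parse_tabular_hits(
      c("other\tch\t100\t50\t0\t0\t1\t50\t1\t50\t0\t90"), "q"),
    "skipped 1")
  expect_equal(nrow(hits), 0L)
})

test_that("hits survive a tabular round trip losslessly", {
  sim <- generate_genome(ig_like_spec(seed = 4))
  hits <- align_seed_extend(sim$query, sim$genome, scoring_scheme())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tabular_hits(hits, path)
  back <- parse_tabular_hits(path, sim$query$id)
  common <- c("query_id", "q_start", "q_end", "subject_id",
              "s_start", "s_end", "strand", "bit_score", "identity")
  expect_equal(as.data.frame(back[common]), as.data.frame(hits[common]))
})

test_that("bit scores follow the Karlin-Altschul normalisation", {
  s1 <- scoring_scheme(lambda = log(2), K = 1)
  expect_equal(bit_score(0, s1), 0)
  expect_equal(bit_score(200, s1), 200)
  # frozen from direct evaluation of (lambda*S - ln K)/ln 2
  expect_equal(bit_score(100, scoring_scheme(lambda = 1.28, K = 0.46)),
               185.78525946750503)
})

test_that("bit-score filtering is inclusive at the threshold and monotone", {
  hits <- tibble::tibble(bit_score = c(199.9, 200.0, 350.0))
  expect_equal(filter_hits(hits, 200)$bit_score, c(200.0, 350.0))
  expect_equal(filter_hits(hits, 0), hits)
  expect_equal(nrow(filter_hits(hits[0, ], 200)), 0L)
  withr::with_seed(7, {
    bits <- runif(50, 0, 500)
    h <- tibble::tibble(bit_score = bits)
    prev <- h
    for (th in c(50, 150, 300, 450)) {
      cur <- filter_hits(h, th)
      expect_true(all(cur$bit_score %in% prev$bit_score))
      prev <- cur
    }
  })
})

test_that("the aligner recovers planted copies with exact scores", {
  q <- rand_dna(400, seed = 11)
  dup <- substring(q, 101, 300)               # 200 bp internal segment
  g <- plant_genome(q, seed = 12, extra = dup)
  scheme <- scoring_scheme(word_size = 16)
  hits <- align_seed_extend(g$query, g$genome, scheme)
  self <- hits[hits$q_start == 0 & hits$q_end == 400, ]
  expect_equal(nrow(self), 1L)
  expect_equal(self$identity, 1)
  expect_equal(self$raw_score, 400L)
  expect_equal(self$s_start, g$locus$start)
  # the duplicated span is found as a non-self hit covering it
  non_self <- hits[hits$s_start >= g$locus$end, ]
  expect_true(any(non_self$q_start <= 100 & non_self$q_end >= 300))
})

test_that("the aligner handles unalignable and undersized input", {
  g <- plant_genome(rand_dna(100, 1), seed = 2)
  g$genome$seq <- paste(rep("N", 2000), collapse = "")
  expect_equal(nrow(suppressMessages(
    align_seed_extend(g$query, g$genome, scoring_scheme()))), 0L)
  short <- tibble::tibble(id = "q", seq = "ACGTACGT")
  expect_error(align_seed_extend(short, g$genome, scoring_scheme()),
               "shorter than word_size")
})

test_that("minus-strand copies are found with forward-strand subject intervals", {
  q <- rand_dna(300, seed = 21)
  rc <- fishprobes::revcomp(substring(q, 51, 250))
  g <- plant_genome(q, seed = 22, extra = rc)
  hits <- align_seed_extend(g$query, g$genome, scoring_scheme())
  minus <- hits[hits$strand == "-", ]
  expect_gte(nrow(minus), 1L)
  expect_true(all(minus$s_start < minus$s_end))
  expect_true(any(minus$q_start <= 50 & minus$q_end >= 250))
})

test_that("every maximal exact repeat of word size or longer yields a containing hit", {
  # brute-force oracle: scan all query windows for exact occurrences and
  # extend them to maximality, independent of the seeded aligner
  w <- 12L
  q <- rand_dna(250, seed = 31)
  seg1 <- substring(q, 40, 79)                # 40 bp
  seg2 <- substring(q, 150, 169)              # 20 bp
  g <- plant_genome(q, seed = 32, extra = c(seg1, seg2))
  scheme <- scoring_scheme(word_size = w)
  hits <- align_seed_extend(g$query, g$genome, scheme)
  qs <- g$query$seq; gs <- g$genome$seq
  nq <- nchar(qs)
  found_repeat <- FALSE
  for (i in 0:(nq - w)) {
    word <- substring(qs, i + 1L, i + w)
    occ <- gregexpr(word, gs, fixed = TRUE)[[1]]
    occ <- occ[occ > 0] - 1L
    for (o in occ) {
      if (o == g$locus$start + i) next        # self occurrence
      # extend this exact match to maximality
      a <- i; b <- o
      while (a > 0 && b > 0 &&
             substring(qs, a, a) == substring(gs, b, b)) { a <- a - 1L; b <- b - 1L }
      len <- i + w - a
      while (a + len < nq &&
             b + len < nchar(gs) &&
             substring(qs, a + len + 1L, a + len + 1L) ==
             substring(gs, b + len + 1L, b + len + 1L)) len <- len + 1L
      found_repeat <- TRUE
      ok <- any(hits$q_start <= a & hits$q_end >= a + len &
                  hits$s_start <= b & hits$s_end >= b + len)
      expect_true(ok, info = sprintf("repeat q:%d len %d uncovered", a, len))
    }
  }
  expect_true(found_repeat)
})
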