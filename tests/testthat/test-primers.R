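test_that("nearest-neighbour Tm matches an independent table-sum oracle", {
  # frozen from biopython MeltingTemp.Tm_NN with the same unified NN table,
  # duplex initiation terms, 50 mM Na+ entropy correction, CT/4 = 12.5 nM
  frozen <- c(AGCGTCCAGTGCATAAGCGT = 56.713687,
              ACGCCAGGCCCGTAACAAGC = 59.973206,
              ATATATATATATATATAT = 20.835667,
              GGCGCGCCGGCCGCGCGGCCGCGCCGC = 83.603426)
  for (s in names(frozen)) {
    expect_equal(melting_temperature(s), unname(frozen[s]), tolerance = 1e-4)
  }
})

test_that("Tm respects duplex symmetry and GC monotonicity", {
  withr::with_seed(12, {
    for (i in 1:5) {
      s <- rand_dna(20, i + 100)
      expect_equal(melting_temperature(s), melting_temperature(revcomp(s)))
      expect_gte(melting_temperature(paste0(s, "GC")), melting_temperature(s))
    }
  })
  expect_error(melting_temperature("ACGTACG"), ">= 8")
  expect_error(melting_temperature("ACGTACGTNACGTACGT"), "A/C/G/T")
})

test_that("primer feasibility rejects on hard bounds and scores deviations", {
  cs <- fishprobes:::primer_constraints_from_config(design_config())
  run <- primer_feasibility(strrep("A", 20), cs)
  expect_false(run$ok)
  expect_match(run$reason, "homopolymer|GC")
  short <- primer_feasibility("ACGTACGTACGT", cs)
  expect_false(short$ok)
  expect_match(short$reason, "length")
  good <- primer_feasibility("AGCGTCCAGTGCATAAGCGT", cs)
  if (good$ok) {
    expect_equal(good$penalty, abs(20 - cs$len_opt) + abs(good$tm - cs$tm_opt))
  }
})

test_that("vectorised candidate enumeration agrees with per-string scoring", {
  cs <- fishprobes:::primer_constraints_from_config(design_config())
  tpl <- rand_dna(400, 30)
  tint <- fishprobes:::seq_to_int(tpl)
  cand <- fishprobes:::enumerate_candidates(tint, 0:99, 18:27, cs)
  expect_gt(nrow(cand), 0L)
  for (i in sample.int(nrow(cand), min(25, nrow(cand)))) {
    s <- substring(tpl, cand$start0[i] + 1L, cand$start0[i] + cand$len[i])
    fb <- primer_feasibility(s, cs)
    # enumeration defers the self-complementarity check, so fb may reject on
    # that alone; everything else must match exactly
    if (fb$ok) {
      expect_equal(cand$tm[i], fb$tm)
      expect_equal(cand$gc[i], fb$gc)
      expect_equal(cand$penalty[i], fb$penalty)
    } else {
      expect_match(fb$reason, "self-complementarity")
    }
  }
})

test_that("complementarity scoring is symmetric and flags palindromic primers", {
  expect_equal(complementarity_score("ACGT", "ACGT"),
               complementarity_score("ACGT"))
  a <- rand_dna(20, 40); b <- rand_dna(20, 41)
  expect_equal(complementarity_score(a, b), complementarity_score(b, a))
  # a primer carrying a 12 bp inverted repeat exceeds the default threshold
  arm <- "GACGGATCCATG"
  hairpin <- paste0(arm, revcomp(arm))
  expect_gte(complementarity_score(hairpin), 12L)
})

test_that("design_pair returns an optimal in-target pair on benign input", {
  tpl <- rand_dna(3000, 50)
  cs <- fishprobes:::primer_constraints_from_config(design_config())
  pair <- design_pair(tpl, 500L, 2500L, cs, label = "T")
  expect_s3_class(pair, "primer_pair")
  expect_gte(pair$product_start, 500L)
  expect_lte(pair$product_end, 2500L)
  expect_gte(pair$product_len, 1000L)
  # the reverse primer is the reverse complement of the template window
  r_start <- pair$reverse$start - nchar(pair$reverse$core_seq) + 1L
  window <- substring(tpl, r_start + 1L, pair$reverse$start + 1L)
  expect_equal(pair$reverse$core_seq, revcomp(window))
  expect_equal(pair$forward$core_seq,
               substring(tpl, pair$product_start + 1L,
                         pair$product_start + nchar(pair$forward$core_seq)))
})

test_that("compositionally impossible templates yield a no-pair error", {
  at <- paste(rep("AT", 1500), collapse = "")
  cs <- fishprobes:::primer_constraints_from_config(design_config())
  expect_error(design_pair(at, 500L, 2500L, cs, label = "Z"),
               class = "fishprobes_no_pair")
})

test_that("the builtin engine matches exhaustive enumeration at reduced margins", {
  cfg <- design_config(primer_search_margin = 30, primer_len_min = 18,
                       primer_len_max = 21)
  cs <- fishprobes:::primer_constraints_from_config(cfg)
  tpl <- rand_dna(2600, 51)
  ts <- 300L; te <- 1800L; tlen <- te - ts
  pair <- tryCatch(design_pair(tpl, ts, te, cs, label = "T"),
                   fishprobes_no_pair = function(e) NULL)
  # exhaustive oracle over every candidate pair, re-scored from strings
  margin <- 30L
  best <- Inf
  for (a in 0:(margin - 1)) for (fl in 18:21) {
    fs <- substring(tpl, ts + a + 1L, ts + a + fl)
    f <- primer_feasibility(fs, cs)
    if (!f$ok) next
    for (b in 0:(margin - 1)) for (rl in 18:21) {
      r_end <- te - b
      plen <- r_end - (ts + a)
      if (plen < max(2L * cs$len_min, tlen - 2L * margin, cs$product_min) ||
          plen > min(tlen + cs$product_slack, cs$product_max)) next
      rs <- revcomp(substring(tpl, r_end - rl + 1L, r_end))
      r <- primer_feasibility(rs, cs)
      if (!r$ok) next
      if (abs(f$tm - r$tm) > cs$max_tm_diff) next
      if (complementarity_score(fs, rs) > cs$max_pair_any) next
      best <- min(best, f$penalty + r$penalty + abs(f$tm - r$tm))
    }
  }
  if (is.null(pair)) {
    expect_identical(best, Inf)
  } else {
    expect_lt(abs(pair$pair_penalty - best), 1e-9)
  }
})

test_that("the linker is prefixed once, lowercase, leaving the core intact", {
  tpl <- rand_dna(3000, 52)
  cs <- fishprobes:::primer_constraints_from_config(design_config())
  pair <- design_pair(tpl, 500L, 2500L, cs, label = "T")
  ext <- extend_five_prime(pair, "atcgat")
  expect_equal(ext$forward$full_seq, paste0("atcgat", pair$forward$core_seq))
  expect_equal(ext$reverse$full_seq, paste0("atcgat", pair$reverse$core_seq))
  expect_equal(ext$forward$tm, pair$forward$tm)   # Tm on the core only
  expect_error(extend_five_prime(ext, "atcgat"), "already extended")
  none <- extend_five_prime(pair, "")
  expect_equal(none$forward$full_seq, pair$forward$core_seq)
  expect_equal(extend_five_prime(pair, "GATTACA")$forward$linker, "gattaca")
})
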