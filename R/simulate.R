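# Deterministic synthetic genomes with planted repeat structure and per-base
# truth labels.  The default geometry echoes an immunoglobulin-heavy-chain-
# like locus: long unique blocks flanking a locally repetitive core, plus a
# repeat family shared with the rest of the genome.  Divergence is modelled
# as uniform random substitutions only (no indels), which keeps the per-base
# truth and the brute-force oracles exact.

#' Specify a synthetic genome with planted repeats
#'
#' @param segments A data frame with one row per genome segment, columns:
#'   `kind` (`"unique"`, `"local_repeat"`, `"global_repeat"`), `family`
#'   (family id within the kind; `NA` for unique), `length` (bp),
#'   `divergence` (per-copy substitution fraction in \[0, 0.1\]), and
#'   `in_locus` (logical: does the segment belong to the query locus?).
#'   Locus segments must be contiguous; local-repeat copies must all be in
#'   the locus; every global-repeat family needs at least one copy inside
#'   and one outside.
#' @param gc Background GC fraction.
#' @param seed Integer seed; the genome is a pure function of the spec.
#' @param avoid_sites Restriction sites kept out of repeat-family master
#'   sequences (default the ClaI site).  A site in the middle of every copy
#'   of a family would make the family un-probeable by construction, which
#'   would defeat the fixture's purpose of providing repetitive probe
#'   targets; unique segments are unconstrained so single-copy targets still
#'   exercise restriction screening.
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(segments, gc = 0.45, seed = 1L,
                        avoid_sites = "ATCGAT") {
  segments <- as_tibble(segments)
  need <- c("kind", "family", "length", "divergence", "in_locus")
  stopifnot(all(need %in% names(segments)))
  segments$length <- as.integer(segments$length)
  if (!all(segments$kind %in% c("unique", "local_repeat", "global_repeat"))) {
    abort("segment kind must be unique, local_repeat, or global_repeat")
  }
  if (any(segments$divergence < 0 | segments$divergence > 0.1)) {
    abort("divergence must be in [0, 0.1]")
  }
  if (sum(segments$length) > 200000L) {
    abort("total genome length exceeds the 200 kb desk-scale limit")
  }
  loc <- which(segments$in_locus)
  if (length(loc) == 0L || !identical(loc, seq(min(loc), max(loc)))) {
    abort("locus segments must form one contiguous run")
  }
  if (any(segments$kind == "local_repeat" & !segments$in_locus)) {
    abort("local_repeat copies must all lie inside the locus")
  }
  glob <- segments[segments$kind == "global_repeat", ]
  for (f in unique(glob$family)) {
    cp <- glob[glob$family == f, ]
    if (!any(cp$in_locus) || !any(!cp$in_locus)) {
      abort(sprintf("global_repeat family %s needs copies both inside and outside the locus", f))
    }
  }
  for (k in c("local_repeat", "global_repeat")) {
    fams <- segments$family[segments$kind == k]
    if (any(table(fams) < 2L)) {
      abort(sprintf("%s families need at least 2 copies", k))
    }
  }
  structure(list(segments = segments, gc = as.numeric(gc),
                 seed = as.integer(seed),
                 avoid_sites = as.character(avoid_sites)),
            class = "genome_spec")
}

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

mutate_seq <- function(seq, divergence) {
  n <- nchar(seq)
  k <- round(divergence * n)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate the genome, query, and truth annotation from a spec
#'
#' Deterministic for a fixed spec (segment layout, GC, seed): repeat copies
#' are derived from one master sequence per family with the stated per-copy
#' substitution divergence, the query is the locus substring of the genome,
#' and truth labels follow the classification definitions by construction
#' (exact for divergence 0; at positive divergence the labels describe the
#' planted structure).
#'
#' @param spec A [genome_spec()].
#' @param genome_id,query_id Sequence ids for the FASTA records.
#' @return A `genome_sim` object: `genome` and `query` record tibbles,
#'   `locus` (0-based half-open genome interval), `truth` (a
#'   `similarity_mask` over the query), `truth_families` (member intervals in
#'   query coordinates), and the generating `spec`.
#' @export
generate_genome <- function(spec, genome_id = "chrSim", query_id = "locus") {
  stopifnot(inherits(spec, "genome_spec"))
  seg <- spec$segments
  withr_seed <- spec$seed
  old <- save_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(withr_seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  # master sequence per repeat family, free of the avoided sites
  avoid <- spec$avoid_sites %||% character()
  masters <- list()
  for (i in seq_len(nrow(seg))) {
    if (seg$kind[i] == "unique") next
    key <- paste(seg$kind[i], seg$family[i])
    if (is.null(masters[[key]])) {
      for (try in 1:1000) {
        cand <- random_dna(seg$length[i], spec$gc)
        if (length(avoid) == 0L ||
            nrow(scan_restriction_sites(cand, avoid)) == 0L) break
      }
      masters[[key]] <- cand
    }
    if (nchar(masters[[key]]) != seg$length[i]) {
      abort(sprintf("all copies of family %s must share the master length", key))
    }
  }
  seqs <- character(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    seqs[i] <- if (seg$kind[i] == "unique") {
      random_dna(seg$length[i], spec$gc)
    } else {
      mutate_seq(masters[[paste(seg$kind[i], seg$family[i])]], seg$divergence[i])
    }
  }
  ends <- cumsum(seg$length)
  starts <- ends - seg$length                # 0-based segment starts
  genome_seq <- paste(seqs, collapse = "")
  loc_idx <- which(seg$in_locus)
  locus <- new_intervals(starts[loc_idx[1]], ends[loc_idx[length(loc_idx)]])
  query_seq <- substring(genome_seq, locus$start + 1L, locus$end)
  lab <- rep(1L, locus$end - locus$start)
  fam_rows <- list()
  for (i in loc_idx) {
    qs <- starts[i] - locus$start; qe <- ends[i] - locus$start
    if (seg$kind[i] == "local_repeat") {
      lab[(qs + 1L):qe] <- 3L
      fam_rows[[length(fam_rows) + 1L]] <- tibble(
        family_key = paste("local", seg$family[i]), start = qs, end = qe)
    } else if (seg$kind[i] == "global_repeat") {
      lab[(qs + 1L):qe] <- 2L
    }
  }
  fams <- bind_rows(fam_rows)
  if (nrow(fams)) {
    keys <- sort(unique(fams$family_key))
    fams$family <- match(fams$family_key, keys)
    fams <- fams[c("family", "start", "end")]
  } else {
    fams <- tibble(family = integer(), start = integer(), end = integer())
  }
  structure(list(
    genome = tibble(id = genome_id, seq = genome_seq,
                    chrom = NA_character_, start = NA_integer_, end = NA_integer_),
    query = tibble(id = query_id, seq = query_seq,
                   chrom = genome_id, start = locus$start + 1L, end = locus$end),
    locus = locus,
    truth = new_similarity_mask(query_id, lab, NA_real_),
    truth_families = fams,
    spec = spec),
    class = "genome_sim")
}

save_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' The default "ig-like" fixture spec
#'
#' Roughly 55 kb: a locus of three long unique blocks (5/6/8 kb) interleaved
#' with a three-copy local repeat family (1.5 kb copies at 2% divergence)
#' and one copy of a global repeat family (1 kb), whose two other copies lie
#' outside the locus — echoing the geometry of a locus with flanking unique
#' stretches around a locally repetitive core.
#'
#' @param seed Integer seed.
#' @param divergence Per-copy substitution fraction (default 0.02).
#' @return A [genome_spec()].
#' @export
ig_like_spec <- function(seed = 1L, divergence = 0.02) {
  seg <- tibble(
    kind = c("unique", "global_repeat", "unique",
             "unique", "local_repeat", "unique", "local_repeat", "unique",
             "local_repeat", "global_repeat", "unique",
             "unique", "global_repeat", "unique"),
    family = c(NA, 1L, NA, NA, 1L, NA, 1L, NA, 1L, 1L, NA, NA, 1L, NA),
    length = c(6000L, 1000L, 4000L,
               5000L, 1500L, 6000L, 1500L, 8000L, 1500L, 1000L, 4200L,
               3000L, 1000L, 6000L),
    divergence = divergence,
    in_locus = c(FALSE, FALSE, FALSE,
                 TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                 FALSE, FALSE, FALSE))
  genome_spec(seg, gc = 0.45, seed = seed)
}

#' A randomised desk-scale locus spec
#'
#' Draws a random geometry in the same family as [ig_like_spec()]: 2–4
#' unique locus blocks (2–6 kb), one local repeat family of 2–3 copies
#' (0.8–1.5 kb), one global repeat family (0.8–1.2 kb; one copy inside, two
#' outside), and 3–6 kb flanks — 20–40 kb of genome in total.  Used for
#' seeded validation sweeps of the classifier against its brute-force
#' oracle.
#'
#' @param seed Integer seed (drives both the geometry and the sequence).
#' @param divergence Per-copy substitution fraction.
#' @return A [genome_spec()].
#' @export
random_locus_spec <- function(seed, divergence = 0) {
  old <- save_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed + 1000003L, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  n_unique <- sample(2:4, 1)
  u_len <- sample(seq(2000L, 6000L, by = 500L), n_unique, replace = TRUE)
  n_local <- sample(2:3, 1)
  l_len <- sample(seq(800L, 1500L, by = 100L), 1)
  g_len <- sample(seq(800L, 1200L, by = 100L), 1)
  # locus: unique blocks interleaved with local copies, one global copy
  kinds <- character(); fams <- integer(); lens <- integer()
  for (i in seq_len(n_unique)) {
    kinds <- c(kinds, "unique"); fams <- c(fams, NA); lens <- c(lens, u_len[i])
    if (i <= n_local) {
      kinds <- c(kinds, "local_repeat"); fams <- c(fams, 1L); lens <- c(lens, l_len)
    }
  }
  kinds <- c(kinds, "global_repeat"); fams <- c(fams, 1L); lens <- c(lens, g_len)
  in_locus <- rep(TRUE, length(kinds))
  flank <- function() sample(seq(3000L, 6000L, by = 500L), 1)
  seg <- tibble(
    kind = c("unique", "global_repeat", kinds, "global_repeat", "unique"),
    family = c(NA, 1L, fams, 1L, NA),
    length = c(flank(), g_len, lens, g_len, flank()),
    divergence = divergence,
    in_locus = c(FALSE, FALSE, in_locus, FALSE, FALSE))
  genome_spec(seg, gc = 0.45, seed = seed)
}

#' Predict the genomic binding loci of a probe in silico
#'
#' Brute-force scan of the probe against both genome strands for stretches
#' where some window of at least `min_match_len` bases matches at identity
#' at least `min_identity` (substitution-only alignment on one diagonal,
#' matching how the synthetic genomes diverge).  Overlapping matched windows
#' are merged into loci; the thresholds echo the 100–300 base fragments a
#' labelled probe is physically sheared into.
#'
#' @param probe_seq Probe (amplicon) sequence, >= `min_match_len` long.
#' @param genome A genome record tibble (or a plain sequence string).
#' @param min_match_len Minimum matched window (bp).
#' @param min_identity Minimum windowed identity.
#' @return A tibble of merged forward-strand genomic loci (`start`, `end`).
#' @export
in_silico_hybridize <- function(probe_seq, genome, min_match_len = 100L,
                                min_identity = 0.85) {
  gseq <- if (is.character(genome)) genome else one_record(genome, "genome")$seq
  if (nchar(probe_seq) < min_match_len) {
    abort("probe shorter than min_match_len")
  }
  pint <- seq_to_int(toupper(probe_seq))
  fwd <- .cpp_hybridize_scan(pint, seq_to_int(gseq), min_match_len, min_identity)
  rint <- seq_to_int(revcomp(gseq))
  rev <- .cpp_hybridize_scan(pint, rint, min_match_len, min_identity)
  ng <- nchar(gseq)
  if (nrow(rev)) {
    rev <- tibble(start = ng - rev$end, end = ng - rev$start)
  }
  loci <- merge_intervals(bind_rows(as_tibble(fwd), as_tibble(rev)),
                          gap = min_match_len)
  loci
}

#' Brute-force per-position similarity mask (classification oracle)
#'
#' Independent of the seeded aligner: enumerates every query window of the
#' minimal length whose all-match score reaches `min_bits`, finds all exact
#' occurrences in the genome (both strands), and labels each query base from
#' the per-position multiplicity — UNIQUE when only the query's own copy
#' exists, SIMILAR_LOCAL when every extra occurrence lies inside the self
#' locus, SIMILAR_GLOBAL otherwise.  Exact for substitution-free repeat
#' structure; use divergence-0 specs when comparing against the pipeline.
#'
#' @param query,genome Record tibbles (single records).
#' @param scheme A [scoring_scheme()] (for the bit-score conversion).
#' @param min_bits Bit-score threshold.
#' @param self Optional self-locus interval as a list with `start`/`end`
#'   (0-based half-open genome coordinates); located by exact full-length
#'   match when omitted.
#' @return A `similarity_mask` over the query.
#' @export
brute_force_mask <- function(query, genome, scheme = scoring_scheme(),
                             min_bits = 200, self = NULL) {
  query <- one_record(query)
  genome <- one_record(genome, "genome")
  nq <- nchar(query$seq); ng <- nchar(genome$seq)
  if (ng > 200000L) abort("brute_force_mask is desk-scale: genome must be <= 200 kb")
  L <- min_alignment_length(min_bits, scheme)
  if (is.null(self)) {
    m <- Biostrings::matchPattern(query$seq, Biostrings::DNAString(genome$seq))
    if (length(m) == 0L) abort("query does not occur verbatim in the genome; pass `self`")
    self <- list(start = Biostrings::start(m)[1] - 1L,
                 end = Biostrings::end(m)[1])
  }
  lab <- rep(1L, nq)
  if (nq >= L) {
    qpos <- 0:(nq - L)
    qwin <- data.table::data.table(
      w = substring(query$seq, qpos + 1L, qpos + L), qpos = qpos)
    gpos <- 0:(ng - L)
    gfwd <- data.table::data.table(
      w = substring(genome$seq, gpos + 1L, gpos + L), gpos = gpos,
      strand = "+")
    grc <- substring(revcomp(genome$seq), gpos + 1L, gpos + L)
    # a revcomp-strand window at rc position p covers forward [ng-p-L, ng-p)
    grev <- data.table::data.table(w = grc, gpos = ng - gpos - L, strand = "-")
    gall <- rbind(gfwd, grev)
    hits <- merge(qwin, gall, by = "w", allow.cartesian = TRUE)
    if (nrow(hits)) {
      is_self <- hits$strand == "+" & hits$gpos == self$start + hits$qpos
      hits <- hits[!is_self]
      if (nrow(hits)) {
        outside <- hits$gpos < self$start | hits$gpos + L > self$end
        sim <- cover_positions(hits$qpos, L, nq)
        glob <- cover_positions(hits$qpos[outside], L, nq)
        lab[sim] <- 3L
        lab[glob] <- 2L
      }
    }
  }
  new_similarity_mask(query$id, lab, min_bits)
}

# logical index of positions covered by windows [p, p+L)
cover_positions <- function(p, L, n) {
  if (length(p) == 0L) return(logical(n))
  iv <- merge_intervals(new_intervals(p, pmin(p + L, n)))
  out <- logical(n)
  for (i in seq_len(nrow(iv))) out[(iv$start[i] + 1L):iv$end[i]] <- TRUE
  out
}

#' Exhaustive optimal selection of repetitive targets (selection oracle)
#'
#' Enumerates every subset of mutually non-overlapping candidates and
#' returns one maximising the cumulative binding length (ties resolved
#' toward lexicographically smaller sorted start positions, matching the
#' greedy tie-break spirit).  Refuses more than 15 candidates.
#'
#' @param candidates A candidate target tibble (with `binding` list-column).
#' @return A list: `selected` (row indices), `value` (optimal cumulative
#'   binding in bp).
#' @export
brute_force_select <- function(candidates) {
  n <- nrow(candidates)
  if (n > 15L) abort("brute_force_select refuses more than 15 candidates")
  if (n == 0L) return(list(selected = integer(), value = 0L))
  conflict <- outer(seq_len(n), seq_len(n), function(i, j) {
    intervals_overlap(candidates$start[i], candidates$end[i],
                      candidates$start[j], candidates$end[j]) & i != j
  })
  # atomic segmentation of all binding endpoints: each candidate covers a
  # fixed set of atomic segments, so a subset's union length is one matrix op
  bp <- sort(unique(unlist(lapply(candidates$binding, function(b) c(b$start, b$end)))))
  seg_s <- bp[-length(bp)]; seg_e <- bp[-1]
  seg_len <- seg_e - seg_s
  covers <- t(vapply(candidates$binding, function(b) {
    hit <- rep(FALSE, length(seg_s))
    for (i in seq_len(nrow(b))) {
      hit <- hit | (seg_s >= b$start[i] & seg_e <= b$end[i])
    }
    hit
  }, logical(length(seg_s))))
  covers <- matrix(covers, nrow = n)
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  best_val <- -1L; best_sel <- integer(); best_starts <- integer()
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, bits) != 0L)
    if (length(sel) > 1L && any(conflict[sel, sel])) next
    val <- if (length(sel)) {
      sum(seg_len[colSums(covers[sel, , drop = FALSE]) > 0L])
    } else 0L
    starts <- sort(candidates$start[sel])
    if (val > best_val ||
        (val == best_val && smaller_lex(starts, best_starts))) {
      best_val <- val; best_sel <- sel; best_starts <- starts
    }
  }
  list(selected = best_sel, value = as.integer(best_val))
}

smaller_lex <- function(a, b) {
  k <- min(length(a), length(b))
  if (k > 0L) {
    for (i in seq_len(k)) {
      if (a[i] != b[i]) return(a[i] < b[i])
    }
  }
  length(a) < length(b)
}
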