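# Probe target design: tiling single-copy amplicons over long unique blocks,
# and choosing repetitive amplicons inside locally repetitive blocks so that
# the cumulative length of their predicted binding sites is as large as
# possible.  All emitted amplicons are screened for forbidden restriction
# sites (ClaI by default) so the templates can later be cloned and verified
# by restriction digest.

target_columns <- function() {
  tibble(kind = character(), label = character(),
         start = integer(), end = integer(),
         binding = list(), cumulative_binding = integer())
}

#' Cumulative binding length of a probe target
#'
#' The total number of genomic bases a probe is predicted to hybridise to:
#' the length of the union of its binding-site intervals.
#'
#' @param binding A data frame of `start`/`end` intervals (0-based
#'   half-open), e.g. the `binding` list-column entry of a target tibble.
#' @return Length of the interval union in bp.
#' @export
cumulative_binding <- function(binding) {
  as.integer(interval_union_length(binding))
}

#' Group within-locus repeats into families
#'
#' Considers only non-self hits whose subject interval lies fully inside the
#' self locus, translates them into query coordinates, and links intervals
#' into families by connected components of the overlap/alignment graph
#' (transitive closure: copies never directly aligned to each other still
#' share a family through intermediate copies).  Member intervals are trimmed
#' to SIMILAR_LOCAL-labelled bases.
#'
#' @param hits Bit-score-filtered hit tibble.
#' @param self_locus A [locate_self()] result.
#' @param mask The [classify()] mask.
#' @param tol Self-hit recognition tolerance in bp (seed word size).
#' @return A tibble (`family`, `start`, `end`) of family member intervals in
#'   query coordinates; empty when the locus has no local repeats.
#' @export
build_repeat_families <- function(hits, self_locus, mask, tol = 16L) {
  inside <- hits$subject_id == self_locus$subject_id &
    hits$s_start >= self_locus$start & hits$s_end <= self_locus$end
  is_self <- hits$strand == "+" &
    abs((hits$s_start - self_locus$start) - hits$q_start) <= tol &
    abs((hits$s_end - self_locus$start) - hits$q_end) <= tol
  local <- hits[inside & !is_self, , drop = FALSE]
  if (nrow(local) == 0L) {
    return(tibble(family = integer(), start = integer(), end = integer()))
  }
  # two intervals per hit: the query side and the subject side translated
  # into query coordinates
  iv <- tibble(
    start = c(local$q_start, local$s_start - self_locus$start),
    end = c(local$q_end, local$s_end - self_locus$start))
  n <- nrow(local)
  parent <- seq_len(nrow(iv))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (h in seq_len(n)) union_(h, h + n)      # alignment edges
  ord <- order(iv$start)
  for (a in seq_along(ord)[-1]) {             # overlap edges (sweep)
    for (b in rev(seq_len(a - 1))) {
      if (iv$end[ord[b]] <= iv$start[ord[a]]) break
      union_(ord[a], ord[b])
    }
  }
  comp <- vapply(seq_len(nrow(iv)), find, integer(1))
  local_regions <- extract_regions(mask, "SIMILAR_LOCAL")[c("start", "end")]
  fams <- lapply(split(seq_len(nrow(iv)), comp), function(ix) {
    members <- merge_intervals(iv[ix, ])
    members <- intersect_intervals(members, local_regions)
    members
  })
  fams <- fams[vapply(fams, nrow, integer(1)) >= 2L]
  if (length(fams) == 0L) {
    return(tibble(family = integer(), start = integer(), end = integer()))
  }
  fams <- fams[order(vapply(fams, function(f) min(f$start), integer(1)))]
  bind_rows(lapply(seq_along(fams), function(i) {
    mutate(fams[[i]], family = i)
  }))[c("family", "start", "end")]
}

# Partition [0, B) into k consecutive lengths within [m, M] maximising the
# covered total; returns lengths (possibly empty).
tile_lengths <- function(B, m, M) {
  k_max <- B %/% m
  if (k_max == 0L) return(integer())
  k <- min(k_max, as.integer(ceiling(B / M)))
  S <- min(B, k * M)
  lens <- integer(k)
  rem <- S
  for (i in seq_len(k)) {
    lens[i] <- min(M, rem - (k - i) * m)
    rem <- rem - lens[i]
  }
  lens
}

#' Tile unique blocks with consecutive single-copy amplicons
#'
#' Each block is partitioned left-to-right into consecutive amplicons with
#' lengths inside the configured limits, maximising the number of covered
#' bases (longest-first); a right-edge remainder shorter than the minimum
#' amplicon length is left uncovered.  Blocks shorter than the minimum are
#' skipped and recorded in the `skipped` attribute.
#'
#' @param blocks A region tibble from [unique_blocks()].
#' @param config A [design_config()].
#' @return A target tibble (kind `"single_copy"`, binding sites equal to the
#'   amplicon interval); skipped blocks are in `attr(, "skipped")`.
#' @export
tile_single_copy <- function(blocks, config = design_config()) {
  m <- config$amplicon_min; M <- config$amplicon_max
  out <- list(); skipped <- list()
  for (i in seq_len(nrow(blocks))) {
    B <- blocks$end[i] - blocks$start[i]
    lens <- tile_lengths(B, m, M)
    if (length(lens) == 0L) {
      skipped[[length(skipped) + 1L]] <- tibble(
        start = blocks$start[i], end = blocks$end[i],
        reason = sprintf("unique block %s (%d bp) shorter than amplicon_min (%d bp)",
                         fmt_interval_1based(blocks$start[i], blocks$end[i]), B, m))
      next
    }
    s <- blocks$start[i] + c(0L, cumsum(lens))[seq_along(lens)]
    out[[length(out) + 1L]] <- tibble(kind = "single_copy",
                                      start = s, end = s + lens)
  }
  targets <- if (length(out)) bind_rows(out) else target_columns()[c("kind", "start", "end")]
  targets <- mutate(targets,
                    binding = map2(.data$start, .data$end, ~ new_intervals(.x, .y)),
                    cumulative_binding = .data$end - .data$start,
                    label = NA_character_)
  targets <- targets[c("kind", "label", "start", "end", "binding", "cumulative_binding")]
  attr(targets, "skipped") <- bind_rows(skipped)
  targets
}

#' Enumerate candidate repetitive probe windows in a similar block
#'
#' Slides windows of lengths between the amplicon limits (length grid and
#' start positions both stepped by half the minimum amplicon length) across
#' the block and keeps windows at least 90% SIMILAR_LOCAL with zero
#' SIMILAR_GLOBAL bases — global similarity would break locus specificity.
#' A window's predicted binding sites are its own interval plus every member
#' of any repeat family that overlaps the window by at least half the
#' minimum amplicon length.
#'
#' @param block One row of [similar_blocks()].
#' @param families [build_repeat_families()] output.
#' @param mask The [classify()] mask.
#' @param config A [design_config()].
#' @return A candidate target tibble (kind `"repetitive"`).
#' @export
candidate_repeat_windows <- function(block, families, mask, config = design_config()) {
  m <- config$amplicon_min; M <- config$amplicon_max
  step <- max(1L, m %/% 2L)
  block_len <- block$end - block$start
  if (block_len < m) return(target_columns())
  # length grid stepped by half the minimum amplicon, plus the full block
  # (capped at the maximum) so narrow repeat blocks can be used whole
  lens <- sort(unique(c(seq.int(m, min(M, block_len), by = step),
                        min(M, block_len))))
  lab <- mask$labels
  cum_local <- c(0L, cumsum(lab == 3L))
  cum_global <- c(0L, cumsum(lab == 2L))
  cand_s <- integer(); cand_e <- integer()
  for (L in lens) {
    s <- seq.int(block$start, block$end - L, by = step)
    local_frac <- (cum_local[s + L + 1L] - cum_local[s + 1L]) / L
    n_global <- cum_global[s + L + 1L] - cum_global[s + 1L]
    ok <- local_frac >= 0.9 & n_global == 0L
    cand_s <- c(cand_s, s[ok]); cand_e <- c(cand_e, s[ok] + L)
  }
  if (length(cand_s) == 0L) return(target_columns())
  binding <- map2(cand_s, cand_e, function(ws, we) {
    own <- new_intervals(ws, we)
    if (nrow(families) == 0L) return(own)
    ov <- overlap_length(ws, we, families$start, families$end)
    fams_hit <- unique(families$family[ov >= m / 2])
    sites <- families[families$family %in% fams_hit, c("start", "end")]
    merge_intervals(bind_rows(own, sites))
  })
  tibble(kind = "repetitive", label = NA_character_,
         start = cand_s, end = cand_e, binding = binding,
         cumulative_binding = map_int(binding, cumulative_binding))
}

#' Greedy maximum-coverage selection of repetitive probe targets
#'
#' Repeatedly selects the candidate whose binding sites add the most new
#' bases to the union already covered, subject to selected amplicons not
#' overlapping each other; stops when the best marginal gain falls below
#' `min_gain`.  Ties break deterministically (smaller start, then shorter
#' window).  Greedy maximum coverage carries the classic (1 − 1/e)
#' approximation guarantee and is exact on instances whose candidates bind
#' disjoint site sets.
#'
#' @param candidates A candidate tibble from [candidate_repeat_windows()]
#'   (possibly concatenated over blocks).
#' @param min_gain Stop once the best marginal gain (bp) is below this.
#' @return The selected target tibble, in selection order.
#' @export
select_repeat_targets <- function(candidates, min_gain = 500L) {
  if (nrow(candidates) == 0L) return(target_columns())
  selected <- integer()
  covered <- new_intervals()
  covered_len <- 0L
  remaining <- seq_len(nrow(candidates))
  while (length(remaining) > 0L) {
    gains <- vapply(remaining, function(i) {
      interval_union_length(bind_rows(covered, candidates$binding[[i]]))
    }, double(1)) - covered_len
    best <- which(gains == max(gains))
    if (length(best) > 1L) {
      st <- candidates$start[remaining[best]]
      ln <- candidates$end[remaining[best]] - st
      best <- best[order(st, ln)[1]]
    }
    if (gains[best] < min_gain) break
    i <- remaining[best]
    selected <- c(selected, i)
    covered <- merge_intervals(bind_rows(covered, candidates$binding[[i]]))
    covered_len <- interval_union_length(covered)
    remaining <- remaining[!intervals_overlap(candidates$start[remaining],
                                              candidates$end[remaining],
                                              candidates$start[i],
                                              candidates$end[i])]
  }
  candidates[selected, , drop = FALSE]
}

#' Scan a sequence for restriction-site occurrences
#'
#' Reports every occurrence of each site or of its reverse complement
#' (palindromic sites such as ClaI ATCGAT coincide with their reverse
#' complement and are reported once).  IUPAC ambiguity codes in the site are
#' honoured; overlapping occurrences are all reported.
#'
#' @param seq A DNA string.
#' @param sites Character vector of recognition sequences (IUPAC).
#' @return A tibble (`site`, `pos`) of 0-based match positions, sorted.
#' @export
#' @examples
#' scan_restriction_sites("GGATCGATGG", "ATCGAT")  # position 2
scan_restriction_sites <- function(seq, sites = "ATCGAT") {
  subject <- Biostrings::DNAString(toupper(seq))
  out <- lapply(sites, function(site) {
    site <- toupper(site)
    pats <- unique(c(site, revcomp(site)))
    pos <- sort(unique(unlist(lapply(pats, function(p) {
      Biostrings::start(Biostrings::matchPattern(p, subject, fixed = FALSE)) - 1L
    }))))
    tibble(site = rep(site, length(pos)), pos = as.integer(pos))
  })
  bind_rows(out)
}

# Scan one query interval for forbidden sites; absolute 0-based positions.
sites_in_interval <- function(template, start, end, sites) {
  if (end - start < min(nchar(sites))) return(integer())
  hits <- scan_restriction_sites(substring(template, start + 1L, end), sites)
  sort(unique(hits$pos + start))
}

#' Screen probe targets for forbidden restriction sites
#'
#' In `"verify"` mode targets are annotated with any occurrences (a `sites`
#' list-column of absolute 0-based positions) and left unchanged.  In
#' `"enforce"` mode amplicon boundaries are moved so no emitted amplicon
#' contains a complete occurrence: single-copy blocks are cut through the
#' middle of every occurrence and re-tiled (which shifts, splits, or drops
#' amplicons as space allows); repetitive targets are cut the same way,
#' keeping pieces that still satisfy the length limits and window purity.
#' Dropped coverage is recorded in the `log` attribute.
#'
#' @param targets A target tibble.
#' @param template The query sequence string.
#' @param config A [design_config()]; `config$forbidden_sites` are screened
#'   and `config$site_mode` picks the default mode.
#' @param blocks Unique blocks (region tibble) the single-copy targets were
#'   tiled from; when `NULL`, each target can only be split in place.
#' @param sblocks Similar blocks the repetitive targets were selected from;
#'   when supplied, an affected repetitive window is re-derived inside the
#'   site-free pieces of its block (shift), otherwise it is split in place.
#' @param families,mask Context for re-validating repetitive pieces.
#' @param mode Override `config$site_mode`.
#' @return The screened target tibble; in enforce mode every amplicon scans
#'   clean.  Log of dropped/changed items in `attr(, "log")`.
#' @export
enforce_restriction_free <- function(targets, template, config = design_config(),
                                     blocks = NULL, sblocks = NULL,
                                     families = NULL, mask = NULL,
                                     mode = config$site_mode) {
  mode <- match.arg(mode, c("enforce", "verify"))
  sites <- config$forbidden_sites
  if (nrow(targets) == 0L || length(sites) == 0L) {
    attr(targets, "log") <- tibble(start = integer(), end = integer(),
                                   reason = character())
    return(targets)
  }
  if (mode == "verify") {
    targets$sites <- map2(targets$start, targets$end,
                          ~ sites_in_interval(template, .x, .y, sites))
    attr(targets, "log") <- tibble(start = integer(), end = integer(),
                                   reason = character())
    return(targets)
  }
  m <- config$amplicon_min
  log <- list()
  sc <- targets[targets$kind == "single_copy", , drop = FALSE]
  rep_t <- targets[targets$kind == "repetitive", , drop = FALSE]
  # --- single-copy: cut blocks at site midpoints, re-tile the pieces -------
  out_sc <- target_columns()
  if (nrow(sc) > 0L) {
    if (is.null(blocks)) blocks <- sc[c("start", "end")]
    pieces <- list()
    for (i in seq_len(nrow(blocks))) {
      occ <- sites_in_interval(template, blocks$start[i], blocks$end[i], sites)
      cuts <- sort(unique(occ + 3L))
      bounds <- c(blocks$start[i], cuts, blocks$end[i])
      pieces[[i]] <- new_intervals(bounds[-length(bounds)], bounds[-1])
      if (length(occ)) {
        log[[length(log) + 1L]] <- tibble(
          start = blocks$start[i], end = blocks$end[i],
          reason = sprintf("unique block %s re-tiled around %d forbidden-site occurrence(s)",
                           fmt_interval_1based(blocks$start[i], blocks$end[i]),
                           length(occ)))
      }
    }
    retiled <- tile_single_copy(bind_rows(pieces), config)
    sk <- attr(retiled, "skipped")
    if (!is.null(sk) && nrow(sk)) log[[length(log) + 1L]] <- sk
    out_sc <- retiled
  }
  # --- repetitive: shift the window into a site-free piece of its block
  # (when the block is known), else cut in place and keep qualifying pieces
  out_rep <- list()
  taken <- new_intervals()                   # intervals already claimed
  for (i in seq_len(nrow(rep_t))) {
    occ <- sites_in_interval(template, rep_t$start[i], rep_t$end[i], sites)
    if (length(occ) == 0L) {
      out_rep[[length(out_rep) + 1L]] <- rep_t[i, ]
      taken <- bind_rows(taken, new_intervals(rep_t$start[i], rep_t$end[i]))
      next
    }
    repl <- NULL
    search_blocks <- if (!is.null(sblocks) && nrow(sblocks)) {
      sblocks[c("start", "end")]
    } else {
      rep_t[i, c("start", "end")]
    }
    cand <- bind_rows(lapply(seq_len(nrow(search_blocks)), function(bi) {
      site_free_candidates(search_blocks[bi, ], template, families, mask, config)
    }))
    if (nrow(cand)) {
      cand <- arrange(cand, desc(.data$cumulative_binding),
                      .data$start - .data$end, .data$start)
    }
    if (nrow(cand)) {
      free <- !map_lgl(seq_len(nrow(cand)), function(ci) {
        any(intervals_overlap(cand$start[ci], cand$end[ci],
                              taken$start, taken$end))
      })
      cand <- cand[free, , drop = FALSE]
      if (nrow(cand)) repl <- cand[1, , drop = FALSE]
    }
    if (!is.null(repl)) {
      out_rep[[length(out_rep) + 1L]] <- repl
      taken <- bind_rows(taken, new_intervals(repl$start, repl$end))
    }
    log[[length(log) + 1L]] <- tibble(
      start = rep_t$start[i], end = rep_t$end[i],
      reason = sprintf("repetitive target %s carried %d forbidden-site occurrence(s); %s",
                       fmt_interval_1based(rep_t$start[i], rep_t$end[i]),
                       length(occ),
                       if (is.null(repl)) "no site-free replacement window, dropped"
                       else sprintf("window moved to %s",
                                    fmt_interval_1based(repl$start, repl$end))))
  }
  out <- bind_rows(out_sc, bind_rows(out_rep))
  out <- arrange(out, .data$start)
  attr(out, "log") <- bind_rows(log)
  out
}

# Candidate repetitive windows inside one block, restricted to pieces free
# of forbidden-site occurrences (cut through the middle of each occurrence).
site_free_candidates <- function(blk, template, families, mask, config,
                                 screen_sites = TRUE) {
  if (screen_sites) {
    occ <- sites_in_interval(template, blk$start, blk$end, config$forbidden_sites)
    bounds <- c(blk$start, sort(unique(occ + 3L)), blk$end)
  } else {
    bounds <- c(blk$start, blk$end)
  }
  ps <- bounds[-length(bounds)]; pe <- bounds[-1]
  cand <- list()
  for (j in seq_along(ps)) {
    if (pe[j] - ps[j] < config$amplicon_min) next
    cw <- candidate_repeat_windows(tibble(start = ps[j], end = pe[j]),
                                   families, mask, config)
    if (nrow(cw)) cand[[length(cand) + 1L]] <- cw
  }
  if (length(cand) == 0L) return(target_columns())
  cand <- bind_rows(cand)
  # most binding first; longer windows preferred (they leave the primer
  # engine room to place a product within the amplicon limits)
  arrange(cand, desc(.data$cumulative_binding),
          .data$start - .data$end, .data$start)
}

# Re-derive a repetitive target for interval [s, e): purity + binding sites.
rebind_repetitive <- function(s, e, families, mask, config) {
  L <- e - s
  if (!is.null(mask)) {
    lab <- mask$labels[(s + 1L):e]
    if (mean(lab == 3L) < 0.9 || any(lab == 2L)) return(NULL)
  }
  own <- new_intervals(s, e)
  binding <- own
  if (!is.null(families) && nrow(families) > 0L) {
    ov <- overlap_length(s, e, families$start, families$end)
    fams_hit <- unique(families$family[ov >= config$amplicon_min / 2])
    sites <- families[families$family %in% fams_hit, c("start", "end")]
    binding <- merge_intervals(bind_rows(own, sites))
  }
  tibble(kind = "repetitive", label = NA_character_, start = s, end = e,
         binding = list(binding),
         cumulative_binding = cumulative_binding(binding))
}

# Alphabetic labels: single-copy A, B, ... in coordinate order; repetitive
# x, y, z, x2, y2, ... mirroring the original track nomenclature.
assign_labels <- function(targets) {
  if (nrow(targets) == 0L) return(targets)
  targets <- arrange(targets, .data$start)
  sc <- which(targets$kind == "single_copy")
  rp <- which(targets$kind == "repetitive")
  mk <- function(base, n) {
    reps <- ceiling(seq_len(n) / length(base))
    suff <- ifelse(reps == 1L, "", as.character(reps))
    paste0(base[(seq_len(n) - 1L) %% length(base) + 1L], suff)
  }
  targets$label[sc] <- mk(LETTERS, length(sc))
  targets$label[rp] <- mk(c("x", "y", "z"), length(rp))
  targets
}
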