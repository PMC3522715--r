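# End-to-end probe design: align (or ingest hits) -> threshold -> locate the
# self locus -> per-base classification -> unique/similar blocks -> single-
# copy tiling + repetitive target selection -> restriction screening ->
# primer pairs.  The returned object carries every intermediate so results
# can be inspected, re-exported, and plotted.

#' Design FISH probes for a query locus
#'
#' Runs the full design pipeline.  Exactly one of `genome` (to use the
#' built-in aligner) or `hits` (pre-computed tabular alignments, already or
#' not yet thresholded) must be supplied.
#'
#' @param query A single query record (one-row tibble from [read_fasta()], or
#'   a list with `id`/`seq`); a `chrom:start-end` header or `chrom`/`start`/
#'   `end` columns declare the query's genomic origin.
#' @param genome A genome record tibble (multi-record allowed).
#' @param hits A hit tibble from [parse_tabular_hits()].
#' @param config A [design_config()].
#' @return A `fish_design` object with components `query`, `config`, `hits`
#'   (thresholded), `self_locus`, `mask`, `unique_blocks`, `similar_blocks`,
#'   `families`, `targets`, `primers`, and `log`; see [tidy.fish_design()]
#'   and [glance.fish_design()].
#' @export
fish_design <- function(query, genome = NULL, hits = NULL,
                        config = design_config()) {
  if (is.list(query) && !is.data.frame(query)) query <- as_tibble(query[lengths(query) > 0])
  query <- one_record(query)
  if (!"chrom" %in% names(query)) {
    query$chrom <- NA_character_; query$start <- NA_integer_; query$end <- NA_integer_
  }
  if (is.null(genome) == is.null(hits)) {
    abort("supply exactly one of `genome` (built-in aligner) or `hits` (parsed alignments)")
  }
  scheme <- scheme_from_config(config)
  if (is.null(hits)) {
    hits <- align_seed_extend(query, genome, scheme)
  }
  hits <- filter_hits(hits, config$min_bits)
  declared <- if (!is.na(query$chrom)) {
    list(chrom = query$chrom, start = query$start, end = query$end)
  }
  self_locus <- locate_self(hits, query, declared = declared)
  mask <- classify(query, hits, self_locus, min_bits = config$min_bits,
                   tol = scheme$word_size)
  ublocks <- unique_blocks(mask, config$min_unique_len)
  sblocks <- similar_blocks(mask, config$max_gap)
  families <- build_repeat_families(hits, self_locus, mask,
                                    tol = scheme$word_size)
  log <- list()
  sc <- tile_single_copy(ublocks, config)
  if (nrow(attr(sc, "skipped") %||% tibble())) log[[length(log) + 1L]] <- attr(sc, "skipped")
  cand <- bind_rows(lapply(seq_len(nrow(sblocks)), function(i) {
    candidate_repeat_windows(sblocks[i, ], families, mask, config)
  }))
  if (nrow(sblocks) == 0L) cand <- target_columns()
  rep_sel <- select_repeat_targets(cand, config$min_gain)
  targets <- bind_rows(sc[names(target_columns())], rep_sel[names(target_columns())])
  targets <- enforce_restriction_free(targets, query$seq, config,
                                      blocks = ublocks, sblocks = sblocks,
                                      families = families, mask = mask,
                                      mode = config$site_mode)
  if (nrow(attr(targets, "log") %||% tibble())) log[[length(log) + 1L]] <- attr(targets, "log")
  targets <- assign_labels(targets)
  constraints <- primer_constraints_from_config(config)
  pres <- design_primers_for_targets(targets, query$seq, constraints,
                                     config$primer_linker)
  if (nrow(pres$log)) log[[length(log) + 1L]] <- pres$log
  primers <- pres$primers
  # a failed pair signals the target must be re-tiled: for repetitive
  # targets, fall back to alternative candidate windows in the same block
  failed_rep <- which(targets$kind == "repetitive" &
                        !targets$label %in% primers$label)
  for (k in failed_rep) {
    if (nrow(sblocks) == 0L) next
    cand <- bind_rows(lapply(seq_len(nrow(sblocks)), function(bi) {
      site_free_candidates(sblocks[bi, ], query$seq, families, mask, config,
                           screen_sites = config$site_mode == "enforce")
    }))
    if (nrow(cand)) {
      cand <- arrange(cand, desc(.data$cumulative_binding),
                      .data$start - .data$end, .data$start)
    }
    others <- targets[-k, , drop = FALSE]
    for (ci in seq_len(nrow(cand))) {
      if (cand$start[ci] == targets$start[k] && cand$end[ci] == targets$end[k]) next
      if (any(intervals_overlap(cand$start[ci], cand$end[ci],
                                others$start, others$end))) next
      retry <- tryCatch(
        design_pair(query$seq, cand$start[ci], cand$end[ci], constraints,
                    label = targets$label[k]),
        fishprobes_no_pair = function(e) NULL)
      if (is.null(retry)) next
      log[[length(log) + 1L]] <- tibble(
        start = targets$start[k], end = targets$end[k],
        reason = sprintf("target %s re-tiled to %s for primer feasibility",
                         targets$label[k],
                         fmt_interval_1based(cand$start[ci], cand$end[ci])))
      targets$start[k] <- cand$start[ci]
      targets$end[k] <- cand$end[ci]
      targets$binding[[k]] <- cand$binding[[ci]]
      targets$cumulative_binding[k] <- cand$cumulative_binding[ci]
      one <- design_primers_for_targets(targets[k, , drop = FALSE], query$seq,
                                        constraints, config$primer_linker)
      primers <- bind_rows(primers, one$primers)
      break
    }
  }
  # a target's deliverable is its amplicon: shrink each probe interval to the
  # designed product so the reported target, the screened interval, and the
  # PCR product coincide
  if (nrow(primers)) {
    for (i in seq_len(nrow(primers))) {
      k <- which(targets$label == primers$label[i])
      s <- primers$product_start[i]; e <- primers$product_end[i]
      targets$start[k] <- s
      targets$end[k] <- e
      binding <- new_intervals(s, e)
      if (targets$kind[k] == "repetitive" && nrow(families) > 0L) {
        ov <- overlap_length(s, e, families$start, families$end)
        fams_hit <- unique(families$family[ov >= config$amplicon_min / 2])
        sites <- families[families$family %in% fams_hit, c("start", "end")]
        binding <- merge_intervals(bind_rows(binding, sites))
      }
      targets$binding[[k]] <- binding
      targets$cumulative_binding[k] <- cumulative_binding(binding)
    }
  }
  designed <- targets$label %in% primers$label
  if (any(!designed)) {
    log[[length(log) + 1L]] <- tibble(
      start = targets$start[!designed], end = targets$end[!designed],
      reason = sprintf("target %s dropped: no feasible primer pair",
                       targets$label[!designed]))
  }
  targets <- targets[designed, , drop = FALSE]
  structure(list(
    query = query, config = config, scheme = scheme, hits = hits,
    self_locus = self_locus, mask = mask,
    unique_blocks = ublocks, similar_blocks = sblocks,
    families = families, targets = targets, primers = primers,
    log = if (length(log)) bind_rows(log) else tibble(start = integer(), end = integer(), reason = character())),
    class = "fish_design")
}

#' @export
print.fish_design <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<fish_design> %s (%s bp) at min_bits = %g\n",
              x$query$id, fmt_bp(g$query_len), x$config$min_bits))
  cat(sprintf("  mask: %s unique / %s globally similar / %s locally repetitive bp\n",
              fmt_bp(g$unique_bp), fmt_bp(g$similar_global_bp), fmt_bp(g$similar_local_bp)))
  cat(sprintf("  %d single-copy + %d repetitive probes; %s bp of probe binding %s bp of sequence\n",
              g$n_single_copy, g$n_repetitive,
              fmt_bp(g$probe_bp), fmt_bp(g$binding_bp)))
  cat(sprintf("  %d primer pairs designed; %d item(s) logged\n",
              g$n_primer_pairs, nrow(x$log)))
  invisible(x)
}

#' Tidy components of a probe design
#'
#' @param x A [fish_design()] result.
#' @param type One of `"targets"` (default; binding sites nested in a
#'   list-column), `"binding"` (one row per binding-site interval),
#'   `"regions"` (the mask as maximal labelled regions), `"blocks"`,
#'   `"primers"`, `"hits"`, `"families"`, or `"log"`.
#' @param ... Unused.
#' @return A tibble; all coordinates 0-based half-open on the query.
#' @export
tidy.fish_design <- function(x, type = c("targets", "binding", "regions",
                                         "blocks", "primers", "hits",
                                         "families", "log"), ...) {
  type <- match.arg(type)
  switch(type,
    targets = x$targets,
    binding = tidyr::unnest(
      mutate(x$targets, binding = map(.data$binding, as_tibble)),
      "binding", names_sep = "_"),
    regions = tidy(x$mask),
    blocks = bind_rows(
      mutate(x$unique_blocks, block = "unique"),
      mutate(x$similar_blocks, block = "similar")),
    primers = x$primers,
    hits = x$hits,
    families = x$families,
    log = x$log)
}

#' One-row summary of a probe design
#'
#' @param x A [fish_design()] result.
#' @param ... Unused.
#' @return A one-row tibble: query length, per-label base counts, probe
#'   counts, total probe length, total cumulative binding (union over all
#'   probes), and primer-pair count.
#' @export
glance.fish_design <- function(x, ...) {
  counts <- tabulate(x$mask$labels, 3L)
  all_binding <- bind_rows(x$targets$binding)
  tibble(
    query_id = x$query$id,
    query_len = length(x$mask$labels),
    min_bits = x$config$min_bits,
    unique_bp = counts[1], similar_global_bp = counts[2],
    similar_local_bp = counts[3],
    n_single_copy = sum(x$targets$kind == "single_copy"),
    n_repetitive = sum(x$targets$kind == "repetitive"),
    probe_bp = sum(x$targets$end - x$targets$start),
    binding_bp = interval_union_length(all_binding),
    n_primer_pairs = nrow(x$primers))
}
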