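# Human-readable run report plus the machine-readable result bundle.
# Reports print 1-based inclusive coordinates (Ensembl style); every BED
# twin of a printed interval is the same interval shifted to 0-based
# half-open.

#' Write the primer/amplicon report table
#'
#' One row per designed pair: target label, linker-extended primer sequences
#' (linker lowercase, core uppercase), Tm and GC of both primers, product
#' length, and the product's 1-based inclusive query coordinates.
#'
#' @param design A [fish_design()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_primer_table <- function(design, path) {
  p <- design$primers
  out <- tibble(
    label = p$label, kind = p$kind,
    forward_primer = p$fwd_seq, reverse_primer = p$rev_seq,
    forward_tm_C = round(p$fwd_tm, 2), reverse_tm_C = round(p$rev_tm, 2),
    forward_gc = round(p$fwd_gc, 3), reverse_gc = round(p$rev_gc, 3),
    product_len_bp = p$product_len,
    product_start = p$product_start + 1L,
    product_end = p$product_end)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write the amplicon sequences as FASTA
#'
#' @param design A [fish_design()] result.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_amplicons <- function(design, path) {
  t <- design$targets
  seqs <- substring(design$query$seq, t$start + 1L, t$end)
  ids <- sprintf("%s %s %s:%s", t$label, t$kind, design$query$id,
                 fmt_interval_1based(t$start, t$end))
  write_fasta(tibble(id = ids, seq = seqs), path)
  invisible(path)
}

#' Write the plain-text run report
#'
#' Echoes every effective parameter, summarises the mask, lists the blocks,
#' targets (with cumulative binding), primer pairs, and the log of skipped
#' or dropped items with reasons.  All coordinates 1-based inclusive.
#'
#' @param design A [fish_design()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(design, path) {
  x <- design
  g <- glance(x)
  reg <- config_registry()
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(fmt, ...) writeLines(sprintf(fmt, ...), con)
  w("fishprobes run report")
  w("=====================")
  w("")
  w("query: %s (%s bp)%s", x$query$id, fmt_bp(g$query_len),
    if (!is.na(x$query$chrom)) sprintf(", declared origin %s:%d-%d",
                                       x$query$chrom, x$query$start, x$query$end) else "")
  w("self locus: %s:%s (%s)", x$self_locus$subject_id,
    fmt_interval_1based(x$self_locus$start, x$self_locus$end), x$self_locus$source)
  w("")
  w("effective configuration")
  w("-----------------------")
  for (k in reg$key) w("%s=%s", k, paste(format(x$config[[k]]), collapse = ","))
  w("")
  w("similarity mask (min_bits = %g)", x$config$min_bits)
  w("-------------------------------")
  counts <- c(g$unique_bp, g$similar_global_bp, g$similar_local_bp)
  for (i in 1:3) {
    w("%-15s %10s bp (%5.1f%%)", MASK_LEVELS[i], fmt_bp(counts[i]),
      100 * counts[i] / g$query_len)
  }
  w("")
  w("blocks")
  w("------")
  for (i in seq_len(nrow(x$unique_blocks))) {
    w("unique  %s (%s bp)",
      fmt_interval_1based(x$unique_blocks$start[i], x$unique_blocks$end[i]),
      fmt_bp(x$unique_blocks$end[i] - x$unique_blocks$start[i]))
  }
  for (i in seq_len(nrow(x$similar_blocks))) {
    w("similar %s (%s bp)",
      fmt_interval_1based(x$similar_blocks$start[i], x$similar_blocks$end[i]),
      fmt_bp(x$similar_blocks$end[i] - x$similar_blocks$start[i]))
  }
  w("")
  w("probe targets")
  w("-------------")
  t <- x$targets
  for (i in seq_len(nrow(t))) {
    w("%-4s %-11s %s (%s bp), binds %s bp at %d site(s)",
      t$label[i], t$kind[i], fmt_interval_1based(t$start[i], t$end[i]),
      fmt_bp(t$end[i] - t$start[i]), fmt_bp(t$cumulative_binding[i]),
      nrow(t$binding[[i]]))
  }
  w("total: %d probes, %s bp of probe sequence binding %s bp",
    nrow(t), fmt_bp(g$probe_bp), fmt_bp(g$binding_bp))
  w("")
  w("primer pairs (linker lowercase, core uppercase)")
  w("-----------------------------------------------")
  p <- x$primers
  for (i in seq_len(nrow(p))) {
    w("%-4s F 5'-%s-3' (Tm %.1f C)  R 5'-%s-3' (Tm %.1f C)  product %s (%d bp)",
      p$label[i], p$fwd_seq[i], p$fwd_tm[i], p$rev_seq[i], p$rev_tm[i],
      fmt_interval_1based(p$product_start[i], p$product_end[i]),
      p$product_len[i])
  }
  w("")
  w("log (%d item(s))", nrow(x$log))
  w("---------------")
  for (i in seq_len(nrow(x$log))) w("- %s", x$log$reason[i])
  invisible(path)
}

#' Write the complete result bundle of a design run
#'
#' Writes, under `out_dir`: `mask.bed` (one record per labelled region),
#' `targets.bed` (BED12 with binding-site blocks), `amplicons.fasta`,
#' `primers.tsv`, `effective_config.cfg`, `report.txt`, and `tracks.png`
#' (unless `figure = FALSE`).
#'
#' @param design A [fish_design()] result.
#' @param out_dir Output directory (created if needed).
#' @param figure Render the track figure?
#' @return Named character vector of the written paths, invisibly.
#' @export
write_results <- function(design, out_dir, figure = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mask = file.path(out_dir, "mask.bed"),
    targets = file.path(out_dir, "targets.bed"),
    amplicons = file.path(out_dir, "amplicons.fasta"),
    primers = file.path(out_dir, "primers.tsv"),
    config = file.path(out_dir, "effective_config.cfg"),
    report = file.path(out_dir, "report.txt"))
  write_bed(tidy(design$mask), paths[["mask"]], track_name = "similarity_mask",
            chrom = design$query$id)
  write_bed(design$targets, paths[["targets"]], track_name = "probe_targets",
            chrom = design$query$id)
  write_amplicons(design, paths[["amplicons"]])
  write_primer_table(design, paths[["primers"]])
  write_config(design$config, paths[["config"]])
  write_report(design, paths[["report"]])
  if (figure) {
    paths <- c(paths, figure = file.path(out_dir, "tracks.png"))
    render_tracks(design, paths[["figure"]])
  }
  invisible(paths)
}
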