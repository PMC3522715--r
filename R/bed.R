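# BED export/import of mask regions and probe targets.  Regions are BED6;
# targets are BED12 with the binding sites as blocks (the record interval
# spans all binding sites and thickStart/thickEnd mark the amplicon itself,
# so the blocks always fit inside the record, as BED12 requires).

#' Write regions or probe targets as BED
#'
#' Region tibbles (`label`, `start`, `end`) become BED6; target tibbles
#' (with a `binding` list-column) become BED12 where chromStart/chromEnd
#' span the union of binding sites, thickStart/thickEnd mark the amplicon
#' interval, and the blocks are the merged binding sites.  Coordinates are
#' written 0-based half-open against the query sequence.
#'
#' @param x A region or target tibble.
#' @param path Output path.
#' @param track_name Optional BED track line name.
#' @param chrom Chromosome/sequence name for column 1 (the query id).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, track_name = NULL, chrom = "query") {
  lines <- character()
  if (!is.null(track_name)) {
    lines <- sprintf('track name="%s"', track_name)
  }
  x <- arrange(as_tibble(x), .data$start)
  if ("binding" %in% names(x)) {
    scores <- rep(0L, nrow(x))
    rows <- vapply(seq_len(nrow(x)), function(i) {
      b <- merge_intervals(x$binding[[i]])
      span_s <- min(b$start); span_e <- max(b$end)
      sprintf("%s\t%d\t%d\t%s\t%d\t+\t%d\t%d\t0\t%d\t%s\t%s",
              chrom, span_s, span_e, x$label[i], scores[i],
              x$start[i], x$end[i], nrow(b),
              paste0(paste(b$end - b$start, collapse = ","), ","),
              paste0(paste(b$start - span_s, collapse = ","), ","))
    }, character(1))
    lines <- c(lines, rows)
  } else {
    if ("label" %in% names(x)) {
      per_label <- split(seq_len(nrow(x)), x$label)
      for (ix in per_label) {
        iv <- x[ix, ]
        if (any(iv$start[-1] < iv$end[-nrow(iv)])) {
          abort(sprintf("overlapping '%s' regions violate region maximality",
                        iv$label[1]))
        }
      }
    }
    name <- if ("label" %in% names(x)) x$label else "."
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t0\t+",
                              chrom, x$start, x$end, name))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#'
#' @param path BED path.
#' @return For BED6, a region tibble (`label`, `start`, `end`); for BED12,
#'   a target-like tibble with the blocks restored into a `binding`
#'   list-column and the amplicon interval in `start`/`end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(label = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- unique(lengths(fields))
  if (length(nf) != 1L) abort("ragged BED file")
  m <- do.call(rbind, fields)
  if (nf >= 12L) {
    span_s <- as.integer(m[, 2])
    binding <- lapply(seq_len(nrow(m)), function(i) {
      sizes <- as.integer(strsplit(m[i, 11], ",")[[1]])
      starts <- as.integer(strsplit(m[i, 12], ",")[[1]])
      new_intervals(span_s[i] + starts, span_s[i] + starts + sizes)
    })
    tibble(label = m[, 4],
           start = as.integer(m[, 7]), end = as.integer(m[, 8]),
           binding = binding,
           cumulative_binding = map_int(binding, cumulative_binding))
  } else {
    tibble(label = m[, 4], start = as.integer(m[, 2]), end = as.integer(m[, 3]))
  }
}
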