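# Flat key=value configuration with "#" comments, mirroring the commented
# configuration file the original tool ships alongside its results.  Every
# knob of the pipeline lives here; load_config() fills unset keys with the
# documented defaults and write_config() emits a fully commented effective
# copy next to the results.

config_registry <- function() {
  tribble_ <- function(...) {
    x <- list(...)
    tibble(key = vapply(x, `[[`, "", 1L),
           type = vapply(x, `[[`, "", 2L),
           default = lapply(x, `[[`, 3L),
           comment = vapply(x, `[[`, "", 4L))
  }
  tribble_(
    list("min_bits", "numeric", 200, "minimum alignment bit score; shorter similarities are ignored"),
    list("min_unique_len", "integer", 4000L, "unique blocks must strictly exceed this length (bp) to be tiled"),
    list("max_gap", "integer", 500L, "permissible gap (bp) inside nearly contiguous similar blocks"),
    list("amplicon_min", "integer", 1000L, "minimum PCR amplicon length (bp)"),
    list("amplicon_max", "integer", 10000L, "maximum PCR amplicon length (bp)"),
    list("forbidden_sites", "character_list", "ATCGAT", "comma-separated restriction sites that must be absent from amplicons (ClaI by default)"),
    list("site_mode", "choice:enforce,verify", "enforce", "enforce = move/split amplicons around forbidden sites; verify = report only"),
    list("min_gain", "integer", 500L, "stop selecting repetitive targets when the marginal binding gain (bp) drops below this"),
    list("match", "integer", 1L, "aligner match reward"),
    list("mismatch", "integer", -2L, "aligner mismatch penalty (negative)"),
    list("lambda", "numeric", 1.28, "Karlin-Altschul lambda for the scoring matrix"),
    list("K", "numeric", 0.46, "Karlin-Altschul K for the scoring matrix"),
    list("word_size", "integer", 16L, "exact-word seed length (bp) of the internal aligner"),
    list("xdrop", "numeric", 20, "X-drop extension cutoff of the internal aligner"),
    list("primer_len_min", "integer", 18L, "minimum primer length (nt)"),
    list("primer_len_opt", "integer", 20L, "optimal primer length (nt)"),
    list("primer_len_max", "integer", 27L, "maximum primer length (nt)"),
    list("primer_tm_min", "numeric", 57, "minimum primer melting temperature (deg C)"),
    list("primer_tm_opt", "numeric", 60, "optimal primer melting temperature (deg C)"),
    list("primer_tm_max", "numeric", 63, "maximum primer melting temperature (deg C)"),
    list("primer_max_tm_diff", "numeric", 3, "maximum Tm difference (deg C) within a pair"),
    list("primer_gc_min", "numeric", 0.2, "minimum primer GC fraction"),
    list("primer_gc_max", "numeric", 0.8, "maximum primer GC fraction"),
    list("primer_max_run", "integer", 4L, "maximum homopolymer run (nt) in a primer"),
    list("primer_max_self_any", "integer", 8L, "maximum self-complementarity score of a primer"),
    list("primer_max_pair_any", "integer", 8L, "maximum cross-complementarity score within a pair"),
    list("primer_search_margin", "integer", 200L, "primer 5' ends are searched within this margin (bp) inside each amplicon end"),
    list("primer_product_slack", "integer", 0L, "extra product length (bp) allowed beyond the target length"),
    list("primer_linker", "character", "atcgat", "5' linker appended to both primers (lowercase in reports)"),
    list("primer_monovalent_mM", "numeric", 50, "monovalent cation concentration (mM) for Tm calculation"),
    list("primer_conc_nM", "numeric", 50, "primer concentration (nM) for Tm calculation"),
    list("plot_width", "numeric", 10, "track figure width (inches)"),
    list("plot_height", "numeric", 2.5, "track figure height (inches)")
  )
}

coerce_config_value <- function(value, type, key) {
  err <- function() abort(sprintf("config key '%s': cannot interpret '%s' as %s",
                                  key, value, type))
  if (type == "numeric") {
    out <- suppressWarnings(as.numeric(value))
    if (is.na(out)) err()
    out
  } else if (type == "integer") {
    out <- suppressWarnings(as.numeric(value))
    if (is.na(out) || out != round(out)) err()
    as.integer(out)
  } else if (type == "character") {
    as.character(value)
  } else if (type == "character_list") {
    trimws(strsplit(as.character(value), ",", fixed = TRUE)[[1]])
  } else if (startsWith(type, "choice:")) {
    choices <- strsplit(sub("^choice:", "", type), ",")[[1]]
    if (!value %in% choices) {
      abort(sprintf("config key '%s': '%s' is not one of %s",
                    key, value, paste(choices, collapse = ", ")))
    }
    value
  } else {
    err()
  }
}

#' Assemble the design configuration
#'
#' All pipeline parameters with their documented defaults; pass named
#' overrides (`design_config(min_bits = 250)`).  Unknown names error.
#'
#' @param ... Named overrides of registry keys (see [write_config()] for the
#'   commented list).
#' @return A `design_config` object (a validated named list).
#' @export
design_config <- function(...) {
  reg <- config_registry()
  cfg <- setNames(reg$default, reg$key)
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), reg$key)
    if (length(unknown) || is.null(names(dots)) || any(names(dots) == "")) {
      abort(sprintf("unknown config key(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    for (k in names(dots)) {
      type <- reg$type[reg$key == k]
      v <- dots[[k]]
      cfg[[k]] <- if (is.character(v)) {
        coerce_config_value(paste(v, collapse = ","), type, k)
      } else {
        coerce_config_value(as.character(v), type, k)
      }
    }
  }
  validate_config(structure(cfg, class = "design_config"))
}

validate_config <- function(cfg) {
  if (!(cfg$amplicon_min > 0L && cfg$amplicon_min <= cfg$amplicon_max)) {
    abort("config requires 0 < amplicon_min <= amplicon_max")
  }
  if (cfg$min_gain < 0L) abort("min_gain must be >= 0")
  if (cfg$min_bits < 0) abort("min_bits must be >= 0")
  for (s in cfg$forbidden_sites) {
    if (!grepl("^[ACGTRYSWKMBDHVN]+$", toupper(s))) {
      abort(sprintf("forbidden site '%s' is not a valid IUPAC DNA string", s))
    }
  }
  with(cfg, {
    if (!(primer_len_min <= primer_len_opt && primer_len_opt <= primer_len_max)) {
      abort("primer lengths must satisfy min <= opt <= max")
    }
    if (!(primer_tm_min <= primer_tm_opt && primer_tm_opt <= primer_tm_max)) {
      abort("primer Tm must satisfy min <= opt <= max")
    }
    if (!(primer_gc_min >= 0 && primer_gc_min <= primer_gc_max && primer_gc_max <= 1)) {
      abort("primer GC window must satisfy 0 <= min <= max <= 1")
    }
  })
  cfg
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  reg <- config_registry()
  for (k in reg$key) {
    cat(sprintf("  %-22s %s\n", k, paste(format(x[[k]]), collapse = ",")))
  }
  invisible(x)
}

scheme_from_config <- function(cfg) {
  scoring_scheme(match = cfg$match, mismatch = cfg$mismatch,
                 lambda = cfg$lambda, K = cfg$K,
                 word_size = cfg$word_size, xdrop = cfg$xdrop)
}

#' Read a key=value configuration file
#'
#' Lines are `key=value` with `#` comments and blank lines ignored.  Unknown
#' keys error (listing them all); unset keys take the documented defaults.
#'
#' @param path Path to the configuration file.
#' @return A [design_config()].
#' @export
load_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(design_config())
  has_eq <- grepl("=", lines, fixed = TRUE)
  if (any(!has_eq)) {
    abort(sprintf("config line without key=value: '%s'", lines[!has_eq][1]))
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  reg <- config_registry()
  unknown <- setdiff(keys, reg$key)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(keys)) {
    abort(sprintf("duplicate config key(s): %s",
                  paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  }
  cfg <- setNames(reg$default, reg$key)
  for (i in seq_along(keys)) {
    type <- reg$type[reg$key == keys[i]]
    cfg[[keys[i]]] <- coerce_config_value(vals[i], type, keys[i])
  }
  validate_config(structure(cfg, class = "design_config"))
}

#' Write a fully commented effective configuration file
#'
#' @param config A [design_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  reg <- config_registry()
  lines <- c("# fishprobes effective configuration",
             "# key = value       (comments describe each parameter)", "")
  for (i in seq_len(nrow(reg))) {
    k <- reg$key[i]
    lines <- c(lines,
               sprintf("# %s", reg$comment[i]),
               sprintf("%s=%s", k, paste(format(config[[k]], scientific = FALSE),
                                         collapse = ",")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

primer_constraints_from_config <- function(cfg) {
  list(len_min = cfg$primer_len_min, len_opt = cfg$primer_len_opt,
       len_max = cfg$primer_len_max,
       tm_min = cfg$primer_tm_min, tm_opt = cfg$primer_tm_opt,
       tm_max = cfg$primer_tm_max, max_tm_diff = cfg$primer_max_tm_diff,
       gc_min = cfg$primer_gc_min, gc_max = cfg$primer_gc_max,
       max_run = cfg$primer_max_run,
       max_self_any = cfg$primer_max_self_any,
       max_pair_any = cfg$primer_max_pair_any,
       search_margin = cfg$primer_search_margin,
       product_slack = cfg$primer_product_slack,
       product_min = cfg$amplicon_min, product_max = cfg$amplicon_max,
       linker = cfg$primer_linker,
       monovalent_mM = cfg$primer_monovalent_mM,
       primer_nM = cfg$primer_conc_nM)
}
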