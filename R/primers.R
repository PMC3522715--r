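# Built-in primer-pair engine.  Candidate primers are scored on length,
# melting temperature, GC, homopolymer runs, and self/pair complementarity;
# the returned pair minimises the summed penalties.  The engine is pluggable:
# anything honouring the same contract (a pair whose product lies inside the
# screened amplicon) can stand behind design_pair().

# Nearest-neighbour duplex parameters, unified oligonucleotide set
# (Allawi & SantaLucia 1997): dH kcal/mol, dS cal/(mol K) per dinucleotide
# step on one strand, 5'->3'.
NN_DH <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
           CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
           GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
           TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
NN_DS <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
           CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
           GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
           TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
# duplex initiation per terminal base pair
INIT_DH <- c(AT = 2.3, GC = 0.1)
INIT_DS <- c(AT = 4.1, GC = -2.8)
GAS_R <- 1.987             # cal/(mol K)

#' Nearest-neighbour melting temperature of a primer
#'
#' Unified nearest-neighbour thermodynamics with duplex initiation terms, a
#' monovalent-salt entropy correction of 0.368 (N−1) ln\[Na+\], and
#' Tm = ΔH / (ΔS + R ln(C/4)) − 273.15 for a non-self-complementary duplex
#' at primer concentration C.
#'
#' @param seq Primer sequence (A/C/G/T, length >= 8).
#' @param monovalent_mM Monovalent cation concentration in mM.
#' @param primer_nM Total primer concentration in nM.
#' @return Melting temperature in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("AGCGTCCAGTGCATAAGCGT")
melting_temperature <- function(seq, monovalent_mM = 50, primer_nM = 50) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 8L) abort("melting_temperature requires a sequence of >= 8 nt")
  if (grepl("[^ACGT]", seq)) abort("melting_temperature requires A/C/G/T only")
  steps <- substring(seq, 1:(n - 1), 2:n)
  ends <- c(substring(seq, 1, 1), substring(seq, n, n))
  end_class <- ifelse(ends %in% c("A", "T"), "AT", "GC")
  dH <- sum(NN_DH[steps]) + sum(INIT_DH[end_class])
  dS <- sum(NN_DS[steps]) + sum(INIT_DS[end_class])
  dS <- dS + 0.368 * (n - 1) * log(monovalent_mM / 1000)
  1000 * dH / (dS + GAS_R * log(primer_nM * 1e-9 / 4)) - 273.15
}

gc_fraction <- function(seq) {
  n <- nchar(seq)
  nchar(gsub("[^GCgc]", "", seq)) / n
}

max_homopolymer_run <- function(seq) {
  r <- rle(strsplit(seq, "")[[1]])
  max(r$lengths)
}

#' Best ungapped antiparallel complementarity score between two primers
#'
#' Within each duplex register the best contiguous segment is scored +1 per
#' Watson–Crick pair and −1 per mismatch; the maximum over all registers is
#' returned.  Use the same sequence twice for self-complementarity.
#'
#' @param a,b Primer sequences, 5'->3'.
#' @return Integer score.
#' @export
complementarity_score <- function(a, b = a) {
  .cpp_max_complementarity(seq_to_int(toupper(a)), seq_to_int(toupper(b)))
}

#' Score one primer candidate against the constraints
#'
#' Hard bounds (length, Tm window, GC window, homopolymer run,
#' self-complementarity) reject; otherwise the penalty is the sum of
#' absolute deviations from the length and Tm optima.
#'
#' @param seq Candidate primer sequence.
#' @param constraints A constraints list (see [design_config()] `primer_*`
#'   keys); defaults taken from `design_config()`.
#' @return A list: `ok`, `reason` (`NA` when ok), `penalty`, `tm`, `gc`.
#' @export
primer_feasibility <- function(seq, constraints = primer_constraints_from_config(design_config())) {
  cs <- constraints
  n <- nchar(seq)
  reject <- function(reason) list(ok = FALSE, reason = reason,
                                  penalty = Inf, tm = NA_real_, gc = NA_real_)
  if (n < cs$len_min || n > cs$len_max) {
    return(reject(sprintf("length %d outside [%d, %d]", n, cs$len_min, cs$len_max)))
  }
  if (grepl("[^ACGTacgt]", seq)) return(reject("non-ACGT characters"))
  gc <- gc_fraction(seq)
  if (gc < cs$gc_min || gc > cs$gc_max) {
    return(reject(sprintf("GC %.2f outside [%.2f, %.2f]", gc, cs$gc_min, cs$gc_max)))
  }
  if (max_homopolymer_run(seq) > cs$max_run) {
    return(reject(sprintf("homopolymer run > %d", cs$max_run)))
  }
  tm <- melting_temperature(seq, cs$monovalent_mM, cs$primer_nM)
  if (tm < cs$tm_min || tm > cs$tm_max) {
    return(reject(sprintf("Tm %.1f outside [%.1f, %.1f]", tm, cs$tm_min, cs$tm_max)))
  }
  if (complementarity_score(seq) > cs$max_self_any) {
    return(reject(sprintf("self-complementarity > %d", cs$max_self_any)))
  }
  list(ok = TRUE, reason = NA_character_,
       penalty = abs(n - cs$len_opt) + abs(tm - cs$tm_opt),
       tm = tm, gc = gc)
}

# Vectorised candidate enumeration over one template strand via prefix sums.
# Returns a tibble of feasible candidates (start0 = 0-based 5' position on
# the forward template for forward primers, or window start for reverse),
# with len, tm, gc, penalty.  Self-complementarity is checked lazily later
# (it is the most expensive filter).
enumerate_candidates <- function(tint, starts, lens, cs) {
  n <- length(tint)
  # NN tables are declared in A,C,G,T x A,C,G,T order, so the dinucleotide
  # index is 4*b1 + b2 + 1; steps touching an N are NA (excluded via cumN)
  idx <- 4L * tint[-n] + tint[-1] + 1L
  idx[tint[-n] < 0L | tint[-1] < 0L] <- NA_integer_
  dH_step <- unname(NN_DH[idx])
  dS_step <- unname(NN_DS[idx])
  cumH <- c(0, cumsum(ifelse(is.na(dH_step), 0, dH_step)))
  cumS <- c(0, cumsum(ifelse(is.na(dS_step), 0, dS_step)))
  is_gc <- tint == 1L | tint == 2L
  cumGC <- c(0L, cumsum(is_gc))
  is_n <- tint < 0L
  cumN <- c(0L, cumsum(is_n))
  # homopolymer runs longer than max_run
  r <- rle(tint)
  bad <- which(r$lengths > cs$max_run)
  run_end <- cumsum(r$lengths); run_start <- run_end - r$lengths
  bad_runs <- new_intervals(run_start[bad], run_end[bad])
  out <- list()
  salt <- function(len) 0.368 * (len - 1) * log(cs$monovalent_mM / 1000)
  denom_c <- GAS_R * log(cs$primer_nM * 1e-9 / 4)
  for (len in lens) {
    s <- starts[starts + len <= n]
    if (length(s) == 0L) next
    e <- s + len
    dH <- cumH[e] - cumH[s + 1L]
    dS <- cumS[e] - cumS[s + 1L]
    term1 <- tint[s + 1L]; term2 <- tint[e]
    at1 <- term1 == 0L | term1 == 3L; at2 <- term2 == 0L | term2 == 3L
    dH <- dH + ifelse(at1, INIT_DH[["AT"]], INIT_DH[["GC"]]) +
      ifelse(at2, INIT_DH[["AT"]], INIT_DH[["GC"]])
    dS <- dS + ifelse(at1, INIT_DS[["AT"]], INIT_DS[["GC"]]) +
      ifelse(at2, INIT_DS[["AT"]], INIT_DS[["GC"]])
    tm <- 1000 * dH / (dS + salt(len) + denom_c) - 273.15
    gc <- (cumGC[e + 1L] - cumGC[s + 1L]) / len
    has_n <- (cumN[e + 1L] - cumN[s + 1L]) > 0L
    run_bad <- rep(FALSE, length(s))
    for (k in seq_len(nrow(bad_runs))) {
      ovl <- pmin(e, bad_runs$end[k]) - pmax(s, bad_runs$start[k])
      run_bad <- run_bad | ovl > cs$max_run
    }
    ok <- !has_n & gc >= cs$gc_min & gc <= cs$gc_max &
      tm >= cs$tm_min & tm <= cs$tm_max & !run_bad
    if (!any(ok)) next
    pen <- abs(len - cs$len_opt) + abs(tm - cs$tm_opt)
    out[[length(out) + 1L]] <- tibble(
      start0 = s[ok], len = len, tm = tm[ok], gc = gc[ok],
      penalty = pen[ok])
  }
  if (length(out) == 0L) {
    return(tibble(start0 = integer(), len = integer(), tm = double(),
                  gc = double(), penalty = double()))
  }
  bind_rows(out)
}

#' Design the optimal primer pair for one probe target
#'
#' Forward candidates start within `search_margin` bp of the target's left
#' edge and reverse candidates end within `search_margin` bp of its right
#' edge, so both primers lie inside the restriction-screened amplicon.
#' Candidates are scored with [primer_feasibility()]'s penalty; a pair is
#' admissible when the Tm difference and mutual complementarity are within
#' bounds and the product length is within the allowed range.  The pair with
#' the smallest `forward + reverse + |ΔTm|` penalty is returned (ties:
#' smaller product, then leftmost forward primer).
#'
#' @param template The query sequence string.
#' @param target_start,target_end The probe target interval (0-based
#'   half-open query coordinates).
#' @param constraints A primer-constraints list (from
#'   `design_config()` `primer_*` keys).
#' @param label Target label used in error messages.
#' @return A `primer_pair` object.
#' @export
design_pair <- function(template, target_start, target_end,
                        constraints = primer_constraints_from_config(design_config()),
                        label = "?") {
  cs <- constraints
  tint <- seq_to_int(toupper(template))
  tlen <- target_end - target_start
  margin <- min(cs$search_margin, max(1L, tlen %/% 2L - cs$len_max))
  no_pair <- function(why) {
    abort(sprintf("no feasible primer pair for target %s: %s", label, why),
          class = "fishprobes_no_pair")
  }
  fwd_starts <- target_start + 0:(margin - 1L)
  fwd <- enumerate_candidates(tint, fwd_starts, cs$len_min:cs$len_max, cs)
  # reverse primer: revcomp of template window [r_end - len, r_end);
  # thermodynamics of the reverse-complement duplex are identical, so
  # enumerate on the forward strand keyed by window start.
  rev_ends <- target_end - 0:(margin - 1L)
  rev_cand <- list()
  for (len in cs$len_min:cs$len_max) {
    st <- rev_ends - len
    cand <- enumerate_candidates(tint, st[st >= 0L], len, cs)
    rev_cand[[length(rev_cand) + 1L]] <- cand
  }
  rev <- bind_rows(rev_cand)
  if (nrow(fwd) == 0L) no_pair("no feasible forward primer (composition/Tm constraints)")
  if (nrow(rev) == 0L) no_pair("no feasible reverse primer (composition/Tm constraints)")
  fwd <- arrange(fwd, .data$penalty, .data$start0, .data$len)
  rev <- mutate(rev, r_end = .data$start0 + .data$len)
  rev <- arrange(rev, .data$penalty, .data$r_end, .data$len)
  # the product is the physical probe: it must stay inside the screened
  # target but also respect the configured amplicon length limits
  prod_min <- max(2L * cs$len_min, tlen - 2L * margin, cs$product_min %||% 0L)
  prod_max <- min(tlen + cs$product_slack, cs$product_max %||% .Machine$integer.max)
  seq_of <- function(s, l) substring(template, s + 1L, s + l)
  self_ok <- new.env(parent = emptyenv())    # memoised self-complementarity
  check_self <- function(s, l) {
    key <- paste0(s, ".", l)
    val <- self_ok[[key]]
    if (is.null(val)) {
      val <- complementarity_score(seq_of(s, l)) <= cs$max_self_any
      self_ok[[key]] <- val
    }
    val
  }
  best <- NULL
  best_key <- c(Inf, Inf, Inf)
  key_less <- function(k) {                  # lexicographic (pen, plen, f0)
    k[1] < best_key[1] ||
      (k[1] == best_key[1] && (k[2] < best_key[2] ||
                                 (k[2] == best_key[2] && k[3] < best_key[3])))
  }
  min_rev_pen <- rev$penalty[1]
  for (i in seq_len(nrow(fwd))) {
    if (fwd$penalty[i] + min_rev_pen > best_key[1]) break
    f0 <- fwd$start0[i]
    f_end <- f0 + fwd$len[i]
    # admissible reverse candidates for this forward, by product length and
    # non-overlap; `which` preserves rev's penalty order
    js <- which(rev$r_end >= f0 + prod_min & rev$r_end <= f0 + prod_max &
                  rev$start0 >= f_end)
    if (length(js) == 0L) next
    if (!check_self(f0, fwd$len[i])) next
    for (j in js) {
      pen0 <- fwd$penalty[i] + rev$penalty[j]
      if (pen0 > best_key[1]) break
      plen <- rev$r_end[j] - f0
      tm_diff <- abs(fwd$tm[i] - rev$tm[j])
      if (tm_diff > cs$max_tm_diff) next
      key <- c(pen0 + tm_diff, plen, f0)
      if (!key_less(key)) next
      if (!check_self(rev$start0[j], rev$len[j])) next
      rseq <- revcomp(seq_of(rev$start0[j], rev$len[j]))
      if (complementarity_score(seq_of(f0, fwd$len[i]), rseq) > cs$max_pair_any) next
      best <- list(fi = i, rj = j, pen = key[1], plen = plen)
      best_key <- key
    }
  }
  if (is.null(best)) {
    no_pair("no admissible combination (Tm difference, product length, or complementarity)")
  }
  i <- best$fi; j <- best$rj
  f_core <- seq_of(fwd$start0[i], fwd$len[i])
  r_core <- revcomp(seq_of(rev$start0[j], rev$len[j]))
  structure(list(
    forward = list(core_seq = f_core, full_seq = f_core, linker = "",
                   strand = "+", start = fwd$start0[i],
                   tm = fwd$tm[i], gc = fwd$gc[i], penalty = fwd$penalty[i]),
    reverse = list(core_seq = r_core, full_seq = r_core, linker = "",
                   strand = "-", start = rev$start0[j] + rev$len[j] - 1L,
                   tm = rev$tm[j], gc = rev$gc[j], penalty = rev$penalty[j]),
    product_start = fwd$start0[i],
    product_end = rev$start0[j] + rev$len[j],
    product_len = best$plen,
    pair_penalty = best$pen),
    class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> product %s (%d bp), penalty %.2f\n",
              fmt_interval_1based(x$product_start, x$product_end),
              x$product_len, x$pair_penalty))
  cat(sprintf("  F 5'-%s-3'  Tm %.1f C, GC %.0f%%\n",
              x$forward$full_seq, x$forward$tm, 100 * x$forward$gc))
  cat(sprintf("  R 5'-%s-3'  Tm %.1f C, GC %.0f%%\n",
              x$reverse$full_seq, x$reverse$tm, 100 * x$reverse$gc))
  invisible(x)
}

#' Prefix both primers of a pair with a 5' linker
#'
#' Appends the (lowercase) linker — by default the ClaI recognition site
#' "atcgat" used for clone screening — to the 5' end of both primers.  The
#' cores and their Tm values are unchanged: the linker is unpaired in early
#' PCR cycles.  Applying a linker twice errors.
#'
#' @param pair A [design_pair()] result.
#' @param linker Linker sequence (stored lowercase).
#' @return The modified `primer_pair`.
#' @export
extend_five_prime <- function(pair, linker = "atcgat") {
  stopifnot(inherits(pair, "primer_pair"))
  if (nzchar(pair$forward$linker) || nzchar(pair$reverse$linker)) {
    abort("primer pair already extended with a 5' linker")
  }
  if (nzchar(linker) && grepl("[^ACGTacgt]", linker)) {
    abort("linker must be a plain DNA string")
  }
  linker <- tolower(linker)
  pair$forward$linker <- linker
  pair$reverse$linker <- linker
  pair$forward$full_seq <- paste0(linker, pair$forward$core_seq)
  pair$reverse$full_seq <- paste0(linker, pair$reverse$core_seq)
  pair
}

# Design pairs for every target; returns list(primers = tibble, log = tibble)
design_primers_for_targets <- function(targets, template, constraints, linker) {
  rows <- list(); log <- list()
  for (i in seq_len(nrow(targets))) {
    pair <- tryCatch(
      design_pair(template, targets$start[i], targets$end[i], constraints,
                  label = targets$label[i]),
      fishprobes_no_pair = function(e) e)
    if (inherits(pair, "condition")) {
      log[[length(log) + 1L]] <- tibble(start = targets$start[i],
                                        end = targets$end[i],
                                        reason = conditionMessage(pair))
      next
    }
    pair <- extend_five_prime(pair, linker)
    rows[[length(rows) + 1L]] <- tibble(
      label = targets$label[i], kind = targets$kind[i],
      target_start = targets$start[i], target_end = targets$end[i],
      fwd_seq = pair$forward$full_seq, rev_seq = pair$reverse$full_seq,
      fwd_tm = pair$forward$tm, rev_tm = pair$reverse$tm,
      fwd_gc = pair$forward$gc, rev_gc = pair$reverse$gc,
      product_start = pair$product_start, product_end = pair$product_end,
      product_len = pair$product_len, pair_penalty = pair$pair_penalty)
  }
  list(primers = if (length(rows)) bind_rows(rows) else tibble(),
       log = bind_rows(log))
}
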