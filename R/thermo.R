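# Unified DNA/DNA nearest-neighbor parameters (dH kcal/mol, dS cal/mol/K),
# 1 M NaCl reference state. Keys are the 5'->3' dimer on one strand.
.NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
.NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
# duplex initiation per terminal base pair
.NN_INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.NN_INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
.GAS_CONST <- 1.987 # cal/(mol K)

#' Duplex hybridization conditions
#'
#' Monovalent cation and total strand concentrations used by the
#' nearest-neighbor melting-temperature model. Both must be strictly
#' positive molarities.
#'
#' @param monovalent_cation_conc Monovalent cation concentration (mol/L).
#' @param strand_conc Total oligonucleotide strand concentration (mol/L).
#' @return A list of class `duplex_conditions`.
#' @examples
#' duplex_conditions()
#' @export
duplex_conditions <- function(monovalent_cation_conc = 0.05,
                              strand_conc = 1e-7) {
  if (!is.numeric(monovalent_cation_conc) || length(monovalent_cation_conc) != 1L ||
      !is.finite(monovalent_cation_conc) || monovalent_cation_conc <= 0) {
    stop("monovalent_cation_conc must be a single positive molarity")
  }
  if (!is.numeric(strand_conc) || length(strand_conc) != 1L ||
      !is.finite(strand_conc) || strand_conc <= 0) {
    stop("strand_conc must be a single positive molarity")
  }
  structure(list(monovalent_cation_conc = monovalent_cation_conc,
                 strand_conc = strand_conc),
            class = "duplex_conditions")
}

.check_dna <- function(seq, min_len = 1L, what = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single DNA string")
  }
  s <- toupper(seq)
  bad <- gsub("[ACGT]", "", s)
  if (nzchar(bad)) {
    stop("invalid sequence: non-ACGT character(s) '",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""), "' in ", what)
  }
  if (nchar(s) < min_len) {
    stop(what, " is too short (", nchar(s), " nt, minimum ", min_len, ")")
  }
  s
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (A/C/G/T).
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("ACGTT")
#' @export
reverse_complement <- function(seq) {
  s <- .check_dna(seq)
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

.is_self_complementary <- function(seq) {
  nchar(seq) %% 2L == 0L && seq == reverse_complement(seq)
}

.tm_from_sums <- function(dh, ds, len, cond, self_comp = FALSE) {
  na <- cond$monovalent_cation_conc
  ct <- cond$strand_conc
  ds_salt <- ds + 0.368 * (len - 1) * log(na)
  x <- if (self_comp) 1 else 4
  if (self_comp) ds_salt <- ds_salt - 1.4
  dh * 1000 / (ds_salt + .GAS_CONST * log(ct / x)) - 273.15
}

#' Nearest-neighbor melting temperature of a perfect duplex
#'
#' Computes the melting temperature (Tm, degrees Celsius) of the
#' perfectly matched DNA/DNA duplex formed by `seq` and its complement,
#' using the unified nearest-neighbor thermodynamic table with duplex
#' initiation terms, a monovalent-salt entropy correction
#' (0.368 (L-1) ln\[Na+\]), and the two-state van't Hoff expression.
#'
#' @param seq DNA string, length >= 8, alphabet A/C/G/T (case-insensitive).
#' @param cond A [duplex_conditions()] object.
#' @return A list of class `tm_result` with fields `tm` (degrees Celsius)
#'   and `method_tag` (`"nearest-neighbor"`).
#' @examples
#' tm_nearest_neighbor("ATGCATGCATGCATGCATGC")$tm
#' @export
tm_nearest_neighbor <- function(seq, cond = duplex_conditions()) {
  s <- .check_dna(seq, min_len = 8L)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  stacks <- paste0(chars[-n], chars[-1L])
  dh <- sum(.NN_DH[stacks]) + .NN_INIT_DH[chars[1L]] + .NN_INIT_DH[chars[n]]
  ds <- sum(.NN_DS[stacks]) + .NN_INIT_DS[chars[1L]] + .NN_INIT_DS[chars[n]]
  tm <- .tm_from_sums(unname(dh), unname(ds), n, cond,
                      self_comp = .is_self_complementary(s))
  structure(list(tm = tm, method_tag = "nearest-neighbor"),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("Tm = %.2f degC (%s)\n", x$tm, x$method_tag))
  invisible(x)
}

# Tm of every window of width `width`, vectorized with cumulative sums.
# Equals tm_nearest_neighbor() window by window (verified in tests);
# the rare self-complementary window is recomputed individually.
.window_tms <- function(seq, width, cond = duplex_conditions()) {
  s <- .check_dna(seq)
  n <- nchar(s)
  if (n < width) return(numeric(0))
  chars <- strsplit(s, "")[[1]]
  stacks <- paste0(chars[-n], chars[-1L])
  dh_c <- cumsum(c(0, unname(.NN_DH[stacks])))
  ds_c <- cumsum(c(0, unname(.NN_DS[stacks])))
  starts <- seq_len(n - width + 1L)
  ends <- starts + width - 1L
  dh <- dh_c[ends] - dh_c[starts] +
    unname(.NN_INIT_DH[chars[starts]]) + unname(.NN_INIT_DH[chars[ends]])
  ds <- ds_c[ends] - ds_c[starts] +
    unname(.NN_INIT_DS[chars[starts]]) + unname(.NN_INIT_DS[chars[ends]])
  tm <- .tm_from_sums(dh, ds, width, cond)
  if (width %% 2L == 0L) {
    for (i in starts) {
      w <- substr(s, i, i + width - 1L)
      if (.is_self_complementary(w)) tm[i] <- tm_nearest_neighbor(w, cond)$tm
    }
  }
  tm
}

#' Linear mismatch penalty on duplex Tm
#'
#' The 1 degree Celsius per 1% sequence mismatch rule: the Tm reduction for
#' `n_mismatch` mismatches in a duplex of `probe_len` base pairs is
#' `100 * n_mismatch / probe_len` degrees Celsius. The penalty is exactly
#' linear in the number of mismatches and ignores mismatch identity and
#' position.
#'
#' @param probe_len Probe (duplex) length in nt, > 0.
#' @param n_mismatch Number of mismatched positions, `0 <= n <= probe_len`.
#'   May be a vector.
#' @return Tm reduction(s) in degrees Celsius.
#' @examples
#' mismatch_tm_penalty(35, 3)  # 8.571...
#' @export
mismatch_tm_penalty <- function(probe_len, n_mismatch) {
  if (!is.numeric(probe_len) || length(probe_len) != 1L || probe_len <= 0 ||
      probe_len != as.integer(probe_len)) {
    stop("probe_len must be a single positive integer")
  }
  if (!is.numeric(n_mismatch) || any(n_mismatch < 0) ||
      any(n_mismatch != floor(n_mismatch))) {
    stop("n_mismatch must be non-negative integer(s)")
  }
  if (any(n_mismatch > probe_len)) {
    stop("n_mismatch cannot exceed probe_len")
  }
  100 * n_mismatch / probe_len
}

#' Truncate a percentage-like value to a fixed number of decimals
#'
#' Truncation (not rounding) toward zero, the convention used when quoting
#' mismatch percentages such as 3/35 = 8.571...% as 8.5%.
#'
#' @param x Numeric vector.
#' @param digits Decimals kept.
#' @return Truncated values.
#' @examples
#' truncate_decimal(mismatch_tm_penalty(35, 3))  # 8.5
#' @export
truncate_decimal <- function(x, digits = 1L) {
  trunc(x * 10^digits + sign(x) * 1e-9) / 10^digits
}

#' Mismatch-adjusted duplex melting temperature
#'
#' Tm of the duplex between a probe and a same-length target window,
#' modeled as the perfect-duplex nearest-neighbor Tm of the probe minus
#' the linear mismatch penalty for the Hamming distance between probe and
#' window.
#'
#' @param probe Probe DNA string, or a one-row probe data frame with a
#'   `sequence` column (as produced by [enumerate_candidates()]).
#' @param target_window Target DNA string, same length as the probe.
#' @param cond A [duplex_conditions()] object.
#' @return A `tm_result` with `method_tag = "adjusted"`.
#' @examples
#' adjusted_duplex_tm("ACGTACGTACGTACGTACGT", "ACGTACGAACGTACGTACGT")
#' @export
adjusted_duplex_tm <- function(probe, target_window,
                               cond = duplex_conditions()) {
  pseq <- if (is.data.frame(probe)) probe$sequence[1L] else probe
  pseq <- .check_dna(pseq, min_len = 8L, what = "probe")
  tw <- .check_dna(target_window, what = "target_window")
  if (nchar(tw) != nchar(pseq)) {
    stop("target_window must have the same length as the probe")
  }
  mm <- hamming_distance(pseq, tw)
  tm0 <- tm_nearest_neighbor(pseq, cond)$tm
  structure(list(tm = tm0 - mismatch_tm_penalty(nchar(pseq), mm),
                 method_tag = "adjusted"),
            class = "tm_result")
}

#' Hamming distance between equal-length DNA strings
#'
#' @param a,b DNA strings of equal length.
#' @return Integer count of mismatched positions.
#' @export
hamming_distance <- function(a, b) {
  a <- .check_dna(a, what = "a"); b <- .check_dna(b, what = "b")
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Screen a sequence for stable hairpin stems
#'
#' Fails when the sequence can fold back on itself with a
#' self-complementary stem of at least `min_stem` base pairs closed by a
#' loop of `loop_range[1]` to `loop_range[2]` unpaired nucleotides. All
#' stem/loop decompositions are enumerated.
#'
#' @param seq DNA string.
#' @param min_stem Minimum stem length (bp) considered stable.
#' @param loop_range Length-2 integer vector, allowed loop sizes (nt).
#' @return A list with `pass` (logical; `TRUE` = no hairpin found) and
#'   `stems`, a data frame of offending stems at length `min_stem`
#'   (0-based `start`, `stem_len`, `loop_len`). A longer stem with an
#'   in-range loop always contains a `min_stem`-length stem (its
#'   innermost base pairs) with the same loop, so scanning stems of
#'   exactly `min_stem` decides the verdict for all stem lengths.
#' @examples
#' hairpin_screen("AAAAAAAAAAGCGCGCTTTTGCGCGC")$pass
#' @export
hairpin_screen <- function(seq, min_stem = 6L, loop_range = c(3L, 8L)) {
  s <- .check_dna(seq)
  n <- nchar(s)
  ints <- utf8ToInt(s)
  comp <- utf8ToInt(chartr("ACGT", "TGCA", s))
  hits <- list()
  stem <- as.integer(min_stem)
  for (loop in loop_range[1L]:loop_range[2L]) {
    span <- 2L * stem + loop
    if (span > n) break
    starts <- seq_len(n - span + 1L)
    ok <- rep(TRUE, length(starts))
    for (j in seq_len(stem)) {  # stem1[j] pairs with stem2[stem + 1 - j]
      ok <- ok & (ints[starts + j - 1L] ==
                    comp[starts + 2L * stem + loop - j])
    }
    if (any(ok)) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = starts[ok] - 1L, stem_len = stem, loop_len = loop)
    }
  }
  stems <- if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(0), stem_len = integer(0), loop_len = integer(0))
  list(pass = nrow(stems) == 0L, stems = stems)
}

#' Screen a sequence for low-complexity repeats
#'
#' Fails when the sequence contains a homopolymer run longer than
#' `max_homopolymer` nt, or a tandem dinucleotide repeat of more than
#' `max_dinuc_repeat` units.
#'
#' @param seq DNA string.
#' @param max_homopolymer Longest tolerated homopolymer run (nt).
#' @param max_dinuc_repeat Most tolerated tandem dinucleotide units.
#' @return A list with `pass`, `max_homopolymer_run` (nt) and
#'   `max_dinuc_units` (units).
#' @examples
#' repeat_screen("ACGTAAAAAAAGT")$pass  # run of 7 A's fails the default 6
#' @export
repeat_screen <- function(seq, max_homopolymer = 6L, max_dinuc_repeat = 5L) {
  s <- .check_dna(seq)
  runs <- rle(strsplit(s, "")[[1]])
  max_homo <- max(runs$lengths)
  max_units <- .max_dinuc_units(s)
  list(pass = max_homo <= max_homopolymer && max_units <= max_dinuc_repeat,
       max_homopolymer_run = max_homo,
       max_dinuc_units = max_units)
}

# Gene-level window screening: flags, for every window start of a given
# width, whether the window fails the hairpin or repeat screens. Exactly
# equivalent to running hairpin_screen()/repeat_screen() per window (a
# stem/run inside a window is the intersection of the window with a
# gene-level stem/run), but computed once per gene.
.screen_windows <- function(s, width, hairpin, repeats) {
  n <- nchar(s)
  n_win <- n - width + 1L
  fail_h <- rep(FALSE, n_win)
  fail_r <- rep(FALSE, n_win)
  flag <- function(fail, lo, hi) {
    lo <- max(1L, lo); hi <- min(n_win, hi)
    if (lo <= hi) fail[lo:hi] <- TRUE
    fail
  }
  if (!is.null(hairpin)) {
    st <- hairpin_screen(s, hairpin$min_stem, hairpin$loop_range)$stems
    if (nrow(st)) {
      span <- 2L * st$stem_len + st$loop_len
      for (k in seq_len(nrow(st))) {
        # windows containing the whole stem-loop: a <= start+1 and
        # a + width - 1 >= start + span
        fail_h <- flag(fail_h, st$start[k] + 1L + span[k] - width,
                       st$start[k] + 1L)
      }
    }
  }
  if (!is.null(repeats)) {
    chars <- strsplit(s, "")[[1]]
    # homopolymer runs: window fails when its overlap with a run exceeds
    # max_homopolymer nt
    r <- rle(chars)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    h <- repeats$max_homopolymer
    for (k in which(r$lengths > h)) {
      # overlap > h: a <= end - h and a + width - 1 >= start + h
      fail_r <- flag(fail_r, starts[k] + h - width + 1L, ends[k] - h)
    }
    # period-2 regions: within one, the longest tandem dinucleotide run in
    # a window of overlap L is floor(L / 2) units
    if (n >= 3L) {
      v <- chars[seq_len(n - 2L)] == chars[3:n]
      rv <- rle(v)
      vend <- cumsum(rv$lengths); vstart <- vend - rv$lengths + 1L
      mu <- repeats$max_dinuc_repeat
      for (k in which(rv$values)) {
        lo <- vstart[k]; hi <- vend[k] + 2L   # region on the sequence
        # overlap >= 2 * (mu + 1) fails
        need <- 2L * (mu + 1L)
        if (hi - lo + 1L >= need) {
          fail_r <- flag(fail_r, lo + need - width, hi - need + 1L)
        }
      }
    }
  }
  list(hairpin = fail_h, `repeat` = fail_r)
}

# longest tandem dinucleotide repeat, in units, over both phases
.max_dinuc_units <- function(s) {
  n <- nchar(s)
  if (n < 2L) return(0L)
  ints <- utf8ToInt(s)
  best <- 1L
  for (phase in 0L:1L) {
    starts <- seq.int(1L + phase, n - 1L, by = 2L)
    if (length(starts) < 1L) next
    dimers <- ints[starts] * 1000L + ints[starts + 1L]
    r <- rle(dimers)
    best <- max(best, r$lengths)
  }
  best
}
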