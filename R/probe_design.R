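# Probe enumeration, quality/Tm filtering, uniqueness against nontargets.
# Probes are 0-based sense-strand windows of their gene; a probe table has
# columns probe_id, gene_id, sequence, start, length, tm_perfect.

.empty_probe_table <- function() {
  data.frame(probe_id = character(0), gene_id = character(0),
             sequence = character(0), start = integer(0),
             length = integer(0), tm_perfect = numeric(0),
             stringsAsFactors = FALSE)
}

.as_record <- function(gene) {
  if (is.data.frame(gene)) gene <- as.list(gene[1L, ])
  if (is.null(gene$gene_type)) gene$gene_type <- "CDS"
  gene
}

#' Enumerate candidate probes for one gene
#'
#' Slides sense-strand windows of every length in `len_range` across the
#' gene and keeps those whose perfect-duplex nearest-neighbor Tm falls in
#' `tm_window` and which pass the hairpin and repeat screens. Candidates
#' are sorted by start position (then length). rRNA records never yield
#' probes.
#'
#' @param gene A sequence record: list or one-row data frame with at least
#'   `seq_id` and `sequence` (and `gene_type`, default `"CDS"`).
#' @param len_range Length-2 vector of probe lengths (nt), default 35-45.
#' @param tm_window Length-2 Tm window (degrees Celsius) or `NULL` to skip
#'   the Tm filter.
#' @param cond [duplex_conditions()].
#' @param hairpin Hairpin screen options, a list
#'   `list(min_stem=, loop_range=)`, or `NULL` to skip.
#' @param repeats Repeat screen options, a list
#'   `list(max_homopolymer=, max_dinuc_repeat=)`, or `NULL` to skip.
#' @return Probe data frame (0-based `start`), with an attribute
#'   `"rejections"`: named counts of windows rejected by reason
#'   (`tm`, `hairpin`, `repeat`) plus `n_windows`.
#' @export
enumerate_candidates <- function(gene, len_range = c(35L, 45L),
                                 tm_window = c(70, 75),
                                 cond = duplex_conditions(),
                                 hairpin = list(min_stem = 6L,
                                                loop_range = c(3L, 8L)),
                                 repeats = list(max_homopolymer = 6L,
                                                max_dinuc_repeat = 5L)) {
  gene <- .as_record(gene)
  if (identical(gene$gene_type, "rRNA")) {
    stop("rRNA records never yield probes (gene ", gene$seq_id, ")")
  }
  s <- .check_dna(gene$sequence, what = paste0("gene ", gene$seq_id))
  n <- nchar(s)
  rej <- c(tm = 0L, hairpin = 0L, `repeat` = 0L)
  out <- list()
  n_windows <- 0L
  if (n >= min(len_range)) {
    for (w in seq.int(min(len_range), min(max(len_range), n))) {
      tms <- .window_tms(s, w, cond)
      starts0 <- seq_along(tms) - 1L
      n_windows <- n_windows + length(tms)
      keep <- rep(TRUE, length(tms))
      if (!is.null(tm_window)) {
        ok <- tms >= tm_window[1L] & tms <= tm_window[2L]
        rej["tm"] <- rej["tm"] + sum(!ok)
        keep <- keep & ok
      }
      scr <- .screen_windows(s, w, hairpin, repeats)
      fail_h <- keep & scr$hairpin
      rej["hairpin"] <- rej["hairpin"] + sum(fail_h)
      keep <- keep & !fail_h
      fail_r <- keep & scr$`repeat`
      rej["repeat"] <- rej["repeat"] + sum(fail_r)
      keep <- keep & !fail_r
      if (any(keep)) {
        idx <- which(keep)
        out[[length(out) + 1L]] <- data.frame(
          probe_id = sprintf("%s_%d_%d", gene$seq_id, starts0[idx], w),
          gene_id = gene$seq_id,
          sequence = substring(s, idx, idx + w - 1L),
          start = starts0[idx],
          length = w,
          tm_perfect = tms[idx],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else .empty_probe_table()
  res <- res[order(res$start, res$length), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "rejections") <- c(rej, n_windows = n_windows)
  res
}

# --- exact full-scan minimum-Hamming machinery -------------------------------

# Concatenate subject sequences (and optionally their reverse complements)
# into one integer vector with zero-spacers wide enough that no window of
# width <= max_w straddles two subjects. Returns the vector plus interval
# bookkeeping for mapping positions back to subjects.
.build_scan_index <- function(subjects, ids, max_w = 45L,
                              both_strands = TRUE) {
  pieces <- list(); piece_ids <- character(0)
  for (k in seq_along(subjects)) {
    pieces[[length(pieces) + 1L]] <- utf8ToInt(toupper(subjects[k]))
    piece_ids <- c(piece_ids, ids[k])
    if (both_strands) {
      pieces[[length(pieces) + 1L]] <-
        utf8ToInt(reverse_complement(subjects[k]))
      piece_ids <- c(piece_ids, ids[k])
    }
  }
  spacer <- rep(0L, max_w)
  vec <- integer(0); starts <- integer(0); ends <- integer(0)
  for (k in seq_along(pieces)) {
    starts <- c(starts, length(vec) + 1L)
    vec <- c(vec, pieces[[k]])
    ends <- c(ends, length(vec))
    vec <- c(vec, spacer)
  }
  list(vec = vec, starts = starts, ends = ends, ids = piece_ids)
}

# Minimum Hamming distance of `probe_seq` over all width-matched windows in
# the scan index; returns mm (Inf when no window exists), the subject id and
# the 0-based offset on the concatenated vector restricted to real windows.
.min_hamming_scan <- function(probe_seq, index) {
  p <- utf8ToInt(toupper(probe_seq))
  w <- length(p)
  v <- index$vec
  n <- length(v)
  if (n < w) return(list(mm = Inf, subject = NA_character_))
  matches <- integer(n - w + 1L)
  for (j in seq_len(w)) {
    matches <- matches + (v[j:(n - w + j)] == p[j])
  }
  # valid starts: window entirely inside one subject piece
  valid <- rep(FALSE, n - w + 1L)
  for (k in seq_along(index$starts)) {
    a <- index$starts[k]; b <- index$ends[k] - w + 1L
    if (b >= a) valid[a:b] <- TRUE
  }
  if (!any(valid)) return(list(mm = Inf, subject = NA_character_))
  mm <- w - matches
  mm[!valid] <- NA_integer_
  best <- which.min(mm)
  piece <- findInterval(best, index$starts)
  list(mm = mm[best], subject = index$ids[piece])
}

#' Uniqueness filter: the 15 degree-Celsius rule
#'
#' A probe is specific when its best nontarget duplex melts at least
#' `delta_tm_min` degrees Celsius below its perfect duplex. Under the
#' linear mismatch penalty this difference equals
#' `100 * mismatches / length`, so a probe is kept iff every same-length
#' window of every nontarget sequence (both strands by default) differs
#' from it at enough positions. A probe whose best offender lies in an
#' rRNA record is rejected with reason `"rrna"`; equality with the
#' threshold keeps the probe ("at least 15 degrees difference").
#'
#' @param candidates Probe data frame from [enumerate_candidates()].
#' @param nontarget_db Data frame of sequence records (`seq_id`,
#'   `sequence`, `gene_type`); must exclude each probe's own gene
#'   (records whose `seq_id` equals the probe's `gene_id` are skipped).
#' @param delta_tm_min Required Tm separation (degrees Celsius).
#' @param both_strands Evaluate nontarget windows on both strands.
#' @return A list with `kept` (probe table) and `rejected` (probe_id,
#'   gene_id, reason `uniqueness`/`rrna`, offender_id, n_mismatch,
#'   delta_tm of the best offending nontarget window).
#' @export
uniqueness_filter <- function(candidates, nontarget_db, delta_tm_min = 15,
                              both_strands = TRUE) {
  if (nrow(candidates) == 0L) {
    return(list(kept = candidates, rejected = .empty_reject_table()))
  }
  if (is.null(nontarget_db) || nrow(nontarget_db) == 0L) {
    warning("empty nontarget database: all candidates kept")
    return(list(kept = candidates, rejected = .empty_reject_table()))
  }
  if (is.null(nontarget_db$gene_type)) nontarget_db$gene_type <- "CDS"
  genes <- unique(candidates$gene_id)
  keep_flag <- logical(nrow(candidates))
  rej_rows <- list()
  for (g in genes) {
    sub <- nontarget_db[nontarget_db$seq_id != g, , drop = FALSE]
    rows_g <- which(candidates$gene_id == g)
    if (nrow(sub) == 0L) { keep_flag[rows_g] <- TRUE; next }
    is_rrna <- sub$gene_type == "rRNA"
    set_r <- if (any(is_rrna))
      .strand_set(sub$sequence[is_rrna], sub$seq_id[is_rrna], both_strands)
    set_c <- if (any(!is_rrna))
      .strand_set(sub$sequence[!is_rrna], sub$seq_id[!is_rrna], both_strands)
    for (i in rows_g) {
      p <- candidates[i, ]
      # probe kept iff no nontarget window within max_mm mismatches, where
      # max_mm is the largest mismatch count with penalty < delta_tm_min
      max_mm <- as.integer(ceiling(delta_tm_min * p$length / 100 - 1e-9)) - 1L
      off_r <- if (any(is_rrna)) .best_offender(p$sequence, set_r, max_mm)
      off_c <- if (any(!is_rrna)) .best_offender(p$sequence, set_c, max_mm)
      off <- if (!is.null(off_r)) c(off_r, reason = "rrna")
             else if (!is.null(off_c)) c(off_c, reason = "uniqueness")
      if (is.null(off)) {
        keep_flag[i] <- TRUE
      } else {
        mm <- as.integer(off[["mm"]])
        rej_rows[[length(rej_rows) + 1L]] <- data.frame(
          probe_id = p$probe_id, gene_id = p$gene_id,
          reason = off[["reason"]], offender_id = off[["subject"]],
          n_mismatch = mm, delta_tm = mismatch_tm_penalty(p$length, mm),
          stringsAsFactors = FALSE)
      }
    }
  }
  kept <- candidates[keep_flag, , drop = FALSE]
  rejected <- if (length(rej_rows)) do.call(rbind, rej_rows) else
    .empty_reject_table()
  rownames(kept) <- NULL; rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

# nontarget sequences (plus reverse complements) as a DNAStringSet; names
# keep the originating subject id
.strand_set <- function(seqs, ids, both_strands = TRUE) {
  fwd <- Biostrings::DNAStringSet(stats::setNames(toupper(seqs), ids))
  if (!both_strands) return(fwd)
  rev <- Biostrings::reverseComplement(fwd)
  names(rev) <- ids
  c(fwd, rev)
}

# best (fewest-mismatch) nontarget window within max_mm mismatches, or NULL.
# The window scan (Biostrings::vcountPattern, no indels) is exhaustive over
# every window of every subject, so this equals the full-scan definition.
.best_offender <- function(probe_seq, set, max_mm) {
  if (max_mm < 0L) return(NULL)
  cnt <- Biostrings::vcountPattern(probe_seq, set, max.mismatch = max_mm,
                                   with.indels = FALSE)
  if (!any(cnt > 0L)) return(NULL)
  offenders <- which(cnt > 0L)
  # exact minimum mismatch count among offending subjects
  for (mm in 0:max_mm) {
    c2 <- Biostrings::vcountPattern(probe_seq, set[offenders],
                                    max.mismatch = mm, with.indels = FALSE)
    if (any(c2 > 0L)) {
      return(list(subject = names(set)[offenders[which(c2 > 0L)[1L]]],
                  mm = mm))
    }
  }
  NULL
}

.empty_reject_table <- function() {
  data.frame(probe_id = character(0), gene_id = character(0),
             reason = character(0), offender_id = character(0),
             n_mismatch = numeric(0), delta_tm = numeric(0),
             stringsAsFactors = FALSE)
}

#' Select up to k probes per gene
#'
#' Greedy selection among surviving candidates: probes are ranked by
#' closeness of `tm_perfect` to the Tm-window midpoint (ties broken by
#' leftmost start), and accepted while they stay at least `min_gap` nt
#' away from every already accepted probe on the same gene
#' (`min_gap = 0` means non-overlapping).
#'
#' @param candidates Probe data frame (single gene or several; selection is
#'   per gene).
#' @param k Maximum probes per gene.
#' @param min_gap Minimum gap (nt) between selected probe intervals.
#' @param tm_mid Target Tm (degrees Celsius); defaults to the midpoint of
#'   `tm_window`.
#' @param tm_window Used only to derive `tm_mid` when that is `NULL`.
#' @return Probe data frame of selected probes, ordered by gene then start.
#' @export
select_probes_per_gene <- function(candidates, k = 1L, min_gap = 0L,
                                   tm_mid = NULL, tm_window = c(70, 75)) {
  if (is.null(tm_mid)) {
    tm_mid <- if (is.null(tm_window)) {
      if (nrow(candidates)) mean(range(candidates$tm_perfect)) else 0
    } else mean(tm_window)
  }
  if (nrow(candidates) == 0L) return(candidates)
  picked <- list()
  for (g in unique(candidates$gene_id)) {
    cand <- candidates[candidates$gene_id == g, , drop = FALSE]
    ord <- order(abs(cand$tm_perfect - tm_mid), cand$start)
    cand <- cand[ord, , drop = FALSE]
    sel <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (length(sel) >= k) break
      s1 <- cand$start[i]; e1 <- s1 + cand$length[i]
      ok <- TRUE
      for (j in sel) {
        s2 <- cand$start[j]; e2 <- s2 + cand$length[j]
        if (!(s1 >= e2 + min_gap || s2 >= e1 + min_gap)) { ok <- FALSE; break }
      }
      if (ok) sel <- c(sel, i)
    }
    picked[[length(picked) + 1L]] <- cand[sel, , drop = FALSE]
  }
  out <- do.call(rbind, picked)
  out <- out[order(out$gene_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Design a probe set for a target gene collection
#'
#' End-to-end design pipeline: per-gene candidate enumeration (length, Tm,
#' hairpin and repeat screens), the 15 degree-Celsius uniqueness rule
#' against every other target gene plus the rRNA decoy set, and greedy
#' per-gene selection. Deterministic for a fixed input order and
#' configuration.
#'
#' @param targets Data frame of CDS sequence records (`seq_id`, `sequence`,
#'   taxonomy columns, `gene_type`).
#' @param rrna Optional data frame of rRNA records used only as nontargets.
#' @param len_range,tm_window,cond,hairpin,repeats See
#'   [enumerate_candidates()].
#' @param delta_tm_min,both_strands See [uniqueness_filter()].
#' @param k,min_gap See [select_probes_per_gene()].
#' @return A list of class `design_result`: `probes` (selected probe
#'   table), `candidates` (all unique candidates), `rejected` (uniqueness
#'   rejections), and `report` (per-gene stage counts:
#'   `n_windows, n_candidates, n_unique, n_selected` and per-reason
#'   rejection counts).
#' @export
design_probe_set <- function(targets, rrna = NULL,
                             len_range = c(35L, 45L), tm_window = c(70, 75),
                             cond = duplex_conditions(),
                             hairpin = list(min_stem = 6L,
                                            loop_range = c(3L, 8L)),
                             repeats = list(max_homopolymer = 6L,
                                            max_dinuc_repeat = 5L),
                             delta_tm_min = 15, both_strands = TRUE,
                             k = 1L, min_gap = 0L) {
  if (is.null(targets) || nrow(targets) == 0L) stop("targets must be non-empty")
  if (is.null(targets$gene_type)) targets$gene_type <- "CDS"
  if (any(targets$gene_type == "rRNA")) {
    stop("rRNA records are nontargets; pass them via `rrna`")
  }
  cand_list <- list(); report <- list()
  for (i in seq_len(nrow(targets))) {
    cand <- enumerate_candidates(targets[i, ], len_range, tm_window, cond,
                                 hairpin, repeats)
    rej <- attr(cand, "rejections")
    report[[targets$seq_id[i]]] <- c(rej, n_candidates = nrow(cand))
    cand_list[[i]] <- cand
  }
  candidates <- do.call(rbind, cand_list)
  nontargets <- rbind(
    targets[, c("seq_id", "sequence", "gene_type")],
    if (!is.null(rrna) && nrow(rrna))
      rrna[, c("seq_id", "sequence", "gene_type")])
  uf <- uniqueness_filter(candidates, nontargets, delta_tm_min, both_strands)
  probes <- select_probes_per_gene(uf$kept, k = k, min_gap = min_gap,
                                   tm_window = tm_window)
  rep_df <- data.frame(
    gene_id = targets$seq_id,
    n_windows = vapply(report, `[[`, 0L, "n_windows"),
    rej_tm = vapply(report, `[[`, 0L, "tm"),
    rej_hairpin = vapply(report, `[[`, 0L, "hairpin"),
    rej_repeat = vapply(report, `[[`, 0L, "repeat"),
    n_candidates = vapply(report, `[[`, 0L, "n_candidates"),
    stringsAsFactors = FALSE)
  rej_by_gene <- table(factor(uf$rejected$gene_id, levels = targets$seq_id))
  rrna_by_gene <- table(factor(
    uf$rejected$gene_id[uf$rejected$reason == "rrna"],
    levels = targets$seq_id))
  rep_df$rej_uniqueness <- as.integer(rej_by_gene) - as.integer(rrna_by_gene)
  rep_df$rej_rrna <- as.integer(rrna_by_gene)
  rep_df$n_unique <- rep_df$n_candidates - as.integer(rej_by_gene)
  sel_by_gene <- table(factor(probes$gene_id, levels = targets$seq_id))
  rep_df$n_selected <- as.integer(sel_by_gene)
  rownames(rep_df) <- NULL
  structure(list(probes = probes, candidates = uf$kept,
                 rejected = uf$rejected, report = rep_df),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("Probe design: %d gene(s), %d probe(s) selected, %d candidate(s) kept, %d rejected by uniqueness/rRNA\n",
              nrow(x$report), nrow(x$probes), nrow(x$candidates),
              nrow(x$rejected)))
  genes0 <- x$report$gene_id[x$report$n_selected == 0L]
  if (length(genes0)) {
    cat("genes without probes:", paste(genes0, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Prescreen probes expressed above background in pooled samples
#'
#' Keeps probes whose normalized signal reaches at least `fold` times the
#' global background mean in one or more pooled samples (inclusive
#' comparison).
#'
#' @param m Normalized probe-by-sample intensity matrix.
#' @param fold Fold-over-background threshold.
#' @param bg Optional [global_background()] model; computed from `m` when
#'   `NULL`.
#' @return Character vector of kept probe ids (rownames of `m`).
#' @export
prescreen_expressed <- function(m, fold = 3, bg = NULL) {
  m <- .as_intensity(m)
  if (is.null(bg)) bg <- global_background(m)
  keep <- rowSums(m >= fold * bg$bg_mean) >= 1L
  rownames(m)[keep]
}
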