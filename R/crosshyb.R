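# Cross-hybridization screening of a probe set against sequence databases:
# ungapped local search with Karlin-Altschul E-values, hit filtering on
# alignment length / E-value / identity, hit-count and taxonomic-rank
# classification, per-database summaries.

#' Parameters for the ungapped local search
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param min_score Minimum raw segment score reported.
#' @param K Karlin-Altschul K for the extreme-value E-value model.
#' @param lambda Karlin-Altschul lambda; when `NULL`, solved from the
#'   scoring system under uniform base composition
#'   (`sum p_i p_j exp(lambda * s_ij) = 1`).
#' @param both_strands Search both strands of the subjects.
#' @return List of class `search_params`.
#' @export
search_params <- function(match = 1, mismatch = -2, min_score = 15,
                          K = 0.35, lambda = NULL, both_strands = TRUE) {
  stopifnot(match > 0, mismatch < 0, min_score > 0, K > 0)
  if (is.null(lambda)) lambda <- .solve_lambda(match, mismatch)
  structure(list(match = match, mismatch = mismatch, min_score = min_score,
                 K = K, lambda = lambda, both_strands = both_strands),
            class = "search_params")
}

.solve_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

# Best-scoring ungapped segment of a +/- score vector; deterministic
# tie-break: maximum score, then smallest start, then smallest end.
# Returns NULL if the best score is < 1.
.best_segment <- function(scores) {
  n <- length(scores)
  P <- c(0, cumsum(scores))          # P[t+1] = sum of first t
  minpre <- cummin(P[seq_len(n)])    # min over P[0..b-1] for segment end b
  gains <- P[2:(n + 1)] - minpre
  M <- max(gains)
  if (M < 1) return(NULL)
  ends <- which(gains == M)
  # smallest start overall: for each candidate end, earliest argmin prefix
  amin <- match(minpre[ends], P[seq_len(n)])  # first index t with P[t]=min
  a <- min(amin)                              # segment starts at index a
  b <- ends[amin == a][1L]
  list(start = a, end = b, score = M)
}

#' Ungapped local search of probes against a sequence database
#'
#' For every probe, subject and strand, scans each alignment diagonal for
#' its maximal-scoring ungapped segment (match/mismatch scoring) and
#' reports segments with raw score at least `params$min_score`. E-values
#' follow the extreme-value model `E = K * m * N * exp(-lambda * S)` with
#' effective search space = probe length times total database length. The
#' scan is exhaustive, so results are deterministic and independent of
#' subject order.
#'
#' @param probes Probe data frame (`probe_id`, `sequence`) or a named
#'   character vector of probe sequences.
#' @param db Data frame of subject records (`seq_id`, `sequence`,
#'   optionally `genus`, `family`, `phylum`).
#' @param params [search_params()].
#' @return Data frame of hits: `probe_id, subject_id, strand, align_start,
#'   align_end` (0-based half-open on the subject's plus strand
#'   coordinates of the scanned strand), `align_len, n_matches,
#'   n_mismatches, identity, overall_identity, score, evalue`, plus
#'   subject taxonomy columns when present in `db`.
#' @export
local_search <- function(probes, db, params = search_params()) {
  if (is.null(db) || nrow(db) == 0L) stop("db must be non-empty")
  if (!is.data.frame(probes)) {
    probes <- data.frame(probe_id = names(probes), sequence = unname(probes),
                         stringsAsFactors = FALSE)
  }
  if (nrow(probes) == 0L || anyNA(probes$sequence)) {
    stop("probes must be a non-empty set with valid sequences")
  }
  N_total <- sum(nchar(db$sequence))
  has_tax <- all(c("genus", "family", "phylum") %in% names(db))
  hits <- list()
  subj_ints <- lapply(db$sequence, function(s) utf8ToInt(toupper(s)))
  subj_rc <- if (params$both_strands)
    lapply(db$sequence, function(s) utf8ToInt(reverse_complement(s))) else NULL
  for (pi in seq_len(nrow(probes))) {
    p <- utf8ToInt(toupper(probes$sequence[pi]))
    w <- length(p)
    for (si in seq_len(nrow(db))) {
      strands <- if (params$both_strands) c("+", "-") else "+"
      for (st in strands) {
        subj <- if (st == "+") subj_ints[[si]] else subj_rc[[si]]
        Ls <- length(subj)
        for (d in seq.int(-(w - 1L), Ls - 1L)) {
          i0 <- max(1L, 1L - d)          # probe index where overlap starts
          j0 <- i0 + d                   # subject index
          len <- min(w - i0, Ls - j0) + 1L
          if (len < 1L) next
          eq <- p[i0:(i0 + len - 1L)] == subj[j0:(j0 + len - 1L)]
          sc <- ifelse(eq, params$match, params$mismatch)
          seg <- .best_segment(sc)
          if (is.null(seg) || seg$score < params$min_score) next
          js <- j0 + seg$start - 1L      # 1-based subject start on strand
          je <- j0 + seg$end - 1L
          nm <- sum(eq[seg$start:seg$end])
          alen <- seg$end - seg$start + 1L
          a0 <- if (st == "+") js - 1L else Ls - je
          a1 <- if (st == "+") je else Ls - js + 1L
          hits[[length(hits) + 1L]] <- data.frame(
            probe_id = probes$probe_id[pi], subject_id = db$seq_id[si],
            strand = st, align_start = a0, align_end = a1,
            align_len = alen, n_matches = nm, n_mismatches = alen - nm,
            identity = nm / alen, overall_identity = nm / w,
            score = seg$score,
            evalue = params$K * w * N_total * exp(-params$lambda * seg$score),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else data.frame(
    probe_id = character(0), subject_id = character(0), strand = character(0),
    align_start = integer(0), align_end = integer(0), align_len = integer(0),
    n_matches = integer(0), n_mismatches = integer(0), identity = numeric(0),
    overall_identity = numeric(0), score = numeric(0), evalue = numeric(0),
    stringsAsFactors = FALSE)
  if (has_tax && nrow(out)) {
    tax <- db[, c("seq_id", "genus", "family", "phylum")]
    names(tax)[1L] <- "subject_id"
    out <- merge(out, tax, by = "subject_id", sort = FALSE)
    out <- out[, c("probe_id", setdiff(names(out), "probe_id"))]
  }
  out <- out[order(out$probe_id, out$evalue, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter cross-hybridization hits on the screening criteria
#'
#' Keeps hits with alignment length at least `min_len`, E-value strictly
#' below `max_evalue` and alignment identity at least `min_identity`.
#' Idempotent and order-independent.
#'
#' @param hits Hit data frame from [local_search()].
#' @param min_len Minimum alignment length (nt).
#' @param max_evalue Strict E-value ceiling ("E less than 0.05%" reads as
#'   5e-4).
#' @param min_identity Minimum alignment identity (fraction).
#' @return Filtered hit data frame.
#' @export
filter_hits <- function(hits, min_len = 30L, max_evalue = 5e-4,
                        min_identity = 0.90) {
  keep <- hits$align_len >= min_len & hits$evalue < max_evalue &
    hits$identity >= min_identity - 1e-12
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimum perfectly matched positions implied by an identity floor
#'
#' `ceiling(align_len * min_identity)`, with a guard against binary
#' floating-point artifacts (so 30 x 0.90 gives 27, not 28).
#'
#' @param align_len Alignment length (nt).
#' @param min_identity Identity floor, in (0, 1].
#' @return Integer count of required perfect matches.
#' @examples
#' min_perfect_matches(30, 0.90)  # 27
#' @export
min_perfect_matches <- function(align_len, min_identity) {
  stopifnot(min_identity > 0, min_identity <= 1)
  as.integer(ceiling(align_len * min_identity - 1e-9))
}

#' Arithmetic consequences of the cross-hybridization hit criteria
#'
#' For a probe of `probe_len` nt screened with hits of at least `min_len`
#' aligned positions at `min_identity` alignment identity: the minimum
#' number of perfect matches per hit, the maximum number of mismatched
#' probe positions (aligned mismatches plus unaligned overhang), and the
#' resulting minimum overall identity over the probe length (percent,
#' truncated to an integer).
#'
#' @param probe_len Probe length (nt).
#' @param min_len Minimum alignment length (nt).
#' @param min_identity Alignment identity floor (fraction).
#' @return List with `min_matches`, `max_mismatches`,
#'   `min_overall_identity_pct`.
#' @examples
#' crosshyb_criteria(35, 30, 0.90)  # 27 matches, 8 mismatches, 77 percent
#' @export
crosshyb_criteria <- function(probe_len = 35L, min_len = 30L,
                              min_identity = 0.90) {
  mm <- min_perfect_matches(min_len, min_identity)
  list(min_matches = mm,
       max_mismatches = as.integer(probe_len - mm),
       min_overall_identity_pct = trunc(100 * mm / probe_len + 1e-9))
}

#' Round half-up
#'
#' Table-style rounding where .5 always rounds away from zero (so 88.45
#' reports as 88.5), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimals kept.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a total, rounded half-up
#'
#' @param n Numerator count(s).
#' @param total Denominator count.
#' @param digits Decimals kept (tables use 1; prose often 0).
#' @return Percentage(s).
#' @examples
#' percent_of(100, 113)  # 88.5
#' @export
percent_of <- function(n, total, digits = 1L) {
  round_half_up(100 * n / total, digits)
}

#' Classify probes by cross-hybridization hit count
#'
#' Bins each probe of the set into `none`, `single`, `double` or
#' `multiple` (3 or more filtered hits), mirroring the hit-class rows of
#' a per-database probe-specificity table.
#'
#' @param hits Filtered hit data frame.
#' @param probe_ids Character vector of all probe ids in the set (probes
#'   without hits count as `none`).
#' @param digits Decimals for reported percentages.
#' @return List with `per_probe` (probe_id, n_hits, class) and `summary`
#'   (class, n, pct over the probe set), plus `n_probes` and `n_hits`.
#' @export
classify_hit_counts <- function(hits, probe_ids, digits = 1L) {
  counts <- table(factor(hits$probe_id, levels = probe_ids))
  n_hits <- as.integer(counts)
  cls <- cut(n_hits, breaks = c(-1, 0, 1, 2, Inf),
             labels = c("none", "single", "double", "multiple"))
  per_probe <- data.frame(probe_id = probe_ids, n_hits = n_hits,
                          class = as.character(cls),
                          stringsAsFactors = FALSE)
  tab <- table(cls)
  summary <- data.frame(class = names(tab), n = as.integer(tab),
                        pct = percent_of(as.integer(tab), length(probe_ids),
                                         digits),
                        stringsAsFactors = FALSE)
  list(per_probe = per_probe, summary = summary,
       n_probes = length(probe_ids), n_hits = nrow(hits))
}

#' Classify a probe's hits by taxonomic rank
#'
#' Compares the taxonomy of each (annotated) hit with the probe's origin:
#' `no-hits` when the probe has none; `all-same-genus` when every
#' annotated hit shares the origin genus; `all-same-family` likewise at
#' family rank; otherwise `some-outside-family`. Hits lacking taxonomy
#' are excluded from the rank comparison and counted separately; a probe
#' whose hits are all unannotated is classed `unclassified`.
#'
#' @param hits Filtered hits for one probe (with `genus`, `family`,
#'   `phylum` columns; `NA` = unannotated).
#' @param origin List or one-row data frame with the probe's `genus`,
#'   `family`, `phylum`.
#' @return List with `category`, `outside_phylum` (flag: any annotated
#'   hit from a different phylum) and `n_unannotated`.
#' @export
classify_taxonomy <- function(hits, origin) {
  if (is.data.frame(origin)) origin <- as.list(origin[1L, ])
  stopifnot(!is.null(origin$genus), !is.null(origin$family),
            !is.null(origin$phylum))
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(category = "no-hits", outside_phylum = FALSE,
                n_unannotated = 0L))
  }
  ann <- !is.na(hits$genus) & !is.na(hits$family) & !is.na(hits$phylum)
  n_un <- sum(!ann)
  h <- hits[ann, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(list(category = "unclassified", outside_phylum = FALSE,
                n_unannotated = n_un))
  }
  category <- if (all(h$genus == origin$genus)) "all-same-genus"
  else if (all(h$family == origin$family)) "all-same-family"
  else "some-outside-family"
  list(category = category,
       outside_phylum = any(h$phylum != origin$phylum),
       n_unannotated = n_un)
}

#' Probe-set taxonomy summary (hit-class and rank rows)
#'
#' Builds the per-database specificity summary: total probes with hits,
#' single/double/multiple hit classes, and the cumulative taxonomic-rank
#' rows (probes with all hits from the same genus; same family, which
#' includes the same-genus probes; some hits outside the family, with the
#' outside-phylum subset).
#'
#' @param hits Filtered hit data frame (with taxonomy columns).
#' @param probes Probe data frame with `probe_id` and origin taxonomy
#'   columns `genus`, `family`, `phylum`.
#' @param digits Decimals for percentages.
#' @return Data frame with `row`, `n`, `pct` (percent of all probes).
#' @export
summarize_taxonomy <- function(hits, probes, digits = 1L) {
  hc <- classify_hit_counts(hits, probes$probe_id, digits)
  cats <- character(nrow(probes)); outside_ph <- logical(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    ct <- classify_taxonomy(
      hits[hits$probe_id == probes$probe_id[i], , drop = FALSE],
      probes[i, c("genus", "family", "phylum")])
    cats[i] <- ct$category; outside_ph[i] <- ct$outside_phylum
  }
  n_tot <- nrow(probes)
  n <- c(sum(hc$per_probe$n_hits > 0L),
         sum(hc$per_probe$class == "single"),
         sum(hc$per_probe$class == "double"),
         sum(hc$per_probe$class == "multiple"),
         sum(cats == "all-same-genus"),
         sum(cats %in% c("all-same-genus", "all-same-family")),
         sum(cats == "some-outside-family"),
         sum(outside_ph),
         sum(cats == "unclassified"))
  data.frame(
    row = c("probes_with_hits", "single_hits", "double_hits",
            "multiple_hits", "all_same_genus", "all_same_family",
            "some_outside_family", "some_outside_phylum", "unannotated_only"),
    n = n, pct = percent_of(n, n_tot, digits), stringsAsFactors = FALSE)
}

#' Per-database cross-hybridization summary
#'
#' One row per database: total length (bp), number of sequences, number
#' of filtered hits and number of probes with at least one hit.
#'
#' @param probes Probe data frame (`probe_id`, `sequence`).
#' @param dbs Named list of subject databases (each a record data frame).
#' @param params [search_params()].
#' @param min_len,max_evalue,min_identity Passed to [filter_hits()].
#' @return Data frame with one row per database, plus the filtered hits as
#'   attribute `"hits"` (a named list).
#' @export
summarize_databases <- function(probes, dbs, params = search_params(),
                                min_len = 30L, max_evalue = 5e-4,
                                min_identity = 0.90) {
  rows <- list(); all_hits <- list()
  for (nm in names(dbs)) {
    db <- dbs[[nm]]
    if (is.null(db) || nrow(db) == 0L) {
      rows[[nm]] <- data.frame(database = nm, total_bp = 0L,
                               n_sequences = 0L, n_hits = 0L,
                               n_probes_with_hits = 0L,
                               stringsAsFactors = FALSE)
      all_hits[[nm]] <- NULL
      next
    }
    h <- filter_hits(local_search(probes, db, params),
                     min_len, max_evalue, min_identity)
    rows[[nm]] <- data.frame(
      database = nm, total_bp = sum(nchar(db$sequence)),
      n_sequences = nrow(db), n_hits = nrow(h),
      n_probes_with_hits = length(unique(h$probe_id)),
      stringsAsFactors = FALSE)
    all_hits[[nm]] <- h
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "hits") <- all_hits
  out
}
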