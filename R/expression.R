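# Microarray expression statistics: replicate handling, quantile
# normalization, pooled lowest-5% background, expression calls,
# fold-over-background, seasonal freshwater baselines, log2 differential
# ratios and selection, phylum/family rollups, Spearman correlations and
# the one-way ANOVA probe filter.

.as_intensity <- function(m, require_normalized = FALSE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expected a numeric matrix")
  if (anyNA(m)) stop("intensity matrix contains missing values")
  if (any(m < 0)) stop("intensity matrix contains negative values")
  st <- attr(m, "state")
  if (require_normalized && identical(st, "raw")) {
    stop("matrix is in raw state; quantile_normalize() it first")
  }
  m
}

#' Average replicate hybridizations into per-sample columns
#'
#' Arithmetic mean of the replicate columns mapped to each sample.
#'
#' @param m Probe-by-hybridization matrix.
#' @param replicate_of Character vector (length `ncol(m)`) giving the
#'   sample id of each column.
#' @return Probe-by-sample matrix, columns in first-appearance order of
#'   `replicate_of`; samples with a single replicate pass through with a
#'   warning.
#' @export
average_replicates <- function(m, replicate_of) {
  m <- .as_intensity(m)
  if (length(replicate_of) != ncol(m)) {
    stop("replicate_of must name a sample per column")
  }
  samples <- unique(replicate_of)
  singles <- samples[tabulate(factor(replicate_of, levels = samples)) == 1L]
  if (length(singles)) {
    warning("single replicate for sample(s): ",
            paste(singles, collapse = ", "))
  }
  out <- vapply(samples, function(s) {
    rowMeans(m[, replicate_of == s, drop = FALSE])
  }, numeric(nrow(m)))
  dimnames(out) <- list(rownames(m), samples)
  attr(out, "state") <- attr(m, "state")
  out
}

#' Concordance between two replicate hybridizations
#'
#' Squared Pearson correlation of log signals and the fraction of probes
#' whose replicate ratio leaves the standard 2-fold band.
#'
#' @param a,b Positive intensity vectors over the same probe index.
#' @param fold Band half-width as a ratio (default 2-fold).
#' @return List with `r_squared` and `fraction_outside_2fold`.
#' @export
replicate_concordance <- function(a, b, fold = 2) {
  if (length(a) != length(b)) stop("replicates must share the probe index")
  if (any(a <= 0) || any(b <= 0)) stop("signals must be positive for logs")
  la <- log(a); lb <- log(b)
  if (stats::sd(la) == 0 || stats::sd(lb) == 0) {
    stop("undefined correlation: zero-variance replicate column")
  }
  ratio <- a / b
  list(r_squared = stats::cor(la, lb)^2,
       fraction_outside_2fold = mean(ratio > fold | ratio < 1 / fold))
}

#' Quantile normalization
#'
#' Forces every sample column to the same empirical distribution: the
#' row-wise mean of the column-sorted values, mapped back through each
#' column's ranks. Ties receive the mean of the quantile values they
#' straddle, so within-column rank order is preserved.
#'
#' @param m Probe-by-sample matrix (at least 2 columns).
#' @return Normalized matrix (attribute `state = "normalized"`).
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantile_normalize <- function(m) {
  m <- .as_intensity(m)
  if (ncol(m) < 2L) stop("quantile normalization needs at least 2 samples")
  ref <- rowMeans(apply(m, 2L, sort))
  out <- apply(m, 2L, function(x) {
    r <- rank(x, ties.method = "average")
    (ref[floor(r)] + ref[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(m)
  attr(out, "state") <- "normalized"
  out
}

#' Global background model from pooled signals
#'
#' Pools every probe-by-sample value across all normalized arrays and
#' takes the mean of the lowest `fraction` of signals as the background;
#' the standard deviation is, by default, that of the same lowest subset
#' (`sd_scope = "all"` uses the SD of all pooled signals instead).
#'
#' @param m Normalized intensity matrix.
#' @param fraction Fraction of lowest signals pooled (default 0.05).
#' @param sd_scope `"lowest"` or `"all"`.
#' @return List of class `background_model`: `bg_mean`, `bg_sd`,
#'   `fraction`, `n_pooled`.
#' @export
global_background <- function(m, fraction = 0.05,
                              sd_scope = c("lowest", "all")) {
  m <- .as_intensity(m, require_normalized = TRUE)
  sd_scope <- match.arg(sd_scope)
  pool <- sort(as.vector(m))
  k <- as.integer(floor(fraction * length(pool)))
  if (k < 2L) stop("fraction * n must be at least 2 pooled values")
  subset <- pool[seq_len(k)]
  structure(list(bg_mean = mean(subset),
                 bg_sd = if (sd_scope == "lowest") stats::sd(subset)
                         else stats::sd(pool),
                 fraction = fraction, n_pooled = k),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("Background: mean %.3f, SD %.3f (lowest %.0f%% = %d signals)\n",
              x$bg_mean, x$bg_sd, 100 * x$fraction, x$n_pooled))
  invisible(x)
}

#' Call significantly expressed probes
#'
#' A probe is expressed when its normalized signal strictly exceeds
#' `bg_mean + k_sd * bg_sd` in at least `min_samples` samples.
#'
#' @param m Normalized intensity matrix.
#' @param bg [global_background()] model.
#' @param k_sd SD multiplier (default 3).
#' @param min_samples Minimum qualifying samples (default 2).
#' @return Named logical vector over probes.
#' @export
call_expressed <- function(m, bg, k_sd = 3, min_samples = 2L) {
  m <- .as_intensity(m, require_normalized = TRUE)
  thr <- bg$bg_mean + k_sd * bg$bg_sd
  rowSums(m > thr) >= min_samples
}

#' Log2 fold over background
#'
#' `log2(value / bg_mean)`, floored at 0 for values at or below the
#' background mean (heat-map convention).
#'
#' @param m Normalized intensity matrix.
#' @param bg [global_background()] model with `bg_mean > 0`.
#' @return Matrix of log2 fold-over-background values.
#' @export
fold_over_background <- function(m, bg) {
  m <- .as_intensity(m, require_normalized = TRUE)
  if (bg$bg_mean <= 0) stop("bg_mean must be positive")
  out <- log2(pmax(m, bg$bg_mean) / bg$bg_mean)
  attr(out, "state") <- NULL
  out
}

#' Validate sample metadata
#'
#' Checks the metadata contract: required columns, exactly two baseline
#' samples per season, and river habitat for every baseline sample.
#'
#' @param meta Data frame with columns `sample_id`, `season`, `habitat`,
#'   `is_baseline` (and typically `salinity_psu`, `depth_class`,
#'   `location_code`).
#' @return `meta`, invisibly, on success; otherwise an error naming the
#'   offending season(s).
#' @export
validate_sample_meta <- function(meta) {
  need <- c("sample_id", "season", "habitat", "is_baseline")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  nb <- tapply(meta$is_baseline, meta$season, sum)
  bad <- names(nb)[nb != 2L]
  if (length(bad)) {
    stop("each season needs exactly 2 baseline samples; offending season(s): ",
         paste(sprintf("%s (%d)", bad, nb[bad]), collapse = ", "))
  }
  if (any(meta$habitat[meta$is_baseline] != "river")) {
    stop("baseline samples must come from the river habitat")
  }
  invisible(meta)
}

#' Seasonal freshwater baselines
#'
#' For each season, the arithmetic mean of the two freshwater (river)
#' baseline sample columns, per probe.
#'
#' @param m Normalized intensity matrix (columns named by sample id).
#' @param meta Sample metadata (see [validate_sample_meta()]).
#' @return Probe-by-season baseline matrix.
#' @export
freshwater_baseline <- function(m, meta) {
  m <- .as_intensity(m, require_normalized = TRUE)
  validate_sample_meta(meta)
  seasons <- unique(meta$season)
  out <- vapply(seasons, function(s) {
    ids <- meta$sample_id[meta$season == s & meta$is_baseline]
    if (!all(ids %in% colnames(m))) {
      stop("baseline sample(s) missing from matrix for season ", s)
    }
    rowMeans(m[, ids, drop = FALSE])
  }, numeric(nrow(m)))
  dimnames(out) <- list(rownames(m), seasons)
  out
}

#' Log2 expression ratios over the seasonal freshwater baseline
#'
#' Clamps the matrix at the background mean (so logs stay defined), then
#' computes `log2(sample) - log2(seasonal baseline)` for every probe in
#' every non-baseline sample.
#'
#' @param m Normalized intensity matrix.
#' @param meta Sample metadata.
#' @param bg [global_background()] model used for clamping; `NULL`
#'   disables clamping (all values must already be positive).
#' @return List of class `differential_table`: `log2_ratio`
#'   (probe by non-baseline sample), `baselines`, `meta` (non-baseline
#'   rows), and `n_clamped`.
#' @export
differential_ratios <- function(m, meta, bg = NULL) {
  m <- .as_intensity(m, require_normalized = TRUE)
  validate_sample_meta(meta)
  n_clamped <- 0L
  if (!is.null(bg)) {
    n_clamped <- sum(m < bg$bg_mean)
    m[m < bg$bg_mean] <- bg$bg_mean
    attr(m, "state") <- "normalized"
  }
  if (any(m <= 0)) stop("non-positive intensities; supply a background model")
  baselines <- freshwater_baseline(m, meta)
  if (any(baselines <= 0)) stop("baseline value <= 0 after clamping")
  nb <- meta[!meta$is_baseline, , drop = FALSE]
  ratio <- vapply(seq_len(nrow(nb)), function(i) {
    log2(m[, nb$sample_id[i]]) - log2(baselines[, nb$season[i]])
  }, numeric(nrow(m)))
  dimnames(ratio) <- list(rownames(m), nb$sample_id)
  structure(list(log2_ratio = ratio, baselines = baselines, meta = nb,
                 n_clamped = n_clamped),
            class = "differential_table")
}

#' @export
print.differential_table <- function(x, ...) {
  cat(sprintf("Differential table: %d probes x %d non-baseline samples (%d value(s) clamped at background)\n",
              nrow(x$log2_ratio), ncol(x$log2_ratio), x$n_clamped))
  invisible(x)
}

.ratio_matrix <- function(dt) {
  if (inherits(dt, "differential_table")) dt$log2_ratio else as.matrix(dt)
}

#' Select differentially expressed probes
#'
#' A probe is differential when its baseline-relative ratio reaches at
#' least `fold`-fold (either direction) in at least `min_samples`
#' samples; both comparisons are inclusive. A ratio of exactly zero is
#' no variation and never qualifies, so at `fold = 1` the selection
#' reduces to "any nonzero ratio in at least `min_samples` samples".
#'
#' @param dt A `differential_table` or log2-ratio matrix.
#' @param fold Fold-change threshold (>= 1, default 2).
#' @param min_samples Minimum qualifying samples (default 2).
#' @return Named logical vector over probes.
#' @export
select_differential <- function(dt, fold = 2, min_samples = 2L) {
  stopifnot(fold >= 1)
  r <- .ratio_matrix(dt)
  rowSums(abs(r) >= log2(fold) & r != 0) >= min_samples
}

#' Upregulated gene set within a sample cluster
#'
#' Probes whose ratio strictly exceeds `fold`-fold above the seasonal
#' freshwater baseline in at least `min_samples` of the cluster's samples
#' (upregulation only).
#'
#' @param dt A `differential_table` or log2-ratio matrix.
#' @param cluster_samples Sample ids (subset of the ratio columns).
#' @param fold Fold threshold (strict, default 2).
#' @param min_samples Minimum qualifying samples.
#' @return Character vector of probe ids.
#' @export
upregulated_set <- function(dt, cluster_samples, fold = 2, min_samples = 2L) {
  r <- .ratio_matrix(dt)
  if (length(cluster_samples) == 0L) return(character(0))
  if (!all(cluster_samples %in% colnames(r))) {
    stop("cluster_samples must be non-baseline sample ids")
  }
  r <- r[, cluster_samples, drop = FALSE]
  rownames(r)[rowSums(r > log2(fold)) >= min_samples]
}

#' Phylum-by-season median fold-change table
#'
#' For each phylum and season, the median normalized signal over the
#' phylum's expressed probes across the season's samples, expressed as a
#' fold change over the median of the entire normalized data set. Also
#' reports per-phylum probe counts, expressed counts and percent
#' expressed.
#'
#' @param m Normalized intensity matrix.
#' @param expressed Logical vector over probes (see [call_expressed()]).
#' @param taxonomy Data frame mapping `probe_id` to `phylum`.
#' @param meta Sample metadata (season assignments).
#' @param digits Decimals for the percent-expressed column.
#' @return Data frame: one row per phylum with `n_probes`, `n_expressed`,
#'   `pct_expressed` and one fold-change column per season (`NA` when a
#'   phylum has no expressed probes).
#' @export
phylum_fold_table <- function(m, expressed, taxonomy, meta, digits = 1L) {
  m <- .as_intensity(m, require_normalized = TRUE)
  global_median <- stats::median(m)
  seasons <- unique(meta$season)
  phyla <- unique(taxonomy$phylum)
  rows <- lapply(phyla, function(ph) {
    ids <- taxonomy$probe_id[taxonomy$phylum == ph]
    ids_expr <- ids[expressed[ids]]
    folds <- vapply(seasons, function(s) {
      cols <- meta$sample_id[meta$season == s]
      if (length(ids_expr) == 0L) return(NA_real_)
      stats::median(m[ids_expr, cols, drop = FALSE]) / global_median
    }, 0)
    out <- data.frame(phylum = ph, n_probes = length(ids),
                      n_expressed = length(ids_expr),
                      pct_expressed = percent_of(length(ids_expr),
                                                 length(ids), digits),
                      stringsAsFactors = FALSE)
    out[seasons] <- as.list(folds)
    out
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_probes), , drop = FALSE]
}

#' Family composition of a gene set
#'
#' Percentage of the gene set contributed by each family; families
#' represented by fewer than `min_probes` probes on the whole array are
#' folded into `"other"`. Percentages sum to 100 up to rounding.
#'
#' @param gene_set Character vector of probe/gene ids.
#' @param taxonomy Data frame mapping `probe_id` to `family` for the whole
#'   array.
#' @param min_probes Array-wide family size below which a family is
#'   suppressed into `"other"`.
#' @param digits Decimals for percentages.
#' @return Data frame `family`, `n`, `pct`, sorted by decreasing `n` with
#'   `"other"` last.
#' @export
family_composition <- function(gene_set, taxonomy, min_probes = 15L,
                               digits = 1L) {
  fam_sizes <- table(taxonomy$family)
  shown <- names(fam_sizes)[fam_sizes >= min_probes]
  fam <- taxonomy$family[match(gene_set, taxonomy$probe_id)]
  if (anyNA(fam)) stop("taxonomy does not cover the full gene set")
  fam[!(fam %in% shown)] <- "other"
  tab <- table(fam)
  out <- data.frame(family = names(tab), n = as.integer(tab),
                    pct = percent_of(as.integer(tab), length(gene_set),
                                     digits),
                    stringsAsFactors = FALSE)
  is_other <- out$family == "other"
  out <- rbind(out[!is_other, ][order(-out$n[!is_other]), , drop = FALSE],
               out[is_other, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Pairwise sample correlations
#'
#' Spearman rank (default) or Pearson correlations between sample
#' columns; constant columns give `NA` entries with a warning.
#'
#' @param x Probe-by-sample matrix, or a `differential_table`.
#' @param method `"spearman"` or `"pearson"`.
#' @return Sample-by-sample correlation matrix.
#' @export
pairwise_correlation <- function(x, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  r <- .ratio_matrix(x)
  if (nrow(r) < 3L) stop("need at least 3 probes")
  sds <- apply(r, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("constant column(s): ",
            paste(colnames(r)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  }
  suppressWarnings(stats::cor(r, method = method))
}

#' One-way ANOVA probe filter
#'
#' Per-probe fixed-effects one-way F test of the log2 ratios across
#' sample groups (via `stats::oneway.test(var.equal = TRUE)`); probes
#' with P below `alpha` are kept. No multiplicity correction by default
#' (`adjust = "BH"` enables Benjamini-Hochberg). Probes with essentially
#' zero total variance are guarded: their P is `NA` and they are never
#' selected.
#'
#' @param dt A `differential_table` or log2-ratio matrix.
#' @param group_labels Group label per sample column (at least 2 groups,
#'   each with at least 2 samples).
#' @param alpha Significance threshold on (adjusted) P.
#' @param adjust `"none"` or any `stats::p.adjust` method.
#' @return List with `p_values` (named) and `selected` (named logical).
#' @export
anova_filter <- function(dt, group_labels, alpha = 0.001, adjust = "none") {
  r <- .ratio_matrix(dt)
  g <- factor(group_labels)
  if (length(g) != ncol(r)) stop("one group label per sample column required")
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  p <- apply(r, 1L, function(x) {
    if (stats::var(x) < 1e-24) return(NA_real_)
    out <- tryCatch(stats::oneway.test(x ~ g, var.equal = TRUE)$p.value,
                    error = function(e) NA_real_)
    out
  })
  padj <- if (adjust == "none") p else stats::p.adjust(p, method = adjust)
  selected <- !is.na(padj) & padj < alpha
  names(selected) <- rownames(r)
  list(p_values = p, selected = selected)
}
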