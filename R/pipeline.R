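# End-to-end expression pipeline: the chain a field study runs after
# scanning — replicate averaging, quantile normalization, global
# background, expression calls, freshwater-baseline log2 ratios,
# differential selection, and optional 2D clustering of the selected set.

#' Run the expression analysis pipeline
#'
#' Chains [average_replicates()] (when a replicate map is given),
#' [quantile_normalize()], [global_background()], [call_expressed()],
#' [differential_ratios()], [select_differential()] and, optionally,
#' [two_d_cluster()] of the selected probes.
#'
#' @param m Raw probe-by-sample intensity matrix.
#' @param meta Sample metadata (see [validate_sample_meta()]).
#' @param replicate_of Optional replicate-to-sample map for the columns
#'   of `m`.
#' @param bg_fraction Background pool fraction.
#' @param sd_scope Background SD scope (see [global_background()]).
#' @param k_sd,min_samples_expressed Expression-call parameters.
#' @param fold,min_samples_differential Differential-selection
#'   parameters.
#' @param cluster Also 2D-cluster the selected probes (needs >= 2
#'   selected).
#' @return List of class `expression_pipeline`: `normalized`, `background`,
#'   `expressed`, `ratios` (a `differential_table`), `selected`,
#'   `clustering` (or `NULL`).
#' @export
run_expression_pipeline <- function(m, meta, replicate_of = NULL,
                                    bg_fraction = 0.05,
                                    sd_scope = "lowest",
                                    k_sd = 3, min_samples_expressed = 2L,
                                    fold = 2, min_samples_differential = 2L,
                                    cluster = FALSE) {
  if (!is.null(replicate_of)) m <- average_replicates(m, replicate_of)
  norm <- quantile_normalize(m)
  bg <- global_background(norm, bg_fraction, sd_scope)
  expressed <- call_expressed(norm, bg, k_sd, min_samples_expressed)
  ratios <- differential_ratios(norm, meta, bg)
  selected <- select_differential(ratios, fold, min_samples_differential)
  clustering <- NULL
  if (cluster && sum(selected) >= 2L) {
    clustering <- two_d_cluster(ratios$log2_ratio[selected, , drop = FALSE])
  }
  structure(list(normalized = norm, background = bg, expressed = expressed,
                 ratios = ratios, selected = selected,
                 clustering = clustering),
            class = "expression_pipeline")
}

#' @export
print.expression_pipeline <- function(x, ...) {
  cat(sprintf("Expression pipeline: %d probes x %d samples | background %.2f | %d expressed (%.1f%%) | %d differential (%.1f%%)\n",
              nrow(x$normalized), ncol(x$normalized), x$background$bg_mean,
              sum(x$expressed),
              percent_of(sum(x$expressed), length(x$expressed)),
              sum(x$selected),
              percent_of(sum(x$selected), length(x$selected))))
  invisible(x)
}
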