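# Seeded generators for every input the toolkit consumes: taxonomically
# structured gene sets with controlled homolog divergence, rRNA decoys,
# hybridization signals, and study-shaped intensity matrices with planted
# expression/differential truth. All generators are reproducible per seed.

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(len) {
  paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

# per-site substitution channel: with probability `prob`, resample the base
# uniformly from all four (so the realized per-site change rate is 3/4 prob).
# Two lineages with total resample probabilities u and v from a common
# ancestor then agree at a site with probability 1/4 + 3/4 (1-u)(1-v).
.mutate <- function(seq, prob) {
  if (prob <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < prob
  if (any(hit)) chars[hit] <- sample(.BASES, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

# total resample probability giving expected pairwise identity `t` between
# two lineages at symmetric divergence from their common ancestor:
# t = 1/4 + 3/4 (1-w)^2
.divergence_for_identity <- function(t) {
  if (t < 0.25 || t > 1) stop("identity targets must lie in [0.25, 1]")
  1 - sqrt((4 * t - 1) / 3)
}

#' Specification of a synthetic microbial community
#'
#' Defines the taxonomic scaffold (phyla / families / genera / genes) and
#' the target pairwise sequence identities at each taxonomic distance for
#' [simulate_community()]. Identity levels must decrease strictly with
#' taxonomic distance.
#'
#' @param n_phyla,families_per_phylum,genera_per_family,genes_per_genus
#'   Scaffold counts.
#' @param homolog_identity_levels Named fractions `genus`, `family`,
#'   `phylum`: expected pairwise identity between homologs of the same
#'   genus, of different genera within a family, and of different
#'   families within a phylum.
#' @param gene_length_range Gene length range (nt).
#' @param rrna_count Number of rRNA decoys to pair with the community.
#' @param seed RNG seed.
#' @return List of class `community_spec`.
#' @export
community_spec <- function(n_phyla = 2L, families_per_phylum = 2L,
                           genera_per_family = 2L, genes_per_genus = 2L,
                           homolog_identity_levels =
                             c(genus = 0.95, family = 0.85, phylum = 0.70),
                           gene_length_range = c(450L, 600L),
                           rrna_count = 5L, seed = 1L) {
  lv <- homolog_identity_levels
  if (!all(c("genus", "family", "phylum") %in% names(lv))) {
    stop("homolog_identity_levels needs named entries genus, family, phylum")
  }
  if (!(lv["genus"] > lv["family"] && lv["family"] > lv["phylum"])) {
    stop("identity levels must strictly decrease with taxonomic distance")
  }
  structure(list(n_phyla = n_phyla,
                 families_per_phylum = families_per_phylum,
                 genera_per_family = genera_per_family,
                 genes_per_genus = genes_per_genus,
                 homolog_identity_levels = lv,
                 gene_length_range = gene_length_range,
                 rrna_count = rrna_count, seed = seed),
            class = "community_spec")
}

#' Simulate a taxonomically structured gene community
#'
#' Generates one homologous gene set per phylum: a random phylum root is
#' mutated along the family and genus branches so that the expected
#' pairwise identity between genes equals the requested level at each
#' taxonomic distance (within genus, between genera of a family, between
#' families of a phylum; different phyla are unrelated). Substitutions
#' are uniform over positions and bases (no indels), so Hamming
#' bookkeeping stays exact. Deterministic per seed.
#'
#' @param spec A [community_spec()].
#' @return Data frame of sequence records: `seq_id, sequence, organism,
#'   genus, family, phylum, gene_type, functional_category`.
#' @export
simulate_community <- function(spec = community_spec()) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  lv <- spec$homolog_identity_levels
  w_gene <- .divergence_for_identity(lv[["genus"]])
  w_fam <- .divergence_for_identity(lv[["family"]])
  w_phy <- .divergence_for_identity(lv[["phylum"]])
  # branch resample probabilities composing to the leaf totals
  b_genus <- 1 - (1 - w_fam) / (1 - w_gene)   # family base -> genus base
  b_family <- 1 - (1 - w_phy) / (1 - w_fam)   # phylum root -> family base
  cats <- c("nitrogen", "carbon", "housekeeping", "light", "other")
  rows <- list()
  for (p in seq_len(spec$n_phyla)) {
    len <- sample(seq.int(spec$gene_length_range[1L],
                          spec$gene_length_range[2L]), 1L)
    phylum <- sprintf("phylum%02d", p)
    root <- .random_dna(len)
    for (f in seq_len(spec$families_per_phylum)) {
      family <- sprintf("%s_fam%02d", phylum, f)
      fam_base <- .mutate(root, b_family)
      for (g in seq_len(spec$genera_per_family)) {
        genus <- sprintf("%s_gen%02d", family, g)
        gen_base <- .mutate(fam_base, b_genus)
        for (j in seq_len(spec$genes_per_genus)) {
          gene <- .mutate(gen_base, w_gene)
          rows[[length(rows) + 1L]] <- data.frame(
            seq_id = sprintf("%s_gene%02d", genus, j),
            sequence = gene,
            organism = sprintf("%s_sp%02d", genus, j),
            genus = genus, family = family, phylum = phylum,
            gene_type = "CDS",
            functional_category = cats[(j - 1L) %% length(cats) + 1L],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate conserved rRNA decoy sequences
#'
#' Draws `n` sequences around a common conserved core so that pairwise
#' identity stays at or above roughly 0.80, labeled `gene_type = "rRNA"`.
#' rRNA records never yield probes; they act only as uniqueness-filter
#' nontargets.
#'
#' @param n Number of decoys.
#' @param length Sequence length (nt).
#' @param pairwise_identity Target expected pairwise identity (default
#'   0.90, comfortably above the 0.80 floor).
#' @param seed RNG seed.
#' @return Sequence-record data frame with `gene_type = "rRNA"`.
#' @export
simulate_rrna <- function(n, length = 800L, pairwise_identity = 0.90,
                          seed = 1L) {
  stopifnot(n > 0)
  set.seed(seed)
  w <- .divergence_for_identity(pairwise_identity)
  core <- .random_dna(length)
  rows <- lapply(seq_len(n), function(i) {
    data.frame(seq_id = sprintf("rrna%03d", i),
               sequence = .mutate(core, w),
               organism = sprintf("rrna_clone%03d", i),
               genus = "unclassified", family = "unclassified",
               phylum = "unclassified", gene_type = "rRNA",
               functional_category = "other", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate one probe's hybridization signal
#'
#' Signal = background + sum over targets of abundance times a mismatch
#' response that is 1 for a perfect duplex, decreases linearly with the
#' mismatch-Tm penalty of the best same-length window (both strands), and
#' reaches 0 at a Tm separation of `delta_tm_zero` (15 degrees Celsius by
#' default, where hybridization drops to background). Multiplicative
#' log-normal noise in log2 units.
#'
#' @param probe_seq Probe sequence.
#' @param targets Data frame with `sequence` and `abundance` (>= 0)
#'   columns.
#' @param bg Background intensity.
#' @param noise_sd_log2 Log2-scale noise SD (0 = deterministic).
#' @param delta_tm_zero Tm separation at which the response reaches 0.
#' @param seed Optional RNG seed.
#' @return Simulated intensity (scalar).
#' @export
simulate_hybridization_signal <- function(probe_seq, targets, bg,
                                          noise_sd_log2 = 0,
                                          delta_tm_zero = 15,
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(targets$abundance >= 0))
  w <- nchar(probe_seq)
  contrib <- 0
  if (nrow(targets)) {
    for (i in seq_len(nrow(targets))) {
      one <- .build_scan_index(targets$sequence[i], "t", max_w = w,
                               both_strands = TRUE)
      mm <- .min_hamming_scan(probe_seq, one)$mm
      dtm <- if (is.finite(mm)) mismatch_tm_penalty(w, mm) else Inf
      response <- max(0, 1 - dtm / delta_tm_zero)
      contrib <- contrib + targets$abundance[i] * response
    }
  }
  signal <- bg + contrib
  if (noise_sd_log2 > 0) signal <- signal * 2^stats::rnorm(1, 0, noise_sd_log2)
  signal
}

#' Simulate a seasonal hybridization study with planted truth
#'
#' Builds a probe-by-sample intensity matrix shaped like a seasonal field
#' study: `n_seasons` seasons with `samples_per_season` samples each, two
#' river (0 PSU) baseline samples per season, remaining samples spread
#' over estuary / plume / ocean habitats. Signals follow the additive
#' optical model `intensity = background floor + target abundance`:
#' expressed probes receive a continuous log-normal abundance
#' (`bg_level * 2^N(expr_mean_log2, expr_sd_log2)`); unexpressed probes
#' have zero abundance and sit exactly at the floor, so at zero noise
#' the expressed flag is exactly recoverable from the background + 3 SD
#' call. A fraction of the clearly expressed probes (abundance at least
#' `2^diff_min_log2` times the floor; an effect planted on a probe at
#' the optical floor would be unobservable) is planted as differential:
#' in the non-baseline samples of their assigned season their abundance
#' (never the floor) is multiplied or divided by `differential_fold`.
#' Multiplicative log-normal noise is applied in log2 units. The full
#' planted truth is returned.
#'
#' @param probe_ids Character vector of probe ids (rows).
#' @param n_seasons Number of seasons (cycled from April, June, August,
#'   November).
#' @param samples_per_season Samples per season (including the 2
#'   baselines).
#' @param frac_expressed Fraction of probes expressed above background.
#' @param frac_differential Fraction of the clearly expressed probes
#'   planted as differential.
#' @param differential_fold Planted fold change (applied up for half the
#'   planted probes, down for the other half).
#' @param noise_sd_log2 Log2 noise SD (0 = noiseless).
#' @param bg_level Background intensity floor.
#' @param expr_mean_log2,expr_sd_log2 Log2 parameters of the expressed
#'   abundance distribution over the background floor.
#' @param diff_min_log2 Log2 abundance-over-floor eligibility bound for
#'   planting differential effects.
#' @param seed RNG seed.
#' @return List of class `simulated_study`: `matrix` (raw-state
#'   intensities), `meta` (sample metadata), `truth` (list: `expressed`,
#'   `differential`, `direction`, `season`, `fold`, `sample_clusters`).
#' @export
simulate_study <- function(probe_ids, n_seasons = 4L,
                           samples_per_season = 16L,
                           frac_expressed = 0.9, frac_differential = 0.2,
                           differential_fold = 4, noise_sd_log2 = 0.2,
                           bg_level = 100, expr_mean_log2 = 3.5,
                           expr_sd_log2 = 1.5, diff_min_log2 = 2,
                           seed = 1L) {
  stopifnot(samples_per_season >= 3L, n_seasons >= 1L)
  set.seed(seed)
  n <- length(probe_ids)
  seasons <- rep(c("April", "June", "August", "November"),
                 length.out = n_seasons)
  habitats <- c("estuary", "plume", "ocean")
  meta_rows <- list()
  for (s in seq_len(n_seasons)) {
    for (i in seq_len(samples_per_season)) {
      is_b <- i <= 2L
      hab <- if (is_b) "river" else habitats[(i - 3L) %% 3L + 1L]
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%s_%02d", substr(seasons[s], 1L, 3L),
                            toupper(substr(hab, 1L, 1L)), i),
        season = seasons[s], habitat = hab,
        salinity_psu = if (is_b) 0 else
          c(estuary = 10, plume = 25, ocean = 32)[[hab]] +
          stats::runif(1, -2, 2),
        depth_class = if (i %% 4L == 0L) "mid" else "surface",
        location_code = if (is_b) "BA" else toupper(substr(hab, 1L, 3L)),
        is_baseline = is_b, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  validate_sample_meta(meta)

  expressed <- stats::setNames(rep(FALSE, n), probe_ids)
  expressed[sample.int(n, round(frac_expressed * n))] <- TRUE
  # continuous log-normal target abundance for expressed probes; 0 = no
  # target (probe sits at the optical floor)
  abundance <- stats::setNames(rep(0, n), probe_ids)
  ne <- sum(expressed)
  abundance[expressed] <- bg_level *
    2^stats::rnorm(ne, expr_mean_log2, expr_sd_log2)

  # differential effects are planted only on clearly expressed probes
  # (abundance >= bg_level * 2^diff_min_log2): a fold change on a probe at
  # the optical floor is unobservable by construction
  differential <- stats::setNames(rep(FALSE, n), probe_ids)
  eligible <- probe_ids[abundance >= bg_level * 2^diff_min_log2]
  diff_ids <- sample(eligible, round(frac_differential * length(eligible)))
  differential[diff_ids] <- TRUE
  direction <- stats::setNames(rep(0L, n), probe_ids)
  if (length(diff_ids)) {
    direction[diff_ids] <- rep_len(c(1L, -1L), length(diff_ids))
  }
  diff_season <- stats::setNames(rep(NA_character_, n), probe_ids)
  if (length(diff_ids)) {
    diff_season[diff_ids] <- sample(unique(meta$season), length(diff_ids),
                                    replace = TRUE)
  }

  # additive optical model: signal = background floor + target abundance
  # (differential effects scale the abundance, never the floor, so no
  # value can dip below the array background)
  ab <- matrix(abundance, nrow = n, ncol = nrow(meta),
               dimnames = list(probe_ids, meta$sample_id))
  for (id in diff_ids) {
    cols <- meta$season == diff_season[id] & !meta$is_baseline
    ab[id, cols] <- ab[id, cols] * differential_fold^direction[id]
  }
  m <- bg_level + ab
  if (noise_sd_log2 > 0) {
    m <- m * 2^matrix(stats::rnorm(length(m), 0, noise_sd_log2), nrow = n)
  }
  attr(m, "state") <- "raw"
  truth <- list(expressed = expressed, differential = differential,
                direction = direction, season = diff_season,
                fold = differential_fold,
                sample_clusters = stats::setNames(meta$season,
                                                  meta$sample_id))
  structure(list(matrix = m, meta = meta, truth = truth),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("Simulated study: %d probes x %d samples (%d seasons), %d expressed, %d differential\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$meta$season)), sum(x$truth$expressed),
              sum(x$truth$differential)))
  invisible(x)
}

#' Estuary residence time
#'
#' `R = V / (86400 Q)`: the residence time in days of an estuary of
#' volume `V` (cubic meters) at river discharge `Q` (cubic meters per
#' second).
#'
#' @param volume_m3 Estuary volume (m^3).
#' @param discharge_m3s River discharge (m^3/s), > 0.
#' @return Residence time in days.
#' @examples
#' residence_time(5e9, 2.5e4)  # ~2.31 days
#' @export
residence_time <- function(volume_m3, discharge_m3s) {
  if (any(discharge_m3s <= 0)) stop("discharge must be positive")
  volume_m3 / (86400 * discharge_m3s)
}
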