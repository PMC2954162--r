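# Expression pipeline statistics: replicate handling, normalization,
# background, calls, baselines, ratios, rollups, correlations, ANOVA.

named_matrix <- function(vals, nr, nc, prefix = c("p", "s")) {
  matrix(vals, nr, nc, dimnames = list(sprintf("%s%03d", prefix[1], 1:nr),
                                       sprintf("%s%02d", prefix[2], 1:nc)))
}

test_that("replicate averaging is the per-probe arithmetic mean", {
  m <- named_matrix(c(2, 10, 4, 20, 7, 7), 2, 3)
  expect_warning(out <- average_replicates(m, c("A", "A", "B")), "single")
  expect_identical(colnames(out), c("A", "B"))
  expect_identical(unname(out[, "A"]), c(3, 15))
  expect_warning(average_replicates(m[, 1, drop = FALSE], "A"), "single")
  set.seed(71)
  r <- named_matrix(runif(40, 1, 100), 10, 4)
  out2 <- average_replicates(r, c("x", "x", "y", "y"))
  expect_equal(unname(out2[, "x"]), unname((r[, 1] + r[, 2]) / 2))
  # identical replicates pass through unchanged
  same <- average_replicates(cbind(r[, 1], r[, 1]), c("z", "z"))
  expect_equal(unname(same[, "z"]), unname(r[, 1]))
})

test_that("replicate concordance reports R^2 and the 2-fold fraction", {
  a <- c(1, 5, 20, 80, 200)
  same <- replicate_concordance(a, a)
  expect_equal(same$r_squared, 1)
  expect_identical(same$fraction_outside_2fold, 0)
  off <- replicate_concordance(2.1 * a, a)
  expect_identical(off$fraction_outside_2fold, 1)
  expect_equal(off$r_squared, 1)   # scaling preserves log correlation
  expect_error(replicate_concordance(rep(2, 5), a), "zero-variance")
  # noisy replicate: R^2 close to the closed-form expectation
  set.seed(72)
  x <- 2^rnorm(2000, 8, 1.5)
  y <- x * 2^rnorm(2000, 0, 0.15)
  cc <- replicate_concordance(x, y)
  rho2 <- (1.5^2 / (1.5^2 + 0.15^2))  # var(signal)/var(signal+noise)
  expect_lt(abs(cc$r_squared - rho2), 0.02)
})

test_that("quantile normalization matches the hand-worked example and oracle", {
  m <- named_matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  out <- quantile_normalize(m)
  expect_equal(unname(out), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)),
               ignore_attr = TRUE)
  # identical-distribution columns keep their sorted values
  m2 <- named_matrix(c(1, 2, 3, 3, 1, 2), 3, 2)
  out2 <- quantile_normalize(m2)
  expect_equal(sort(out2[, 1]), sort(m2[, 1]))
  expect_equal(unname(sort(out2[, 2])), c(1, 2, 3))
  set.seed(73)
  for (rep in 1:10) {
    # tied (rounded) values: oracle equality exercises the tie dialect
    r <- named_matrix(round(2^runif(80 * 6, 0, 10)), 80, 6)
    got <- quantile_normalize(r)
    expect_equal(unname(got), unname(oracle_quantile_normalize(r)),
                 ignore_attr = TRUE)
    for (j in 1:6) expect_identical(rank(got[, j], ties.method = "average"),
                                    rank(r[, j], ties.method = "average"))
    # tie-free values: all columns share one empirical distribution
    r2 <- named_matrix(2^runif(80 * 6, 0, 10), 80, 6)
    got2 <- quantile_normalize(r2)
    expect_equal(unname(got2), unname(oracle_quantile_normalize(r2)),
                 ignore_attr = TRUE)
    for (j in 2:6) expect_equal(sort(got2[, j]), sort(got2[, 1]),
                                ignore_attr = TRUE)
  }
})

test_that("quantile normalization agrees with limma on tie-free matrices", {
  skip_if_not_installed("limma")
  set.seed(74)
  m <- named_matrix(2^runif(300, 0, 12), 50, 6)
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("global background is the mean/SD of the pooled lowest 5%", {
  vals <- c(rep(2, 5), seq(10, 104, by = 1))
  m <- named_matrix(sample(vals), 25, 4)
  attr(m, "state") <- "normalized"
  bg <- global_background(m)
  expect_identical(bg$bg_mean, 2)
  expect_identical(bg$bg_sd, 0)
  expect_identical(bg$n_pooled, 5L)
  # constant matrix: background equals the constant
  mc <- named_matrix(rep(7, 100), 25, 4); attr(mc, "state") <- "normalized"
  expect_identical(global_background(mc)$bg_mean, 7)
  set.seed(75)
  for (rep in 1:20) {
    r <- named_matrix(2^runif(240, 0, 10), 40, 6)
    attr(r, "state") <- "normalized"
    got <- global_background(r)
    exp <- oracle_background(r)
    expect_equal(got$bg_mean, exp$bg_mean)
    expect_equal(got$bg_sd, exp$bg_sd)
  }
  raw <- named_matrix(2^runif(100, 0, 8), 25, 4); attr(raw, "state") <- "raw"
  expect_error(global_background(raw), "raw state")
  small <- named_matrix(1:8, 4, 2); attr(small, "state") <- "normalized"
  expect_error(global_background(small), "at least 2")
})

test_that("expression calls use a strict threshold in >= 2 samples", {
  bg <- structure(list(bg_mean = 10, bg_sd = 2), class = "background_model")
  thr <- 16  # 10 + 3 * 2
  m <- named_matrix(c(17, 17, 5,   17, 5, 5,   16, 16, 16), 3, 3)
  attr(m, "state") <- "normalized"
  got <- call_expressed(m, bg)
  expect_identical(unname(got), c(TRUE, FALSE, FALSE))
  # bg_sd 0 and value == bg_mean: strict inequality keeps it out
  bg0 <- structure(list(bg_mean = 10, bg_sd = 0), class = "background_model")
  m0 <- named_matrix(rep(10, 9), 3, 3); attr(m0, "state") <- "normalized"
  expect_identical(unname(call_expressed(m0, bg0)), rep(FALSE, 3))
})

test_that("fold over background floors at zero and is elementwise log2", {
  bg <- structure(list(bg_mean = 50, bg_sd = 1), class = "background_model")
  m <- named_matrix(c(50, 200, 25, 400), 2, 2)
  attr(m, "state") <- "normalized"
  out <- fold_over_background(m, bg)
  expect_equal(unname(out), cbind(c(0, 2), c(0, 3)))
  set.seed(76)
  r <- named_matrix(2^runif(60, 4, 9), 10, 6); attr(r, "state") <- "normalized"
  expect_equal(unname(fold_over_background(r, bg)),
               unname(pmax(log2(r / 50), 0)), ignore_attr = TRUE)
})

test_that("seasonal baselines average exactly the two river samples", {
  meta <- make_meta(c("April", "June"), 4L)
  m <- named_matrix(0, 3, 8)
  colnames(m) <- meta$sample_id
  m[] <- 2^matrix(runif(24, 3, 8), 3)
  m[1, meta$sample_id[1:2]] <- c(10, 10)
  m[2, meta$sample_id[1:2]] <- c(8, 16)
  attr(m, "state") <- "normalized"
  b <- freshwater_baseline(m, meta)
  expect_identical(colnames(b), c("April", "June"))
  expect_identical(unname(b[1:2, "April"]), c(10, 12))
  expect_equal(unname(b[, "June"]),
               unname(rowMeans(m[, meta$sample_id[5:6]])))
  # wrong baseline count errors, naming the season
  bad <- meta; bad$is_baseline[2] <- FALSE
  expect_error(freshwater_baseline(m, bad), "April")
})

test_that("differential ratios are log2 sample minus seasonal baseline", {
  meta <- make_meta("April", 5L)
  m <- named_matrix(0, 2, 5); colnames(m) <- meta$sample_id
  m[1, ] <- c(100, 100, 100, 400, 25)
  m[2, ] <- c(64, 64, 64, 64, 64)
  attr(m, "state") <- "normalized"
  dt <- differential_ratios(m, meta)
  expect_identical(colnames(dt$log2_ratio), meta$sample_id[3:5])
  expect_equal(unname(dt$log2_ratio[1, ]), c(0, 2, -2))
  expect_equal(unname(dt$log2_ratio[2, ]), c(0, 0, 0))
  # clamping: values below bg_mean rise to it before logs
  bg <- structure(list(bg_mean = 50, bg_sd = 0), class = "background_model")
  dt2 <- differential_ratios(m, meta, bg)
  expect_equal(unname(dt2$log2_ratio[1, 3]), -1)  # 25 -> 50 vs baseline 100
  expect_identical(dt2$n_clamped, 1L)
})

test_that("differential selection is inclusive, monotone and oracle-exact", {
  r <- rbind(exact2 = c(1, -1, 0, 0), one3 = c(log2(3), 0, 0, 0),
             null = c(0.5, 0.9, -0.99, 0))
  colnames(r) <- paste0("s", 1:4)
  sel <- select_differential(r)
  expect_identical(unname(sel), c(TRUE, FALSE, FALSE))
  # fold = 1 selects every probe with nonzero ratios in >= 2 samples
  expect_identical(unname(select_differential(r, fold = 1)),
                   c(TRUE, FALSE, TRUE))
  set.seed(77)
  for (rep in 1:20) {
    rr <- named_matrix(rnorm(200, 0, 1), 25, 8)
    for (f in c(1.5, 2, 3)) {
      expect_identical(unname(select_differential(rr, fold = f)),
                       unname(oracle_select_differential(rr, fold = f)))
    }
    # monotone: raising the fold never adds probes
    s2 <- select_differential(rr, fold = 2); s3 <- select_differential(rr, 3)
    expect_true(all(s2 | !s3))
  }
})

test_that("phylum fold table is group median over global median", {
  meta <- make_meta("April", 4L)
  tax <- data.frame(probe_id = sprintf("p%03d", 1:4),
                    phylum = c("A", "A", "B", "B"), stringsAsFactors = FALSE)
  m <- named_matrix(10, 4, 4); colnames(m) <- meta$sample_id
  m[3:4, ] <- 20    # phylum B uniformly 2x the global median region
  attr(m, "state") <- "normalized"
  expressed <- setNames(rep(TRUE, 4), rownames(m))
  tab <- phylum_fold_table(m, expressed, tax, meta)
  gm <- median(m)
  expect_equal(tab$April[tab$phylum == "B"], 20 / gm)
  expect_equal(tab$April[tab$phylum == "A"], 10 / gm)
  # constant matrix: all fold changes 1
  mc <- named_matrix(5, 4, 4); colnames(mc) <- meta$sample_id
  attr(mc, "state") <- "normalized"
  tc <- phylum_fold_table(mc, expressed, tax, meta)
  expect_true(all(tc$April == 1))
  # phylum with zero expressed probes yields NA cells
  e2 <- setNames(c(TRUE, TRUE, FALSE, FALSE), rownames(m))
  t2 <- phylum_fold_table(m, e2, tax, meta)
  expect_true(is.na(t2$April[t2$phylum == "B"]))
  expect_identical(t2$pct_expressed[t2$phylum == "B"], 0)
})

test_that("family composition folds sub-threshold families into other", {
  tax <- data.frame(probe_id = sprintf("p%03d", 1:40),
                    family = c(rep("F1", 20), rep("F2", 15), rep("F3", 5)),
                    stringsAsFactors = FALSE)
  gs <- sprintf("p%03d", c(1:10, 21:25, 36:40))  # 10 F1, 5 F2, 5 F3
  out <- family_composition(gs, tax, min_probes = 15L)
  expect_identical(out$pct[out$family == "F1"], 50)
  expect_identical(out$pct[out$family == "F2"], 25)
  expect_false("F3" %in% out$family)              # 5 probes on array < 15
  expect_identical(out$pct[out$family == "other"], 25)
  expect_equal(sum(out$pct), 100, tolerance = 0.2)
  set.seed(78)
  for (rep in 1:5) {
    gs2 <- sample(tax$probe_id, 17)
    o2 <- family_composition(gs2, tax, min_probes = 15L)
    expect_equal(sum(o2$n), 17L)
    expect_lt(abs(sum(o2$pct) - 100), 0.3)
  }
})

test_that("upregulated sets are one-sided and cluster-restricted", {
  r <- rbind(up = c(1.5, 1.5, 0, 0), down = c(-3, -3, -3, -3),
             lone = c(2, 0, 0, 0))
  colnames(r) <- paste0("s", 1:4)
  expect_identical(upregulated_set(r, c("s1", "s2")), "up")
  expect_identical(upregulated_set(r, c("s3", "s4")), character(0))
  expect_identical(upregulated_set(r, character(0)), character(0))
  expect_error(upregulated_set(r, "nope"), "non-baseline")
})

test_that("pairwise correlations are Spearman rank by default", {
  m <- named_matrix(0, 5, 3)
  m[, 1] <- c(1, 2, 3, 4, 5)
  m[, 2] <- c(2, 4, 8, 16, 32)   # monotone transform of column 1
  m[, 3] <- c(5, 4, 3, 2, 1)     # rank reversal
  cc <- pairwise_correlation(m)
  expect_equal(cc[1, 1], 1, ignore_attr = TRUE)
  expect_equal(cc[1, 2], 1, ignore_attr = TRUE)
  expect_equal(cc[1, 3], -1, ignore_attr = TRUE)
  # equals rank-then-Pearson
  set.seed(79)
  r <- named_matrix(rnorm(60), 12, 5)
  got <- pairwise_correlation(r)
  exp <- cor(apply(r, 2, rank))
  expect_equal(unname(got), unname(exp))
  r[, 2] <- 3
  expect_warning(cc2 <- pairwise_correlation(r), "constant")
  expect_true(is.na(cc2[1, 2]))
})

test_that("ANOVA filter has power on planted shifts and guards degeneracy", {
  g <- rep(c("a", "b"), each = 4)
  set.seed(80)
  # planted 8-fold (3 log2 units) shift, sigma 0.25: essentially sure pick
  r <- rbind(shift = c(rnorm(4, 0, 0.25), rnorm(4, 3, 0.25)),
             null = rnorm(8, 0, 0.25),
             const = rep(1, 8))
  colnames(r) <- paste0("s", 1:8)
  out <- anova_filter(r, g, alpha = 0.001)
  expect_true(out$selected[["shift"]])
  expect_false(out$selected[["null"]])
  expect_false(out$selected[["const"]])        # variance guard
  expect_true(is.na(out$p_values[["const"]]))
  expect_error(anova_filter(r, rep("a", 8)), "2 groups")
  expect_error(anova_filter(r, c(rep("a", 7), "b")), "at least 2 samples")
  # BH adjustment only shrinks the selection
  out_bh <- anova_filter(r, g, alpha = 0.001, adjust = "BH")
  expect_true(all(!out_bh$selected | out$selected))
})
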