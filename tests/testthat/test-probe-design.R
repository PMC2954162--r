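# Candidate enumeration, the 15C uniqueness rule, per-gene selection and
# the end-to-end design pipeline.

gene_rec <- function(seq, id = "g1") list(seq_id = id, sequence = seq)

test_that("enumeration counts windows and honors the filters", {
  g <- gene_rec(rand_dna(100))
  set.seed(51)
  g <- gene_rec(rand_dna(100))
  cand <- enumerate_candidates(g, len_range = c(35L, 35L), tm_window = NULL,
                               hairpin = NULL, repeats = NULL)
  expect_identical(nrow(cand), 66L)  # L - w + 1
  expect_identical(cand$start, 0:65)
  expect_true(all(cand$sequence == substring(g$sequence, cand$start + 1,
                                             cand$start + 35)))
  # too-short gene
  short <- enumerate_candidates(gene_rec(rand_dna(30)), len_range = c(35L, 45L))
  expect_identical(nrow(short), 0L)
  # rRNA records never yield probes
  expect_error(enumerate_candidates(list(seq_id = "r", sequence = rand_dna(60),
                                         gene_type = "rRNA")), "rRNA")
})

test_that("enumeration equals brute-force filtering on a GC-gradient gene", {
  set.seed(52)
  # GC content rising along the gene so the Tm filter bites asymmetrically
  chunks <- vapply(seq(0.25, 0.75, length.out = 6),
                   function(g) rand_dna(30, gc = g), "")
  g <- gene_rec(paste(chunks, collapse = ""))
  tmw <- c(66, 76)
  cand <- enumerate_candidates(g, len_range = c(35L, 37L), tm_window = tmw)
  oracle <- list()
  for (w in 35:37) {
    for (i in seq_len(nchar(g$sequence) - w + 1L)) {
      win <- substr(g$sequence, i, i + w - 1L)
      tm <- tm_nearest_neighbor(win)$tm
      if (tm >= tmw[1] && tm <= tmw[2] && hairpin_screen(win)$pass &&
          repeat_screen(win)$pass) {
        oracle[[length(oracle) + 1L]] <- data.frame(start = i - 1L,
                                                    length = w, tm = tm)
      }
    }
  }
  om <- do.call(rbind, oracle)
  om <- om[order(om$start, om$length), ]
  expect_identical(cand$start, om$start)
  expect_identical(cand$length, om$length)
  expect_equal(cand$tm_perfect, om$tm, tolerance = 1e-10)
  # stage counts reconcile: enumerated = kept + sum(rejected by reason)
  rej <- attr(cand, "rejections")
  expect_identical(unname(rej["n_windows"]),
                   nrow(cand) + unname(sum(rej[c("tm", "hairpin", "repeat")])))
})

test_that("uniqueness filter enforces the 15C rule with boundary kept", {
  set.seed(53)
  g <- gene_rec(rand_dna(40))
  cand <- enumerate_candidates(g, len_range = c(40L, 40L), tm_window = NULL,
                               hairpin = NULL, repeats = NULL)
  expect_identical(nrow(cand), 1L)
  mutate_at <- function(s, idx) {
    ch <- strsplit(s, "")[[1]]
    ch[idx] <- vapply(ch[idx], function(b) setdiff(c("A","C","G","T"), b)[1], "")
    paste(ch, collapse = "")
  }
  # exact copy in a nontarget -> rejected at delta 0
  nt_exact <- data.frame(seq_id = "nt", sequence = g$sequence,
                         gene_type = "CDS", stringsAsFactors = FALSE)
  r <- uniqueness_filter(cand, nt_exact)
  expect_identical(nrow(r$kept), 0L)
  expect_identical(r$rejected$reason, "uniqueness")
  expect_identical(r$rejected$n_mismatch, 0L)
  expect_identical(r$rejected$delta_tm, 0)
  # closest window at exactly 6 mismatches in a 40-mer: penalty 15.0, kept
  nt6 <- data.frame(seq_id = "nt", sequence = mutate_at(g$sequence, c(2, 9, 16, 23, 30, 37)),
                    gene_type = "CDS", stringsAsFactors = FALSE)
  r6 <- uniqueness_filter(cand, nt6)
  expect_identical(nrow(r6$kept), 1L)
  # 5 mismatches: penalty 12.5 < 15, rejected
  nt5 <- data.frame(seq_id = "nt", sequence = mutate_at(g$sequence, c(2, 9, 16, 23, 30)),
                    gene_type = "CDS", stringsAsFactors = FALSE)
  r5 <- uniqueness_filter(cand, nt5)
  expect_identical(nrow(r5$kept), 0L)
  expect_identical(r5$rejected$n_mismatch, 5L)
  expect_equal(r5$rejected$delta_tm, 12.5)
  # a perfect match on the nontarget's reverse strand also rejects
  nt_rc <- data.frame(seq_id = "nt", sequence = reverse_complement(g$sequence),
                      gene_type = "CDS", stringsAsFactors = FALSE)
  expect_identical(nrow(uniqueness_filter(cand, nt_rc)$kept), 0L)
  expect_identical(nrow(uniqueness_filter(cand, nt_rc, both_strands = FALSE)$kept), 1L)
  # rRNA offender wins the reason code
  rr <- data.frame(seq_id = "rr", sequence = g$sequence, gene_type = "rRNA",
                   stringsAsFactors = FALSE)
  rb <- uniqueness_filter(cand, rbind(nt6, rr))
  expect_identical(rb$rejected$reason, "rrna")
  # empty nontarget set keeps everything with a warning
  expect_warning(r0 <- uniqueness_filter(cand, nt_exact[0, ]), "empty")
  expect_identical(nrow(r0$kept), 1L)
})

test_that("uniqueness partition equals the full-scan oracle on random sets", {
  set.seed(54)
  for (rep in 1:6) {
    g <- gene_rec(rand_dna(90))
    cand <- enumerate_candidates(g, len_range = c(35L, 36L), tm_window = NULL,
                                 hairpin = NULL, repeats = NULL)
    # nontargets: one distant random gene plus one mutated copy of the gene
    ch <- strsplit(g$sequence, "")[[1]]
    k <- sample(3:8, 1)
    idx <- sample(90, k)
    ch[idx] <- vapply(ch[idx], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    nts <- data.frame(seq_id = c("far", "near"),
                      sequence = c(rand_dna(120), paste(ch, collapse = "")),
                      gene_type = "CDS", stringsAsFactors = FALSE)
    r <- uniqueness_filter(cand, nts)
    expected_keep <- vapply(seq_len(nrow(cand)), function(i) {
      mm <- oracle_min_hamming(cand$sequence[i], nts$sequence)
      mismatch_tm_penalty(cand$length[i], min(mm, cand$length[i])) >= 15
    }, TRUE)
    expect_identical(sort(r$kept$probe_id), sort(cand$probe_id[expected_keep]))
  }
})

test_that("per-gene selection is greedy on Tm closeness with non-overlap", {
  cand <- data.frame(
    probe_id = c("a", "b", "c"), gene_id = "g",
    sequence = c(rand_dna(35), rand_dna(35), rand_dna(35)),
    start = c(0L, 10L, 50L), length = 35L,
    tm_perfect = c(74.9, 72.5, 73.4), stringsAsFactors = FALSE)
  # k = 1: the probe closest to the 72.5 midpoint wins
  s1 <- select_probes_per_gene(cand, k = 1L, tm_window = c(70, 75))
  expect_identical(s1$probe_id, "b")
  # k = 3 but a and b overlap: b (closest) then c
  s2 <- select_probes_per_gene(cand, k = 3L, tm_window = c(70, 75))
  expect_identical(sort(s2$probe_id), c("b", "c"))
  # all candidates overlapping one locus -> exactly one selected
  cand$start <- c(0L, 1L, 2L)
  expect_identical(nrow(select_probes_per_gene(cand, k = 5L,
                                               tm_window = c(70, 75))), 1L)
})

test_that("selection equals a best-first oracle on random candidate sets", {
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    cand <- data.frame(
      probe_id = sprintf("p%02d", 1:n), gene_id = "g",
      sequence = vapply(1:n, function(i) rand_dna(35), ""),
      start = sort(sample(0:120, n)), length = 35L,
      tm_perfect = runif(n, 69, 76), stringsAsFactors = FALSE)
    k <- sample(1:4, 1)
    got <- select_probes_per_gene(cand, k = k, tm_window = c(70, 75))
    # oracle: repeatedly take the best-ranked candidate compatible with picks
    ord <- order(abs(cand$tm_perfect - 72.5), cand$start)
    picks <- integer(0)
    for (i in ord) {
      if (length(picks) >= k) break
      ok <- all(vapply(picks, function(j) {
        cand$start[i] >= cand$start[j] + 35L ||
          cand$start[j] >= cand$start[i] + 35L
      }, TRUE))
      if (ok) picks <- c(picks, i)
    }
    expect_identical(sort(got$probe_id), sort(cand$probe_id[picks]))
  }
})

test_that("design pipeline handles paralogs, rRNA decoys and reporting", {
  set.seed(56)
  seqs <- c(rand_dna(120), rand_dna(120))
  targets <- data.frame(
    seq_id = c("gA", "gB", "gB_copy"),
    sequence = c(seqs, seqs[2]),        # gB and gB_copy identical paralogs
    gene_type = "CDS", stringsAsFactors = FALSE)
  rrna <- simulate_rrna(2, 150, seed = 3)
  des <- design_probe_set(targets, rrna, len_range = c(35L, 35L),
                          tm_window = NULL)
  # identical paralogs reject each other's probes entirely
  expect_false(any(des$probes$gene_id %in% c("gB", "gB_copy")))
  expect_identical(nrow(des$probes[des$probes$gene_id == "gA", ]), 1L)
  # report reconciles per gene: candidates = unique + rejected
  rep <- des$report
  expect_identical(rep$n_candidates,
                   rep$n_unique + rep$rej_uniqueness + rep$rej_rrna)
  expect_true(all(rep$n_windows >=
                    rep$n_candidates + rep$rej_tm + rep$rej_hairpin +
                    rep$rej_repeat))
  expect_true(all(rep$n_selected <= rep$n_unique))
  # no probe originates from an rRNA record
  expect_error(design_probe_set(rbind(targets, rrna[, names(targets)[1:3]][0, ]),
                                rrna = NULL), NA)
  expect_true(all(des$probes$gene_id %in% targets$seq_id))
  # single gene with no nontargets yields one probe at k = 1
  one <- design_probe_set(targets[1, ], len_range = c(35L, 35L),
                          tm_window = NULL)
  expect_identical(nrow(one$probes), 1L)
})

test_that("designing on a gene subset reproduces the full run per gene", {
  set.seed(57)
  comm <- simulate_community(community_spec(
    n_phyla = 2L, families_per_phylum = 1L, genera_per_family = 2L,
    genes_per_genus = 1L,
    homolog_identity_levels = c(genus = 0.95, family = 0.78, phylum = 0.70),
    gene_length_range = c(150L, 180L), rrna_count = 2L, seed = 8L))
  full <- design_probe_set(comm, len_range = c(35L, 35L), tm_window = NULL)
  # rerun gene 1 against the same fixed nontarget database
  cand1 <- enumerate_candidates(comm[1, ], len_range = c(35L, 35L),
                                tm_window = NULL)
  u1 <- uniqueness_filter(cand1, comm[, c("seq_id", "sequence", "gene_type")])
  expect_identical(sort(u1$kept$probe_id),
                   sort(full$candidates$probe_id[
                     full$candidates$gene_id == comm$seq_id[1]]))
})

test_that("3-fold background prescreen keeps at-least-3x probes", {
  m <- rbind(p1 = c(300, 80), p2 = c(299.99, 80), p3 = c(80, 90))
  colnames(m) <- c("s1", "s2")
  attr(m, "state") <- "normalized"
  bg <- list(bg_mean = 100, bg_sd = 0)
  expect_identical(prescreen_expressed(m, fold = 3, bg = bg), "p1")
  # all-background matrix keeps nothing
  m2 <- matrix(100, 3, 2, dimnames = list(paste0("p", 1:3), c("a", "b")))
  attr(m2, "state") <- "normalized"
  expect_identical(prescreen_expressed(m2, fold = 3,
                                       bg = list(bg_mean = 100, bg_sd = 0)),
                   character(0))
})
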