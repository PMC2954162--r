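# Independent brute-force oracles and fixture builders. Oracles use naive
# enumeration so they stay structurally independent of the package's
# implementations.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

str_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# nested-loop minimum Hamming distance of probe over all same-length
# windows of the subjects (both strands)
oracle_min_hamming <- function(probe, subjects, both_strands = TRUE) {
  w <- nchar(probe)
  best <- Inf
  seqs <- subjects
  if (both_strands) seqs <- c(seqs, vapply(subjects, revcomp_chr, ""))
  for (s in seqs) {
    if (nchar(s) < w) next
    for (i in seq_len(nchar(s) - w + 1L)) {
      best <- min(best, str_hamming(probe, substr(s, i, i + w - 1L)))
    }
  }
  best
}

oracle_quantile_normalize <- function(m) {
  srt <- apply(m, 2, sort)
  ref <- rowMeans(srt)
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    out[, j] <- (ref[floor(r)] + ref[ceiling(r)]) / 2
  }
  out
}

oracle_background <- function(m, fraction = 0.05) {
  pool <- sort(as.vector(m))
  sub <- pool[seq_len(floor(fraction * length(pool)))]
  list(bg_mean = mean(sub), bg_sd = sd(sub))
}

oracle_call_expressed <- function(m, thr, min_samples = 2L) {
  apply(m, 1L, function(x) sum(x > thr) >= min_samples)
}

oracle_select_differential <- function(r, fold = 2, min_samples = 2L) {
  apply(r, 1L, function(x) sum(abs(x) >= log2(fold)) >= min_samples)
}

# naive O(n^3) agglomerative complete linkage with the same declared tie
# rule (pair containing the smallest original leaf, then smallest partner),
# returning the merge heights and the leaf partition at each step
oracle_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        key <- c(h, min(unlist(clusters[c(i, j)])),
                 max(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || h < best$key[1] ||
            (h == best$key[1] && (key[2] < best$key[2] ||
             (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    heights <- c(heights, best$key[1])
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1L]] <- merged
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# exhaustive ungapped local search: per subject, strand and diagonal,
# enumerate every segment, keep the best by (score, then smallest start,
# then smallest end); report if score >= min_score
oracle_local_search <- function(probe, db_seqs, params) {
  out <- list()
  pl <- strsplit(probe, "")[[1]]
  w <- length(pl)
  for (si in seq_along(db_seqs)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") db_seqs[si] else revcomp_chr(db_seqs[si])
      sl <- strsplit(s, "")[[1]]
      Ls <- length(sl)
      for (d in (-(w - 1L)):(Ls - 1L)) {
        i0 <- max(1L, 1L - d)
        len <- min(w - i0, Ls - (i0 + d)) + 1L
        if (len < 1L) next
        eq <- pl[i0:(i0 + len - 1L)] == sl[(i0 + d):(i0 + d + len - 1L)]
        sc <- ifelse(eq, params$match, params$mismatch)
        P <- c(0, cumsum(sc))
        best <- NULL
        for (a in seq_len(len)) {
          for (b in a:len) {
            v <- P[b + 1L] - P[a]
            if (is.null(best) || v > best$v) best <- list(v = v, a = a, b = b)
          }
        }
        if (best$v >= params$min_score) {
          js <- i0 + d + best$a - 1L; je <- i0 + d + best$b - 1L
          nm <- sum(eq[best$a:best$b])
          out[[length(out) + 1L]] <- data.frame(
            subject = si, strand = strand,
            start = if (strand == "+") js - 1L else Ls - je,
            end = if (strand == "+") je else Ls - js + 1L,
            score = best$v, n_matches = nm,
            align_len = best$b - best$a + 1L)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# small seasonal metadata block: `per_season` samples, first two baselines
make_meta <- function(seasons = c("April", "June"), per_season = 6L) {
  do.call(rbind, lapply(seasons, function(s) {
    data.frame(
      sample_id = sprintf("%s_%02d", substr(s, 1, 3), seq_len(per_season)),
      season = s,
      habitat = c("river", "river",
                  rep(c("estuary", "plume", "ocean"),
                      length.out = per_season - 2L)),
      salinity_psu = c(0, 0, rep(20, per_season - 2L)),
      depth_class = "surface", location_code = "X",
      is_baseline = c(TRUE, TRUE, rep(FALSE, per_season - 2L)),
      stringsAsFactors = FALSE)
  }))
}
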