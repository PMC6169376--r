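# Shared small-scale fixtures, built once per test run.

.fix <- new.env()

# 300 kb ancestor, 5 lines, modest SV load: enough events of every class to
# exercise calling without slowing the suite down
small_study <- function() {
  if (is.null(.fix$small)) {
    anc <- simulate_ancestor(
      3e5, n_chroms = 1,
      repeat_config = default_repeat_config(tandem_array_count = 25L,
                                            dispersed_repeat_count = 4L),
      seed = 42)
    pl <- plant_svs(anc, default_line_tree(), rate_per_branch = 3,
                    seed = 43, min_spacing = 5000,
                    inv_size_range = c(10000, 20000), end_margin = 20000)
    .fix$small <- list(anc = anc, genomes = pl$genomes, truth = pl$truth)
  }
  .fix$small
}

# a deterministic two-block plus-strand chain for gap-calling tests
toy_chain <- function(ref_gap, query_gap, strand = "+") {
  b1 <- data.frame(ref_chrom = "chr1", ref_start = 0, ref_end = 1000,
                   query_chrom = "chr1", query_start = 0, query_end = 1000,
                   strand = strand, block_len = 1000, chain_id = 1L,
                   stringsAsFactors = FALSE)
  if (strand == "+") {
    b2 <- data.frame(ref_chrom = "chr1", ref_start = 1000 + ref_gap,
                     ref_end = 2000 + ref_gap, query_chrom = "chr1",
                     query_start = 1000 + query_gap,
                     query_end = 2000 + query_gap, strand = strand,
                     block_len = 1000, chain_id = 1L, stringsAsFactors = FALSE)
  } else {
    # on '-' the query runs backwards along the reference
    b1$query_start <- 2000; b1$query_end <- 3000
    b2 <- data.frame(ref_chrom = "chr1", ref_start = 1000 + ref_gap,
                     ref_end = 2000 + ref_gap, query_chrom = "chr1",
                     query_start = 1000 - query_gap,
                     query_end = 2000 - query_gap, strand = strand,
                     block_len = 1000, chain_id = 1L, stringsAsFactors = FALSE)
  }
  rbind(b1, b2)
}

# random SV record table across lines with clustered breakpoints
random_sv_records <- function(n, lines = paste0("L", 1:5), n_loci = 40,
                              tol_spread = 6, seed = 1) {
  set.seed(seed)
  loci_start <- sort(sample.int(1e6, n_loci))
  loci_type <- sample(c("insertion", "deletion"), n_loci, replace = TRUE)
  pick <- sample.int(n_loci, n, replace = TRUE)
  st <- loci_start[pick] + sample.int(tol_spread, n, replace = TRUE) - 1
  data.frame(line_id = sample(lines, n, replace = TRUE), chrom = "chr1",
             start = st, end = st + ifelse(loci_type[pick] == "deletion",
                                           100, 0),
             size_bp = 100, sv_type = loci_type[pick], method = "sequence",
             validated = FALSE, stringsAsFactors = FALSE)
}

# independent plain-R dynamic program over all label pairings (the oracle
# for align_map on small maps); returns the optimal score
brute_force_map_score <- function(query, reference, miss_penalty = 3,
                                  false_penalty = 3, sizing_weight = 150,
                                  sizing_cap = 12, cap_from = 800,
                                  match_bonus = 6, band = 5) {
  r <- reference$labels; q <- query$labels
  n <- length(r); m <- length(q)
  f <- matrix(-Inf, n, m) # best score of a matching ending with pair (i, j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best_prev <- 0
      for (pi in seq_len(i - 1)) {
        for (pj in seq_len(j - 1)) {
          if (i - pi - 1 > band || j - pj - 1 > band) next
          dr <- r[i] - r[pi]; dq <- q[j] - q[pj]
          ad <- abs(dq - dr)
          szc <- sizing_weight * ad / max(dr, 1000)
          step <- if (ad >= cap_from) min(szc, sizing_cap) else
            szc + miss_penalty * (i - pi - 1) + false_penalty * (j - pj - 1)
          cand <- f[pi, pj] - step
          if (cand > best_prev) best_prev <- cand
        }
      }
      f[i, j] <- best_prev + match_bonus
    }
  }
  max(f, 0)
}

# score an explicit matching under the align_map objective
score_map_matching <- function(pairs, query, reference, miss_penalty = 3,
                               false_penalty = 3, sizing_weight = 150,
                               sizing_cap = 12, cap_from = 800,
                               match_bonus = 6) {
  r <- reference$labels; q <- query$labels
  s <- match_bonus * nrow(pairs)
  if (nrow(pairs) > 1) {
    for (t in 2:nrow(pairs)) {
      dr <- r[pairs[t, 1]] - r[pairs[t - 1, 1]]
      dq <- q[pairs[t, 2]] - q[pairs[t - 1, 2]]
      ad <- abs(dq - dr)
      szc <- sizing_weight * ad / max(dr, 1000)
      step <- if (ad >= cap_from) min(szc, sizing_cap) else
        szc + miss_penalty * (pairs[t, 1] - pairs[t - 1, 1] - 1) +
        false_penalty * (pairs[t, 2] - pairs[t - 1, 2] - 1)
      s <- s - step
    }
  }
  s
}
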