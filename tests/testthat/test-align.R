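test_that("anchoring recovers identity, insertions, and reverse complements", {
  set.seed(101)
  seqs <- c(chr1 = rand_seq(20000), chr2 = rand_seq(15000))
  ref <- genome("ref", seqs)

  a <- find_unique_anchors(ref, genome("same", seqs))
  expect_equal(nrow(a), 2)
  expect_equal(a$ref_start, c(0, 0))
  expect_equal(a$ref_end, unname(nchar(seqs)[match(a$ref_chrom,
                                                   names(seqs))]))
  expect_true(all(a$strand == "+"))

  ins <- rand_seq(200)
  q <- genome("ins", c(chr1 = paste0(substr(seqs[1], 1, 12000), ins,
                                     substr(seqs[1], 12001, 20000)),
                       chr2 = seqs[2]))
  a <- find_unique_anchors(ref, q)
  a1 <- a[a$ref_chrom == "chr1", ]
  expect_equal(nrow(a1), 2)
  # two anchors abutting the insertion point on the reference, 200 bp apart
  # on the query (up to chance micro-homology at the junction)
  expect_lte(abs(a1$ref_end[1] - 12000), 2)
  expect_lte(abs(a1$ref_start[2] - 12000), 2)
  gap_q <- a1$query_start[2] - a1$query_end[1]
  gap_r <- a1$ref_start[2] - a1$ref_end[1]
  expect_equal(gap_q - gap_r, 200)

  rc <- genome("rc", c(chr1 = revcomp_chr(seqs[["chr1"]])))
  a <- find_unique_anchors(genome("r1", seqs["chr1"]), rc)
  expect_equal(nrow(a), 1)
  expect_equal(a$strand, "-")
  expect_equal(a$ref_end - a$ref_start, 20000)
})

test_that("anchors never contain a mismatch", {
  st <- small_study()
  q <- st$genomes$L1
  a <- find_unique_anchors(st$anc$genome, q)
  pick <- a[sample.int(nrow(a), min(nrow(a), 20)), ]
  for (i in seq_len(nrow(pick))) {
    b <- pick[i, ]
    rseq <- substr(st$anc$genome$seqs[[b$ref_chrom]], b$ref_start + 1,
                   b$ref_end)
    qseq <- substr(q$seqs[[b$query_chrom]], b$query_start + 1, b$query_end)
    if (b$strand == "-") qseq <- revcomp_chr(qseq)
    expect_identical(rseq, qseq)
  }
})

test_that("chaining joins co-linear anchors within max_gap and not beyond", {
  a <- data.frame(
    ref_chrom = "chr1", ref_start = c(0, 2000), ref_end = c(1000, 3000),
    query_chrom = "chr1", query_start = c(0, 2000), query_end = c(1000, 3000),
    strand = "+", block_len = 1000, stringsAsFactors = FALSE)
  expect_equal(length(unique(chain_anchors(a, max_gap = 10000)$chain_id)), 1)
  expect_equal(length(unique(chain_anchors(a, max_gap = 500)$chain_id)), 2)
})

test_that("chaining is invariant to anchor input order", {
  st <- small_study()
  a <- find_unique_anchors(st$anc$genome, st$genomes$L2)
  c1 <- chain_anchors(a)
  set.seed(9)
  c2 <- chain_anchors(a[sample.int(nrow(a)), ])
  key <- function(x) paste(x$ref_chrom, x$ref_start, x$chain_id)
  expect_identical(sort(key(c1)), sort(key(c2)))
})

test_that("greedy chains match a dynamic-programming chaining oracle", {
  # peel-longest-chain DP under the same compatibility rules
  compatible <- function(t, a, max_gap) {
    if (t$strand != a$strand || t$query_chrom != a$query_chrom ||
        t$ref_chrom != a$ref_chrom) return(FALSE)
    rgap <- a$ref_start - t$ref_end
    if (rgap > max_gap) return(FALSE)
    if (a$strand == "+") {
      qgap <- a$query_start - t$query_end
      mono <- a$query_start > t$query_start
      qov <- t$query_end - a$query_start
    } else {
      qgap <- t$query_start - a$query_end
      mono <- a$query_end < t$query_end
      qov <- a$query_end - t$query_start
    }
    if (qgap > max_gap || !mono) return(FALSE)
    max(-rgap, qov, 0) <= a$block_len / 2
  }
  oracle_chains <- function(anchors, max_gap) {
    a <- anchors[order(anchors$ref_chrom, anchors$ref_start,
                       anchors$query_start), ]
    n <- nrow(a)
    unassigned <- rep(TRUE, n)
    cid <- integer(n)
    cur <- 0L
    while (any(unassigned)) {
      idx <- which(unassigned)
      len <- rep(1L, length(idx)); pre <- rep(0L, length(idx))
      for (x in seq_along(idx)) for (y in seq_len(x - 1)) {
        if (compatible(a[idx[y], ], a[idx[x], ], max_gap) &&
            len[y] + 1 > len[x]) { len[x] <- len[y] + 1L; pre[x] <- y }
      }
      best <- which.max(len)
      chain <- best
      while (pre[chain[1]] > 0) chain <- c(pre[chain[1]], chain)
      cur <- cur + 1L
      cid[idx[chain]] <- cur
      unassigned[idx[chain]] <- FALSE
    }
    split(paste(a$ref_chrom, a$ref_start), cid)
  }
  st <- small_study()
  for (line in c("L1", "L3")) {
    a <- find_unique_anchors(st$anc$genome, st$genomes[[line]])
    a <- a[seq_len(min(nrow(a), 20)), ]
    got <- chain_anchors(a, max_gap = 50000)
    got_sets <- split(paste(got$ref_chrom, got$ref_start), got$chain_id)
    want_sets <- oracle_chains(a, max_gap = 50000)
    norm <- function(s) sort(vapply(s, function(x) paste(sort(x),
                                                         collapse = "|"), ""))
    expect_identical(norm(got_sets), norm(want_sets))
  }
})

test_that("match filters keep 500+ singletons and 100+ cluster members", {
  mk <- function(len, chain) data.frame(
    ref_chrom = "chr1", ref_start = 0, ref_end = len, query_chrom = "chr1",
    query_start = 0, query_end = len, strand = "+", block_len = len,
    chain_id = chain, stringsAsFactors = FALSE)
  expect_equal(nrow(filter_alignments(mk(499, 1))), 0)
  expect_equal(nrow(filter_alignments(mk(500, 1))), 1)
  two <- rbind(mk(150, 1), mk(150, 1))
  expect_equal(nrow(filter_alignments(two)), 2)
  expect_equal(nrow(filter_alignments(mk(150, 1))), 0)
  expect_equal(nrow(filter_alignments(mk(99, 1))), 0)
})

test_that("filtered chains tile an SV-free genome pair almost completely", {
  set.seed(77)
  seqs <- c(chr1 = rand_seq(3e5))
  ref <- genome("ref", seqs)
  blocks <- filter_alignments(chain_anchors(
    find_unique_anchors(ref, genome("twin", seqs))))
  covered <- sum(blocks$ref_end - blocks$ref_start)
  expect_gte(covered / 3e5, 0.999)
})

test_that("PAF records round-trip and survive hand-written input", {
  tmp <- tempfile(fileext = ".paf")
  writeLines(c(
    "q1\t5000\t100\t900\t+\tchr1\t9000\t200\t1000\t800\t800\t60\tcg:Z:800=",
    "q1\t5000\t1000\t2000\t-\tchr2\t9000\t3000\t4000\t1000\t1000\t60"),
    tmp)
  b <- read_paf(tmp)
  expect_equal(nrow(b), 2)
  expect_equal(b$ref_start, c(200, 3000))
  expect_equal(b$query_start, c(100, 1000)) # minus strand: forward coords
  expect_equal(b$strand, c("+", "-"))
  expect_equal(b$cigar, c("800=", NA))

  out <- tempfile(fileext = ".paf")
  write_paf(b, out, query_lengths = c(q1 = 5000),
            ref_lengths = c(chr1 = 9000, chr2 = 9000))
  b2 <- read_paf(out)
  expect_equal(b2[c("ref_chrom", "ref_start", "ref_end", "query_chrom",
                    "query_start", "query_end", "strand", "cigar")],
               b[c("ref_chrom", "ref_start", "ref_end", "query_chrom",
                   "query_start", "query_end", "strand", "cigar")])

  bad <- tempfile()
  writeLines("q1\t100\t0\t50", bad)
  expect_error(read_paf(bad), "line 1")
})
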