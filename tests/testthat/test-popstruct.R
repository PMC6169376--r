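mk_sv <- function(line, start, end = start, type = "deletion",
                  chrom = "chr1") {
  data.frame(line_id = line, chrom = chrom, start = start, end = end,
             size_bp = max(end - start, 100), sv_type = type,
             method = "sequence", validated = FALSE, stringsAsFactors = FALSE)
}

test_that("coincidence matching applies the 3 bp tolerance exactly", {
  lines <- paste0("L", 1:5)
  same <- do.call(rbind, lapply(lines, mk_sv, start = 100, end = 600))
  pm <- match_svs(same)
  expect_equal(nrow(pm$mat), 1)
  expect_true(all(pm$mat == 1))

  # starts differ by 3 -> one locus; by 4 -> two loci
  d3 <- rbind(mk_sv("L1", 100, 600), mk_sv("L2", 103, 600))
  expect_equal(nrow(match_svs(d3)$mat), 1)
  d4 <- rbind(mk_sv("L1", 100, 600), mk_sv("L2", 104, 600))
  expect_equal(nrow(match_svs(d4)$mat), 2)
  # ends must agree too
  e4 <- rbind(mk_sv("L1", 100, 600), mk_sv("L2", 100, 605))
  expect_equal(nrow(match_svs(e4)$mat), 2)
  # class identity is part of coincidence
  t2 <- rbind(mk_sv("L1", 100, 600, "deletion"),
              mk_sv("L2", 100, 600, "tandem_contraction"))
  expect_equal(nrow(match_svs(t2)$mat), 2)

  # single linkage: A-B (3) and B-C (3) chain into ONE locus despite A-C = 6
  chain <- rbind(mk_sv("L1", 100, 600), mk_sv("L2", 103, 600),
                 mk_sv("L3", 106, 600))
  pm <- match_svs(chain)
  expect_equal(nrow(pm$mat), 1)
  expect_equal(pm$loci$start, 100)
  expect_equal(pm$loci$end, 600)
})

test_that("tolerance matching equals an exhaustive pairwise oracle", {
  svs <- random_sv_records(1000, seed = 7)
  pm <- match_svs(svs, tol = 3)
  # oracle: O(n^2) pairwise coincidence + union-find
  n <- nrow(svs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (svs$chrom[i] == svs$chrom[j] && svs$sv_type[i] == svs$sv_type[j] &&
        abs(svs$start[i] - svs$start[j]) <= 3 &&
        abs(svs$end[i] - svs$end[j]) <= 3) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  want <- length(unique(comp))
  expect_equal(nrow(pm$mat), want)
  # per-component membership identical
  want_rows <- sort(unname(vapply(split(seq_len(n), comp), function(ix)
    paste(sort(unique(svs$line_id[ix])), collapse = ","), "")))
  got_rows <- sort(apply(pm$mat, 1, function(r)
    paste(pm$lines[r == 1], collapse = ",")))
  expect_equal(got_rows, want_rows)
})

test_that("matching with tol 0 keeps distinct records distinct", {
  svs <- random_sv_records(300, seed = 9)
  pm <- match_svs(svs, tol = 0)
  want <- nrow(unique(svs[c("chrom", "start", "end", "sv_type")]))
  expect_equal(nrow(pm$mat), want)
})

test_that("the presence matrix ignores input order", {
  svs <- random_sv_records(400, seed = 11)
  pm1 <- match_svs(svs)
  set.seed(2)
  pm2 <- match_svs(svs[sample.int(nrow(svs)), ])
  ord <- function(pm) order(pm$loci$chrom, pm$loci$start, pm$loci$sv_type)
  expect_equal(pm1$mat[ord(pm1), ], pm2$mat[ord(pm2), ])
})

test_that("sharing statistics match hand and brute-force computation", {
  pm <- structure(list(
    loci = data.frame(chrom = "chr1", start = 1:3, end = 2:4,
                      sv_type = "deletion"),
    lines = c("A", "B"),
    mat = matrix(c(1, 1, 1, 0, 0, 1), nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, c("A", "B"))),
    provenance = list(1, 2, 3)), class = "presence_matrix")
  s <- sharing_stats(pm)
  expect_equal(s$pairwise_percent["A", "B"], 50)
  expect_equal(s$pairwise_percent["B", "A"], 50)
  expect_equal(s$shared_in_all, 1)

  all1 <- pm
  all1$mat <- matrix(1L, 4, 2, dimnames = list(NULL, c("A", "B")))
  expect_true(all(sharing_stats(all1)$pairwise_percent == 100))

  set.seed(13)
  m <- matrix(rbinom(2500, 1, 0.4), 500, 5,
              dimnames = list(NULL, paste0("L", 1:5)))
  pm$mat <- m; pm$lines <- colnames(m)
  s <- sharing_stats(pm)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(s$pairwise_percent[i, j],
                 100 * sum(m[, i] & m[, j]) / sum(m[, i]))
  }
  expect_equal(s$shared_in_all, sum(rowSums(m) == 5))
})

test_that("Jaccard distance has the documented extremes and properties", {
  pm <- list(mat = cbind(A = c(1, 1, 0), B = c(1, 1, 0), C = c(0, 0, 1)),
             lines = c("A", "B", "C"))
  class(pm) <- "presence_matrix"
  d <- as.matrix(sv_distance(pm))
  expect_equal(d["A", "B"], 0) # identical columns
  expect_equal(d["A", "C"], 1) # disjoint columns
  expect_equal(diag(d), setNames(c(0, 0, 0), c("A", "B", "C")))

  set.seed(17)
  for (rep in 1:20) {
    m <- matrix(rbinom(120, 1, 0.5), 40, 3, dimnames = list(NULL, c("x", "y", "z")))
    dm <- as.matrix(sv_distance(structure(list(mat = m,
                                               lines = colnames(m)),
                                          class = "presence_matrix")))
    for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3))) {
      expect_lte(dm[p[1], p[3]], dm[p[1], p[2]] + dm[p[2], p[3]] + 1e-12)
    }
  }
})

test_that("UPGMA clustering recovers simple and exhaustive cases", {
  d <- as.dist(matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  tr <- cluster_lines(d)
  expect_true(list(c("A", "B")) %in% tr$clades ||
                any(vapply(tr$clades, identical, TRUE, y = c("A", "B"))))

  # ultrametric input reproduced exactly
  hts <- tr$hclust$height
  expect_equal(hts, c(0.1, 0.9))

  # 4-leaf check against exhaustive topology scoring: the UPGMA tree must
  # join the closest pair first
  set.seed(19)
  for (rep in 1:10) {
    m <- matrix(runif(16, 0.2, 1), 4)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:4], letters[1:4])
    tr <- cluster_lines(as.dist(m))
    pair <- which(m == min(m[upper.tri(m)]), arr.ind = TRUE)[1, ]
    first <- sort(rownames(m)[pair])
    expect_true(any(vapply(tr$clades, identical, TRUE, y = first)))
  }
})

test_that("bootstrap gives certainty for unbreakable clades and AU closed forms", {
  # two identical column groups: no resample can break them
  set.seed(23)
  m <- cbind(a = rbinom(60, 1, 0.5), b = 0, c = rbinom(60, 1, 0.5), d = 0)
  m[, "b"] <- m[, "a"]; m[, "d"] <- m[, "c"]
  pm <- structure(list(mat = m, lines = colnames(m),
                       loci = data.frame(chrom = "chr1", start = 1:60,
                                         end = 2:61, sv_type = "deletion")),
                  class = "presence_matrix")
  tr <- bootstrap_support(pm, B = 200, scales = c(0.6, 1.0, 1.4), seed = 1)
  ab <- which(vapply(tr$clades, identical, TRUE, y = c("a", "b")))
  cd <- which(vapply(tr$clades, identical, TRUE, y = c("c", "d")))
  expect_equal(tr$support$bp[c(ab, cd)], c(100, 100))
  expect_equal(tr$support$au[c(ab, cd)], c(100, 100))

  # BP_r = 0.5 at every scale -> v = c = 0 -> AU = 50
  expect_equal(au_from_multiscale(rep(0.5, 5),
                                  c(0.6, 0.8, 1.0, 1.2, 1.4)), 50)
  expect_equal(au_from_multiscale(c(0, 0, 1, 1, 1), c(0.6, 0.8, 1, 1.2, 1.4)),
               100)
  expect_error(bootstrap_support(pm, B = 50), "at least 100")
  expect_error(bootstrap_support(pm, B = 200, scales = c(0.5, 0.8)), "1.0")
})

test_that("the rate estimate is the documented arithmetic", {
  expect_equal(estimate_rate(100, 1, 1)$rate, 50)
  expect_equal(estimate_rate(100, 0.5, 1)$rate, 100)
  set.seed(29)
  for (rep in 1:20) {
    n <- sample(10:5000, 1); t <- runif(1, 0.1, 10); g <- runif(1, 1, 200)
    expect_equal(estimate_rate(2 * n, t, g)$rate,
                 2 * estimate_rate(n, t, g)$rate)
  }
  expect_error(estimate_rate(0, 1, 1))
})

test_that("presence matrix and support tree serialize", {
  svs <- random_sv_records(60, seed = 31)
  pm <- match_svs(svs)
  tmp <- tempfile(fileext = ".tsv")
  write_presence_matrix(pm, tmp)
  tab <- read.table(tmp, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), nrow(pm$mat))
  expect_true(all(paste0("L", 1:5) %in% colnames(tab)))

  tr <- bootstrap_support(pm, B = 100, scales = c(1.0), seed = 2)
  nwk <- write_tree_newick(tr)
  expect_match(nwk, "^\\(")
  expect_match(nwk, ";$")
  expect_match(nwk, "\\[[0-9.]+/[0-9.]+\\]")
  # the topology part parses as a tree once comments are stripped
  parsed <- ape::read.tree(text = gsub("\\[[^]]*\\]", "", nwk))
  expect_setequal(parsed$tip.label, paste0("L", 1:5))
})
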