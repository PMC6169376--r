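test_that("in-silico digestion finds motif sites on both strands", {
  g <- genome("g", c(chr1 = "AAAAAAAAAAAAAAAAAAAAAAAAAAAAAA"))
  expect_length(digest_genome(g, "CACGAG")$chr1$labels, 0)

  set.seed(21)
  base <- strsplit(rand_seq(5000), "")[[1]]
  base[base == "C"] <- "A" # remove chance CACGAG / CTCGTG occurrences
  s <- paste(base, collapse = "")
  plant_at <- c(500, 2000, 2006, 4400) # third site on the minus strand
  motif <- "CACGAG"
  s <- paste0(substr(s, 1, 500), motif, substr(s, 507, 2000), motif,
              revcomp_chr(motif), substr(s, 2013, 4400), motif,
              substr(s, 4407, 5000))
  got <- digest_genome(genome("g", c(chr1 = s)), motif)$chr1$labels
  expect_equal(got, plant_at)

  # both-strand counting against a naive scan oracle
  set.seed(22)
  rs <- rand_seq(200000)
  got <- digest_genome(genome("g", c(chr1 = rs)), motif)$chr1$labels
  naive <- sort(unique(c(
    gregexpr(motif, rs, fixed = TRUE)[[1]],
    gregexpr(revcomp_chr(motif), rs, fixed = TRUE)[[1]]))) - 1
  naive <- naive[naive >= 0]
  expect_equal(got, naive)
})

test_that("map alignment is exact on identical maps and handles skips", {
  ref <- list(map_id = "chr1", length_bp = 20000,
              labels = c(1000, 3000, 5500, 8000, 11000, 14000, 17000))
  al <- align_map(ref, ref)
  expect_equal(al$pairs[, 1], seq_along(ref$labels))
  expect_equal(al$pairs[, 2], seq_along(ref$labels))

  miss1 <- list(map_id = "chr1", length_bp = 20000,
                labels = ref$labels[-4])
  al <- align_map(miss1, ref)
  expect_equal(al$pairs[, 1], c(1, 2, 3, 5, 6, 7)) # ref label 4 skipped
  expect_equal(al$pairs[, 2], 1:6)

  false1 <- list(map_id = "chr1", length_bp = 20000,
                 labels = sort(c(ref$labels, 9200)))
  al <- align_map(false1, ref)
  expect_equal(al$pairs[, 1], 1:7)
  expect_equal(al$pairs[, 2], c(1, 2, 3, 4, 6, 7, 8)) # false label skipped

  expect_error(align_map(list(labels = 1), ref), "at least 2")
})

test_that("map alignment equals the exhaustive DP optimum on small maps", {
  set.seed(33)
  for (case in 1:12) {
    n <- sample(4:12, 1)
    ref <- list(map_id = "c", length_bp = 40000,
                labels = sort(sample.int(30000, n)))
    # mutate: drop, add, jitter
    lab <- ref$labels
    if (n > 4) lab <- lab[-sample.int(n, 1)]
    lab <- sort(c(lab, sample.int(30000, 1)))
    lab <- pmax(0, lab + sample(-30:30, length(lab), replace = TRUE))
    lab <- sort(unique(lab))
    q <- list(map_id = "c", length_bp = 40000, labels = lab)
    got <- align_map(q, ref)
    want <- brute_force_map_score(q, ref)
    expect_equal(got$score, want, tolerance = 1e-9)
    # the returned pairs really achieve the reported score
    expect_equal(unname(score_map_matching(got$pairs, q, ref)), got$score,
                 tolerance = 1e-9)
  }
})

test_that("optical SV detection honors the 1 kb floor and exact sizes", {
  set.seed(44)
  base <- rand_seq(200000)
  ref <- genome("ref", c(chr1 = base))
  del <- genome("del", c(chr1 = paste0(substr(base, 1, 100000),
                                       substr(base, 105001, 200000))))
  rm <- digest_genome(ref)$chr1
  qm <- simulate_label_map(del, miss_prob = 0, false_per_100kb = 0,
                           sizing_cv = 0, seed = 1)$chr1
  svs <- detect_map_svs(align_map(qm, rm), qm, rm, "del")
  expect_equal(nrow(svs), 1)
  expect_equal(svs$sv_type, "deletion")
  expect_equal(svs$size_bp, 5000)
  expect_equal(svs$method, "optical")
  expect_true(svs$start <= 100000 && svs$end >= 105000)

  # an SV-free noiseless map yields nothing
  same <- simulate_label_map(ref, miss_prob = 0, false_per_100kb = 0,
                             sizing_cv = 0, seed = 1)$chr1
  expect_equal(nrow(detect_map_svs(align_map(same, rm), same, rm, "x")), 0)

  # d = 999 with the 1 kb floor: no call; d = 1000 is reported
  rl <- seq(1000, by = 2000, length.out = 12)
  ref999 <- list(map_id = "c", length_bp = 50000, labels = rl)
  q999 <- list(map_id = "c", length_bp = 50000,
               labels = rl + c(rep(0, 6), rep(999, 6)))
  al <- align_map(q999, ref999)
  expect_equal(nrow(detect_map_svs(al, q999, ref999, "x")), 0)
  q1000 <- list(map_id = "c", length_bp = 50000,
                labels = rl + c(rep(0, 6), rep(1000, 6)))
  al <- align_map(q1000, ref999)
  got <- detect_map_svs(al, q1000, ref999, "x")
  expect_equal(got$size_bp, 1000)
  expect_equal(got$sv_type, "insertion")
})

test_that("cross-validation pads by one label interval and guards sign", {
  ref_maps <- list(chr1 = list(map_id = "chr1", length_bp = 100000,
                               labels = c(10000, 20000, 30000, 40000)))
  seq_sv <- function(type, start, end) data.frame(
    line_id = "L1", chrom = "chr1", start = start, end = end,
    size_bp = max(end - start, 120), sv_type = type, method = "sequence",
    validated = FALSE, stringsAsFactors = FALSE)
  opt_sv <- function(type, start, end) data.frame(
    line_id = "L1", chrom = "chr1", start = start, end = end,
    size_bp = 2000, sv_type = type, method = "optical", validated = FALSE,
    stringsAsFactors = FALSE)

  # sequence deletion inside the optical deletion's label interval
  got <- cross_validate(seq_sv("deletion", 22000, 24000),
                        opt_sv("deletion", 20000, 30000), ref_maps)
  expect_equal(nrow(got), 1)
  expect_true(got$validated)

  # opposite signs never validate
  got <- cross_validate(seq_sv("insertion", 22000, 22000),
                        opt_sv("deletion", 20000, 30000), ref_maps)
  expect_equal(nrow(got), 0)

  # the padding reaches the flanking labels: an optical call just beyond the
  # sequence interval but inside the flanking label interval validates
  got <- cross_validate(seq_sv("deletion", 22000, 24000),
                        opt_sv("deletion", 30000, 40000), ref_maps)
  expect_equal(nrow(got), 0) # [30000,40000) does not overlap (20000,30000)
  got <- cross_validate(seq_sv("deletion", 22000, 24000),
                        opt_sv("deletion", 25000, 40000), ref_maps)
  expect_equal(nrow(got), 1)
})

test_that("cross-validation matches an exhaustive overlap oracle", {
  set.seed(55)
  ref_maps <- list(chr1 = list(map_id = "chr1", length_bp = 1e6,
                               labels = sort(sample.int(1e6, 400))))
  gain <- c("insertion", "tandem_expansion", "repeat_expansion")
  st <- sort(sample.int(9e5, 120))
  seq_svs <- data.frame(
    line_id = "L1", chrom = "chr1", start = st,
    end = st + sample(0:3000, 120, replace = TRUE),
    size_bp = sample(50:5000, 120, replace = TRUE),
    sv_type = sample(sv_classes(), 120, replace = TRUE),
    method = "sequence", validated = FALSE, stringsAsFactors = FALSE)
  ost <- sort(sample.int(9e5, 40))
  map_svs <- data.frame(
    line_id = "L1", chrom = "chr1", start = ost, end = ost + 8000,
    size_bp = 2000, sv_type = sample(c("insertion", "deletion"), 40,
                                     replace = TRUE),
    method = "optical", validated = FALSE, stringsAsFactors = FALSE)
  got <- cross_validate(seq_svs, map_svs, ref_maps)
  lab <- ref_maps$chr1$labels
  want <- vapply(seq_len(nrow(seq_svs)), function(i) {
    sv <- seq_svs[i, ]
    if (sv$sv_type == "inversion") return(FALSE)
    lo <- max(c(0, lab[lab < sv$start]))
    hi <- min(c(ref_maps$chr1$length_bp, lab[lab > sv$end]))
    ok <- FALSE
    for (j in seq_len(nrow(map_svs))) {
      same_sign <- (sv$sv_type %in% gain) ==
        (map_svs$sv_type[j] == "insertion")
      if (same_sign && map_svs$start[j] < hi && map_svs$end[j] > lo) ok <- TRUE
    }
    ok
  }, logical(1))
  expect_equal(nrow(got), sum(want))
  expect_equal(paste(got$start, got$sv_type),
               paste(seq_svs$start[want], seq_svs$sv_type[want]))
})

test_that("label map TSV and CMAP readers work", {
  maps <- list(chr1 = list(map_id = "chr1", length_bp = 5000,
                           labels = c(100, 900, 4000)),
               chr2 = list(map_id = "chr2", length_bp = 3000,
                           labels = numeric(0)))
  tmp <- tempfile(fileext = ".tsv")
  write_label_maps(maps, tmp)
  back <- read_label_maps(tmp)
  expect_equal(back$chr1$labels, maps$chr1$labels)
  expect_equal(back$chr2$labels, numeric(0))
  expect_equal(back$chr1$length_bp, 5000)

  cmap <- tempfile(fileext = ".cmap")
  writeLines(c(
    "# CMAP File Version:  0.1",
    "#h CMapId\tContigLength\tNumSites\tSiteID\tLabelChannel\tPosition",
    "#f int\tfloat\tint\tint\tint\tfloat",
    "1\t20000.0\t3\t1\t1\t1500.0",
    "1\t20000.0\t3\t2\t1\t7700.0",
    "1\t20000.0\t3\t3\t0\t20000.0",
    "2\t9000.0\t1\t1\t1\t4000.0"), cmap)
  got <- read_cmap(cmap)
  expect_equal(got[["1"]]$labels, c(1500, 7700))
  expect_equal(got[["1"]]$length_bp, 20000)
  expect_equal(got[["2"]]$labels, 4000)
  expect_error(read_cmap(tmp), "#h")
})
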