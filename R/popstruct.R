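#' Tolerance-match SVs across lines into a presence/absence matrix
#'
#' Two records are coincident when they share chromosome and SV class and
#' both their start and end positions differ by at most `tol` bp. Loci are
#' the connected components of the coincidence graph (single linkage, so
#' chains of near-matches merge); the consensus key of a locus is the
#' component-wise minimum start and maximum end. Cell (locus, line) is 1 when
#' the line contributed at least one record; two records of the same line in
#' one component are kept and noted as a merge.
#'
#' @param svs SV data.frame across lines (column `line_id`).
#' @param tol coincidence tolerance in bp (default 3).
#' @param lines optional character vector fixing the column order; defaults
#'   to the sorted line ids present, which makes the matrix invariant to
#'   input order.
#' @return Object of class `presence_matrix`: list with `loci` (data.frame
#'   chrom, start, end, sv_type), `lines`, binary `mat` (loci x lines) and
#'   `provenance` (list of contributing record indices per locus).
#' @export
match_svs <- function(svs, tol = 3L, lines = NULL) {
  stopifnot(tol >= 0)
  if (is.null(lines)) lines <- sort(unique(svs$line_id))
  n <- nrow(svs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  if (n > 1) {
    key <- paste(svs$chrom, svs$sv_type, sep = "\r")
    for (k in unique(key)) {
      idx <- which(key == k)
      idx <- idx[order(svs$start[idx])]
      st <- svs$start[idx]; en <- svs$end[idx]
      for (a in seq_along(idx)) {
        b <- a + 1L
        while (b <= length(idx) && st[b] - st[a] <= tol) {
          if (abs(en[b] - en[a]) <= tol) union2(idx[a], idx[b])
          b <- b + 1L
        }
      }
    }
  }
  comp <- if (n) vapply(seq_len(n), find, 0L) else integer(0)
  ids <- unique(comp)
  loci <- data.frame(chrom = character(length(ids)),
                     start = numeric(length(ids)),
                     end = numeric(length(ids)),
                     sv_type = character(length(ids)),
                     stringsAsFactors = FALSE)
  mat <- matrix(0L, nrow = length(ids), ncol = length(lines),
                dimnames = list(NULL, lines))
  prov <- vector("list", length(ids))
  for (t in seq_along(ids)) {
    sel <- which(comp == ids[t])
    loci$chrom[t] <- svs$chrom[sel[1]]
    loci$start[t] <- min(svs$start[sel])
    loci$end[t] <- max(svs$end[sel])
    loci$sv_type[t] <- svs$sv_type[sel[1]]
    mat[t, unique(svs$line_id[sel])] <- 1L
    prov[[t]] <- sel
    dup <- table(svs$line_id[sel])
    if (any(dup > 1)) {
      message("match_svs: merged ", sum(dup > 1),
              " same-line record pair(s) at ", loci$chrom[t], ":",
              loci$start[t])
    }
  }
  ord <- order(loci$chrom, loci$start, loci$sv_type)
  structure(list(loci = loci[ord, , drop = FALSE],
                 lines = lines,
                 mat = mat[ord, , drop = FALSE],
                 provenance = prov[ord]),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("<presence_matrix>", nrow(x$mat), "loci x", length(x$lines), "lines\n")
  invisible(x)
}

#' Sharing statistics of a presence matrix
#'
#' `pairwise_percent[i, j]` is the percentage of line i's loci that line j
#' also carries (row-normalized, hence asymmetric); `shared_in_all` counts
#' loci present in every line.
#'
#' @param pm a `presence_matrix`.
#' @return list with `pairwise_percent` (lines x lines, NA row for a line
#'   with zero loci), `shared_in_all`, and `per_line_counts`.
#' @export
sharing_stats <- function(pm) {
  m <- pm$mat
  if (nrow(m) == 0) stop("empty presence matrix")
  counts <- colSums(m)
  inter <- crossprod(m)
  pct <- 100 * sweep(inter, 1, counts, "/")
  pct[counts == 0, ] <- NA_real_
  list(pairwise_percent = pct,
       shared_in_all = sum(rowSums(m) == ncol(m)),
       per_line_counts = counts)
}

#' Jaccard distance between lines
#'
#' `d(i, j) = 1 - |loci_i intersect loci_j| / |loci_i union loci_j|` on the
#' binary presence matrix; identical columns give 0, disjoint columns 1, and
#' two lines with no loci at all are at distance 0.
#'
#' @param pm a `presence_matrix`.
#' @param method distance; only `"jaccard"` is implemented.
#' @return A `dist` over the lines (lexicographic label order).
#' @export
sv_distance <- function(pm, method = c("jaccard")) {
  method <- match.arg(method)
  m <- pm$mat
  stopifnot(ncol(m) >= 2)
  inter <- crossprod(m)
  sizes <- colSums(m)
  un <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / pmax(un, 1)
  d[un == 0] <- 0
  as.dist(d)
}

#' Average-linkage (UPGMA) clustering of lines
#'
#' Wraps [stats::hclust()] with labels pre-sorted lexicographically so that
#' merge ties resolve toward the smallest leaf.
#'
#' @param d a `dist` over line ids.
#' @return Object of class `sv_cluster_tree`: list with `hclust`, `leaves`,
#'   `clades` (leaf sets of the internal nodes) and a `support` data.frame
#'   (bp, au; NA until [bootstrap_support()] fills them).
#' @export
cluster_lines <- function(d) {
  labs <- attr(d, "Labels")
  m <- as.matrix(d)
  ord <- order(labs)
  d2 <- as.dist(m[ord, ord])
  hc <- hclust(d2, method = "average")
  clades <- hclust_clades(hc)
  structure(list(hclust = hc, leaves = hc$labels, clades = clades,
                 support = data.frame(bp = rep(NA_real_, length(clades)),
                                      au = rep(NA_real_, length(clades)))),
            class = "sv_cluster_tree")
}

# leaf sets of the internal nodes of an hclust, in merge order
hclust_clades <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    take <- function(x) if (x < 0) hc$labels[-x] else sets[[x]]
    sets[[i]] <- sort(c(take(hc$merge[i, 1]), take(hc$merge[i, 2])))
  }
  sets
}

#' @export
print.sv_cluster_tree <- function(x, ...) {
  cat("<sv_cluster_tree>", length(x$leaves), "leaves\n")
  for (i in seq_along(x$clades)) {
    cat(sprintf("  (%s) AU=%s BP=%s\n", paste(x$clades[[i]], collapse = ","),
                format(x$support$au[i]), format(x$support$bp[i])))
  }
  invisible(x)
}

#' Multiscale bootstrap supports (BP and AU) for the line tree
#'
#' For each scale r, draws `B` resamples of `ceiling(r * n_loci)` matrix rows
#' with replacement, reclusters, and records per-clade frequencies BP_r. The
#' plain bootstrap probability is `BP = 100 * BP_1`. The approximately
#' unbiased support uses the multiscale model: `z(r) = qnorm(1 - BP_r)` is
#' fit as `z = v * sqrt(r) + c / sqrt(r)` by weighted least squares over
#' scales with `0 < BP_r < 1`, and `AU = 100 * (1 - pnorm(v - c))`. Clades
#' with degenerate BP_r at every scale (all 0 or 1) fall back to
#' `AU = 100 * BP_1`.
#'
#' @param pm a `presence_matrix`.
#' @param B resamples per scale (at least 100; default 1000).
#' @param scales resampling scale factors; must include 1.0.
#' @param seed integer RNG seed.
#' @return An `sv_cluster_tree` of the full data with `support` filled in.
#' @export
bootstrap_support <- function(pm, B = 1000L, scales = seq(0.5, 1.4, by = 0.1),
                              seed = 1L) {
  if (B < 100) stop("B must be at least 100")
  if (!any(abs(scales - 1) < 1e-9)) stop("scales must include 1.0")
  m <- pm$mat
  n <- nrow(m)
  if (n == 0) stop("empty presence matrix")
  tree <- cluster_lines(sv_distance(pm))
  clades <- tree$clades
  # only non-trivial clades vary; the root clade always has support 100
  set.seed(seed)
  bp <- matrix(0, nrow = length(clades), ncol = length(scales))
  keymap <- vapply(clades, paste, "", collapse = "\r")
  for (si in seq_along(scales)) {
    nr <- ceiling(scales[si] * n)
    hits <- numeric(length(clades))
    for (b in seq_len(B)) {
      w <- tabulate(sample.int(n, nr, replace = TRUE), nbins = n)
      inter <- crossprod(m * sqrt(w)) # t(m) %*% diag(w) %*% m
      sizes <- colSums(m * w)
      un <- outer(sizes, sizes, "+") - inter
      d <- 1 - inter / pmax(un, 1)
      d[un == 0] <- 0
      hc <- hclust(as.dist(d), method = "average")
      got <- vapply(hclust_clades(hc), paste, "", collapse = "\r")
      hits <- hits + (keymap %in% got)
    }
    bp[, si] <- hits / B
  }
  s1 <- which(abs(scales - 1) < 1e-9)[1]
  au <- numeric(length(clades))
  for (ci in seq_along(clades)) {
    p <- bp[ci, ]
    usable <- which(p > 0 & p < 1)
    if (length(usable) < 2) { au[ci] <- 100 * p[s1]; next }
    r <- scales[usable]
    z <- qnorm(1 - p[usable])
    wls <- B * dnorm(qnorm(p[usable]))^2 / (p[usable] * (1 - p[usable]))
    X <- cbind(sqrt(r), 1 / sqrt(r))
    fit <- lm.wfit(X, z, wls)
    au[ci] <- unname(100 * (1 - pnorm(fit$coefficients[1] -
                                        fit$coefficients[2])))
  }
  tree$support <- data.frame(bp = 100 * bp[, s1], au = au)
  tree$bp_scales <- structure(bp, dimnames = list(NULL, scales))
  tree
}

#' Fit the multiscale-bootstrap model for one clade
#'
#' Exposed building block of [bootstrap_support()]: given per-scale bootstrap
#' frequencies, returns the AU support on the 0-100 scale.
#'
#' @param bp_r per-scale bootstrap frequencies in `[0, 1]`.
#' @param scales matching scale factors (must include 1.0).
#' @param B resamples behind each frequency (for the WLS weights).
#' @return AU support in `[0, 100]`.
#' @export
au_from_multiscale <- function(bp_r, scales, B = 1000L) {
  s1 <- which(abs(scales - 1) < 1e-9)[1]
  usable <- which(bp_r > 0 & bp_r < 1)
  if (length(usable) < 2) return(100 * bp_r[s1])
  r <- scales[usable]
  z <- qnorm(1 - bp_r[usable])
  wls <- B * dnorm(qnorm(bp_r[usable]))^2 / (bp_r[usable] * (1 - bp_r[usable]))
  X <- cbind(sqrt(r), 1 / sqrt(r))
  fit <- lm.wfit(X, z, wls)
  unname(100 * (1 - pnorm(fit$coefficients[1] - fit$coefficients[2])))
}

#' SV rate per million years per megabase
#'
#' `rate = sv_count / (2 * divergence_my * genome_mb)`; the factor 2 counts
#' the two lineages separating a line from the reference since their split.
#'
#' @param sv_count number of SVs between one line and the reference.
#' @param divergence_my divergence time in million years.
#' @param genome_mb aligned genome size in Mb.
#' @return list (class `rate_estimate`) with the inputs and `rate`.
#' @export
estimate_rate <- function(sv_count, divergence_my, genome_mb) {
  stopifnot(sv_count > 0, divergence_my > 0, genome_mb > 0)
  structure(list(sv_count = sv_count, divergence_my = divergence_my,
                 genome_mb = genome_mb,
                 rate = sv_count / (2 * divergence_my * genome_mb)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%d SVs / (2 x %.3g MY x %.3g Mb) = %.3g SVs/MY/Mb\n",
              x$sv_count, x$divergence_my, x$genome_mb, x$rate))
  invisible(x)
}

#' Write a presence matrix as TSV
#' @param pm a `presence_matrix`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(pm, path) {
  tab <- cbind(pm$loci, as.data.frame(pm$mat))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize the line tree as newick with AU/BP node comments
#'
#' Internal nodes carry a bracketed comment `[AU/BP]` after their closing
#' parenthesis; heights come from the UPGMA merge heights.
#'
#' @param tree an `sv_cluster_tree`.
#' @param path optional file; when NULL the newick string is returned.
#' @return The newick string (invisibly when written to a file).
#' @export
write_tree_newick <- function(tree, path = NULL) {
  hc <- tree$hclust
  hts <- hc$height
  node_str <- function(x, parent_h) {
    if (x < 0) {
      sprintf("%s:%.6g", hc$labels[-x], parent_h)
    } else {
      lab <- sprintf("[%.1f/%.1f]", tree$support$au[x], tree$support$bp[x])
      if (anyNA(tree$support[x, ])) lab <- ""
      sprintf("(%s,%s)%s:%.6g",
              node_str(hc$merge[x, 1], hts[x] / 2),
              node_str(hc$merge[x, 2], hts[x] / 2),
              lab, (parent_h - hts[x] / 2))
    }
  }
  root <- nrow(hc$merge)
  lab <- sprintf("[%.1f/%.1f]", tree$support$au[root], tree$support$bp[root])
  if (anyNA(tree$support[root, ])) lab <- ""
  nwk <- sprintf("(%s,%s)%s;", node_str(hc$merge[root, 1], hts[root] / 2),
                 node_str(hc$merge[root, 2], hts[root] / 2), lab)
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
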