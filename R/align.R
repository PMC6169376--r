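#' Find unique-anchor alignment blocks between two genomes
#'
#' Seeds at k-mers that occur exactly once in each genome (canonical form, so
#' both orientations are handled) and extends each seed to a maximal exact
#' match. This is the internal stand-in for an external whole-genome aligner:
#' genomes differing structurally but not by substitutions decompose into
#' long exact blocks separated by the SV loci.
#'
#' @param reference,query [genome()] objects.
#' @param k seed length, 15..31 (default 21).
#' @return data.frame of alignment blocks (ref_chrom, ref_start, ref_end,
#'   query_chrom, query_start, query_end, strand, block_len), 0-based
#'   half-open, query coordinates always on the forward query strand, sorted
#'   by (ref_chrom, ref_start).
#' @export
find_unique_anchors <- function(reference, query, k = 21L) {
  stopifnot(inherits(reference, "genome"), inherits(query, "genome"),
            k >= 15, k <= 64)
  if (k > 31) stop("internal anchoring supports k <= 31")
  rcat <- paste(reference$seqs, collapse = "N")
  qcat <- paste(query$seqs, collapse = "N")
  a <- .anchors_cpp(rcat, qcat, as.integer(k))
  if (nrow(a) == 0) {
    return(data.frame(ref_chrom = character(), ref_start = numeric(),
                      ref_end = numeric(), query_chrom = character(),
                      query_start = numeric(), query_end = numeric(),
                      strand = character(), block_len = numeric(),
                      stringsAsFactors = FALSE))
  }
  roff <- cumsum(c(0, nchar(reference$seqs) + 1))
  qoff <- cumsum(c(0, nchar(query$seqs) + 1))
  ri <- findInterval(a$ref_start, roff[-length(roff)])
  qi <- findInterval(a$query_start, qoff[-length(qoff)])
  out <- data.frame(
    ref_chrom = names(reference$seqs)[ri],
    ref_start = a$ref_start - roff[ri],
    ref_end = a$ref_end - roff[ri],
    query_chrom = names(query$seqs)[qi],
    query_start = a$query_start - qoff[qi],
    query_end = a$query_end - qoff[qi],
    strand = a$strand,
    stringsAsFactors = FALSE)
  out$block_len <- out$ref_end - out$ref_start
  out[order(out$ref_chrom, out$ref_start, out$query_start), , drop = FALSE]
}

#' Chain co-linear anchors
#'
#' Greedy chaining of same-strand anchors on one (ref_chrom, query_chrom)
#' pair: an anchor joins the most recently extended compatible chain when its
#' reference and query gaps to the chain tail are both at most `max_gap` and
#' query order is monotonic (increasing on `+`, decreasing on `-`). Anchors
#' overlapping the chain tail by more than half their own length are dropped.
#'
#' @param anchors data.frame as returned by [find_unique_anchors()].
#' @param max_gap maximum bridged gap in bp on either genome (default 50 kb,
#'   above the size of the large majority of SVs).
#' @return The retained anchors with a `chain_id` column, sorted by
#'   (ref_chrom, ref_start).
#' @export
chain_anchors <- function(anchors, max_gap = 50000L) {
  a <- anchors[order(anchors$ref_chrom, anchors$ref_start, anchors$query_start),
               , drop = FALSE]
  n <- nrow(a)
  chain_id <- integer(n)
  keep <- rep(TRUE, n)
  if (n == 0) { a$chain_id <- integer(0); return(a) }
  # open chains: bookkeeping of the tail anchor of each chain
  tails <- list()
  next_chain <- 1L
  for (i in seq_len(n)) {
    assigned <- FALSE
    best <- NULL
    for (ci in rev(seq_along(tails))) {
      t <- tails[[ci]]
      if (t$ref_chrom != a$ref_chrom[i] || t$query_chrom != a$query_chrom[i] ||
          t$strand != a$strand[i]) next
      rgap <- a$ref_start[i] - t$ref_end
      if (rgap > max_gap) next
      if (a$strand[i] == "+") {
        qgap <- a$query_start[i] - t$query_end
        mono <- a$query_start[i] > t$query_start
        qov <- t$query_end - a$query_start[i]
      } else {
        qgap <- t$query_start - a$query_end[i]
        mono <- a$query_end[i] < t$query_end
        qov <- a$query_end[i] - t$query_start
      }
      if (qgap > max_gap || !mono) next
      ov <- max(-rgap, qov, 0)
      if (ov > a$block_len[i] / 2) { keep[i] <- FALSE; assigned <- TRUE; break }
      best <- ci
      break
    }
    if (assigned) next
    if (!is.null(best)) {
      chain_id[i] <- attr(tails[[best]], "id")
      tails[[best]] <- structure(as.list(a[i, ]), id = chain_id[i])
    } else {
      chain_id[i] <- next_chain
      tails[[length(tails) + 1]] <- structure(as.list(a[i, ]), id = next_chain)
      next_chain <- next_chain + 1L
    }
  }
  a$chain_id <- chain_id
  a[keep, , drop = FALSE]
}

#' Apply the match-length filters
#'
#' A block of at least `min_match` bp always survives; a block in
#' `[min_cluster_match, min_match)` survives only when its chain retains at
#' least two blocks of at least `min_cluster_match` bp; shorter blocks and
#' emptied chains are removed.
#'
#' @param chains data.frame with a `chain_id` column ([chain_anchors()]).
#' @param min_match single-match minimum length in bp (default 500).
#' @param min_cluster_match clustered-match minimum length in bp (default 100).
#' @return Filtered data.frame.
#' @export
filter_alignments <- function(chains, min_match = 500L,
                              min_cluster_match = 100L) {
  x <- chains[chains$block_len >= min_cluster_match, , drop = FALSE]
  if (nrow(x) == 0) return(x)
  sz <- table(x$chain_id)
  in_cluster <- sz[as.character(x$chain_id)] >= 2
  x[x$block_len >= min_match | in_cluster, , drop = FALSE]
}

#' Read alignment blocks from a PAF file
#'
#' Maps PAF records (minimap2 and compatible aligners) to alignment blocks.
#' Coordinates are kept 0-based half-open; minus-strand query coordinates
#' stay on the forward query strand as PAF defines them. A `cg:Z` CIGAR tag
#' is retained when present.
#'
#' @param path PAF file.
#' @return data.frame of alignment blocks with an extra `cigar` column
#'   (NA when absent).
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(ref_chrom = character(), ref_start = numeric(),
                      ref_end = numeric(), query_chrom = character(),
                      query_start = numeric(), query_end = numeric(),
                      strand = character(), block_len = numeric(),
                      cigar = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 12) stop("malformed PAF line ", i, ": fewer than 12 columns")
    num <- suppressWarnings(as.numeric(p[c(2:4, 7:12)]))
    if (anyNA(num)) stop("malformed PAF line ", i, ": non-numeric coordinate")
    if (!p[5] %in% c("+", "-")) stop("malformed PAF line ", i, ": bad strand")
    cg <- NA_character_
    if (length(p) > 12) {
      tag <- grep("^cg:Z:", p[13:length(p)], value = TRUE)
      if (length(tag)) cg <- sub("^cg:Z:", "", tag[1])
    }
    out[[i]] <- data.frame(
      ref_chrom = p[6], ref_start = as.numeric(p[8]),
      ref_end = as.numeric(p[9]), query_chrom = p[1],
      query_start = as.numeric(p[3]), query_end = as.numeric(p[4]),
      strand = p[5],
      block_len = as.numeric(p[9]) - as.numeric(p[8]),
      cigar = cg, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(res$ref_chrom, res$ref_start), , drop = FALSE]
}

#' Write alignment blocks as PAF
#'
#' @param blocks data.frame of alignment blocks; a `cigar` column, when
#'   present and non-NA, is emitted as a `cg:Z` tag.
#' @param path output file.
#' @param query_lengths,ref_lengths optional named vectors of sequence
#'   lengths; defaults to the maximum end coordinate seen per sequence.
#' @return `path`, invisibly.
#' @export
write_paf <- function(blocks, path, query_lengths = NULL, ref_lengths = NULL) {
  len_of <- function(given, name, end) {
    if (!is.null(given) && name %in% names(given)) given[[name]]
    else max(end)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    ql <- len_of(query_lengths, b$query_chrom,
                 blocks$query_end[blocks$query_chrom == b$query_chrom])
    rl <- len_of(ref_lengths, b$ref_chrom,
                 blocks$ref_end[blocks$ref_chrom == b$ref_chrom])
    m <- min(b$query_end - b$query_start, b$ref_end - b$ref_start)
    fields <- c(b$query_chrom, ql, b$query_start, b$query_end, b$strand,
                b$ref_chrom, rl, b$ref_start, b$ref_end, m,
                max(b$query_end - b$query_start, b$ref_end - b$ref_start), 60)
    if (!is.null(blocks$cigar) && !is.na(b$cigar)) {
      fields <- c(fields, paste0("cg:Z:", b$cigar))
    }
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}
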