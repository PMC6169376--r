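#' Empty SV record table
#'
#' SV records are plain data.frames with columns line_id, chrom, start, end,
#' size_bp, sv_type, method, validated; coordinates are 0-based half-open on
#' the reference, insertions have `end == start`.
#'
#' @return A zero-row SV data.frame.
#' @export
sv_records <- function() {
  data.frame(line_id = character(), chrom = character(), start = numeric(),
             end = numeric(), size_bp = numeric(), sv_type = character(),
             method = character(), validated = logical(),
             stringsAsFactors = FALSE)
}

#' Classify an alignment gap pair into an SV class
#'
#' Between two consecutive co-linear alignment blocks, let `ref_gap` and
#' `query_gap` be the signed distances between them on each genome (negative
#' when the blocks overlap on that genome). The net size is
#' `query_gap - ref_gap`; calls outside `[min_size, max_size]` in magnitude
#' are suppressed. For query gains (size > 0): both gaps nonnegative is an
#' insertion, reference overlap only a tandem expansion, overlap on both
#' genomes a repeat expansion; query losses mirror to deletion, tandem
#' contraction and repeat contraction. This decision table is the package's
#' normative definition of the six classes.
#'
#' @param ref_gap,query_gap signed integer vectors (recycled to equal length).
#' @param min_size,max_size size bounds in bp (defaults 50 and 50000).
#' @return data.frame (sv_type, size_bp) with NA rows where no call is made.
#' @export
classify_gap <- function(ref_gap, query_gap, min_size = 50L,
                         max_size = 50000L) {
  n <- max(length(ref_gap), length(query_gap))
  r <- rep_len(ref_gap, n); q <- rep_len(query_gap, n)
  size <- q - r
  type <- rep(NA_character_, n)
  gain <- size > 0
  loss <- size < 0
  type[gain & r >= 0 & q >= 0] <- "insertion"
  type[gain & r < 0 & q >= 0] <- "tandem_expansion"
  type[gain & r < 0 & q < 0] <- "repeat_expansion"
  type[loss & r >= 0 & q >= 0] <- "deletion"
  type[loss & r >= 0 & q < 0] <- "tandem_contraction"
  type[loss & r < 0 & q < 0] <- "repeat_contraction"
  type[abs(size) < min_size | abs(size) > max_size] <- NA_character_
  data.frame(sv_type = type, size_bp = ifelse(is.na(type), NA_real_,
                                              abs(size)))
}

#' Call SVs between consecutive blocks of a chain
#'
#' Applies [classify_gap()] to every consecutive block pair of a single-strand
#' chain. The reference interval of a call is
#' `[min(ref_end1, ref_start2), max(ref_end1, ref_start2))` for
#' reference-consuming classes and a zero-length anchor point for insertions.
#'
#' @param chain data.frame of blocks of one chain, sorted by ref_start.
#' @param line_id line identifier stamped on the records.
#' @param min_size,max_size size bounds in bp.
#' @return SV data.frame (`method = "sequence"`, `validated = FALSE`).
#' @export
call_between_alignments <- function(chain, line_id, min_size = 50L,
                                    max_size = 50000L) {
  n <- nrow(chain)
  if (n < 2) return(sv_records())
  stopifnot(length(unique(chain$strand)) == 1,
            length(unique(chain$ref_chrom)) == 1)
  i1 <- seq_len(n - 1); i2 <- i1 + 1
  ref_gap <- chain$ref_start[i2] - chain$ref_end[i1]
  if (chain$strand[1] == "+") {
    query_gap <- chain$query_start[i2] - chain$query_end[i1]
  } else {
    query_gap <- chain$query_start[i1] - chain$query_end[i2]
  }
  cl <- classify_gap(ref_gap, query_gap, min_size, max_size)
  hit <- which(!is.na(cl$sv_type))
  if (length(hit) == 0) return(sv_records())
  lo <- pmin(chain$ref_end[i1], chain$ref_start[i2])[hit]
  hi <- pmax(chain$ref_end[i1], chain$ref_start[i2])[hit]
  ins <- cl$sv_type[hit] == "insertion"
  hi[ins] <- lo[ins]
  data.frame(line_id = line_id, chrom = chain$ref_chrom[1], start = lo,
             end = hi, size_bp = cl$size_bp[hit], sv_type = cl$sv_type[hit],
             method = "sequence", validated = FALSE,
             stringsAsFactors = FALSE)
}

#' Call insertions and deletions within a CIGAR alignment
#'
#' For blocks read from PAF with a `cg:Z` CIGAR, every I/D run with length in
#' `[min_size, max_size]` becomes an insertion/deletion record at its
#' reference position. Only applicable to external alignments; internal
#' anchors are exact and carry no CIGAR.
#'
#' @param block single-row data.frame with `cigar`.
#' @param line_id line identifier.
#' @param min_size,max_size size bounds in bp.
#' @return SV data.frame.
#' @export
call_within_alignment <- function(block, line_id, min_size = 50L,
                                  max_size = 50000L) {
  stopifnot(nrow(block) == 1, !is.na(block$cigar))
  ops <- regmatches(block$cigar, gregexpr("\\d+[MIDNSHP=X]", block$cigar))[[1]]
  if (length(ops) == 0 ||
      nchar(paste(ops, collapse = "")) != nchar(block$cigar)) {
    stop("unparseable CIGAR: ", block$cigar)
  }
  len <- as.numeric(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  ref_consume <- op %in% c("M", "=", "X", "D", "N")
  query_consume <- op %in% c("M", "=", "X", "I")
  if (sum(len[ref_consume]) != block$ref_end - block$ref_start) {
    stop("CIGAR reference length does not match block coordinates")
  }
  if (sum(len[query_consume]) != block$query_end - block$query_start) {
    stop("CIGAR query length does not match block coordinates")
  }
  pos <- block$ref_start + cumsum(c(0, (len * ref_consume)[-length(len)]))
  keep <- op %in% c("I", "D") & len >= min_size & len <= max_size
  if (!any(keep)) return(sv_records())
  data.frame(line_id = line_id, chrom = block$ref_chrom, start = pos[keep],
             end = ifelse(op[keep] == "D", pos[keep] + len[keep], pos[keep]),
             size_bp = len[keep],
             sv_type = ifelse(op[keep] == "D", "deletion", "insertion"),
             method = "sequence", validated = FALSE,
             stringsAsFactors = FALSE)
}

#' Detect inversions from strand-flipped alignment blocks
#'
#' A maximal run of minus-strand blocks whose reference span is flanked on
#' both sides by plus-strand blocks of the same query chromosome, and whose
#' query coordinates fall between the flanks (consistent with a reversed
#' segment), is reported as an inversion over the run's reference span. A
#' whole-chromosome reverse-complement alignment has no plus flank and is not
#' called.
#'
#' @param blocks data.frame of (filtered) alignment blocks, both strands.
#' @param line_id line identifier.
#' @param min_size minimum reported reference span in bp (default 10 kb).
#' @param flank_slack tolerated bp of query-coordinate disorder at the flanks.
#' @return SV data.frame of inversions (`method = "sequence"`).
#' @export
detect_inversions <- function(blocks, line_id, min_size = 10000L,
                              flank_slack = 1000L) {
  out <- list()
  if (nrow(blocks) == 0) return(sv_records())
  for (key in unique(paste(blocks$ref_chrom, blocks$query_chrom, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    b <- blocks[blocks$ref_chrom == parts[1] & blocks$query_chrom == parts[2],
                , drop = FALSE]
    b <- b[order(b$ref_start), , drop = FALSE]
    r <- rle(b$strand)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (r$values[k] != "-" || k == 1 || k == length(r$values)) next
      run <- b[starts[k]:ends[k], , drop = FALSE]
      left <- b[ends[k - 1], ]; right <- b[starts[k + 1], ]
      if (left$strand != "+" || right$strand != "+") next
      qlo <- min(run$query_start); qhi <- max(run$query_end)
      if (qlo < left$query_end - flank_slack ||
          qhi > right$query_start + flank_slack) next
      span_lo <- min(run$ref_start); span_hi <- max(run$ref_end)
      if (span_hi - span_lo < min_size) next
      out[[length(out) + 1]] <- data.frame(
        line_id = line_id, chrom = parts[1], start = span_lo, end = span_hi,
        size_bp = span_hi - span_lo, sv_type = "inversion",
        method = "sequence", validated = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(sv_records())
  do.call(rbind, out)
}

#' Write / read SV records as BED6+3
#'
#' Columns: chrom, start, end, name (`line:type`), score (size), strand
#' (`.`), sv_type, method, validated. The round trip is lossless.
#'
#' @param svs SV data.frame.
#' @param path file path.
#' @return `write_svs()` returns `path` invisibly; `read_svs()` the records.
#' @export
write_svs <- function(svs, path) {
  bed <- data.frame(chrom = svs$chrom, start = svs$start, end = svs$end,
                    name = paste0(svs$line_id, ":", svs$sv_type),
                    score = svs$size_bp, strand = ".",
                    sv_type = svs$sv_type, method = svs$method,
                    validated = tolower(as.character(svs$validated)))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_svs
#' @export
read_svs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(sv_records())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 9) stop("malformed SV BED row ", i, ": expected 9 columns")
    st <- suppressWarnings(as.numeric(p[2])); en <- suppressWarnings(as.numeric(p[3]))
    sz <- suppressWarnings(as.numeric(p[5]))
    if (anyNA(c(st, en, sz))) stop("malformed SV BED row ", i, ": non-numeric")
    if (st < 0 || en < st) stop("malformed SV BED row ", i, ": bad interval")
    out[[i]] <- data.frame(
      line_id = sub(":[^:]*$", "", p[4]), chrom = p[1], start = st, end = en,
      size_bp = sz, sv_type = p[7], method = p[8],
      validated = identical(p[9], "true"), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Export SV records in an Assemblytics-style table
#'
#' Interoperability export using the column names of the Assemblytics
#' between-alignment variant table.
#'
#' @param svs SV data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
export_assemblytics <- function(svs, path) {
  tab <- data.frame(
    reference = svs$chrom, ref_start = svs$start, ref_stop = svs$end,
    ID = sprintf("%s_sv_%d", svs$line_id, seq_len(nrow(svs))),
    size = svs$size_bp, strand = "+",
    type = c(insertion = "Insertion", deletion = "Deletion",
             tandem_expansion = "Tandem_expansion",
             tandem_contraction = "Tandem_contraction",
             repeat_expansion = "Repeat_expansion",
             repeat_contraction = "Repeat_contraction",
             inversion = "Inversion")[svs$sv_type],
    method = svs$method, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
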