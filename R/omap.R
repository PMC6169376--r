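#' In-silico digest: label maps of a genome
#'
#' Exact occurrence positions of a nicking-enzyme recognition motif on both
#' strands, per chromosome, sorted and deduplicated. Positions are 0-based
#' starts of the motif match on the forward strand.
#'
#' @param genome a [genome()].
#' @param motif 6-mer recognition sequence, ACGT only.
#' @return Named list of label maps, one per chromosome: each a list with
#'   `map_id` (the chromosome), `length_bp`, and integer `labels`.
#' @export
digest_genome <- function(genome, motif = "CACGAG") {
  stopifnot(inherits(genome, "genome"), nchar(motif) == 6)
  if (grepl("[^ACGT]", motif)) stop("motif must contain only A, C, G, T")
  fwd <- Biostrings::DNAString(motif)
  rev <- Biostrings::reverseComplement(fwd)
  out <- lapply(names(genome$seqs), function(ch) {
    s <- Biostrings::DNAString(genome$seqs[[ch]])
    hits <- c(Biostrings::start(Biostrings::matchPattern(fwd, s)),
              Biostrings::start(Biostrings::matchPattern(rev, s)))
    list(map_id = ch, length_bp = length(s),
         labels = sort(unique(hits)) - 1L)
  })
  names(out) <- names(genome$seqs)
  out
}

#' @rdname digest_genome
#' @export
digest_reference <- digest_genome

#' Align a query label map to a reference label map
#'
#' Dynamic program over label pairs maximizing the sum over matched pairs of
#' `match_bonus` minus `sizing_weight * |dq - dr| / max(dr, 1000)` for the
#' inter-label distance discrepancy, minus `miss_penalty` per skipped
#' reference label and `false_penalty` per skipped query label, with at most
#' `band` consecutive skips per step. Leading and trailing unmatched labels
#' are free. Returns the optimal monotone matching.
#'
#' @param query,reference label maps (lists with `labels`), each with at
#'   least 2 labels.
#' @param miss_penalty,false_penalty per-skip penalties (default 3).
#' @param sizing_weight weight of the sizing discrepancy term (default 150).
#'   The weight is high so that pairing a label a few hundred bp off-register
#'   costs more than skipping it, which keeps SV sizes from leaking into
#'   neighbouring intervals; at the default sizing noise (cv 0.005) a true
#'   match still costs well under the match bonus.
#' @param sizing_cap upper bound on the sizing cost of one step (default 12),
#'   so that spanning a real SV costs a bounded "opening" amount and the
#'   program crosses it rather than abandoning the alignment.
#' @param cap_from discrepancy size in bp from which `sizing_cap` applies
#'   (default 800): discrepancies this large are treated as candidate SVs
#'   with a bounded opening cost, smaller ones as misalignment and priced in
#'   full.
#' @param match_bonus reward per matched label pair (default 6); without a
#'   positive reward the empty matching would be optimal, and the reward must
#'   exceed the expected per-pair noise cost by enough that an alignment
#'   crossing many SVs stays profitable end to end.
#' @param band maximum consecutive skipped labels per step (default 5).
#' @return list with `pairs` (two-column matrix of 1-based ref/query label
#'   indices, both strictly increasing) and `score`.
#' @export
align_map <- function(query, reference, miss_penalty = 3, false_penalty = 3,
                      sizing_weight = 150, sizing_cap = 12, cap_from = 800,
                      match_bonus = 6, band = 5L) {
  if (length(reference$labels) < 2 || length(query$labels) < 2) {
    stop("both maps must have at least 2 labels")
  }
  r <- .align_map_cpp(as.numeric(reference$labels), as.numeric(query$labels),
                      miss_penalty, false_penalty, sizing_weight, sizing_cap,
                      cap_from, match_bonus, as.integer(band))
  list(pairs = cbind(ref_index = r$ref_index + 1L,
                     query_index = r$query_index + 1L),
       score = r$score)
}

#' Detect large SVs from a map alignment
#'
#' For each consecutive matched label pair, the difference `d` between the
#' query and reference inter-label distances is an indel signal. Because an
#' inserted segment can itself carry labels (and local misalignments around
#' missed/false labels produce compensating discrepancies), consecutive
#' intervals with `|d| >= merge_floor` are aggregated and their net
#' discrepancy is the event size: the SV is the distance change between the
#' nearest well-aligned flanking labels. Net sizes of at least
#' `min_size_map` are reported, insertions for gains and deletions for
#' losses, over the merged reference interval. The default 1 kb floor
#' reflects the resolution of optical-map SV detection.
#'
#' @param alignment result of [align_map()].
#' @param query,reference the aligned label maps.
#' @param line_id line identifier.
#' @param min_size_map reported size floor in bp (default 1000).
#' @param merge_floor per-interval significance floor in bp for aggregation
#'   (default 500, far above sizing noise on typical label spacing).
#' @return SV data.frame (`method = "optical"`).
#' @export
detect_map_svs <- function(alignment, query, reference, line_id,
                           min_size_map = 1000L, merge_floor = 500L) {
  pr <- alignment$pairs
  if (is.null(pr) || nrow(pr) < 2) return(sv_records())
  i <- pr[, 1]; j <- pr[, 2]
  dr <- diff(reference$labels[i])
  dq <- diff(query$labels[j])
  d <- dq - dr
  sig <- abs(d) >= min(merge_floor, min_size_map)
  if (!any(sig)) return(sv_records())
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (k in which(r$values)) {
    tot <- sum(d[starts[k]:ends[k]])
    if (abs(tot) < min_size_map) next
    out[[length(out) + 1]] <- data.frame(
      line_id = line_id, chrom = reference$map_id,
      start = reference$labels[i[starts[k]]],
      end = reference$labels[i[ends[k] + 1]],
      size_bp = abs(tot),
      sv_type = if (tot > 0) "insertion" else "deletion",
      method = "optical", validated = FALSE, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(sv_records())
  do.call(rbind, out)
}

#' Cross-validate sequence SVs against optical SVs
#'
#' A sequence SV is validated when some optical SV of the same sign (gain
#' classes insertion/tandem_expansion/repeat_expansion against optical
#' insertions; loss classes against optical deletions) overlaps its reference
#' interval padded outward to one flanking reference label on each side —
#' optical breakpoint uncertainty is bounded by label spacing. One optical SV
#' may validate several sequence SVs.
#'
#' @param seq_svs,map_svs SV data.frames for one line on the same reference.
#' @param ref_maps reference digest ([digest_genome()] of the reference),
#'   needed to compute the flanking label intervals.
#' @return The validated subset of `seq_svs` with `validated = TRUE`.
#' @export
cross_validate <- function(seq_svs, map_svs, ref_maps) {
  if (nrow(seq_svs) == 0) return(seq_svs)
  gain <- c("insertion", "tandem_expansion", "repeat_expansion")
  loss <- c("deletion", "tandem_contraction", "repeat_contraction")
  ok <- logical(nrow(seq_svs))
  for (idx in seq_len(nrow(seq_svs))) {
    sv <- seq_svs[idx, ]
    if (!sv$sv_type %in% c(gain, loss)) next
    want <- if (sv$sv_type %in% gain) "insertion" else "deletion"
    m <- ref_maps[[sv$chrom]]
    if (is.null(m)) next
    lab <- m$labels
    before <- lab[lab < sv$start]
    after <- lab[lab > sv$end]
    lo <- if (length(before)) max(before) else 0
    hi <- if (length(after)) min(after) else m$length_bp
    cand <- map_svs[map_svs$chrom == sv$chrom & map_svs$sv_type == want, ,
                    drop = FALSE]
    ok[idx] <- any(cand$start < hi & cand$end > lo)
  }
  out <- seq_svs[ok, , drop = FALSE]
  if (nrow(out)) out$validated <- TRUE
  out
}

#' Write / read label maps as TSV
#'
#' Format: for each map a header line `#<map_id><TAB><length_bp>` followed by
#' one label position per row.
#'
#' @param maps named list of label maps.
#' @param path file path.
#' @return `write_label_maps()` returns `path` invisibly; `read_label_maps()`
#'   the named list of maps.
#' @export
write_label_maps <- function(maps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in maps) {
    writeLines(sprintf("#%s\t%d", m$map_id, as.integer(m$length_bp)), con)
    if (length(m$labels)) writeLines(format(m$labels, scientific = FALSE,
                                            trim = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_label_maps
#' @export
read_label_maps <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#", lines)
  if (length(hdr) == 0) stop("no map headers in ", path)
  maps <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    h <- strsplit(sub("^#", "", lines[hdr[k]]), "\t", fixed = TRUE)[[1]]
    body <- lines[seq2(hdr[k] + 1L, bounds[k + 1] - 1L)]
    lab <- if (length(body)) as.numeric(body) else numeric(0)
    if (anyNA(lab)) stop("malformed label position under map ", h[1])
    maps[[h[1]]] <- list(map_id = h[1], length_bp = as.numeric(h[2]),
                         labels = lab)
  }
  maps
}

seq2 <- function(from, to) if (from > to) integer(0) else seq(from, to)

#' Read a CMAP text file (column subset)
#'
#' Parses the documented CMAP text layout, using the `CMapId`,
#' `ContigLength` and `Position` columns; label channel and quality columns
#' are ignored. Returns the same label-map lists as [read_label_maps()].
#'
#' @param path CMAP file.
#' @return Named list of label maps keyed by CMapId.
#' @export
read_cmap <- function(path) {
  lines <- readLines(path)
  head_line <- grep("^#h", lines, value = TRUE)
  if (length(head_line) == 0) stop("CMAP header (#h) not found in ", path)
  cols <- strsplit(sub("^#h\\s*", "", head_line[1]), "\\s+")[[1]]
  need <- c("CMapId", "ContigLength", "Position")
  if (!all(need %in% cols)) {
    stop("CMAP header lacks required columns: ",
         paste(setdiff(need, cols), collapse = ", "))
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) return(list())
  mat <- do.call(rbind, strsplit(body, "\\s+"))
  id <- mat[, match("CMapId", cols)]
  len <- as.numeric(mat[, match("ContigLength", cols)])
  pos <- as.numeric(mat[, match("Position", cols)])
  maps <- list()
  for (u in unique(id)) {
    sel <- id == u
    p <- sort(unique(pos[sel]))
    # the terminal row at ContigLength marks the molecule end, not a label
    p <- p[p < len[sel][1]]
    maps[[u]] <- list(map_id = u, length_bp = len[sel][1], labels = p)
  }
  maps
}
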