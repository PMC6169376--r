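#' Intersect SVs with exons by sorted sweep
#'
#' Reports every (SV, exon) pair with positive interval overlap on the
#' reference; a zero-length insertion overlaps an exon when its insertion
#' point lies strictly inside the exon. The sweep sorts both inputs once and
#' advances a pruned pool of active exons, O((n+m) log(n+m)).
#'
#' @param svs SV data.frame (reference coordinates).
#' @param exons exon data.frame (chrom, start, end, gene_id, exon_id),
#'   0-based half-open.
#' @return data.frame (sv_row, line_id, sv_type, chrom, sv_start, sv_end,
#'   size_bp, exon_id, gene_id, overlap_bp); `overlap_bp` is 0 for
#'   insertions.
#' @export
intersect_exons <- function(svs, exons) {
  empty <- data.frame(sv_row = integer(), line_id = character(),
                      sv_type = character(), chrom = character(),
                      sv_start = numeric(), sv_end = numeric(),
                      size_bp = numeric(), exon_id = character(),
                      gene_id = character(), overlap_bp = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(svs) == 0 || nrow(exons) == 0) return(empty)
  out <- list()
  for (ch in intersect(unique(svs$chrom), unique(exons$chrom))) {
    sv <- svs[svs$chrom == ch, , drop = FALSE]
    sv_row <- which(svs$chrom == ch)
    ex <- exons[exons$chrom == ch, , drop = FALSE]
    so <- order(sv$start)
    sv <- sv[so, , drop = FALSE]; sv_row <- sv_row[so]
    ex <- ex[order(ex$start), , drop = FALSE]
    active <- integer(0)
    nxt <- 1L
    for (i in seq_len(nrow(sv))) {
      ins <- sv$sv_type[i] == "insertion" & sv$end[i] == sv$start[i]
      # exons starting before the sv end (strictly before the point for
      # insertions) become candidates; stale exons ending at or before the
      # sv start can never overlap this or any later sv
      while (nxt <= nrow(ex) && ex$start[nxt] < max(sv$end[i], sv$start[i] +
                                                      (!ins))) {
        active <- c(active, nxt)
        nxt <- nxt + 1L
      }
      if (length(active)) active <- active[ex$end[active] > sv$start[i]]
      if (ins) {
        hit <- active[ex$start[active] < sv$start[i] &
                        ex$end[active] > sv$start[i]]
        ov <- rep(0, length(hit))
      } else {
        hit <- active[ex$start[active] < sv$end[i]]
        ov <- pmin(ex$end[hit], sv$end[i]) - pmax(ex$start[hit], sv$start[i])
      }
      if (length(hit)) {
        out[[length(out) + 1]] <- data.frame(
          sv_row = sv_row[i], line_id = sv$line_id[i],
          sv_type = sv$sv_type[i], chrom = ch, sv_start = sv$start[i],
          sv_end = sv$end[i], size_bp = sv$size_bp[i],
          exon_id = ex$exon_id[hit], gene_id = ex$gene_id[hit],
          overlap_bp = ov, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize exonic impact of SVs
#'
#' Counts distinct exons touched per line, distinct SVs with exonic overlap
#' per class, and affected exonic base pairs per class. Reference-consuming
#' classes contribute their summed overlap; insertions at an exonic point
#' contribute their full inserted length, since an insertion adds sequence
#' into the exon while consuming no reference span.
#'
#' @param overlaps result of [intersect_exons()].
#' @param svs the SV data.frame the overlaps were computed from.
#' @return list with `per_line_exon_count`, `per_class_count`,
#'   `per_class_bp`, and a tidy `per_line_class` data.frame.
#' @export
exon_impact_summary <- function(overlaps, svs) {
  classes <- sv_classes()
  zero <- setNames(numeric(length(classes)), classes)
  if (nrow(overlaps) == 0) {
    return(list(per_line_exon_count = setNames(numeric(0), character(0)),
                per_class_count = zero, per_class_bp = zero,
                per_line_class = data.frame(line_id = character(),
                                            sv_type = character(),
                                            n_sv = numeric(), bp = numeric())))
  }
  bp <- ifelse(overlaps$sv_type == "insertion", overlaps$size_bp,
               overlaps$overlap_bp)
  per_line_exon <- tapply(overlaps$exon_id, overlaps$line_id,
                          function(x) length(unique(x)))
  sv_key <- paste(overlaps$line_id, overlaps$sv_row)
  first <- !duplicated(sv_key)
  per_class_count <- zero
  tc <- table(overlaps$sv_type[first])
  per_class_count[names(tc)] <- as.numeric(tc)
  per_class_bp <- zero
  tb <- tapply(bp, overlaps$sv_type, sum)
  per_class_bp[names(tb)] <- as.numeric(tb)
  agg <- aggregate(cbind(bp = bp),
                   by = list(line_id = overlaps$line_id,
                             sv_type = overlaps$sv_type), FUN = sum)
  aggn <- aggregate(list(n_sv = first),
                    by = list(line_id = overlaps$line_id,
                              sv_type = overlaps$sv_type), FUN = sum)
  per_line_class <- merge(aggn, agg)
  list(per_line_exon_count = c(per_line_exon),
       per_class_count = per_class_count,
       per_class_bp = per_class_bp,
       per_line_class = per_line_class)
}

#' Write / read exon annotations as GFF3
#'
#' Exons are emitted as `exon` features with `ID` and `Parent` attributes;
#' on read, only `exon` features are kept and GFF3 1-based closed
#' coordinates are converted to 0-based half-open.
#'
#' @param exons exon data.frame.
#' @param path file path.
#' @return `write_gff3_exons()` returns `path` invisibly; `read_gff3_exons()`
#'   the exon data.frame.
#' @export
write_gff3_exons <- function(exons, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start + 1, end = exons$end),
    strand = "+")
  gr$type <- "exon"
  gr$ID <- exons$exon_id
  gr$Parent <- exons$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3_exons
#' @export
read_gff3_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "exon"]
  parent <- gr$Parent
  if (!is.character(parent)) { # CharacterList when read back from GFF3
    parent <- vapply(as.list(parent),
                     function(x) if (length(x)) x[[1]] else NA_character_, "")
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             gene_id = as.character(parent),
             exon_id = as.character(gr$ID), stringsAsFactors = FALSE)
}

#' Write / read exon annotations as BED
#'
#' BED6+1: chrom, start, end, exon_id, 0, strand, gene_id.
#'
#' @param exons exon data.frame.
#' @param path file path.
#' @return `write_bed_exons()` returns `path` invisibly; `read_bed_exons()`
#'   the exon data.frame.
#' @export
write_bed_exons <- function(exons, path) {
  tab <- data.frame(exons$chrom, exons$start, exons$end, exons$exon_id, 0L,
                    "+", exons$gene_id)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed_exons
#' @export
read_bed_exons <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", "numeric", "numeric",
                                   "character", "numeric", "character",
                                   "character"))
  data.frame(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
             gene_id = tab[[7]], exon_id = tab[[4]], stringsAsFactors = FALSE)
}
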