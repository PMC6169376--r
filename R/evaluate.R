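#' Score called SVs against a planted truth table
#'
#' Expands the truth table to one expected event per carrier line and
#' greedily matches calls one-to-one within each line. Matching rules by
#' class: insertions and deletions must agree on breakpoints within
#' `indel_tol` bp (default 1, i.e. essentially exact); copy-number classes
#' must fall inside the planted locus padded by `locus_tol` bp with the size
#' agreeing within `size_tol` bp; inversions must reciprocally overlap the
#' planted span by at least `inv_overlap`.
#'
#' @param truth truth data.frame from [plant_svs()].
#' @param calls SV data.frame across lines.
#' @param indel_tol breakpoint tolerance for insertions/deletions (bp).
#' @param locus_tol locus padding for copy-number classes (bp).
#' @param size_tol size tolerance for copy-number classes (bp).
#' @param inv_overlap minimum reciprocal overlap for inversions.
#' @return list with counts (`tp`, `fp`, `fn`), `precision`, `recall`, `f1`,
#'   and a `per_class` data.frame.
#' @export
evaluate_calls <- function(truth, calls, indel_tol = 1, locus_tol = 50,
                           size_tol = 10, inv_overlap = 0.8) {
  carriers <- strsplit(truth$carriers, ",", fixed = TRUE)
  exp_truth <- truth[rep(seq_len(nrow(truth)), lengths(carriers)), ,
                     drop = FALSE]
  exp_truth$line_id <- unlist(carriers)
  matched_call <- rep(FALSE, nrow(calls))
  matched_truth <- rep(FALSE, nrow(exp_truth))
  for (ti in seq_len(nrow(exp_truth))) {
    tr <- exp_truth[ti, ]
    cand <- which(!matched_call & calls$line_id == tr$line_id &
                    calls$chrom == tr$chrom & calls$sv_type == tr$sv_type)
    if (length(cand) == 0) next
    ok <- switch(
      tr$sv_type,
      insertion = abs(calls$start[cand] - tr$ref_start) <= indel_tol,
      deletion = abs(calls$start[cand] - tr$ref_start) <= indel_tol &
        abs(calls$end[cand] - tr$ref_end) <= indel_tol,
      inversion = {
        ov <- pmin(calls$end[cand], tr$ref_end) -
          pmax(calls$start[cand], tr$ref_start)
        ov / pmax(calls$end[cand] - calls$start[cand],
                  tr$ref_end - tr$ref_start) >= inv_overlap
      },
      calls$start[cand] >= tr$ref_start - locus_tol &
        calls$end[cand] <= tr$ref_end + locus_tol &
        abs(calls$size_bp[cand] - tr$size_bp) <= size_tol)
    hit <- cand[ok]
    if (length(hit)) {
      matched_call[hit[1]] <- TRUE
      matched_truth[ti] <- TRUE
    }
  }
  per_class <- do.call(rbind, lapply(sv_classes(), function(cl) {
    sel <- exp_truth$sv_type == cl
    data.frame(sv_type = cl, n_truth = sum(sel),
               recovered = sum(matched_truth[sel]),
               n_calls = sum(calls$sv_type == cl),
               stringsAsFactors = FALSE)
  }))
  tp <- sum(matched_truth)
  fp <- sum(!matched_call)
  fn <- sum(!matched_truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!anyNA(c(precision, recall)) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1, per_class = per_class)
}

#' Score optical-map SV calls against planted truth
#'
#' Only size-changing classes are considered (an inversion is balanced and
#' leaves inter-label distances unchanged, so it carries no optical indel
#' signal). A planted SV is recovered when an optical call of the same sign
#' overlaps its locus padded by `pad` bp and agrees in size within
#' `3 * sizing_cv * interval + slack`.
#'
#' @param truth truth data.frame from [plant_svs()].
#' @param map_calls optical SV data.frame for one line.
#' @param line line id (calls are matched against this line's truth events).
#' @param sizing_cv the sizing noise used when simulating the maps.
#' @param pad locus padding in bp (default 2000, about one label interval).
#' @param slack additive size slack in bp (default 25, covering label
#'   position rounding).
#' @return data.frame of this line's size-changing truth events with a
#'   `recovered` logical column.
#' @export
evaluate_map_calls <- function(truth, map_calls, line, sizing_cv = 0,
                               pad = 2000, slack = 25) {
  gain <- c("insertion", "tandem_expansion", "repeat_expansion")
  loss <- c("deletion", "tandem_contraction", "repeat_contraction")
  sel <- truth$sv_type %in% c(gain, loss) &
    vapply(strsplit(truth$carriers, ",", fixed = TRUE),
           function(x) line %in% x, logical(1))
  tr <- truth[sel, , drop = FALSE]
  rec <- logical(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    want <- if (tr$sv_type[i] %in% gain) "insertion" else "deletion"
    cand <- map_calls[map_calls$chrom == tr$chrom[i] &
                        map_calls$sv_type == want, , drop = FALSE]
    if (nrow(cand) == 0) next
    ov <- cand$start < tr$ref_end[i] + pad & cand$end > tr$ref_start[i] - pad
    # sizing noise accrues over the measured query distance, which for an
    # insertion exceeds the reference interval by the inserted length
    tol <- 3 * sizing_cv * (cand$end - cand$start + cand$size_bp) + slack
    rec[i] <- any(ov & abs(cand$size_bp - tr$size_bp[i]) <= tol)
  }
  tr$recovered <- rec
  tr
}
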