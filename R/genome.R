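#' Genome container
#'
#' A genome is a named list with an `id` and a named character vector `seqs`
#' holding one upper-case ACGT string per chromosome. This mirrors what a
#' per-line assembly FASTA contains, kept as plain strings because the SV
#' planting machinery edits sequences by splicing.
#'
#' @param id single string naming the genome (e.g. a line id).
#' @param seqs named character vector of chromosome sequences (ACGT only).
#' @return An object of class `genome`.
#' @export
genome <- function(id, seqs) {
  stopifnot(is.character(id), length(id) == 1L, is.character(seqs),
            !is.null(names(seqs)), all(nzchar(names(seqs))))
  if (any(grepl("[^ACGT]", seqs))) {
    stop("genome sequences must contain only A, C, G, T")
  }
  if (any(nchar(seqs) == 0L)) stop("all chromosomes must have length > 0")
  structure(list(id = id, seqs = seqs), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome>", x$id, ":", length(x$seqs), "chromosome(s),",
      sum(nchar(x$seqs)), "bp\n")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param g a [genome()].
#' @return Named integer vector of chromosome lengths in bp.
#' @export
genome_lengths <- function(g) {
  stopifnot(inherits(g, "genome"))
  vapply(g$seqs, nchar, integer(1))
}

#' Write / read a genome as FASTA
#' @param g a [genome()].
#' @param path file path.
#' @return `write_genome_fasta()` returns `path` invisibly; `read_genome_fasta()`
#'   returns a [genome()].
#' @export
write_genome_fasta <- function(g, path) {
  stopifnot(inherits(g, "genome"))
  x <- Biostrings::DNAStringSet(g$seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param id genome id to attach on read (default: file name without extension).
#' @export
read_genome_fasta <- function(path, id = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  genome(id, toupper(seqs))
}

# reverse complement of a plain character sequence
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# random ACGT string
rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# uniform integers on [lo, hi], immune to sample()'s scalar expansion
rand_int <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}
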