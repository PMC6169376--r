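#' Default repeat configuration for the synthetic ancestor
#'
#' Controls the repeat structures inserted into the simulated ancestor genome:
#' tandem arrays (the substrate of the four copy-number SV classes) and
#' dispersed repeat copies (background repetitive sequence in which alignment
#' seeds cannot be placed).
#'
#' @param tandem_unit_range integer length-2, bp length range of a tandem unit.
#' @param tandem_copy_range integer length-2, copies per array.
#' @param tandem_array_count number of tandem arrays genome-wide.
#' @param dispersed_repeat_length bp length of the dispersed repeat family.
#' @param dispersed_repeat_count number of dispersed copies genome-wide.
#' @return A list with the five components above.
#' @export
default_repeat_config <- function(tandem_unit_range = c(15L, 30L),
                                  tandem_copy_range = c(6L, 15L),
                                  tandem_array_count = 150L,
                                  dispersed_repeat_length = 500L,
                                  dispersed_repeat_count = 20L) {
  list(tandem_unit_range = as.integer(tandem_unit_range),
       tandem_copy_range = as.integer(tandem_copy_range),
       tandem_array_count = as.integer(tandem_array_count),
       dispersed_repeat_length = as.integer(dispersed_repeat_length),
       dispersed_repeat_count = as.integer(dispersed_repeat_count))
}

#' Simulate an ancestor (reference) genome with recorded repeat structures
#'
#' Generates `length_bp` of uniform random ACGT sequence split across
#' `n_chroms` chromosomes, then splices in tandem arrays and dispersed repeat
#' copies at recorded, well-separated positions. The final genome is therefore
#' `length_bp` plus the summed repeat footprint; repeat coordinates are
#' returned so SV planting can target them.
#'
#' @param length_bp total random backbone length in bp (excluding repeats).
#' @param n_chroms number of chromosomes.
#' @param repeat_config see [default_repeat_config()].
#' @param seed integer RNG seed; identical seeds give identical genomes.
#' @return list with `genome` (a [genome()], id `"ancestor"`) and `features`,
#'   a data.frame (chrom, start, end, kind, unit_len, copies) in 0-based
#'   half-open coordinates.
#' @export
simulate_ancestor <- function(length_bp, n_chroms = 2L,
                              repeat_config = default_repeat_config(),
                              seed = 1L) {
  rc <- repeat_config
  stopifnot(length_bp > 0, n_chroms >= 1,
            rc$tandem_array_count >= 0, rc$dispersed_repeat_count >= 0,
            rc$dispersed_repeat_length > 0,
            diff(range(rc$tandem_unit_range)) >= 0,
            rc$tandem_unit_range[1] > 0, rc$tandem_copy_range[1] > 0)
  if (length_bp < 10 * rc$dispersed_repeat_length) {
    stop("length_bp must be at least 10x dispersed_repeat_length")
  }
  set.seed(seed)
  chrom_len <- rep(length_bp %/% n_chroms, n_chroms)
  chrom_len[n_chroms] <- chrom_len[n_chroms] + length_bp %% n_chroms
  chrom_names <- paste0("chr", seq_len(n_chroms))

  # one dispersed repeat family, identical copies
  fam <- rand_seq(rc$dispersed_repeat_length)
  n_feat <- rc$tandem_array_count + rc$dispersed_repeat_count
  feat_kind <- c(rep("tandem", rc$tandem_array_count),
                 rep("dispersed", rc$dispersed_repeat_count))
  feat_chrom <- sample(seq_len(n_chroms), n_feat, replace = TRUE,
                       prob = chrom_len)

  seqs <- character(n_chroms)
  names(seqs) <- chrom_names
  feats <- list()
  for (ci in seq_len(n_chroms)) {
    base <- rand_seq(chrom_len[ci])
    idx <- which(feat_chrom == ci)
    if (length(idx) == 0L) { seqs[ci] <- base; next }
    # insertion points >= 1 kb from the ends and >= 2 kb apart, drawn by
    # placing sorted uniforms in the slack left after reserving the gaps
    nf <- length(idx)
    slack <- chrom_len[ci] - 2000 - (nf - 1) * 2000
    if (slack <= nf) stop("could not place repeat features; genome too small")
    pts <- 1000 + sort(sample.int(slack, nf)) + (seq_len(nf) - 1) * 2000
    fseq <- character(length(idx))
    ulen <- integer(length(idx)); ncop <- integer(length(idx))
    for (t in seq_along(idx)) {
      if (feat_kind[idx[t]] == "tandem") {
        u <- rand_int(rc$tandem_unit_range[1], rc$tandem_unit_range[2])
        k <- rand_int(rc$tandem_copy_range[1], rc$tandem_copy_range[2])
        fseq[t] <- strrep(rand_seq(u), k)
        ulen[t] <- u; ncop[t] <- k
      } else {
        fseq[t] <- fam
        ulen[t] <- rc$dispersed_repeat_length; ncop[t] <- 1L
      }
    }
    # splice features in at pts (ascending), tracking the coordinate shift
    pieces <- character(2 * length(pts) + 1)
    prev <- 0L
    for (t in seq_along(pts)) {
      pieces[2 * t - 1] <- substr(base, prev + 1, pts[t])
      pieces[2 * t] <- fseq[t]
      prev <- pts[t]
    }
    pieces[2 * length(pts) + 1] <- substr(base, prev + 1, chrom_len[ci])
    seqs[ci] <- paste(pieces, collapse = "")
    shift <- cumsum(c(0L, nchar(fseq)[-length(fseq)]))
    st <- pts + shift
    feats[[ci]] <- data.frame(chrom = chrom_names[ci], start = st,
                              end = st + nchar(fseq),
                              kind = feat_kind[idx], unit_len = ulen,
                              copies = ncop, stringsAsFactors = FALSE)
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               kind = character(), unit_len = integer(), copies = integer())
  rownames(features) <- NULL
  list(genome = genome("ancestor", seqs), features = features)
}

#' Default line tree
#'
#' A rooted 5-leaf tree in abstract time units, mirroring a study design of
#' one line per continent with one clearly differentiated outgroup line. All
#' root-to-leaf paths have length 2.2 units.
#'
#' @return An [ape::read.tree()] `phylo` object.
#' @export
default_line_tree <- function() {
  ape::read.tree(text = "(((L1:1,L2:1):0.6,(L3:1,L4:1):0.6):0.6,L5:2.2);")
}

#' Default SV class weights
#' @return Named numeric vector over the seven planted SV classes.
#' @export
default_type_weights <- function() {
  c(insertion = 0.34, deletion = 0.34,
    tandem_expansion = 0.07, tandem_contraction = 0.07,
    repeat_expansion = 0.07, repeat_contraction = 0.07,
    inversion = 0.04)
}

sv_classes <- function() names(default_type_weights())

# leaves under each node of an ape phylo, as a list indexed by node number
tips_under <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  out <- vector("list", nnode)
  for (i in seq_len(ntip)) out[[i]] <- tree$tip.label[i]
  # postorder visits children before parents, so sets accumulate bottom-up
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  lapply(out, sort)
}

#' Plant structural variants along a line tree
#'
#' Draws Poisson(rate_per_branch * branch_length) SV events on every branch of
#' `tree`, mutates the ancestor genome accordingly, and propagates each event
#' to all leaves descending from its branch. Insertions, deletions and
#' inversions are placed in unique (non-repeat) sequence; the four copy-number
#' classes change the copy number of recorded tandem arrays, with the copy
#' delta chosen so that the alignment-gap signature of the event matches its
#' class (tandem_* when the changed span is at least the span that remains
#' aligned, repeat_* when it is smaller). All planted loci are pairwise
#' disjoint on the reference and kept at least `min_spacing` bp apart, and
#' indel/inversion junctions are re-drawn until free of flanking
#' micro-homology, so every event has one unambiguous truth locus.
#'
#' @param ancestor result of [simulate_ancestor()].
#' @param tree rooted `phylo` with branch lengths; leaves are line ids.
#' @param rate_per_branch expected SV events per unit branch length.
#' @param size_sampler function(n) returning n sizes in bp; default log-uniform
#'   on 50 bp to 10 kb.
#' @param type_weights named nonnegative weights over SV classes.
#' @param seed integer RNG seed.
#' @param min_spacing minimum bp between planted loci (default 5000, above
#'   typical nick-label spacing so that co-located events cannot confound
#'   optical size measurement).
#' @param min_size minimum SV size in bp (default 50).
#' @param inv_size_range inversion size range in bp (default 10 to 30 kb).
#' @param end_margin minimum distance of a planted locus from a chromosome
#'   end in bp (default 25 kb): detection from label maps needs flanking
#'   aligned labels on both sides, which chromosome ends cannot provide.
#' @param stem_length length of a stem branch between the reference and the
#'   root of the line tree (default 0). Events on the stem are carried by
#'   every line: they model divergence specific to the reference genome, the
#'   source of loci shared by all lines.
#' @return list with `genomes` (named list of leaf [genome()]s) and `truth`, a
#'   data.frame (branch_id, sv_type, chrom, ref_start, ref_end, size_bp,
#'   carriers) with carriers as comma-joined leaf ids; reference (ancestor)
#'   0-based half-open coordinates, insertions as zero-length intervals.
#' @export
plant_svs <- function(ancestor, tree = default_line_tree(), rate_per_branch,
                      size_sampler = NULL, type_weights = default_type_weights(),
                      seed = 1L, min_spacing = 5000L, min_size = 50L,
                      inv_size_range = c(10000L, 30000L),
                      end_margin = 25000L, stem_length = 0) {
  stopifnot(rate_per_branch >= 0, all(type_weights >= 0), any(type_weights > 0),
            inherits(tree, "phylo"), !is.null(tree$edge.length))
  g <- ancestor$genome
  features <- ancestor$features
  if (is.null(size_sampler)) {
    size_sampler <- function(n) round(exp(runif(n, log(50), log(10000))))
  }
  set.seed(seed)
  chrom_len <- genome_lengths(g)
  chroms <- names(g$seqs)
  tipsets <- tips_under(tree)
  ntip <- length(tree$tip.label)

  occ <- data.frame(chrom = character(), start = numeric(), end = numeric())
  arrays <- features[features$kind == "tandem", , drop = FALSE]
  array_used <- rep(FALSE, nrow(arrays))
  free_of_occ <- function(ch, s, e) {
    !any(occ$chrom == ch & occ$start < e + min_spacing &
           occ$end > s - min_spacing)
  }
  feat_free <- function(ch, s, e) {
    !any(features$chrom == ch & features$start < e + 100 &
           features$end > s - 100)
  }
  base_at <- function(ch, pos0) substr(g$seqs[[ch]], pos0 + 1, pos0 + 1)
  comp1 <- c(A = "T", C = "G", G = "C", T = "A")

  # draw the event skeleton for every branch first, then place large events
  # (inversions) before small ones so late placements still find room
  classes <- names(type_weights)
  skel <- list()
  if (stem_length > 0) {
    n_ev <- rpois(1, rate_per_branch * stem_length)
    if (n_ev > 0) {
      for (ty in sample(classes, n_ev, replace = TRUE, prob = type_weights)) {
        skel[[length(skel) + 1]] <- list(type = ty, branch_id = "stem",
                                         carriers = sort(tree$tip.label))
      }
    }
  }
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    branch_id <- paste0("b", e, "_",
                        if (child <= ntip) tree$tip.label[child]
                        else paste0("n", child))
    n_ev <- rpois(1, rate_per_branch * tree$edge.length[e])
    if (n_ev == 0) next
    types <- sample(classes, n_ev, replace = TRUE, prob = type_weights)
    for (ty in types) {
      skel[[length(skel) + 1]] <- list(type = ty, branch_id = branch_id,
                                       carriers = tipsets[[child]])
    }
  }
  # placement order: copy-number events first (their tandem arrays are at
  # fixed positions), then inversions (large), then freely movable indels
  prio <- vapply(skel, function(x) {
    switch(x$type, insertion = 3, deletion = 3, inversion = 2, 1)
  }, numeric(1))
  skel <- skel[order(prio)]
  events <- list()
  for (sk in skel) {
    ty <- sk$type
    {
      ev <- NULL
      if (ty %in% c("insertion", "deletion", "inversion")) {
        L <- if (ty == "inversion") {
          round(runif(1, inv_size_range[1], inv_size_range[2]))
        } else max(min_size, size_sampler(1))
        for (try in 1:2000) {
          ch <- sample(chroms, 1, prob = chrom_len)
          span <- if (ty == "insertion") 0L else L
          if (chrom_len[[ch]] < span + 2 * end_margin + 2) next
          p <- rand_int(end_margin, chrom_len[[ch]] - span - end_margin)
          if (!free_of_occ(ch, p, p + span) || !feat_free(ch, p, p + span)) next
          if (ty == "deletion") {
            # junctions must not extend: first/last deleted base must differ
            # from the base the alignment would otherwise continue into
            if (base_at(ch, p) == base_at(ch, p + L)) next
            if (base_at(ch, p + L - 1) == base_at(ch, p - 1)) next
            ev <- list(type = ty, chrom = ch, start = p, end = p + L,
                       size = L)
          } else if (ty == "insertion") {
            ins <- rand_seq(L)
            alt <- function(b) sample(setdiff(c("A","C","G","T"), b), 1)
            if (substr(ins, 1, 1) == base_at(ch, p)) {
              substr(ins, 1, 1) <- alt(base_at(ch, p))
            }
            if (substr(ins, L, L) == base_at(ch, p - 1)) {
              substr(ins, L, L) <- alt(base_at(ch, p - 1))
            }
            ev <- list(type = ty, chrom = ch, start = p, end = p,
                       size = L, ins_seq = ins)
          } else { # inversion: junctions must not be revcomp-extendable
            if (base_at(ch, p) == comp1[[base_at(ch, p + L - 1)]]) next
            if (base_at(ch, p + L) == comp1[[base_at(ch, p - 1)]]) next
            ev <- list(type = ty, chrom = ch, start = p, end = p + L,
                       size = L)
          }
          break
        }
        if (is.null(ev)) stop("plant_svs: could not place a ", ty,
                              " after bounded attempts")
      } else {
        # copy-number event on a tandem array; the copy delta m*u decides the
        # alignment signature: tandem_* needs delta >= span left aligned,
        # repeat_* needs delta < span left aligned (see vignette)
        S <- max(min_size, size_sampler(1))
        cand <- which(!array_used)
        cand <- cand[vapply(cand, function(i) {
          free_of_occ(arrays$chrom[i], arrays$start[i], arrays$end[i]) &&
            arrays$start[i] >= end_margin &&
            arrays$end[i] <= chrom_len[[arrays$chrom[i]]] - end_margin
        }, logical(1))]
        pick <- NULL
        for (i in cand[sample.int(length(cand))]) {
          u <- arrays$unit_len[i]; k <- arrays$copies[i]; s <- u * k
          lo <- hi <- NA_integer_
          if (ty == "tandem_expansion") {
            lo <- ceiling((s + 50) / u); hi <- lo + ceiling(10000 / u)
          } else if (ty == "repeat_expansion") {
            lo <- ceiling(50 / u); hi <- floor((s - 50) / u)
          } else if (ty == "tandem_contraction") {
            lo <- max(floor(k / 2) + 1, ceiling(50 / u))
            hi <- k - max(1, ceiling(30 / u))
          } else { # repeat_contraction
            lo <- ceiling(50 / u); hi <- floor((k - 1) / 2)
          }
          if (is.na(lo) || lo > hi) next
          m <- min(max(round(S / u), lo), hi)
          pick <- list(i = i, m = m, u = u)
          break
        }
        if (is.null(pick)) {
          stop("plant_svs: no eligible tandem array left for ", ty)
        }
        i <- pick$i
        array_used[i] <- TRUE
        ev <- list(type = ty, chrom = arrays$chrom[i],
                   start = arrays$start[i], end = arrays$end[i],
                   size = pick$m * pick$u, m = pick$m, u = pick$u)
      }
      occ <- rbind(occ, data.frame(chrom = ev$chrom, start = ev$start,
                                   end = ev$end))
      ev$branch_id <- sk$branch_id
      ev$carriers <- sk$carriers
      events[[length(events) + 1]] <- ev
    }
  }

  truth <- if (length(events)) {
    data.frame(
      branch_id = vapply(events, `[[`, "", "branch_id"),
      sv_type = vapply(events, `[[`, "", "type"),
      chrom = vapply(events, `[[`, "", "chrom"),
      ref_start = vapply(events, `[[`, 0, "start"),
      ref_end = vapply(events, `[[`, 0, "end"),
      size_bp = vapply(events, `[[`, 0, "size"),
      carriers = vapply(events, function(x) paste(x$carriers, collapse = ","),
                        ""),
      stringsAsFactors = FALSE)
  } else {
    data.frame(branch_id = character(), sv_type = character(),
               chrom = character(), ref_start = numeric(),
               ref_end = numeric(), size_bp = numeric(),
               carriers = character(), stringsAsFactors = FALSE)
  }

  genomes <- lapply(tree$tip.label, function(leaf) {
    seqs <- g$seqs
    mine <- Filter(function(ev) leaf %in% ev$carriers, events)
    if (length(mine)) {
      ord <- order(vapply(mine, `[[`, "", "chrom"),
                   -vapply(mine, `[[`, 0, "start"))
      for (ev in mine[ord]) {
        s <- seqs[[ev$chrom]]
        n <- nchar(s)
        seqs[[ev$chrom]] <- switch(
          ev$type,
          insertion = paste0(substr(s, 1, ev$start), ev$ins_seq,
                             substr(s, ev$start + 1, n)),
          deletion = paste0(substr(s, 1, ev$start),
                            substr(s, ev$end + 1, n)),
          inversion = paste0(substr(s, 1, ev$start),
                             revcomp_chr(substr(s, ev$start + 1, ev$end)),
                             substr(s, ev$end + 1, n)),
          tandem_expansion = ,
          repeat_expansion = paste0(
            substr(s, 1, ev$start),
            strrep(substr(s, ev$start + 1, ev$start + ev$u), ev$m),
            substr(s, ev$start + 1, n)),
          tandem_contraction = ,
          repeat_contraction = paste0(
            substr(s, 1, ev$start),
            substr(s, ev$start + ev$m * ev$u + 1, n)))
      }
    }
    genome(leaf, seqs)
  })
  names(genomes) <- tree$tip.label
  list(genomes = genomes, truth = truth)
}

#' Simulate a non-overlapping exon annotation
#'
#' Places `n_genes` genes with a random number of fixed-strand exons each,
#' gene footprints non-overlapping, exons disjoint genome-wide.
#'
#' @param genome a [genome()].
#' @param n_genes number of genes.
#' @param exons_per_gene_range integer length-2 range.
#' @param exon_length_range integer length-2 range in bp.
#' @param seed integer RNG seed.
#' @return data.frame (chrom, start, end, gene_id, exon_id) in 0-based
#'   half-open coordinates.
#' @export
simulate_annotation <- function(genome, n_genes,
                                exons_per_gene_range = c(2L, 6L),
                                exon_length_range = c(100L, 400L),
                                seed = 1L) {
  stopifnot(inherits(genome, "genome"), n_genes >= 0)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), gene_id = character(),
                      exon_id = character(), stringsAsFactors = FALSE)
  if (n_genes == 0) return(empty)
  set.seed(seed)
  chrom_len <- genome_lengths(genome)
  max_exon_bp <- exons_per_gene_range[2] * exon_length_range[2]
  if (n_genes * max_exon_bp > 0.8 * sum(chrom_len)) {
    stop("requested exon footprint exceeds genome capacity")
  }
  occ <- lapply(chrom_len, function(...) {
    data.frame(start = numeric(), end = numeric())
  })
  rows <- vector("list", n_genes)
  for (gi in seq_len(n_genes)) {
    placed <- FALSE
    for (try in 1:300) {
      ch <- sample(names(chrom_len), 1, prob = chrom_len)
      ne <- rand_int(exons_per_gene_range[1], exons_per_gene_range[2])
      lens <- rand_int(exon_length_range[1], exon_length_range[2], ne)
      introns <- if (ne > 1) rand_int(200, 2000, ne - 1) else integer(0)
      span <- sum(lens) + sum(introns)
      if (span + 200 >= chrom_len[[ch]]) next
      p <- rand_int(100, chrom_len[[ch]] - span - 100)
      o <- occ[[ch]]
      if (any(o$start < p + span & o$end > p)) next
      occ[[ch]] <- rbind(o, data.frame(start = p, end = p + span))
      st <- p + cumsum(c(0, head(lens, -1) + introns))
      gid <- sprintf("g%04d", gi)
      rows[[gi]] <- data.frame(chrom = ch, start = st, end = st + lens,
                               gene_id = gid,
                               exon_id = sprintf("%s.e%d", gid, seq_len(ne)),
                               stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place gene ", gi, "; genome too crowded")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate noisy nick-site label maps for a genome
#'
#' Produces one label map per chromosome: true motif occurrence positions
#' (both strands), each dropped with probability `miss_prob`, false labels
#' added at `false_per_100kb` per 100 kb (Poisson), and inter-label distances
#' perturbed multiplicatively by Normal(1, `sizing_cv`) then re-accumulated.
#' This emulates a per-line consensus optical map; molecule-level assembly is
#' out of scope.
#'
#' @param genome a [genome()].
#' @param motif 6-mer recognition sequence (default the BssSI site `CACGAG`).
#' @param miss_prob per-label drop probability in `[0, 1]`.
#' @param false_per_100kb expected false labels per 100 kb.
#' @param sizing_cv coefficient of variation of inter-label distances.
#' @param seed integer RNG seed.
#' @return Named list of label maps (one per chromosome); each is a list with
#'   `map_id`, `length_bp` and strictly increasing integer `labels`.
#' @export
simulate_label_map <- function(genome, motif = "CACGAG", miss_prob = 0,
                               false_per_100kb = 0, sizing_cv = 0,
                               seed = 1L) {
  stopifnot(nchar(motif) == 6, miss_prob >= 0, miss_prob <= 1,
            false_per_100kb >= 0, sizing_cv >= 0)
  if (grepl("[^ACGT]", motif)) stop("motif must contain only A, C, G, T")
  set.seed(seed)
  digest <- digest_genome(genome, motif)
  lapply(digest, function(m) {
    L <- m$length_bp
    lab <- m$labels
    if (miss_prob > 0 && length(lab)) lab <- lab[runif(length(lab)) > miss_prob]
    nf <- rpois(1, false_per_100kb * L / 1e5)
    if (nf > 0) lab <- sort(unique(c(lab, sample(0:(L - 1), nf))))
    if (sizing_cv > 0 && length(lab)) {
      gaps <- diff(c(0, lab, L))
      f <- pmax(0.05, rnorm(length(gaps), 1, sizing_cv))
      gaps <- pmax(c(0, rep(1, length(gaps) - 1)), round(gaps * f))
      pos <- cumsum(gaps)
      list(map_id = m$map_id, length_bp = pos[length(pos)],
           labels = pos[-length(pos)])
    } else {
      list(map_id = m$map_id, length_bp = L, labels = lab)
    }
  })
}
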