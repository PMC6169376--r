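#' Default pipeline configuration
#'
#' Every numeric threshold of the analysis is surfaced here: the 50 bp SV
#' floor and 50 kb ceiling, the 500/100 single/clustered match filters, the
#' 1 kb optical size floor and the 3 bp coincidence tolerance, plus the
#' simulation scale (a 5 Mb ancestor, five lines on the default tree,
#' roughly 100 SVs per line — a desk-scale proxy for ~120 Mb assemblies).
#'
#' @param seed integer master seed.
#' @return A nested configuration list (version, seed, simulation,
#'   thresholds, bootstrap, rate).
#' @export
default_config <- function(seed = 1L) {
  list(
    version = 1L,
    seed = as.integer(seed),
    simulation = list(
      genome_size = 5e6,
      n_chroms = 2L,
      tree_newick = "(((L1:1,L2:1):0.6,(L3:1,L4:1):0.6):0.6,L5:2.2);",
      rate_per_branch = 45,
      stem_length = 0.3,
      type_weights = as.list(default_type_weights()),
      size_range = c(50L, 10000L),
      inv_size_range = c(10000L, 30000L),
      min_spacing = 5000L,
      repeat_config = default_repeat_config(),
      annotation = list(n_genes = 300L, exons_per_gene = c(2L, 6L),
                        exon_length = c(100L, 400L)),
      label_map = list(motif = "CACGAG", miss_prob = 0.1,
                       false_per_100kb = 1, sizing_cv = 0.005)
    ),
    thresholds = list(
      min_size = 50L, max_size = 50000L,
      min_match = 500L, min_cluster_match = 100L,
      map_min_size = 1000L, tol = 3L,
      k = 21L, max_gap = 50000L, inversion_min_size = 10000L
    ),
    bootstrap = list(B = 1000L, scales = seq(0.5, 1.4, by = 0.1)),
    rate = list(divergence_my = 2.2)
  )
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return `read_config()` returns the configuration list; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  merge_cfg <- function(a, b) {
    for (k in names(b)) {
      a[[k]] <- if (is.list(a[[k]]) && is.list(b[[k]])) merge_cfg(a[[k]], b[[k]])
      else b[[k]]
    }
    a
  }
  merge_cfg(base, cfg)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

size_sampler_from <- function(size_range) {
  force(size_range)
  function(n) round(exp(runif(n, log(size_range[1]), log(size_range[2]))))
}

#' Simulate the full study inputs
#'
#' Ancestor genome, per-line genomes with planted SVs along the line tree,
#' exon annotation and per-line noisy label maps, with ground truth.
#'
#' @param config configuration list ([default_config()]).
#' @return list (ancestor, features, tree, genomes, truth, exons,
#'   line_maps, ref_maps).
#' @export
simulate_study <- function(config = default_config()) {
  sim <- config$simulation
  anc <- simulate_ancestor(sim$genome_size, sim$n_chroms,
                           sim$repeat_config, seed = config$seed)
  tree <- ape::read.tree(text = sim$tree_newick)
  planted <- plant_svs(anc, tree, sim$rate_per_branch,
                       size_sampler = size_sampler_from(sim$size_range),
                       type_weights = unlist(sim$type_weights),
                       seed = config$seed + 1L,
                       min_spacing = sim$min_spacing,
                       min_size = config$thresholds$min_size,
                       inv_size_range = sim$inv_size_range,
                       stem_length = if (is.null(sim$stem_length)) 0 else
                         sim$stem_length)
  exons <- simulate_annotation(anc$genome, sim$annotation$n_genes,
                               sim$annotation$exons_per_gene,
                               sim$annotation$exon_length,
                               seed = config$seed + 2L)
  lm <- sim$label_map
  line_maps <- lapply(seq_along(planted$genomes), function(i) {
    simulate_label_map(planted$genomes[[i]], lm$motif, lm$miss_prob,
                       lm$false_per_100kb, lm$sizing_cv,
                       seed = config$seed + 10L + i)
  })
  names(line_maps) <- names(planted$genomes)
  list(ancestor = anc$genome, features = anc$features, tree = tree,
       genomes = planted$genomes, truth = planted$truth, exons = exons,
       line_maps = line_maps,
       ref_maps = digest_genome(anc$genome, lm$motif))
}

#' Sequence-based SV calls for one line
#'
#' Unique-anchor alignment, chaining, match-length filtering, gap
#' classification between consecutive blocks, and inversion detection.
#'
#' @param reference,query [genome()] objects.
#' @param line_id line identifier.
#' @param thresholds threshold sub-list of the configuration.
#' @return SV data.frame (`method = "sequence"`).
#' @export
call_line_svs <- function(reference, query, line_id,
                          thresholds = default_config()$thresholds) {
  th <- thresholds
  anchors <- find_unique_anchors(reference, query, k = th$k)
  chains <- chain_anchors(anchors, max_gap = th$max_gap)
  blocks <- filter_alignments(chains, th$min_match, th$min_cluster_match)
  calls <- list()
  for (cid in unique(blocks$chain_id)) {
    ch <- blocks[blocks$chain_id == cid, , drop = FALSE]
    if (ch$strand[1] != "+") next
    calls[[length(calls) + 1]] <- call_between_alignments(
      ch, line_id, th$min_size, th$max_size)
  }
  inv <- detect_inversions(blocks, line_id, th$inversion_min_size)
  res <- do.call(rbind, c(calls, list(inv)))
  if (is.null(res)) res <- sv_records()
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Optical-map SV calls for one line
#'
#' Aligns each per-chromosome line label map to the reference digest and
#' extracts inter-label distance discrepancies of at least the optical size
#' floor.
#'
#' @param ref_maps reference digest maps.
#' @param line_maps the line's label maps (named by chromosome).
#' @param line_id line identifier.
#' @param thresholds threshold sub-list of the configuration.
#' @return SV data.frame (`method = "optical"`).
#' @export
optical_line_svs <- function(ref_maps, line_maps, line_id,
                             thresholds = default_config()$thresholds) {
  out <- lapply(names(ref_maps), function(ch) {
    q <- line_maps[[ch]]
    r <- ref_maps[[ch]]
    if (is.null(q) || length(q$labels) < 2 || length(r$labels) < 2) {
      return(sv_records())
    }
    al <- align_map(q, r)
    detect_map_svs(al, q, r, line_id, thresholds$map_min_size)
  })
  do.call(rbind, out)
}

#' Run the full analysis pipeline on simulated data
#'
#' simulate -> align -> sequence SV calling -> optical SV calling ->
#' cross-validation -> coincidence matrix, sharing and relationship tree ->
#' exon impact -> rate estimate. Deterministic given `config$seed`. When
#' `outdir` is given, every intermediate is written in its documented
#' plain-text format.
#'
#' @param config configuration list ([default_config()]).
#' @param outdir optional output directory.
#' @param run_bootstrap logical; compute BP/AU supports (default TRUE).
#' @param quiet suppress progress messages.
#' @return A run report: list with per-line class/method counts, validation
#'   counts, truth-vs-call scores, sharing statistics, the support tree,
#'   exon impact summaries, the rate estimate, and the configuration.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         run_bootstrap = TRUE, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  th <- config$thresholds
  say("stage simulate: seed ", config$seed)
  study <- simulate_study(config)
  lines <- names(study$genomes)
  say("stage simulate: ", nrow(study$truth), " planted SV events, ",
      length(lines), " lines")

  seq_calls <- list(); opt_calls <- list(); val_calls <- list()
  for (ln in lines) {
    seq_calls[[ln]] <- call_line_svs(study$ancestor, study$genomes[[ln]],
                                     ln, th)
    opt_calls[[ln]] <- optical_line_svs(study$ref_maps, study$line_maps[[ln]],
                                        ln, th)
    val_calls[[ln]] <- cross_validate(seq_calls[[ln]], opt_calls[[ln]],
                                      study$ref_maps)
    say("stage call: ", ln, " sequence=", nrow(seq_calls[[ln]]),
        " optical=", nrow(opt_calls[[ln]]),
        " validated=", nrow(val_calls[[ln]]))
  }
  all_seq <- do.call(rbind, seq_calls)
  all_opt <- do.call(rbind, opt_calls)
  all_val <- do.call(rbind, val_calls)

  score <- evaluate_calls(study$truth, all_seq)
  say("stage evaluate: F1 = ", round(score$f1, 4))

  pm <- match_svs(all_seq, tol = th$tol, lines = lines)
  shares <- if (nrow(pm$mat) > 0) sharing_stats(pm) else NULL
  tree <- NULL
  if (nrow(pm$mat) > 0 && length(lines) >= 2) {
    tree <- if (run_bootstrap) {
      bootstrap_support(pm, B = config$bootstrap$B,
                        scales = config$bootstrap$scales,
                        seed = config$seed + 100L)
    } else cluster_lines(sv_distance(pm))
    say("stage concordance: ", nrow(pm$mat), " loci, shared in all = ",
        if (is.null(shares)) 0 else shares$shared_in_all)
  }

  overlaps <- intersect_exons(all_val, study$exons)
  impact <- exon_impact_summary(overlaps, all_val)

  mean_count <- mean(vapply(seq_calls, nrow, 0))
  rate <- estimate_rate(max(1, round(mean_count)), config$rate$divergence_my,
                        sum(genome_lengths(study$ancestor)) / 1e6)

  report <- list(
    config = config,
    lines = lines,
    per_line_counts = lapply(seq_calls, function(x) table(x$sv_type)),
    per_line_sequence = vapply(seq_calls, nrow, 0),
    per_line_optical = vapply(opt_calls, nrow, 0),
    per_line_validated = vapply(val_calls, nrow, 0),
    truth_score = score,
    n_loci = nrow(pm$mat),
    sharing = shares,
    tree = tree,
    newick = if (!is.null(tree)) write_tree_newick(tree) else NA_character_,
    exon_impact = impact,
    rate = rate)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_genome_fasta(study$ancestor, file.path(outdir, "ancestor.fa"))
    for (ln in lines) {
      write_genome_fasta(study$genomes[[ln]],
                         file.path(outdir, paste0(ln, ".fa")))
      write_svs(seq_calls[[ln]], file.path(outdir, paste0(ln, ".seq_svs.bed")))
      write_svs(opt_calls[[ln]], file.path(outdir, paste0(ln, ".opt_svs.bed")))
      write_svs(val_calls[[ln]],
                file.path(outdir, paste0(ln, ".validated_svs.bed")))
      write_label_maps(study$line_maps[[ln]],
                       file.path(outdir, paste0(ln, ".labels.tsv")))
    }
    write.table(study$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_gff3_exons(study$exons, file.path(outdir, "exons.gff3"))
    write_bed_exons(study$exons, file.path(outdir, "exons.bed"))
    if (nrow(pm$mat) > 0) {
      write_presence_matrix(pm, file.path(outdir, "presence_matrix.tsv"))
    }
    if (!is.null(shares)) {
      write.table(shares$pairwise_percent,
                  file.path(outdir, "sharing_percent.tsv"), sep = "\t",
                  quote = FALSE)
    }
    if (!is.null(tree)) write_tree_newick(tree, file.path(outdir, "tree.nwk"))
    if (nrow(overlaps)) {
      write.table(overlaps, file.path(outdir, "exon_overlaps.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(per_line_sequence = report$per_line_sequence,
           per_line_optical = report$per_line_optical,
           per_line_validated = report$per_line_validated,
           f1 = score$f1,
           n_loci = report$n_loci,
           shared_in_all = if (is.null(shares)) 0 else shares$shared_in_all,
           newick = report$newick,
           rate_per_my_per_mb = rate$rate),
      file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  report
}
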