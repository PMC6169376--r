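#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
#
# Builds the default synthetic study: a 5 Mb two-chromosome ancestor
# (standing in for the reference genome), five derived lines whose genomes
# differ from it by SVs planted along a known 5-leaf tree (~100 SVs per
# line, matching the per-Mb SV density of a fly-line comparison), an exon
# annotation, and per-line noisy nick-label maps. Everything is written in
# plain-text formats under results/study/ together with the ground truth.

library(svconcord)

outdir <- "results/study"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- default_config(seed = 1)
write_config(cfg, file.path(outdir, "config.yaml"))

study <- simulate_study(cfg)

write_genome_fasta(study$ancestor, file.path(outdir, "ancestor.fa"))
for (ln in names(study$genomes)) {
  write_genome_fasta(study$genomes[[ln]], file.path(outdir, paste0(ln, ".fa")))
  write_label_maps(study$line_maps[[ln]],
                   file.path(outdir, paste0(ln, ".labels.tsv")))
}
write_label_maps(study$ref_maps, file.path(outdir, "reference.labels.tsv"))
write.table(study$truth, file.path(outdir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_gff3_exons(study$exons, file.path(outdir, "exons.gff3"))
write_bed_exons(study$exons, file.path(outdir, "exons.bed"))

cat(sprintf(
  "simulated %d planted SV events over %d lines; ancestor %.2f Mb; %d exons\n",
  nrow(study$truth), length(study$genomes),
  sum(genome_lengths(study$ancestor)) / 1e6, nrow(study$exons)))
print(table(study$truth$sv_type))
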