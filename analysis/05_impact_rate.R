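#!/usr/bin/env Rscript
# Stage 5: exonic impact of validated SVs and the SV rate.
#
# Intersects the cross-validated SV calls with the exon annotation (only
# independently confirmed SVs enter the impact analysis), tallies affected
# exons and base pairs per class, and turns the mean per-line SV count into
# a rate per million years per megabase using the simulated divergence.

library(svconcord)

indir <- "results/study"
optdir <- "results/optical"
outdir <- "results/impact"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- read_config(file.path(indir, "config.yaml"))
exons <- read_gff3_exons(file.path(indir, "exons.gff3"))
beds <- list.files(optdir, pattern = "\\.validated_svs\\.bed$",
                   full.names = TRUE)
val <- do.call(rbind, lapply(beds, read_svs))

ov <- intersect_exons(val, exons)
write.table(ov, file.path(outdir, "exon_overlaps.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
imp <- exon_impact_summary(ov, val)
cat("exons touched per line:\n"); print(imp$per_line_exon_count)
cat("exonic SVs by class:\n"); print(imp$per_class_count)
cat("exonic bp affected by class:\n"); print(imp$per_class_bp)
write.table(imp$per_line_class, file.path(outdir, "impact_by_line_class.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

seq_beds <- list.files("results/calls", pattern = "\\.seq_svs\\.bed$",
                       full.names = TRUE)
mean_count <- mean(vapply(seq_beds, function(p) nrow(read_svs(p)), 0))
ref <- read_genome_fasta(file.path(indir, "ancestor.fa"))
rate <- estimate_rate(round(mean_count), cfg$rate$divergence_my,
                      sum(genome_lengths(ref)) / 1e6)
print(rate)
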