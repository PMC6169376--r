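#!/usr/bin/env Rscript
# Stage 4: cross-line SV coincidence and the relationship tree.
#
# Matches SVs across lines with the 3 bp breakpoint tolerance into a
# presence/absence matrix of loci x lines, computes sharing statistics
# (what fraction of each line's SVs each other line carries, and how many
# loci all five share), and clusters the lines by Jaccard distance with
# UPGMA, attaching bootstrap (BP) and approximately unbiased (AU) supports
# from a multiscale bootstrap.

library(svconcord)

calldir <- "results/calls"
outdir <- "results/tree"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

beds <- list.files(calldir, pattern = "\\.seq_svs\\.bed$", full.names = TRUE)
svs <- do.call(rbind, lapply(beds, read_svs))

pm <- match_svs(svs, tol = 3)
write_presence_matrix(pm, file.path(outdir, "presence_matrix.tsv"))
cat(sprintf("%d consensus loci across %d lines\n", nrow(pm$mat),
            length(pm$lines)))

sh <- sharing_stats(pm)
write.table(round(sh$pairwise_percent, 2),
            file.path(outdir, "sharing_percent.tsv"), sep = "\t",
            quote = FALSE)
cat(sprintf("loci shared by all lines: %d\n", sh$shared_in_all))
cat("pairwise sharing (%, row line's SVs found in column line):\n")
print(round(sh$pairwise_percent, 1))

tree <- bootstrap_support(pm, B = 1000, scales = seq(0.5, 1.4, by = 0.1),
                          seed = 1)
nwk <- write_tree_newick(tree, file.path(outdir, "tree.nwk"))
cat("tree (AU/BP as node comments):\n", nwk, "\n")
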