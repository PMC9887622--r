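#!/usr/bin/env Rscript
## Reconstruct ancestral intron presence on the gene tree by Dollo
## parsimony and by the two-state gain/loss Markov model (pruning +
## root-to-tip pass, rates of the generating process), then summarize
## which duplications carried introns in their preduplication state.

library(spliceotrace)

fix <- "results/fixture"
if (!file.exists("results/intron_matrix.tsv")) {
  stop("run analysis/02_map_introns.R first")
}
tree <- read_newick(file.path(fix, "gene_tree.nwk"))
mat <- read_intron_matrix("results/intron_matrix.tsv")

dollo <- dollo_reconstruct(tree, mat[tree$tip.label, , drop = FALSE])
write.table(data.frame(node = rownames(dollo$states), dollo$states,
                       check.names = FALSE),
            "results/dollo_states.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("Dollo: ", ncol(dollo$states), " sites, ", nrow(dollo$losses),
        " loss events across the tree")

L <- 200L  # generator settings of 01_simulate.R
gain_site <- 0.05 * L / (3 * L - 1)
mk <- markov_posterior(tree, mat[tree$tip.label, , drop = FALSE],
                       gain_rate = gain_site, loss_rate = 0.2)
truth <- read_table(file.path(fix, "node_states.tsv"), c(node = "character"))
rownames(truth) <- truth$node
internal <- setdiff(rownames(mk$calls), tree$tip.label)
tm <- as.matrix(truth[internal, colnames(mat)])
storage.mode(tm) <- "integer"
message("Markov internal-state recovery vs truth: ",
        round(mean(mk$calls[internal, ] == tm), 4))

dups <- read_table(file.path(fix, "duplications.tsv"),
                   c(node = "character", class = "character"))
predup <- preduplication_sites(dollo, dups$node)
records <- data.frame(node = dups$node, class = dups$class,
                      n_preduplication = lengths(predup)[dups$node])
summ <- shared_intron_summary(records)
write.table(summ, "results/shared_intron_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(summ))) {
  message(sprintf("%s duplications: %d/%d with preduplication introns (%d%%)",
                  summ$class[i], summ$n_with_shared[i], summ$n_total[i],
                  summ$pct_with_shared[i]))
}
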