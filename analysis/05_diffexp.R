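#!/usr/bin/env Rscript
# Stage 5: differential expression between the domain groups.
#
# Welch tests over the 6647-gene universe, BH adjustment per comparison,
# DEG definition BHp < 0.01 with the 1.35x ratio gate. Top tables are
# ranked by the expression ratio, not by BHp.

library(krtgauge)

axis <- readRDS("scratch/axis.rds")
qc <- readRDS("scratch/qc.rds")
V <- axis$os$matrix

comparisons <- c("D0-D1", "D1-D2", "D2-D3", "D1-D23", "D0-D123",
                 "D123-D4i.1", "D4i.1-D4i.2")
degs <- lapply(comparisons, function(p)
  compare_domains(V, axis$groups, p, universe = qc$universe,
                  alpha = 0.01, rho = qc$gate$rho))
names(degs) <- comparisons
saveRDS(degs, "scratch/degs.rds")

summ <- deg_summary(degs)
write.table(summ, "results/table3_deg_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

topfile <- c("D0-D1" = "results/table4_top_d0_d1.tsv",
             "D123-D4i.1" = "results/table5_top_d123_d4i1.tsv",
             "D4i.1-D4i.2" = "results/table6_top_d4i1_d4i2.tsv")
for (p in names(topfile)) {
  tt <- rbind(cbind(direction = "down", head(degs[[p]]$top_down, 20)),
              cbind(direction = "up", head(degs[[p]]$top_up, 20)))
  write.table(tt, topfile[p], sep = "\t", quote = FALSE, row.names = FALSE)
}

# significant-gene yield by expression level (2000-gene bins over the most
# expressed 8000 genes of the simulated panel)
yield <- bhp_yield_by_expression(V, axis$groups, "D0-D123",
                                 n_quantiles = 4, genes_per_quantile = 2000)
write.table(yield, "results/fig5_bhp_yield.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("ungated down/up DEG counts per comparison:")
for (i in seq_len(nrow(summ)))
  message("  ", summ$comparison[i], ": ", summ$down_all[i], " / ",
          summ$up_all[i], " (ratio ", summ$down_up_ratio[i], ")")
message("BHp-yield per expression bin (high to low): ",
        paste(yield$n_signif, collapse = " / "))
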