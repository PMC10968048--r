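#!/usr/bin/env Rscript
# Stage 4: constancy controls.
#
# Mitochondrial (MT-) and ribosomal (RPS/RPL) family ratios across the
# domain ladder probe cell health and normalisation; their most extreme
# between-domain ratio calibrates the DEG fold-change gate. Sentinel genes
# with a-priori expectations (correlating: ALDH3A1, ALDH1A1, TKT, GJA1,
# KRT3; invariant: EEF1A1, EIF1, ACTG1, ACTB, GAPDH) are reported per
# transition.

library(krtgauge)

study <- readRDS("scratch/study.rds")
axis <- readRDS("scratch/axis.rds")

universe <- select_gene_universe(axis$os$matrix, 6647)
cov <- coverage_fraction(study[[1]]$cm)

fam <- family_ratio_stats(axis$os$matrix, axis$groups, universe = universe)
write.table(fam$stats, "results/table2_family_ratios.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(fam$per_gene, "results/fig3_family_ratios_per_gene.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# gate calibration from the adjacent-pair ratios of the invariant families
adj <- fam$per_gene$ratio[fam$per_gene$pair != "D0vD4i.2"]
gate <- calibrate_ratio_gate(adj)

sent <- sentinel_report(axis$os$matrix, axis$groups, universe = universe)
write.table(sent$report, "results/fig4_sentinels.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

saveRDS(list(universe = universe, gate = gate), "scratch/qc.rds")

message("coverage: ", cov$detected, " of ", cov$probed, " probed genes (",
        cov$percent, "% of the simulated panel's probed count)")
message("family mean ratios span ",
        round(min(fam$stats$mean), 3), "-", round(max(fam$stats$mean), 3),
        "; calibrated ratio gate: ", gate$rho,
        " (reciprocal ", gate$reciprocal, ")")
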