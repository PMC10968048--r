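#!/usr/bin/env Rscript
# Stage 6: trajectory cohorts and gene-gauge correlation.
#
# Genes are classified by their behaviour over the informative transitions
# (continuous down/up, changing only at the start of gauge expression);
# quantile-binned correlations against the gauge are computed on the
# amalgamated axis and within D4, and high-correlation sets are
# intersected across the replicate samples.

library(krtgauge)

study <- readRDS("scratch/study.rds")
prep <- readRDS("scratch/prep.rds")
axis <- readRDS("scratch/axis.rds")
degs <- readRDS("scratch/degs.rds")

cohorts <- classify_trajectory(degs[c("D0-D1", "D123-D4i.1",
                                      "D4i.1-D4i.2")])
counts <- attr(cohorts, "counts")
write.table(cohorts[cohorts$label != "other", ],
            "results/table7_cohorts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# correlation on the pooled axis (20 bins) and the cross-sample
# intersection of high correlators
qp <- quantile_profile(axis$os, n_quantiles = 20)
cc_amalgam <- gauge_correlation(qp)
ccs <- lapply(prep, function(p) {
  os <- order_by_gauge(p$nm, "KRT12")
  gauge_correlation(quantile_profile(os, n_quantiles = 20))
})
hi <- intersect_high_correlation(ccs, cc_min = 0.90)
top <- cc_amalgam[order(-cc_amalgam$cc), ]
top <- rbind(head(top, 25), tail(top[!is.na(top$cc), ], 25))
top$in_cross_sample_intersection <- top$gene %in% hi
write.table(top, "results/table10_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# keratin and early-peak profiles across the 20 quantiles of D4
d4_start <- unname(axis$dp$boundaries["D3"]) + 1L
qp_d4 <- quantile_profile(axis$os, n_quantiles = 20, offset = d4_start)
kp <- keratin_profile(qp_d4)
write.table(data.frame(gene = rownames(kp$trajectories),
                       round(kp$trajectories, 3), cc = round(kp$cc$cc, 3)),
            "results/fig6_keratin_profiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
peak <- data.frame(gene = c("GPHA2", "KRT75"),
                   round(qp_d4$profile[c("GPHA2", "KRT75"), ], 3))
write.table(peak, "results/fig7_gpha2_krt75.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("cohort sizes: ",
        paste(names(counts), counts, sep = "=", collapse = ", "))
message(length(hi), " genes exceed CC 0.90 in all three samples")
message("GPHA2 peaks in D4 quantile ",
        which.max(qp_d4$profile["GPHA2", ]),
        "; KRT75 in quantile ", which.max(qp_d4$profile["KRT75", ]))
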