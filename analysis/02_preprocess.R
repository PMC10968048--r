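#!/usr/bin/env Rscript
# Stage 2: purge non-epithelial cells, trim by mean gene count, normalise.
#
# Cells carrying melanocyte markers (DCT/TYR/TYRP1/MLANA, any nonzero
# count) are removed first — including epithelial-melanocyte duplets —
# then Langerhans, blood and conjunctival (AQP5) cells; remaining cells
# must express KRT5, KRT14 or KRT12. Kept cells are restricted to
# 0.5 < MGC < 2.5 and scaled to unit MGC.

library(krtgauge)

study <- readRDS("scratch/study.rds")
panel <- marker_panel(blood = c("PTPRC", "CD52"), langerhans = "CD207")

prep <- lapply(names(study), function(s) {
  cm <- study[[s]]$cm
  fl <- flag_cells(cm, panel)
  tr <- trim_by_mgc(cm, fl, low = 0.5, high = 2.5)
  list(qc = tr$qc, cm = tr$cm,
       nm = normalize_to_unit_mgc(tr$cm, sample_label = s))
})
names(prep) <- names(study)
saveRDS(prep, "scratch/prep.rds")

acct <- accounting(lapply(prep, function(p) list(qc = p$qc, cm = p$cm)))
write.table(acct, "results/table1_accounting.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

kept <- acct$n[acct$category == "mgc_kept"]
message("kept cells within the MGC limits per sample: ",
        paste(kept, collapse = " / "),
        " (amalgam: ", sum(kept), " cells)")
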