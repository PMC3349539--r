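#!/usr/bin/env Rscript
# Stage 1: estimate the motif-function probability landscape by
# Monte-Carlo parameter sampling and set it against the packaged
# reference table. The estimator's priors are a package choice (the
# original quantification used unpublished parameter ranges), so the
# comparison is qualitative: modal classes and row structure.

library(fflscape)

dir.create("results", showWarnings = FALSE)
seed <- 20120119
n_per_motif <- 400

message("Estimating landscape with ", n_per_motif, " parameter sets per ",
        "motif (seed ", seed, ") ...")
ls <- estimate_landscape(n_per_motif, seed = seed)
write_probability_table(ls, "results/landscape_estimated.csv")
write.csv(ls$excluded, "results/landscape_exclusions.csv",
          row.names = FALSE)

ref <- ffl_reference_table2()
modal_est <- colnames(ls$table)[apply(ls$table, 1, which.max)]
modal_ref <- colnames(ref)[apply(ref, 1, which.max)]
summary <- data.frame(motif = rownames(ls$table),
                      modal_estimated = modal_est,
                      modal_reference = modal_ref,
                      agree = modal_est == modal_ref)
write.csv(summary, "results/landscape_modal_classes.csv",
          row.names = FALSE)

print(ls)
message("Modal classes agree with the reference for ",
        sum(summary$agree), "/8 motifs.")
message("Excluded (no-response/ambiguous/failed) samples: ",
        sum(ls$excluded[, -1]), " of ", 8 * n_per_motif)
message("Wrote results/landscape_estimated.csv")
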