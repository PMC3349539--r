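#!/usr/bin/env Rscript
# Stage 3: mutational robustness and evolvability. Computes robustness
# (diagonal mass) and evolvability E = 1 - R_accumulated / R_single from
# the packaged reference transition matrices, and demonstrates the
# simulation protocol itself on one motif at reduced scale (the
# reference matrices were derived on a different mutation substrate, so
# simulated matrices are qualitative companions, not replacements).

library(fflscape)

dir.create("results", showWarnings = FALSE)

single <- suppressWarnings(ffl_reference_transitions("single"))
acc <- ffl_reference_transitions("accumulated")
E <- mapply(evolvability, single, acc)
tab <- data.frame(motif = names(E),
                  robustness_single = vapply(single, robustness,
                                             numeric(1)),
                  robustness_accumulated = vapply(acc, robustness,
                                                  numeric(1)),
                  evolvability = E)
write.csv(tab, "results/evolvability_reference.csv", row.names = FALSE)
print(tab, digits = 3, row.names = FALSE)
message("Most evolvable motifs: ",
        paste(tab$motif[order(-tab$evolvability)][1:2], collapse = ", "))

# reduced-scale simulated protocol for one motif
cfg <- mutation_config(n_parameter_sets = 60, max_rounds = 25,
                       seed = 20120119)
tm <- transition_matrices("C1", cfg)
write_transition_matrices(list(C1 = tm$single),
                          "results/transitions_C1_single_simulated.csv")
write_transition_matrices(list(C1 = tm$accumulated),
                          "results/transitions_C1_accumulated_simulated.csv")
message(sprintf(
  "Simulated C1 (60 circuits x 25 rounds): R_single = %.3f, R_acc = %.3f, E = %.3f",
  robustness(tm$single), robustness(tm$accumulated),
  suppressWarnings(evolvability(tm))))
message("Note: under parameter-level mutation the accumulated regime can ",
        "drift circuits into *more* robust regions, so simulated E sits ",
        "near (or slightly below) zero; the reference matrices, derived ",
        "on the qualitative-condition substrate, remain the quantitative ",
        "source for E.")
message("Wrote results/evolvability_reference.csv")
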