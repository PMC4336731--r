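#!/usr/bin/env Rscript
# Step 2: fit the two-test cascade on the full simulated cohort.
#
# Trains every eligible subgroup-specific classifier pair (restenosis test on
# the BMS arm, hazard test on the DES arm), selects feature sets and
# operating points by the NPV + PPV objective, scores all candidate
# classification trees and serializes the winning cascade. Resubstitution
# numbers printed here are training-set quantities; honest estimates come
# from step 3.

suppressPackageStartupMessages(library(stentstrat))
args <- commandArgs(trailingOnly = TRUE)
endpoint_h <- if (length(args) >= 1) args[1] else "hazard_3y"

co <- read_cohort("results/cohort.csv")
cascade <- train_cascade(co, "angio_restenosis_6m", endpoint_h)
write_cascade_json(cascade, "results/cascade.json")

cat("selected classification tree (", length(cascade$leaf_ids), "leaves ):\n")
for (id in cascade$leaf_ids) {
  p <- cascade$leaf_pairs[[id]]
  cat(sprintf("  %-20s T_R: (%s,%s) spec level %.2f  NPV %.3f | T_H: (%s,%s) spec level %.2f  PPV %.3f\n",
              id, p$model_R$clinical_set, p$model_R$biomarker_set, p$level_R,
              p$npv_R, p$model_H$clinical_set, p$model_H$biomarker_set,
              p$level_H, p$ppv_H))
}
cat(sprintf("training objective NPV+PPV = %.4f over %d compared trees; %d leaf classifiers fitted\n",
            cascade$objective, cascade$n_trees_compared,
            cascade$n_leaf_classifiers))
cat("wrote results/cascade.json\n")
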