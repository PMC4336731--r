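#!/usr/bin/env Rscript
# Step 4: per-patient cost comparison and the stent-cost sensitivity grid.
#
# Applies the cost model to the serialized cascade's held-out effectiveness
# (a single stratified split here; CV-level cost distributions come from
# step 3) and sweeps BMS/DES procedure costs +/-25% in 1.25% steps.

suppressPackageStartupMessages(library(stentstrat))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

co <- read_cohort("results/cohort.csv")
cascade <- read_cascade_json("results/cascade.json")
set.seed(seed)
test_idx <- sample(nrow(co), round(0.3 * nrow(co)))
train <- co[-test_idx, ]; test <- co[test_idx, ]
cascade <- train_cascade(train, cascade$endpoint_r, cascade$endpoint_h)
ev <- evaluate_cascade(cascade, test)
ct <- cost_table()
cst <- estimate_costs(ev, ct)

tab <- data.frame(
  quantity = c("initial_baseline", "initial_proposed",
               "corrective_baseline", "corrective_proposed",
               "total_savings", "savings_pct"),
  value = c(cst$initial_baseline, cst$initial_proposed,
            cst$corrective_baseline, cst$corrective_proposed,
            cst$total_savings, cst$savings_pct))
write.csv(tab, "results/costs.csv", row.names = FALSE)
print(tab, row.names = FALSE)

g <- sensitivity_grid(ev, ct)
grid_df <- data.frame(bms_cost = rep(g$bms_costs, times = length(g$des_costs)),
                      des_cost = rep(g$des_costs, each = length(g$bms_costs)),
                      savings = as.vector(g$savings))
write.csv(grid_df, "results/cost_sensitivity_grid.csv", row.names = FALSE)
cat(sprintf("\nsensitivity grid: savings range %.0f to %.0f USD over BMS %.0f-%.0f / DES %.0f-%.0f\n",
            min(g$savings), max(g$savings), min(g$bms_costs), max(g$bms_costs),
            min(g$des_costs), max(g$des_costs)))
cat("wrote results/costs.csv and results/cost_sensitivity_grid.csv\n")
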