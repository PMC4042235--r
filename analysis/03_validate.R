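#!/usr/bin/env Rscript
# Validate the fitted model: training r2/F/standard errors, leave-one-out
# q2, external pred_r2 on the held-out compounds, and a 100-permutation
# Y-randomization with Z-scores and normal-curve areas. Writes
# results/validation.json and a flat randomization table.

suppressMessages(library(fieldqsar))

mols <- read_molecules("results/series/molecules.sdf", "sdf")
acts <- read_activities("results/series/activities.csv")
mols <- lapply(mols, assign_peoe_charges)
grid <- with(jsonlite::read_json("results/series/grid.json", simplifyVector = TRUE),
             grid_spec(origin, spacing, counts))
m <- filter_invariant_columns(assemble_descriptor_matrix(mols, acts, grid), 0.1)
split <- activity_ranked_split(m, n_test = 5)
model <- read_model_json("results/model.json")

report <- validate_model(m, split, model, n_permutations = 100, seed = 42)
print(report)
write_validation_report(report, "results/validation.json",
                        "results/randomization.csv")

cat("\nValidity thresholds: r2, q2 > 0.6 and pred_r2 > 0.5\n")
cat(sprintf("  r2 = %.4f  q2 = %.4f  pred_r2 = %.4f  =>  %s\n",
            report$r2, report$q2, report$pred_r2,
            if (report$r2 > 0.6 && report$q2 > 0.6 && report$pred_r2 > 0.5)
              "model accepted" else "model rejected"))
if (!is.null(report$z_scores)) {
  cat("\nY-randomization:\n")
  for (nm in names(report$z_scores))
    cat(sprintf("  Z(%s) = %.4f  (%.2f%% of the normal curve)\n",
                nm, report$z_scores[[nm]], report$normal_areas[[nm]]))
}
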