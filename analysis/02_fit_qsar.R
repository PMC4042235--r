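#!/usr/bin/env Rscript
# Rebuild the descriptor matrix from the serialized series (through the same
# readers a real dataset would use), split it, check the split with
# unicolumn statistics, select four descriptors stepwise-forward, and fit
# the PLS model. Writes the model equation and the unicolumn/contribution
# tables under results/.

suppressMessages(library(fieldqsar))

mols <- read_molecules("results/series/molecules.sdf", "sdf")
acts <- read_activities("results/series/activities.csv")
mols <- lapply(mols, assign_peoe_charges)
grid <- with(jsonlite::read_json("results/series/grid.json", simplifyVector = TRUE),
             grid_spec(origin, spacing, counts))

full <- assemble_descriptor_matrix(mols, acts, grid)
m <- filter_invariant_columns(full, variance_cutoff = 0.1)
cat(sprintf("Descriptors: %d -> %d after removing invariable columns\n",
            ncol(full$values), ncol(m$values)))

split <- activity_ranked_split(m, n_test = 5)
uni <- unicolumn_report(m, split)
write.csv(uni, "results/unicolumn.csv", row.names = FALSE)
print(uni, digits = 4)
interp <- check_split_interpolative(m$activities[split$train_ids],
                                    m$activities[split$test_ids])
cat("Test set interpolative:", isTRUE(interp), "\n\n")

selected <- stepwise_forward_select(m, split, max_descriptors = 4)
cat("Stepwise-forward selection (q2 trace):\n")
print(round(attr(selected, "q2_trace"), 4))

model <- fit_pls(m, split, selected, max_components = 4)
print(model)
write_model_json(model, "results/model.json")

contrib <- contribution_percentages(model, m, split)
write.csv(data.frame(descriptor = names(contrib),
                     contribution_percent = unname(contrib)),
          "results/contributions.csv", row.names = FALSE)
cat("\nDescriptor contributions (%):\n")
print(round(contrib, 2))

truth <- jsonlite::read_json("results/series/truth.json", simplifyVector = TRUE)
cat("\nPlanted descriptors were:", paste(truth$informative_descriptors,
                                         collapse = ", "), "\n")
cat("Recovered:", paste(intersect(selected, truth$informative_descriptors),
                        collapse = ", "), "\n")
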