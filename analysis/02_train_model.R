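#!/usr/bin/env Rscript
# Step 2: train the gene-pair risk model on the largest cohort.
#
# Cohort 1 is split 2:1 into a training set and an internal validation set.
# The full nested pipeline (gene screening -> gene LASSO -> pair construction
# -> prevalence filter -> per-pair FDR -> pair LASSO -> maximally selected
# cutpoint) runs on the training set only; the validation third is never seen
# during selection and provides a first unbiased concordance estimate.
#
# Usage: Rscript analysis/02_train_model.R   (after 01_simulate_cohorts.R)
# Writes: results/model.json, results/train_stage_counts.tsv,
#         results/internal_validation.tsv

suppressPackageStartupMessages(library(pairstage))

data_dir <- "results/data"
dir.create("results", showWarnings = FALSE)

expr <- read_expression(file.path(data_dir, "cohort_1_expression.tsv"))
clin <- read_clinical(file.path(data_dir, "cohort_1_clinical.tsv"))
al <- align_samples(expr, clin)

# deterministic 2:1 split stratified by event status
set.seed(20260102)
ev <- al$clinical$os_event
train_idx <- sort(unlist(lapply(split(seq_along(ev), ev), function(ix)
  sample(ix, round(2 / 3 * length(ix))))))
valid_idx <- setdiff(seq_along(ev), train_idx)
cat(sprintf("cohort 1 split: %d train / %d validation (events %d / %d)\n",
            length(train_idx), length(valid_idx),
            sum(ev[train_idx]), sum(ev[valid_idx])))

# the whole simulated panel is the candidate (cell-death) gene set
candidates <- rownames(al$expression)

model <- train_cell_death_model(
  al$expression[, train_idx],
  al$clinical[train_idx, ],
  candidate_genes = candidates,
  config = cd_config(seed = 20260103))

print(model)
write_model(model, "results/model.json")

sc <- model$provenance$stage_counts
utils::write.table(data.frame(stage = names(sc), count = unlist(sc)),
                   "results/train_stage_counts.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# internal validation: concordance on the held-out third
rk <- compute_risk_scores(model, al$expression[, valid_idx])
cc <- harrell_cindex(rk$risk_score, al$clinical$os_time[valid_idx],
                     al$clinical$os_event[valid_idx])
print(cc)
utils::write.table(
  data.frame(set = "cohort_1_validation", n = length(valid_idx),
             c_index = cc$c_index, se = cc$se,
             lo95 = cc$c_index - 1.96 * cc$se,
             hi95 = cc$c_index + 1.96 * cc$se),
  "results/internal_validation.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)

# how much of the simulated truth was recovered (possible only because the
# data are synthetic; real analyses skip this block)
truth <- utils::read.delim(file.path(data_dir, "true_pairs.tsv"))
model_genes <- unique(c(model$pairs$anchor, model$pairs$partner))
recovery <- mean(truth$anchor %in% model_genes | truth$partner %in% model_genes)
cat(sprintf("true-pair recovery (either gene selected): %.0f%%\n",
            100 * recovery))
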