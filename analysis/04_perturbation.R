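#!/usr/bin/env Rscript
# Degree of Biochemical Perturbation: per-sample mean absolute z-deviation
# from the no-steatosis reference, the >2 SD perturbed rule, and per-marker
# perturbation fold differences.

library(bioperturb)

panel <- read_panel("results/panel.csv")
dbp <- classify_perturbed(dbp_scores(panel))

write.csv(data.frame(sample_id = names(dbp$sample_score),
                     group = dbp$group, score = unname(dbp$sample_score),
                     perturbed = unname(dbp$perturbed)),
          "results/dbp_scores.csv", row.names = FALSE,
          fileEncoding = "UTF-8")
ft <- dbp_fold_table(dbp)
write.csv(ft, "results/dbp_fold.csv", row.names = FALSE,
          fileEncoding = "UTF-8")

mw <- mann_whitney(dbp$sample_score[dbp$group == "case"],
                   dbp$sample_score[dbp$group == "control"])
cat(sprintf("DBP score: control median %.2f, case median %.2f (Mann-Whitney p %.2g)\n",
            median(dbp$sample_score[dbp$group == "control"]),
            median(dbp$sample_score[dbp$group == "case"]), mw$p_raw))
cat(sprintf("perturbed (> %.2f): %d/36 controls, %d/36 cases\n",
            dbp$threshold, sum(dbp$perturbed[dbp$group == "control"]),
            sum(dbp$perturbed[dbp$group == "case"])))
cat(sprintf("markers with Holm-significant perturbation: %s\n",
            paste(ft$marker[ft$significant], collapse = ", ")))
cat("wrote results/dbp_scores.csv, dbp_fold.csv\n")
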