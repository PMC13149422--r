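#!/usr/bin/env Rscript
# Phenotype-side analysis on a simulated pot experiment: treatment percent
# changes, shoot P content, PUE, STI, delta-RDM contrast groups, the
# STI(SDM) ~ STI(RDM) Spearman correlation, and the two-way ANOVA with a
# replicate block. Also reproduces the percent-change arithmetic from the
# published treatment means.

suppressMessages(library(phosgwas))
dir.create("results", showWarnings = FALSE)

# arithmetic reproductions from published means
cat(sprintf("published SDM 4.82 -> 3.68 g: %.1f%% reduction\n",
            -percent_change(4.82, 3.68)))
cat(sprintf("published RDM 1.43 -> 1.10 g: %.1f%% reduction\n",
            -percent_change(1.43, 1.10)))
cat(sprintf("published PUE (0.30,0.28) -> (0.40,0.40): %.1f%% increase\n",
            percent_change(mean(c(0.30, 0.28)), mean(c(0.40, 0.40)))))

tab <- simulate_pot_experiment(n_accessions = 200, seed = 7)
m <- function(tr, tx) mean(tab$value[tab$trait == tr & tab$treatment == tx])
cat(sprintf("simulated SDM: HP %.2f, LP %.2f (%.1f%%); RDM: HP %.2f, LP %.2f (%.1f%%)\n",
            m("SDM", "HP"), m("SDM", "LP"),
            percent_change(m("SDM", "HP"), m("SDM", "LP")),
            m("RDM", "HP"), m("RDM", "LP"),
            percent_change(m("RDM", "HP"), m("RDM", "LP"))))

idx <- efficiency_indices(tab)
write.table(idx, "results/04_efficiency_indices.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PUE: HP %.3f, LP %.3f g DM / mg P (%.1f%% change)\n",
            mean(idx$PUE_HP), mean(idx$PUE_LP),
            percent_change(mean(idx$PUE_HP), mean(idx$PUE_LP))))
cat(sprintf("Spearman rho STI(SDM) ~ STI(RDM): %.2f\n",
            spearman_rho(idx$STI_SDM, idx$STI_RDM)))

groups <- delta_rdm_groups(tab, n_extreme = 30, n_pick = 10)
write.table(groups, "results/04_delta_rdm_groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("delta-RDM groups: %d high, %d low of %d ranked accessions\n",
            sum(groups$group == "High dRDM"), sum(groups$group == "Low dRDM"),
            nrow(groups)))

# ANOVA on the 20-accession subset, SDM
sub <- tab[tab$accession_id %in%
             groups$accession_id[groups$group != "none"], ]
sub$group <- groups$group[match(sub$accession_id, groups$accession_id)]
p <- anova_two_way(sub, trait = "SDM")
cat("ANOVA (SDM): ",
    paste(sprintf("%s p=%.3g", names(p), p), collapse = "; "), "\n")
write.table(data.frame(term = names(p), p_value = unname(p)),
            "results/04_anova_sdm.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
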