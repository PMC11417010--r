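#!/usr/bin/env Rscript
# Site filtering and population-structure summaries on the synthetic dataset:
# call-rate / MAF / heterozygosity filters, IBS distances, PCoA, PERMANOVA,
# per-sample heterozygosity and Hudson FST. Mirrors the structure stage of
# the two-bay study; outputs TSV tables under results/.

library(jointsfs)

gm <- read_genotype_vcf("results/synthetic_bays.vcf",
                        "results/synthetic_bays.popmap.tsv")
message("loaded: ", n_sites(gm), " SNPs, ", nrow(gm$calls), " samples")

cfg <- site_filter_config(min_call_fraction = 0.75, min_maf = 0.025,
                          max_het_fraction = 0.5)
flt <- apply_site_filters(gm, cfg)
message("after filters: ", n_sites(flt), " SNPs")
write.table(attr(flt, "audit"), "results/site_audit.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_vcf(flt, "results/synthetic_bays.filtered.vcf")

D <- ibs_distance(flt)
pc <- pcoa(D)
coords <- data.frame(id = rownames(pc$coordinates),
                     deme = flt$samples$deme,
                     pc$coordinates[, 1:4])
write.table(coords, "results/pcoa_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("PCoA axis 1 explains ",
        round(100 * pc$prop_variance[1], 2), "% of positive-eigenvalue variance")

pm <- permanova(D, flt$samples$deme, n_perm = 999, seed = 1)
print(pm)
write.table(data.frame(R2 = pm$R2, pseudo_F = pm$pseudo_F,
                       p_value = pm$p_value, n_perm = pm$n_permutations),
            "results/permanova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

het <- sample_heterozygosity(flt)
write.table(data.frame(id = names(het), deme = flt$samples$deme,
                       heterozygosity = het),
            "results/heterozygosity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

fst <- fst_hudson(flt)
message(sprintf("weighted global FST = %.6f", fst$global))
write.table(fst$per_site, "results/fst_per_site.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(sprintf("global_weighted_fst\t%.8f", fst$global),
           "results/fst_global.tsv")
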