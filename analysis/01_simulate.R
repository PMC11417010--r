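#!/usr/bin/env Rscript
# Generate the synthetic two-bay dataset that stands in for the bonnethead
# shark 2bRAD genotypes: 20 + 69 diploids over tens of thousands of short
# tags, under the best-fit demographic history (ancestral growth, recent
# split, one-way Tampa Bay -> Biscayne Bay gene flow), with uniform
# missingness. Writes VCF + population map + truth record under results/.

library(jointsfs)

dir.create("results", showWarnings = FALSE)
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

cfg <- bonnethead_preset(seed = seed)
message("simulating ", cfg$n_contigs, " tags x ", sum(cfg$deme_sizes),
        " diploids ...")
sim <- emit_genotype_matrix(cfg)
print(sim$gm)
print(sim$truth)

write_vcf(sim$gm, "results/synthetic_bays.vcf")
write_popmap(sim$gm$samples, "results/synthetic_bays.popmap.tsv")
write_truth_yaml(sim$truth, "results/synthetic_bays.truth.yaml")
message("wrote results/synthetic_bays.{vcf,popmap.tsv,truth.yaml}")
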