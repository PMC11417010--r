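#!/usr/bin/env Rscript
# Build the folded joint SFS from the (call-rate filtered only) genotypes:
# the MAF filter is deliberately NOT applied here, because rare alleles are
# exactly what the SFS models. Projects both demes down to equal haploid
# sizes, folds, and writes the spectrum plus 100 contig-bootstrap replicates.

library(jointsfs)

gm <- read_genotype_vcf("results/synthetic_bays.vcf",
                        "results/synthetic_bays.popmap.tsv")
# the SFS stage keeps low-frequency variants: call-rate filter only
flt <- apply_site_filters(gm, site_filter_config(min_call_fraction = 0.75,
                                                 min_maf = 0,
                                                 max_het_fraction = 0.5))
message("sites entering the SFS: ", n_sites(flt))

# projection to 36 genomes per deme, as in the two-bay analysis
proj <- c(36, 36)
sfs <- observed_sfs(flt, proj[1], proj[2])
folded <- fold_sfs(sfs)
print(folded)
write_sfs(folded, "results/observed_36x36_folded.fs")

dir.create("results/bootstraps", showWarnings = FALSE)
boots <- bootstrap_contigs(flt, proj[1], proj[2], B = 100, seed = 42)
for (b in seq_along(boots)) {
  write_sfs(fold_sfs(boots[[b]]),
            sprintf("results/bootstraps/boot_%03d.fs", b))
}
message("wrote results/observed_36x36_folded.fs and 100 bootstrap spectra")

# a smaller 12x12 projection used by the model-fitting stage (faster, and
# the seven catalog models have at most 7 free parameters)
small <- fold_sfs(observed_sfs(flt, 12, 12))
write_sfs(small, "results/observed_12x12_folded.fs")
dir.create("results/bootstraps_12", showWarnings = FALSE)
boots12 <- bootstrap_contigs(flt, 12, 12, B = 100, seed = 42)
for (b in seq_along(boots12)) {
  write_sfs(fold_sfs(boots12[[b]]),
            sprintf("results/bootstraps_12/boot_%03d.fs", b))
}
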