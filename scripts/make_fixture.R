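#!/usr/bin/env Rscript
# Regenerates the packaged synthetic fixture under inst/extdata/.
# Run from the repository root with the package loadable (devtools).
# The fixture is seed-fixed (seed 20200807) and validated for internal
# coherence: planted QC violators, and only they, fail the QC cascade.

suppressMessages(devtools::load_all(".", quiet = TRUE))

cfg <- sim_config(
  n_genes = 200, n_proteins = 60, n_terms = 30,
  de_fraction = 0.15, effect_log2fc = 2, nb_dispersion = 0.05,
  lib_size_mean = 2e5, lib_size_cv = 0.1,
  peptide_cv_percent = 10, peptides_mean = 6, rep_log2_sd = 0.04,
  regulated_fraction = 0.4,
  n_enriched_terms = 3, enriched_odds_ratio = 10,
  seed = 20200807
)

rna <- simulate_counts(cfg)
tmt <- simulate_tmt(cfg)
ann <- simulate_annotations(cfg, rna$truth$gene_id, rna$truth$is_de)

# --- coherence checks: the shipped truth must describe the shipped data
pr <- run_proteomics(tmt$records, contaminants = "^CON_", seed = 1)
planted <- tmt$truth[tmt$truth$qc_violation_label != "none", ]
con <- planted$accession[planted$qc_violation_label == "contaminant"]
stopifnot(setequal(pr$contaminants_removed, con))
viol <- planted[planted$qc_violation_label != "contaminant", ]
stopifnot(setequal(pr$excluded$accession, viol$accession))
m <- merge(pr$excluded, viol, by = "accession")
stopifnot(all(m$reason == m$qc_violation_label))
clean_reg <- tmt$truth[tmt$truth$qc_violation_label == "none" &
                         tmt$truth$planted_regulated, ]
called <- pr$profiles$accession[pr$profiles$regulated]
stopifnot(setequal(called, clean_reg$accession))
message("fixture coherence checks passed")

outdir <- file.path("inst", "extdata")
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
w <- function(x, f) utils::write.table(
  x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)

write_counts(rna$counts, file.path(outdir, "fixture_counts.tsv"))
w(rna$design, "fixture_samples.tsv")
w(rna$truth, "fixture_rna_truth.tsv")
rec <- tmt$records
for (ch in paste0("tmt", 126:131)) rec[[ch]] <- signif(rec[[ch]], 7)
w(rec, "fixture_proteins.tsv")
w(tmt$truth, "fixture_protein_truth.tsv")
w(ann$annotations, "fixture_annotations.tsv")
w(ann$truth, "fixture_annotation_truth.tsv")
writeLines("^CON_", file.path(outdir, "fixture_contaminants.txt"))
message("fixture written to ", outdir)
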