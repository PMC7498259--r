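# Small builders for constructed (non-simulated) test inputs.

# Long-form peptide records for one or more proteins with reporter values
# chosen directly; `channels` is a named list of 6-vectors per peptide.
make_records <- function(accession, channels, gene_symbol = accession) {
  ch_names <- paste0("tmt", 126:131)
  rows <- lapply(seq_along(channels), function(i) {
    v <- channels[[i]]
    stats::setNames(as.list(v), ch_names)
  })
  d <- dplyr::bind_rows(rows)
  tibble::tibble(accession = rep(accession, length(channels)),
                 gene_symbol = rep(gene_symbol, length(channels)),
                 peptide_id = sprintf("%s_p%d", accession,
                                      seq_along(channels))) |>
    dplyr::bind_cols(d)
}

# Protein profile rows with directly specified summary fields, matching
# the summarize_protein() column layout (per-replicate log2 ratios are
# derived from the requested means and discordances).
make_profile <- function(accession = "P1", n_peptides = 5,
                         mean_l2 = c(d3_d1 = 0, d7_d1 = 0, d7_d3 = 0),
                         disc = c(d3_d1 = 0, d7_d1 = 0, d7_d3 = 0),
                         cv = 10) {
  out <- tibble::tibble(accession = accession, gene_symbol = accession,
                        n_peptides = n_peptides)
  for (cc in c("d3_d1", "d7_d1", "d7_d3")) {
    a <- mean_l2[[cc]] + disc[[cc]] / 2
    b <- mean_l2[[cc]] - disc[[cc]] / 2
    out[[paste0("ratio_", cc, "_A")]] <- 2^a
    out[[paste0("ratio_", cc, "_B")]] <- 2^b
    out[[paste0("l2_", cc, "_A")]] <- a
    out[[paste0("l2_", cc, "_B")]] <- b
    out[[paste0("cv_", cc, "_A")]] <- cv
    out[[paste0("cv_", cc, "_B")]] <- cv
    out[[paste0("mean_l2_", cc)]] <- mean_l2[[cc]]
    out[[paste0("disc_", cc)]] <- abs(disc[[cc]])
  }
  out
}
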