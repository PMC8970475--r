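#!/usr/bin/env Rscript
# OPTIONAL, NETWORKED helper (not part of the test suite): downloads the
# dystrophin (DMD) reference CDS (NM_004006) from NCBI efetch and reports
# its zero-codons and extremely biased codons. Expected result: no
# zero-codons under the family_present policy, and exactly the four GC-rich
# codons UCG, CCG, ACG, GCG under the default redundancy-based cutoff.
# Usage: Rscript scripts/fetch_dmd.R [out.fasta]

suppressPackageStartupMessages(library(codonfp))

args <- commandArgs(trailingOnly = TRUE)
out <- if (length(args) >= 1) args[1] else "scratch/dmd_cds.fasta"
dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)

url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?",
              "db=nuccore&id=NM_004006&rettype=fasta_cds_na&retmode=text")
message("fetching DMD CDS (NM_004006) from NCBI ...")
utils::download.file(url, out, quiet = TRUE)

res <- cds_bias_summary(out)
cat("CDS length (codons):", res$gene_length_codons, "\n")
cat("zero-codons (family_present):",
    if (length(res$zero_codons) == 0) "none" else
      paste(res$zero_codons, collapse = ", "), "\n")
cat("extremely biased codons (t(d) = 0.5/d):",
    paste(res$extremely_biased, collapse = ", "), "\n")
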