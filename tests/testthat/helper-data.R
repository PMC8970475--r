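# Fixture builders: everything is generated in code at test time.

CODE <- build_genetic_code()
sense_degeneracy_vec <- codonfp:::sense_degeneracy(CODE)
sense_aa_vec <- codonfp:::sense_amino_acid(CODE)

# write a small cohort to temp FASTA + metadata and read it back through
# the validated I/O path
make_cds_set <- function(accession, sequence,
                         gene_id = accession,
                         species = "Homo_sapiens",
                         tissue = "muscle",
                         cohort = "DC",
                         exon_count = seq_along(accession),
                         expression_class = NA_character_,
                         permissive = FALSE) {
  n <- length(accession)
  df <- data.frame(accession = accession, gene_id = rep_len(gene_id, n),
                   species = rep_len(species, n), tissue = rep_len(tissue, n),
                   cohort = rep_len(cohort, n),
                   exon_count = rep_len(exon_count, n),
                   expression_class = rep_len(expression_class, n),
                   stringsAsFactors = FALSE)
  fa <- tempfile(fileext = ".fasta")
  md <- tempfile(fileext = ".tsv")
  writeLines(paste0(">", accession, "\n", sequence), fa)
  utils::write.table(df, md, sep = "\t", quote = FALSE, row.names = FALSE)
  read_cds_fasta(fa, md, permissive = permissive)
}

# one low/high fingerprint-pair trial: returns zero-codon totals of both
# cohorts and the adjusted Rand index of the 2-cluster row cut against the
# cohort labels
fingerprint_trial <- function(seed, n_genes = 20, len = 400,
                              concentration = 0.9, code = CODE) {
  base <- cohort_spec(n_genes = n_genes, length_range = c(len, len),
                      seed = seed, code = code)
  pair <- generate_fingerprint_pair(base, concentration = concentration,
                                    code = code)
  recs <- rbind(pair$low$records, pair$high$records)
  class(recs) <- c("cds_set", "data.frame")
  counts <- count_cohort(recs, code)
  z_low <- sum(vapply(counts[pair$low$records$gene_id], function(cc)
    length(zero_codons(cc, code)$zero_codons), integer(1)))
  z_high <- sum(vapply(counts[pair$high$records$gene_id], function(cc)
    length(zero_codons(cc, code)$zero_codons), integer(1)))
  profiles <- lapply(counts, cu_values, code = code)
  mat <- build_matrix(profiles,
                      stats::setNames(recs$exon_count, recs$gene_id),
                      code = code)
  cl <- cut_clusters(complete_linkage(euclidean_distance(mat, "rows")), 2)
  truth <- stats::setNames(recs$cohort, recs$gene_id)[names(cl)]
  list(z_low = z_low, z_high = z_high,
       ari = mclust::adjustedRandIndex(cl, truth),
       pair = pair, mat = mat, recs = recs)
}
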