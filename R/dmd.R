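# Convenience check for the dystrophin (DMD) rare-codon result: DMD keeps
# every codon type in use (no zero-codons under the family_present policy)
# and only four extremely biased, GC-rich codons (UCG, CCG, ACG, GCG) under
# the redundancy-based cutoff. The CDS itself is not shipped; fetch it with
# scripts/fetch_dmd.R (network) or supply any local CDS FASTA.

#' Zero-codon and extreme-bias summary for one CDS
#'
#' Reads a single-record CDS FASTA (e.g. the DMD transcript NM_004006
#' fetched by `scripts/fetch_dmd.R`), and reports its zero-codons and
#' extremely biased codons under the default redundancy-based cutoff.
#'
#' @param fasta_path path to a FASTA holding exactly one CDS.
#' @param cutoff optional per-degeneracy cutoff override, see
#'   [extremely_biased_codons()].
#' @param permissive passed to the validator.
#' @return list with `gene_length_codons`, `zero_codons` (family_present
#'   policy) and `extremely_biased`.
#' @export
cds_bias_summary <- function(fasta_path, cutoff = NULL, permissive = FALSE) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  stopifnot(length(seqs) == 1L)
  seq <- chartr("T", "U", toupper(as.character(seqs[[1]])))
  if (nchar(seq) %% 3L != 0L) {
    stop("CDS length is not a multiple of 3", call. = FALSE)
  }
  if (!permissive && has_internal_stop(seq)) {
    stop("CDS has an internal in-frame stop codon", call. = FALSE)
  }
  code <- build_genetic_code()
  cc <- count_codons(seq, sub("\\s.*$", "", names(seqs)[1]), code)
  prof <- cu_values(cc, code)
  list(gene_length_codons = nchar(seq) %/% 3L,
       zero_codons = zero_codons(cc, code)$zero_codons,
       extremely_biased = extremely_biased_codons(prof, code, cutoff))
}
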