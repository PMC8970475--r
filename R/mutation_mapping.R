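# "Mapping-on-codons": place coding substitutions on the reference codon
# they alter, classify the consequence under the standard code, and tabulate
# per-codon-type mutation burden against CU values.
#
# Variants are tallied against the REFERENCE codon type (the codon that is
# the site of the mutation), not the mutant codon. Synonymous and stop-loss
# changes are classified but excluded from the tallies with explicit
# reasons, matching the missense + nonsense scope of the analysis.

#' Codon number and offset of a CDS position
#'
#' @param cds_pos 1-based position(s) within the CDS.
#' @return data.frame with `codon_number` (1-based) and `offset` (0..2).
#' @examples
#' codon_index(c(1, 3, 4))
#' @export
codon_index <- function(cds_pos) {
  cds_pos <- as.integer(cds_pos)
  stopifnot(all(cds_pos >= 1L))
  data.frame(codon_number = (cds_pos - 1L) %/% 3L + 1L,
             offset = (cds_pos - 1L) %% 3L)
}

#' Classify a single-base codon substitution
#'
#' Translates the reference and substituted codons under the standard code:
#' sense-to-stop is `nonsense`, stop-to-sense is `stop_loss`, an unchanged
#' product (including stop-to-stop) is `synonymous`, and any other
#' amino-acid change is `missense`.
#'
#' @param ref_codon reference codon (RNA triplet).
#' @param offset position within the codon, 0..2.
#' @param alt_base the substituted base.
#' @param code a `genetic_code`.
#' @return one of `"missense"`, `"nonsense"`, `"synonymous"`, `"stop_loss"`.
#' @examples
#' classify_substitution("GAA", 0, "U")  # nonsense (UAA)
#' classify_substitution("GAA", 1, "U")  # missense (GUA)
#' @export
classify_substitution <- function(ref_codon, offset, alt_base,
                                  code = build_genetic_code()) {
  ref_codon <- normalize_codon(ref_codon)
  stopifnot(length(ref_codon) == 1L, offset %in% 0:2)
  alt_base <- chartr("T", "U", toupper(alt_base))
  stopifnot(alt_base %in% CODON_BASES)
  alt_codon <- ref_codon
  substr(alt_codon, offset + 1L, offset + 1L) <- alt_base
  ref_aa <- code$mapping[[ref_codon]]
  alt_aa <- code$mapping[[alt_codon]]
  if (ref_aa == alt_aa) return("synonymous")
  if (alt_aa == "STOP") return("nonsense")
  if (ref_aa == "STOP") return("stop_loss")
  "missense"
}

#' Map coding variants onto codons
#'
#' Checks each variant against the CDS (position in range, reference base
#' matching the sequence, codon free of ambiguity codes), classifies its
#' consequence, and tallies accepted missense and nonsense variants at the
#' reference codon type. Synonymous and stop-loss changes, out-of-range
#' positions and reference mismatches are excluded with explicit reasons.
#'
#' @param rec a single-row `cds_set` (or list with `gene_id` and
#'   `sequence`).
#' @param variants data.frame from [read_variant_table()]; all rows must
#'   target `rec`'s gene.
#' @param code a `genetic_code`.
#' @return an object of class `codon_mutation_map`: list with `gene_id`,
#'   `per_codon_type` (64 x 2 integer matrix, columns `missense`,
#'   `nonsense`), `occurrences` (codon counts of the CDS), `n_accepted`,
#'   and `excluded` (data.frame `row`, `cds_pos`, `reason`).
#' @examples
#' rec <- list(gene_id = "G", sequence = "AUGGAAUAA")
#' v <- data.frame(gene_id = "G", cds_pos = c(4, 5, 6),
#'                 ref = c("G", "A", "A"), alt = c("U", "U", "G"))
#' m <- map_variants(rec, v)
#' m$per_codon_type["GAA", ]  # 1 missense, 1 nonsense; pos 6 is synonymous
#' @export
map_variants <- function(rec, variants, code = build_genetic_code()) {
  if (inherits(rec, "cds_set") || is.data.frame(rec)) {
    stopifnot(nrow(rec) == 1L)
    rec <- list(gene_id = rec$gene_id, sequence = rec$sequence)
  }
  seq <- chartr("T", "U", toupper(rec$sequence))
  if (nrow(variants) > 0 && !all(variants$gene_id == rec$gene_id)) {
    stop("variants target gene(s) other than ", rec$gene_id, call. = FALSE)
  }
  occurrences <- count_codons(seq, rec$gene_id, code)$counts
  tallies <- matrix(0L, nrow = length(all_codons(code)), ncol = 2,
                    dimnames = list(all_codons(code),
                                    c("missense", "nonsense")))
  excl <- list()
  n_acc <- 0L
  L <- nchar(seq)
  for (i in seq_len(nrow(variants))) {
    pos <- variants$cds_pos[i]
    reason <- NULL
    if (pos < 1L || pos > L) {
      reason <- "out_of_range"
    } else if (substr(seq, pos, pos) != variants$ref[i]) {
      reason <- "ref_mismatch"
    } else {
      ci <- codon_index(pos)
      start <- (ci$codon_number - 1L) * 3L + 1L
      ref_codon <- substr(seq, start, start + 2L)
      if (grepl("[^ACGU]", ref_codon)) {
        reason <- "ambiguous_codon"
      } else {
        cls <- classify_substitution(ref_codon, ci$offset, variants$alt[i],
                                     code)
        if (cls %in% c("missense", "nonsense")) {
          tallies[ref_codon, cls] <- tallies[ref_codon, cls] + 1L
          n_acc <- n_acc + 1L
        } else {
          reason <- cls
        }
      }
    }
    if (!is.null(reason)) {
      excl[[length(excl) + 1L]] <- data.frame(row = i, cds_pos = pos,
                                              reason = reason,
                                              stringsAsFactors = FALSE)
    }
  }
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(row = integer(0), cds_pos = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  structure(
    list(gene_id = rec$gene_id,
         per_codon_type = tallies,
         occurrences = occurrences,
         n_accepted = n_acc,
         excluded = excluded),
    class = "codon_mutation_map")
}

#' Per-codon mutation burden joined with CU values
#'
#' For every sense codon: the number of accepted mutations, its share of all
#' accepted mutations, and the occurrence-normalized rate (mutations per
#' occurrence of the codon in the CDS), joined with the gene's CU value so
#' that the relation between mutation burden and codon usage can be
#' inspected (e.g. as a Spearman rank correlation via [spearman_cu()]).
#'
#' @param map a `codon_mutation_map`.
#' @param profile the `cu_profile` of the same gene.
#' @param code a `genetic_code`.
#' @return data.frame with `codon`, `amino_acid`, `cu`, `occurrences`,
#'   `missense`, `nonsense`, `count`, `share`, `rate`.
#' @export
mutation_burden <- function(map, profile, code = build_genetic_code()) {
  stopifnot(inherits(map, "codon_mutation_map"),
            inherits(profile, "cu_profile"))
  if (map$gene_id != profile$gene_id) {
    stop("map and profile come from different genes", call. = FALSE)
  }
  cods <- code$sense_codons
  mis <- map$per_codon_type[cods, "missense"]
  non <- map$per_codon_type[cods, "nonsense"]
  count <- mis + non
  occ <- map$occurrences[cods]
  total <- map$n_accepted
  out <- data.frame(
    codon = cods,
    amino_acid = unname(sense_amino_acid(code)),
    cu = unname(profile$cu[cods]),
    occurrences = unname(occ),
    missense = unname(mis),
    nonsense = unname(non),
    count = unname(count),
    share = if (total > 0) unname(count) / total else NA_real_,
    rate = unname(ifelse(occ > 0, count / occ, NA_real_)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
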