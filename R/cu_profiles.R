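# Per-gene codon counting, within-family CU values, stop-codon usage,
# zero-codon and extreme-bias detection.
#
# The CU value of a codon is its count divided by the total count of all
# synonymous codons of the same amino acid in the gene (or pooled cohort);
# it is computed independently for each of the 18 considered amino-acid
# families. Met (AUG), Trp (UGG) and the stop codons never enter CU values;
# the terminal stop is tracked separately for stop-codon usage.

#' Count codons of a coding sequence
#'
#' Frame-0, non-overlapping triplet counts over all 64 codons. Triplets
#' containing ambiguity codes are excluded and tallied in `excluded_codons`.
#' The terminal stop (when present) is counted here but never enters sense
#' statistics downstream.
#'
#' @param x a sequence string (RNA or DNA), or a single-row `cds_set`.
#' @param gene_id label for the counts; defaults to the record's `gene_id`
#'   or `"gene"` for a bare string.
#' @param code a `genetic_code`.
#' @return an object of class `codon_counts`: list with `gene_id`,
#'   `counts` (named integer vector over the 64 codons) and
#'   `excluded_codons`.
#' @examples
#' cc <- count_codons("AUGCUGCUGUAA")
#' cc$counts[c("AUG", "CUG", "UAA")]
#' @export
count_codons <- function(x, gene_id = NULL, code = build_genetic_code()) {
  if (inherits(x, "cds_set") || is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    if (is.null(gene_id)) gene_id <- x$gene_id
    x <- x$sequence
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (is.null(gene_id)) gene_id <- "gene"
  seq <- chartr("T", "U", toupper(x))
  if (nchar(seq) %% 3L != 0L) {
    stop("sequence length is not a multiple of 3", call. = FALSE)
  }
  trip <- codon_split(seq)
  ok <- !grepl("[^ACGU]", trip)
  counts <- table(factor(trip[ok], levels = all_codons(code)))
  structure(
    list(gene_id = gene_id,
         counts = stats::setNames(as.integer(counts), names(counts)),
         excluded_codons = sum(!ok)),
    class = "codon_counts")
}

#' Count codons for every record of a cohort
#'
#' @param records a `cds_set`.
#' @param code a `genetic_code`.
#' @return a list of `codon_counts`, one per record, named by `gene_id`.
#' @export
count_cohort <- function(records, code = build_genetic_code()) {
  stopifnot(inherits(records, "cds_set"))
  out <- lapply(seq_len(nrow(records)), function(i)
    count_codons(records$sequence[i], records$gene_id[i], code))
  names(out) <- records$gene_id
  out
}

#' Sum codon counts over a cohort
#'
#' Element-wise sum of per-gene counts, used for pooled (cohort-level) CU
#' values.
#'
#' @param cohort a non-empty list of `codon_counts`.
#' @param label `gene_id` for the pooled vector (the cohort label).
#' @return a `codon_counts` object.
#' @export
pool_cohort_counts <- function(cohort, label = "pooled") {
  stopifnot(is.list(cohort), length(cohort) > 0)
  stopifnot(all(vapply(cohort, inherits, logical(1), "codon_counts")))
  counts <- Reduce(`+`, lapply(cohort, `[[`, "counts"))
  structure(
    list(gene_id = label,
         counts = counts,
         excluded_codons = sum(vapply(cohort, `[[`, numeric(1),
                                      "excluded_codons"))),
    class = "codon_counts")
}

#' Within-family codon usage values
#'
#' For every one of the 18 considered amino-acid families, each codon's CU
#' value is its count divided by the family total in this gene. Families
#' whose amino acid does not occur at all are marked absent
#' (`family_present = FALSE`) and their CU entries are `NA` rather than 0,
#' since no usage choice was observed.
#'
#' @param counts a `codon_counts`.
#' @param code a `genetic_code`.
#' @return an object of class `cu_profile`: list with `gene_id`, `cu`
#'   (named numeric over the 59 sense codons, `NA` for absent families),
#'   `family_present` (named logical over the 18 considered amino acids), and
#'   `terminal_stop` (the gene's stop codon, or `NA` if it has none).
#' @examples
#' p <- cu_values(count_codons("AUGCUGCUGUAA"))
#' p$cu["CUG"]           # 1: the only Leu codon used
#' p$family_present["P"] # FALSE: no proline in this CDS
#' @export
cu_values <- function(counts, code = build_genetic_code()) {
  stopifnot(inherits(counts, "codon_counts"))
  aa <- sense_amino_acid(code)
  n <- counts$counts[code$sense_codons]
  fam_tot <- tapply(n, aa, sum)
  fam_tot <- stats::setNames(as.numeric(fam_tot[code$considered]),
                             code$considered)
  present <- fam_tot > 0
  cu <- as.numeric(ifelse(present[aa], n / fam_tot[aa], NA_real_))
  names(cu) <- code$sense_codons

  stops <- counts$counts[code$stop_codons]
  terminal <- if (sum(stops) > 0) code$stop_codons[which.max(stops)] else NA_character_
  structure(
    list(gene_id = counts$gene_id,
         cu = cu,
         family_present = present,
         terminal_stop = terminal),
    class = "cu_profile")
}

#' Stop codon usage of a cohort
#'
#' Frequency of UAA, UAG and UGA among the terminal stop codons of the genes
#' that have one; genes without a terminal stop are excluded from the
#' denominator.
#'
#' @param records a `cds_set`.
#' @return named numeric over the three stop codons, summing to 1; a
#'   zero-length vector (with a warning) if no gene has a terminal stop.
#' @export
stop_codon_usage <- function(records) {
  stopifnot(inherits(records, "cds_set"))
  seqs <- records$sequence[records$has_terminal_stop]
  if (length(seqs) == 0L) {
    warning("no gene in the cohort has a terminal stop codon", call. = FALSE)
    return(stats::setNames(numeric(0), character(0)))
  }
  last3 <- substring(seqs, nchar(seqs) - 2L, nchar(seqs))
  tab <- table(factor(last3, levels = STOP_CODONS))
  stats::setNames(as.numeric(tab) / length(seqs), STOP_CODONS)
}

#' Detect zero-codons of a gene
#'
#' A zero-codon is a synonymous sense codon with zero occurrences — the
#' extreme of codon usage bias. Under the default `family_present` policy a
#' codon counts only when its amino acid does occur in the gene (so the zero
#' reflects codon choice, not protein composition); under `raw`, every
#' unused sense codon is reported. Met, Trp and stop codons are never
#' reported.
#'
#' @param counts a `codon_counts`.
#' @param code a `genetic_code`.
#' @param policy `"family_present"` (default) or `"raw"`.
#' @return an object of class `zero_codon_report`: list with `gene_id`,
#'   `zero_codons` (character vector, canonical codon order) and `policy`.
#' @examples
#' zero_codons(count_codons("AUGCUGCUGUAA"))$zero_codons  # other 5 Leu codons
#' @export
zero_codons <- function(counts, code = build_genetic_code(),
                        policy = c("family_present", "raw")) {
  stopifnot(inherits(counts, "codon_counts"))
  policy <- match.arg(policy)
  n <- counts$counts[code$sense_codons]
  zero <- n == 0L
  if (policy == "family_present") {
    aa <- sense_amino_acid(code)
    fam_tot <- tapply(n, aa, sum)
    zero <- zero & fam_tot[aa] > 0
  }
  structure(
    list(gene_id = counts$gene_id,
         zero_codons = code$sense_codons[zero],
         policy = policy),
    class = "zero_codon_report")
}

#' Extremely biased codons under a redundancy-based cutoff
#'
#' Flags sense codons whose CU value falls below a degeneracy-dependent
#' cutoff `t(d)`. The default is half the uniform expectation,
#' `t(d) = 0.5/d` (i.e. 0.25, 0.167, 0.125 and 0.083 for families of 2, 3,
#' 4 and 6 codons), overridable per degeneracy. Codons of absent families
#' are never flagged.
#'
#' @param profile a `cu_profile`.
#' @param code a `genetic_code`.
#' @param cutoff optional named numeric of per-degeneracy thresholds, e.g.
#'   `c("2" = 0.25, "3" = 0.17, "4" = 0.125, "6" = 0.083)`; defaults to
#'   `0.5/d`.
#' @return character vector of flagged codons, in canonical order.
#' @export
extremely_biased_codons <- function(profile, code = build_genetic_code(),
                                    cutoff = NULL) {
  stopifnot(inherits(profile, "cu_profile"))
  deg <- sense_degeneracy(code)
  thr <- 0.5 / deg
  if (!is.null(cutoff)) {
    stopifnot(!is.null(names(cutoff)))
    hit <- as.character(deg) %in% names(cutoff)
    thr[hit] <- cutoff[as.character(deg)[hit]]
  }
  cu <- profile$cu[code$sense_codons]
  flagged <- !is.na(cu) & cu < thr
  code$sense_codons[flagged]
}

#' Long-format CU table for a cohort
#'
#' One row per gene and sense codon with count, CU value, zero-codon flag
#' and extreme-bias flag — the per-gene table exported by the pipeline.
#'
#' @param cohort list of `codon_counts` (e.g. from [count_cohort()]).
#' @param code a `genetic_code`.
#' @param policy zero-codon policy, see [zero_codons()].
#' @param cutoff see [extremely_biased_codons()].
#' @return data.frame with columns `gene_id`, `codon`, `amino_acid`,
#'   `count`, `cu`, `zero_codon`, `extremely_biased`.
#' @export
cu_long_table <- function(cohort, code = build_genetic_code(),
                          policy = "family_present", cutoff = NULL) {
  rows <- lapply(cohort, function(cc) {
    prof <- cu_values(cc, code)
    zc <- zero_codons(cc, code, policy)$zero_codons
    eb <- extremely_biased_codons(prof, code, cutoff)
    data.frame(
      gene_id = cc$gene_id,
      codon = code$sense_codons,
      amino_acid = unname(sense_amino_acid(code)),
      count = unname(cc$counts[code$sense_codons]),
      cu = unname(prof$cu),
      zero_codon = code$sense_codons %in% zc,
      extremely_biased = code$sense_codons %in% eb,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
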