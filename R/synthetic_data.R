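# Seeded generators of CDS cohorts with controlled codon-preference
# structure and of variant lists with known per-codon intensities, so every
# analysis stage has ground truth. All generators are pure functions of
# their spec + seed.
#
# By construction, amino-acid composition and codon preferences are
# independent: CU values are meaningful conditional on amino-acid usage,
# which is exactly the assumption the within-family normalization makes.

#' Specify a synthetic CDS cohort
#'
#' Each gene is generated by drawing a length (codons, uniform over
#' `length_range`), drawing amino acids i.i.d. from `aa_composition` over
#' the 18 considered amino acids, drawing each codon from its family's
#' preference vector, then prepending AUG and appending a stop codon drawn
#' from `stop_distribution`. Codons listed in `injected_zero_codons` get
#' preference mass 0 (their families renormalized), so they are guaranteed
#' zero-codons of every gene.
#'
#' @param n_genes number of genes.
#' @param length_range `c(min, max)` gene body length in codons (default
#'   300-1500, the typical span of tissue-specific disease genes).
#' @param preference optional named list, amino acid -> named probability
#'   vector over its codons; default uniform within every family.
#' @param aa_composition optional named probability vector over the 18
#'   considered amino acids; default uniform.
#' @param injected_zero_codons sense codons forced to zero usage.
#' @param stop_distribution named probabilities over UAA, UAG, UGA.
#' @param label,species,tissue,cohort metadata stamped on the records.
#' @param seed integer seed; the generator is deterministic given the spec.
#' @param code a `genetic_code`.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes,
                        length_range = c(300L, 1500L),
                        preference = NULL,
                        aa_composition = NULL,
                        injected_zero_codons = character(0),
                        stop_distribution = c(UAA = 1/3, UAG = 1/3, UGA = 1/3),
                        label = "synthetic", species = "synthetic",
                        tissue = "other", cohort = "unlabeled",
                        seed = 1L, code = build_genetic_code()) {
  stopifnot(n_genes >= 1, length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2])
  if (is.null(aa_composition)) {
    aa_composition <- stats::setNames(rep(1 / length(code$considered),
                                          length(code$considered)),
                                      code$considered)
  }
  stopifnot(setequal(names(aa_composition), code$considered),
            abs(sum(aa_composition) - 1) < 1e-8, all(aa_composition >= 0))
  aa_composition <- aa_composition[code$considered]

  pref <- lapply(code$considered, function(a) {
    cods <- code$families[[a]]$codons
    p <- if (!is.null(preference) && !is.null(preference[[a]])) {
      stopifnot(setequal(names(preference[[a]]), cods))
      preference[[a]][cods]
    } else {
      stats::setNames(rep(1 / length(cods), length(cods)), cods)
    }
    stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
    p
  })
  names(pref) <- code$considered

  bad <- setdiff(injected_zero_codons, code$sense_codons)
  if (length(bad) > 0) {
    stop("injected_zero_codons must be considered sense codons, not: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (z in injected_zero_codons) {
    a <- unname(code$mapping[z])
    p <- pref[[a]]
    p[z] <- 0
    if (sum(p) == 0 && aa_composition[[a]] > 0) {
      stop("family ", a, " would have no usable codon after injecting ",
           "zero-codons", call. = FALSE)
    }
    pref[[a]] <- p / sum(p)
  }

  stopifnot(setequal(names(stop_distribution), STOP_CODONS),
            abs(sum(stop_distribution) - 1) < 1e-8)
  structure(
    list(n_genes = as.integer(n_genes),
         length_range = as.integer(length_range),
         preference = pref,
         aa_composition = aa_composition,
         injected_zero_codons = injected_zero_codons,
         stop_distribution = stop_distribution[STOP_CODONS],
         label = label, species = species, tissue = tissue, cohort = cohort,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Generate a synthetic CDS cohort with ground truth
#'
#' @param spec a `cohort_spec`.
#' @param code a `genetic_code`.
#' @return list with `records` (a `cds_set`; exon counts are distinct random
#'   integers so exon ordering is well defined) and `ground_truth` (list
#'   with per-gene realized `counts` incl. AUG and stop, the
#'   `injected_zero_codons` registry and per-gene `lengths` in codons).
#' @examples
#' cs <- cohort_spec(n_genes = 3, length_range = c(10, 20), seed = 42)
#' gen <- generate_cohort(cs)
#' gen$records$gene_id
#' @export
generate_cohort <- function(spec, code = build_genetic_code()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  lens <- if (spec$length_range[1] == spec$length_range[2]) {
    rep(spec$length_range[1], n)
  } else {
    sample(seq(spec$length_range[1], spec$length_range[2]), n, replace = TRUE)
  }
  exon_counts <- sample.int(10 * n + 100L, n)
  ids <- sprintf("%s_g%03d", spec$label, seq_len(n))

  seqs <- character(n)
  gt_counts <- vector("list", n)
  for (i in seq_len(n)) {
    aa <- sample(names(spec$aa_composition), lens[i], replace = TRUE,
                 prob = spec$aa_composition)
    codons <- character(lens[i])
    for (a in unique(aa)) {
      idx <- which(aa == a)
      p <- spec$preference[[a]]
      codons[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
    }
    stop_codon <- sample(names(spec$stop_distribution), 1,
                         prob = spec$stop_distribution)
    full <- c("AUG", codons, stop_codon)
    seqs[i] <- paste(full, collapse = "")
    gt_counts[[i]] <- table(factor(full, levels = all_codons(code)))
  }
  names(gt_counts) <- ids

  records <- new_cds_set(data.frame(
    accession = ids,
    gene_id = ids,
    species = spec$species,
    tissue = spec$tissue,
    cohort = spec$cohort,
    exon_count = exon_counts,
    expression_class = NA_character_,
    sequence = seqs,
    has_terminal_stop = TRUE,
    stringsAsFactors = FALSE))
  list(records = records,
       ground_truth = list(counts = gt_counts,
                           injected_zero_codons = spec$injected_zero_codons,
                           lengths = stats::setNames(lens, ids)))
}

#' Generate a matched low-bias / high-bias cohort pair
#'
#' Emulates the contrast between disease-causing-like genes that retain
#' multiple codon usage and non-disease-causing-like genes with strong bias:
#' cohort `low` uses uniform within-family preferences (no extreme bias),
#' cohort `high` concentrates probability mass `concentration` on one
#' preferred codon per family and spreads the remainder equally over the
#' rest.
#'
#' @param base_spec a `cohort_spec` giving sizes, lengths, composition and
#'   seed; `low` uses `base_spec$seed`, `high` uses `base_spec$seed + 1`.
#' @param biased_codons optional preferred codons (at most one per family);
#'   families not covered default to their alphabetically first codon.
#' @param concentration mass on the preferred codon, in (1/degeneracy, 1].
#' @param code a `genetic_code`.
#' @return list with elements `low` and `high`, each as returned by
#'   [generate_cohort()], plus `preferred_codons`.
#' @export
generate_fingerprint_pair <- function(base_spec, biased_codons = NULL,
                                      concentration = 0.9,
                                      code = build_genetic_code()) {
  stopifnot(inherits(base_spec, "cohort_spec"),
            concentration > 0, concentration <= 1)
  preferred <- vapply(code$considered, function(a)
    code$families[[a]]$codons[1], character(1))
  if (!is.null(biased_codons)) {
    fams <- unname(code$mapping[normalize_codon(biased_codons)])
    if (anyDuplicated(fams)) {
      stop("at most one biased codon per family", call. = FALSE)
    }
    preferred[fams] <- normalize_codon(biased_codons)
  }
  high_pref <- lapply(code$considered, function(a) {
    cods <- code$families[[a]]$codons
    d <- length(cods)
    if (concentration <= 1 / d) {
      stop("concentration must exceed 1/degeneracy (", 1 / d, ") for family ",
           a, call. = FALSE)
    }
    p <- stats::setNames(rep((1 - concentration) / (d - 1), d), cods)
    p[preferred[[a]]] <- concentration
    p
  })
  names(high_pref) <- code$considered

  low_spec <- base_spec
  low_spec$label <- paste0(base_spec$label, "_low")
  low_spec$cohort <- "DC"
  low_spec$preference <- lapply(code$considered, function(a) {
    cods <- code$families[[a]]$codons
    stats::setNames(rep(1 / length(cods), length(cods)), cods)
  })
  names(low_spec$preference) <- code$considered

  high_spec <- base_spec
  high_spec$label <- paste0(base_spec$label, "_high")
  high_spec$cohort <- "NDC"
  high_spec$preference <- high_pref
  high_spec$seed <- base_spec$seed + 1L

  list(low = generate_cohort(low_spec, code),
       high = generate_cohort(high_spec, code),
       preferred_codons = preferred)
}

#' Generate coding variants with known per-codon-type intensities
#'
#' Samples `n_variants` codon sites with probability proportional to
#' `intensity(codon type) * occurrences`, then within the chosen codon
#' samples uniformly among the single-base substitutions whose consequence
#' is missense or nonsense (every sense codon has at least one such
#' substitution under the standard code). The realized per-codon-type
#' tallies are returned as ground truth for [map_variants()].
#'
#' @param rec a single-row `cds_set` or list with `gene_id`, `sequence`.
#' @param intensity named nonnegative rates per codon type; codon types not
#'   named get rate 0.
#' @param n_variants number of variants to draw.
#' @param seed integer seed.
#' @param code a `genetic_code`.
#' @return list with `variants` (data.frame as from [read_variant_table()])
#'   and `ground_truth` (64 x 2 matrix of missense/nonsense tallies).
#' @export
generate_variants <- function(rec, intensity, n_variants, seed = 1L,
                              code = build_genetic_code()) {
  if (inherits(rec, "cds_set") || is.data.frame(rec)) {
    stopifnot(nrow(rec) == 1L)
    rec <- list(gene_id = rec$gene_id, sequence = rec$sequence)
  }
  stopifnot(all(intensity >= 0), n_variants >= 1)
  set.seed(as.integer(seed))
  seq <- chartr("T", "U", toupper(rec$sequence))
  trip <- codon_split(seq)
  w <- intensity[trip]
  w[is.na(w)] <- 0
  w <- as.numeric(w)
  if (sum(w) == 0) {
    stop("no CDS codon has positive intensity", call. = FALSE)
  }
  # all missense/nonsense single-base substitutions, per codon type
  sub_table <- function(cod) {
    out <- list()
    for (off in 0:2) {
      for (alt in setdiff(CODON_BASES, substr(cod, off + 1L, off + 1L))) {
        cls <- classify_substitution(cod, off, alt, code)
        if (cls %in% c("missense", "nonsense")) {
          out[[length(out) + 1L]] <- list(offset = off, alt = alt, class = cls)
        }
      }
    }
    out
  }
  subs <- lapply(stats::setNames(nm = unique(trip[w > 0])), sub_table)

  sites <- sample(seq_along(trip), n_variants, replace = TRUE, prob = w)
  gt <- matrix(0L, nrow = length(all_codons(code)), ncol = 2,
               dimnames = list(all_codons(code), c("missense", "nonsense")))
  rows <- vector("list", n_variants)
  for (k in seq_len(n_variants)) {
    s <- sites[k]
    cod <- trip[s]
    choice <- subs[[cod]][[sample.int(length(subs[[cod]]), 1)]]
    pos <- (s - 1L) * 3L + choice$offset + 1L
    rows[[k]] <- data.frame(
      gene_id = rec$gene_id,
      cds_pos = pos,
      ref = substr(cod, choice$offset + 1L, choice$offset + 1L),
      alt = choice$alt,
      class = choice$class,
      stringsAsFactors = FALSE)
    gt[cod, choice$class] <- gt[cod, choice$class] + 1L
  }
  list(variants = do.call(rbind, rows), ground_truth = gt)
}

#' Write a generated cohort to disk in the formats sequence_io reads
#'
#' @param gen result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written (`fasta`, `metadata`,
#'   `ground_truth`).
#' @export
write_cohort <- function(gen, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  meta <- file.path(dir, paste0(prefix, "_metadata.tsv"))
  gtf <- file.path(dir, paste0(prefix, "_ground_truth.json"))
  write_cds_fasta(gen$records, fasta, meta)
  gt <- gen$ground_truth
  gt$counts <- lapply(gt$counts, function(x)
    as.list(stats::setNames(as.integer(x), names(x))))
  jsonlite::write_json(gt, gtf, auto_unbox = TRUE)
  invisible(list(fasta = fasta, metadata = meta, ground_truth = gtf))
}
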