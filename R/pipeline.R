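# Config-driven end-to-end runs: per-cohort CU tables, fingerprint
# clusterings, zero-codon tables, differential codon prioritization and
# mutation mapping, with a JSON manifest for reproducibility. All stages are
# the exported module functions; the pipeline only sequences them and writes
# files, so individual stages re-run on intermediate files give identical
# results.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full codon-usage analysis pipeline
#'
#' Two input modes: `files` (CDS FASTA + metadata TSV + optional variant
#' TSV) or `synthetic` (a low/high-bias fingerprint cohort pair generated
#' from the run seed). Stages: codon counting, per-gene (or pooled) CU
#' matrix, row and column complete-linkage clusterings (exported as
#' Newick), zero-codon cohort table, per-codon differential tests with
#' prioritization, and, when variants are given, mapping-on-codons. Outputs
#' are plain TSV/Newick/JSON files plus a manifest; identical config + seed
#' give identical outputs.
#'
#' @param config a named list or a path to a YAML file. Recognized fields:
#'   `mode` ("files" or "synthetic"); `fasta`, `metadata`, `variants`
#'   (files mode); `n_genes`, `gene_length`, `concentration` (synthetic
#'   mode, defaults 20 / 400 / 0.9); `matrix_level` ("gene" or "pooled");
#'   `zero_policy` ("family_present" or "raw"); `cutoff` (named
#'   per-degeneracy thresholds); `alpha`; `adjust` ("none" or "BH");
#'   `comparisons` (list of `list(var, a, b)` row-grouping comparisons;
#'   default: cohort DC vs NDC when both present, plus all tissue pairs);
#'   `seed`; `out_dir`.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(mode = "files", matrix_level = "gene",
                   zero_policy = "family_present", cutoff = NULL,
                   alpha = 0.05, adjust = "none", comparisons = NULL,
                   seed = 1L, out_dir = "codonfp_run",
                   n_genes = 20L, gene_length = 400L, concentration = 0.9)
  config <- utils::modifyList(defaults, config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  code <- build_genetic_code()
  outputs <- character(0)

  variants <- NULL
  if (config$mode == "synthetic") {
    base <- cohort_spec(
      n_genes = config$n_genes,
      length_range = rep(as.integer(config$gene_length), 2),
      label = "sim", species = "synthetic", tissue = "other",
      seed = as.integer(config$seed))
    pair <- generate_fingerprint_pair(base, concentration = config$concentration,
                                      code = code)
    records <- new_cds_set(rbind(pair$low$records, pair$high$records))
  } else if (config$mode == "files") {
    stopifnot(!is.null(config$fasta), !is.null(config$metadata))
    records <- read_cds_fasta(config$fasta, config$metadata)
    records <- select_longest_isoform(records)
    if (!is.null(config$variants)) variants <- read_variant_table(config$variants)
  } else {
    stop("unknown mode: ", config$mode, call. = FALSE)
  }

  counts <- count_cohort(records, code)
  outputs <- c(outputs, write_tsv(
    cu_long_table(counts, code, config$zero_policy,
                  unlist(config$cutoff)),
    file.path(config$out_dir, "cu_values.tsv")))

  if (config$matrix_level == "pooled") {
    key <- interaction(records$species, records$tissue, records$cohort,
                       drop = TRUE, sep = ".")
    pooled <- lapply(levels(key), function(lv)
      pool_cohort_counts(counts[key == lv], lv))
    profiles <- lapply(pooled, cu_values, code = code)
    exon <- stats::setNames(rep(0L, length(pooled)),
                            vapply(pooled, `[[`, character(1), "gene_id"))
    mat <- build_matrix(profiles, exon, ordering = "as_is", code = code)
    row_group <- NULL
  } else {
    profiles <- lapply(counts, cu_values, code = code)
    exon <- stats::setNames(records$exon_count, records$gene_id)
    mat <- build_matrix(profiles, exon, ordering = "exon_count", code = code)
    row_group <- stats::setNames(records$cohort, records$gene_id)
  }
  mat_df <- data.frame(gene_id = mat$row_ids, mat$values,
                       check.names = FALSE, stringsAsFactors = FALSE)
  outputs <- c(outputs, write_tsv(mat_df,
                                  file.path(config$out_dir, "cu_matrix.tsv")))

  cluster_summary <- list()
  if (nrow(mat$values) >= 2) {
    rows_cr <- complete_linkage(euclidean_distance(mat, "rows"), "rows")
    as_newick(rows_cr, file.path(config$out_dir, "gene_dendrogram.nwk"))
    outputs <- c(outputs, file.path(config$out_dir, "gene_dendrogram.nwk"))
    cluster_summary$gene_leaf_order <- rows_cr$leaf_order
  }
  cols_cr <- complete_linkage(euclidean_distance(mat, "cols"), "cols")
  as_newick(cols_cr, file.path(config$out_dir, "codon_dendrogram.nwk"))
  outputs <- c(outputs, file.path(config$out_dir, "codon_dendrogram.nwk"))
  cluster_summary$codon_leaf_order <- cols_cr$leaf_order

  zc_tab <- zero_codon_table(records, code, config$zero_policy)
  outputs <- c(outputs, write_tsv(zc_tab,
                                  file.path(config$out_dir,
                                            "zero_codon_table.tsv")))

  stop_usage <- stop_codon_usage(records)

  diff_all <- NULL
  prioritized <- character(0)
  comparisons <- config$comparisons
  if (is.null(comparisons) && !is.null(row_group)) {
    comparisons <- list()
    if (all(c("DC", "NDC") %in% records$cohort)) {
      comparisons <- c(comparisons,
                       list(list(var = "cohort", a = "DC", b = "NDC")))
    }
    tissues <- sort(unique(records$tissue))
    if (length(tissues) > 1) {
      prs <- utils::combn(tissues, 2, simplify = FALSE)
      comparisons <- c(comparisons, lapply(prs, function(p)
        list(var = "tissue", a = p[1], b = p[2])))
    }
  }
  if (!is.null(comparisons) && length(comparisons) > 0 &&
      config$matrix_level == "gene") {
    diffs <- lapply(comparisons, function(cmp) {
      grp <- stats::setNames(records[[cmp$var]], records$gene_id)
      differential_codon_usage(mat, grp, cmp$a, cmp$b, code = code)
    })
    diff_all <- do.call(rbind, diffs)
    outputs <- c(outputs, write_tsv(diff_all,
                                    file.path(config$out_dir,
                                              "differential_codons.tsv")))
    # prioritize on the minimum p per codon over the comparison set
    ok <- !is.na(diff_all$p_value)
    if (any(ok)) {
      pmin_df <- stats::aggregate(p_value ~ codon, diff_all[ok, ], min)
      prioritized <- prioritize_codons(pmin_df, config$alpha, config$adjust)
    }
    outputs <- c(outputs, write_tsv(
      data.frame(rank = seq_along(prioritized), codon = prioritized),
      file.path(config$out_dir, "prioritized_codons.tsv")))
  }

  mutation_summary <- NULL
  if (!is.null(variants)) {
    maps <- lapply(unique(variants$gene_id), function(g) {
      idx <- which(records$gene_id == g)
      if (length(idx) == 0) stop("variants for unknown gene ", g,
                                 call. = FALSE)
      rec <- records[idx[1], , drop = FALSE]
      m <- map_variants(rec, variants[variants$gene_id == g, , drop = FALSE],
                        code)
      burden <- mutation_burden(m, cu_values(count_codons(rec, code = code),
                                             code), code)
      burden$gene_id <- g
      list(map = m, burden = burden)
    })
    burden_all <- do.call(rbind, lapply(maps, `[[`, "burden"))
    outputs <- c(outputs, write_tsv(burden_all,
                                    file.path(config$out_dir,
                                              "mutation_burden.tsv")))
    excl_all <- do.call(rbind, lapply(maps, function(m)
      cbind(gene_id = m$map$gene_id, m$map$excluded)))
    outputs <- c(outputs, write_tsv(excl_all,
                                    file.path(config$out_dir,
                                              "mutation_exclusions.tsv")))
    mutation_summary <- list(
      n_accepted = sum(vapply(maps, function(m) m$map$n_accepted, integer(1))),
      n_excluded = sum(vapply(maps, function(m) nrow(m$map$excluded),
                              integer(1))))
  }

  manifest <- list(
    package = "codonfp",
    version = as.character(utils::packageVersion("codonfp")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    n_records = nrow(records),
    n_cohort_cells = nrow(zc_tab),
    zero_codon_totals = stats::setNames(
      as.list(zc_tab$per_gene_sum),
      paste(zc_tab$species, zc_tab$tissue, zc_tab$cohort, sep = ".")),
    stop_codon_usage = as.list(stop_usage),
    prioritized_codons = prioritized,
    clustering = cluster_summary,
    mutation_mapping = mutation_summary,
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
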