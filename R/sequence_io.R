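# CDS FASTA + metadata + variant table I/O.
#
# A cohort of coding sequences is represented as a plain data.frame of class
# "cds_set" with one row per CDS and columns:
#   accession, gene_id, species, tissue, cohort, exon_count,
#   expression_class, sequence (RNA, uppercase), has_terminal_stop.
# CDS coordinates everywhere are 1-based, fully closed, on the coding strand
# (HGVS c. numbering); there is no genomic/strand arithmetic in the package.

STOP_CODONS <- c("UAA", "UAG", "UGA")

new_cds_set <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("cds_set", "data.frame")
  df
}

# split a sequence into frame-0 triplets
codon_split <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

has_internal_stop <- function(seq) {
  trip <- codon_split(seq)
  if (length(trip) <= 1L) return(FALSE)
  any(trip[-length(trip)] %in% STOP_CODONS)
}

#' Read and validate a CDS FASTA with cohort metadata
#'
#' Reads one complete coding sequence per FASTA record, normalizes it to
#' uppercase RNA (`T` transliterated to `U`), joins each record to its row in
#' a tab-separated metadata table by accession (the first word of the FASTA
#' header), and validates the CDS invariants: length a multiple of 3 and no
#' in-frame internal stop codon. Ambiguity codes (e.g. `N`) are tolerated in
#' the sequence with a warning; codons containing them are excluded from all
#' downstream counts.
#'
#' @param fasta_path path to the CDS FASTA file.
#' @param metadata_path path to a TSV with columns `accession`, `gene_id`,
#'   `species`, `tissue`, `cohort`, `exon_count` and optionally
#'   `expression_class`; `#`-comment lines allowed.
#' @param permissive if TRUE, internal-stop violations are downgraded to
#'   warnings and the offending records kept (frame violations always fail).
#' @return a `cds_set` data.frame in FASTA file order.
#' @examples
#' fa <- system.file("extdata", "toy_cds.fasta", package = "codonfp")
#' md <- system.file("extdata", "toy_metadata.tsv", package = "codonfp")
#' cds <- read_cds_fasta(fa, md)
#' cds$gene_id
#' @export
read_cds_fasta <- function(fasta_path, metadata_path, permissive = FALSE) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  sequences <- chartr("Tt", "Uu", toupper(as.character(seqs)))
  sequences <- toupper(sequences)

  meta <- utils::read.delim(metadata_path, comment.char = "#",
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  required <- c("accession", "gene_id", "species", "tissue", "cohort",
                "exon_count")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"expression_class" %in% names(meta)) meta$expression_class <- NA_character_

  unknown <- setdiff(ids, meta$accession)
  if (length(unknown) > 0) {
    stop("no metadata row for accession(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  m <- meta[match(ids, meta$accession), ]
  df <- data.frame(
    accession = ids,
    gene_id = m$gene_id,
    species = m$species,
    tissue = m$tissue,
    cohort = m$cohort,
    exon_count = as.integer(m$exon_count),
    expression_class = as.character(m$expression_class),
    sequence = unname(sequences),
    stringsAsFactors = FALSE)

  problems <- character(0)
  frame_bad <- nchar(df$sequence) %% 3L != 0L
  if (any(frame_bad)) {
    problems <- c(problems, paste0(df$accession[frame_bad],
                                   ": length not a multiple of 3"))
  }
  ambiguous <- grepl("[^ACGU]", df$sequence)
  if (any(ambiguous)) {
    warning("ambiguity codes in: ",
            paste(df$accession[ambiguous], collapse = ", "),
            "; containing codons will be excluded from counts",
            call. = FALSE)
  }
  stop_bad <- !frame_bad & vapply(df$sequence, has_internal_stop, logical(1))
  if (any(stop_bad)) {
    msg <- paste0(df$accession[stop_bad], ": internal in-frame stop codon")
    if (permissive) {
      warning("keeping records with internal stops: ",
              paste(msg, collapse = "; "), call. = FALSE)
    } else {
      problems <- c(problems, msg)
    }
  }
  if (length(problems) > 0) {
    stop("invalid CDS record(s):\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }

  last3 <- substring(df$sequence, nchar(df$sequence) - 2L, nchar(df$sequence))
  df$has_terminal_stop <- last3 %in% STOP_CODONS
  new_cds_set(df)
}

#' Write a cds_set back to FASTA (+ metadata TSV)
#'
#' Inverse of [read_cds_fasta()]: sequences are written in RNA spelling,
#' headers are the accessions, and the metadata columns go to a TSV so that
#' re-reading yields an identical `cds_set`.
#'
#' @param records a `cds_set`.
#' @param fasta_path,metadata_path output paths.
#' @return invisibly, the input `records`.
#' @export
write_cds_fasta <- function(records, fasta_path, metadata_path) {
  stopifnot(inherits(records, "cds_set"))
  ss <- Biostrings::BStringSet(records$sequence)
  names(ss) <- records$accession
  Biostrings::writeXStringSet(ss, fasta_path)
  meta_cols <- c("accession", "gene_id", "species", "tissue", "cohort",
                 "exon_count", "expression_class")
  utils::write.table(records[, meta_cols], metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(records)
}

#' Keep the longest isoform per gene and species
#'
#' Collapses a `cds_set` to exactly one record per `(gene_id, species)` pair:
#' the one with the longest coding sequence. Ties are broken by the
#' lexicographically smallest accession, so the selection is deterministic.
#'
#' @param records a `cds_set`.
#' @return a `cds_set` with one row per gene/species, in original file order.
#' @export
select_longest_isoform <- function(records) {
  stopifnot(inherits(records, "cds_set"))
  if (nrow(records) == 0L) return(records)
  key <- paste(records$gene_id, records$species, sep = "\r")
  ord <- order(key, -nchar(records$sequence), records$accession)
  keep_first <- !duplicated(key[ord])
  keep <- sort(ord[keep_first])
  new_cds_set(records[keep, , drop = FALSE])
}

#' Read a coding-variant table
#'
#' Parses a TSV of single-base coding substitutions. Either explicit columns
#' `gene_id`, `cds_pos`, `ref`, `alt` (optional `class`) or a `hgvs_c` column
#' in the `c.<pos><ref>><alt>` dialect (e.g. `c.123A>T`) are accepted. Bases
#' are normalized to RNA. Rows violating the variant invariants
#' (`cds_pos >= 1`, single-base ref/alt, `ref != alt`) fail with their line
#' numbers reported.
#'
#' @param path path to the TSV (header required, `#` comments allowed).
#' @return a data.frame with columns `gene_id`, `cds_pos`, `ref`, `alt`,
#'   `class` (`NA` when not reported).
#' @examples
#' vf <- system.file("extdata", "toy_variants.tsv", package = "codonfp")
#' head(read_variant_table(vf))
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if ("hgvs_c" %in% names(tab) && !all(c("cds_pos", "ref", "alt") %in% names(tab))) {
    m <- regmatches(tab$hgvs_c,
                    regexec("^c\\.([0-9]+)([ACGTUacgtu])>([ACGTUacgtu])$",
                            tab$hgvs_c))
    bad <- vapply(m, length, integer(1)) != 4L
    if (any(bad)) {
      stop("unparsable hgvs_c at row(s): ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    }
    tab$cds_pos <- as.integer(vapply(m, `[`, character(1), 2L))
    tab$ref <- vapply(m, `[`, character(1), 3L)
    tab$alt <- vapply(m, `[`, character(1), 4L)
  }
  needed <- c("gene_id", "cds_pos", "ref", "alt")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    stop("variant table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    gene_id = as.character(tab$gene_id),
    cds_pos = as.integer(tab$cds_pos),
    ref = chartr("T", "U", toupper(as.character(tab$ref))),
    alt = chartr("T", "U", toupper(as.character(tab$alt))),
    class = if ("class" %in% names(tab)) as.character(tab$class) else NA_character_,
    stringsAsFactors = FALSE)

  bad <- is.na(out$cds_pos) | out$cds_pos < 1L |
    !out$ref %in% CODON_BASES | !out$alt %in% CODON_BASES |
    out$ref == out$alt
  if (any(bad)) {
    stop("invalid variant row(s): ", paste(which(bad), collapse = ", "),
         " (need cds_pos >= 1, single RNA ref/alt bases, ref != alt)",
         call. = FALSE)
  }
  out
}
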