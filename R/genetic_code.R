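# Canonical internal spelling is RNA (A/C/G/U), uppercase. DNA input (T) is
# transliterated on ingestion; every exported table prints RNA codons.

CODON_BASES <- c("A", "C", "G", "U")

#' Build the standard genetic code table
#'
#' Returns the standard nuclear genetic code organized into amino-acid
#' synonymy families, the vocabulary used by every other function in the
#' package. Codons are spelled in RNA. The three stop codons (UAA, UAG, UGA)
#' form a dedicated `STOP` family; methionine (AUG) and tryptophan (UGG) are
#' single-codon families and are excluded from the 18 "considered" amino
#' acids over which within-family codon usage values are computed.
#'
#' @return An object of class `genetic_code`: a list with elements
#'   \describe{
#'     \item{mapping}{named character vector over all 64 codons; values are
#'       one-letter amino-acid codes or `"STOP"`.}
#'     \item{families}{named list of families, each with `amino_acid`,
#'       `codons` (sorted), and `degeneracy` (1, 2, 3, 4 or 6).}
#'     \item{considered}{the 18 amino acids with >1 synonymous codon
#'       (all sense amino acids except Met and Trp).}
#'     \item{sense_codons}{the 59 codons of the considered families, grouped
#'       by amino acid (alphabetical) then codon — the canonical column
#'       order of every CU matrix and table.}
#'     \item{stop_codons}{UAA, UAG, UGA.}
#'   }
#' @examples
#' code <- build_genetic_code()
#' code$mapping[["AUG"]]          # "M"
#' code$families$L$degeneracy     # 6
#' length(code$sense_codons)      # 59
#' @export
build_genetic_code <- function() {
  dna <- Biostrings::GENETIC_CODE
  codons <- chartr("T", "U", names(dna))
  aa <- ifelse(dna == "*", "STOP", unname(dna))
  ord <- order(codons)
  mapping <- stats::setNames(aa[ord], codons[ord])

  fam_names <- sort(unique(mapping))
  families <- lapply(fam_names, function(a) {
    cods <- sort(names(mapping)[mapping == a])
    list(amino_acid = a, codons = cods, degeneracy = length(cods))
  })
  names(families) <- fam_names

  considered <- setdiff(fam_names, c("M", "W", "STOP"))
  sense_codons <- unlist(lapply(families[considered], `[[`, "codons"),
                         use.names = FALSE)
  structure(
    list(mapping = mapping,
         families = families,
         considered = considered,
         sense_codons = sense_codons,
         stop_codons = families$STOP$codons),
    class = "genetic_code")
}

#' Validate and normalize codon strings
#'
#' @param x character vector of triplets.
#' @param dna_ok if TRUE, `T` is transliterated to `U` before validation.
#' @return the normalized (uppercase RNA) codons.
#' @keywords internal
normalize_codon <- function(x, dna_ok = TRUE) {
  x <- toupper(as.character(x))
  if (dna_ok) x <- chartr("T", "U", x)
  bad <- nchar(x) != 3L | grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(x[bad]), collapse = ", "),
         " (must be 3 letters over A/C/G/U)", call. = FALSE)
  }
  x
}

#' Translate a codon under the standard code
#'
#' @param code a `genetic_code` from [build_genetic_code()].
#' @param codon character vector of triplets (RNA; `T` accepted and
#'   transliterated).
#' @return character vector of one-letter amino-acid codes, `"STOP"` for
#'   stop codons.
#' @examples
#' code <- build_genetic_code()
#' translate_codon(code, "CUG")  # "L"
#' translate_codon(code, "UAA")  # "STOP"
#' @export
translate_codon <- function(code, codon) {
  stopifnot(inherits(code, "genetic_code"))
  unname(code$mapping[normalize_codon(codon)])
}

#' Look up the synonymy family of a codon
#'
#' @inheritParams translate_codon
#' @param codon a single triplet.
#' @return the family (list with `amino_acid`, `codons`, `degeneracy`)
#'   containing `codon`.
#' @examples
#' code <- build_genetic_code()
#' family_of(code, "UCG")$degeneracy  # 6 (Ser)
#' @export
family_of <- function(code, codon) {
  stopifnot(inherits(code, "genetic_code"), length(codon) == 1L)
  code$families[[translate_codon(code, codon)]]
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Standard genetic code: 64 codons,", length(x$families) - 1L,
      "amino acids + STOP;", length(x$considered),
      "considered families spanning", length(x$sense_codons), "sense codons\n")
  invisible(x)
}

# All 64 codons in the package's canonical (alphabetical) count order.
all_codons <- function(code = NULL) {
  if (is.null(code)) code <- build_genetic_code()
  names(code$mapping)
}

# degeneracy, indexed by codon, over the considered sense codons
sense_degeneracy <- function(code) {
  stats::setNames(
    unlist(lapply(code$considered, function(a)
      rep(code$families[[a]]$degeneracy, code$families[[a]]$degeneracy))),
    code$sense_codons)
}

# amino acid, indexed by codon, over the considered sense codons
sense_amino_acid <- function(code) {
  stats::setNames(unname(code$mapping[code$sense_codons]), code$sense_codons)
}
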