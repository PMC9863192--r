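#' Genetic code object for codon-usage statistics
#'
#' Wraps an NCBI translation table as the structure the codon-usage and
#' selection-rate machinery needs: the codon to amino-acid map, the stop set,
#' and the partition of sense codons into synonymous families.  The default is
#' translation table 5, the invertebrate mitochondrial code, under which
#' TGA = Trp, AGA/AGG = Ser and ATA = Met, leaving 62 sense codons and the two
#' stops TAA/TAG.  Under this code serine is an eight-fold family and there
#' are no single-codon amino acids, so the degeneracy classes are twelve
#' two-fold, six four-fold, one six-fold (Leu) and one eight-fold (Ser)
#' family.
#'
#' @param table NCBI translation table identifier (integer or string);
#'   default `5` (invertebrate mitochondrial).
#' @return An object of class `genetic_code`: a list with elements
#'   `id`, `codon_aa` (named character, 64 codons), `codons`, `stop_codons`,
#'   `sense_codons`, `families` (list of codon vectors, one per amino acid)
#'   and `degeneracy` (named integer per sense codon).
#' @examples
#' code <- genetic_code()
#' length(code$sense_codons)  # 62
#' @export
genetic_code <- function(table = 5L) {
  id <- as.character(table)
  map <- Biostrings::getGeneticCode(id)
  codons <- names(map)
  sense <- codons[map != "*"]
  fams <- split(sense, map[sense])
  deg <- stats::setNames(lengths(fams)[map[sense]], sense)
  structure(list(
    id = id,
    codon_aa = map,
    codons = codons,
    stop_codons = codons[map == "*"],
    sense_codons = sense,
    families = fams,
    degeneracy = deg
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code (NCBI table ", x$id, "): ",
      length(x$sense_codons), " sense codons, stops ",
      paste(x$stop_codons, collapse = "/"), "\n", sep = "")
  deg <- table(lengths(x$families))
  cat("Synonymous family degeneracies: ",
      paste(sprintf("%s-fold x%d", names(deg), as.integer(deg)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Synonymous families with the display-level split of Leu into Leu1 (CTN) /
# Leu2 (TTR) and Ser into Ser1 (AGN) / Ser2 (TCN), the convention used on
# RSCU bar plots.  Denominators of RSCU change accordingly when split = TRUE.
code_families <- function(code, split = FALSE) {
  fams <- code$families
  if (!split) return(fams)
  splt <- list()
  for (aa in names(fams)) {
    f <- fams[[aa]]
    if (aa == "L" && length(f) > 4) {
      splt[["L1"]] <- f[substr(f, 1, 1) == "C"]
      splt[["L2"]] <- f[substr(f, 1, 1) == "T"]
    } else if (aa == "S" && length(f) > 4) {
      splt[["S1"]] <- f[substr(f, 1, 2) == "AG"]
      splt[["S2"]] <- f[substr(f, 1, 2) == "TC"]
    } else {
      splt[[aa]] <- f
    }
  }
  splt
}

translate_codons <- function(codons, code) {
  aa <- code$codon_aa[codons]
  aa[is.na(aa)] <- "X"        # codons containing N
  unname(aa)
}
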