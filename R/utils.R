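`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

# reverse complement of a single DNA string; N maps to N
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANTGCAN", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

# split an in-frame sequence into codons; a trailing 1-2 nt remainder is dropped
codon_split <- function(x) {
  x <- toupper(x)
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# counts of A/C/G/T (N and anything else excluded)
base_counts <- function(x) {
  ch <- seq_chars(x)
  tab <- table(factor(ch, levels = DNA_BASES))
  stats::setNames(as.integer(tab), DNA_BASES)
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", toupper(x))
  if (any(bad))
    stop(what, " contains characters outside {A,C,G,T,N}; IUPAC ambiguity ",
         "codes other than N are not supported", call. = FALSE)
  invisible(TRUE)
}

new_df <- function(...) data.frame(..., stringsAsFactors = FALSE)
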