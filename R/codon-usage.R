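# Codon-usage-bias statistics: codon counting under an arbitrary genetic
# code (default: invertebrate mitochondrial, table 5), RSCU with
# over/under-representation calls, positional G+C content, and Wright's
# effective number of codons with its mutation-only expectation curve.

#' Count codons of a set of coding sequences
#'
#' Sequences are read in frame from position 1.  A trailing incomplete codon
#' (1-2 nt, as left by mRNAs with truncated stop codons T/TA) is dropped;
#' codons containing `N` are skipped; stop codons are excluded from
#' `n_codons` and from all downstream statistics.  A stop codon before the
#' final codon of a sequence triggers a warning naming the sequence and the
#' codon position (it is still excluded, not counted as sense).
#'
#' @param cds character vector (or list) of coding sequences, each at least
#'   3 nt, ideally named by gene.
#' @param code a [genetic_code()]; default table 5.
#' @return Object of class `codon_usage_summary`: `codon_counts` (named
#'   integer, 64 codons), `n_codons` (sense codons counted), `n_stop_codons`,
#'   `code`.
#' @examples
#' cu <- count_codons(c(gene = "ATGTTTTAA"))
#' cu$n_codons  # 2: ATG + TTT, TAA excluded
#' @export
count_codons <- function(cds, code = genetic_code()) {
  if (is.list(cds)) cds <- unlist(cds)
  stopifnot(is.character(cds), length(cds) >= 1)
  if (any(nchar(cds) < 3)) stop("every coding sequence must be >= 3 nt")
  nms <- names(cds) %||% paste0("seq", seq_along(cds))
  counts <- stats::setNames(integer(length(code$codons)), code$codons)
  n_stop <- 0L
  for (i in seq_along(cds)) {
    check_dna(cds[i], nms[i])
    cod <- codon_split(cds[i])
    ok <- !grepl("N", cod, fixed = TRUE)
    is_stop <- cod %in% code$stop_codons
    internal <- which(is_stop & seq_along(cod) < length(cod))
    if (length(internal))
      warning("internal stop codon(s) in ", nms[i], " at codon position(s) ",
              paste(internal, collapse = ", "), "; excluded from counts",
              call. = FALSE)
    n_stop <- n_stop + sum(is_stop & ok)
    keep <- cod[ok & !is_stop]
    if (length(keep)) {
      tab <- table(keep)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
  }
  structure(list(codon_counts = counts,
                 n_codons = sum(counts[code$sense_codons]),
                 n_stop_codons = n_stop,
                 code = code),
            class = "codon_usage_summary")
}

#' @export
print.codon_usage_summary <- function(x, ...) {
  cat("<codon_usage_summary> ", x$n_codons, " sense codons (",
      x$n_stop_codons, " stops excluded), code table ", x$code$id, "\n",
      sep = "")
  top <- sort(x$codon_counts, decreasing = TRUE)[1:5]
  cat("  top codons:", paste(sprintf("%s=%d", names(top), top), collapse = " "),
      "\n")
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = observed(c) / (family_total / family_size)`: the observed
#' count of a codon divided by the count expected if all codons of its
#' synonymous family were used equally.  Codons of a family with zero total
#' count are `NA` (no usage to normalize), while an unused codon of a
#' present family is 0.  Within every present family the RSCU values sum to
#' the family size.
#'
#' @param x a `codon_usage_summary` from [count_codons()].
#' @param split_families split Leu into Leu1 (CUN) / Leu2 (UUR) and Ser into
#'   Ser1 (AGN) / Ser2 (UCN) for display-style denominators.
#' @return Named numeric vector over the sense codons.
#' @export
rscu <- function(x, split_families = FALSE) {
  stopifnot(inherits(x, "codon_usage_summary"))
  fams <- code_families(x$code, split = split_families)
  out <- stats::setNames(rep(NA_real_, length(x$code$sense_codons)),
                         x$code$sense_codons)
  for (f in fams) {
    tot <- sum(x$codon_counts[f])
    if (tot > 0) out[f] <- x$codon_counts[f] / (tot / length(f))
  }
  out
}

#' Classify codons by RSCU thresholds
#'
#' Codons with RSCU > 1.6 are called overrepresented and codons with
#' RSCU < 0.6 underrepresented (strict inequalities); a codon with count 0
#' in a family that is otherwise used is "unused"; everything else is
#' "neutral".  Codons of absent families stay `NA`.
#'
#' @param r named RSCU vector from [rscu()].
#' @return List: `class` (named character), `counts` (table over the four
#'   classes), `mean_rscu` (mean RSCU per class).
#' @export
classify_rscu <- function(r) {
  cls <- rep(NA_character_, length(r))
  names(cls) <- names(r)
  def <- !is.na(r)
  cls[def & r == 0] <- "unused"
  cls[def & r > 0 & r < 0.6] <- "underrepresented"
  cls[def & r > 1.6] <- "overrepresented"
  cls[def & is.na(cls)] <- "neutral"
  lev <- c("overrepresented", "underrepresented", "unused", "neutral")
  list(class = cls,
       counts = table(factor(cls, levels = lev)),
       mean_rscu = vapply(lev, function(l) {
         v <- r[!is.na(cls) & cls == l]
         if (length(v)) mean(v) else NA_real_
       }, numeric(1)))
}

#' Positional G+C content of counted codons
#'
#' G+C fraction at each codon position, computed over sense codons only
#' (stop codons are excluded upstream) and over all amino acids including
#' Met and Trp.  `gc12` is the arithmetic mean of `gc1` and `gc2`.
#'
#' @param x a `codon_usage_summary`.
#' @param synonymous_only restrict to codons of families with degeneracy
#'   >= 2 (a no-op under table 5, where every family is at least two-fold).
#' @return Named list: `gc1`, `gc2`, `gc3`, `gc12`.
#' @export
gc_positions <- function(x, synonymous_only = FALSE) {
  stopifnot(inherits(x, "codon_usage_summary"))
  sense <- x$code$sense_codons
  if (synonymous_only) sense <- sense[x$code$degeneracy[sense] >= 2]
  cnt <- x$codon_counts[sense]
  n <- sum(cnt)
  if (n == 0L) {
    warning("no sense codons counted: positional GC undefined", call. = FALSE)
    return(list(gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_, gc12 = NA_real_))
  }
  gcp <- function(pos)
    sum(cnt[substr(sense, pos, pos) %in% c("G", "C")]) / n
  gc1 <- gcp(1); gc2 <- gcp(2); gc3 <- gcp(3)
  list(gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = (gc1 + gc2) / 2)
}

#' Wright's effective number of codons (ENC)
#'
#' Wright's estimator adapted to the degeneracy classes of the active code.
#' For each synonymous family with at least two counted codons the codon
#' homozygosity is estimated as `F = (n * sum(p_i^2) - 1) / (n - 1)`;
#' families are grouped by degeneracy (under table 5: twelve 2-fold, six
#' 4-fold, one 6-fold and one 8-fold family), and
#' `ENC = sum_c K_c / Fbar_c` where `K_c` is the number of amino acids in
#' class `c` and `Fbar_c` the mean of the eligible `F` values (non-positive
#' estimates are excluded).  A class with no eligible family borrows the
#' mean of the next lower-degeneracy class that has one (4-fold from
#' 2-fold, 6-/8-fold from 4-fold; Wright-style interpolation, a message is
#' emitted).  The result is
#' clipped to `[20, number of sense codons]`; 20 corresponds to a single
#' codon per amino acid, the upper bound (62 under table 5) to uniform
#' usage.
#'
#' @param x a `codon_usage_summary`.
#' @return ENC value, or `NA` with a warning when no class is estimable.
#' @export
enc <- function(x) {
  stopifnot(inherits(x, "codon_usage_summary"))
  code <- x$code
  counts <- x$codon_counts
  deg <- lengths(code$families)
  classes <- split(names(code$families), deg)
  fhat <- function(codons) {
    n <- sum(counts[codons])
    if (n < 2) return(NA_real_)
    p <- counts[codons] / n
    (n * sum(p^2) - 1) / (n - 1)
  }
  k_c <- lengths(classes)
  fbar <- vapply(classes, function(aas) {
    v <- vapply(code$families[aas], fhat, numeric(1))
    v <- v[!is.na(v) & v > 0]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  # Wright-style interpolation for missing classes: a class with no eligible
  # family borrows the mean of the next lower-degeneracy class that has one
  # (4-fold from 2-fold, 6- and 8-fold from 4-fold).  Extreme A+T-rich
  # genomes can empty every 4-fold family (all require G/C at position 1 or
  # 2), and the 2-fold class is the only one guaranteed to survive.
  for (cl in as.character(sort(as.integer(names(fbar))))) {
    if (!is.na(fbar[[cl]])) next
    lower <- names(fbar)[as.integer(names(fbar)) < as.integer(cl) &
                           !is.na(fbar)]
    if (length(lower)) {
      src <- lower[which.max(as.integer(lower))]
      fbar[[cl]] <- fbar[[src]]
      message("ENC: no eligible ", cl, "-fold family; substituted the ",
              src, "-fold class mean")
    }
  }
  if (any(is.na(fbar))) {
    warning("ENC undefined: degeneracy class(es) ",
            paste(names(fbar)[is.na(fbar)], collapse = ", "),
            " have no eligible family", call. = FALSE)
    return(NA_real_)
  }
  val <- sum(k_c / fbar)
  min(max(val, 20), length(code$sense_codons))
}

#' Expected ENC under mutation pressure alone
#'
#' Wright's expectation for the effective number of codons of a gene whose
#' codon usage is shaped only by its silent-site G+C content `s` (GC3):
#' `ENC*(s) = 2 + s + 29 / (s^2 + (1 - s)^2)`.  Points falling clearly below
#' this curve on an ENC-GC3 plot indicate codon usage bias beyond what base
#' composition alone explains, i.e. selection.
#'
#' @param gc3 numeric vector of GC3 fractions in `[0, 1]`.
#' @return Expected ENC values (31 at the endpoints, maximum 60.5 at
#'   `s = 0.5`).
#' @examples
#' enc_expected(0.5)  # 60.5
#' @export
enc_expected <- function(gc3) {
  stopifnot(is.numeric(gc3), all(gc3 >= 0 & gc3 <= 1, na.rm = TRUE))
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' One-call codon-usage summary
#'
#' Convenience wrapper: counts codons and attaches RSCU, RSCU classes,
#' positional GC and ENC.
#'
#' @inheritParams count_codons
#' @return A `codon_usage_summary` with extra elements `rscu`,
#'   `rscu_class`, `gc1`, `gc2`, `gc3`, `gc12`, `enc`.
#' @export
codon_usage <- function(cds, code = genetic_code()) {
  x <- count_codons(cds, code)
  x$rscu <- rscu(x)
  x$rscu_class <- classify_rscu(x$rscu)$class
  gc <- gc_positions(x)
  x[c("gc1", "gc2", "gc3", "gc12")] <- gc[c("gc1", "gc2", "gc3", "gc12")]
  x$enc <- enc(x)
  x
}
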