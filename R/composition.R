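#' AT and GC strand skews
#'
#' Standard strand-asymmetry measures of Perna & Kocher:
#' `AT skew = (A - T)/(A + T)` and `GC skew = (G - C)/(G + C)`, computed on
#' the counts of unambiguous bases.  When the relevant base pair is absent
#' the skew is undefined and returned as `NA` with a warning.
#'
#' @param seq nucleotide string (A/C/G/T/N).
#' @return Numeric skew in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' at_skew("AAAA")  # 1
#' gc_skew("GGGC")  # 0.5
#' @export
at_skew <- function(seq) {
  n <- base_counts(seq)
  if (n[["A"]] + n[["T"]] == 0L) {
    warning("AT skew undefined: no A or T bases", call. = FALSE)
    return(NA_real_)
  }
  (n[["A"]] - n[["T"]]) / (n[["A"]] + n[["T"]])
}

#' @rdname at_skew
#' @export
gc_skew <- function(seq) {
  n <- base_counts(seq)
  if (n[["G"]] + n[["C"]] == 0L) {
    warning("GC skew undefined: no G or C bases", call. = FALSE)
    return(NA_real_)
  }
  (n[["G"]] - n[["C"]]) / (n[["G"]] + n[["C"]])
}

#' Base composition of one genome partition
#'
#' Computes length, base fractions, A+T content and AT/GC skews for one
#' partition of a mitogenome.  All metrics follow the majority-strand
#' convention: partition sequences are concatenated exactly as stored on the
#' majority strand (minus-strand features are not reverse-complemented).
#' `N` bases count toward `length_bp` but are excluded from both numerator
#' and denominator of every fraction.
#'
#' @param record a [mitogenome_record()].
#' @param partition one of `"whole"`, `"PCG"`, `"tRNA"`, `"rRNA"`, `"CR"`.
#' @return One-row data frame: `record_id`, `partition`, `length_bp`,
#'   `frac_a`, `frac_c`, `frac_g`, `frac_t`, `at_content`, `at_skew`,
#'   `gc_skew`.  An empty partition yields length 0 and `NA` metrics.
#' @export
composition_summary <- function(record,
                                partition = c("whole", "PCG", "tRNA", "rRNA", "CR")) {
  partition <- match.arg(partition)
  seqs <- extract_partition(record, partition, coding_strand = FALSE)
  s <- paste(seqs, collapse = "")
  len <- nchar(s)
  if (len == 0L) {
    return(new_df(record_id = record$id, partition = partition, length_bp = 0L,
                  frac_a = NA_real_, frac_c = NA_real_, frac_g = NA_real_,
                  frac_t = NA_real_, at_content = NA_real_,
                  at_skew = NA_real_, gc_skew = NA_real_))
  }
  n <- base_counts(s)
  tot <- sum(n)
  fr <- if (tot > 0) n / tot else rep(NA_real_, 4)
  atsk <- if (n[["A"]] + n[["T"]] > 0)
    (n[["A"]] - n[["T"]]) / (n[["A"]] + n[["T"]]) else NA_real_
  gcsk <- if (n[["G"]] + n[["C"]] > 0)
    (n[["G"]] - n[["C"]]) / (n[["G"]] + n[["C"]]) else NA_real_
  new_df(record_id = record$id, partition = partition, length_bp = len,
         frac_a = fr[["A"]], frac_c = fr[["C"]], frac_g = fr[["G"]],
         frac_t = fr[["T"]],
         at_content = fr[["A"]] + fr[["T"]],
         at_skew = atsk, gc_skew = gcsk)
}

#' Composition table over records and partitions
#'
#' @param records list of [mitogenome_record()] objects.
#' @param partitions partitions to tabulate.
#' @return Data frame, one row per record x non-degenerate partition.
#' @export
composition_table <- function(records,
                              partitions = c("whole", "PCG", "tRNA", "rRNA", "CR")) {
  rows <- list()
  for (rec in records)
    for (p in partitions)
      rows[[length(rows) + 1L]] <- composition_summary(rec, p)
  do.call(rbind, rows)
}

#' Two-group comparison of a composition metric
#'
#' Compares a metric (e.g. A+T content) between two groups of genomes with a
#' two-sided Mann-Whitney U test (default) or Welch t test.  Significance
#' tiers follow the usual plot annotation: `"***"` for p < 0.01, `"**"` for
#' p < 0.05, `"ns"` otherwise.  With a singleton group the p value is
#' flagged unreliable.
#'
#' @param a,b numeric vectors of the metric in the two groups.
#' @param method `"wilcox"` (rank-based, default) or `"t"`.
#' @return List of class `group_comparison`: `statistic`, `p_value`, `tier`,
#'   `median_a`, `median_b`, `diff_medians`, `n_a`, `n_b`, `method`,
#'   `reliable`.
#' @export
group_compare <- function(a, b, method = c("wilcox", "t")) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ht <- if (method == "wilcox")
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  else stats::t.test(a, b)
  p <- ht$p.value
  if (!is.finite(p)) p <- 1  # fully tied samples: no evidence against the null
  reliable <- min(length(a), length(b)) >= 2
  if (!reliable)
    warning("singleton group: p value unreliable", call. = FALSE)
  structure(list(
    statistic = unname(ht$statistic),
    p_value = p,
    tier = if (p < 0.01) "***" else if (p < 0.05) "**" else "ns",
    median_a = stats::median(a), median_b = stats::median(b),
    diff_medians = stats::median(a) - stats::median(b),
    n_a = length(a), n_b = length(b),
    method = method, reliable = reliable
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Two-sample %s test: statistic = %.4g, p = %.4g [%s]\n",
              if (x$method == "wilcox") "Mann-Whitney U" else "Welch t",
              x$statistic, x$p_value, x$tier))
  cat(sprintf("  medians: %.4g (n=%d) vs %.4g (n=%d), difference %.4g\n",
              x$median_a, x$n_a, x$median_b, x$n_b, x$diff_medians))
  if (!x$reliable) cat("  (singleton group: p unreliable)\n")
  invisible(x)
}
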