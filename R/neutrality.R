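# Neutrality-plot machinery: simple OLS fits for the ENC-GC3 and GC12-GC3
# relationships and the partition of codon-usage determinants into mutation
# pressure (slope) and selection (1 - slope).

#' Simple ordinary-least-squares fit
#'
#' Fits `y = intercept + slope * x` and reports the correlation, the F
#' statistic of the slope (`F = r^2 (n-2) / (1-r^2)`, referred to
#' `F(1, n-2)`) and its two-sided p value — the reporting style used for
#' ENC-GC3 and neutrality-plot regressions.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`; `x` must not be
#'   constant.
#' @return Object of class `regression_fit`: `n`, `slope`, `intercept`,
#'   `r`, `F_stat`, `p_value`, `residual_sd`.
#' @examples
#' fit <- ols_fit(c(0, 1, 2), c(1, 3, 5))
#' fit$slope      # 2
#' fit$intercept  # 1
#' @export
ols_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 points for a regression fit")
  if (diff(range(x)) == 0) stop("x is constant: fit is degenerate")
  fit <- stats::lm(y ~ x)
  # a residual-free fit (points exactly on a line) is a legitimate input
  # here; summary.lm's "essentially perfect fit" caution is muffled
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  r <- stats::cor(x, y)
  F_stat <- if (!is.null(sm$fstatistic)) unname(sm$fstatistic["value"]) else Inf
  structure(list(
    n = n,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = r,
    F_stat = F_stat,
    p_value = stats::pf(F_stat, 1, n - 2, lower.tail = FALSE),
    residual_sd = sm$sigma
  ), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): y = %.4g + %.4g x\n", x$n, x$intercept, x$slope))
  cat(sprintf("  r = %.4g, F(1, %d) = %.4g, p = %.4g, residual sd = %.4g\n",
              x$r, x$n - 2, x$F_stat, x$p_value, x$residual_sd))
  invisible(x)
}

#' Mutation/selection partition from a neutrality-plot slope
#'
#' On a GC12-versus-GC3 neutrality plot the regression slope estimates the
#' fraction of the compositional trend that directional mutation pressure
#' explains; the complement is attributed to selection.  A slope of 1 means
#' mutation alone, a slope of 0 means selection alone.  Slopes outside
#' `[0, 1]` are reported as-is with a warning, since the interpretation
#' breaks down there.
#'
#' @param fit a `regression_fit` from [ols_fit()] of GC12 on GC3 (or a bare
#'   numeric slope).
#' @return List: `mutation_pct = 100 * slope`,
#'   `selection_pct = 100 * (1 - slope)`; the two always sum to 100.
#' @examples
#' neutrality_partition(0.5045)  # mutation 50.45%, selection 49.55%
#' @export
neutrality_partition <- function(fit) {
  slope <- if (inherits(fit, "regression_fit")) fit$slope else as.numeric(fit)
  stopifnot(length(slope) == 1, is.finite(slope))
  if (slope < 0 || slope > 1)
    warning("slope ", format(slope), " outside [0, 1]: ",
            "mutation/selection partition not interpretable", call. = FALSE)
  list(mutation_pct = 100 * slope, selection_pct = 100 * (1 - slope))
}

#' Neutrality-plot points for a set of mitogenomes
#'
#' One point per species: codon positions are pooled over the concatenated
#' protein-coding genes (coding strands), then GC3 and GC12 are computed
#' from the pooled codon counts.  Records without any annotated PCG are
#' skipped with a warning.
#'
#' @param records list of [mitogenome_record()] objects.
#' @param code a [genetic_code()].
#' @return Data frame: `record_id`, `gc3`, `gc12`.
#' @export
neutrality_points <- function(records, code = genetic_code()) {
  rows <- list()
  for (rec in records) {
    cds <- extract_partition(rec, "PCG")
    if (!length(cds)) {
      warning("record ", rec$id, " has no protein-coding genes; skipped",
              call. = FALSE)
      next
    }
    gc <- gc_positions(count_codons(cds, code))
    rows[[length(rows) + 1L]] <- new_df(record_id = rec$id,
                                        gc3 = gc$gc3, gc12 = gc$gc12)
  }
  if (!length(rows)) stop("no record with protein-coding genes")
  do.call(rbind, rows)
}

#' ENC-GC3 points with the mutation-only expectation
#'
#' Per species: pooled PCG codon counts give GC3 and the observed ENC;
#' `enc_null` is [enc_expected()] at that GC3.  The vertical gap
#' `enc_null - enc` measures codon-usage bias beyond base composition.
#'
#' @inheritParams neutrality_points
#' @return Data frame: `record_id`, `gc3`, `enc`, `enc_null`.
#' @export
enc_gc3_points <- function(records, code = genetic_code()) {
  rows <- list()
  for (rec in records) {
    cds <- extract_partition(rec, "PCG")
    if (!length(cds)) {
      warning("record ", rec$id, " has no protein-coding genes; skipped",
              call. = FALSE)
      next
    }
    cu <- count_codons(cds, code)
    gc <- gc_positions(cu)
    rows[[length(rows) + 1L]] <- new_df(record_id = rec$id, gc3 = gc$gc3,
                                        enc = enc(cu),
                                        enc_null = enc_expected(gc$gc3))
  }
  if (!length(rows)) stop("no record with protein-coding genes")
  do.call(rbind, rows)
}
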