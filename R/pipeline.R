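# End-to-end comparative pipeline over labelled groups of mitogenomes:
# composition + group tests, pooled RSCU per group, ENC-GC3 table,
# neutrality fit and mutation/selection partition per group, per-gene
# Ka/Ks per group, and the gene-order comparison matrix, with one summary
# JSON tying the headline numbers together.

#' Group manifest for the comparative pipeline
#'
#' @param paths character vector of GenBank file paths.
#' @param groups group label per path (>= 1 distinct label, non-empty).
#' @param reference optional path to the reference mitogenome used for
#'   Ka/Ks (skipped when `NULL`).
#' @return Object of class `group_manifest`.
#' @export
group_manifest <- function(paths, groups, reference = NULL) {
  stopifnot(length(paths) == length(groups), length(paths) >= 1)
  groups <- as.character(groups)
  if (any(is.na(groups) | !nzchar(groups))) stop("group labels must be non-empty")
  structure(list(paths = paths, groups = groups, reference = reference),
            class = "group_manifest")
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparative pipeline
#'
#' Parses every genome in the manifest and writes, under `outdir`:
#' `composition.tsv` (per record x partition), `composition_tests.tsv`
#' (two-group tests per partition/metric when two or more groups are
#' present), `rscu_<group>.tsv` (pooled codon table per group),
#' `enc_gc3.tsv` (per-record GC3, ENC and mutation-only expectation),
#' `neutrality.tsv` (per-record GC12/GC3 points), `kaks.tsv` (per
#' species x gene, when a reference is given), `gene_order_distances.tsv`
#' and `adjacency_freq.tsv`, plus `summary.json` with the headline
#' statistics and a warning log.  Any stage failure removes the partial
#' outputs and aborts with a stage-tagged error.
#'
#' @param manifest a [group_manifest()].
#' @param outdir output directory (created if needed).
#' @param code a [genetic_code()].
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
run_pipeline <- function(manifest, outdir, code = genetic_code()) {
  stopifnot(inherits(manifest, "group_manifest"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  stage <- "setup"
  emit <- function(d, name) {
    p <- file.path(outdir, name)
    .write_tsv(d, p)
    written <<- c(written, p)
    p
  }
  tryCatch({
    stage <- "parse"
    records <- withCallingHandlers(
      lapply(manifest$paths, read_genbank),
      warning = function(w) { note("parse: ", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    ids <- vapply(records, `[[`, "", "id")
    groups <- manifest$groups
    glev <- unique(groups)
    reference <- if (!is.null(manifest$reference))
      read_genbank(manifest$reference) else NULL

    stage <- "composition"
    comp <- composition_table(records)
    comp$group <- groups[match(comp$record_id, ids)]
    emit(comp, "composition.tsv")
    tests <- list()
    if (length(glev) >= 2) {
      for (p in unique(comp$partition))
        for (metric in c("length_bp", "at_content", "at_skew", "gc_skew")) {
          a <- comp[comp$partition == p & comp$group == glev[1], metric]
          b <- comp[comp$partition == p & comp$group == glev[2], metric]
          if (sum(!is.na(a)) < 1 || sum(!is.na(b)) < 1) next
          gt <- suppressWarnings(group_compare(a, b))
          tests[[length(tests) + 1L]] <-
            new_df(partition = p, metric = metric, statistic = gt$statistic,
                   p_value = gt$p_value, tier = gt$tier,
                   median_a = gt$median_a, median_b = gt$median_b)
        }
      if (length(tests)) emit(do.call(rbind, tests), "composition_tests.tsv")
    }

    stage <- "codon_usage"
    group_cu <- list()
    for (gl in glev) {
      cds <- unlist(lapply(records[groups == gl],
                           extract_partition, kind = "PCG"))
      cu <- withCallingHandlers(
        codon_usage(cds, code),
        warning = function(w) { note("codon_usage[", gl, "]: ",
                                     conditionMessage(w))
                                invokeRestart("muffleWarning") })
      group_cu[[gl]] <- cu
      tab <- new_df(codon = code$sense_codons,
                    aa = unname(code$codon_aa[code$sense_codons]),
                    count = unname(cu$codon_counts[code$sense_codons]),
                    rscu = unname(cu$rscu[code$sense_codons]),
                    class = unname(cu$rscu_class[code$sense_codons]))
      emit(tab, sprintf("rscu_%s.tsv", gsub("[^A-Za-z0-9_-]", "_", gl)))
    }

    stage <- "enc_gc3"
    encpts <- enc_gc3_points(records, code)
    encpts$group <- groups[match(encpts$record_id, ids)]
    emit(encpts, "enc_gc3.tsv")

    stage <- "neutrality"
    neut <- neutrality_points(records, code)
    neut$group <- groups[match(neut$record_id, ids)]
    emit(neut, "neutrality.tsv")
    neut_fits <- list()
    for (gl in glev) {
      d <- neut[neut$group == gl, ]
      if (nrow(d) >= 3 && diff(range(d$gc3)) > 0) {
        fit <- ols_fit(d$gc3, d$gc12)
        part <- suppressWarnings(neutrality_partition(fit))
        neut_fits[[gl]] <- list(n = fit$n, slope = fit$slope,
                                intercept = fit$intercept, r = fit$r,
                                F_stat = fit$F_stat, p_value = fit$p_value,
                                mutation_pct = part$mutation_pct,
                                selection_pct = part$selection_pct)
      } else note("neutrality[", gl, "]: too few points for a fit")
    }

    stage <- "kaks"
    kaks_summary <- NULL
    if (!is.null(reference)) {
      rows <- list()
      for (gl in glev) {
        gk <- withCallingHandlers(
          suppressMessages(group_kaks(records[groups == gl], reference,
                                      code = code)),
          warning = function(w) { note("kaks[", gl, "]: ", conditionMessage(w))
                                  invokeRestart("muffleWarning") })
        d <- gk$pairs; d$group <- gl
        rows[[gl]] <- d
        pg <- gk$per_gene; pg$group <- gl
        kaks_summary <- rbind(kaks_summary, pg)
      }
      emit(do.call(rbind, rows), "kaks.tsv")
      emit(kaks_summary, "kaks_per_gene.tsv")
    }

    stage <- "gene_order"
    orders <- withCallingHandlers(
      lapply(records, extract_order),
      warning = function(w) { note("gene_order: ", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    names(orders) <- ids
    if (!is.null(reference)) {
      orders[[reference$id]] <- extract_order(reference)
    }
    om <- order_matrix(orders)
    dm <- data.frame(record_id = rownames(om$distances), om$distances,
                     check.names = FALSE, stringsAsFactors = FALSE)
    emit(dm, "gene_order_distances.tsv")
    emit(om$adjacency_freq, "adjacency_freq.tsv")

    stage <- "summary"
    summary <- list(
      n_records = length(records),
      groups = stats::setNames(as.list(tabulate(factor(groups, glev),
                                                length(glev))), glev),
      at_content_mean = lapply(stats::setNames(glev, glev), function(gl) {
        d <- comp[comp$group == gl, ]
        lapply(split(d$at_content, d$partition), function(v)
          if (all(is.na(v))) NA else mean(v, na.rm = TRUE))
      }),
      composition_tests = if (length(tests)) do.call(rbind, tests) else NULL,
      rscu_class_counts = lapply(group_cu, function(cu)
        as.list(classify_rscu(cu$rscu)$counts)),
      enc = lapply(group_cu, function(cu) cu$enc),
      enc_mean_per_record = lapply(stats::setNames(glev, glev), function(gl)
        mean(encpts$enc[encpts$group == gl], na.rm = TRUE)),
      neutrality = neut_fits,
      kaks_per_gene = kaks_summary,
      warnings = log
    )
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows", pretty = TRUE)
    written <- c(written, file.path(outdir, "summary.json"))
    invisible(summary)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
}
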