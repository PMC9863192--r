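# Pairwise Ka/Ks by the Nei-Gojobori (1986) pathway-counting method with
# Jukes-Cantor correction, computed per mitochondrial protein-coding gene
# against a designated reference species.
#
# Potential sites: at each codon position the synonymous fraction is the
# share of the one-step changes NOT leading to a stop codon that preserve
# the amino acid; summed over the three positions this gives s in [0, 3]
# per codon, and N + S = 3 per codon by construction.  Observed
# differences: codon pairs differing at k positions are decomposed into the
# k! orderings of single steps; orderings passing through a stop codon are
# excluded, and synonymous/nonsynonymous step counts are averaged over the
# remaining equally weighted pathways.  If every complete pathway is
# blocked, the pair contributes the average over the maximal stop-free
# prefixes of the orderings (logged).

.ng_cache <- new.env(parent = emptyenv())

.perms <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

.mutate_codon <- function(codon, pos, base) {
  substr(codon, pos, pos) <- base
  codon
}

ng_tables <- function(code) {
  key <- code$id
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  codons <- code$codons
  aa <- code$codon_aa
  is_stop <- aa == "*"

  syn_sites <- stats::setNames(rep(NA_real_, 64L), codons)
  for (cd in codons[!is_stop]) {
    s <- 0
    for (pos in 1:3) {
      ref <- substr(cd, pos, pos)
      alts <- vapply(setdiff(DNA_BASES, ref), function(b) .mutate_codon(cd, pos, b), "")
      keep <- !is_stop[alts]
      if (any(keep)) s <- s + sum(aa[alts[keep]] == aa[[cd]]) / sum(keep)
    }
    syn_sites[cd] <- s
  }

  Sd <- Nd <- matrix(NA_real_, 64L, 64L, dimnames = list(codons, codons))
  partial <- matrix(FALSE, 64L, 64L, dimnames = list(codons, codons))
  sense <- codons[!is_stop]
  for (a in sense) {
    ab <- seq_chars(a)
    for (b in sense) {
      if (a == b) { Sd[a, b] <- 0; Nd[a, b] <- 0; next }
      bb <- seq_chars(b)
      d <- which(ab != bb)
      k <- length(d)
      paths <- list(); prefixes <- list()
      for (pm in .perms[[as.character(k)]]) {
        cur <- a; syn <- 0; non <- 0; blocked <- FALSE
        for (pos in d[pm]) {
          nxt <- .mutate_codon(cur, pos, bb[pos])
          if (is_stop[[nxt]]) { blocked <- TRUE; break }
          if (aa[[nxt]] == aa[[cur]]) syn <- syn + 1 else non <- non + 1
          cur <- nxt
        }
        rec <- c(syn, non)
        if (blocked) prefixes[[length(prefixes) + 1L]] <- rec
        else paths[[length(paths) + 1L]] <- rec
      }
      if (length(paths)) {
        m <- colMeans(do.call(rbind, paths))
      } else {
        # all complete pathways pass through a stop: average the stop-free
        # prefixes instead (undercounts the pair's differences, logged)
        m <- colMeans(do.call(rbind, prefixes))
        partial[a, b] <- TRUE
      }
      Sd[a, b] <- m[1]; Nd[a, b] <- m[2]
    }
  }
  tabs <- list(syn_sites = syn_sites, Sd = Sd, Nd = Nd, partial = partial)
  assign(key, tabs, envir = .ng_cache)
  tabs
}

# CodonAlignment -------------------------------------------------------------

#' Codon alignment container
#'
#' Two gap-aligned coding sequences represented as equal-length codon
#' vectors; gap codons are `"---"` (gaps only in whole-codon units, so the
#' frame is never shifted).
#'
#' @param a_codons,b_codons character vectors of codons / `"---"` gaps,
#'   equal length.
#' @param gene optional gene name carried through to results.
#' @return Object of class `codon_alignment`.
#' @export
codon_alignment <- function(a_codons, b_codons, gene = NA_character_) {
  stopifnot(length(a_codons) == length(b_codons))
  ok <- grepl("^([ACGTN]{3}|---)$", a_codons) & grepl("^([ACGTN]{3}|---)$", b_codons)
  if (!all(ok)) stop("alignment entries must be 3-nt codons or '---' gaps")
  structure(list(a_codons = a_codons, b_codons = b_codons, gene = gene),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  n <- length(x$a_codons)
  ng <- sum(x$a_codons != "---" & x$b_codons != "---")
  cat("<codon_alignment>", if (!is.na(x$gene)) x$gene, ":", n,
      "aligned codons,", ng, "gap-free pairs\n")
  invisible(x)
}

.load_blosum62 <- function() {
  if (is.null(.ng_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ng_cache$BLOSUM62 <- e$BLOSUM62
  }
  .ng_cache$BLOSUM62
}

#' Align two coding sequences codon-wise
#'
#' Global protein-level Needleman-Wunsch alignment (BLOSUM62, affine gap
#' penalties: opening 10, extension 1) back-translated to codons, so gaps
#' always fall on codon boundaries.  Terminal stop codons are removed
#' before alignment; internal stops are tolerated with a warning (they are
#' excluded from downstream Ka/Ks counting).
#'
#' @param seq_a,seq_b in-frame coding sequences (>= 3 nt).
#' @param code a [genetic_code()].
#' @param gene optional gene label.
#' @return A [codon_alignment()].
#' @export
align_codons <- function(seq_a, seq_b, code = genetic_code(),
                         gene = NA_character_) {
  prep <- function(s, who) {
    if (!nchar(s)) stop("empty sequence for ", who)
    check_dna(s, who)
    cod <- codon_split(s)
    if (!length(cod)) stop(who, " shorter than one codon")
    if (cod[length(cod)] %in% code$stop_codons) cod <- cod[-length(cod)]
    aa <- translate_codons(cod, code)
    if (any(aa == "*"))
      warning("internal stop codon(s) in ", who,
              if (!is.na(gene)) paste0(" (", gene, ")"),
              "; excluded from rate estimation", call. = FALSE)
    list(cod = cod, aa = paste(aa, collapse = ""))
  }
  A <- prep(seq_a, "seq_a"); B <- prep(seq_b, "seq_b")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(A$aa), Biostrings::AAString(B$aa),
    substitutionMatrix = .load_blosum62(),
    gapOpening = 10, gapExtension = 1, type = "global")
  pat <- seq_chars(as.character(Biostrings::pattern(pa)))
  sub <- seq_chars(as.character(Biostrings::subject(pa)))
  back <- function(aln_chars, codons) {
    out <- character(length(aln_chars)); j <- 0L
    for (i in seq_along(aln_chars)) {
      if (aln_chars[i] == "-") out[i] <- "---"
      else { j <- j + 1L; out[i] <- codons[j] }
    }
    out
  }
  codon_alignment(back(pat, A$cod), back(sub, B$cod), gene = gene)
}

# Nei-Gojobori ---------------------------------------------------------------

#' Ka/Ks by the Nei-Gojobori pathway method
#'
#' Counts potential synonymous/nonsynonymous sites and observed
#' differences over the gap-free codon pairs of an alignment (equal pathway
#' weighting, stop-avoiding pathways; see the package vignette), converts
#' the proportions with the Jukes-Cantor multiple-hit correction
#' `d = -(3/4) ln(1 - (4/3) p)`, and classifies the selection regime:
#' Ka/Ks < 1 purifying, = 1 neutral (tolerance 1e-9), > 1 positive.
#'
#' @param aln a [codon_alignment()] (or from [align_codons()]).
#' @param code a [genetic_code()].
#' @param min_codons minimum recommended gap-free codon pairs (warning
#'   below this).
#' @return Object of class `kaks_result`: `gene`, `n_codons`, `N_sites`,
#'   `S_sites`, `Nd`, `Sd`, `pN`, `pS`, `Ka`, `Ks`, `ratio`, `regime`.
#'   `ratio` is `NA` for identical sequences (regime `"undefined"`) and
#'   `Inf` when `Ks = 0 < Ka` (regime `"positive"`).
#' @export
nei_gojobori <- function(aln, code = genetic_code(), min_codons = 10L) {
  stopifnot(inherits(aln, "codon_alignment"))
  tabs <- ng_tables(code)
  a <- aln$a_codons; b <- aln$b_codons
  usable <- a != "---" & b != "---" &
    !grepl("N", a, fixed = TRUE) & !grepl("N", b, fixed = TRUE) &
    !(a %in% code$stop_codons) & !(b %in% code$stop_codons)
  a <- a[usable]; b <- b[usable]
  nc <- length(a)
  if (nc == 0L) stop("no usable codon pairs in alignment")
  if (nc < min_codons)
    warning("only ", nc, " usable codon pairs: estimates will be noisy",
            call. = FALSE)
  n_partial <- sum(tabs$partial[cbind(a, b)])
  if (n_partial > 0)
    message("nei_gojobori: ", n_partial,
            " codon pair(s) had all pathways blocked by stop codons; ",
            "stop-free prefixes used")
  S_sites <- sum((tabs$syn_sites[a] + tabs$syn_sites[b]) / 2)
  N_sites <- 3 * nc - S_sites
  Sd <- sum(tabs$Sd[cbind(a, b)])
  Nd <- sum(tabs$Nd[cbind(a, b)])
  pS <- if (S_sites > 0) Sd / S_sites else NA_real_
  pN <- if (N_sites > 0) Nd / N_sites else NA_real_
  jc <- function(p) {
    if (is.na(p) || p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ka <- jc(pN); Ks <- jc(pS)
  tol <- 1e-9
  if (is.na(Ka) || is.na(Ks)) {
    ratio <- NA_real_; regime <- "undefined"
  } else if (Ks == 0) {
    if (Ka > 0) { ratio <- Inf; regime <- "positive" }
    else { ratio <- NA_real_; regime <- "undefined" }
  } else {
    ratio <- Ka / Ks
    regime <- if (abs(ratio - 1) <= tol) "neutral"
              else if (ratio < 1) "purifying" else "positive"
  }
  structure(list(gene = aln$gene, n_codons = nc,
                 N_sites = N_sites, S_sites = S_sites,
                 Nd = Nd, Sd = Sd, pN = pN, pS = pS,
                 Ka = Ka, Ks = Ks, ratio = ratio, regime = regime),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result>%s %d codon pairs\n",
              if (!is.na(x$gene)) paste0(" ", x$gene, ":") else "", x$n_codons))
  cat(sprintf("  sites N = %.2f, S = %.2f; differences Nd = %.2f, Sd = %.2f\n",
              x$N_sites, x$S_sites, x$Nd, x$Sd))
  cat(sprintf("  Ka = %.4g, Ks = %.4g, Ka/Ks = %.4g [%s]\n",
              x$Ka, x$Ks, x$ratio, x$regime))
  invisible(x)
}

#' Per-gene Ka/Ks of a group of species against a reference
#'
#' Aligns each species' copy of each protein-coding gene to the reference
#' copy, runs [nei_gojobori()], and summarizes per-gene means of the
#' defined ratios.  Genes missing from a species are skipped with a
#' message; the reference must carry every requested gene.
#'
#' @param records list of [mitogenome_record()] objects.
#' @param reference reference [mitogenome_record()] (e.g. the ancestral-order
#'   outgroup used for all comparisons).
#' @param genes gene names to analyse (default: the 13 PCGs).
#' @param code a [genetic_code()].
#' @param ratio_method `"mean_of_ratios"` (default) averages the per-species
#'   Ka/Ks values; `"ratio_of_means"` divides mean Ka by mean Ks instead.
#' @return List with `pairs` (one row per species x gene: `record_id`,
#'   `gene`, `Ka`, `Ks`, `ratio`, `regime`) and `per_gene` (per-gene
#'   summary: `gene`, `mean_ratio`, `n_defined`, `n_undefined`).
#' @export
group_kaks <- function(records, reference, genes = PCG_NAMES,
                       code = genetic_code(),
                       ratio_method = c("mean_of_ratios", "ratio_of_means")) {
  ratio_method <- match.arg(ratio_method)
  ref_cds <- extract_partition(reference, "PCG")
  missing_ref <- setdiff(genes, names(ref_cds))
  if (length(missing_ref))
    stop("reference ", reference$id, " lacks gene(s): ",
         paste(missing_ref, collapse = ", "))
  rows <- list()
  for (rec in records) {
    cds <- extract_partition(rec, "PCG")
    for (g in genes) {
      if (!g %in% names(cds)) {
        message("gene ", g, " missing in ", rec$id, "; skipped")
        next
      }
      res <- nei_gojobori(align_codons(cds[[g]], ref_cds[[g]], code, gene = g),
                          code)
      rows[[length(rows) + 1L]] <-
        new_df(record_id = rec$id, gene = g, Ka = res$Ka, Ks = res$Ks,
               ratio = res$ratio, regime = res$regime)
    }
  }
  pairs <- do.call(rbind, rows)
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    d <- pairs[pairs$gene == g, , drop = FALSE]
    def <- is.finite(d$ratio)
    mr <- if (ratio_method == "mean_of_ratios") {
      if (any(def)) mean(d$ratio[def]) else NA_real_
    } else {
      ks <- mean(d$Ks[is.finite(d$Ks)])
      ka <- mean(d$Ka[is.finite(d$Ka)])
      if (is.finite(ks) && ks > 0) ka / ks else NA_real_
    }
    new_df(gene = g, mean_ratio = mr, n_defined = sum(def),
           n_undefined = sum(!def))
  }))
  list(pairs = pairs, per_gene = per_gene)
}
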