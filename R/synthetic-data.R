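# Synthetic annotated mitogenomes and divergent CDS pairs with known ground
# truth, emulating the statistical structure of scale-insect mitogenomes:
# extreme A+T richness (~86%), strong codon bias, 37 canonical genes with
# truncated tRNAs, a variable-length control region, and tRNA-block
# rearrangements relative to the ancestral insect gene order.

# default protein lengths (codons, incl. start, excl. stop), round figures
# near real insect mitochondrial genes; nad4L and atp8 stay short so their
# Ka/Ks estimates stay volatile, as observed in real data
DEFAULT_PCG_CODONS <- c(
  cox1 = 512L, cox2 = 229L, cox3 = 262L, cytb = 378L,
  nad1 = 312L, nad2 = 324L, nad3 = 117L, nad4 = 446L, nad4L = 89L,
  nad5 = 572L, nad6 = 160L, atp6 = 224L, atp8 = 53L)

DEFAULT_RRNA_BP <- c(rrnL = 1250L, rrnS = 750L)

#' Specification for synthetic mitogenome generation
#'
#' Bundles every tunable of [make_mitogenome()].  Defaults reproduce the
#' headline features of scale-insect mitogenomes: a whole-genome A+T target
#' of 0.86, a strongly biased per-species codon distribution (Dirichlet
#' concentration 0.15; smaller = stronger bias, ENC lower), truncated
#' tRNAs of 50-66 nt, a 100-1400 bp control region, and two random
#' tRNA-block rearrangements applied to the ancestral gene order.
#'
#' @param seed integer master seed; generation is deterministic under
#'   `(seed, index)`.
#' @param n_species number of genomes intended from this spec.
#' @param at_target whole-genome A+T fraction target (realized within
#'   +/- 0.02); values above 0.95 are rejected as infeasible.
#' @param codon_dirichlet_alpha Dirichlet concentration multiplier for the
#'   per-species codon usage distribution.
#' @param gene_order a [gene_order()] including a `CR` token; default the
#'   ancestral \emph{D. yakuba} arrangement.
#' @param n_rearrangements number of random tRNA-block
#'   transpositions/inversions applied per species.
#' @param trna_len_range,cr_len_range length ranges (bp) for tRNAs and the
#'   control region.
#' @param pcg_len_table named integer vector of codon counts per PCG.
#' @param code a [genetic_code()].
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_species = 5L, at_target = 0.86,
                           codon_dirichlet_alpha = 0.15,
                           gene_order = NULL, n_rearrangements = 2L,
                           trna_len_range = c(50L, 66L),
                           cr_len_range = c(100L, 1400L),
                           pcg_len_table = DEFAULT_PCG_CODONS,
                           code = genetic_code()) {
  stopifnot(at_target > 0, at_target < 1, n_rearrangements >= 0,
            codon_dirichlet_alpha > 0)
  if (at_target > 0.95)
    stop("at_target > 0.95 is infeasible for protein-coding sequence")
  if (is.null(gene_order))
    gene_order <- ancestral_gene_order(include_cr = TRUE, normalize = FALSE)
  stopifnot(inherits(gene_order, "gene_order"))
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 at_target = at_target,
                 codon_dirichlet_alpha = codon_dirichlet_alpha,
                 gene_order = gene_order,
                 n_rearrangements = as.integer(n_rearrangements),
                 trna_len_range = as.integer(trna_len_range),
                 cr_len_range = as.integer(cr_len_range),
                 pcg_len_table = pcg_len_table, code = code),
            class = "synthetic_spec")
}

# codon probabilities of an iid-nucleotide ("mutation only") model with the
# given per-position G+C fraction, restricted to sense codons; this is the
# null under which Wright's expected-ENC curve is derived
null_codon_probs <- function(gc, code) {
  pb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sense <- code$sense_codons
  w <- vapply(sense, function(cd) prod(pb[seq_chars(cd)]), numeric(1))
  w / sum(w)
}

.derive_seed <- function(seed, index) {
  ((abs(as.integer(seed)) %% 1000003L) * 2011L + as.integer(index) * 7L) %% 2147483647L
}

.sample_bases <- function(n, at) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

# random tRNA-block transposition or inversion applied to a token order
.rearrange_trna_block <- function(genes, strands) {
  is_trna <- genes %in% TRNA_NAMES
  starts <- which(is_trna)
  if (!length(starts)) return(list(genes = genes, strands = strands))
  s <- sample(starts, 1L)
  max_len <- 0L
  while (s + max_len <= length(genes) && is_trna[s + max_len]) max_len <- max_len + 1L
  len <- sample(seq_len(min(3L, max_len)), 1L)
  block <- s:(s + len - 1L)
  if (stats::runif(1) < 0.5) {
    # inversion: reverse the block and flip its signs
    genes[block] <- rev(genes[block])
    strands[block] <- rev(ifelse(strands[block] == "+", "-", "+"))
  } else {
    # transposition: move the block after a random position outside it
    gs <- genes[block]; ss <- strands[block]
    genes <- genes[-block]; strands <- strands[-block]
    pos <- sample(0:length(genes), 1L)
    genes <- append(genes, gs, after = pos)
    strands <- append(strands, ss, after = pos)
  }
  list(genes = genes, strands = strands)
}

#' Generate one synthetic annotated mitogenome
#'
#' Draws a per-species codon usage distribution from a Dirichlet tilted
#' toward A/T-rich codons, builds the 13 protein-coding genes codon-wise
#' (ATN start, TAA/TAG stop, no internal stops by construction), samples
#' tRNA/rRNA/control-region/spacer sequences from an iid base model at the
#' A+T target, lays the genes out in the (optionally rearranged) gene
#' order with random 0-30 bp spacers, and redraws until the realized
#' whole-genome A+T content is within +/- 0.02 of the target.  Output is
#' deterministic under `(spec$seed, index)`.
#'
#' @param spec a [synthetic_spec()].
#' @param index species index (1-based), part of the random stream key.
#' @param write_to optional path: also write the record as a GenBank flat
#'   file via [write_genbank()].
#' @return A [mitogenome_record()].  The realized codon probability vector
#'   is attached as attribute `"codon_probs"`, the realized (possibly
#'   rearranged) order as attribute `"true_order"`.
#' @export
make_mitogenome <- function(spec, index = 1L, write_to = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(.derive_seed(spec$seed, index))
  code <- spec$code
  at <- spec$at_target

  # fixed per-species gene order (drawn once, independent of AT redraws)
  g <- spec$gene_order$genes; s <- spec$gene_order$strands
  if (spec$n_rearrangements > 0)
    for (k in seq_len(spec$n_rearrangements)) {
      r <- .rearrange_trna_block(g, s)
      g <- r$genes; s <- r$strands
    }

  q <- null_codon_probs(1 - at, code)
  alpha <- spec$codon_dirichlet_alpha * length(code$sense_codons) * q
  sense <- code$sense_codons
  starts <- intersect(c("ATT", "ATA", "ATG", "ATC"), sense)

  for (attempt in seq_len(100L)) {
    gam <- stats::rgamma(length(alpha), shape = alpha)
    if (all(gam == 0)) next
    p <- gam / sum(gam)

    gene_seqs <- list()
    for (i in seq_along(g)) {
      nm <- g[i]
      if (nm %in% PCG_NAMES) {
        ncod <- spec$pcg_len_table[[nm]]
        body <- sample(sense, ncod - 1L, replace = TRUE, prob = p)
        gene_seqs[[nm]] <- paste0(
          sample(starts, 1L, prob = c(0.5, 0.3, 0.15, 0.05)[seq_along(starts)]),
          paste(body, collapse = ""),
          sample(c("TAA", "TAG"), 1L, prob = c(0.9, 0.1)))
      } else if (nm %in% TRNA_NAMES) {
        gene_seqs[[nm]] <- .sample_bases(
          sample(spec$trna_len_range[1]:spec$trna_len_range[2], 1L), at)
      } else if (nm %in% RRNA_NAMES) {
        gene_seqs[[nm]] <- .sample_bases(DEFAULT_RRNA_BP[[nm]], at)
      } else if (nm == "CR") {
        gene_seqs[[nm]] <- .sample_bases(
          sample(spec$cr_len_range[1]:spec$cr_len_range[2], 1L), at)
      } else stop("unknown gene token in order: ", nm)
    }

    # layout with random spacers
    pieces <- character(0)
    feats <- list()
    pos <- 1L
    for (i in seq_along(g)) {
      nm <- g[i]
      coding <- gene_seqs[[nm]]
      stored <- if (s[i] == "-") revcomp(coding) else coding
      len <- nchar(stored)
      feats[[i]] <- gene_feature(nm, kind_of_gene(nm), pos, pos + len - 1L,
                                 strand = if (nm == "CR") "+" else s[i],
                                 wraps = FALSE)
      pieces <- c(pieces, stored)
      pos <- pos + len
      spacer <- sample(0:30, 1L)
      if (spacer > 0 && i < length(g)) {
        pieces <- c(pieces, .sample_bases(spacer, at))
        pos <- pos + spacer
      }
    }
    sequence <- paste(pieces, collapse = "")
    n <- base_counts(sequence)
    realized_at <- (n[["A"]] + n[["T"]]) / sum(n)
    if (abs(realized_at - at) <= 0.02) {
      rec <- mitogenome_record(id = sprintf("SYN%03d", index),
                               sequence = sequence,
                               features = do.call(rbind, feats),
                               organism = sprintf("Synthetic coccoid %d", index))
      attr(rec, "codon_probs") <- p
      attr(rec, "true_order") <- gene_order(g, s, record_id = rec$id,
                                            normalize = FALSE)
      if (!is.null(write_to)) write_genbank(rec, write_to)
      return(rec)
    }
  }
  stop("could not realize A+T target ", at, " within +/- 0.02 in 100 draws")
}

# divergence simulation ------------------------------------------------------

#' Specification for a divergent coding-sequence pair
#'
#' @param seed integer seed.
#' @param n_codons number of codons in the ancestral sequence.
#' @param omega true Ka/Ks: the ratio of the acceptance probabilities of
#'   nonsynonymous to synonymous candidate substitutions (the larger of the
#'   two is 1, so omega > 1 models positive selection; changes to stop
#'   codons are always rejected).
#' @param target_dS expected synonymous substitutions per synonymous site,
#'   in (0, 0.7).
#' @param code a [genetic_code()].
#' @return Object of class `divergence_spec`.
#' @export
divergence_spec <- function(seed = 1L, n_codons = 300L, omega = 1,
                            target_dS = 0.2, code = genetic_code()) {
  stopifnot(omega > 0, target_dS > 0, target_dS < 0.7, n_codons >= 10)
  structure(list(seed = as.integer(seed), n_codons = as.integer(n_codons),
                 omega = omega, target_dS = target_dS, code = code),
            class = "divergence_spec")
}

#' Simulate a divergent coding-sequence pair with known ground truth
#'
#' Starting from an ancestral in-frame sequence (by default drawn uniformly
#' over the sense codons), candidate point mutations are placed by a
#' Poisson process over nucleotide sites and accepted with probabilities in
#' the ratio `1 : omega` for synonymous versus nonsynonymous changes (the
#' larger acceptance probability is 1); mutations creating stop codons are
#' always rejected.  The Poisson intensity is calibrated so the
#' expected accepted synonymous divergence equals `target_dS` (per
#' Nei-Gojobori synonymous site of the ancestor).  Accepted substitution
#' counts are returned as ground truth for parameter-recovery tests.
#'
#' @param dspec a [divergence_spec()].
#' @param ancestral optional ancestral CDS (multiple of 3 nt, no stops);
#'   generated when `NULL`.
#' @return List: `seq_a` (ancestor), `seq_b` (derived), `realized_dS`,
#'   `realized_dN` (accepted substitutions per ancestral NG site),
#'   `n_syn_subs`, `n_nonsyn_subs`, `S_sites`, `N_sites`.
#' @export
simulate_divergence <- function(dspec, ancestral = NULL) {
  stopifnot(inherits(dspec, "divergence_spec"))
  set.seed(dspec$seed)
  code <- dspec$code
  tabs <- ng_tables(code)
  sense <- code$sense_codons
  if (is.null(ancestral)) {
    cod <- sample(sense, dspec$n_codons, replace = TRUE)
  } else {
    check_dna(ancestral, "ancestral")
    cod <- codon_split(ancestral)
    if (any(cod %in% code$stop_codons)) stop("ancestral sequence contains stop codons")
  }
  ncod <- length(cod)
  L <- 3L * ncod

  # per-codon count of synonymous single-nucleotide changes (out of 9)
  syn_changes <- vapply(sense, function(cd) {
    tot <- 0L
    for (pos in 1:3) for (b in setdiff(DNA_BASES, substr(cd, pos, pos))) {
      alt <- .mutate_codon(cd, pos, b)
      if (code$codon_aa[[alt]] != "*" &&
          code$codon_aa[[alt]] == code$codon_aa[[cd]]) tot <- tot + 1L
    }
    tot
  }, integer(1))

  S_sites <- sum(tabs$syn_sites[cod])
  N_sites <- 3 * ncod - S_sites
  n_syn_total <- sum(syn_changes[cod])
  if (n_syn_total == 0) stop("ancestral sequence admits no synonymous change")
  # Relative acceptance rates: the nonsynonymous/synonymous acceptance
  # ratio equals omega, with the larger of the two equal to 1 so that
  # omega > 1 (positive selection) is representable.
  p_syn <- min(1, 1 / dspec$omega)
  p_non <- min(1, dspec$omega)
  # each event is uniform over the 3L possible single-base changes, so
  # P(candidate synonymous) = n_syn_total / (3L) and the expected accepted
  # synonymous count is lambda * p_syn * n_syn_total / (3L)
  lambda <- dspec$target_dS * S_sites * 3 * L / (n_syn_total * p_syn)

  derived <- cod
  n_events <- stats::rpois(1L, lambda)
  n_syn <- 0L; n_non <- 0L
  aamap <- code$codon_aa
  stops <- code$stop_codons
  for (e in seq_len(n_events)) {
    j <- sample.int(ncod, 1L)
    pos <- sample.int(3L, 1L)
    cur <- derived[j]
    b <- sample(setdiff(DNA_BASES, substr(cur, pos, pos)), 1L)
    alt <- .mutate_codon(cur, pos, b)
    if (alt %in% stops) next
    if (aamap[[alt]] == aamap[[cur]]) {
      if (stats::runif(1) < p_syn) { derived[j] <- alt; n_syn <- n_syn + 1L }
    } else {
      if (stats::runif(1) < p_non) { derived[j] <- alt; n_non <- n_non + 1L }
    }
  }
  list(seq_a = paste(cod, collapse = ""),
       seq_b = paste(derived, collapse = ""),
       realized_dS = n_syn / S_sites,
       realized_dN = n_non / N_sites,
       n_syn_subs = n_syn, n_nonsyn_subs = n_non,
       S_sites = S_sites, N_sites = N_sites)
}
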