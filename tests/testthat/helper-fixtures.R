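# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately written as naive, separate code paths (explicit
# loops, exhaustive enumeration) so they cannot share a bug with the
# package implementation.

# --- fixture builders -------------------------------------------------------

# lay named coding-strand gene sequences head-to-tail (2-bp spacers) into a
# mitogenome_record; gene kind inferred from the canonical name
toy_record_from_genes <- function(genes, strands = NULL, id = "TOY") {
  if (is.null(strands)) strands <- rep("+", length(genes))
  feats <- list(); pieces <- character(0); pos <- 1L
  for (i in seq_along(genes)) {
    nm <- names(genes)[i]
    coding <- genes[[i]]
    stored <- if (strands[i] == "-") mitocomp:::revcomp(coding) else coding
    len <- nchar(stored)
    feats[[i]] <- data.frame(name = nm, kind = mitocomp:::kind_of_gene(nm),
                             start = pos, end = pos + len - 1L,
                             strand = strands[i], wraps = FALSE,
                             stringsAsFactors = FALSE)
    pieces <- c(pieces, stored, "AA")
    pos <- pos + len + 2L
  }
  mitogenome_record(id, paste(pieces, collapse = ""), do.call(rbind, feats))
}

random_cds <- function(n_codons, code = genetic_code(), prob = NULL) {
  paste(sample(code$sense_codons, n_codons, replace = TRUE, prob = prob),
        collapse = "")
}

# random signed circular gene order over n toy genes
random_signed_order <- function(n) {
  gene_order(sample(paste0("g", seq_len(n))),
             sample(c("+", "-"), n, replace = TRUE),
             normalize = FALSE)
}

# --- counting oracles -------------------------------------------------------

# single-pass base counter with an explicit if/else chain
oracle_base_fracs <- function(seq) {
  a <- c <- g <- t <- 0L
  for (ch in strsplit(toupper(seq), "")[[1]]) {
    if (ch == "A") a <- a + 1L
    else if (ch == "C") c <- c + 1L
    else if (ch == "G") g <- g + 1L
    else if (ch == "T") t <- t + 1L
  }
  tot <- a + c + g + t
  list(a = a, c = c, g = g, t = t,
       frac = c(A = a, C = c, G = g, T = t) / tot)
}

# frame-0 3-mer histogram stepper
oracle_codon_hist <- function(seq) {
  seq <- toupper(seq)
  out <- list()
  i <- 1L
  while (i + 2L <= nchar(seq)) {
    cd <- substr(seq, i, i + 2L)
    out[[cd]] <- (out[[cd]] %||% 0L) + 1L
    i <- i + 3L
  }
  unlist(out)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# --- codon-usage oracles ----------------------------------------------------

oracle_rscu <- function(counts, families) {
  out <- list()
  for (fam in families) {
    tot <- 0
    for (cd in fam) tot <- tot + counts[[cd]]
    for (cd in fam) {
      out[[cd]] <- if (tot == 0) NA_real_
                   else counts[[cd] ] / (tot / length(fam))
    }
  }
  unlist(out)
}

oracle_rscu_classes <- function(rscu_values) {
  cls <- character(0)
  for (nm in names(rscu_values)) {
    v <- rscu_values[[nm]]
    cls[nm] <- if (is.na(v)) NA_character_
      else if (v == 0) "unused"
      else if (v > 1.6) "overrepresented"
      else if (v < 0.6) "underrepresented"
      else "neutral"
  }
  cls
}

# independent ENC: explicit per-family F-hat, explicit class bookkeeping
oracle_enc <- function(counts, code) {
  deg_of <- lengths(code$families)
  acc <- list()  # per degeneracy: vector of F-hat
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    n <- 0
    for (cd in fam) n <- n + counts[[cd]]
    if (n < 2) next
    ss <- 0
    for (cd in fam) ss <- ss + (counts[[cd]] / n)^2
    f <- (n * ss - 1) / (n - 1)
    if (f <= 0) next
    key <- as.character(deg_of[[aa]])
    acc[[key]] <- c(acc[[key]], f)
  }
  total <- 0
  for (d in sort(unique(deg_of))) {
    key <- as.character(d)
    k <- sum(deg_of == d)
    if (is.null(acc[[key]])) return(NA_real_)  # oracle has no fallback
    total <- total + k / mean(acc[[key]])
  }
  min(max(total, 20), length(code$sense_codons))
}

# --- gene-order oracles -----------------------------------------------------

# every physical junction of a signed circular order, represented by BOTH
# readings so set comparison is reading-direction independent
oracle_junctions <- function(genes, strands) {
  n <- length(genes)
  tok <- ifelse(strands == "-", paste0("-", genes), genes)
  flip <- function(x) ifelse(grepl("^-", x), sub("^-", "", x), paste0("-", x))
  out <- character(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    r1 <- paste(tok[i], tok[j])
    r2 <- paste(flip(tok[j]), flip(tok[i]))
    out <- c(out, paste(sort(c(r1, r2)), collapse = " | "))
  }
  unique(out)
}

oracle_breakpoints <- function(a, b) {
  ja <- oracle_junctions(a$genes, a$strands)
  jb <- oracle_junctions(b$genes, b$strands)
  sum(!(ja %in% jb))
}

# --- alignment oracle -------------------------------------------------------

# Gotoh affine-gap global alignment score; a gap of length k costs
# open + k * ext (first gap position pays both), matching the convention of
# the package's aligner
gotoh_score <- function(a, b, mat, open = 10, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- E <- F_ <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in seq_len(m)) E[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) F_[i + 1, 1] <- -(open + i * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[a[i], b[j]]
    M[i + 1, j + 1] <- s + max(M[i, j], E[i, j], F_[i, j])
    E[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                           E[i + 1, j] - ext,
                           F_[i + 1, j] - open - ext)
    F_[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                            F_[i, j + 1] - ext,
                            E[i, j + 1] - open - ext)
  }
  max(M[n + 1, m + 1], E[n + 1, m + 1], F_[n + 1, m + 1])
}
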