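# canonical token sets -------------------------------------------------------

PCG_NAMES  <- c("atp6", "atp8", "cox1", "cox2", "cox3", "cytb",
                "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
RRNA_NAMES <- c("rrnL", "rrnS")
TRNA_NAMES <- c("trnA", "trnR", "trnN", "trnD", "trnC", "trnQ", "trnE",
                "trnG", "trnH", "trnI", "trnK", "trnM", "trnF", "trnP",
                "trnT", "trnW", "trnY", "trnV",
                "trnL1", "trnL2", "trnS1", "trnS2")
CANONICAL_GENES <- c(PCG_NAMES, TRNA_NAMES, RRNA_NAMES)

kind_of_gene <- function(name) {
  ifelse(name %in% PCG_NAMES, "PCG",
  ifelse(name %in% TRNA_NAMES, "tRNA",
  ifelse(name %in% RRNA_NAMES, "rRNA",
  ifelse(name == "CR", "CR", NA_character_))))
}

# MitogenomeRecord -----------------------------------------------------------

#' Construct an annotated circular mitogenome record
#'
#' The central container of the package: the majority-strand sequence of a
#' circular mitogenome plus a table of typed, stranded gene features.
#' Coordinates are 1-based inclusive (GenBank convention); a feature crossing
#' the origin of the circular molecule carries `wraps = TRUE` and has
#' `start > end`.
#'
#' @param id accession or sample identifier.
#' @param sequence majority-strand nucleotide string over A/C/G/T/N; any
#'   other IUPAC ambiguity code is rejected.
#' @param features data frame with columns `name` (canonical gene token or
#'   `"CR"` or `"?"`), `kind` (`"PCG"`, `"tRNA"`, `"rRNA"`, `"CR"`),
#'   `start`, `end`, `strand` (`"+"`/`"-"`), `wraps` (logical).
#' @param organism free-text organism name.
#' @return An object of class `mitogenome_record` with elements `id`,
#'   `organism`, `sequence`, `length`, `features` (sorted by start).
#' @seealso [read_genbank()], [extract_partition()]
#' @export
mitogenome_record <- function(id, sequence, features, organism = "") {
  sequence <- toupper(sequence)
  check_dna(sequence, paste0("sequence of ", id))
  len <- nchar(sequence)
  stopifnot(is.data.frame(features))
  need <- c("name", "kind", "start", "end", "strand", "wraps")
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  f <- features[need]
  f$start <- as.integer(f$start); f$end <- as.integer(f$end)
  if (nrow(f)) {
    if (any(f$start < 1L | f$start > len | f$end < 1L | f$end > len))
      stop("feature coordinates outside [1, ", len, "]")
    bad <- !f$wraps & f$start > f$end
    if (any(bad)) stop("non-wrapping feature with start > end: ",
                       paste(f$name[bad], collapse = ", "))
    f <- f[order(f$start), , drop = FALSE]
    rownames(f) <- NULL
  }
  structure(list(id = id, organism = organism, sequence = sequence,
                 length = len, features = f),
            class = "mitogenome_record")
}

#' @export
print.mitogenome_record <- function(x, ...) {
  cat("<mitogenome_record> ", x$id,
      if (nzchar(x$organism)) paste0(" (", x$organism, ")"), "\n",
      "  ", x$length, " bp circular; ", nrow(x$features), " features (",
      sum(x$features$kind == "PCG"), " PCG, ",
      sum(x$features$kind == "tRNA"), " tRNA, ",
      sum(x$features$kind == "rRNA"), " rRNA, ",
      sum(x$features$kind == "CR"), " CR)\n", sep = "")
  invisible(x)
}

gene_feature <- function(name, kind, start, end, strand = "+", wraps = FALSE) {
  new_df(name = name, kind = kind, start = as.integer(start),
         end = as.integer(end), strand = strand, wraps = wraps)
}

feature_length <- function(feat, genome_length) {
  ifelse(feat$wraps,
         genome_length - feat$start + 1L + feat$end,
         feat$end - feat$start + 1L)
}

# slice one feature from the majority strand, unwrapping across the origin
feature_sequence <- function(record, i, coding_strand = TRUE) {
  f <- record$features[i, ]
  s <- if (f$wraps)
    paste0(substr(record$sequence, f$start, record$length),
           substr(record$sequence, 1L, f$end))
  else substr(record$sequence, f$start, f$end)
  if (coding_strand && identical(f$strand, "-")) revcomp(s) else s
}

# gene-name normalization ----------------------------------------------------

AA3 <- c(ala = "A", arg = "R", asn = "N", asp = "D", cys = "C", gln = "Q",
         glu = "E", gly = "G", his = "H", ile = "I", leu = "L", lys = "K",
         met = "M", phe = "F", pro = "P", ser = "S", thr = "T", trp = "W",
         tyr = "Y", val = "V")

.squash <- function(x) gsub("[^a-z0-9]+", "", tolower(x))

GENE_SYNONYMS <- local({
  syn <- list(
    atp6  = c("atp6", "atpase6", "atpsynthasef0subunit6", "atpsynthase6"),
    atp8  = c("atp8", "atpase8", "atpsynthasef0subunit8", "atpsynthase8"),
    cox1  = c("cox1", "coi", "co1", "coxi", "cytochromecoxidasesubunit1",
              "cytochromecoxidasesubuniti", "cytochromeoxidasesubunit1"),
    cox2  = c("cox2", "coii", "co2", "coxii", "cytochromecoxidasesubunit2",
              "cytochromecoxidasesubunitii"),
    cox3  = c("cox3", "coiii", "co3", "coxiii", "cytochromecoxidasesubunit3",
              "cytochromecoxidasesubunitiii"),
    cytb  = c("cytb", "cob", "cb", "cytochromeb"),
    nad1  = c("nad1", "nd1", "nadh1", "nadhdehydrogenasesubunit1"),
    nad2  = c("nad2", "nd2", "nadh2", "nadhdehydrogenasesubunit2"),
    nad3  = c("nad3", "nd3", "nadh3", "nadhdehydrogenasesubunit3"),
    nad4  = c("nad4", "nd4", "nadh4", "nadhdehydrogenasesubunit4"),
    nad4L = c("nad4l", "nd4l", "nadhdehydrogenasesubunit4l"),
    nad5  = c("nad5", "nd5", "nadh5", "nadhdehydrogenasesubunit5"),
    nad6  = c("nad6", "nd6", "nadh6", "nadhdehydrogenasesubunit6"),
    rrnL  = c("rrnl", "16s", "16srrna", "16sribosomalrna", "lrrna",
              "lsurrna", "rrn16", "largesubunitribosomalrna"),
    rrnS  = c("rrns", "12s", "12srrna", "12sribosomalrna", "srrna",
              "ssurrna", "rrn12", "smallsubunitribosomalrna"),
    CR    = c("cr", "dloop", "controlregion", "atrichregion",
              "putativecontrolregion")
  )
  tab <- stats::setNames(rep(names(syn), lengths(syn)), unlist(syn))
  tab
})

# decide trnL1/trnL2 (or trnS1/trnS2) from an anticodon string
.trna_from_anticodon <- function(anticodon) {
  ac <- toupper(gsub("U", "T", gsub("[^acgtu]", "", tolower(anticodon))))
  if (nchar(ac) != 3) return(NA_character_)
  cod <- revcomp(ac)  # representative decoded codon, 5'->3'
  two <- substr(cod, 1, 2)
  if (two == "CT") return("trnL1")
  if (cod %in% c("TTA", "TTG")) return("trnL2")
  if (two == "AG") return("trnS1")
  if (two == "TC") return("trnS2")
  NA_character_
}

#' Normalize a mitochondrial gene name to its canonical token
#'
#' Total function mapping the many synonyms found in deposited annotations
#' (COI/COX1/cox1, ND4L/nad4L, CYTB/COB, 16S/rrnL, tRNA-Leu(UUR)/trnL2, ...)
#' to the 37 canonical tokens plus `"CR"`.  The leucine and serine tRNA
#' isoacceptors are disambiguated from a codon-family tag in the name or
#' product (`CUN`/`UUR`, `AGN`/`UCN`, or an explicit 1/2 suffix), falling
#' back to the anticodon sequence when supplied.  Anything unrecognized maps
#' to `"?"` rather than erroring.
#'
#' @param raw gene name as annotated (e.g. from a `/gene` qualifier).
#' @param product optional `/product` qualifier text used as fallback.
#' @param anticodon optional anticodon sequence (DNA or RNA alphabet) for
#'   trnL/trnS disambiguation.
#' @return One of the canonical tokens, `"CR"`, or `"?"`.
#' @examples
#' normalize_gene_name("ND4L")            # "nad4L"
#' normalize_gene_name("tRNA-Ser(AGN)")   # "trnS1"
#' normalize_gene_name("COIII")           # "cox3"
#' @export
normalize_gene_name <- function(raw, product = NULL, anticodon = NULL) {
  raw <- as.character(raw %||% "")
  if (is.na(raw)) raw <- ""
  txt <- if (nzchar(raw)) raw else as.character(product %||% "")
  key <- .squash(txt)
  if (!nzchar(key)) return("?")
  if (txt %in% CANONICAL_GENES || txt == "CR") return(txt)
  hit <- unname(GENE_SYNONYMS[key])
  if (!is.na(hit)) return(hit)

  # tRNA patterns: trnX, trnX-..., tRNA-Xyz(...), with L/S family tags
  for (cand in unique(c(key, .squash(product %||% "")))) {
    if (!nzchar(cand)) next
    m <- regmatches(cand, regexec("^trna?([a-z0-9]*)$", cand))[[1]]
    if (length(m) == 2 && nzchar(m[2])) {
      rest <- m[2]
      aa <- NA_character_
      if (substr(rest, 1, 3) %in% names(AA3)) {
        aa <- AA3[[substr(rest, 1, 3)]]
        tag <- substr(rest, 4, nchar(rest))
      } else if (toupper(substr(rest, 1, 1)) %in% AA3) {
        aa <- toupper(substr(rest, 1, 1))
        tag <- substr(rest, 2, nchar(rest))
      } else tag <- ""
      if (!is.na(aa)) {
        if (!aa %in% c("L", "S")) return(paste0("trn", aa))
        # leucine / serine isoacceptors
        if (grepl("cun", tag)) return("trnL1")
        if (grepl("uur|ttr", tag)) return("trnL2")
        if (grepl("agn|agy", tag)) return("trnS1")
        if (grepl("ucn|tcn", tag)) return("trnS2")
        if (tag %in% c("1", "2")) return(paste0("trn", aa, tag))
        if (!is.null(anticodon)) {
          ac <- .trna_from_anticodon(anticodon)
          if (!is.na(ac) && substr(ac, 4, 4) == aa) return(ac)
        }
        return("?")
      }
    }
  }
  "?"
}

# GenBank flat-file reader ---------------------------------------------------

.parse_span <- function(s) {
  s <- gsub("[<>]", "", s)
  if (grepl("\\.\\.", s)) {
    parts <- as.integer(strsplit(s, "..", fixed = TRUE)[[1]])
    c(parts[1], parts[2])
  } else {
    v <- as.integer(s); c(v, v)
  }
}

.parse_location <- function(loc) {
  loc <- gsub("[[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^(join|order)\\(", loc)) {
    inner <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    spans <- lapply(strsplit(inner, ",", fixed = TRUE)[[1]], .parse_span)
    start <- spans[[1]][1]
    end <- spans[[length(spans)]][2]
    wraps <- start > end
  } else {
    sp <- .parse_span(loc)
    start <- sp[1]; end <- sp[2]
  }
  list(start = start, end = end, strand = strand, wraps = wraps)
}

.qualifier <- function(qlines, name) {
  pat <- paste0("^/", name, "(=|$)")
  i <- grep(pat, qlines)
  if (!length(i)) return(NULL)
  val <- sub(paste0("^/", name, "=?"), "", qlines[i[1]])
  gsub("^\"|\"$", "", val)
}

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Minimal flat-file parser covering the subset of the format produced by
#' mitogenome annotation pipelines (and by [write_genbank()]): LOCUS,
#' ACCESSION, ORGANISM, a FEATURES table with `CDS`, `tRNA`, `rRNA`,
#' `D-loop` and control-region `misc_feature` entries (locations may be
#' `complement(...)` and/or origin-spanning `join(...)`), and an ORIGIN
#' sequence block.  Gene names are normalized with [normalize_gene_name()];
#' a feature whose name cannot be mapped is retained with name `"?"` and a
#' warning, and feature types outside the four kinds are skipped.
#'
#' @param path path to a GenBank flat file.
#' @return A [mitogenome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- NA_character_
  if (length(locus)) id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "[[:space:]]+")[[1]][1]
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(sub("^ACCESSION", "", acc[1])), "[[:space:]]+")[[1]][1]
    if (!is.na(a) && nzchar(a)) id <- a
  }
  org <- grep("^[[:space:]]{0,4}ORGANISM", lines, value = TRUE)
  organism <- if (length(org)) trimws(sub("^[[:space:]]*ORGANISM", "", org[1])) else ""

  io <- grep("^ORIGIN", lines)
  if (!length(io)) stop("no ORIGIN sequence block in ", path, call. = FALSE)
  iend <- grep("^//", lines)
  iend <- if (length(iend)) iend[iend > io[1]][1] else length(lines) + 1L
  seq_lines <- lines[(io[1] + 1L):(iend - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("empty sequence block in ", path, call. = FALSE)

  ifeat <- grep("^FEATURES", lines)
  feats <- list()
  if (length(ifeat)) {
    block <- lines[(ifeat[1] + 1L):(io[1] - 1L)]
    keys <- which(grepl("^ {1,10}\\S", block) & !grepl("^ {12,}", block))
    bounds <- c(keys, length(block) + 1L)
    for (k in seq_along(keys)) {
      chunk <- block[keys[k]:(bounds[k + 1L] - 1L)]
      key <- sub("^\\s*(\\S+).*$", "\\1", chunk[1])
      body <- c(sub("^\\s*\\S+\\s*", "", chunk[1]), trimws(chunk[-1]))
      body <- body[nzchar(body)]
      qstart <- grep("^/", body)
      locstr <- paste(body[seq_len(if (length(qstart)) qstart[1] - 1L else length(body))],
                      collapse = "")
      # re-join qualifier continuation lines
      qlines <- character(0)
      if (length(qstart)) {
        idx <- qstart[1]:length(body)
        cur <- character(0)
        for (ln in body[idx]) {
          if (startsWith(ln, "/")) { qlines <- c(qlines, cur); cur <- ln }
          else cur <- paste(cur, ln)
        }
        qlines <- c(qlines, cur)
      }
      feats[[length(feats) + 1L]] <- list(key = key, loc = locstr, q = qlines)
    }
  }

  rows <- list()
  for (ft in feats) {
    kind <- switch(ft$key,
                   CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                   `D-loop` = "CR", misc_feature = "misc", NA_character_)
    if (is.na(kind)) next
    note <- .qualifier(ft$q, "note") %||% ""
    if (kind == "misc") {
      if (grepl("control region|a\\+t[- ]rich|d-loop", tolower(note))) kind <- "CR"
      else next
    }
    loc <- .parse_location(ft$loc)
    if (kind == "CR") {
      nm <- "CR"
    } else {
      gene <- .qualifier(ft$q, "gene")
      product <- .qualifier(ft$q, "product")
      antic <- .qualifier(ft$q, "anticodon")
      acseq <- if (!is.null(antic)) sub(".*seq:([A-Za-z]+).*", "\\1", antic) else NULL
      nm <- normalize_gene_name(gene %||% "", product = product, anticodon = acseq)
      if (nm == "?") {
        warning("could not map gene name ", sQuote(gene %||% product %||% "<unnamed>"),
                " in ", id, "; retained as \"?\"", call. = FALSE)
      } else if (kind_of_gene(nm) != kind) {
        # trust the feature type over the name-derived kind
        warning("feature type ", ft$key, " disagrees with gene name ", nm,
                " in ", id, call. = FALSE)
      }
    }
    rows[[length(rows) + 1L]] <-
      gene_feature(nm, kind, loc$start, loc$end, loc$strand, loc$wraps)
  }
  features <- if (length(rows)) do.call(rbind, rows) else
    gene_feature(character(0), character(0), integer(0), integer(0),
                 character(0), logical(0))
  mitogenome_record(id = id %||% basename(path), sequence = sequence,
                    features = features, organism = organism)
}

# GenBank writer -------------------------------------------------------------

.format_location <- function(f, genome_length) {
  core <- if (f$wraps)
    sprintf("join(%d..%d,1..%d)", f$start, genome_length, f$end)
  else sprintf("%d..%d", f$start, f$end)
  if (identical(f$strand, "-")) sprintf("complement(%s)", core) else core
}

#' Write a mitogenome record as a GenBank flat file
#'
#' Emits the subset of the format that [read_genbank()] parses, so that a
#' write/read round trip preserves sequence, coordinates, strands and gene
#' names bit-exactly.  Output is deterministic (fixed date stamp).
#'
#' @param record a [mitogenome_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  f <- record$features
  kind_key <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "D-loop")
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     circular INV 01-JAN-2000",
            record$id, record$length),
    sprintf("DEFINITION  %s mitochondrion, complete genome.",
            if (nzchar(record$organism)) record$organism else record$id),
    sprintf("ACCESSION   %s", record$id),
    "SOURCE      mitochondrion",
    sprintf("  ORGANISM  %s", record$organism),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", record$length),
    sprintf("                     /organism=\"%s\"", record$organism),
    "                     /organelle=\"mitochondrion\""
  )
  for (i in seq_len(nrow(f))) {
    key <- kind_key[[f$kind[i]]]
    out <- c(out,
             sprintf("     %-15s %s", key, .format_location(f[i, ], record$length)))
    if (f$kind[i] == "CR") {
      out <- c(out, "                     /note=\"control region\"")
    } else {
      out <- c(out, sprintf("                     /gene=\"%s\"", f$name[i]))
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(record$sequence)
  starts <- seq(1L, record$length, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, record$length))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", st, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

# partition extraction -------------------------------------------------------

#' Extract partition sequences from a mitogenome
#'
#' Returns the sequences of all features of one kind.  With
#' `coding_strand = TRUE` (the default) minus-strand features are
#' reverse-complemented so every sequence reads 5'->3' on its own coding
#' strand; with `coding_strand = FALSE` sequences are returned exactly as
#' stored on the majority strand, the convention used for composition and
#' skew statistics.
#'
#' @param record a [mitogenome_record()].
#' @param kind one of `"whole"`, `"PCG"`, `"tRNA"`, `"rRNA"`, `"CR"`.
#' @param coding_strand reverse-complement minus-strand features?
#' @return Named character vector of sequences (possibly empty).  For
#'   `"whole"`, the single majority-strand sequence named by the record id.
#' @export
extract_partition <- function(record,
                              kind = c("whole", "PCG", "tRNA", "rRNA", "CR"),
                              coding_strand = TRUE) {
  kind <- match.arg(kind)
  if (kind == "whole")
    return(stats::setNames(record$sequence, record$id))
  idx <- which(record$features$kind == kind)
  if (!length(idx)) return(stats::setNames(character(0), character(0)))
  seqs <- vapply(idx, function(i) feature_sequence(record, i, coding_strand), "")
  stats::setNames(seqs, record$features$name[idx])
}

# FASTA ----------------------------------------------------------------------

#' Write sequences as multi-FASTA
#'
#' @param entries named character vector (names become headers; everything
#'   after the first whitespace token survives in the header line but most
#'   downstream parsers treat only the first token as the id).
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
export_fasta <- function(entries, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  nms <- names(entries) %||% paste0("seq", seq_along(entries))
  for (i in seq_along(entries)) {
    writeLines(paste0(">", nms[i]), con)
    s <- entries[[i]]
    if (nchar(s)) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Read a multi-FASTA file of DNA sequences
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` returning a plain named
#' character vector.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
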