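# Signed circular gene-order extraction and comparison: shared adjacencies
# and breakpoint distance, the rearrangement statistics used in place of
# full scenario reconstruction.

#' Signed circular gene order
#'
#' A circular sequence of (gene token, strand sign) pairs.  Orders are
#' rotation-normalized to start at `cox1` when that gene is present (the
#' sign of `cox1` is preserved; only the rotation changes, which never
#' affects any comparison statistic).
#'
#' @param genes character vector of canonical gene tokens (unique).
#' @param strands `"+"`/`"-"` per gene (or signed tokens already merged
#'   into `genes` via [parse_gene_order()]).
#' @param record_id optional identifier.
#' @param normalize rotate to start at `cox1`?
#' @return Object of class `gene_order`: `record_id`, `genes`, `strands`,
#'   `normalized`.
#' @export
gene_order <- function(genes, strands = rep("+", length(genes)),
                       record_id = NA_character_, normalize = TRUE) {
  stopifnot(length(genes) == length(strands),
            all(strands %in% c("+", "-")))
  if (anyDuplicated(genes))
    stop("duplicate gene tokens in order: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  normalized <- FALSE
  if (normalize) {
    i <- match("cox1", genes)
    if (is.na(i)) {
      warning("cox1 absent: rotation normalization skipped", call. = FALSE)
    } else {
      idx <- c(i:length(genes), seq_len(i - 1L))
      genes <- genes[idx]; strands <- strands[idx]
      normalized <- TRUE
    }
  }
  structure(list(record_id = record_id, genes = genes, strands = strands,
                 normalized = normalized),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat("<gene_order>", if (!is.na(x$record_id)) x$record_id, ":",
      length(x$genes), "genes\n ", format_gene_order(x), "\n")
  invisible(x)
}

#' Format / parse one-line gene-order strings
#'
#' The text form is space-separated tokens with a `-` prefix for
#' minor-strand genes, e.g. `"cox1 trnL2 cox2 -trnK"`.
#'
#' @param order a [gene_order()].
#' @return `format_gene_order`: a single string.
#' @export
format_gene_order <- function(order) {
  paste(ifelse(order$strands == "-", paste0("-", order$genes), order$genes),
        collapse = " ")
}

#' @rdname format_gene_order
#' @param text one-line order string.
#' @param record_id,normalize passed to [gene_order()].
#' @return `parse_gene_order`: a [gene_order()].
#' @export
parse_gene_order <- function(text, record_id = NA_character_, normalize = TRUE) {
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  neg <- startsWith(toks, "-")
  gene_order(sub("^-", "", toks), ifelse(neg, "-", "+"),
             record_id = record_id, normalize = normalize)
}

#' Extract the signed gene order of a mitogenome
#'
#' Genes are listed by ascending start coordinate around the circle with
#' their strand signs.  Duplicate gene names collapse to the first
#' occurrence with a warning.  The control region is excluded by default
#' (it is length-variable and often unannotated).
#'
#' @param record a [mitogenome_record()].
#' @param include_cr keep the `CR` pseudo-gene in the order?
#' @param normalize rotate to start at `cox1`?
#' @return A [gene_order()].
#' @export
extract_order <- function(record, include_cr = FALSE, normalize = TRUE) {
  f <- record$features
  if (!include_cr) f <- f[f$kind != "CR", , drop = FALSE]
  f <- f[f$name != "?", , drop = FALSE]
  f <- f[order(f$start), , drop = FALSE]
  if (anyDuplicated(f$name)) {
    warning("duplicate gene(s) ",
            paste(unique(f$name[duplicated(f$name)]), collapse = ", "),
            " in ", record$id, ": keeping first occurrence", call. = FALSE)
    f <- f[!duplicated(f$name), , drop = FALSE]
  }
  gene_order(f$name, f$strand, record_id = record$id, normalize = normalize)
}

# signed circular adjacency set ----------------------------------------------
# A directed signed adjacency (x, y) describes the junction where the head
# of x meets the tail of y reading around the circle.  The same physical
# junction read on the other strand is (-y, -x); both encodings are
# collapsed to one canonical string so that adjacency comparison does not
# depend on an arbitrary reading direction.

.signed <- function(genes, strands) ifelse(strands == "-", paste0("-", genes), genes)

.flip <- function(tok) ifelse(startsWith(tok, "-"), sub("^-", "", tok),
                              paste0("-", tok))

adjacency_set <- function(order) {
  n <- length(order$genes)
  if (n < 2) stop("need at least 2 genes for adjacencies")
  tok <- .signed(order$genes, order$strands)
  nxt <- c(2:n, 1L)
  fwd <- paste(tok, tok[nxt], sep = " > ")
  rev <- paste(.flip(tok[nxt]), .flip(tok), sep = " > ")
  unique(pmin(fwd, rev))
}

restrict_order <- function(order, genes) {
  keep <- order$genes %in% genes
  gene_order(order$genes[keep], order$strands[keep],
             record_id = order$record_id, normalize = FALSE)
}

#' Shared signed adjacencies of two circular gene orders
#'
#' Both orders are restricted to their common gene set (removing a gene
#' joins its neighbours, as on the circle), then the canonical signed
#' adjacency sets are intersected.
#'
#' @param a,b [gene_order()] objects.
#' @return List: `shared` (character vector of canonical adjacency strings),
#'   `count`, `n_common` (common gene count).
#' @export
shared_adjacencies <- function(a, b) {
  common <- intersect(a$genes, b$genes)
  if (length(common) < 2)
    stop("fewer than 2 genes in common: adjacency comparison undefined")
  sa <- adjacency_set(restrict_order(a, common))
  sb <- adjacency_set(restrict_order(b, common))
  sh <- intersect(sa, sb)
  list(shared = sh, count = length(sh), n_common = length(common))
}

#' Breakpoint distance between circular gene orders
#'
#' The number of signed adjacencies of one order absent from the other
#' after restriction to the common gene set.  On equal gene sets this is a
#' symmetric pseudometric: zero exactly when the orders coincide up to
#' rotation (or reading direction).
#'
#' @param a,b [gene_order()] objects.
#' @return Non-negative integer.
#' @examples
#' x <- parse_gene_order("cox1 trnL2 cox2 -trnK atp8 atp6")
#' breakpoint_distance(x, x)  # 0
#' @export
breakpoint_distance <- function(a, b) {
  sh <- shared_adjacencies(a, b)
  sh$n_common - sh$count
}

#' Pairwise gene-order distance matrix and adjacency conservation
#'
#' @param orders list of [gene_order()] objects (>= 2), named or identified
#'   by their `record_id`.
#' @return List: `distances` (symmetric matrix of breakpoint distances) and
#'   `adjacency_freq` (data frame of canonical adjacencies with the
#'   fraction of orders containing each, sorted descending).
#' @export
order_matrix <- function(orders) {
  stopifnot(length(orders) >= 2)
  ids <- names(orders) %||% vapply(orders, function(o)
    o$record_id %||% NA_character_, "")
  ids[is.na(ids) | !nzchar(ids)] <- paste0("order", which(is.na(ids) | !nzchar(ids)))
  n <- length(orders)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- breakpoint_distance(orders[[i]], orders[[j]])
    m[i, j] <- d; m[j, i] <- d
  }
  all_adj <- lapply(orders, adjacency_set)
  freq <- sort(table(unlist(all_adj)) / length(orders), decreasing = TRUE)
  list(distances = m,
       adjacency_freq = new_df(adjacency = names(freq),
                               frequency = as.numeric(freq)))
}

#' Ancestral insect mitochondrial gene order
#'
#' The 37-gene (plus control region) order of \emph{Drosophila yakuba},
#' conventionally used as the ancestral reference arrangement for insect
#' mitogenome rearrangement analysis.  Shipped as a plain-text fixture.
#'
#' @param include_cr keep the control-region token?
#' @param normalize rotate to start at `cox1`?
#' @return A [gene_order()].
#' @export
ancestral_gene_order <- function(include_cr = FALSE, normalize = TRUE) {
  path <- system.file("extdata", "dyak_gene_order.txt", package = "mitocomp",
                      mustWork = TRUE)
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!startsWith(trimws(txt), "#") & nzchar(trimws(txt))][1]
  ord <- parse_gene_order(txt, record_id = "ancestral", normalize = normalize)
  if (!include_cr) {
    keep <- ord$genes != "CR"
    ord <- gene_order(ord$genes[keep], ord$strands[keep],
                      record_id = "ancestral", normalize = normalize)
  }
  ord
}
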