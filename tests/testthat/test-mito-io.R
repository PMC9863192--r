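test_that("GenBank write/read round trip preserves the record bit-exactly", {
  spec <- synthetic_spec(seed = 11, n_rearrangements = 1)
  rec <- make_mitogenome(spec, 1)
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, gb)
  rec2 <- read_genbank(gb)
  expect_identical(rec2$sequence, rec$sequence)
  expect_identical(rec2$length, rec$length)
  expect_identical(rec2$features, rec$features)
  expect_identical(rec2$id, rec$id)
  expect_equal(nrow(rec2$features), 38L)  # 37 genes + CR
})

test_that("gene-name normalization maps synonyms, is total and idempotent", {
  cases <- c(ND4L = "nad4L", COIII = "cox3", COI = "cox1", CYTB = "cytb",
             COB = "cytb", `16S` = "rrnL", `12S ribosomal RNA` = "rrnS",
             `tRNA-Trp` = "trnW", trnW = "trnW", `D-loop` = "CR",
             `control region` = "CR", `ATPase6` = "atp6", nad2 = "nad2",
             garbage = "?")
  for (i in seq_along(cases))
    expect_identical(normalize_gene_name(names(cases)[i]), unname(cases[i]))
  expect_identical(normalize_gene_name(""), "?")
  expect_identical(normalize_gene_name(NA), "?")
  # idempotence on canonical tokens
  for (tok in c("nad4L", "trnL1", "trnS2", "rrnL", "CR"))
    expect_identical(normalize_gene_name(tok), tok)
})

test_that("trnL/trnS isoacceptors are disambiguated by tag or anticodon", {
  expect_identical(normalize_gene_name("tRNA-Ser(AGN)"), "trnS1")
  expect_identical(normalize_gene_name("tRNA-Ser(UCN)"), "trnS2")
  expect_identical(normalize_gene_name("tRNA-Leu(CUN)"), "trnL1")
  expect_identical(normalize_gene_name("tRNA-Leu(UUR)"), "trnL2")
  # anticodon-based rescue: UAG decodes CUN codons -> trnL1, GCU -> AGN -> trnS1
  expect_identical(normalize_gene_name("tRNA-Leu", anticodon = "uag"), "trnL1")
  expect_identical(normalize_gene_name("tRNA-Leu", anticodon = "taa"), "trnL2")
  expect_identical(normalize_gene_name("tRNA-Ser", anticodon = "gct"), "trnS1")
  expect_identical(normalize_gene_name("tRNA-Ser", anticodon = "tga"), "trnS2")
  # neither tag nor anticodon: flagged rather than guessed
  expect_identical(normalize_gene_name("tRNA-Ser"), "?")
})

test_that("partition extraction honours strand and origin-wrapping semantics", {
  # toy 100-bp circle with a wrapping tRNA (start 95, end 6)
  base <- paste(rep("ACGT", 25), collapse = "")
  feats <- rbind(
    data.frame(name = "cox1", kind = "PCG", start = 10, end = 21,
               strand = "+", wraps = FALSE, stringsAsFactors = FALSE),
    data.frame(name = "trnQ", kind = "tRNA", start = 30, end = 39,
               strand = "-", wraps = FALSE, stringsAsFactors = FALSE),
    data.frame(name = "trnI", kind = "tRNA", start = 95, end = 6,
               strand = "+", wraps = TRUE, stringsAsFactors = FALSE))
  rec <- mitogenome_record("TOY", base, feats)

  whole <- extract_partition(rec, "whole")
  expect_identical(unname(whole), base)
  expect_identical(nchar(whole[[1]]), rec$length)

  trnas <- extract_partition(rec, "tRNA")
  # wrapping feature concatenates tail + head, manual slice as oracle
  manual <- paste0(substr(base, 95, 100), substr(base, 1, 6))
  expect_identical(unname(trnas[["trnI"]]), manual)
  # minus-strand feature comes back reverse-complemented...
  expect_identical(trnas[["trnQ"]], mitocomp:::revcomp(substr(base, 30, 39)))
  # ...and reverse-complement twice is the identity
  expect_identical(mitocomp:::revcomp(mitocomp:::revcomp(trnas[["trnQ"]])),
                   trnas[["trnQ"]])
  # empty partition is an empty vector, not an error
  expect_length(extract_partition(rec, "CR"), 0)
})

test_that("PCG partition footprint matches the summed feature lengths", {
  rec <- make_mitogenome(synthetic_spec(seed = 3), 2)
  pcg <- extract_partition(rec, "PCG")
  f <- rec$features[rec$features$kind == "PCG", ]
  brute <- sum(ifelse(f$wraps, rec$length - f$start + 1 + f$end,
                      f$end - f$start + 1))
  expect_identical(sum(nchar(pcg)), as.integer(brute))
  expect_length(pcg, 13)
})

test_that("FASTA export round-trips through an independent parser", {
  entries <- c(cox1 = "ATGAAATTTCCC", `gene with spaces` = "ACGT",
               longone = paste(rep("ACGTACGTAC", 20), collapse = ""))
  fa <- withr::local_tempfile(fileext = ".fa")
  export_fasta(entries, fa)
  back <- read_fasta(fa)  # Biostrings parser, not our writer's inverse
  expect_identical(unname(back), unname(entries))
  expect_identical(names(back), names(entries))
  # 70-column wrapping
  expect_true(all(nchar(readLines(fa)) <= 70))
  # empty set gives an empty file
  export_fasta(character(0), fa)
  expect_identical(readLines(fa), character(0))
})

test_that("parser rejects malformed input and flags unmappable names", {
  expect_error(mitogenome_record("X", "ACGTRYK", data.frame(
    name = character(0), kind = character(0), start = integer(0),
    end = integer(0), strand = character(0), wraps = logical(0))),
    "ambiguity")

  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 4 bp", "FEATURES             Location/Qualifiers",
               "     CDS             1..4", "                     /gene=\"cox1\""),
             gb)
  expect_error(read_genbank(gb), "sequence block")

  rec <- make_mitogenome(synthetic_spec(seed = 5), 1)
  gb2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, gb2)
  txt <- readLines(gb2)
  txt <- sub("/gene=\"cox1\"", "/gene=\"mystery_orf\"", txt, fixed = TRUE)
  writeLines(txt, gb2)
  expect_warning(rec2 <- read_genbank(gb2), "could not map")
  expect_true("?" %in% rec2$features$name)
  expect_identical(sum(rec2$features$name == "?"), 1L)
  expect_identical(rec2$features$kind[rec2$features$name == "?"], "PCG")
})
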