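code5 <- genetic_code()

test_that("the invertebrate mitochondrial code is wired correctly", {
  expect_length(code5$sense_codons, 62)
  expect_identical(sort(code5$stop_codons), c("TAA", "TAG"))
  expect_identical(unname(code5$codon_aa["TGA"]), "W")
  expect_identical(unname(code5$codon_aa["ATA"]), "M")
  expect_identical(unname(code5$codon_aa["AGA"]), "S")
  # degeneracy classes: twelve 2-fold, six 4-fold, Leu 6-fold, Ser 8-fold
  deg <- table(lengths(code5$families))
  expect_identical(as.integer(deg[c("2", "4", "6", "8")]), c(12L, 6L, 1L, 1L))
  # families partition the sense codons
  expect_setequal(unlist(code5$families), code5$sense_codons)
})

test_that("codon counting drops stops, dangling bases and N codons", {
  cu <- count_codons(c(g = "ATGTTTTAA"))
  expect_identical(unname(cu$codon_counts[c("ATG", "TTT")]), c(1L, 1L))
  expect_identical(cu$n_codons, 2L)        # TAA excluded
  expect_identical(cu$n_stop_codons, 1L)

  cu2 <- count_codons(c(g = "ATGTTTT"))    # dangling T dropped
  expect_identical(cu2$n_codons, 2L)

  cu3 <- count_codons(c(g = "ATGNNNTTT"))  # N codon skipped
  expect_identical(cu3$n_codons, 2L)

  expect_warning(count_codons(c(bad = "ATGTAATTTTAA")), "internal stop")
})

test_that("codon counts equal the frame-0 3-mer histogram oracle", {
  set.seed(55)
  for (rep in 1:3) {
    s <- random_cds(500, code5)
    cu <- count_codons(s, code5)
    want <- oracle_codon_hist(s)
    got <- cu$codon_counts[cu$codon_counts > 0]
    expect_identical(got[order(names(got))],
                     want[order(names(want))])
  }
})

test_that("RSCU matches its definition on hand-computed families", {
  # 2-fold family (Phe), counts (3, 3) -> (1, 1)
  r <- rscu(count_codons(paste(c(rep("TTT", 3), rep("TTC", 3)), collapse = "")))
  expect_equal(unname(r[c("TTT", "TTC")]), c(1, 1))
  # 2-fold extreme (6, 0) -> (2, 0)
  r <- rscu(count_codons(paste(rep("TTT", 6), collapse = "")))
  expect_equal(unname(r[c("TTT", "TTC")]), c(2, 0))
  # 4-fold family (Pro), counts (4, 2, 1, 1) -> (2, 1, 0.5, 0.5)
  cds <- paste(c(rep("CCT", 4), rep("CCC", 2), "CCA", "CCG"), collapse = "")
  r <- rscu(count_codons(cds))
  expect_equal(unname(r[c("CCT", "CCC", "CCA", "CCG")]), c(2, 1, 0.5, 0.5))
  # absent family flagged NA, not 0
  expect_true(is.na(r["GGA"]))
})

test_that("RSCU family sums and classes match the brute-force oracle", {
  set.seed(202)
  for (rep in 1:10) {
    cds <- random_cds(300, code5,
                      prob = mitocomp:::null_codon_probs(runif(1, 0.1, 0.6), code5))
    cu <- count_codons(cds, code5)
    r <- rscu(cu)
    want <- oracle_rscu(as.list(cu$codon_counts), code5$families)
    expect_equal(r[names(want)], want, tolerance = 1e-12)
    # family-sum conservation
    for (fam in code5$families) {
      if (sum(cu$codon_counts[fam]) > 0)
        expect_equal(sum(r[fam]), length(fam), tolerance = 1e-9)
    }
    cls <- classify_rscu(r)$class
    expect_identical(cls[names(want)], oracle_rscu_classes(want))
  }
})

test_that("RSCU thresholds are strict at 1.6 and 0.6", {
  r <- c(AAA = 1.7, AAG = 0.3)
  expect_identical(unname(classify_rscu(r)$class["AAA"]), "overrepresented")
  # a codon sitting exactly on a threshold is neutral
  r2 <- c(AAA = 1.4, AAG = 0.6)
  expect_identical(unname(classify_rscu(r2)$class["AAG"]), "neutral")
  r3 <- c(AAA = 1.6, AAG = 0.4)
  expect_identical(unname(classify_rscu(r3)$class["AAA"]), "neutral")
  expect_identical(unname(classify_rscu(r3)$class["AAG"]), "underrepresented")
})

test_that("positional GC content matches hand counts and the enumeration oracle", {
  gp <- gc_positions(count_codons("ATGTTT"))
  expect_equal(gp$gc3, 0.5)          # G and T at third positions
  expect_equal(gp$gc1, 0)
  expect_equal(gp$gc12, (gp$gc1 + gp$gc2) / 2)

  gp2 <- gc_positions(count_codons(paste(rep("GCG", 10), collapse = "")))
  expect_equal(gp2$gc3, 1)

  # uniform usage of every sense codon: enumeration oracle for position 3
  n_gc3 <- sum(vapply(code5$sense_codons,
                      function(cd) substr(cd, 3, 3) %in% c("G", "C"),
                      logical(1)))
  gp3 <- gc_positions(count_codons(paste(code5$sense_codons, collapse = "")))
  expect_equal(gp3$gc3, n_gc3 / 62)
  expect_equal(n_gc3, 31L)  # 16 ending C + 16 ending G - stop TAG
})

test_that("ENC hits its analytic limits and the dual-implementation oracle", {
  # floor: one codon per amino acid
  one_per_aa <- vapply(code5$families, `[`, "", 1)
  floor_cds <- paste(rep(one_per_aa, each = 3), collapse = "")
  expect_identical(enc(count_codons(floor_cds)), 20)

  # asymptotic no-bias limit: uniform draw over sense codons
  set.seed(77)
  u <- random_cds(50000, code5)
  expect_lt(abs(enc(count_codons(u)) - 62), 0.5)

  # small fixed table, one family per degeneracy class, vs the oracle
  cds <- paste(c(rep("TTT", 6), rep("TTC", 2),                       # Phe 2-fold
                 rep("CCT", 5), "CCC", "CCA", "CCG",                 # Pro 4-fold
                 rep("TTA", 7), rep("CTA", 3), "CTT", "CTC",         # Leu 6-fold
                 rep("TCA", 4), rep("AGT", 2), "TCT", "AGA"),        # Ser 8-fold
               collapse = "")
  cu <- count_codons(cds)
  expect_equal(enc(cu), oracle_enc(as.list(cu$codon_counts), code5),
               tolerance = 1e-12)

  # random tables against the oracle whenever the oracle is defined
  set.seed(13)
  for (rep in 1:5) {
    cu <- count_codons(random_cds(800, code5), code5)
    want <- oracle_enc(as.list(cu$codon_counts), code5)
    if (!is.na(want)) expect_equal(suppressMessages(enc(cu)), want,
                                   tolerance = 1e-12)
  }
})

test_that("ENC converges monotonically under integer scaling of the counts", {
  # scaling the counts leaves the codon proportions fixed while growing n,
  # so each family homozygosity estimate rises toward sum(p^2) and ENC
  # decreases monotonically toward its large-sample value
  base_cods <- c(rep("TTT", 4), "TTC", rep("CCT", 3), "CCA",
                 rep("TTA", 5), "CTT", rep("TCA", 3), "AGT")
  encs <- vapply(c(1, 2, 4, 8, 64), function(k)
    enc(count_codons(paste(rep(base_cods, k), collapse = ""))), numeric(1))
  expect_true(all(diff(encs) <= 1e-9))
  # convergence: successive changes shrink
  expect_lt(abs(encs[5] - encs[4]), abs(encs[2] - encs[1]))
})

test_that("the mutation-only ENC expectation follows the corrected Wright curve", {
  expect_equal(enc_expected(0.5), 2.5 + 29 / 0.5)   # 60.5
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  # grid-search oracle: the linear +s term shifts the curve's maximum just
  # above the symmetric point, to s = 0.502 on a 0.001 grid
  s <- seq(0.001, 0.999, by = 0.001)
  expect_equal(s[which.max(enc_expected(s))], 0.502, tolerance = 1e-9)
  expect_error(enc_expected(1.2))
})
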