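code5 <- genetic_code()

test_that("codon-wise alignment handles identity, indels and the DP oracle", {
  # identical sequences align gap-free
  s <- "ATGAAATTTCCC"
  aln <- align_codons(s, s)
  expect_false(any(aln$a_codons == "---"))
  expect_identical(aln$a_codons, aln$b_codons)

  # one inserted codon: alignment spans 3 codons with one gap
  aln2 <- align_codons("ATGTTT", "ATGGCTTTT")
  expect_length(aln2$a_codons, 3)
  expect_identical(sum(aln2$a_codons == "---"), 1L)
  expect_identical(paste(aln2$b_codons, collapse = ""), "ATGGCTTTT")

  # protein-level score equals an independently coded Gotoh DP
  blosum <- mitocomp:::.load_blosum62()
  set.seed(42)
  for (rep in 1:3) {
    na <- sample(40:60, 1)
    a_cod <- sample(code5$sense_codons, na, replace = TRUE)
    # derive b by local edits so the pair is alignable
    b_cod <- a_cod
    b_cod[sample(na, 5)] <- sample(code5$sense_codons, 5, replace = TRUE)
    b_cod <- b_cod[-sample(na, 2)]
    aln <- align_codons(paste(a_cod, collapse = ""), paste(b_cod, collapse = ""))
    prot <- function(cods) paste(mitocomp:::translate_codons(
      cods[cods != "---"], code5), collapse = "")
    got <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(prot(aln$a_codons)),
      Biostrings::AAString(prot(aln$b_codons)),
      substitutionMatrix = blosum, gapOpening = 10, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
    expect_equal(got, gotoh_score(prot(aln$a_codons), prot(aln$b_codons), blosum))
  }

  expect_error(align_codons("", "ATG"), "empty")
})

test_that("Nei-Gojobori counts sites and differences as defined", {
  # identical sequences: zero rates, undefined ratio
  s <- random_cds(60, code5)
  res <- nei_gojobori(align_codons(s, s), code5)
  expect_equal(res$Ka, 0)
  expect_equal(res$Ks, 0)
  expect_true(is.na(res$ratio))
  expect_identical(res$regime, "undefined")

  # exactly one synonymous third-position difference among 100 Phe/Leu codons
  a <- rep(c("TTT", "TTA"), 50)
  b <- a; b[1] <- "TTC"
  res2 <- nei_gojobori(codon_alignment(a, b), code5)
  expect_equal(res2$Sd, 1)
  expect_equal(res2$Nd, 0)
  expect_equal(res2$Ka, 0)
  expect_gt(res2$Ks, 0)

  # one nonsynonymous difference with no synonymous change: Ks = 0 < Ka
  a3 <- rep("TTT", 20); b3 <- a3; b3[1] <- "ATT"
  res3 <- suppressWarnings(nei_gojobori(codon_alignment(a3, b3), code5))
  expect_identical(res3$regime, "positive")
  expect_identical(res3$ratio, Inf)
})

test_that("site counts conserve N + S = 3 codons and the method is symmetric", {
  set.seed(321)
  for (rep in 1:5) {
    a <- sample(code5$sense_codons, 80, replace = TRUE)
    b <- sample(code5$sense_codons, 80, replace = TRUE)
    ra <- suppressMessages(nei_gojobori(codon_alignment(a, b), code5))
    expect_equal(ra$N_sites + ra$S_sites, 3 * ra$n_codons, tolerance = 1e-9)
    rb <- suppressMessages(nei_gojobori(codon_alignment(b, a), code5))
    expect_equal(ra$Ka, rb$Ka, tolerance = 1e-12)
    expect_equal(ra$Ks, rb$Ks, tolerance = 1e-12)
    expect_equal(ra$S_sites, rb$S_sites, tolerance = 1e-12)
    expect_equal(ra$Sd, rb$Sd, tolerance = 1e-12)
  }
})

test_that("neutral simulation is recovered near ratio 1", {
  ratios <- vapply(1:50, function(i) {
    d <- simulate_divergence(divergence_spec(seed = 5000 + i, n_codons = 300,
                                             omega = 1, target_dS = 0.2))
    nei_gojobori(codon_alignment(mitocomp:::codon_split(d$seq_a),
                                 mitocomp:::codon_split(d$seq_b)), code5)$ratio
  }, numeric(1))
  m <- mean(ratios[is.finite(ratios)])
  expect_gt(m, 0.85)
  expect_lt(m, 1.15)
})

test_that("recovered Ka/Ks is monotone in the simulated omega", {
  mean_ratio <- function(omega) {
    mean(vapply(1:8, function(i) {
      d <- simulate_divergence(divergence_spec(seed = 7000 + i, n_codons = 300,
                                               omega = omega, target_dS = 0.2))
      nei_gojobori(codon_alignment(mitocomp:::codon_split(d$seq_a),
                                   mitocomp:::codon_split(d$seq_b)), code5)$ratio
    }, numeric(1)))
  }
  ms <- vapply(c(0.1, 0.5, 1, 2), mean_ratio, numeric(1))
  expect_true(all(diff(ms) > 0))
})

test_that("per-gene group Ka/Ks straddles 1 according to gene-specific omega", {
  # two genes evolving from one ancestor: atp6 under purifying selection
  # (omega 0.2), nad3 under positive selection (omega 1.5)
  set.seed(88)
  anc_atp6 <- random_cds(220, code5)
  anc_nad3 <- random_cds(120, code5)
  ref <- toy_record_from_genes(c(atp6 = anc_atp6, nad3 = anc_nad3), id = "REF")
  recs <- lapply(1:3, function(i) {
    da <- simulate_divergence(divergence_spec(seed = 10 * i, omega = 0.2,
                                              target_dS = 0.3), anc_atp6)
    dn <- simulate_divergence(divergence_spec(seed = 10 * i + 1, omega = 1.5,
                                              target_dS = 0.3), anc_nad3)
    toy_record_from_genes(c(atp6 = da$seq_b, nad3 = dn$seq_b),
                          id = paste0("SP", i))
  })
  gk <- group_kaks(recs, ref, genes = c("atp6", "nad3"), code = code5)
  pg <- gk$per_gene
  expect_lt(pg$mean_ratio[pg$gene == "atp6"], 1)
  expect_gt(pg$mean_ratio[pg$gene == "nad3"], 1)
  expect_identical(nrow(gk$pairs), 6L)

  # group consisting of the reference itself: everything undefined
  self <- group_kaks(list(ref), ref, genes = c("atp6", "nad3"), code = code5)
  expect_true(all(self$pairs$regime == "undefined"))
  expect_identical(self$per_gene$n_undefined, c(1L, 1L))

  # reference missing a requested gene is a hard error
  expect_error(group_kaks(recs, ref, genes = c("atp6", "cox1")), "lacks")
})

test_that("near-zero omega yields near-zero nonsynonymous divergence", {
  d <- simulate_divergence(divergence_spec(seed = 31, n_codons = 500,
                                           omega = 1e-6, target_dS = 0.3))
  expect_equal(d$n_nonsyn_subs, 0L)
  res <- nei_gojobori(codon_alignment(mitocomp:::codon_split(d$seq_a),
                                      mitocomp:::codon_split(d$seq_b)), code5)
  expect_lt(res$Ka, 0.005)
  expect_gt(res$Ks, 0.15)
})
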