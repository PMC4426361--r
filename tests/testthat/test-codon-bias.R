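test_that("count_codons drops the stop, skips N codons, rejects internal stops", {
  tab <- count_codons("ATGGCTGCTTAA")
  expect_equal(as.numeric(tab[["ATG"]]), 1)
  expect_equal(as.numeric(tab[["GCT"]]), 2)
  expect_equal(sum(tab), 3)

  tab2 <- count_codons("ATGNNNGCT")
  expect_equal(attr(tab2, "skipped"), 1L)
  expect_equal(sum(tab2), 2)

  expect_error(count_codons("ATGTAAGCT"), "codon 2")
  expect_error(count_codons("ATGC"), "divisible by 3")
})

test_that("Nc is 20 for maximal bias and matches direct evaluation when uniform", {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  aa <- gc[sense]
  # one codon per amino acid, heavily used
  one_per <- vapply(split(sense, aa), `[`, character(1L), 1L)
  max_bias <- codon_usage(setNames(rep(500, length(one_per)), one_per))
  expect_equal(as.numeric(effective_number_of_codons(max_bias)), 20)

  # every sense codon exactly 100 times: finite-sample Nc slightly above 61;
  # frozen from the independent formula oracle
  uniform <- codon_usage(setNames(rep(100, length(sense)), sense))
  nc_u <- as.numeric(effective_number_of_codons(uniform))
  counts <- setNames(rep(100, length(sense)), sense)
  expect_equal(nc_u, oracle_nc(counts), tolerance = 1e-12)
  expect_gt(nc_u, 61)
  expect_lt(nc_u, 62)
})

test_that("Nc and CAI match independent oracles on random genes", {
  set.seed(77)
  ref <- random_usage(4000L)
  w <- relative_adaptiveness(ref)
  for (i in 1:50) {
    tab <- random_usage(sample(100:400, 1L))
    counts <- as.numeric(tab)
    names(counts) <- names(unclass(tab))
    nc <- as.numeric(effective_number_of_codons(tab))
    expect_equal(nc, oracle_nc(counts), tolerance = 1e-9)
    expect_equal(cai(tab, w), oracle_cai(counts, w), tolerance = 1e-9)
  }
})

test_that("uniform-regime genes have near-maximal Nc", {
  set.seed(41)
  opt <- mullerf:::.default_optimal_codons()
  for (i in 1:20) {
    tab <- count_codons(mullerf:::.sample_cds(3000L, 0, opt))
    nc <- as.numeric(effective_number_of_codons(tab))
    expect_gte(nc, 57); expect_lte(nc, 61.5)
  }
})

test_that("relative adaptiveness floors zero counts and normalizes per family", {
  ref <- codon_usage(c(GCT = 90, GCC = 10, GCA = 0, GCG = 0))
  w <- relative_adaptiveness(ref)
  expect_equal(w[["GCT"]], 1)
  expect_equal(w[["GCC"]], 10 / 90)
  expect_equal(w[["GCA"]], 0.5 / 90)
  expect_equal(w[["GCG"]], 0.5 / 90)
  # single-codon families always get w = 1
  expect_equal(w[["ATG"]], 1)
  expect_equal(w[["TGG"]], 1)

  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  uniform <- codon_usage(setNames(rep(10, length(sense)), sense))
  expect_true(all(relative_adaptiveness(uniform) == 1))
})

test_that("cai is the geometric mean over eligible codons", {
  ref <- codon_usage(c(GCT = 90, GCC = 10, GCA = 0, GCG = 0, TTT = 50,
                       TTC = 50))
  w <- relative_adaptiveness(ref)
  gene_opt <- codon_usage(c(GCT = 7, ATG = 2))
  expect_equal(cai(gene_opt, w), 1)

  w2 <- w; w2[["GCC"]] <- 0.25; w2[["GCT"]] <- 1
  gene2 <- codon_usage(c(GCT = 1, GCC = 1))
  expect_equal(cai(gene2, w2), 0.5)

  expect_error(cai(codon_usage(c(ATG = 5)), w), "eligible")
})

test_that("cai is invariant to codon order and multiset duplication", {
  set.seed(13)
  w <- relative_adaptiveness(random_usage(3000L))
  tab <- random_usage(150L)
  doubled <- codon_usage(setNames(2 * as.numeric(tab), names(unclass(tab))))
  expect_equal(cai(doubled, w), cai(tab, w), tolerance = 1e-12)
})

test_that("Nc converges monotonically toward its large-count limit", {
  set.seed(99)
  base <- random_usage(300L)
  nm <- names(unclass(base))
  scaled <- lapply(c(1, 10, 100, 1000), function(f)
    codon_usage(setNames(f * as.numeric(base), nm)))
  ncs <- vapply(scaled, function(t)
    as.numeric(effective_number_of_codons(t)), numeric(1L))
  # infinite-count limit: F-hat -> sum p^2 per family
  expect_true(all(diff(ncs) < 0))
  expect_lt(ncs[4L], ncs[1L])
})

test_that("no_bias_cai evaluates the stated baseline formula", {
  gcode <- Biostrings::GENETIC_CODE
  sense <- names(gcode)[gcode != "*"]
  uniform <- codon_usage(setNames(rep(10, length(sense)), sense))
  expect_equal(no_bias_cai(relative_adaptiveness(uniform)), 1)

  # every two-fold family at w = {1, 0.5}, all others uniform
  w <- setNames(rep(1, length(sense)), sense)
  aa <- gcode[sense]
  twofold <- names(table(aa))[table(aa) == 2]
  for (a in twofold) w[sense[aa == a][2L]] <- 0.5
  expect_equal(no_bias_cai(w), exp(9 * log(0.5) / 59), tolerance = 1e-12)

  # flooring w upward never decreases the baseline
  w_hi <- pmax(w, 0.75)
  expect_gte(no_bias_cai(w_hi), no_bias_cai(w))

  # equal-family weighting is exposed as an option
  expect_equal(no_bias_cai(w, weighting = "equal_family"),
               exp(mean(c(rep(log(0.5) / 2, 9), rep(0, 9)))), tolerance = 1e-12)
})

test_that("reference-set selection is self-consistent", {
  set.seed(55)
  opt <- mullerf:::.default_optimal_codons()
  tabs <- lapply(1:12, function(i)
    count_codons(mullerf:::.sample_cds(200L, 0.5, opt)))
  names(tabs) <- sprintf("g%02d", 1:12)
  rs <- select_reference_set(tabs, top_fraction = 0.25)
  expect_true(rs$converged)
  expect_length(rs$genes, 3L)
  # re-scoring with the converged w reproduces the same top set
  scores <- vapply(tabs, cai, numeric(1L), w = rs$w)
  expect_setequal(names(sort(scores, decreasing = TRUE))[1:3], rs$genes)

  expect_error(select_reference_set(tabs[1:2]), "at least 10")
})

test_that("loess regime call recovers planted trends", {
  set.seed(10)
  nc <- runif(60, 25, 60)
  up <- loess_regime(nc, nc / 100)
  expect_equal(up$verdict, "mutational_bias")
  expect_equal(up$n_positive, 60L)
  expect_equal(up$fitted, nc / 100, tolerance = 1e-9)

  down <- loess_regime(nc, 1 - nc / 100)
  expect_equal(down$verdict, "selection")
  expect_equal(down$n_negative, 60L)

  expect_error(loess_regime(rep(30, 25), runif(25)), "degenerate")
  expect_error(loess_regime(nc[1:10], nc[1:10] / 100), "at least 20")
})
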