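small_cfg <- function(seed = 1L, ...) {
  args <- list(seed = seed, region_length = 40000L, n_genes = 6L,
               target_transposon_density = 0.2)
  user <- list(...)
  for (nm in names(user)) args[[nm]] <- user[[nm]]
  do.call(synth_config, args)
}

test_that("generate_genome is deterministic and hits the planted density", {
  cfg <- small_cfg(seed = 5L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome$seq, g2$genome$seq)
  expect_identical(g1$fragments, g2$fragments)

  density <- sum(g1$fragments$end - g1$fragments$start) / cfg$region_length
  expect_gte(density, cfg$target_transposon_density - 0.02)
  expect_lte(density, cfg$target_transposon_density + 0.02)
  expect_true(all(g1$fragments$end - g1$fragments$start >= 50L))
})

test_that("zero target density yields no fragments and binomial GC", {
  cfg <- small_cfg(seed = 2L, target_transposon_density = 0,
                   dinucleotide_runs = data.frame(dinuc = character(),
                                                  units = integer(),
                                                  copies = integer()))
  g <- generate_genome(cfg)
  expect_equal(nrow(g$fragments), 0L)
  n_gc <- sum(strsplit(g$genome$seq, "")[[1L]] %in% c("G", "C"))
  L <- cfg$region_length
  p <- cfg$background_gc
  expect_lt(abs(n_gc - L * p), 3 * sqrt(L * p * (1 - p)))
})

test_that("planted truth is recoverable from the emitted genome", {
  cfg <- small_cfg(seed = 9L)
  g <- generate_genome(cfg)
  for (i in seq_len(nrow(g$fragments)))
    expect_identical(substring(g$genome$seq, g$fragments$start[i] + 1L,
                               g$fragments$end[i]),
                     g$fragments$sequence[i])
  for (i in seq_len(nrow(g$runs))) {
    run <- substring(g$genome$seq, g$runs$start[i] + 1L, g$runs$end[i])
    expect_identical(run, strrep(g$runs$dinuc[i], g$runs$units[i]))
  }
  # planted fragments survive gene planting
  gm <- generate_gene_models(cfg, g)
  for (i in seq_len(nrow(g$fragments)))
    expect_identical(substring(gm$genome$seq, g$fragments$start[i] + 1L,
                               g$fragments$end[i]),
                     g$fragments$sequence[i])
})

test_that("planted genes have valid, recoverable CDS structure", {
  cfg <- small_cfg(seed = 3L)
  gm <- generate_gene_models(cfg, generate_genome(cfg))
  expect_length(gm$models, cfg$n_genes)
  stops <- c("TAA", "TAG", "TGA")
  for (m in gm$models) {
    cds <- extract_cds(m, gm$genome)
    expect_equal(nchar(cds) %% 3L, 0L)
    expect_equal(substr(cds, 1L, 3L), "ATG")
    expect_true(substr(cds, nchar(cds) - 2L, nchar(cds)) %in% stops)
    codons <- substring(cds, seq(1L, nchar(cds) - 3L, 3L),
                        seq(3L, nchar(cds) - 1L, 3L))
    expect_false(any(codons[-length(codons)] %in% stops))
  }
})

test_that("lambda = 1 with the optimal table uses only optimal codons", {
  opt <- mullerf:::.default_optimal_codons()
  cfg <- small_cfg(seed = 4L, codon_lambda = 1, n_genes = 3L)
  gm <- generate_gene_models(cfg, generate_genome(cfg))
  code <- Biostrings::GENETIC_CODE
  for (m in gm$models) {
    tab <- count_codons(extract_cds(m, gm$genome))
    used <- names(unclass(tab))[as.numeric(tab) > 0]
    used <- setdiff(used, "ATG")  # forced start codon
    expect_true(all(used %in% opt))
  }
})

test_that("lambda = 0 gives uniform within-family codon frequencies", {
  cfg <- synth_config(seed = 6L, region_length = 150000L, n_genes = 4L,
                      target_transposon_density = 0, codon_lambda = 0,
                      exon_count_distribution = list(dist = "fixed", value = 1),
                      exon_size_distribution = list(dist = "fixed", value = 7500))
  gm <- generate_gene_models(cfg, generate_genome(cfg))
  pooled <- Reduce(`+`, lapply(gm$models, function(m)
    as.numeric(count_codons(extract_cds(m, gm$genome)))))
  names(pooled) <- names(unclass(count_codons("ATGTAA")))
  code <- Biostrings::GENETIC_CODE
  fams <- split(names(pooled), code[names(pooled)])
  for (fam in fams) {
    if (length(fam) == 1L) next
    n <- sum(pooled[fam])
    p0 <- 1 / length(fam)
    se <- sqrt(n * p0 * (1 - p0))
    expect_true(all(abs(pooled[fam] - n * p0) < 4 * se + 3),
                label = paste("family", paste(fam, collapse = ",")))
  }
})

test_that("degenerate single-exon configuration flags median intron as 0", {
  cfg <- small_cfg(seed = 8L,
                   exon_count_distribution = list(dist = "fixed", value = 1))
  gm <- generate_gene_models(cfg, generate_genome(cfg))
  fv <- extract_features(gm$models[[1L]])
  expect_true(fv$single_exon)
  expect_equal(fv$median_intron_size, 0)
  expect_equal(fv$n_coding_exons, 1L)
})

test_that("ortholog tables plant reversals and wanderers as configured", {
  cfg0 <- synth_config(seed = 1L, n_genes = 10L, n_reversals = 0L,
                       n_wanderers = 0L)
  ot <- generate_ortholog_table(cfg0)
  ord <- shared_signed_order(ot$table, "spA", "spB")
  expect_equal(as.integer(ord), 1:10)

  cfg1 <- synth_config(seed = 2L, n_genes = 10L, n_reversals = 1L)
  ot1 <- generate_ortholog_table(cfg1)
  perm <- ot1$truth$permutation
  changed <- which(perm != 1:10 | perm < 0)
  expect_gte(length(changed), 1L)
  expect_equal(perm[changed], -rev(seq(min(changed), max(changed))))

  cfg3 <- synth_config(seed = 3L, n_genes = 20L, n_reversals = 3L)
  ot3 <- generate_ortholog_table(cfg3)
  d <- reversal_distance(shared_signed_order(ot3$table, "spA", "spB"))
  expect_lte(d, 3L)

  cfgw <- synth_config(seed = 4L, n_genes = 10L, n_reversals = 2L,
                       n_wanderers = 3L)
  otw <- generate_ortholog_table(cfgw)
  wf <- find_wanderers(otw$table)
  expect_setequal(wf$wanderers$gene_id, otw$truth$wanderers)

  expect_error(generate_ortholog_table(
    synth_config(seed = 5L, n_genes = 3L, n_wanderers = 4L)),
    "n_wanderers")
})

test_that("codon cohorts carry the planted regime structure", {
  sel <- generate_codon_cohort(60L, "selection", seed = 21L, n_codons = 200L)
  # high-lambda genes are more biased (lower Nc) and better adapted
  hi <- sel$lambda > 0.6; lo <- sel$lambda < 0.3
  expect_lt(median(sel$nc[hi]), median(sel$nc[lo]))
  expect_gt(median(sel$cai[hi]), median(sel$cai[lo]))
  mut <- generate_codon_cohort(60L, "mutational_bias", seed = 21L,
                               n_codons = 200L)
  hi <- mut$lambda > 0.6; lo <- mut$lambda < 0.3
  expect_lt(median(mut$nc[hi]), median(mut$nc[lo]))
  expect_lt(median(mut$cai[hi]), median(mut$cai[lo]))
})

test_that("write_fixtures emits a mutually consistent file bundle", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(seed = 13L)
  paths <- write_fixtures(cfg, dir)
  expect_true(all(file.exists(paths)))
  genome <- read_fasta(paths[["fasta"]])[[1L]]
  models <- read_bed12(paths[["genes"]])
  reps <- read_repeat_bed(paths[["repeats"]])
  gm <- generate_gene_models(cfg, generate_genome(cfg))
  expect_identical(genome$seq, gm$genome$seq)
  expect_equal(length(models), cfg$n_genes)
  expect_identical(models[[1L]]$exons, gm$models[[1L]]$exons)
  expect_equal(nrow(reps), nrow(gm$fragments))
  ot <- read_ortholog_table(paths[["orthologs"]])
  expect_s3_class(ot, "ortholog_table")
})
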