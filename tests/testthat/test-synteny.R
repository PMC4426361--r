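mk_table <- function(...) {
  rows <- list(...)
  ortholog_table(
    gene_id = vapply(rows, `[[`, character(1L), 1L),
    species = vapply(rows, `[[`, character(1L), 2L),
    element = vapply(rows, `[[`, character(1L), 3L),
    scaffold = "s",
    position = as.integer(vapply(rows, `[[`, character(1L), 4L)),
    strand = vapply(rows, `[[`, character(1L), 5L))
}

test_that("find_wanderers applies the F-anchored definition", {
  tab <- mk_table(
    c("w1", "sp1", "F", "1", "+"), c("w1", "sp2", "A", "1", "+"),
    c("k1", "sp1", "F", "2", "+"), c("k1", "sp2", "F", "2", "+"),
    c("m1", "sp1", "D", "3", "+"), c("m1", "sp2", "E", "3", "+"),
    c("u1", "sp1", "F", "4", "+"))
  res <- find_wanderers(tab)
  expect_equal(res$wanderers$gene_id, "w1")
  expect_equal(res$wanderers$from, "F")
  expect_equal(res$wanderers$to, "A")
  expect_equal(res$other_moves$gene_id, "m1")
  expect_equal(res$unplaced$gene_id, "u1")
  expect_false("k1" %in% res$wanderers$gene_id)
  expect_error(find_wanderers(tab[tab$species == "sp1", ]), "2 species")
})

test_that("shared_signed_order ranks by species A and signs by strand agreement", {
  tab <- mk_table(
    c("g1", "a", "F", "1", "+"), c("g2", "a", "F", "2", "+"),
    c("g3", "a", "F", "3", "+"), c("g4", "a", "F", "4", "+"),
    c("g1", "b", "F", "1", "+"), c("g3", "b", "F", "2", "-"),
    c("g2", "b", "F", "3", "-"), c("g4", "b", "F", "4", "+"))
  expect_equal(as.integer(shared_signed_order(tab, "a", "b")),
               c(1L, -3L, -2L, 4L))

  ident <- mk_table(
    c("g1", "a", "F", "1", "+"), c("g2", "a", "F", "2", "-"),
    c("g1", "b", "F", "1", "+"), c("g2", "b", "F", "2", "-"))
  expect_equal(as.integer(shared_signed_order(ident, "a", "b")), c(1L, 2L))

  flipped <- mk_table(
    c("g1", "a", "F", "1", "+"), c("g2", "a", "F", "2", "+"),
    c("g3", "a", "F", "3", "+"),
    c("g3", "b", "F", "1", "-"), c("g2", "b", "F", "2", "-"),
    c("g1", "b", "F", "3", "-"))
  expect_equal(as.integer(shared_signed_order(flipped, "a", "b")),
               c(-3L, -2L, -1L))

  # genes off the focal element in either species are excluded
  mixed <- mk_table(
    c("g1", "a", "F", "1", "+"), c("g2", "a", "A", "2", "+"),
    c("g1", "b", "F", "1", "+"), c("g2", "b", "F", "2", "+"),
    c("g3", "a", "F", "5", "+"), c("g3", "b", "F", "5", "+"))
  expect_length(shared_signed_order(mixed, "a", "b"), 2L)
  expect_error(shared_signed_order(mixed[1:4, ], "a", "b"), "fewer than 2")
})

test_that("syntenic_blocks counts co-conserved runs", {
  b1 <- syntenic_blocks(1:8)
  expect_equal(b1$n_blocks, 1L)
  expect_equal(b1$mean_genes_per_block, 8)

  b2 <- syntenic_blocks(c(2L, 1L))
  expect_equal(b2$n_blocks, 2L)
  expect_equal(b2$mean_genes_per_block, 1)

  b3 <- syntenic_blocks(c(1L, 2L, -5L, -4L, -3L, 6L))
  expect_equal(b3$n_blocks, 3L)
  expect_equal(b3$mean_genes_per_block, 2)
  expect_equal(b3$block_id, c(1L, 1L, 2L, 2L, 2L, 3L))

  # sign-discordant neighbours break blocks even when consecutive
  expect_equal(syntenic_blocks(c(1L, -2L))$n_blocks, 2L)
})

test_that("reversal_distance satisfies definitional cases and properties", {
  expect_equal(reversal_distance(1:6), 0L)
  expect_equal(reversal_distance(-1L), 1L)
  expect_equal(reversal_distance(c(2L, 1L)), 3L)
  expect_equal(reversal_distance(c(-2L, -1L)), 1L)
  expect_error(reversal_distance(c(1L, 3L)), "signed permutation")

  set.seed(17)
  inv_perm <- function(p) {
    out <- integer(length(p))
    out[abs(p)] <- seq_along(p) * sign(p)
    out
  }
  for (rep in 1:20) {
    n <- sample(3:8, 1L)
    p <- as.integer(sample(n) * sample(c(-1L, 1L), n, TRUE))
    d <- reversal_distance(p)
    expect_equal(reversal_distance(inv_perm(p)), d)
    expect_equal(d == 0L, identical(p, seq_len(n)))
    # block-count lower bound relationship
    blocks <- syntenic_blocks(p)$n_blocks
    expect_lte(d, length(p) + 1L)
  }
})

test_that("orientation = 'both' scores the global flip too", {
  p <- c(-3L, -2L, -1L)   # the whole element read backwards
  expect_equal(reversal_distance(p), 1L)
  expect_equal(reversal_distance(p, orientation = "both"), 0L)
})

test_that("reversal_scenario replays to the identity in d steps", {
  expect_equal(nrow(reversal_scenario(1:5)), 0L)
  sc <- reversal_scenario(-1L)
  expect_equal(nrow(sc), 1L)

  set.seed(29)
  for (rep in 1:15) {
    n <- sample(4:10, 1L)
    p <- as.integer(sample(n) * sample(c(-1L, 1L), n, TRUE))
    d <- reversal_distance(p)
    sc <- reversal_scenario(p)
    expect_equal(nrow(sc), d)
    cur <- p
    for (r in seq_len(nrow(sc)))
      cur <- mullerf:::.apply_reversal(cur, sc$i[r], sc$j[r])
    expect_identical(cur, seq_len(n))
  }
})

test_that("synteny_report assembles a consistent bundle", {
  cfg <- synth_config(seed = 37L, n_genes = 15L, n_reversals = 4L,
                      n_wanderers = 2L)
  ot <- generate_ortholog_table(cfg)
  rep_out <- synteny_report(ot$table, "spA", "spB")
  expect_equal(rep_out$n_shared, 13L)   # wanderers excluded from the element
  expect_lte(rep_out$reversal_distance, 6L)
  expect_equal(nrow(rep_out$scenario), rep_out$reversal_distance)
  expect_setequal(rep_out$wanderers$wanderers$gene_id, ot$truth$wanderers)
  expect_equal(rep_out$n_shared / rep_out$n_blocks,
               rep_out$mean_genes_per_block)
})

test_that("wanderer hotspot windows count flagged genes", {
  cfg <- synth_config(seed = 41L, n_genes = 20L, n_reversals = 0L,
                      n_wanderers = 0L)
  ot <- generate_ortholog_table(cfg)
  hs <- wanderer_hotspots(ot$table, "spA", c("g003", "g004", "g015"),
                          window = 10L)
  expect_equal(sum(hs$n_wanderers), 3L)
  expect_equal(hs$n_wanderers[1L], 2L)
  expect_equal(sum(hs$n_genes), 20L)
})

test_that("write_grimm emits the two-genome permutation format", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_grimm(c(2L, -1L, 3L), f)
  lines <- readLines(f)
  expect_equal(lines[2L], "1 2 3 $")
  expect_equal(lines[4L], "2 -1 3 $")
})
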