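test_that("read_fasta parses, upper-cases, and maps ambiguity codes to N", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "acgt", ">b", "NNN"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_equal(recs[["a"]]$seq, "ACGT")
  expect_equal(length(recs[["b"]]), 3L)

  writeLines(c(">a", "ACRT"), f)
  expect_warning(recs <- read_fasta(f), "1 ambiguous")
  expect_equal(recs[["a"]]$seq, "ACNT")

  expect_error(read_fasta(file.path(tempdir(), "absent.fa")), "not found")
})

test_that("seq_record rejects empty ids and zero-length sequences", {
  expect_error(seq_record("", "ACGT"), "non-empty")
  expect_error(seq_record("x", ""), "zero-length")
})

test_that("read_bed12 clips blocks to the thick region", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste("c", 0, 1000, "g1.t1", 0, "+", 100, 900, "0,0,0", 2,
                   "200,200,", "0,800,", sep = "\t"), f)
  m <- read_bed12(f)[[1L]]
  expect_equal(m$exons$start, c(100L, 800L))
  expect_equal(m$exons$end, c(200L, 900L))
  expect_equal(m$gene_id, "g1")
  expect_equal(m$transcript_id, "t1")

  # middle block entirely inside thick stays unclipped
  writeLines(paste("c", 0, 1000, "g2.t1", 0, "+", 150, 850, "0,0,0", 3,
                   "200,200,200,", "0,400,800,", sep = "\t"), f)
  m <- read_bed12(f)[[1L]]
  expect_equal(m$exons$start, c(150L, 400L, 800L))
  expect_equal(m$exons$end, c(200L, 600L, 850L))

  # degenerate thick region
  writeLines(paste("c", 0, 1000, "g3.t1", 0, "+", 500, 500, "0,0,0", 1,
                   "1000,", "0,", sep = "\t"), f)
  expect_error(read_bed12(f), "no coding region")
})

test_that("BED12 round-trip preserves coding exons exactly", {
  set.seed(42)
  f <- withr::local_tempfile(fileext = ".bed")
  for (rep in 1:20) {
    n_ex <- sample(1:6, 1L)
    sizes <- sample(30:300, n_ex, replace = TRUE)
    gaps <- sample(50:800, n_ex, replace = TRUE)
    starts <- cumsum(gaps) + cumsum(c(0L, sizes[-n_ex]))
    ends <- starts + sizes
    m <- gene_model(paste0("g", rep), "t1", "chr1", sample(c("+", "-"), 1L),
                    starts, ends)
    write_bed12(list(m), f)
    back <- read_bed12(f)[[1L]]
    expect_identical(back$exons, m$exons)
    expect_identical(back$strand, m$strand)
  }
})

test_that("read_repeatmasker_out converts coordinates and repeat classes", {
  f <- withr::local_tempfile(fileext = ".out")
  hdr <- c("   SW   perc perc perc  query     position in query   matching repeat",
           "score   div. del. ins.  sequence  begin  end  (left)  repeat class/family",
           "")
  row1 <- " 1000  10.0  0.0  0.0  chrF  101  200  (500)  +  jockey  LINE/CR1  1 100 (0)  1"
  row2 <- "  900  11.0  0.0  0.0  chrF  300  350  (400)  C  DNAREP1  RC/Helitron  1 51 (0)  2"
  writeLines(c(hdr, row1, row2), f)
  fr <- read_repeatmasker_out(f)
  expect_equal(fr$start, c(100L, 299L))
  expect_equal(fr$end, c(200L, 350L))
  expect_equal(fr$repeat_class, c("LINE", "RC"))
  expect_equal(fr$strand, c("+", "-"))

  writeLines(hdr, f)
  expect_equal(nrow(read_repeatmasker_out(f)), 0L)
})

test_that("merge_same_class unions only within a class", {
  fr <- repeat_fragments(chrom = "c", start = c(0L, 50L), end = c(100L, 150L),
                         repeat_class = c("DNA", "DNA"))
  m <- merge_same_class(fr)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 150L))

  fr2 <- repeat_fragments("c", c(0L, 50L), c(100L, 150L), c("DNA", "LTR"))
  m2 <- merge_same_class(fr2)
  expect_equal(nrow(m2), 2L)
  expect_equal(m2$end - m2$start, c(100L, 100L))

  # book-ended fragments merge; disjoint ones do not
  fr3 <- repeat_fragments("c", c(0L, 10L, 30L), c(10L, 20L, 40L), "DNA")
  m3 <- merge_same_class(fr3)
  expect_equal(m3$start, c(0L, 30L))
  expect_equal(m3$end, c(20L, 40L))
})

test_that("merge_same_class is idempotent and order-independent", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 30L
    s <- sample(0:2000, n, replace = TRUE)
    fr <- repeat_fragments(sample(c("c1", "c2"), n, TRUE), s,
                           s + sample(10:200, n, TRUE),
                           sample(c("DNA", "LTR", "LINE"), n, TRUE))
    m1 <- merge_same_class(fr)
    m2 <- merge_same_class(fr[sample(n), ])
    expect_identical(m1, m2)
    expect_identical(merge_same_class(m1), m1)
    expect_lte(sum(m1$end - m1$start), sum(fr$end - fr$start))
  }
})

test_that("overlap_bases matches examples and the per-base oracle", {
  a <- genomic_intervals("c", 0L, 100L)
  b <- genomic_intervals("c", 50L, 150L)
  expect_equal(overlap_bases(a, b), 50)
  expect_equal(overlap_bases(a, genomic_intervals("c", 500L, 600L)), 0)
  a2 <- genomic_intervals(c("c", "c"), c(0L, 20L), c(10L, 30L))
  expect_equal(overlap_bases(a2, genomic_intervals("c", 5L, 25L)), 10)

  set.seed(11)
  for (rep in 1:10) {
    mk <- function() {
      n <- sample(3:12, 1L)
      s <- sample(0:5000, n, replace = TRUE)
      genomic_intervals(sample(c("x", "y"), n, TRUE), s,
                        s + sample(1:500, n, TRUE))
    }
    a <- mk(); b <- mk()
    expect_equal(overlap_bases(a, b), oracle_overlap_bases(a, b))
    expect_equal(overlap_bases(a, b), overlap_bases(b, a))
  }
})

test_that("read_gff3 builds coding-only gene models", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tCDS\t101\t200\t.\t+\t0\tID=c1;Parent=tA",
               "chr1\tsrc\tCDS\t301\t400\t.\t+\t1\tID=c2;Parent=tA"), f)
  m <- read_gff3(f)[[1L]]
  expect_equal(m$exons$start, c(100L, 300L))
  expect_equal(m$exons$end, c(200L, 400L))
})

test_that("extract_cds splices and reverse-complements", {
  g <- seq_record("c", "AAATGGCCTTTAAGGG")
  m_plus <- gene_model("g", "t", "c", "+", c(2L, 10L), c(8L, 13L))
  expect_equal(extract_cds(m_plus, g), "ATGGCCTAA")
  m_minus <- gene_model("g", "t", "c", "-", c(2L, 10L), c(8L, 13L))
  expect_equal(extract_cds(m_minus, g), revcomp("ATGGCCTAA"))
})
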