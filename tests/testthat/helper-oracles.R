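# Independent oracles (no shared code with the package implementations)
# and small fixture builders used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-base membership oracle for interval overlap on short sequences
oracle_overlap_bases <- function(a, b, max_pos = 10000L) {
  total <- 0L
  for (ch in union(a$chrom, b$chrom)) {
    ina <- logical(max_pos); inb <- logical(max_pos)
    aa <- a[a$chrom == ch, , drop = FALSE]
    bb <- b[b$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(aa))) ina[(aa$start[i] + 1L):aa$end[i]] <- TRUE
    for (i in seq_len(nrow(bb))) inb[(bb$start[i] + 1L):bb$end[i]] <- TRUE
    total <- total + sum(ina & inb)
  }
  total
}

# direct Wright Nc evaluation, written independently of the package
oracle_nc <- function(counts) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  aa <- code[sense]
  fam_of <- split(sense, aa)
  f_by_class <- list()
  for (fam in fam_of) {
    k <- length(fam)
    if (k == 1L) next
    n <- sum(counts[fam], na.rm = TRUE)
    if (n <= 1) next
    p <- counts[fam] / n
    p[is.na(p)] <- 0
    fh <- (n * sum(p^2) - 1) / (n - 1)
    f_by_class[[as.character(k)]] <- c(f_by_class[[as.character(k)]], fh)
  }
  fb <- function(k) if (is.null(f_by_class[[k]])) NA_real_ else
    mean(f_by_class[[k]])
  f2 <- fb("2"); f3 <- fb("3"); f4 <- fb("4"); f6 <- fb("6")
  # Wright's rule: the single 3-fold family (Ile) is imputed when missing
  # or when its homozygosity estimate degenerates to 0
  if ((is.na(f3) || f3 == 0) && !is.na(f2) && !is.na(f4))
    f3 <- (f2 + f4) / 2
  2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
}

# direct CAI evaluation (geometric mean over eligible codons)
oracle_cai <- function(counts, w) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  aa <- code[sense]
  multi <- sense[aa %in% names(table(aa))[table(aa) > 1]]
  counts <- counts[names(counts) %in% multi]
  counts <- counts[counts > 0]
  exp(sum(counts * log(w[names(counts)])) / sum(counts))
}

# random codon-usage table over a random multiset of sense codons
random_usage <- function(n_codons = 200L) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  tab <- table(sample(sense, n_codons, replace = TRUE,
                      prob = runif(length(sense), 0.2, 1)))
  codon_usage(tab)
}

# random DNA string
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# all signed permutations of 1..n as a list
all_signed_perms <- function(n) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (r in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], r)
    out
  }
  signs <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
  out <- vector("list", factorial(n) * 2^n)
  k <- 0L
  for (p in perms(seq_len(n))) for (s in seq_len(nrow(signs))) {
    k <- k + 1L
    out[[k]] <- as.integer(p * signs[s, ])
  }
  out
}

# Breslauer-style Tm evaluated independently (own table transcription)
oracle_tm <- function(win, dna_conc_nM = 50, salt_mM = 50) {
  H <- c(AA = 9.1, AC = 6.5, AG = 7.8, AT = 8.6, CA = 5.8, CC = 11.0,
         CG = 11.9, CT = 7.8, GA = 5.6, GC = 11.1, GG = 11.0, GT = 6.5,
         TA = 6.0, TC = 5.6, TG = 5.8, TT = 9.1)
  S <- c(AA = 24.0, AC = 17.3, AG = 20.8, AT = 23.9, CA = 12.9, CC = 26.6,
         CG = 27.8, CT = 20.8, GA = 13.5, GC = 26.7, GG = 26.6, GT = 17.3,
         TA = 16.9, TC = 13.5, TG = 12.9, TT = 24.0)
  stacks <- substring(win, 1:8, 2:9)
  dh <- -sum(H[stacks]); ds <- -sum(S[stacks]) - 10.8
  1000 * dh / (ds + 1.987 * log(dna_conc_nM * 1e-9 / 4)) - 273.15 +
    16.6 * log10(salt_mM * 1e-3)
}
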