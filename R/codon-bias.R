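# Standard genetic code bookkeeping.  Synonymous family sizes under the
# standard code: 2 single-codon families (Met, Trp), 9 two-fold, 1 three-fold
# (Ile), 5 four-fold, 3 six-fold (Leu, Ser, Arg) -- 61 sense codons in all.

.codon_space <- function() {
  b <- c("T", "C", "A", "G")
  paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
}

.genetic_code_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.genetic_code_env$tab)) {
    codons <- .codon_space()
    aa <- Biostrings::GENETIC_CODE[codons]
    sense <- codons[aa != "*"]
    aa_sense <- aa[aa != "*"]
    fam_size <- table(aa_sense)[aa_sense]
    .genetic_code_env$tab <- list(
      codons = codons, aa = aa,
      stops = codons[aa == "*"],
      sense = sense, aa_sense = setNames(as.character(aa_sense), sense),
      family_size = setNames(as.integer(fam_size), sense),
      # CAI-eligible codons: all sense codons except the single-codon
      # families Met (ATG) and Trp (TGG)
      eligible = sense[as.integer(fam_size) > 1L])
  }
  .genetic_code_env$tab
}

#' Construct a codon usage table
#'
#' @param counts Named numeric vector of codon counts; names must be sense
#'   codons of the standard genetic code (stop codons are rejected).
#' @return A named numeric vector over all 61 sense codons (class
#'   `codon_usage`), zero-filled for unobserved codons.
#' @export
codon_usage <- function(counts) {
  gc <- .genetic_code()
  if (is.null(names(counts))) stop("counts must be a named vector")
  names(counts) <- toupper(chartr("U", "T", names(counts)))
  unknown <- setdiff(names(counts), gc$sense)
  if (length(unknown))
    stop("not sense codons of the standard code: ",
         paste(unknown, collapse = ", "))
  if (any(counts < 0)) stop("codon counts must be non-negative")
  full <- setNames(numeric(length(gc$sense)), gc$sense)
  if (length(counts)) {
    agg <- tapply(as.numeric(counts), names(counts), sum)
    full[names(agg)] <- agg
  }
  structure(full, class = "codon_usage")
}

#' Count codons in a coding sequence
#'
#' The terminal stop codon is dropped; codons containing `N` are skipped and
#' their number recorded in the `skipped` attribute; an internal stop codon
#' is an error naming the offending codon index (1-based).
#'
#' @param cds In-frame coding sequence (length divisible by 3).
#' @return A [codon_usage()] table with attribute `skipped`.
#' @export
count_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not divisible by 3")
  if (n == 0L) stop("empty CDS")
  gc <- .genetic_code()
  starts <- seq(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  if (codons[length(codons)] %in% gc$stops)
    codons <- codons[-length(codons)]
  has_n <- grepl("N", codons, fixed = TRUE)
  skipped <- sum(has_n)
  codons <- codons[!has_n]
  internal_stop <- which(codons %in% gc$stops)
  if (length(internal_stop))
    stop("internal stop codon at codon ", internal_stop[1L])
  if (length(codons) == 0L)
    return(structure(codon_usage(setNames(numeric(0), character(0))),
                     skipped = skipped))
  tab <- codon_usage(table(codons))
  attr(tab, "skipped") <- skipped
  tab
}

#' Wright's effective number of codons (Nc)
#'
#' Nc measures departure from uniform synonymous codon usage: 61 means no
#' bias, 20 maximal bias (one codon per amino acid).  Per amino acid with
#' total count n and codon frequencies p_i, the family homozygosity is
#' estimated as F = (n * sum(p_i^2) - 1) / (n - 1); families with n <= 1 are
#' skipped.  F is averaged within family-size classes and
#' Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6.  When the single three-fold family
#' (Ile) is unobserved or its F undefined, F3 is imputed as (F2 + F4)/2 and
#' the result carries the attribute `imputed_f3 = TRUE`.  The value is
#' reported unclamped (it can slightly exceed 61 in finite samples).
#'
#' @param table A [codon_usage()] table.
#' @return Nc as a numeric scalar, or `NA` with attribute
#'   `undefined = TRUE` when no multi-codon family has n >= 2 (or a needed
#'   size class is missing).
#' @export
effective_number_of_codons <- function(table) {
  gc <- .genetic_code()
  if (sum(table) < 1) stop("at least one codon must be counted")
  counts <- as.numeric(table)
  names(counts) <- names(unclass(table))
  fams <- split(counts, gc$aa_sense[names(counts)])
  f_by_size <- list()
  for (fam in fams) {
    size <- length(fam)
    if (size == 1L) next
    n <- sum(fam)
    if (n <= 1) next
    p <- fam / n
    f_hat <- (n * sum(p^2) - 1) / (n - 1)
    key <- as.character(size)
    f_by_size[[key]] <- c(f_by_size[[key]], f_hat)
  }
  fbar <- vapply(c("2", "3", "4", "6"), function(k) {
    v <- f_by_size[[k]]
    if (is.null(v)) NA_real_ else mean(v)
  }, numeric(1L))
  # a size-class average of exactly 0 cannot be inverted; treat as undefined
  fbar[!is.na(fbar) & fbar == 0] <- NA_real_
  imputed <- FALSE
  if (is.na(fbar["3"]) && !is.na(fbar["2"]) && !is.na(fbar["4"])) {
    fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
    imputed <- TRUE
  }
  if (anyNA(fbar))
    return(structure(NA_real_, undefined = TRUE))
  structure(2 + 9 / fbar["2"] + 1 / fbar["3"] + 5 / fbar["4"] + 3 / fbar["6"],
            names = NULL, imputed_f3 = imputed)
}

#' Relative adaptiveness (w) of codons from a reference usage table
#'
#' Unobserved codons in the reference receive a pseudo-count before
#' frequencies are formed, so every w is strictly positive; within each
#' synonymous family the most frequent codon gets w = 1.
#'
#' @param reference A [codon_usage()] table pooled over the reference gene
#'   set.
#' @param floor Pseudo-count assigned to zero-count codons (default 0.5).
#' @return Named numeric vector w over the 61 sense codons, in (0, 1].
#' @export
relative_adaptiveness <- function(reference, floor = 0.5) {
  gc <- .genetic_code()
  counts <- as.numeric(reference)
  names(counts) <- names(unclass(reference))
  counts[counts == 0] <- floor
  w <- counts
  for (fam in split(names(counts), gc$aa_sense[names(counts)])) {
    w[fam] <- counts[fam] / max(counts[fam])
  }
  w
}

#' Codon adaptation index (CAI) of one gene
#'
#' Geometric mean of the relative adaptiveness values of the gene's codons,
#' excluding stop codons (never in the table) and the single-codon families
#' Met and Trp.
#'
#' @param table The gene's [codon_usage()] table.
#' @param w Relative adaptiveness from [relative_adaptiveness()].
#' @return CAI in (0, 1].
#' @export
cai <- function(table, w) {
  gc <- .genetic_code()
  counts <- as.numeric(table)
  names(counts) <- names(unclass(table))
  counts <- counts[gc$eligible]
  n <- sum(counts)
  if (n < 1) stop("no CAI-eligible codons in gene")
  exp(sum(counts * log(w[gc$eligible])) / n)
}

#' CAI of a hypothetical gene with no codon bias
#'
#' The no-bias baseline uses every eligible codon with equal frequency
#' within its synonymous family.  With `weighting = "codon_count"` (default)
#' families are weighted by their codon counts, i.e. the baseline is the
#' geometric mean of w over the 59 eligible codons; `"equal_family"` weights
#' each family equally instead.
#'
#' @param w Relative adaptiveness vector.
#' @param weighting Family weighting rule.
#' @return The no-bias CAI value.
#' @export
no_bias_cai <- function(w, weighting = c("codon_count", "equal_family")) {
  weighting <- match.arg(weighting)
  gc <- .genetic_code()
  lw <- log(w[gc$eligible])
  if (weighting == "codon_count") return(exp(mean(lw)))
  fam <- split(lw, gc$aa_sense[gc$eligible])
  exp(mean(vapply(fam, mean, numeric(1L))))
}

#' Self-consistent dominant-bias reference gene set
#'
#' Iteratively selects the genes exhibiting the dominant codon bias of a
#' population: initialise w from the pooled usage of all genes, score every
#' gene by CAI, re-estimate w from the pooled usage of the top fraction, and
#' repeat until the selected set is stable (or `max_iter` is reached, in
#' which case the last set is returned flagged as non-converged).  Ties in
#' CAI are broken by input order.
#'
#' @param tables Named list of per-gene [codon_usage()] tables (>= 10 genes).
#' @param top_fraction Fraction of genes forming the reference set.
#' @param max_iter Iteration cap.
#' @param floor Pseudo-count passed to [relative_adaptiveness()].
#' @return List with `genes` (reference ids), `table` (pooled usage), `w`,
#'   `iterations`, and `converged`.
#' @export
select_reference_set <- function(tables, top_fraction = 0.1, max_iter = 20L,
                                 floor = 0.5) {
  n <- length(tables)
  if (n < 10L) stop("reference-set selection needs at least 10 genes")
  ids <- names(tables)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  k <- max(1L, round(top_fraction * n))
  pool <- function(idx) {
    m <- rowSums(vapply(tables[idx], function(t) as.numeric(t),
                        numeric(61L)))
    codon_usage(setNames(m, names(unclass(tables[[1L]]))))
  }
  current <- seq_len(n)   # start from the whole-population table
  selected <- integer(0)
  converged <- FALSE
  iterations <- 0L
  w <- relative_adaptiveness(pool(current), floor = floor)
  repeat {
    iterations <- iterations + 1L
    scores <- vapply(tables, cai, numeric(1L), w = w)
    new_sel <- order(-scores, seq_len(n))[seq_len(k)]
    new_sel <- sort(new_sel)
    if (identical(new_sel, selected)) { converged <- TRUE; break }
    selected <- new_sel
    w <- relative_adaptiveness(pool(selected), floor = floor)
    if (iterations >= max_iter) break
  }
  if (!converged)
    warning("reference set did not converge after ", max_iter, " iterations")
  list(genes = ids[selected], table = pool(selected), w = w,
       iterations = iterations, converged = converged)
}

#' Per-species codon usage summary table
#'
#' A cusp-style 61-row table: codon, amino acid, within-family fraction,
#' frequency per 1000 codons, and raw count.
#'
#' @param table A [codon_usage()] table.
#' @return A data.frame with one row per sense codon.
#' @export
codon_usage_summary <- function(table) {
  gc <- .genetic_code()
  counts <- as.numeric(table)
  names(counts) <- names(unclass(table))
  total <- sum(counts)
  frac <- counts
  for (fam in split(names(counts), gc$aa_sense[names(counts)])) {
    fam_total <- sum(counts[fam])
    frac[fam] <- if (fam_total > 0) counts[fam] / fam_total else NA_real_
  }
  data.frame(codon = names(counts), aa = unname(gc$aa_sense[names(counts)]),
             fraction = unname(frac),
             per_1000 = if (total > 0) unname(1000 * counts / total) else NA_real_,
             count = unname(counts), stringsAsFactors = FALSE)
}
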