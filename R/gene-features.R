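# The eight per-gene characteristics feeding the Distance-Distance
# analysis, plus the Kruskal-Wallis group comparison with post-hoc tests.

#' Select the most comprehensive isoform per gene
#'
#' Per gene, the isoform with the largest coding region (sum of coding
#' exons); ties are broken by lexicographic transcript id (a convention,
#' recorded in the `ties` attribute).
#'
#' @param models List of [gene_model()] objects (>= 1 isoform per gene).
#' @return Named list of one [gene_model()] per gene, in order of first
#'   appearance.
#' @export
select_comprehensive_isoform <- function(models) {
  gids <- vapply(models, `[[`, character(1L), "gene_id")
  ties <- character(0)
  picked <- lapply(split(seq_along(models), factor(gids, levels = unique(gids))),
                   function(idx) {
    sizes <- vapply(models[idx], coding_size, numeric(1L))
    best <- idx[sizes == max(sizes)]
    if (length(best) > 1L) {
      tids <- vapply(models[best], `[[`, character(1L), "transcript_id")
      ties <<- c(ties, models[[best[1L]]]$gene_id)
      best <- best[order(tids)][1L]
    }
    models[[best]]
  })
  structure(picked, ties = ties)
}

#' Extract the eight gene characteristics of one gene model
#'
#' coding span (first exon start to last exon end, introns included);
#' intron repeat size (bases of the cross-class union of transposon
#' fragments falling inside introns); coding region size; number of coding
#' exons; median coding exon size; median intron size (0, flagged, for
#' single-exon genes so the multivariate stage sees complete vectors); and
#' the codon-bias statistics Nc and CAI supplied by the caller.
#'
#' @param model A [gene_model()].
#' @param repeats Repeat-fragment data.frame (may be empty).
#' @param nc,cai Per-gene codon-bias values.
#' @return A one-row data.frame (class `gene_feature_vector`) with a
#'   `single_exon` flag column.
#' @export
extract_features <- function(model, repeats = .empty_fragments(),
                             nc = NA_real_, cai = NA_real_) {
  ex <- model$exons
  n_ex <- nrow(ex)
  span <- ex$end[n_ex] - ex$start[1L]
  coding <- sum(ex$end - ex$start)
  single <- n_ex == 1L
  if (single) {
    introns <- data.frame(chrom = character(), start = integer(),
                          end = integer())
    med_intron <- 0
    intron_rep <- 0
  } else {
    introns <- data.frame(chrom = model$chrom, start = ex$end[-n_ex],
                          end = ex$start[-1L], stringsAsFactors = FALSE)
    med_intron <- median(introns$end - introns$start)
    rep_chr <- repeats[repeats$chrom == model$chrom, , drop = FALSE]
    intron_rep <- overlap_bases(introns, rep_chr)
  }
  structure(data.frame(gene_id = model$gene_id,
                       coding_span = span,
                       intron_repeat_size = intron_rep,
                       coding_region_size = coding,
                       n_coding_exons = n_ex,
                       median_coding_exon_size = median(ex$end - ex$start),
                       median_intron_size = med_intron,
                       nc = nc, cai = cai,
                       single_exon = single,
                       stringsAsFactors = FALSE),
            class = c("gene_feature_vector", "data.frame"))
}

#' Build the gene feature table for a cohort
#'
#' Runs isoform selection, codon counting (from the genome sequence), Nc,
#' CAI and [extract_features()] over a set of gene models.
#'
#' @param models List of [gene_model()] objects (all isoforms).
#' @param genome [seq_record()] or named list of them.
#' @param repeats Repeat-fragment data.frame.
#' @param w Relative adaptiveness for CAI; when `NULL` it is derived from a
#'   self-consistent reference set over the cohort
#'   ([select_reference_set()]).
#' @return data.frame with one row per gene: the eight characteristics plus
#'   flags.
#' @export
gene_feature_table <- function(models, genome, repeats = .empty_fragments(),
                               w = NULL) {
  picked <- select_comprehensive_isoform(models)
  tables <- lapply(picked, function(m) count_codons(extract_cds(m, genome)))
  names(tables) <- vapply(picked, `[[`, character(1L), "gene_id")
  if (is.null(w)) w <- select_reference_set(tables)$w
  rows <- lapply(seq_along(picked), function(i) {
    nc <- suppressWarnings(effective_number_of_codons(tables[[i]]))
    extract_features(picked[[i]], repeats, nc = as.numeric(nc),
                     cai = cai(tables[[i]], w))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank sum test
#'
#' Mid-rank treatment of ties with the standard tie correction; the p-value
#' comes from the chi-square approximation with k - 1 degrees of freedom.
#' When every observation is identical the tie-correction denominator is 0
#' and the test is defined as H = 0, p = 1.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return List with `statistic` (H), `df`, and `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) == 0L)) stop("groups must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n_i <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(n_i * rbar^2) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) {
    H <- 0; p <- 1
  } else {
    H <- H / C
    p <- pchisq(H, df = length(groups) - 1L, lower.tail = FALSE)
  }
  list(statistic = H, df = length(groups) - 1L, p.value = p)
}

#' Multiple comparisons after Kruskal-Wallis
#'
#' Siegel-Castellan critical-difference procedure: groups i and j differ
#' when |Rbar_i - Rbar_j| exceeds
#' z(1 - alpha / (k (k - 1))) * sqrt(N (N + 1) / 12 * (1/n_i + 1/n_j)).
#'
#' @param groups List of numeric vectors (as [kruskal_wallis()]).
#' @param alpha Family-wise significance level (default 0.05).
#' @return data.frame of pairs: i, j, observed difference of mean ranks,
#'   critical difference, significant flag.
#' @export
kw_posthoc <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n_i <- lengths(groups)
  z <- stats::qnorm(1 - alpha / (k * (k - 1)))
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  out <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    crit <- z * sqrt(N * (N + 1) / 12 * (1 / n_i[i] + 1 / n_i[j]))
    obs <- abs(rbar[i] - rbar[j])
    out[[length(out) + 1L]] <- data.frame(
      group_i = nm[i], group_j = nm[j], diff_mean_rank = unname(obs),
      critical = crit, significant = unname(obs > crit),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
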