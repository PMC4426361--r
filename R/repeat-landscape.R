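# Repeat-side scanners: k-mer occurrence spectra, dinucleotide-run
# tabulation, sliding-window repeat density, masked-fraction summaries.

#' k-mer occurrence spectrum
#'
#' Tallies every k-mer window (strand as given, no canonicalization) across
#' the input sequences, skipping windows that contain `N`, and reports the
#' spectrum: how many distinct k-mers occur exactly c times.
#'
#' @param seqs A [seq_record()] or list of them (plain strings accepted).
#' @param k Word length (the repeat-landscape convention is 13).
#' @return A `kmer_spectrum` list: `k`, `histogram` (data.frame count /
#'   n_kmers), `total_windows` (N-free windows tallied), `skipped_windows`.
#' @export
kmer_spectrum <- function(seqs, k) {
  if (k < 1L) stop("k must be >= 1")
  if (inherits(seqs, "seq_record") || is.character(seqs)) seqs <- list(seqs)
  strings <- vapply(seqs, function(s)
    if (inherits(s, "seq_record")) s$seq else toupper(s), character(1L))
  if (all(nchar(strings) < k))
    stop("k = ", k, " is larger than every input sequence")
  tallies <- new.env(parent = emptyenv())
  total <- 0L; skipped <- 0L
  counts <- NULL
  for (s in strings) {
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    words <- substring(s, starts, starts + k - 1L)
    has_n <- grepl("N", words, fixed = TRUE)
    skipped <- skipped + sum(has_n)
    words <- words[!has_n]
    total <- total + length(words)
    if (length(words)) {
      tab <- table(words)
      counts <- if (is.null(counts)) tab else {
        merged <- c(counts, tab)
        tapply(as.integer(merged), names(merged), sum)
      }
    }
  }
  hist <- if (is.null(counts) || length(counts) == 0L) {
    data.frame(count = integer(), n_kmers = integer())
  } else {
    h <- table(as.integer(counts))
    data.frame(count = as.integer(names(h)), n_kmers = as.integer(h))
  }
  structure(list(k = as.integer(k), histogram = hist,
                 total_windows = total, skipped_windows = skipped),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("<kmer_spectrum> k=%d, %d windows, %d distinct k-mers\n",
              x$k, x$total_windows, sum(x$histogram$n_kmers)))
  invisible(x)
}

# maximal dinucleotide runs of d (2-character unit) in seq, via the two
# phase lattices; returns integer vector of maximal run lengths (in units)
.maximal_runs <- function(chars, d1, d2) {
  L <- length(chars)
  if (L < 2L) return(integer())
  m <- chars[-L] == d1 & chars[-1L] == d2   # match at start positions 1..L-1
  runs <- integer()
  for (phase in 1:2) {
    idx <- seq(phase, L - 1L, by = 2L)
    if (!length(idx)) next
    r <- rle(m[idx])
    runs <- c(runs, r$lengths[r$values])
  }
  runs
}

#' Tabulate dinucleotide repeat runs
#'
#' For each of the 16 dinucleotides d and each repeat size u in
#' `[min_units, max_units]`, counts the (potentially overlapping) matches of
#' d repeated u times, the maximal runs of exactly u units, and a cumulative
#' (>= u) match table with a +1 pseudocount for log-scale plotting.  Only
#' the given strand is scanned; dinucleotide runs are symmetric under
#' reverse complementation up to relabeling (an AC run is a GT run on the
#' other strand).
#'
#' @param seq A DNA string or [seq_record()].
#' @param min_units,max_units Repeat-size range in dinucleotide units
#'   (default 2..100).
#' @return A `dinuc_run_table` list: `table` (long data.frame dinuc / units
#'   / matches / maximal_runs / cumulative_plus_1) and `max_run` (named
#'   vector: longest maximal run per dinucleotide, in units, unclamped).
#' @export
scan_dinucleotide_runs <- function(seq, min_units = 2L, max_units = 100L) {
  if (min_units > max_units) stop("min_units > max_units")
  if (inherits(seq, "seq_record")) seq <- seq$seq
  chars <- strsplit(toupper(seq), "")[[1L]]
  bases <- c("A", "C", "G", "T")
  dinucs <- as.vector(outer(bases, bases, paste0))
  units <- min_units:max_units
  rows <- vector("list", 16L)
  max_run <- setNames(integer(16L), dinucs)
  for (di in seq_along(dinucs)) {
    d <- dinucs[di]
    runs <- .maximal_runs(chars, substr(d, 1L, 1L), substr(d, 2L, 2L))
    # a repeat run needs at least min_units consecutive units; shorter
    # maximal runs (isolated dinucleotide matches) do not count
    long_runs <- runs[runs >= min_units]
    max_run[di] <- if (length(long_runs)) max(long_runs) else 0L
    matches <- vapply(units, function(u)
      sum(pmax(0L, runs - u + 1L)), integer(1L))
    maximal <- vapply(units, function(u) sum(runs == u), integer(1L))
    cumulative <- rev(cumsum(rev(matches))) + 1L
    rows[[di]] <- data.frame(dinuc = d, units = units, matches = matches,
                             maximal_runs = maximal,
                             cumulative_plus_1 = cumulative,
                             stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), max_run = max_run),
            class = "dinuc_run_table")
}

# window starts over [region$start, region$end): full windows while
# start + window <= end, plus one trailing partial window only when the
# last full window does not already reach the region end
.window_coords <- function(region, window, step) {
  rs <- region$start; re <- region$end
  if (re <= rs) stop("empty region")
  starts <- integer(0)
  s <- rs
  while (s + window <= re) { starts <- c(starts, s); s <- s + step }
  ends <- pmin(starts + window, re)
  if (length(starts) == 0L || max(ends) < re) {
    starts <- c(starts, s)
    ends <- c(ends, re)
  }
  data.frame(start = starts, end = ends)
}

#' Sliding-window repeat density
#'
#' Fragments are first merged within class (overlaps of the same repeat
#' class union; different classes never merge) and then unioned across
#' classes, so a base covered twice counts once.  Density is covered bases
#' over window length; a trailing partial window is normalized by its own
#' length.
#'
#' @param fragments Repeat-fragment data.frame.
#' @param region A single-row interval data.frame (see
#'   [genomic_intervals()]).
#' @param window,step Window and step sizes in bp (defaults 1000/500).
#' @return data.frame: chrom, start, end, density, partial flag.
#' @export
window_density <- function(fragments, region, window = 1000L, step = 500L) {
  if (window < step || step < 1L) stop("need window >= step >= 1")
  wins <- .window_coords(region, window, step)
  frag <- fragments[fragments$chrom == region$chrom, , drop = FALSE]
  merged <- merge_same_class(frag)
  u <- if (nrow(merged) == 0L) IRanges::IRanges() else
    IRanges::reduce(.iv_to_iranges(merged$start, merged$end))
  wir <- .iv_to_iranges(wins$start, wins$end)
  cov <- numeric(nrow(wins))
  if (length(u) > 0L) {
    hits <- IRanges::findOverlaps(wir, u)
    if (length(hits) > 0L) {
      pw <- BiocGenerics::width(IRanges::pintersect(
        wir[S4Vectors::queryHits(hits)], u[S4Vectors::subjectHits(hits)]))
      agg <- tapply(pw, S4Vectors::queryHits(hits), sum)
      cov[as.integer(names(agg))] <- agg
    }
  }
  data.frame(chrom = region$chrom, start = wins$start, end = wins$end,
             density = cov / (wins$end - wins$start),
             partial = (wins$end - wins$start) < window,
             stringsAsFactors = FALSE)
}

#' Masked fraction of a region, by repeat class and in total
#'
#' Per-class fractions use same-class-merged coverage clipped to the
#' region; `total` is the cross-class union, so total <= sum of per-class
#' fractions.
#'
#' @param fragments Repeat-fragment data.frame.
#' @param region A single-row interval data.frame.
#' @param by_class Include per-class entries (default TRUE).
#' @return Named numeric vector of fractions, always including `total`.
#' @export
masked_fraction <- function(fragments, region, by_class = TRUE) {
  len <- region$end - region$start
  frag <- fragments[fragments$chrom == region$chrom, , drop = FALSE]
  clip <- function(df) {
    s <- pmax(df$start, region$start); e <- pmin(df$end, region$end)
    keep <- s < e
    data.frame(chrom = df$chrom[keep], start = s[keep], end = e[keep])
  }
  out <- numeric(0)
  if (by_class && nrow(frag) > 0L) {
    merged <- merge_same_class(frag)
    for (cl in sort(unique(merged$repeat_class))) {
      piece <- clip(merged[merged$repeat_class == cl, , drop = FALSE])
      out[cl] <- .union_bp(piece) / len
    }
  }
  total <- if (nrow(frag) == 0L) 0 else .union_bp(clip(frag)) / len
  c(out, total = total)
}
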