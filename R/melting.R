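# Nearest-neighbor duplex melting temperatures, 9-bp sliding-window tracks,
# and the 3-kb-normalized metagene profile with 2-kb flanks.

#' Nearest-neighbor thermodynamic parameter table (Breslauer 1986)
#'
#' Duplex-formation enthalpies (kcal/mol) and entropies (cal/mol/K) for the
#' 16 dinucleotide stacks, stored as negative (exothermic) values, plus the
#' helix-initiation entropy.  The table is symmetric under
#' reverse-complementation of the stack, which makes every window Tm
#' strand-symmetric.  This parameter set matches the table used by classic
#' sliding-window Tm scanners; it is the package contract and is pinned by
#' tests.
#'
#' @return A list with `dH` and `dS` (named by stack) and `dS_init`.
#' @export
nn_parameters <- function() {
  dH <- c(AA = -9.1, AC = -6.5, AG = -7.8, AT = -8.6,
          CA = -5.8, CC = -11.0, CG = -11.9, CT = -7.8,
          GA = -5.6, GC = -11.1, GG = -11.0, GT = -6.5,
          TA = -6.0, TC = -5.6, TG = -5.8, TT = -9.1)
  dS <- c(AA = -24.0, AC = -17.3, AG = -20.8, AT = -23.9,
          CA = -12.9, CC = -26.6, CG = -27.8, CT = -20.8,
          GA = -13.5, GC = -26.7, GG = -26.6, GT = -17.3,
          TA = -16.9, TC = -13.5, TG = -12.9, TT = -24.0)
  list(dH = dH, dS = dS, dS_init = -10.8)
}

.GAS_CONSTANT <- 1.987  # cal / (mol K)

#' Nearest-neighbor melting temperature of one 9-bp window
#'
#' Tm (deg C) = 1000 * dH / (dS + R * ln(C/4)) - 273.15
#'            + 16.6 * log10([Na+]),
#' where dH and dS are summed over the 8 nearest-neighbor stacks plus the
#' initiation entropy, R = 1.987 cal/mol/K, C is the strand concentration in
#' mol/L and [Na+] the salt concentration in mol/L.
#'
#' @param window A 9-base N-free DNA string.
#' @param dna_conc DNA (strand) concentration in nM (default 50).
#' @param salt Na+ concentration in mM (default 50).
#' @return Melting temperature in degrees Celsius.
#' @export
nn_tm <- function(window, dna_conc = 50, salt = 50) {
  window <- toupper(window)
  if (nchar(window) != 9L) stop("window must be exactly 9 bp")
  if (grepl("[^ACGT]", window)) stop("window contains a non-ACGT character")
  tm_track(window, dna_conc = dna_conc, salt = salt)$values[1L]
}

#' Sliding-window melting-temperature track
#'
#' One Tm per window start (window 9 bp, step 1 bp); windows containing `N`
#' carry `NA`.
#'
#' @param seq A DNA string or [seq_record()], length >= 9.
#' @param dna_conc,salt See [nn_tm()].
#' @return A `tm_track` list with `chrom`, `start` (0-based position of the
#'   first window) and `values`.
#' @export
tm_track <- function(seq, dna_conc = 50, salt = 50) {
  chrom <- "."
  if (inherits(seq, "seq_record")) { chrom <- seq$id; seq <- seq$seq }
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 9L) stop("region shorter than the 9 bp window")
  par <- nn_parameters()
  code <- match(strsplit(seq, "")[[1L]], c("A", "C", "G", "T"))  # N -> NA
  stack_idx <- 4L * (code[-L] - 1L) + code[-1L]
  # nn_parameters() is ordered AA,AC,AG,AT,CA,... i.e. 4*(first-1)+second
  dh <- par$dH[stack_idx]
  ds <- par$dS[stack_idx]
  # NA (from N bases) must poison exactly the windows it touches
  w <- 8L
  roll_sum <- function(v) {
    n <- length(v) - w + 1L
    bad <- is.na(v)
    v0 <- ifelse(bad, 0, v)
    cs <- c(0, cumsum(v0))
    s <- cs[(w + 1L):(length(v) + 1L)] - cs[seq_len(n)]
    cb <- c(0, cumsum(bad))
    nbad <- cb[(w + 1L):(length(v) + 1L)] - cb[seq_len(n)]
    s[nbad > 0L] <- NA
    s
  }
  H <- 1000 * roll_sum(dh)
  S <- roll_sum(ds) + par$dS_init
  conc <- dna_conc * 1e-9
  na <- salt * 1e-3
  vals <- H / (S + .GAS_CONSTANT * log(conc / 4)) - 273.15 + 16.6 * log10(na)
  structure(list(chrom = chrom, start = 0L, values = unname(vals)),
            class = "tm_track")
}

# coverage-weighted re-binning of a unit-resolution track onto nbins equal
# bins; exact identity when length(v) == nbins; NA positions carry no weight
.bin_values <- function(v, nbins) {
  m <- length(v)
  if (m == nbins) return(v)
  bad <- is.na(v)
  v0 <- ifelse(bad, 0, v)
  wt <- as.numeric(!bad)
  cs_v <- c(0, cumsum(v0))
  cs_w <- c(0, cumsum(wt))
  # integral of the step function up to fractional coordinate t in [0, m]
  S <- function(cs, vv, t) {
    i <- pmin(floor(t), m - 1L)
    cs[i + 1L] + (t - i) * vv[i + 1L]
  }
  edges <- (0:nbins) * (m / nbins)
  iv <- S(cs_v, v0, edges)
  iw <- S(cs_w, wt, edges)
  num <- diff(iv); den <- diff(iw)
  out <- num / den
  out[den <= 1e-12] <- NA
  out
}

#' Melting-temperature metagene profile
#'
#' For each gene the Tm track is computed over the coding span (start to
#' stop codon, including introns) plus fixed-length flanks; minus-strand
#' genes are reversed so every profile reads 5' to 3'.  Each body track is
#' averaged into `body_bins` equal-width bins (coverage-weighted means);
#' flanks stay at 1-bp resolution.  Positions are aggregated across genes by
#' the median, ignoring missing values (flanks clipped at sequence ends and
#' N-containing windows).
#'
#' @param genes List of [gene_model()] objects (coding span >= 9 bp).
#' @param genome A [seq_record()] or named list of them.
#' @param flank Flank length in bp (default 2000).
#' @param body_bins Number of body bins (default 3000).
#' @param dna_conc,salt See [nn_tm()].
#' @param orient_by_strand Reverse minus-strand profiles (default TRUE).
#' @return A `metagene_profile` list with `upstream`, `body`, `downstream`
#'   median vectors, matching `n_genes_*` counts, and the per-gene matrices.
#' @export
metagene <- function(genes, genome, flank = 2000L, body_bins = 3000L,
                     dna_conc = 50, salt = 50, orient_by_strand = TRUE) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  genes <- Filter(function(g) {
    g$exons$end[nrow(g$exons)] - g$exons$start[1L] >= 9L
  }, genes)
  if (length(genes) == 0L) stop("no eligible genes (coding span >= 9 bp)")
  get_chrom <- function(g) {
    if (inherits(genome, "seq_record")) genome else genome[[g$chrom]]
  }
  up_m <- matrix(NA_real_, length(genes), flank)
  body_m <- matrix(NA_real_, length(genes), body_bins)
  down_m <- matrix(NA_real_, length(genes), flank)
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    chrom <- get_chrom(g)
    if (is.null(chrom)) stop("chromosome not found: ", g$chrom)
    L <- nchar(chrom$seq)
    s <- g$exons$start[1L]; e <- g$exons$end[nrow(g$exons)]
    lo <- s - flank; hi <- e + flank
    avail <- substring(chrom$seq, max(lo, 0L) + 1L, min(hi, L))
    padded <- paste0(strrep("N", max(0L, -lo)), avail,
                     strrep("N", max(0L, hi - L)))
    track <- tm_track(padded, dna_conc = dna_conc, salt = salt)$values
    if (orient_by_strand && g$strand == "-") track <- rev(track)
    span <- e - s
    # window starts: flank upstream, span - 8 body, flank downstream
    up <- track[seq_len(flank)]
    body <- track[flank + seq_len(span - 8L)]
    down <- track[flank + span - 8L + seq_len(flank)]
    up_m[gi, ] <- up
    body_m[gi, ] <- .bin_values(body, body_bins)
    down_m[gi, ] <- down
  }
  med <- function(m) apply(m, 2L, function(col) {
    if (all(is.na(col))) NA_real_ else median(col, na.rm = TRUE)
  })
  ngen <- function(m) colSums(!is.na(m))
  structure(list(upstream = med(up_m), body = med(body_m),
                 downstream = med(down_m),
                 n_genes_upstream = ngen(up_m), n_genes_body = ngen(body_m),
                 n_genes_downstream = ngen(down_m),
                 per_gene = list(upstream = up_m, body = body_m,
                                 downstream = down_m)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %d genes; flanks %d bp, body %d bins; median body Tm %.2f C\n",
              nrow(x$per_gene$body), length(x$upstream), length(x$body),
              median(x$body, na.rm = TRUE)))
  invisible(x)
}
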