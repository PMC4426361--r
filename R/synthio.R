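# Seeded generator of synthetic genomes, gene models, repeat annotations,
# codon-usage regimes and ortholog tables with known planted parameters.
# Every downstream scanner has a recoverable ground truth: planted repeat
# fragments are never overwritten by later features (genes overwrite
# background only; introns may span planted repeats, which is exactly what
# the intron-repeat-size feature measures).

#' Toy transposon library
#'
#' A small fixed consensus library emulating the dominant repeat classes of
#' a Drosophila-like genome: a DINE-1-like helitron, an LTR element, a
#' LINE/CR1-like element and a DNA transposon.  Consensi are deterministic
#' (fixed internal seed) so fixtures are bit-reproducible.
#'
#' @return data.frame with columns name, class, consensus.
#' @export
default_transposon_library <- function() {
  mk <- function(len, gc) paste(sample(c("A", "T", "G", "C"), len,
                                       replace = TRUE,
                                       prob = c((1 - gc) / 2, (1 - gc) / 2,
                                                gc / 2, gc / 2)),
                                collapse = "")
  .with_seed(990001L, data.frame(
    name = c("DINE1-like", "Gypsy-like", "CR1-like", "Tc1-like"),
    class = c("DINE-1", "LTR", "LINE", "DNA"),
    consensus = c(mk(400L, 0.35), mk(1000L, 0.45), mk(800L, 0.40),
                  mk(600L, 0.42)),
    stringsAsFactors = FALSE))
}

#' Synthetic-region configuration
#'
#' Captures every planted parameter of one synthetic species/region.  The
#' two profiles encode the stated contrast between a heterochromatic
#' F-element-like region (high transposon density, large introns, more
#' exons) and a euchromatic D-element-like reference (low density, compact
#' genes).
#'
#' @param seed Integer seed; all outputs are byte-identical given the seed.
#' @param profile `"F"` or `"D"`; sets the defaults below.
#' @param region_length Region length in bp.
#' @param background_gc Background GC fraction.
#' @param transposon_library data.frame(name, class, consensus).
#' @param target_transposon_density Planted transposon density (fraction of
#'   bases; achieved within +/- 2 percentage points).
#' @param dinucleotide_runs data.frame(dinuc, units, copies) of planted
#'   microsatellite runs.
#' @param n_genes Number of genes to plant.
#' @param exon_count_distribution,exon_size_distribution,intron_size_distribution
#'   Named distributions, e.g. `list(dist = "poisson1", lambda = 3)` (1 +
#'   Poisson), `list(dist = "lognormal", meanlog =, sdlog =, min =)`, or
#'   `list(dist = "fixed", value =)`.
#' @param codon_lambda Mixture weight(s) in `[0,1]` between the optimal
#'   codon table (weight lambda) and the uniform within-family table;
#'   scalar or per-gene vector.
#' @param optimal_codons Named character vector amino acid -> optimal codon;
#'   default prefers C-ending (else G-ending) codons, the usual
#'   translationally optimal choice in Drosophila.
#' @param n_reversals,n_wanderers Planted rearrangement counts for the
#'   ortholog table.
#' @param chrom Name of the single synthetic chromosome.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, profile = c("F", "D"),
                         region_length = 150000L,
                         background_gc = NULL,
                         transposon_library = default_transposon_library(),
                         target_transposon_density = NULL,
                         dinucleotide_runs = NULL,
                         n_genes = 20L,
                         exon_count_distribution = NULL,
                         exon_size_distribution = NULL,
                         intron_size_distribution = NULL,
                         codon_lambda = 0.5,
                         optimal_codons = NULL,
                         n_reversals = 3L, n_wanderers = 0L,
                         chrom = NULL) {
  profile <- match.arg(profile)
  f_like <- profile == "F"
  if (is.null(background_gc)) background_gc <- if (f_like) 0.38 else 0.45
  if (is.null(target_transposon_density))
    target_transposon_density <- if (f_like) 0.30 else 0.07
  if (is.null(dinucleotide_runs))
    dinucleotide_runs <- data.frame(
      dinuc = c("CA", "AG", "AT"), units = c(20L, 15L, 30L),
      copies = if (f_like) c(6L, 4L, 3L) else c(2L, 1L, 1L),
      stringsAsFactors = FALSE)
  if (is.null(exon_count_distribution))
    exon_count_distribution <- if (f_like)
      list(dist = "poisson1", lambda = 3) else list(dist = "poisson1", lambda = 1.5)
  if (is.null(exon_size_distribution))
    exon_size_distribution <- list(dist = "lognormal", meanlog = log(200),
                                   sdlog = 0.5, min = 30L)
  if (is.null(intron_size_distribution))
    intron_size_distribution <- if (f_like)
      list(dist = "lognormal", meanlog = log(800), sdlog = 0.7, min = 60L)
    else list(dist = "lognormal", meanlog = log(90), sdlog = 0.5, min = 50L)
  if (is.null(optimal_codons)) optimal_codons <- .default_optimal_codons()
  if (is.null(chrom)) chrom <- paste0("synth", profile)
  stopifnot(background_gc >= 0, background_gc <= 1,
            target_transposon_density >= 0, target_transposon_density <= 1,
            all(codon_lambda >= 0), all(codon_lambda <= 1),
            n_genes >= 0, n_reversals >= 0, n_wanderers >= 0)
  structure(list(seed = as.integer(seed), profile = profile,
                 region_length = as.integer(region_length),
                 background_gc = background_gc,
                 transposon_library = transposon_library,
                 target_transposon_density = target_transposon_density,
                 dinucleotide_runs = dinucleotide_runs,
                 n_genes = as.integer(n_genes),
                 exon_count_distribution = exon_count_distribution,
                 exon_size_distribution = exon_size_distribution,
                 intron_size_distribution = intron_size_distribution,
                 codon_lambda = codon_lambda,
                 optimal_codons = optimal_codons,
                 n_reversals = as.integer(n_reversals),
                 n_wanderers = as.integer(n_wanderers),
                 chrom = chrom),
            class = "synth_config")
}

# translationally optimal codon per amino acid: prefer C-ending, else
# G-ending, else the first codon of the family
.default_optimal_codons <- function() {
  gc <- .genetic_code()
  fams <- split(gc$sense, gc$aa_sense[gc$sense])
  vapply(fams, function(cods) {
    endc <- cods[substr(cods, 3L, 3L) == "C"]
    endg <- cods[substr(cods, 3L, 3L) == "G"]
    if (length(endc)) endc[1L] else if (length(endg)) endg[1L] else cods[1L]
  }, character(1L))
}

.sample_dist <- function(d, n) {
  out <- switch(d$dist,
    fixed = rep(as.integer(d$value), n),
    poisson1 = 1L + stats::rpois(n, d$lambda),
    lognormal = pmax(as.integer(d$min),
                     as.integer(round(stats::rlnorm(n, d$meanlog, d$sdlog)))),
    stop("unknown distribution: ", d$dist))
  out
}

# rejection-sample a free placement [start, start+len) against an IRanges
# of occupied intervals (0-based half-open in/out)
.free_position <- function(len, region_length, occupied, tries = 2000L) {
  if (len > region_length) stop("feature longer than region (", len, " bp)")
  for (t in seq_len(tries)) {
    s <- sample.int(region_length - len + 1L, 1L) - 1L
    cand <- .iv_to_iranges(s, s + len)
    if (length(occupied) == 0L ||
        length(IRanges::findOverlaps(cand, occupied)) == 0L)
      return(s)
  }
  stop("could not place a ", len, " bp feature: region too crowded")
}

#' Generate a synthetic genome with planted repeats
#'
#' Background bases are i.i.d. at the configured GC; dinucleotide runs are
#' planted at recorded positions; transposon fragments (random sub-spans of
#' the library consensi, >= 50 bp, either strand) are inserted without
#' nesting until the planted density is within +/- 2 percentage points of
#' the target.  The returned fragment table is the exact planted truth.
#'
#' @param cfg A [synth_config()].
#' @return List: `genome` ([seq_record()]), `fragments` (planted
#'   repeat-fragment data.frame with a `sequence` truth column), `runs`
#'   (planted dinucleotide runs with coordinates), `config`.
#' @export
generate_genome <- function(cfg) {
  .with_seed(cfg$seed, {
    L <- cfg$region_length
    gcf <- cfg$background_gc
    seqv <- sample(c("A", "T", "G", "C"), L, replace = TRUE,
                   prob = c((1 - gcf) / 2, (1 - gcf) / 2, gcf / 2, gcf / 2))
    occupied <- IRanges::IRanges()
    occupy <- function(s, e) {
      occupied <<- c(occupied, .iv_to_iranges(s, e))
    }
    # dinucleotide runs
    runs <- cfg$dinucleotide_runs
    run_rows <- list()
    if (!is.null(runs) && nrow(runs) > 0L) {
      for (ri in seq_len(nrow(runs))) {
        unit <- strsplit(runs$dinuc[ri], "")[[1L]]
        len <- 2L * runs$units[ri]
        breaker <- setdiff(c("A", "C", "G", "T"), unit)[1L]
        for (cp in seq_len(runs$copies[ri])) {
          s <- .free_position(len + 2L, L, occupied) + 1L
          # guard bases on both sides stop the run from extending into
          # background by chance, so recovered lengths match planted exactly
          seqv[(s + 1L):(s + len)] <- rep(unit, runs$units[ri])
          seqv[s] <- breaker
          seqv[s + len + 1L] <- breaker
          occupy(s - 1L, s + len + 1L)
          run_rows[[length(run_rows) + 1L]] <-
            data.frame(dinuc = runs$dinuc[ri], units = runs$units[ri],
                       start = s, end = s + len, stringsAsFactors = FALSE)
        }
      }
    }
    # guard bases around runs must not extend the run
    # (handled by sampling background there below)
    # transposon fragments
    lib <- cfg$transposon_library
    frag_rows <- list()
    target_bp <- cfg$target_transposon_density * L
    planted <- 0
    if (target_bp > 0) {
      if (max(nchar(lib$consensus)) < 50L)
        stop("target density unreachable: no consensus >= 50 bp")
      while (planted < target_bp) {
        e <- lib[sample.int(nrow(lib), 1L), ]
        clen <- nchar(e$consensus)
        flen <- sample(50:clen, 1L)
        room <- floor(target_bp + 0.02 * L - planted)
        if (flen > room) flen <- max(50L, room)
        cstart <- sample.int(clen - flen + 1L, 1L)
        sub <- substr(e$consensus, cstart, cstart + flen - 1L)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") sub <- revcomp(sub)
        s <- .free_position(flen, L, occupied)
        seqv[(s + 1L):(s + flen)] <- strsplit(sub, "")[[1L]]
        occupy(s, s + flen)
        frag_rows[[length(frag_rows) + 1L]] <-
          data.frame(chrom = cfg$chrom, start = s, end = s + flen,
                     strand = strand, repeat_class = e$class,
                     repeat_name = e$name, sequence = sub,
                     stringsAsFactors = FALSE)
        planted <- planted + flen
      }
    }
    fragments <- if (length(frag_rows)) do.call(rbind, frag_rows)
                 else cbind(.empty_fragments(), sequence = character(0))
    fragments <- fragments[order(fragments$start), , drop = FALSE]
    rownames(fragments) <- NULL
    run_tab <- if (length(run_rows)) do.call(rbind, run_rows) else
      data.frame(dinuc = character(), units = integer(), start = integer(),
                 end = integer())
    list(genome = seq_record(cfg$chrom, paste(seqv, collapse = "")),
         fragments = fragments, runs = run_tab, config = cfg)
  })
}

# sample one CDS of n_codons codons: ATG + mixture internals + stop
.sample_cds <- function(n_codons, lambda, optimal_codons) {
  gc <- .genetic_code()
  aas <- unique(gc$aa_sense)
  m <- max(0L, n_codons - 2L)
  internal <- character(m)
  if (m > 0L) {
    aa_pick <- sample(aas, m, replace = TRUE)
    use_opt <- stats::runif(m) < lambda
    internal[use_opt] <- optimal_codons[aa_pick[use_opt]]
    ni <- which(!use_opt)
    if (length(ni)) {
      fams <- split(gc$sense, gc$aa_sense[gc$sense])
      fam_list <- fams[aa_pick[ni]]
      sizes <- lengths(fam_list)
      pick <- as.integer(floor(stats::runif(length(ni)) * sizes)) + 1L
      off <- cumsum(c(0L, sizes[-length(sizes)]))
      internal[ni] <- unlist(fam_list, use.names = FALSE)[off + pick]
    }
  }
  paste(c("ATG", internal, sample(gc$stops, 1L)), collapse = "")
}

#' Plant gene models into a synthetic genome
#'
#' Exon counts, exon sizes and intron sizes are drawn from the configured
#' distributions; each CDS begins with ATG, ends with a stop, contains no
#' internal stop, and its codons are drawn from
#' lambda * optimal-table + (1 - lambda) * uniform within each synonymous
#' family.  Exons overwrite background sequence only (planted repeats are
#' preserved; introns may span them); minus-strand genes are written
#' reverse-complemented.  Gene coding spans do not overlap each other.
#'
#' @param cfg A [synth_config()].
#' @param genome The output of [generate_genome()] for the same config.
#' @return List: `models` (list of [gene_model()]), `lambda` (named
#'   per-gene truth), `genome` (updated [seq_record()]), `fragments`,
#'   `runs`.
#' @export
generate_gene_models <- function(cfg, genome) {
  .with_seed(cfg$seed + 1000L, {
    L <- cfg$region_length
    seqv <- strsplit(genome$genome$seq, "")[[1L]]
    feat <- rbind(
      if (nrow(genome$fragments)) genome$fragments[, c("start", "end")],
      if (nrow(genome$runs)) genome$runs[, c("start", "end")])
    occupied_feat <- if (is.null(feat) || nrow(feat) == 0L) IRanges::IRanges()
                     else .iv_to_iranges(feat$start, feat$end)
    span_occupied <- IRanges::IRanges()
    lambdas <- rep_len(cfg$codon_lambda, cfg$n_genes)
    models <- vector("list", cfg$n_genes)
    for (g in seq_len(cfg$n_genes)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        n_ex <- .sample_dist(cfg$exon_count_distribution, 1L)
        ex_sizes <- .sample_dist(cfg$exon_size_distribution, n_ex)
        total <- sum(ex_sizes)
        pad <- (3L - total %% 3L) %% 3L
        ex_sizes[n_ex] <- ex_sizes[n_ex] + pad
        if (sum(ex_sizes) < 9L) ex_sizes[n_ex] <- ex_sizes[n_ex] + 9L
        in_sizes <- if (n_ex > 1L)
          .sample_dist(cfg$intron_size_distribution, n_ex - 1L) else integer(0)
        span <- sum(ex_sizes) + sum(in_sizes)
        if (span >= L) next
        s <- sample.int(L - span + 1L, 1L) - 1L
        ex_starts <- s + cumsum(c(0L, head(ex_sizes, -1L) + in_sizes))
        ex_ends <- ex_starts + ex_sizes
        exon_ir <- .iv_to_iranges(ex_starts, ex_ends)
        span_ir <- .iv_to_iranges(s, s + span)
        if (length(IRanges::findOverlaps(exon_ir, occupied_feat)) > 0L) next
        if (length(IRanges::findOverlaps(span_ir, span_occupied)) > 0L) next
        strand <- sample(c("+", "-"), 1L)
        cds <- .sample_cds(sum(ex_sizes) %/% 3L, lambdas[g],
                           cfg$optimal_codons)
        towrite <- if (strand == "-") revcomp(cds) else cds
        off <- 0L
        for (ei in seq_len(n_ex)) {
          piece <- substr(towrite, off + 1L, off + ex_sizes[ei])
          seqv[(ex_starts[ei] + 1L):ex_ends[ei]] <- strsplit(piece, "")[[1L]]
          off <- off + ex_sizes[ei]
        }
        span_occupied <- c(span_occupied, span_ir)
        models[[g]] <- gene_model(sprintf("g%03d", g), "t1", cfg$chrom,
                                  strand, ex_starts, ex_ends)
        placed <- TRUE
        break
      }
      if (!placed) stop("region too small for requested genes (placed ",
                        g - 1L, " of ", cfg$n_genes, ")")
    }
    names(models) <- vapply(models, `[[`, character(1L), "gene_id")
    names(lambdas) <- names(models)
    list(models = models, lambda = lambdas,
         genome = seq_record(cfg$chrom, paste(seqv, collapse = "")),
         fragments = genome$fragments, runs = genome$runs)
  })
}

#' Generate an ortholog table with planted reversals and wanderers
#'
#' Species B's gene order on the focal element is species A's order after
#' `n_reversals` uniformly random signed reversals; `n_wanderers` genes are
#' then re-assigned to a different Muller element in B.  The exact planted
#' truth (reversal list, wanderer set, final signed permutation) is
#' returned alongside.
#'
#' @param cfg A [synth_config()] (uses `n_genes`, `n_reversals`,
#'   `n_wanderers`, `seed`).
#' @param species Names of the two synthetic species.
#' @return List: `table` ([ortholog_table()]), `truth` (list with
#'   `reversals`, `wanderers`, `permutation`).
#' @export
generate_ortholog_table <- function(cfg, species = c("spA", "spB")) {
  .with_seed(cfg$seed + 2000L, {
    n <- cfg$n_genes
    if (n < 2L) stop("need n_genes >= 2")
    if (cfg$n_wanderers > n) stop("n_wanderers > n_genes")
    ids <- sprintf("g%03d", seq_len(n))
    strand_a <- sample(c("+", "-"), n, replace = TRUE)
    perm <- seq_len(n)
    revs <- list()
    for (r in seq_len(cfg$n_reversals)) {
      i <- sample.int(n, 1L)
      j <- if (i < n) sample(i:n, 1L) else n
      perm <- .apply_reversal(perm, i, j)
      revs[[r]] <- c(i = i, j = j)
    }
    wander_ids <- if (cfg$n_wanderers > 0L)
      sample(ids, cfg$n_wanderers) else character(0)
    other_elements <- c("A", "B", "C", "D", "E")
    a_tab <- data.frame(gene_id = ids, species = species[1L], element = "F",
                        scaffold = "scafA_F", position = seq_len(n),
                        strand = strand_a, stringsAsFactors = FALSE)
    b_gene <- ids[abs(perm)]
    b_strand <- ifelse(perm > 0L, strand_a[abs(perm)],
                       ifelse(strand_a[abs(perm)] == "+", "-", "+"))
    b_tab <- data.frame(gene_id = b_gene, species = species[2L],
                        element = "F", scaffold = "scafB_F",
                        position = seq_len(n), strand = b_strand,
                        stringsAsFactors = FALSE)
    if (length(wander_ids)) {
      idx <- match(wander_ids, b_tab$gene_id)
      b_tab$element[idx] <- sample(other_elements, length(idx), replace = TRUE)
      b_tab$scaffold[idx] <- paste0("scafB_", b_tab$element[idx])
      keep <- setdiff(seq_len(n), idx)
      b_tab$position[keep] <- seq_along(keep)
      for (el in unique(b_tab$element[idx]))
        b_tab$position[idx][b_tab$element[idx] == el] <-
          seq_len(sum(b_tab$element[idx] == el))
    }
    tab <- ortholog_table(c(a_tab$gene_id, b_tab$gene_id),
                          c(a_tab$species, b_tab$species),
                          c(a_tab$element, b_tab$element),
                          c(a_tab$scaffold, b_tab$scaffold),
                          c(a_tab$position, b_tab$position),
                          c(a_tab$strand, b_tab$strand))
    truth <- list(
      reversals = if (length(revs))
        as.data.frame(do.call(rbind, revs)) else
        data.frame(i = integer(), j = integer()),
      wanderers = wander_ids,
      permutation = perm)
    list(table = tab, truth = truth)
  })
}

#' Mutationally preferred codon per amino acid (A-, else T-ending)
#'
#' The complement of [.default_optimal_codons()]: emulates an AT-rich
#' mutational pressure whose preferred codons disagree with the
#' translationally optimal (C/G-ending) set.
#' @return Named character vector amino acid -> codon.
#' @keywords internal
.mutational_codons <- function() {
  gc <- .genetic_code()
  fams <- split(gc$sense, gc$aa_sense[gc$sense])
  vapply(fams, function(cods) {
    enda <- cods[substr(cods, 3L, 3L) == "A"]
    endt <- cods[substr(cods, 3L, 3L) == "T"]
    if (length(enda)) enda[1L] else if (length(endt)) endt[1L] else cods[1L]
  }, character(1L))
}

#' Generate a codon-usage cohort with a planted bias regime
#'
#' Emulates the Nc-vs-CAI contrast between codon bias driven by selection
#' and by mutational pressure.  Per-gene mixture weights lambda are drawn
#' uniformly on `[0, lambda_max]`; each gene's codons follow
#' lambda * preferred-table + (1 - lambda) * uniform-within-family.  Under
#' the `"selection"` regime the preferred table IS the species' optimal
#' (reference) table, so strongly biased (low-Nc) genes also have high CAI
#' (negative Nc-CAI slope); under `"mutational_bias"` the preferred table
#' is an AT-ending mutational table disagreeing with the reference, so
#' low-Nc genes have LOW CAI (positive slope).  The CAI reference w is
#' derived, as in the real pipeline, from a species-level reference cohort
#' of strongly optimal-biased genes, independent of the studied cohort.
#'
#' @param n_genes Cohort size.
#' @param regime `"selection"` or `"mutational_bias"`.
#' @param seed Integer seed.
#' @param n_codons Codons per gene.
#' @param lambda_max Upper bound of the per-gene mixture weight.
#' @return List: `tables` (per-gene [codon_usage()]), `lambda`, `nc`,
#'   `cai`, `w` (reference relative adaptiveness), `regime`.
#' @export
generate_codon_cohort <- function(n_genes = 200L,
                                  regime = c("selection", "mutational_bias"),
                                  seed = 1L, n_codons = 300L,
                                  lambda_max = 0.9) {
  regime <- match.arg(regime)
  .with_seed(seed, {
    optimal <- .default_optimal_codons()
    preferred <- if (regime == "selection") optimal else .mutational_codons()
    # species-level reference: pooled usage of 50 strongly optimal genes
    ref_tabs <- lapply(seq_len(50L), function(i)
      count_codons(.sample_cds(n_codons, 0.9, optimal)))
    pooled <- Reduce(`+`, lapply(ref_tabs, as.numeric))
    ref <- codon_usage(setNames(pooled, names(unclass(ref_tabs[[1L]]))))
    w <- relative_adaptiveness(ref)
    lambda <- stats::runif(n_genes, 0, lambda_max)
    tables <- lapply(lambda, function(l)
      count_codons(.sample_cds(n_codons, l, preferred)))
    names(tables) <- sprintf("g%03d", seq_len(n_genes))
    nc <- vapply(tables, function(t)
      as.numeric(effective_number_of_codons(t)), numeric(1L))
    cai_v <- vapply(tables, cai, numeric(1L), w = w)
    list(tables = tables, lambda = setNames(lambda, names(tables)),
         nc = nc, cai = cai_v, w = w, regime = regime)
  })
}

#' Materialize a complete synthetic fixture set on disk
#'
#' Writes FASTA (genome), BED12 (genes), BED6+class (repeats), and TSV
#' truth tables (planted runs, per-gene lambda, ortholog table, reversal
#' and wanderer truth) plus the config as JSON, all with deterministic
#' column order and newline endings.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixtures <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(cfg)
  gm <- generate_gene_models(cfg, gen)
  ot <- generate_ortholog_table(cfg)
  paths <- c(
    fasta = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.bed"),
    repeats = file.path(dir, "repeats.bed"),
    runs = file.path(dir, "planted_runs.tsv"),
    lambda = file.path(dir, "planted_lambda.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    reversals = file.path(dir, "planted_reversals.tsv"),
    wanderers = file.path(dir, "planted_wanderers.tsv"),
    config = file.path(dir, "config.json"))
  write_fasta(gm$genome, paths["fasta"])
  write_bed12(gm$models, paths["genes"])
  write_repeat_bed(gen$fragments, paths["repeats"])
  wt <- function(df, p) {
    con <- file(p, "wb"); on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n")
  }
  wt(gen$runs, paths["runs"])
  wt(data.frame(gene_id = names(gm$lambda), lambda = unname(gm$lambda)),
     paths["lambda"])
  write_ortholog_table(ot$table, paths["orthologs"])
  wt(ot$truth$reversals, paths["reversals"])
  wt(data.frame(gene_id = ot$truth$wanderers), paths["wanderers"])
  cfg_out <- unclass(cfg)
  cfg_out$transposon_library <- NULL
  jsonlite::write_json(cfg_out, paths["config"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
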