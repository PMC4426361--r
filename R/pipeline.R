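# Configuration and orchestration of all stages over one or more analysis
# regions, with deterministic TSV/JSON report assembly.

.default_params <- function() {
  list(window = 1000L, step = 500L, k = 13L,
       flank = 2000L, body_bins = 3000L,
       dna_conc = 50, salt = 50,
       chisq_quantile = 0.975, n_features = 8L,
       top_fraction = 0.1, min_units = 2L, max_units = 100L,
       seed = 1L)
}

.all_stages <- c("repeats", "genes", "codon", "melt", "outliers", "synteny")

#' Load a pipeline configuration
#'
#' A configuration is a JSON file (or an equivalent R list) with `regions`
#' (each: `label`, `fasta`, `genes`, `repeats`, optional `orthologs`),
#' optional `stages` (subset of repeats/genes/codon/melt/outliers/synteny)
#' and optional `params` overriding the defaults (window, step, k, flank,
#' body_bins, dna_conc, salt, chisq_quantile, top_fraction, seed).  Every
#' method parameter of the pipeline surfaces here with the standard
#' analysis value as default.
#'
#' @param config Path to a JSON file, or a list.
#' @return A validated `pipeline_config` list.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  if (is.null(config$regions) || length(config$regions) == 0L)
    stop("config needs at least one region")
  labels <- vapply(config$regions, function(r) r$label %||% "", character(1L))
  if (any(!nzchar(labels)) || anyDuplicated(labels))
    stop("region labels must be present and unique")
  config$stages <- config$stages %||% .all_stages
  bad <- setdiff(config$stages, .all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  params <- .default_params()
  for (nm in names(config$params)) params[[nm]] <- config$params[[nm]]
  config$params <- params
  structure(config, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_tsv <- function(df, path) {
  con <- file(path, "wb"); on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  path
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages per region: repeat landscape (k-mer
#' spectrum, dinucleotide runs, window density, masked fractions), gene
#' features, codon bias (Nc/CAI and the LOESS regime call), melting
#' metagene, Distance-Distance outliers, and synteny/reversal analysis when
#' an ortholog table is configured.  With `outdir` set, one TSV/JSON per
#' stage plus a combined JSON summary and a parameter log are written; the
#' run is reproducible from config + seed.
#'
#' @param config A `pipeline_config`, config list, or JSON path
#'   (see [load_config()]).
#' @param outdir Optional output directory.
#' @return Nested list of stage results per region (class
#'   `pipeline_result`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else load_config(config)
  p <- cfg$params
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  log_lines <- c(sprintf("mullerf %s", as.character(utils::packageVersion("mullerf"))),
                 sprintf("R %s", getRversion()),
                 paste0("param ", names(p), " = ",
                        vapply(p, function(v) paste(format(v), collapse = ","),
                               character(1L))))
  stage <- function(name, region_label, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for region '", region_label, "': ",
           conditionMessage(e), call. = FALSE))
  }
  for (rs in cfg$regions) {
    lab <- rs$label
    need <- function(field) {
      path <- rs[[field]]
      if (is.null(path)) stop("region '", lab, "' has no '", field, "' file")
      if (!file.exists(path)) stop("missing ", field, " file for region '",
                                   lab, "': ", path)
      path
    }
    genome <- stage("io", lab, read_fasta(need("fasta")))
    region <- genomic_intervals(genome[[1L]]$id, 0L, nchar(genome[[1L]]$seq))
    res <- list(label = lab)
    repeats <- NULL
    if (any(c("repeats", "genes", "outliers") %in% cfg$stages)) {
      rp <- need("repeats")
      repeats <- stage("io", lab, {
        if (grepl("\\.out$", rp)) read_repeatmasker_out(rp) else
          read_repeat_bed(rp)
      })
    }
    models <- NULL
    if (any(c("genes", "codon", "melt", "outliers") %in% cfg$stages))
      models <- stage("io", lab, read_bed12(need("genes")))
    if ("repeats" %in% cfg$stages) {
      res$repeats <- stage("repeats", lab, list(
        kmer_spectrum = kmer_spectrum(genome, p$k),
        dinuc_runs = scan_dinucleotide_runs(genome[[1L]],
                                            min_units = p$min_units,
                                            max_units = p$max_units),
        window_density = window_density(repeats, region,
                                        window = p$window, step = p$step),
        masked_fraction = masked_fraction(repeats, region)))
    }
    features <- NULL
    codon_tables <- NULL
    w <- NULL
    if (any(c("genes", "codon", "outliers") %in% cfg$stages)) {
      picked <- select_comprehensive_isoform(models)
      codon_tables <- stage("codon", lab, {
        tabs <- lapply(picked, function(m) count_codons(extract_cds(m, genome)))
        names(tabs) <- vapply(picked, `[[`, character(1L), "gene_id")
        tabs
      })
      w <- stage("codon", lab,
                 select_reference_set(codon_tables,
                                      top_fraction = p$top_fraction)$w)
      features <- stage("genes", lab,
                        gene_feature_table(models, genome, repeats, w = w))
    }
    if ("genes" %in% cfg$stages) res$genes <- list(features = features)
    if ("codon" %in% cfg$stages) {
      finite <- is.finite(features$nc) & is.finite(features$cai)
      regime <- if (sum(finite) >= 20L) {
        stage("codon", lab,
              loess_regime(features$nc[finite], features$cai[finite]))
      } else {
        # small regions (or many genes with undefined Nc) cannot support
        # the smoother; record the reason instead of aborting the bundle
        list(span = NA_real_, verdict = NA_character_,
             n_negative = NA_integer_, n_positive = NA_integer_,
             note = "fewer than 20 genes with defined Nc/CAI")
      }
      res$codon <- list(
        per_gene = features[, c("gene_id", "nc", "cai")],
        usage = codon_usage_summary(Reduce(function(a, b)
          codon_usage(setNames(as.numeric(a) + as.numeric(b),
                               names(unclass(a)))), codon_tables)),
        no_bias_cai = no_bias_cai(w),
        regime = list(span = regime$span, verdict = regime$verdict,
                      n_negative = regime$n_negative,
                      n_positive = regime$n_positive))
    }
    if ("melt" %in% cfg$stages) {
      res$melt <- stage("melt", lab,
                        metagene(models, genome, flank = p$flank,
                                 body_bins = p$body_bins,
                                 dna_conc = p$dna_conc, salt = p$salt))
    }
    if ("outliers" %in% cfg$stages) {
      res$outliers <- stage("outliers", lab, {
        X <- as.matrix(features[, c("coding_span", "intron_repeat_size",
                                    "coding_region_size", "n_coding_exons",
                                    "median_coding_exon_size",
                                    "median_intron_size", "nc", "cai")])
        rownames(X) <- features$gene_id
        complete <- rowSums(!is.finite(X)) == 0L
        dd_analysis(X[complete, , drop = FALSE],
                    quantile = p$chisq_quantile, seed = p$seed)
      })
    }
    if ("synteny" %in% cfg$stages && !is.null(rs$orthologs)) {
      tab <- stage("synteny", lab, read_ortholog_table(need("orthologs")))
      sp <- sort(unique(tab$species))
      res$synteny <- stage("synteny", lab,
                           synteny_report(tab, sp[1L], sp[2L]))
    }
    if (!is.null(outdir)) .write_region_outputs(res, outdir)
    results[[lab]] <- res
  }
  if (!is.null(outdir)) {
    writeLines(log_lines, con <- file(file.path(outdir, "run_log.txt"), "wb"))
    close(con)
    summary <- lapply(results, function(r) {
      list(label = r$label,
           masked_total = if (!is.null(r$repeats))
             unname(r$repeats$masked_fraction["total"]) else NULL,
           n_genes = if (!is.null(r$genes)) nrow(r$genes$features) else NULL,
           regime = if (!is.null(r$codon)) r$codon$regime$verdict else NULL,
           n_rd_outliers = if (!is.null(r$outliers))
             sum(r$outliers$outlier_rd) else NULL,
           reversal_distance = if (!is.null(r$synteny))
             r$synteny$reversal_distance else NULL)
    })
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(results, class = "pipeline_result")
}

.write_region_outputs <- function(res, outdir) {
  lab <- res$label
  fp <- function(name, ext) file.path(outdir, paste0(lab, ".", name, ".", ext))
  if (!is.null(res$repeats)) {
    .write_tsv(res$repeats$kmer_spectrum$histogram, fp("kmer_spectrum", "tsv"))
    .write_tsv(res$repeats$dinuc_runs$table, fp("dinuc_runs", "tsv"))
    .write_tsv(res$repeats$window_density, fp("window_density", "tsv"))
    mf <- res$repeats$masked_fraction
    .write_tsv(data.frame(class = names(mf), fraction = unname(mf)),
               fp("masked_fraction", "tsv"))
  }
  if (!is.null(res$genes))
    .write_tsv(res$genes$features, fp("gene_features", "tsv"))
  if (!is.null(res$codon)) {
    .write_tsv(res$codon$per_gene, fp("codon_bias", "tsv"))
    .write_tsv(res$codon$usage, fp("codon_usage", "tsv"))
    jsonlite::write_json(c(res$codon$regime,
                           list(no_bias_cai = res$codon$no_bias_cai)),
                         fp("regime", "json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$melt)) {
    m <- res$melt
    prof <- data.frame(
      segment = rep(c("upstream", "body", "downstream"),
                    c(length(m$upstream), length(m$body), length(m$downstream))),
      index = c(seq_along(m$upstream), seq_along(m$body),
                seq_along(m$downstream)),
      median_tm = c(m$upstream, m$body, m$downstream),
      n_genes = c(m$n_genes_upstream, m$n_genes_body, m$n_genes_downstream))
    .write_tsv(prof, fp("metagene", "tsv"))
  }
  if (!is.null(res$outliers)) {
    out <- cbind(gene_id = rownames(res$outliers), res$outliers)
    .write_tsv(out, fp("dd_outliers", "tsv"))
  }
  if (!is.null(res$synteny)) {
    s <- res$synteny
    jsonlite::write_json(
      list(species = s$species, element = s$element, n_shared = s$n_shared,
           order = s$order, n_blocks = s$n_blocks,
           mean_genes_per_block = s$mean_genes_per_block,
           reversal_distance = s$reversal_distance,
           scenario = s$scenario,
           n_wanderers = if (is.null(s$wanderers$wanderers)) 0L else
             nrow(s$wanderers$wanderers)),
      fp("synteny", "json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(NULL)
}
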