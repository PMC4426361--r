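#' @importFrom stats median mad quantile qchisq pchisq cov setNames
#' @importFrom utils read.table write.table head tail
NULL

# All internal coordinates are 0-based half-open (BED native).  GFF3 and
# RepeatMasker coordinates are converted on read.  IRanges (1-based closed)
# is used internally for interval algebra; the two helpers below are the only
# places where the conversion happens.

.iv_to_iranges <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

.iranges_to_iv <- function(ir) {
  data.frame(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

#' Construct a sequence record
#'
#' A `seq_record` is a named nucleotide sequence over the alphabet
#' \{A, C, G, T, N\}; it is the substrate for every scanner in the package.
#'
#' @param id Non-empty record identifier.
#' @param seq Nucleotide string; lower case is accepted and upper-cased,
#'   IUPAC ambiguity codes are collapsed to `N`.
#' @return An object of class `seq_record` with fields `id` and `seq`.
#' @export
seq_record <- function(id, seq) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("record id must be a non-empty string")
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("zero-length record: ", id)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    seq <- gsub("[^ACGTN]", "N", seq)
    attr(seq, "n_ambiguous") <- nchar(bad)
  }
  structure(list(id = id, seq = as.character(seq)), class = "seq_record",
            n_ambiguous = if (nzchar(bad)) nchar(bad) else 0L)
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d bp)\n", x$id, nchar(x$seq)))
  invisible(x)
}

#' @export
length.seq_record <- function(x) nchar(x$seq)

#' Read a FASTA file
#'
#' Sequences are upper-cased; characters outside \{A,C,G,T,N\} are mapped to
#' `N` and the total number of such substitutions is reported via a warning.
#'
#' @param path Path to a FASTA file.
#' @return A named list of [seq_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(ids))) stop("empty record id in ", path)
  n_amb <- 0L
  out <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    rec <- seq_record(ids[i], as.character(ss[[i]]))
    n_amb <- n_amb + attr(rec, "n_ambiguous")
    out[[i]] <- rec
  }
  if (n_amb > 0L)
    warning(sprintf("%d ambiguous bases mapped to N in %s", n_amb, path))
  names(out) <- ids
  out
}

#' Write sequence records to FASTA
#'
#' @param records A list of [seq_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "wb")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con, sep = "\n")
    s <- r$seq
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Construct a genomic interval table
#'
#' Intervals are 0-based half-open, BED style.
#'
#' @param chrom Chromosome/scaffold names.
#' @param start 0-based inclusive starts.
#' @param end Exclusive ends.
#' @param strand Strand, one of `"+"`, `"-"`, `"."`.
#' @return A data.frame with columns chrom/start/end/strand.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(!nzchar(chrom))) stop("chrom must be non-empty")
  if (any(start < 0L) || any(start >= end))
    stop("intervals must satisfy 0 <= start < end")
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of +, -, .")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = rep_len(as.character(strand), length(chrom)),
             stringsAsFactors = FALSE)
}

#' Construct a repeat-fragment table
#'
#' @inheritParams genomic_intervals
#' @param repeat_class Repeat class label (e.g. `"DNA"`, `"LTR"`, `"DINE-1"`).
#' @param repeat_name Repeat/consensus name; defaults to the class.
#' @return A data.frame with columns chrom/start/end/strand/repeat_class/repeat_name.
#' @export
repeat_fragments <- function(chrom, start, end, repeat_class,
                             repeat_name = repeat_class, strand = ".") {
  iv <- genomic_intervals(chrom, start, end, strand)
  if (any(!nzchar(repeat_class))) stop("repeat_class must be non-empty")
  iv$repeat_class <- rep_len(as.character(repeat_class), nrow(iv))
  iv$repeat_name <- rep_len(as.character(repeat_name), nrow(iv))
  iv
}

.empty_fragments <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), repeat_class = character(),
             repeat_name = character(), stringsAsFactors = FALSE)
}

#' Construct a gene model
#'
#' A gene model is a stranded chain of coding exons for one isoform; UTRs are
#' not represented (all size statistics downstream are coding-only).
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Parallel vectors of 0-based half-open coding
#'   exon coordinates, sorted and pairwise non-overlapping.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand,
                       exon_starts, exon_ends) {
  if (!strand %in% c("+", "-")) stop("gene strand must be + or -")
  exon_starts <- as.integer(exon_starts); exon_ends <- as.integer(exon_ends)
  if (length(exon_starts) < 1L) stop("gene model needs at least one exon")
  if (any(exon_starts >= exon_ends) || any(exon_starts < 0L))
    stop("invalid exon coordinates for ", transcript_id)
  if (is.unsorted(exon_starts, strictly = TRUE) && length(exon_starts) > 1L)
    stop("exons must be sorted by start for ", transcript_id)
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] < exon_ends[-length(exon_ends)]))
    stop("exons overlap in ", transcript_id)
  total <- sum(exon_ends - exon_starts)
  if (total < 3L) stop("total coding length < 3 for ", transcript_id)
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand,
                 exons = data.frame(start = exon_starts, end = exon_ends)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s/%s %s:%d-%d (%s) %d coding exon(s), %d bp coding\n",
              x$gene_id, x$transcript_id, x$chrom, x$exons$start[1L],
              x$exons$end[nrow(x$exons)], x$strand, nrow(x$exons),
              sum(x$exons$end - x$exons$start)))
  invisible(x)
}

#' Total coding length of a gene model
#' @param model A [gene_model()].
#' @return Coding-region size in bp (sum of coding exon lengths).
#' @export
coding_size <- function(model) sum(model$exons$end - model$exons$start)

#' Read gene models from a BED12 file
#'
#' One `gene_model` is produced per line.  Coding exons are the blocks
#' clipped to `[thickStart, thickEnd)`; blocks entirely outside the thick
#' region are dropped.  The BED `name` field is interpreted as
#' `geneID.transcriptID` when it contains a dot, otherwise gene and
#' transcript ids coincide.
#'
#' @param path Path to a 12-column BED file.
#' @return A list of [gene_model()] objects in file order.
#' @export
read_bed12 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "integer", "integer",
                                   "character", "character", "character",
                                   "integer", "integer", "character",
                                   "integer", "character", "character"))
  if (ncol(tab) < 12L) stop("expected 12 BED columns in ", path)
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    chrom <- tab[i, 1L]; chromStart <- tab[i, 2L]
    name <- tab[i, 4L]; strand <- tab[i, 6L]
    thickStart <- tab[i, 7L]; thickEnd <- tab[i, 8L]
    nblocks <- tab[i, 10L]
    sizes <- as.integer(strsplit(tab[i, 11L], ",")[[1L]])
    offs  <- as.integer(strsplit(tab[i, 12L], ",")[[1L]])
    if (length(sizes) != nblocks || length(offs) != nblocks)
      stop("blockCount mismatch at line ", i, " of ", path)
    if (thickStart > thickEnd) stop("thickStart > thickEnd at line ", i)
    if (thickStart == thickEnd) stop("no coding region at line ", i, " (", name, ")")
    bs <- chromStart + offs
    be <- bs + sizes
    if (is.unsorted(bs)) stop("unsorted blocks at line ", i, " of ", path)
    cs <- pmax(bs, thickStart); ce <- pmin(be, thickEnd)
    keep <- cs < ce
    if (!any(keep)) stop("no block overlaps the coding region at line ", i)
    ids <- strsplit(name, ".", fixed = TRUE)[[1L]]
    gid <- ids[1L]
    tid <- if (length(ids) > 1L) paste(ids[-1L], collapse = ".") else name
    out[[i]] <- gene_model(gid, tid, chrom, strand, cs[keep], ce[keep])
  }
  out
}

#' Write gene models to BED12
#'
#' The thick region spans the full coding extent, so a written model
#' round-trips through [read_bed12()] with identical coding exons.
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(models, path) {
  if (inherits(models, "gene_model")) models <- list(models)
  lines <- vapply(models, function(m) {
    s <- m$exons$start; e <- m$exons$end
    paste(m$chrom, s[1L], e[length(e)],
          paste0(m$gene_id, ".", m$transcript_id), 0L, m$strand,
          s[1L], e[length(e)], "0,0,0", length(s),
          paste0(paste(e - s, collapse = ","), ","),
          paste0(paste(s - s[1L], collapse = ","), ","),
          sep = "\t")
  }, character(1L))
  writeLines(lines, con <- file(path, "wb"), sep = "\n"); close(con)
  invisible(path)
}

#' Read a RepeatMasker .out file
#'
#' Parses the standard whitespace-separated layout (3 header lines).
#' 1-based inclusive coordinates are converted to 0-based half-open; the
#' repeat class is the class/family column truncated before `"/"`; the
#' complement marker `"C"` becomes strand `"-"`.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return A repeat-fragment data.frame (see [repeat_fragments()]).
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_fragments())
  fields <- strsplit(lines, "\\s+")
  nf <- lengths(fields)
  if (any(nf < 14L))
    stop("malformed RepeatMasker row (", min(nf), " columns) in ", path)
  parse_row <- function(f) {
    begin <- as.integer(f[6L]); end <- as.integer(f[7L])
    if (end < begin) stop("end < begin in RepeatMasker row for ", f[5L])
    c(chrom = f[5L], start = begin - 1L, end = end,
      strand = if (f[9L] == "C") "-" else "+",
      repeat_name = f[10L],
      repeat_class = sub("/.*$", "", f[11L]))
  }
  rows <- t(vapply(fields, parse_row, character(6L)))
  repeat_fragments(chrom = rows[, "chrom"],
                   start = as.integer(rows[, "start"]),
                   end = as.integer(rows[, "end"]),
                   repeat_class = rows[, "repeat_class"],
                   repeat_name = rows[, "repeat_name"],
                   strand = rows[, "strand"])
}

#' Merge overlapping repeat fragments of the same class
#'
#' Within each (chrom, repeat_class) pair, overlapping or book-ended
#' fragments are unioned; fragments of different classes never merge even
#' when they overlap.  Output is sorted by chrom, class, start.
#'
#' @param fragments A repeat-fragment data.frame.
#' @return A merged, sorted repeat-fragment data.frame (strand `"."`,
#'   repeat_name = repeat_class for merged records).
#' @export
merge_same_class <- function(fragments) {
  if (nrow(fragments) == 0L) return(.empty_fragments())
  key <- paste(fragments$chrom, fragments$repeat_class, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(fragments)), key), function(idx) {
    ir <- BiocGenerics::sort(.iv_to_iranges(fragments$start[idx],
                                            fragments$end[idx]))
    red <- IRanges::reduce(ir)
    iv <- .iranges_to_iv(red)
    data.frame(chrom = fragments$chrom[idx[1L]], start = iv$start,
               end = iv$end, strand = ".",
               repeat_class = fragments$repeat_class[idx[1L]],
               repeat_name = fragments$repeat_class[idx[1L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$repeat_class, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total bases in the intersection of two interval sets
#'
#' Computes `|union(a) \eqn{\cap} union(b)|` per chromosome and sums.
#' Symmetric, and never larger than the smaller union.
#'
#' @param a,b Interval data.frames with chrom/start/end columns.
#' @return Total overlapping bases (numeric scalar).
#' @export
overlap_bases <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  total <- 0
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- IRanges::reduce(.iv_to_iranges(a$start[a$chrom == ch],
                                         a$end[a$chrom == ch]))
    ib <- IRanges::reduce(.iv_to_iranges(b$start[b$chrom == ch],
                                         b$end[b$chrom == ch]))
    total <- total + sum(BiocGenerics::width(IRanges::intersect(ia, ib)))
  }
  total
}

# union length (bp) of an interval data.frame, single chrom namespace
.union_bp <- function(iv) {
  if (nrow(iv) == 0L) return(0)
  sum(vapply(split(seq_len(nrow(iv)), iv$chrom), function(idx) {
    sum(BiocGenerics::width(IRanges::reduce(
      .iv_to_iranges(iv$start[idx], iv$end[idx]))))
  }, numeric(1L)))
}

#' Extract the spliced coding sequence of a gene model
#'
#' Exon sequences are concatenated in genomic order; minus-strand models are
#' reverse-complemented so the result always reads 5' to 3'.
#'
#' @param model A [gene_model()].
#' @param genome A [seq_record()] (or named list of them) providing
#'   `model$chrom`.
#' @return The CDS as an upper-case string.
#' @export
extract_cds <- function(model, genome) {
  if (!inherits(genome, "seq_record")) {
    genome <- genome[[model$chrom]]
    if (is.null(genome)) stop("chromosome not found: ", model$chrom)
  }
  parts <- substring(genome$seq, model$exons$start + 1L, model$exons$end)
  cds <- paste(parts, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  cds
}

#' Read / write repeat fragments as BED6+class
#'
#' Column layout: chrom, start, end, name (repeat name), score, strand,
#' class (column 7).
#'
#' @param path File path.
#' @return A repeat-fragment data.frame (reader); `path` invisibly
#'   (writer).
#' @export
read_repeat_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 7L) stop("expected BED6+class (7 columns) in ", path)
  repeat_fragments(chrom = tab[[1L]], start = tab[[2L]], end = tab[[3L]],
                   repeat_class = tab[[7L]], repeat_name = tab[[4L]],
                   strand = tab[[6L]])
}

#' @rdname read_repeat_bed
#' @param fragments A repeat-fragment data.frame.
#' @export
write_repeat_bed <- function(fragments, path) {
  con <- file(path, "wb"); on.exit(close(con))
  out <- data.frame(fragments$chrom, fragments$start, fragments$end,
                    fragments$repeat_name, 0L, fragments$strand,
                    fragments$repeat_class)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read gene models from a GFF3 file (CDS features only)
#'
#' Groups `CDS` features by their `Parent` attribute (one transcript per
#' Parent); 1-based inclusive GFF coordinates are converted to 0-based
#' half-open.  Only coding exons are represented, matching the BED12
#' reader's coding-only convention.
#'
#' @param path Path to a GFF3 file.
#' @return A list of [gene_model()] objects.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, length, integer(1L)) == 9L]
  f <- f[vapply(f, function(x) x[3L] == "CDS", logical(1L))]
  if (!length(f)) return(list())
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))[[1L]]
    if (length(m) < 2L) NA_character_ else m[2L]
  }
  df <- data.frame(
    chrom = vapply(f, `[[`, character(1L), 1L),
    start = as.integer(vapply(f, `[[`, character(1L), 4L)) - 1L,
    end = as.integer(vapply(f, `[[`, character(1L), 5L)),
    strand = vapply(f, `[[`, character(1L), 7L),
    parent = vapply(f, function(x) attr_get(x[9L], "Parent"), character(1L)),
    stringsAsFactors = FALSE)
  if (anyNA(df$parent)) stop("CDS feature without Parent attribute in ", path)
  lapply(split(df, factor(df$parent, levels = unique(df$parent))), function(d) {
    d <- d[order(d$start), ]
    gene_model(d$parent[1L], d$parent[1L], d$chrom[1L], d$strand[1L],
               d$start, d$end)
  })
}

#' Reverse complement of a DNA string
#' @param seq DNA string over \{A,C,G,T,N\}.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1L]]), collapse = ""))
}
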