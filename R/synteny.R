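# Ortholog placement tables, wanderer-gene detection, syntenic blocks.

#' Construct / validate an ortholog placement table
#'
#' Long format: one row per (gene, species) placement.
#'
#' @param gene_id,species,element,scaffold,position,strand Parallel vectors;
#'   `position` is the ordinal position of the gene within its Muller
#'   element in that species, unique within (species, element).
#' @return A data.frame of class `ortholog_table`.
#' @export
ortholog_table <- function(gene_id, species, element, scaffold, position,
                           strand) {
  if (!all(strand %in% c("+", "-"))) stop("strands must be + or -")
  tab <- data.frame(gene_id = as.character(gene_id),
                    species = as.character(species),
                    element = as.character(element),
                    scaffold = as.character(scaffold),
                    position = as.integer(position),
                    strand = as.character(strand),
                    stringsAsFactors = FALSE)
  key <- paste(tab$species, tab$element, sep = "\r")
  dup <- unlist(lapply(split(tab$position, key), duplicated))
  if (any(dup)) stop("ordinal positions must be unique within (species, element)")
  class(tab) <- c("ortholog_table", "data.frame")
  tab
}

#' Read / write ortholog tables as TSV
#' @param path File path.
#' @return An `ortholog_table` (reader); `path` invisibly (writer).
#' @export
read_ortholog_table <- function(path) {
  # colClasses is explicit because the F element's label would otherwise
  # be parsed as the logical FALSE
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = c(gene_id = "character",
                                   species = "character",
                                   element = "character",
                                   scaffold = "character",
                                   position = "integer",
                                   strand = "character"))
  ortholog_table(tab$gene_id, tab$species, tab$element, tab$scaffold,
                 tab$position, tab$strand)
}

#' @rdname read_ortholog_table
#' @param table An `ortholog_table`.
#' @export
write_ortholog_table <- function(table, path) {
  con <- file(path, "wb"); on.exit(close(con))
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Identify wanderer genes between species pairs
#'
#' A gene is a wanderer for a species pair when its Muller-element labels
#' differ between the two species and at least one of the labels is the
#' focal element (the F element by default).  Moves not involving the focal
#' element are reported separately as `other_moves`; genes absent from one
#' species are listed as `unplaced`, never as wanderers.
#'
#' @param table An [ortholog_table()] covering >= 2 species.
#' @param focal_element Element anchoring the wanderer definition.
#' @return List with data.frames `wanderers`, `other_moves` and `unplaced`
#'   (gene, species_a, species_b, from, to).
#' @export
find_wanderers <- function(table, focal_element = "F") {
  species <- sort(unique(table$species))
  if (length(species) < 2L) stop("need at least 2 species")
  wa <- list(); om <- list(); un <- list()
  for (ai in seq_len(length(species) - 1L)) for (bi in (ai + 1L):length(species)) {
    sa <- species[ai]; sb <- species[bi]
    ta <- table[table$species == sa, ]; tb <- table[table$species == sb, ]
    shared <- intersect(ta$gene_id, tb$gene_id)
    ea <- ta$element[match(shared, ta$gene_id)]
    eb <- tb$element[match(shared, tb$gene_id)]
    moved <- ea != eb
    anchored <- moved & (ea == focal_element | eb == focal_element)
    mk <- function(idx) if (!any(idx)) NULL else
      data.frame(gene_id = shared[idx], species_a = sa, species_b = sb,
                 from = ea[idx], to = eb[idx], stringsAsFactors = FALSE)
    wa[[length(wa) + 1L]] <- mk(anchored)
    om[[length(om) + 1L]] <- mk(moved & !anchored)
    only <- c(setdiff(ta$gene_id, tb$gene_id), setdiff(tb$gene_id, ta$gene_id))
    if (length(only))
      un[[length(un) + 1L]] <- data.frame(
        gene_id = only, species_a = sa, species_b = sb,
        missing_in = ifelse(only %in% ta$gene_id, sb, sa),
        stringsAsFactors = FALSE)
  }
  bind <- function(l) {
    l <- Filter(Negate(is.null), l)
    if (!length(l)) return(NULL)
    out <- do.call(rbind, l); rownames(out) <- NULL; out
  }
  list(wanderers = bind(wa), other_moves = bind(om), unplaced = bind(un))
}

#' Windowed wanderer-hotspot summary
#'
#' Counts wanderer genes per fixed-width positional window along the focal
#' element of the anchor species, a testable stand-in for the descriptive
#' hotspot inspection of alignment nets.
#'
#' @param table An [ortholog_table()].
#' @param species Anchor species providing the gene order.
#' @param wanderer_ids Gene ids flagged by [find_wanderers()].
#' @param window Window width in genes (default 10).
#' @param focal_element Element scanned (default "F").
#' @return A data.frame (window_start, window_end, n_genes, n_wanderers).
#' @export
wanderer_hotspots <- function(table, species, wanderer_ids, window = 10L,
                              focal_element = "F") {
  ta <- table[table$species == species & table$element == focal_element, ]
  ta <- ta[order(ta$position), ]
  n <- nrow(ta)
  if (n == 0L) stop("no genes on the focal element for ", species)
  starts <- seq(1L, n, by = window)
  do.call(rbind, lapply(starts, function(s) {
    e <- min(s + window - 1L, n)
    ids <- ta$gene_id[s:e]
    data.frame(window_start = s, window_end = e, n_genes = e - s + 1L,
               n_wanderers = sum(ids %in% wanderer_ids))
  }))
}

#' Shared signed gene order between two species
#'
#' Restricts to genes located on `element` in BOTH species, labels them 1..n
#' in species-A positional order, and emits species B's order as signed
#' integers (positive when the strands agree with species A).
#'
#' @param table An [ortholog_table()].
#' @param species_a,species_b Species names.
#' @param element Muller element (default "F").
#' @return Integer vector: a signed permutation of 1..n (n >= 2), with the
#'   shared gene ids (in species-A order) as the `genes` attribute.
#' @export
shared_signed_order <- function(table, species_a, species_b, element = "F") {
  ta <- table[table$species == species_a & table$element == element, ]
  tb <- table[table$species == species_b & table$element == element, ]
  shared <- intersect(ta$gene_id, tb$gene_id)
  if (length(shared) < 2L) stop("fewer than 2 shared genes on element ", element)
  ta <- ta[match(shared, ta$gene_id), ]
  tb <- tb[match(shared, tb$gene_id), ]
  ord_a <- order(ta$position)
  label <- setNames(seq_along(shared), ta$gene_id[ord_a])   # 1..n by A order
  strand_a <- setNames(ta$strand, ta$gene_id)
  ord_b <- order(tb$position)
  out <- vapply(ord_b, function(i) {
    g <- tb$gene_id[i]
    sgn <- if (tb$strand[i] == strand_a[g]) 1L else -1L
    sgn * label[[g]]
  }, integer(1L))
  structure(out, genes = ta$gene_id[ord_a])
}

#' Syntenic blocks of a signed gene order
#'
#' A block is a maximal run of genes whose order and orientation are
#' co-conserved: consecutive entries satisfy pi(k+1) = pi(k) + 1 with equal
#' signs.  With positive signs this is an unbroken forward segment
#' (+3, +4, +5); with negative signs it is an intact reversed segment,
#' which reads (-5, -4, -3) in position order.  Sign-discordant or
#' non-consecutive neighbours break the block.
#'
#' @param order Signed permutation of 1..n.
#' @return List with `n_blocks`, `mean_genes_per_block` (n / n_blocks), and
#'   `block_id` assigning each position to its block.
#' @export
syntenic_blocks <- function(order) {
  order <- .check_signed_perm(order)
  n <- length(order)
  block_id <- integer(n)
  block_id[1L] <- 1L
  if (n > 1L) for (k in 2:n) {
    a <- order[k - 1L]; b <- order[k]
    joined <- b == a + 1L && sign(a) == sign(b)
    block_id[k] <- if (joined) block_id[k - 1L] else block_id[k - 1L] + 1L
  }
  nb <- block_id[n]
  list(n_blocks = nb, mean_genes_per_block = n / nb, block_id = block_id)
}

#' Full synteny/rearrangement report for a species pair
#'
#' @param table An [ortholog_table()].
#' @param species_a,species_b Species names.
#' @param element Muller element (default "F").
#' @param scenario Also reconstruct a parsimonious reversal scenario.
#' @param orientation Passed to [reversal_distance()].
#' @return List with the shared signed order, block statistics, reversal
#'   distance, optional scenario, and the wanderer report.
#' @export
synteny_report <- function(table, species_a, species_b, element = "F",
                           scenario = TRUE, orientation = "fixed") {
  ord <- shared_signed_order(table, species_a, species_b, element)
  blocks <- syntenic_blocks(ord)
  d <- reversal_distance(ord, orientation = orientation)
  list(species = c(species_a, species_b), element = element,
       n_shared = length(ord), order = as.integer(ord),
       genes = attr(ord, "genes"),
       n_blocks = blocks$n_blocks,
       mean_genes_per_block = blocks$mean_genes_per_block,
       reversal_distance = d,
       scenario = if (scenario) reversal_scenario(ord) else NULL,
       wanderers = find_wanderers(table, focal_element = element))
}

#' Write a GRIMM-style permutation file
#'
#' Two-genome single-chromosome format for cross-checking against external
#' rearrangement tools.
#'
#' @param order Signed permutation (species B relative to A).
#' @param path Output path.
#' @param names Genome names.
#' @return `path`, invisibly.
#' @export
write_grimm <- function(order, path, names = c("genomeA", "genomeB")) {
  order <- .check_signed_perm(order)
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c(paste0(">", names[1L]),
               paste(c(seq_along(order), "$"), collapse = " "),
               paste0(">", names[2L]),
               paste(c(order, "$"), collapse = " ")), con, sep = "\n")
  invisible(path)
}
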