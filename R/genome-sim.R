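#' Simulate a reference genome with gene models and a repeat mask
#'
#' Generates a set of random scaffolds together with non-overlapping gene
#' models (each with one or more coding exons whose total length is a multiple
#' of three) and a repeat annotation covering a requested fraction of the
#' genome. The object stands in for a real draft assembly (scaffolds not yet
#' anchored to chromosomes) so that the whole mapping pipeline can run without
#' any external download.
#'
#' All coordinates are 1-based inclusive. Exporters ([write_genes_gff3()],
#' [write_repeats_bed()]) convert to each format's own convention.
#'
#' @param n_scaffolds Number of scaffolds to simulate.
#' @param scaffold_len Length of each scaffold in bp (at least 10 kb).
#' @param gene_density Genes per Mb of scaffold.
#' @param repeat_fraction Fraction of each scaffold annotated as repeat,
#'   in `[0, 0.5]`.
#' @param seed Integer seed; the same seed gives a byte-identical genome.
#'
#' @return A `ReferenceGenome` object: a list with elements
#'   `scaffolds` (a [Biostrings::DNAStringSet]), `genes` (data.frame with
#'   `gene_id`, `scaffold`, `start`, `end`, `strand`, `annotation`),
#'   `cds` (data.frame with `gene_id`, `scaffold`, `start`, `end`,
#'   `exon_rank`, `frame`; `exon_rank` runs in coding order) and
#'   `repeats` (data.frame with `scaffold`, `start`, `end`).
#'
#' @examples
#' g <- make_genome(2, 50000, gene_density = 40, repeat_fraction = 0.1, seed = 1)
#' g
#' @export
make_genome <- function(n_scaffolds, scaffold_len, gene_density,
                        repeat_fraction, seed) {
  check_scalar(n_scaffolds, "n_scaffolds", lower = 1, integer = TRUE)
  check_scalar(scaffold_len, "scaffold_len", lower = 1e4, integer = TRUE)
  check_scalar(gene_density, "gene_density", lower = 0)
  check_scalar(repeat_fraction, "repeat_fraction", lower = 0, upper = 0.5)

  scaffold_ids <- sprintf("scaffold%02d", seq_len(n_scaffolds))

  with_sim_seed(seed, {
    seqs <- vapply(scaffold_ids, function(id) {
      paste(sample(c("A", "C", "G", "T"), scaffold_len, replace = TRUE),
            collapse = "")
    }, character(1))
    scaffolds <- Biostrings::DNAStringSet(seqs)
    names(scaffolds) <- scaffold_ids

    genes <- list()
    cds <- list()
    gene_counter <- 0L
    n_genes <- round(gene_density * scaffold_len / 1e6)
    for (sc in scaffold_ids) {
      if (n_genes < 1) next
      slot_w <- scaffold_len %/% n_genes
      for (j in seq_len(n_genes)) {
        gene_counter <- gene_counter + 1L
        gid <- sprintf("GENE%04d", gene_counter)
        model <- random_gene_model(slot_w)
        offset <- (j - 1L) * slot_w +
          sample.int(max(1L, slot_w - model$len), 1L)
        strand <- sample(c("+", "-"), 1L)
        exon_starts <- offset + model$exon_starts
        exon_ends <- offset + model$exon_ends
        # coding order follows the strand
        ord <- if (strand == "+") seq_along(exon_starts) else rev(seq_along(exon_starts))
        frames <- (cumsum(c(0L, (exon_ends - exon_starts + 1L)[ord])) %% 3L)[seq_along(ord)]
        genes[[gene_counter]] <- df(
          gene_id = gid, scaffold = sc,
          start = offset + 1L, end = offset + model$len,
          strand = strand,
          annotation = sprintf("hypothetical protein %s", gid)
        )
        cds[[gene_counter]] <- df(
          gene_id = gid, scaffold = sc,
          start = exon_starts[ord], end = exon_ends[ord],
          exon_rank = seq_along(ord), frame = frames
        )
      }
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      df(gene_id = character(), scaffold = character(), start = integer(),
         end = integer(), strand = character(), annotation = character())
    cds <- if (length(cds)) do.call(rbind, cds) else
      df(gene_id = character(), scaffold = character(), start = integer(),
         end = integer(), exon_rank = integer(), frame = integer())

    repeats <- list()
    target <- round(repeat_fraction * scaffold_len)
    for (sc in scaffold_ids) {
      if (target < 1) next
      n_slots <- max(1L, ceiling(target / 600))
      slot_w <- scaffold_len %/% n_slots
      # split the exact target across slots
      lens <- diff(round(seq(0, target, length.out = n_slots + 1L)))
      starts <- (seq_len(n_slots) - 1L) * slot_w +
        vapply(pmax(1L, slot_w - lens), function(m) sample.int(m, 1L), integer(1))
      keep <- lens > 0
      repeats[[sc]] <- df(scaffold = sc, start = starts[keep],
                          end = starts[keep] + lens[keep] - 1L)
    }
    repeats <- if (length(repeats)) do.call(rbind, repeats) else
      df(scaffold = character(), start = integer(), end = integer())

    structure(
      list(scaffolds = scaffolds, genes = genes, cds = cds, repeats = repeats,
           params = list(n_scaffolds = n_scaffolds, scaffold_len = scaffold_len,
                         gene_density = gene_density,
                         repeat_fraction = repeat_fraction, seed = seed)),
      class = "ReferenceGenome"
    )
  })
}

# Draw exon/intron structure fitting inside a slot of width `slot_w`.
# Exon lengths are multiples of 3 so every CDS translates cleanly.
random_gene_model <- function(slot_w) {
  budget <- slot_w - 2L
  if (budget < 153L) {
    stop("gene_density too high: gene models do not fit on the scaffold",
         call. = FALSE)
  }
  repeat {
    n_exon <- sample(1:3, 1L)
    exons <- 3L * sample(50:150, n_exon, replace = TRUE)
    introns <- if (n_exon > 1L) sample(60:200, n_exon - 1L, replace = TRUE) else integer()
    len <- sum(exons) + sum(introns)
    if (len <= budget) break
    # shrink to the minimal single-exon gene if the draw cannot fit
    if (budget < 400L) {
      n_exon <- 1L
      exons <- 150L
      introns <- integer()
      len <- 150L
      break
    }
  }
  starts <- integer(n_exon)
  ends <- integer(n_exon)
  pos <- 1L
  for (k in seq_len(n_exon)) {
    starts[k] <- pos
    ends[k] <- pos + exons[k] - 1L
    pos <- ends[k] + 1L + if (k < n_exon) introns[k] else 0L
  }
  list(exon_starts = starts, exon_ends = ends, len = len)
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat("ReferenceGenome:", length(x$scaffolds), "scaffolds of",
      unique(Biostrings::width(x$scaffolds)), "bp;",
      nrow(x$genes), "genes;", nrow(x$repeats), "repeat intervals",
      sprintf("(%.1f%% of genome)\n",
              100 * sum(x$repeats$end - x$repeats$start + 1) /
                sum(Biostrings::width(x$scaffolds))))
  invisible(x)
}

#' Scaffold lengths of a simulated genome
#'
#' @param genome A `ReferenceGenome`.
#' @return Named integer vector of scaffold lengths in bp.
#' @export
scaffold_lengths <- function(genome) {
  stopifnot(inherits(genome, "ReferenceGenome"))
  stats::setNames(Biostrings::width(genome$scaffolds), names(genome$scaffolds))
}
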