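#' Write simulator outputs in standard formats
#'
#' `write_genome_fasta()` writes the scaffolds as FASTA;
#' `write_genes_gff3()` writes gene models (gene + CDS features, 1-based
#' GFF3); `write_repeats_bed()` writes the repeat mask (BED, 0-based
#' half-open on disk); `write_truth_vcf()` writes the truth variant set as a
#' VCF with one sample column per parent (gzip-compressed, as produced by
#' vcfR). GFF3/BED need the rtracklayer package, VCF needs vcfR.
#'
#' @param genome A `ReferenceGenome`.
#' @param path Output file path (for `write_truth_vcf()` it should end in
#'   `.vcf.gz`).
#' @return The path, invisibly.
#' @name simulator-io
NULL

#' @rdname simulator-io
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "ReferenceGenome"))
  Biostrings::writeXStringSet(genome$scaffolds, path)
  invisible(path)
}

#' @rdname simulator-io
#' @export
write_genes_gff3 <- function(genome, path) {
  stopifnot(inherits(genome, "ReferenceGenome"))
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to write GFF3", call. = FALSE)
  }
  g <- genome$genes
  cds <- genome$cds
  gr_gene <- GenomicRanges::GRanges(
    g$scaffold, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id, Note = g$annotation)
  strand_of <- g$strand[match(cds$gene_id, g$gene_id)]
  gr_cds <- GenomicRanges::GRanges(
    cds$scaffold, IRanges::IRanges(cds$start, cds$end), strand = strand_of,
    type = "CDS", ID = paste0(cds$gene_id, ".cds", cds$exon_rank),
    Parent = cds$gene_id)
  S4Vectors::mcols(gr_cds)$phase <- cds$frame
  rtracklayer::export(c(gr_gene, gr_cds), path, format = "gff3")
  invisible(path)
}

#' @rdname simulator-io
#' @export
write_repeats_bed <- function(genome, path) {
  stopifnot(inherits(genome, "ReferenceGenome"))
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to write BED", call. = FALSE)
  }
  rtracklayer::export(as_granges(genome$repeats), path, format = "bed")
  invisible(path)
}

#' @rdname simulator-io
#' @param parents A `ParentPair`.
#' @export
write_truth_vcf <- function(parents, path) {
  stopifnot(inherits(parents, "ParentPair"))
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("vcfR is required to write VCF", call. = FALSE)
  }
  v <- parents$truth
  alt <- ifelse(v$alt %in% c("<INV>", "<CTX>", "<ITX>"), v$alt, v$alt)
  fix <- cbind(
    CHROM = v$scaffold, POS = as.character(v$pos), ID = v$variant_id,
    REF = v$ref, ALT = alt, QUAL = ".", FILTER = "PASS",
    INFO = paste0("KIND=", v$kind,
                  ifelse(v$sv_len > 0, paste0(";SVLEN=", v$sv_len), "")))
  gt_of <- function(par) ifelse(v$carrier %in% c(par, "both"), "1/1", "0/0")
  gt <- cbind(FORMAT = "GT", parent_M = gt_of("M"), parent_P = gt_of("P"))
  meta <- c("##fileformat=VCFv4.2",
            "##source=superbsa simulator (synthetic truth set)",
            "##INFO=<ID=KIND,Number=1,Type=String,Description=\"Variant kind\">",
            "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  out <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(out, file = path)
  invisible(path)
}

#' Read a parental variant call set from VCF
#'
#' Converts a per-sample VCF into the flat call table used by
#' [filter_snp_calls()], [validate_sv()] and [differential_variants()]:
#' depth is taken from the DP field (FORMAT if present, else INFO), quality
#' from QUAL, zygosity from the GT field, and the variant kind from a KIND
#' INFO key when present (SNP otherwise for single-base substitutions,
#' INS/DEL by allele length).
#'
#' @param path VCF file (optionally gzip-compressed).
#' @param sample Sample column to read (default: the first).
#' @return data.frame of calls: `sample`, `scaffold`, `pos`, `kind`, `ref`,
#'   `alt`, `depth`, `quality`, `zygosity`.
#' @export
read_parent_vcf <- function(path, sample = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("vcfR is required to read VCF", call. = FALSE)
  }
  x <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(x), stringsAsFactors = FALSE)
  samples <- colnames(x@gt)[-1]
  if (is.null(sample)) sample <- samples[1]
  stopifnot(sample %in% samples)
  gt <- vcfR::extract.gt(x, element = "GT")[, sample]
  dp <- suppressWarnings(vcfR::extract.gt(x, element = "DP", as.numeric = TRUE))
  depth <- if (!is.null(dp) && sample %in% colnames(dp)) dp[, sample] else NA_real_
  if (all(is.na(depth))) {
    info_dp <- vcfR::extract.info(x, element = "DP", as.numeric = TRUE)
    if (!is.null(info_dp)) depth <- info_dp
  }
  kind <- vcfR::extract.info(x, element = "KIND")
  if (is.null(kind) || all(is.na(kind))) {
    kind <- ifelse(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
                     !grepl("<", fix$ALT, fixed = TRUE), "SNP",
                   ifelse(nchar(fix$ALT) > nchar(fix$REF), "INS", "DEL"))
  }
  called <- !is.na(gt) & gt %in% c("0/1", "1/0", "0|1", "1|0", "1/1", "1|1")
  zyg <- ifelse(gt %in% c("1/1", "1|1"), "hom", "het")
  out <- df(sample = sample, scaffold = fix$CHROM, pos = as.integer(fix$POS),
            kind = kind, ref = fix$REF, alt = fix$ALT,
            depth = as.numeric(depth),
            quality = suppressWarnings(as.numeric(fix$QUAL)),
            zygosity = zyg)
  out[called, , drop = FALSE]
}

#' Tab-separated table helpers
#'
#' Thin wrappers over [utils::write.table()]/[utils::read.delim()] with the
#' conventions used throughout the package (header, no quoting, no row
#' names).
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return `read_tsv()` returns a data.frame; `write_tsv()` the path,
#'   invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a candidate-region table and recompute its summary arithmetic
#'
#' Region tables (one row per candidate region with kb-rounded bounds, a
#' comma-separated marker list and a gene count) are re-checked
#' arithmetically: size must equal end minus start, and the table totals
#' (regions, distinct markers, genes) are recomputed from the rows.
#'
#' @param path TSV with columns `scaffold`, `start`, `end`, `size`,
#'   `markers`, `gene_number`.
#' @return The table, with attributes `n_regions`, `n_markers` (distinct
#'   markers across rows) and `n_genes` (summed gene counts).
#' @export
read_region_table <- function(path) {
  x <- read_tsv(path)
  need <- c("scaffold", "start", "end", "size", "markers", "gene_number")
  stopifnot(all(need %in% names(x)))
  if (!all(x$size == x$end - x$start)) {
    stop("region table is inconsistent: size != end - start", call. = FALSE)
  }
  attr(x, "n_regions") <- nrow(x)
  attr(x, "n_markers") <- length(unique(unlist(strsplit(x$markers, ","))))
  attr(x, "n_genes") <- sum(x$gene_number)
  x
}
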