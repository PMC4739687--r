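#' Annotate variants against gene models
#'
#' Classifies each variant as genic or intergenic, genic variants as exonic
#' or intronic, and exonic SNPs as synonymous or non-synonymous by mutating
#' the affected codon of the spliced coding sequence and translating it with
#' the standard genetic code. Minus-strand genes are handled on the reverse
#' complement.
#'
#' @param calls data.frame with columns `scaffold`, `pos`, `kind`, `ref`,
#'   `alt`.
#' @param genome A `ReferenceGenome` (supplies gene models, CDS intervals and
#'   scaffold sequence).
#' @return data.frame with one row per call: `region_class`
#'   (`genic`/`intergenic`), `sub_class` (`exonic`/`intronic`/`none`),
#'   `coding_effect` (`synonymous`/`non_synonymous`/`none`) and `gene_id`
#'   (empty string for intergenic variants).
#' @export
annotate_variants <- function(calls, genome) {
  stopifnot(inherits(genome, "ReferenceGenome"),
            all(c("scaffold", "pos", "kind", "ref", "alt") %in% names(calls)))
  n <- nrow(calls)
  region <- rep("intergenic", n)
  sub <- rep("none", n)
  effect <- rep("none", n)
  gene_id <- rep("", n)
  if (n == 0L) {
    return(df(region_class = region, sub_class = sub, coding_effect = effect,
              gene_id = gene_id))
  }

  genes <- genome$genes
  hit <- suppressWarnings(GenomicRanges::findOverlaps(
    as_granges(df(scaffold = calls$scaffold, start = calls$pos, end = calls$pos)),
    as_granges(genes), select = "first"))

  cds_cache <- new.env(parent = emptyenv())
  for (i in which(!is.na(hit))) {
    g <- genes[hit[i], ]
    region[i] <- "genic"
    gene_id[i] <- g$gene_id
    cds <- genome$cds[genome$cds$gene_id == g$gene_id, , drop = FALSE]
    in_exon <- calls$pos[i] >= cds$start & calls$pos[i] <= cds$end
    if (!any(in_exon)) {
      sub[i] <- "intronic"
      next
    }
    sub[i] <- "exonic"
    if (calls$kind[i] != "SNP") next
    effect[i] <- snp_coding_effect(calls$pos[i], calls$alt[i], g, cds,
                                   genome, cds_cache)
  }
  df(region_class = region, sub_class = sub, coding_effect = effect,
     gene_id = gene_id)
}

# Synonymous/non-synonymous decision for one exonic SNP.
snp_coding_effect <- function(pos, alt, gene, cds, genome, cache) {
  cds <- cds[order(cds$exon_rank), , drop = FALSE]
  widths <- cds$end - cds$start + 1L
  if (sum(widths) %% 3L != 0L) {
    stop("CDS length of ", gene$gene_id, " is not a multiple of 3", call. = FALSE)
  }
  key <- gene$gene_id
  if (!exists(key, envir = cache)) {
    pieces <- Biostrings::extractAt(
      genome$scaffolds[[gene$scaffold]],
      IRanges::IRanges(cds$start, cds$end))
    if (gene$strand == "-") {
      pieces <- Biostrings::reverseComplement(pieces)
    }
    assign(key, unlist(pieces), envir = cache)
  }
  cds_seq <- get(key, envir = cache)

  exon_i <- which(pos >= cds$start & pos <= cds$end)[1]
  offset_before <- if (exon_i > 1L) sum(widths[seq_len(exon_i - 1L)]) else 0L
  within <- if (gene$strand == "+") pos - cds$start[exon_i] + 1L
            else cds$end[exon_i] - pos + 1L
  cds_pos <- offset_before + within
  alt_base <- if (gene$strand == "+") alt else
    as.character(Biostrings::complement(Biostrings::DNAString(alt)))

  codon_i <- (cds_pos - 1L) %/% 3L
  codon <- as.character(Biostrings::subseq(cds_seq, codon_i * 3L + 1L,
                                           codon_i * 3L + 3L))
  mutated <- codon
  substr(mutated, (cds_pos - 1L) %% 3L + 1L, (cds_pos - 1L) %% 3L + 1L) <- alt_base
  code <- Biostrings::GENETIC_CODE
  if (code[[codon]] == code[[mutated]]) "synonymous" else "non_synonymous"
}

#' Summarise an annotated variant set
#'
#' Reproduces the standard annotation partition (genic/intergenic,
#' exonic/intronic, synonymous/non-synonymous), the transition/transversion
#' counts and Ts/Tv ratio of the SNPs, and the relative frequencies of the
#' structural-variant types.
#'
#' @param calls data.frame of calls (`kind`, `ref`, `alt`) cbound with their
#'   [annotate_variants()] columns; annotation columns may be absent, in
#'   which case only substitution and SV-type summaries are computed.
#' @return List of class `VariantSummary` with elements `counts` (named
#'   vector: total, snp, genic, intergenic, exonic, intronic, synonymous,
#'   non_synonymous), `transitions`, `transversions`, `ts_tv`, and
#'   `sv_fractions` (named, summing to 1; `NULL` when there are no SVs).
#' @export
variant_summary <- function(calls) {
  stopifnot("kind" %in% names(calls))
  snp <- calls[calls$kind == "SNP", , drop = FALSE]
  has_annot <- all(c("region_class", "sub_class", "coding_effect") %in% names(calls))
  counts <- c(
    total = nrow(calls), snp = nrow(snp),
    genic = if (has_annot) sum(calls$region_class == "genic") else NA,
    intergenic = if (has_annot) sum(calls$region_class == "intergenic") else NA,
    exonic = if (has_annot) sum(calls$sub_class == "exonic") else NA,
    intronic = if (has_annot) sum(calls$sub_class == "intronic") else NA,
    synonymous = if (has_annot) sum(calls$coding_effect == "synonymous") else NA,
    non_synonymous = if (has_annot) sum(calls$coding_effect == "non_synonymous") else NA
  )
  ts <- sum(classify_substitution(snp$ref, snp$alt) == "transition")
  tv <- nrow(snp) - ts
  svs <- calls[calls$kind != "SNP", , drop = FALSE]
  sv_fractions <- if (nrow(svs)) {
    tab <- table(svs$kind)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  } else NULL
  structure(list(counts = counts, transitions = ts, transversions = tv,
                 ts_tv = if (tv > 0) ts / tv else NA_real_,
                 sv_fractions = sv_fractions),
            class = "VariantSummary")
}

#' @export
print.VariantSummary <- function(x, ...) {
  cat("VariantSummary:", x$counts[["total"]], "variants;",
      x$counts[["snp"]], "SNPs; Ts/Tv =",
      formatC(x$ts_tv, digits = 3, format = "f"), "\n")
  if (!is.na(x$counts[["genic"]])) {
    cat("  genic:", x$counts[["genic"]], " intergenic:", x$counts[["intergenic"]],
        " exonic:", x$counts[["exonic"]], " intronic:", x$counts[["intronic"]],
        " syn:", x$counts[["synonymous"]], " nonsyn:", x$counts[["non_synonymous"]],
        "\n")
  }
  invisible(x)
}

#' Genes polymorphic between the two parents
#'
#' A gene qualifies when it contains at least one differential
#' non-synonymous SNP, or at least one validated exonic structural variant
#' or indel.
#'
#' @param snps Annotated differential SNP table: needs `coding_effect` and
#'   `gene_id` columns (e.g. [differential_variants()] output cbound with
#'   [annotate_variants()]).
#' @param svs Annotated, validated SV/indel table with `sub_class` and
#'   `gene_id` columns, or `NULL`.
#' @return Sorted character vector of gene ids.
#' @export
polymorphic_genes <- function(snps, svs = NULL) {
  stopifnot(all(c("coding_effect", "gene_id") %in% names(snps)))
  ids <- snps$gene_id[snps$coding_effect == "non_synonymous"]
  if (!is.null(svs) && nrow(svs)) {
    stopifnot(all(c("sub_class", "gene_id") %in% names(svs)))
    ids <- c(ids, svs$gene_id[svs$sub_class == "exonic"])
  }
  sort(unique(ids[ids != ""]))
}
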