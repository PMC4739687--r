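#' Classify a fruit phenotype into a trait class
#'
#' Applies the trait-class rules of the cross: sweet-and-sour first
#' (TSS > 12 and pH < 5, the F1-like combination), then sweet (TSS >= 8 and
#' pH > 5.3), sour (TSS < 8 and pH <= 5.3) and non-sweet non-sour (TSS < 8
#' and pH > 5.3). The four published classes do not tile the (TSS, pH)
#' plane (e.g. TSS 9 with pH 5.0 matches none), so the remainder is
#' returned as `unclassified`; every input receives exactly one class.
#'
#' @param tss Total soluble solids, degrees Brix (vectorised).
#' @param ph Juice pH (vectorised).
#' @return Character vector of classes: `sweet`, `sour`, `sweet_and_sour`,
#'   `non_sweet_non_sour` or `unclassified`.
#' @examples
#' classify_phenotype(c(12.7, 6.8, 12.6, 9.0), c(6.1, 4.4, 4.8, 5.0))
#' @export
classify_phenotype <- function(tss, ph) {
  stopifnot(length(tss) == length(ph))
  out <- rep("unclassified", length(tss))
  out[tss < 8 & ph > 5.3] <- "non_sweet_non_sour"
  out[tss < 8 & ph <= 5.3] <- "sour"
  out[tss >= 8 & ph > 5.3] <- "sweet"
  out[tss > 12 & ph < 5] <- "sweet_and_sour"
  out
}

#' Select the three extreme-phenotype bulks from an F2 population
#'
#' Builds the sweet, sour and non-sweet-non-sour DNA bulks used by
#' super-BSA.
#'
#' With `method = "threshold"` (the published pool rules) a plant qualifies
#' for the sweet pool with TSS > 12 and pH > 6, for the sour pool with
#' TSS < 8 and pH < 5, and for the non-sweet-non-sour pool with TSS < 8 and
#' pH > 5.3; the most extreme qualifiers are taken (sweet: by TSS
#' descending; sour: by pH ascending; non-sweet-non-sour: by TSS ascending,
#' then pH descending), and a pool with fewer than `bulk_size` qualifiers
#' is an error naming the deficient pool.
#'
#' With `method = "extreme-rank"` the pools are the most extreme plants by
#' phenotype rank, mirroring the structure of the published rules without
#' their fixed cutoffs: sweet = the `bulk_size` plants with the largest
#' TSS-rank + pH-rank sum (sweet-parent-like: high in both), sour = the
#' smallest rank sum (sour-parent-like: low in both), and non-sweet-non-sour
#' = the highest-pH `bulk_size` plants among the `3 * bulk_size` remaining
#' plants with the lowest TSS (recombinant: clearly non-sweet, then as
#' non-sour as possible). This rule always yields three disjoint full
#' pools; it is the one a breeder falls back to when the fixed thresholds
#' leave too few qualifiers, which is the generic situation for an F2 whose
#' trait means match the emulated cross (see the vignette).
#'
#' @param records Phenotype data.frame with `plant_id`, `tss`, `ph`.
#' @param bulk_size Plants per bulk (default 50).
#' @param method `"threshold"` (published qualification rules, strict) or
#'   `"extreme-rank"` (rank-based extremes, always feasible).
#' @return Named list of disjoint plant-id vectors: `sweet`, `sour`, `nsns`,
#'   each of length `bulk_size`.
#' @export
select_bulks <- function(records, bulk_size = 50,
                         method = c("threshold", "extreme-rank")) {
  stopifnot(all(c("plant_id", "tss", "ph") %in% names(records)))
  check_scalar(bulk_size, "bulk_size", lower = 1, integer = TRUE)
  method <- match.arg(method)

  if (method == "threshold") {
    pools <- list()
    q_sweet <- records[records$tss > 12 & records$ph > 6, , drop = FALSE]
    pools$sweet <- q_sweet$plant_id[order(-q_sweet$tss)][seq_len(min(bulk_size, nrow(q_sweet)))]
    q_sour <- records[records$tss < 8 & records$ph < 5, , drop = FALSE]
    pools$sour <- q_sour$plant_id[order(q_sour$ph)][seq_len(min(bulk_size, nrow(q_sour)))]
    q_nsns <- records[records$tss < 8 & records$ph > 5.3, , drop = FALSE]
    pools$nsns <- q_nsns$plant_id[order(q_nsns$tss, -q_nsns$ph)][seq_len(min(bulk_size, nrow(q_nsns)))]
    short <- names(pools)[lengths(pools) < bulk_size]
    if (length(short)) {
      stop("not enough qualifying plants for pool(s): ",
           paste(short, collapse = ", "), call. = FALSE)
    }
  } else {
    if (nrow(records) < 3 * bulk_size) {
      stop("not enough plants for three disjoint pools", call. = FALSE)
    }
    r_t <- rank(records$tss, ties.method = "first")
    r_p <- rank(records$ph, ties.method = "first")
    if (length(unique(records$tss)) == 1L && length(unique(records$ph)) == 1L) {
      stop("all plants have identical phenotypes; no extremes to pool",
           call. = FALSE)
    }
    pools <- list()
    pools$sweet <- records$plant_id[order(-(r_t + r_p))][seq_len(bulk_size)]
    pools$sour <- records$plant_id[order(r_t + r_p)][seq_len(bulk_size)]
    rest <- !(records$plant_id %in% c(pools$sweet, pools$sour))
    rr <- records[rest, , drop = FALSE]
    low_tss <- rr[order(rr$tss), , drop = FALSE][
      seq_len(min(3L * bulk_size, nrow(rr))), , drop = FALSE]
    pools$nsns <- low_tss$plant_id[order(-low_tss$ph)][seq_len(bulk_size)]
  }
  stopifnot(!anyDuplicated(unlist(pools)))
  pools
}

#' Report candidate genes from anchored markers and trait regions
#'
#' For each differential marker of a trait that is anchored inside a gene
#' lying in one of that trait's candidate regions, emits one row per
#' (marker, gene) pair -- a marker whose anchored interval overlaps two
#' genes yields two rows. The parental-polymorphism flag records whether
#' the gene belongs to the polymorphic-gene set from the parental
#' resequencing comparison; the annotation text is carried over from the
#' gene models.
#'
#' @param regions Region table from [call_regions()] for one trait (must
#'   have a `trait` column with a single value).
#' @param anchors Anchor table (`marker_id`, `chrom`, `start`, `end`) on the
#'   same coordinate system as `genes`; `chrom` is matched against the gene
#'   scaffold/chromosome ids.
#' @param genes Gene-model data.frame (`gene_id`, `scaffold`, `start`,
#'   `end`, optional `annotation`) or a `ReferenceGenome`.
#' @param polymorphic_set Character vector of polymorphic gene ids (from
#'   [polymorphic_genes()]).
#' @return data.frame of `CandidateGene` rows: `marker_id`, `gene_id`,
#'   `trait`, `polymorphic`, `annotation`.
#' @export
report_candidates <- function(regions, anchors, genes,
                              polymorphic_set = character()) {
  if (inherits(genes, "ReferenceGenome")) genes <- genes$genes
  stopifnot(all(c("trait", "scaffold", "start", "end", "markers") %in% names(regions)),
            all(c("marker_id", "chrom", "start", "end") %in% names(anchors)))
  empty <- df(marker_id = character(), gene_id = character(),
              trait = character(), polymorphic = logical(),
              annotation = character())
  if (!nrow(regions) || !nrow(anchors) || !nrow(genes)) return(empty)
  trait <- unique(regions$trait)
  stopifnot(length(trait) == 1L)

  region_markers <- unique(unlist(strsplit(regions$markers, ",")))
  a <- anchors[anchors$marker_id %in% region_markers, , drop = FALSE]
  if (!nrow(a)) return(empty)

  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    as_granges(a, seqnames = "chrom"),
    as_granges(genes)))
  if (!length(hits)) return(empty)
  mk <- a$marker_id[S4Vectors::queryHits(hits)]
  gn <- genes[S4Vectors::subjectHits(hits), , drop = FALSE]

  # the gene must itself lie in a candidate region of this trait
  in_region <- suppressWarnings(
    IRanges::overlapsAny(as_granges(gn), as_granges(regions)))
  if (!any(in_region)) return(empty)
  out <- df(marker_id = mk[in_region], gene_id = gn$gene_id[in_region],
            trait = trait,
            polymorphic = gn$gene_id[in_region] %in% polymorphic_set,
            annotation = if (!is.null(gn$annotation)) gn$annotation[in_region]
                         else "")
  out <- unique(out)
  rownames(out) <- NULL
  out
}
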