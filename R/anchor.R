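#' Anchor scaffold markers onto a chromosome assembly
#'
#' Places each marker sequence on the assembly by near-exact matching on
#' both strands (ungapped, allowing up to `floor((1 - min_identity) * len)`
#' mismatches), counting distinct hit loci after merging overlapping
#' matches. Markers hitting more than `max_hits` distinct locations are
#' discarded as promiscuous (the multi-map rule is strictly "more than");
#' retained markers report their best hit (fewest mismatches; ties broken by
#' the lexicographically smallest (chromosome, start), which is logged).
#'
#' @param markers Named character vector or [Biostrings::DNAStringSet] of
#'   marker sequences.
#' @param assembly [Biostrings::DNAStringSet] of chromosome sequences.
#' @param min_identity Minimum ungapped identity of a hit, in `(0.8, 1]`.
#' @param max_hits Maximum tolerated number of distinct hit loci.
#' @return List with `anchors` (data.frame `marker_id`, `chrom`, `start`,
#'   `end`, `strand`, `hit_count`) and `discarded` (data.frame `marker_id`,
#'   `hit_count`, `reason` in `"multi_mapped"`/`"no_hit"`).
#' @export
anchor_markers <- function(markers, assembly, min_identity = 0.95,
                           max_hits = 2) {
  check_scalar(min_identity, "min_identity", lower = 0.8 + 1e-12, upper = 1)
  check_scalar(max_hits, "max_hits", lower = 1, integer = TRUE)
  if (is.character(markers)) markers <- Biostrings::DNAStringSet(markers)
  stopifnot(inherits(markers, "DNAStringSet"), inherits(assembly, "DNAStringSet"))
  if (is.null(names(markers))) {
    names(markers) <- sprintf("marker%03d", seq_along(markers))
  }
  anchors <- list()
  discarded <- list()
  for (id in names(markers)) {
    mk <- markers[[id]]
    max_mm <- floor((1 - min_identity) * length(mk))
    hits <- list()
    for (chrom in names(assembly)) {
      subject <- assembly[[chrom]]
      if (length(mk) > length(subject)) next
      for (strand in c("+", "-")) {
        patt <- if (strand == "+") mk else Biostrings::reverseComplement(mk)
        m <- Biostrings::matchPattern(patt, subject, max.mismatch = max_mm)
        if (length(m) == 0L) next
        mm <- vapply(seq_along(m), function(k) {
          Biostrings::neditStartingAt(patt, subject,
                                      starting.at = Biostrings::start(m)[k])
        }, integer(1))
        hits[[length(hits) + 1L]] <- df(
          chrom = chrom, start = Biostrings::start(m),
          end = Biostrings::end(m), strand = strand, mismatches = mm)
      }
    }
    hits <- if (length(hits)) do.call(rbind, hits) else NULL
    if (is.null(hits) || !nrow(hits)) {
      discarded[[id]] <- df(marker_id = id, hit_count = 0L, reason = "no_hit")
      next
    }
    # merge overlapping matches into distinct loci (a mismatch-tolerant
    # search can report several offsets of the same locus)
    gr <- GenomicRanges::reduce(as_granges(hits, seqnames = "chrom"))
    n_loci <- length(gr)
    if (n_loci > max_hits) {
      discarded[[id]] <- df(marker_id = id, hit_count = n_loci,
                            reason = "multi_mapped")
      next
    }
    best <- hits[order(hits$mismatches, hits$chrom, hits$start), , drop = FALSE][1, ]
    if (sum(hits$mismatches == best$mismatches) > 1L) {
      message("marker ", id, ": best-hit tie broken by coordinate order")
    }
    anchors[[id]] <- df(marker_id = id, chrom = best$chrom, start = best$start,
                        end = best$end, strand = best$strand,
                        hit_count = n_loci)
  }
  empty_a <- df(marker_id = character(), chrom = character(), start = integer(),
                end = integer(), strand = character(), hit_count = integer())
  empty_d <- df(marker_id = character(), hit_count = integer(),
                reason = character())
  list(anchors = if (length(anchors)) do.call(rbind, c(anchors, list(make.row.names = FALSE))) else empty_a,
       discarded = if (length(discarded)) do.call(rbind, c(discarded, list(make.row.names = FALSE))) else empty_d)
}

#' Project anchored markers to a per-chromosome fine-map table
#'
#' Groups retained anchors by chromosome and sorts them by start coordinate,
#' producing the conventional fine-map table (chromosome, marker, start,
#' end) for one trait.
#'
#' @param anchors data.frame from [anchor_markers()]`$anchors`.
#' @param trait `"sweet"` or `"sour"`.
#' @return data.frame with `chrom`, `marker_id`, `start`, `end`, `trait`,
#'   sorted by (`chrom`, `start`).
#' @export
project_regions <- function(anchors, trait = c("sweet", "sour")) {
  trait <- match.arg(trait)
  stopifnot(all(c("marker_id", "chrom", "start", "end") %in% names(anchors)))
  out <- anchors[order(anchors$chrom, anchors$start),
                 c("chrom", "marker_id", "start", "end"), drop = FALSE]
  out$trait <- rep(trait, nrow(out))
  rownames(out) <- NULL
  out
}
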