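#' In-silico double-enzyme digestion with size selection
#'
#' Cuts the input sequence at the start of every occurrence of either
#' enzyme recognition site (defaults XhoI = CTCGAG and MseI = TTAA) and
#' returns the fragments between consecutive cuts, in 1-based inclusive
#' coordinates on the input. Concatenating all fragments in coordinate order
#' reconstructs the input exactly; only fragments whose length falls inside
#' the size-selection window are retained as SLAF candidates.
#'
#' @param sequence A [Biostrings::DNAString] or single character string.
#' @param enzymes Character vector of exact recognition motifs.
#' @param size_window Numeric `c(min, max)` fragment length window in bp.
#' @return List with data.frames `fragments` (all fragments: `start`, `end`,
#'   `length`) and `selected` (those inside the window).
#' @export
digest <- function(sequence, enzymes = c("CTCGAG", "TTAA"),
                   size_window = c(314, 414)) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  stopifnot(length(size_window) == 2, size_window[1] <= size_window[2])
  len <- length(sequence)
  empty <- df(start = integer(), end = integer(), length = integer())
  if (len == 0L) return(list(fragments = empty, selected = empty))
  cuts <- sort(unique(unlist(lapply(enzymes, function(e) {
    Biostrings::start(Biostrings::matchPattern(e, sequence))
  }))))
  cuts <- cuts[cuts > 1L]
  bounds <- c(1L, cuts, len + 1L)
  frags <- df(start = bounds[-length(bounds)], end = bounds[-1L] - 1L)
  frags$length <- frags$end - frags$start + 1L
  list(fragments = frags,
       selected = frags[frags$length >= size_window[1] &
                          frags$length <= size_window[2], , drop = FALSE])
}

#' Cluster SLAF tags into loci by sequence identity
#'
#' Groups fixed-length tag sequences with single-linkage clustering: two tags
#' belong to the same locus when their ungapped identity (matching positions
#' over tag length) exceeds the threshold, directly or through a chain of
#' intermediates. The partition equals the transitive closure of the pairwise
#' identity relation and is therefore independent of input order; group
#' numbers follow the lexicographic order of each group's smallest sequence.
#'
#' @param tags data.frame with at least a `sequence` column; all sequences
#'   must have equal length.
#' @param identity_threshold Identity that must be exceeded for two tags to
#'   be linked, in `(0.5, 1]` (default 0.9, i.e. "over 90% identity").
#' @return The input data.frame with an integer `locus_group` column.
#' @export
cluster_tags <- function(tags, identity_threshold = 0.9) {
  stopifnot("sequence" %in% names(tags))
  check_scalar(identity_threshold, "identity_threshold", lower = 0.5 + 1e-12,
               upper = 1)
  seqs <- sort(unique(tags$sequence))
  if (length(unique(nchar(seqs))) > 1L) {
    stop("all tag sequences must have the same length", call. = FALSE)
  }
  n <- length(seqs)
  comp <- seq_len(n)
  if (n > 1L) {
    m <- do.call(rbind, strsplit(seqs, ""))
    find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (mean(m[i, ] == m[j, ]) > identity_threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
  }
  group_of_seq <- match(comp, sort(unique(comp)))
  tags$locus_group <- group_of_seq[match(tags$sequence, seqs)]
  tags
}

#' Apply the locus-level SLAF filters
#'
#' Aggregates a clustered tag table into loci and assigns the two filtering
#' categories: loci with more than `max_tags` distinct tag sequences are
#' repetitive (`repeat`), and loci whose summed depth fails the depth rules
#' are `low_depth`. Retained loci carry 1-4 distinct tags and are flagged
#' polymorphic when they carry 2-4.
#'
#' Two depth rules coexist in SLAF practice and both are exposed: loci are
#' retained only with total depth strictly greater than `min_depth`
#' (default 10x), and, when `low_depth_cutoff` is given, only with total
#' depth at least that cutoff (the emulated study quotes a 164-read cutoff
#' alongside the 10x selection; the two cannot be reconciled from the text,
#' so the cutoff is off by default).
#'
#' @param tags Output of [cluster_tags()], with columns `sequence`, `depth`
#'   and `locus_group` (and optionally `sample`).
#' @param max_tags Maximum distinct tag sequences for a non-repetitive locus.
#' @param min_depth Total-depth selection threshold (strict).
#' @param low_depth_cutoff Optional minimum total depth (non-strict), or
#'   `NULL`.
#' @return data.frame of loci: `locus_group`, `n_tags`, `total_depth`,
#'   `category` (`"repeat"`, `"low_depth"` or `"untyped"`), `polymorphic`,
#'   `retained`.
#' @export
filter_loci <- function(tags, max_tags = 4, min_depth = 10,
                        low_depth_cutoff = NULL) {
  stopifnot(all(c("sequence", "depth", "locus_group") %in% names(tags)))
  check_scalar(max_tags, "max_tags", lower = 1, integer = TRUE)
  check_scalar(min_depth, "min_depth", lower = 0)
  groups <- split(tags, tags$locus_group)
  out <- do.call(rbind, lapply(groups, function(g) {
    df(locus_group = g$locus_group[1],
       n_tags = length(unique(g$sequence)),
       total_depth = sum(g$depth))
  }))
  rownames(out) <- NULL
  low <- out$total_depth <= min_depth |
    (!is.null(low_depth_cutoff) & out$total_depth < (low_depth_cutoff %||% 0))
  out$category <- ifelse(out$n_tags > max_tags, "repeat",
                         ifelse(low, "low_depth", "untyped"))
  out$polymorphic <- out$category == "untyped" & out$n_tags >= 2
  out$retained <- out$category == "untyped"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Type a retained SLAF locus as a marker category
#'
#' Given the distinct tag sequences of a retained locus (and optionally the
#' two parental allele sequences at that locus), assigns the marker
#' category: a single tag is `no_polymorphism`; tags of equal length
#' differing only by substitutions are `SNP`, or `EPSNP` when a differing
#' position falls inside an occurrence of an enzyme recognition site in any
#' tag (a substitution that creates or destroys a cut site); tags of unequal
#' length are `INDEL`; tags not attributable to either parent are `unknown`.
#'
#' @param tag_seqs Character vector of distinct tag sequences (1-4).
#' @param parent_alleles Optional character vector of the parental tag
#'   sequences at this locus; when given, every tag must match one of them.
#' @param enzymes Enzyme recognition motifs used for the EPSNP check.
#' @return One of `"SNP"`, `"EPSNP"`, `"INDEL"`, `"no_polymorphism"`,
#'   `"unknown"`.
#' @export
type_marker <- function(tag_seqs, parent_alleles = NULL,
                        enzymes = c("CTCGAG", "TTAA")) {
  tag_seqs <- unique(tag_seqs)
  stopifnot(length(tag_seqs) >= 1, length(tag_seqs) <= 4)
  if (length(tag_seqs) == 1L) return("no_polymorphism")
  if (!is.null(parent_alleles) && !all(tag_seqs %in% parent_alleles)) {
    return("unknown")
  }
  if (length(unique(nchar(tag_seqs))) > 1L) return("INDEL")
  m <- do.call(rbind, strsplit(tag_seqs, ""))
  diff_pos <- which(apply(m, 2, function(col) length(unique(col)) > 1))
  site_hit <- any(vapply(tag_seqs, function(s) {
    any(vapply(enzymes, function(e) {
      starts <- unlist(gregexpr(e, s, fixed = TRUE))
      starts <- starts[starts > 0]
      any(vapply(starts, function(st) {
        any(diff_pos >= st & diff_pos <= st + nchar(e) - 1L)
      }, logical(1)))
    }, logical(1)))
  }, logical(1)))
  if (site_hit) "EPSNP" else "SNP"
}

#' Summarise SLAF locus categories
#'
#' @param categories Character vector of locus categories (one per locus),
#'   or a data.frame with a `category` column.
#' @return data.frame with `category`, `n` and `percent` (percent of total,
#'   rounded to 2 decimals), ordered SNP, EPSNP, INDEL, no_polymorphism,
#'   unknown, repeat, low_depth; only categories present are reported. The
#'   total locus count is attached as attribute `total`.
#' @export
slaf_summary <- function(categories) {
  if (is.data.frame(categories)) categories <- categories$category
  order_ref <- c("SNP", "EPSNP", "INDEL", "no_polymorphism", "unknown",
                 "repeat", "low_depth")
  tab <- table(categories)
  cats <- intersect(order_ref, names(tab))
  cats <- c(cats, setdiff(names(tab), order_ref))
  out <- df(category = cats, n = as.integer(tab[cats]),
            percent = round(100 * as.integer(tab[cats]) / sum(tab), 2))
  attr(out, "total") <- sum(tab)
  out
}
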