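#' Construct a QTL specification for a simulated trait
#'
#' A QTL specification places trait loci on scaffolds and defines the genetic
#' model used by [assign_phenotypes()]: for a plant carrying `g` copies of the
#' sweet-parent (maternal, "M") allele at a locus with additive effect `a` and
#' dominance degree `d`, the locus contributes `2a` (g = 2), `a (1 + d)`
#' (g = 1) or `0` (g = 0) to the trait value on top of the trait baseline.
#'
#' Effects are expressed per copy of the sweet-parent allele and must be
#' non-negative for both traits: the sweet parent carries the trait-raising
#' allele for TSS and the pH-raising allele (equivalently, the sour parent's
#' allele lowers pH, so its effect is non-positive from that side).
#'
#' @param trait `"TSS"` or `"pH"`.
#' @param scaffold Character vector of scaffold ids, one per QTL.
#' @param pos Integer vector of 1-based positions, one per QTL.
#' @param effect Additive effect per sweet-parent allele copy (trait units).
#' @param dominance Dominance degree in `[-1, 1]`; 0 is purely additive,
#'   positive values push heterozygotes toward the sweet parent.
#' @param baseline Trait value of a plant with zero sweet-parent alleles
#'   (the sour-parent mean).
#' @param residual_sd Environmental (residual) standard deviation.
#'
#' @return A data.frame of class `QtlSpec`.
#' @seealso [default_qtls()] for the study-default architecture.
#' @export
qtl_spec <- function(trait, scaffold, pos, effect, dominance = 0,
                     baseline, residual_sd) {
  trait <- match.arg(trait, c("TSS", "pH"))
  n <- length(scaffold)
  stopifnot(length(pos) == n, length(effect) == n)
  if (any(effect < 0)) {
    stop("QTL effects are per sweet-parent allele copy and must be >= 0",
         call. = FALSE)
  }
  check_scalar(baseline, "baseline")
  check_scalar(residual_sd, "residual_sd", lower = 0)
  dominance <- rep_len(dominance, n)
  if (any(dominance < -1 | dominance > 1)) {
    stop("`dominance` must be in [-1, 1]", call. = FALSE)
  }
  out <- df(trait = trait, scaffold = as.character(scaffold),
            pos = as.integer(pos), effect = as.numeric(effect),
            dominance = as.numeric(dominance),
            baseline = baseline, residual_sd = residual_sd)
  class(out) <- c("QtlSpec", "data.frame")
  out
}

#' Check a QTL specification against a parental trait mean
#'
#' Verifies that `baseline + 2 * sum(effect)` reproduces the high-parent
#' (sweet-parent) mean to within one residual standard deviation.
#'
#' @param qtls A `QtlSpec`.
#' @param high_parent_mean Observed mean of the parent homozygous for all
#'   sweet alleles.
#' @return `TRUE` invisibly; errors if the specification is inconsistent.
#' @export
validate_qtls <- function(qtls, high_parent_mean) {
  stopifnot(inherits(qtls, "QtlSpec"))
  expected <- qtls$baseline[1] + 2 * sum(qtls$effect)
  if (abs(expected - high_parent_mean) > qtls$residual_sd[1]) {
    stop(sprintf(
      "baseline + 2*sum(effects) = %.3f is more than one residual sd from the high-parent mean %.3f",
      expected, high_parent_mean), call. = FALSE)
  }
  invisible(TRUE)
}

#' Study-default QTL architectures for TSS and pH
#'
#' The defaults emulate greenhouse parental means of 12.7 degrees Brix versus
#' 6.8 for TSS and pH 6.1 versus 4.4: four TSS QTLs of equal effect 0.7375
#' (so that baseline 6.8 plus twice their sum is exactly 12.7) with partial
#' dominance 0.8 toward the sweet parent, and four pH QTLs (one major, three
#' minor, effects summing to 0.85) with dominance -0.5 toward the sour parent.
#' QTLs are placed at the midpoints of the first four (TSS) and next four (pH)
#' scaffolds. The dominance values reproduce F1 and F2 population means close
#' to those of the emulated cross; see the package vignette for the reasoning.
#'
#' @param genome A `ReferenceGenome` with at least eight scaffolds.
#' @param trait `"TSS"` or `"pH"`.
#' @return A `QtlSpec` with four rows.
#' @export
default_qtls <- function(genome, trait = c("TSS", "pH")) {
  trait <- match.arg(trait)
  lens <- scaffold_lengths(genome)
  if (length(lens) < 8) {
    stop("default QTL layout needs at least 8 scaffolds", call. = FALSE)
  }
  mid <- as.integer(lens %/% 2L)
  if (trait == "TSS") {
    qtl_spec("TSS", names(lens)[1:4], mid[1:4], effect = rep(0.7375, 4),
             dominance = 0.8, baseline = 6.8, residual_sd = 0.9)
  } else {
    qtl_spec("pH", names(lens)[5:8], mid[5:8],
             effect = c(0.70, 0.05, 0.05, 0.05),
             dominance = -0.5, baseline = 4.4, residual_sd = 0.2)
  }
}

#' Simulate two homozygous diverged parents
#'
#' Plants SNPs, small indels and structural variants (SVs) on the reference to
#' define the two parental haplotypes of the cross. Both parents are fully
#' homozygous; each variant records which parent carries the non-reference
#' allele (`"M"` = female/sweet, `"P"` = male/sour, or `"both"` for shared,
#' non-differential variants). Every QTL position receives a discriminating
#' SNP whose alternate allele is carried by the sweet parent, and no deletion
#' is allowed to span a QTL position.
#'
#' @param genome A `ReferenceGenome`.
#' @param snp_rate,indel_rate,sv_rate Per-bp variant rates (>= 0).
#' @param qtls A `QtlSpec` (or rbind of several), or `NULL`.
#' @param seed Integer seed.
#' @param ts_prob Probability that a simulated SNP is a transition
#'   (C/T or G/A); the default 0.71 emulates the transition-enriched
#'   substitution spectrum typical of plant resequencing (Ts/Tv near 2.4).
#' @param shared_fraction Fraction of variants carried by both parents
#'   (present but not differential).
#'
#' @return A `ParentPair` object: list with `truth` (data.frame of variants:
#'   `variant_id`, `scaffold`, `pos`, `kind` in SNP/INS/DEL/DII/CTX/ITX/INV,
#'   `ref`, `alt`, `carrier`, `sv_len`, `partner_scaffold`, `partner_pos`,
#'   `is_qtl`, `trait`) and `qtls`.
#' @export
make_parents <- function(genome, snp_rate, indel_rate, sv_rate, qtls = NULL,
                         seed, ts_prob = 0.71, shared_fraction = 0.15) {
  stopifnot(inherits(genome, "ReferenceGenome"))
  check_scalar(snp_rate, "snp_rate", lower = 0, upper = 1)
  check_scalar(indel_rate, "indel_rate", lower = 0, upper = 1)
  check_scalar(sv_rate, "sv_rate", lower = 0, upper = 1)
  check_scalar(ts_prob, "ts_prob", lower = 0, upper = 1)
  check_scalar(shared_fraction, "shared_fraction", lower = 0, upper = 1)
  lens <- scaffold_lengths(genome)
  if (!is.null(qtls)) {
    stopifnot(inherits(qtls, "QtlSpec") || is.data.frame(qtls))
    if (!all(qtls$scaffold %in% names(lens))) {
      stop("QTL scaffold not present in the genome", call. = FALSE)
    }
    if (any(qtls$pos < 1 | qtls$pos > lens[qtls$scaffold])) {
      stop("QTL position outside its scaffold", call. = FALSE)
    }
  }

  transition_of <- c(A = "G", G = "A", C = "T", T = "C")

  with_sim_seed(seed, {
    rows <- list()
    for (sc in names(lens)) {
      len <- lens[[sc]]
      chars <- strsplit(as.character(genome$scaffolds[[sc]]), "")[[1]]
      qtl_here <- if (is.null(qtls)) NULL else qtls[qtls$scaffold == sc, , drop = FALSE]

      n_snp <- stats::rbinom(1L, len, snp_rate)
      snp_pos <- if (n_snp > 0) sort(sample.int(len, n_snp)) else integer()
      # QTL positions always carry an M-borne SNP
      snp_pos <- setdiff(snp_pos, qtl_here$pos)
      if (length(snp_pos)) {
        ref <- chars[snp_pos]
        is_ts <- stats::runif(length(snp_pos)) < ts_prob
        alt <- ifelse(is_ts, transition_of[ref],
                      vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                             c(b, transition_of[[b]])), 1L),
                             character(1)))
        carrier <- sample(c("M", "P", "both"), length(snp_pos), replace = TRUE,
                          prob = c((1 - shared_fraction) / 2,
                                   (1 - shared_fraction) / 2, shared_fraction))
        snps <- df(scaffold = sc, pos = snp_pos, kind = "SNP",
                   ref = ref, alt = unname(alt), carrier = carrier,
                   sv_len = 0L, partner_scaffold = NA_character_,
                   partner_pos = NA_integer_, is_qtl = FALSE,
                   trait = NA_character_)
      } else {
        snps <- df(scaffold = character(), pos = integer(), kind = character(),
                   ref = character(), alt = character(), carrier = character(),
                   sv_len = integer(), partner_scaffold = character(),
                   partner_pos = integer(), is_qtl = logical(),
                   trait = character())
      }
      if (!is.null(qtl_here) && nrow(qtl_here)) {
        qref <- chars[qtl_here$pos]
        qalt <- vapply(qref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                       character(1))
        snps <- rbind(snps, df(
          scaffold = sc, pos = qtl_here$pos, kind = "SNP", ref = qref,
          alt = unname(qalt), carrier = "M", sv_len = 0L,
          partner_scaffold = NA_character_, partner_pos = NA_integer_,
          is_qtl = TRUE, trait = qtl_here$trait))
      }

      n_indel <- stats::rbinom(1L, len, indel_rate)
      n_sv <- stats::rbinom(1L, len, sv_rate)
      indels <- simulate_length_variants(
        sc, chars, len, n_indel, kinds = c(INS = 0.5, DEL = 0.5),
        len_range = c(1L, 10L), shared_fraction = shared_fraction)
      svs <- simulate_length_variants(
        sc, chars, len, n_sv,
        kinds = c(INS = 0.475, DEL = 0.475, ITX = 0.03, CTX = 0.013,
                  DII = 0.005, INV = 0.002),
        len_range = c(50L, 500L), shared_fraction = shared_fraction,
        scaffold_ids = names(lens), scaffold_lens = lens)

      out <- rbind(snps, indels, svs)
      # drop any deletion/inversion span covering a QTL position, and keep
      # variant footprints non-overlapping so haplotypes materialise cleanly
      if (nrow(out)) {
        span_end <- out$pos + ifelse(out$kind %in% c("DEL", "DII", "INV"),
                                     out$sv_len, 0L)
        if (!is.null(qtl_here) && nrow(qtl_here)) {
          covers_qtl <- vapply(seq_len(nrow(out)), function(i) {
            !out$is_qtl[i] && any(qtl_here$pos >= out$pos[i] &
                                    qtl_here$pos <= span_end[i])
          }, logical(1))
          out <- out[!covers_qtl, , drop = FALSE]
          span_end <- span_end[!covers_qtl]
        }
        ord <- order(out$pos, -out$is_qtl)
        out <- out[ord, , drop = FALSE]
        span_end <- span_end[ord]
        keep <- logical(nrow(out))
        last_end <- 0L
        for (i in seq_len(nrow(out))) {
          if (out$pos[i] > last_end) {
            keep[i] <- TRUE
            last_end <- span_end[i]
          } else if (out$is_qtl[i]) {
            # QTL SNPs always win over an overlapping variant
            keep[i] <- TRUE
          }
        }
        out <- out[keep, , drop = FALSE]
      }
      rows[[sc]] <- out
    }
    truth <- do.call(rbind, rows)
    truth <- truth[order(match(truth$scaffold, names(lens)), truth$pos), , drop = FALSE]
    rownames(truth) <- NULL
    if (nrow(truth)) {
      truth$variant_id <- sprintf("VAR%06d", seq_len(nrow(truth)))
      truth <- truth[, c("variant_id", setdiff(names(truth), "variant_id"))]
    } else {
      truth <- cbind(df(variant_id = character()), truth)
    }
    structure(list(truth = truth, qtls = qtls, seed = seed), class = "ParentPair")
  })
}

# Generate indel/SV rows at random non-QTL positions (helper for make_parents).
simulate_length_variants <- function(sc, chars, len, n, kinds, len_range,
                                     shared_fraction, scaffold_ids = sc,
                                     scaffold_lens = stats::setNames(len, sc)) {
  empty <- df(scaffold = character(), pos = integer(), kind = character(),
              ref = character(), alt = character(), carrier = character(),
              sv_len = integer(), partner_scaffold = character(),
              partner_pos = integer(), is_qtl = logical(), trait = character())
  if (n < 1) return(empty)
  max_len <- len_range[2]
  pos <- sort(sample.int(len - max_len - 1L, n))
  kind <- sample(names(kinds), n, replace = TRUE, prob = kinds)
  sv_len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  carrier <- sample(c("M", "P", "both"), n, replace = TRUE,
                    prob = c((1 - shared_fraction) / 2,
                             (1 - shared_fraction) / 2, shared_fraction))
  ref <- character(n)
  alt <- character(n)
  partner_sc <- rep(NA_character_, n)
  partner_pos <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    anchor <- chars[pos[i]]
    rand_seq <- function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                                  collapse = "")
    switch(kind[i],
      INS = { ref[i] <- anchor; alt[i] <- paste0(anchor, rand_seq(sv_len[i])) },
      DEL = { ref[i] <- paste(chars[pos[i]:(pos[i] + sv_len[i])], collapse = "")
              alt[i] <- anchor },
      DII = { ref[i] <- paste(chars[pos[i]:(pos[i] + sv_len[i])], collapse = "")
              alt[i] <- paste0(anchor, rand_seq(max(1L, sv_len[i] %/% 2L))) },
      INV = { ref[i] <- paste(chars[pos[i]:(pos[i] + sv_len[i])], collapse = "")
              alt[i] <- "<INV>" },
      CTX = { ref[i] <- anchor; alt[i] <- "<CTX>"
              partner_sc[i] <- sample(setdiff(scaffold_ids, sc), 1L)
              partner_pos[i] <- sample.int(scaffold_lens[[partner_sc[i]]], 1L) },
      ITX = { ref[i] <- anchor; alt[i] <- "<ITX>"
              partner_sc[i] <- sc
              partner_pos[i] <- sample.int(len, 1L) }
    )
  }
  df(scaffold = sc, pos = pos, kind = kind, ref = ref, alt = alt,
     carrier = carrier, sv_len = sv_len, partner_scaffold = partner_sc,
     partner_pos = partner_pos, is_qtl = FALSE, trait = NA_character_)
}

#' @export
print.ParentPair <- function(x, ...) {
  tab <- table(x$truth$kind)
  cat("ParentPair:", nrow(x$truth), "truth variants (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ");",
      sum(x$truth$carrier != "both"), "differential;",
      sum(x$truth$is_qtl), "QTL sites\n")
  invisible(x)
}

#' Materialise a parent's haplotype sequences
#'
#' Applies a parent's SNPs, indels, deletions, insertions and inversions to
#' the reference scaffolds. Translocation records (CTX/ITX) describe partner
#' coordinates only and do not alter the linear sequence.
#'
#' @param parents A `ParentPair` from [make_parents()].
#' @param genome The `ReferenceGenome` the parents were simulated on.
#' @param which `"M"` (female/sweet) or `"P"` (male/sour).
#' @return A [Biostrings::DNAStringSet] of parental scaffold sequences.
#' @export
parent_sequences <- function(parents, genome, which = c("M", "P")) {
  which <- match.arg(which)
  stopifnot(inherits(parents, "ParentPair"), inherits(genome, "ReferenceGenome"))
  v <- parents$truth
  v <- v[v$carrier %in% c(which, "both") & !v$kind %in% c("CTX", "ITX"), , drop = FALSE]
  out <- genome$scaffolds
  for (sc in names(out)) {
    vv <- v[v$scaffold == sc, , drop = FALSE]
    if (!nrow(vv)) next
    span <- ifelse(vv$kind %in% c("DEL", "DII", "INV"), vv$sv_len, 0L)
    at <- IRanges::IRanges(start = vv$pos, end = vv$pos + span)
    value <- vv$alt
    inv <- vv$kind == "INV"
    if (any(inv)) {
      value[inv] <- as.character(Biostrings::reverseComplement(
        Biostrings::extractAt(out[[sc]], at[inv])))
    }
    out[[sc]] <- Biostrings::replaceAt(out[[sc]], at,
                                       Biostrings::DNAStringSet(value))
  }
  out
}
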