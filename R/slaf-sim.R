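#' Sequencing depth model for the simulator
#'
#' @param parent_depth Mean resequencing depth of each parent (default 13x,
#'   the scale of a typical short-read parental resequencing run).
#' @param pool_depth Mean pooled SLAF depth per locus and pool (default 160x).
#' @param error_rate Per-base probability that a read reports the wrong
#'   parental allele, in `[0, 0.05]`.
#' @param overdispersion Depth overdispersion `phi` (variance =
#'   `mu + phi * mu^2`); 0 degenerates to Poisson. SLAF depth is drawn from a
#'   negative binomial because amplified reduced-representation libraries are
#'   overdispersed relative to Poisson.
#' @return A list of class `DepthModel`.
#' @export
depth_model <- function(parent_depth = 13, pool_depth = 160,
                        error_rate = 0.01, overdispersion = 0.05) {
  check_scalar(parent_depth, "parent_depth", lower = 1e-9)
  check_scalar(pool_depth, "pool_depth", lower = 1e-9)
  check_scalar(error_rate, "error_rate", lower = 0, upper = 0.05)
  check_scalar(overdispersion, "overdispersion", lower = 0)
  structure(list(parent_depth = parent_depth, pool_depth = pool_depth,
                 error_rate = error_rate, overdispersion = overdispersion),
            class = "DepthModel")
}

# Draw depths: negative binomial with mean mu, or Poisson when phi == 0.
draw_depth <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Derive SLAF loci from the simulated genome
#'
#' Digests every reference scaffold with the two restriction enzymes, keeps
#' fragments inside the size-selection window, and links each fragment to the
#' truth variants it contains. A locus is polymorphic when it contains at
#' least one differential parental SNP; its tag-discriminating site (the
#' first such SNP) determines the parental origin of reads in the pools.
#'
#' @param genome A `ReferenceGenome`.
#' @param parents A `ParentPair`.
#' @param size_window Fragment size-selection window in bp.
#' @param enzymes Recognition sites of the two enzymes (defaults XhoI =
#'   CTCGAG and MseI = TTAA).
#' @return data.frame with `locus_id`, `scaffold`, `start`, `end`, `pos`
#'   (leftmost coordinate), `site_id` (discriminating truth SNP or `NA`) and
#'   `polymorphic`.
#' @export
slaf_loci_from_genome <- function(genome, parents, size_window = c(314, 414),
                                  enzymes = c("CTCGAG", "TTAA")) {
  stopifnot(inherits(genome, "ReferenceGenome"), inherits(parents, "ParentPair"))
  snps <- parents$truth[parents$truth$kind == "SNP" &
                          parents$truth$carrier != "both", , drop = FALSE]
  out <- list()
  for (sc in names(genome$scaffolds)) {
    frags <- digest(genome$scaffolds[[sc]], enzymes = enzymes,
                    size_window = size_window)$selected
    if (!nrow(frags)) next
    sc_snps <- snps[snps$scaffold == sc, , drop = FALSE]
    if (nrow(sc_snps)) {
      # first differential SNP at or after the fragment start
      hit <- findInterval(frags$start - 1L, sc_snps$pos) + 1L
      ok <- hit <= nrow(sc_snps) & sc_snps$pos[pmin(hit, nrow(sc_snps))] <= frags$end
      site <- ifelse(ok, sc_snps$variant_id[pmin(hit, nrow(sc_snps))], NA_character_)
    } else {
      site <- rep(NA_character_, nrow(frags))
    }
    out[[sc]] <- df(scaffold = sc, start = frags$start, end = frags$end,
                    pos = frags$start, site_id = site)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$locus_id <- sprintf("SLAF%05d", seq_len(nrow(res)))
  res$polymorphic <- !is.na(res$site_id)
  res[, c("locus_id", "scaffold", "start", "end", "pos", "site_id", "polymorphic")]
}

#' Simulate pooled SLAF allele depths for the five DNA pools
#'
#' For every polymorphic locus and every pool, a total read depth is drawn
#' around the pooled mean (negative binomial, see [depth_model()]); reads are
#' assigned to the sweet-parent ("M") or sour-parent ("P") allele binomially
#' at the pool's true M-allele frequency, then flipped at the sequencing
#' error rate. The two parental pools are fixed for their own allele
#' (frequency 1 and 0 before error).
#'
#' @param genotypes An `F2Genotypes` object.
#' @param bulks Named list with elements `sweet`, `sour`, `nsns`: character
#'   vectors of plant ids, equal-sized, disjoint and non-empty.
#' @param loci Locus table from [slaf_loci_from_genome()] (or any data.frame
#'   with `locus_id`, `scaffold`, `pos`, `site_id`); only polymorphic loci
#'   (non-`NA` `site_id`) receive depths.
#' @param model A `DepthModel`.
#' @param seed Integer seed.
#' @return data.frame with one row per polymorphic locus: `locus_id`,
#'   `scaffold`, `pos`, and `M_`/`P_` depth columns for pools `parent_m`,
#'   `parent_p`, `sweet`, `sour`, `nsns`.
#' @export
simulate_slaf_depths <- function(genotypes, bulks, loci, model = depth_model(),
                                 seed) {
  stopifnot(inherits(genotypes, "F2Genotypes"), inherits(model, "DepthModel"))
  if (!all(c("sweet", "sour", "nsns") %in% names(bulks))) {
    stop("`bulks` must have elements sweet, sour and nsns", call. = FALSE)
  }
  sizes <- lengths(bulks[c("sweet", "sour", "nsns")])
  if (any(sizes == 0L)) stop("empty bulk", call. = FALSE)
  if (length(unique(sizes)) != 1L) {
    stop("the three F2 bulks must have equal size", call. = FALSE)
  }
  all_ids <- unlist(bulks[c("sweet", "sour", "nsns")], use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("bulks must be disjoint", call. = FALSE)
  if (!all(all_ids %in% colnames(genotypes$geno))) {
    stop("unknown plant id in bulks", call. = FALSE)
  }
  keep <- !is.na(loci$site_id)
  loci <- loci[keep, , drop = FALSE]
  rows <- match(loci$site_id, rownames(genotypes$geno))
  if (anyNA(rows)) stop("locus site_id not present in genotype table", call. = FALSE)
  n <- nrow(loci)

  freq <- cbind(
    parent_m = rep(1, n),
    parent_p = rep(0, n),
    sweet = rowMeans(genotypes$geno[rows, bulks$sweet, drop = FALSE]) / 2,
    sour = rowMeans(genotypes$geno[rows, bulks$sour, drop = FALSE]) / 2,
    nsns = rowMeans(genotypes$geno[rows, bulks$nsns, drop = FALSE]) / 2
  )

  with_sim_seed(seed, {
    out <- df(locus_id = loci$locus_id, scaffold = loci$scaffold, pos = loci$pos)
    for (pool in colnames(freq)) {
      depth <- draw_depth(n, model$pool_depth, model$overdispersion)
      p_m <- freq[, pool] * (1 - model$error_rate) +
        (1 - freq[, pool]) * model$error_rate
      m <- stats::rbinom(n, depth, p_m)
      out[[paste0("M_", pool)]] <- m
      out[[paste0("P_", pool)]] <- depth - m
    }
    out
  })
}

#' Simulate parental resequencing variant calls
#'
#' Produces per-parent SNP/SV call tables in the shape consumed by
#' [filter_snp_calls()] and [validate_sv()]: each truth variant carried by
#' the parent becomes a homozygous call with a Poisson read depth around the
#' parental resequencing mean and a quality score.
#'
#' @param parents A `ParentPair`.
#' @param model A `DepthModel`.
#' @param seed Integer seed.
#' @return Named list with data.frames `M` and `P` of calls (`sample`,
#'   `scaffold`, `pos`, `kind`, `ref`, `alt`, `depth`, `quality`, `zygosity`).
#' @export
simulate_parent_calls <- function(parents, model = depth_model(), seed) {
  stopifnot(inherits(parents, "ParentPair"), inherits(model, "DepthModel"))
  with_sim_seed(seed, {
    lapply(stats::setNames(c("M", "P"), c("M", "P")), function(par) {
      v <- parents$truth[parents$truth$carrier %in% c(par, "both"), , drop = FALSE]
      df(sample = par, scaffold = v$scaffold, pos = v$pos, kind = v$kind,
         ref = v$ref, alt = v$alt,
         depth = stats::rpois(nrow(v), model$parent_depth),
         quality = round(stats::runif(nrow(v), 25, 60), 1),
         zygosity = "hom")
    })
  })
}
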