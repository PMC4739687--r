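#' Configuration of the simulated F2 cross
#'
#' @param n_f2 Number of F2 plants; must allow three non-overlapping bulks
#'   (default 500 plants for three 50-plant bulks).
#' @param crossovers_per_scaffold Expected number of crossovers per scaffold
#'   per gamete (Poisson mean; the crossover process has no interference, so
#'   recombinant fractions follow the Haldane map function). The default
#'   0.05 corresponds to a sub-megabase scaffold of a genome with a few
#'   centimorgans per megabase, the regime of a typical melon assembly.
#' @param seed Integer seed.
#' @param bulk_size Bulk size used for the feasibility check (default 50).
#' @param n_bulks Number of F2 bulks (default 3).
#' @return A list of class `CrossConfig`.
#' @export
cross_config <- function(n_f2 = 500, crossovers_per_scaffold = 0.05, seed = 1,
                         bulk_size = 50, n_bulks = 3) {
  check_scalar(n_f2, "n_f2", lower = 1, integer = TRUE)
  check_scalar(crossovers_per_scaffold, "crossovers_per_scaffold", lower = 0)
  check_scalar(bulk_size, "bulk_size", lower = 1, integer = TRUE)
  check_scalar(n_bulks, "n_bulks", lower = 1, integer = TRUE)
  if (n_f2 < bulk_size * n_bulks) {
    stop("n_f2 must be at least bulk_size * n_bulks (", bulk_size * n_bulks,
         ")", call. = FALSE)
  }
  structure(list(n_f2 = as.integer(n_f2),
                 crossovers_per_scaffold = crossovers_per_scaffold,
                 seed = check_seed(seed)),
            class = "CrossConfig")
}

#' Simulate an F2 population from the parental cross
#'
#' Self-pollination of the F1: each F2 plant receives two recombinant gametes.
#' Per gamete and scaffold the number of crossovers is Poisson with mean
#' `crossovers_per_scaffold` and breakpoints are uniform, i.e. a
#' no-interference (Haldane) model. The genotype at every truth-variant site
#' is the number of sweet-parent ("M") chromosome copies (0, 1 or 2), so
#' across many plants single-site genotypes segregate 1:2:1.
#'
#' @param parents A `ParentPair` from [make_parents()].
#' @param genome The `ReferenceGenome` used to build the parents.
#' @param cross A `CrossConfig`.
#' @return An `F2Genotypes` object: list with `sites` (the truth-variant
#'   table) and `geno`, an integer matrix of M-allele copy counts with one
#'   row per site and one column per plant (`F2_0001`, ...).
#' @export
simulate_cross <- function(parents, genome, cross = cross_config()) {
  stopifnot(inherits(parents, "ParentPair"), inherits(genome, "ReferenceGenome"),
            inherits(cross, "CrossConfig"))
  sites <- parents$truth
  lens <- scaffold_lengths(genome)
  n <- cross$n_f2
  geno <- matrix(0L, nrow = nrow(sites), ncol = n,
                 dimnames = list(sites$variant_id, sprintf("F2_%04d", seq_len(n))))
  with_sim_seed(cross$seed, {
    for (sc in unique(sites$scaffold)) {
      rows <- which(sites$scaffold == sc)
      pos <- sites$pos[rows]
      len <- lens[[sc]]
      for (j in seq_len(n)) {
        geno[rows, j] <- gamete_origin(pos, len, cross$crossovers_per_scaffold) +
          gamete_origin(pos, len, cross$crossovers_per_scaffold)
      }
    }
    structure(list(sites = sites, geno = geno, cross = cross),
              class = "F2Genotypes")
  })
}

# Parental origin (1 = M) of one gamete at the given positions.
gamete_origin <- function(pos, len, rate) {
  phase <- sample(0:1, 1L)
  n_xo <- stats::rpois(1L, rate)
  if (n_xo == 0L) return(rep(phase, length(pos)))
  bp <- sort(stats::runif(n_xo, 1, len))
  (phase + findInterval(pos, bp)) %% 2L
}

#' @export
print.F2Genotypes <- function(x, ...) {
  cat("F2Genotypes:", ncol(x$geno), "plants x", nrow(x$geno), "truth sites\n")
  invisible(x)
}

#' Assign TSS and pH phenotypes to simulated F2 plants
#'
#' Each trait is baseline + the sum of per-QTL contributions (see
#' [qtl_spec()] for the dominance parameterisation) + Gaussian residual
#' noise. Records carry no trait class; see [classify_phenotype()].
#'
#' @param genotypes An `F2Genotypes` object.
#' @param qtls_tss,qtls_ph `QtlSpec` objects for the two traits. Every QTL
#'   must coincide with a truth-variant site.
#' @param seed Integer seed for the residual noise.
#' @return A data.frame of phenotype records: `plant_id`, `generation`,
#'   `tss` (degrees Brix), `ph`.
#' @export
assign_phenotypes <- function(genotypes, qtls_tss, qtls_ph, seed) {
  stopifnot(inherits(genotypes, "F2Genotypes"))
  n <- ncol(genotypes$geno)
  with_sim_seed(seed, {
    tss <- qtl_trait_values(genotypes, qtls_tss) +
      stats::rnorm(n, 0, qtls_tss$residual_sd[1])
    ph <- qtl_trait_values(genotypes, qtls_ph) +
      stats::rnorm(n, 0, qtls_ph$residual_sd[1])
    df(plant_id = colnames(genotypes$geno), generation = "F2",
       tss = tss, ph = ph)
  })
}

# Genetic trait values (baseline + QTL contributions) for all plants.
qtl_trait_values <- function(genotypes, qtls) {
  stopifnot(inherits(qtls, "QtlSpec") || is.data.frame(qtls))
  sites <- genotypes$sites
  value <- rep(qtls$baseline[1], ncol(genotypes$geno))
  for (i in seq_len(nrow(qtls))) {
    row <- which(sites$scaffold == qtls$scaffold[i] & sites$pos == qtls$pos[i])
    if (length(row) != 1L) {
      stop("QTL at ", qtls$scaffold[i], ":", qtls$pos[i],
           " has no matching genotype site", call. = FALSE)
    }
    e <- qtls$effect[i]
    d <- qtls$dominance[i]
    value <- value + c(0, e * (1 + d), 2 * e)[genotypes$geno[row, ] + 1L]
  }
  value
}
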