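#' Run the full super-BSA study emulation
#'
#' End-to-end driver over the simulator and the analysis modules: simulate a
#' reference genome and two homozygous parents carrying the default QTL
#' architecture, self an F1 to an F2 population, phenotype it, select the
#' three extreme bulks, derive SLAF loci by in-silico digestion, simulate
#' pooled allele depths, compute the per-marker ratio statistics and call
#' candidate trait regions with their gene counts.
#'
#' All randomness derives from the single `seed`; sub-steps use seeds
#' derived from it, so a run is fully reproducible.
#'
#' @param seed Integer master seed.
#' @param n_scaffolds,scaffold_len,gene_density,repeat_fraction Genome
#'   parameters (see [make_genome()]). At least 8 scaffolds are needed for
#'   the default QTL layout.
#' @param snp_rate,indel_rate,sv_rate Parental variant rates (see
#'   [make_parents()]); the SNP default emulates the genome-wide SNP density
#'   of a diverged melon cross (a few SNPs per kb).
#' @param n_f2 F2 population size (default 500).
#' @param bulk_size Plants per bulk (default 50).
#' @param crossovers_per_scaffold Expected crossovers per scaffold per
#'   gamete.
#' @param model A `DepthModel`.
#' @param min_run,threshold Region-calling parameters (see
#'   [call_regions()], [compute_ratio()]).
#' @return A list of class `SuperBsaRun` with elements `genome`, `parents`,
#'   `qtls_tss`, `qtls_ph`, `phenotypes`, `bulks`, `loci`, `depths`,
#'   `ratios`, `regions_sweet`, `regions_sour`.
#' @export
run_super_bsa <- function(seed,
                          n_scaffolds = 10, scaffold_len = 4e5,
                          gene_density = 100, repeat_fraction = 0.05,
                          snp_rate = 5e-3, indel_rate = 2e-4, sv_rate = 5e-5,
                          n_f2 = 500, bulk_size = 50,
                          crossovers_per_scaffold = 0.05,
                          model = depth_model(),
                          min_run = 2, threshold = 3) {
  seed <- check_seed(seed)
  ds <- function(k) (abs(seed) %% 1000000L) * 1000L + k

  genome <- make_genome(n_scaffolds, scaffold_len, gene_density,
                        repeat_fraction, seed = ds(1L))
  qtls_tss <- default_qtls(genome, "TSS")
  qtls_ph <- default_qtls(genome, "pH")
  parents <- make_parents(genome, snp_rate, indel_rate, sv_rate,
                          qtls = rbind(qtls_tss, qtls_ph), seed = ds(2L))
  f2 <- simulate_cross(parents, genome,
                       cross_config(n_f2, crossovers_per_scaffold, seed = ds(3L),
                                    bulk_size = bulk_size))
  phenotypes <- assign_phenotypes(f2, qtls_tss, qtls_ph, seed = ds(4L))
  bulks <- select_bulks(phenotypes, bulk_size, method = "extreme-rank")
  loci <- slaf_loci_from_genome(genome, parents)
  depths <- simulate_slaf_depths(f2, bulks, loci, model, seed = ds(5L))
  ratios <- bulk_ratios(depths, threshold = threshold)
  regions_sweet <- call_regions(ratios, trait = "sweet", min_run = min_run)
  regions_sour <- call_regions(ratios, trait = "sour", min_run = min_run)
  if (nrow(regions_sweet)) {
    regions_sweet$gene_number <- count_region_genes(regions_sweet, genome)
  }
  if (nrow(regions_sour)) {
    regions_sour$gene_number <- count_region_genes(regions_sour, genome)
  }
  structure(list(genome = genome, parents = parents, qtls_tss = qtls_tss,
                 qtls_ph = qtls_ph, genotypes = f2, phenotypes = phenotypes,
                 bulks = bulks, loci = loci, depths = depths, ratios = ratios,
                 regions_sweet = regions_sweet, regions_sour = regions_sour,
                 seed = seed),
            class = "SuperBsaRun")
}

#' @export
print.SuperBsaRun <- function(x, ...) {
  cat("SuperBsaRun (seed", x$seed, ")\n")
  cat("  F2 plants:", nrow(x$phenotypes),
      sprintf("| TSS mean %.2f | pH mean %.2f\n",
              mean(x$phenotypes$tss), mean(x$phenotypes$ph)))
  cat("  polymorphic SLAF markers:", nrow(x$ratios), "\n")
  cat("  differential markers: sweet", sum(x$ratios$differential_sweet),
      "| sour", sum(x$ratios$differential_sour), "\n")
  cat("  candidate regions: sweet", nrow(x$regions_sweet),
      "on", paste(unique(x$regions_sweet$scaffold), collapse = ","),
      "| sour", nrow(x$regions_sour),
      "on", paste(unique(x$regions_sour$scaffold), collapse = ","), "\n")
  invisible(x)
}

#' Which planted QTL scaffolds were recovered by called regions
#'
#' @param run A `SuperBsaRun`.
#' @return List with logical vectors `tss_in_sour`, `tss_in_sweet`,
#'   `ph_in_sweet`, `ph_in_sour`, named by QTL scaffold: whether each
#'   planted QTL's scaffold carries at least one called region of the
#'   respective trait.
#' @export
qtl_recovery <- function(run) {
  stopifnot(inherits(run, "SuperBsaRun"))
  hit <- function(qtls, regions) {
    stats::setNames(qtls$scaffold %in% regions$scaffold, qtls$scaffold)
  }
  list(tss_in_sweet = hit(run$qtls_tss, run$regions_sweet),
       tss_in_sour = hit(run$qtls_tss, run$regions_sour),
       ph_in_sweet = hit(run$qtls_ph, run$regions_sweet),
       ph_in_sour = hit(run$qtls_ph, run$regions_sour))
}
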