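test_that("phenotype classification follows the published rules with precedence", {
  expect_equal(classify_phenotype(12.7, 6.1), "sweet")
  expect_equal(classify_phenotype(6.8, 4.4), "sour")
  expect_equal(classify_phenotype(12.6, 4.8), "sweet_and_sour")
  expect_equal(classify_phenotype(7.0, 5.5), "non_sweet_non_sour")
  # the published classes leave gaps: TSS >= 8 with pH <= 5.3 but TSS <= 12
  expect_equal(classify_phenotype(9.0, 5.0), "unclassified")
  # boundary: sweet_and_sour takes precedence over sour-side pH
  expect_equal(classify_phenotype(12.1, 4.9), "sweet_and_sour")
})

test_that("every phenotype receives exactly one class", {
  grid <- expand.grid(tss = seq(4, 16, by = 0.5), ph = seq(3.5, 7, by = 0.1))
  cls <- classify_phenotype(grid$tss, grid$ph)
  expect_false(anyNA(cls))
  expect_true(all(cls %in% c("sweet", "sour", "sweet_and_sour",
                             "non_sweet_non_sour", "unclassified")))
})

test_that("threshold bulk selection takes the most extreme qualifiers", {
  withr::with_seed(121, {
    records <- data.frame(
      plant_id = sprintf("F2_%04d", 1:500),
      tss = c(stats::runif(200, 12.1, 15), stats::runif(300, 5, 7.9)),
      ph = c(stats::runif(200, 6.05, 6.8),
             stats::runif(150, 4.0, 4.9), stats::runif(150, 5.35, 6.5)),
      stringsAsFactors = FALSE)
  })
  pools <- select_bulks(records, bulk_size = 50, method = "threshold")
  expect_true(all(lengths(pools) == 50))
  expect_equal(anyDuplicated(unlist(pools)), 0)
  # sweet pool is the 50 highest-TSS qualifiers
  q <- records[records$tss > 12 & records$ph > 6, ]
  expect_setequal(pools$sweet, q$plant_id[order(-q$tss)][1:50])
  # sour pool is ordered by ascending pH among qualifiers
  qs <- records[records$tss < 8 & records$ph < 5, ]
  expect_setequal(pools$sour, qs$plant_id[order(qs$ph)][1:50])
})

test_that("threshold selection errors name the deficient pool", {
  records <- data.frame(plant_id = c("a", "b", "c"),
                        tss = c(13, 6, 6), ph = c(6.5, 4.5, 5.5),
                        stringsAsFactors = FALSE)
  pools <- select_bulks(records, bulk_size = 1, method = "threshold")
  expect_equal(lengths(pools), c(sweet = 1L, sour = 1L, nsns = 1L))
  expect_error(select_bulks(records, bulk_size = 2, method = "threshold"),
               "sweet.*sour.*nsns|sweet, sour, nsns")
})

test_that("rank-based selection always fills three disjoint extreme pools", {
  withr::with_seed(122, {
    records <- data.frame(plant_id = sprintf("p%03d", 1:300),
                          tss = stats::rnorm(300, 10.9, 1.4),
                          ph = stats::rnorm(300, 5.2, 0.6),
                          stringsAsFactors = FALSE)
  })
  pools <- select_bulks(records, bulk_size = 50, method = "extreme-rank")
  expect_true(all(lengths(pools) == 50))
  expect_equal(anyDuplicated(unlist(pools)), 0)
  # pools sit where they should in phenotype space
  m <- function(ids, col) mean(records[[col]][records$plant_id %in% ids])
  expect_gt(m(pools$sweet, "tss"), m(pools$sour, "tss"))
  expect_gt(m(pools$sweet, "ph"), m(pools$sour, "ph"))
  expect_lt(m(pools$nsns, "tss"), mean(records$tss))
  expect_gt(m(pools$nsns, "ph"), m(pools$sour, "ph"))
  # identical phenotypes leave nothing to rank
  flat <- data.frame(plant_id = sprintf("p%03d", 1:200), tss = 10, ph = 5)
  expect_error(select_bulks(flat, 50, method = "extreme-rank"), "identical")
})

test_that("candidate reporting joins markers, genes, regions and polymorphisms", {
  genes <- data.frame(
    gene_id = c("G1", "G2", "G3"), scaffold = "s1",
    start = c(1000L, 5000L, 9000L), end = c(2000L, 6000L, 9500L),
    annotation = c("sugar transporter", "unknown protein", "kinase"),
    stringsAsFactors = FALSE)
  regions <- data.frame(trait = "sweet", scaffold = "s1",
                        start = 0L, end = 7000L, size = 7000L,
                        n_markers = 2L, markers = "M1,M2",
                        stringsAsFactors = FALSE)
  anchors <- data.frame(
    marker_id = c("M1", "M2", "M3"), chrom = "s1",
    start = c(1500L, 4000L, 9100L), end = c(1580L, 4080L, 9180L),
    stringsAsFactors = FALSE)
  out <- report_candidates(regions, anchors, genes, polymorphic_set = "G1")
  # M1 lies in polymorphic G1; M2 is intergenic; M3 is not a region marker
  expect_equal(nrow(out), 1)
  expect_equal(out$marker_id, "M1")
  expect_equal(out$gene_id, "G1")
  expect_true(out$polymorphic)
  expect_equal(out$annotation, "sugar transporter")
})

test_that("candidate reporting equals a brute-force triple join", {
  withr::with_seed(123, {
    genes <- data.frame(gene_id = sprintf("G%02d", 1:10), scaffold = "s1",
                        start = seq(1000L, 91000L, by = 10000L),
                        stringsAsFactors = FALSE)
    genes$end <- genes$start + 3000L
    genes$annotation <- paste("gene", genes$gene_id)
    anchors <- data.frame(marker_id = sprintf("M%02d", 1:9), chrom = "s1",
                          start = sample.int(95000, 9), stringsAsFactors = FALSE)
    anchors$end <- anchors$start + 80L
    poly <- sample(genes$gene_id, 4)
  })
  regions <- data.frame(trait = "sour", scaffold = "s1", start = 0L,
                        end = 60000L, size = 60000L, n_markers = 9L,
                        markers = paste(anchors$marker_id, collapse = ","),
                        stringsAsFactors = FALSE)
  out <- report_candidates(regions, anchors, genes, poly)
  oracle <- list()
  for (i in seq_len(nrow(anchors))) for (j in seq_len(nrow(genes))) {
    overlaps_gene <- anchors$start[i] <= genes$end[j] &
      anchors$end[i] >= genes$start[j]
    gene_in_region <- genes$start[j] <= regions$end & genes$end[j] >= regions$start
    if (overlaps_gene && gene_in_region) {
      oracle[[length(oracle) + 1]] <- paste(anchors$marker_id[i],
                                            genes$gene_id[j])
    }
  }
  expect_setequal(paste(out$marker_id, out$gene_id), unlist(oracle))
  expect_equal(out$polymorphic, out$gene_id %in% poly)
})
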