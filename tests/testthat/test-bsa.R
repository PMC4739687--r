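test_that("the ratio statistic applies sentinel, threshold and display cap", {
  r <- compute_ratio(30, 10)
  expect_equal(r$ratio, 3)
  expect_true(r$differential)
  r <- compute_ratio(50, 0)
  expect_equal(r$ratio, 1000)
  expect_true(r$differential)
  r <- compute_ratio(100, 1)
  expect_equal(r$ratio, 100)
  expect_equal(r$display, 20)
  expect_true(r$differential)
  # the zero-denominator rule dominates the degenerate 0/0 marker
  r <- compute_ratio(0, 0)
  expect_equal(r$ratio, 1000)
  r <- compute_ratio(2, 10)
  expect_false(r$differential)
  expect_error(compute_ratio(-1, 5), "non-negative")
})

test_that("raising the threshold never increases the differential count", {
  withr::with_seed(101, {
    num <- stats::rpois(500, 40)
    den <- stats::rpois(500, 40)
  })
  counts <- vapply(c(1, 2, 3, 5, 10), function(th) {
    sum(compute_ratio(num, den, threshold = th)$differential)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("parental-origin depth splits sum tag depths per bulk", {
  tag_depths <- data.frame(
    bulk = c("sweet", "sweet", "sour", "sour", "sweet"),
    sequence = c("AAA", "CCC", "AAA", "CCC", "GGG"),
    depth = c(40L, 8L, 5L, 30L, 3L), stringsAsFactors = FALSE)
  expect_message(
    res <- assign_parental_origin(tag_depths, c(M = "AAA", P = "CCC")),
    "neither parent")
  sweet <- res$depths[res$depths$bulk == "sweet", ]
  expect_equal(sweet$M, 40)
  expect_equal(sweet$P, 8)
  expect_false(res$unknown)
})

test_that("region calling reproduces the kb-rounded worked example", {
  markers <- data.frame(
    marker_id = c("SLAF8215", "SLAFx", "SLAF8216"),
    scaffold = "scaffold06", pos = c(861471L, 867000L, 874414L),
    differential = TRUE, stringsAsFactors = FALSE)
  rg <- call_regions(markers, min_run = 2, bin = 1000)
  expect_equal(nrow(rg), 1)
  expect_equal(rg$start, 861000)
  expect_equal(rg$end, 875000)
  expect_equal(rg$size, 14000)
  expect_equal(rg$n_markers, 3)
  # a non-differential marker breaks the run
  broken <- data.frame(marker_id = paste0("m", 1:4), scaffold = "s1",
                       pos = c(100L, 200L, 300L, 400L) * 1000L,
                       differential = c(TRUE, FALSE, TRUE, TRUE),
                       stringsAsFactors = FALSE)
  rg2 <- call_regions(broken, min_run = 2, bin = 1000)
  expect_equal(nrow(rg2), 1)
  expect_equal(rg2$markers, "m3,m4")
  # min_run = 3 enforces the three-marker rule
  expect_equal(nrow(call_regions(broken, min_run = 3, bin = 1000)), 0)
})

test_that("region calling equals an exhaustive run-finding oracle", {
  withr::with_seed(102, {
    markers <- data.frame(
      marker_id = sprintf("m%03d", 1:200),
      scaffold = sample(c("s1", "s2", "s3"), 200, TRUE),
      pos = sample.int(5e6, 200),
      differential = stats::runif(200) < 0.4, stringsAsFactors = FALSE)
  })
  markers <- markers[order(markers$scaffold, markers$pos), ]
  got <- call_regions(markers, min_run = 2, bin = 1000)

  oracle <- list()
  for (sc in unique(markers$scaffold)) {
    m <- markers[markers$scaffold == sc, ]
    i <- 1
    while (i <= nrow(m)) {
      if (m$differential[i]) {
        j <- i
        while (j < nrow(m) && m$differential[j + 1]) j <- j + 1
        if (j - i + 1 >= 2) {
          oracle[[length(oracle) + 1]] <- data.frame(
            scaffold = sc,
            start = (m$pos[i] %/% 1000) * 1000,
            end = ceiling(m$pos[j] / 1000) * 1000,
            markers = paste(m$marker_id[i:j], collapse = ","),
            stringsAsFactors = FALSE)
        }
        i <- j + 1
      } else i <- i + 1
    }
  }
  oracle <- do.call(rbind, oracle)
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$start, oracle$start)
  expect_equal(got$end, oracle$end)
  expect_equal(got$markers, oracle$markers)

  # maximality: every differential marker inside a region belongs to it
  for (k in seq_len(nrow(got))) {
    inside <- markers$scaffold == got$scaffold[k] &
      markers$pos >= got$start[k] & markers$pos <= got$end[k] &
      markers$differential
    expect_true(all(markers$marker_id[inside] %in%
                      strsplit(got$markers[k], ",")[[1]]))
  }

  # unsorted input is sorted internally with a warning, same result
  perm <- withr::with_seed(103, sample(nrow(markers)))
  expect_warning(got2 <- call_regions(markers[perm, ], min_run = 2, bin = 1000),
                 "sort")
  expect_equal(got2$markers, got$markers)
})

test_that("gene counting matches a brute-force interval-overlap scan", {
  regions <- data.frame(scaffold = "s1", start = 5372000L, end = 5401000L)
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), scaffold = "s1",
                      start = c(5380000L, 5400500L, 6000000L),
                      end = c(5381000L, 5402000L, 6001000L),
                      stringsAsFactors = FALSE)
  expect_equal(count_region_genes(regions, genes), 2)
  expect_equal(count_region_genes(data.frame(scaffold = "s2", start = 1L,
                                             end = 10L), genes), 0)
  withr::with_seed(104, {
    genes50 <- data.frame(
      gene_id = sprintf("g%02d", 1:50),
      scaffold = sample(c("s1", "s2"), 50, TRUE),
      start = sample.int(1e6, 50), stringsAsFactors = FALSE)
    genes50$end <- genes50$start + sample.int(5000, 50)
    regions10 <- data.frame(scaffold = sample(c("s1", "s2"), 10, TRUE),
                            start = sample.int(1e6, 10))
    regions10$end <- regions10$start + sample.int(50000, 10)
  })
  got <- count_region_genes(regions10, genes50)
  oracle <- vapply(seq_len(10), function(i) {
    sum(genes50$scaffold == regions10$scaffold[i] &
          genes50$start <= regions10$end[i] &
          genes50$end >= regions10$start[i])
  }, numeric(1))
  expect_equal(as.numeric(got), oracle)
})

test_that("marker density reports Mb per marker", {
  expect_equal(marker_density(0.9e6, 10), 0.09)
  expect_equal(round(marker_density(2.75e6, 14), 1), 0.2)
  expect_equal(marker_density(0, 1), 0)
  expect_error(marker_density(1e6, 0), "at least one")
})

test_that("swapping bulk labels swaps the sweet and sour statistics", {
  withr::with_seed(105, {
    depths <- data.frame(
      locus_id = sprintf("L%02d", 1:40), scaffold = "s1",
      pos = sort(sample.int(1e6, 40)),
      M_sweet = stats::rpois(40, 80), P_sweet = stats::rpois(40, 80),
      M_sour = stats::rpois(40, 80), P_sour = stats::rpois(40, 80),
      M_nsns = stats::rpois(40, 80), P_nsns = stats::rpois(40, 80),
      stringsAsFactors = FALSE)
  })
  r <- bulk_ratios(depths)
  # swap: sweet <-> sour pools and M <-> P allele labels
  swapped <- depths
  swapped$M_sweet <- depths$P_sour
  swapped$P_sour <- depths$M_sweet
  swapped$M_nsns <- depths$P_nsns
  swapped$P_nsns <- depths$M_nsns
  r2 <- bulk_ratios(swapped)
  expect_equal(r2$ratio_sweet, r$ratio_sour)
  expect_equal(r2$ratio_sour, r$ratio_sweet)
})
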