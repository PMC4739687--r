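test_that("coding SNPs are classified by codon translation", {
  g <- toy_coding_genome()
  # codon 2 of the CDS is GAA (positions 14-16); GAA->GAG keeps Glu,
  # GAA->GTA gives Val
  calls <- data.frame(
    scaffold = "chrT", pos = c(16L, 15L, 5L),
    kind = "SNP", ref = c("A", "A", "A"), alt = c("G", "T", "G"),
    stringsAsFactors = FALSE)
  a <- annotate_variants(calls, g)
  expect_equal(a$region_class, c("genic", "genic", "intergenic"))
  expect_equal(a$sub_class, c("exonic", "exonic", "none"))
  expect_equal(a$coding_effect, c("synonymous", "non_synonymous", "none"))
  expect_equal(a$gene_id, c("G1", "G1", ""))
})

test_that("intronic variants and non-SNP exonic variants get no coding effect", {
  seq <- paste(rep(c("A", "C", "G", "T"), 250), collapse = "")
  genes <- data.frame(gene_id = "G2", scaffold = "chrU", start = 101L,
                      end = 400L, strand = "+", annotation = "g2",
                      stringsAsFactors = FALSE)
  cds <- data.frame(gene_id = "G2", scaffold = "chrU",
                    start = c(101L, 301L), end = c(250L, 400L),
                    exon_rank = 1:2, frame = c(0L, 0L),
                    stringsAsFactors = FALSE)
  g <- manual_genome(c(chrU = seq), genes, cds)
  calls <- data.frame(scaffold = "chrU", pos = c(275L, 320L),
                      kind = c("SNP", "DEL"), ref = c("G", "G"),
                      alt = c("A", "G"), stringsAsFactors = FALSE)
  a <- annotate_variants(calls, g)
  expect_equal(a$sub_class, c("intronic", "exonic"))
  expect_equal(a$coding_effect, c("none", "none"))
})

test_that("minus-strand effects agree with whole-CDS translation", {
  withr::with_seed(55, {
    seq <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
    genes <- data.frame(gene_id = "GM", scaffold = "chrV", start = 201L,
                        end = 550L, strand = "-", annotation = "gm",
                        stringsAsFactors = FALSE)
    # coding order on minus strand: rightmost exon first
    cds <- data.frame(gene_id = "GM", scaffold = "chrV",
                      start = c(401L, 201L), end = c(550L, 350L),
                      exon_rank = 1:2, frame = c(0L, 0L),
                      stringsAsFactors = FALSE)
    g <- manual_genome(c(chrV = seq), genes, cds)

    splice_translate <- function(seqstr) {
      pieces <- lapply(order(cds$exon_rank), function(k) {
        p <- Biostrings::DNAString(substr(seqstr, cds$start[k], cds$end[k]))
        Biostrings::reverseComplement(p)
      })
      prot <- Biostrings::translate(do.call(Biostrings::xscat, pieces),
                                    if.fuzzy.codon = "solve")
      as.character(prot)
    }

    chars <- strsplit(seq, "")[[1]]
    exon_pos <- c(201:350, 401:550)
    test_pos <- sample(exon_pos, 25)
    for (pos in test_pos) {
      ref <- chars[pos]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      call <- data.frame(scaffold = "chrV", pos = pos, kind = "SNP",
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
      got <- annotate_variants(call, g)$coding_effect
      mut <- chars
      mut[pos] <- alt
      same_protein <- splice_translate(seq) ==
        splice_translate(paste(mut, collapse = ""))
      expect_equal(got, if (same_protein) "synonymous" else "non_synonymous")
    }
  })
})

test_that("annotation partitions are conserved on a simulated call set", {
  g <- make_genome(2, 50000, 200, 0.1, seed = 61)
  p <- make_parents(g, 2e-3, 1e-4, 5e-5, qtls = NULL, seed = 62)
  calls <- p$truth[, c("scaffold", "pos", "kind", "ref", "alt")]
  a <- annotate_variants(calls, g)
  s <- variant_summary(cbind(calls, a))
  expect_equal(s$counts[["genic"]] + s$counts[["intergenic"]],
               s$counts[["total"]])
  expect_equal(sum(a$sub_class %in% c("exonic", "intronic")),
               s$counts[["genic"]])
  n_exonic_snps <- sum(a$sub_class == "exonic" & calls$kind == "SNP")
  expect_equal(s$counts[["synonymous"]] + s$counts[["non_synonymous"]],
               n_exonic_snps)
  expect_equal(s$transitions + s$transversions, s$counts[["snp"]])
  if (!is.null(s$sv_fractions)) {
    expect_equal(sum(s$sv_fractions), 1, tolerance = 1e-9)
  }
})

test_that("Ts/Tv reflects the substitution process", {
  # uniformly random substitutions: a third are transitions, Ts/Tv -> 0.5
  withr::with_seed(71, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, 10000, TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  })
  s <- variant_summary(data.frame(kind = "SNP", ref = ref, alt = alt,
                                  stringsAsFactors = FALSE))
  p_ts <- 1 / 3
  band <- 3 * sqrt(p_ts * (1 - p_ts) / 10000)
  obs <- s$transitions / 10000
  expect_gt(obs, p_ts - band)
  expect_lt(obs, p_ts + band)
  # a transition-enriched simulator (Ts probability 0.71) gives the
  # Ts/Tv ~ 2.4 regime seen in plant resequencing
  g <- make_genome(2, 500000, 0, 0, seed = 72)
  p <- make_parents(g, 2e-3, 0, 0, qtls = NULL, seed = 73, ts_prob = 0.71)
  s2 <- variant_summary(p$truth)
  expect_gt(s2$ts_tv, 2.1)
  expect_lt(s2$ts_tv, 2.8)
})

test_that("polymorphic genes require non-synonymous SNPs or exonic SVs", {
  snps <- data.frame(coding_effect = c("synonymous", "non_synonymous", "none"),
                     gene_id = c("GA", "GB", ""), stringsAsFactors = FALSE)
  svs <- data.frame(sub_class = c("exonic", "intronic"),
                    gene_id = c("GC", "GD"), stringsAsFactors = FALSE)
  expect_setequal(polymorphic_genes(snps, svs), c("GB", "GC"))
  expect_setequal(polymorphic_genes(snps), "GB")
})

test_that("polymorphic gene calls match a brute-force scan on planted variants", {
  g <- make_genome(1, 50000, 100, 0, seed = 81)
  p <- make_parents(g, 2e-3, 2e-4, 1e-4, qtls = NULL, seed = 82)
  diff <- p$truth[p$truth$carrier != "both", ]
  a <- annotate_variants(diff[, c("scaffold", "pos", "kind", "ref", "alt")], g)
  snps <- cbind(diff, a)[diff$kind == "SNP", ]
  svs <- cbind(diff, a)[diff$kind != "SNP", ]
  got <- polymorphic_genes(snps, svs)

  # oracle: scan every gene for qualifying planted variants
  oracle <- character()
  for (i in seq_len(nrow(g$genes))) {
    gn <- g$genes[i, ]
    cds <- g$cds[g$cds$gene_id == gn$gene_id, ]
    in_exon <- function(pos) any(pos >= cds$start & pos <= cds$end)
    hits <- diff[diff$scaffold == gn$scaffold & diff$pos >= gn$start &
                   diff$pos <= gn$end, ]
    qual <- FALSE
    for (j in seq_len(nrow(hits))) {
      if (!in_exon(hits$pos[j])) next
      if (hits$kind[j] != "SNP") { qual <- TRUE; break }
      eff <- a$coding_effect[diff$variant_id == hits$variant_id[j]]
      if (eff == "non_synonymous") { qual <- TRUE; break }
    }
    if (qual) oracle <- c(oracle, gn$gene_id)
  }
  expect_setequal(got, oracle)
})
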