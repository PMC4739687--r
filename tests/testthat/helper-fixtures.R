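# Shared in-code fixtures: tiny hand-built genomes, parents and genotype
# objects with fully known truth, so tests control every coordinate.

# Build a ReferenceGenome directly from explicit pieces.
manual_genome <- function(seqs, genes = NULL, cds = NULL, repeats = NULL) {
  empty_genes <- data.frame(gene_id = character(), scaffold = character(),
                            start = integer(), end = integer(),
                            strand = character(), annotation = character(),
                            stringsAsFactors = FALSE)
  empty_cds <- data.frame(gene_id = character(), scaffold = character(),
                          start = integer(), end = integer(),
                          exon_rank = integer(), frame = integer(),
                          stringsAsFactors = FALSE)
  empty_rep <- data.frame(scaffold = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  structure(list(scaffolds = Biostrings::DNAStringSet(seqs),
                 genes = genes %||% empty_genes,
                 cds = cds %||% empty_cds,
                 repeats = repeats %||% empty_rep,
                 params = list()),
            class = "ReferenceGenome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal ParentPair from an explicit truth table.
manual_parents <- function(truth, qtls = NULL) {
  structure(list(truth = truth, qtls = qtls, seed = 0L), class = "ParentPair")
}

# Minimal F2Genotypes from explicit sites and genotype matrix.
manual_genotypes <- function(sites, geno) {
  rownames(geno) <- sites$variant_id
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("F2_%04d", seq_len(ncol(geno)))
  }
  structure(list(sites = sites, geno = geno, cross = NULL),
            class = "F2Genotypes")
}

# A tiny plus-strand single-exon gene whose CDS is ATG + 8x GAA + TAA,
# embedded at position 11 of a 50 bp scaffold. Codon arithmetic in the
# annotation tests is done against this layout.
toy_coding_genome <- function() {
  cds_seq <- paste0("ATG", strrep("GAA", 8), "TAA")   # 30 bp
  seq <- paste0(strrep("A", 10), cds_seq, strrep("C", 10))
  genes <- data.frame(gene_id = "G1", scaffold = "chrT", start = 11L,
                      end = 40L, strand = "+", annotation = "toy gene",
                      stringsAsFactors = FALSE)
  cds <- data.frame(gene_id = "G1", scaffold = "chrT", start = 11L, end = 40L,
                    exon_rank = 1L, frame = 0L, stringsAsFactors = FALSE)
  manual_genome(c(chrT = seq), genes, cds)
}

# Random fixed-length tag set: a few seed sequences plus noisy copies, so
# identity clustering has non-trivial structure.
random_tag_set <- function(n_seeds = 5, copies = 5, len = 80, mut = 3,
                           seed = 42) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seeds <- replicate(n_seeds, paste(sample(bases, len, TRUE), collapse = ""))
    tags <- unlist(lapply(seeds, function(s) {
      c(s, replicate(copies - 1, {
        chars <- strsplit(s, "")[[1]]
        at <- sample(len, sample(seq_len(mut), 1))
        chars[at] <- sample(bases, length(at), TRUE)
        paste(chars, collapse = "")
      }))
    }))
    data.frame(tag_id = sprintf("T%03d", seq_along(tags)), sequence = tags,
               depth = 10L, stringsAsFactors = FALSE)
  })
}

# Independent transitive-closure clustering oracle (boolean matrix closure).
closure_partition <- function(seqs, threshold) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && mean(m[i, ] == m[j, ]) > threshold) adj[i, j] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) { cid <- cid + 1L; comp[adj[i, ] > 0] <- cid }
  }
  comp
}

# Partition equality up to label renaming.
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}
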