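test_that("well-formed FASTA files read into per-gene alignments", {
  d <- withr::local_tempdir()
  s1 <- c(tA = strrep("ACG", 100), tB = strrep("ACG", 100),
          tC = strrep("ACT", 100))
  s2 <- c(tA = strrep("GGATTT", 75), tB = strrep("GGATTT", 75),
          tC = strrep("GGATTT", 75))
  f1 <- write_fasta(s1, file.path(d, "g1.fasta"))
  f2 <- write_fasta(s2, file.path(d, "g2.fasta"))
  alns <- read_gene_alignments(c(f1, f2))
  expect_length(alns, 2L)
  expect_equal(alns[[1]]$gene_id, "g1")
  expect_equal(alns[[1]]$length, 300L)
  expect_equal(alns[[2]]$length, 450L)
  expect_equal(names(alns[[1]]$sequences), c("tA", "tB", "tC"))
})

test_that("malformed input is rejected", {
  d <- withr::local_tempdir()
  f <- write_fasta(c(tA = "ACGACG", tB = "ACG"), file.path(d, "bad.fasta"))
  expect_error(read_gene_alignments(f), "unequal")

  f1 <- write_fasta(c(tA = "ACGACG", tB = "ACGACG"), file.path(d, "a.fa"))
  f2 <- write_fasta(c(tA = "ACGACG", tX = "ACGACG"), file.path(d, "b.fa"))
  expect_error(read_gene_alignments(c(f1, f2)), "taxon set")

  expect_error(gene_alignment("g", c(tA = "ACGX", tB = "ACGT")), "invalid")
})

test_that("out-of-frame genes warn and are excluded from concatenation", {
  expect_warning(g <- gene_alignment("g", c(tA = "ACGT", tB = "ACGT")),
                 "out-of-frame")
  expect_false(g$in_frame)
  g2 <- gene_alignment("h", c(tA = "ACGACG", tB = "ACGACG"))
  aln <- suppressWarnings(concatenate_genes(list(g, g2)))
  expect_equal(nrow(aln$gene_spans), 1L)
  expect_error(concatenate_genes(list(g, g2), keep = c("g", "h")),
               "out-of-frame")
})

test_that("single-copy/full-length filter applies the selection rule", {
  tab <- data.frame(
    gene_id   = c("geneA", "geneA", "geneA",
                  "geneB", "geneB", "geneB",
                  "geneC", "geneC", "geneC"),
    genome_id = rep(c("g1", "g2", "g3"), 3),
    copy_count = c(1, 1, 1,  1, 2, 1,  1, 1, 1),
    length     = c(300, 300, 300,  90, 90, 90,  150, 150, 153))
  expect_equal(filter_single_copy_full_length(tab, c("g1", "g2", "g3")),
               "geneA")
  expect_equal(filter_single_copy_full_length(tab[0, ], c("g1", "g2")),
               character(0))
  all_ok <- tab[tab$gene_id == "geneA", ]
  expect_equal(filter_single_copy_full_length(all_ok, c("g1", "g2", "g3")),
               "geneA")
  # a gene with a missing row counts as absent
  expect_equal(filter_single_copy_full_length(tab[-1, ], c("g1", "g2", "g3")),
               character(0))
})

test_that("adding a genome never grows the filtered gene set", {
  set.seed(7)
  for (rep in 1:20) {
    genomes <- paste0("g", 1:4)
    genes <- paste0("gene", 1:8)
    tab <- expand.grid(gene_id = genes, genome_id = genomes,
                       stringsAsFactors = FALSE)
    tab$copy_count <- sample(0:2, nrow(tab), replace = TRUE, prob = c(.2, .6, .2))
    tab$length <- sample(c(300, 303), nrow(tab), replace = TRUE)
    s3 <- filter_single_copy_full_length(tab, genomes[1:3])
    s4 <- filter_single_copy_full_length(tab, genomes)
    expect_true(all(s4 %in% s3))
  }
})

test_that("concatenation lays out spans in input order with per-gene frames", {
  g1 <- gene_alignment("g1", c(tA = strrep("AAA", 100), tB = strrep("AAA", 100)))
  g2 <- gene_alignment("g2", c(tA = strrep("CCG", 150), tB = strrep("CCG", 150)))
  aln <- concatenate_genes(list(g1, g2))
  expect_equal(ncol(aln$seq), 750L)
  expect_equal(aln$gene_spans$start, c(1L, 301L))
  expect_equal(aln$gene_spans$end, c(300L, 750L))
  # first site of the second gene is codon position 1 despite global offset
  expect_equal(aln$position_index[301], 1L)
  pos <- codon_positions(aln)
  expect_equal(lengths(pos), c(`1` = 250L, `2` = 250L, `3` = 250L))
  expect_equal(sort(unlist(pos)), 1:750, ignore_attr = TRUE)

  empty <- concatenate_genes(list(g1, g2), keep = character(0))
  expect_equal(ncol(empty$seq), 0L)
})

test_that("codon-position sets are disjoint and exhaustive on simulated genes", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  sim <- simulate_codon_alignment(tree, rates = c(.01, .01, .02),
                                  gene_lengths = c(40, 33, 50, 21, 60),
                                  seed = 5)
  aln <- sim$alignment
  pos <- codon_positions(aln)
  expect_equal(sum(lengths(pos)), ncol(aln$seq))
  expect_equal(length(Reduce(intersect, pos)), 0L)
  expect_true(all(lengths(pos) == ncol(aln$seq) / 3))
})

test_that("write-then-read round-trips the alignment matrix exactly", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  sim <- simulate_codon_alignment(tree, rates = 0.02,
                                  gene_lengths = c(30, 45, 21, 60, 24),
                                  seed = 11)
  d <- withr::local_tempdir()
  fa <- file.path(d, "aln.fasta"); sp <- file.path(d, "spans.tsv")
  write_codon_alignment(sim$alignment, fa, sp)
  back <- read_codon_alignment(fa, sp)
  expect_identical(back$seq, sim$alignment$seq)
  expect_equal(back$gene_spans, sim$alignment$gene_spans)
  expect_identical(back$position_index, sim$alignment$position_index)
})

test_that("ortholog tables require the documented columns", {
  d <- withr::local_tempdir()
  p <- file.path(d, "orth.tsv")
  df <- data.frame(gene_id = "g", genome_id = "x", copy_count = 1, length = 3)
  write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_ortholog_table(p)$gene_id, "g")
  write.table(df[, -4], p, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_ortholog_table(p), "lacks columns")
})
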