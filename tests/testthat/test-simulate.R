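test_that("identical seeds give byte-identical simulations", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  s1 <- simulate_codon_alignment(tree, rates = c(.01, .02, .05),
                                 n_codons = 800, seed = 61)
  s2 <- simulate_codon_alignment(tree, rates = c(.01, .02, .05),
                                 n_codons = 800, seed = 61)
  expect_identical(s1$alignment$seq, s2$alignment$seq)
  expect_identical(s1$truth$pairwise_differences,
                   s2$truth$pairwise_differences)

  cfg <- scenario_config("introgression", symbiont_bp = 9000,
                         n_symbiont_genes = 9, n_nuclear_genes = 2,
                         nuclear_gene_codons = 100, mito_bp = 3000,
                         seed = 62)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  expect_identical(a$symbiont$alignment$seq, b$symbiont$alignment$seq)
})

test_that("zero rates leave all taxa identical", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  s <- simulate_codon_alignment(tree, rates = 0, n_codons = 200, seed = 63)
  expect_equal(s$truth$pairwise_differences$total, c(0L, 0L, 0L))
  expect_identical(s$alignment$seq["a", ], s$alignment$seq["c", ])
})

test_that("simulated alignments carry no stop codons in any taxon", {
  tree <- ape::read.tree(text = "(a:1,b:1);")
  s <- simulate_codon_alignment(tree, rates = 0.1, n_codons = 3000,
                                seed = 64)
  code <- Biostrings::GENETIC_CODE
  for (t in c("a", "b")) {
    x <- s$alignment$seq[t, ]
    m <- matrix(x, nrow = 3)
    codons <- paste0(m[1, ], m[2, ], m[3, ])
    expect_false(any(code[codons] == "*"))
  }
})

test_that("realized difference counts match the analytic expectation", {
  # neutral, omega = 1: expected pairwise differences ~ 2 * r_p * t * L_p
  tree <- ape::read.tree(text = "(a:1,b:1);")
  r <- c(1e-3, 2e-3, 5e-3); L <- 30000
  set.seed(65)
  diffs <- replicate(40, {
    s <- simulate_codon_alignment(tree, rates = r, n_codons = L)
    unlist(s$truth$pairwise_differences[1, c("pos1", "pos2", "pos3")])
  })
  expected <- 2 * r * L
  for (p in 1:3) {
    se <- sqrt(expected[p] / 40)
    # stop-codon rejection slightly depresses the realized rate, well
    # within a few percent at these divergences
    expect_lt(abs(mean(diffs[p, ]) - expected[p]), 4 * se + 0.04 * expected[p])
  }
})

test_that("scenario configuration enforces mode constraints", {
  expect_error(scenario_config("cladogenic", transfer_time = 1.5))
  expect_error(scenario_config("cladogenic", symbiont_bp = 1000))
  cfg_i <- scenario_config("introgression")
  expect_equal(cfg_i$t_mito, cfg_i$t_symb)
  expect_lt(cfg_i$t_symb, 1)
  cfg_h <- scenario_config("horizontal")
  expect_lt(cfg_h$t_symb, cfg_h$t_mito)
  cfg_c <- scenario_config("cladogenic")
  expect_equal(cfg_c$t_symb, 1)
})

test_that("each emitted track validates against its truth table", {
  cfg <- scenario_config("horizontal", symbiont_bp = 60000,
                         n_symbiont_genes = 20, seed = 66)
  scn <- simulate_scenario(cfg)
  tt <- scn$symbiont$truth$pairwise_differences
  w <- paste0("w_", cfg$taxa)
  dc <- count_pairwise_differences(scn$symbiont$alignment, w[1], w[2])
  expect_equal(dc$differences, tt$total[tt$taxon_a == w[1] &
                                          tt$taxon_b == w[2]])
  # gene lengths add up
  expect_equal(ncol(scn$symbiont$alignment$seq), cfg$symbiont_bp)
  expect_equal(ncol(scn$nuclear$alignment$seq),
               3 * cfg$n_nuclear_genes * cfg$nuclear_gene_codons)
})

test_that("scenario truth recovery: estimated divergences classify correctly", {
  # cladogenic at the Nasonia calibration ratio
  scn_c <- simulate_scenario(scenario_config(
    "cladogenic", calibration_ratio = 0.30, symbiont_bp = 150000,
    n_symbiont_genes = 150, seed = 67))
  expect_equal(analyze_scenario(scn_c)$mode, "cladogenic_plausible")

  # introgression: symbiont and mito young together
  scn_i <- simulate_scenario(scenario_config("introgression", seed = 68))
  expect_equal(analyze_scenario(scn_i)$mode, "introgression")

  # horizontal: symbiont younger than mito
  scn_h <- simulate_scenario(scenario_config("horizontal", seed = 69))
  expect_equal(analyze_scenario(scn_h)$mode, "horizontal")

  # without mito the rejected call degrades to noncladogenic_transfer
  expect_equal(analyze_scenario(scn_h, use_mito = FALSE)$mode,
               "noncladogenic_transfer")
})

test_that("study presets expose the fixture geometry", {
  p <- wri_like_preset()
  expect_equal(sum(p$gene_lengths) * 3, 704883)
  expect_equal(length(p$gene_lengths), 703)
  expect_equal(unname(p$true_ages["root"]), 3.51)
  p48 <- wri_like_preset(48000, 48)
  expect_equal(sum(p48$gene_lengths) * 3, 48000)
  # rates scale to preserve expected variant counts
  expect_equal(p48$rates / p$rates, rep(704883 / 48000, 3))

  h <- host_like_preset()
  expect_equal(length(h$tree$tip.label), 5L)
  expect_equal(sum(h$gene_lengths), 9000)
  expect_equal(unname(h$true_ages[c("outgroup", "melsim")]), c(1.96, 0.72))
})
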