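tiny_tree <- ape::read.tree(text = "((a:1,b:1):1,c:2);")

test_that("zero rates give finite likelihood only for identical sequences", {
  base <- strrep("ATGGCTTGC", 40)
  aln <- toy_alignment(c(a = base, b = base, c = base))
  ll0 <- clock_log_likelihood(aln, tiny_tree, ages = c(2, 1),
                              rates = c(0, 0, 0), kappa = 1,
                              freqs = rep(0.25, 4))
  expect_true(is.finite(ll0))

  b2 <- base
  substr(b2, 5, 5) <- "A"
  aln2 <- toy_alignment(c(a = base, b = b2, c = base))
  ll <- clock_log_likelihood(aln2, tiny_tree, ages = c(2, 1),
                             rates = c(0, 0, 0), kappa = 1,
                             freqs = rep(0.25, 4))
  expect_identical(ll, -Inf)
})

test_that("likelihood is invariant to the rate/time rescaling", {
  sim <- simulate_codon_alignment(tiny_tree, rates = c(.01, .02, .05),
                                  n_codons = 1500, seed = 23)
  aln <- sim$alignment
  ll1 <- clock_log_likelihood(aln, tiny_tree, ages = c(2, 1),
                              rates = c(.01, .02, .05))
  ll2 <- clock_log_likelihood(aln, tiny_tree, ages = c(4, 2),
                              rates = c(.005, .01, .025))
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("invalid age assignments are rejected", {
  sim <- simulate_codon_alignment(tiny_tree, rates = .01, n_codons = 300,
                                  seed = 3)
  expect_error(clock_log_likelihood(sim$alignment, tiny_tree,
                                    ages = c(-1, 1), rates = rep(.01, 3)),
               "negative")
  expect_error(clock_log_likelihood(sim$alignment, tiny_tree,
                                    ages = c(0.5, 1), rates = rep(.01, 3)),
               "topology")
})

test_that("two-taxon maximum likelihood equals the corrected distance", {
  # under JC (kappa = 1, uniform frequencies) the ML expected number of
  # substitutions between two taxa is the closed-form corrected distance
  two <- ape::read.tree(text = "(a:1,b:1);")
  n <- 3000
  base <- strrep("ACGTCA", n / 6)
  nd <- 300                                 # p = 0.1
  b2 <- base
  for (i in seq_len(nd)) {
    ch <- substr(base, 10 * i, 10 * i)
    substr(b2, 10 * i, 10 * i) <- setdiff(c("A", "C", "G", "T"), ch)[1]
  }
  aln <- toy_alignment(c(a = base, b = b2))
  opt <- optimize(function(r)
    clock_log_likelihood(aln, two, ages = 1, rates = rep(r, 3), kappa = 1,
                         freqs = rep(0.25, 4)),
    c(1e-6, 1), maximum = TRUE)
  p <- nd / n
  d_jc <- -0.75 * log(1 - 4 * p / 3)
  expect_equal(2 * opt$maximum, d_jc, tolerance = 0.01)
})

test_that("symmetric trio root age approximates the distance ratio", {
  # d(ab) = x, d(ac) = d(bc) = y at small divergence => root age ~ y/x
  L <- 30000
  base <- strrep("ATGGCTACTGGC", L / 12)
  a <- base; b <- base; c_ <- base
  flip <- function(s, i, to) { substr(s, i, i) <- to; s }
  # 60 a/b differences, split so c matches each equally often
  for (i in 1:30) a <- flip(a, 2 * i, "A")
  for (i in 31:60) b <- flip(b, 2 * i, "A")
  # 90 further sites where c differs from both
  for (i in 1:90) c_ <- flip(c_, 200 + 3 * i, "A")
  aln <- toy_alignment(c(a = a, b = b, c = c_))
  fit <- chronogram(aln, tiny_tree, reference = c("a", "b"))
  x <- count_pairwise_differences(aln, "a", "b")$differences / L
  y <- count_pairwise_differences(aln, "a", "c")$differences / L
  expect_equal(node_age(fit, c("a", "c"))$age, y / x, tolerance = 0.06)
})

test_that("the reference node age is exactly 1 and ages order correctly", {
  sim <- simulate_codon_alignment(tiny_tree, rates = c(.004, .002, .01),
                                  n_codons = 5000, seed = 29)
  fit <- chronogram(sim$alignment, tiny_tree, reference = c("a", "b"))
  expect_identical(node_age(fit, c("a", "b"))$age, 1)
  expect_gt(node_age(fit, c("a", "c"))$age, 1)  # parent older than child
  expect_equal(unname(coef(fit)[["kappa"]]), fit$kappa)
  expect_s3_class(logLik(fit), "logLik")
})

test_that("chronogram recovers a known age ratio with bootstrap intervals", {
  p <- wri_like_preset(total_bp = 48000, n_genes = 16, ratio = 3.51)
  sim <- simulate_codon_alignment(p$tree, p$rates,
                                  gene_lengths = p$gene_lengths, seed = 37)
  fit <- chronogram(sim$alignment, p$tree, p$reference, bootstrap = 30,
                    seed = 38)
  ra <- node_age(fit, c("wSuz", "wRi"))
  expect_gt(ra$age, 1.5)
  expect_lt(ra$lower, ra$age)
  expect_gt(ra$upper, ra$age)
  s <- summary(fit)
  expect_true(all(c("age", "lower", "upper") %in% names(s$nodes)))
})

test_that("parametric simulation from a fit is reproducible", {
  sim <- simulate_codon_alignment(tiny_tree, rates = .01, n_codons = 1000,
                                  seed = 41)
  fit <- chronogram(sim$alignment, tiny_tree, reference = c("a", "b"))
  s1 <- simulate(fit, nsim = 1, seed = 5)[[1]]
  s2 <- simulate(fit, nsim = 1, seed = 5)[[1]]
  expect_identical(s1$seq, s2$seq)
  expect_equal(ncol(s1$seq), 3000L)
})

test_that("clock simulator matches analytic pairwise expectations", {
  # expected pairwise differences at position p: about 2 * r_p * t * L_p
  two <- ape::read.tree(text = "(a:1,b:1);")
  r <- c(2e-3, 1e-3, 4e-3); L <- 20000
  set.seed(43)
  diffs <- replicate(30, {
    aln <- simulate_clock_alignment(two, ages = 1, rates = r, kappa = 1,
                                    freqs = rep(0.25, 4), n_codons = L)
    count_pairwise_differences(aln, "a", "b")$per_position$differences
  })
  expected <- 2 * r * L
  for (p in 1:3) {
    se <- sqrt(expected[p] / 30)
    expect_lt(abs(mean(diffs[p, ]) - expected[p]), 4 * se)
  }
})
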