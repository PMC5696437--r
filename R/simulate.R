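## Synthetic-data generators: coding alignments evolved under a strict
## clock with per-codon-position rates and rejection-tuned ka/ks, the
## three acquisition scenarios, and read-depth profiles with planted CNVs.

#' Simulate a coding alignment under a strict clock with selection
#'
#' Sites evolve independently under an event-based continuous-time chain:
#' at codon position p, change proposals arrive at rate `rates[p]` per
#' unit branch duration and move to one of the three other bases uniformly
#' (kappa = 1, uniform frequencies). A proposal creating a stop codon is
#' always rejected; a nonsynonymous proposal is accepted with probability
#' `omega` (synonymous proposals always) — rejection-tuning the realized
#' ka/ks toward `omega`. The root sequence is uniform over the 61 sense
#' codons.
#'
#' @param tree Rooted `phylo` with branch lengths in (relative) time.
#' @param rates Per-codon-position substitution rates per unit time
#'   (length 3, or length 1 recycled).
#' @param omega Target ka/ks in (0, 1]; 1 = no selection.
#' @param n_codons Total codons (ignored when `gene_lengths` given).
#' @param gene_lengths Integer vector of codons per gene; genes are
#'   emitted as separate [gene_alignment()]s and concatenated.
#' @param seed Optional RNG seed.
#' @return A list of class `codiv_sim`: `alignment` (`codon_alignment`),
#'   `genes` (list of `gene_alignment`), and `truth` (parameters plus
#'   realized pairwise difference counts per codon position).
#' @export
simulate_codon_alignment <- function(tree, rates, omega = 1,
                                     n_codons = NULL, gene_lengths = NULL,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must carry branch durations")
  if (length(rates) == 1L) rates <- rep(rates, 3L)
  stopifnot(length(rates) == 3L, all(rates >= 0))
  if (!(omega > 0 && omega <= 10)) stop("omega must be in (0, 10]")
  if (is.null(gene_lengths)) {
    stopifnot(!is.null(n_codons))
    gene_lengths <- n_codons
  }
  n_codons <- sum(gene_lengths)
  code <- genetic_code()
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge; elen <- tr$edge.length
  root <- ntip + 1L
  L <- 3L * n_codons
  pos_rate <- rates[rep_len(1:3, L)]

  root_codons <- sample(sense_codons(), n_codons, replace = TRUE)
  states <- vector("list", max(edge))
  states[[root]] <- unlist(strsplit(root_codons, "", fixed = TRUE),
                           use.names = FALSE)
  ## ALT[b, j]: the j-th alternative base to b (uniform proposal kernel)
  ALT <- t(vapply(BASES, function(b) setdiff(BASES, b), character(3)))
  n_proposed <- 0L; n_accepted <- 0L
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    s <- states[[par]]
    k <- rpois(L, pos_rate * elen[e])
    ## process one proposal per site per round so codon context stays
    ## current; simultaneous proposals within one codon are serialized
    while (any(k > 0L)) {
      sites <- which(k > 0L)
      k[sites] <- k[sites] - 1L
      cidx <- (sites - 1L) %/% 3L
      multi <- duplicated(cidx) | duplicated(cidx, fromLast = TRUE)
      batches <- c(list(sites[!multi]), as.list(sites[multi]))
      for (v in batches) {
        v <- as.integer(v)
        if (!length(v)) next
        n <- length(v)
        n_proposed <- n_proposed + n
        c0 <- 3L * ((v - 1L) %/% 3L)
        off <- v - c0
        oldc <- paste0(s[c0 + 1L], s[c0 + 2L], s[c0 + 3L])
        to <- ALT[cbind(match(s[v], BASES),
                        sample.int(3L, n, replace = TRUE))]
        newc <- oldc
        substr(newc, off, off) <- to
        aa_old <- code[oldc]; aa_new <- code[newc]
        accept <- aa_new != "*" &
          (aa_new == aa_old | runif(n) <= min(omega, 1))
        s[v[accept]] <- to[accept]
        n_accepted <- n_accepted + sum(accept)
      }
    }
    states[[ch]] <- s
  }

  taxa <- tr$tip.label
  seqmat <- do.call(rbind, states[seq_len(ntip)])
  rownames(seqmat) <- taxa
  ends <- cumsum(3L * gene_lengths)
  starts <- ends - 3L * gene_lengths + 1L
  spans <- data.frame(gene_id = sprintf("gene%04d", seq_along(gene_lengths)),
                      start = starts, end = ends, stringsAsFactors = FALSE)
  aln <- new_codon_alignment(seqmat, spans)
  genes <- lapply(seq_len(nrow(spans)), function(i) {
    seqs <- apply(seqmat[, starts[i]:ends[i], drop = FALSE], 1L,
                  paste, collapse = "")
    gene_alignment(spans$gene_id[i], seqs)
  })

  pairs <- utils::combn(taxa, 2L)
  truth_diffs <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- seqmat[pairs[1L, j], ]; b <- seqmat[pairs[2L, j], ]
    d <- a != b
    pos <- rep_len(1:3, L)
    data.frame(taxon_a = pairs[1L, j], taxon_b = pairs[2L, j],
               pos1 = sum(d[pos == 1L]), pos2 = sum(d[pos == 2L]),
               pos3 = sum(d[pos == 3L]), total = sum(d),
               stringsAsFactors = FALSE)
  }))
  structure(list(alignment = aln, genes = genes,
                 truth = list(tree = tr, rates = rates, omega = omega,
                              n_codons = n_codons,
                              pairwise_differences = truth_diffs,
                              proposals = n_proposed,
                              substitutions = n_accepted)),
            class = "codiv_sim")
}

#' @export
print.codiv_sim <- function(x, ...) {
  cat(sprintf("<codiv_sim> %d taxa, %d genes, %d codons, %d substitutions\n",
              length(x$alignment$taxa), length(x$genes),
              x$truth$n_codons, x$truth$substitutions))
  invisible(x)
}

## evenly distribute n codons over k genes
split_codons <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  c(rep(base + 1L, extra), rep(base, k - extra))
}

two_clade_tree <- function(taxa, focal_age, outgroup_age) {
  txt <- sprintf("((%s:%g,%s:%g):%g,%s:%g);", taxa[1], focal_age,
                 taxa[2], focal_age, outgroup_age - focal_age,
                 taxa[3], outgroup_age)
  ape::read.tree(text = txt)
}

#' Configure an acquisition scenario
#'
#' Defines the study conditions for a three-genome experiment: a host
#' species pair plus outgroup, with nuclear, mitochondrial and symbiont
#' tracks that share the host topology but whose focal divergence times
#' depend on the acquisition mode. Under cladogenic transmission all three
#' coalesce at the host split (relative time 1); under introgression the
#' mitochondrion and symbiont both coalesce at `transfer_time`; under
#' horizontal transmission only the symbiont does.
#'
#' Divergence scales default to the focal system's magnitudes: host
#' nuclear pairwise divergence per codon position
#' `c(1.10e-2, 4.73e-3, 9.20e-2)` (silent-site k_s about 0.12), symbiont
#' silent divergence `calibration_ratio` times the host's, and a
#' mitochondrial clock `mito_rate_ratio` times the nuclear silent rate.
#'
#' @param mode `"cladogenic"`, `"introgression"` or `"horizontal"`.
#' @param taxa Three host labels: species pair then outgroup.
#' @param host_divergence Pairwise nuclear divergence of the focal pair
#'   per codon position (at relative time 1).
#' @param host_ks Nominal silent-site divergence of the focal pair.
#' @param outgroup_age Outgroup divergence in units of the focal host
#'   split.
#' @param calibration_ratio Symbiont/host k_s ratio under codivergence
#'   used to set the symbiont clock.
#' @param transfer_time Transfer time as a fraction of the host split age
#'   (introgression and horizontal modes).
#' @param mito_rate_ratio Mitochondrial/nuclear silent rate ratio.
#' @param n_nuclear_genes,nuclear_gene_codons Nuclear track size.
#' @param symbiont_bp,n_symbiont_genes Symbiont track size (total bp must
#'   be divisible by 3).
#' @param mito_bp Mitochondrial locus length (single non-recombining
#'   locus).
#' @param seed RNG seed for [simulate_scenario()].
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(mode = c("cladogenic", "introgression",
                                     "horizontal"),
                            taxa = c("hostA", "hostB", "outgroup"),
                            host_divergence = c(1.10e-2, 4.73e-3, 9.20e-2),
                            host_ks = 0.12,
                            outgroup_age = 1.96,
                            calibration_ratio = 0.13,
                            transfer_time = 0.005,
                            mito_rate_ratio = 5,
                            n_nuclear_genes = 18,
                            nuclear_gene_codons = 500,
                            symbiont_bp = 704883,
                            n_symbiont_genes = 703,
                            mito_bp = 15000,
                            seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(taxa) == 3L, symbiont_bp %% 3 == 0, mito_bp %% 3 == 0,
            outgroup_age > 1, transfer_time > 0, transfer_time < 1,
            all(host_divergence > 0), host_ks > 0, calibration_ratio > 0)
  t_symb <- switch(mode, cladogenic = 1, introgression = transfer_time,
                   horizontal = transfer_time)
  t_mito <- switch(mode, cladogenic = 1, introgression = transfer_time,
                   horizontal = 1)
  structure(list(mode = mode, taxa = taxa,
                 host_divergence = host_divergence, host_ks = host_ks,
                 outgroup_age = outgroup_age,
                 calibration_ratio = calibration_ratio,
                 transfer_time = transfer_time, t_symb = t_symb,
                 t_mito = t_mito, mito_rate_ratio = mito_rate_ratio,
                 n_nuclear_genes = n_nuclear_genes,
                 nuclear_gene_codons = nuclear_gene_codons,
                 symbiont_bp = symbiont_bp,
                 n_symbiont_genes = n_symbiont_genes, mito_bp = mito_bp,
                 seed = seed),
            class = "scenario_config")
}

#' Simulate the three genomic tracks of an acquisition scenario
#'
#' @param config A [scenario_config()].
#' @return A list of class `codiv_scenario` with elements `nuclear`,
#'   `mito`, `symbiont` (each a `codiv_sim`) and `truth` (the track
#'   divergence times, expected divergences, and the mitochondrial rate
#'   ratio needed to put mito divergence on the nuclear scale).
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  symb_taxa <- paste0("w_", cfg$taxa)
  nuc_tree <- two_clade_tree(cfg$taxa, 1, cfg$outgroup_age)
  mito_tree <- two_clade_tree(paste0("mt_", cfg$taxa), cfg$t_mito,
                              cfg$outgroup_age)
  symb_tree <- two_clade_tree(symb_taxa, cfg$t_symb, cfg$outgroup_age)

  nuc_rates <- cfg$host_divergence / 2        # pairwise -> per lineage
  symb_rate <- cfg$calibration_ratio * cfg$host_ks / 2
  mito_rate <- cfg$mito_rate_ratio * cfg$host_ks / 2

  nuclear <- simulate_codon_alignment(
    nuc_tree, nuc_rates,
    gene_lengths = rep(cfg$nuclear_gene_codons, cfg$n_nuclear_genes))
  mito <- simulate_codon_alignment(mito_tree, rep(mito_rate, 3L),
                                   n_codons = cfg$mito_bp %/% 3L)
  symbiont <- simulate_codon_alignment(
    symb_tree, rep(symb_rate, 3L),
    gene_lengths = split_codons(cfg$symbiont_bp %/% 3L,
                                cfg$n_symbiont_genes))

  truth <- list(
    mode = cfg$mode,
    divergence_times = c(nuclear = 1, mito = cfg$t_mito,
                         symbiont = cfg$t_symb),
    expected = list(
      nuclear_pairwise = cfg$host_divergence,
      symbiont_divergence = cfg$calibration_ratio * cfg$host_ks * cfg$t_symb,
      mito_divergence = cfg$mito_rate_ratio * cfg$host_ks * cfg$t_mito),
    mito_rate_ratio = cfg$mito_rate_ratio,
    config = cfg)
  structure(list(nuclear = nuclear, mito = mito, symbiont = symbiont,
                 truth = truth),
            class = "codiv_scenario")
}

#' @export
print.codiv_scenario <- function(x, ...) {
  cat(sprintf("<codiv_scenario> mode = %s\n", x$truth$mode))
  cat(sprintf("  divergence times (host split = 1): nuclear 1, mito %g, symbiont %g\n",
              x$truth$divergence_times["mito"],
              x$truth$divergence_times["symbiont"]))
  invisible(x)
}

#' Estimate divergences from a simulated scenario and classify it
#'
#' Runs the analysis pipeline on a [simulate_scenario()] result: host
#' nuclear and symbiont silent-site rates via [kaks_pair()], the
#' mitochondrial divergence rescaled to the nuclear silent scale by the
#' assumed mitochondrial rate ratio, then [classify_transmission()].
#'
#' @param scenario A `codiv_scenario`.
#' @param calibrations Calibration table (default
#'   [wolbachia_calibrations()]).
#' @param use_mito Pass the mitochondrial divergence to the classifier?
#' @return The `transmission_call`, with the estimated divergences
#'   attached as attribute `"estimates"`.
#' @export
analyze_scenario <- function(scenario, calibrations = wolbachia_calibrations(),
                             use_mito = TRUE) {
  stopifnot(inherits(scenario, "codiv_scenario"))
  cfg <- scenario$truth$config
  host <- kaks_pair(scenario$nuclear$alignment, cfg$taxa[1], cfg$taxa[2])
  symb <- kaks_pair(scenario$symbiont$alignment,
                    paste0("w_", cfg$taxa[1]), paste0("w_", cfg$taxa[2]))
  mito_div <- NULL
  if (use_mito) {
    mdc <- count_pairwise_differences(scenario$mito$alignment,
                                      paste0("mt_", cfg$taxa[1]),
                                      paste0("mt_", cfg$taxa[2]))
    mito_div <- (mdc$differences / mdc$sites) / scenario$truth$mito_rate_ratio
  }
  call <- classify_transmission(nuclear_div = host$ks,
                                symbiont_div = symb$ks,
                                mito_div = mito_div,
                                calibrations = calibrations)
  attr(call, "estimates") <- list(host_ks = host$ks, host_ka = host$ka,
                                  symbiont_ks = symb$ks,
                                  symbiont_ka = symb$ka,
                                  mito_div_scaled = mito_div)
  call
}

#' Symbiont-track study fixture (wRi-like)
#'
#' Three wRi-like Wolbachia on the topology ((wSuz, wSpc), wRi): reference
#' node (the wSuz-wSpc split) at relative age 1, root at `ratio` (default
#' 3.51). At the full 704,883-bp size the per-position rates put the
#' sister-pair divergence at the observed few-times-1e-5 scale; when
#' `total_bp` is reduced the rates are scaled up by `704883 / total_bp`
#' so the expected numbers of variants (~28 within the pair, ~100 to the
#' outgroup) are preserved.
#'
#' @param total_bp Alignment size in bp (divisible by 3).
#' @param n_genes Number of genes the codons are split across.
#' @param ratio True root age relative to the reference node.
#' @return List with `tree`, `rates`, `gene_lengths`, `reference` and
#'   `true_ages`.
#' @export
wri_like_preset <- function(total_bp = 704883, n_genes = 703,
                            ratio = 3.51) {
  stopifnot(total_bp %% 3 == 0)
  base_rates <- c(2.5e-5, 1.6e-5, 2.0e-5)   # per lineage per unit time
  scale <- 704883 / total_bp
  tree <- ape::read.tree(text = sprintf(
    "((wSuz:1,wSpc:1):%g,wRi:%g);", ratio - 1, ratio))
  list(tree = tree, rates = base_rates * scale,
       gene_lengths = split_codons(total_bp %/% 3L, n_genes),
       reference = c("wSuz", "wSpc"),
       true_ages = c(reference = 1, root = ratio))
}

#' Host-track study fixture
#'
#' Five melanogaster-group hosts: the focal sister pair (reference node,
#' age 1), their outgroup at 1.96, a melanogaster/simulans pair at 0.72,
#' root at 2.5. Per-position rates give the focal pair the observed
#' nuclear pairwise divergences (1.10e-2, 4.73e-3, 9.20e-2).
#'
#' @param n_genes,gene_codons Fixture size: `n_genes` genes of
#'   `gene_codons` codons.
#' @return List with `tree`, `rates`, `gene_lengths`, `reference` and
#'   `true_ages` (the two benchmark relative ages 1.96 and 0.72).
#' @export
host_like_preset <- function(n_genes = 18, gene_codons = 500) {
  tree <- ape::read.tree(text = paste0(
    "(((suzukii:1,subpulchrella:1):0.96,biarmipes:1.96):0.54,",
    "(melanogaster:0.72,simulans:0.72):1.78);"))
  list(tree = tree, rates = c(1.10e-2, 4.73e-3, 9.20e-2) / 2,
       gene_lengths = rep(gene_codons, n_genes),
       reference = c("suzukii", "subpulchrella"),
       true_ages = c(reference = 1, outgroup = 1.96, melsim = 0.72,
                     root = 2.5))
}
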