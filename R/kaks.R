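## Nei-Gojobori (1986) synonymous/nonsynonymous site and difference
## counting with equal pathway weighting, stop-traversing pathways excluded.

BASES <- c("A", "C", "G", "T")

genetic_code <- function() {
  if (is.null(.codiv$code)) {
    code <- Biostrings::GENETIC_CODE
    .codiv$code <- code
    .codiv$sense <- names(code)[code != "*"]
  }
  .codiv$code
}

#' The 61 sense codons of the standard genetic code
#' @return Character vector of codons.
#' @export
sense_codons <- function() {
  genetic_code()
  .codiv$sense
}

mutate_codon <- function(codon, pos, base) {
  substr(codon, pos, pos) <- base
  codon
}

#' Synonymous and nonsynonymous site fractions of a codon
#'
#' For each of the three positions, the synonymous fraction is the
#' proportion of the single-nucleotide changes that do not alter the amino
#' acid, among changes that do not create a stop codon; the nonsynonymous
#' fraction is its complement, so the two totals always sum to 3.
#'
#' @param codon A sense codon (standard genetic code).
#' @return Named numeric `c(synonymous, nonsynonymous)`.
#' @export
syn_nonsyn_sites <- function(codon) {
  code <- genetic_code()
  codon <- toupper(codon)
  aa <- code[codon]
  if (is.na(aa)) stop("not a codon: ", codon)
  if (aa == "*") stop("stop codon: ", codon)
  s <- 0
  for (pos in 1:3) {
    from <- substr(codon, pos, pos)
    neigh <- vapply(setdiff(BASES, from), mutate_codon,
                    "", codon = codon, pos = pos)
    aas <- code[neigh]
    keep <- aas != "*"
    if (any(keep)) s <- s + mean(aas[keep] == aa)
  }
  c(synonymous = s, nonsynonymous = 3 - s)
}

.perms <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

#' Pathway-averaged synonymous/nonsynonymous differences between codons
#'
#' All minimal mutational pathways from `codon_a` to `codon_b` are
#' enumerated; pathways passing through a stop codon are discarded; the
#' synonymous and nonsynonymous step counts are averaged over the
#' remaining pathways with equal weight. Their sum equals the Hamming
#' distance of the codons.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric `c(synonymous, nonsynonymous)`; both `NA` if
#'   every pathway traverses a stop codon.
#' @export
pathway_differences <- function(codon_a, codon_b) {
  code <- genetic_code()
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  for (cd in c(codon_a, codon_b)) {
    aa <- code[cd]
    if (is.na(aa)) stop("not a codon: ", cd)
    if (aa == "*") stop("stop codon: ", cd)
  }
  pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(synonymous = 0, nonsynonymous = 0))
  sd_tot <- 0; nd_tot <- 0; n_ok <- 0L
  for (ord in .perms[[as.character(k)]]) {
    cur <- codon_a
    sd <- 0; nd <- 0; ok <- TRUE
    for (p in pos[ord]) {
      nxt <- mutate_codon(cur, p, substr(codon_b, p, p))
      if (code[nxt] == "*") { ok <- FALSE; break }
      if (code[nxt] == code[cur]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_ok <- n_ok + 1L }
  }
  if (n_ok == 0L) return(c(synonymous = NA_real_, nonsynonymous = NA_real_))
  c(synonymous = sd_tot / n_ok, nonsynonymous = nd_tot / n_ok)
}

## cached per-codon site fractions for the 61 sense codons
codon_site_table <- function() {
  if (is.null(.codiv$site_tab)) {
    sc <- sense_codons()
    tab <- t(vapply(sc, syn_nonsyn_sites, c(synonymous = 0, nonsynonymous = 0)))
    .codiv$site_tab <- tab
  }
  .codiv$site_tab
}

ng86_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Nei-Gojobori k_s and k_a for an aligned in-frame pair
#'
#' Codons containing a gap, `N`, or a stop codon in either taxon are
#' skipped. Site totals are the mean of the two sequences' counts;
#' differences are pathway-averaged ([pathway_differences()]); proportions
#' are Jukes-Cantor corrected where below 3/4 (above that the logarithm is
#' undefined and the uncorrected proportion is returned with a warning).
#'
#' @param aln A `codon_alignment`.
#' @param a,b Taxon names.
#' @return Object of class `kaks_estimate` with fields `S`, `N`
#'   (synonymous/nonsynonymous sites), `Sd`, `Nd` (pathway-averaged
#'   differences), `ps`, `pn` (proportions), `ks`, `ka` (corrected rates)
#'   and `ratio` (`ks/ka`, 2 significant figures), plus skipped-codon
#'   bookkeeping.
#' @export
kaks_pair <- function(aln, a, b) {
  stopifnot(inherits(aln, "codon_alignment"))
  for (t in c(a, b))
    if (!t %in% aln$taxa) stop("unknown taxon: ", t)
  code <- genetic_code()
  ca <- site_codons(aln, a)
  cb <- site_codons(aln, b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  aa_a <- code[ca[clean]]; aa_b <- code[cb[clean]]
  sense <- aa_a != "*" & aa_b != "*"
  n_stop <- sum(!sense)
  ia <- ca[clean][sense]; ib <- cb[clean][sense]
  if (!length(ia)) stop("no usable codons")

  tab <- codon_site_table()
  S <- (sum(tab[ia, "synonymous"]) + sum(tab[ib, "synonymous"])) / 2
  N <- (sum(tab[ia, "nonsynonymous"]) + sum(tab[ib, "nonsynonymous"])) / 2

  d <- which(ia != ib)
  Sd <- 0; Nd <- 0; n_allstop <- 0L
  if (length(d)) {
    pairs <- paste(ia[d], ib[d])
    for (up in unique(pairs)) {
      cnt <- sum(pairs == up)
      cds <- strsplit(up, " ")[[1]]
      pd <- pathway_differences(cds[1], cds[2])
      if (anyNA(pd)) { n_allstop <- n_allstop + cnt; next }
      Sd <- Sd + cnt * pd[["synonymous"]]
      Nd <- Nd + cnt * pd[["nonsynonymous"]]
    }
  }
  ps <- Sd / S; pn <- Nd / N
  ks <- ng86_correct(ps); ka <- ng86_correct(pn)
  if (is.na(ks) && !is.na(ps)) { warning("p_s >= 0.75; uncorrected"); ks <- ps }
  if (is.na(ka) && !is.na(pn)) { warning("p_n >= 0.75; uncorrected"); ka <- pn }
  structure(list(pair = c(a, b), codons = length(ia), S = S, N = N,
                 Sd = Sd, Nd = Nd, ps = ps, pn = pn, ks = ks, ka = ka,
                 ratio = if (ka > 0) signif(ks / ka, 2) else Inf,
                 skipped_stop = n_stop, skipped_all_stop_paths = n_allstop),
            class = "kaks_estimate")
}

## codon strings of one taxon, honoring per-gene reading frame
site_codons <- function(aln, taxon) {
  x <- aln$seq[taxon, ]
  parts <- lapply(seq_len(nrow(aln$gene_spans)), function(i) {
    m <- matrix(x[seq.int(aln$gene_spans$start[i], aln$gene_spans$end[i])],
                nrow = 3L)
    paste0(m[1, ], m[2, ], m[3, ])
  })
  unlist(parts, use.names = FALSE)
}

#' @export
print.kaks_estimate <- function(x, ...) {
  cat(sprintf("<kaks_estimate> %s vs %s (%d codons)\n",
              x$pair[1], x$pair[2], x$codons))
  cat(sprintf("  S = %.1f  N = %.1f  Sd = %.2f  Nd = %.2f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  k_s = %.4g  k_a = %.4g  k_s/k_a = %s\n",
              x$ks, x$ka, format(x$ratio)))
  invisible(x)
}
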