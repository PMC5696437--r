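## Strict-clock relative-age chronogram with per-codon-position rate
## multipliers. Likelihood: independent sites, HKY with empirical base
## frequencies and a single transition/transversion ratio; the expected
## number of substitutions on a branch at codon position p is r_p times the
## branch duration. Ages are relative: a reference node is fixed at 1.

ACGT_IDX <- c(A = 1L, C = 2L, G = 3L, T = 4L)

prep_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be strictly bifurcating")
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  list(tree = tr, ntip = ntip, nnode = tr$Nnode, edge = tr$edge,
       root = ntip + 1L)
}

empirical_freqs <- function(aln, taxa) {
  x <- aln$seq[taxa, , drop = FALSE]
  counts <- vapply(BASES, function(b) sum(x == b), 0)
  counts / sum(counts)
}

## site-pattern compression per codon position; keeps the pattern
## character matrix for distance-based initialization
pattern_data <- function(aln, taxa) {
  lapply(setNames(1:3, 1:3), function(p) {
    sub <- aln$seq[taxa, aln$position_index == p, drop = FALSE]
    key <- do.call(paste0, lapply(seq_len(nrow(sub)), function(i) sub[i, ]))
    u <- unique(key)
    counts <- tabulate(match(key, u), nbins = length(u))
    chars <- sub[, match(u, key), drop = FALSE]
    npat <- length(u)
    tipL <- lapply(seq_along(taxa), function(i) {
      L <- matrix(0, 4L, npat)
      idx <- ACGT_IDX[chars[i, ]]
      known <- !is.na(idx)
      L[cbind(idx[known], which(known))] <- 1
      L[, !known] <- 1            # gap/N: uninformative
      L
    })
    list(tipL = tipL, counts = counts, chars = chars,
         nsites = sum(counts))
  })
}

## HKY rate matrix (mean rate 1), eigendecomposed via the reversible
## symmetrization so P(nu) = A diag(exp(lambda nu)) Ainv
hky_eigen <- function(kappa, freqs) {
  ts_pair <- matrix(c(1, 3, 2, 4), 2)   # A<->G, C<->T
  Q <- matrix(freqs, 4, 4, byrow = TRUE)
  Q[1, 3] <- Q[1, 3] * kappa; Q[3, 1] <- Q[3, 1] * kappa
  Q[2, 4] <- Q[2, 4] * kappa; Q[4, 2] <- Q[4, 2] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  sp <- sqrt(freqs)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(A = e$vectors / sp, Ainv = t(e$vectors) * rep(sp, each = 4L),
       lambda = e$values)
}

hky_prob <- function(eig, nu) {
  if (nu <= 0) return(diag(4))
  P <- eig$A %*% (exp(eig$lambda * nu) * eig$Ainv)
  P[P < 0] <- 0
  P
}

clock_ll <- function(pd, ts, ages, rates, kappa, freqs) {
  durs <- ages[ts$edge[, 1]] - ages[ts$edge[, 2]]
  if (any(durs < 0) || any(rates < 0)) return(-Inf)
  eig <- hky_eigen(kappa, freqs)
  ll <- 0
  nn <- ts$ntip + ts$nnode
  for (p in 1:3) {
    dat <- pd[[p]]
    L <- vector("list", nn)
    L[seq_len(ts$ntip)] <- dat$tipL
    for (e in seq_len(nrow(ts$edge))) {
      par <- ts$edge[e, 1L]; ch <- ts$edge[e, 2L]
      contrib <- hky_prob(eig, rates[p] * durs[e]) %*% L[[ch]]
      L[[par]] <- if (is.null(L[[par]])) contrib else L[[par]] * contrib
    }
    site <- colSums(L[[ts$root]] * freqs)
    if (any(site <= 0)) return(-Inf)
    ll <- ll + sum(dat$counts * log(site))
  }
  ll
}

#' Strict-clock partitioned log-likelihood
#'
#' Log-likelihood of a codon alignment on a rooted ultrametric tree under
#' the partitioned HKY clock: node ages (tips at 0) plus one rate
#' multiplier per codon position; the expected substitutions on a branch
#' at position p equal `rates[p]` times the branch duration.
#'
#' @param aln A `codon_alignment`.
#' @param tree Rooted bifurcating `phylo`; tip labels must be taxa of `aln`.
#' @param ages Numeric vector of internal-node ages in ape node order
#'   (nodes `Ntip+1 ... Ntip+Nnode`); tips are at age 0.
#' @param rates Positive numeric length 3, per codon position.
#' @param kappa Transition/transversion rate ratio.
#' @param freqs Base frequencies (A, C, G, T); default empirical.
#' @return Log-likelihood (scalar; `-Inf` for impossible configurations).
#' @export
clock_log_likelihood <- function(aln, tree, ages, rates, kappa = 2,
                                 freqs = NULL) {
  ts <- prep_tree(tree)
  taxa <- ts$tree$tip.label
  stopifnot(all(taxa %in% aln$taxa), length(ages) == ts$nnode,
            length(rates) == 3L)
  if (any(ages < 0)) stop("negative ages")
  if (is.null(freqs)) freqs <- empirical_freqs(aln, taxa)
  pd <- pattern_data(aln, taxa)
  full_ages <- c(numeric(ts$ntip), ages)
  durs <- full_ages[ts$edge[, 1]] - full_ages[ts$edge[, 2]]
  if (any(durs < 0)) stop("ages do not respect the topology (non-ultrametric)")
  clock_ll(pd, ts, full_ages, rates, kappa, freqs)
}

## tip descendants of every node, postorder accumulation
node_descendants <- function(ts) {
  desc <- vector("list", ts$ntip + ts$nnode)
  for (i in seq_len(ts$ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(ts$edge)))
    desc[[ts$edge[e, 1L]]] <- c(desc[[ts$edge[e, 1L]]], desc[[ts$edge[e, 2L]]])
  desc
}

jc_dist <- function(p) -0.75 * log(pmax(1 - 4 * p / 3, 1e-12))

## distance-based starting values: node ages from mean cross-pair
## corrected distances, scaled so the reference node sits at 1
init_clock <- function(pd, ts, ref_node) {
  ntip <- ts$ntip
  pdist <- function(part, i, j) {
    ci <- part$chars[i, ]; cj <- part$chars[j, ]
    ok <- ci %in% BASES & cj %in% BASES
    n <- sum(part$counts[ok])
    if (n == 0) return(0)
    sum(part$counts[ok & ci != cj]) / n
  }
  Dp <- lapply(1:3, function(p) {
    D <- matrix(0, ntip, ntip)
    for (i in seq_len(ntip - 1L)) for (j in (i + 1L):ntip)
      D[i, j] <- D[j, i] <- jc_dist(pdist(pd[[p]], i, j))
    D
  })
  w <- vapply(pd, `[[`, 0, "nsites")
  D <- Reduce(`+`, Map(`*`, Dp, w)) / sum(w)

  desc <- node_descendants(ts)
  kids <- split(ts$edge[, 2L], ts$edge[, 1L])
  internal <- seq.int(ntip + 1L, ntip + ts$nnode)
  cross_mean <- function(Dm, n) {
    ch <- kids[[as.character(n)]]
    mean(Dm[desc[[ch[1L]]], desc[[ch[2L]]]])
  }
  ages <- numeric(ntip + ts$nnode)
  for (n in internal) ages[n] <- cross_mean(D, n) / 2
  ref_age <- ages[ref_node]
  if (!is.finite(ref_age) || ref_age <= 0) {
    depth <- numeric(ntip + ts$nnode)                 # degenerate data:
    for (e in seq_len(nrow(ts$edge)))                 # topological depths
      depth[ts$edge[e, 1L]] <- max(depth[ts$edge[e, 1L]],
                                   depth[ts$edge[e, 2L]] + 1)
    ages <- depth / max(depth[ref_node], 1)
    ref_age <- 1
  }
  ages <- ages / ref_age
  ages[!is.finite(ages)] <- 1
  ## repair orderings while keeping the reference at 1: shrink violating
  ## non-reference children top-down, then raise violating ancestors
  for (e in rev(seq_len(nrow(ts$edge)))) {
    par <- ts$edge[e, 1L]; ch <- ts$edge[e, 2L]
    if (ch > ntip && ch != ref_node && ages[ch] >= ages[par])
      ages[ch] <- 0.9 * ages[par]
  }
  for (e in seq_len(nrow(ts$edge))) {
    par <- ts$edge[e, 1L]; ch <- ts$edge[e, 2L]
    if (ages[par] <= ages[ch]) ages[par] <- 1.1 * ages[ch] + 1e-8
  }
  ## after normalization the reference node sits at 1, so the per-unit-time
  ## rate is half the cross-pair distance at the reference node
  rates <- vapply(1:3, function(p) {
    max(cross_mean(Dp[[p]], ref_node) / 2, 1e-9)
  }, 0)
  list(ages = ages, rates = rates, kappa = 2)
}

fit_clock <- function(pd, ts, freqs, ref_node, init = NULL,
                      fix_kappa = FALSE, maxit = 2000, reltol = 1e-9) {
  ntip <- ts$ntip
  internal <- seq.int(ntip + 1L, ntip + ts$nnode)
  free <- setdiff(internal, ref_node)
  if (is.null(init)) init <- init_clock(pd, ts, ref_node)
  nf <- length(free)
  objective <- function(par) {
    ages <- numeric(ntip + ts$nnode)
    ages[ref_node] <- 1
    if (nf) ages[free] <- exp(par[seq_len(nf)])
    rates <- exp(par[nf + 1:3])
    kappa <- if (fix_kappa) init$kappa else exp(par[nf + 4L])
    if (kappa > 1e3 || any(rates > 10) || any(ages > 1e4)) return(1e10)
    ll <- clock_ll(pd, ts, ages, rates, kappa, freqs)
    if (!is.finite(ll)) 1e10 else -ll
  }
  par0 <- c(log(pmax(init$ages[free], 1e-8)),
            log(pmax(init$rates, 1e-10)),
            if (!fix_kappa) log(init$kappa))
  opt <- optim(par0, objective, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol))
  ages <- numeric(ntip + ts$nnode)
  ages[ref_node] <- 1
  if (nf) ages[free] <- exp(opt$par[seq_len(nf)])
  rates <- exp(opt$par[nf + 1:3])
  kappa <- if (fix_kappa) init$kappa else exp(opt$par[nf + 4L])
  list(ages = ages, rates = rates, kappa = kappa, logLik = -opt$value,
       convergence = opt$convergence, free = free)
}

#' Fit a relative-age strict-clock chronogram
#'
#' Maximum-likelihood node ages and per-codon-position rate multipliers
#' under the partitioned HKY clock ([clock_log_likelihood()]), with the
#' age of a chosen reference node fixed at exactly 1; all other ages are
#' reported relative to it (resolving the rate/time confounding).
#' Uncertainty comes from a parametric bootstrap: alignments are
#' resimulated under the fitted model, refitted (transition/transversion
#' ratio held at its fitted value), and percentile intervals taken.
#'
#' @param aln A `codon_alignment` (at least 3 taxa on the tree).
#' @param tree Rooted bifurcating topology (`phylo`); branch lengths are
#'   ignored, only the topology is used.
#' @param reference Character vector of two tip labels; their MRCA is the
#'   reference node.
#' @param bootstrap Number of parametric-bootstrap replicates (0 = none).
#' @param seed Optional RNG seed for the bootstrap.
#' @param level Interval level, default 0.95.
#' @param maxit Optimizer iteration cap.
#' @return Object of class `chronogram` with fitted `ages` (full node
#'   vector, tips 0, reference exactly 1), `rates`, `kappa`, `freqs`,
#'   `logLik`, bootstrap draws and percentile `intervals`.
#' @seealso [node_age()] to extract the relative age of any clade.
#' @export
chronogram <- function(aln, tree, reference, bootstrap = 0, seed = NULL,
                       level = 0.95, maxit = 4000) {
  ts <- prep_tree(tree)
  taxa <- ts$tree$tip.label
  if (ts$ntip < 3L) stop("need at least 3 taxa")
  stopifnot(all(taxa %in% aln$taxa), length(reference) == 2L)
  ref_node <- ape::getMRCA(ts$tree, reference)
  pd <- pattern_data(aln, taxa)
  freqs <- empirical_freqs(aln, taxa)
  fit <- fit_clock(pd, ts, freqs, ref_node, maxit = maxit)
  if (fit$convergence != 0)
    warning("optimizer did not report convergence (code ",
            fit$convergence, ")")
  n_codons <- pd[[1]]$nsites
  boot <- NULL; intervals <- NULL
  if (bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    warm <- list(ages = fit$ages, rates = fit$rates, kappa = fit$kappa)
    draws <- vapply(seq_len(bootstrap), function(b) {
      sim <- simulate_clock_alignment(ts$tree, fit$ages, fit$rates,
                                      fit$kappa, freqs, n_codons)
      bpd <- pattern_data(sim, taxa)
      bf <- fit_clock(bpd, ts, freqs, ref_node, init = warm,
                      fix_kappa = TRUE, maxit = 500, reltol = 1e-8)
      c(bf$ages[seq.int(ts$ntip + 1L, ts$ntip + ts$nnode)], bf$rates)
    }, numeric(ts$nnode + 3L))
    rownames(draws) <- c(paste0("age_", seq.int(ts$ntip + 1L,
                                                ts$ntip + ts$nnode)),
                         paste0("rate_", 1:3))
    a <- (1 - level) / 2
    intervals <- t(apply(draws, 1L, quantile, probs = c(a, 1 - a),
                         names = FALSE, type = 6))
    colnames(intervals) <- c("lower", "upper")
    boot <- draws
  }
  structure(list(tree = ts$tree, reference = reference,
                 reference_node = ref_node,
                 ages = fit$ages, rates = fit$rates, kappa = fit$kappa,
                 freqs = freqs, logLik = fit$logLik,
                 convergence = fit$convergence,
                 nsites = sum(vapply(pd, `[[`, 0, "nsites")),
                 n_codons = n_codons, level = level,
                 boot = boot, intervals = intervals),
            class = "chronogram")
}

#' Relative age of a clade in a fitted chronogram
#'
#' @param object A fitted `chronogram`.
#' @param tips Two or more tip labels; the MRCA's age is returned.
#' @return List with `node`, `age` and (when the fit was bootstrapped)
#'   `lower`/`upper` percentile bounds.
#' @export
node_age <- function(object, tips) {
  stopifnot(inherits(object, "chronogram"))
  node <- ape::getMRCA(object$tree, tips)
  out <- list(node = node, age = object$ages[node])
  if (!is.null(object$intervals)) {
    ci <- object$intervals[paste0("age_", node), ]
    out$lower <- ci[["lower"]]; out$upper <- ci[["upper"]]
  }
  out
}

#' @export
print.chronogram <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  cat(sprintf("<chronogram> %d taxa, %d sites; reference node (%s, %s) at age 1\n",
              ntip, x$nsites, x$reference[1], x$reference[2]))
  cat(sprintf("  rate multipliers: %.4g %.4g %.4g  kappa: %.3g  logLik: %.2f\n",
              x$rates[1], x$rates[2], x$rates[3], x$kappa, x$logLik))
  internal <- seq.int(ntip + 1L, ntip + x$tree$Nnode)
  ages <- x$ages[internal]
  cat("  node ages:", paste(sprintf("%.3g", ages), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.chronogram <- function(object, ...) {
  ntip <- length(object$tree$tip.label)
  internal <- seq.int(ntip + 1L, ntip + object$tree$Nnode)
  desc <- node_descendants(prep_tree(object$tree))
  clade <- vapply(internal, function(n) {
    t <- object$tree$tip.label[desc[[n]]]
    paste(t[c(1, length(t))], collapse = "..")
  }, "")
  tab <- data.frame(node = internal, clade = clade,
                    age = object$ages[internal])
  if (!is.null(object$intervals)) {
    tab$lower <- object$intervals[paste0("age_", internal), "lower"]
    tab$upper <- object$intervals[paste0("age_", internal), "upper"]
  }
  structure(list(nodes = tab, rates = object$rates, kappa = object$kappa,
                 logLik = object$logLik, reference = object$reference),
            class = "summary.chronogram")
}

#' @export
print.summary.chronogram <- function(x, ...) {
  cat("Relative-age chronogram (reference clade",
      paste0("(", x$reference[1], ", ", x$reference[2], ")"), "= 1)\n")
  print(x$nodes, row.names = FALSE, digits = 4)
  cat(sprintf("rates: %.4g %.4g %.4g   kappa: %.3g   logLik: %.2f\n",
              x$rates[1], x$rates[2], x$rates[3], x$kappa, x$logLik))
  invisible(x)
}

#' @export
coef.chronogram <- function(object, ...) {
  ntip <- length(object$tree$tip.label)
  internal <- seq.int(ntip + 1L, ntip + object$tree$Nnode)
  c(setNames(object$ages[internal], paste0("age_", internal)),
    setNames(object$rates, paste0("rate_", 1:3)),
    kappa = object$kappa)
}

#' @export
logLik.chronogram <- function(object, ...) {
  df <- object$tree$Nnode - 1L + 3L + 1L
  structure(object$logLik, df = df, nobs = object$nsites, class = "logLik")
}

#' @export
plot.chronogram <- function(x, ...) {
  tr <- x$tree
  tr$edge.length <- x$ages[tr$edge[, 1]] - x$ages[tr$edge[, 2]]
  ape::plot.phylo(tr, ...)
  ape::axisPhylo()
  invisible(x)
}

#' @export
simulate.chronogram <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    simulate_clock_alignment(object$tree, object$ages, object$rates,
                             object$kappa, object$freqs, object$n_codons))
}

#' Simulate sites under the fitted HKY clock model
#'
#' Exact nucleotide-level sampler for the partitioned strict-clock HKY
#' model: states are drawn at the root from the base frequencies and
#' propagated through each branch with the HKY transition matrix at
#' `rates[p] * duration`. This is the engine behind the chronogram's
#' parametric bootstrap.
#'
#' @param tree Rooted bifurcating `phylo` (node numbering defines `ages`).
#' @param ages Full node-age vector (tips 0), or internal ages only.
#' @param rates Per-codon-position rate multipliers.
#' @param kappa Transition/transversion ratio.
#' @param freqs Base frequencies (A, C, G, T).
#' @param n_codons Number of codons (sites = 3 * n_codons).
#' @param seed Optional RNG seed.
#' @return A `codon_alignment`.
#' @export
simulate_clock_alignment <- function(tree, ages, rates, kappa, freqs,
                                     n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ts <- prep_tree(tree)
  if (length(ages) == ts$nnode) ages <- c(numeric(ts$ntip), ages)
  stopifnot(length(ages) == ts$ntip + ts$nnode)
  eig <- hky_eigen(kappa, freqs)
  states <- vector("list", ts$ntip + ts$nnode)
  states[[ts$root]] <- lapply(1:3, function(p)
    sample.int(4L, n_codons, replace = TRUE, prob = freqs))
  for (e in rev(seq_len(nrow(ts$edge)))) {
    par <- ts$edge[e, 1L]; ch <- ts$edge[e, 2L]
    dur <- ages[par] - ages[ch]
    states[[ch]] <- lapply(1:3, function(p) {
      P <- hky_prob(eig, rates[p] * dur)
      parent <- states[[par]][[p]]
      child <- parent
      for (s in 1:4) {
        idx <- which(parent == s)
        if (length(idx))
          child[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                   prob = P[s, ])
      }
      child
    })
  }
  L <- 3L * n_codons
  seqmat <- matrix("", ts$ntip, L, dimnames = list(ts$tree$tip.label, NULL))
  for (i in seq_len(ts$ntip)) {
    s <- integer(L)
    for (p in 1:3) s[seq.int(p, L, by = 3L)] <- states[[i]][[p]]
    seqmat[i, ] <- BASES[s]
  }
  new_codon_alignment(seqmat, data.frame(gene_id = "sim", start = 1L,
                                         end = L, stringsAsFactors = FALSE))
}
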