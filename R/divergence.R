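## Pairwise difference counts by codon position, divergence estimates with
## Jeffreys binomial intervals, and shared/private variant partitioning.

#' Count pairwise nucleotide differences by codon position
#'
#' Sites where either sequence carries a non-ACGT character (gap, N) are
#' excluded from both the difference and the usable-site count, so each
#' pair has its own usable-site denominator.
#'
#' @param aln A `codon_alignment`.
#' @param a,b Taxon names.
#' @return An object of class `difference_count`: per-position and overall
#'   `(sites, differences)`.
#' @export
count_pairwise_differences <- function(aln, a, b) {
  stopifnot(inherits(aln, "codon_alignment"))
  for (t in c(a, b))
    if (!t %in% aln$taxa) stop("unknown taxon: ", t)
  x <- aln$seq[a, ]
  y <- aln$seq[b, ]
  usable <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  diff <- usable & x != y
  per <- vapply(1:3, function(p) {
    at <- aln$position_index == p
    c(sites = sum(usable & at), differences = sum(diff & at))
  }, c(sites = 0, differences = 0))
  structure(list(
    pair = c(a, b),
    per_position = data.frame(position = 1:3,
                              sites = per["sites", ],
                              differences = per["differences", ]),
    sites = sum(per["sites", ]),
    differences = sum(per["differences", ])
  ), class = "difference_count")
}

#' @export
print.difference_count <- function(x, ...) {
  cat(sprintf("<difference_count> %s vs %s: %d differences / %d usable sites\n",
              x$pair[1], x$pair[2], x$differences, x$sites))
  print(x$per_position, row.names = FALSE)
  invisible(x)
}

## Jeffreys 95% binomial interval; lower pinned to 0 at x = 0 and upper to
## 1 at x = n (standard boundary modification).
jeffreys_interval <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else qbeta(a, x + 0.5, n - x + 0.5)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 0.5, n - x + 0.5)
  c(lower = lo, upper = hi)
}

#' Render a proportion as a percentage string
#'
#' One significant figure below 0.01%, two otherwise (the convention used
#' for reporting sub-0.1% whole-genome divergences).
#'
#' @param p Proportion in `[0, 1]`.
#' @return Character, e.g. `"0.004%"`.
#' @export
format_divergence_percent <- function(p) {
  pct <- 100 * p
  out <- vapply(pct, function(v) {
    sig <- if (abs(v) < 0.01) 1L else 2L
    format(signif(v, sig), scientific = FALSE, trim = TRUE,
           drop0trailing = TRUE)
  }, "")
  paste0(out, "%")
}

#' Estimate pairwise divergence with Jeffreys intervals
#'
#' Point estimate is differences/sites; 95% intervals use the Jeffreys
#' binomial method, per codon position and overall.
#'
#' Can be called either on a `difference_count` or directly with counts:
#' `pairwise_divergence(28, 704883)`.
#'
#' @param x A `difference_count`, or a number of differences.
#' @param sites Usable sites when `x` is a count.
#' @param level Interval level (default 0.95).
#' @return An object of class `divergence_estimate` with a per-position
#'   table, overall estimate, intervals and the rendered percentage.
#' @export
pairwise_divergence <- function(x, sites = NULL, level = 0.95) {
  if (inherits(x, "difference_count")) {
    dc <- x
  } else {
    stopifnot(is.numeric(x), is.numeric(sites))
    dc <- list(pair = c(NA, NA),
               per_position = NULL,
               sites = sites, differences = x)
  }
  if (dc$sites <= 0) stop("no usable sites")
  est_row <- function(d, n) {
    ci <- jeffreys_interval(d, n, level)
    data.frame(sites = n, differences = d, estimate = d / n,
               lower = ci[["lower"]], upper = ci[["upper"]])
  }
  overall <- est_row(dc$differences, dc$sites)
  per <- NULL
  if (!is.null(dc$per_position)) {
    per <- do.call(rbind, lapply(1:3, function(p) {
      r <- dc$per_position[p, ]
      if (r$sites == 0)
        data.frame(sites = 0, differences = 0, estimate = NA,
                   lower = NA, upper = NA)
      else est_row(r$differences, r$sites)
    }))
    per <- cbind(position = 1:3, per)
  }
  structure(list(pair = dc$pair, per_position = per, overall = overall,
                 percent = format_divergence_percent(overall$estimate),
                 level = level),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat("<divergence_estimate>")
  if (!is.na(x$pair[1])) cat(sprintf(" %s vs %s", x$pair[1], x$pair[2]))
  cat("\n")
  if (!is.null(x$per_position)) {
    cat("per codon position:\n")
    print(x$per_position, row.names = FALSE, digits = 3)
  }
  cat(sprintf("overall: %d/%d = %.3g (%s), %d%% CI [%.3g, %.3g]\n",
              x$overall$differences, x$overall$sites, x$overall$estimate,
              x$percent, round(100 * x$level), x$overall$lower,
              x$overall$upper))
  invisible(x)
}

#' Partition variants of an ingroup pair into shared and private
#'
#' For taxa `a`, `b` (ingroup) and `c` (outgroup), over sites where all
#' three are ACGT: a site with `a == b != c` is a shared derived
#' difference; `a != b, b == c` is private to `a`; `a != b, a == c` is
#' private to `b`. Sites where all three states differ are counted
#' separately (`all_different`) and not classified.
#'
#' @param aln A `codon_alignment`.
#' @param ingroup Character vector of the two ingroup taxa.
#' @param outgroup Outgroup taxon name.
#' @return A list of counts with class `snv_partition`.
#' @export
partition_shared_private <- function(aln, ingroup, outgroup) {
  stopifnot(inherits(aln, "codon_alignment"), length(ingroup) == 2L)
  for (t in c(ingroup, outgroup))
    if (!t %in% aln$taxa) stop("unknown taxon: ", t)
  a <- aln$seq[ingroup[1], ]
  b <- aln$seq[ingroup[2], ]
  c_ <- aln$seq[outgroup, ]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T") &
    c_ %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]; c_ <- c_[ok]
  shared <- sum(a == b & a != c_)
  private_a <- sum(a != b & b == c_)
  private_b <- sum(a != b & a == c_)
  all_diff <- sum(a != b & a != c_ & b != c_)
  structure(list(ingroup = ingroup, outgroup = outgroup,
                 shared = shared, private_a = private_a,
                 private_b = private_b, all_different = all_diff,
                 usable_sites = sum(ok)),
            class = "snv_partition")
}

#' @export
print.snv_partition <- function(x, ...) {
  cat(sprintf("<snv_partition> (%s, %s) vs %s\n", x$ingroup[1], x$ingroup[2],
              x$outgroup))
  cat(sprintf("  shared: %d  private %s: %d  private %s: %d  all-different: %d\n",
              x$shared, x$ingroup[1], x$private_a, x$ingroup[2], x$private_b,
              x$all_different))
  invisible(x)
}
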