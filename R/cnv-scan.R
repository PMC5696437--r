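## Read-depth normalization, copy-number variant calling against a control
## alignment, and Kolmogorov-Smirnov significance.

window_means <- function(depth, window) {
  n <- length(depth)
  idx <- (seq_len(n) - 1L) %/% window
  as.numeric(rowsum(depth, idx) / tabulate(idx + 1L))
}

#' Normalized read-depth profile
#'
#' Depth is averaged in non-overlapping windows and divided by the
#' genome-wide mean (the mean over all windows), making profiles
#' invariant to overall coverage.
#'
#' @param depth Per-base depth vector (or an existing `depth_profile`,
#'   returned unchanged if the window matches).
#' @param window Window size in bp (default 1000).
#' @param contig Contig label.
#' @return Object of class `depth_profile` with raw window means (`mean`),
#'   normalized values (`norm`), `genome_mean`, `window` and
#'   `genome_length`.
#' @export
normalize_depth <- function(depth, window = 1000, contig = "genome") {
  if (inherits(depth, "depth_profile")) {
    if (depth$window != window)
      stop("profile window ", depth$window, " != requested ", window)
    return(depth)
  }
  if (!length(depth)) stop("empty depth vector")
  if (all(depth == 0)) stop("all-zero depth")
  m <- window_means(depth, window)
  gm <- mean(m)
  structure(list(contig = contig, window = window, n_windows = length(m),
                 mean = m, norm = m / gm, genome_mean = gm,
                 genome_length = length(depth)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %s: %d windows of %d bp, genome mean %.2f\n",
              x$contig, x$n_windows, x$window, x$genome_mean))
  invisible(x)
}

#' Read a depth table
#'
#' Accepts either per-base format (`contig`, `pos`, `depth`) or
#' fixed-window format (`contig`, `win_start`, `win_end`, `mean_depth`).
#'
#' @param path TSV path with header.
#' @return For per-base input, a numeric depth vector ordered by
#'   position; for windowed input, the data frame as read.
#' @export
read_depth_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (all(c("pos", "depth") %in% names(tab)))
    return(tab$depth[order(tab$pos)])
  if (all(c("win_start", "win_end", "mean_depth") %in% names(tab)))
    return(tab)
  stop("unrecognized depth table columns: ",
       paste(names(tab), collapse = ", "))
}

#' Read reference-ploidy regions (BED)
#'
#' BED intervals (0-based half-open) of regions present in more than one
#' copy in the reference; an optional 4th column gives the ploidy
#' (default 2). Returned 1-based inclusive.
#'
#' @param path BED file path (no header).
#' @return Data frame `start`, `end`, `ploidy`.
#' @export
read_ploidy_bed <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  ploidy <- if (ncol(tab) >= 4) as.integer(tab[[4]]) else rep(2L, nrow(tab))
  ploidy[is.na(ploidy)] <- 2L
  data.frame(start = tab[[2]] + 1L, end = tab[[3]], ploidy = ploidy)
}

window_ploidy <- function(n_windows, window, ploidy_regions) {
  pl <- rep(1L, n_windows)
  if (is.null(ploidy_regions) || !nrow(ploidy_regions)) return(pl)
  if (is.null(ploidy_regions$ploidy)) ploidy_regions$ploidy <- 2L
  mid <- (seq_len(n_windows) - 1L) * window + window / 2
  for (i in seq_len(nrow(ploidy_regions))) {
    hit <- mid >= ploidy_regions$start[i] & mid <= ploidy_regions$end[i]
    pl[hit] <- ploidy_regions$ploidy[i]
  }
  pl
}

#' Call copy-number variants from sample vs control depth
#'
#' Per window, the copy estimate is
#' `round(ploidy * sample_norm / control_norm)` where ploidy is the
#' reference copy number of the window (1 outside `ploidy_regions`). Runs
#' of at least `min_windows` consecutive windows sharing the same
#' non-reference copy estimate are merged into one call; each call gets a
#' two-sample Kolmogorov-Smirnov p-value comparing its windows'
#' sample/control ratios with the genome-wide background (all windows
#' outside any call).
#'
#' @param sample,control Per-base depth vectors, or `depth_profile`s
#'   already at `window`.
#' @param window Calling window in bp (default 500).
#' @param ploidy_regions Optional data frame `start`, `end`
#'   (1-based inclusive) and optional `ploidy` (default 2): regions
#'   duplicated in the reference.
#' @param min_windows Minimum run length per call (default 4, i.e. 2 kb).
#' @return Data frame of class `cnv_calls`: `start`, `end` (1-based
#'   inclusive), `from_copy`, `to_copy`, `n_windows`, `p_value`
#'   (`NA` for degenerate single-window comparisons). The per-window
#'   ratio vector is attached as attribute `"ratio"`.
#' @export
call_cnv <- function(sample, control, window = 500, ploidy_regions = NULL,
                     min_windows = 4) {
  sp <- normalize_depth(sample, window, contig = "sample")
  cp <- normalize_depth(control, window, contig = "control")
  if (sp$n_windows != cp$n_windows)
    stop("sample and control window grids differ (",
         sp$n_windows, " vs ", cp$n_windows, ")")
  ratio <- sp$norm / cp$norm
  ratio[cp$norm == 0] <- NA
  ploidy <- window_ploidy(sp$n_windows, window, ploidy_regions)
  copy <- ifelse(is.na(ratio), ploidy, as.integer(round(ratio * ploidy)))

  state <- paste(copy, ploidy)
  state[copy == ploidy] <- "ref"
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "ref" & r$lengths >= min_windows
  calls <- data.frame(start = (starts[keep] - 1L) * window + 1L,
                      end = pmin(ends[keep] * window, sp$genome_length),
                      from_copy = ploidy[starts[keep]],
                      to_copy = copy[starts[keep]],
                      n_windows = r$lengths[keep])
  in_call <- rep(FALSE, sp$n_windows)
  for (i in which(keep)) in_call[starts[i]:ends[i]] <- TRUE
  background <- ratio[!in_call & !is.na(ratio)]
  calls$p_value <- vapply(which(keep), function(i) {
    cnv_significance(ratio[starts[i]:ends[i]], background)
  }, 0)
  structure(calls, class = c("cnv_calls", "data.frame"),
            ratio = ratio, window = window)
}

#' Kolmogorov-Smirnov significance of a depth-ratio segment
#'
#' Two-sample KS test of the call windows' sample/control ratios against
#' the genome-wide background distribution.
#'
#' @param call_ratios Ratio values of the call's windows (>= 2 for a
#'   defined p-value).
#' @param background_ratios Genome-wide background ratio values.
#' @return p-value, or `NA` for degenerate (single-window) calls.
#' @export
cnv_significance <- function(call_ratios, background_ratios) {
  call_ratios <- call_ratios[!is.na(call_ratios)]
  if (length(call_ratios) < 2L || length(background_ratios) < 2L)
    return(NA_real_)
  suppressWarnings(ks.test(call_ratios, background_ratios)$p.value)
}

#' Write CNV calls as BED-like TSV
#'
#' @param calls A `cnv_calls` data frame.
#' @param path Output path.
#' @return `calls`, invisibly.
#' @export
write_cnv_calls <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(calls)
}

#' Simulate sample and control depth with planted CNVs
#'
#' Per-base depth is Poisson with mean
#' `mean_depth * copy / reference_ploidy`; the control carries the
#' reference copy number everywhere, the sample carries the planted
#' changes. Regions listed in `duplicated_regions` are present twice in
#' the reference (ploidy 2), emulating collapsed mapping onto a reference
#' with near-identical segmental duplications.
#'
#' @param genome_length Genome length in bp.
#' @param mean_depth Haploid mean coverage.
#' @param cnv_spec Data frame `start`, `end` (1-based inclusive),
#'   `from_copy`, `to_copy`; `from_copy` must match the reference ploidy
#'   of the interval, and intervals must not overlap.
#' @param duplicated_regions Optional data frame `start`, `end` of
#'   reference-duplicated (ploidy 2) regions.
#' @param seed Optional RNG seed.
#' @return List with `sample`, `control` (integer per-base depths) and
#'   `truth` (the spec as planted).
#' @export
simulate_depth <- function(genome_length, mean_depth, cnv_spec = NULL,
                           duplicated_regions = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref_ploidy <- rep(1, genome_length)
  if (!is.null(duplicated_regions))
    for (i in seq_len(nrow(duplicated_regions)))
      ref_ploidy[duplicated_regions$start[i]:duplicated_regions$end[i]] <- 2
  sample_copy <- ref_ploidy
  if (!is.null(cnv_spec) && nrow(cnv_spec)) {
    o <- order(cnv_spec$start)
    if (any(cnv_spec$start[o][-1] <= cnv_spec$end[o][-nrow(cnv_spec)]))
      stop("overlapping CNV intervals")
    for (i in seq_len(nrow(cnv_spec))) {
      span <- cnv_spec$start[i]:cnv_spec$end[i]
      if (any(ref_ploidy[span] != cnv_spec$from_copy[i]))
        stop("from_copy does not match reference ploidy in interval ", i)
      sample_copy[span] <- cnv_spec$to_copy[i]
    }
  }
  list(sample = rpois(genome_length, mean_depth * sample_copy / ref_ploidy),
       control = rpois(genome_length, mean_depth),
       truth = list(cnv_spec = cnv_spec,
                    duplicated_regions = duplicated_regions,
                    mean_depth = mean_depth,
                    genome_length = genome_length))
}
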