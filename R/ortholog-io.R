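## Reading per-gene alignments, the single-copy/full-length ortholog filter,
## concatenation, and codon-position indexing.

VALID_CHARS <- c("A", "C", "G", "T", "N", "-")

#' Construct a per-gene alignment
#'
#' @param gene_id Gene identifier.
#' @param sequences Named character vector of aligned nucleotide strings
#'   (one per taxon). All must have equal length; alphabet restricted to
#'   `A, C, G, T, N, -` (case-insensitive).
#'
#' @details Genes whose alignment length is not divisible by 3 are accepted
#'   with a warning and flagged out-of-frame (`in_frame = FALSE`); they are
#'   excluded from concatenation by default.
#'
#' @return An object of class `gene_alignment`: a list with elements
#'   `gene_id`, `sequences`, `length`, `in_frame`.
#' @export
gene_alignment <- function(gene_id, sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("'sequences' must be uniquely named by taxon")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop(sprintf("gene '%s': sequences have unequal lengths (%s)",
                 gene_id, paste(unique(lens), collapse = ", ")))
  chars <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  bad <- setdiff(chars, VALID_CHARS)
  if (length(bad))
    stop(sprintf("gene '%s': invalid characters: %s", gene_id,
                 paste(bad, collapse = " ")))
  len <- lens[[1]]
  in_frame <- len %% 3L == 0L
  if (!in_frame)
    warning(sprintf("gene '%s': length %d not divisible by 3; flagged out-of-frame",
                    gene_id, len))
  sequences <- sequences[order(names(sequences))]
  structure(list(gene_id = gene_id, sequences = sequences,
                 length = len, in_frame = in_frame),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s: %d taxa, %d sites%s\n", x$gene_id,
              length(x$sequences), x$length,
              if (x$in_frame) "" else " (out of frame)"))
  invisible(x)
}

#' Read aligned FASTA files, one gene per file
#'
#' Each file must contain one aligned sequence per taxon; the taxon set must
#' be identical across files. Taxon order is normalized (sorted). The gene
#' identifier is the file name without extension.
#'
#' @param paths Character vector of FASTA file paths.
#' @return A list of [gene_alignment()] objects.
#' @export
read_gene_alignments <- function(paths) {
  out <- lapply(paths, function(p) {
    ss <- Biostrings::readBStringSet(p)
    seqs <- setNames(as.character(ss), names(ss))
    gene_alignment(sub("\\.[^.]*$", "", basename(p)), seqs)
  })
  taxa <- lapply(out, function(g) names(g$sequences))
  for (i in seq_along(out))
    if (!identical(taxa[[i]], taxa[[1L]]))
      stop(sprintf("taxon set of '%s' differs from '%s'",
                   out[[i]]$gene_id, out[[1L]]$gene_id))
  out
}

#' Read an ortholog/copy-number table
#'
#' Tab-separated with header columns `gene_id`, `genome_id`, `copy_count`,
#' `length` (one row per gene/genome pair; absent genes may be omitted or
#' given `copy_count = 0`).
#'
#' @param path TSV file path.
#' @return A data frame.
#' @export
read_ortholog_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "genome_id", "copy_count", "length")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("ortholog table lacks columns: ", paste(miss, collapse = ", "))
  tab
}

#' Select single-copy, full-length genes
#'
#' A gene is kept when it is present in exactly one copy in every genome of
#' `genomes` and its observed length is identical across those genomes.
#' A gene with no row for some genome is treated as absent (copy count 0)
#' and excluded.
#'
#' @param ortholog_table Data frame as from [read_ortholog_table()].
#' @param genomes Character vector of genome identifiers that must all
#'   carry the gene.
#' @return Sorted character vector of retained gene identifiers.
#' @export
filter_single_copy_full_length <- function(ortholog_table, genomes) {
  genomes <- unique(genomes)
  tab <- ortholog_table[ortholog_table$genome_id %in% genomes, , drop = FALSE]
  if (nrow(tab) == 0L) return(character(0))
  keep <- vapply(split(tab, tab$gene_id), function(g) {
    nrow(g) == length(genomes) &&
      all(g$copy_count == 1L) &&
      length(unique(g$length)) == 1L
  }, logical(1))
  sort(names(keep)[keep])
}

## internal constructor: seqmat is a character matrix (taxa x sites)
new_codon_alignment <- function(seqmat, gene_spans) {
  pos <- integer(ncol(seqmat))
  for (i in seq_len(nrow(gene_spans))) {
    idx <- seq.int(gene_spans$start[i], gene_spans$end[i])
    pos[idx] <- rep_len(1:3, length(idx))
  }
  structure(list(taxa = rownames(seqmat), seq = seqmat,
                 gene_spans = gene_spans, position_index = pos),
            class = "codon_alignment")
}

#' Concatenate gene alignments into a codon-indexed alignment
#'
#' Kept genes are concatenated in input order. Each gene starts in reading
#' frame 1, so codon position is assigned per gene, never globally. Gene
#' spans use 1-based inclusive coordinates.
#'
#' @param alignments List of [gene_alignment()] objects sharing one taxon set.
#' @param keep Gene identifiers to retain; default all in-frame genes.
#' @return An object of class `codon_alignment` with elements `taxa`,
#'   `seq` (character matrix, taxa x sites), `gene_spans`
#'   (`gene_id`, `start`, `end`) and `position_index` (codon position 1-3
#'   of every site).
#' @export
concatenate_genes <- function(alignments, keep = NULL) {
  ids <- vapply(alignments, `[[`, "", "gene_id")
  if (is.null(keep))
    keep <- ids[vapply(alignments, `[[`, TRUE, "in_frame")]
  missing <- setdiff(keep, ids)
  if (length(missing))
    stop("genes not present in 'alignments': ", paste(missing, collapse = ", "))
  alns <- alignments[match(keep, ids)]
  bad <- !vapply(alns, `[[`, TRUE, "in_frame")
  if (any(bad))
    stop("out-of-frame genes cannot be concatenated: ",
         paste(keep[bad], collapse = ", "))

  taxa <- if (length(alns)) names(alns[[1L]]$sequences) else character(0)
  for (g in alns)
    if (!identical(names(g$sequences), taxa))
      stop(sprintf("gene '%s' has a different taxon set", g$gene_id))

  lens <- vapply(alns, `[[`, 0L, "length")
  total <- sum(lens)
  seqmat <- matrix("N", nrow = length(taxa), ncol = total,
                   dimnames = list(taxa, NULL))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  for (i in seq_along(alns)) {
    chars <- strsplit(alns[[i]]$sequences, "", fixed = TRUE)
    for (t in seq_along(taxa))
      seqmat[t, starts[i]:ends[i]] <- chars[[t]]
  }
  spans <- data.frame(gene_id = if (length(alns)) keep else character(0),
                      start = if (length(alns)) starts else integer(0),
                      end = if (length(alns)) ends else integer(0),
                      stringsAsFactors = FALSE)
  new_codon_alignment(seqmat, spans)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d taxa, %d genes, %d sites\n",
              length(x$taxa), nrow(x$gene_spans), ncol(x$seq)))
  cat("  taxa:", paste(x$taxa, collapse = ", "), "\n")
  invisible(x)
}

#' Site indices by codon position
#'
#' @param aln A `codon_alignment`.
#' @return A list with components `"1"`, `"2"`, `"3"` of site indices; the
#'   three sets are disjoint and jointly cover every site.
#' @export
codon_positions <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  lapply(setNames(1:3, as.character(1:3)),
         function(p) which(aln$position_index == p))
}

#' Write / read a concatenated alignment
#'
#' The alignment is written as FASTA plus a gene-span TSV
#' (`gene_id`, `start`, `end`; 1-based inclusive); reading the pair back
#' reproduces the matrix exactly.
#'
#' @param aln A `codon_alignment`.
#' @param fasta,spans File paths for the FASTA matrix and the span table.
#' @return `write_codon_alignment()` returns `aln` invisibly;
#'   `read_codon_alignment()` returns a `codon_alignment`.
#' @export
write_codon_alignment <- function(aln, fasta, spans) {
  stopifnot(inherits(aln, "codon_alignment"))
  seqs <- apply(aln$seq, 1L, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", aln$taxa), seqs)), fasta)
  write.table(aln$gene_spans, spans, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(aln)
}

#' @rdname write_codon_alignment
#' @export
read_codon_alignment <- function(fasta, spans) {
  ss <- Biostrings::readBStringSet(fasta)
  seqs <- toupper(setNames(as.character(ss), names(ss)))
  spans_df <- read.delim(spans, stringsAsFactors = FALSE)
  chars <- strsplit(seqs, "", fixed = TRUE)
  seqmat <- do.call(rbind, chars)
  rownames(seqmat) <- names(seqs)
  new_codon_alignment(seqmat, spans_df)
}
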