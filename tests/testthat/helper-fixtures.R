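# small builders used across the suite

toy_alignment <- function(seqs, gene_lengths = NULL) {
  if (is.null(gene_lengths)) {
    return(concatenate_genes(list(gene_alignment("g1", seqs))))
  }
  starts <- cumsum(c(1, gene_lengths[-length(gene_lengths)]))
  genes <- lapply(seq_along(gene_lengths), function(i) {
    gene_alignment(paste0("g", i),
                   substr(seqs, starts[i], starts[i] + gene_lengths[i] - 1))
  })
  concatenate_genes(genes)
}

# sequence of n repeats of a codon with named single-site substitutions
codon_seq <- function(codon, n) paste(rep(codon, n), collapse = "")

write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  path
}
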