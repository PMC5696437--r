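# Independent brute-force Nei-Gojobori oracles (recursive depth-first
# pathway enumeration), used to validate the package's counting.

.oracle_code <- Biostrings::GENETIC_CODE

brute_pathway <- function(a, b) {
  rec <- function(cur, target) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(pos)) return(list(c(0, 0)))
    out <- list()
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(target, p, p)
      if (.oracle_code[nxt] == "*") next
      step <- if (.oracle_code[nxt] == .oracle_code[cur]) c(1, 0) else c(0, 1)
      for (rest in rec(nxt, target))
        out[[length(out) + 1L]] <- step + rest
    }
    out
  }
  paths <- rec(a, b)
  if (!length(paths)) return(c(NA_real_, NA_real_))
  colMeans(do.call(rbind, paths))
}

brute_sites <- function(codon) {
  s <- 0
  for (p in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), substr(codon, p, p))
    neigh <- vapply(alts, function(b) {
      x <- codon; substr(x, p, p) <- b; x
    }, "")
    aas <- .oracle_code[neigh]
    ok <- aas != "*"
    if (any(ok)) s <- s + sum(aas[ok] == .oracle_code[codon]) / sum(ok)
  }
  c(s, 3 - s)
}
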