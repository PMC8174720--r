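# Small in-code fixtures shared across test files.

# Build an indel_set from a compact spec: list of c(ref, alt) allele pairs
# and a dosage matrix (variants x accessions).
toy_indel_set <- function(alleles, dosages, ids = NULL,
                          acc = paste0("ACC", seq_len(ncol(dosages)))) {
  n <- length(alleles)
  v <- data.frame(
    id = if (is.null(ids)) paste0("v", seq_len(n)) else ids,
    chrom = "chr1", pos = 100L * seq_len(n),
    ref = vapply(alleles, `[`, "", 1),
    alt = vapply(alleles, `[`, "", 2),
    stringsAsFactors = FALSE)
  colnames(dosages) <- acc
  indel_set(v, dosages)
}

# Genotype matrix from a character vector of row strings, e.g.
# c(acc1 = "aab", acc2 = "abb").
gm_from_strings <- function(rows, markers = NULL) {
  m <- do.call(rbind, lapply(rows, function(s)
    strsplit(s, "", fixed = TRUE)[[1]]))
  rownames(m) <- names(rows)
  colnames(m) <- if (is.null(markers)) paste0("TB", seq_len(ncol(m)))
    else markers
  m
}

# DNA helpers for e-PCR fixtures.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
rc <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

# Independent brute-force e-PCR oracle: scans all (i, j) position pairs
# with plain substring comparison. Deliberately written without reusing
# any package internals.
epcr_oracle <- function(forward, reverse, template, max_mismatch = 0) {
  hamming <- function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  lt <- nchar(template); lf <- nchar(forward)
  rcr <- rc(reverse); lr <- nchar(rcr)
  hits <- list()
  for (i in seq_len(max(0, lt - lf + 1))) {
    segf <- substr(template, i, i + lf - 1)
    mf <- hamming(segf, forward)
    okf <- mf <= max_mismatch &&
      (max_mismatch == 0 ||
         substr(segf, lf, lf) == substr(forward, lf, lf))
    if (!okf) next
    for (j in seq_len(max(0, lt - lr + 1))) {
      if (j < i + lf) next
      segr <- substr(template, j, j + lr - 1)
      mr <- hamming(segr, rcr)
      okr <- mr <= max_mismatch &&
        (max_mismatch == 0 ||
           substr(segr, 1, 1) == substr(rcr, 1, 1))
      if (okr)
        hits[[length(hits) + 1]] <- data.frame(
          start = i, end = j + lr - 1, length = j + lr - i,
          forward_mismatches = mf, reverse_mismatches = mr)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), forward_mismatches = integer(),
                      reverse_mismatches = integer()))
  out <- do.call(rbind, hits)
  out[order(out$start, out$end), , drop = FALSE]
}

# Explicit-summation PIC oracles (independent of the vectorized forms).
pic_simple_oracle <- function(p) {
  s <- 0
  for (j in seq_along(p)) s <- s + p[j]^2
  1 - s
}
pic_botstein_oracle <- function(p) {
  s <- 0
  for (j in seq_along(p)) s <- s + p[j]^2
  cross <- 0
  if (length(p) >= 2)
    for (j in seq_len(length(p) - 1)) for (k in (j + 1):length(p))
      cross <- cross + 2 * p[j]^2 * p[k]^2
  1 - s - cross
}
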