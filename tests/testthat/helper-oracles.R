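# Independent oracles written against the definitions, not the package
# internals: string-level reverse complement, brute-force window counting,
# an exact hash-map trio filter, and a brute-force z-score.

oracle_revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

oracle_canonical <- function(s) {
  rc <- oracle_revcomp(s)
  ifelse(rc < s, rc, s)
}

# enumerate every k-window of every read, drop windows with non-ACGT
# characters, canonicalize, tabulate
oracle_count <- function(reads, k) {
  wins <- unlist(lapply(reads, function(r) {
    L <- nchar(r)
    if (L < k) return(character())
    substring(r, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  }))
  wins <- wins[!grepl("[^ACGT]", wins)]
  if (!length(wins)) return(integer(0))
  tab <- table(oracle_canonical(wins))
  setNames(as.integer(tab), names(tab))
}

# exact trio ratio filter over hash-map (named vector) lookups
oracle_filter <- function(child_tab, father_tab, mother_tab, tau0 = 0.3) {
  ff <- father_tab$counts[match(child_tab$kmers, father_tab$kmers)]
  fm <- mother_tab$counts[match(child_tab$kmers, mother_tab$kmers)]
  ff[is.na(ff)] <- 0L
  fm[is.na(fm)] <- 0L
  keep <- ff / child_tab$counts < tau0 & fm / child_tab$counts < tau0
  child_tab$kmers[keep]
}

# brute-force z-score from an exact neighbor-count lookup function
oracle_zscore <- function(kmer, f, lookup) {
  k <- nchar(kmer)
  nbs <- character()
  for (i in seq_len(k)) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(kmer, i, i))) {
      nb <- kmer
      substr(nb, i, i) <- b
      nbs <- c(nbs, oracle_canonical(nb))
    }
  }
  nbs <- setdiff(unique(nbs), kmer)
  vals <- vapply(nbs, lookup, numeric(1L))
  vals <- vals[vals > 0]
  nn <- c(f, vals)
  mu <- mean(nn)
  sd_pop <- sqrt(mean((nn - mu)^2))
  if (sd_pop == 0) 0 else (f - mu) / sd_pop
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# n distinct random canonical k-mers
random_kmers <- function(n, k = 31L) {
  out <- character(0)
  while (length(out) < n) {
    more <- vapply(seq_len(n), function(i) random_seq(k), character(1L))
    out <- unique(c(out, oracle_canonical(more)))
  }
  out[seq_len(n)]
}
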