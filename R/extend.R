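#' Extend a seed k-mer into a maximal unambiguous contig
#'
#' Starting from a kept k-mer, the sequence is elongated to the right by
#' appending the unique base `x` for which `suffix(s, k-1) + x` has a
#' positive decoded count in the child store, then symmetrically to the
#' left. A phase stops on a branch (more than one continuation), a dead end
#' (none), or when appending would exceed `max_len`; a branch stop does not
#' discard the contig built so far. Queries are canonicalized, so extension
#' crosses strand representation transparently.
#'
#' @param seed A k-length seed k-mer present in the child store.
#' @param child The child's `cbf` store.
#' @param max_len Maximum contig length (default 1000; must be `>= k`).
#' @return An object of class `contig`: a list with `sequence`, `seed`,
#'   `left_stop` and `right_stop` (each stop one of `"branch"`,
#'   `"dead_end"`, `"max_len"`).
#' @export
extend_kmer <- function(seed, child, max_len = 1000L) {
  stopifnot(inherits(child, "cbf"))
  seed <- as.character(seed)
  if (length(seed) != 1L || nchar(seed) != child$k)
    stop("seed must be a single k-mer of length ", child$k)
  max_len <- as.integer(max_len)
  if (max_len < child$k) stop("max_len must be >= k")
  if (cbf_decode(child, seed) == 0L)
    stop("seed k-mer is absent from the child store: ", seed)
  res <- rc_extend(seed, child$b_plus, child$b_minus, child$m, child$h,
                   child$seeds[1L], child$seeds[2L], max_len)
  structure(list(sequence = res$sequence, seed = seed,
                 left_stop = res$left_stop, right_stop = res$right_stop),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("contig: %d bp (seed %s, left stop %s, right stop %s)\n",
              nchar(x$sequence), x$seed, x$left_stop, x$right_stop))
  invisible(x)
}

#' Extend every kept k-mer and deduplicate the contigs
#'
#' One contig is produced per seed; a contig whose sequence (or reverse
#' complement) is a substring of another emitted contig is dropped, since
#' adjacent seeds from the same variant reconstruct the same path.
#' Containment is resolved longest-first (ties broken lexicographically)
#' for a deterministic result.
#'
#' @param kept A [kmer_table()] of seed k-mers (e.g. from
#'   [correct_kmers()]).
#' @param child The child's `cbf` store.
#' @param max_len Maximum contig length (default 1000).
#' @return A [Biostrings::DNAStringSet] of deduplicated contigs. Names
#'   follow `seed=<kmer> left=<stop> right=<stop> len=<n>`; the same fields
#'   are available via `S4Vectors::mcols()`.
#' @export
extend_all <- function(kept, child, max_len = 1000L) {
  stopifnot(inherits(kept, "kmer_table"))
  if (!length(kept$kmers)) {
    out <- Biostrings::DNAStringSet()
    return(out)
  }
  contigs <- lapply(kept$kmers, extend_kmer, child = child,
                    max_len = max_len)
  seqs <- vapply(contigs, `[[`, character(1L), "sequence")
  ord <- order(-nchar(seqs), seqs, method = "radix")
  keep_ord <- rc_dedup_contained(seqs[ord])
  idx <- ord[keep_ord]
  sel <- contigs[idx]
  out <- Biostrings::DNAStringSet(seqs[idx])
  meta <- S4Vectors::DataFrame(
    seed = vapply(sel, `[[`, character(1L), "seed"),
    left_stop = vapply(sel, `[[`, character(1L), "left_stop"),
    right_stop = vapply(sel, `[[`, character(1L), "right_stop"),
    len = nchar(seqs[idx]))
  S4Vectors::mcols(out) <- meta
  names(out) <- sprintf("seed=%s left=%s right=%s len=%d",
                        meta$seed, meta$left_stop, meta$right_stop, meta$len)
  out
}

#' Write contigs to FASTA
#'
#' Sequences are wrapped at 80 columns; headers carry the seed, the two
#' termination reasons and the length.
#'
#' @param contigs A `DNAStringSet` from [extend_all()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  Biostrings::writeXStringSet(contigs, path, width = 80L)
  invisible(path)
}
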