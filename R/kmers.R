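#' Reverse complement of nucleotide sequences
#'
#' @param seq Character vector of sequences over the alphabet A/C/G/T.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAA"))
revcomp <- function(seq) rc_revcomp(as.character(seq))

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer
#' and its reverse complement. All counting and membership queries in the
#' package operate on canonical k-mers so that forward and reverse reads
#' collapse onto the same key.
#'
#' @param seq Character vector of sequences over A/C/G/T.
#' @return Character vector of canonical forms; idempotent.
#' @export
#' @examples
#' canonical(c("ACG", "TTT", "AT"))  # "ACG", "AAA", "AT"
canonical <- function(seq) rc_canonical(as.character(seq))

#' Construct a counted k-mer table
#'
#' A `kmer_table` holds canonical k-mers with their occurrence counts,
#' sorted lexicographically. It is the exact (non-probabilistic) counterpart
#' of a coupled Bloom filter and is what [count_kmers()] returns.
#'
#' @param kmers Character vector of distinct canonical k-mers.
#' @param counts Integer vector of occurrence counts (`>= min_count`).
#' @param k K-mer length; inferred from `kmers` when missing.
#' @param min_count Minimum count retained in the table.
#' @param validate Check the class invariants (length, alphabet,
#'   canonical form, count floor, uniqueness). Disable only for internally
#'   produced inputs.
#' @return An object of class `kmer_table` with fields `k`, `min_count`,
#'   `kmers` and `counts`.
#' @export
kmer_table <- function(kmers, counts, k = NULL, min_count = 1L,
                       validate = TRUE) {
  kmers <- as.character(kmers)
  counts <- as.integer(counts)
  if (length(kmers) != length(counts))
    stop("kmers and counts must have equal length")
  if (is.null(k)) {
    k <- if (length(kmers)) nchar(kmers[1L]) else 0L
  }
  k <- as.integer(k)
  min_count <- as.integer(min_count)
  if (validate && length(kmers)) {
    if (any(nchar(kmers) != k))
      stop("all k-mers must have length k = ", k)
    can <- rc_canonical(kmers)  # also rejects non-ACGT characters
    if (any(can != kmers))
      stop("k-mers must be canonical (lexicographic min of self and reverse complement)")
    if (any(counts < min_count))
      stop("all counts must be >= min_count = ", min_count)
    if (anyDuplicated(kmers))
      stop("duplicate k-mers in table")
  }
  ord <- order(kmers, method = "radix")
  structure(list(k = k, min_count = min_count,
                 kmers = kmers[ord], counts = counts[ord]),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: %d canonical %d-mers (min_count = %d)\n",
              length(x$kmers), x$k, x$min_count))
  if (length(x$kmers)) {
    n <- min(5L, length(x$kmers))
    cat(paste0("  ", x$kmers[seq_len(n)], "\t", x$counts[seq_len(n)],
               collapse = "\n"), "\n")
    if (length(x$kmers) > n) cat("  ...\n")
  }
  invisible(x)
}

#' @export
length.kmer_table <- function(x) length(x$kmers)

#' Count canonical k-mers in a set of reads
#'
#' Every k-window consisting only of A/C/G/T contributes one occurrence to
#' its canonical k-mer; windows containing any other character (e.g. N) are
#' skipped. Base qualities play no role: sequencing errors are handled
#' downstream by the z-score correction stage.
#'
#' @param reads Character vector of read sequences.
#' @param k K-mer length (default 31; odd values avoid palindromic k-mers).
#' @param min_count Entries with a count below this are dropped (default 1,
#'   i.e. keep everything).
#' @return A [kmer_table()].
#' @export
#' @examples
#' count_kmers(c("ACGT"), k = 3)  # ACG counted twice via canonicalization
count_kmers <- function(reads, k = 31L, min_count = 1L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  res <- rc_count_kmers(as.character(reads), k)
  keep <- res$count >= min_count
  kmer_table(res$kmer[keep], res$count[keep], k = k,
             min_count = as.integer(min_count), validate = FALSE)
}

#' Read sequences from FASTQ files
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] accepting plain or
#' gzipped 4-line FASTQ.
#'
#' @param files Character vector of FASTQ(.gz) paths.
#' @return Character vector of read sequences (uppercased).
#' @export
read_fastq <- function(files) {
  reads <- lapply(files, function(f) {
    if (!file.exists(f)) stop("FASTQ file not found: ", f)
    .check_fastq_structure(f)
    rec <- tryCatch(
      Biostrings::readDNAStringSet(f, format = "fastq"),
      error = function(e) stop("malformed FASTQ in '", f, "': ",
                               conditionMessage(e), call. = FALSE))
    toupper(as.character(rec))
  })
  unname(unlist(reads))
}

# structural validation of 4-line FASTQ records; the sequence parsing
# itself is delegated to Biostrings
.check_fastq_structure <- function(f) {
  lines <- readLines(f, warn = FALSE)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("malformed FASTQ in '", f, "': truncated record ",
         n %/% 4L + 1L, " (", n, " lines, not a multiple of 4)")
  if (n == 0L) return(invisible())
  heads <- seq(1L, n, by = 4L)
  bad <- which(!startsWith(lines[heads], "@"))
  if (length(bad))
    stop("malformed FASTQ in '", f, "': record ", bad[1L],
         " does not start with '@'")
  seps <- which(!startsWith(lines[heads + 2L], "+"))
  if (length(seps))
    stop("malformed FASTQ in '", f, "': record ", seps[1L],
         " lacks the '+' separator line")
  invisible()
}

#' Count canonical k-mers directly from FASTQ files
#'
#' @inheritParams count_kmers
#' @param files Character vector of FASTQ(.gz) paths (e.g. R1 and R2 of a
#'   paired-end run; mates are simply pooled).
#' @return A [kmer_table()].
#' @export
count_fastq <- function(files, k = 31L, min_count = 1L) {
  reads <- read_fastq(files)
  if (!length(reads)) stop("no reads found in: ", paste(files, collapse = ", "))
  count_kmers(reads, k = k, min_count = min_count)
}

#' Write a counted k-mer table to TSV
#'
#' Lines are `kmer<TAB>count`, sorted lexicographically by k-mer, with no
#' header.
#'
#' @param table A [kmer_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(table, path) {
  stopifnot(inherits(table, "kmer_table"))
  if (!length(table$kmers)) {
    file.create(path)
  } else {
    data.table::fwrite(
      data.table::data.table(table$kmers, table$counts),
      file = path, sep = "\t", col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a counted k-mer table from TSV
#'
#' @param path TSV path as written by [write_kmer_table()].
#' @param min_count Minimum count to retain.
#' @return A [kmer_table()].
#' @export
read_kmer_table <- function(path, min_count = 1L) {
  if (!file.exists(path)) stop("k-mer table not found: ", path)
  if (file.size(path) == 0)
    return(kmer_table(character(), integer(), k = 0L,
                      min_count = as.integer(min_count)))
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("kmer", "count"),
                          colClasses = list(character = 1L, integer = 2L))
  if (anyDuplicated(dt$kmer))
    stop("duplicate k-mer in table file: ",
         dt$kmer[anyDuplicated(dt$kmer)][1L])
  keep <- dt$count >= min_count
  kmer_table(dt$kmer[keep], dt$count[keep],
             min_count = as.integer(min_count))
}
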