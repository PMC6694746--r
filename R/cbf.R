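#' Bloom filter sizing formula
#'
#' Number of bit positions per plane for `n` keys at target false-positive
#' rate `p`: `m = ceiling(-n * ln(p) / (ln 2)^2)`.
#'
#' @param n Number of k-mers to encode (`>= 1`).
#' @param p Target false-positive rate, strictly between 0 and 1.
#' @return Number of bits `m` (double, exact integer value).
#' @export
#' @examples
#' bloom_size(1000, 0.01)  # 9586
bloom_size <- function(n, p) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  ceiling(-as.numeric(n) * log(p) / log(2)^2)
}

#' Create an empty coupled Bloom filter
#'
#' A coupled Bloom filter pairs a membership bit plane `B+` with a count bit
#' plane `B-` of the same length `m`. A k-mer with count `f` sets its `h`
#' membership bits and assigns bit `i` of `min(f, 2^h - 1)` to the
#' count-plane position selected by hash function `i`. Counts of colliding
#' keys can therefore overwrite each other; the structure trades exact
#' counts for O(1) membership and constant memory.
#'
#' @param k K-mer length the filter stores.
#' @param m Number of bit positions per plane.
#' @param h Number of hash functions, equal to the count bit width
#'   (1--30; default 8, saturating counts at 255).
#' @param seeds Two integer seeds defining the hash family (stored in the
#'   filter so that serialization is self-describing).
#' @param n,p Bookkeeping: number of keys the filter was sized for and the
#'   target false-positive rate (recorded, not enforced).
#' @return An object of class `cbf`.
#' @seealso [encode_kmers()] for sizing + insertion in one call.
#' @export
cbf_new <- function(k, m, h = 8L, seeds = c(7L, 13L), n = 0, p = NA_real_) {
  k <- as.integer(k); h <- as.integer(h)
  m <- as.numeric(m)
  if (k < 1L) stop("k must be >= 1")
  if (h < 1L || h > 30L) stop("h must be in 1..30")
  if (m < 1) stop("m must be >= 1")
  if (length(seeds) != 2L) stop("seeds must be two integers")
  nbytes <- as.integer(ceiling(m / 8))
  structure(list(k = k, m = m, h = h, seeds = as.integer(seeds),
                 n = as.numeric(n), p = as.numeric(p),
                 b_plus = raw(nbytes), b_minus = raw(nbytes)),
            class = "cbf")
}

#' Insert counted k-mers into a coupled Bloom filter
#'
#' Keys are canonicalized before hashing; counts saturate at `2^h - 1`.
#' Count bits are assigned (last write wins), so later colliding inserts can
#' corrupt earlier counts -- an accepted approximation of the structure.
#'
#' @param filter A [cbf_new()] object.
#' @param kmers Character vector of k-mers (length `k`).
#' @param counts Integer vector of counts.
#' @return The updated `cbf` (functional update; the input is unchanged).
#' @export
cbf_insert <- function(filter, kmers, counts) {
  stopifnot(inherits(filter, "cbf"))
  kmers <- as.character(kmers)
  if (length(kmers) != length(counts))
    stop("kmers and counts must have equal length")
  if (length(kmers) && any(nchar(kmers) != filter$k))
    stop("k-mer length does not match filter k = ", filter$k)
  planes <- rc_cbf_insert(filter$b_plus, filter$b_minus,
                          kmers, as.integer(counts),
                          filter$m, filter$h,
                          filter$seeds[1L], filter$seeds[2L])
  filter$b_plus <- planes$b_plus
  filter$b_minus <- planes$b_minus
  filter
}

#' Encode a counted k-mer table into a coupled Bloom filter
#'
#' Sizes the planes with [bloom_size()] from the table size and the target
#' false-positive rate, then inserts every entry.
#'
#' @param table A [kmer_table()]; must be non-empty.
#' @param p Target false-positive rate (default 0.01).
#' @param h Count bit width / number of hash functions (default 8).
#' @param seeds Two integer hash seeds.
#' @param m Optional explicit plane size overriding [bloom_size()] (used
#'   e.g. to study collision behavior).
#' @return A `cbf` object.
#' @export
encode_kmers <- function(table, p = 0.01, h = 8L, seeds = c(7L, 13L),
                         m = NULL) {
  stopifnot(inherits(table, "kmer_table"))
  n <- length(table$kmers)
  if (n == 0L) stop("cannot encode an empty k-mer table")
  if (is.null(m)) m <- bloom_size(n, p)
  filt <- cbf_new(table$k, m, h = h, seeds = seeds, n = n, p = p)
  cbf_insert(filt, table$kmers, table$counts)
}

#' Decode approximate counts from a coupled Bloom filter
#'
#' Queries are canonicalized internally, so either strand may be passed.
#' A query whose membership bits are not all set decodes to 0 (absent); an
#' inserted k-mer always decodes to a positive value (no false negatives),
#' though the value itself may be corrupted by collisions. Because
#' membership bits are never cleared, a passing query whose assembled count
#' bits read 0 can only be a collision artifact (every inserted count is
#' at least 1), so such values are reported as 1.
#'
#' @param filter A `cbf` object.
#' @param queries Character vector of k-length sequences.
#' @return Integer vector of decoded counts (0 = absent).
#' @export
cbf_decode <- function(filter, queries) {
  stopifnot(inherits(filter, "cbf"))
  queries <- as.character(queries)
  if (!length(queries)) return(integer())
  if (any(nchar(queries) != filter$k))
    stop("query length does not match filter k = ", filter$k)
  rc_cbf_decode(filter$b_plus, filter$b_minus, queries,
                filter$m, filter$h, filter$seeds[1L], filter$seeds[2L])
}

#' @export
print.cbf <- function(x, ...) {
  cat(sprintf(
    "coupled Bloom filter: k = %d, m = %s bits x 2 planes, h = %d, n = %s, p = %s\n",
    x$k, format(x$m, big.mark = ","), x$h,
    format(x$n, big.mark = ","), format(x$p)))
  invisible(x)
}

CBF_MAGIC <- "CBF1"

#' Serialize a coupled Bloom filter to a binary file
#'
#' Layout: 4-byte magic `"CBF1"`, int version, int k, int h, two int hash
#' seeds, doubles n/m/p, int plane byte length, then the two raw bit planes
#' (membership first). Round-trips bit-exactly via [read_cbf()].
#'
#' @param filter A `cbf` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cbf <- function(filter, path) {
  stopifnot(inherits(filter, "cbf"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(CBF_MAGIC, con, nchars = 4L, eos = NULL)
  writeBin(c(1L, filter$k, filter$h, filter$seeds), con, size = 4L)
  writeBin(c(filter$n, filter$m, filter$p), con, size = 8L)
  writeBin(length(filter$b_plus), con, size = 4L)
  writeBin(filter$b_plus, con)
  writeBin(filter$b_minus, con)
  invisible(path)
}

#' Deserialize a coupled Bloom filter written by [write_cbf()]
#'
#' @param path Input path.
#' @return A `cbf` object.
#' @export
read_cbf <- function(path) {
  if (!file.exists(path)) stop("filter file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchars = 4L, useBytes = TRUE)
  if (!identical(magic, CBF_MAGIC))
    stop("not a coupled Bloom filter file: ", path)
  ints <- readBin(con, "integer", n = 5L, size = 4L)
  if (ints[1L] != 1L) stop("unsupported filter version: ", ints[1L])
  dbls <- readBin(con, "double", n = 3L, size = 8L)
  nbytes <- readBin(con, "integer", n = 1L, size = 4L)
  bp <- readBin(con, "raw", n = nbytes)
  bm <- readBin(con, "raw", n = nbytes)
  structure(list(k = ints[2L], m = dbls[2L], h = ints[3L],
                 seeds = ints[4:5], n = dbls[1L], p = dbls[3L],
                 b_plus = bp, b_minus = bm),
            class = "cbf")
}
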