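#' Bundle the three encoded k-mer stores of a trio
#'
#' @param father,mother,child `cbf` objects built from the father's,
#'   mother's and child's counted k-mer tables.
#' @param tau0 Count-ratio threshold: a child k-mer is kept when both
#'   parent/child count ratios are strictly below `tau0` (default 0.3).
#' @return An object of class `trio_stores`.
#' @export
trio_stores <- function(father, mother, child, tau0 = 0.3) {
  for (f in list(father, mother, child))
    if (!inherits(f, "cbf")) stop("father, mother and child must be cbf objects")
  if (father$k != child$k || mother$k != child$k)
    stop("all three filters must share the same k")
  if (!(tau0 > 0 && tau0 <= 1)) stop("tau0 must be in (0, 1]")
  structure(list(father = father, mother = mother, child = child,
                 tau0 = tau0), class = "trio_stores")
}

#' @export
print.trio_stores <- function(x, ...) {
  cat(sprintf("trio k-mer stores: k = %d, tau0 = %g\n", x$child$k, x$tau0))
  invisible(x)
}

#' Parent/child count ratios for every child k-mer
#'
#' Iteration is driven by the exact child table (Bloom filters cannot be
#' enumerated); parental counts are decoded from the father/mother stores.
#' The ratio of a parent absent from the store is 0.
#'
#' @param child_table The child's exact [kmer_table()].
#' @param stores A [trio_stores()] object.
#' @return A data.frame with columns `kmer`, `f_c`, `f_f`, `f_m`,
#'   `r_fc`, `r_mc`.
#' @export
trio_ratios <- function(child_table, stores) {
  stopifnot(inherits(child_table, "kmer_table"),
            inherits(stores, "trio_stores"))
  if (child_table$k != stores$child$k)
    stop("k mismatch between child table (", child_table$k,
         ") and stores (", stores$child$k, ")")
  f_c <- child_table$counts
  f_f <- cbf_decode(stores$father, child_table$kmers)
  f_m <- cbf_decode(stores$mother, child_table$kmers)
  data.frame(kmer = child_table$kmers, f_c = f_c, f_f = f_f, f_m = f_m,
             r_fc = f_f / f_c, r_mc = f_m / f_c,
             stringsAsFactors = FALSE)
}

#' Ratio filtering: keep child k-mers scarce in both parents
#'
#' A child k-mer is kept when `f_f / f_c < tau0` and `f_m / f_c < tau0`
#' (strict inequalities; a k-mer absent from a parent has ratio 0 and
#' passes, which is exactly the de novo signature).
#'
#' @inheritParams trio_ratios
#' @return The kept subset as a [kmer_table()] (child counts carried
#'   through).
#' @export
filter_trio <- function(child_table, stores) {
  r <- trio_ratios(child_table, stores)
  keep <- r$r_fc < stores$tau0 & r$r_mc < stores$tau0
  kmer_table(r$kmer[keep], r$f_c[keep], k = child_table$k,
             min_count = child_table$min_count, validate = FALSE)
}

#' Z-score of k-mers against their Hamming-distance-1 neighbors
#'
#' For each k-mer the `3k` single-substitution neighbors are canonicalized,
#' deduplicated, and looked up in the child store; those with a positive
#' decoded count form `N`. The z-score is `(f - mu) / sigma` where `mu` and
#' `sigma` are the population mean and standard deviation of the counts over
#' `N + {kmer}` (the k-mer's own exact count included). When `sigma == 0`
#' (no present neighbors, or all counts equal) the z-score is 0 by
#' convention; `sigma` is returned so callers can treat that case
#' explicitly. For fixed-length k-mers only substitutions preserve k, so
#' distance-1 neighbors are substitution neighbors.
#'
#' @param kmers Character vector of canonical k-mers.
#' @param counts Their exact counts (`f`).
#' @param child The child's `cbf` store used for neighbor lookups.
#' @return A data.frame with columns `z`, `sigma`, `n_neighbors`.
#' @export
kmer_zscore <- function(kmers, counts, child) {
  stopifnot(inherits(child, "cbf"))
  kmers <- as.character(kmers)
  if (length(kmers) != length(counts))
    stop("kmers and counts must have equal length")
  if (!length(kmers))
    return(data.frame(z = numeric(), sigma = numeric(),
                      n_neighbors = integer()))
  if (any(nchar(kmers) != child$k))
    stop("k-mer length does not match store k = ", child$k)
  res <- rc_zscore(kmers, as.integer(counts),
                   child$b_plus, child$b_minus, child$m, child$h,
                   child$seeds[1L], child$seeds[2L])
  data.frame(z = res$z, sigma = res$sigma, n_neighbors = res$n_neighbors)
}

#' Remove sequencing-error k-mers by the z-score rule
#'
#' A k-mer is considered error-free and retained when `z > z0` and
#' `f > f0` (strict inequalities). An isolated or degenerate k-mer with
#' `sigma == 0` has no evidence of being the error shadow of a neighbor,
#' so it is retained whenever `f > f0`.
#'
#' @param kept A [kmer_table()] (typically the output of [filter_trio()]).
#' @param child The child's `cbf` store.
#' @param z0 Z-score threshold (default 0.8).
#' @param f0 Minimum count (default 4; a count of exactly `f0` is removed).
#' @return The error-free subset as a [kmer_table()].
#' @export
correct_kmers <- function(kept, child, z0 = 0.8, f0 = 4) {
  stopifnot(inherits(kept, "kmer_table"))
  if (!length(kept$kmers)) return(kept)
  zs <- kmer_zscore(kept$kmers, kept$counts, child)
  keep <- (zs$z > z0 | zs$sigma == 0) & kept$counts > f0
  kmer_table(kept$kmers[keep], kept$counts[keep], k = kept$k,
             min_count = kept$min_count, validate = FALSE)
}

#' Histogram of parent/child count ratios
#'
#' Bins each child k-mer's per-parent count ratio into
#' `0`, `(0, 0.1]`, `(0.1, 0.2]`, `(0.2, 0.3]` and `> 0.3`. The `combined`
#' column bins the maximum of the two parental ratios, i.e. the quantity
#' the joint filtering rule thresholds (a k-mer is child-unique only when
#' both ratios are 0).
#'
#' @inheritParams trio_ratios
#' @param max_count Restrict the histogram to child k-mers with
#'   `f_c <= max_count` (default `Inf`, i.e. all).
#' @return A data.frame with columns `bin`, `father`, `mother`, `combined`.
#' @export
ratio_profile <- function(child_table, stores, max_count = Inf) {
  r <- trio_ratios(child_table, stores)
  r <- r[r$f_c <= max_count, , drop = FALSE]
  bin1 <- function(x) {
    cut(x, breaks = c(-Inf, 0, 0.1, 0.2, 0.3, Inf),
        labels = c("0", "(0,0.1]", "(0.1,0.2]", "(0.2,0.3]", ">0.3"))
  }
  lv <- c("0", "(0,0.1]", "(0.1,0.2]", "(0.2,0.3]", ">0.3")
  tab <- function(x) as.integer(table(factor(bin1(x), levels = lv)))
  data.frame(bin = lv,
             father = tab(r$r_fc),
             mother = tab(r$r_mc),
             combined = tab(pmax(r$r_fc, r$r_mc)),
             stringsAsFactors = FALSE)
}
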