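# small deterministic trio: three k-mers with hand-picked counts, encoded
# into generously sized filters so decoded counts are exact
make_toy_stores <- function(child_counts, father_counts, mother_counts,
                            kmers = c("AAACG", "AACCG", "AAGGG"),
                            tau0 = 0.3) {
  mk <- function(counts) {
    keep <- counts > 0L
    if (!any(keep))  # a store never holding any of the toy k-mers
      return(exact_cbf(kmer_table("CCCCC", 1L, k = 5L)))
    exact_cbf(kmer_table(kmers[keep], counts[keep], k = 5L))
  }
  list(stores = trio_stores(mk(father_counts), mk(mother_counts),
                            mk(child_counts), tau0 = tau0),
       child = kmer_table(kmers[child_counts > 0L],
                          child_counts[child_counts > 0L], k = 5L))
}

test_that("ratio filtering keeps child k-mers scarce in both parents, strict at tau0", {
  toy <- make_toy_stores(child_counts = c(10L, 10L, 5L),
                         father_counts = c(2L, 3L, 0L),
                         mother_counts = c(1L, 0L, 0L))
  kept <- filter_trio(toy$child, toy$stores)
  # AAACG: ratios 0.2 / 0.1 -> kept; AACCG: 0.3 is not < 0.3 -> rejected;
  # AAGGG: both parents absent, ratios 0 -> kept (the de novo signature)
  expect_setequal(kept$kmers, c("AAACG", "AAGGG"))
  expect_equal(kept$counts[kept$kmers == "AAACG"], 10L)

  r <- trio_ratios(toy$child, toy$stores)
  expect_equal(r$r_fc, r$f_f / r$f_c)
  expect_equal(r$r_mc, r$f_m / r$f_c)
})

test_that("filtering rejects mismatched k between table and stores", {
  toy <- make_toy_stores(c(5L, 5L, 5L), c(0L, 0L, 0L), c(0L, 0L, 0L))
  wrong <- kmer_table("ACG", 3L, k = 3L)
  expect_error(filter_trio(wrong, toy$stores), "k mismatch")
})

test_that("Bloom-backed filtering matches the exact hash-map filter on small trios", {
  set.seed(505)
  for (trial in 1:3) {
    genome <- random_seq(3000)
    reads <- substring(genome, seq(1, 2900, by = 7), seq(1, 2900, by = 7) + 99)
    ctab <- count_kmers(reads, k = 15)
    ftab <- count_kmers(reads[seq(1, length(reads), 2)], k = 15)
    mtab <- count_kmers(reads[seq(2, length(reads), 2)], k = 15)
    stores <- trio_stores(exact_cbf(ftab), exact_cbf(mtab), exact_cbf(ctab))
    kept <- filter_trio(ctab, stores)
    expect_setequal(kept$kmers, oracle_filter(ctab, ftab, mtab, 0.3))
  }
})

test_that("z-scores reproduce hand-computed population moments", {
  # kappa with count 10 and three present neighbors of count 2:
  # mu = 4, population sd = sqrt(12), z = 6/sqrt(12) = 1.7321
  kmers <- c("AAAAA", "CAAAA", "GAAAA", "TAAAA")
  store <- exact_cbf(kmer_table(canonical(kmers), c(10L, 2L, 2L, 2L), k = 5L))
  zs <- kmer_zscore("AAAAA", 10L, store)
  expect_equal(zs$z, 6 / sqrt(12), tolerance = 1e-12)
  expect_equal(zs$n_neighbors, 3L)

  # no present neighbors: N' = {kappa}, sigma = 0, z = 0 by convention
  iso <- exact_cbf(kmer_table("AAAAA", 10L, k = 5L))
  z0 <- kmer_zscore("AAAAA", 10L, iso)
  expect_equal(z0$z, 0)
  expect_equal(z0$sigma, 0)

  # all counts equal: sigma = 0, z = 0
  eq <- exact_cbf(kmer_table(canonical(c("AAAAA", "CAAAA", "GAAAA")),
                             c(5L, 5L, 5L), k = 5L))
  zeq <- kmer_zscore("AAAAA", 5L, eq)
  expect_equal(zeq$z, 0)
  expect_equal(zeq$sigma, 0)
})

test_that("z-scores agree with the brute-force oracle on a random exact store", {
  set.seed(606)
  genome <- random_seq(400)
  tab <- count_kmers(genome, k = 9)
  store <- exact_cbf(tab)
  lookup <- function(km) {
    i <- match(km, tab$kmers)
    if (is.na(i)) 0 else tab$counts[i]
  }
  pick <- sample(length(tab$kmers), 25L)
  zs <- kmer_zscore(tab$kmers[pick], tab$counts[pick], store)
  zo <- vapply(pick, function(i) oracle_zscore(tab$kmers[i], tab$counts[i],
                                               lookup), numeric(1L))
  expect_equal(zs$z, zo, tolerance = 1e-10)
})

test_that("correction applies strict thresholds with the sigma-zero escape", {
  kmers <- canonical(c("AAAAA", "CAAAA", "GAAAA", "TAAAA"))
  store <- exact_cbf(kmer_table(kmers, c(10L, 2L, 2L, 2L), k = 5L))

  # z = 1.73 > 0.8 and f = 10 > 4 -> kept
  kept <- correct_kmers(kmer_table("AAAAA", 10L, k = 5L), store)
  expect_equal(kept$kmers, "AAAAA")

  # f = 4 fails the strict count threshold even with a high z
  store4 <- exact_cbf(kmer_table(kmers, c(4L, 1L, 1L, 1L), k = 5L))
  expect_length(correct_kmers(kmer_table("AAAAA", 4L, k = 5L),
                              store4)$kmers, 0L)

  # isolated k-mer (no neighbors): sigma = 0 escape keeps it when f > f0
  iso <- exact_cbf(kmer_table("AAAAA", 6L, k = 5L))
  expect_equal(correct_kmers(kmer_table("AAAAA", 6L, k = 5L), iso)$kmers,
               "AAAAA")
  expect_length(correct_kmers(kmer_table("AAAAA", 6L, k = 5L), iso,
                              f0 = 6)$kmers, 0L)
})

test_that("correction is monotone in z0 and f0", {
  fx <- clean_fixture()
  kept <- fx$kept
  base <- correct_kmers(kept, fx$stores$child, z0 = 0.8, f0 = 4)
  for (z0 in c(1.2, 2)) {
    tighter <- correct_kmers(kept, fx$stores$child, z0 = z0, f0 = 4)
    expect_true(all(tighter$kmers %in% base$kmers))
  }
  for (f0 in c(6, 10)) {
    tighter <- correct_kmers(kept, fx$stores$child, z0 = 0.8, f0 = f0)
    expect_true(all(tighter$kmers %in% base$kmers))
  }
})

test_that("ratio histogram bins per parent and for the joint criterion", {
  kmers <- c("AAACG", "AACCG", "AAGGG", "AATGG")
  child <- kmer_table(kmers, c(20L, 20L, 20L, 20L), k = 5L)
  father <- c(0L, 1L, 5L, 18L)    # ratios 0, 0.05, 0.25, 0.9
  mother <- c(0L, 0L, 0L, 0L)
  mk <- function(counts) {
    keep <- counts > 0L
    if (!any(keep)) return(exact_cbf(kmer_table("CCCCC", 1L, k = 5L)))
    exact_cbf(kmer_table(kmers[keep], counts[keep], k = 5L))
  }
  stores <- trio_stores(mk(father), mk(mother), exact_cbf(child))
  prof <- ratio_profile(child, stores)
  expect_equal(prof$bin, c("0", "(0,0.1]", "(0.1,0.2]", "(0.2,0.3]", ">0.3"))
  expect_equal(prof$father, c(1L, 1L, 0L, 1L, 1L))
  expect_equal(prof$mother, c(4L, 0L, 0L, 0L, 0L))
  # joint column uses the max of the two parental ratios
  expect_equal(prof$combined, prof$father)
  expect_equal(sum(prof$father), length(child$kmers))
  # count restriction drops rows, never adds
  prof5 <- ratio_profile(child, stores, max_count = 5)
  expect_true(all(prof5$father <= prof$father))
})
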