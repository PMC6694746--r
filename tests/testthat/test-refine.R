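# hand-built single-contig reference + VCF text fixtures

write_ref <- function(seq, chrom = "chr1") {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seq, chrom)), path)
  path
}

write_vcf_text <- function(rows, chrom = "chr1") {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", chrom),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
  path
}

test_that("alt windows enumerate exactly the k-mers the variant creates", {
  set.seed(808)
  # SNV in the middle of a 61-base locus with k = 31: 31 windows
  locus <- random_seq(61)
  ref <- setNames(locus, "chr1")
  refb <- substr(locus, 31, 31)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1L]
  w <- alt_window_kmers(ref, "chr1", 31L, refb, alt, k = 31L)
  expect_length(w, 31L)
  expect_true(all(w == canonical(w)))

  # SNV five bases from the end: flank truncation leaves 6 windows
  refb2 <- substr(locus, 56, 56)
  alt2 <- setdiff(c("A", "C", "G", "T"), refb2)[1L]
  expect_length(alt_window_kmers(ref, "chr1", 56L, refb2, alt2, k = 31L), 6L)

  # 1-base deletion in AAACAAA with k = 3: windows spanning the junction
  del_ref <- setNames("AAACAAA", "chr1")
  wdel <- alt_window_kmers(del_ref, "chr1", 3L, "AC", "A", k = 3L)
  expect_length(wdel, 1L)   # all three spanning windows are AAA
  expect_equal(wdel, "AAA")

  # the same deletion in a non-degenerate context gives 3 distinct windows
  del_ref2 <- setNames("ATACGTA", "chr1")
  wdel2 <- alt_window_kmers(del_ref2, "chr1", 3L, "AC", "A", k = 3L)
  expect_length(wdel2, 3L)

  expect_error(alt_window_kmers(ref, "chr1", 31L, "N", "A", 31L),
               "mismatch|non-ACGT")
  expect_error(alt_window_kmers(ref, "chr1", 10L, "TTTTT", "T", 31L),
               "mismatch")
  expect_error(alt_window_kmers(ref, "chr2", 10L, "A", "T", 31L),
               "not found")
})

test_that("refinement applies both criteria with min_sum boundary at 3", {
  set.seed(809)
  locus <- random_seq(121)
  refpath <- write_ref(locus)
  k <- 31L
  pos <- 61L
  refb <- substr(locus, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1L]
  wins <- alt_window_kmers(setNames(locus, "chr1"), "chr1", pos, refb, alt, k)

  vcf <- write_vcf_text(sprintf("chr1\t%d\t.\t%s\t%s\t.\t.\t.", pos, refb, alt))

  # two supporting k-mers with counts 2 and 1: sum 3 -> pass
  kept3 <- kmer_table(wins[1:2], c(2L, 1L), k = k)
  res <- refine_vcf(vcf, refpath, kept3, k = k, min_sum = 3L)
  expect_true(res$pass)
  expect_equal(res$support_kmers, 2L)
  expect_equal(res$support_count_sum, 3L)

  # single supporting k-mer with count 2: sum 2 -> fail
  kept2 <- kmer_table(wins[1L], 2L, k = k)
  expect_false(refine_vcf(vcf, refpath, kept2, k = k, min_sum = 3L)$pass)

  # no alt window in the kept set -> fail regardless of counts
  other <- setdiff(canonical(vapply(1:60, function(i) random_seq(k),
                                    character(1L))), wins)
  kept0 <- kmer_table(other[1:10], rep(50L, 10L), k = k)
  res0 <- refine_vcf(vcf, refpath, kept0, k = k, min_sum = 3L)
  expect_false(res0$pass)
  expect_equal(res0$support_kmers, 0L)
})

test_that("the passing set shrinks monotonically in min_sum", {
  set.seed(810)
  locus <- random_seq(400)
  refpath <- write_ref(locus)
  k <- 31L
  rows <- character()
  kept_km <- character(); kept_ct <- integer()
  for (pos in c(60L, 160L, 260L, 360L)) {
    refb <- substr(locus, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), refb)[1L]
    rows <- c(rows, sprintf("chr1\t%d\t.\t%s\t%s\t.\t.\t.", pos, refb, alt))
    wins <- alt_window_kmers(setNames(locus, "chr1"), "chr1", pos, refb,
                             alt, k)
    n_sup <- (pos %/% 60L)  # varying support: 1..6 k-mers of count 1
    kept_km <- c(kept_km, wins[seq_len(min(n_sup, length(wins)))])
    kept_ct <- c(kept_ct, rep(1L, min(n_sup, length(wins))))
  }
  kept <- kmer_table(kept_km, kept_ct, k = k)
  vcf <- write_vcf_text(rows)
  passed <- vapply(1:6, function(ms)
    sum(refine_vcf(vcf, refpath, kept, k = k, min_sum = ms)$pass),
    numeric(1L))
  expect_true(all(diff(passed) <= 0))
})

test_that("multi-allelic records split, symbolic alleles skip, soft mode flags", {
  set.seed(811)
  locus <- random_seq(121)
  refpath <- write_ref(locus)
  k <- 31L
  pos <- 61L
  refb <- substr(locus, pos, pos)
  alts <- setdiff(c("A", "C", "G", "T"), refb)
  wins1 <- alt_window_kmers(setNames(locus, "chr1"), "chr1", pos, refb,
                            alts[1L], k)
  kept <- kmer_table(wins1[1:3], c(2L, 2L, 2L), k = k)

  vcf <- write_vcf_text(sprintf("chr1\t%d\t.\t%s\t%s,%s\t.\t.\t.",
                                pos, refb, alts[1L], alts[2L]))
  res <- refine_vcf(vcf, refpath, kept, k = k)
  expect_equal(nrow(res), 2L)         # one row per alternate allele
  expect_equal(res$pass, c(TRUE, FALSE))

  vcf_sym <- write_vcf_text(c(
    sprintf("chr1\t%d\t.\t%s\t<DEL>\t.\t.\t.", pos, refb),
    sprintf("chr1\t%d\t.\t%s\t%s\t.\t.\t.", pos, refb, alts[1L])))
  expect_warning(res_sym <- refine_vcf(vcf_sym, refpath, kept, k = k),
                 "symbolic")
  expect_equal(nrow(res_sym), 1L)

  # soft mode keeps failing records, flagging FILTER
  out <- withr::local_tempfile(fileext = ".vcf.gz")
  vcf2 <- write_vcf_text(c(
    sprintf("chr1\t%d\t.\t%s\t%s\t.\t.\t.", pos, refb, alts[1L]),
    sprintf("chr1\t%d\t.\t%s\t%s\t.\t.\t.", 10L, substr(locus, 10L, 10L),
            setdiff(c("A", "C", "G", "T"), substr(locus, 10L, 10L))[1L])))
  res2 <- refine_vcf(vcf2, refpath, kept, k = k, soft = TRUE, out = out)
  refined <- attr(res2, "vcf")
  expect_equal(nrow(refined@fix), 2L)
  expect_setequal(refined@fix[, "FILTER"], c("PASS", "kmer_fail"))
  expect_true(file.exists(out))
  back <- vcfR::read.vcfR(out, verbose = FALSE)
  expect_equal(nrow(back@fix), 2L)
  expect_true(all(grepl("KSUP=", back@fix[, "INFO"])))
  # position-sorted output
  expect_true(!is.unsorted(as.integer(back@fix[, "POS"])))
})

test_that("hard mode drops failing records and annotates the survivors", {
  set.seed(812)
  locus <- random_seq(121)
  refpath <- write_ref(locus)
  k <- 31L
  pos <- 61L
  refb <- substr(locus, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1L]
  wins <- alt_window_kmers(setNames(locus, "chr1"), "chr1", pos, refb, alt, k)
  kept <- kmer_table(wins[1:2], c(5L, 5L), k = k)
  far <- 10L
  vcf <- write_vcf_text(c(
    sprintf("chr1\t%d\t.\t%s\t%s\t.\t.\t.", pos, refb, alt),
    sprintf("chr1\t%d\t.\t%s\t%s\t.\t.\t.", far, substr(locus, far, far),
            setdiff(c("A", "C", "G", "T"), substr(locus, far, far))[1L])))
  res <- refine_vcf(vcf, refpath, kept, k = k)
  refined <- attr(res, "vcf")
  expect_equal(nrow(refined@fix), 1L)  # record count <= input count
  expect_equal(as.integer(refined@fix[, "POS"]), pos)
  expect_match(refined@fix[, "INFO"], "KSUP=2;KSUM=10")
})
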