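# VCF refinement against kept-k-mer evidence. External aligner/caller
# output comes in as VCF; coordinates are 1-based at the interface and all
# internal window arithmetic is done on spliced local haplotypes.

.as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (methods::is(reference, "DNAStringSet")) {
    seqs <- toupper(as.character(reference))
    # FASTA headers: keep the first whitespace-delimited token
    names(seqs) <- sub("\\s.*$", "", names(reference))
    return(seqs)
  }
  if (is.character(reference) && !is.null(names(reference)))
    return(toupper(reference))
  stop("reference must be a FASTA path, a DNAStringSet, or a named character vector")
}

#' Alt-haplotype k-mers covering a variant
#'
#' Splices the alternate allele into the reference with up to `k - 1` bases
#' of flank on each side (truncated at contig ends) and returns every
#' k-window of the spliced sequence that overlaps the alternate allele,
#' canonicalized and deduplicated. These are the k-mers that exist because
#' of the variant: an SNV with full flanks is covered by exactly `k`
#' windows, and a pure deletion by the windows spanning its junction
#' (the anchor base).
#'
#' @param reference FASTA path, `DNAStringSet`, or named character vector of
#'   contig sequences.
#' @param chrom Contig name.
#' @param pos 1-based position of the first reference-allele base (VCF
#'   convention: indels carry an anchor base).
#' @param ref,alt Reference and alternate allele strings (sequence-resolved;
#'   no symbolic alleles).
#' @param k K-mer length.
#' @return Character vector of canonical k-mers (possibly empty when the
#'   locus is shorter than `k`).
#' @export
alt_window_kmers <- function(reference, chrom, pos, ref, alt, k) {
  seqs <- .as_reference(reference)
  if (!chrom %in% names(seqs))
    stop("contig '", chrom, "' not found in reference")
  chromseq <- seqs[[chrom]]
  L <- nchar(chromseq)
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  if (pos < 1L || pos + nchar(ref) - 1L > L)
    stop("variant at ", chrom, ":", pos, " outside the reference")
  obs <- substr(chromseq, pos, pos + nchar(ref) - 1L)
  if (obs != ref)
    stop("reference allele mismatch at ", chrom, ":", pos,
         " (VCF says '", ref, "', genome has '", obs, "')")
  left <- substr(chromseq, max(1L, pos - (k - 1L)), pos - 1L)
  rstart <- pos + nchar(ref)
  right <- substr(chromseq, rstart, min(L, rstart + k - 2L))
  alt_seq <- paste0(left, alt, right)
  if (nchar(alt_seq) < k) return(character())
  astart <- nchar(left) + 1L            # alt-allele span within alt_seq
  aend <- nchar(left) + nchar(alt)
  w <- seq_len(nchar(alt_seq) - k + 1L)
  w <- w[w <= aend & w + k - 1L >= astart]
  if (!length(w)) return(character())
  unique(canonical(substring(alt_seq, w, w + k - 1L)))
}

.read_vcf_fix <- function(calls) {
  if (is.character(calls) && length(calls) == 1L) {
    if (!file.exists(calls)) stop("VCF not found: ", calls)
    calls <- vcfR::read.vcfR(calls, verbose = FALSE)
  }
  if (!methods::is(calls, "vcfR"))
    stop("calls must be a VCF path or a vcfR object")
  calls
}

#' Refine called variants by kept-k-mer support
#'
#' Each (sequence-resolved) VCF record is evaluated against the kept k-mer
#' set: its alt-haplotype windows ([alt_window_kmers()]) are looked up, and
#' the record passes when at least one window is found (`support_kmers >=
#' 1`) and the summed counts of the found windows reach `min_sum`.
#' Multi-allelic records are split per alternate allele; symbolic alleles
#' (`<DEL>`, breakends) are skipped with a warning. Failing records are
#' dropped from the output VCF, or flagged in FILTER when `soft = TRUE`;
#' the evidence is annotated in INFO as `KSUP` (supporting k-mers) and
#' `KSUM` (their count sum).
#'
#' @param calls VCF path (plain or gzipped) or a `vcfR` object.
#' @param reference FASTA path, `DNAStringSet`, or named character vector.
#' @param kept A [kmer_table()] of kept k-mers with counts.
#' @param k K-mer length; defaults to `kept$k`.
#' @param min_sum Minimum summed count of supporting k-mers (default 3;
#'   a sum of exactly 3 passes).
#' @param soft Keep failing records with `FILTER = "kmer_fail"` instead of
#'   dropping them.
#' @param out Optional path for the refined VCF (written with
#'   [vcfR::write.vcf()]; use a `.vcf.gz` suffix).
#' @return A data.frame with one row per evaluated allele: `chrom`, `pos`,
#'   `ref`, `alt`, `support_kmers`, `support_count_sum`, `pass`. The
#'   refined `vcfR` object is attached as attribute `"vcf"`.
#' @export
refine_vcf <- function(calls, reference, kept, k = NULL, min_sum = 3L,
                       soft = FALSE, out = NULL) {
  stopifnot(inherits(kept, "kmer_table"))
  if (is.null(k)) k <- kept$k
  vcf <- .read_vcf_fix(calls)
  seqs <- .as_reference(reference)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  rows <- vector("list", n)
  rec_pass <- logical(n)
  rec_info <- character(n)
  for (i in seq_len(n)) {
    chrom <- unname(fix[i, "CHROM"])
    if (!chrom %in% names(seqs))
      stop("VCF contig '", chrom, "' not found in the reference FASTA")
    pos <- unname(as.integer(fix[i, "POS"]))
    ref <- unname(fix[i, "REF"])
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    # anything that is not a plain sequence allele (<DEL>, breakends, *)
    symbolic <- !grepl("^[ACGTacgt]+$", alts)
    if (any(symbolic)) {
      warning("skipping symbolic allele(s) at ", chrom, ":", pos,
              " (", paste(alts[symbolic], collapse = ","), ")")
      alts <- alts[!symbolic]
    }
    if (!length(alts)) {
      rec_pass[i] <- FALSE
      rec_info[i] <- "KSUP=0;KSUM=0"
      next
    }
    sup_k <- integer(length(alts))
    sup_s <- integer(length(alts))
    for (a in seq_along(alts)) {
      wins <- alt_window_kmers(seqs, chrom, pos, ref, alts[a], k)
      hit <- match(wins, kept$kmers)
      hit <- hit[!is.na(hit)]
      sup_k[a] <- length(hit)
      sup_s[a] <- sum(kept$counts[hit])
    }
    pass <- sup_k >= 1L & sup_s >= min_sum
    rows[[i]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                            alt = alts, support_kmers = sup_k,
                            support_count_sum = sup_s, pass = pass,
                            stringsAsFactors = FALSE)
    # a record survives when any of its alleles is supported
    rec_pass[i] <- any(pass)
    rec_info[i] <- sprintf("KSUP=%s;KSUM=%s",
                           paste(sup_k, collapse = ","),
                           paste(sup_s, collapse = ","))
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(res))
    res <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      support_kmers = integer(),
                      support_count_sum = integer(), pass = logical(),
                      stringsAsFactors = FALSE)

  refined <- .annotate_and_subset_vcf(vcf, rec_pass, rec_info, soft)
  if (!is.null(out)) vcfR::write.vcf(refined, file = out)
  attr(res, "vcf") <- refined
  res
}

.annotate_and_subset_vcf <- function(vcf, rec_pass, rec_info, soft) {
  fx <- vcf@fix
  info <- fx[, "INFO"]
  info <- ifelse(is.na(info) | info == "." | info == "",
                 rec_info, paste0(info, ";", rec_info))
  fx[, "INFO"] <- info
  if (soft) {
    fx[, "FILTER"] <- ifelse(rec_pass, "PASS", "kmer_fail")
    sel <- rep(TRUE, nrow(fx))
  } else {
    sel <- rec_pass
  }
  fx <- fx[sel, , drop = FALSE]
  ord <- order(fx[, "CHROM"], as.integer(fx[, "POS"]), method = "radix")
  fx <- fx[ord, , drop = FALSE]
  gt <- vcf@gt
  if (length(gt) && nrow(gt) == length(sel))
    gt <- gt[sel, , drop = FALSE][ord, , drop = FALSE]
  meta <- vcf@meta
  add <- c(
    '##INFO=<ID=KSUP,Number=A,Type=Integer,Description="Kept k-mers covering the alt allele">',
    '##INFO=<ID=KSUM,Number=A,Type=Integer,Description="Summed count of covering kept k-mers">')
  if (soft)
    add <- c(add, '##FILTER=<ID=kmer_fail,Description="Insufficient kept k-mer support">')
  meta <- c(meta, add[!add %in% meta])
  methods::new("vcfR", meta = meta, fix = fx, gt = gt)
}
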