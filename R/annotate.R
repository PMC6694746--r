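# Gene-proximity filter for lncRNA candidates: variants falling both inside
# a gene region extended by a fixed distance and inside an lncRNA interval.

.as_regions <- function(x, what = "regions") {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop(what, " BED file not found: ", x)
    x <- tryCatch(rtracklayer::import(x, format = "bed"),
                  error = function(e) stop("malformed BED for ", what, " ('",
                                           conditionMessage(e), "')",
                                           call. = FALSE))
  }
  if (is.data.frame(x)) {
    nm <- if ("name" %in% names(x)) x$name else
      paste0(what, "_", seq_len(nrow(x)))
    x <- GenomicRanges::GRanges(
      x$chrom, IRanges::IRanges(x$start + 1L, x$end), name = nm)
  }
  if (!methods::is(x, "GRanges"))
    stop(what, " must be a BED path, a GRanges, or a data.frame with chrom/start/end")
  if (is.null(x$name) || anyNA(x$name))
    x$name <- paste0(what, "_", seq_along(x))
  x
}

.variant_positions <- function(variants) {
  if (is.character(variants) && length(variants) == 1L) {
    if (!file.exists(variants)) stop("VCF not found: ", variants)
    variants <- vcfR::read.vcfR(variants, verbose = FALSE)
  }
  if (methods::is(variants, "vcfR")) {
    fix <- vcfR::getFIX(variants)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                         dimnames = list(NULL, names(fix)))
    variants <- data.frame(chrom = fix[, "CHROM"],
                           pos = as.integer(fix[, "POS"]),
                           ref = fix[, "REF"], alt = fix[, "ALT"],
                           stringsAsFactors = FALSE)
  }
  if (!is.data.frame(variants) || !all(c("chrom", "pos") %in% names(variants)))
    stop("variants must be a VCF path, a vcfR object, or a data.frame with chrom/pos")
  variants
}

#' Variants near genes and inside lncRNA annotations
#'
#' Extends every gene region by `distance` bp upstream and downstream
#' (clamped at position 1; strand is ignored, the extension is symmetric)
#' and reports each variant whose position lies inside an extended gene
#' region and inside an lncRNA interval. For indels the VCF anchor-base
#' position is used. All qualifying (variant, gene, lncRNA) triples are
#' emitted.
#'
#' @param variants VCF path, `vcfR` object, or data.frame with at least
#'   `chrom` and `pos` (1-based).
#' @param genes,lncrnas BED3+ paths, `GRanges`, or data.frames with
#'   `chrom`/`start`/`end` (0-based half-open) and optional `name`.
#' @param distance Extension distance in bp (`>= 0`); the field's
#'   conventional grid is 100, 200, 500 and 1000.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt` (when
#'   available), `gene`, `lncrna`, `distance`, ordered by position then
#'   gene then lncRNA (independent of input record order).
#' @export
proximal_lncrna_variants <- function(variants, genes, lncrnas, distance) {
  distance <- as.integer(distance)
  if (length(distance) != 1L || is.na(distance) || distance < 0L)
    stop("distance must be a single non-negative integer")
  vdf <- .variant_positions(variants)
  g <- .as_regions(genes, "gene")
  l <- .as_regions(lncrnas, "lncrna")
  gext <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(g),
    IRanges::IRanges(pmax(GenomicRanges::start(g) - distance, 1L),
                     GenomicRanges::end(g) + distance),
    name = g$name)
  v <- GenomicRanges::GRanges(vdf$chrom, IRanges::IRanges(vdf$pos, vdf$pos))
  ov_g <- GenomicRanges::findOverlaps(v, gext)
  ov_l <- GenomicRanges::findOverlaps(v, l)
  dg <- data.frame(vi = S4Vectors::queryHits(ov_g),
                   gene = gext$name[S4Vectors::subjectHits(ov_g)],
                   stringsAsFactors = FALSE)
  dl <- data.frame(vi = S4Vectors::queryHits(ov_l),
                   lncrna = l$name[S4Vectors::subjectHits(ov_l)],
                   stringsAsFactors = FALSE)
  hits <- merge(dg, dl, by = "vi")
  res <- data.frame(chrom = vdf$chrom[hits$vi], pos = vdf$pos[hits$vi],
                    stringsAsFactors = FALSE)
  if (!is.null(vdf$ref)) res$ref <- vdf$ref[hits$vi]
  if (!is.null(vdf$alt)) res$alt <- vdf$alt[hits$vi]
  res$gene <- hits$gene
  res$lncrna <- hits$lncrna
  res$distance <- rep(distance, nrow(res))
  res <- res[order(res$chrom, res$pos, res$gene, res$lncrna,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}
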