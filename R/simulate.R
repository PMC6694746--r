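# Synthetic diploid trio generator: a random single-chromosome reference,
# heterozygous parental variants transmitted to the child, child-only de
# novo variants, and uniform-coverage reads with i.i.d. substitution
# errors. Deliberately simple (uniform base composition, no repeats, no
# quality model) -- just enough structure to exercise every stage of the
# method with an exact ground truth.

BASES <- c("A", "C", "G", "T")

#' Configuration for a simulated trio
#'
#' @param genome_length Reference length in bp.
#' @param coverage Per-individual fold coverage (default 30).
#' @param read_length Read length in bp (default 151).
#' @param error_rate Per-base substitution error probability
#'   (`0 <= error_rate < 0.1`).
#' @param n_inherited Number of parental heterozygous variants, split
#'   between the parents; each sits on the transmitted haplotype, so all
#'   are inherited by the child.
#' @param n_denovo Number of child-only variants.
#' @param indel_fraction Fraction of variants that are short indels
#'   (1--6 bp); the rest are SNVs.
#' @param min_spacing Minimum distance between planted variants (default
#'   100 bp, i.e. at least `2k` for the default `k = 31`, so per-variant
#'   k-mer accounting stays exact).
#' @param seed RNG seed; every simulation output is reproducible from it.
#' @param chrom Name of the single simulated chromosome.
#' @return An object of class `trio_sim_config`.
#' @export
trio_sim_config <- function(genome_length = 1e5, coverage = 30,
                            read_length = 151L, error_rate = 0.01,
                            n_inherited = 40L, n_denovo = 20L,
                            indel_fraction = 0.2, min_spacing = 100L,
                            seed = 1L, chrom = "chr1") {
  cfg <- list(genome_length = as.integer(genome_length),
              coverage = as.numeric(coverage),
              read_length = as.integer(read_length),
              error_rate = as.numeric(error_rate),
              n_inherited = as.integer(n_inherited),
              n_denovo = as.integer(n_denovo),
              indel_fraction = as.numeric(indel_fraction),
              min_spacing = as.integer(min_spacing),
              seed = as.integer(seed), chrom = as.character(chrom))
  if (cfg$genome_length < 2L * cfg$read_length)
    stop("genome_length must be at least twice the read length")
  if (cfg$coverage <= 0) stop("coverage must be > 0")
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.1)
    stop("error_rate must be in [0, 0.1)")
  if (cfg$n_inherited < 0L || cfg$n_denovo < 0L)
    stop("variant counts must be >= 0")
  if (cfg$indel_fraction < 0 || cfg$indel_fraction > 1)
    stop("indel_fraction must be in [0, 1]")
  structure(cfg, class = "trio_sim_config")
}

# non-overlapping variant positions with pairwise gaps >= min_spacing
.draw_positions <- function(n, genome_length, min_spacing) {
  if (n == 0L) return(integer())
  lo <- min_spacing + 1L
  hi <- genome_length - min_spacing
  if (hi < lo) stop("genome too short for the requested variant spacing")
  cand <- sort(sample(lo:hi, min(n * 10L, hi - lo + 1L)))
  keep <- integer(0)
  last <- -Inf
  for (p in cand) {
    if (p - last >= min_spacing) {
      keep <- c(keep, p)
      last <- p
      if (length(keep) == n) break
    }
  }
  if (length(keep) < n)
    stop("could not place ", n, " variants with spacing >= ", min_spacing,
         " on a ", genome_length, " bp genome; lower the counts or spacing")
  keep
}

.draw_variant <- function(reference, pos, indel_fraction) {
  if (runif(1) < indel_fraction) {
    len <- sample.int(6L, 1L)
    anchor <- substr(reference, pos, pos)
    if (runif(1) < 0.5) {  # insertion after the anchor base
      ins <- paste(sample(BASES, len, replace = TRUE), collapse = "")
      list(ref = anchor, alt = paste0(anchor, ins))
    } else {               # deletion of `len` bases after the anchor
      list(ref = substr(reference, pos, pos + len), alt = anchor)
    }
  } else {
    refb <- substr(reference, pos, pos)
    list(ref = refb, alt = sample(setdiff(BASES, refb), 1L))
  }
}

# splice a variant table into the reference, right to left
.apply_variants <- function(reference, variants) {
  if (!nrow(variants)) return(reference)
  variants <- variants[order(-variants$pos), , drop = FALSE]
  seq <- reference
  for (i in seq_len(nrow(variants))) {
    p <- variants$pos[i]
    seq <- paste0(substr(seq, 1L, p - 1L), variants$alt[i],
                  substr(seq, p + nchar(variants$ref[i]), nchar(seq)))
  }
  seq
}

.sample_reads <- function(haps, n_reads, read_length, error_rate) {
  hap_of <- sample.int(2L, n_reads, replace = TRUE)
  reads <- character(n_reads)
  for (h in 1:2) {
    idx <- which(hap_of == h)
    if (!length(idx)) next
    span <- nchar(haps[[h]]) - read_length + 1L
    starts <- sample.int(span, length(idx), replace = TRUE)
    reads[idx] <- substring(haps[[h]], starts, starts + read_length - 1L)
  }
  flip <- runif(n_reads) < 0.5
  if (any(flip)) reads[flip] <- rc_revcomp(reads[flip])
  if (error_rate > 0) {
    total <- n_reads * read_length
    nerr <- rbinom(1L, total, error_rate)
    if (nerr > 0L) {
      at <- sample.int(total, nerr)
      ri <- (at - 1L) %/% read_length + 1L
      off <- (at - 1L) %% read_length + 1L
      for (e in seq_len(nerr)) {
        cur <- substr(reads[ri[e]], off[e], off[e])
        substr(reads[ri[e]], off[e], off[e]) <-
          sample(setdiff(BASES, cur), 1L)
      }
    }
  }
  reads
}

#' Simulate a diploid trio with planted inherited and de novo variants
#'
#' Generates a random reference, gives each parent heterozygous variants on
#' the haplotype transmitted to the child (Mendelian inheritance of one
#' haplotype per parent), adds child-only de novo variants, and samples
#' uniform-coverage reads with i.i.d. substitution errors from both
#' haplotypes of every individual. Fully reproducible from the config seed.
#'
#' @param config A [trio_sim_config()].
#' @return An object of class `trio_sim`: a list with `config`, `reference`
#'   (string), `haplotypes` (two per member; haplotype 1 is the parent's
#'   transmitted one), `variants` (data.frame with `chrom`, `pos`, `ref`,
#'   `alt`, `origin` in father/mother/denovo, and the child haplotype `hap`
#'   carrying it), and `reads` (character vectors per member).
#' @export
simulate_trio <- function(config = trio_sim_config()) {
  stopifnot(inherits(config, "trio_sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  reference <- paste(sample(BASES, L, replace = TRUE), collapse = "")

  n_tot <- config$n_inherited + config$n_denovo
  pos <- .draw_positions(n_tot, L, config$min_spacing)
  pos <- sample(pos)  # shuffle before assigning origins
  n_f <- ceiling(config$n_inherited / 2)
  origin <- c(rep("father", n_f),
              rep("mother", config$n_inherited - n_f),
              rep("denovo", config$n_denovo))
  variants <- data.frame(chrom = config$chrom, pos = pos,
                         ref = NA_character_, alt = NA_character_,
                         origin = origin, hap = NA_character_,
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(variants))) {
    v <- .draw_variant(reference, variants$pos[i], config$indel_fraction)
    variants$ref[i] <- v$ref
    variants$alt[i] <- v$alt
  }
  is_dn <- variants$origin == "denovo"
  variants$hap[is_dn] <- sample(c("A", "B"), sum(is_dn), replace = TRUE)
  variants$hap[variants$origin == "father"] <- "A"
  variants$hap[variants$origin == "mother"] <- "B"
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  is_dn <- variants$origin == "denovo"

  vf <- variants[variants$origin == "father", , drop = FALSE]
  vm <- variants[variants$origin == "mother", , drop = FALSE]
  haplotypes <- list(
    father = c(.apply_variants(reference, vf), reference),
    mother = c(.apply_variants(reference, vm), reference),
    child = c(
      .apply_variants(reference, rbind(
        vf, variants[is_dn & variants$hap == "A", , drop = FALSE])),
      .apply_variants(reference, rbind(
        vm, variants[is_dn & variants$hap == "B", , drop = FALSE]))))

  n_reads <- round(L * config$coverage / config$read_length)
  reads <- lapply(haplotypes, .sample_reads, n_reads = n_reads,
                  read_length = config$read_length,
                  error_rate = config$error_rate)

  structure(list(config = config, reference = reference,
                 haplotypes = haplotypes, variants = variants,
                 reads = reads),
            class = "trio_sim")
}

#' @export
print.trio_sim <- function(x, ...) {
  cat(sprintf(
    "simulated trio: %s bp genome, %gx coverage, %d bp reads, error %g\n",
    format(x$config$genome_length, big.mark = ","), x$config$coverage,
    x$config$read_length, x$config$error_rate))
  cat(sprintf("  variants: %d inherited, %d de novo\n",
              sum(x$variants$origin != "denovo"),
              sum(x$variants$origin == "denovo")))
  invisible(x)
}

#' Write FASTQ records with constant qualities
#'
#' The method ignores base qualities, so a constant quality string is
#' emitted.
#'
#' @param reads Character vector of read sequences.
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @param ids Optional read names (default `read_1 ... read_n`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
  lines <- as.vector(rbind(paste0("@", ids), reads, "+",
                           vapply(nchar(reads), strrep, character(1L),
                                  x = "I")))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

.sim_vcfR <- function(sim, denovo_only = FALSE) {
  v <- sim$variants
  if (denovo_only) v <- v[v$origin == "denovo", , drop = FALSE]
  info <- paste0("ORIGIN=", v$origin,
                 ifelse(v$origin == "denovo", ";DENOVO", ""))
  fx <- cbind(CHROM = v$chrom, POS = as.character(v$pos), ID = ".",
              REF = v$ref, ALT = v$alt, QUAL = ".", FILTER = ".",
              INFO = info)
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##contig=<ID=%s,length=%d>", sim$config$chrom,
                    sim$config$genome_length),
            '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="Planted origin: father, mother or denovo">',
            '##INFO=<ID=DENOVO,Number=0,Type=Flag,Description="Child-only planted variant">')
  methods::new("vcfR", meta = meta, fix = fx,
               gt = matrix(character(), nrow = nrow(fx), ncol = 0L))
}

#' Write a simulated trio to disk
#'
#' Produces `ref.fa`, one FASTQ per member, the ground-truth VCF (de novo
#' variants carry a `DENOVO` flag in INFO) and a truth TSV.
#'
#' @param sim A [simulate_trio()] result.
#' @param dir Output directory (created if needed).
#' @param gzip Gzip the FASTQ files (default TRUE).
#' @return Named list of written paths.
#' @export
write_trio <- function(sim, dir, gzip = TRUE) {
  stopifnot(inherits(sim, "trio_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fq.gz" else ".fq"
  paths <- list(ref = file.path(dir, "ref.fa"),
                father = file.path(dir, paste0("father_R1", ext)),
                mother = file.path(dir, paste0("mother_R1", ext)),
                child = file.path(dir, paste0("child_R1", ext)),
                truth_vcf = file.path(dir, "truth.vcf.gz"),
                truth_tsv = file.path(dir, "truth.tsv"))
  refset <- Biostrings::DNAStringSet(setNames(sim$reference,
                                              sim$config$chrom))
  Biostrings::writeXStringSet(refset, paths$ref, width = 80L)
  for (m in c("father", "mother", "child"))
    write_fastq(sim$reads[[m]], paths[[m]],
                ids = paste0(m, "_", seq_along(sim$reads[[m]])))
  vcfR::write.vcf(.sim_vcfR(sim), file = paths$truth_vcf)
  data.table::fwrite(sim$variants, paths$truth_tsv, sep = "\t")
  invisible(paths)
}

#' Exact genome k-mer sets of a simulated trio
#'
#' Counts canonical k-mers directly on the truth haplotypes
#' (coverage-free), yielding the exact k-mer content of each genome and
#' the child-unique set -- the ground truth the read-based pipeline is
#' judged against.
#'
#' @param sim A [simulate_trio()] result.
#' @param k K-mer length.
#' @return A list with `father`, `mother`, `child` ([kmer_table()]s over
#'   the two haplotypes of each member) and `child_unique` (character
#'   vector of child k-mers absent from both parents' genomes).
#' @export
truth_kmer_sets <- function(sim, k = 31L) {
  stopifnot(inherits(sim, "trio_sim"))
  tabs <- lapply(sim$haplotypes, count_kmers, k = k)
  parental <- c(tabs$father$kmers, tabs$mother$kmers)
  list(father = tabs$father, mother = tabs$mother, child = tabs$child,
       child_unique = setdiff(tabs$child$kmers, parental))
}

#' Alt-haplotype k-mers of each planted de novo variant
#'
#' @param sim A [simulate_trio()] result.
#' @param k K-mer length.
#' @return Named list (one element per de novo variant, named
#'   `chrom:pos`) of canonical alt-window k-mers.
#' @export
denovo_variant_kmers <- function(sim, k = 31L) {
  stopifnot(inherits(sim, "trio_sim"))
  ref <- setNames(sim$reference, sim$config$chrom)
  dn <- sim$variants[sim$variants$origin == "denovo", , drop = FALSE]
  out <- lapply(seq_len(nrow(dn)), function(i)
    alt_window_kmers(ref, dn$chrom[i], dn$pos[i], dn$ref[i], dn$alt[i], k))
  names(out) <- paste0(dn$chrom, ":", dn$pos)
  out
}
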