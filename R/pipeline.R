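#' Pipeline parameter set
#'
#' Collects every tunable of the method with its conventional default:
#' `k = 31`, Bloom false-positive target `p = 0.01`, count bit width
#' `h = 8`, ratio threshold `tau0 = 0.3`, error-correction thresholds
#' `z0 = 0.8` and `f0 = 4`, extension cap `max_len = 1000`, refinement
#' count-sum floor `min_sum = 3`.
#'
#' @param k K-mer length.
#' @param p Bloom filter target false-positive rate.
#' @param h Count bit width / number of hash functions.
#' @param tau0 Parent/child count-ratio threshold.
#' @param z0,f0 Error-correction thresholds.
#' @param max_len Maximum contig length.
#' @param min_sum Minimum summed k-mer support in refinement.
#' @param min_count Minimum k-mer count retained when counting.
#' @param threads Reserved; the implementation is single-threaded and
#'   results are independent of any work partitioning.
#' @param seed Seed for the hash family of the Bloom filters.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 31L, p = 0.01, h = 8L, tau0 = 0.3,
                            z0 = 0.8, f0 = 4, max_len = 1000L,
                            min_sum = 3L, min_count = 1L, threads = 1L,
                            seed = 1L) {
  structure(list(k = as.integer(k), p = p, h = as.integer(h), tau0 = tau0,
                 z0 = z0, f0 = f0, max_len = as.integer(max_len),
                 min_sum = as.integer(min_sum),
                 min_count = as.integer(min_count),
                 threads = as.integer(threads), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the trio mining pipeline end to end
#'
#' count -> encode -> ratio filter -> error correction -> extension, with
#' optional k-mer refinement of an externally called VCF and an optional
#' gene-proximity lncRNA screen. The external aligner/caller is
#' deliberately not shelled out: the pipeline emits contigs as FASTA and
#' accepts their called variants back as VCF, keeping those tools the
#' user's choice.
#'
#' @param father,mother,child Character vectors of FASTQ(.gz) paths per
#'   member (paired files are pooled).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param calls Optional VCF of called variants to refine (requires
#'   `reference`).
#' @param reference Optional reference FASTA used by the refinement stage.
#' @param genes,lncrnas Optional BED files enabling the lncRNA proximity
#'   screen of the refined variants.
#' @param distances Gene-extension distances for the lncRNA screen.
#' @return The run manifest (also written to `manifest.json`): parameters,
#'   input md5 hashes, and the counts of k-mers/contigs/variants at every
#'   stage. Stage outputs are written to `out_dir` (`child.tsv`,
#'   `kept.tsv`, `contigs.fa`, `refined.vcf.gz`, `lncrna_candidates.tsv`).
#' @export
run_pipeline <- function(father, mother, child, out_dir,
                         config = pipeline_config(),
                         calls = NULL, reference = NULL,
                         genes = NULL, lncrnas = NULL,
                         distances = c(100L, 200L, 500L, 1000L)) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(calls) && is.null(reference))
    stop("refinement requested (calls given) but no reference FASTA; ",
         "pass `reference` or drop `calls`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(father = father, mother = mother, child = child)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("input FASTQ not found: ", paste(missing, collapse = ", "))

  seeds <- c(config$seed, config$seed + 101L)
  tables <- list(father = count_fastq(father, config$k, config$min_count),
                 mother = count_fastq(mother, config$k, config$min_count),
                 child = count_fastq(child, config$k, config$min_count))
  write_kmer_table(tables$child, file.path(out_dir, "child.tsv"))

  stores <- trio_stores(
    encode_kmers(tables$father, p = config$p, h = config$h, seeds = seeds),
    encode_kmers(tables$mother, p = config$p, h = config$h, seeds = seeds),
    encode_kmers(tables$child, p = config$p, h = config$h, seeds = seeds),
    tau0 = config$tau0)

  kept_ratio <- filter_trio(tables$child, stores)
  kept <- correct_kmers(kept_ratio, stores$child,
                        z0 = config$z0, f0 = config$f0)
  write_kmer_table(kept, file.path(out_dir, "kept.tsv"))

  contigs <- extend_all(kept, stores$child, max_len = config$max_len)
  write_contigs(contigs, file.path(out_dir, "contigs.fa"))

  manifest <- list(
    parameters = unclass(config),
    inputs = as.list(tools::md5sum(inputs)),
    counts = list(
      father_kmers = length(tables$father),
      mother_kmers = length(tables$mother),
      child_kmers = length(tables$child),
      kept_after_ratio = length(kept_ratio),
      kept_after_correction = length(kept),
      contigs = length(contigs)))

  if (!is.null(calls)) {
    res <- refine_vcf(calls, reference, kept, k = config$k,
                      min_sum = config$min_sum,
                      out = file.path(out_dir, "refined.vcf.gz"))
    manifest$counts$variants_in <- nrow(res)
    manifest$counts$variants_passed <- sum(res$pass)
    if (!is.null(genes) && !is.null(lncrnas)) {
      passed <- res[res$pass, , drop = FALSE]
      cand <- do.call(rbind, lapply(distances, function(d)
        proximal_lncrna_variants(passed, genes, lncrnas, d)))
      data.table::fwrite(cand, file.path(out_dir, "lncrna_candidates.tsv"),
                         sep = "\t")
      manifest$counts$lncrna_candidates <-
        as.list(setNames(vapply(distances, function(d)
          sum(cand$distance == d), integer(1L)),
          paste0("d", distances)))
    }
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
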