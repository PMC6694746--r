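# Shared simulated-trio fixtures, built once per test run and cached.
# `trio_fixture()` is the 100 kb / 30x / 1% error study trio used by the
# statistical checks; `clean_fixture()` is its error-free counterpart used
# by the extension checks.

.fixture_cache <- new.env(parent = emptyenv())

.fixture <- function(name, maker) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, maker(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

.build_trio <- function(cfg) {
  sim <- simulate_trio(cfg)
  tabs <- lapply(sim$reads, count_kmers, k = 31L)
  seeds <- c(2024L, 2125L)
  stores <- trio_stores(
    encode_kmers(tabs$father, p = 0.01, h = 8L, seeds = seeds),
    encode_kmers(tabs$mother, p = 0.01, h = 8L, seeds = seeds),
    encode_kmers(tabs$child, p = 0.01, h = 8L, seeds = seeds),
    tau0 = 0.3)
  kept <- filter_trio(tabs$child, stores)
  corrected <- correct_kmers(kept, stores$child, z0 = 0.8, f0 = 4)
  truth <- truth_kmer_sets(sim, 31L)
  list(sim = sim, tabs = tabs, stores = stores, kept = kept,
       corrected = corrected, truth = truth)
}

trio_fixture <- function() {
  .fixture("trio", function() .build_trio(
    trio_sim_config(genome_length = 1e5, coverage = 30, read_length = 151L,
                    error_rate = 0.01, n_inherited = 40L, n_denovo = 20L,
                    indel_fraction = 0.2, seed = 7L)))
}

clean_fixture <- function() {
  .fixture("clean", function() .build_trio(
    trio_sim_config(genome_length = 5e4, coverage = 30, read_length = 151L,
                    error_rate = 0, n_inherited = 20L, n_denovo = 10L,
                    indel_fraction = 0, seed = 19L)))
}

# a generously sized filter: collision-free in practice, so decoded counts
# are exact and membership false positives are negligible
exact_cbf <- function(table, h = 8L, seeds = c(5L, 6L)) {
  encode_kmers(table, h = h, seeds = seeds,
               m = max(4096 * length(table$kmers), 1e5))
}
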