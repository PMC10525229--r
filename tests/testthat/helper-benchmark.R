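# Shared, lazily-computed experiment runs. The desk-scale benchmark takes a
# couple of minutes; several test files assert different properties of the
# same run, so it is computed once per session.

.bench_cache <- new.env(parent = emptyenv())

get_benchmark <- function() {
  if (is.null(.bench_cache$ga)) {
    .bench_cache$ga <- run_experiment(experiment_config(seed = 1))
  }
  .bench_cache$ga
}

get_benchmark_noga <- function() {
  if (is.null(.bench_cache$noga)) {
    .bench_cache$noga <- run_experiment(experiment_config(ga = NULL, seed = 1))
  }
  .bench_cache$noga
}

tiny_experiment_config <- function(seed = 1, out_dir = NULL) {
  experiment_config(
    synth = synth_config(n_recordings = 2, duration_range = c(12, 12),
                         events_per_class = 3),
    ga = ga_config(genome_length = 32, population_size = 12, generations = 5),
    seed = seed, out_dir = out_dir)
}
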