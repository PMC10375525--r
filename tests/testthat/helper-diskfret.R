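# shared fixtures, all generated in code

table1 <- function() read_lifetime_table(lifetime_table_path())

# coupled-disk study defaults
cptmv_spec <- function(...) ring_array_spec(17, 1.95, 2, 2.5, ...)

sample3_components <- function() table_components(table1(), 3)
sample7_components <- function() table_components(table1(), 7)

# random but valid ring/coupling parameters for property tests
random_coupled_geometry <- function() {
  spec <- ring_array_spec(sample(3:20, 1), stats::runif(1, 0.5, 3),
                          sample(1:2, 1), stats::runif(1, 0, 4),
                          stats::runif(1, 0, 2 * pi))
  couple_disks(spec, spec, closest_pair = stats::runif(1, 2, 10))
}
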