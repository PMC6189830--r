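# small hand-built event table satisfying all invariants
tiny_events <- function() {
  data.frame(
    droplet_id = 1:4,
    clone = c("hit", "null", "null", "hit"),
    n_cells = c(12L, 12L, 12L, 12L),
    n_apoptotic = c(11L, 1L, 6L, 3L),
    sorted_positive = c(TRUE, FALSE, TRUE, FALSE),
    n_colonies_recovered = c(2L, 0L, 1L, 1L),
    n_positive_colonies = c(2L, 0L, 0L, 1L),
    stringsAsFactors = FALSE
  )
}

# default p19-style assay used across simulator tests
p19_assay <- function(...) {
  assay_params(hit_fraction = 0.001, p_background = 0.10, p_hit = 0.9,
               aggregate_size = 12L, ...)
}
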