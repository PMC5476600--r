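# Shared fixtures and a cache for expensive computations reused across
# test files (single-threaded test run; plain environment memoization).

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

hg08 <- phase_hg(0.8)

two_layer <- model_skin_two_layer()
three_layer <- model_skin_three_layer()
gauss_beam <- default_beam()

semi_inf_medium <- layered_medium(list(
  layer_optics(0.02, 10, hg08, 1.4, Inf)))

# the two-layer medium split into identical halves (merging identity)
two_layer_split <- layered_medium(list(
  layer_optics(0.02, 10, hg08, 1.4, 1),
  layer_optics(0.02, 10, hg08, 1.4, 1),
  layer_optics(0.03, 2.5, hg08, 1.4, Inf)))

# area-weighted average of a sampled radial curve over annular bins;
# values must be supplied at the Gauss nodes of bin_gauss_nodes()
bin_gauss_nodes <- function(r_edges, n_sub = 4) {
  gl <- lapply(seq_len(length(r_edges) - 1), function(i)
    pracma::gaussLegendre(n_sub, r_edges[i], r_edges[i + 1]))
  list(r = unlist(lapply(gl, `[[`, "x")), gl = gl)
}

bin_average_values <- function(nodes, values) {
  vapply(seq_along(nodes$gl), function(i) {
    g <- nodes$gl[[i]]
    v <- values[match(g$x, nodes$r)]
    sum(g$w * g$x * v) / sum(g$w * g$x)
  }, 0)
}

# MC tally layout shared by the time-domain acceptance checks
tr_time_edges <- c(seq(10, 100, by = 10), seq(120, 400, by = 20),
                   seq(440, 1000, by = 40), seq(1080, 2520, by = 80))
tr_r_edges <- c(1.8, 2.2)

time_fixture_mc <- function() cached("time_mc", {
  run_elastic(two_layer, gauss_beam,
              mc_config(1.2e7, seed = 1234, r_edges = tr_r_edges,
                        t_edges = tr_time_edges))
})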