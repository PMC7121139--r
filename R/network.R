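#' Build a random three-population network
#'
#' Realizes the neuron table and the directed connectivity. Population sizes
#' are `fraction * n_total` allocated by largest remainder so they always sum
#' to `n_total` (defaults: 3400 excitatory, 200 leader, 400 interneuron).
#' Each ordered pair (i, j), i != j, is connected independently with the
#' source population's probability `pc`; every edge carries the source's
#' weight `ws`. The damage term `dam` starts at 0 for all neurons.
#'
#' Wiring uses a stream derived from `config$seed` (key `"wiring"`), so
#' silencing and initialization draws never perturb the realized graph.
#'
#' @param config A [network_config()].
#' @return An `iaf_network`: list with `neurons` (data.frame: `id`,
#'   `population`, `v0`, `tau_m`, `dam`), `edges` (CSR by source:
#'   `src_ptr` 0-based offsets, `targets` 1-based ids, `w_src` per-source
#'   weight) and `n`.
#' @export
build_network <- function(config) {
  validate_config(config)
  n <- as.integer(config$n_total)
  sizes <- allocate_counts(vapply(config$populations, `[[`, numeric(1), "fraction"), n)
  pop_names <- vapply(config$populations, `[[`, character(1), "name")
  population <- factor(rep(pop_names, sizes), levels = pop_names)
  v0 <- rep(vapply(config$populations, `[[`, numeric(1), "v0"), sizes)
  tau_m <- rep(vapply(config$populations, function(p)
    if (is.null(p$tau_m)) config$tau_m else p$tau_m, numeric(1)), sizes)
  pc <- rep(vapply(config$populations, `[[`, numeric(1), "pc"), sizes)
  w_src <- rep(vapply(config$populations, `[[`, numeric(1), "ws"), sizes)

  wiring_seed <- derive_seed(config$seed, "wiring")
  set.seed(wiring_seed)
  tgt_list <- vector("list", n)
  for (i in seq_len(n)) {
    if (pc[i] <= 0) {
      tgt_list[[i]] <- integer(0)
    } else {
      hits <- which(stats::runif(n) < pc[i])
      tgt_list[[i]] <- hits[hits != i]
    }
  }
  lens <- lengths(tgt_list)
  structure(
    list(
      neurons = data.frame(id = seq_len(n), population = population,
                           v0 = v0, tau_m = tau_m, dam = numeric(n)),
      edges = list(src_ptr = c(0L, cumsum(lens)),
                   targets = as.integer(unlist(tgt_list, use.names = FALSE)),
                   w_src = w_src),
      n = n,
      wiring_seed = wiring_seed),
    class = "iaf_network")
}

#' Number of directed edges in a network
#' @param network An `iaf_network`.
#' @return Integer edge count.
#' @export
edge_count <- function(network) length(network$edges$targets)

#' Out-neighbours of one neuron
#' @param network An `iaf_network`.
#' @param i Neuron id (1-based).
#' @return Integer vector of postsynaptic neuron ids.
#' @export
out_neighbors <- function(network, i) {
  p <- network$edges$src_ptr
  network$edges$targets[seq.int(p[i] + 1L, length.out = p[i + 1L] - p[i])]
}

#' @export
print.iaf_network <- function(x, ...) {
  tab <- table(x$neurons$population)
  cat(sprintf("<iaf_network> %d neurons (%s), %d directed edges, %d silenced\n",
              x$n, paste(names(tab), tab, sep = "=", collapse = ", "),
              edge_count(x), sum(x$neurons$dam != 0)))
  invisible(x)
}

#' Draw the initial neuron state
#'
#' Membrane potentials start uniform on `[v_init_low, v_init_high]`
#' (default -60 to -50 mV), synaptic variables and refractory countdowns at
#' zero. The draw uses a stream derived from `seed` (key `"init"`), distinct
#' from the wiring stream.
#'
#' @param network An `iaf_network`.
#' @param config A [network_config()].
#' @param seed Master seed (defaults to `config$seed`).
#' @return A `neuron_state` list: `v`, `ge`, `gi`, `refractory_remaining`.
#' @export
initialize_state <- function(network, config, seed = config$seed) {
  set.seed(derive_seed(seed, "init"))
  structure(
    list(v = stats::runif(network$n, config$v_init_low, config$v_init_high),
         ge = numeric(network$n),
         gi = numeric(network$n),
         refractory_remaining = numeric(network$n)),
    class = "neuron_state")
}
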