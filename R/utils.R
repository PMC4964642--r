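# internal helpers shared across modules

# run code with a temporarily seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_symmetric <- function(m, what = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stopf("%s must be a square matrix", what)
  if (max(abs(m - t(m))) > tol)
    stopf("%s must be symmetric", what)
  invisible(m)
}

# abs(i - j) separation matrix for an n-node chain
separation_matrix <- function(n) abs(outer(seq_len(n), seq_len(n), "-"))

is_connected_adj <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
  igraph::is_connected(g)
}

n_components_adj <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
  igraph::components(g)$no
}
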