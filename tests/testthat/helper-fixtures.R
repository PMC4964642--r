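# fixtures and independent oracles used across the suite

# -- fixture builders -------------------------------------------------------

pdb_atom_line <- function(serial, resn, chain, resno, x, y, z,
                          alt = " ", occ = 1.00, icode = " ",
                          record = "ATOM") {
  sprintf("%-6s%5d  CA %1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          record, serial, alt, resn, chain, resno, icode, x, y, z, occ, 0)
}

# small hand-written PDB: 3 residues of chain A, 2 of chain B
tiny_pdb_text <- function() {
  c(pdb_atom_line(1, "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(3, "LYS", "A", 3, 7.6, 0, 0),
    pdb_atom_line(4, "SER", "B", 1, 50, 50, 50),
    pdb_atom_line(5, "THR", "B", 2, 53.8, 50, 50),
    "END")
}

# symmetric random 0/1 adjacency with zero diagonal
random_adjacency <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}

# weighted network container with weights >= 1 on links (entropy-feasible)
random_weighted_network <- function(n, p = 0.4, seed = 1, spread = 3) {
  set.seed(seed)
  adj <- random_adjacency(n, p, seed)
  w <- matrix(0, n, n)
  raw <- matrix(runif(n * n, 0, spread), n, n)
  raw <- (raw + t(raw)) / 2
  w <- (1 + raw) * adj
  structure(list(weights = w, shift = 0, n_residues = n),
            class = "weighted_contact_network")
}

random_potentials <- function(seed = 1, lo = -3, hi = 1) {
  set.seed(seed)
  aa <- pcnfold:::STANDARD_AA
  m <- matrix(runif(400, lo, hi), 20, 20, dimnames = list(aa, aa))
  potential_matrix((m + t(m)) / 2, name = sprintf("synthetic_%d", seed))
}

random_trace <- function(n, seed = 1, scale = 10) {
  set.seed(seed)
  ca_trace(sample(pcnfold:::STANDARD_AA, n, replace = TRUE),
           matrix(runif(3 * n, 0, scale), n, 3),
           source_id = sprintf("rand_%d", seed))
}

# -- independent oracles (plain double loops / BFS, no package internals) ---

oracle_distances <- function(coords) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
  d
}

oracle_threshold <- function(d, thr) {
  n <- nrow(d)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && d[i, j] > 0 && d[i, j] <= thr) a[i, j] <- 1
  a
}

oracle_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] != 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  max(comp)
}

# exhaustive break-order: strip diagonals 1, 2, ... until BFS finds > 1 component
oracle_break_order <- function(adj) {
  n <- nrow(adj)
  for (d in seq_len(n - 1)) {
    for (i in seq_len(n)) for (j in seq_len(n))
      if (abs(i - j) == d) adj[i, j] <- 0
    if (oracle_components(adj) > 1) return(d)
  }
  n - 1L
}

oracle_diagonal_counts <- function(adj) {
  n <- nrow(adj)
  counts <- integer(n - 1)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i < j && adj[i, j] == 1) {
      d <- j - i
      counts[d] <- counts[d] + 1L
    }
  counts
}
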