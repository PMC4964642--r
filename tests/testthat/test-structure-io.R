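# PDB parsing, distance matrices, PCN construction, potential weighting

test_that("hand-written ATOM records parse into an ordered C-alpha trace", {
  tr <- read_ca_trace(tiny_pdb_text())  # chain = "first" -> A
  expect_s3_class(tr, "ca_trace")
  expect_equal(length(tr$residues), 3)
  expect_equal(tr$residues, c("A", "G", "K"))
  expect_equal(tr$coords[, 1], c(0, 3.8, 7.6))
  expect_equal(tr$chain_id, "A")

  trB <- read_ca_trace(tiny_pdb_text(), chain = "B")
  expect_equal(trB$residues, c("S", "T"))
})

test_that("parse errors are loud and specific", {
  expect_error(read_ca_trace(tiny_pdb_text(), chain = "Z"), "chain 'Z' not found")
  expect_error(read_ca_trace(c(pdb_atom_line(1, "ALA", "A", 1, 0, 0, 0), "END")),
               "fewer than 2")
  no_ca <- "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O"
  expect_error(read_ca_trace(c(no_ca, "END")), "no C-alpha|cannot parse")
  bad_res <- c(pdb_atom_line(1, "UNK", "A", 1, 0, 0, 0),
               pdb_atom_line(2, "ALA", "A", 2, 3.8, 0, 0), "END")
  expect_error(read_ca_trace(bad_res), "UNK")
})

test_that("altLoc duplicates resolve to one coordinate per residue", {
  txt <- c(pdb_atom_line(1, "ALA", "A", 1, 0, 0, 0),
           pdb_atom_line(2, "GLY", "A", 2, 3.8, 0, 0, alt = "A", occ = 0.40),
           pdb_atom_line(3, "GLY", "A", 2, 4.2, 0, 0, alt = "B", occ = 0.60),
           pdb_atom_line(4, "LYS", "A", 3, 7.6, 0, 0),
           "END")
  tr <- read_ca_trace(txt)
  # residue-number dedup oracle: unique resno count
  expect_equal(length(tr$residues), 3)
  expect_equal(tr$coords[2, 1], 4.2)  # higher occupancy wins

  # occupancy tie -> altLoc letter order
  txt_tie <- c(pdb_atom_line(1, "ALA", "A", 1, 0, 0, 0),
               pdb_atom_line(2, "GLY", "A", 2, 3.8, 0, 0, alt = "B", occ = 0.50),
               pdb_atom_line(3, "GLY", "A", 2, 4.2, 0, 0, alt = "A", occ = 0.50),
               pdb_atom_line(4, "LYS", "A", 3, 7.6, 0, 0),
               "END")
  tr2 <- read_ca_trace(txt_tie)
  expect_equal(tr2$coords[2, 1], 4.2)  # altLoc A preferred on ties
})

test_that("MSE maps to M (HETATM), gaps warn but keep consecutive nodes", {
  txt <- c(pdb_atom_line(1, "ALA", "A", 1, 0, 0, 0),
           pdb_atom_line(2, "MSE", "A", 2, 3.8, 0, 0, record = "HETATM"),
           pdb_atom_line(3, "GLY", "A", 7, 7.6, 0, 0),
           "END")
  expect_warning(tr <- read_ca_trace(txt), "gap")
  expect_equal(tr$residues, c("A", "M", "G"))
  expect_equal(length(tr$residues), 3)
})

test_that("distance matrix matches the double-loop oracle", {
  tr <- ca_trace(c("A", "G"), rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(distance_matrix(tr)[1, 2], 5.0)

  tr20 <- random_trace(20, seed = 4)
  d <- distance_matrix(tr20)
  expect_equal(d, oracle_distances(tr20$coords), tolerance = 1e-12)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
})

test_that("PCN thresholding is inclusive at 8 A and matches brute force", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 7.99
  d[1, 3] <- d[3, 1] <- 8.01
  d[2, 3] <- d[3, 2] <- 8.00
  pcn <- build_pcn(d)
  expect_equal(pcn$adjacency[1, 2], 1)  # below threshold
  expect_equal(pcn$adjacency[1, 3], 0)  # above threshold
  expect_equal(pcn$adjacency[2, 3], 1)  # inclusive boundary

  # all pairs beyond cutoff -> empty network
  far <- oracle_distances(rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0)))
  expect_equal(sum(build_pcn(far)$adjacency), 0)

  tr <- random_trace(15, seed = 9, scale = 12)
  d <- distance_matrix(tr)
  expect_equal(build_pcn(d)$adjacency, oracle_threshold(d, 8))
  expect_error(build_pcn(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCN is invariant under rigid rotation and translation", {
  tr <- random_trace(25, seed = 2, scale = 15)
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  moved <- ca_trace(tr$residues,
                    t(R %*% t(tr$coords)) + matrix(c(5, -3, 11), 25, 3, byrow = TRUE))
  expect_equal(build_pcn(distance_matrix(tr))$adjacency,
               build_pcn(distance_matrix(moved))$adjacency)
})

test_that("contact potentials weight links with the min-weight-one shift", {
  # two links with raw potentials -2.0 and 0.5 -> shift 3.0, weights 1.0, 3.5
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- 1
  adj[2, 3] <- adj[3, 2] <- 1
  pcn <- contact_network(adj)
  aa <- pcnfold:::STANDARD_AA
  m <- matrix(0, 20, 20, dimnames = list(aa, aa))
  m["A", "G"] <- m["G", "A"] <- -2.0
  m["G", "K"] <- m["K", "G"] <- 0.5
  tr <- ca_trace(c("A", "G", "K"), rbind(c(0,0,0), c(1,0,0), c(2,0,0)))
  w <- apply_contact_potentials(pcn, tr, potential_matrix(m))
  expect_equal(w$shift, 3.0)
  expect_equal(w$weights[1, 2], 1.0)
  expect_equal(w$weights[2, 3], 3.5)
  expect_equal(w$weights[1, 3], 0)

  # all raw potentials equal -> every link weight exactly 1
  flat <- potential_matrix(matrix(-1.7, 20, 20, dimnames = list(aa, aa)))
  w2 <- apply_contact_potentials(pcn, tr, flat)
  expect_equal(w2$weights[w2$weights > 0], c(1, 1, 1, 1))
})

test_that("weight support equals adjacency support on random inputs", {
  for (seed in 1:5) {
    tr <- random_trace(12, seed = seed, scale = 8)
    pcn <- build_pcn(distance_matrix(tr))
    w <- apply_contact_potentials(pcn, tr, random_potentials(seed))
    expect_equal(1 * (w$weights > 0), pcn$adjacency)
    nz <- w$weights[upper.tri(w$weights)]
    nz <- nz[nz > 0]
    if (length(nz)) expect_equal(min(nz), 1)
    expect_equal(w$weights, t(w$weights))
  }
})

test_that("written contact matrices round-trip bit-exactly", {
  net <- make_banded_network(9, c(1, 3, 4))
  path <- withr::local_tempfile(fileext = ".txt")
  write_contact_matrix(net, path)
  expect_identical(read_contact_matrix(path)$adjacency, net$adjacency)

  # edge list carries 1-based indices and weights
  epath <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, epath)
  edges <- read.table(epath, header = TRUE)
  expect_equal(nrow(edges), sum(net$adjacency) / 2)
  expect_true(all(edges$i < edges$j))
})

test_that("PDB writer round-trips through the reader", {
  tr <- make_helix_trace(12, sequence_seed = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ca_pdb(tr, path)
  back <- read_ca_trace(path)
  expect_equal(back$residues, tr$residues)
  expect_equal(back$coords, tr$coords, tolerance = 1e-3)  # PDB has 3 decimals
})
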