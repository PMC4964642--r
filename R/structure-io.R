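# structure_io: PDB -> C-alpha trace -> contact networks

# three-letter -> one-letter map for the 20 standard residues plus the two
# substitutions accepted here (selenomethionine, selenocysteine)
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "C"
)
AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)
STANDARD_AA <- sort(unique(unname(AA3TO1)))

#' Construct a C-alpha trace
#'
#' A `ca_trace` holds, for one chain, the ordered one-letter residue
#' identities and the matching 3D C-alpha coordinates in Angstrom.
#'
#' @param residues character vector of one-letter amino-acid codes.
#' @param coords numeric matrix with one row per residue and columns x, y, z.
#' @param chain_id chain identifier (single string).
#' @param source_id identifier of the originating structure.
#' @return An object of class `ca_trace`.
#' @export
ca_trace <- function(residues, coords, chain_id = "A", source_id = "trace") {
  coords <- as.matrix(coords)
  if (length(residues) != nrow(coords))
    stopf("residues (%d) and coords (%d rows) differ in length",
          length(residues), nrow(coords))
  if (length(residues) < 2L)
    stopf("a C-alpha trace needs at least 2 residues, got %d", length(residues))
  if (ncol(coords) != 3L) stopf("coords must have 3 columns")
  if (!all(is.finite(coords))) stopf("coords must be finite")
  bad <- setdiff(unique(residues), STANDARD_AA)
  if (length(bad))
    stopf("unmappable residue code(s): %s", paste(bad, collapse = ", "))
  structure(
    list(residues = as.character(residues),
         coords = unname(coords),
         chain_id = as.character(chain_id),
         source_id = as.character(source_id)),
    class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("C-alpha trace '%s' chain %s: %d residues\n",
              x$source_id, x$chain_id, length(x$residues)))
  cat("  sequence:", paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' Read a C-alpha trace from a PDB structure
#'
#' Parses ATOM records (plus HETATM for MSE/SEC) of the first model, selects
#' one chain, resolves alternate locations by keeping the highest-occupancy
#' conformer (ties broken by altLoc letter order), and maps residues to
#' one-letter codes (MSE -> M, SEC -> C; anything else is an error).
#' Sequence-number gaps are kept as consecutive node positions and reported
#' with a warning.
#'
#' @param pdb path to a PDB file, the text of one (a single string with
#'   newlines or a character vector of lines), or a `bio3d` `pdb` object.
#' @param chain chain identifier, or `"first"` (default) for the first chain
#'   that carries C-alpha atoms.
#' @return A [ca_trace()].
#' @export
read_ca_trace <- function(pdb, chain = "first") {
  src <- "pdb"
  if (inherits(pdb, "pdb")) {
    obj <- pdb
  } else {
    if (length(pdb) == 1L && !grepl("\n", pdb) &&
        grepl("\\.(pdb|ent)$|/", pdb) && !file.exists(pdb))
      stopf("file not found: %s", pdb)
    if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
      path <- pdb
      src <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
    } else {
      path <- tempfile(fileext = ".pdb")
      on.exit(unlink(path))
      writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), path)
    }
    obj <- tryCatch(
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
      error = function(e) stopf("cannot parse PDB input: %s", conditionMessage(e)))
  }

  at <- obj$atom
  keep <- at$elety == "CA" &
    (at$type == "ATOM" | at$resid %in% c("MSE", "SEC"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stopf("no C-alpha ATOM records found")

  at$chain[is.na(at$chain)] <- " "
  chains <- unique(at$chain)
  if (identical(chain, "first")) {
    chain <- chains[1L]
  } else if (!chain %in% chains) {
    stopf("chain '%s' not found (available: %s)", chain,
          paste(chains, collapse = ", "))
  }
  at <- at[at$chain == chain, , drop = FALSE]

  # altLoc resolution: per residue keep highest occupancy, ties by altLoc order
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$resno, at$insert, sep = "_")
  ord <- order(at$resno, at$insert, -occ, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]

  if (nrow(at) < 2L)
    stopf("chain '%s' has fewer than 2 C-alpha residues", chain)

  gaps <- diff(at$resno)
  n_gap <- sum(gaps > 1L)
  if (n_gap > 0L)
    warning(sprintf(
      "chain '%s': %d sequence-number gap(s) (%d missing residue(s)); nodes kept consecutive",
      chain, n_gap, sum(pmax(gaps - 1L, 0L))), call. = FALSE)

  res3 <- at$resid
  unknown <- setdiff(unique(res3), names(AA3TO1))
  if (length(unknown))
    stopf("unmappable residue code(s): %s", paste(unknown, collapse = ", "))

  ca_trace(residues = unname(AA3TO1[res3]),
           coords = cbind(at$x, at$y, at$z),
           chain_id = chain, source_id = src)
}

#' Pairwise C-alpha distance matrix
#'
#' @param trace a [ca_trace()].
#' @return Symmetric `N_C x N_C` matrix of Euclidean distances in Angstrom.
#' @export
distance_matrix <- function(trace) {
  stopifnot(inherits(trace, "ca_trace"))
  unname(as.matrix(stats::dist(trace$coords)))
}

#' Construct a contact network
#'
#' @param adjacency square symmetric 0/1 matrix with zero diagonal.
#' @return An object of class `contact_network` with fields `adjacency` and
#'   `n_residues`.
#' @export
contact_network <- function(adjacency) {
  adjacency <- unname(as.matrix(adjacency))
  check_symmetric(adjacency, "adjacency")
  if (!all(adjacency %in% c(0, 1))) stopf("adjacency entries must be 0/1")
  if (any(diag(adjacency) != 0)) stopf("adjacency must have a zero diagonal")
  storage.mode(adjacency) <- "double"
  structure(list(adjacency = adjacency, n_residues = nrow(adjacency)),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("Protein contact network: %d residues, %d links\n",
              x$n_residues, sum(x$adjacency) / 2))
  invisible(x)
}

#' Build the protein contact network from a distance matrix
#'
#' Residues i != j are in contact when `0 < d_ij <= threshold`; the default
#' 8 Angstrom cutoff is inclusive.
#'
#' @param distances symmetric distance matrix (Angstrom) with zero diagonal.
#' @param threshold contact cutoff in Angstrom (default 8).
#' @return A [contact_network()].
#' @export
build_pcn <- function(distances, threshold = 8.0) {
  check_symmetric(distances, "distance matrix")
  if (any(distances < 0)) stopf("distances must be nonnegative")
  adj <- 1 * (distances > 0 & distances <= threshold)
  diag(adj) <- 0
  contact_network(adj)
}

#' Read a 20x20 contact-potential matrix
#'
#' Reads a TSV whose first column and header are one-letter residue codes.
#' The package ships the Miyazawa-Jernigan inter-residue contact energies as
#' `system.file("extdata", "mj_contact_potentials.tsv", package = "pcnfold")`.
#'
#' @param path TSV file path.
#' @param name label for the matrix.
#' @return Object of class `potential_matrix` with fields `values` (named
#'   20x20 symmetric matrix) and `name`.
#' @export
read_potential_matrix <- function(path, name = basename(path)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  potential_matrix(m, name = name)
}

#' @rdname read_potential_matrix
#' @param values named square symmetric numeric matrix covering the 20
#'   standard residues.
#' @export
potential_matrix <- function(values, name = "potentials") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("potential matrix must carry residue-code dimnames")
  miss <- setdiff(STANDARD_AA, rownames(values))
  if (length(miss))
    stopf("potential matrix missing residue(s): %s", paste(miss, collapse = ", "))
  values <- values[STANDARD_AA, STANDARD_AA]
  check_symmetric(unname(values), "potential matrix")
  structure(list(values = values, name = name), class = "potential_matrix")
}

#' The shipped Miyazawa-Jernigan contact potential
#' @return A [potential_matrix()].
#' @export
default_potentials <- function() {
  read_potential_matrix(
    system.file("extdata", "mj_contact_potentials.tsv", package = "pcnfold"),
    name = "miyazawa-jernigan")
}

#' Weight PCN links with shifted contact potentials
#'
#' Each link (i, j) receives weight `P[r_i, r_j] + shift`, the Hadamard
#' product of the PCN with the per-protein potential matrix; `shift` is
#' chosen per protein so the smallest link weight equals one (contact
#' potentials can be negative, and the network-entropy calculation needs
#' positive weights).  Non-links keep weight zero.
#'
#' @param pcn a [contact_network()].
#' @param trace the matching [ca_trace()].
#' @param potentials a [potential_matrix()] (default: shipped MJ matrix).
#' @return Object of class `weighted_contact_network` with fields `weights`,
#'   `shift`, `n_residues`.
#' @export
apply_contact_potentials <- function(pcn, trace, potentials = default_potentials()) {
  stopifnot(inherits(pcn, "contact_network"), inherits(trace, "ca_trace"))
  if (pcn$n_residues != length(trace$residues))
    stopf("pcn (%d) and trace (%d) sizes differ",
          pcn$n_residues, length(trace$residues))
  if (!inherits(potentials, "potential_matrix"))
    potentials <- potential_matrix(potentials)
  bad <- setdiff(unique(trace$residues), rownames(potentials$values))
  if (length(bad))
    stopf("residue(s) not in potential matrix: %s", paste(bad, collapse = ", "))

  raw <- potentials$values[trace$residues, trace$residues]
  adj <- pcn$adjacency
  if (sum(adj) == 0) {
    shift <- 0
    w <- adj * 0
  } else {
    shift <- 1 - min(raw[adj == 1])
    w <- (raw + shift) * adj
  }
  structure(list(weights = unname(w), shift = shift, n_residues = pcn$n_residues),
            class = "weighted_contact_network")
}

#' @export
print.weighted_contact_network <- function(x, ...) {
  nz <- x$weights[upper.tri(x$weights)]
  nz <- nz[nz > 0]
  cat(sprintf(
    "Weighted PCN: %d residues, %d links, shift %.3f, weights in [%.3f, %.3f]\n",
    x$n_residues, length(nz), x$shift,
    if (length(nz)) min(nz) else NA, if (length(nz)) max(nz) else NA))
  invisible(x)
}

# ---- plain-text writers / readers ----------------------------------------

#' Write / read a contact network as a dense 0/1 matrix
#'
#' Whitespace-separated dense text, one row per residue; round-trips exactly.
#'
#' @param net a [contact_network()].
#' @param path output / input file.
#' @export
write_contact_matrix <- function(net, path) {
  stopifnot(inherits(net, "contact_network"))
  utils::write.table(net$adjacency, path, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  contact_network(m)
}

#' Write a (weighted) network as an edge list
#'
#' Columns `i j weight` with 1-based residue indices, i < j; weight is 1 for
#' an unweighted [contact_network()].
#'
#' @param net a [contact_network()] or `weighted_contact_network`.
#' @param path output file.
#' @export
write_edge_list <- function(net, path) {
  w <- if (inherits(net, "weighted_contact_network")) net$weights else net$adjacency
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], weight = w[idx])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a C-alpha trace as a minimal PDB file
#'
#' @param trace a [ca_trace()].
#' @param path output file.
#' @export
write_ca_pdb <- function(trace, path) {
  stopifnot(inherits(trace, "ca_trace"))
  n <- length(trace$residues)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(trace$coords)),
    type = rep("ATOM", n),
    resno = seq_len(n),
    resid = unname(AA1TO3[trace$residues]),
    elety = rep("CA", n),
    chain = rep(trace$chain_id, n))
  invisible(path)
}
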