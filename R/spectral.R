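# spectral: backbone reduction and Laplacian eigenvalue features

#' Backbone-breaking diagonal count b
#'
#' `b` is the smallest number of leading d-diagonals (links with sequence
#' separation `|i - j| <= b`) whose removal splits the PCN into more than one
#' component.  Before spectral analysis, `b - 1` diagonals are removed: the
#' most aggressive backbone stripping that keeps the network connected, so
#' the Laplacian spectrum reflects the protein's long-range contacts and is
#' unique (single zero eigenvalue).
#'
#' @param pcn a connected [contact_network()].
#' @return Integer `b`, `1 <= b <= N_C - 1`.
#' @export
backbone_break_order <- function(pcn) {
  stopifnot(inherits(pcn, "contact_network"))
  adj <- pcn$adjacency
  if (!is_connected_adj(adj))
    stopf("input network is already disconnected")
  sep <- separation_matrix(pcn$n_residues)
  for (d in seq_len(pcn$n_residues - 1L)) {
    adj[sep == d] <- 0
    if (!is_connected_adj(adj)) return(d)
  }
  # removing all diagonals always isolates every node
  pcn$n_residues - 1L
}

#' Remove leading backbone diagonals
#'
#' Deletes all links with separation `|i - j| <= b - 1`; with `b = 1` the
#' network is returned unchanged.  By the definition of `b` the result must
#' remain connected; a disconnected result signals an inconsistent `b`.
#'
#' @param pcn a [contact_network()].
#' @param b break order from [backbone_break_order()].
#' @return The reduced [contact_network()].
#' @export
remove_backbone_diagonals <- function(pcn, b) {
  stopifnot(inherits(pcn, "contact_network"))
  b <- as.integer(b)
  if (b < 1L) stopf("b must be >= 1")
  if (b == 1L) return(pcn)
  adj <- pcn$adjacency
  sep <- separation_matrix(pcn$n_residues)
  adj[sep <= b - 1L & sep > 0L] <- 0
  out <- contact_network(adj)
  if (!is_connected_adj(adj))
    stopf("internal inconsistency: removing %d diagonals disconnected the network", b - 1L)
  out
}

#' Laplacian spectrum of a contact network
#'
#' Combinatorial Laplacian `L = D - A` (degree matrix minus adjacency);
#' positive semi-definite, smallest eigenvalue 0, with one near-zero
#' eigenvalue per connected component.
#'
#' @param net a [contact_network()].
#' @return Numeric vector of `N_C` eigenvalues in ascending order.
#' @export
laplacian_spectrum <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  adj <- net$adjacency
  L <- diag(rowSums(adj)) - adj
  sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
}

#' Largest rescaled Laplacian eigenvalues
#'
#' The three largest eigenvalues divided by the residue count `N_C`
#' (the highest vibrational frequencies of the network, made approximately
#' size-independent).
#'
#' @param spectrum ascending eigenvalues from [laplacian_spectrum()].
#' @param n_residues `N_C` of the parsed trace (the rescaling constant).
#' @return Named numeric vector `lambda_N`, `lambda_N1`, `lambda_N2`
#'   (non-increasing).
#' @export
lambda_features <- function(spectrum, n_residues) {
  if (length(spectrum) != n_residues)
    stopf("spectrum length (%d) != n_residues (%d)", length(spectrum), n_residues)
  if (n_residues < 3L) stopf("need at least 3 residues for lambda features")
  top <- sort(spectrum, decreasing = TRUE)[1:3]
  c(lambda_N = top[1], lambda_N1 = top[2], lambda_N2 = top[3]) / n_residues
}

#' Backbone-reduced spectral summary of a PCN
#'
#' Runs the full procedure: find `b`, remove `b - 1` diagonals, take the
#' Laplacian spectrum of the reduced (still connected) network, and rescale
#' the three largest eigenvalues by `N_C`.
#'
#' @param pcn a connected [contact_network()].
#' @return Object of class `spectral_summary` with fields `b`, `reduced`,
#'   `eigenvalues`, `lambda_features`.
#' @export
spectral_summary <- function(pcn) {
  b <- backbone_break_order(pcn)
  red <- remove_backbone_diagonals(pcn, b)
  ev <- laplacian_spectrum(red)
  structure(list(b = b, reduced = red, eigenvalues = ev,
                 lambda_features = lambda_features(ev, pcn$n_residues)),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  lf <- x$lambda_features
  cat(sprintf("Spectral summary: b = %d (%d diagonal(s) removed)\n", x$b, x$b - 1L))
  cat(sprintf("  lambda_N = %.4f, lambda_N-1 = %.4f, lambda_N-2 = %.4f\n",
              lf[1], lf[2], lf[3]))
  invisible(x)
}
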