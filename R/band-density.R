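# band_density: d-diagonal occupancy and the inter-residue link density R0

#' Link counts per sequence separation
#'
#' The d-diagonal of the adjacency matrix collects all links between
#' residues with `|i - j| = d`.
#'
#' @param net a [contact_network()].
#' @return Object of class `diagonal_profile`: integer vector `counts`
#'   indexed by `d = 1 .. N_C - 1`.
#' @export
diagonal_profile <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  n <- net$n_residues
  adj <- net$adjacency
  counts <- vapply(seq_len(n - 1L), function(d) {
    idx <- cbind(seq_len(n - d), seq_len(n - d) + d)
    as.integer(sum(adj[idx]))
  }, integer(1))
  structure(list(counts = counts, n_residues = n), class = "diagonal_profile")
}

#' @export
print.diagonal_profile <- function(x, ...) {
  occ <- which(x$counts > 0)
  cat(sprintf("Diagonal profile over %d separations: %d occupied\n",
              length(x$counts), length(occ)))
  invisible(x)
}

#' Inter-residue link density R0
#'
#' Fraction (over `N_C`) of sequence separations `d` in `1 .. N_C - 1` whose
#' diagonal carries no link.  Low `R0` means residues interact at many
#' levels of sequence separation (diffuse, cooperative contacts); high `R0`
#' means localized interactions.  The denominator is `N_C`, so the maximum
#' is `(N_C - 1)/N_C < 1`.
#'
#' @param net a [contact_network()].
#' @return `R0` in `[0, (N_C - 1)/N_C]`.
#' @export
link_density_R0 <- function(net) {
  prof <- diagonal_profile(net)
  sum(prof$counts == 0) / net$n_residues
}
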