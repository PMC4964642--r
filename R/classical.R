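# classical: comparator observables N_C, <h>, CO, LRCO

#' The Kyte-Doolittle hydropathy scale
#'
#' Loads the shipped 20-residue scale (positive = hydrophobic).
#'
#' @return Object of class `hydropathy_scale`: named numeric vector `values`
#'   over one-letter codes, plus `name`.
#' @export
kyte_doolittle <- function() {
  path <- system.file("extdata", "kyte_doolittle.tsv", package = "pcnfold")
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  hydropathy_scale(stats::setNames(df$hydropathy, df$residue), "kyte-doolittle")
}

#' @rdname kyte_doolittle
#' @param values named numeric vector covering the 20 standard residues.
#' @param name scale label.
#' @export
hydropathy_scale <- function(values, name = "custom") {
  miss <- setdiff(STANDARD_AA, names(values))
  if (length(miss))
    stopf("hydropathy scale missing residue(s): %s", paste(miss, collapse = ", "))
  structure(list(values = values, name = name), class = "hydropathy_scale")
}

#' Mean hydropathy of a sequence
#'
#' Arithmetic mean of per-residue hydropathy indices; hydrophobic collapse
#' is a classical driver of folding, so `<h>` is a standard comparator.
#'
#' @param residues character vector of one-letter codes, or a [ca_trace()].
#' @param scale a [hydropathy_scale()] (default Kyte-Doolittle).
#' @return Mean hydropathy (dimensionless).
#' @export
mean_hydropathy <- function(residues, scale = kyte_doolittle()) {
  if (inherits(residues, "ca_trace")) residues <- residues$residues
  if (!inherits(scale, "hydropathy_scale")) scale <- hydropathy_scale(scale)
  bad <- setdiff(unique(residues), names(scale$values))
  if (length(bad))
    stopf("residue(s) not in hydropathy scale: %s", paste(bad, collapse = ", "))
  mean(scale$values[residues])
}

#' Relative contact order
#'
#' `CO = (1 / (L_C * N_C)) * sum over links of |i - j|`, where `L_C` is the
#' number of links of the full PCN (backbone contacts included).
#'
#' @param pcn a [contact_network()] with at least one link.
#' @return Relative contact order in `(0, (N_C - 1)/N_C]`.
#' @export
contact_order <- function(pcn) {
  stopifnot(inherits(pcn, "contact_network"))
  sep <- separation_matrix(pcn$n_residues)
  up <- upper.tri(sep)
  links <- pcn$adjacency[up] == 1
  L_C <- sum(links)
  if (L_C == 0) stopf("contact order undefined for a network with no links")
  sum(sep[up][links]) / (L_C * pcn$n_residues)
}

#' Long-range contact order
#'
#' Number of contacts with sequence separation strictly greater than
#' `min_sep`, per residue: `LRCO = |{links: |i - j| > min_sep}| / N_C`.
#'
#' @param pcn a [contact_network()].
#' @param min_sep separation floor (default 12, the conventional long-range
#'   cutoff).
#' @return `LRCO >= 0`; 0 when no long-range contact exists.
#' @export
long_range_contact_order <- function(pcn, min_sep = 12L) {
  stopifnot(inherits(pcn, "contact_network"))
  sep <- separation_matrix(pcn$n_residues)
  up <- upper.tri(sep)
  sum(pcn$adjacency[up] == 1 & sep[up] > min_sep) / pcn$n_residues
}
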