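# synthetic_fixtures: deterministic generators of networks, traces and
# labelled feature clouds, so every stage is testable offline

#' Banded contact network
#'
#' Link (i, j) present iff `|i - j|` is in `occupied`; exact and
#' deterministic.  Exercises the diagonal-profile, R0 and backbone-breaking
#' machinery with hand-computable answers.
#'
#' @param n number of nodes.
#' @param occupied set of sequence separations in `1 .. n - 1`.
#' @return A [contact_network()].
#' @export
make_banded_network <- function(n, occupied) {
  occupied <- as.integer(occupied)
  if (length(occupied) && (min(occupied) < 1L || max(occupied) > n - 1L))
    stopf("occupied separations must lie in 1 .. n-1")
  sep <- separation_matrix(n)
  contact_network(1 * (sep %in% occupied & sep > 0))
}

#' Idealised helical C-alpha trace
#'
#' Regular helix with the alpha-helix geometry (rise 1.5 A, radius 2.3 A,
#' turn 100 degrees per residue by default); at these parameters the 8 A
#' PCN occupies a fixed set of low separations independent of length.
#'
#' @param n number of residues (>= 4).
#' @param rise rise per residue in Angstrom.
#' @param radius helix radius in Angstrom.
#' @param turn rotation per residue in radians.
#' @param sequence_seed seed for the random amino-acid sequence.
#' @return A [ca_trace()].
#' @export
make_helix_trace <- function(n, rise = 1.5, radius = 2.3,
                             turn = 100 * pi / 180, sequence_seed = 1L) {
  if (n < 4L) stopf("need n >= 4")
  i <- seq_len(n) - 1L
  coords <- cbind(radius * cos(i * turn), radius * sin(i * turn), rise * i)
  res <- with_seed(sequence_seed, sample(STANDARD_AA, n, replace = TRUE))
  ca_trace(res, coords, chain_id = "A",
           source_id = sprintf("helix_n%d", n))
}

#' Random compact self-avoiding chain ("globule")
#'
#' Chain growth with fixed 3.8 A consecutive C-alpha spacing inside a sphere
#' of radius `c_pack * n^(1/3)`, rejecting steps that come closer than
#' `min_sep` A to any earlier non-bonded residue.  Mimics protein-like
#' contact densities (connected PCNs with long-range contacts, typically
#' b >= 2) without any physics.
#'
#' @param n number of residues (>= 10).
#' @param seed integer seed; same seed, same trace.
#' @param c_pack packing coefficient of the confining sphere (A per
#'   n^(1/3); default 3.2, near globular-protein density).
#' @param min_sep self-avoidance distance in Angstrom.
#' @param max_tries step-level retry cap before the chain restarts.
#' @return A [ca_trace()].
#' @export
make_random_globule <- function(n, seed = 1L, c_pack = 3.2, min_sep = 3.5,
                                max_tries = 200L) {
  if (n < 10L) stopf("need n >= 10")
  radius <- c_pack * n^(1 / 3)
  bond <- 3.8
  with_seed(seed, {
    for (restart in seq_len(50L)) {
      coords <- matrix(NA_real_, n, 3)
      coords[1, ] <- 0
      ok <- TRUE
      for (i in 2:n) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          cand <- coords[i - 1, ] + bond * u
          if (sqrt(sum(cand^2)) > radius) next
          if (i > 2) {
            d2 <- rowSums((coords[1:(i - 2), , drop = FALSE] -
                             matrix(cand, i - 2, 3, byrow = TRUE))^2)
            if (min(d2) < min_sep^2) next
          }
          coords[i, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) {
        res <- sample(STANDARD_AA, n, replace = TRUE)
        return(ca_trace(res, coords, chain_id = "A",
                        source_id = sprintf("globule_n%d_s%d", n, seed)))
      }
    }
    stopf("globule generation failed after repeated restarts (n = %d)", n)
  })
}

#' Two-class Gaussian feature clouds with homology groups
#'
#' Draws `n_per_class` feature vectors per class from the given Gaussians
#' and assigns consecutive proteins within each class to homology groups of
#' size `group_size`.  With known parameters the Bayes-optimal accuracy is
#' computable, giving the classifier tests an analytic yardstick.
#'
#' @param n_per_class samples per class (MS first, then TS).
#' @param means list of two mean vectors (MS, TS).
#' @param covariances list of two covariance matrices (MS, TS).
#' @param group_size homology-group size (default 1, i.e. singletons).
#' @param seed integer seed.
#' @param feature_names optional feature column names.
#' @return A [labeled_dataset()].
#' @export
make_two_class_features <- function(n_per_class, means, covariances,
                                    group_size = 1L, seed = 1L,
                                    feature_names = NULL) {
  stopifnot(length(means) == 2L, length(covariances) == 2L)
  d <- length(means[[1]])
  X <- with_seed(seed, rbind(
    MASS::mvrnorm(n_per_class, means[[1]], covariances[[1]]),
    MASS::mvrnorm(n_per_class, means[[2]], covariances[[2]])))
  X <- matrix(X, ncol = d)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(d))
  colnames(X) <- feature_names
  labels <- rep(c("MS", "TS"), each = n_per_class)
  grp_in_class <- (seq_len(n_per_class) - 1L) %/% group_size
  groups <- c(paste0("gMS", grp_in_class), paste0("gTS", grp_in_class))
  labeled_dataset(ids = sprintf("p%03d", seq_len(2 * n_per_class)),
                  features = X, labels = labels, groups = groups)
}
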