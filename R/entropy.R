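# network_entropy: canonical maximum-entropy ensembles of weighted networks
#
# Weights live on the nonnegative integers.  Two ensembles:
#   strength-only : pi_ij(w) = (1 - q)(q)^w,            q = x_i x_j < 1
#   strength+degree: pi_ij(0) = 1/Z,
#                    pi_ij(w>=1) = Y q^w / Z,           Y = y_i y_j,
#                    Z = 1 + Y q/(1-q)
# with x_i = exp(-alpha_i), y_i = exp(-beta_i).  Constraints are canonical:
# ensemble means of per-node strengths (and degrees) match the observed ones.
# Both fits minimise the convex dual (log-partition minus linear term) by
# damped Newton with Armijo backtracking, so the dual decreases monotonically.

#' Node strength and degree sequences of a weighted network
#'
#' Degree `k_i` counts a node's links; strength `s_i` sums its link weights.
#'
#' @param wnet a `weighted_contact_network` (see [apply_contact_potentials()])
#'   or a [contact_network()] (unit weights).
#' @return Object of class `node_constraints` with fields `strengths`,
#'   `degrees`.
#' @export
node_constraints <- function(wnet) {
  w <- if (inherits(wnet, "weighted_contact_network")) wnet$weights
       else if (inherits(wnet, "contact_network")) wnet$adjacency
       else stopf("wnet must be a (weighted) contact network")
  structure(list(strengths = rowSums(w), degrees = rowSums(w > 0)),
            class = "node_constraints")
}

# empty-network fit shared by both ensembles
empty_fit <- function(kind, n) {
  structure(list(kind = kind,
                 alpha = rep(Inf, n),
                 beta = if (kind == "strength_and_degree") rep(Inf, n) else NULL,
                 entropy = 0, residuals = rep(0, n),
                 converged = TRUE, iterations = 0L, dual_path = numeric(0)),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("Ensemble fit (%s): entropy %.6f nats, %s in %d iterations (max residual %.2e)\n",
              x$kind, x$entropy,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, max(x$residuals)))
  invisible(x)
}

# damped Newton on a convex dual.  fns provides:
#   grad(th)    gradient (= fitted - target)
#   hess(th)    Hessian
#   dual(th)    dual objective
#   feasible(th) TRUE iff th in the open domain
newton_descent <- function(th, fns, tolerance, max_iter) {
  # Armijo backtracking along direction d; initial step capped by a trust
  # radius in the (log-multiplier) parameter space so near-singular Hessians
  # cannot catapult the iterate out of the feasible region
  line_search <- function(th, f0, g, d, radius = 2) {
    dmax <- max(abs(d))
    if (!is.finite(dmax) || dmax == 0) return(NULL)
    step <- min(1, radius / dmax)
    while (step * dmax > 1e-13) {
      th_try <- th + step * d
      if (fns$feasible(th_try)) {
        f_try <- fns$dual(th_try)
        if (is.finite(f_try) &&
            f_try <= f0 + 1e-4 * step * sum(g * d) + 1e-12)
          return(th_try)
      }
      step <- step / 2
    }
    NULL
  }
  dual_path <- numeric(0)
  g <- fns$grad(th)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    f0 <- fns$dual(th)
    dual_path[it] <- f0
    if (max(abs(g)) <= tolerance) break
    H <- fns$hess(th)
    ridge <- 1e-12 * mean(abs(diag(H))) + 1e-300
    d <- tryCatch(solve(H + diag(ridge, nrow(H)), -g),
                  error = function(e) NULL)
    th_new <- NULL
    if (!is.null(d)) {
      # a (trust-capped) Newton step that shrinks the residual is taken as
      # is: near the optimum the dual stagnates at double precision while
      # the gradient still converges quadratically
      dmax <- max(abs(d))
      if (is.finite(dmax) && dmax > 0) {
        th_try <- th + min(1, 2 / dmax) * d
        if (fns$feasible(th_try) &&
            max(abs(fns$grad(th_try))) < max(abs(g)))
          th_new <- th_try
      }
      if (is.null(th_new) && sum(g * d) < 0)
        th_new <- line_search(th, f0, g, d)
    }
    if (is.null(th_new))  # fall back to steepest descent on the dual
      th_new <- line_search(th, f0, g, -g / max(abs(g)))
    if (is.null(th_new)) break  # stalled
    th <- th_new
    g <- fns$grad(th)
  }
  list(theta = th, grad = g, iterations = it,
       converged = max(abs(g)) <= tolerance, dual_path = dual_path)
}

off_upper <- function(m) m[upper.tri(m)]

#' Fit the strength-constrained maximum-entropy ensemble
#'
#' Per-pair weight distributions are geometric on `{0, 1, 2, ...}` with
#' occupation numbers `q_ij = x_i x_j`; the per-node multipliers are tuned so
#' the ensemble-average strengths match the observed ones.  The ensemble
#' entropy `S_s` (nats) is the sum of per-pair geometric entropies in closed
#' form.
#'
#' @param constraints a [node_constraints()] (degrees are ignored here).
#' @param tolerance maximum permitted absolute constraint residual.
#' @param max_iter iteration cap.
#' @return Object of class `ensemble_fit` with fields `kind`, `alpha`,
#'   `entropy`, `residuals`, `converged`, `iterations`, `dual_path`.
#' @export
fit_strength_ensemble <- function(constraints, tolerance = 1e-8, max_iter = 10000L) {
  stopifnot(inherits(constraints, "node_constraints"))
  s <- constraints$strengths
  n <- length(s)
  if (any(!is.finite(s)) || any(s < 0)) stopf("strengths must be finite and >= 0")
  act <- which(s > 0)
  if (length(act) == 0L) return(empty_fit("strength_only", n))
  if (length(act) == 1L)
    stopf("infeasible constraints: a single node with positive strength")
  sa <- s[act]
  m <- length(sa)
  iu <- which(upper.tri(matrix(0, m, m)))

  qmat <- function(t) {
    Q <- exp(outer(t, t, "+")); diag(Q) <- 0; Q
  }
  fns <- list(
    feasible = function(t) max(outer(t, t, "+")[iu]) < -1e-14,
    grad = function(t) {
      Q <- qmat(t); rowSums(Q / (1 - Q)) - sa
    },
    hess = function(t) {
      Q <- qmat(t)
      V <- Q / (1 - Q)^2
      H <- V; diag(H) <- rowSums(V); H
    },
    dual = function(t) {
      Q <- qmat(t)
      -sum(log1p(-Q[iu])) - sum(t * sa)
    })

  t0 <- log(sa / (1 + sum(sa)))
  res <- newton_descent(t0, fns, tolerance, max_iter)
  Q <- qmat(res$theta)
  mu <- Q / (1 - Q)
  muu <- mu[iu]
  ent <- sum(ifelse(muu > 0, (1 + muu) * log1p(muu) - muu * log(pmax(muu, 1e-300)), 0))

  residuals <- rep(0, n)
  residuals[act] <- abs(res$grad)
  alpha <- rep(Inf, n)
  alpha[act] <- -res$theta
  if (!res$converged)
    warning(sprintf("strength ensemble not converged: max residual %.3e",
                    max(residuals)), call. = FALSE)
  structure(list(kind = "strength_only", alpha = alpha, beta = NULL,
                 entropy = ent, residuals = residuals,
                 converged = res$converged, iterations = res$iterations,
                 dual_path = res$dual_path),
            class = "ensemble_fit")
}

# binary configuration-model limit: when s_i == k_i for every node, weights
# are almost surely 0/1 and the ensemble collapses to Bernoulli links
fit_binary_configuration <- function(k, act, n, tolerance, max_iter) {
  ka <- k[act]
  m <- length(ka)
  iu <- which(upper.tri(matrix(0, m, m)))
  lmat <- function(u) { L <- exp(outer(u, u, "+")); diag(L) <- 0; L }
  fns <- list(
    feasible = function(u) all(is.finite(exp(outer(u, u, "+")))),
    grad = function(u) { L <- lmat(u); rowSums(L / (1 + L)) - ka },
    hess = function(u) {
      L <- lmat(u); V <- L / (1 + L)^2
      H <- V; diag(H) <- rowSums(V); H
    },
    dual = function(u) { L <- lmat(u); sum(log1p(L[iu])) - sum(u * ka) })
  u0 <- log(ka / (1 + sum(ka)))
  res <- newton_descent(u0, fns, tolerance, max_iter)
  L <- lmat(res$theta)
  p <- (L / (1 + L))[iu]
  ent <- sum(ifelse(p > 0 & p < 1,
                    -p * log(p) - (1 - p) * log1p(-p), 0))
  residuals <- rep(0, n)
  residuals[act] <- abs(res$grad)
  beta <- rep(Inf, n); beta[act] <- -res$theta
  if (!res$converged)
    warning(sprintf("degree ensemble not converged: max residual %.3e",
                    max(residuals)), call. = FALSE)
  structure(list(kind = "strength_and_degree",
                 alpha = rep(Inf, n),  # weight multipliers diverge: w <= 1 a.s.
                 beta = beta, entropy = ent, residuals = residuals,
                 converged = res$converged, iterations = res$iterations,
                 dual_path = res$dual_path),
            class = "ensemble_fit")
}

#' Fit the strength-and-degree-constrained maximum-entropy ensemble
#'
#' Per-pair distributions `pi_ij(0) = 1/Z_ij`,
#' `pi_ij(w >= 1) = y_i y_j (x_i x_j)^w / Z_ij`; both the ensemble-average
#' degrees and strengths are matched.  The entropy `S_ks` is evaluated in
#' closed form per pair.  Networks whose strengths equal their degrees (all
#' link weights exactly one) are handled as the Bernoulli-link limit of the
#' family, where the weight multipliers diverge.
#'
#' @inheritParams fit_strength_ensemble
#' @return An `ensemble_fit`, with per-node `alpha` (strength) and `beta`
#'   (degree) multipliers.
#' @export
fit_strength_degree_ensemble <- function(constraints, tolerance = 1e-8,
                                         max_iter = 10000L) {
  stopifnot(inherits(constraints, "node_constraints"))
  s <- constraints$strengths
  k <- constraints$degrees
  n <- length(s)
  if (any(!is.finite(s)) || any(s < 0)) stopf("strengths must be finite and >= 0")
  if (any(k < 0) || any(abs(k - round(k)) > 1e-9)) stopf("degrees must be nonnegative integers")
  if (any((s > 0) != (k > 0)))
    stopf("infeasible constraints: s_i > 0 must coincide with k_i > 0")
  act <- which(k > 0)
  if (length(act) == 0L) return(empty_fit("strength_and_degree", n))
  if (any(k[act] > length(act) - 1L))
    stopf("infeasible constraints: k_i exceeds the number of possible partners")
  if (any(s[act] - k[act] < -1e-9))
    stopf("infeasible constraints: s_i < k_i is impossible with weights >= 1")
  if (max(s[act] - k[act]) < 1e-9)
    return(fit_binary_configuration(k, act, n, tolerance, max_iter))

  sa <- s[act]; ka <- k[act]
  m <- length(act)
  iu <- which(upper.tri(matrix(0, m, m)))

  parts <- function(th) {
    t <- th[1:m]; u <- th[(m + 1):(2 * m)]
    Q <- exp(outer(t, t, "+")); diag(Q) <- 0
    Y <- exp(outer(u, u, "+")); diag(Y) <- 0
    A <- Y * Q / (1 - Q)
    P <- A / (1 + A)
    Mu <- P / (1 - Q); diag(Mu) <- 0
    list(Q = Q, Y = Y, A = A, P = P, Mu = Mu)
  }
  fns <- list(
    feasible = function(th) {
      t <- th[1:m]
      max(outer(t, t, "+")[iu]) < -1e-14 && all(is.finite(exp(th)))
    },
    grad = function(th) {
      pp <- parts(th)
      c(rowSums(pp$Mu) - sa, rowSums(pp$P) - ka)
    },
    hess = function(th) {
      pp <- parts(th)
      Q <- pp$Q; P <- pp$P
      Vw <- P * (1 - P + Q) / (1 - Q)^2   # Var(w)
      Cw <- P * (1 - P) / (1 - Q)         # Cov(w, link)
      Vi <- P * (1 - P)                   # Var(link)
      diag(Vw) <- 0; diag(Cw) <- 0; diag(Vi) <- 0
      Htt <- Vw; diag(Htt) <- rowSums(Vw)
      Htu <- Cw; diag(Htu) <- rowSums(Cw)
      Huu <- Vi; diag(Huu) <- rowSums(Vi)
      rbind(cbind(Htt, Htu), cbind(Htu, Huu))
    },
    dual = function(th) {
      t <- th[1:m]; u <- th[(m + 1):(2 * m)]
      pp <- parts(th)
      sum(log1p(pp$A[iu])) - sum(t * sa) - sum(u * ka)
    })

  th0 <- c(log(sa / (1 + sum(sa))), log(ka / (1 + sum(ka))))
  res <- newton_descent(th0, fns, tolerance, max_iter)
  pp <- parts(res$theta)
  q <- pp$Q[iu]; Y <- pp$Y[iu]; p <- pp$P[iu]; mu <- pp$Mu[iu]; A <- pp$A[iu]
  # S_ij = ln Z - p ln Y - mu ln q  (ln Z = log1p(A))
  ent_pair <- log1p(A) -
    ifelse(p > 0, p * log(pmax(Y, 1e-300)), 0) -
    ifelse(mu > 0, mu * log(pmax(q, 1e-300)), 0)
  ent <- sum(ent_pair)

  residuals <- rep(0, n)
  g <- res$grad
  residuals[act] <- pmax(abs(g[1:m]), abs(g[(m + 1):(2 * m)]))
  alpha <- rep(Inf, n); alpha[act] <- -res$theta[1:m]
  beta <- rep(Inf, n); beta[act] <- -res$theta[(m + 1):(2 * m)]
  if (!res$converged)
    warning(sprintf("strength+degree ensemble not converged: max residual %.3e",
                    max(residuals)), call. = FALSE)
  structure(list(kind = "strength_and_degree", alpha = alpha, beta = beta,
                 entropy = ent, residuals = residuals,
                 converged = res$converged, iterations = res$iterations,
                 dual_path = res$dual_path),
            class = "ensemble_fit")
}

#' Ensemble-entropy ratio S_R
#'
#' `S_R = S_s / S_ks`: the closer to 1, the less information the degree
#' sequence adds beyond the strengths; large `S_R` means the strength
#' sequence is compatible with many degree sequences (many candidate PCNs),
#' the regime expected for multi-state folders.
#'
#' @param S_s entropy of the strength-constrained ensemble (nats), or an
#'   `ensemble_fit`.
#' @param S_ks entropy of the strength+degree-constrained ensemble (nats),
#'   or an `ensemble_fit`.
#' @return `S_s / S_ks` (dimensionless, >= 1 for fits on the same network).
#' @export
entropy_ratio <- function(S_s, S_ks) {
  if (inherits(S_s, "ensemble_fit")) S_s <- S_s$entropy
  if (inherits(S_ks, "ensemble_fit")) S_ks <- S_ks$entropy
  if (!is.finite(S_ks) || S_ks <= 0)
    stopf("undefined entropy ratio: S_ks = %g (degenerate network)", S_ks)
  S_s / S_ks
}

#' Entropy observables of a weighted PCN
#'
#' Convenience wrapper: fits both ensembles on the network's strength and
#' degree sequences and returns `S_s`, `S_ks` and `S_R`.
#'
#' @param wnet a `weighted_contact_network`.
#' @inheritParams fit_strength_ensemble
#' @return Named list `S_s`, `S_ks`, `S_R`, plus both fits.
#' @export
entropy_observables <- function(wnet, tolerance = 1e-8, max_iter = 10000L) {
  nc <- node_constraints(wnet)
  fs <- fit_strength_ensemble(nc, tolerance, max_iter)
  fk <- fit_strength_degree_ensemble(nc, tolerance, max_iter)
  list(S_s = fs$entropy, S_ks = fk$entropy,
       S_R = entropy_ratio(fs$entropy, fk$entropy),
       fit_s = fs, fit_ks = fk)
}
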