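#' Intrinsic CAR structure matrix from an areal lattice
#'
#' Returns the graph Laplacian Q = D - W (degree minus adjacency), the
#' structure matrix of the intrinsic conditional autoregression used for
#' the spatially structured effect. Q is symmetric positive semidefinite
#' with null space spanned by the indicator vectors of the connected
#' components, so its rank is `n_areas - n_components`. Isolated areas
#' (degree zero) are their own component and their field value is pinned
#' to zero by the sum-to-zero constraint; a message notes them.
#'
#' @param lattice an `area_lattice`, or a symmetric 0/1 adjacency matrix.
#' @return structure matrix with attributes `rank` and `components`.
#' @export
icar_structure <- function(lattice) {
  adj <- if (inherits(lattice, "area_lattice")) lattice$adj else as.matrix(lattice)
  if (any(adj != t(adj))) stop("adjacency must be symmetric")
  if (any(diag(adj) != 0)) stop("adjacency must have a zero diagonal")
  deg <- rowSums(adj)
  if (any(deg == 0))
    message(sum(deg == 0), " isolated area(s): each forms its own component ",
            "with its spatial effect pinned to 0")
  Q <- diag(deg, nrow = nrow(adj)) - adj
  dimnames(Q) <- dimnames(adj)
  comp <- graph_components(adj)
  attr(Q, "rank") <- nrow(Q) - max(comp)
  attr(Q, "components") <- comp
  Q
}

#' Second-order random-walk structure matrix
#'
#' Penalty matrix of the RW2 prior: Q = D2' D2 where D2 is the
#' second-difference operator, so x'Qx = sum of squared second differences.
#' Pentadiagonal, rank T - 2, null space spanned by the constant and
#' linear vectors.
#'
#' @param T number of time points, at least 4.
#' @return T x T structure matrix with attribute `rank`.
#' @export
rw2_structure <- function(T) {
  if (T < 4) stop("RW2 structure needs T >= 4")
  D2 <- matrix(0, T - 2, T)
  for (t in seq_len(T - 2)) D2[t, t:(t + 2)] <- c(1, -2, 1)
  Q <- crossprod(D2)
  attr(Q, "rank") <- T - 2L
  Q
}

#' Space-time interaction structure matrix
#'
#' Kronecker-product structure of the interaction field delta (stored with
#' the area index varying fastest, i.e. vec of an n x T matrix):
#' type I is fully unstructured (identity, rank nT); type II couples the
#' temporally structured effect with the unstructured spatial effect
#' (RW2 within each area: Q_gamma (x) I_n, rank n(T-2)); type III couples
#' the spatially structured effect with the unstructured temporal effect
#' (ICAR within each time slice: I_T (x) Q_u, rank T(n - n_components)).
#'
#' @param interaction_type one of "I", "II", "III".
#' @param lattice an `area_lattice`.
#' @param T number of time points.
#' @return list with `Q` (nT x nT structure matrix) and `rank`
#'   (generalized rank, used as the exponent in the conjugate precision
#'   update).
#' @export
interaction_structure <- function(interaction_type, lattice, T) {
  n <- lattice$n_areas
  switch(interaction_type,
    "I" = list(Q = diag(n * T), rank = n * T),
    "II" = {
      Qg <- rw2_structure(T)
      list(Q = kronecker(Qg, diag(n)), rank = n * (T - 2L))
    },
    "III" = {
      Qu <- icar_structure(lattice)
      list(Q = kronecker(diag(T), Qu),
           rank = T * (n - lattice$n_components))
    },
    stop("interaction_type must be one of 'I', 'II', 'III' ",
         "(no structure matrix exists for 'none')")
  )
}

#' Sample an intrinsic (or proper) Gaussian Markov random field
#'
#' Draws from the Gaussian with precision `tau * Q` by eigen-decomposition
#' of the structure matrix Q, setting the null-space coordinates to zero.
#' The draw is therefore constrained to the row space of Q: per-component
#' sum-to-zero for an ICAR structure, orthogonal to the constant and
#' linear vectors for an RW2 structure. Exact at desk scale (up to a few
#' hundred nodes).
#'
#' @param Q symmetric positive semidefinite structure matrix.
#' @param tau positive scalar precision multiplier.
#' @param seed optional integer seed.
#' @return numeric vector of length nrow(Q).
#' @export
sample_gmrf <- function(Q, tau, seed = NULL) {
  Q <- unclass(as.matrix(Q))
  if (any(abs(Q - t(Q)) > 1e-12 * max(1, max(abs(Q)))))
    stop("structure matrix must be symmetric")
  if (!is.numeric(tau) || tau <= 0) stop("'tau' must be a positive scalar")
  if (!is.null(seed)) set.seed(as.integer(seed))
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values
  tol <- 1e-10 * max(abs(lam), 1)
  if (any(lam < -tol)) stop("structure matrix is not positive semidefinite")
  keep <- lam > tol
  z <- stats::rnorm(sum(keep))
  drop(eg$vectors[, keep, drop = FALSE] %*% (z / sqrt(tau * lam[keep])))
}

#' Conjugate posterior of a GMRF precision
#'
#' For a field x with improper density proportional to
#' tau^(rank/2) exp(-tau/2 x'Qx) and a Gamma(shape, rate) prior on tau,
#' the full conditional of tau is Gamma(shape + rank/2, rate + x'Qx/2).
#'
#' @param field numeric field vector.
#' @param Q structure matrix.
#' @param rank generalized rank of Q.
#' @param shape,rate Gamma hyperprior parameters.
#' @return list with `shape` and `rate` of the Gamma full conditional.
#' @export
precision_posterior <- function(field, Q, rank, shape, rate) {
  quad <- drop(crossprod(field, as.matrix(Q) %*% field))
  list(shape = shape + rank / 2, rate = rate + quad / 2)
}
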