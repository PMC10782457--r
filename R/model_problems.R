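# Synthetic ADC(2)-structured block problems.
#
# Reproducible random systems with the folded block structure (symmetric
# singles block, singles-doubles coupling, diagonal doubles block above the
# singles spectrum) so the response and eigensolvers are testable without
# any quantum-chemistry backend. Eigenvalue clustering of the singles block
# is controllable to emulate spectral regions of high or low density of
# states.

#' Generate a synthetic folded block problem
#'
#' @param n_s,n_d singles and doubles dimensions (`>= 1`).
#' @param clustering eigenvalue-clustering exponent for the singles block:
#'   `1` gives evenly spread eigenvalues over `singles_range`; larger
#'   values concentrate them near the lower edge (higher local density of
#'   states).
#' @param coupling root-mean-square singles-doubles coupling strength.
#' @param singles_range range of the singles-block eigenvalues (hartree).
#' @param doubles_gap distance between the upper singles edge and the lower
#'   doubles-diagonal edge; the default keeps the doubles manifold above
#'   the singles spectrum, as in the physical problem for valence windows.
#' @param doubles_span width of the doubles diagonal.
#' @param seed integer seed; the problem is fully reproducible from its
#'   arguments.
#' @return a `model_problem` implementing the workspace contraction
#'   interface (`sigma_singles`, `couple_ds`, `couple_sd`,
#'   `doubles_diagonal`, `assemble_dense`, ...).
#' @export
generate_model_problem <- function(n_s, n_d, clustering = 1, coupling = 0.1,
                                   singles_range = c(0.25, 0.8),
                                   doubles_gap = 0.3, doubles_span = 2,
                                   seed = 1L) {
  if (n_s < 1L || n_d < 1L) stop("n_s and n_d must be >= 1")
  set.seed(seed)
  u <- if (n_s == 1L) 0.5 else seq(0, 1, length.out = n_s)
  lam <- singles_range[1] + diff(singles_range) * u^clustering
  Q <- qr.Q(qr(matrix(rnorm(n_s * n_s), n_s, n_s)))
  if (n_s == 1L) Q <- matrix(1, 1, 1)
  M_ss <- Q %*% (lam * t(Q))
  M_ss <- (M_ss + t(M_ss)) / 2
  M_sd <- matrix(rnorm(n_s * n_d, sd = coupling), n_s, n_d)
  dlo <- singles_range[2] + doubles_gap
  d <- sort(dlo + doubles_span * runif(n_d))
  rhs <- rnorm(n_s)
  structure(list(M_ss = M_ss, M_sd = M_sd, d = d, rhs = rhs,
                 n_s = n_s, n_d = n_d, seed = seed,
                 params = list(clustering = clustering, coupling = coupling,
                               singles_range = singles_range,
                               doubles_gap = doubles_gap,
                               doubles_span = doubles_span)),
            class = "model_problem")
}

#' @export
n_singles.model_problem <- function(ws) ws$n_s
#' @export
n_doubles.model_problem <- function(ws) ws$n_d
#' @export
sigma_singles.model_problem <- function(ws, b) as.vector(ws$M_ss %*% b)
#' @export
couple_ds.model_problem <- function(ws, b) as.vector(crossprod(ws$M_sd, b))
#' @export
couple_sd.model_problem <- function(ws, v) as.vector(ws$M_sd %*% v)
#' @export
doubles_diagonal.model_problem <- function(ws) ws$d
#' @export
singles_diagonal.model_problem <- function(ws) diag(ws$M_ss)
#' @export
adc1_matrix.model_problem <- function(ws) ws$M_ss
#' @export
assemble_dense.model_problem <- function(ws, cap = 5000L) {
  if (ws$n_s + ws$n_d > cap)
    stop("dense oracle dimension exceeds cap ", cap)
  M <- rbind(cbind(ws$M_ss, ws$M_sd),
             cbind(t(ws$M_sd), diag(ws$d, ws$n_d, ws$n_d)))
  structure(list(M = M, ns = ws$n_s, nd = ws$n_d), class = "dense_adc_matrix")
}

#' Density of states of a model problem
#'
#' Gaussian-broadened eigenvalue density, in states per eV, averaged over a
#' window of the full (singles+doubles) spectrum.
#'
#' @param problem a `model_problem`.
#' @param window `c(lo, hi)` in hartree.
#' @param broadening Gaussian sigma (hartree).
#' @return states per eV.
#' @export
dos_estimate <- function(problem, window, broadening = 0.01) {
  if (window[2] <= window[1]) {
    warning("empty window; returning 0")
    return(0)
  }
  ev <- eigen(assemble_dense(problem)$M, symmetric = TRUE,
              only.values = TRUE)$values
  weight <- stats::pnorm(window[2], ev, broadening) -
    stats::pnorm(window[1], ev, broadening)
  width_ev <- convert_units(window[2] - window[1], "hartree", "ev")
  sum(weight) / width_ev
}
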