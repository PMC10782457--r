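# Folded nonlinear ADC(2) eigensolver.
#
# Exact elimination of the diagonal doubles block turns the eigenproblem
# into M_eff(w) y = w y with M_eff(w) = M_ss + M_sd (w - M_dd)^{-1} M_ds, a
# nonlinear eigenvalue problem solved by a reduced-space block method:
# Ritz extraction in a growing trial subspace at the current eigenvalue,
# Newton-Raphson refinement of the eigenvalue through the contraction
# Theta(w) = y^T M_eff(w) y and its derivative, progressive root-by-root
# convergence with a block of higher roots feeding the subspace, and
# controlled subspace collapse.

# ADC(1) secular matrix (first-order singles block)
adc1_matrix <- function(ws) UseMethod("adc1_matrix")
#' @export
adc1_matrix.adc_workspace <- function(ws) ws$m1

#' ADC(1) guess for the folded eigensolver
#'
#' Lowest eigenpairs of the first-order singles block, used as the initial
#' subspace and eigenvalue guesses.
#'
#' @param ws workspace.
#' @param n_states number of states (`<= n_singles(ws)`).
#' @return list with `values` and `vectors` (columns orthonormal).
#' @export
adc1_guess <- function(ws, n_states) {
  ns <- n_singles(ws)
  if (n_states > ns)
    stop("n_states = ", n_states, " exceeds the singles dimension ", ns)
  e <- eigen((adc1_matrix(ws) + t(adc1_matrix(ws))) / 2, symmetric = TRUE)
  ord <- order(e$values)
  list(values = e$values[ord][seq_len(n_states)],
       vectors = e$vectors[, ord, drop = FALSE][, seq_len(n_states), drop = FALSE])
}

#' Theta contraction of the folded eigenproblem
#'
#' `Theta(w) = y^T M_eff(w) y` for a normalized singles vector; its
#' derivative `Theta'(w) = -y^T M_sd (w - M_dd)^{-2} M_ds y <= 0`.
#'
#' @param ws workspace.
#' @param y normalized singles vector.
#' @param omega trial eigenvalue (hartree).
#' @param floor smallest allowed `|omega - d|` against the doubles diagonal.
#' @export
theta_contraction <- function(ws, y, omega, floor = 1e-10) {
  d <- doubles_diagonal(ws)
  if (any(abs(omega - d) < floor))
    stop("trial eigenvalue collides with a doubles-diagonal entry")
  hy <- couple_ds(ws, y)
  sum(y * sigma_singles(ws, y)) + sum(hy^2 / (omega - d))
}

#' @rdname theta_contraction
#' @export
theta_derivative <- function(ws, y, omega, floor = 1e-10) {
  d <- doubles_diagonal(ws)
  if (any(abs(omega - d) < floor))
    stop("trial eigenvalue collides with a doubles-diagonal entry")
  hy <- couple_ds(ws, y)
  -sum(hy^2 / (omega - d)^2)
}

#' Newton-Raphson eigenvalue update
#'
#' `w_{n+1} = w_n - (Theta(w_n) - w_n) / (Theta'(w_n) - 1)`; the fixed
#' point is `Theta(w) = w`. When `|Theta' - 1|` is below `floor` the step
#' is rejected (caller falls back to the plain Ritz value).
#'
#' @param omega current eigenvalue.
#' @param theta value of the contraction at `omega`.
#' @param dtheta derivative of the contraction at `omega`.
#' @param floor rejection threshold on `|Theta' - 1|`.
#' @export
newton_update <- function(omega, theta, dtheta, floor = 1e-12) {
  if (abs(dtheta - 1) < floor)
    stop("degenerate Newton step: |Theta' - 1| below floor")
  omega - (theta - omega) / (dtheta - 1)
}

#' Solve the folded nonlinear ADC(2) eigenproblem
#'
#' Converges the lowest `n_states` folded roots progressively. Convergence
#' requires BOTH the residual norm and the Newton eigenvalue error to fall
#' below their thresholds. Subspace vectors are generated from the
#' nonconverged eigenvectors of the current root and the next
#' `block_width - 1` higher roots; the subspace is collapsed when its
#' dimension reaches `max_subspace` or no new vector survives the
#' linear-dependence filter.
#'
#' @param ws workspace (molecular or model).
#' @param n_states number of states requested.
#' @param block_width roots fed into the subspace per iteration.
#' @param max_subspace collapse threshold on the subspace dimension.
#' @param tol_residual residual-norm convergence threshold.
#' @param tol_eigenvalue eigenvalue-error convergence threshold (hartree).
#' @param max_iter global iteration cap.
#' @param stall_window flag a root as stalled when its residual has not
#'   decreased over this many iterations.
#' @param ortho_tol linear-dependence drop tolerance.
#' @return list of `eigen_state` objects (ascending eigenvalues): `omega`
#'   (hartree), `Y_s`, `Y_d` (full-space normalized), `residual_norm`,
#'   `eigenvalue_error`, `converged`, plus solver diagnostics as
#'   `attr(, "diagnostics")`.
#' @export
solve_states <- function(ws, n_states, block_width = 5L, max_subspace = 200L,
                         tol_residual = 1e-5, tol_eigenvalue = 1e-6,
                         max_iter = 500L, stall_window = 15L,
                         ortho_tol = 1e-8) {
  ns <- n_singles(ws)
  nd <- n_doubles(ws)
  if (n_states < 1L) stop("n_states must be >= 1")
  if (n_states > ns) stop("n_states exceeds singles dimension")
  d <- doubles_diagonal(ws)
  d0 <- singles_diagonal(ws)
  guess <- adc1_guess(ws, min(ns, n_states + 2L))
  V <- guess$vectors
  sig_cols <- function(M) {
    Sms <- matrix(apply(M, 2, function(x) sigma_singles(ws, x)), nrow = ns)
    Dds <- matrix(apply(M, 2, function(x) couple_ds(ws, x)), nrow = nd)
    list(S = Sms, D = Dds)
  }
  sc <- sig_cols(V); Sms <- sc$S; Dds <- sc$D
  conv_states <- list()
  Cfull <- matrix(0, ns, 0)             # locked converged eigenvectors
  prev_y <- guess$vectors[, 1]
  omega_r <- guess$values[1]
  root <- 1L
  iter <- 0L
  records <- list()
  stall <- 0L; best_res <- Inf
  collapse_events <- 0L
  while (root <= n_states && iter < max_iter) {
    iter <- iter + 1L
    H <- Sms + matrix(apply(Dds, 2, function(h)
      couple_sd(ws, h / (omega_r - d))), nrow = ns)
    Hred <- crossprod(V, H)
    Hred <- (Hred + t(Hred)) / 2
    e <- eigen(Hred, symmetric = TRUE)
    ord <- order(e$values)
    vals <- e$values[ord]
    vecs <- e$vectors[, ord, drop = FALSE]
    m <- length(vals)
    # deflate locked directions in coefficient space
    Ccoef <- crossprod(V, Cfull)
    cdefl <- vecs - Ccoef %*% crossprod(Ccoef, vecs)
    dn <- sqrt(colSums(cdefl^2))
    live <- which(dn > 0.3)
    if (length(live) == 0L) {
      # subspace exhausted relative to the locked roots: top up with fresh
      # directions from the ADC(1) basis (or random complement)
      fresh <- .orthonormalize(V, adc1_guess(ws, min(ns, ncol(V) + block_width))$vectors,
                               ortho_tol)
      if (is.null(fresh))
        fresh <- .orthonormalize(V, matrix(rnorm(ns * block_width), ns), ortho_tol)
      if (is.null(fresh)) break
      V <- cbind(V, fresh)
      scf_ <- sig_cols(fresh)
      Sms <- cbind(Sms, scf_$S); Dds <- cbind(Dds, scf_$D)
      next
    }
    Ydefl <- V %*% (cdefl[, live, drop = FALSE] %*% diag(1 / dn[live],
                                                         length(live)))
    ov <- abs(crossprod(Ydefl, prev_y))
    tr <- live[which.max(ov)]
    # iterate: deflate only against locked roots degenerate with this one
    # (eigenvectors of the nonlinear family at distant omega are genuinely
    # non-orthogonal; projecting them out would corrupt the Ritz vector)
    conv_omegas <- vapply(conv_states, function(s) s$omega, numeric(1))
    near <- which(abs(conv_omegas - vals[tr]) < 1e-6)
    ctr <- vecs[, tr]
    if (length(near)) {
      Cn <- crossprod(V, Cfull[, near, drop = FALSE])
      ctr <- ctr - Cn %*% crossprod(Cn, ctr)
      ctr <- as.vector(ctr) / sqrt(sum(ctr^2))
    }
    y <- as.vector(V %*% ctr)
    lam <- sum(ctr * (Hred %*% ctr))    # Theta(omega_r) for the deflated vector
    hy <- as.vector(Dds %*% ctr)
    dtheta <- -sum(hy^2 / (omega_r - d)^2)
    omega_new <- tryCatch(newton_update(omega_r, lam, dtheta),
                          error = function(e) lam)
    ev_err <- abs(omega_new - omega_r)
    rvec <- as.vector(H %*% ctr) - omega_new * y +
      couple_sd(ws, (1 / (omega_new - d) - 1 / (omega_r - d)) * hy)
    rn <- sqrt(sum(rvec^2))
    records[[length(records) + 1L]] <- data.frame(
      iteration = iter, root = root, omega = omega_new, residual = rn,
      eigenvalue_error = ev_err, subspace_dim = ncol(V))
    if (rn < best_res * (1 - 1e-12)) { best_res <- rn; stall <- 0L } else
      stall <- stall + 1L
    done <- (rn <= tol_residual && ev_err <= tol_eigenvalue)
    stalled <- (!done && stall > stall_window)
    if (done || stalled) {
      if (stalled)
        warning(sprintf("root %d stalled (residual %.3e); continuing", root, rn))
      conv_states[[root]] <- list(omega = omega_new, y = y, residual_norm = rn,
                                  eigenvalue_error = ev_err, converged = done,
                                  iterations = iter)
      Cfull <- cbind(Cfull, y)
      root <- root + 1L
      stall <- 0L; best_res <- Inf
      if (root <= n_states) {
        # next root: lowest deflated Ritz pair (degenerate partners first)
        Ccoef <- crossprod(V, Cfull)
        cdefl <- vecs - Ccoef %*% crossprod(Ccoef, vecs)
        dn <- sqrt(colSums(cdefl^2))
        live <- which(dn > 0.3)
        if (length(live)) {
          nxt <- live[which.min(vals[live])]
          prev_y <- as.vector(V %*% cdefl[, nxt]) / dn[nxt]
          omega_r <- vals[nxt]
        } else {
          prev_y <- rnorm(ns)
          prev_y <- prev_y / sqrt(sum(prev_y^2))
          omega_r <- omega_new
        }
      }
      next
    }
    prev_y <- y
    omega_r <- omega_new
    # expansion: current root plus the next higher live roots
    live_sorted <- live[order(vals[live])]
    start <- match(tr, live_sorted)
    win <- live_sorted[start:min(start + block_width - 1L, length(live_sorted))]
    cand <- NULL
    for (k in win) {
      wk <- vals[k]
      if (min(abs(wk - d)) < 1e-8) next
      rk <- as.vector(H %*% vecs[, k]) - wk * as.vector(V %*% vecs[, k])
      p <- (d0 - wk) / ((d0 - wk)^2 + 1e-4)
      cand <- cbind(cand, p * rk)
    }
    newV <- if (!is.null(cand)) .orthonormalize(V, cand, ortho_tol) else NULL
    need_collapse <- is.null(newV) || ncol(V) + ncol(newV) > max_subspace
    if (need_collapse) {
      collapse_events <- collapse_events + 1L
      nkeep <- min(length(live_sorted), n_states - root + block_width)
      Ywin <- V %*% cdefl[, live_sorted[seq_len(nkeep)], drop = FALSE]
      keep <- cbind(Cfull, y, Ywin)
      Vnew <- .orthonormalize(NULL, keep, ortho_tol)
      if (is.null(Vnew) || ncol(Vnew) <= ncol(Cfull)) {
        # nothing usable beyond the locked space: add fresh directions
        Vnew <- cbind(Cfull, .orthonormalize(Cfull,
          adc1_guess(ws, min(ns, n_states + block_width))$vectors, ortho_tol))
      }
      V <- Vnew
      sc <- sig_cols(V); Sms <- sc$S; Dds <- sc$D
    } else {
      V <- cbind(V, newV)
      scn <- sig_cols(newV)
      Sms <- cbind(Sms, scn$S); Dds <- cbind(Dds, scn$D)
    }
  }
  if (root <= n_states)
    warning(sprintf("eigensolver stopped after %d iterations with %d of %d roots",
                    iter, root - 1L, n_states))
  states <- lapply(conv_states, function(s) {
    yd <- couple_ds(ws, s$y) / (s$omega - d)
    nrm <- sqrt(sum(s$y^2) + sum(yd^2))
    structure(list(omega = s$omega, Y_s = s$y / nrm, Y_d = yd / nrm,
                   residual_norm = s$residual_norm,
                   eigenvalue_error = s$eigenvalue_error,
                   converged = s$converged, iterations = s$iterations),
              class = "eigen_state")
  })
  ord <- order(vapply(states, function(s) s$omega, numeric(1)))
  states <- states[ord]
  attr(states, "diagnostics") <- list(
    records = do.call(rbind, records), iterations = iter,
    collapses = collapse_events, final_subspace = ncol(V))
  states
}

#' @export
print.eigen_state <- function(x, ...) {
  cat(sprintf("<ADC(2) state: %.6f hartree (%.4f eV), |r| = %.1e%s>\n",
              x$omega, convert_units(x$omega, "hartree", "ev"),
              x$residual_norm, if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}
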