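# Folded complex-polarization-propagator (CPP) linear-response solver.
#
# The damped response equation (M - (w + i*gamma)) X = B over the full
# singles+doubles space is folded exactly onto the p-h manifold using the
# diagonal doubles block: the folded operator A(w) = M_ss - M_sd
# diag(1/(d - w - i*gamma)) M_ds splits into real and imaginary parts A' and
# A'' whose actions on a trial vector are the sigma'/sigma'' pairs. The
# complex folded equation is solved in real algebra as the symmetric coupled
# system
#     [ A'-w    g-A'' ] [X^R]   [ B'^R ]
#     [ g-A''   w-A'  ] [X^I] = [-B'^I ]
# in an iterative subspace with either a separate trial basis per frequency
# or one common pool for all frequencies.

#' Equidistant frequency grid
#'
#' @param start,stop window ends (inclusive).
#' @param count number of points, or `NULL` if `step` given.
#' @param step spacing, or `NULL` if `count` given; if both are given they
#'   must agree.
#' @return numeric vector of frequencies.
#' @export
freq_grid <- function(start, stop, count = NULL, step = NULL) {
  if (stop < start) stop("stop must be >= start")
  if (is.null(count) && is.null(step))
    stop("give count or step")
  if (!is.null(step)) {
    if (step <= 0) stop("step must be positive")
    n <- round((stop - start) / step) + 1L
    if (abs((start + (n - 1L) * step) - stop) > 1e-9 * max(1, abs(stop)))
      stop("step does not divide the window evenly")
    if (!is.null(count) && count != n)
      stop("count and step are inconsistent: step implies ", n, " points")
    count <- n
  }
  if (count < 1L) stop("count must be >= 1")
  if (count == 1L) return(start)
  seq(start, stop, length.out = count)
}

#' Real/imaginary folding weights
#'
#' Elementwise parts of `1/(d - omega - i*gamma)` over the doubles diagonal.
#' @param d doubles diagonal vector (hartree).
#' @param omega (signed) frequency (hartree).
#' @param gamma damping (hartree, >= 0).
#' @param floor smallest allowed `|d - omega|` when `gamma = 0`.
#' @return list with `re` and `im` weight vectors.
#' @export
fold_weights <- function(d, omega, gamma, floor = 1e-8) {
  x <- d - omega
  if (gamma == 0 && any(abs(x) < floor))
    stop("undamped resolvent hits a doubles-diagonal resonance")
  den <- x^2 + gamma^2
  list(re = x / den, im = gamma / den)
}

.couple_ds_c <- function(ws, x) {
  if (is.complex(x)) couple_ds(ws, Re(x)) + 1i * couple_ds(ws, Im(x))
  else couple_ds(ws, x)
}
.couple_sd_c <- function(ws, x) {
  if (is.complex(x)) couple_sd(ws, Re(x)) + 1i * couple_sd(ws, Im(x))
  else couple_sd(ws, x)
}

#' Sigma pair of the folded operator
#'
#' Returns `sigma' = A'(omega) b` and `sigma'' = A''(omega) b` for a real
#' trial vector `b`.
#' @param ws workspace (molecular or model).
#' @param b real singles vector.
#' @inheritParams fold_weights
#' @export
build_sigma_pair <- function(ws, b, omega, gamma) {
  d <- doubles_diagonal(ws)
  w <- fold_weights(d, omega, gamma)
  hb <- couple_ds(ws, b)
  list(sp = sigma_singles(ws, b) - couple_sd(ws, w$re * hb),
       spp = -couple_sd(ws, w$im * hb))
}

#' Fold a full-space right-hand side onto the singles manifold
#'
#' `B' = B_s - M_sd [1/(d - omega - i gamma)] B_d`; reduces to `B_s` when
#' the doubles block vanishes.
#' @param ws workspace.
#' @param B_s singles block (numeric or complex).
#' @param B_d doubles block or `NULL`.
#' @inheritParams fold_weights
#' @return complex folded right-hand side.
#' @export
fold_rhs <- function(ws, B_s, B_d = NULL, omega = 0, gamma = 0) {
  out <- as.complex(B_s)
  if (!is.null(B_d) && any(B_d != 0)) {
    d <- doubles_diagonal(ws)
    w <- fold_weights(d, omega, gamma)
    out <- out - .couple_sd_c(ws, (w$re + 1i * w$im) * B_d)
  }
  out
}

#' One folded complex response equation
#'
#' @param operator label for bookkeeping.
#' @param omega signed frequency (hartree); the negative-frequency branch of
#'   the response function is a system with `omega < 0`.
#' @param gamma damping (hartree, > 0 for complex response).
#' @param B_s,B_d right-hand side blocks (doubles may be `NULL`).
#' @param threshold relative residual convergence threshold.
#' @param id optional identifier.
#' @export
folded_system <- function(operator, omega, gamma, B_s, B_d = NULL,
                          threshold = 1e-4, id = NULL) {
  structure(list(operator = operator, omega = omega, gamma = gamma,
                 B_s = B_s, B_d = B_d, threshold = threshold,
                 id = if (is.null(id)) operator else id),
            class = "folded_system")
}

# modified Gram-Schmidt with re-orthogonalization; returns accepted columns
.orthonormalize <- function(V, cols, tol = 1e-8) {
  out <- NULL
  for (k in seq_len(ncol(cols))) {
    v <- cols[, k]
    nrm0 <- sqrt(sum(v^2))
    if (nrm0 < .Machine$double.eps) next
    v <- v / nrm0
    for (pass in 1:2) {
      if (!is.null(V) && ncol(V) > 0) v <- v - V %*% crossprod(V, v)
      if (!is.null(out)) v <- v - out %*% crossprod(out, v)
    }
    nrm <- sqrt(sum(v^2))
    if (nrm > tol) out <- cbind(out, v / nrm)
  }
  out
}

#' Solve the reduced folded response equation
#'
#' Projects the real coupled system onto the span of the trial vectors and
#' solves the `2m x 2m` reduced equation.
#'
#' @param subspace list with orthonormal trial matrix `V` and the stored
#'   sigma pairs `SP`, `SPP` (same number of columns as `V`).
#' @param system a `folded_system` (its folded RHS is expected in
#'   `system$rhs_folded`, a complex vector; [cpp_solve()] fills it).
#' @return list with reduced coefficients (`zR`, `zI`), the assembled
#'   complex solution `X`, the full-space residual and its relative norm.
#' @export
solve_reduced <- function(subspace, system) {
  V <- subspace$V; SP <- subspace$SP; SPP <- subspace$SPP
  m <- ncol(V)
  w <- system$omega; gam <- system$gamma
  B <- system$rhs_folded
  BR <- Re(B); BI <- Im(B)
  A1 <- crossprod(V, SP)
  A2 <- crossprod(V, SPP)
  A1 <- (A1 + t(A1)) / 2
  A2 <- (A2 + t(A2)) / 2
  Im_ <- diag(m)
  K <- rbind(cbind(A1 - w * Im_, gam * Im_ - A2),
             cbind(gam * Im_ - A2, w * Im_ - A1))
  g <- c(crossprod(V, BR), -crossprod(V, BI))
  rc <- rcond(K)
  if (!is.finite(rc) || rc < 1e-14)
    stop(sprintf("reduced folded system is ill-conditioned (rcond = %.2e)", rc))
  z <- solve(K, g)
  zR <- z[seq_len(m)]; zI <- z[m + seq_len(m)]
  XR <- as.vector(V %*% zR); XI <- as.vector(V %*% zI)
  r1 <- as.vector(SP %*% zR - w * XR + gam * XI - SPP %*% zI) - BR
  r2 <- as.vector(SPP %*% zR - gam * XR + SP %*% zI - w * XI) - BI
  bn <- sqrt(sum(BR^2) + sum(BI^2))
  rn <- sqrt(sum(r1^2) + sum(r2^2))
  list(zR = zR, zI = zI, X = XR + 1i * XI, r1 = r1, r2 = r2,
       relres = if (bn > 0) rn / bn else 0, rhs_norm = bn)
}

# approximate singles diagonal used for preconditioning
singles_diagonal <- function(ws) UseMethod("singles_diagonal")
#' @export
singles_diagonal.adc_workspace <- function(ws) {
  eps <- ws$orbital_energies
  as.vector(outer(-eps[seq_len(ws$n_occ)],
                  eps[(ws$n_occ + 1L):ws$n_so], `+`))
}

#' Iterative subspace solution of folded CPP equations
#'
#' Solves a set of folded complex response equations with either separate
#' trial subspaces per frequency (each handling all right-hand sides at
#' that frequency) or one common pool of trial vectors for all systems.
#' Trial vectors are spawned from preconditioned residuals; sigma pairs are
#' frequency-dependent and are counted per construction.
#'
#' @param ws workspace.
#' @param systems list of [folded_system()] objects.
#' @param strategy `"separate"` or `"common"` subspace construction.
#' @param common_pool for the common strategy: `"all"` pools trial vectors
#'   across operators as well as frequencies (default); `"per-operator"`
#'   keeps one common pool per operator label.
#' @param max_iter iteration cap.
#' @param ortho_tol linear-dependence drop tolerance.
#' @return list with `solutions` (per system: complex `X_s`, reconstructed
#'   complex `X_d`, convergence flag, residual history) and `diagnostics`
#'   (per-iteration records plus trial-vector / sigma-pair counters).
#' @export
cpp_solve <- function(ws, systems, strategy = c("separate", "common"),
                      common_pool = c("all", "per-operator"),
                      max_iter = 100L, ortho_tol = 1e-8) {
  strategy <- match.arg(strategy)
  common_pool <- match.arg(common_pool)
  ns <- n_singles(ws)
  d0 <- singles_diagonal(ws)
  nsys <- length(systems)
  for (k in seq_len(nsys)) {
    s <- systems[[k]]
    systems[[k]]$rhs_folded <- fold_rhs(ws, s$B_s, s$B_d, s$omega, s$gamma)
    systems[[k]]$.key <- sprintf("%.12g|%.12g", s$omega, s$gamma)
  }
  keys <- vapply(systems, function(s) s$.key, character(1))
  groups <- if (strategy == "separate") {
    split(seq_len(nsys), keys)
  } else if (common_pool == "all") {
    list(all = seq_len(nsys))
  } else {
    split(seq_len(nsys), vapply(systems, function(s) s$operator, character(1)))
  }

  solutions <- vector("list", nsys)
  records <- list()
  totals <- list()
  for (gname in names(groups)) {
    gi <- groups[[gname]]
    gkeys <- unique(keys[gi])
    V <- NULL
    SP <- lapply(gkeys, function(k) NULL); names(SP) <- gkeys
    SPP <- SP
    converged <- setNames(rep(FALSE, length(gi)), as.character(gi))
    relres <- setNames(rep(Inf, length(gi)), as.character(gi))
    hist <- lapply(gi, function(k) numeric(0)); names(hist) <- as.character(gi)
    n_trial <- 0L
    n_sigma <- setNames(rep(0L, length(gkeys)), gkeys)
    sols <- list()
    # zero-RHS systems converge immediately with zero solution
    for (k in gi) {
      if (sqrt(sum(abs(systems[[k]]$rhs_folded)^2)) == 0) {
        converged[as.character(k)] <- TRUE
        relres[as.character(k)] <- 0
        sols[[as.character(k)]] <- rep(0 + 0i, ns)
        hist[[as.character(k)]] <- 0
      }
    }
    # initial trial vectors: preconditioned folded RHS, real and imaginary
    init <- NULL
    for (k in gi) {
      if (converged[as.character(k)]) next
      s <- systems[[k]]
      p <- (d0 - s$omega) / ((d0 - s$omega)^2 + s$gamma^2)
      init <- cbind(init, p * Re(s$rhs_folded), p * Im(s$rhs_folded))
    }
    iter <- 0L
    it_records <- list()
    newV <- if (!is.null(init)) .orthonormalize(NULL, init, ortho_tol) else NULL
    while (any(!converged) && iter < max_iter) {
      iter <- iter + 1L
      if (is.null(newV) || ncol(newV) == 0) break
      n_new <- ncol(newV)
      n_trial <- n_trial + n_new
      unconv_keys <- unique(keys[gi[!converged]])
      it_records[[iter]] <- data.frame(
        iteration = iter, new_vectors = n_new,
        unconverged_frequencies = length(unconv_keys),
        sigma_built = n_new * length(unconv_keys))
      for (key in unconv_keys) {
        s0 <- systems[[gi[match(key, keys[gi])]]]
        add_p <- matrix(0, ns, n_new); add_pp <- matrix(0, ns, n_new)
        for (c_ in seq_len(n_new)) {
          pr <- build_sigma_pair(ws, newV[, c_], s0$omega, s0$gamma)
          add_p[, c_] <- pr$sp; add_pp[, c_] <- pr$spp
        }
        SP[[key]] <- cbind(SP[[key]], add_p)
        SPP[[key]] <- cbind(SPP[[key]], add_pp)
        n_sigma[key] <- n_sigma[key] + n_new
      }
      V <- cbind(V, newV)
      cand <- NULL
      for (k in gi) {
        kc <- as.character(k)
        if (converged[kc]) next
        s <- systems[[k]]
        # converged frequencies' sigma stores may lag the pool; guard
        mk <- min(ncol(SP[[s$.key]]), ncol(V))
        red <- solve_reduced(list(V = V[, seq_len(mk), drop = FALSE],
                                  SP = SP[[s$.key]][, seq_len(mk), drop = FALSE],
                                  SPP = SPP[[s$.key]][, seq_len(mk), drop = FALSE]),
                             s)
        relres[kc] <- red$relres
        hist[[kc]] <- c(hist[[kc]], red$relres)
        sols[[kc]] <- red$X
        records[[length(records) + 1L]] <- data.frame(
          group = gname, iteration = iter, system = s$id,
          omega = s$omega, residual = red$relres, subspace_dim = ncol(V),
          stringsAsFactors = FALSE)
        if (red$relres <= s$threshold) {
          converged[kc] <- TRUE
        } else {
          p <- (d0 - s$omega) / ((d0 - s$omega)^2 + s$gamma^2)
          cand <- cbind(cand, p * red$r1, p * red$r2)
        }
      }
      newV <- if (!is.null(cand)) .orthonormalize(V, cand, ortho_tol) else NULL
    }
    if (any(!converged))
      warning(sprintf("%d folded system(s) in group %s not converged in %d iterations",
                      sum(!converged), gname, iter))
    for (k in gi) {
      kc <- as.character(k)
      s <- systems[[k]]
      X <- sols[[kc]]
      d <- doubles_diagonal(ws)
      wts <- fold_weights(d, s$omega, s$gamma)
      wc <- wts$re + 1i * wts$im
      Bd <- if (is.null(s$B_d)) 0 else s$B_d
      Xd <- wc * (Bd - .couple_ds_c(ws, X))
      solutions[[k]] <- structure(list(
        X_s = X, X_d = Xd, omega = s$omega, gamma = s$gamma,
        operator = s$operator, id = s$id, converged = converged[kc],
        relres = relres[kc], residual_history = hist[[kc]],
        iterations = length(hist[[kc]])), class = "response_solution")
    }
    totals[[gname]] <- list(
      iterations = iter, trial_vectors = n_trial, sigma_pairs = n_sigma,
      per_iteration = if (length(it_records)) do.call(rbind, it_records) else NULL)
  }
  diag_df <- if (length(records)) do.call(rbind, records) else
    data.frame(group = character(0), iteration = integer(0),
               system = character(0), omega = numeric(0),
               residual = numeric(0), subspace_dim = integer(0))
  list(solutions = solutions,
       diagnostics = list(records = diag_df, groups = totals,
                          strategy = strategy, n_systems = nsys,
                          n_frequencies = length(unique(keys))))
}

#' Response-function contribution of one solved equation
#'
#' `A^dagger X` over the full space, with the doubles product evaluated
#' through the reconstructed `X_d`.
#'
#' @param A a `transition_moment_set` for the left-hand operator.
#' @param X a converged `response_solution`.
#' @param allow_unconverged contract anyway for a flagged solution.
#' @return complex scalar.
#' @export
response_value <- function(A, X, allow_unconverged = FALSE) {
  if (!isTRUE(X$converged) && !allow_unconverged)
    stop("response solution not converged; pass allow_unconverged = TRUE")
  sum(Conj(A$F_s) * X$X_s) + sum(Conj(A$F_d) * X$X_d)
}
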