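# naive nested-loop evaluation of each of the 13 second-order terms
naive_second_order_terms <- function(ws, theta) {
  no <- ws$n_occ; nv <- ws$n_vir
  o <- seq_len(no); v <- (no + 1L):ws$n_so
  eps <- ws$orbital_energies; g <- ws$g; t2 <- ws$t2
  too <- theta[o, o]; tvv <- theta[v, v]
  tov <- theta[o, v]; tvo <- theta[v, o]
  Dia <- outer(eps[o], eps[v], `-`)
  D2 <- outer(outer(eps[o], eps[o], `+`), outer(eps[v], eps[v], `+`), `-`)
  ts2A <- matrix(0, no, nv); ts2B <- matrix(0, no, nv)
  for (i in o) for (a in seq_len(nv)) {
    s1 <- 0; s2 <- 0
    for (j in o) for (b in seq_len(nv)) for (cc in seq_len(nv))
      s1 <- s1 + g[j, v[a], v[b], v[cc]] * t2[i, j, b, cc]
    for (j in o) for (k in o) for (b in seq_len(nv))
      s2 <- s2 + g[j, k, i, v[b]] * t2[j, k, a, b]
    ts2A[i, a] <- -0.5 * s1 / Dia[i, a]
    ts2B[i, a] <- -0.5 * s2 / Dia[i, a]
  }
  tdpp <- array(0, c(no, no, nv, nv)); tdhh <- tdpp; tdr <- tdpp
  for (i in o) for (j in o) for (a in seq_len(nv)) for (b in seq_len(nv)) {
    s <- 0
    for (cc in seq_len(nv)) for (dd in seq_len(nv))
      s <- s + g[v[a], v[b], v[cc], v[dd]] * t2[i, j, cc, dd]
    tdpp[i, j, a, b] <- 0.5 * s / D2[i, j, a, b]
    s <- 0
    for (k in o) for (l in o) s <- s + g[k, l, i, j] * t2[k, l, a, b]
    tdhh[i, j, a, b] <- 0.5 * s / D2[i, j, a, b]
    s <- 0
    for (k in o) for (cc in seq_len(nv))
      s <- s + g[k, v[b], v[cc], j] * t2[i, k, a, cc]
    tdr[i, j, a, b] <- s / D2[i, j, a, b]
  }
  ovc <- function(td) {
    r <- matrix(0, no, nv)
    for (i in o) for (a in seq_len(nv)) {
      s <- 0
      for (j in o) for (b in seq_len(nv)) s <- s + tov[j, b] * td[i, j, a, b]
      r[i, a] <- s
    }
    r
  }
  ch <- matrix(0, no, nv); roo <- ch; rvv <- ch
  for (i in o) for (a in seq_len(nv)) {
    s <- 0
    for (j in o) for (b in seq_len(nv)) for (k in o) for (cc in seq_len(nv))
      s <- s + t2[i, j, a, b] * t2[j, k, b, cc] * tvo[cc, k]
    ch[i, a] <- 0.5 * s
    s <- 0
    for (k in o) {
      w <- 0
      for (j in o) for (b in seq_len(nv)) for (cc in seq_len(nv))
        w <- w + t2[i, j, b, cc] * t2[j, k, b, cc]
      s <- s + w * tvo[a, k]
    }
    roo[i, a] <- 0.25 * s
    s <- 0
    for (cc in seq_len(nv)) {
      w <- 0
      for (j in o) for (k in o) for (b in seq_len(nv))
        w <- w + t2[j, k, a, b] * t2[j, k, b, cc]
      s <- s + w * tvo[cc, i]
    }
    rvv[i, a] <- 0.25 * s
  }
  list(vv_ts2A = ts2A %*% t(tvv), vv_ts2B = ts2B %*% t(tvv),
       oo_ts2A = -t(too) %*% ts2A, oo_ts2B = -t(too) %*% ts2B,
       pp_ladder = ovc(tdpp), hh_ladder = ovc(tdhh),
       ring_1 = ovc(tdr), ring_2 = -ovc(aperm(tdr, c(2, 1, 3, 4))),
       ring_3 = -ovc(aperm(tdr, c(1, 2, 4, 3))),
       ring_4 = ovc(aperm(tdr, c(2, 1, 4, 3))),
       tt_chain = ch, tt_rho_oo = roo, tt_rho_vv = rvv)
}
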