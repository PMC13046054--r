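# Independent brute-force Dijkstra oracle, written in plain R with no
# priority queue: linear scan for the cheapest unsettled node. Shares nothing
# with the package's search implementation; only the cost-map definition is
# taken as given.

oracle_edge_cost <- function(cm, pr, pc, qr, qc) {
  dr <- qr - pr; dc <- qc - pc
  len <- if (dr != 0 && dc != 0) sqrt(2) else 1
  gpr <- cm$grad_row[pr, pc]; gpc <- cm$grad_col[pr, pc]
  gqr <- cm$grad_row[qr, qc]; gqc <- cm$grad_col[qr, qc]
  if (gpr == 0 && gpc == 0 && gqr == 0 && gqc == 0) {
    fd <- 0
  } else {
    dpr <- -gpc; dpc <- gpr
    dqr <- -gqc; dqc <- gqr
    lr <- dr / len; lc <- dc / len
    if (dpr * lr + dpc * lc < 0) { lr <- -lr; lc <- -lc }
    d_p <- max(-1, min(1, dpr * lr + dpc * lc))
    d_q <- max(-1, min(1, lr * dqr + lc * dqc))
    fd <- (acos(d_p) + acos(d_q)) * 2 / (3 * pi)
  }
  w <- cm$weights
  (w[["z"]] * cm$laplacian_cost[qr, qc] + w[["d"]] * fd +
     w[["g"]] * cm$gradient_cost[qr, qc]) * len
}

oracle_dijkstra_cost <- function(cm, start, end) {
  nr <- nrow(cm$gradient_cost); nc <- ncol(cm$gradient_cost)
  n <- nr * nc
  dist <- rep(Inf, n)
  settled <- rep(FALSE, n)
  id <- function(r, c) (c - 1L) * nr + r
  dist[id(start[1], start[2])] <- 0
  target <- id(end[1], end[2])
  moves <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                 c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    d <- dist; d[settled] <- Inf
    u <- which.min(d)
    if (!is.finite(d[u])) break
    settled[u] <- TRUE
    if (u == target) break
    ur <- (u - 1L) %% nr + 1L; uc <- (u - 1L) %/% nr + 1L
    for (k in 1:8) {
      vr <- ur + moves[k, 1]; vc <- uc + moves[k, 2]
      if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
      v <- id(vr, vc)
      if (settled[v]) next
      alt <- dist[u] + oracle_edge_cost(cm, ur, uc, vr, vc)
      if (alt < dist[v]) dist[v] <- alt
    }
  }
  dist[target]
}
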