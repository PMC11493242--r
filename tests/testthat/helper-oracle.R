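# Independent R reference for the photon transport: pure-R sampling
# primitives and an exhaustive breadth-first enumeration of the full
# transmit/reflect split tree. Used to cross-check the recursive tracer.

ref_clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

ref_sample_index <- function(a, u) {
  n <- dim(a)
  u <- ref_clamp(u, 0, n - 1)
  i0 <- floor(u)
  i0 <- ifelse(i0 > n - 2, ifelse(n >= 2, n - 2, 0), i0)
  i1 <- ifelse(n >= 2, i0 + 1, 0)
  f <- ref_clamp(u - i0, 0, 1)
  v <- function(i, j, k) a[i + 1, j + 1, k + 1]
  c00 <- v(i0[1], i0[2], i0[3]) * (1 - f[1]) + v(i1[1], i0[2], i0[3]) * f[1]
  c10 <- v(i0[1], i1[2], i0[3]) * (1 - f[1]) + v(i1[1], i1[2], i0[3]) * f[1]
  c01 <- v(i0[1], i0[2], i1[3]) * (1 - f[1]) + v(i1[1], i0[2], i1[3]) * f[1]
  c11 <- v(i0[1], i1[2], i1[3]) * (1 - f[1]) + v(i1[1], i1[2], i1[3]) * f[1]
  c0 <- c00 * (1 - f[2]) + c10 * f[2]
  c1 <- c01 * (1 - f[2]) + c11 * f[2]
  c0 * (1 - f[3]) + c1 * f[3]
}

ref_sample_phys <- function(vol, p) {
  ref_sample_index(vol$data, (p - vol$origin) / vol$spacing)
}

ref_gradient <- function(vol, p) {
  u <- (p - vol$origin) / vol$spacing
  n <- dim(vol$data)
  g <- numeric(3)
  for (a in 1:3) {
    ua <- ref_clamp(u[a], 0, n[a] - 1)
    up <- ref_clamp(ua + 1, 0, n[a] - 1)
    um <- ref_clamp(ua - 1, 0, n[a] - 1)
    gap <- (up - um) * vol$spacing[a]
    if (gap <= 0) next
    q <- u; q[a] <- up; vp <- ref_sample_index(vol$data, q)
    q <- u; q[a] <- um; vm <- ref_sample_index(vol$data, q)
    g[a] <- (vp - vm) / gap
  }
  g
}

ref_tf_eval <- function(tf, x) {
  n <- length(tf$v)
  if (x <= tf$v[1]) return(tf$rgba[1, ])
  if (x >= tf$v[n]) return(tf$rgba[n, ])
  lo <- findInterval(x, tf$v)
  dv <- tf$v[lo + 1] - tf$v[lo]
  t <- if (dv > 0) (x - tf$v[lo]) / dv else 1
  tf$rgba[lo, ] + (tf$rgba[lo + 1, ] - tf$rgba[lo, ]) * t
}

ref_box_intersect <- function(vol, o, d) {
  b <- list(lo = vol$origin - 0.5 * vol$spacing,
            hi = vol$origin + (dim(vol$data) - 1) * vol$spacing +
              0.5 * vol$spacing)
  t0 <- -Inf; t1 <- Inf
  for (a in 1:3) {
    if (abs(d[a]) < 1e-15) {
      if (o[a] < b$lo[a] || o[a] > b$hi[a]) return(NULL)
    } else {
      ta <- (b$lo[a] - o[a]) / d[a]
      tb <- (b$hi[a] - o[a]) / d[a]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      if (ta > t0) t0 <- ta
      if (tb < t1) t1 <- tb
    }
  }
  if (t1 <= t0) NULL else c(t0, t1)
}

ref_cell_index <- function(vol, p) {
  n <- dim(vol$data)
  idx <- floor((p - vol$origin) / vol$spacing + 0.5)
  pmin(pmax(idx, 0), n - 1) + 1  # 1-based
}

# Exhaustive enumeration of the binary split tree with an explicit queue.
# cfg: list(step [mm], epsilon [fraction of root energy], F0, max_depth,
# gradient_threshold). Returns per-cell deposits and the energy balance.
ref_trace_enumerate <- function(vol, tf, origin, direction, energy, cfg) {
  deposits <- array(0, dim(vol$data))
  dep <- 0; exi <- 0; drp <- 0
  eps_abs <- cfg$epsilon * energy
  queue <- list(list(o = origin, d = direction, E = energy, depth = 0L))
  while (length(queue)) {
    node <- queue[[1]]; queue <- queue[-1]
    bi <- ref_box_intersect(vol, node$o, node$d)
    if (is.null(bi)) { exi <- exi + node$E; next }
    t0 <- max(bi[1], 0); t1 <- bi[2]
    if (t1 <= t0) { exi <- exi + node$E; next }
    E <- node$E
    terminated <- FALSE
    nsteps <- ceiling((t1 - t0) / cfg$step)
    for (k in seq_len(nsteps) - 1) {
      t <- t0 + (k + 0.5) * cfg$step
      if (t > t1) break
      p <- node$o + t * node$d
      alpha <- ref_tf_eval(tf, ref_sample_phys(vol, p))[4]
      if (alpha <= 0) next
      gr <- ref_gradient(vol, p)
      gn <- sqrt(sum(gr^2))
      have_normal <- gn >= cfg$gradient_threshold
      F <- 0
      if (have_normal) {
        coshv <- ref_clamp(abs(sum(gr * node$d) / gn), 0, 1)
        m <- 1 - coshv
        F <- cfg$F0 + (1 - cfg$F0) * m * m * m * m * m
      }
      Fp <- min(F, alpha)
      LT <- E * (1 - alpha)
      LR <- E * Fp
      LC <- E - LR - LT
      if (LC < 0) LC <- 0
      ci <- ref_cell_index(vol, p)
      deposits[ci[1], ci[2], ci[3]] <- deposits[ci[1], ci[2], ci[3]] + LC
      dep <- dep + LC
      if (LR > 0) {
        pushed <- FALSE
        if (have_normal && LR >= eps_abs && node$depth + 1 <= cfg$max_depth) {
          nrm <- gr / gn
          r <- node$d - 2 * sum(node$d * nrm) * nrm
          rn <- sqrt(sum(r^2))
          if (rn > 0) {
            queue[[length(queue) + 1]] <-
              list(o = p, d = r / rn, E = LR, depth = node$depth + 1L)
            pushed <- TRUE
          }
        }
        if (!pushed) drp <- drp + LR
      }
      E <- LT
      if (E < eps_abs) { drp <- drp + E; terminated <- TRUE; break }
    }
    if (!terminated) exi <- exi + E
  }
  list(deposits = deposits, deposited = dep, exited = exi, dropped = drp)
}
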