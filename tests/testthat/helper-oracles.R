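# Independent reference implementations used as oracles.  These are written
# as direct per-pixel / per-column loops, deliberately sharing no code with
# the package internals.

# mirror-with-edge index (symmetric padding convention)
mirror_idx <- function(i, n) {
  ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))
}

circ_shift <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  m[((seq_len(n) - 1L - dr) %% n) + 1L, ((seq_len(p) - 1L - dc) %% p) + 1L]
}

# Naive per-column orthogonal matching pursuit (greedy + LS refit).
naive_omp <- function(D, X, residual_tol = 0.01, max_atoms = NULL) {
  if (is.null(max_atoms)) max_atoms <- max(1L, nrow(D) %/% 2L)
  K <- ncol(D); P <- ncol(X)
  codes <- matrix(0, K, P)
  for (p in seq_len(P)) {
    x <- X[, p]
    target <- max(residual_tol * sqrt(sum(x^2)), 1e-12)
    r <- x
    sel <- integer(0)
    gamma <- numeric(0)
    while (sqrt(sum(r^2)) > target && length(sel) < max_atoms) {
      corr <- abs(crossprod(D, r))
      corr[sel] <- -Inf
      k <- which.max(corr)
      if (corr[k] <= 1e-14) break
      cand <- c(sel, k)
      Dm <- D[, cand, drop = FALSE]
      g <- tryCatch(qr.solve(crossprod(Dm), crossprod(Dm, x)),
                    error = function(e) NULL)
      if (is.null(g)) break
      sel <- cand
      gamma <- g
      r <- x - Dm %*% g
    }
    codes[sel, p] <- gamma
  }
  codes
}

# Scalar simplified-PCNN recurrence for one uncoupled neuron (beta = 0).
pcnn_scalar_oracle <- function(I, params, n_iter = params$N_max) {
  theta <- 1; y <- 0; O <- 0
  fired_at <- integer(0)
  for (n in seq_len(n_iter)) {
    theta <- exp(-params$alpha_theta) * theta + params$V_theta * y
    y <- as.numeric(I > theta)
    O <- O + y
    if (y == 1) fired_at <- c(fired_at, n)
  }
  list(O = O, fired_at = fired_at)
}

# Double-loop local spatial frequency (first differences zero at the border,
# window means with mirrored indexing).
naive_spatial_frequency <- function(x, window = 3L) {
  nr <- nrow(x); nc <- ncol(x)
  dh <- matrix(0, nr, nc); dv <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (j > 1) dh[i, j] <- x[i, j] - x[i, j - 1]
    if (i > 1) dv[i, j] <- x[i, j] - x[i - 1, j]
  }
  p <- (window - 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (du in -p:p) for (dv_ in -p:p) {
      u <- mirror_idx(i + du, nr); v <- mirror_idx(j + dv_, nc)
      s <- s + dh[u, v]^2 + dv[u, v]^2
    }
    out[i, j] <- sqrt(s / window^2)
  }
  out
}

# Double-loop link-strength maps (EOL / VI / SD).
naive_link_maps <- function(x, window = 3L, vi_alpha = 0.7) {
  nr <- nrow(x); nc <- ncol(x)
  p <- (window - 1L) %/% 2L
  g <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    f_uu <- x[mirror_idx(i - 1, nr), j] - 2 * x[i, j] + x[mirror_idx(i + 1, nr), j]
    f_vv <- x[i, mirror_idx(j - 1, nc)] - 2 * x[i, j] + x[i, mirror_idx(j + 1, nc)]
    g[i, j] <- f_uu + f_vv
  }
  eol <- vi <- sdm <- matrix(0, nr, nc)
  N <- window^2
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- numeric(N); gv <- numeric(N); t <- 1
    for (du in -p:p) for (dv_ in -p:p) {
      u <- mirror_idx(i + du, nr); v <- mirror_idx(j + dv_, nc)
      vals[t] <- x[u, v]; gv[t] <- g[u, v]; t <- t + 1
    }
    m <- mean(vals)
    ms <- max(m, 1e-6)
    eol[i, j] <- sum(gv^2)
    vi[i, j] <- (1 / ms)^vi_alpha * sum(abs(vals - m)) / (N * ms)
    sdm[i, j] <- sqrt(sum((vals - m)^2) / N)
  }
  list(eol = eol, vi = vi, sd = sdm)
}

# Per-pixel Q^AB/F reference (unnormalised sigmoid scaling).
naive_qabf <- function(a, b, f) {
  sobel <- function(x) {
    nr <- nrow(x); nc <- ncol(x)
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
    gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      sx <- 0; sy <- 0
      for (di in -1:1) for (dj in -1:1) {
        # convolution: kernel index is the negated offset
        u <- mirror_idx(i - di, nr); v <- mirror_idx(j - dj, nc)
        sx <- sx + kx[di + 2, dj + 2] * x[u, v]
        sy <- sy + kx[dj + 2, di + 2] * x[u, v]
      }
      gx[i, j] <- sx; gy[i, j] <- sy
    }
    gmag <- sqrt(gx^2 + gy^2)
    ang <- atan2(gy, gx)
    ang[ang > pi / 2] <- ang[ang > pi / 2] - pi
    ang[ang <= -pi / 2] <- ang[ang <= -pi / 2] + pi
    list(g = gmag, a = ang)
  }
  qq <- function(s, ff) {
    gmax <- pmax(s$g, ff$g)
    G <- ifelse(gmax == 0, 1, pmin(s$g, ff$g) / ifelse(gmax == 0, 1, gmax))
    d <- abs(s$a - ff$a); d <- pmin(d, pi - d)
    A <- 1 - d / (pi / 2)
    (0.9994 / (1 + exp(-15 * (G - 0.5)))) * (0.9879 / (1 + exp(-22 * (A - 0.8))))
  }
  sa <- sobel(a); sb <- sobel(b); sf <- sobel(f)
  num <- sum(qq(sa, sf) * sa$g + qq(sb, sf) * sb$g)
  num / sum(sa$g + sb$g)
}

# Planted 1-sparse dictionary problem.
planted_problem <- function(d = 8L, K = 16L, P = 200L, seed = 5L) {
  withr::with_seed(seed, {
    D0 <- matrix(rnorm(d * K), d)
    D0 <- sweep(D0, 2, sqrt(colSums(D0^2)), `/`)
    idx <- rep(seq_len(K), length.out = P)
    coef <- runif(P, 0.5, 2) * sample(c(-1, 1), P, replace = TRUE)
    V <- D0[, idx] * rep(coef, each = d)
    list(D0 = D0, V = V, idx = idx, coef = coef)
  })
}

light_config <- function(seed = 1L) {
  fusion_config(
    nsct = list(levels = 2L, directions = c(2L, 4L)),
    sparse = list(window = 4L, n_atoms = 32L, ksvd_iterations = 3L,
                  seed = seed),
    pcnn = list(N_max = 30L)
  )
}
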