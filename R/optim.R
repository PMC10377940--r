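# Internal optimization machinery for the intersection-information measures.
#
# The degradation measure maximizes the convex function I(Q;T) over the
# polytope of channel stacks {KU(i)} with K(i) KU(i) equal for all i; its
# maximum sits at a vertex, so small problems are solved by exhaustive
# vertex enumeration of the affine slice {x >= 0, Ax = b} and larger ones by
# multistart feasible ascent (reported as a lower bound).

# Build the linear system A x = b for the degradation polytope.
# x stacks vec(KU(i)) (column-major, KU(i) is c_i x m) for i = 1..n.
degradation_polytope <- function(channels, m) {
  k <- nrow(channels[[1]])
  cs <- vapply(channels, ncol, integer(1))
  n <- length(channels)
  offs <- c(0L, cumsum(cs * m))
  L <- offs[n + 1L]
  rows <- list()
  rhs <- numeric(0)
  # row-stochasticity of each KU(i)
  for (i in seq_len(n)) {
    for (r in seq_len(cs[i])) {
      a <- numeric(L)
      a[offs[i] + (seq_len(m) - 1L) * cs[i] + r] <- 1
      rows[[length(rows) + 1L]] <- a
      rhs <- c(rhs, 1)
    }
  }
  # K(i) KU(i) = K(1) KU(1) for i >= 2
  K1 <- ch_mat(channels[[1]])
  for (i in seq_len(n)[-1]) {
    Ki <- ch_mat(channels[[i]])
    for (q in seq_len(m)) {
      for (t in seq_len(k)) {
        a <- numeric(L)
        a[offs[1] + (q - 1L) * cs[1] + seq_len(cs[1])] <- -K1[t, ]
        a[offs[i] + (q - 1L) * cs[i] + seq_len(cs[i])] <- Ki[t, ]
        rows[[length(rows) + 1L]] <- a
        rhs <- c(rhs, 0)
      }
    }
  }
  A <- do.call(rbind, rows)
  x0 <- rep(1 / m, L)  # all-uniform KU rows: constant Q, always feasible
  sv <- svd(A, nv = ncol(A))
  rank <- sum(sv$d > 1e-10 * max(sv$d))
  N <- if (rank < ncol(A)) sv$v[, (rank + 1L):ncol(A), drop = FALSE] else
    matrix(0, ncol(A), 0)
  list(A = A, b = rhs, x0 = x0, N = N, offs = offs, cs = cs, m = m, k = k,
       L = L)
}

# Extract KU(i) blocks / the candidate KQ from a stacked x.
poly_ku <- function(poly, x, i) {
  matrix(x[(poly$offs[i] + 1L):poly$offs[i + 1L]], nrow = poly$cs[i])
}

poly_kq <- function(poly, x, channels) {
  ch_mat(channels[[1]]) %*% poly_ku(poly, x, 1L)
}

# Enumerate vertices of {x >= 0, x = x0 + N z}: every vertex activates
# dim-many linearly independent bounds.  Returns a matrix with one vertex
# per column (always includes x0's face if x0 is itself a vertex).
enumerate_vertices <- function(x0, N, feas_tol = 1e-9) {
  d <- ncol(N)
  L <- length(x0)
  if (d == 0L) return(matrix(x0, ncol = 1L))
  combos <- utils::combn(L, d)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (ci in seq_len(ncol(combos))) {
    idx <- combos[, ci]
    B <- N[idx, , drop = FALSE]
    qrB <- qr(B)
    if (qrB$rank < d) next
    z <- qr.coef(qrB, -x0[idx])
    x <- x0 + as.numeric(N %*% z)
    if (min(x) < -feas_tol) next
    x[x < 0] <- 0
    key <- paste(sprintf("%.8f", round(x, 8)), collapse = ",")
    if (!exists(key, envir = seen, inherits = FALSE)) {
      assign(key, TRUE, envir = seen)
      out[[length(out) + 1L]] <- x
    }
  }
  if (length(out) == 0L) matrix(x0, ncol = 1L) else do.call(cbind, out)
}

# Gradient of I(p_t, KQ(x)) with respect to x (only the KU(1) block moves
# the objective once the equality constraints are imposed via N).
degradation_gradient <- function(poly, x, p_t, channels) {
  K1 <- ch_mat(channels[[1]])
  KQ <- K1 %*% poly_ku(poly, x, 1L)
  qy <- as.numeric(p_t %*% KQ)
  Gq <- matrix(0, poly$k, poly$m)
  pos <- qy > 0
  for (t in which(p_t > 0)) {
    Gq[t, pos] <- p_t[t] * log2(pmax(KQ[t, pos], 1e-12) / qy[pos])
  }
  g <- numeric(poly$L)
  g[(poly$offs[1] + 1L):poly$offs[2]] <- as.vector(crossprod(K1, Gq))
  g
}

# Multistart feasible ascent over the degradation polytope (z-space).
# Convexity of the objective means each line segment attains its maximum at
# an endpoint, so every move jumps to the feasible boundary.
ascend_degradation <- function(poly, p_t, channels, starts, opts) {
  N <- poly$N
  f <- function(x) mi_kernel(p_t, poly_kq(poly, x, channels))
  best_x <- poly$x0
  best_f <- f(best_x)
  step_to_boundary <- function(x, w) {
    neg <- w < -1e-14
    if (!any(neg)) return(Inf)
    min(x[neg] / -w[neg])
  }
  for (s in starts) {
    # project onto the affine hull (starts may carry ~1e-8 constraint slack)
    z <- as.numeric(crossprod(N, s - poly$x0))
    x <- poly$x0 + as.numeric(N %*% z)
    if (min(x) < -1e-6) next
    x[x < 0] <- 0
    fx <- f(x)
    for (iter in seq_len(opts$max_iter)) {
      g <- degradation_gradient(poly, x, p_t, channels)
      dirs <- list(as.numeric(crossprod(N, g)))
      for (r in seq_len(opts$n_dirs)) {
        dirs[[length(dirs) + 1L]] <- stats::rnorm(ncol(N))
      }
      improved <- FALSE
      for (dz in dirs) {
        nz <- sqrt(sum(dz^2))
        if (nz < 1e-14) next
        dz <- dz / nz
        for (sgn in c(1, -1)) {
          w <- as.numeric(N %*% (sgn * dz))
          alpha <- step_to_boundary(x, w)
          if (!is.finite(alpha) || alpha < 1e-12) next
          cand <- x + alpha * w
          cand[cand < 0] <- 0
          fc <- f(cand)
          if (fc > fx + 1e-12) {
            x <- cand; fx <- fc; improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (!improved) break
    }
    if (fx > best_f) {
      best_f <- fx
      best_x <- x
    }
  }
  list(x = best_x, value = best_f)
}

# Stack a full x from per-source KU matrices.
stack_ku <- function(poly, kus) {
  x <- numeric(poly$L)
  for (i in seq_along(kus)) {
    x[(poly$offs[i] + 1L):poly$offs[i + 1L]] <- as.vector(kus[[i]])
  }
  x
}

# Try to express KQ as a degradation of every source channel; returns the
# stacked x when all residuals pass, else NULL.
degradation_certificates <- function(poly, channels, KQ, tol = 1e-7) {
  kus <- vector("list", length(channels))
  for (i in seq_along(channels)) {
    fit <- solve_stochastic_ls(ch_mat(channels[[i]]), KQ)
    if (fit$residual > tol) return(NULL)
    kus[[i]] <- fit$KU
  }
  stack_ku(poly, kus)
}

# ---------------------------------------------------------------------------
# Feasible ascent over KQ directly (sampled-constraint relaxations of the
# less-noisy / more-capable measures).  `feasible` must define a convex set.

ascend_kq <- function(start, p_t, feasible, opts) {
  k <- nrow(start); m <- ncol(start)
  f <- function(K) mi_kernel(p_t, K)
  x <- start
  fx <- f(x)
  grad <- function(K) {
    qy <- as.numeric(p_t %*% K)
    G <- matrix(0, k, m)
    pos <- qy > 0
    for (t in which(p_t > 0)) {
      G[t, pos] <- p_t[t] * log2(pmax(K[t, pos], 1e-12) / qy[pos])
    }
    G - rowMeans(G)  # keep row sums unchanged
  }
  max_alpha_box <- function(K, D) {
    neg <- D < -1e-14
    if (!any(neg)) return(Inf)
    min(K[neg] / -D[neg])
  }
  feasible_step <- function(K, D, box) {
    # feasible alphas form an interval [0, amax]; bisect for amax
    if (!is.finite(box)) box <- 1
    if (feasible(K + box * D)) return(box)
    lo <- 0; hi <- box
    for (it in seq_len(15)) {
      mid <- (lo + hi) / 2
      if (feasible(K + mid * D)) lo <- mid else hi <- mid
    }
    lo
  }
  for (iter in seq_len(opts$max_iter)) {
    dirs <- list(grad(x))
    for (r in seq_len(opts$n_dirs)) {
      D <- matrix(stats::rnorm(k * m), k, m)
      dirs[[length(dirs) + 1L]] <- D - rowMeans(D)
    }
    improved <- FALSE
    for (D in dirs) {
      nd <- sqrt(sum(D^2))
      if (nd < 1e-14) next
      D <- D / nd
      for (sgn in c(1, -1)) {
        Ds <- sgn * D
        box <- max_alpha_box(x, Ds)
        if (box < 1e-12) next
        alpha <- feasible_step(x, Ds, box)
        if (alpha < 1e-12) next
        cand <- x + alpha * Ds
        cand[cand < 0] <- 0
        cand <- cand / rowSums(cand)
        fc <- f(cand)
        if (fc > fx + 1e-12 && feasible(cand)) {
          x <- cand; fx <- fc; improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  list(K = x, value = fx)
}

# Pad a channel with zero columns up to m outputs.
pad_channel <- function(K, m) {
  K <- ch_mat(K)
  if (ncol(K) >= m) return(K[, seq_len(m), drop = FALSE])
  cbind(K, matrix(0, nrow(K), m - ncol(K)))
}

# Largest feasible shrinkage of a random channel toward the constant
# (always-feasible) channel; used to diversify ascent starts.
shrink_to_feasible <- function(Krand, feasible) {
  k <- nrow(Krand)
  const <- matrix(colMeans(Krand), k, ncol(Krand), byrow = TRUE)
  if (feasible(Krand)) return(Krand)
  lo <- 0; hi <- 1
  for (it in seq_len(20)) {
    mid <- (lo + hi) / 2
    if (feasible((1 - mid) * const + mid * Krand)) lo <- mid else hi <- mid
  }
  (1 - 0.95 * lo) * const + 0.95 * lo * Krand
}
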