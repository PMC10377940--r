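# Decision procedures for the channel preorders, with certificates.
#
# Orientation convention used throughout: check(w, v) decides whether
# w <= v in the given order, i.e. whether v is the more informative channel
# (v "less noisy" / "more capable" than w; w a degradation of v).

order_verdict <- function(relation, status, certificate = NULL, ...) {
  structure(list(relation = relation, status = status,
                 certificate = certificate, details = list(...)),
            class = "order_verdict")
}

#' @export
print.order_verdict <- function(x, ...) {
  cat(sprintf("order check [%s]: %s\n", x$relation, x$status))
  if (!is.null(x$details$resolution)) {
    cat(sprintf("  grid resolution: %g\n", x$details$resolution))
  }
  if (!is.null(x$certificate)) cat("  certificate attached\n")
  invisible(x)
}

check_same_input <- function(w, v) {
  if (nrow(w) != nrow(v)) {
    pid_error("INPUT_MISMATCH", "channels must share the input alphabet")
  }
}

# Least squares over row-stochastic matrices: minimize ||W - V KU||_F^2.
# quadprog solves the ridge-regularized QP; the active set of that solution
# is then polished by an exact equality-constrained least-squares solve so
# the reported residual is free of ridge bias.
solve_stochastic_ls <- function(V, W) {
  V <- ch_mat(V); W <- ch_mat(W)
  a <- ncol(V); b <- ncol(W); k <- nrow(V)
  VtV <- crossprod(V)
  ridge <- 1e-10 * max(1, sum(diag(VtV)))
  D <- kronecker(diag(b), VtV) + ridge * diag(a * b)
  d <- as.vector(crossprod(V, W))
  E <- matrix(0, a, a * b)
  for (r in seq_len(a)) E[r, (seq_len(b) - 1L) * a + r] <- 1
  Amat <- t(rbind(E, diag(a * b)))
  bvec <- c(rep(1, a), rep(0, a * b))
  sol <- tryCatch(
    quadprog::solve.QP(D, d, Amat, bvec, meq = a)$solution,
    error = function(e) NULL
  )
  if (is.null(sol)) {
    # Fall back to heavier regularization; feasible set is never empty.
    D2 <- D + 1e-6 * diag(a * b)
    sol <- quadprog::solve.QP(D2, d, Amat, bvec, meq = a)$solution
  }
  sol[sol < 0] <- 0
  x <- polish_active_set(V, W, E, sol)
  KU <- matrix(x, nrow = a)
  KU[KU < 0] <- 0
  KU <- KU / rowSums(KU)
  list(KU = KU, residual = max(abs(W - V %*% KU)))
}

# Exact equality-constrained least squares on the free (inactive) entries.
polish_active_set <- function(V, W, E, x, active_tol = 1e-7) {
  a <- ncol(V); b <- ncol(W)
  M <- kronecker(diag(b), V)
  free <- which(x > active_tol)
  if (length(free) == 0L) return(x)
  Mf <- M[, free, drop = FALSE]
  Ef <- E[, free, drop = FALSE]
  keep <- rowSums(abs(Ef)) > 0
  Ef <- Ef[keep, , drop = FALSE]
  nf <- length(free); ne <- nrow(Ef)
  KKT <- rbind(cbind(crossprod(Mf), t(Ef)),
               cbind(Ef, matrix(0, ne, ne)))
  rhs <- c(crossprod(Mf, as.vector(W)), rep(1, ne))
  sv <- svd(KKT)
  pos <- sv$d > 1e-11 * max(sv$d)
  sol <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
  xf <- sol[seq_len(nf)]
  if (any(xf < -1e-9)) return(x)  # polish left the feasible set; keep QP point
  out <- numeric(length(x))
  out[free] <- pmax(xf, 0)
  out
}

#' Decide the degradation (Blackwell) order between two channels
#'
#' `degradation_check(w, v)` decides whether `w` is a degradation of `v`,
#' i.e. whether a row-stochastic `KU` exists with `w = v %*% KU`.  The
#' feasibility problem is solved as a convex least-squares program over
#' row-stochastic matrices; the order HOLDS iff the optimal infinity-norm
#' residual is at most `tol`, in which case `KU` is returned as certificate.
#'
#' @param w,v Channels with the same input alphabet.
#' @param tol Residual tolerance for feasibility (default `1e-7`).
#' @return An `order_verdict` with status `"HOLDS"` (certificate: `KU`) or
#'   `"VIOLATED"` (details carry the minimal residual).
#' @examples
#' k <- ds_example()
#' degradation_check(k$K4, k$K3)$status  # "VIOLATED"
#' @export
degradation_check <- function(w, v, tol = 1e-7) {
  w <- if (is_channel(w)) w else channel(w)
  v <- if (is_channel(v)) v else channel(v)
  check_same_input(w, v)
  fit <- solve_stochastic_ls(v, w)
  if (fit$residual <= tol) {
    ku <- channel(fit$KU, colnames(v), colnames(w))
    order_verdict("degradation", "HOLDS", certificate = ku,
                  residual = fit$residual, tol = tol)
  } else {
    order_verdict("degradation", "VIOLATED",
                  residual = fit$residual, tol = tol)
  }
}

#' JoinMeet operator on two channel columns
#'
#' Replaces column `i` by the entrywise maximum of columns `i` and `j`, and
#' column `j` by the entrywise minimum, leaving other columns unchanged.
#' Row sums (and in fact each row's multiset of entries) are preserved.
#'
#' @param K A channel.
#' @param i,j Distinct column indices.
#' @return The transformed channel.
#' @examples
#' k <- ds_example()
#' all.equal(unclass(joinmeet(k$K3, 1, 2)), unclass(k$K4),
#'           check.attributes = FALSE)
#' @export
joinmeet <- function(K, i, j) {
  K <- if (is_channel(K)) K else channel(K)
  i <- as.integer(i); j <- as.integer(j)
  if (i == j || min(i, j) < 1L || max(i, j) > ncol(K)) {
    pid_error("BAD_INDEX", "i and j must be distinct valid column indices")
  }
  out <- ch_mat(K)
  hi <- pmax(out[, i], out[, j])
  lo <- pmin(out[, i], out[, j])
  out[, i] <- hi
  out[, j] <- lo
  channel(out, rownames(K), colnames(K))
}

channel_key <- function(m) paste(sprintf("%.9f", round(m, 9)), collapse = ",")

#' All channels reachable by JoinMeet operations
#'
#' Breadth-first enumeration of the set of channels obtainable from `v` by
#' finite compositions of the JoinMeet operator.  The set is finite because
#' each row's multiset of entries is invariant.  Exploration order over
#' column pairs is lexicographic, so certificates are reproducible.
#'
#' @param v A channel.
#' @param max_nodes Cap on the number of distinct channels explored.
#' @return A list of channels (first element is `v`); each carries a
#'   `"joinmeet_path"` attribute (list of `c(i, j)` steps from `v`), and the
#'   list carries a logical `"truncated"` attribute.
#' @export
supermodular_closure <- function(v, max_nodes = 10000) {
  v <- if (is_channel(v)) v else channel(v)
  cols <- ncol(v)
  pairs <- list()
  for (i in seq_len(cols)) {
    for (j in seq_len(cols)) if (i != j) pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  seen <- new.env(parent = emptyenv())
  out <- list()
  queue <- list(structure(v, joinmeet_path = list()))
  assign(channel_key(ch_mat(v)), TRUE, envir = seen)
  n_seen <- 1L
  truncated <- FALSE
  while (length(queue) > 0L) {
    node <- queue[[1L]]
    queue <- queue[-1L]
    out[[length(out) + 1L]] <- node
    for (pr in pairs) {
      child <- joinmeet(node, pr[1], pr[2])
      key <- channel_key(ch_mat(child))
      if (!exists(key, envir = seen, inherits = FALSE)) {
        if (n_seen >= max_nodes) {
          truncated <- TRUE
          next
        }
        assign(key, TRUE, envir = seen)
        n_seen <- n_seen + 1L
        attr(child, "joinmeet_path") <-
          c(attr(node, "joinmeet_path"), list(pr))
        queue[[length(queue) + 1L]] <- child
      }
    }
  }
  attr(out, "truncated") <- truncated
  out
}

#' Decide the supermodularity order between two channels
#'
#' HOLDS iff `w` equals a finite JoinMeet composition applied to `v`
#' (entrywise within 1e-9); the certificate is the sequence of `(i, j)`
#' steps.  VIOLATED when the closure was fully enumerated without a match;
#' UNKNOWN when enumeration was truncated at `max_nodes`.
#'
#' @inheritParams supermodular_closure
#' @param w Candidate smaller channel (same shape as `v`).
#' @return An `order_verdict`.
#' @export
supermodularity_check <- function(w, v, max_nodes = 10000) {
  w <- if (is_channel(w)) w else channel(w)
  v <- if (is_channel(v)) v else channel(v)
  if (!all(dim(w) == dim(v))) {
    pid_error("SHAPE_MISMATCH", "channels must have identical shape")
  }
  closure <- supermodular_closure(v, max_nodes)
  for (node in closure) {
    if (max(abs(ch_mat(node) - ch_mat(w))) <= 1e-9) {
      return(order_verdict("supermodular", "HOLDS",
                           certificate = attr(node, "joinmeet_path"),
                           nodes = length(closure)))
    }
  }
  if (isTRUE(attr(closure, "truncated"))) {
    order_verdict("supermodular", "UNKNOWN", nodes = length(closure),
                  truncated = TRUE)
  } else {
    order_verdict("supermodular", "VIOLATED", nodes = length(closure))
  }
}

#' Sound-but-incomplete check of the degradation/supermodularity order
#'
#' Searches for a chain of degradation and JoinMeet steps certifying
#' `w <= v` in the combined order.  With `depth = 1` only a direct
#' degradation or a direct JoinMeet composition is accepted; with
#' `depth >= 2` the search also accepts `w <=d u <=s v` for any member `u`
#' of the supermodular closure of `v`.  No known procedure decides this
#' order, so the checker never claims VIOLATED: failure to find a chain
#' yields UNKNOWN.
#'
#' @inheritParams degradation_check
#' @param depth Number of alternations searched (default 2).
#' @param max_nodes Cap for closure enumeration.
#' @return An `order_verdict` with status `"HOLDS"` (certificate: list with
#'   the JoinMeet path and, if needed, the degradation matrix `KU`) or
#'   `"UNKNOWN"`.
#' @examples
#' k <- ds_example()
#' ds_check(k$K4, k$K3)$status  # "HOLDS" via one JoinMeet step
#' @export
ds_check <- function(w, v, depth = 2, tol = 1e-7, max_nodes = 10000) {
  w <- if (is_channel(w)) w else channel(w)
  v <- if (is_channel(v)) v else channel(v)
  if (nrow(w) != nrow(v)) {
    pid_error("SHAPE_MISMATCH", "channels must share the input alphabet")
  }
  deg <- degradation_check(w, v, tol)
  if (deg$status == "HOLDS") {
    return(order_verdict("ds", "HOLDS",
                         certificate = list(joinmeet = list(),
                                            KU = deg$certificate),
                         via = "degradation"))
  }
  if (all(dim(w) == dim(v))) {
    sup <- supermodularity_check(w, v, max_nodes)
    if (sup$status == "HOLDS") {
      return(order_verdict("ds", "HOLDS",
                           certificate = list(joinmeet = sup$certificate,
                                              KU = NULL),
                           via = "supermodular"))
    }
  }
  if (depth >= 2) {
    closure <- supermodular_closure(v, max_nodes)
    for (node in closure[-1L]) {
      deg <- degradation_check(w, node, tol)
      if (deg$status == "HOLDS") {
        return(order_verdict("ds", "HOLDS",
                             certificate = list(
                               joinmeet = attr(node, "joinmeet_path"),
                               KU = deg$certificate),
                             via = "degradation after joinmeet"))
      }
    }
  }
  order_verdict("ds", "UNKNOWN", depth = depth)
}

#' Grid check of the less-noisy order
#'
#' Tests `w <=ln v` ("v is less noisy than w") through the chi-squared
#' contraction characterization: the order requires
#' `chi2(pV || qV) >= chi2(pW || qW)` for every pair of target
#' distributions.  The check evaluates all ordered pairs from the simplex
#' grid with the given step; a failing pair is returned as certificate.  A
#' grid can only certify violation, never the order itself, hence the
#' `NO_VIOLATION_AT_RESOLUTION` status.
#'
#' @inheritParams degradation_check
#' @param grid_step Simplex grid step in (0, 0.5].
#' @return An `order_verdict`; on violation the certificate is
#'   `list(p = , q = )` with the evaluated chi-squared values in details.
#' @examples
#' k <- ds_example()
#' less_noisy_check(k$K4, k$K3)$certificate$p  # c(0, 0, 1)
#' @export
less_noisy_check <- function(w, v, grid_step = 0.1) {
  w <- if (is_channel(w)) w else channel(w)
  v <- if (is_channel(v)) v else channel(v)
  check_same_input(w, v)
  if (!(grid_step > 0 && grid_step <= 0.5)) {
    pid_error("BAD_GRID_STEP", "grid_step must be in (0, 0.5]")
  }
  P <- simplex_grid(nrow(w), grid_step)
  PW <- P %*% ch_mat(w)
  PV <- P %*% ch_mat(v)
  n <- nrow(P)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      cw <- chi2_divergence(PW[a, ], PW[b, ])
      cv <- chi2_divergence(PV[a, ], PV[b, ])
      # requirement: cv >= cw; Inf on the v side always satisfies it
      if (cv < cw - 1e-12) {
        return(order_verdict(
          "less_noisy", "VIOLATED",
          certificate = list(p = P[a, ], q = P[b, ]),
          chi2_v = cv, chi2_w = cw, resolution = grid_step))
      }
    }
  }
  order_verdict("less_noisy", "NO_VIOLATION_AT_RESOLUTION",
                resolution = grid_step)
}

# d I(p, K) / d p_t = D(K[t,] || pK) - 1/ln(2); used by the local refiner.
# The output marginal is clamped away from 0 so gradients stay finite at the
# simplex boundary (the refiner only needs a descent direction there).
mi_grad_p <- function(p, K) {
  q <- pmax(as.numeric(p %*% K), 1e-12)
  vapply(seq_len(nrow(K)), function(t) sum(xlog2x_over(K[t, ], q)),
         numeric(1)) - 1 / log(2)
}

#' Grid check of the more-capable order
#'
#' Tests `w <=mc v` ("v more capable"): the order requires
#' `I(p, w) <= I(p, v)` for every target distribution p.  The gap
#' `I(p, v) - I(p, w)` is evaluated on the simplex grid; optionally the worst
#' grid point is refined by projected gradient descent on the gap.  VIOLATED
#' (with certificate p) when the gap drops below `-1e-9`.
#'
#' @inheritParams less_noisy_check
#' @param refine Run local refinement from the worst grid point.
#' @return An `order_verdict`.
#' @export
more_capable_check <- function(w, v, grid_step = 0.1, refine = TRUE) {
  w <- if (is_channel(w)) w else channel(w)
  v <- if (is_channel(v)) v else channel(v)
  check_same_input(w, v)
  W <- ch_mat(w); V <- ch_mat(v)
  P <- simplex_grid(nrow(w), grid_step)
  gap <- vapply(seq_len(nrow(P)), function(i) {
    mi_kernel(P[i, ], V) - mi_kernel(P[i, ], W)
  }, numeric(1))
  worst <- which.min(gap)
  best_p <- P[worst, ]
  best_gap <- gap[worst]
  if (refine) {
    p <- best_p
    step <- grid_step
    for (iter in seq_len(200)) {
      g <- mi_grad_p(p, V) - mi_grad_p(p, W)  # gradient of the gap
      g <- g - mean(g)
      if (sqrt(sum(g^2)) < 1e-12) break
      cand <- p - step * g / max(sqrt(sum(g^2)), 1e-12)
      cand[cand < 0] <- 0
      s <- sum(cand)
      if (s <= 0) break
      cand <- cand / s
      gc_ <- mi_kernel(cand, V) - mi_kernel(cand, W)
      if (gc_ < best_gap - 1e-15) {
        p <- cand; best_gap <- gc_; best_p <- cand
      } else {
        step <- step / 2
        if (step < 1e-6) break
      }
    }
  }
  if (best_gap < -1e-9) {
    order_verdict("more_capable", "VIOLATED",
                  certificate = list(p = best_p),
                  gap = best_gap, resolution = grid_step)
  } else {
    order_verdict("more_capable", "NO_VIOLATION_AT_RESOLUTION",
                  gap = best_gap, resolution = grid_step)
  }
}
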