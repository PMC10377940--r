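# Intersection-information measures.
#
# Every measure maximizes I(Q;T) over channels KQ from T to an auxiliary
# variable Q constrained to sit below each source channel in a chosen
# preorder.  The degradation measure is solved exactly on small problems
# (vertex enumeration of its polytope); the less-noisy and more-capable
# measures are reported as brackets: a certified achievable lower bound and
# a sampled-constraint upper bound.

#' Options for the intersection-information optimizers
#'
#' @param q_cap Output alphabet size for Q; `NULL` uses
#'   `sum(|Y_i|) - n + 1`, the support size known to suffice for the
#'   degradation measure (for the less-noisy / more-capable measures this
#'   sufficiency is an open question; the cap is a configurable default).
#' @param grid_step Simplex grid step for constraint samples and order
#'   checks (default 0.1, the resolution used for the printed tables).
#' @param n_sample Number of random simplex points added to the
#'   more-capable constraint sample.
#' @param n_pairs Number of random simplex pairs added to the less-noisy
#'   constraint sample.
#' @param max_pairs Cap on the number of chi-squared constraint pairs
#'   (grid pairs are subsampled deterministically beyond it).
#' @param restarts Number of random multistart ascents (warm starts --
#'   source channels, constant channel, common-part channel, degradation
#'   argmax -- are always added on top).
#' @param max_iter,n_dirs Ascent iterations and random directions per
#'   iteration.
#' @param seed Seed for all randomness in the optimizers.
#' @param tol Residual tolerance for degradation feasibility.
#' @param collapse_tol Brackets tighter than this collapse to EXACT.
#' @param vertex_dim_cap,vertex_combo_cap Vertex enumeration is used when
#'   the polytope dimension and the number of candidate bases stay within
#'   these caps; otherwise multistart ascent reports a lower bound.
#' @param use_degradation_lower Use the degradation measure (always a valid
#'   lower bound by the order-implication chain) to seed and bound the
#'   less-noisy / more-capable / ds measures.
#' @param warm_channels Optional list of candidate KQ matrices (rows = target
#'   alphabet) added to the multistart pool after a feasibility check.
#' @return A list of options for the `ii_*` functions.
#' @export
ii_opts <- function(q_cap = NULL, grid_step = 0.1, n_sample = 500,
                    n_pairs = 500, max_pairs = 4000, restarts = 12,
                    max_iter = 40, n_dirs = 6, seed = 0, tol = 1e-7,
                    collapse_tol = 1e-4, vertex_dim_cap = 12,
                    vertex_combo_cap = 2e5, use_degradation_lower = TRUE,
                    warm_channels = list()) {
  list(q_cap = q_cap, grid_step = grid_step, n_sample = n_sample,
       n_pairs = n_pairs, max_pairs = max_pairs, restarts = restarts,
       max_iter = max_iter, n_dirs = n_dirs, seed = seed, tol = tol,
       collapse_tol = collapse_tol, vertex_dim_cap = vertex_dim_cap,
       vertex_combo_cap = vertex_combo_cap,
       use_degradation_lower = use_degradation_lower,
       warm_channels = warm_channels)
}

ii_result <- function(measure, value, status, lower = value, upper = value,
                      channel = NULL, diagnostics = list()) {
  structure(list(measure = measure, value = value, status = status,
                 lower = lower, upper = upper, channel = channel,
                 diagnostics = diagnostics),
            class = "ii_measure")
}

#' @export
print.ii_measure <- function(x, digits = 4, ...) {
  if (x$status == "BRACKET") {
    cat(sprintf("I_cap[%s] in [%.*f, %.*f] bits (bracket)\n",
                x$measure, digits, x$lower, digits, x$upper))
  } else {
    cat(sprintf("I_cap[%s] = %.*f bits (%s)\n",
                x$measure, digits, x$value, x$status))
  }
  invisible(x)
}

validate_measure_inputs <- function(p_t, channels) {
  p_t <- simplex_point(p_t)
  if (!is.list(channels) || length(channels) < 1L) {
    pid_error("INPUT_MISMATCH", "channels must be a non-empty list")
  }
  channels <- lapply(channels, function(K) if (is_channel(K)) K else channel(K))
  for (K in channels) {
    if (nrow(K) != length(p_t)) {
      pid_error("INPUT_MISMATCH",
                "all channels must share the input alphabet of p_t")
    }
  }
  list(p_t = p_t, channels = channels)
}

q_support_cap <- function(channels, opts) {
  if (!is.null(opts$q_cap)) return(as.integer(opts$q_cap))
  sum(vapply(channels, ncol, integer(1))) - length(channels) + 1L
}

# Conditionally independent source joint implied by (p_t, channels):
# p(y1..yn) = sum_t p(t) prod_i K(i)[t, y_i].  This is the joint under which
# channel-based measures interpret deterministic common parts.
ci_source_array <- function(p_t, channels) {
  dims <- vapply(channels, ncol, integer(1))
  labs <- lapply(channels, colnames)
  arr <- array(0, dim = dims, dimnames = labs)
  for (t in which(p_t > 0)) {
    slice <- ch_mat(channels[[1]])[t, ]
    for (i in seq_along(channels)[-1]) {
      slice <- outer(slice, ch_mat(channels[[i]])[t, ])
    }
    arr <- arr + p_t[t] * array(slice, dim = dims)
  }
  arr
}

# Common-part channel KQ (columns = connected components) for channel-based
# measures, built from the conditionally independent source joint.  Q is a
# deterministic function of every source, hence below every source in all
# of the preorders.
common_part_channel <- function(p_t, channels) {
  arr <- ci_source_array(p_t, channels)
  lab <- support_components(arr)
  K1 <- ch_mat(channels[[1]])
  ncomp <- lab$n
  KQ <- matrix(0, nrow(K1), ncomp)
  for (y in seq_len(ncol(K1))) {
    KQ[, lab$labels[[1]][y]] <- KQ[, lab$labels[[1]][y]] + K1[, y]
  }
  KQ
}

# Connected components of the co-occurrence graph over per-variable
# outcomes: outcomes are joined when some outcome tuple with positive mass
# contains both.  Returns per-variable component labels.
support_components <- function(arr) {
  dims <- dim(arr)
  if (is.null(dims)) dims <- length(arr)
  n <- length(dims)
  offs <- c(0L, cumsum(dims))
  pos <- which(arr > .tol_internal, arr.ind = TRUE)
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 1L)
  edges <- integer(0)
  if (n >= 2L) {
    for (r in seq_len(nrow(pos))) {
      for (i in 2L:n) {
        edges <- c(edges, offs[1] + pos[r, 1], offs[i] + pos[r, i])
      }
    }
  }
  g <- igraph::make_empty_graph(n = offs[n + 1L], directed = FALSE)
  if (length(edges) > 0L) {
    g <- igraph::add_edges(g, edges)
  }
  comp <- igraph::components(g)$membership
  labels <- lapply(seq_len(n), function(i) {
    lv <- comp[(offs[i] + 1L):offs[i + 1L]]
    names(lv) <- dimnames(arr)[[i]]
    lv
  })
  # relabel components to consecutive ids in order of first appearance
  used <- unique(unlist(labels))
  relab <- match(unlist(labels), used)
  labels <- utils::relist(relab, labels)
  for (i in seq_len(n)) names(labels[[i]]) <- dimnames(arr)[[i]]
  list(labels = labels, n = length(used))
}

#' Maximal common random variable of the sources
#'
#' Builds the bipartite (for n = 2; n-partite in general) graph whose
#' vertices are source outcomes, with an edge whenever two outcomes co-occur
#' with positive probability, and labels each outcome with its connected
#' component.  The component index is the maximal variable Q that is a
#' deterministic function of every source.
#'
#' @param joint A [joint_from_table()] object.
#' @param sources Source indices (default: all variables after the first,
#'   i.e. the target is excluded; pass `sources = 0` plus others to include
#'   it, or a joint that holds only source variables with
#'   `target_included = FALSE`).
#' @param target_included Set to `FALSE` when `joint` holds only the source
#'   variables (no target in the first slot).
#' @return An object of class `"common_part"`: per-source outcome labels,
#'   the distribution `q` of the common variable, and its component count.
#' @examples
#' cp <- common_part_labeling(gate_joint("COPY"))
#' cp$n_components  # 1: independent sources have a trivial common part
#' @export
common_part_labeling <- function(joint, sources = NULL,
                                 target_included = TRUE) {
  idx <- if (!is.null(sources)) {
    vapply(sources, function(s) source_index(joint, s), integer(1))
  } else if (target_included) {
    seq_along(joint$vars)[-1]
  } else {
    seq_along(joint$vars)
  }
  if (length(idx) < 2L) {
    pid_error("BAD_SOURCE", "need at least two sources for a common part")
  }
  arr <- marginal_array(joint, idx)
  lab <- support_components(arr)
  mass <- numeric(lab$n)
  pos <- which(arr > 0, arr.ind = TRUE)
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 1L)
  for (r in seq_len(nrow(pos))) {
    cmp <- lab$labels[[1]][pos[r, 1]]
    mass[cmp] <- mass[cmp] + arr[matrix(pos[r, ], 1)]
  }
  names(lab$labels) <- joint$vars[idx]
  structure(list(labels = lab$labels, n_components = lab$n,
                 q = simplex_point(mass / sum(mass),
                                   paste0("q", seq_len(lab$n)))),
            class = "common_part")
}

#' @export
print.common_part <- function(x, ...) {
  cat(sprintf("common part: %d component(s); H(Q) = %.4f bits\n",
              x$n_components, entropy_bits(x$q)))
  invisible(x)
}

#' Gacs-Korner common information, in bits
#'
#' The entropy of the maximal variable Q that is a deterministic function of
#' every source: `C(Y1 ^ Y2) = H(Q)` with Q the connected-component label of
#' the positive-probability support graph.
#'
#' @inheritParams common_part_labeling
#' @return Common information in bits.
#' @examples
#' gacs_korner(gate_joint("COPY"))  # 0 for independent sources
#' @export
gacs_korner <- function(joint, sources = NULL, target_included = TRUE) {
  cp <- common_part_labeling(joint, sources, target_included)
  entropy_bits(cp$q)
}

#' Deterministic (functional) intersection information
#'
#' The redundancy under the order "Q is a deterministic function of Y":
#' `max I(Q;T)` over Q with `Q = f_i(Y_i)` for every source.  The maximum is
#' attained by the maximal common random variable (any other common function
#' is a coarsening of it, and coarsening cannot raise `I(Q;T)`), so the
#' value is exact.
#'
#' @param joint A [joint_from_table()] with target first and n >= 2 sources.
#' @return An `ii_measure` result (status EXACT) with the channel from T to
#'   the common variable attached.
#' @examples
#' ii_deterministic(gate_joint("AND"))$value  # 0
#' @export
ii_deterministic <- function(joint) {
  if (n_sources(joint) < 2L) {
    pid_error("INPUT_MISMATCH", "need at least two sources")
  }
  cp <- common_part_labeling(joint)
  m1 <- marginal_array(joint, c(1L, 2L))  # (T, Y1) pairwise marginal
  lab <- cp$labels[[1]]
  tq <- matrix(0, nrow(m1), cp$n_components)
  for (y in seq_len(ncol(m1))) {
    tq[, lab[y]] <- tq[, lab[y]] + m1[, y]
  }
  pt <- rowSums(tq)
  keep <- pt > 0
  KQ <- channel(tq[keep, , drop = FALSE] / pt[keep],
                rownames(m1)[keep], paste0("q", seq_len(cp$n_components)))
  value <- mi_kernel(simplex_point(pt[keep]), ch_mat(KQ))
  ii_result("deterministic", value, "EXACT", channel = KQ,
            diagnostics = list(n_components = cp$n_components))
}

#' Minimum-mutual-information redundancy
#'
#' `min_i I(T;Y_i)`: an upper bound for every order-based intersection
#' information measure, and a PID measure in its own right.
#'
#' @param p_t Target marginal.
#' @param channels List of channels from T to each source.
#' @return An `ii_measure` (status EXACT); the minimizing source channel is
#'   attached.
#' @export
ii_mmi <- function(p_t, channels) {
  v <- validate_measure_inputs(p_t, channels)
  mis <- vapply(v$channels, function(K) mi_kernel(v$p_t, ch_mat(K)),
                numeric(1))
  j <- which.min(mis)
  ii_result("mmi", mis[j], "EXACT", channel = v$channels[[j]],
            diagnostics = list(source_mi = mis))
}

#' Degradation (Blackwell) intersection information
#'
#' Maximizes `I(Q;T)` over channels KQ that are a degradation of every
#' source channel: `KQ = K(i) KU(i)` with each `KU(i)` row-stochastic.  The
#' constraints are linear in the stacked `KU(i)` and the objective is convex,
#' so the maximum sits at a vertex of the feasible polytope.  Small problems
#' (polytope dimension and basis count within the `ii_opts()` caps) are
#' solved exactly by vertex enumeration; larger ones by multistart feasible
#' ascent, reported as a lower bound.
#'
#' @inheritParams ii_mmi
#' @param opts Options from [ii_opts()].
#' @return An `ii_measure` with the optimizing channel KQ.
#' @examples
#' ch <- lapply(1:2, function(i) channel_from_joint(gate_joint("AND"), i))
#' ii_degradation(ch[[1]]$p_t, list(ch[[1]]$K, ch[[2]]$K))$value  # 0.311
#' @export
ii_degradation <- function(p_t, channels, opts = ii_opts()) {
  v <- validate_measure_inputs(p_t, channels)
  p_t <- v$p_t; channels <- v$channels
  m <- q_support_cap(channels, opts)
  poly <- degradation_polytope(channels, m)
  d <- ncol(poly$N)
  combos <- if (d > 0) choose(poly$L, d) else 0
  exact <- d <= opts$vertex_dim_cap && combos <= opts$vertex_combo_cap
  if (exact) {
    verts <- enumerate_vertices(poly$x0, poly$N)
    vals <- apply(verts, 2L, function(x) {
      mi_kernel(p_t, poly_kq(poly, x, channels))
    })
    j <- which.max(vals)
    best_x <- verts[, j]
    best_f <- vals[j]
    diag_ <- list(method = "vertex_enumeration", n_vertices = ncol(verts),
                  dim = d, seed = opts$seed)
    status <- "EXACT"
  } else {
    starts <- degradation_starts(poly, p_t, channels, opts)
    res <- with_seed(opts$seed, function() {
      ascend_degradation(poly, p_t, channels, starts, opts)
    })
    best_x <- res$x
    best_f <- res$value
    diag_ <- list(method = "multistart_ascent", n_starts = length(starts),
                  dim = d, seed = opts$seed)
    status <- "LOWER_BOUND"
  }
  KQ <- channel(poly_kq(poly, best_x, channels),
                names(p_t), paste0("q", seq_len(m)))
  ii_result("degradation", max(best_f, 0), status, channel = KQ,
            diagnostics = diag_)
}

# Warm + random starts for the degradation ascent (stacked-x vectors).
degradation_starts <- function(poly, p_t, channels, opts) {
  starts <- list(poly$x0)
  # each source channel as candidate Q
  m <- poly$m
  cands <- c(lapply(channels, ch_mat), opts$warm_channels)
  for (Kc in cands) {
    if (ncol(Kc) > m || nrow(Kc) != poly$k) next
    KQ <- pad_channel(Kc, m)
    x <- degradation_certificates(poly, channels, KQ, tol = 1e-6)
    if (!is.null(x)) starts[[length(starts) + 1L]] <- x
  }
  # deterministic common-part variable (always feasible)
  cp <- common_part_channel(p_t, channels)
  if (ncol(cp) <= m) {
    kus <- lapply(seq_along(channels), function(i) {
      # exact deterministic KU: output y -> its component
      arr <- ci_source_array(p_t, channels)
      lab <- support_components(arr)$labels[[i]]
      KU <- matrix(0, ncol(channels[[i]]), m)
      for (y in seq_along(lab)) KU[y, lab[y]] <- 1
      KU
    })
    starts[[length(starts) + 1L]] <- stack_ku(poly, kus)
  }
  # hit-and-run interior points
  hr <- with_seed(opts$seed + 1, function() {
    out <- list()
    x <- poly$x0
    for (r in seq_len(max(opts$restarts - length(starts), 0))) {
      for (s in seq_len(3)) {
        dz <- stats::rnorm(ncol(poly$N))
        w <- as.numeric(poly$N %*% dz)
        neg <- w < -1e-14
        pos <- w > 1e-14
        amax <- if (any(neg)) min(x[neg] / -w[neg]) else 0
        amin <- if (any(pos)) -min(x[pos] / w[pos]) else 0
        a <- stats::runif(1, 0.9 * amin, 0.9 * amax)
        x <- pmax(x + a * w, 0)
      }
      out[[length(out) + 1L]] <- x
      x <- poly$x0
    }
    out
  })
  c(starts, hr)
}

# Shared bracket machinery for the sampled-constraint measures.
bracket_measure <- function(name, p_t, channels, opts, constraints) {
  m <- q_support_cap(channels, opts)
  # widening Q's alphabet only relaxes the problem, so warm channels with
  # more outputs than the cap simply enlarge it
  if (length(opts$warm_channels) > 0L) {
    m <- max(m, vapply(opts$warm_channels, ncol, integer(1)))
  }
  k <- length(p_t)
  feasible <- constraints$feasible
  mis <- vapply(channels, function(K) mi_kernel(p_t, ch_mat(K)), numeric(1))
  mmi <- min(mis)

  # ---- certified lower bounds (each comes with an order argument) ----
  const <- matrix(rep(colSums(p_t * ch_mat(channels[[1]])), each = k), k,
                  ncol(channels[[1]]))
  lower_candidates <- list(list(value = 0, K = pad_channel(channel(const), m),
                                via = "constant"))
  cp <- common_part_channel(p_t, channels)
  lower_candidates[[length(lower_candidates) + 1L]] <-
    list(value = mi_kernel(p_t, cp), K = pad_channel(cp, m),
         via = "common part")
  d_res <- NULL
  if (isTRUE(opts$use_degradation_lower)) {
    d_res <- if (!is.null(opts$.d_result)) opts$.d_result else
      ii_degradation(p_t, channels, opts)
    lower_candidates[[length(lower_candidates) + 1L]] <-
      list(value = d_res$value, K = pad_channel(d_res$channel, m),
           via = "degradation")
  }
  for (j in seq_along(channels)) {
    passes <- all(vapply(seq_along(channels)[-j], function(i) {
      constraints$source_check(channels[[j]], channels[[i]])
    }, logical(1)))
    # a source that truly sits below the others satisfies every sampled
    # constraint, so sampled feasibility is a strictly stronger filter than
    # the grid check alone
    if (passes && feasible(pad_channel(channels[[j]], m))) {
      lower_candidates[[length(lower_candidates) + 1L]] <-
        list(value = mis[j], K = pad_channel(channels[[j]], m),
             via = sprintf("source %d", j))
    }
  }
  lv <- vapply(lower_candidates, function(c_) c_$value, numeric(1))
  jbest <- which.max(lv)
  lower <- lv[jbest]
  lower_K <- lower_candidates[[jbest]]$K

  # ---- sampled-constraint upper bound via multistart ascent ----
  starts <- list(pad_channel(channel(const), m))
  for (c_ in lower_candidates) {
    if (feasible(c_$K)) starts[[length(starts) + 1L]] <- c_$K
  }
  for (Kw in opts$warm_channels) {
    Kw <- pad_channel(Kw, m)
    if (nrow(Kw) == k && feasible(Kw)) starts[[length(starts) + 1L]] <- Kw
  }
  rnd <- with_seed(opts$seed + 2, function() {
    lapply(seq_len(opts$restarts), function(r) {
      shrink_to_feasible(runif_simplex(k, m), feasible)
    })
  })
  starts <- c(starts, rnd)
  best <- list(K = starts[[1]], value = mi_kernel(p_t, starts[[1]]))
  res <- with_seed(opts$seed + 3, function() {
    b <- best
    for (s in starts) {
      if (!feasible(s)) next
      r <- ascend_kq(s, p_t, feasible, opts)
      if (r$value > b$value) b <- r
    }
    b
  })
  # the measure chain caps every order measure at min_i I(T;Y_i)
  upper <- min(max(res$value, lower), mmi)
  lower <- min(lower, upper)
  status <- if (upper - lower <= opts$collapse_tol) "EXACT" else "BRACKET"
  value <- lower
  KQ <- channel(if (res$value >= lower) res$K else lower_K,
                names(p_t), paste0("q", seq_len(m)))
  diag_ <- c(constraints$diagnostics,
             list(restarts = opts$restarts, seed = opts$seed,
                  lower_via = lower_candidates[[jbest]]$via,
                  source_mi = mis,
                  degradation_value = if (!is.null(d_res)) d_res$value))
  ii_result(name, value, status, lower = lower, upper = upper,
            channel = KQ, diagnostics = diag_)
}

#' Less-noisy intersection information (bracket)
#'
#' Redundancy under the less-noisy order.  The uncountable chi-squared
#' contraction constraints are sampled on the simplex grid (plus seeded
#' random pairs), giving an upper bound via multistart ascent; certified
#' lower bounds come from feasible constructions (constant Q, the
#' common-part variable, the degradation argmax, and any source that passes
#' the less-noisy grid check against all other sources).  The bracket
#' collapses to EXACT when the two bounds meet within `collapse_tol`.
#'
#' @inheritParams ii_degradation
#' @return An `ii_measure` with `lower`/`upper` bounds; `value` is the
#'   certified lower bound.
#' @export
ii_less_noisy <- function(p_t, channels, opts = ii_opts()) {
  v <- validate_measure_inputs(p_t, channels)
  p_t <- v$p_t; channels <- v$channels
  k <- length(p_t)
  pts <- rbind(simplex_grid(k, opts$grid_step), matrix(p_t, nrow = 1))
  prs <- expand.grid(a = seq_len(nrow(pts)), b = seq_len(nrow(pts)))
  prs <- prs[prs$a != prs$b, , drop = FALSE]
  extra <- with_seed(opts$seed + 4, function() {
    list(u = runif_simplex(opts$n_pairs, k), v = runif_simplex(opts$n_pairs, k))
  })
  P_a <- rbind(pts[prs$a, , drop = FALSE], extra$u)
  P_b <- rbind(pts[prs$b, , drop = FALSE], extra$v)
  if (nrow(P_a) > opts$max_pairs) {
    keep <- with_seed(opts$seed + 5, function() {
      sample.int(nrow(P_a), opts$max_pairs)
    })
    P_a <- P_a[keep, , drop = FALSE]
    P_b <- P_b[keep, , drop = FALSE]
  }
  # RHS: tightest source channel per pair
  rhs <- rep(Inf, nrow(P_a))
  for (K in channels) {
    M <- ch_mat(K)
    A <- P_a %*% M
    B <- P_b %*% M
    rhs <- pmin(rhs, chi2_rows(A, B))
  }
  feasible <- function(KQ) {
    A <- P_a %*% KQ
    B <- P_b %*% KQ
    all(chi2_rows(A, B) <= rhs + 1e-9)
  }
  source_check <- function(w, v_) {
    less_noisy_check(w, v_, opts$grid_step)$status != "VIOLATED"
  }
  bracket_measure("less_noisy", p_t, channels, opts,
                  list(feasible = feasible, source_check = source_check,
                       diagnostics = list(n_constraints = nrow(P_a),
                                          grid_step = opts$grid_step)))
}

# Row-wise chi2(A[i,] || B[i,]) with the 0-denominator conventions.
chi2_rows <- function(A, B) {
  D2 <- (A - B)^2
  bad <- (B <= 0) & (D2 > .tol_internal^2)
  ratio <- ifelse(B > 0, D2 / B, 0)
  out <- rowSums(ratio)
  out[rowSums(bad) > 0] <- Inf
  out
}

#' More-capable intersection information (bracket)
#'
#' Redundancy under the more-capable order.  The constraints
#' `I(p, KQ) <= min_i I(p, K(i))` are sampled over the simplex grid, the
#' target marginal itself, and seeded random draws, giving an upper bound
#' via multistart ascent; lower bounds as in [ii_less_noisy()] with the
#' more-capable grid check for sources.  Because the target marginal is in
#' the constraint sample, the upper bound never exceeds `min_i I(T;Y_i)`.
#'
#' @inheritParams ii_degradation
#' @return An `ii_measure` with `lower`/`upper` bounds.
#' @export
ii_more_capable <- function(p_t, channels, opts = ii_opts()) {
  v <- validate_measure_inputs(p_t, channels)
  p_t <- v$p_t; channels <- v$channels
  k <- length(p_t)
  P <- rbind(simplex_grid(k, opts$grid_step), matrix(p_t, nrow = 1),
             with_seed(opts$seed + 6, function() {
               runif_simplex(opts$n_sample, k)
             }))
  rhs <- rep(Inf, nrow(P))
  for (K in channels) {
    rhs <- pmin(rhs, mi_rows(P, ch_mat(K)))
  }
  feasible <- function(KQ) {
    all(mi_rows(P, KQ) <= rhs + 1e-9)
  }
  source_check <- function(w, v_) {
    more_capable_check(w, v_, opts$grid_step)$status != "VIOLATED"
  }
  bracket_measure("more_capable", p_t, channels, opts,
                  list(feasible = feasible, source_check = source_check,
                       diagnostics = list(n_constraints = nrow(P),
                                          grid_step = opts$grid_step)))
}

# I(P[s,], K) for every row s at once (bits).
mi_rows <- function(P, K) {
  Kl <- xlog2x_over(K, rep(1, length(K)))
  dim(Kl) <- dim(K)
  term1 <- as.numeric(P %*% rowSums(Kl))
  M <- P %*% K
  Ml <- xlog2x_over(M, rep(1, length(M)))
  dim(Ml) <- dim(M)
  pmax(term1 - rowSums(Ml), 0)
}

#' Degradation/supermodularity intersection information (bracket)
#'
#' Redundancy under chains of degradation and JoinMeet steps.  No complete
#' decision procedure for the order is known, so the measure is bracketed:
#' the lower bound is the best of the degradation measure and any source
#' certified below all others by [ds_check()]; the upper bound is the
#' more-capable upper bound (the ds order implies the more-capable order).
#'
#' @inheritParams ii_degradation
#' @return An `ii_measure`; EXACT only when the bounds meet.
#' @export
ii_ds <- function(p_t, channels, opts = ii_opts()) {
  v <- validate_measure_inputs(p_t, channels)
  p_t <- v$p_t; channels <- v$channels
  m <- q_support_cap(channels, opts)
  d_res <- if (!is.null(opts$.d_result)) opts$.d_result else
    ii_degradation(p_t, channels, opts)
  mis <- vapply(channels, function(K) mi_kernel(p_t, ch_mat(K)), numeric(1))
  cands <- list(list(value = d_res$value, K = pad_channel(d_res$channel, m),
                     via = "degradation"))
  cp <- common_part_channel(p_t, channels)
  cands[[length(cands) + 1L]] <- list(value = mi_kernel(p_t, cp),
                                      K = pad_channel(cp, m),
                                      via = "common part")
  for (j in seq_along(channels)) {
    ok <- all(vapply(seq_along(channels)[-j], function(i) {
      ds_check(channels[[j]], channels[[i]], tol = opts$tol)$status == "HOLDS"
    }, logical(1)))
    if (ok) {
      cands[[length(cands) + 1L]] <-
        list(value = mis[j], K = pad_channel(channels[[j]], m),
             via = sprintf("source %d", j))
    }
  }
  lv <- vapply(cands, function(c_) c_$value, numeric(1))
  jb <- which.max(lv)
  lower <- lv[jb]
  opts_mc <- opts
  opts_mc$.d_result <- d_res
  mc <- ii_more_capable(p_t, channels, opts_mc)
  upper <- max(mc$upper, lower)
  status <- if (upper - lower <= opts$collapse_tol) "EXACT" else "BRACKET"
  ii_result("ds", lower, status, lower = lower, upper = upper,
            channel = channel(cands[[jb]]$K, names(p_t),
                              paste0("q", seq_len(m))),
            diagnostics = list(lower_via = cands[[jb]]$via,
                               degradation_value = d_res$value,
                               mc_upper = mc$upper, seed = opts$seed))
}
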