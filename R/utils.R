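# Internal helpers shared across the package.

# Input tolerance: probabilities are accepted and renormalized when their sum
# deviates from 1 by at most .tol_input; internal assertions use .tol_internal.
.tol_input <- 1e-6 * (1 + 1e-9)  # slack so a sum of exactly 0.999999 passes
.tol_internal <- 1e-9

pid_error <- function(code, msg) {
  stop(errorCondition(msg, class = c(code, "pidchannels_error")))
}

# Locale-independent ordering so matrices are reproducible bit-for-bit.
lex_sort <- function(x) sort(unique(as.character(x)), method = "radix")

# x * log2(x / y) with the 0 * log 0 := 0 convention.  Assumes y > 0 wherever
# x > 0 (true for all uses: y is a marginal dominating x).
xlog2x_over <- function(x, y) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos] / y[pos])
  out
}

# Evaluate f under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards, so seeded routines never disturb user RNG.
with_seed <- function(seed, f) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  f()
}

# Dirichlet(1) rows: uniform draws from the simplex.
runif_simplex <- function(n, k) {
  g <- matrix(stats::rgamma(n * k, shape = 1), nrow = n)
  g / rowSums(g)
}

# All points of the probability simplex over k outcomes whose entries are
# multiples of `step` (step must divide 1 to working precision).
simplex_grid <- function(k, step = 0.1) {
  m <- round(1 / step)
  if (abs(m * step - 1) > 1e-9) {
    pid_error("BAD_GRID_STEP", "grid step must divide 1")
  }
  rec <- function(k, total) {
    if (k == 1L) return(matrix(total, ncol = 1L))
    do.call(rbind, lapply(0:total, function(i) {
      cbind(i, rec(k - 1L, total - i))
    }))
  }
  unname(rec(as.integer(k), m) / m)
}
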