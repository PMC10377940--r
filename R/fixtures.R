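# Deterministic fixtures: the classic logic-gate joints and the two
# counterexample channel pairs, plus seeded random generators for
# property-style tests.

#' Logic-gate joint distributions
#'
#' Builds the joint distribution of a two-input gate with independent
#' equiprobable binary inputs (overridable): `T = Y1 AND Y2`,
#' `T = Y1 + Y2` (integer sum), a copy target `T = (Y1, Y2)`, the identity
#' target `T = Y1`, or `T = Y1 XOR Y2`.
#'
#' @param name One of `"AND"`, `"SUM"`, `"COPY"`, `"IDENT_Y1"`, `"XOR"`.
#' @param input_probs Probabilities of the four `(y1, y2)` input pairs in
#'   the order (0,0), (0,1), (1,0), (1,1); defaults to all 1/4.
#' @return A [joint_from_table()] object with variables `T, Y1, Y2`.
#' @examples
#' gate_joint("AND")
#' @export
gate_joint <- function(name, input_probs = rep(1 / 4, 4)) {
  name <- toupper(name)
  y <- expand.grid(Y2 = c("0", "1"), Y1 = c("0", "1"),
                   stringsAsFactors = FALSE)[, c("Y1", "Y2")]
  # reorder to (0,0), (0,1), (1,0), (1,1)
  y <- y[order(y$Y1, y$Y2), ]
  t_val <- switch(
    name,
    AND = as.character(as.integer(y$Y1 == "1" & y$Y2 == "1")),
    SUM = as.character(as.integer(y$Y1) + as.integer(y$Y2)),
    COPY = paste0(y$Y1, y$Y2),
    IDENT_Y1 = y$Y1,
    XOR = as.character(as.integer(xor(y$Y1 == "1", y$Y2 == "1"))),
    pid_error("UNKNOWN_GATE", sprintf("unknown gate '%s'", name))
  )
  joint_from_table(data.frame(T = t_val, Y1 = y$Y1, Y2 = y$Y2,
                              p = as.numeric(input_probs),
                              stringsAsFactors = FALSE))
}

#' Counterexample channel pair 1 (binary channels)
#'
#' The 2x2 channel pair for which the less-noisy order holds in one
#' direction while no degradation exists:
#' `K1 = [[0.25, 0.75], [0.35, 0.65]]`,
#' `K2 = [[0.675, 0.325], [0.745, 0.255]]`.
#' The matrices are stored as printed; the parametric construction behind
#' them is not reproduced here.
#'
#' @return `list(K1 = , K2 = )` of channels sharing a binary input alphabet.
#' @export
counterexample1 <- function() {
  list(K1 = channel(rbind(c(0.25, 0.75), c(0.35, 0.65)),
                    c("0", "1"), c("0", "1")),
       K2 = channel(rbind(c(0.675, 0.325), c(0.745, 0.255)),
                    c("0", "1"), c("0", "1")))
}

#' Degradation/supermodularity example channel pair
#'
#' The 3x2 pair with `K4 = joinmeet(K3, 1, 2)`, so K4 sits below K3 in the
#' degradation/supermodularity order even though it is not a degradation of
#' K3: `K3 = [[1,0],[0,1],[.5,.5]]`, `K4 = [[1,0],[1,0],[.5,.5]]`.
#'
#' @return `list(K3 = , K4 = )` of channels on a ternary input alphabet.
#' @export
ds_example <- function() {
  list(K3 = channel(rbind(c(1, 0), c(0, 1), c(0.5, 0.5)),
                    c("0", "1", "2"), c("0", "1")),
       K4 = channel(rbind(c(1, 0), c(1, 0), c(0.5, 0.5)),
                    c("0", "1", "2"), c("0", "1")))
}

check_size <- function(...) {
  if (any(unlist(list(...)) < 1L)) pid_error("BAD_SIZE", "sizes must be >= 1")
}

#' Random channel with Dirichlet(1) rows
#'
#' @param n_in,n_out Input/output alphabet sizes (>= 1).
#' @param seed Seed making the draw reproducible.
#' @return A [channel()].
#' @export
random_channel <- function(n_in, n_out, seed = 1) {
  check_size(n_in, n_out)
  m <- with_seed(seed, function() runif_simplex(n_in, n_out))
  channel(m)
}

#' Random joint distribution (uniform Dirichlet over the full table)
#'
#' @param alphabet_sizes Integer vector of alphabet sizes, target first.
#' @param seed Seed making the draw reproducible.
#' @return A [joint_from_table()] object.
#' @export
random_joint <- function(alphabet_sizes, seed = 1) {
  check_size(alphabet_sizes)
  sizes <- as.integer(alphabet_sizes)
  total <- prod(sizes)
  p <- with_seed(seed, function() as.numeric(runif_simplex(1, total)))
  grid <- expand.grid(lapply(sizes, function(s) as.character(seq_len(s) - 1L)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- c("T", paste0("Y", seq_len(length(sizes) - 1L)))
  grid$p <- p
  joint_from_table(grid)
}

#' Random degraded channel pair
#'
#' Draws `V` (`n_in x n_mid`) and a post-processing channel `KU`
#' (`n_mid x n_out`), returning `W = V KU`, which is a degradation of `V`
#' by construction.
#'
#' @param n_in,n_mid,n_out Alphabet sizes (>= 1).
#' @param seed Seed making the draw reproducible.
#' @return `list(W = , V = , KU = )`.
#' @export
random_degraded_pair <- function(n_in, n_mid, n_out, seed = 1) {
  check_size(n_in, n_mid, n_out)
  ms <- with_seed(seed, function() {
    list(V = runif_simplex(n_in, n_mid), KU = runif_simplex(n_mid, n_out))
  })
  V <- channel(ms$V)
  KU <- channel(ms$KU)
  list(W = channel(ch_mat(V) %*% ch_mat(KU)), V = V, KU = KU)
}
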