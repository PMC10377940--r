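# Joint distributions, simplex points, channels, and Shannon quantities.
# All information quantities are in bits (log base 2), matching the printed
# logic-gate values (0.311, 0.5, 1).

#' Probability vector over a finite alphabet
#'
#' Validates (and, within a 1e-6 tolerance, renormalizes) a probability
#' vector.  Used for target marginals p(t) and constraint-sample points.
#'
#' @param weights Numeric vector of non-negative weights summing to 1 within
#'   1e-6.
#' @param labels Optional character vector of outcome labels.
#' @return A named numeric vector summing to exactly 1.
#' @examples
#' simplex_point(c(3, 1) / 4, c("0", "1"))
#' @export
simplex_point <- function(weights, labels = NULL) {
  w <- as.numeric(weights)
  if (any(!is.finite(w))) pid_error("NEGATIVE_PROB", "non-finite probability")
  if (any(w < -.tol_internal)) {
    pid_error("NEGATIVE_PROB", "negative probability in simplex point")
  }
  w[w < 0] <- 0
  s <- sum(w)
  if (abs(s - 1) > .tol_input) {
    pid_error("SUM_FAR_FROM_ONE",
              sprintf("probabilities sum to %.8g, not 1", s))
  }
  w <- w / s
  if (!is.null(labels)) {
    names(w) <- as.character(labels)
  } else if (is.null(names(w))) {
    names(w) <- as.character(seq_along(w) - 1L)
  }
  w
}

#' Row-stochastic channel matrix
#'
#' A channel from a finite input alphabet to a finite output alphabet is a
#' row-stochastic matrix `K[t, y] = p(y | t)`.  Rows are validated to be
#' probability vectors (renormalized within the 1e-6 input tolerance).
#'
#' @param mat Numeric matrix of conditional probabilities.
#' @param input_labels,output_labels Optional label vectors; default to
#'   existing dimnames or 0-based integer labels.
#' @return A matrix of class `"channel"` with dimnames set.
#' @examples
#' channel(rbind(c(1, 0), c(0.5, 0.5)))
#' @export
channel <- function(mat, input_labels = NULL, output_labels = NULL) {
  m <- as.matrix(mat)
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < -.tol_internal)) {
    pid_error("NEGATIVE_PROB", "channel entries must be finite and >= 0")
  }
  m[m < 0] <- 0
  rs <- rowSums(m)
  if (any(abs(rs - 1) > .tol_input)) {
    pid_error("SUM_FAR_FROM_ONE", "channel rows must sum to 1 within 1e-6")
  }
  m <- m / rs
  inlab <- as.character(
    if (!is.null(input_labels)) input_labels
    else if (!is.null(rownames(m))) rownames(m)
    else seq_len(nrow(m)) - 1L
  )
  outlab <- as.character(
    if (!is.null(output_labels)) output_labels
    else if (!is.null(colnames(m))) colnames(m)
    else seq_len(ncol(m)) - 1L
  )
  dim(m) <- unname(dim(m))
  dimnames(m) <- list(inlab, outlab)
  class(m) <- c("channel", class(m))
  m
}

#' @export
print.channel <- function(x, digits = 4, ...) {
  cat(sprintf("channel: %d inputs -> %d outputs\n", nrow(x), ncol(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

is_channel <- function(x) inherits(x, "channel")

# Strip class so %*% etc. behave as plain matrices.
ch_mat <- function(x) {
  m <- unclass(x)
  attr(m, "dropped_inputs") <- NULL
  m
}

#' Joint distribution over a target and source variables
#'
#' Builds a finite discrete joint distribution from a table of outcome tuples
#' and probabilities.  The first variable is always the target T; the
#' remaining variables are the sources Y1, ..., Yn.  Outcome labels are
#' ordered lexicographically so that derived matrices are reproducible.
#'
#' @param records A data.frame whose last column (or a column named `p`)
#'   holds probabilities and whose remaining columns hold outcome labels,
#'   target first.  Alternatively a list of `list(outcome_tuple, prob)` pairs.
#' @param vars Optional variable names (target first); defaults to the
#'   data.frame column names or `T, Y1, ..., Yn`.
#' @return An object of class `"joint_dist"`: a list with elements `vars`,
#'   `alphabets` (named list of sorted outcome labels) and `p`
#'   (an n-dimensional probability array with dimnames).
#' @details Probabilities must be non-negative, duplicate outcome tuples are
#'   an error, and the total mass must be 1 within 1e-6 (it is renormalized).
#' @examples
#' joint_from_table(data.frame(
#'   T = c("0", "0", "1"), Y1 = c("0", "1", "1"), p = c(0.25, 0.25, 0.5)
#' ))
#' @export
joint_from_table <- function(records, vars = NULL) {
  if (is.data.frame(records)) {
    df <- records
    pcol <- if ("p" %in% names(df)) "p" else names(df)[ncol(df)]
    p <- as.numeric(df[[pcol]])
    out <- df[setdiff(names(df), pcol)]
  } else if (is.list(records)) {
    p <- vapply(records, function(r) as.numeric(r[[2]]), numeric(1))
    tuples <- lapply(records, function(r) as.character(unlist(r[[1]])))
    arity <- unique(vapply(tuples, length, integer(1)))
    if (length(arity) != 1L) {
      pid_error("BAD_ARITY", "all outcome tuples must have the same arity")
    }
    out <- as.data.frame(do.call(rbind, tuples), stringsAsFactors = FALSE)
  } else {
    pid_error("BAD_INPUT", "records must be a data.frame or list")
  }
  if (ncol(out) < 1L) pid_error("BAD_INPUT", "no outcome columns")
  out[] <- lapply(out, as.character)
  if (any(!is.finite(p)) || any(p < -.tol_internal)) {
    pid_error("NEGATIVE_PROB", "probabilities must be finite and >= 0")
  }
  p[p < 0] <- 0
  key <- do.call(paste, c(out, sep = "\r"))
  if (anyDuplicated(key)) {
    pid_error("DUPLICATE_OUTCOME", "duplicate outcome tuples in table")
  }
  s <- sum(p)
  if (abs(s - 1) > .tol_input) {
    pid_error("SUM_FAR_FROM_ONE",
              sprintf("probabilities sum to %.8g, not 1", s))
  }
  p <- p / s
  if (is.null(vars)) {
    vars <- names(out)
    if (is.null(vars) || any(vars == "") ||
        all(grepl("^V[0-9]+$", vars))) {
      vars <- c("T", paste0("Y", seq_len(ncol(out) - 1L)))
    }
  }
  alphabets <- lapply(out, lex_sort)
  names(alphabets) <- vars
  arr <- array(0, dim = vapply(alphabets, length, integer(1)),
               dimnames = alphabets)
  idx <- as.matrix(as.data.frame(Map(function(col, alpha) {
    match(col, alpha)
  }, out, alphabets)))
  arr[idx] <- p
  structure(list(vars = vars, alphabets = alphabets, p = arr),
            class = "joint_dist")
}

#' @export
print.joint_dist <- function(x, ...) {
  cat(sprintf("joint distribution over (%s): %s outcomes, %d with mass\n",
              paste(x$vars, collapse = ", "),
              paste(dim(x$p), collapse = " x "),
              sum(x$p > 0)))
  invisible(x)
}

n_sources <- function(joint) length(joint$vars) - 1L

#' @export
as.data.frame.joint_dist <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  grid <- expand.grid(x$alphabets, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$p <- as.vector(x$p)
  grid <- grid[grid$p > 0, , drop = FALSE]
  ord <- do.call(order, grid[x$vars])
  out <- grid[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Marginal array over a subset of variable indices (1 = target).
marginal_array <- function(joint, idx) {
  apply(joint$p, idx, sum)
}

#' Target marginal of a joint distribution
#'
#' @param joint A [joint_from_table()] object.
#' @return A simplex point over the target alphabet.
#' @export
target_marginal <- function(joint) {
  pt <- marginal_array(joint, 1L)
  simplex_point(as.numeric(pt), names(pt))
}

#' Channel from the target to one source
#'
#' Extracts the row-stochastic matrix `K[t, y] = p(y | t)` for one source
#' from a joint distribution, together with the target marginal p(t).
#' Target outcomes with zero mass have no defined conditional row and are
#' dropped from the channel input alphabet; the dropped labels are recorded
#' in the `"dropped_inputs"` attribute of the channel.
#'
#' @param joint A [joint_from_table()] object.
#' @param source Source index (1 = first source) or source variable name.
#' @return `list(p_t = <simplex point>, K = <channel>)`.
#' @examples
#' ch <- channel_from_joint(gate_joint("AND"), 1)
#' ch$K  # rows (2/3, 1/3) and (0, 1)
#' @export
channel_from_joint <- function(joint, source) {
  i <- source_index(joint, source)
  m <- marginal_array(joint, c(1L, i))
  pt <- rowSums(m)
  keep <- pt > 0
  if (!any(keep)) pid_error("EMPTY_SUPPORT", "target marginal is all zero")
  K <- m[keep, , drop = FALSE] / pt[keep]
  K <- channel(K, rownames(m)[keep], colnames(m))
  if (any(!keep)) attr(K, "dropped_inputs") <- rownames(m)[!keep]
  list(p_t = simplex_point(pt[keep], names(pt)[keep]), K = K)
}

source_index <- function(joint, source) {
  if (is.character(source)) {
    i <- match(source, joint$vars)
    if (is.na(i) || i == 1L) pid_error("BAD_SOURCE", "unknown source variable")
    return(i)
  }
  i <- as.integer(source) + 1L
  if (i < 2L || i > length(joint$vars)) {
    pid_error("BAD_SOURCE", "source index out of range")
  }
  i
}

#' Channel from the target to a tuple of sources
#'
#' Builds the channel from T to the product outcome (Yi1, ..., Yik) directly
#' from the joint distribution (not from the per-source channels), as needed
#' for the source (Y1, ..., Yn) appearing in the monotonicity axioms.
#'
#' @param joint A [joint_from_table()] object.
#' @param sources Distinct source indices or names (non-empty).
#' @return `list(p_t = <simplex point>, K = <channel>)`; tuple outputs are
#'   labelled `"y1,y2"` etc.
#' @export
tuple_channel <- function(joint, sources) {
  if (length(sources) < 1L) pid_error("BAD_SOURCE", "need at least one source")
  idx <- vapply(sources, function(s) source_index(joint, s), integer(1))
  if (anyDuplicated(idx)) pid_error("BAD_SOURCE", "source indices must be distinct")
  m <- marginal_array(joint, c(1L, idx))
  tdim <- dim(m)[1]
  flat <- matrix(m, nrow = tdim)
  labs <- expand.grid(joint$alphabets[idx], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  # lexicographic tuple order (first source major), as everywhere else
  perm <- do.call(order, labs)
  flat <- flat[, perm, drop = FALSE]
  colnames(flat) <- do.call(paste, c(labs[perm, , drop = FALSE], sep = ","))
  rownames(flat) <- joint$alphabets[[1]]
  pt <- rowSums(flat)
  keep <- pt > 0
  if (!any(keep)) pid_error("EMPTY_SUPPORT", "target marginal is all zero")
  K <- channel(flat[keep, , drop = FALSE] / pt[keep])
  if (any(!keep)) attr(K, "dropped_inputs") <- rownames(flat)[!keep]
  list(p_t = simplex_point(pt[keep], names(pt)[keep]), K = K)
}

#' Joint distribution from a target marginal and source channels
#'
#' Builds the conditionally independent joint
#' `p(t, y1, ..., yn) = p(t) * prod_i K(i)[t, y_i]`, the construction used
#' when a decomposition problem is specified by its channels.
#'
#' @param p_t Target marginal (labels become the target alphabet).
#' @param channels List of channels with `length(p_t)` rows.
#' @param vars Optional variable names (target first).
#' @return A [joint_from_table()] object.
#' @examples
#' ce <- counterexample1()
#' joint_from_channels(c(0.4, 0.6), list(ce$K1, ce$K2))
#' @export
joint_from_channels <- function(p_t, channels, vars = NULL) {
  p_t <- simplex_point(p_t)
  channels <- lapply(channels, function(K) if (is_channel(K)) K else channel(K))
  for (K in channels) {
    if (nrow(K) != length(p_t)) {
      pid_error("DIMENSION_MISMATCH",
                "all channels must have length(p_t) rows")
    }
  }
  alphabets <- c(list(names(p_t)), lapply(channels, colnames))
  grid <- expand.grid(rev(alphabets), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, length(alphabets):1]
  names(grid) <- if (!is.null(vars)) vars else
    c("T", paste0("Y", seq_along(channels)))
  p <- p_t[match(grid[[1]], names(p_t))]
  for (i in seq_along(channels)) {
    M <- ch_mat(channels[[i]])
    p <- p * M[cbind(match(grid[[1]], rownames(channels[[i]])),
                     match(grid[[i + 1L]], colnames(channels[[i]])))]
  }
  grid$p <- as.numeric(p)
  joint_from_table(grid, vars = names(grid)[-length(grid)])
}

#' Shannon entropy in bits
#'
#' @param p A probability vector (validated via [simplex_point()]).
#' @return Entropy `-sum p log2 p` in bits, with `0 log 0 := 0`.
#' @examples
#' entropy_bits(c(0.5, 0.5))  # 1
#' @export
entropy_bits <- function(p) {
  p <- simplex_point(p)
  -sum(xlog2x_over(p, rep(1, length(p))))
}

#' Mutual information of a target marginal and a channel, in bits
#'
#' Computes `I(T;Y)` for `p(t, y) = p_t[t] * K[t, y]`, in log base 2.
#'
#' @param p_t Probability vector over the channel input alphabet.
#' @param K A [channel()] with `length(p_t)` rows.
#' @return Mutual information in bits (non-negative; 0 iff all positively
#'   weighted rows of `K` coincide).
#' @examples
#' mutual_information(c(0.5, 0.5), channel(diag(2)))  # 1
#' @export
mutual_information <- function(p_t, K) {
  p_t <- simplex_point(p_t)
  K <- if (is_channel(K)) K else channel(K)
  if (length(p_t) != nrow(K)) {
    pid_error("DIMENSION_MISMATCH", "p_t length must equal nrow(K)")
  }
  mi_kernel(p_t, ch_mat(K))
}

# Unvalidated fast path used in inner loops.
mi_kernel <- function(p_t, K) {
  q <- as.numeric(p_t %*% K)
  s <- 0
  for (t in which(p_t > 0)) {
    s <- s + p_t[t] * sum(xlog2x_over(K[t, ], q))
  }
  max(s, 0)
}

#' Specific information of each target outcome, in bits
#'
#' The specific information of outcome `t` is
#' `I(Y; T = t) = sum_y p(y|t) * (log2 p(t|y) - log2 p(t))`; its expectation
#' under p(t) is the mutual information.  (This is the Williams–Beer form of
#' specific information; see the methods vignette for the choice.)
#'
#' @inheritParams mutual_information
#' @return Named numeric vector of per-outcome values in bits.
#' @export
specific_information <- function(p_t, K) {
  p_t <- simplex_point(p_t)
  K <- if (is_channel(K)) K else channel(K)
  if (length(p_t) != nrow(K)) {
    pid_error("DIMENSION_MISMATCH", "p_t length must equal nrow(K)")
  }
  M <- ch_mat(K)
  q <- as.numeric(p_t %*% M)
  out <- vapply(seq_along(p_t), function(t) {
    sum(xlog2x_over(M[t, ], q))
  }, numeric(1))
  names(out) <- names(p_t)
  out
}

#' Chi-squared divergence between two probability vectors
#'
#' `chi2(u || v) = sum_i (u_i - v_i)^2 / v_i`, with the conventions
#' `0/0 := 0` and `positive/0 := +Inf`.
#'
#' @param u,v Numeric probability vectors of equal length.
#' @return A non-negative (possibly infinite) scalar.
#' @examples
#' chi2_divergence(c(1, 0), c(0.5, 0.5))  # 1
#' @export
chi2_divergence <- function(u, v) {
  if (length(u) != length(v)) {
    pid_error("DIMENSION_MISMATCH", "u and v must have equal length")
  }
  d <- (u - v)^2
  if (any(d > .tol_internal^2 & v == 0)) return(Inf)
  ok <- v > 0
  sum(d[ok] / v[ok])
}
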