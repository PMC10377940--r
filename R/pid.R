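# Bivariate partial information decomposition built on an intersection
# information measure.

measure_names <- c(d = "degradation", degradation = "degradation",
                   ln = "less_noisy", less_noisy = "less_noisy",
                   mc = "more_capable", more_capable = "more_capable",
                   ds = "ds",
                   mmi = "mmi",
                   det = "deterministic", deterministic = "deterministic")

run_measure <- function(measure, joint, p_t, channels, opts) {
  switch(measure,
         degradation = ii_degradation(p_t, channels, opts),
         less_noisy = ii_less_noisy(p_t, channels, opts),
         more_capable = ii_more_capable(p_t, channels, opts),
         ds = ii_ds(p_t, channels, opts),
         mmi = ii_mmi(p_t, channels),
         deterministic = ii_deterministic(joint),
         pid_error("UNSUPPORTED_MEASURE",
                   sprintf("unsupported measure '%s'", measure)))
}

#' Partial information decomposition of a bivariate system
#'
#' Decomposes `I(T; (Y1, Y2)) = R + U1 + U2 + S` for a three-variable joint
#' distribution (target first).  Redundancy R is the chosen intersection
#' information measure; unique informations follow from
#' `Ui = I(T;Yi) - R` and synergy from the total.  When the measure is only
#' bracketed (less-noisy, more-capable, ds), the bracket propagates to all
#' four components as an interval; point estimates use the certified lower
#' bound of R.
#'
#' @param joint A [joint_from_table()] object with exactly two sources.
#' @param measure Redundancy measure: `"degradation"` (`"d"`),
#'   `"less_noisy"` (`"ln"`), `"more_capable"` (`"mc"`), `"ds"`, `"mmi"`, or
#'   `"deterministic"` (`"det"`).
#' @param opts Options from [ii_opts()].
#' @return An object of class `"pid"` with components `R`, `U1`, `U2`, `S`
#'   (each `c(lower, upper)`), point estimates via [coef()], the source and
#'   joint mutual informations, and the full `ii_measure` result.
#' @examples
#' fit <- pid(gate_joint("AND"), "degradation")
#' coef(fit)  # R = 0.311, U1 = U2 = 0, S = 0.5
#' @export
pid <- function(joint, measure = "degradation", opts = ii_opts()) {
  if (!inherits(joint, "joint_dist")) {
    pid_error("BAD_INPUT", "joint must be a joint_dist")
  }
  if (n_sources(joint) != 2L) {
    pid_error("UNSUPPORTED_MEASURE",
              "pid() decomposes exactly two sources")
  }
  mname <- measure_names[[match.arg(measure, names(measure_names))]]
  c1 <- channel_from_joint(joint, 1L)
  c2 <- channel_from_joint(joint, 2L)
  c12 <- tuple_channel(joint, c(1L, 2L))
  p_t <- c1$p_t
  I1 <- mutual_information(p_t, c1$K)
  I2 <- mutual_information(p_t, c2$K)
  I12 <- mutual_information(p_t, c12$K)
  res <- run_measure(mname, joint, p_t, list(c1$K, c2$K), opts)
  R <- c(lower = res$lower, upper = res$upper)
  U1 <- c(lower = I1 - R[["upper"]], upper = I1 - R[["lower"]])
  U2 <- c(lower = I2 - R[["upper"]], upper = I2 - R[["lower"]])
  S <- c(lower = I12 - I1 - I2 + R[["lower"]],
         upper = I12 - I1 - I2 + R[["upper"]])
  structure(list(measure = mname, result = res,
                 R = R, U1 = U1, U2 = U2, S = S,
                 I1 = I1, I2 = I2, total = I12,
                 vars = joint$vars),
            class = "pid")
}

fmt_comp <- function(x, digits) {
  x[abs(x) < 5e-10] <- 0  # avoid printing -0.0000
  if (abs(x[["upper"]] - x[["lower"]]) <= 1e-9) {
    sprintf("%.*f", digits, x[["lower"]])
  } else {
    sprintf("[%.*f, %.*f]", digits, x[["lower"]], digits, x[["upper"]])
  }
}

#' @export
print.pid <- function(x, digits = 4, ...) {
  cat(sprintf("bivariate PID (%s measure), all values in bits\n", x$measure))
  cat(sprintf("  I(T;(Y1,Y2)) = %.*f\n", digits, x$total))
  cat(sprintf("  redundancy R = %s (%s)\n", fmt_comp(x$R, digits),
              x$result$status))
  cat(sprintf("  unique U1    = %s\n", fmt_comp(x$U1, digits)))
  cat(sprintf("  unique U2    = %s\n", fmt_comp(x$U2, digits)))
  cat(sprintf("  synergy S    = %s\n", fmt_comp(x$S, digits)))
  invisible(x)
}

#' @export
summary.pid <- function(object, ...) {
  out <- list(
    measure = object$measure,
    status = object$result$status,
    components = rbind(R = object$R, U1 = object$U1, U2 = object$U2,
                       S = object$S),
    source_mi = c(I1 = object$I1, I2 = object$I2, total = object$total),
    identity_gap = object$total -
      (object$R[["lower"]] + object$U1[["upper"]] + object$U2[["upper"]] +
         object$S[["lower"]])
  )
  class(out) <- "summary.pid"
  out
}

#' @export
print.summary.pid <- function(x, digits = 4, ...) {
  cat(sprintf("PID summary (%s, %s)\n", x$measure, x$status))
  print(round(x$components, digits))
  cat("source mutual informations (bits):\n")
  print(round(x$source_mi, digits))
  invisible(x)
}

#' @export
coef.pid <- function(object, ...) {
  c(redundancy = object$R[["lower"]],
    unique1 = object$U1[["upper"]],
    unique2 = object$U2[["upper"]],
    synergy = object$S[["lower"]])
}
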