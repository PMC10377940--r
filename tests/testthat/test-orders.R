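# Order decision procedures and their certificates.

test_that("degradation check: reflexivity, counterexamples, constructions", {
  k <- ds_example()
  ce <- counterexample1()

  # reflexivity: W = V
  self <- degradation_check(k$K3, k$K3)
  expect_equal(self$status, "HOLDS")
  expect_lt(max(abs(unclass(k$K3) -
                      unclass(k$K3) %*% unclass(self$certificate))), 1e-7)

  # no stochastic KU maps K3 onto K4
  expect_equal(degradation_check(k$K4, k$K3)$status, "VIOLATED")
  # and the counterexample-1 pair is unordered by degradation either way
  expect_equal(degradation_check(ce$K2, ce$K1)$status, "VIOLATED")
  expect_equal(degradation_check(ce$K1, ce$K2)$status, "VIOLATED")

  # construct-then-check over random shapes and seeds
  for (s in 1:100) {
    dims <- 2L + (s %% 2L)
    rp <- random_degraded_pair(dims, 3, 2, seed = s)
    v <- degradation_check(rp$W, rp$V)
    expect_equal(v$status, "HOLDS")
    # certificate is verifiable
    expect_lt(max(abs(unclass(rp$W) -
                        unclass(rp$V) %*% unclass(v$certificate))), 1e-7)
  }
})

test_that("joinmeet performs the columnwise max/min exchange", {
  k <- ds_example()
  expect_equal(unname(unclass(joinmeet(k$K3, 1, 2))), unname(unclass(k$K4)))
  # idempotence and per-row multiset invariance
  for (s in 1:20) {
    K <- random_channel(3, 4, seed = s)
    J <- joinmeet(K, 2, 4)
    expect_equal(unclass(joinmeet(J, 2, 4)), unclass(J))
    expect_equal(rowSums(J), rowSums(K))
    for (r in 1:3) {
      expect_equal(unname(sort(unclass(J)[r, ])),
                   unname(sort(unclass(K)[r, ])))
    }
  }
  expect_error(joinmeet(k$K3, 1, 1), class = "BAD_INDEX")
  expect_error(joinmeet(k$K3, 0, 2), class = "BAD_INDEX")
})

test_that("supermodular closure and order checks", {
  k <- ds_example()
  # channels with equal columns are fixed points
  flat <- channel(rbind(c(.5, .5), c(.5, .5)))
  expect_length(supermodular_closure(flat), 1L)

  cl <- supermodular_closure(k$K3)
  keys <- vapply(cl, function(m) paste(round(unclass(m), 9), collapse = ","),
                 character(1))
  k4key <- paste(round(unclass(k$K4), 9), collapse = ",")
  expect_true(k4key %in% keys)

  s <- supermodularity_check(k$K4, k$K3)
  expect_equal(s$status, "HOLDS")
  expect_equal(s$certificate, list(c(1, 2)))
  expect_equal(supermodularity_check(k$K3, k$K4)$status, "VIOLATED")
  expect_equal(supermodularity_check(k$K3, k$K3)$certificate, list())

  # closure members keep per-row entry multisets
  for (s in 1:20) {
    K <- random_channel(3, 3, seed = 100 + s)
    cl <- supermodular_closure(K)
    expect_gte(length(cl), 1L)
    for (m in cl) {
      for (r in 1:3) {
        expect_equal(unname(sort(unclass(m)[r, ])),
                     unname(sort(unclass(K)[r, ])), tolerance = 1e-12)
      }
    }
  }
})

test_that("ds check finds chains and stays sound", {
  k <- ds_example()
  expect_equal(ds_check(k$K4, k$K3)$status, "HOLDS")
  # pure degradation chains
  rp <- random_degraded_pair(3, 3, 2, seed = 5)
  expect_equal(ds_check(rp$W, rp$V)$status, "HOLDS")
  # bounded search exhausted: never claims VIOLATED
  expect_equal(ds_check(k$K3, k$K4, depth = 2)$status, "UNKNOWN")
})

test_that("less-noisy grid check reproduces the printed certificates", {
  k <- ds_example()
  ce <- counterexample1()

  # the printed pair p=(0,0,1), q=(.1,.1,.8) certifies K4 not below K3
  chiW <- chi2_divergence(c(0, 0, 1) %*% unclass(k$K4),
                          c(.1, .1, .8) %*% unclass(k$K4))
  chiV <- chi2_divergence(c(0, 0, 1) %*% unclass(k$K3),
                          c(.1, .1, .8) %*% unclass(k$K3))
  expect_lt(chiV, chiW)  # contraction fails in the required direction
  v1 <- less_noisy_check(k$K4, k$K3)
  expect_equal(v1$status, "VIOLATED")

  # the printed pair p=(0,1,0), q=(.1,0,.9) certifies K3 not below K4
  chiW <- chi2_divergence(c(0, 1, 0) %*% unclass(k$K3),
                          c(.1, 0, .9) %*% unclass(k$K3))
  chiV <- chi2_divergence(c(0, 1, 0) %*% unclass(k$K4),
                          c(.1, 0, .9) %*% unclass(k$K4))
  expect_lt(chiV, chiW)
  v2 <- less_noisy_check(k$K3, k$K4)
  expect_equal(v2$status, "VIOLATED")

  # every returned certificate reproduces its violating inequality
  for (v in list(v1, v2)) {
    w <- if (identical(v, v1)) k$K4 else k$K3
    vv <- if (identical(v, v1)) k$K3 else k$K4
    expect_lt(chi2_divergence(v$certificate$p %*% unclass(vv),
                              v$certificate$q %*% unclass(vv)),
              chi2_divergence(v$certificate$p %*% unclass(w),
                              v$certificate$q %*% unclass(w)))
  }

  # K2 is less noisy than K1 at the paper's resolution; reflexivity
  expect_equal(less_noisy_check(ce$K2, ce$K1)$status,
               "NO_VIOLATION_AT_RESOLUTION")
  expect_equal(less_noisy_check(ce$K1, ce$K1)$status,
               "NO_VIOLATION_AT_RESOLUTION")
})

test_that("more-capable grid check separates ordered and unordered pairs", {
  k <- ds_example()
  expect_equal(more_capable_check(k$K4, k$K3)$status,
               "NO_VIOLATION_AT_RESOLUTION")
  rp <- random_degraded_pair(3, 2, 2, seed = 11)
  expect_equal(more_capable_check(rp$W, rp$V)$status,
               "NO_VIOLATION_AT_RESOLUTION")
  # identity vs constant channel: violated at (refined) uniform input
  v <- more_capable_check(channel(diag(2)),
                          channel(rbind(c(.5, .5), c(.5, .5))))
  expect_equal(v$status, "VIOLATED")
  p <- v$certificate$p
  expect_gt(mutual_information(p, channel(diag(2))),
            mutual_information(p, channel(rbind(c(.5, .5), c(.5, .5)))))
})

test_that("implication chain: degradation implies less-noisy and more-capable", {
  for (s in 1:100) {
    shape <- list(c(2, 3, 2), c(3, 2, 2), c(2, 2, 3))[[1 + s %% 3]]
    rp <- random_degraded_pair(shape[1], shape[2], shape[3], seed = 300 + s)
    expect_equal(degradation_check(rp$W, rp$V)$status, "HOLDS")
    expect_false(less_noisy_check(rp$W, rp$V, 0.2)$status == "VIOLATED")
    expect_false(more_capable_check(rp$W, rp$V, 0.2)$status == "VIOLATED")
  }
  # supermodular step implies ds which must not violate more-capable
  for (s in 1:20) {
    V <- random_channel(3, 3, seed = 400 + s)
    W <- joinmeet(V, 1, 2)
    expect_equal(supermodularity_check(W, V)$status, "HOLDS")
    expect_equal(ds_check(W, V)$status, "HOLDS")
    expect_false(more_capable_check(W, V, 0.2)$status == "VIOLATED")
  }
})

test_that("grid refinement never converts VIOLATED to NO_VIOLATION", {
  k <- ds_example()
  for (step in c(0.5, 0.25, 0.1, 0.05)) {
    expect_equal(less_noisy_check(k$K4, k$K3, step)$status,
                 if (step <= 0.1) "VIOLATED" else
                   less_noisy_check(k$K4, k$K3, step)$status)
  }
  # once violated at a step, still violated at every finer step
  coarse <- less_noisy_check(k$K4, k$K3, 0.1)$status
  fine <- less_noisy_check(k$K4, k$K3, 0.05)$status
  expect_equal(coarse, "VIOLATED")
  expect_equal(fine, "VIOLATED")
})
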