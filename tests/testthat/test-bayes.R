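test_that("observe counts correctly and expands the model", {
  m <- dirichlet_model()
  expect_equal(m$counts, 0L); expect_equal(m$t, 0L)

  m <- observe(m, NULL)            # first observation fills dimension 1
  expect_equal(m$counts, 1L); expect_equal(m$t, 1L)

  m$counts <- 3L; m$t <- 3L
  m2 <- observe(m, NULL)
  expect_equal(m2$counts, c(3L, 1L)); expect_equal(m2$t, 4L)

  p0 <- posterior(m2)$mean[1]
  m3 <- observe(m2, 1)
  expect_equal(m3$counts, c(4L, 1L))
  expect_gt(posterior(m3)$mean[1], p0)   # mean monotone in the count

  expect_error(observe(m2, 3), "out of range")
  expect_error(observe(m2, 0), "out of range")
  expect_error(posterior(dirichlet_model()), "undefined")
})

test_that("posterior means are the closed form and intervals match qbeta", {
  m <- dirichlet_model(gamma0 = 1)
  m$counts <- c(3L, 1L); m$t <- 4L
  post <- posterior(m)
  expect_equal(post$mean, c(4, 2) / 6)
  expect_equal(sum(post$mean), 1)

  # arbitrary gamma0 / counts: closed form to machine precision
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    m <- dirichlet_model(gamma0 = runif(1, 0.2, 3))
    m$counts <- as.integer(rmultinom(1, sample(10:200, 1), runif(k) + 0.1))
    m$t <- sum(m$counts)
    post <- posterior(m)
    expect_equal(post$mean, (m$gamma0 + m$counts) / (k * m$gamma0 + m$t),
                 tolerance = 1e-15)
    expect_equal(sum(post$mean), 1, tolerance = 1e-12)
    expect_true(all(post$lower <= post$mean & post$mean <= post$upper))
  }

  # k = 1 convention: point mass at 1 with zero-width interval
  m1 <- dirichlet_model(); m1 <- observe(m1, NULL)
  expect_equal(posterior(m1), list(mean = 1, lower = 1, upper = 1))
})

test_that("credible intervals match an independent quantile oracle", {
  m <- dirichlet_model(gamma0 = 1, level = 0.95)
  m$counts <- c(30L, 10L); m$t <- 40L
  post <- posterior(m)
  # marginal of solution 1 is Beta(31, 11)
  expect_equal(post$lower[1], beta_quantile_oracle(0.025, 31, 11),
               tolerance = 1e-8)
  expect_equal(post$upper[1], beta_quantile_oracle(0.975, 31, 11),
               tolerance = 1e-8)
  expect_equal(post$lower[2], beta_quantile_oracle(0.025, 11, 31),
               tolerance = 1e-8)
  expect_equal(post$upper[2], beta_quantile_oracle(0.975, 11, 31),
               tolerance = 1e-8)
})

test_that("stabilisation, separation and max-trials fire as specified", {
  mk <- function(counts, gamma0 = 1, level = 0.95) {
    m <- dirichlet_model(gamma0 = gamma0, level = level)
    m$counts <- as.integer(counts); m$t <- sum(counts)
    m
  }

  # single dimension stabilises once past t_min
  m <- mk(12)
  st <- check_convergence(m, delta = 0.1, t_max = 50, t_min = 10)
  expect_equal(st$cause, "STABILISATION"); expect_true(st$converged)
  expect_equal(check_convergence(mk(5), t_min = 10)$cause, "RUNNING")

  # counts (48, 2): Beta(49,3) 2.5% quantile exceeds Beta(3,49) 97.5% quantile
  sep <- check_convergence(mk(c(48, 2)), delta = 0.1, t_max = 50)
  expect_equal(sep$cause, "SEPARATION")
  expect_equal(sep$dominant_index, 1L)

  # balanced 4-way counts at t = t_max: wide overlapping intervals
  mt <- check_convergence(mk(c(12, 13, 12, 13)), delta = 0.1, t_max = 50)
  expect_equal(mt$cause, "MAX_TRIALS")
  expect_false(mt$converged)
  expect_gt(mt$max_width, 0.1)
})

test_that("convergence predicates agree with brute-force evaluation on enumerated counts", {
  brute <- function(counts, gamma0, level, delta) {
    k <- length(counts); t <- sum(counts)
    a <- gamma0 + counts; b <- k * gamma0 + t - a
    lo <- up <- numeric(k)
    for (i in seq_len(k)) {
      lo[i] <- beta_quantile_oracle((1 - level) / 2, a[i], b[i])
      up[i] <- beta_quantile_oracle(1 - (1 - level) / 2, a[i], b[i])
    }
    stab <- max(up - lo) <= delta
    sep <- any(vapply(seq_len(k), function(i) lo[i] > max(up[-i]), logical(1)))
    list(stab = stab, sep = sep)
  }
  cases <- list(c(10, 2), c(48, 2), c(25, 25), c(40, 5, 5), c(96, 2, 2),
                c(17, 1, 1, 1), c(190, 5, 5))
  for (counts in cases) {
    m <- dirichlet_model(); m$counts <- as.integer(counts); m$t <- sum(counts)
    ref <- brute(counts, 1, 0.95, delta = 0.1)
    st <- check_convergence(m, delta = 0.1, t_max = 1000, t_min = 1)
    expected <- if (ref$stab) "STABILISATION" else if (ref$sep) "SEPARATION"
                else "RUNNING"
    expect_equal(st$cause, expected, info = paste(counts, collapse = ","))
  }
})

test_that("the posterior is exchangeable and intervals shrink with more data", {
  # observation order does not matter: only counts enter the posterior
  seqs <- list(c(1, 1, 2, 1, 3, 2), c(3, 2, 1, 1, 2, 1))
  fit_seq <- function(s) {
    m <- dirichlet_model()
    seen <- integer(0)
    for (x in s) {
      if (x %in% seen) m <- observe(m, match(x, seen))
      else { m <- observe(m, NULL); seen <- c(seen, x) }
    }
    m
  }
  m1 <- fit_seq(seqs[[1]]); m2 <- fit_seq(seqs[[2]])
  expect_equal(sort(m1$counts), sort(m2$counts))
  expect_equal(m1$t, m2$t)

  # median max interval width decreases from t = 20 to t = 100
  set.seed(33)
  p <- c(0.5, 0.3, 0.2)
  width_at <- function(t) {
    replicate(100, {
      m <- dirichlet_model()
      m$counts <- as.integer(rmultinom(1, t, p)); m$t <- t
      post <- posterior(m)
      max(post$upper - post$lower)
    })
  }
  expect_lt(median(width_at(100)), median(width_at(20)))
})
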