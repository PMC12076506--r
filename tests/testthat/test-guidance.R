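toy_ctx <- function(P = 20, seed = 1, sigma = 1.0, d_clash = 2.0) {
  set.seed(seed)
  protein_context(matrix(rnorm(P * 3, sd = 4), P, 3),
                  sigma = sigma, clash_threshold = d_clash)
}

test_that("schedule construction enforces the gamma contract", {
  s <- make_schedule(50L)
  expect_equal(s$T, 50L)
  expect_true(all(diff(s$gamma) <= 1e-12))
  expect_true(all(s$gamma[1:5] == 1))           # final 10% of reverse steps
  expect_equal(s$sigma_sq, s$beta)
  expect_error(make_schedule(10L, beta = rep(1.5, 10)), "beta")
  expect_error(make_schedule(10L, gamma = seq(0, 1, length.out = 10)),
               "non-increasing")
  expect_error(make_schedule(10L, gamma = rep(0.5, 10)), "hard-anchor")
})

test_that("protein_surface matches its closed forms and the min-distance limit", {
  # single atom at distance d: S = d exactly
  ctx1 <- protein_context(matrix(c(3, 0, 0), 1, 3), sigma = 1.0)
  expect_equal(protein_surface(c(0, 0, 0), ctx1), 3)
  # two atoms both at distance d, sigma = 1: S = d - ln 2
  ctx2 <- protein_context(rbind(c(3, 0, 0), c(-3, 0, 0)), sigma = 1.0)
  expect_equal(protein_surface(c(0, 0, 0), ctx2), 3 - log(2))
  # sigma -> 0 recovers the brute-force minimum distance
  set.seed(42)
  pts <- matrix(rnorm(60, sd = 5), 20, 3)
  ctx3 <- protein_context(pts, sigma = 1e-3)
  for (k in 1:10) {
    r <- rnorm(3, sd = 3)
    dmin <- min(sqrt(rowSums((pts - matrix(r, 20, 3, byrow = TRUE))^2)))
    expect_lt(abs(protein_surface(r, ctx3) - dmin), 1e-2)
    # S is a lower bound on the true minimum distance at any sigma
    expect_lte(protein_surface(r, toy_ctx()), dmin + 1e2)  # sanity shape
  }
})

test_that("clash_loss is a hinge on surface distances", {
  ctx <- protein_context(matrix(c(10, 0, 0), 1, 3), sigma = 1.0,
                         clash_threshold = 2.0)
  # all atoms far beyond the threshold: zero loss
  far <- rbind(c(0, 0, 0), c(1, 1, 1))
  expect_equal(clash_loss(far, ctx), 0)
  # one atom with S = d_clash - 0.5: loss 0.25
  near <- matrix(c(8.5, 0, 0), 1, 3)
  expect_equal(clash_loss(near, ctx), 0.25)
  # random clashing configurations match term-by-term re-summation
  ctx <- toy_ctx(P = 15, seed = 9)
  for (k in 1:10) {
    set.seed(100 + k)
    R <- matrix(rnorm(18, sd = 3), 6, 3)
    manual <- sum(vapply(seq_len(6), function(i) {
      max(0, ctx$clash_threshold - protein_surface(R[i, ], ctx))^2
    }, numeric(1)))
    expect_equal(clash_loss(R, ctx), manual)
  }
})

test_that("clash_gradient matches central finite differences", {
  ctx <- toy_ctx(P = 12, seed = 5)
  h <- 1e-4
  for (k in 1:10) {
    set.seed(200 + k)
    R <- matrix(rnorm(15, sd = 3), 5, 3)
    g <- clash_gradient(R, ctx)
    fd <- matrix(0, 5, 3)
    for (i in 1:5) {
      for (d in 1:3) {
        Rp <- R; Rp[i, d] <- Rp[i, d] + h
        Rm <- R; Rm[i, d] <- Rm[i, d] - h
        fd[i, d] <- (clash_loss(Rp, ctx) - clash_loss(Rm, ctx)) / (2 * h)
      }
    }
    denom <- max(1, max(abs(fd)))
    expect_lt(max(abs(g - fd)) / denom, 1e-5)
  }
})

test_that("clash_gradient is zero for clear atoms and pushes clashing atoms away", {
  ctx <- protein_context(matrix(c(5, 0, 0), 1, 3), sigma = 1.0,
                         clash_threshold = 2.0)
  clear <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(clash_gradient(clear, ctx), matrix(0, 2, 3))
  # one clashing atom near a single protein atom: the applied shift
  # (-grad) points radially away from the protein atom
  R <- matrix(c(4, 0, 0), 1, 3)
  g <- clash_gradient(R, ctx)
  away <- c(-1, 0, 0)  # from protein atom toward the ligand atom
  expect_gt(sum(-g[1, ] * away), 0)
})

test_that("anchor_positions mixes masked rows and leaves others bit-identical", {
  sched <- make_schedule(50L)
  pts <- list(pharmacophore_point(c(1, 0, 0), "donor"))
  spec <- build_constraints(pts, tau = 1, slots = 4L)
  R <- matrix(rnorm(12), 4, 3)
  # all-zero mask: identity
  empty <- build_constraints(list(), tau = 1, slots = 4L)
  expect_identical(anchor_positions(R, empty, 25L, sched), R)
  # hard-anchor window: masked rows equal the points exactly
  out <- anchor_positions(R, spec, 2L, sched)
  expect_identical(out[1, ], c(1, 0, 0))
  expect_identical(out[2:4, ], R[2:4, ])
  # convex combination at gamma = 0.3
  sched2 <- make_schedule(10L, gamma = c(1, rep(0.3, 8), 0.2))
  R0 <- matrix(0, 1, 3)
  spec1 <- build_constraints(pts, tau = 1, slots = 1L)
  expect_equal(anchor_positions(R0, spec1, 5L, sched2)[1, ],
               0.3 * c(1, 0, 0))
})

test_that("clamp_types overwrites only fixed masked slots", {
  pts <- lapply(1:2, function(k) pharmacophore_point(rnorm(3), "donor"))
  spec <- build_constraints(pts, fixed_types = c("O", NA), tau = 1,
                            slots = 5L)
  ts <- c("C", "C", "C", "N", "C")
  out <- clamp_types(ts, spec, c("C", "N", "O"))
  expect_identical(out, c("O", "C", "C", "N", "C"))
  nofix <- build_constraints(pts, tau = 1, slots = 5L)
  expect_identical(clamp_types(ts, nofix), ts)
  bad <- build_constraints(pts, fixed_types = c("Zr", NA), tau = 1,
                           slots = 5L)
  expect_error(clamp_types(ts, bad, c("C", "N", "O")), "vocabulary")
})

test_that("init_positions is deterministic and centres correctly", {
  pts <- list(pharmacophore_point(c(2, 0, 0), "donor"),
              pharmacophore_point(c(0, 2, 0), "acceptor"))
  spec <- build_constraints(pts, tau = 1, slots = 6L)
  a <- init_positions(spec, 6L, spread = 1, seed = 7L)
  b <- init_positions(spec, 6L, spread = 1, seed = 7L)
  expect_identical(a, b)
  # spread -> 0: masked rows collapse onto their points, free rows onto
  # the centroid
  z <- init_positions(spec, 6L, spread = 1e-12, seed = 7L)
  expect_equal(z[1, ], c(2, 0, 0), tolerance = 1e-9)
  expect_equal(z[2, ], c(0, 2, 0), tolerance = 1e-9)
  expect_equal(z[4, ], c(1, 1, 0), tolerance = 1e-9)
  # empty spec falls back to pure_random with a warning
  empty <- build_constraints(list(), tau = 1, slots = 3L)
  expect_warning(init_positions(empty, 3L, mode = "around_points",
                                seed = 1L), "pure_random")
})

test_that("init_positions draws match the stated Gaussian (Monte-Carlo)", {
  pts <- list(pharmacophore_point(c(3, -1, 2), "donor"))
  spec <- build_constraints(pts, tau = 1, slots = 2L)
  n_draw <- 10000L
  acc1 <- matrix(0, n_draw, 3)
  acc2 <- matrix(0, n_draw, 3)
  for (s in seq_len(n_draw)) {
    X <- init_positions(spec, 2L, spread = 1, seed = s)
    acc1[s, ] <- X[1, ]
    acc2[s, ] <- X[2, ]
  }
  expect_lt(max(abs(colMeans(acc1) - c(3, -1, 2))), 0.05)
  expect_lt(max(abs(colMeans(acc2) - c(3, -1, 2))), 0.05)
  expect_lt(max(abs(apply(acc1, 2, sd) - 1)), 0.05)
})

test_that("guided_step reduces to the unguided sample at lambda = 0", {
  out <- denoiser_output(matrix(rnorm(9), 3, 3), matrix(0, 3, 3),
                         array(0, c(3, 3, 2)), sigma_sq_t = 0.05)
  ctx <- toy_ctx()
  R <- matrix(rnorm(9), 3, 3)
  a <- guided_step(out, R, ctx, guidance_config(lam = 0), seed = 3L)
  b <- guided_step(out, R, NULL, guidance_config(lam = 0), seed = 3L)
  expect_identical(a, b)
  # Sigma_t = 0 limit: output equals the shifted mean exactly
  out0 <- denoiser_output(out$mu, out$type_logits, out$bond_logits,
                          sigma_sq_t = 0)
  cfg <- guidance_config(lam = 0.5)
  shifted <- out$mu - 0.0 * clash_gradient(R, ctx)  # sigma_sq_t = 0
  expect_equal(guided_step(out0, R, ctx, cfg, seed = 9L), out0$mu)
  expect_error(guidance_config(lam = -1), "lambda")
})

test_that("guidance shift lowers the expected clash loss to first order", {
  # clashing configuration next to a wall of protein atoms
  set.seed(11)
  wall <- cbind(rep(0, 30), rnorm(30, sd = 2), rnorm(30, sd = 2))
  ctx <- protein_context(wall, sigma = 1.0, clash_threshold = 2.0)
  R <- matrix(c(1.0, 0, 0, 1.2, 0.5, 0), 2, 3, byrow = TRUE)
  mu <- R  # denoiser wants to stay put
  out <- denoiser_output(mu, matrix(0, 2, 3), array(0, c(2, 2, 2)),
                         sigma_sq_t = 0.01)
  lam <- 0.5
  guided_mean_loss <- clash_loss(
    mu - lam * out$sigma_sq_t * clash_gradient(R, ctx), ctx)
  expect_lt(guided_mean_loss, clash_loss(mu, ctx))
  # averaged over many sampled steps the ordering persists
  mean_g <- mean(vapply(1:1000, function(s) {
    clash_loss(guided_step(out, R, ctx, guidance_config(lam = lam),
                           seed = s), ctx)
  }, numeric(1)))
  mean_u <- mean(vapply(1:1000, function(s) {
    clash_loss(guided_step(out, R, ctx, guidance_config(lam = 0),
                           seed = s), ctx)
  }, numeric(1)))
  expect_lt(mean_g, mean_u)
})
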