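test_that("discrete arc length approximates analytic contour lengths", {
  expect_equal(length_term(matrix(3, 30, 30), eps = 1), 0)
  # signed distance to a circle of radius 20 on a 101x101 grid
  R <- 20
  g <- expand.grid(r = 0:100, c = 0:100)
  sd <- matrix(R - sqrt((g$r - 50)^2 + (g$c - 50)^2), 101, 101)
  expect_equal(length_term(sd, eps = 1), 2 * pi * R, tolerance = 0.15)
  # a wiggly contour is longer than a smooth one enclosing similar area
  th <- atan2(matrix(g$r - 50, 101, 101), matrix(g$c - 50, 101, 101))
  wig <- matrix(R + 4 * sin(8 * th), 101, 101) -
    sqrt(matrix((g$r - 50)^2 + (g$c - 50)^2, 101, 101))
  expect_gt(length_term(wig, eps = 1), length_term(sd, eps = 1))
})

test_that("total energy composes the component values", {
  inst <- rand_instance(16, 16, seed = 2)
  p <- hybrid_params(alpha = 1.3, beta = 0.7, omega = 0.2, r = 3)
  e <- total_energy(inst$I, inst$phi, p)
  gs <- global_means(inst$I, inst$phi, p$eps)
  kern <- ball_kernel(p$r)
  expect_equal(e$global, global_energy(inst$I, inst$phi, gs, p$eps))
  expect_equal(e$local_printed, local_energy(inst$I, inst$phi, kern, p$eps))
  expect_equal(e$local_residual,
               local_residual_energy(inst$I, inst$phi, kern, p$eps))
  expect_equal(e$length, length_term(inst$phi, p$eps))
  expect_equal(e$total,
               1.3 * e$global + 0.7 * e$local_printed + 0.2 * e$length)
  # brute-force check of the printed local part on the same instance
  expect_equal(e$local_printed, oracle_local_energy(inst$I, inst$phi, 3, 1),
               tolerance = 1e-9)
})

test_that("a zero-velocity step is the identity", {
  inst <- rand_instance(12, 12, seed = 4)
  p <- hybrid_params(alpha = 0, beta = 0, omega = 1e-300)
  expect_equal(evolve_step(inst$phi, inst$I, p), inst$phi, tolerance = 1e-290)
})

test_that("numerical blow-up is reported with the offending term", {
  # a non-finite intensity poisons the global force; the step must fail
  # loudly, naming the term, rather than propagate NaNs
  I <- matrix(runif(64), 8, 8)
  I[3, 3] <- Inf
  phi <- init_levelset(c(8, 8), region_circle(4, 4, 2))
  p <- hybrid_params(alpha = 1, beta = 0, omega = 0.1)
  expect_error(evolve(I, phi, p), "global")
  p2 <- hybrid_params(alpha = 0, beta = 1, omega = 0.1)
  expect_error(evolve(I, phi, p2), "local")
})

test_that("evolution respects max_iters = 0 and records the initial energy", {
  inst <- rand_instance(10, 10, seed = 6)
  p <- hybrid_params(max_iters = 0, r = 3)
  res <- evolve(inst$I, inst$phi, p)
  expect_identical(res$phi, inst$phi)
  expect_false(res$converged)
  expect_equal(res$iterations, 0L)
  expect_equal(nrow(res$energies), 1L)
  expect_equal(res$energies$iteration[1], 0L)
  expect_identical(res$mask, mask_from_levelset(inst$phi))
})

test_that("evolution is deterministic: identical inputs give identical traces", {
  ph <- make_phantom(phantom_spec("gourd", noise_sigma = 0.05, seed = 3))
  phi0 <- init_levelset(dim(ph$image), region_circle(29, 28, 10))
  p <- hybrid_params(max_iters = 60, r = 5)
  r1 <- evolve(ph$image, phi0, p)
  r2 <- evolve(ph$image, phi0, p)
  expect_identical(r1$phi, r2$phi)
  expect_identical(r1$energies, r2$energies)
  expect_identical(r1$mask, r2$mask)
})

test_that("starting at the ground truth stays at the ground truth", {
  ph <- make_phantom(phantom_spec("gourd", noise_sigma = 0))
  phi0 <- init_levelset(dim(ph$image), ph$mask)
  res <- evolve(ph$image, phi0, hybrid_params(max_iters = 500))
  expect_true(res$converged)
  expect_lt(res$iterations, 500)
  expect_gte(dice(res$mask, ph$mask), 0.99)
})

test_that("the fitting residual decreases over a short run on a phantom", {
  ph <- make_phantom(phantom_spec("three_objects", fg_level = 0.55,
                                  bg_level = 0.25, bias = bias_linear(0.4),
                                  noise_sigma = 0.03, seed = 3))
  phi0 <- init_levelset(dim(ph$image), region_circle(46, 27, 12))
  p <- hybrid_params(max_iters = 200)
  res <- evolve(ph$image, phi0, p)
  e <- res$energies
  resid <- p$alpha * e$global + p$beta * e$local_residual
  expect_lt(resid[length(resid)], resid[1])
})

test_that("energy CSV export round-trips the trace", {
  inst <- rand_instance(12, 12, seed = 8)
  res <- evolve(inst$I, inst$phi, hybrid_params(max_iters = 10, r = 3,
                                                check_every = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_energy_csv(res, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("iteration", "total", "global", "local_printed",
                              "local_residual", "length"))
  expect_equal(back$total, res$energies$total, tolerance = 1e-12)
})

test_that("tidy, glance and autoplot expose the fit", {
  inst <- rand_instance(12, 12, seed = 10)
  res <- evolve(inst$I, inst$phi, hybrid_params(max_iters = 10, r = 3))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_identical(td, res$energies)
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$iterations, res$iterations)
  expect_s3_class(autoplot(res), "ggplot")
})
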