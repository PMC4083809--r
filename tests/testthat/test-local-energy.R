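test_that("ball kernel follows the strict-distance definition", {
  # r = 1: only the center (neighbors are at distance exactly 1)
  expect_equal(sum(ball_kernel(1)$window), 1)
  expect_equal(dim(ball_kernel(1)$window), c(3, 3))
  # r = 1.5: full 3x3 neighborhood (sqrt(2) ~ 1.414 < 1.5)
  expect_equal(sum(ball_kernel(1.5)$window), 9)
  # window side and symmetry
  k9 <- ball_kernel(9)$window
  expect_equal(dim(k9), c(19, 19))
  expect_identical(k9, t(k9))
  expect_identical(k9, k9[19:1, ])
  expect_equal(k9[10, 10], 1)
  # element count matches the brute-force enumeration for several radii
  for (r in c(2, 3.7, 9)) {
    expect_identical(ball_kernel(r)$window, oracle_ball_window(r))
  }
  expect_error(ball_kernel(0.5), "radius")
})

test_that("local statistics match the brute-force double loop", {
  inst <- rand_instance(32, 32, seed = 21)
  st <- local_stats(inst$I, inst$phi, ball_kernel(4.5), eps = 1)
  or <- oracle_local_stats(inst$I, inst$phi, 4.5, eps = 1)
  expect_equal(st$Au, or$Au, tolerance = 1e-10)
  expect_equal(st$Av, or$Av, tolerance = 1e-10)
  expect_equal(st$u, or$u, tolerance = 1e-10)
  expect_equal(st$v, or$v, tolerance = 1e-10)
  expect_identical(st$ok, or$ok)
})

test_that("ball mass is conserved and means stay in range", {
  inst <- rand_instance(24, 24, seed = 5)
  kern <- ball_kernel(6)
  st <- local_stats(inst$I, inst$phi, kern, eps = 0.8)
  area <- ball_correlate(matrix(1, 24, 24), kern)
  # conservation at every pixel (to rounding), including near the borders
  expect_equal(st$Au + st$Av, area, tolerance = 1e-14)
  expect_true(all(st$u[st$ok] >= 0 & st$u[st$ok] <= 1))
  expect_true(all(st$v[st$ok] >= 0 & st$v[st$ok] <= 1))
  # constant image: u = v wherever defined
  Ic <- matrix(0.6, 24, 24)
  stc <- local_stats(Ic, inst$phi, kern, eps = 0.8)
  expect_equal(stc$u[stc$ok], stc$v[stc$ok], tolerance = 1e-12)
})

test_that("a ball covering the whole image reduces local means to global means", {
  inst <- rand_instance(16, 16, seed = 9)
  r <- ceiling(sqrt(2) * 16) + 1  # radius beyond the image diagonal
  st <- local_stats(inst$I, inst$phi, ball_kernel(r), eps = 1)
  gs <- global_means(inst$I, inst$phi, eps = 1)
  expect_true(all(st$ok))
  expect_equal(st$u, matrix(gs$m, 16, 16), tolerance = 1e-6)
  expect_equal(st$v, matrix(gs$n, 16, 16), tolerance = 1e-6)
})

test_that("local energies match brute-force loops and behave on phantoms", {
  inst <- rand_instance(16, 16, seed = 13)
  kern <- ball_kernel(3.2)
  e <- local_energy(inst$I, inst$phi, kern, eps = 1)
  expect_equal(e, oracle_local_energy(inst$I, inst$phi, 3.2, eps = 1),
               tolerance = 1e-9)
  expect_gte(e, 0)
  # constant image: zero separation
  expect_equal(local_energy(matrix(0.2, 16, 16), inst$phi, kern, eps = 1), 0)

  # the separation energy is largest for the true segmentation of a sharp
  # two-phase image, among shifted candidate contours
  A <- matrix(FALSE, 24, 24); A[8:16, 8:16] <- TRUE
  I <- ifelse(A, 0.9, 0.1)
  kern <- ball_kernel(5)
  vals <- sapply(c(0, 3, 6), function(shift) {
    B <- matrix(FALSE, 24, 24)
    B[(8:16) + shift, pmin((8:16) + shift, 24)] <- TRUE
    phi <- init_levelset(c(24, 24), B)
    local_energy(I, phi, kern, eps = 0.5)
  })
  expect_true(which.max(vals) == 1L)
})

test_that("local residual energy matches its definition on a small instance", {
  inst <- rand_instance(12, 12, seed = 17)
  r <- 2.5; eps <- 1
  er <- local_residual_energy(inst$I, inst$phi, ball_kernel(r), eps)
  or <- oracle_local_stats(inst$I, inst$phi, r, eps)
  h <- heaviside_eps(inst$phi, eps)
  k <- ceiling(r)
  eo <- 0
  for (i in 1:12) {
    for (j in 1:12) {
      if (!or$ok[i, j]) next
      for (a in max(1, i - k):min(12, i + k)) {
        for (b in max(1, j - k):min(12, j + k)) {
          if (sqrt((a - i)^2 + (b - j)^2) < r) {
            eo <- eo + h[a, b] * (inst$I[a, b] - or$u[i, j])^2 +
              (1 - h[a, b]) * (inst$I[a, b] - or$v[i, j])^2
          }
        }
      }
    }
  }
  expect_equal(er, eo, tolerance = 1e-9)
})

test_that("local force equals the brute-force double loop in both forms", {
  inst <- rand_instance(24, 24, seed = 31)
  kern <- ball_kernel(4)
  st <- local_stats(inst$I, inst$phi, kern, eps = 1)
  for (form in c("mean_separation", "as_printed")) {
    f <- local_force(inst$I, inst$phi, st, kern, eps = 1, form = form)
    fo <- oracle_local_force(inst$I, inst$phi, 4, eps = 1, form = form)
    expect_equal(f, fo, tolerance = 1e-8)
  }
})

test_that("local force vanishes in degenerate and well-classified settings", {
  # constant image: both forms identically zero
  Ic <- matrix(0.5, 16, 16)
  phi <- init_levelset(c(16, 16), region_circle(8, 8, 4))
  kern <- ball_kernel(3)
  st <- local_stats(Ic, phi, kern, eps = 1)
  expect_equal(local_force(Ic, phi, st, kern, 1), matrix(0, 16, 16),
               tolerance = 1e-12)

  # sharp two-level image with phi on the true boundary: negligible force on
  # interior pixels whose covering balls never reach the contour
  A <- matrix(FALSE, 32, 32); A[10:22, 10:22] <- TRUE
  I <- ifelse(A, 0.8, 0.2)
  phi <- init_levelset(c(32, 32), A)
  st <- local_stats(I, phi, kern, eps = 0.05)
  f <- local_force(I, phi, st, kern, eps = 0.05)
  far_inside <- matrix(FALSE, 32, 32); far_inside[15:17, 15:17] <- TRUE
  expect_lt(max(abs(f[far_inside])), 1e-3)
})

test_that("transposing the instance transposes all local fields", {
  inst <- rand_instance(20, 14, seed = 41)
  kern <- ball_kernel(3.5)
  st <- local_stats(inst$I, inst$phi, kern, eps = 1)
  stt <- local_stats(t(inst$I), t(inst$phi), kern, eps = 1)
  # transposition permutes the summation order, so agreement is to rounding
  expect_equal(stt$u, t(st$u), tolerance = 1e-12)
  expect_equal(stt$v, t(st$v), tolerance = 1e-12)
  expect_equal(stt$Au, t(st$Au), tolerance = 1e-12)
  expect_equal(stt$Av, t(st$Av), tolerance = 1e-12)
  f <- local_force(inst$I, inst$phi, st, kern, 1)
  ft <- local_force(t(inst$I), t(inst$phi), stt, kern, 1)
  expect_equal(ft, t(f), tolerance = 1e-10)
})
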