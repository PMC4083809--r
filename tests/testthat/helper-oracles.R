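# Brute-force double-loop oracles for the ball-localized quantities, written
# independently of the package's correlation-based implementations. All loops
# gather in-domain pixels only, mirroring the discrete integrals over the
# image domain.

oracle_ball_window <- function(r) {
  k <- ceiling(r)
  w <- matrix(0, 2 * k + 1, 2 * k + 1)
  for (a in -k:k) {
    for (b in -k:k) {
      if (sqrt(a^2 + b^2) < r) w[a + k + 1, b + k + 1] <- 1
    }
  }
  w
}

oracle_local_stats <- function(I, phi, r, eps) {
  nr <- nrow(I); nc <- ncol(I)
  k <- ceiling(r)
  h <- 0.5 * (1 + (2 / pi) * atan(phi / eps))
  Au <- Av <- u <- v <- matrix(0, nr, nc)
  ok <- matrix(TRUE, nr, nc)
  for (i in 1:nr) {
    for (j in 1:nc) {
      su <- sv <- nu <- nv <- 0
      for (a in max(1, i - k):min(nr, i + k)) {
        for (b in max(1, j - k):min(nc, j + k)) {
          if (sqrt((a - i)^2 + (b - j)^2) < r) {
            nu <- nu + h[a, b]
            nv <- nv + (1 - h[a, b])
            su <- su + h[a, b] * I[a, b]
            sv <- sv + (1 - h[a, b]) * I[a, b]
          }
        }
      }
      Au[i, j] <- nu; Av[i, j] <- nv
      if (nu > 1e-10 && nv > 1e-10) {
        u[i, j] <- su / nu; v[i, j] <- sv / nv
      } else {
        ok[i, j] <- FALSE
      }
    }
  }
  list(u = u, v = v, Au = Au, Av = Av, ok = ok)
}

oracle_local_energy <- function(I, phi, r, eps) {
  st <- oracle_local_stats(I, phi, r, eps)
  nr <- nrow(I); nc <- ncol(I)
  k <- ceiling(r)
  e <- 0
  for (i in 1:nr) {
    for (j in 1:nc) {
      if (!st$ok[i, j]) next
      for (a in max(1, i - k):min(nr, i + k)) {
        for (b in max(1, j - k):min(nc, j + k)) {
          if (sqrt((a - i)^2 + (b - j)^2) < r) {
            e <- e + (st$u[i, j] - st$v[i, j])^2
          }
        }
      }
    }
  }
  e
}

oracle_local_force <- function(I, phi, r, eps, form = "mean_separation") {
  st <- oracle_local_stats(I, phi, r, eps)
  nr <- nrow(I); nc <- ncol(I)
  k <- ceiling(r)
  F <- matrix(0, nr, nc)
  for (i in 1:nr) {         # ball centers x
    for (j in 1:nc) {
      if (!st$ok[i, j]) next
      ui <- st$u[i, j]; vi <- st$v[i, j]
      Aui <- st$Au[i, j]; Avi <- st$Av[i, j]
      for (a in max(1, i - k):min(nr, i + k)) {   # covered pixels y
        for (b in max(1, j - k):min(nc, j + k)) {
          if (sqrt((a - i)^2 + (b - j)^2) < r) {
            F[a, b] <- F[a, b] + if (form == "mean_separation") {
              (ui - vi) * ((I[a, b] - ui) / Aui + (I[a, b] - vi) / Avi)
            } else {
              (I[a, b] - ui)^2 / Aui - (I[a, b] - vi)^2 / Avi
            }
          }
        }
      }
    }
  }
  F
}

# small random test instance with a coherent two-phase structure
rand_instance <- function(nr, nc, seed) {
  set.seed(seed)
  I <- matrix(runif(nr * nc), nr, nc)
  phi <- matrix(runif(nr * nc, -2, 2), nr, nc)
  list(I = I, phi = phi)
}
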