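test_that("non-interacting filament gives the all-ones matrix with spectrum {2, 0}", {
  tm <- build_transfer_matrix(lattice_spec("filament"), energy_params())
  expect_equal(tm$entries, matrix(1, 2, 2))
  ev <- sort(Mod(eigen(tm$entries)$values), decreasing = TRUE)
  expect_equal(ev, c(2, 0), tolerance = 1e-12)
})

test_that("three-state filament matrix has the printed layout with exp(-R) interfaces", {
  p <- energy_params(R1 = 0.31, R2 = 0.52, R3 = 0.17, P1 = 0.8, P2 = 1.3)
  tm <- build_transfer_matrix(lattice_spec("filament", q = 3), p)
  u1 <- exp(-p$R1); u2 <- exp(-p$R2); u3 <- exp(-p$R3)
  s1 <- p$s1; s2 <- p$s2
  ## rows: from coil/helix/sheet; columns likewise (propagation on the
  ## entered state, one interface factor per unlike pair)
  expected <- rbind(c(1, s1 * u1, s2 * u2),
                    c(u1, s1, s2 * u3),
                    c(u2, s1 * u3, s2))
  expect_equal(tm$entries, expected, tolerance = 1e-14)
})

test_that("two-filament strip carries s^2 b in the all-sheet diagonal and factorizes at B = 0", {
  p <- energy_params(P2 = 0.9, R2 = 0.4, B = 0.7)
  tm <- build_transfer_matrix(lattice_spec("strip", Ly = 2), p)
  i_ss <- which(tm$state_labels == "ss")
  expect_equal(tm$entries[i_ss, i_ss], p$s2^2 * p$b, tolerance = 1e-14)
  ## B = 0: entrywise equality with the Kronecker product of filament matrices
  p0 <- update_params(p, B = 0)
  strip0 <- build_transfer_matrix(lattice_spec("strip", Ly = 2), p0)
  fil <- build_transfer_matrix(lattice_spec("filament"), p0)
  expect_equal(strip0$entries, kronecker(fil$entries, fil$entries),
               tolerance = 1e-14)
})

test_that("q = 2 filament characteristic polynomial is lambda^2 - (1+s) lambda + s (1 - sigma)", {
  p <- energy_params(P2 = 0.7, R2 = 0.45)
  tm <- build_transfer_matrix(lattice_spec("filament"), p)
  s <- p$s2; sig <- p$sigma2
  expect_equal(sum(diag(tm$entries)), 1 + s, tolerance = 1e-14)
  expect_equal(det(tm$entries), s * (1 - sig), tolerance = 1e-14)
  lam1 <- max(Re(eigen(tm$entries)$values))
  expect_equal(lam1, (1 + s + sqrt((s - 1)^2 + 4 * s * sig)) / 2,
               tolerance = 1e-12)
})

test_that("open partition matches counting limits and the enumeration oracle", {
  ## unit weights: q^N configurations
  tm1 <- build_transfer_matrix(lattice_spec("filament"), energy_params())
  expect_equal(partition_open(tm1, 3), 8, tolerance = 1e-14)
  ## sigma -> 0, s = 2: only all-coil and all-sheet survive: 1 + 2^3 = 9
  p <- energy_params(P2 = log(2), R2 = 25)
  tm2 <- build_transfer_matrix(lattice_spec("filament"), p)
  expect_equal(partition_open(tm2, 3), 9, tolerance = 1e-6)
  ## seeded draws, both propagation placements, against enumeration
  set.seed(421)
  for (draw in 1:6) {
    pr <- random_params()
    for (mod in canonical_zoo[c(1, 5, 8)]) {
      tm <- build_transfer_matrix(mod$spec, pr)
      for (pl in c("site", "bond")) {
        zo <- partition_open(tm, mod$Lx, prop = pl)
        ze <- enumerate_partition(mod$spec, mod$Lx, pr, prop = pl)$Z
        expect_equal(zo, ze, tolerance = 1e-10)
      }
    }
  }
})

test_that("periodic partition equals the trace and its oracle, and approaches the eigenvalue limit", {
  tm1 <- build_transfer_matrix(lattice_spec("filament"), energy_params())
  expect_equal(partition_periodic(tm1, 4), 16, tolerance = 1e-14)
  p <- energy_params(P2 = log(2), R2 = -log(0.25) / 2)  # sigma2 = 0.25
  tm <- build_transfer_matrix(lattice_spec("filament"), p)
  expect_equal(partition_periodic(tm, 3),
               enumerate_partition(lattice_spec("filament"), 3, p,
                                   boundary = "periodic")$Z,
               tolerance = 1e-12)
  lam1 <- max(Re(eigen(tm$entries)$values))
  gap8 <- log(partition_periodic(tm, 8)) / 8 - log(lam1)
  gap16 <- log(partition_periodic(tm, 16)) / 16 - log(lam1)
  expect_lt(abs(gap16), abs(gap8))
  expect_lt(abs(log(partition_periodic(tm, 64)) / 64 - log(lam1)), 1e-10)
})

test_that("spectral decomposition reproduces matrix-power partitions", {
  set.seed(99)
  for (draw in 1:5) {
    p <- energy_params(P2 = runif(1, -1, 1), R2 = runif(1, 0.05, 1.5),
                       K = runif(1, -0.3, 0.3))
    tm <- build_transfer_matrix(lattice_spec("strip", Ly = 2), p)
    sd <- spectral_decompose(tm, "free")
    expect_false(sd$use_powers)
    expect_gt(Re(sd$values[1]), 0)
    for (Lx in c(1, 2, 5, 16)) {
      expect_equal(partition_spectral(sd, Lx), partition_open(tm, Lx),
                   tolerance = 1e-8)
    }
  }
})

test_that("one-directional and symmetric interface placements share a spectrum", {
  sigma <- 0.013; s <- 1.7
  fold <- amyloidtm:::.folding_tm(sigma, s)
  agg <- build_transfer_matrix(lattice_spec("filament"),
                               energy_params(P2 = log(s), R2 = -log(sigma) / 2))
  ev1 <- sort(Re(eigen(fold)$values))
  ev2 <- sort(Re(eigen(agg$entries)$values))
  expect_equal(ev1, ev2, tolerance = 1e-12)
})

test_that("log_derivative is exact on powers and matches closed forms and the oracle", {
  expect_equal(log_derivative(function(s) s^12, 2.7), 12, tolerance = 1e-9)
  ## thermodynamic-limit partition: d ln lambda1^N / d ln s at sigma = 1 is N s/(s+1)
  N <- 40
  d <- log_derivative(function(s) zb_partition_thermolimit(N, 1, s), 3)
  expect_equal(d, N * 3 / 4, tolerance = 1e-7)
  ## strip partition: s2-derivative equals the mean weighted sheet count
  p <- energy_params(P2 = 0.8, R2 = 0.3, B = 0.4, K = 0.1)
  spec <- lattice_spec("strip", Ly = 2)
  tm_of <- function(s2) build_transfer_matrix(spec, update_params(p, P2 = log(s2)))
  for (pl in c("site", "bond")) {
    d <- log_derivative(function(s2) partition_open(tm_of(s2), 5, prop = pl), p$s2)
    en <- enumerate_partition(spec, 5, p, prop = pl)$expectations
    want <- if (pl == "site") en$n_sheet else en$n_sheet_prop
    expect_equal(d, want, tolerance = 1e-7)
  }
})

test_that("log_derivative rejects non-positive fields", {
  expect_error(log_derivative(function(x) -x, 1), "positive")
  expect_error(log_derivative(function(x) x, -1), "positive")
})
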