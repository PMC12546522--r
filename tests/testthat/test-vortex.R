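rigid_rotation <- function(mesh, omega = 2)
  cbind(-omega * mesh$points[, 2], omega * mesh$points[, 1], 0)

test_that("velocity gradient is exact for affine fields", {
  b <- make_tet_ball(1, 0.3)
  g <- velocity_gradient(b, rigid_rotation(b, 3))
  expect_equal(g[, 1, 2], rep(-3, nrow(b$tets)), tolerance = 1e-12)
  expect_equal(g[, 2, 1], rep(3, nrow(b$tets)), tolerance = 1e-12)
  expect_equal(max(abs(c(g[, 1, 1], g[, 2, 2], g[, 3, 3]))), 0,
               tolerance = 1e-12)

  gc <- velocity_gradient(b, matrix(5, nrow(b$points), 3))
  expect_equal(max(abs(gc)), 0)
})

test_that("per-cell gradients converge O(h) for a quadratic field", {
  err <- vapply(c(0.3, 0.15, 0.075), function(h) {
    b <- make_tet_ball(1, h)
    u <- cbind(b$points[, 1]^2, 0 * b$points[, 1], 0 * b$points[, 1])
    g <- velocity_gradient(b, u)
    cent <- (b$points[b$tets[, 1], ] + b$points[b$tets[, 2], ] +
               b$points[b$tets[, 3], ] + b$points[b$tets[, 4], ]) / 4
    mean(abs(g[, 1, 1] - 2 * cent[, 1]))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2])
  expect_lt(err[3] / err[1], 0.5)       # at least first-order decay
})

test_that("Q-criterion has its closed-form values and lambda2 agrees", {
  b <- make_tet_ball(1, 0.3)
  omega <- 2.5
  g <- velocity_gradient(b, rigid_rotation(b, omega))
  expect_equal(q_values(g), rep(omega^2, nrow(b$tets)), tolerance = 1e-10)
  expect_true(all(vortex_core_mask(g, "Q", 0)))

  # pure shear: Q = 0 exactly, not masked at threshold 0
  shear <- cbind(1.3 * b$points[, 2], 0 * b$points[, 1], 0 * b$points[, 1])
  gs <- velocity_gradient(b, shear)
  expect_equal(max(abs(q_values(gs))), 0, tolerance = 1e-12)
  expect_false(any(vortex_core_mask(gs, "Q", 0)))

  # lambda2 agrees with Q on rigid rotation and shear
  expect_true(all(vortex_core_mask(g, "lambda2", 0)))
  expect_false(any(vortex_core_mask(gs, "lambda2", 0)))
  expect_error(vortex_core_mask(g, "lambda3"), "arg")
})

test_that("Q-mask matches the brute-force oracle cell-for-cell", {
  b <- make_tet_ball(1, 0.25)
  v <- make_vortex_velocity_series(
    b, blobs = list(list(center = c(0.2, -0.1, 0), sigma = 0.3, omega = 4)),
    phases = 2)
  vel <- v$field$values[, , 1]
  g <- velocity_gradient(b, vel)
  expect_identical(vortex_core_mask(g, "Q", 0), oracle_q_mask(b, vel, 0))
})

test_that("vortex volume sums masked cell volumes", {
  b <- make_tet_ball(1, 0.4)
  m <- nrow(b$tets)
  all_mask <- matrix(TRUE, m, 2)
  expect_equal(vortex_volume(all_mask, b)$vv, rep(total_volume(b), 2))
  expect_equal(vortex_volume(matrix(FALSE, m, 1), b)$vv, 0)

  # blob volume against a dense-grid point-count oracle
  sigma <- 0.25
  b2 <- make_tet_ball(1, sigma / 4)
  v <- make_vortex_velocity_series(
    b2, blobs = list(list(center = c(0, 0, 0), sigma = sigma, omega = 10)),
    phases = 2)
  g <- velocity_gradient(b2, v$field$values[, , 1])
  thr <- v$truth$suggested_q_threshold
  mask <- vortex_core_mask(g, "Q", thr)
  vv <- vortex_volume(matrix(mask, ncol = 1), b2)$vv
  # oracle: count dense grid points where analytic Q > thr
  gs <- seq(-1, 1, length.out = 161)
  gp <- as.matrix(expand.grid(gs, gs, gs))
  r2 <- rowSums(gp^2)
  z2 <- gp[, 3]^2
  alpha <- 2 - r2 / sigma^2
  bracket <- alpha^2 + 2 * alpha * z2 / sigma^2 +
    r2 * (2 * z2 - r2) / sigma^4
  qa <- 100 * exp(-r2 / sigma^2) * bracket / 4
  vol_oracle <- sum(qa > thr & r2 < 1) * (gs[2] - gs[1])^3
  expect_equal(vv, vol_oracle, tolerance = 0.10)
})

test_that("core counting honours adjacency, min_cells and NOC-STD", {
  b <- make_tet_ball(1, 0.15)
  thr <- 1
  two <- make_vortex_velocity_series(b, blobs = list(
    list(center = c(-0.45, 0, 0), sigma = 0.11, omega = 10),
    list(center = c(0.45, 0, 0), sigma = 0.11, omega = 10)), phases = 4)
  vs <- vortex_summary(two$field, threshold = two$truth$suggested_q_threshold)
  expect_equal(vs$noc, rep(2L, 4))
  expect_equal(vs$noc_std, 0)

  # alternating 1/2 cores over 20 phases -> population std 0.5
  # reuse the two face-connected components of the real field as mask atoms
  masks <- matrix(FALSE, nrow(b$tets), 20)
  g <- velocity_gradient(b, two$field$values[, , 1])
  m0 <- vortex_core_mask(g, "Q", two$truth$suggested_q_threshold)
  cc0 <- count_cores(matrix(m0, ncol = 1), b, min_cells = 5)
  lab <- cc0$labels[[1]]
  for (k in 1:20) masks[, k] <- if (k %% 2 == 1) lab == 1 else lab > 0
  cc <- count_cores(masks, b, min_cells = 5)
  expect_equal(cc$noc, rep(c(1L, 2L), 10))
  expect_equal(cc$noc_std, 0.5)
  # sample std by flag
  ccs <- count_cores(masks, b, min_cells = 5, sample = TRUE)
  expect_equal(ccs$noc_std, stats::sd(rep(c(1, 2), 10)))

  # min_cells filter removes small components
  tiny <- matrix(FALSE, nrow(b$tets), 1)
  tiny[which(lab == 1)[1:3], 1] <- TRUE
  expect_equal(count_cores(tiny, b, min_cells = 5)$noc, 0L)
  expect_gte(count_cores(tiny, b, min_cells = 0)$noc, 1L)
})

test_that("DVO covers identical, disjoint, shifted and empty masks", {
  b <- make_tet_ball(1, 0.3)
  m <- nrow(b$tets)
  a <- logical(m); a[1:100] <- TRUE
  d <- logical(m); d[201:300] <- TRUE
  sh <- logical(m); sh[51:150] <- TRUE

  same <- degree_of_overlap(cbind(a, a), b, cyclic = FALSE)
  expect_equal(same$dvo, 1)

  disj <- degree_of_overlap(cbind(a, d), b, cyclic = FALSE)
  expect_equal(disj$dvo, 0)

  # shifted: oracle volume bookkeeping
  vols <- b$cell_volumes
  expect_equal(degree_of_overlap(cbind(a, sh), b, cyclic = FALSE)$dvo,
               sum(vols[51:100]) / sum(vols[1:150]))
  # min normalization
  expect_equal(degree_of_overlap(cbind(a, sh), b, cyclic = FALSE,
                                 normalization = "min")$dvo,
               sum(vols[51:100]) / min(sum(vols[1:100]), sum(vols[51:150])))

  empty <- logical(m)
  both_empty <- degree_of_overlap(cbind(empty, empty), b, cyclic = FALSE)
  expect_equal(both_empty$dvo, 1)
  expect_equal(both_empty$flagged, 1L)
  one_empty <- degree_of_overlap(cbind(a, empty), b, cyclic = FALSE)
  expect_equal(one_empty$dvo, 0)

  # cyclic pairing yields P pairs, open chain P-1
  m3 <- cbind(a, a, a)
  expect_equal(length(degree_of_overlap(m3, b)$dvo), 3)
  expect_equal(length(degree_of_overlap(m3, b, cyclic = FALSE)$dvo), 2)
})

test_that("outputs are frame-independent and Galilean-invariant", {
  b <- make_tet_ball(1, 0.2)
  v <- make_vortex_velocity_series(
    b, blobs = list(list(center = c(0.1, 0, 0), sigma = 0.3, omega = 6)),
    phases = 3)
  vs <- vortex_summary(v$field, threshold = 0.5)

  # uniform translation added to every phase: identical summary
  vals <- v$field$values
  vals[, 1, ] <- vals[, 1, ] + 0.7
  vs_g <- vortex_summary(field_series(b, vals, units = "m/s"),
                         threshold = 0.5)
  expect_identical(vs_g$core_masks, vs$core_masks)
  expect_equal(vs_g$vv, vs$vv)

  # rigid rotation of mesh + velocity: Q values unchanged
  th <- 0.5
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  br <- volume_mesh(b$points %*% t(R), b$tets)
  q0 <- q_values(velocity_gradient(b, v$field$values[, , 1]))
  q1 <- q_values(velocity_gradient(br, v$field$values[, , 1] %*% t(R)))
  expect_equal(q1, q0, tolerance = 1e-10)
})

test_that("steady series gives DVO 1 everywhere; displacement lowers DVO", {
  b <- make_tet_ball(1, 0.2)
  steady <- make_vortex_velocity_series(
    b, blobs = list(list(center = c(0, 0, 0), sigma = 0.3, omega = 6)),
    phases = 5)
  vs <- vortex_summary(steady$field,
                       threshold = steady$truth$suggested_q_threshold)
  expect_equal(vs$dvo, rep(1, 5))
  expect_equal(vs$noc_std, 0)

  mean_dvo_at_step <- function(step) {
    mv <- make_vortex_velocity_series(
      b, blobs = list(list(
        center = function(t) c(step * t * 5, 0, 0),   # 5 phases, step per phase
        sigma = 0.3, omega = 6)),
      phases = 5)
    vortex_summary(mv$field, threshold = mv$truth$suggested_q_threshold,
                   cyclic = FALSE)$mean_dvo
  }
  dvos <- vapply(c(0, 0.05, 0.1, 0.15), mean_dvo_at_step, numeric(1))
  expect_true(all(diff(dvos) <= 1e-12))
})
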