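test_that("relative displacements follow the stacking definition", {
  ref <- as_reference(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
                      element = rep("C", 3))
  nb <- manual_neighborhood(ref, 1L, c(2L, 3L))
  frame <- ref$xyz + rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0))
  expect_equal(displacements(ref, frame, nb), c(1, 0, 0, 0, 2, 0))
  # frame = reference, and reference + global translation, both give zero
  expect_equal(displacements(ref, ref$xyz, nb), rep(0, 6))
  shifted <- sweep(frame, 2L, c(3, -1, 2), "+")
  expect_equal(displacements(ref, shifted, nb),
               displacements(ref, frame, nb))
})

test_that("projection operator is a symmetric idempotent annihilating R", {
  ref <- make_reference("cloud", n_atoms = 150, seed = 8)
  nb <- build_neighborhood(ref, 3, k = 20)
  P <- build_projection(nb)
  expect_lt(max(abs(P - t(P))), 1e-12)
  expect_lt(max(abs(P %*% P - P)), 1e-10)
  expect_lt(max(abs(P %*% nb$R)), 1e-10)
  expect_equal(sum(diag(P)), 3 * 20 - 9, tolerance = 1e-10)
  # P annihilates R vec(D0) for arbitrary D0
  D0 <- matrix(rnorm(9, sd = 0.3), 3, 3)
  aff <- nb$R %*% as.vector(t(D0))
  expect_lt(max(abs(P %*% aff)), 1e-10 * max(1, max(abs(aff))))
})

test_that("chi vanishes on affine fields and recovers planted residuals", {
  ref <- make_reference("cloud", n_atoms = 200, seed = 4)
  nb <- build_neighborhood(ref, 10, k = 25)
  P <- build_projection(nb)
  D0 <- rotation_matrix(35, 1) - diag(3) + 0.04
  delta_aff <- drop(nb$R %*% as.vector(t(D0)))
  expect_lt(chi_projected(delta_aff, P), 1e-10 * sum(delta_aff^2))
  expect_equal(chi_projected(rep(0, 3 * nb$n), P), 0)
  # additivity: for delta = affine + perp with R^T perp = 0,
  # chi equals |perp|^2 exactly
  set.seed(31)
  perp <- drop(P %*% rnorm(3 * nb$n))
  expect_lt(max(abs(crossprod(nb$R, perp))), 1e-10)
  delta <- delta_aff + perp
  expect_equal(chi_projected(delta, P), sum(perp^2), tolerance = 1e-10)
  expect_error(chi_projected(rep(0, 5), P), "dimension mismatch")
})

test_that("direct least-squares fit recovers the deformation matrix", {
  ref <- make_reference("cloud", n_atoms = 200, seed = 4)
  nb <- build_neighborhood(ref, 10, k = 25)
  D0 <- matrix(c(0.02, -0.01, 0, 0.01, 0.03, 0.005, 0, 0, -0.02), 3, 3)
  delta <- drop(nb$R %*% as.vector(t(D0)))
  fit <- chi_direct(delta, nb)
  expect_equal(fit$D, D0, tolerance = 1e-8)
  expect_lt(fit$residual, 1e-10)
  # a globally rotated frame is affine: residual ~ 0 and D + I is the rotation
  Rot <- rotation_matrix(20, 3)
  frame <- ref$xyz
  ctr <- ref$xyz[nb$center, ]
  frame <- sweep(sweep(frame, 2L, ctr) %*% t(Rot), 2L, ctr, "+")
  d_rot <- displacements(ref, frame, nb)
  fit_rot <- chi_direct(d_rot, nb)
  expect_lt(fit_rot$residual, 1e-10 * sum(d_rot^2))
  expect_equal(fit_rot$D + diag(3), Rot, tolerance = 1e-8)
})

test_that("projection and minimisation routes agree over random instances", {
  ref <- make_reference("cloud", n_atoms = 300, seed = 6)
  set.seed(99)
  for (rep in 1:20) {
    nb <- build_neighborhood(ref, sample(300, 1), k = sample(12:40, 1))
    P <- build_projection(nb)
    delta <- rnorm(3 * nb$n)
    cp <- chi_projected(delta, P)
    cd <- chi_direct(delta, nb)$residual
    expect_lt(abs(cp - cd), 1e-8 * cp)
  }
})

test_that("grid search around the optimum never beats the normal equations", {
  ref <- make_reference("cloud", n_atoms = 150, seed = 5)
  nb <- build_neighborhood(ref, 4, k = 15)
  set.seed(12)
  delta <- rnorm(3 * nb$n, sd = 0.5)
  fit <- chi_direct(delta, nb)
  for (rep in 1:50) {
    Dtry <- fit$D + matrix(rnorm(9, sd = 0.05), 3, 3)
    resid_try <- sum((delta - nb$R %*% as.vector(t(Dtry)))^2)
    expect_gte(resid_try, fit$residual - 1e-12)
  }
})

test_that("chi is invariant under rigid motions and member permutation", {
  ref <- make_reference("cloud", n_atoms = 200, seed = 14)
  nb <- build_neighborhood(ref, 17, k = 22)
  P <- build_projection(nb)
  set.seed(3)
  frame <- ref$xyz + matrix(rnorm(nrow(ref$xyz) * 3, sd = 0.3), ncol = 3)
  chi0 <- chi_projected(displacements(ref, frame, nb), P)
  Rot <- rotation_matrix(73, 2) %*% rotation_matrix(-21, 1)
  moved <- sweep(frame %*% t(Rot), 2L, c(5, -3, 9), "+")
  chi1 <- chi_projected(displacements(ref, moved, nb), P)
  expect_lt(abs(chi1 - chi0), 1e-8 * chi0)
  # permuted member order with consistently rebuilt R gives identical chi
  perm <- sample(nb$n)
  nb_p <- manual_neighborhood(ref, nb$center, nb$members[perm])
  chi2 <- chi_direct(displacements(ref, frame, nb_p), nb_p)$residual
  expect_lt(abs(chi2 - chi0), 1e-8 * chi0)
})

test_that("cached-projection chi series matches frame-by-frame evaluation", {
  ref <- make_reference("cloud", n_atoms = 120, seed = 21)
  nb <- build_neighborhood(ref, 8, k = 15)
  P <- build_projection(nb)
  ens <- mode_ensemble(ref, list(planted_mode(nb, amp = 0.5, seed = 2)),
                       noise_sigma = 0.1, T = 12, seed = 7)
  series <- chi_series(ref, ens, nb, P)
  direct <- vapply(seq_len(12), function(t) {
    chi_projected(displacements(ref, frame_coords(ens, t), nb), P)
  }, numeric(1))
  expect_identical(series, direct)
})

test_that("ill-conditioned neighborhoods are refused by the projector", {
  # nearly planar cloud: tiny z spread makes R^T R ill-conditioned
  set.seed(2)
  xyz <- cbind(matrix(runif(40, 0, 10), ncol = 2), runif(20, 0, 1e-4))
  ref <- as_reference(xyz, element = rep("C", 20))
  nb <- build_neighborhood(ref, 1, radius = 30, min_size = 5)
  expect_error(build_projection(nb), "ill-conditioned")
})
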