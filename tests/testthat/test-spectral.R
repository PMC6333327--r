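test_that("correlator matches hand computations and the iid limit", {
  expect_error(correlator(matrix(1, 6, 1)), "at least 2 frames")
  # all frames at the reference: C = 0
  ref <- make_reference("cloud", n_atoms = 100, seed = 2)
  nb <- build_neighborhood(ref, 1, k = 12)
  ens <- as_ensemble(array(rep(ref$xyz, each = 3),
                           dim = c(3, ref$natoms, 3)))
  Dm <- sapply(1:3, function(t) displacements(ref, frame_coords(ens, t), nb))
  expect_equal(max(abs(correlator(Dm))), 0)
  # two frames delta and -delta: C = delta delta^T
  set.seed(4)
  d <- rnorm(36)
  C <- correlator(cbind(d, -d))
  expect_equal(unclass(C), tcrossprod(d), ignore_attr = TRUE)
  # iid N(0, sigma^2): diagonal mean within 3 SE of sigma^2 at T = 10 dim
  dim <- 36L; Tn <- 360L; sig <- 0.7
  Cn <- correlator(gaussian_deltas(dim, Tn, sig, seed = 8))
  se <- sig^2 * sqrt(2 / Tn) / sqrt(dim)  # SE of the mean of dim diagonals
  expect_lt(abs(mean(diag(Cn)) - sig^2), 3 * se)
})

test_that("PCP spectrum has the closed form for isotropic C", {
  ref <- make_reference("cloud", n_atoms = 150, seed = 3)
  nb <- build_neighborhood(ref, 2, k = 20)
  P <- build_projection(nb)
  sig2 <- 0.49
  C <- structure(diag(sig2, 60), class = c("nap_correlator", "matrix"),
                 n_frames = 100L)
  sp <- pcp_spectrum(P, C)
  # sigma^2 with multiplicity 3n - 9, zero with multiplicity 9
  expect_equal(sp$values[1:51], rep(sig2, 51), tolerance = 1e-10)
  expect_lt(max(abs(sp$values[52:60])), 1e-10)
  expect_equal(sp$n_zero, 9L)
  expect_lt(sp$gap, 1e-10)
  expect_lt(max(abs(crossprod(sp$vectors) - diag(60))), 1e-8)
})

test_that("rank-1 injected mode gives a pure gap and is recovered exactly", {
  ref <- make_reference("cloud", n_atoms = 150, seed = 3)
  nb <- build_neighborhood(ref, 2, k = 20)
  P <- build_projection(nb)
  e <- planted_mode(nb, seed = 6)
  ev <- as.vector(t(e$field))
  a2 <- 2.5
  C <- structure(a2 * tcrossprod(ev), class = c("nap_correlator", "matrix"),
                 n_frames = 100L)
  sp <- pcp_spectrum(P, C)
  expect_equal(sp$values[1], a2, tolerance = 1e-10)
  expect_lt(max(abs(sp$values[-1])), 1e-10)
  expect_equal(sp$gap, 1, tolerance = 1e-10)
  mode <- dominant_mode(sp, nb)
  expect_gte(mode_overlap(mode, e$field), 0.999)
})

test_that("eigenvalue sum equals the time-averaged chi (trace identity)", {
  ref <- make_reference("cloud", n_atoms = 200, seed = 11)
  nb <- build_neighborhood(ref, 6, k = 30)
  P <- build_projection(nb)
  ens <- mode_ensemble(ref, list(planted_mode(nb, amp = 0.4, seed = 1)),
                       noise_sigma = 0.15, T = 60, seed = 9)
  Dm <- sapply(seq_len(60),
               function(t) displacements(ref, frame_coords(ens, t), nb))
  sp <- pcp_spectrum(P, correlator(Dm))
  mean_chi <- mean(chi_series(ref, ens, nb, P))
  expect_lt(abs(sum(sp$values) - mean_chi), 1e-8 * mean_chi)
  # affine annihilation holds for sampled C too
  expect_lt(sp$values[length(sp$values) - 8], 1e-10 * sp$values[1])
})

test_that("dominant mode recovery and degeneracy flagging behave", {
  ref <- make_reference("cloud", n_atoms = 250, seed = 13)
  nb <- build_neighborhood(ref, 9, k = 40)
  P <- build_projection(nb)
  e <- planted_mode(nb, amp = 1, seed = 17)
  ens <- mode_ensemble(ref, list(e), noise_sigma = 0.1, T = 500, seed = 18)
  Dm <- sapply(seq_len(500),
               function(t) displacements(ref, frame_coords(ens, t), nb))
  sp <- pcp_spectrum(P, correlator(Dm))
  mode <- dominant_mode(sp, nb)
  expect_gte(mode_overlap(mode, e$field), 0.9)
  expect_false(attr(mode, "degenerate"))
  # flat spectrum: degenerate top pair is flagged
  Cflat <- structure(diag(1, 3 * nb$n), class = c("nap_correlator", "matrix"),
                     n_frames = 10L)
  spf <- pcp_spectrum(P, Cflat)
  expect_warning(dominant_mode(spf, nb), "degenerate")
})

test_that("isotropic-noise gap shrinks as the ensemble grows", {
  ref <- make_reference("cloud", n_atoms = 200, seed = 23)
  sites <- c(3, 50, 120)
  gap_at <- function(T) {
    vapply(sites, function(a) {
      nb <- build_neighborhood(ref, a, k = 25)
      P <- build_projection(nb)
      del <- gaussian_deltas(3 * nb$n, T, sigma = 0.2, seed = 1000 + a + T)
      pcp_spectrum(P, correlator(del))$gap
    }, numeric(1))
  }
  expect_lt(median(gap_at(1000)), median(gap_at(50)))
})

test_that("Marchenko-Pastur fit matches a Wishart null and flags spikes", {
  ref <- make_reference("cloud", n_atoms = 400, seed = 7)
  nb <- build_neighborhood(ref, 1, k = 53)   # non-affine dim 150
  P <- build_projection(nb)
  del <- gaussian_deltas(3 * nb$n, 600, seed = 11)
  C <- correlator(del)
  sp <- pcp_spectrum(P, C)
  fit <- mp_fit(sp, 600)
  expect_equal(fit$q, 150 / 600)
  expect_lt(fit$ks_stat, 0.08)
  # spike 50x above the MP edge is flagged outside the support
  e <- as.vector(t(planted_mode(nb, seed = 5)$field))
  C2 <- structure(C + (50 * fit$lambda_plus) * tcrossprod(e),
                  class = class(C), n_frames = 600L)
  sp2 <- pcp_spectrum(P, C2)
  fit2 <- mp_fit(sp2, 600)
  expect_true(1L %in% fit2$outliers)
  expect_gt(sp2$values[1], fit2$lambda_plus)
})

test_that("a point-mass spectrum is far from the MP law", {
  # all non-zero eigenvalues equal, q = 0.25: KS distance is large
  sp <- list(values = c(rep(1, 40), rep(0, 9)), n_frames = 160L)
  class(sp) <- "nap_spectrum"
  fit <- mp_fit(sp)
  expect_gt(fit$ks_stat, 0.3)
  # q >= 1 still returns a fit, with a point-mass warning
  expect_warning(mp_fit(sp, n_frames = 20L), "point mass")
})
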