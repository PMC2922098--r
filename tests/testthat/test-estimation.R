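test_that("linear interpolation and forward-difference derivatives behave", {
  f <- interpolate_fixed(c(0, 1), c(0, 100))
  expect_equal(f$value(0.5), 50)
  expect_equal(f$deriv(0.2), 100)
  g <- interpolate_fixed(0:5, rep(7, 6))
  expect_equal(g$value(2.3), 7)
  expect_equal(g$deriv(2.3), 0)
  lin <- interpolate_fixed(0:5, 3 * (0:5) + 2)
  expect_equal(lin$value(c(0.1, 2.7, 4.9)), 3 * c(0.1, 2.7, 4.9) + 2)
  expect_equal(lin$deriv(c(0.1, 4.9)), c(3, 3))
  expect_error(interpolate_fixed(1, 1), "two time points")
})

test_that("monomer data inversion is consistent with the forward totals map", {
  set.seed(13)
  mono <- array(10^stats::runif(6 * 4 * 3, 0, 3), c(6, 4, 3))
  tot <- mono
  for (w in 1:4) for (d in 1:3)
    tot[, w, d] <- totals_from_monomers(mono[, w, d], ref_topology)
  back <- monomer_data(tot, ref_topology)
  expect_equal(back, mono, tolerance = 1e-8)
  expect_true(all(back <= tot + 1e-9))  # dimer-bound content is non-negative
  tiny <- sparse_gamma_topology()
  expect_equal(monomer_data(tot, tiny), tot, tolerance = 1e-8)
})

test_that("Km initialization follows the half-maximal sensitivity rule", {
  typ <- stats::setNames(c(500, 100, 100, 200, 50, 400), FLORAL_GENES)
  km0 <- initialize_km(typ, ref_topology)
  env <- floralfate:::topology_env(ref_topology)
  D <- floralfate:::qss_dimer_vec(typ, env)
  # SHP's single activator slot is [AG SEP]
  expect_equal(unname(km0$SHP[1]),
               min(max(D[match("AG:SEP", FLORAL_DIMERS)], 10), 1e3))
  # clipping at the nominal lower bound
  km_small <- initialize_km(stats::setNames(rep(1, 6), FLORAL_GENES), ref_topology)
  expect_true(all(unlist(km_small) >= 10))
  # a Michaelis-Menten term is maximally Km-sensitive at input = Km
  km <- 200
  mm <- function(a, k) a / (k + a)
  dmm_dk <- function(a) (mm(a, km + 0.01) - mm(a, km - 0.01)) / 0.02
  grid <- 10^seq(0, 4, 0.1)
  sens <- abs(vapply(grid, dmm_dk, numeric(1)))
  expect_equal(max(sens), 1 / (4 * km), tolerance = 1e-3)
  expect_equal(grid[which.max(sens)], km, tolerance = 0.1)
})

test_that("each decoupled objective depends only on its own gene's parameters", {
  grid <- generate_truth(synthetic_config(sigma = 0, sampling_days = 0:5))
  mono <- monomer_data(grid)
  pb <- estimation_problem("AP1", mono)
  r0 <- floralfate:::decoupled_residuals(pb, ref_params)
  perturbed <- ref_params
  perturbed$beta$SEP <- perturbed$beta$SEP * 2
  perturbed$dc["PI"] <- perturbed$dc["PI"] * 3
  r1 <- floralfate:::decoupled_residuals(pb, perturbed)
  expect_identical(r0, r1)
})

test_that("a decoupled equation refits data generated by itself", {
  grid <- generate_truth(synthetic_config(sigma = 0))
  mono <- monomer_data(grid)
  pb <- estimation_problem("SHP", mono)
  # replace SHP's data by the decoupled equation's own solution at truth
  for (w in 1:4)
    pb$monomers[5, w, ] <- floralfate:::integrate_decoupled(pb, ref_params, w)
  pb2 <- estimation_problem("SHP", pb$monomers)
  r <- floralfate:::decoupled_residuals(pb2, ref_params)
  expect_lt(sum(r^2), 1e-6 * sum(pb2$monomers[5, , -1]^2))
})

test_that("a perturbed start recovers the SHP trajectory", {
  grid <- generate_truth(synthetic_config(sigma = 0))
  mono <- monomer_data(grid)
  pb <- estimation_problem("SHP", mono)
  init <- gene_free_params(perturb_params(ref_params, factor = 3, seed = 21), "SHP")
  fit <- fit_equation(pb, init = init, restarts = 1, seed = 21, maxiter = 60)
  expect_true(all(abs(fit$epsilon) <= 0.05))
  expect_gte(fit$objective, 0)
})

test_that("fitting is deterministic under a fixed seed", {
  grid <- generate_truth(synthetic_config(sigma = 0))
  mono <- monomer_data(grid)
  pb <- estimation_problem("SEP", mono)
  init <- gene_free_params(ref_params, "SEP")
  f1 <- suppressWarnings(fit_equation(pb, init = init, restarts = 1, seed = 5, maxiter = 5))
  f2 <- suppressWarnings(fit_equation(pb, init = init, restarts = 1, seed = 5, maxiter = 5))
  expect_identical(f1$params_vector, f2$params_vector)
})
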