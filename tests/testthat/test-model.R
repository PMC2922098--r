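test_that("production vanishes without activating dimers and saturates under repression", {
  zero <- stats::setNames(rep(0, 7), FLORAL_DIMERS)
  for (g in FLORAL_GENES)
    expect_equal(production_rate(g, zero, ref_params, ref_topology), 0)
  # half-maximal activation identity for the single-activator gene SHP
  half <- production_rate("SHP",
                          c("AG:SEP" = ref_params$km$SHP[1], "AP3:PI" = 0),
                          ref_params, ref_topology)
  expect_equal(half, ref_params$beta$SHP / 2)
  expect_equal(half, 2.05e2)
  # full repression limit
  crushed <- production_rate("SHP", c("AG:SEP" = 1e9, "AP3:PI" = 1e12),
                             ref_params, ref_topology)
  expect_lt(crushed, 1e-6 * ref_params$beta$SHP)
  expect_error(production_rate("SHP", c("AG:SEP" = 1), ref_params, ref_topology),
               "missing dimer")
  expect_error(production_rate("XXX", zero), "unknown gene")
})

test_that("triggers act only on their genes, whorls and window", {
  sch <- trigger_schedule()
  expect_equal(trigger_input("AP3", 1.5, 3, sch, ref_params), 4.5e4)
  expect_equal(trigger_input("AP3", 1.5, 2, sch, ref_params), 4.5e4)
  expect_equal(trigger_input("AG", 1.5, 4, sch, ref_params), 3.4e3)
  expect_equal(trigger_input("AP3", 2.5, 3, sch, ref_params), 0)  # window closed
  expect_equal(trigger_input("AP3", 2.0, 3, sch, ref_params), 0)  # half-open
  expect_equal(trigger_input("AP3", 1.5, 1, sch, ref_params), 0)  # wrong whorl
  expect_equal(trigger_input("AG", 1.5, 2, sch, ref_params), 0)
  expect_equal(trigger_input("AP1", 1.5, 3, sch, ref_params), 0)  # no trigger
})

test_that("the origin is a fixed point of the coupled model outside the trigger window", {
  z <- rep(0, 13)
  expect_equal(unname(coupled_rhs(z, t = 0.5, whorl = 3)), rep(0, 13))
  expect_equal(unname(coupled_rhs(z, t = 3.0, whorl = 3)), rep(0, 13))
  # during the window the triggered genes are produced
  d <- coupled_rhs(z, t = 1.5, whorl = 3)
  expect_equal(unname(d[2]), ref_params$p2)
  expect_equal(unname(d[4]), ref_params$p4)
  expect_error(coupled_rhs(rep(-1, 13), 0, 1), "negative")
})

test_that("dimer kinetics relax to the affinity equilibrium", {
  # monomers nearly frozen (inert production/decay), dimers start at zero:
  # each dimer converges to gamma * xi * xj
  p <- inert_params()
  x0 <- c(200, 150, 100, 50, 25, 300)
  out <- simulate_full(c(x0, rep(0, 7)), times = c(0, 0.05, 0.5), whorl = 1,
                       params = p, koff = 1440)
  D_end <- out[nrow(out), 8:14]
  env <- floralfate:::topology_env(ref_topology)
  x_end <- out[nrow(out), 2:7]
  expect_equal(unname(D_end), unname(floralfate:::qss_dimer_vec(x_end, env)),
               tolerance = 1e-4)
})

test_that("total gene content is conserved when production and decay are off", {
  p <- inert_params()
  x0 <- c(200, 150, 100, 50, 25, 300)
  out <- simulate_full(c(x0, rep(0, 7)), times = seq(0, 1, 0.25), whorl = 2,
                       params = p, koff = 1440, rtol = 1e-10, atol = 1e-10)
  env <- floralfate:::topology_env(ref_topology)
  totals <- apply(out, 1, function(row) {
    x <- row[2:7]; D <- row[8:14]
    tot <- x
    for (k in 1:7) {
      s <- if (env$homo[k]) 2 else 1
      tot[env$i1[k]] <- tot[env$i1[k]] + s * D[k]
      if (!env$homo[k]) tot[env$i2[k]] <- tot[env$i2[k]] + D[k]
    }
    tot
  })
  for (i in 1:6)
    expect_equal(unname(totals[i, ]), rep(unname(totals[i, 1]), ncol(totals)),
                 tolerance = 1e-7)
})

test_that("with negligible dimerization the monomers decay exponentially", {
  topo <- sparse_gamma_topology()
  p <- floral_params(beta = lapply(ref_params$beta, function(b) b * 0 + 1e-12),
                     km = ref_params$km, dc = ref_params$dc, p2 = 1e-12, p4 = 1e-12)
  x0 <- c(500, 400, 300, 200, 100, 600)
  tt <- seq(0, 0.1, 0.02)
  out <- simulate_full(c(x0, rep(0, 7)), times = tt, whorl = 1,
                       topology = topo, params = p, rtol = 1e-10, atol = 1e-10)
  for (i in 1:6)
    expect_equal(out[, 1 + i], x0[i] * exp(-ref_params$dc[i] * tt),
                 tolerance = 1e-6)
})

test_that("a zero state with no triggers stays zero", {
  out <- simulate_full(rep(0, 13), times = 0:5, whorl = 1)
  expect_equal(max(abs(out[, -1])), 0)
})
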