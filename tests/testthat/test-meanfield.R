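# Mean-field theory: transfer function, input moments, self-consistent
# solutions with and without quenched disorder, and coupling matching.

test_that("transfer function is bounded, monotone and numerically stable", {
  np <- neuron_params()
  r <- transfer_rate(seq(-500, 200, by = 5), 8, np$tau_m_E, np$V_r_E,
                     np$V_th_E, np$tau_ref_E, np$tau_syn_E)
  expect_true(all(r >= 0))
  expect_true(all(r < 1 / np$tau_ref_E))
  expect_true(all(diff(r) >= 0))
  expect_lt(r[1], 1e-10)
  expect_error(transfer_rate(10, -1, np$tau_m_E, np$V_r_E, np$V_th_E,
                             np$tau_ref_E, np$tau_syn_E), "sigma")
})

test_that("the closed-form transfer integral matches direct quadrature", {
  # the tabulated/exact decomposition against composite Gauss-Legendre
  set.seed(2)
  for (k in 1:20) {
    lo <- runif(1, -12, 2)
    hi <- lo + runif(1, 0.1, 6)
    hi <- min(hi, 4)
    if (hi <= lo) next
    quad <- arousalnet:::.erfcx_integral(lo, hi)
    cf <- arousalnet:::.erfcx_cum(hi) - arousalnet:::.erfcx_cum(lo)
    expect_lt(abs(quad - cf) / abs(quad), 1e-8)
  }
})

test_that("input moments reduce correctly in degenerate cases", {
  arch <- tiny_arch()
  npop <- 2 * (arch$p + 1)
  m0 <- mft_input_moments(rep(0, npop), arch)
  isE <- m0$pops$alpha == "E"
  expect_equal(unname(m0$mu[isE]),
               rep(arch$C_ext_E * arch$J_ext_E * arch$nu_o_E, sum(isE)))
  # Jplus = J and a uniform rate vector: identical mu across populations of
  # the same type
  arch0 <- tiny_arch(Jplus_ratio = 1)
  m1 <- mft_input_moments(rep(c(3, 8), each = arch0$p + 1), arch0)
  expect_lt(diff(range(m1$mu[isE])), 1e-10)
  expect_error(mft_input_moments(rep(0, 3), arch), "length")
})

test_that("input moments match the ensemble average of realized networks", {
  arch <- random_exact_arch(3)  # integer-exact class counts
  neuron <- neuron_params()
  set.seed(4)
  p <- arch$p
  rates <- c(runif(p + 1, 1, 30), runif(p + 1, 2, 20))
  m <- mft_input_moments(rates, arch)
  # per-cell rate vector from population rates
  acc <- NULL
  n_draws <- 8
  for (k in seq_len(n_draws)) {
    inst <- build_clustered(arch, neuron, seed = 100 + k)
    pop_idx <- ifelse(inst$pop == "E", 0, p + 1) + inst$cluster_of
    nu_cell <- rates[pop_idx]
    W <- weight_matrix(inst)
    mu_cells <- drop(W %*% nu_cell) +
      ifelse(inst$pop == "E", arch$C_ext_E * arch$J_ext_E * arch$nu_o_E,
             arch$C_ext_I * arch$J_ext_I * arch$nu_o_I)
    # average within each (alpha, gamma) population
    mu_pop <- tapply(mu_cells, pop_idx, mean)
    acc <- if (is.null(acc)) mu_pop else acc + mu_pop
  }
  emp <- acc / n_draws
  # scale-relative tolerance (some population means sit near zero through
  # excitation/inhibition cancellation; subgroup rounding adds a small
  # systematic offset)
  expect_lt(max(abs(emp - m$mu)) / max(abs(m$mu)), 0.02)
})

test_that("the uniform state is self-consistent and residuals re-evaluate", {
  cfg <- default_config("reduced")
  sol <- solve_mft(cfg$arch, cfg$neuron, nA = 0)
  expect_identical(sol$state_kind, "uniform")
  expect_lt(sol$residual, 1e-8)
  expect_lt(diff(range(sol$rates[seq_len(cfg$arch$p)])), 1e-8)
  # independent re-evaluation of the fixed point
  m <- mft_input_moments(sol$rates, cfg$arch)
  pn <- arousalnet:::.pop_neuron(cfg$neuron, m$pops)
  out <- arousalnet:::.phi_all(m$mu, m$sigma2, pn)
  expect_lt(max(abs(out - sol$rates)), 1e-8)
  expect_true(all(sol$rates >= 0 &
                    sol$rates <= 1 / cfg$neuron$tau_ref_E))
})

test_that("cluster states exist only above a critical intracluster coupling", {
  cfg <- default_config("reduced")
  weak <- cfg$arch; weak$Jplus["E", "E"] <- weak$J["E", "E"] * 2
  s_weak <- solve_mft(weak, cfg$neuron, nA = 1)
  expect_identical(s_weak$state_kind, "not_found")
  strong <- cfg$arch; strong$Jplus["E", "E"] <- strong$J["E", "E"] * 10
  s_strong <- solve_mft(strong, cfg$neuron, nA = 1)
  expect_identical(s_strong$state_kind, "cluster_state")
  expect_gt(s_strong$nu_up, s_strong$nu_down)
  expect_lt(s_strong$residual, 1e-8)
})

test_that("quenched theory reduces to the plain theory at dH = 0", {
  cfg <- default_config("reduced")
  plain <- solve_mft(cfg$arch, cfg$neuron, nA = 1, nu_high = 40)
  quen <- solve_quenched_mft(cfg$arch, cfg$neuron, dH_E = 0, nA = 1,
                             nu_high = 40)
  expect_lt(max(abs(plain$rates - quen$rates)), 1e-6)
  expect_lt(max(quen$s2), 1e-10)
})

test_that("increasing heterogeneity narrows and then removes cluster states", {
  cfg <- default_config("reduced")
  arch <- cfg$arch
  arch$Jplus["E", "E"] <- arch$J["E", "E"] * 10
  sols <- lapply(c(0, 0.15, 0.5), function(dh)
    solve_quenched_mft(arch, cfg$neuron, dH_E = dh, nA = 1, nu_high = 60))
  kinds <- vapply(sols, function(s) s$state_kind, character(1))
  expect_identical(kinds[1], "cluster_state")
  if (kinds[2] == "cluster_state") {
    expect_lt(sols[[2]]$nu_up, sols[[1]]$nu_up)
    expect_gt(sols[[2]]$nu_down, sols[[1]]$nu_down)
  }
  expect_false(kinds[3] == "cluster_state")
  # uniform branch still solvable there
  u <- solve_quenched_mft(arch, cfg$neuron, dH_E = 0.5, nA = 0)
  expect_identical(u$state_kind, "uniform")
})

test_that("quenched Gaussian integrals are converged in the node count", {
  # the Gaussian averages themselves at fixed inputs
  np <- neuron_params()
  gauss_moments <- function(n_quad, mu_bar, Delta, sig) {
    gh <- pracma::gaussHermite(n_quad)
    z <- sqrt(2) * gh$x
    w <- gh$w / sqrt(pi)
    r <- transfer_rate(mu_bar + Delta * z, sig, np$tau_m_E, np$V_r_E,
                       np$V_th_E, np$tau_ref_E, np$tau_syn_E)
    c(sum(w * r), sum(w * r^2))
  }
  for (pars in list(c(60, 10, 7), c(75, 20, 9))) {
    m40 <- gauss_moments(40, pars[1], pars[2], pars[3])
    m80 <- gauss_moments(80, pars[1], pars[2], pars[3])
    expect_lt(abs(m40[1] - m80[1]) / m80[1], 1e-6)
    expect_lt(abs(m40[2] - m80[2]) / m80[2], 1e-5)
  }
  # the self-consistent solutions also agree closely; near-critical
  # fixed points amplify the ~1e-6 quadrature error through their
  # susceptibility, so the comparison is at the rate scale
  cfg <- default_config("reduced")
  s40 <- solve_quenched_mft(cfg$arch, cfg$neuron, dH_E = 0.1, nA = 1,
                            nu_high = 40, n_quad = 40)
  s80 <- solve_quenched_mft(cfg$arch, cfg$neuron, dH_E = 0.1, nA = 1,
                            nu_high = 40, n_quad = 80)
  expect_lt(max(abs(s40$rates - s80$rates)), 0.05)
})

test_that("coupling matching returns the grid argmin and flags empty grids", {
  cfg <- default_config("reduced")
  arch <- cfg$arch
  # build a small reference: MFT rate at a known coupling
  ref_c <- arch$J["E", "E"] * 10
  aref <- arch; aref$Jplus["E", "E"] <- ref_c
  ref <- solve_mft(aref, cfg$neuron, nA = 1)
  grid <- arch$J["E", "E"] * c(8, 9, 10, 11)
  m <- match_intracluster_coupling(ref$nu_up, arch, cfg$neuron,
                                   coupling_grid = grid, nA_star = 1)
  expect_equal(m$Jplus_mft, ref_c)
  # refining the grid moves the match by at most one coarse step
  grid2 <- arch$J["E", "E"] * seq(8, 11, by = 0.25)
  m2 <- match_intracluster_coupling(ref$nu_up, arch, cfg$neuron,
                                    coupling_grid = grid2, nA_star = 1)
  expect_lt(abs(m2$Jplus_mft - m$Jplus_mft), arch$J["E", "E"] * 1 + 1e-12)
  none <- match_intracluster_coupling(30, arch, cfg$neuron,
                                      coupling_grid = arch$J["E", "E"] * 2,
                                      nA_star = 1)
  expect_true(is.na(none$Jplus_mft))
})
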