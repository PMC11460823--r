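# Mean-field theory for clustered E/I networks of LIF neurons with
# exponential synapses, under the diffusion approximation. Populations are
# indexed (alpha, gamma): alpha in {E, I}, gamma in 1..p for clusters and
# p+1 for the unclustered background, ordered E1..E(p+1), I1..I(p+1).

# synaptic correction constant a = -zeta(1/2)/2
.mft_a <- 0.730177254404794

pop_table <- function(p) {
  data.frame(alpha = rep(c("E", "I"), each = p + 1),
             gamma = rep(seq_len(p + 1), 2),
             stringsAsFactors = FALSE)
}

#' Steady-state transfer function of the LIF neuron with synaptic filtering
#'
#' Firing rate of a leaky integrate-and-fire neuron receiving Gaussian
#' white-noise current with mean `mu` and noise intensity `sigma` (the
#' stationary membrane-potential mean is `tau_m * mu` and its standard
#' deviation scales as `sigma * sqrt(tau_m)`), including the first-order
#' correction for a small synaptic time constant via the boundary shift
#' `a * sqrt(tau_s / tau_m)` with `a = -zeta(1/2)/2`:
#' \deqn{\Phi = \left[\tau_{ref} + \tau_m \sqrt{\pi}
#'   \int_{q_r}^{q_t} e^{x^2}\mathrm{erfc}(-x)\,dx\right]^{-1}.}
#' The integrand is evaluated as the scaled complementary error function
#' `erfcx(-x)`, which is finite for all arguments, so the quadrature is
#' stable far into the mean-driven and strongly subthreshold regimes.
#'
#' @param mu input mean (threshold units per second).
#' @param sigma input noise scale (`> 0`).
#' @param tau_m membrane time constant (s).
#' @param V_r,V_th reset and threshold.
#' @param tau_ref refractory period (s).
#' @param tau_s synaptic time constant used for the boundary correction (s).
#' @return Firing rate in spikes/s (vectorized over `mu`).
#' @export
transfer_rate <- function(mu, sigma, tau_m, V_r, V_th, tau_ref, tau_s) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  corr <- .mft_a * sqrt(tau_s / tau_m)
  qr <- (V_r - tau_m * mu) / (sqrt(tau_m) * sigma) + corr
  qt <- (V_th - tau_m * mu) / (sqrt(tau_m) * sigma) + corr
  n <- max(length(mu), length(sigma))
  qr <- rep_len(qr, n); qt <- rep_len(qt, n)
  tau_m <- rep_len(tau_m, n); tau_ref <- rep_len(tau_ref, n)
  I <- .erfcx_cum(qt) - .erfcx_cum(qr)
  r <- 1 / (tau_ref + tau_m * sqrt(pi) * I)
  r[!is.finite(r)] <- 0  # barrier so high the integral overflows: rate ~ 0
  r
}

# Cumulative C(q) = int_0^q erfcx(-x) dx, exactly decomposed as
#   C(q) = sqrt(pi) * erfi(max(q, 0)) - G(|q|),
# with G(s) = int_0^s erfcx(u) du, a smooth bounded-derivative function
# tabulated once on a fine grid (log-corrected asymptotic tail beyond):
# for q > 0, erfcx(-x) = 2 exp(x^2) - erfcx(x); for q < 0 the substitution
# u = -x gives -int_0^{|q|} erfcx(u) du.
.erfcx_cum <- function(q) {
  G <- .erfcx_G()
  E <- .expsq_int()
  pos <- pmax(q, 0)
  2 * E(pos) - G(abs(q))
}

# int_0^q exp(x^2) dx, tabulated once as a natural spline of its logarithm
# (stable over the full useful range; beyond q = 26.5 the rate underflows
# and Inf is returned so the transfer function evaluates to zero)
.expsq_env <- new.env(parent = emptyenv())
.expsq_int <- function() {
  if (!is.null(.expsq_env$fun)) return(.expsq_env$fun)
  h <- 0.005
  s <- seq(0, 26.6, by = h)
  gl <- pracma::gaussLegendre(7, -1, 1)
  # per-interval integral in log space: log I_k = b^2 + log int e^{x^2-b^2}
  nseg <- length(s) - 1L
  a <- s[-length(s)]; b <- s[-1]
  logI <- numeric(nseg)
  for (k in seq_len(nseg)) {
    x <- 0.5 * h * gl$x + 0.5 * (a[k] + b[k])
    logI[k] <- b[k]^2 + log(0.5 * h * sum(gl$w * exp(x^2 - b[k]^2)))
  }
  # cumulative log-sum-exp
  logC <- numeric(nseg)
  logC[1] <- logI[1]
  for (k in 2:nseg) {
    m <- max(logC[k - 1], logI[k])
    logC[k] <- m + log(exp(logC[k - 1] - m) + exp(logI[k] - m))
  }
  spl <- stats::splinefun(b, logC, method = "natural")
  f <- function(x) {
    out <- numeric(length(x))
    tiny <- x < 0.01
    out[tiny] <- x[tiny] + x[tiny]^3 / 3 + x[tiny]^5 / 10
    mid <- !tiny & x <= 26.6
    out[mid] <- exp(spl(x[mid]))
    out[x > 26.6] <- Inf
    out
  }
  .expsq_env$fun <- f
  f
}

# erfcx that stays finite for large arguments (pracma overflows near 27):
# asymptotic series 1/(x sqrt(pi)) (1 - 1/(2x^2) + 3/(4x^4) - 15/(8x^6))
.erfcx_safe <- function(x) {
  out <- numeric(length(x))
  big <- x > 20
  out[!big] <- pracma::erfcx(x[!big])
  if (any(big)) {
    xb <- x[big]
    out[big] <- (1 - 1 / (2 * xb^2) + 3 / (4 * xb^4) - 15 / (8 * xb^6)) /
      (xb * sqrt(pi))
  }
  out
}

.erfcx_G_env <- new.env(parent = emptyenv())
.erfcx_G <- function() {
  if (!is.null(.erfcx_G_env$fun)) return(.erfcx_G_env$fun)
  h <- 0.02
  s <- seq(0, 60, by = h)
  gl <- pracma::gaussLegendre(7, -1, 1)
  incr <- vapply(seq_len(length(s) - 1L), function(i) {
    a <- s[i]; b <- s[i + 1L]
    x <- 0.5 * (b - a) * gl$x + 0.5 * (a + b)
    0.5 * (b - a) * sum(gl$w * .erfcx_safe(x))
  }, numeric(1))
  cum <- c(0, cumsum(incr))
  spl <- stats::splinefun(s, cum, method = "natural")
  tail_val <- cum[length(cum)]
  f <- function(x) {
    out <- numeric(length(x))
    inside <- x <= 60
    out[inside] <- spl(x[inside])
    out[!inside] <- tail_val + log(x[!inside] / 60) / sqrt(pi)
    out
  }
  .erfcx_G_env$fun <- f
  f
}

# integral of erfcx(-x) over [lo, hi] by composite Gauss-Legendre quadrature
.erfcx_integral <- function(lo, hi) {
  stopifnot(hi >= lo)
  if (hi == lo) return(0)
  nseg <- max(4L, ceiling((hi - lo) / 0.25))
  edges <- seq(lo, hi, length.out = nseg + 1L)
  gl <- .gl16
  tot <- 0
  for (k in seq_len(nseg)) {
    a <- edges[k]; b <- edges[k + 1L]
    x <- 0.5 * (b - a) * gl$x + 0.5 * (a + b)
    tot <- tot + 0.5 * (b - a) * sum(gl$w * .erfcx_safe(-x))
  }
  tot
}

.gl16 <- local({
  g <- pracma::gaussLegendre(16, -1, 1)
  list(x = g$x, w = g$w)
})

# Coefficient matrices mapping population rates to input moments:
#   mu     = M1 %*% nu + mu_ext
#   sigma2 = M2 %*% nu + var_ext
# and, under quenched disorder, Delta2 = M2 %*% s2 + var_ext_quenched.
mft_matrices <- function(arch, depress = TRUE) {
  p <- arch$p
  npop <- 2L * (p + 1L)
  pops <- pop_table(p)
  Cm <- arch$C
  J <- arch$J
  Jp <- arch$Jplus
  Jm <- if (depress) jminus_matrix(arch) else arch$J
  f <- c(E = arch$f_E, I = arch$f_I)
  M1 <- matrix(0, npop, npop)
  M2 <- matrix(0, npop, npop)
  for (i in seq_len(npop)) {
    a <- pops$alpha[i]; ga <- pops$gamma[i]
    for (j in seq_len(npop)) {
      b <- pops$alpha[j]; gb <- pops$gamma[j]
      if (gb <= p) {                       # presynaptic cluster
        cnt <- Cm[a, b] * f[b]
        w <- if (ga <= p && gb == ga) Jp[a, b] else Jm[a, b]
      } else {                             # presynaptic background
        cnt <- (1 - p * f[b]) * Cm[a, b]
        w <- if (ga <= p) Jm[a, b] else J[a, b]
      }
      M1[i, j] <- cnt * w
      M2[i, j] <- cnt * w^2
    }
  }
  mu_ext <- ifelse(pops$alpha == "E",
                   arch$C_ext_E * arch$J_ext_E * arch$nu_o_E,
                   arch$C_ext_I * arch$J_ext_I * arch$nu_o_I)
  var_ext <- ifelse(pops$alpha == "E",
                    arch$C_ext_E * arch$J_ext_E^2 * arch$nu_o_E,
                    arch$C_ext_I * arch$J_ext_I^2 * arch$nu_o_I)
  list(M1 = M1, M2 = M2, mu_ext = mu_ext, var_ext = var_ext, pops = pops)
}

#' Input moments of every population given a vector of population rates
#'
#' Assembles the mean `mu` and variance `sigma^2` of the synaptic input to
#' each of the `2(p+1)` populations (p E clusters, E background, p I
#' clusters, I background) from same-cluster (potentiated), other-cluster
#' and background (depressed) recurrent terms plus the external drive.
#'
#' @param rates numeric vector of length `2(p+1)`, ordered E1..E(p+1),
#'   I1..I(p+1).
#' @param arch an [arch_params()] object.
#' @param depress logical; if `FALSE` inter-cluster weights are not
#'   depressed (used by the reduced two-cluster analyses).
#' @return list with `mu`, `sigma2` and the population table.
#' @export
mft_input_moments <- function(rates, arch, depress = TRUE) {
  mats <- mft_matrices(arch, depress)
  if (length(rates) != nrow(mats$M1))
    stop("rate vector must have length 2(p+1)")
  list(mu = drop(mats$M1 %*% rates) + mats$mu_ext,
       sigma2 = drop(mats$M2 %*% rates) + mats$var_ext,
       pops = mats$pops)
}

# per-population transfer parameters, aligned with pop_table ordering
.pop_neuron <- function(neuron, pops) {
  isE <- pops$alpha == "E"
  list(tau_m = ifelse(isE, neuron$tau_m_E, neuron$tau_m_I),
       V_r = ifelse(isE, neuron$V_r_E, neuron$V_r_I),
       V_th = ifelse(isE, neuron$V_th_E, neuron$V_th_I),
       tau_ref = ifelse(isE, neuron$tau_ref_E, neuron$tau_ref_I),
       tau_s = rep(neuron$tau_syn_E, length(isE)))
}

.phi_all <- function(mu, sigma2, pn) {
  sig <- sqrt(pmax(sigma2, 1e-300))
  transfer_rate(mu, sig, pn$tau_m, pn$V_r, pn$V_th, pn$tau_ref, pn$tau_s)
}

# seed rate vector with nA active clusters
.seed_rates <- function(p, nA, nu_high, nu_low) {
  nu <- rep(nu_low, 2 * (p + 1))
  if (nA > 0) {
    nu[seq_len(nA)] <- nu_high                 # E clusters
    nu[(p + 1) + seq_len(nA)] <- nu_high       # I clusters
  }
  nu
}

# classify a converged rate vector: how many E clusters are "active"
.count_active <- function(nuE_clusters, gap_tol = 0.5) {
  rng <- range(nuE_clusters)
  if (diff(rng) < gap_tol) return(0L)
  thr <- mean(rng)
  sum(nuE_clusters > thr)
}

#' Self-consistent mean-field rates of the clustered network
#'
#' Solves the fixed-point equations `nu = Phi(mu(nu), sigma(nu))` for all
#' `2(p+1)` populations by damped fixed-point iteration, seeded to search
#' for a state with `nA` active clusters (first `nA` E and I cluster rates
#' started at `nu_high`, the rest at `nu_low`). A solution is reported as
#' `cluster_state` only if the number of active clusters at convergence
#' matches the seed; otherwise `state_kind` is `"uniform"` (when `nA`
#' converged to 0 and the seed was 0) or `"not_found"`.
#'
#' @param arch an [arch_params()] object.
#' @param neuron a [neuron_params()] object.
#' @param nA intended number of active clusters (`0 <= nA <= p`).
#' @param nu_high,nu_low seed rates in spikes/s.
#' @param tol convergence tolerance on the self-consistency residual.
#' @param max_iter iteration cap; non-convergence yields `"not_found"`.
#' @param damping initial damping factor of the fixed-point update.
#' @param depress propagate to [mft_input_moments()].
#' @return An object of class `mft_solution`: list with `rates` (named by
#'   population), `nA`, `state_kind`, `residual`, `converged`, and for
#'   cluster states the active/inactive E-cluster rates `nu_up`, `nu_down`.
#' @export
solve_mft <- function(arch, neuron, nA = 0, nu_high = 50, nu_low = 2,
                      tol = 1e-10, max_iter = 5000, damping = 0.3,
                      depress = TRUE) {
  if (nA < 0 || nA > arch$p) stop("nA must be in [0, p]")
  mats <- mft_matrices(arch, depress)
  pn <- .pop_neuron(neuron, mats$pops)
  nu <- .seed_rates(arch$p, nA, nu_high, nu_low)
  eta <- damping
  res <- Inf
  for (it in seq_len(max_iter)) {
    mu <- drop(mats$M1 %*% nu) + mats$mu_ext
    s2 <- drop(mats$M2 %*% nu) + mats$var_ext
    out <- .phi_all(mu, s2, pn)
    new_res <- max(abs(out - nu))
    eta <- if (new_res > res) max(eta * 0.5, 0.01) else min(eta * 1.05, 0.9)
    res <- new_res
    nu <- nu + eta * (out - nu)
    if (res < tol) break
  }
  converged <- res < tol
  p <- arch$p
  nuE <- nu[seq_len(p)]
  nA_found <- .count_active(nuE)
  kind <- if (!converged) "not_found"
          else if (nA_found == 0 && nA == 0) "uniform"
          else if (nA_found == nA && nA > 0) "cluster_state"
          else "not_found"
  sol <- list(rates = stats::setNames(nu, paste0(mats$pops$alpha,
                                                 mats$pops$gamma)),
              nA = nA, nA_found = nA_found, state_kind = kind,
              residual = res, converged = converged)
  if (kind == "cluster_state") {
    thr <- mean(range(nuE))
    sol$nu_up <- mean(nuE[nuE > thr])
    sol$nu_down <- mean(nuE[nuE <= thr])
  }
  class(sol) <- "mft_solution"
  sol
}

#' Quenched-disorder mean-field rates under heterogeneous background input
#'
#' Extends [solve_mft()] to the case where the mean background input varies
#' across cells (arousal heterogeneity modulation `dH`). Each population is
#' described by the spatial mean `nu_bar` and variance `s2` of its firing
#' rates; rates are parameterized by a standard Gaussian variable `z`
#' through `nu(z) = Phi(mu_bar + Delta * z, sigma)`, with `Delta^2`
#' collecting the quenched external variance `(C_ext J_ext dH nu_o)^2` and
#' the rate variances fed back through the recurrent weights. The spatial
#' heterogeneity of the input variance `sigma` is neglected. Gaussian
#' integrals use Gauss-Hermite quadrature.
#'
#' At `dH = 0` the solution collapses onto the plain theory (`s2 = 0`).
#'
#' @inheritParams solve_mft
#' @param dH_E,dH_I heterogeneity strengths.
#' @param n_quad number of Gauss-Hermite nodes.
#' @param drop_s2 if `TRUE`, the rate-variance feedback `s2` is set to zero
#'   (the approximation used by the effective two-cluster theory).
#' @return An `mft_solution` with `rates` (= spatial means `nu_bar`) and
#'   additionally `s2`, the within-population rate variances.
#' @export
solve_quenched_mft <- function(arch, neuron, dH_E = 0, dH_I = 0, nA = 0,
                               nu_high = 50, nu_low = 2, tol = 1e-10,
                               max_iter = 5000, damping = 0.3,
                               n_quad = 60, depress = TRUE,
                               drop_s2 = FALSE) {
  if (dH_E < 0 || dH_I < 0) stop("dH must be non-negative")
  if (nA < 0 || nA > arch$p) stop("nA must be in [0, p]")
  mats <- mft_matrices(arch, depress)
  pn <- .pop_neuron(neuron, mats$pops)
  gh <- pracma::gaussHermite(n_quad)
  z <- sqrt(2) * gh$x
  wz <- gh$w / sqrt(pi)               # weights for E[f(Z)], Z ~ N(0,1)
  var_ext_q <- ifelse(mats$pops$alpha == "E",
                      (arch$C_ext_E * arch$J_ext_E * dH_E * arch$nu_o_E)^2,
                      (arch$C_ext_I * arch$J_ext_I * dH_I * arch$nu_o_I)^2)
  npop <- nrow(mats$M1)
  nu <- .seed_rates(arch$p, nA, nu_high, nu_low)
  s2 <- rep(0, npop)
  eta <- damping
  res <- Inf
  for (it in seq_len(max_iter)) {
    mu_bar <- drop(mats$M1 %*% nu) + mats$mu_ext
    sig2 <- drop(mats$M2 %*% nu) + mats$var_ext
    Delta2 <- var_ext_q + if (drop_s2) 0 else drop(mats$M2 %*% s2)
    Delta <- sqrt(pmax(Delta2, 0))
    nu_new <- numeric(npop)
    s2_new <- numeric(npop)
    sig <- sqrt(pmax(sig2, 1e-300))
    for (i in seq_len(npop)) {
      if (Delta[i] == 0) {
        r <- transfer_rate(mu_bar[i], sig[i], pn$tau_m[i], pn$V_r[i],
                           pn$V_th[i], pn$tau_ref[i], pn$tau_s[i])
        nu_new[i] <- r
        s2_new[i] <- 0
      } else {
        rz <- transfer_rate(mu_bar[i] + Delta[i] * z, sig[i], pn$tau_m[i],
                            pn$V_r[i], pn$V_th[i], pn$tau_ref[i], pn$tau_s[i])
        m1 <- sum(wz * rz)
        m2 <- sum(wz * rz^2)
        nu_new[i] <- m1
        s2_new[i] <- max(m2 - m1^2, 0)
      }
    }
    new_res <- max(abs(nu_new - nu), abs(s2_new - s2))
    eta <- if (new_res > res) max(eta * 0.5, 0.01) else min(eta * 1.05, 0.9)
    res <- new_res
    nu <- nu + eta * (nu_new - nu)
    s2 <- s2 + eta * (s2_new - s2)
    if (res < tol) break
  }
  converged <- res < tol
  p <- arch$p
  nuE <- nu[seq_len(p)]
  nA_found <- .count_active(nuE)
  kind <- if (!converged) "not_found"
          else if (nA_found == 0 && nA == 0) "uniform"
          else if (nA_found == nA && nA > 0) "cluster_state"
          else "not_found"
  sol <- list(rates = stats::setNames(nu, paste0(mats$pops$alpha,
                                                 mats$pops$gamma)),
              s2 = s2, nA = nA, nA_found = nA_found, state_kind = kind,
              residual = res, converged = converged,
              dH_E = dH_E, dH_I = dH_I)
  if (kind == "cluster_state") {
    thr <- mean(range(nuE))
    sol$nu_up <- mean(nuE[nuE > thr])
    sol$nu_down <- mean(nuE[nuE <= thr])
  }
  class(sol) <- "mft_solution"
  sol
}

#' Match the mean-field intracluster coupling to a simulated cluster rate
#'
#' Finite-size simulations develop cluster states at weaker intracluster
#' coupling than the mean-field theory predicts. To compare the two on equal
#' footing, this scans a grid of `Jplus_EE` values and returns the one whose
#' mean-field active-cluster rate (for the most likely number of active
#' clusters `nA_star`) most closely matches the rate measured in simulation.
#'
#' @param nu_up_sim simulated active-cluster rate (spikes/s) at the
#'   simulation coupling.
#' @param arch,neuron network parameters (the `Jplus_EE` entry is replaced
#'   by each grid value in turn).
#' @param coupling_grid numeric vector of `Jplus_EE` values to scan.
#' @param nA_star number of active clusters to condition on.
#' @param ... passed to [solve_mft()].
#' @return list with `Jplus_mft` (matched coupling, `NA` if no cluster state
#'   exists anywhere on the grid), `nu_up_mft`, and the per-grid table.
#' @export
match_intracluster_coupling <- function(nu_up_sim, arch, neuron,
                                        coupling_grid, nA_star = 3, ...) {
  tab <- data.frame(Jplus_EE = coupling_grid, nu_up = NA_real_)
  for (k in seq_along(coupling_grid)) {
    a <- arch
    a$Jplus["E", "E"] <- coupling_grid[k]
    sol <- solve_mft(a, neuron, nA = nA_star, ...)
    if (sol$state_kind == "cluster_state") tab$nu_up[k] <- sol$nu_up
  }
  if (all(is.na(tab$nu_up)))
    return(list(Jplus_mft = NA_real_, nu_up_mft = NA_real_, grid = tab))
  k <- which.min(abs(tab$nu_up - nu_up_sim))
  list(Jplus_mft = tab$Jplus_EE[k], nu_up_mft = tab$nu_up[k], grid = tab)
}
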