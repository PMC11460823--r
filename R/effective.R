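# Effective mean-field theory of a reduced two-cluster network.
#
# The reduced network has populations E1, E2 (the two in-focus clusters),
# Eb and Ib (ambient background populations); inter-cluster weights are not
# depressed. For frozen in-focus rates the ambient rates adapt
# self-consistently; the induced output rates of the in-focus populations
# define a 2D flow whose fixed points are the cluster states (wells) and
# the symmetric state (saddle in the bistable regime). Integrating the flow
# along the path well-saddle-well yields a 1D effective potential whose
# barrier height h measures the robustness of the attractors. Under the
# heterogeneity modulation the rate-variance feedback is neglected
# (only the quenched external variance enters).

#' Two-cluster reduced architecture
#'
#' Convenience constructor for the architecture consumed by
#' [effective_flow_map()]: `p = 2` E clusters with undepressed
#' inter-cluster weights. With `f_I = 0` (the default reduced layout) the
#' inhibitory population is a single ambient pool.
#'
#' @inheritParams arch_params
#' @return An `arch_params` with `p = 2`.
#' @export
two_cluster_arch <- function(N_E, N_I, f_E, f_I = 0,
                             p_EE, p_EI, p_IE, p_II,
                             J_EE, J_EI, J_IE, J_II,
                             Jplus_EE,
                             C_ext_E, C_ext_I, J_ext_E, J_ext_I,
                             nu_o_E, nu_o_I) {
  arch_params(N_E = N_E, N_I = N_I, p = 2, f_E = f_E, f_I = f_I,
              p_EE = p_EE, p_EI = p_EI, p_IE = p_IE, p_II = p_II,
              J_EE = J_EE, J_EI = J_EI, J_IE = J_IE, J_II = J_II,
              Jplus_EE = Jplus_EE,
              C_ext_E = C_ext_E, C_ext_I = C_ext_I,
              J_ext_E = J_ext_E, J_ext_I = J_ext_I,
              nu_o_E = nu_o_E, nu_o_I = nu_o_I)
}

# population order in the reduced system (subset of the full 2(p+1) order):
# E1, E2, Eb | I1, I2, Ib. The I clusters are retained but, with f_I > 0,
# they behave like additional in-focus/ambient populations; here we treat
# I1, I2, Ib all as ambient so the flow is strictly two-dimensional.
.eff_system <- function(arch, neuron, dH_E = 0, n_quad = 60) {
  mats <- mft_matrices(arch, depress = FALSE)
  pn <- .pop_neuron(neuron, mats$pops)
  gh <- pracma::gaussHermite(n_quad)
  list(mats = mats, pn = pn,
       z = sqrt(2) * gh$x, wz = gh$w / sqrt(pi),
       # quenched external variance (E populations only; dH_I = 0)
       Dq = ifelse(mats$pops$alpha == "E",
                   (arch$C_ext_E * arch$J_ext_E * dH_E * arch$nu_o_E)^2, 0),
       idxE = c(1L, 2L), idxAmb = c(3L, 4L, 5L, 6L))
}

# population-averaged rate via the z-parameterized transfer function
.eff_rate <- function(sys, i, mu_bar, sig) {
  D <- sqrt(sys$Dq[i])
  if (D == 0)
    return(transfer_rate(mu_bar[i], sig[i], sys$pn$tau_m[i], sys$pn$V_r[i],
                         sys$pn$V_th[i], sys$pn$tau_ref[i], sys$pn$tau_s[i]))
  rz <- transfer_rate(mu_bar[i] + D * sys$z, sig[i], sys$pn$tau_m[i],
                      sys$pn$V_r[i], sys$pn$V_th[i], sys$pn$tau_ref[i],
                      sys$pn$tau_s[i])
  sum(sys$wz * rz)
}

# solve ambient populations self-consistently at frozen in-focus rates:
# a few damped fixed-point steps to enter the basin, then Newton on
# F(amb) = Phi(amb) - amb with a finite-difference Jacobian
.eff_ambient <- function(sys, nu_in, amb0, tol = 1e-9, max_iter = 60,
                         damping = 0.5) {
  phi_amb <- function(amb) {
    nu <- c(nu_in, amb)
    mu <- drop(sys$mats$M1 %*% nu) + sys$mats$mu_ext
    s2 <- drop(sys$mats$M2 %*% nu) + sys$mats$var_ext
    sig <- sqrt(pmax(s2, 1e-300))
    vapply(sys$idxAmb, function(i) .eff_rate(sys, i, mu, sig), numeric(1))
  }
  amb <- amb0
  eta <- damping
  res <- Inf
  for (it in seq_len(10)) {
    out <- phi_amb(amb)
    r <- max(abs(out - amb))
    eta <- if (r > res) max(eta * 0.5, 0.1) else min(eta * 1.3, 1)
    res <- r
    amb <- amb + eta * (out - amb)
    if (res < tol) return(list(amb = amb, converged = TRUE, residual = res))
  }
  m <- length(amb)
  h <- 1e-5
  for (it in seq_len(max_iter)) {
    F0 <- phi_amb(amb) - amb
    res <- max(abs(F0))
    if (res < tol) return(list(amb = amb, converged = TRUE, residual = res))
    J <- matrix(0, m, m)
    for (k in seq_len(m)) {
      ap <- amb; ap[k] <- ap[k] + h
      J[, k] <- ((phi_amb(ap) - ap) - F0) / h
    }
    step <- tryCatch(solve(J, -F0), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    if (max(abs(step)) > 30) step <- step * 30 / max(abs(step))
    amb <- pmax(amb + step, 0)
  }
  list(amb = amb, converged = res < tol, residual = res)
}

# induced output rates of the in-focus populations
.eff_out <- function(sys, nu_in, amb) {
  nu <- c(nu_in, amb)
  mu <- drop(sys$mats$M1 %*% nu) + sys$mats$mu_ext
  s2 <- drop(sys$mats$M2 %*% nu) + sys$mats$var_ext
  sig <- sqrt(pmax(s2, 1e-300))
  vapply(sys$idxE, function(i) .eff_rate(sys, i, mu, sig), numeric(1))
}

#' Effective two-cluster flow map
#'
#' For every grid point of frozen in-focus rates `(nu1, nu2)` the ambient
#' populations are solved self-consistently and the induced output rates of
#' the two clusters computed; `F = nu_out - nu_in` defines the flow.
#' Fixed points are located by damped iteration of the composed map from
#' asymmetric and symmetric seeds, and classified by the eigenvalues of the
#' flow Jacobian (finite differences).
#'
#' @param arch a [two_cluster_arch()] (p = 2).
#' @param neuron a [neuron_params()].
#' @param dH_E heterogeneity-modulation strength (rate-variance feedback is
#'   neglected).
#' @param grid numeric vector of in-focus rates (spikes/s) defining the
#'   square grid.
#' @param seeds_high,seeds_low seed rates for the fixed-point searches.
#' @param n_quad Gauss-Hermite nodes for the quenched average.
#' @return An object of class `flow_map`: `grid`, `F1`, `F2` (flow
#'   components on the grid), `fixed_points` (data.frame with `nu1`, `nu2`,
#'   `stable`), `failed_nodes`, plus the system handle used internally.
#' @export
effective_flow_map <- function(arch, neuron, dH_E = 0,
                               grid = seq(0, 80, by = 2),
                               seeds_high = 50, seeds_low = 1,
                               n_quad = 60) {
  if (arch$p != 2) stop("effective theory expects a 2-cluster architecture")
  sys <- .eff_system(arch, neuron, dH_E, n_quad)
  # ambient order: Eb, I1, I2, Ib (the I "clusters" are empty when f_I = 0
  # and then carry no feedback; Ib is the functional ambient I population)
  amb0 <- c(5, 10, 10, 10)
  ng <- length(grid)
  F1 <- F2 <- matrix(NA_real_, ng, ng)
  failed <- 0L
  amb_prev <- amb0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    nin <- c(grid[i], grid[j])
    amb <- .eff_ambient(sys, nin, amb_prev)
    if (!amb$converged) { failed <- failed + 1L; next }
    amb_prev <- amb$amb
    out <- .eff_out(sys, nin, amb$amb)
    F1[i, j] <- out[1] - nin[1]
    F2[i, j] <- out[2] - nin[2]
  }
  fp <- .eff_fixed_points(sys, seeds_high, seeds_low, amb0)
  structure(list(grid = grid, F1 = F1, F2 = F2, fixed_points = fp,
                 failed_nodes = failed, sys = sys, dH_E = dH_E),
            class = "flow_map")
}

# find a fixed point of the composed in-focus map nu -> nu_out(nu):
# a short damped-iteration phase locates the basin, then Newton iterations
# on F(nu) = nu_out(nu) - nu (finite-difference Jacobian) polish the root.
# Ambient solves are warm-started throughout.
.eff_iterate <- function(sys, start, amb0, tol = 1e-9, max_iter = 200,
                         damping = 0.3, symmetric = FALSE) {
  nu <- start
  eta <- damping
  res <- Inf
  amb_prev <- amb0
  gmap <- function(x) {
    amb <- .eff_ambient(sys, x, amb_prev)
    if (!amb$converged) return(NULL)
    amb_prev <<- amb$amb
    .eff_out(sys, x, amb$amb)
  }
  for (it in seq_len(40)) {
    out <- gmap(nu)
    if (is.null(out)) return(NULL)
    if (symmetric) out <- rep(mean(out), 2)
    r <- max(abs(out - nu))
    eta <- if (r > res) max(eta * 0.5, 0.05) else min(eta * 1.2, 0.9)
    res <- r
    nu <- nu + eta * (out - nu)
    if (symmetric) nu <- rep(mean(nu), 2)
    if (res < tol) return(nu)
  }
  h <- 1e-4
  for (it in seq_len(max_iter)) {
    out <- gmap(nu)
    if (is.null(out)) return(NULL)
    if (symmetric) {
      x0 <- mean(nu)
      F0 <- mean(out) - x0
      if (abs(F0) < tol) return(rep(x0, 2))
      op <- gmap(rep(x0 + h, 2))
      if (is.null(op)) return(NULL)
      dF <- (mean(op) - (x0 + h) - F0) / h
      if (!is.finite(dF) || abs(dF) < 1e-12) return(NULL)
      x1 <- max(x0 - F0 / dF, 0)
      if (abs(x1 - x0) > 20) x1 <- x0 - sign(F0 / dF) * 20
      nu <- rep(x1, 2)
    } else {
      F0 <- out - nu
      if (max(abs(F0)) < tol) return(nu)
      J <- matrix(0, 2, 2)
      for (k in 1:2) {
        xp <- nu; xp[k] <- xp[k] + h
        op <- gmap(xp)
        if (is.null(op)) return(NULL)
        J[, k] <- ((op - xp) - F0) / h
      }
      step <- tryCatch(solve(J, -F0), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) return(NULL)
      if (max(abs(step)) > 20) step <- step * 20 / max(abs(step))
      nu <- pmax(nu + step, 0)
    }
  }
  NULL
}

.eff_flow_jacobian <- function(sys, nu, amb0, h = 1e-4) {
  J <- matrix(0, 2, 2)
  for (k in 1:2) {
    up <- nu; up[k] <- up[k] + h
    dn <- nu; dn[k] <- max(dn[k] - h, 0)
    fu <- .eff_out(sys, up, .eff_ambient(sys, up, amb0)$amb) - up
    fd <- .eff_out(sys, dn, .eff_ambient(sys, dn, amb0)$amb) - dn
    J[, k] <- (fu - fd) / (up[k] - dn[k])
  }
  J
}

.eff_fixed_points <- function(sys, seeds_high, seeds_low, amb0) {
  cands <- list(c(seeds_high, seeds_low), c(seeds_low, seeds_high))
  fps <- list()
  for (s in cands) {
    fp <- .eff_iterate(sys, s, amb0)
    if (!is.null(fp)) fps[[length(fps) + 1L]] <- fp
  }
  # symmetric state via the symmetry-restricted iteration
  for (s0 in c(seeds_low, (seeds_high + seeds_low) / 2, seeds_high)) {
    fp <- .eff_iterate(sys, rep(s0, 2), amb0, symmetric = TRUE)
    if (!is.null(fp)) fps[[length(fps) + 1L]] <- fp
  }
  if (!length(fps))
    return(data.frame(nu1 = numeric(0), nu2 = numeric(0),
                      stable = logical(0)))
  m <- do.call(rbind, fps)
  # deduplicate
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(i - 1L))
    if (keep[j] && max(abs(m[i, ] - m[j, ])) < 0.05) keep[i] <- FALSE
  m <- m[keep, , drop = FALSE]
  stable <- vapply(seq_len(nrow(m)), function(i) {
    J <- .eff_flow_jacobian(sys, m[i, ], amb0)
    all(Re(eigen(J, only.values = TRUE)$values) < 0)
  }, logical(1))
  data.frame(nu1 = m[, 1], nu2 = m[, 2], stable = stable)
}

#' One-dimensional effective potential and barrier height
#'
#' Integrates the negative projection of the flow along the piecewise-linear
#' path well-1 -> saddle -> well-2 (the straight-segment convention; the
#' absolute value of the barrier depends on this path choice, its trend
#' across modulation strengths does not). In the single-well regime the
#' potential is computed along the diagonal through the unique fixed point
#' and the barrier height is zero.
#'
#' @param flow a `flow_map` from [effective_flow_map()].
#' @param n_path points per path segment.
#' @return An object of class `effective_potential`: `s` (path coordinate),
#'   `U` (potential, zero at the first well), `wells`, `saddle` (or `NULL`),
#'   `barrier_height`, `bistable`.
#' @export
effective_potential <- function(flow, n_path = 200) {
  fp <- flow$fixed_points
  sys <- flow$sys
  amb0 <- c(5, 10, 10, 10)
  wells <- fp[fp$stable, , drop = FALSE]
  saddles <- fp[!fp$stable, , drop = FALSE]
  amb_state <- amb0
  flow_at <- function(x) {
    amb <- .eff_ambient(sys, x, amb_state)
    amb_state <<- amb$amb
    .eff_out(sys, x, amb$amb) - x
  }
  line_int <- function(a, b) {
    # -int F . dl along the straight segment a -> b
    ts <- seq(0, 1, length.out = n_path)
    dl <- (b - a) / (n_path - 1)
    vals <- vapply(ts, function(u) {
      x <- a + u * (b - a)
      -sum(flow_at(x) * dl)
    }, numeric(1))
    # trapezoid accumulation of the projected flow
    cumsum(c(0, (vals[-1] + vals[-n_path]) / 2))
  }
  if (nrow(wells) >= 2 && nrow(saddles) >= 1) {
    w1 <- as.numeric(wells[1, 1:2]); w2 <- as.numeric(wells[2, 1:2])
    sd <- as.numeric(saddles[which.min((saddles$nu1 - saddles$nu2)^2), 1:2])
    U1 <- line_int(w1, sd)
    U2 <- line_int(sd, w2)
    U <- c(U1, U1[length(U1)] + U2[-1])
    s <- seq(0, 1, length.out = length(U))
    # barrier relative to the deeper of the two path ends (wells)
    h <- U1[length(U1)] - min(0, U1[length(U1)] + U2[length(U2)])
    structure(list(s = s, U = U, wells = wells, saddle = sd,
                   barrier_height = max(h, 0), bistable = TRUE),
              class = "effective_potential")
  } else {
    # single-well regime
    ctr <- if (nrow(wells)) as.numeric(wells[1, 1:2])
           else as.numeric(fp[1, 1:2])
    a <- pmax(ctr - 15, 0); b <- ctr + 15
    U <- line_int(a, b)
    structure(list(s = seq(0, 1, length.out = length(U)), U = U,
                   wells = wells, saddle = NULL,
                   barrier_height = 0, bistable = FALSE),
              class = "effective_potential")
  }
}

#' Barrier height across a heterogeneity-modulation sweep
#'
#' @param arch a [two_cluster_arch()].
#' @param neuron a [neuron_params()].
#' @param dH_grid heterogeneity strengths to scan.
#' @param ... passed to [effective_flow_map()].
#' @return data.frame with `dH_E`, `barrier_height`, `bistable`,
#'   `n_fixed_points`.
#' @export
barrier_height_sweep <- function(arch, neuron, dH_grid, ...) {
  out <- lapply(dH_grid, function(dh) {
    fl <- effective_flow_map(arch, neuron, dH_E = dh, ...)
    pot <- effective_potential(fl)
    data.frame(dH_E = dh, barrier_height = pot$barrier_height,
               bistable = pot$bistable,
               n_fixed_points = nrow(fl$fixed_points))
  })
  do.call(rbind, out)
}
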