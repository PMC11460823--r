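# Construction of realized uniform and clustered network instances.
#
# A network_instance stores the realized synapses in compressed sparse row
# form keyed by the *presynaptic* cell (the layout the simulator consumes),
# plus cluster assignments and population labels. Cluster indices run
# 1..p, with p+1 denoting the unclustered background population (all cells
# in the uniform architecture).

# split `total` in-degree into per-class counts, rounding each class but
# keeping the per-cell total exact (residual absorbed by the "other
# clusters" class for clustered cells, the clustered class for background
# cells)
.split_indegree_clustered <- function(C_ab, f_b, p) {
  f_b <- unname(f_b); C_ab <- unname(C_ab)
  n_same <- round(f_b * C_ab)
  n_bg <- round((1 - p * f_b) * C_ab)
  n_other <- C_ab - n_same - n_bg
  if (n_other < 0) stop("infeasible in-degree split")
  c(same = n_same, other = n_other, bg = n_bg)
}

.split_indegree_background <- function(C_ab, f_b, p) {
  f_b <- unname(f_b); C_ab <- unname(C_ab)
  n_bg <- round((1 - p * f_b) * C_ab)
  n_cl <- C_ab - n_bg
  c(cl = n_cl, bg = n_bg)
}

# sample `k` elements from `pool` without replacement (robust to length-1
# pools, unlike sample())
.draw <- function(pool, k) {
  if (k == 0) return(integer(0))
  if (k > length(pool)) stop("in-degree exceeds candidate pool")
  pool[sample.int(length(pool), k)]
}

.finish_instance <- function(arch, neuron, kind, pop, cluster_of,
                             pre, post, w, seed) {
  n <- length(pop)
  o <- order(pre, post)
  pre <- pre[o]; post <- post[o]; w <- w[o]
  ptr <- c(0L, cumsum(tabulate(pre, nbins = n)))
  structure(list(arch = arch, neuron = neuron, kind = kind,
                 n = n, n_E = arch$N_E, n_I = arch$N_I,
                 pop = pop, cluster_of = cluster_of,
                 syn = list(ptr = as.integer(ptr), pre = as.integer(pre),
                            post = as.integer(post), w = w),
                 seed = seed),
            class = "network_instance")
}

#' Build a uniform (unclustered) network instance
#'
#' Every cell of type `a` receives connections from exactly
#' `C_ab = p_ab * N_b` randomly chosen cells of type `b`, each with weight
#' `J_ab`. Self-connections are excluded and presynaptic partners are drawn
#' without replacement. Identical seeds give identical instances.
#'
#' @param arch an [arch_params()] object.
#' @param neuron a [neuron_params()] object.
#' @param seed integer seed for the realization.
#' @return A `network_instance`.
#' @export
build_uniform <- function(arch, neuron, seed = 1) {
  set.seed(seed)
  n <- arch$N_E + arch$N_I
  pop <- rep(c("E", "I"), c(arch$N_E, arch$N_I))
  idx <- list(E = seq_len(arch$N_E), I = arch$N_E + seq_len(arch$N_I))
  pre <- post <- integer(0); w <- numeric(0)
  pres <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    a <- pop[i]
    for (b in c("E", "I")) {
      cand <- setdiff(idx[[b]], i)
      src <- .draw(cand, arch$C[a, b])
      if (length(src)) {
        k <- k + 1L
        pres[[k]] <- cbind(src, i, arch$J[a, b])
      }
    }
  }
  m <- if (k > 0) do.call(rbind, pres[seq_len(k)])
       else matrix(numeric(0), 0, 3)
  .finish_instance(arch, neuron, "uniform", pop,
                   rep(arch$p + 1L, n), m[, 1], m[, 2], m[, 3], seed)
}

#' Build a clustered network instance
#'
#' Each of the `p` clusters contains `f_E * N_E` excitatory and `f_I * N_I`
#' inhibitory cells (rounded); remaining cells form the background. A
#' clustered cell of type `a` receives `f_b * C_ab` connections from its own
#' cluster (weight `Jplus_ab`), `(p-1) f_b C_ab` from other clusters and
#' `(1 - p f_b) C_ab` from the background (weight `Jminus_ab`); background
#' cells receive `p f_b C_ab` from clusters (weight `Jminus_ab`) and
#' `(1 - p f_b) C_ab` from the background (weight `J_ab`). Class counts are
#' rounded with the residual absorbed so that every cell's total in-degree
#' equals `C_ab` exactly, preserving the total synapse count of the uniform
#' architecture.
#'
#' @inheritParams build_uniform
#' @return A `network_instance`.
#' @export
build_clustered <- function(arch, neuron, seed = 1) {
  set.seed(seed)
  p <- arch$p
  n <- arch$N_E + arch$N_I
  pop <- rep(c("E", "I"), c(arch$N_E, arch$N_I))
  g_E <- round(arch$f_E * arch$N_E)
  g_I <- round(arch$f_I * arch$N_I)
  if (p * g_E > arch$N_E || p * g_I > arch$N_I)
    stop("cluster sizes exceed population")
  cluster_of <- integer(n)
  # clusters are contiguous blocks of a random permutation
  permE <- sample.int(arch$N_E)
  permI <- arch$N_E + sample.int(arch$N_I)
  cluster_of[permE] <- rep(c(seq_len(p), p + 1L),
                           c(rep(g_E, p), arch$N_E - p * g_E))
  cluster_of[permI] <- rep(c(seq_len(p), p + 1L),
                           c(rep(g_I, p), arch$N_I - p * g_I))
  Jm <- jminus_matrix(arch)
  members <- lapply(seq_len(p + 1L), function(g) which(cluster_of == g))
  membE <- lapply(members, function(m) m[pop[m] == "E"])
  membI <- lapply(members, function(m) m[pop[m] == "I"])
  memb <- list(E = membE, I = membI)
  allE <- which(pop == "E"); allI <- which(pop == "I")
  pres <- vector("list", 2L * n)
  k <- 0L
  f <- c(E = arch$f_E, I = arch$f_I)
  for (i in seq_len(n)) {
    a <- pop[i]
    gi <- cluster_of[i]
    for (b in c("E", "I")) {
      C_ab <- arch$C[a, b]
      if (gi <= p) {
        cnt <- .split_indegree_clustered(C_ab, f[b], p)
        same_pool <- setdiff(memb[[b]][[gi]], i)
        other_pool <- setdiff(if (b == "E") allE else allI,
                              c(memb[[b]][[gi]], memb[[b]][[p + 1L]]))
        bg_pool <- setdiff(memb[[b]][[p + 1L]], i)
        src <- c(.draw(same_pool, cnt["same"]),
                 .draw(other_pool, cnt["other"]),
                 .draw(bg_pool, cnt["bg"]))
        ws <- c(rep(arch$Jplus[a, b], cnt["same"]),
                rep(Jm[a, b], cnt["other"] + cnt["bg"]))
      } else {
        cnt <- .split_indegree_background(C_ab, f[b], p)
        cl_pool <- setdiff(if (b == "E") allE else allI,
                           c(memb[[b]][[p + 1L]], i))
        bg_pool <- setdiff(memb[[b]][[p + 1L]], i)
        src <- c(.draw(cl_pool, cnt["cl"]), .draw(bg_pool, cnt["bg"]))
        ws <- c(rep(Jm[a, b], cnt["cl"]), rep(arch$J[a, b], cnt["bg"]))
      }
      if (length(src)) {
        k <- k + 1L
        pres[[k]] <- cbind(src, i, ws)
      }
    }
  }
  m <- if (k > 0) do.call(rbind, pres[seq_len(k)])
       else matrix(numeric(0), 0, 3)
  .finish_instance(arch, neuron, "clustered", pop, cluster_of,
                   m[, 1], m[, 2], m[, 3], seed)
}

#' Dense weight matrix of an instance (post x pre)
#'
#' Convenience accessor for inspection and invariants; intended for the
#' moderate network sizes used here.
#'
#' @param instance a `network_instance`.
#' @return `n x n` matrix `W` with `W[i, j]` the weight from `j` to `i`.
#' @export
weight_matrix <- function(instance) {
  W <- matrix(0, instance$n, instance$n)
  W[cbind(instance$syn$post, instance$syn$pre)] <- instance$syn$w
  W
}

#' Quenched standard-normal draws for the heterogeneity modulation
#'
#' Draws the per-cell `z` values used by the input-heterogeneity arousal
#' modulation. In the clustered architecture every cluster of a given
#' population reuses the same within-cluster realization (cells at the same
#' within-cluster slot share `z`), so that all clusters receive the same
#' spatially-averaged input; background cells draw independently. In the
#' uniform architecture all cells draw independently.
#'
#' @param instance a `network_instance`.
#' @param seed integer seed (quenched: one draw per realization).
#' @return numeric vector of length `n`.
#' @export
arousal_z <- function(instance, seed = 1) {
  set.seed(seed)
  n <- instance$n
  z <- numeric(n)
  p <- instance$arch$p
  if (instance$kind == "uniform") return(stats::rnorm(n))
  for (a in c("E", "I")) {
    cl1 <- which(instance$pop == a & instance$cluster_of == 1L)
    slot_z <- stats::rnorm(length(cl1))
    for (g in seq_len(p)) {
      mem <- which(instance$pop == a & instance$cluster_of == g)
      z[mem] <- slot_z[seq_along(mem)]
    }
    bg <- which(instance$pop == a & instance$cluster_of == p + 1L)
    z[bg] <- stats::rnorm(length(bg))
  }
  z
}

#' Per-cell background input rates under an arousal modulation
#'
#' For the mean modulation, every cell of population `a` receives
#' `nu_o_a * (1 + dM_a)`. For the heterogeneity modulation, cell `i`
#' receives `nu_o_a * (1 + z_i * dH_a)`, truncated at zero (inputs are not
#' allowed to go negative); the truncation is applied after drawing `z`,
#' not by redrawing.
#'
#' @param instance a `network_instance`.
#' @param modulation an [arousal_modulation()].
#' @param z quenched draws from [arousal_z()] (required for the
#'   heterogeneity kind).
#' @return numeric vector of per-cell external rates (spikes/s per synapse).
#' @export
assign_external_rates <- function(instance, modulation, z = NULL) {
  isE <- instance$pop == "E"
  nu_o <- ifelse(isE, instance$arch$nu_o_E, instance$arch$nu_o_I)
  if (modulation$kind == "mean") {
    dM <- ifelse(isE, modulation$dM_E, modulation$dM_I)
    return(nu_o * (1 + dM))
  }
  if (is.null(z)) stop("heterogeneity modulation requires quenched draws z")
  dH <- ifelse(isE, modulation$dH_E, modulation$dH_I)
  pmax(nu_o * (1 + z * dH), 0)
}

#' Generate a set of sensory stimuli for a network instance
#'
#' Each stimulus targets a random `frac_clusters` of the clusters, and
#' within each targeted cluster a random `frac_cells` of its E cells.
#' Different stimuli may target overlapping sets. For a uniform instance the
#' same total number of E cells is drawn at random from the whole E
#' population. Only E cells receive stimulation.
#'
#' @param instance a `network_instance`.
#' @param n_stimuli number of stimuli (default five, mirroring five tones).
#' @param frac_clusters,frac_cells targeted fractions in (0, 1].
#' @param A_stim amplitude factor relative to the baseline background mean.
#' @param tau_r,tau_d rise and decay time constants (s), `tau_d > tau_r`.
#' @param t_stim onset time within a trial (s).
#' @param seed integer seed.
#' @return list of `stimulus_spec` objects (fields `stim_id`,
#'   `targeted_clusters`, `targeted_cells`, `A_stim_E`, `tau_r`, `tau_d`,
#'   `t_stim`).
#' @export
make_stimulus_set <- function(instance, n_stimuli = 5, frac_clusters = 0.5,
                              frac_cells = 0.5, A_stim = 0.075,
                              tau_r = 0.02, tau_d = 0.1, t_stim = 1,
                              seed = 1) {
  if (frac_clusters <= 0 || frac_clusters > 1 ||
      frac_cells <= 0 || frac_cells > 1)
    stop("targeted fractions must lie in (0, 1]")
  if (tau_d <= tau_r || tau_r <= 0) stop("need tau_d > tau_r > 0")
  set.seed(seed)
  p <- instance$arch$p
  clustered <- instance$kind == "clustered"
  n_cl <- round(frac_clusters * p)
  # matched total count for uniform instances
  g_E <- round(instance$arch$f_E * instance$arch$N_E)
  n_cells_per_cl <- round(frac_cells * g_E)
  out <- vector("list", n_stimuli)
  for (s in seq_len(n_stimuli)) {
    if (clustered) {
      cl <- sort(.draw(seq_len(p), n_cl))
      cells <- unlist(lapply(cl, function(g) {
        mem <- which(instance$pop == "E" & instance$cluster_of == g)
        sort(.draw(mem, n_cells_per_cl))
      }))
    } else {
      cl <- integer(0)
      cells <- sort(.draw(which(instance$pop == "E"),
                          n_cl * n_cells_per_cl))
    }
    out[[s]] <- structure(list(stim_id = s, targeted_clusters = cl,
                               targeted_cells = cells, A_stim_E = A_stim,
                               tau_r = tau_r, tau_d = tau_d,
                               t_stim = t_stim),
                          class = "stimulus_spec")
  }
  out
}

# peak-normalization constant of the difference of exponentials
.stim_gamma <- function(tau_r, tau_d) {
  r <- tau_r / tau_d
  1 / (r^(tau_r / (tau_d - tau_r)) - r^(tau_d / (tau_d - tau_r)))
}

#' Stimulus input current at time t
#'
#' The stimulus-related input to a targeted cell is
#' `A_stim * nu_o * C_ext * J_ext * s(t)`, where `s(t)` is a difference of
#' exponentials normalized to unit peak, and zero before onset. Inhibitory
#' cells receive no stimulation.
#'
#' @param t time (s), vectorized.
#' @param spec a `stimulus_spec`.
#' @param nu_o,C_ext,J_ext baseline background drive parameters of the
#'   targeted population.
#' @return input current values.
#' @export
stimulus_current <- function(t, spec, nu_o, C_ext, J_ext) {
  if (spec$tau_d <= spec$tau_r) stop("need tau_d > tau_r")
  g <- .stim_gamma(spec$tau_r, spec$tau_d)
  u <- t - spec$t_stim
  s <- ifelse(u >= 0,
              g * (exp(-u / spec$tau_d) - exp(-u / spec$tau_r)), 0)
  spec$A_stim_E * nu_o * C_ext * J_ext * s
}
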