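#' Neuron parameters for the leaky integrate-and-fire model
#'
#' Membrane, threshold/reset, refractory and synaptic time constants for the
#' excitatory (E) and inhibitory (I) populations. Voltages are expressed in
#' threshold units (dimensionless); all times are in seconds.
#'
#' @param tau_m_E,tau_m_I membrane time constants (s).
#' @param V_th_E,V_th_I spike thresholds.
#' @param V_r_E,V_r_I reset potentials (must lie below the thresholds).
#' @param tau_ref_E,tau_ref_I absolute refractory periods (s).
#' @param tau_syn_E,tau_syn_I synaptic time constants of E and I synapses (s).
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(tau_m_E = 0.020, tau_m_I = 0.020,
                          V_th_E = 1.5, V_th_I = 0.75,
                          V_r_E = 0, V_r_I = 0,
                          tau_ref_E = 0.005, tau_ref_I = 0.005,
                          tau_syn_E = 0.005, tau_syn_I = 0.005) {
  np <- list(tau_m_E = tau_m_E, tau_m_I = tau_m_I,
             V_th_E = V_th_E, V_th_I = V_th_I,
             V_r_E = V_r_E, V_r_I = V_r_I,
             tau_ref_E = tau_ref_E, tau_ref_I = tau_ref_I,
             tau_syn_E = tau_syn_E, tau_syn_I = tau_syn_I)
  tms <- unlist(np[c("tau_m_E", "tau_m_I", "tau_ref_E", "tau_ref_I",
                     "tau_syn_E", "tau_syn_I")])
  if (any(tms[1:2] <= 0) || any(tms[5:6] <= 0) || any(tms[3:4] < 0))
    stop("time constants must be positive (refractory periods non-negative)")
  if (V_r_E >= V_th_E || V_r_I >= V_th_I)
    stop("reset potential must lie below threshold")
  structure(np, class = "neuron_params")
}

#' Architecture parameters for uniform and clustered E/I networks
#'
#' Describes population sizes, cluster layout, in-degrees, synaptic weights
#' and background external drive. In the clustered architecture each of the
#' `p` clusters contains `f_E * N_E` excitatory and `f_I * N_I` inhibitory
#' cells; the remaining cells form an unclustered background population.
#' Within-cluster weights are potentiated to `Jplus_ab`, while between-cluster
#' (and cluster-background) weights are depressed to the value that keeps the
#' total summed synaptic weight identical to the uniform network (see
#' [depressed_intercluster_weight()]).
#'
#' Inhibitory weights (`J_EI`, `J_II` and their within-cluster versions) are
#' negative by convention.
#'
#' @param N_E,N_I numbers of E and I cells.
#' @param p number of clusters (per population).
#' @param f_E,f_I fraction of each population belonging to one cluster
#'   (`p * f <= 1`).
#' @param p_EE,p_EI,p_IE,p_II connection probabilities; the in-degree of an
#'   `a` cell from population `b` is `C_ab = p_ab * N_b`.
#' @param J_EE,J_EI,J_IE,J_II baseline synaptic weights (post from pre).
#' @param Jplus_EE,Jplus_EI,Jplus_IE,Jplus_II within-cluster weights; default
#'   to the baseline values (no potentiation).
#' @param C_ext_E,C_ext_I number of external excitatory synapses per E/I cell.
#' @param J_ext_E,J_ext_I external synaptic weights.
#' @param nu_o_E,nu_o_I baseline external rates per synapse (spikes/s).
#' @return An object of class `arch_params`.
#' @export
arch_params <- function(N_E, N_I, p, f_E, f_I,
                        p_EE, p_EI, p_IE, p_II,
                        J_EE, J_EI, J_IE, J_II,
                        Jplus_EE = J_EE, Jplus_EI = J_EI,
                        Jplus_IE = J_IE, Jplus_II = J_II,
                        C_ext_E, C_ext_I, J_ext_E, J_ext_I,
                        nu_o_E, nu_o_I) {
  if (p < 1 || p != round(p)) stop("p must be a positive integer")
  if (p * f_E > 1 + 1e-12 || p * f_I > 1 + 1e-12)
    stop("p * f_a must not exceed 1")
  if (any(c(f_E, f_I) < 0)) stop("cluster fractions must be non-negative")
  J <- matrix(c(J_EE, J_EI, J_IE, J_II), 2, 2, byrow = TRUE,
              dimnames = list(c("E", "I"), c("E", "I")))
  Jp <- matrix(c(Jplus_EE, Jplus_EI, Jplus_IE, Jplus_II), 2, 2, byrow = TRUE,
               dimnames = list(c("E", "I"), c("E", "I")))
  Cmat <- matrix(c(p_EE * N_E, p_EI * N_I, p_IE * N_E, p_II * N_I),
                 2, 2, byrow = TRUE,
                 dimnames = list(c("E", "I"), c("E", "I")))
  if (any(abs(Cmat - round(Cmat)) > 1e-8))
    stop("in-degrees C_ab = p_ab * N_b must be integers")
  if (any(round(Cmat) > rep(c(N_E, N_I), each = 2)))
    stop("infeasible in-degree: C_ab exceeds N_b")
  structure(list(N_E = N_E, N_I = N_I, p = p, f_E = f_E, f_I = f_I,
                 C = round(Cmat), J = J, Jplus = Jp,
                 C_ext_E = C_ext_E, C_ext_I = C_ext_I,
                 J_ext_E = J_ext_E, J_ext_I = J_ext_I,
                 nu_o_E = nu_o_E, nu_o_I = nu_o_I),
            class = "arch_params")
}

#' Depressed inter-cluster weight preserving the total summed weight
#'
#' When within-cluster weights are potentiated from `J_ab` to `Jplus_ab`,
#' between-cluster and cluster-background weights are depressed so that the
#' sum of all synaptic weights in the clustered network equals that of the
#' uniform network:
#' \deqn{J^-_{ab} = \frac{(f_a + f_b - p f_a f_b) J_{ab} - f_a f_b J^+_{ab}}
#'                      {f_a + f_b - p f_a f_b - f_a f_b}.}
#'
#' @param J_ab baseline weight.
#' @param Jplus_ab within-cluster weight.
#' @param f_a,f_b cluster fractions of the post- and pre-synaptic populations.
#' @param p number of clusters.
#' @return The depressed weight `Jminus_ab`.
#' @export
depressed_intercluster_weight <- function(J_ab, Jplus_ab, f_a, f_b, p) {
  den <- f_a + f_b - p * f_a * f_b - f_a * f_b
  if (abs(den) < 1e-14)
    stop("degenerate cluster fractions: zero denominator in J-minus")
  ((f_a + f_b - p * f_a * f_b) * J_ab - f_a * f_b * Jplus_ab) / den
}

# 2x2 matrix of depressed weights for all (post, pre) pairs
jminus_matrix <- function(arch) {
  f <- c(E = arch$f_E, I = arch$f_I)
  Jm <- arch$J
  for (a in c("E", "I")) for (b in c("E", "I"))
    Jm[a, b] <- depressed_intercluster_weight(arch$J[a, b],
                                              arch$Jplus[a, b],
                                              f[a], f[b], arch$p)
  Jm
}

#' Arousal modulation of the background external input
#'
#' Arousal is modeled as a change in the rates of the Poisson background
#' inputs. Two kinds are supported: `"mean"` uniformly scales the rate of
#' every cell in a population (`nu = nu_o * (1 + dM)`), while
#' `"heterogeneity"` draws a quenched per-cell offset
#' (`nu_i = nu_o * (1 + z_i * dH)` with `z_i ~ N(0,1)`, clipped at zero).
#' The standard-normal draws are made once per network realization; in the
#' clustered architecture every cluster receives the same realization of the
#' within-cluster draw so that all clusters see the same spatially-averaged
#' input.
#'
#' @param kind `"mean"` or `"heterogeneity"`.
#' @param dH_E,dH_I heterogeneity strengths (dimensionless, `>= 0`).
#' @param dM_E,dM_I mean-modulation strengths (dimensionless, `>= 0`).
#' @return An object of class `arousal_modulation`.
#' @export
arousal_modulation <- function(kind = c("heterogeneity", "mean"),
                               dH_E = 0, dH_I = 0, dM_E = 0, dM_I = 0) {
  kind <- match.arg(kind)
  if (any(c(dH_E, dH_I, dM_E, dM_I) < 0))
    stop("modulation strengths must be non-negative")
  structure(list(kind = kind, dH_E = dH_E, dH_I = dH_I,
                 dM_E = dM_E, dM_I = dM_I),
            class = "arousal_modulation")
}

#' Shipped default model configurations
#'
#' Returns the bundled parameter sets. `"reduced"` is the workhorse
#' architecture used throughout the package's analyses and tests: a
#' 500-neuron clustered E/I network (6 clusters) calibrated, via the
#' package's mean-field theory, to sit in the metastable multi-attractor
#' regime at zero arousal modulation. `"full"` is a larger architecture
#' (2000 neurons, 18 clusters) with the same cell parameters, matching the
#' cluster count implied by 19 decoding features (one per cluster plus one
#' background cell). `"two_cluster"` is the reduced two-cluster network used
#' by the effective mean-field theory; its inter-cluster weights are not
#' depressed.
#'
#' @param name one of `"reduced"`, `"full"`, `"two_cluster"`.
#' @return A list with elements `arch` ([arch_params()]), `neuron`
#'   ([neuron_params()]) and `notes` (character, provenance of the values).
#' @export
default_config <- function(name = c("reduced", "full", "two_cluster")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("config_", name, ".yaml"),
                      package = "arousalnet")
  if (!nzchar(path)) stop("bundled config not found: ", name)
  read_config(path)
}

#' Read a model configuration from a YAML file
#'
#' The file must contain `neuron` and `architecture` sections whose fields
#' mirror the arguments of [neuron_params()] and [arch_params()], and may
#' contain a free-form `notes` field.
#'
#' @param path path to a YAML config file.
#' @return A list with elements `arch`, `neuron`, `notes`.
#' @seealso [write_config()]
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  list(arch = do.call(arch_params, y$architecture),
       neuron = do.call(neuron_params, y$neuron),
       notes = if (is.null(y$notes)) "" else y$notes)
}

#' Write a model configuration to a YAML file
#'
#' @param config list with `arch` and `neuron` entries (and optional `notes`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  a <- config$arch
  y <- list(
    neuron = unclass(config$neuron),
    architecture = list(
      N_E = a$N_E, N_I = a$N_I, p = a$p, f_E = a$f_E, f_I = a$f_I,
      p_EE = a$C["E", "E"] / a$N_E, p_EI = a$C["E", "I"] / a$N_I,
      p_IE = a$C["I", "E"] / a$N_E, p_II = a$C["I", "I"] / a$N_I,
      J_EE = a$J["E", "E"], J_EI = a$J["E", "I"],
      J_IE = a$J["I", "E"], J_II = a$J["I", "I"],
      Jplus_EE = a$Jplus["E", "E"], Jplus_EI = a$Jplus["E", "I"],
      Jplus_IE = a$Jplus["I", "E"], Jplus_II = a$Jplus["I", "I"],
      C_ext_E = a$C_ext_E, C_ext_I = a$C_ext_I,
      J_ext_E = a$J_ext_E, J_ext_I = a$J_ext_I,
      nu_o_E = a$nu_o_E, nu_o_I = a$nu_o_I),
    notes = if (is.null(config$notes)) "" else config$notes)
  yaml::write_yaml(y, path)
  invisible(path)
}
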