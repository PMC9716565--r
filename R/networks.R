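#' Core network genotype
#'
#' A genotype is one combination of the eight swept Core parameters: the four
#' connection weights and the four adaptation constants shared by the two CPG
#' (I) neurons.
#'
#' @param w_EI,w_EO Positive weights of the ipsilateral input connections
#'   (input to CPG, input to output neuron).
#' @param w_II,w_IO Negative weights of the contralateral inhibitory
#'   connections (CPG to CPG, CPG to output neuron).
#' @param g_adapt Adaptation conductance (S).
#' @param delta_A Adaptation increment per spike.
#' @param p Adaptation activation exponent.
#' @param tau_adapt Adaptation decay time constant (s).
#' @return A one-row tibble.
#' @export
core_genotype <- function(w_EI, w_EO, w_II, w_IO, g_adapt, delta_A, p, tau_adapt) {
  if (w_EI <= 0 || w_EO <= 0) abort("w_EI and w_EO must be positive")
  if (w_II >= 0 || w_IO >= 0) abort("w_II and w_IO must be negative")
  tibble(w_EI = w_EI, w_EO = w_EO, w_II = w_II, w_IO = w_IO,
         g_adapt = g_adapt, delta_A = delta_A, p = p, tau_adapt = tau_adapt)
}

#' Comprehensive network genotype
#'
#' @param w_AI Weight of the adaptation-to-inhibitory connection (printed
#'   negative in the phase-1 grid; the sign selects the synapse class).
#' @param w_IIL,w_ICL Negative weights of the inhibitory-to-contralateral
#'   turning connections (to IL and CL respectively).
#' @param g_adapt,p,delta_A,tau_adapt Adaptation constants of the A neurons.
#' @return A one-row tibble.
#' @export
comprehensive_genotype <- function(w_AI, g_adapt, p, delta_A, tau_adapt,
                                   w_IIL = -5, w_ICL = -5) {
  if (w_IIL >= 0 || w_ICL >= 0) abort("w_IIL and w_ICL must be negative")
  tibble(w_AI = w_AI, w_IIL = w_IIL, w_ICL = w_ICL,
         g_adapt = g_adapt, p = p, delta_A = delta_A, tau_adapt = tau_adapt)
}

#' Showcase genotypes
#'
#' Named parameter combinations that produce the intended adaptive behavior:
#' flip-flopping under symmetric input, steering under asymmetric input.
#'
#' @return A genotype tibble.
#' @export
core_showcase <- function() {
  core_genotype(w_EI = 0.5, w_EO = 0.5, w_II = -3, w_IO = -5,
                g_adapt = 2e-7, delta_A = 0.1, p = 3, tau_adapt = 0.5)
}

#' @rdname core_showcase
#' @export
comprehensive_showcase <- function() {
  comprehensive_genotype(w_AI = -2.5, w_IIL = -12, w_ICL = -8.8,
                         g_adapt = 4e-7, p = 0.05, delta_A = 4, tau_adapt = 0.5)
}

.mirror_sides <- function(ids) {
  # E_L -> (E, L) etc.
  base <- sub("_[LR]$", "", ids)
  side <- sub("^.*_", "", ids)
  list(base = base, side = side)
}

#' Build the Core architecture
#'
#' Six neurons (`E`, `I`, `O` on each side). Input neurons make ipsilateral
#' excitatory connections to the CPG (I) and output (O) neurons; each CPG
#' neuron inhibits the contralateral CPG and output neuron. The I neurons are
#' adapting; the O neurons carry the tonic drive that sets their spontaneous
#' rate.
#'
#' @param genotype A [core_genotype()].
#' @param g_unit Conductance per unit weight (S).
#' @return A `snn_network` with attribute `architecture = "core"`.
#' @export
core_network <- function(genotype, g_unit = LAL_G_UNIT) {
  g <- as.list(genotype[1, ])
  adapt <- list(g_adapt = g$g_adapt, delta_A = g$delta_A, p = g$p,
                tau_adapt = g$tau_adapt, adapting = TRUE)
  neurons <- tibble(
    id = c("E_L", "E_R", "I_L", "I_R", "O_L", "O_R"),
    label = rep(c("E", "I", "O"), each = 2),
    side = rep(c("L", "R"), 3),
    params = list(
      neuron_params(), neuron_params(),
      do.call(neuron_params, adapt),     # both I neurons share the genotype's
      do.call(neuron_params, adapt),     # adaptation constants
      neuron_params(I0 = LAL_CORE_TONIC[["O"]]),
      neuron_params(I0 = LAL_CORE_TONIC[["O"]])))
  synapses <- tibble(
    pre  = c("E_L", "E_R", "E_L", "E_R", "I_L", "I_R", "I_L", "I_R"),
    post = c("I_L", "I_R", "O_L", "O_R", "I_R", "I_L", "O_R", "O_L"),
    weight = c(g$w_EI, g$w_EI, g$w_EO, g$w_EO, g$w_II, g$w_II, g$w_IO, g$w_IO))
  net <- network_spec(neurons, synapses, g_unit = g_unit)
  attr(net, "architecture") <- "core"
  net
}

#' Build the Comprehensive architecture
#'
#' Twelve neurons (`E`, `V`, `IL`, `CL`, `A`, `I` on each side). Inputs (E)
#' excite the ipsilateral motor-control group (V, IL, CL); velocity neurons
#' (V) drive the ipsilateral adaptation neurons (A), which drive the
#' ipsilateral inhibitory neurons (I); the I neurons inhibit the contralateral
#' V, IL and CL neurons, closing the CPG loop. CL neurons additionally couple
#' to the contralateral IL neurons, which differentiates the inner and outer
#' turn commands (Ackermann-like steering). The A neurons are adapting; V, IL
#' and CL carry tonic drives above rheobase so they are spontaneously active.
#'
#' @param genotype A [comprehensive_genotype()].
#' @param fixed A named list of the non-swept weights (`w_EV`, `w_EIL`,
#'   `w_ECL`, `w_VA`, `w_IV`, `w_CLIL`); defaults are documented package
#'   constants.
#' @param g_unit Conductance per unit weight (S).
#' @return A `snn_network` with attribute `architecture = "comprehensive"`.
#' @export
comprehensive_network <- function(genotype, fixed = LAL_COMPREHENSIVE_FIXED,
                                  g_unit = LAL_G_UNIT) {
  g <- as.list(genotype[1, ])
  f <- modifyList(LAL_COMPREHENSIVE_FIXED, fixed)
  adapt <- list(g_adapt = g$g_adapt, delta_A = g$delta_A, p = g$p,
                tau_adapt = g$tau_adapt, adapting = TRUE)
  tonic <- LAL_COMPREHENSIVE_TONIC
  mk <- function(label) {
    if (label == "A") do.call(neuron_params, adapt)
    else neuron_params(I0 = tonic[[label]])
  }
  labels <- c("E", "V", "IL", "CL", "A", "I")
  neurons <- tibble(
    id = paste(rep(labels, each = 2), c("L", "R"), sep = "_"),
    label = rep(labels, each = 2),
    side = rep(c("L", "R"), 6),
    params = purrr::map(rep(labels, each = 2), mk))
  one_side <- function(s, o) {
    tibble(
      pre  = paste(c("E", "E", "E", "V", "A", "I", "I", "I", "CL"), s, sep = "_"),
      post = paste0(c("V_", "IL_", "CL_", "A_", "I_", "V_", "IL_", "CL_", "IL_"),
                    c(s, s, s, s, s, o, o, o, o)),
      weight = c(f$w_EV, f$w_EIL, f$w_ECL, f$w_VA, g$w_AI,
                 f$w_IV, g$w_IIL, g$w_ICL, f$w_CLIL))
  }
  synapses <- bind_rows(one_side("L", "R"), one_side("R", "L"))
  net <- network_spec(neurons, synapses, g_unit = g_unit)
  attr(net, "architecture") <- "comprehensive"
  net
}

#' Input currents from stimulus-reliability fractions
#'
#' The overall input level codes the reliability of a navigation stimulus;
#' left/right balance codes direction. Each input neuron receives a static
#' current `frac * I_max`.
#'
#' @param left_frac,right_frac Fractions in `[0, 1]`.
#' @param I_max Maximum input current (A).
#' @param ids Input-neuron ids (identical in both architectures).
#' @return A named numeric vector of currents (A) for [sim_config()].
#' @export
input_currents <- function(left_frac, right_frac, I_max = LAL_I_MAX,
                           ids = c("E_L", "E_R")) {
  if (any(c(left_frac, right_frac) < 0) || any(c(left_frac, right_frac) > 1))
    abort("input fractions must lie in [0, 1]")
  setNames(c(left_frac, right_frac) * I_max, ids)
}

#' Parameter grids
#'
#' Cartesian products of the swept parameter columns: 5^8 = 390,625 Core
#' genotypes; 6 * 5^4 = 3,750 Comprehensive phase-1 genotypes; 10 x 10
#' phase-2 weight pairs.
#'
#' @return A tibble with one row per genotype (or weight pair) and a leading
#'   `genotype_id` column.
#' @export
core_grid <- function() {
  g <- LAL_CORE_GRID
  grid <- tidyr::expand_grid(
    w_EI = g$w, w_EO = g$w, w_II = -g$w, w_IO = -g$w,
    g_adapt = g$g_adapt, delta_A = g$delta_A, p = g$p, tau_adapt = g$tau_adapt)
  bind_cols(tibble(genotype_id = seq_len(nrow(grid))), grid)
}

#' @rdname core_grid
#' @export
comprehensive_phase1_grid <- function() {
  g <- LAL_COMPREHENSIVE_GRID
  grid <- tidyr::expand_grid(
    w_AI = g$w_AI, g_adapt = g$g_adapt, p = g$p, delta_A = g$delta_A,
    tau_adapt = g$tau_adapt)
  bind_cols(tibble(genotype_id = seq_len(nrow(grid))), grid)
}

#' @rdname core_grid
#' @export
comprehensive_phase2_weights <- function() {
  grid <- tidyr::expand_grid(w_IIL = LAL_PHASE2_WEIGHTS, w_ICL = LAL_PHASE2_WEIGHTS)
  bind_cols(tibble(pair_id = seq_len(nrow(grid))), grid)
}

#' Showcase-neighbourhood genotypes for the robustness experiment
#'
#' The Core showcase genotype and five single-parameter variants inside its
#' flip-flop regime (slower/stronger adaptation, weaker CPG inhibition). Each
#' produces switching that speeds up with symmetric input; together they are
#' the default genotype set for [noise_robustness()].
#'
#' @return A genotype tibble with a `genotype_id` column.
#' @export
robustness_presets <- function() {
  base <- core_showcase()
  vars <- bind_rows(
    base,
    dplyr::mutate(base, tau_adapt = 0.3),
    dplyr::mutate(base, delta_A = 0.2),
    dplyr::mutate(base, g_adapt = 4e-7),
    dplyr::mutate(base, p = 2),
    dplyr::mutate(base, w_II = -2))
  bind_cols(tibble(genotype_id = seq_len(nrow(vars))), vars)
}
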