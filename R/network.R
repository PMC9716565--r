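#' Neuron parameter set
#'
#' Builds a complete parameter list for one adapting leaky integrate-and-fire
#' neuron. Unspecified fields fall back to the shared membrane constants
#' (`Cm` = 0.5 nF, `g_leak` = 5 nS, `V_leak` = -60 mV, `V_th` = -50 mV,
#' `V_spike` = 20 mV, `V_reset` = -65 mV, `V_adapt` = -70 mV,
#' `t_refract` = 1 ms). All values are SI (volts, seconds, amperes, siemens).
#'
#' @param ... named overrides of any default field, e.g. `I0`, `g_adapt`,
#'   `delta_A`, `p`, `tau_adapt`, `adapting`.
#' @return A named list with one entry per parameter.
#' @examples
#' neuron_params(I0 = 3.7698e-10)  # a tonically driven output neuron
#' @export
neuron_params <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(LAL_NEURON_DEFAULTS))
  if (length(unknown) > 0)
    abort(paste0("unknown neuron parameter(s): ", paste(unknown, collapse = ", ")))
  p <- modifyList(LAL_NEURON_DEFAULTS, over)
  num <- p[setdiff(names(p), "adapting")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), TRUE)))
    abort("neuron parameters must be finite scalars")
  if (!(p$V_reset <= p$V_leak && p$V_leak < p$V_th && p$V_th < p$V_spike))
    abort("neuron potentials must satisfy V_reset <= V_leak < V_th < V_spike")
  if (p$Cm <= 0 || p$g_leak <= 0 || p$tau_adapt <= 0)
    abort("Cm, g_leak and tau_adapt must be positive")
  if (p$t_refract < 0 || p$g_adapt < 0 || p$delta_A < 0 || p$p <= 0)
    abort("t_refract, g_adapt, delta_A must be >= 0 and p > 0")
  p
}

#' Assemble a network specification
#'
#' Combines a neuron table and a synapse table into a `snn_network` object,
#' the input to [simulate_network()] and [simulate_agent()].
#'
#' Synapse class follows the sign convention of the connection weight: a
#' positive weight selects the excitatory class (reversal 0 mV, decay 20 ms)
#' and a negative weight the inhibitory class (reversal -80 mV, decay 30 ms).
#' Only `|weight|` scales the conductance, `g_syn = |weight| * g_unit`, so the
#' printed signed weights keep their physical meaning without a sign-cancelling
#' double negative in the synaptic current.
#'
#' @param neurons A data frame with columns `id`, `label`, `side` and a
#'   list-column `params` of [neuron_params()] lists.
#' @param synapses A data frame with columns `pre`, `post` (neuron ids) and
#'   `weight` (signed, dimensionless).
#' @param g_unit Conductance per unit `|weight|` in siemens.
#' @return A `snn_network` object: a list with tibbles `neurons` and
#'   `synapses` (the latter augmented with `g_syn`, `V_rev`, `tau_syn`).
#' @seealso [core_network()], [comprehensive_network()]
#' @export
network_spec <- function(neurons, synapses, g_unit = LAL_G_UNIT) {
  neurons <- as_tibble(neurons)
  if (anyDuplicated(neurons$id) > 0) abort("neuron ids must be unique")
  synapses <- as_tibble(synapses)
  if (nrow(synapses) > 0) {
    bad <- setdiff(c(synapses$pre, synapses$post), neurons$id)
    if (length(bad) > 0)
      abort(paste0("synapse endpoint(s) not in neuron table: ",
                   paste(unique(bad), collapse = ", ")))
    if (any(synapses$weight == 0)) abort("synapse weights must be non-zero")
    inh <- synapses$weight < 0
    synapses <- synapses %>%
      mutate(
        g_syn   = abs(.data$weight) * g_unit,
        V_rev   = ifelse(inh, LAL_SYNAPSE_CLASS$V_rev_in, LAL_SYNAPSE_CLASS$V_rev_ex),
        tau_syn = ifelse(inh, LAL_SYNAPSE_CLASS$tau_syn_in, LAL_SYNAPSE_CLASS$tau_syn_ex))
  } else {
    synapses <- tibble(pre = character(), post = character(), weight = numeric(),
                       g_syn = numeric(), V_rev = numeric(), tau_syn = numeric())
  }
  structure(list(neurons = neurons, synapses = synapses, g_unit = g_unit),
            class = "snn_network")
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf("<snn_network> %d neurons, %d synapses\n",
              nrow(x$neurons), nrow(x$synapses)))
  cat("neurons: ", paste(x$neurons$id, collapse = " "), "\n")
  invisible(x)
}

# Internal: neuron parameter matrix in the column order the C++ core expects.
.neuron_matrix <- function(net, input_currents = NULL) {
  cols <- c("Cm", "g_leak", "V_leak", "V_th", "V_spike", "V_reset", "V_adapt",
            "t_refract", "I0", "g_adapt", "delta_A", "p", "tau_adapt", "adapting")
  m <- t(vapply(net$neurons$params, function(p) {
    unlist(p[cols], use.names = FALSE)
  }, numeric(length(cols))))
  colnames(m) <- cols
  I_ext <- rep(0, nrow(m))
  if (!is.null(input_currents)) {
    idx <- match(names(input_currents), net$neurons$id)
    if (anyNA(idx))
      abort("input_currents names must be neuron ids")
    I_ext[idx] <- unname(input_currents)
  }
  cbind(m, I_ext = I_ext)
}

# Internal: synapse matrix with 0-based endpoint indices.
.synapse_matrix <- function(net) {
  s <- net$synapses
  if (nrow(s) == 0) return(matrix(numeric(0), ncol = 5))
  cbind(pre = match(s$pre, net$neurons$id) - 1L,
        post = match(s$post, net$neurons$id) - 1L,
        g_syn = s$g_syn, V_rev = s$V_rev, tau_syn = s$tau_syn)
}
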