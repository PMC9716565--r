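# The five input conditions of the sweep battery: four symmetric levels and
# one asymmetric combination.
LAL_BATTERY <- list(
  `25` = c(0.25, 0.25), `50` = c(0.50, 0.50), `75` = c(0.75, 0.75),
  `100` = c(1.00, 1.00), asym = c(0.25, 1.00))

#' Deterministic seed schedule
#'
#' Derives one RNG seed per (genotype, input condition, repetition) from a
#' base seed so sweeps are reproducible, resumable and chunkable.
#'
#' @param base_seed Integer base seed.
#' @param genotype_id Integer genotype identifier.
#' @param condition Condition index (1..5) or name from the battery.
#' @param rep Repetition index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
battery_seed <- function(base_seed, genotype_id, condition = 1L, rep = 1L) {
  if (is.character(condition)) condition <- match(condition, names(LAL_BATTERY))
  as.integer((as.double(base_seed) %% 2147483647 * 1000003 +
                as.double(genotype_id) * 10007 +
                as.double(condition) * 101 + as.double(rep)) %% 2147483647)
}

#' Run the five-condition input battery for one genotype
#'
#' Simulates the embodied agent under symmetric 25, 50, 75 and 100% input and
#' the asymmetric 25% left / 100% right combination, each run with its own
#' seed from the deterministic schedule.
#'
#' @param genotype A one-row genotype tibble.
#' @param architecture `"core"` or `"comprehensive"`.
#' @param base_seed Base seed for [battery_seed()].
#' @param genotype_id Identifier used in the seed schedule.
#' @param n_steps,noise_scale Simulation settings.
#' @param act Actuator parameters.
#' @param record_traces Keep full traces (off by default: spikes and the
#'   trajectory are always recorded).
#' @return A named list of five `animat_sim` objects
#'   (`"25"`, `"50"`, `"75"`, `"100"`, `"asym"`).
#' @export
run_input_battery <- function(genotype, architecture = c("core", "comprehensive"),
                              base_seed = 1L, genotype_id = 1L,
                              n_steps = LAL_N_STEPS,
                              noise_scale = LAL_NOISE_SCALE,
                              act = actuator_params(), record_traces = FALSE) {
  architecture <- match.arg(architecture)
  net <- if (architecture == "core") core_network(genotype)
         else comprehensive_network(genotype)
  purrr::imap(LAL_BATTERY, function(frac, cond) {
    cfg <- sim_config(n_steps = n_steps, noise_scale = noise_scale,
                      seed = battery_seed(base_seed, genotype_id, cond),
                      input_currents = input_currents(frac[1], frac[2]))
    simulate_agent(net, cfg, act = act, record_traces = record_traces)
  })
}

# Neuron roles per architecture for the exclusion rules.
.cpg_ids <- function(architecture) {
  if (architecture == "core") c("I_L", "I_R")
  else c("A_L", "A_R", "I_L", "I_R")
}
.output_ids <- function(architecture) {
  if (architecture == "core") c("O_L", "O_R")
  else c("V_L", "V_R", "IL_L", "IL_R", "CL_L", "CL_R")
}

# Maximal spike count in any sliding 1-s window of a sorted spike train.
.window_rate <- function(sp, width = 1) {
  n <- length(sp)
  if (n == 0) return(0)
  max(findInterval(sp + width - 1e-9, sp) - seq_len(n) + 1)
}

#' Summarise a battery into one row per input condition
#'
#' Computes, per run: the summed CPG-layer spike count, the maximal output
#' rate over the output/descending neurons, and the trajectory metrics. The
#' rate statistic is, by default, the largest spike count in any sliding 1-s
#' window (spikes/s, matching the unit of the exclusion rule); the peak of
#' the Gaussian-kernel spike density function (sigma 50 ms) is available as
#' an alternative that reads instantaneous burst rate instead.
#'
#' @param battery The list returned by [run_input_battery()].
#' @param architecture `"core"` or `"comprehensive"`.
#' @param omega_threshold Segmentation threshold (rad/ms).
#' @param rate_stat `"window"` (sliding 1-s spike count, default) or `"sdf"`
#'   (peak spike density).
#' @return A tibble with columns `condition`, `cpg_spikes`, `peak_rate`,
#'   and a list-column `metrics` of [trajectory_metrics()].
#' @export
battery_summary <- function(battery, architecture = c("core", "comprehensive"),
                            omega_threshold = LAL_OMEGA_THRESHOLD,
                            rate_stat = c("window", "sdf")) {
  architecture <- match.arg(architecture)
  rate_stat <- match.arg(rate_stat)
  cpg <- .cpg_ids(architecture)
  outs <- .output_ids(architecture)
  purrr::imap_dfr(battery, function(sim, cond) {
    n <- sim$cfg$n_steps
    peak <- if (rate_stat == "window")
      max(vapply(outs, function(id) .window_rate(sim$spikes[[id]]), numeric(1)))
    else max(vapply(outs, function(id)
      max(.sdf_values(sim$spikes[[id]], n, sim$cfg$dt), 0), numeric(1)))
    tibble(condition = cond,
           cpg_spikes = sum(lengths(sim$spikes[cpg])),
           peak_rate = peak,
           metrics = list(trajectory_metrics(sim$trajectory,
                                             omega_threshold = omega_threshold)))
  })
}

#' Apply the exclusion rules to per-run summaries
#'
#' A genotype is excluded when any of its five runs is unsuccessful: a
#' symmetric-input run whose CPG layer produced fewer than 2 spikes (no
#' flip-flopping possible; reason `cpg_silent`), or any run whose peak output
#' rate exceeds the architecture's limit (60 Hz Core, 120 Hz Comprehensive;
#' reason `output_rate`). `cpg_silent` takes precedence when both apply.
#'
#' @param summaries A tibble of per-run summaries with columns `genotype_id`,
#'   `condition`, `cpg_spikes`, `peak_rate` (e.g. stacked [battery_summary()]
#'   results).
#' @param architecture `"core"` or `"comprehensive"`.
#' @param rate_limit Peak-rate threshold in Hz; defaults to the
#'   architecture's limit.
#' @return A tibble with one row per genotype: `genotype_id`, `excluded`,
#'   `reason` (`NA` when retained).
#' @export
apply_exclusion <- function(summaries, architecture = c("core", "comprehensive"),
                            rate_limit = NULL) {
  architecture <- match.arg(architecture)
  if (is.null(rate_limit)) rate_limit <- LAL_RATE_LIMITS[[architecture]]
  summaries %>%
    group_by(.data$genotype_id) %>%
    summarise(
      cpg_silent = any(.data$cpg_spikes < 2 & .data$condition != "asym"),
      rate_high = any(.data$peak_rate > rate_limit), .groups = "drop") %>%
    mutate(excluded = .data$cpg_silent | .data$rate_high,
           reason = dplyr::case_when(.data$cpg_silent ~ "cpg_silent",
                                     .data$rate_high ~ "output_rate",
                                     TRUE ~ NA_character_)) %>%
    select("genotype_id", "excluded", "reason")
}

#' Sweep a set of genotypes through the full battery pipeline
#'
#' For every genotype: run the five-condition battery, apply the exclusion
#' rules, and for retained genotypes score the six sinuosity/stability
#' conditions and classify the movement phenotype.
#'
#' @param grid A genotype tibble with a `genotype_id` column (e.g.
#'   [core_grid()] or a subsample of it).
#' @param architecture `"core"` or `"comprehensive"`.
#' @param base_seed Base seed of the deterministic schedule.
#' @param n_steps,noise_scale,act Simulation settings.
#' @param progress Print a dot every 100 genotypes.
#' @return A `sweep_result` tibble: one row per genotype with its parameters,
#'   `excluded`/`reason`, per-level switch counts (`switches_25` ..
#'   `switches_100`), the asymmetric-run trajectory angle
#'   (`traj_angle_asym`), condition flags `c1`..`c6`, `n_conditions_met`,
#'   and phenotype `major`/`subtype` (all `NA` for excluded genotypes).
#' @export
sweep_genotypes <- function(grid, architecture = c("core", "comprehensive"),
                            base_seed = 1L, n_steps = LAL_N_STEPS,
                            noise_scale = LAL_NOISE_SCALE,
                            act = actuator_params(), progress = FALSE) {
  architecture <- match.arg(architecture)
  rate_limit <- LAL_RATE_LIMITS[[architecture]]
  param_cols <- setdiff(names(grid), "genotype_id")
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    gid <- grid$genotype_id[i]
    if (progress && i %% 100 == 0) cat(".")
    battery <- run_input_battery(grid[i, param_cols],
                                 architecture = architecture,
                                 base_seed = base_seed, genotype_id = gid,
                                 n_steps = n_steps, noise_scale = noise_scale,
                                 act = act)
    smry <- battery_summary(battery, architecture)
    excl <- apply_exclusion(mutate(smry, genotype_id = gid), architecture,
                            rate_limit = rate_limit)
    sym <- smry$metrics[match(c("25", "50", "75", "100"), smry$condition)]
    switches <- vapply(sym, `[[`, numeric(1), "n_transitions")
    out <- tibble(genotype_id = gid,
                  excluded = excl$excluded, reason = excl$reason,
                  switches_25 = switches[1], switches_50 = switches[2],
                  switches_75 = switches[3], switches_100 = switches[4],
                  traj_angle_asym =
                    smry$metrics[[match("asym", smry$condition)]]$trajectory_angle,
                  cpg_spikes_min = min(smry$cpg_spikes[smry$condition != "asym"]),
                  peak_rate_max = max(smry$peak_rate))
    if (excl$excluded) {
      out <- bind_cols(out, tibble(c1 = NA, c2 = NA, c3 = NA, c4 = NA, c5 = NA,
                                   c6 = NA, n_conditions_met = NA_integer_,
                                   major = NA_character_,
                                   subtype = NA_character_))
    } else {
      cond <- evaluate_conditions(sym)
      phen <- classify_phenotype(NULL, metrics_by_input = sym,
                                 v_max = act$v_max)
      out <- bind_cols(out, cond %>% rename(n_conditions_met = "n_met"), phen)
    }
    bind_cols(grid[i, ], out[, setdiff(names(out), "genotype_id")])
  })
  res <- bind_rows(rows)
  if (progress) cat("\n")
  class(res) <- c("sweep_result", class(res))
  attr(res, "architecture") <- architecture
  res
}

#' Filter genotypes by the number of conditions met
#'
#' @param records A [sweep_genotypes()] result.
#' @param min_conditions Minimum number of the six conditions met (4, 5 or 6).
#' @return The retained rows with `n_conditions_met >= min_conditions`.
#' @export
select_phenotypes <- function(records, min_conditions) {
  filter(records, !.data$excluded,
         .data$n_conditions_met >= min_conditions)
}

#' PCA over genotype parameters
#'
#' Eigen-decomposition of the scaled parameter matrix of a set of genotypes,
#' to ask whether successful genotypes concentrate in a low-dimensional
#' subspace. Constant columns are left centred at zero by a zero-variance
#' guard.
#'
#' @param genotypes A tibble of genotypes (a `genotype_id` column and any
#'   non-numeric columns are dropped).
#' @param scaling `"minmax"` (to `[0, 1]`) or `"zscore"` (unit variance).
#' @return A tibble with `component`, `variance` and `prop_variance`
#'   (descending; proportions sum to 1).
#' @export
pca_genotypes <- function(genotypes, scaling = c("minmax", "zscore")) {
  scaling <- match.arg(scaling)
  num <- genotypes[, setdiff(names(genotypes), "genotype_id")]
  num <- num[, vapply(num, is.numeric, TRUE), drop = FALSE]
  if (nrow(num) < 2) abort("need at least two genotypes")
  X <- as.matrix(num)
  X <- apply(X, 2, function(col) {
    r <- range(col)
    if (r[1] == r[2]) return(rep(0, length(col)))     # zero-variance guard
    if (scaling == "minmax") (col - r[1]) / (r[2] - r[1])
    else (col - mean(col)) / sd(col)
  })
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  tibble(component = seq_along(v), variance = v, prop_variance = v / sum(v))
}

#' Noise-robustness experiment
#'
#' Repeats the four symmetric-input runs of each genotype many times per
#' noise level, scaling the multiplicative noise amplitude by each factor,
#' and records the switch (transition) count and trajectory angle of every
#' run. The initial membrane potentials are drawn once per genotype and held
#' fixed across repetitions, so the only source of across-repetition
#' variability is the multiplicative noise term itself.
#'
#' @param genotypes A genotype tibble with `genotype_id`.
#' @param architecture `"core"` or `"comprehensive"`.
#' @param noise_factors Multipliers of the reference noise amplitude.
#' @param input_levels Symmetric input fractions.
#' @param n_reps Repetitions per (genotype, factor, level) cell.
#' @param base_seed Base seed of the schedule (each repetition gets its own
#'   seed).
#' @param n_steps,act Simulation settings.
#' @return A `robustness_result` tibble, one row per run: `genotype_id`,
#'   `noise_factor`, `input`, `rep`, `switches`, `traj_angle`.
#' @export
noise_robustness <- function(genotypes, architecture = "core",
                             noise_factors = c(0.1, 1, 5),
                             input_levels = c(0.25, 0.5, 0.75, 1),
                             n_reps = 100, base_seed = 1L,
                             n_steps = LAL_N_STEPS, act = actuator_params()) {
  param_cols <- setdiff(names(genotypes), "genotype_id")
  cells <- tidyr::expand_grid(gi = seq_len(nrow(genotypes)),
                              noise_factor = noise_factors,
                              input = input_levels)
  res <- purrr::pmap_dfr(cells, function(gi, noise_factor, input) {
    gid <- genotypes$genotype_id[gi]
    net <- if (architecture == "core")
      core_network(genotypes[gi, param_cols])
    else comprehensive_network(genotypes[gi, param_cols])
    # one fixed initial state per genotype, shared by all reps and factors
    set.seed(battery_seed(base_seed, gid, 5L, 0L))
    V0 <- .initial_V(net, list(init = "random"))
    cond <- match(input, input_levels)
    runs <- purrr::map_dfr(seq_len(n_reps), function(r) {
      cfg <- sim_config(n_steps = n_steps,
                        noise_scale = LAL_NOISE_SCALE * noise_factor,
                        seed = battery_seed(base_seed, gid, cond, r),
                        input_currents = input_currents(input, input),
                        init = V0)
      sim <- simulate_agent(net, cfg, act = act, record_traces = FALSE)
      m <- trajectory_metrics(sim$trajectory)
      tibble(rep = r, switches = m$n_transitions,
             traj_angle = m$trajectory_angle)
    })
    bind_cols(tibble(genotype_id = gid, noise_factor = noise_factor,
                     input = input), runs)
  })
  class(res) <- c("robustness_result", class(res))
  res
}

#' Summarise a robustness experiment per cell
#'
#' @param x A [noise_robustness()] result.
#' @param ... Unused.
#' @return A tibble per (genotype, noise factor, input): `n`,
#'   `mean_switches`, `var_switches`, `mean_angle`, `sd_angle`.
#' @export
glance.robustness_result <- function(x, ...) {
  x %>%
    group_by(.data$genotype_id, .data$noise_factor, .data$input) %>%
    summarise(n = n(), mean_switches = mean(.data$switches),
              var_switches = var(.data$switches),
              mean_angle = mean(.data$traj_angle),
              sd_angle = sd(.data$traj_angle), .groups = "drop")
}

#' Pick genotypes for the robustness experiment
#'
#' An operational stand-in for hand-picking the genotypes that best
#' approximate the desired behaviour, which is defined by switching that
#' speeds up with input: retained genotypes are ranked first by whether their
#' switch counts increase with input level (weakly monotone with a strict
#' overall rise), then by the number of conditions met, then by id, and the
#' top `n` are returned.
#'
#' @param records A [sweep_genotypes()] result.
#' @param n Number of genotypes to return.
#' @return The selected rows of `records`.
#' @export
select_robustness_genotypes <- function(records, n = 25) {
  records %>%
    filter(!.data$excluded) %>%
    mutate(mono = vapply(seq_len(n()), function(i)
      .mono_inc(c(.data$switches_25[i], .data$switches_50[i],
                  .data$switches_75[i], .data$switches_100[i])), TRUE)) %>%
    arrange(dplyr::desc(.data$mono), dplyr::desc(.data$n_conditions_met),
            .data$genotype_id) %>%
    head(n)
}
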