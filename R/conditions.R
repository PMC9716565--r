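# Strict rank concordance across ordered input levels: every consecutive
# difference weakly in the required direction and at least one strictly so.
.mono_inc <- function(x) {
  if (anyNA(x)) return(FALSE)
  d <- diff(x)
  all(d >= 0) && any(d > 0)
}
.mono_dec <- function(x) .mono_inc(-x)

#' Sinuosity and stability conditions across input levels
#'
#' Assesses the six conditions a desirable genotype should meet across the
#' four symmetric input levels (25, 50, 75, 100%):
#' \describe{
#'   \item{c1}{the number of transitions increases with input amplitude (or
#'     transitions vanish at the highest input);}
#'   \item{c2}{segment lengths decrease with input (median per level; the
#'     vanish clause also satisfies this);}
#'   \item{c3}{the per-segment sinuosity difference decreases with input
#'     (median per level; likewise covered by the vanish clause);}
#'   \item{c4}{the median intersegment angle stays within +-0.1 rad;}
#'   \item{c5}{the first-to-last segment angle stays within +-0.25 rad;}
#'   \item{c6}{the trajectory angle stays within +-0.25 rad.}
#' }
#' Monotonicity (c1-c3) is strict rank concordance over the four levels: no
#' step against the trend and at least one step with it. The angle conditions
#' (c4-c6) are evaluated per level and the worst case across levels must stay
#' within the limit; a level with no defined angle (fewer than two
#' transitions) imposes no constraint.
#'
#' @param metrics_by_input A list of four [trajectory_metrics()], ordered by
#'   increasing symmetric input level.
#' @param angle_limits Named numeric limits for `intersegment`, `first_last`
#'   and `trajectory` angles (rad).
#' @return A one-row tibble with logicals `c1`..`c6` and the count `n_met`.
#' @export
evaluate_conditions <- function(metrics_by_input,
                                angle_limits = LAL_ANGLE_LIMITS) {
  stopifnot(length(metrics_by_input) == 4)
  m <- metrics_by_input
  trans <- vapply(m, `[[`, numeric(1), "n_transitions")
  vanish <- trans[4] == 0
  med_or_na <- function(v) if (length(v) > 0) median(v) else NA_real_
  seg_len <- vapply(m, function(x) med_or_na(x$segment_lengths), numeric(1))
  sin_diff <- vapply(m, function(x) med_or_na(x$sinuosity_diffs), numeric(1))
  c1 <- vanish || .mono_inc(trans)
  c2 <- vanish || .mono_dec(seg_len)
  c3 <- vanish || .mono_dec(sin_diff)
  worst <- function(field) {
    v <- vapply(m, function(x) {
      vals <- x[[field]]
      if (length(vals) == 0 || all(is.na(vals))) NA_real_
      else max(abs(if (field == "intersegment_angles") median(vals) else vals))
    }, numeric(1))
    if (all(is.na(v))) 0 else max(v, na.rm = TRUE)
  }
  c4 <- worst("intersegment_angles") <= angle_limits[["intersegment"]]
  c5 <- worst("first_last_angle") <= angle_limits[["first_last"]]
  c6 <- worst("trajectory_angle") <= angle_limits[["trajectory"]]
  flags <- c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6)
  bind_cols(as_tibble(as.list(flags)), tibble(n_met = sum(flags)))
}

# Label a single run. Rules are applied in a fixed order so every trajectory
# gets exactly one label.
.run_label <- function(m, v_max = 1) {
  if (m$final_speed < 0.05 * v_max) return("stopping")
  if (m$path_length > 0 && m$net_displacement < 0.1 * m$path_length &&
      m$n_transitions >= 8) return("chaos")
  if (abs(m$cum_heading) > 2 * pi) return("loop")
  if (abs(m$cum_heading) > pi / 2 && m$n_transitions <= 1) return("curve")
  if (m$n_transitions <= 1 && m$path_length > 0 &&
      m$net_displacement / m$path_length > 0.9) return("straight")
  "zigzag"
}

#' Classify the movement phenotype of a genotype
#'
#' An explicit, deterministic heuristic standing in for visual inspection of
#' trajectories. Each of the four symmetric-input runs is labelled
#' (`stopping`, `chaos`, `loop`, `curve`, `straight`, `zigzag`) from its
#' metrics; the genotype's major phenotype is the modal run label (ties
#' broken in the order zigzag, loop, curve, straight, chaos, stopping). A
#' zig-zag genotype is assigned one subtype:
#' \describe{
#'   \item{c}{loop at the lowest input but zig-zag at the highest;}
#'   \item{d}{asymmetric: worst-case |trajectory angle| beyond 0.25 rad while
#'     transitions still increase with input;}
#'   \item{a}{transitions increase with input (curvier to straighter);}
#'   \item{b}{transitions decrease with input;}
#'   \item{e}{curvaceous: pooled median per-segment sinuosity ratio
#'     (arc minus chord over chord) above `e_threshold`;}
#'   \item{g}{transitions present at some inputs only;}
#'   \item{f}{otherwise: plain zig-zagging with no monotone trend.}
#' }
#'
#' @param trajs_by_input List of four trajectory tibbles, ordered by
#'   increasing symmetric input level.
#' @param metrics_by_input Optional precomputed list of
#'   [trajectory_metrics()]; computed from the trajectories when NULL.
#' @param v_max Actuator saturation velocity (for the stopping rule).
#' @param e_threshold Sinuosity ratio above which a zig-zag is `e`.
#' @param omega_threshold Passed to the segmentation.
#' @return A one-row tibble with `major` and `subtype` (`none` unless the
#'   major phenotype is zig-zag).
#' @export
classify_phenotype <- function(trajs_by_input, metrics_by_input = NULL,
                               v_max = 1, e_threshold = 0.2,
                               omega_threshold = LAL_OMEGA_THRESHOLD) {
  if (is.null(metrics_by_input))
    metrics_by_input <- purrr::map(trajs_by_input, trajectory_metrics,
                                   omega_threshold = omega_threshold)
  m <- metrics_by_input
  stopifnot(length(m) == 4)
  labels <- vapply(m, .run_label, character(1), v_max = v_max)
  priority <- c("zigzag", "loop", "curve", "straight", "chaos", "stopping")
  tab <- table(factor(labels, levels = priority))
  major <- names(tab)[which.max(tab)]   # which.max takes the first maximum,
  subtype <- "none"                     # i.e. the highest-priority label
  if (major == "zigzag") {
    trans <- vapply(m, `[[`, numeric(1), "n_transitions")
    worst_angle <- max(abs(vapply(m, `[[`, numeric(1), "trajectory_angle")))
    ratios <- unlist(purrr::map(m, function(x) {
      ok <- x$segment_lengths > 0
      x$sinuosity_diffs[ok] / x$segment_lengths[ok]
    }))
    subtype <- if (labels[1] == "loop" && labels[4] == "zigzag") "c"
    else if (worst_angle > LAL_ANGLE_LIMITS[["trajectory"]] && .mono_inc(trans)) "d"
    else if (.mono_inc(trans)) "a"
    else if (.mono_dec(trans)) "b"
    else if (length(ratios) > 0 && median(ratios) > e_threshold) "e"
    else if (any(trans == 0) && any(trans > 0)) "g"
    else "f"
  }
  tibble(major = major, subtype = subtype)
}
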