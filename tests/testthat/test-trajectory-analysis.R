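test_that("segmentation finds sign changes of the masked angular velocity", {
  # straight path: no transitions, empty underlying path
  seg <- segment_trajectory(synthetic_trajectory(rep(0, 500)))
  expect_equal(length(seg$transition_indices), 0)
  expect_equal(nrow(seg$underlying_path), 0)
  # alternating 400-step blocks over 2000 steps: 4 interior sign changes
  om <- square_omega(2000, half = 400, amp = 0.01)
  seg2 <- segment_trajectory(synthetic_trajectory(om))
  expect_equal(seg2$transition_indices, c(401, 801, 1201, 1601))
  # constant-omega circle: no transitions
  seg3 <- segment_trajectory(synthetic_trajectory(rep(0.002, 1000)))
  expect_equal(length(seg3$transition_indices), 0)
  # sub-threshold oscillation is masked out entirely
  seg4 <- segment_trajectory(synthetic_trajectory(square_omega(2000, 200, amp = 5e-4)))
  expect_equal(length(seg4$transition_indices), 0)
})

test_that("transition indices mark where the new turning sign first appears", {
  om <- c(rep(0.01, 100), rep(-0.01, 100), rep(0.01, 100))
  seg <- segment_trajectory(synthetic_trajectory(om))
  expect_equal(seg$transition_indices, c(101, 201))
  expect_true(all(diff(seg$transition_indices) > 0))
  expect_true(all(seg$segments$chord_length <= seg$segments$actual_length + 1e-12))
})

test_that("metrics recover the arc-chord difference of semicircular segments", {
  # alternating omega with half-period T such that omega*T = pi: each segment
  # between transitions is a semicircle of radius v/omega
  v <- 0.5; amp <- 0.01; half <- round(pi / amp)   # pi/0.01 ~ 314 steps
  om <- square_omega(2000, half = half, amp = amp)
  traj <- synthetic_trajectory(om, speed = v)
  m <- trajectory_metrics(traj)
  R <- v * LAL_DT / (amp * LAL_DT * 1e3)  # v/omega in length units
  expect_gt(m$n_transitions, 2)
  # diff = (pi/2 - 1) * diameter for a semicircular arc
  expect_equal(median(m$sinuosity_diffs), (pi / 2 - 1) * 2 * R, tolerance = 0.02)
  expect_equal(median(m$segment_lengths), 2 * R, tolerance = 0.02)
})

test_that("straight paths have zero sinuosity and zero trajectory angle", {
  m <- trajectory_metrics(synthetic_trajectory(rep(0, 800)))
  expect_equal(m$n_transitions, 0)
  expect_length(m$sinuosity_diffs, 0)
  expect_equal(m$trajectory_angle, 0)
  expect_equal(m$net_displacement, m$path_length, tolerance = 1e-12)
})

test_that("mirroring a trajectory negates all angle metrics", {
  om <- square_omega(1600, half = 170, amp = 0.008) +
    0.002 * sin(seq_len(1600) / 90)
  a <- trajectory_metrics(synthetic_trajectory(om))
  b <- trajectory_metrics(synthetic_trajectory(-om))
  expect_equal(a$intersegment_angles, -b$intersegment_angles)
  expect_equal(a$first_last_angle, -b$first_last_angle)
  expect_equal(a$trajectory_angle, -b$trajectory_angle)
  expect_equal(a$sinuosity_diffs, b$sinuosity_diffs)
})

test_that("metrics scale correctly under uniform spatial scaling", {
  om <- square_omega(1200, half = 150, amp = 0.01)
  t1 <- synthetic_trajectory(om, speed = 0.3)
  t2 <- synthetic_trajectory(om, speed = 0.6)   # doubled lengths, same angles
  m1 <- trajectory_metrics(t1)
  m2 <- trajectory_metrics(t2)
  expect_equal(m1$n_transitions, m2$n_transitions)
  expect_equal(2 * m1$segment_lengths, m2$segment_lengths, tolerance = 1e-9)
  expect_equal(2 * m1$sinuosity_diffs, m2$sinuosity_diffs, tolerance = 1e-9)
  expect_equal(m1$intersegment_angles, m2$intersegment_angles, tolerance = 1e-9)
  # chord lengths never exceed total path length
  expect_lte(sum(m1$segment_lengths), m1$path_length)
})

test_that("condition scoring applies strict concordance and the vanish clause", {
  mk <- function(trans, seglen, sin_d, inter, fl, ta) {
    structure(list(n_transitions = trans, segment_lengths = seglen,
                   sinuosity_diffs = sin_d, intersegment_angles = inter,
                   first_last_angle = fl, trajectory_angle = ta,
                   path_length = 1, net_displacement = 1, cum_heading = 0,
                   final_speed = 0.5), class = "trajectory_metrics")
  }
  # monotone transitions up, segments/sinuosity down, tight angles: 6/6
  good <- lapply(1:4, function(i)
    mk(c(2, 4, 6, 9)[i], rep(1 / i, 3), rep(0.1 / i, 3),
       c(0.01, -0.02, 0.03), 0.1, 0.05))
  r <- evaluate_conditions(good)
  expect_true(all(unlist(r[paste0("c", 1:6)])))
  expect_equal(r$n_met, 6)
  # decreasing transitions fail c1
  bad <- lapply(1:4, function(i)
    mk(c(9, 6, 4, 2)[i], rep(1 / i, 3), rep(0.1 / i, 3),
       c(0.01, -0.02, 0.03), 0.1, 0.05))
  expect_false(evaluate_conditions(bad)$c1)
  # a single counter-step breaks strict concordance
  wobble <- lapply(1:4, function(i)
    mk(c(2, 6, 5, 9)[i], rep(1 / i, 3), rep(0.1 / i, 3),
       c(0.01, -0.02, 0.03), 0.1, 0.05))
  expect_false(evaluate_conditions(wobble)$c1)
  # all-straight degenerate: transitions vanish, angles trivially stable: 6/6
  straight <- lapply(1:4, function(i)
    trajectory_metrics(synthetic_trajectory(rep(0, 400))))
  rs <- evaluate_conditions(straight)
  expect_equal(rs$n_met, 6)
  # loose trajectory angle fails c6
  tilted <- lapply(1:4, function(i)
    mk(c(2, 4, 6, 9)[i], rep(1 / i, 3), rep(0.1 / i, 3),
       c(0.01, -0.02, 0.03), 0.1, 0.4))
  expect_false(evaluate_conditions(tilted)$c6)
})

test_that("phenotype classification is total, deterministic and matches constructions", {
  n <- 2000
  mk_trajs <- function(oms, speed = 0.5)
    lapply(oms, synthetic_trajectory, speed = speed)
  # straight
  straight <- mk_trajs(replicate(4, rep(0, n), simplify = FALSE))
  expect_equal(classify_phenotype(straight)$major, "straight")
  # constant omega, total turn in (pi/2, 2*pi): curve
  curve <- mk_trajs(replicate(4, rep(0.002, n), simplify = FALSE))
  lab <- classify_phenotype(curve)
  expect_equal(lab$major, "curve")
  expect_equal(lab$subtype, "none")
  # constant omega, many full loops: loop
  loop <- mk_trajs(replicate(4, rep(0.01, n), simplify = FALSE))
  expect_equal(classify_phenotype(loop)$major, "loop")
  # square wave with period shrinking as input grows: zigzag subtype a
  zza <- mk_trajs(lapply(c(500, 250, 125, 100), function(h)
    square_omega(n, half = h, amp = 0.002, centered = TRUE)))
  laba <- classify_phenotype(zza)
  expect_equal(laba$major, "zigzag")
  expect_equal(laba$subtype, "a")
  # reversed: subtype b
  zzb <- mk_trajs(lapply(c(100, 125, 250, 500), function(h)
    square_omega(n, half = h, amp = 0.002, centered = TRUE)))
  expect_equal(classify_phenotype(zzb)$subtype, "b")
  # stopped agent: final speed ~ 0
  stopped <- lapply(1:4, function(i) {
    tr <- synthetic_trajectory(rep(0, n), speed = c(rep(0.5, n / 2), rep(0, n / 2)))
    tr
  })
  expect_equal(classify_phenotype(stopped)$major, "stopping")
  # determinism
  expect_identical(classify_phenotype(zza), classify_phenotype(zza))
})
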