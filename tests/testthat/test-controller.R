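geom <- tunnel_geometry()
white <- texture_condition("white")
striped <- texture_condition("striped")
params <- controller_params()

test_that("the control law maps perceived samples to commands as documented", {
  # null error -> altitude hold
  null_s <- perceived_invariants(kinematic_state(t = 1), rod_config("parallel"),
                                 white, geom)
  expect_equal(command_vertical_speed(null_s, params, 14), 0)
  # converging stimulation over white ground -> climb command
  conv_s <- perceived_invariants(kinematic_state(t = 3),
                                 rod_config("dynamic_converging"), white, geom)
  cmd <- command_vertical_speed(conv_s, params, 14)
  expect_gt(cmd, 0)
  # and it equals the blended-gain formula for a centered level state
  w1 <- params$w_osrc * 0.1; w2 <- params$w_sarc
  e <- (w2 * (2 / 12.5)) / (w1 + w2)
  expect_equal(cmd, params$k_gain * e * 14, tolerance = 1e-12)
  # diverging with safety on -> descent vetoed
  div_s <- perceived_invariants(kinematic_state(t = 3),
                                rod_config("dynamic_diverging"), white, geom)
  expect_equal(command_vertical_speed(div_s, params, 14), 0)
  # safety off -> symmetric descent command
  off <- controller_params(safety_mode = FALSE)
  expect_equal(command_vertical_speed(div_s, off, 14), -cmd, tolerance = 1e-12)
  # over striped ground the rods are ignored entirely
  conv_str <- perceived_invariants(kinematic_state(t = 3),
                                   rod_config("dynamic_converging"), striped, geom)
  expect_equal(command_vertical_speed(conv_str, params, 14), 0)
})

test_that("descents corroborated by OSRC pass the safety veto", {
  # descending agent: both channels report a (true) climb need -> no veto issue;
  # ascending agent: both report descent need, OSRC corroborates -> allowed
  up <- perceived_invariants(kinematic_state(t = 1, vz = 5),
                             rod_config("parallel"), white, geom)
  expect_lt(command_vertical_speed(up, params, 14), 0)
  # but below the floor margin every descent is suppressed
  low <- perceived_invariants(kinematic_state(t = 1, vz = 5, z = 1.5),
                              rod_config("parallel"), white, geom)
  expect_equal(command_vertical_speed(low, params, 1.5), 0)
})

test_that("commands are clipped to vz_max", {
  s <- perceived_invariants(kinematic_state(t = 1, vz = -200, z = 5),
                            rod_config("parallel"), white, geom)
  expect_equal(command_vertical_speed(s, params, 5), params$vz_max)
})

test_that("null closed-loop flight holds altitude to numerical precision", {
  for (tex in list(white, striped)) {
    cfg <- sim_config(texture = tex)
    tr <- simulate_flight(cfg, params)
    expect_lt(max(abs(tr$z - 14)), 1e-6)
  }
})

test_that("striped ground suppresses any rod response", {
  for (mode in c("dynamic_converging", "dynamic_diverging",
                 "static_converging", "narrow")) {
    cfg <- sim_config(rods = rod_config(mode), texture = striped)
    tr <- simulate_flight(cfg, params)
    expect_lt(max(abs(tr$z - 14)), 0.1)
  }
})

test_that("white-ground responses match the predicted pattern", {
  conv <- simulate_flight(sim_config(rods = rod_config("dynamic_converging"),
                                     texture = white), params)
  expect_gt(conv$z[301], conv$z[201])   # climbs after onset (t = 3 vs 2 s)
  expect_lt(max(abs(conv$z[1:201] - 14)), 1e-6)  # quiet before onset
  div_on <- simulate_flight(sim_config(rods = rod_config("dynamic_diverging"),
                                       texture = white), params)
  expect_lt(max(abs(div_on$z - 14)), 1e-6)  # safety veto: no descent at all
  div_off <- simulate_flight(sim_config(rods = rod_config("dynamic_diverging"),
                                        texture = white),
                             controller_params(safety_mode = FALSE))
  expect_lt(div_off$z[301], div_off$z[201])
})

test_that("trajectories stay inside the tunnel and on the 100 Hz grid", {
  cfg <- sim_config(rods = rod_config("dynamic_converging"), texture = white,
                    altitude_noise_sd = 0.25, seed = 99)
  tr <- simulate_flight(cfg, params)
  expect_true(all(tr$z > 0 & tr$z < geom$height))
  expect_equal(diff(tr$t), rep(0.01, nrow(tr) - 1), tolerance = 1e-9)
  # flight ends at the exit when the tunnel is shorter than duration allows
  fast <- simulate_flight(sim_config(forward_speed = 110), params)
  expect_equal(max(fast$t), 2)
  expect_lte(max(fast$x), geom$length + 1e-9)
})

test_that("simulation is reproducible and dt-refinement consistent", {
  cfg <- sim_config(rods = rod_config("dynamic_converging"), texture = white,
                    altitude_noise_sd = 0.3, pixel_quantize = TRUE, seed = 5)
  t1 <- simulate_flight(cfg, params)
  t2 <- simulate_flight(cfg, params)
  expect_identical(t1$z, t2$z)
  # halving dt changes the noise-free solution only at O(dt)
  c1 <- sim_config(rods = rod_config("dynamic_converging"), texture = white)
  c2 <- sim_config(rods = rod_config("dynamic_converging"), texture = white,
                   dt = 0.005)
  z1 <- simulate_flight(c1, params)$z
  z2 <- simulate_flight(c2, params)$z
  expect_equal(length(z1), length(z2))
  expect_lt(max(abs(z1 - z2)), 0.05)
  expect_error(sim_config(dt = 0.003), "10 ms")
})
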