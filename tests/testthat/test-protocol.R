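small_geom <- boundary_geometry("oblate", 1200, 400)

test_that("chemistry-only runs conserve actin exactly", {
  cfg <- make_config(geometry = small_geom, G_uM = 10, formin_uM = 0.1,
                     n_seed = 5L, t_total = 5, seed = 3)
  traj <- run_simulation(cfg)
  st <- traj$state
  V <- effective_volume_L(small_geom)
  expected <- concentration_to_copies(10, V) + 5L * 30L
  expect_identical(actin_inventory(st)[["total"]], as.integer(expected))
  expect_identical(formin_inventory(st)[["total"]],
                   concentration_to_copies(0.1, V))
})

test_that("snapshot times advance by the configured cadence", {
  cfg <- make_config(geometry = small_geom, G_uM = 5, n_seed = 3L,
                     t_total = 3, snapshot_every = 0.5, seed = 4)
  traj <- run_simulation(cfg)
  tms <- vapply(traj$snapshots, `[[`, 0, "time")
  expect_equal(diff(tms), rep(0.5, length(tms) - 1), tolerance = 1e-9)
})

test_that("scheduled species appear only after their time", {
  cfg <- make_config(geometry = small_geom, G_uM = 10, n_seed = 5L,
                     t_total = 4, seed = 5,
                     schedule = list(
                       list(time = 2, action = "add_species",
                            species = "NMII", conc_uM = 0.2),
                       list(time = 2, action = "add_species",
                            species = "linker", conc_uM = 4)))
  traj <- run_simulation(cfg)
  for (sn in traj$snapshots) {
    nm <- sum(sn$grid_counts[, "NMII"]) + nrow(sn$motors)
    # the action fires at the first window boundary after its time
    if (sn$time <= 2) expect_equal(nm, 0) else expect_gt(nm, 0)
  }
})

test_that("treadmilling-inhibition presets set the printed rate values", {
  cfg <- scenario("baseline_ring", seed = 1, scaled_down = TRUE,
                  t_total = 10)
  cfg <- apply_latA(cfg, "weak", time = 5)
  la <- cfg$schedule[[which(vapply(cfg$schedule, function(a)
    a$action == "latA", TRUE))]]
  expect_equal(la$time, 5)
  st <- actoring:::init_state_from_config(cfg)
  actoring:::apply_action(st, la)
  expect_equal(st$cp$k_on_BE, 11.6)
  expect_equal(st$cp$k_off_BE, 2.1)
  expect_equal(st$cp$k_off_PE, 2.4)
  expect_equal(st$cp$k_on_PE, 1.3)
  actoring:::apply_action(st, list(action = "latA", level = "strong"))
  expect_equal(st$cp$k_on_BE, 3.48)
  expect_equal(st$cp$k_off_BE, 11.2)
  expect_equal(st$cp$k_off_PE, 4.8)
  # applying the same level twice is idempotent on the schedule
  cfg2 <- apply_latA(apply_latA(cfg, "weak", 5), "weak", 5)
  expect_equal(sum(vapply(cfg2$schedule, function(a)
    a$action == "latA", TRUE)), 1L)
  expect_error(apply_latA(cfg, "none"))
})

test_that("scenario presets encode the standard protocol numbers", {
  cfg <- scenario("baseline_cluster", seed = 1)
  expect_equal(cfg$G_uM, 40)
  expect_equal(cfg$formin_uM, 0.1)          # 100 nM nucleator
  adds <- Filter(function(a) a$action == "add_species", cfg$schedule)
  expect_equal(vapply(adds, function(a) a$time, 0), c(300, 300))
  expect_equal(adds[[1]]$conc_uM, 0.06)     # NMII
  expect_equal(adds[[2]]$conc_uM, 4)        # alpha-actinin
  expect_equal(scenario("latA_weak")$schedule[[3]]$time, 800)
  cly <- scenario("calyA", seed = 1)
  expect_equal(cly$G_uM, 80)
  expect_equal(cly$NMII_uM, 0.18)
  y <- scenario("y27632", seed = 1)
  expect_equal(y$schedule[[1]]$delta_uM, -0.04)
})

test_that("motor-level perturbations add and remove copies correctly", {
  cfg <- make_config(geometry = small_geom, NMII_uM = 0.2, seed = 6)
  st <- actoring:::init_state_from_config(cfg)
  V <- effective_volume_L(small_geom)
  n0 <- actoring:::grid_total(st$grid, "NMII")
  actoring:::apply_nmii_delta(st, 0.1)
  expect_equal(actoring:::grid_total(st$grid, "NMII"),
               n0 + concentration_to_copies(0.1, V))
  actoring:::apply_nmii_delta(st, -0.1)
  expect_equal(actoring:::grid_total(st$grid, "NMII"), n0)
  expect_error(actoring:::apply_nmii_delta(st, -10), "exceeds")
  # removal digs into bound motors when the pool is short
  set.seed(6)
  two_parallel(st, 200)
  prs <- find_binding_pairs(st, "motor")
  bind_motor(st, prs[1, ])
  pool <- actoring:::grid_total(st$grid, "NMII")
  actoring:::apply_nmii_delta(st, -copies_to_concentration(pool + 1, V))
  expect_equal(sum(st$motors$active), 0L)
  expect_equal(actoring:::grid_total(st$grid, "NMII"), 0L)
})

test_that("preformed rings are valid and strongly peripheral", {
  set.seed(8)
  cfg <- scenario("preformed_ring", seed = 8, scaled_down = TRUE)
  st <- init_preformed_ring(cfg, annulus_nm = 300)
  expect_identical(validate_state(st), character(0))
  sn <- take_snapshot(st)
  expect_gte(r_median(sn), 0.8)
  expect_gt(sum(sn$grid_counts[, "G"]), 0)
  expect_error(init_preformed_ring(cfg, annulus_nm = 0), "positive")
  # bound motors/linkers where geometry permits
  expect_gt(nrow(sn$linkers) + nrow(sn$motors), 0)
})

test_that("frozen chemistry ends the run early with a status", {
  cfg <- make_config(geometry = small_geom, G_uM = 0, formin_uM = 0,
                     n_seed = 2L, t_total = 5, seed = 9,
                     chem = list(k_on_BE = 0, k_on_PE = 0, k_off_BE = 0,
                                 k_off_PE = 0, k_destruction = 0,
                                 k_nu = 0, k_off_formin = 0))
  traj <- run_simulation(cfg)
  expect_equal(traj$status, "frozen")
  expect_lt(traj$state$time, 5)
})
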