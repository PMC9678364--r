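ring_snap <- function(frac = 0.9, width = 30, n = 20000, seed = 1)
  make_snapshot(morphology_spec("ring", n_monomers = n,
                                ring_radius_frac = frac,
                                ring_width_nm = width, seed = seed))

test_that("radial density is area-normalized and integrates to one", {
  sn <- ring_snap(0.525, 1, n = 5000)   # centered inside one radial bin
  rd <- radial_density(sn, n_bins = 20)
  expect_equal(sum(rd$rho * diff(seq(0, 1, length.out = 21))), 1)
  # a thin annulus occupies essentially one radial bin
  expect_gt(max(rd$rho) / sum(rd$rho), 0.8)
  expect_equal(rd$r[which.max(rd$rho)], 0.525, tolerance = 0.03)
  # uniform disk: flat area-normalized profile away from the rim
  snu <- make_snapshot(morphology_spec("uniform", n_monomers = 60000,
                                       seed = 2))
  rdu <- radial_density(snu, n_bins = 10)
  mid <- rdu$rho[2:8]
  expect_lt(stats::sd(mid) / mean(mid), 0.15)
})

test_that("r_median recovers the analytic values of known morphologies", {
  snu <- make_snapshot(morphology_spec("uniform", n_monomers = 1e6,
                                       seed = 3))
  expect_equal(r_median(snu), 1 / sqrt(2), tolerance = 0.01)
  expect_equal(r_median(ring_snap(0.9, 50, seed = 4)), 0.9,
               tolerance = 0.02)
  snc <- make_snapshot(morphology_spec(
    "clusters", n_monomers = 20000, n_clusters = 1,
    cluster_centers = matrix(c(0, 0), 1), cluster_sigma_nm = 120,
    seed = 5))
  expect_lt(r_median(snc), 0.3)
  expect_error(r_median(structure(list(filaments = list(),
                                       geom = boundary_geometry()),
                                  class = "acto_snapshot")), "empty")
})

test_that("remodeling rate detects the linear segment", {
  t <- seq(300, 800, by = 2)
  s1 <- data.frame(time = t, r_median = 0.4 + 0.001 * t)
  r1 <- remodeling_rate(s1)
  expect_equal(r1$slope, 0.001, tolerance = 1e-6)
  s2 <- data.frame(time = t, r_median = rep(0.55, length(t)))
  expect_equal(remodeling_rate(s2)$slope, 0, tolerance = 1e-12)
  # linear rise then plateau: slope of the linear piece
  y <- ifelse(t < 500, 0.3 + 0.002 * (t - 300), 0.7)
  set.seed(6)
  r3 <- remodeling_rate(data.frame(time = t,
                                   r_median = y + rnorm(length(t), 0, 1e-4)))
  expect_equal(r3$slope, 0.002, tolerance = 0.02)
  expect_lt(r3$window[2], 525)
  expect_error(remodeling_rate(data.frame(time = 300:305,
                                          r_median = rep(0.5, 6))),
               "too short")
})

test_that("treadmilling rate recovers constructed event streams", {
  # deterministic stream: 10 filaments gaining 5 monomers per 10 s
  tms <- seq(0, 1000, by = 10)
  snaps <- lapply(tms, function(t) {
    s <- list(time = t, n_filaments = 10L,
              counters = c(be_add = 5 * t, be_rem = 0, pe_add = 0,
                           pe_rem = 5 * t, nuc = 0, destr = 0,
                           forced_unbind = 0),
              filaments = list(), energy = NULL, labeled = NULL)
    class(s) <- "acto_snapshot"; s
  })
  traj <- structure(list(snapshots = snaps), class = "acto_trajectory")
  tr <- treadmilling_rate(traj, t_start = 0)
  expect_equal(tr$r_TM, 0.5)
  expect_equal(tr$r_PE, 0.5)   # balanced by construction
  # Poisson stream at the same rates
  el <- make_event_log(0.5, 0.5, n_filaments = 10L, t_total = 1000,
                       seed = 7)
  tr2 <- treadmilling_rate(el, t_start = 0)
  se <- sqrt(0.5 * 10 * 1000) / (10 * 1000)
  expect_lt(abs(tr2$r_TM - 0.5), 3 * se)
  expect_error(treadmilling_rate(el, t_start = 2000), "no snapshots")
})

test_that("turnover halftime matches the analytic exponential half-life", {
  tl <- make_turnover_log(k = 0.01, n0 = 1e5, t_total = 400)
  th <- turnover_halftime(tl)
  expect_false(th$censored)
  expect_equal(th$t_half, log(2) / 0.01, tolerance = 0.02)
  # doubling the rate halves the halftime
  th2 <- turnover_halftime(make_turnover_log(k = 0.02, n0 = 1e5,
                                             t_total = 400))
  expect_equal(th$t_half / th2$t_half, 2, tolerance = 0.05)
  # a frozen network never reaches 50% turnover
  frozen <- make_turnover_log(k = 0, t_total = 100)
  expect_true(turnover_halftime(frozen)$censored)
})

test_that("cluster detection obeys threshold, connectivity and size rules", {
  mkmap <- function(conc) list(conc = conc,
                               x = seq_len(nrow(conc)),
                               y = seq_len(ncol(conc)))
  m <- matrix(0, 10, 10)
  m[3:4, 2:4] <- 200                       # 2 x 3 block
  cs <- actoring:::detect_clusters_on_map(mkmap(m))
  expect_length(cs$clusters, 1)
  expect_equal(cs$clusters[[1]]$n_bins, 6L)
  expect_equal(cs$clusters[[1]]$mean_conc, 200)
  expect_equal(local_concentration(cs), 200)
  m2 <- matrix(0, 10, 10); m2[3, 2:4] <- 200   # 3 bins: below size cut
  expect_length(actoring:::detect_clusters_on_map(mkmap(m2))$clusters, 0)
  # two blocks separated by a sub-threshold bin stay separate
  m3 <- matrix(0, 10, 10)
  m3[2:3, 2:3] <- 200; m3[2:3, 5:6] <- 300; m3[2:3, 4] <- 100
  cs3 <- actoring:::detect_clusters_on_map(mkmap(m3))
  expect_length(cs3$clusters, 2)
  expect_equal(local_concentration(cs3), 250)  # equal bin counts
  expect_error(local_concentration(
    actoring:::detect_clusters_on_map(mkmap(matrix(0, 5, 5)))), "empty")
})

test_that("component labeling equals an independent union-find oracle", {
  set.seed(9)
  for (rep in 1:100) {
    mask <- matrix(runif(15 * 15) < 0.4, 15, 15)
    a <- actoring:::label_components(mask)
    b <- uf_components(mask)
    # same partition up to label permutation
    expect_equal(max(a), max(b))
    for (k in seq_len(max(a))) {
      cells <- which(a == k)
      expect_equal(length(unique(b[cells])), 1L)
    }
  }
})

test_that("cluster detection on snapshots measures local concentration", {
  # one dense central cluster of known mass
  sn <- make_snapshot(morphology_spec(
    "clusters", n_monomers = 30000, n_clusters = 1,
    cluster_centers = matrix(c(0, 0), 1), cluster_sigma_nm = 100,
    seed = 10))
  cs <- detect_clusters(sn)
  expect_gt(length(cs$clusters), 0)
  expect_gt(local_concentration(cs), 160)
  # all member bins are above threshold
  for (cl in cs$clusters) expect_true(all(cl$bins$conc >= 160))
})

test_that("orientation distribution separates tangential from radial", {
  ring <- ring_snap(0.85, 20, seed = 11)
  o1 <- orientation_distribution(ring)
  expect_lt(stats::median(o1$angles), 10)
  # radial spokes: build filaments pointing outward
  st <- tiny_state(diameter = 4000)
  for (th in seq(0, 2 * pi - 0.1, length.out = 24)) {
    u <- c(cos(th), sin(th), 0)
    sf <- sfil(u * 800, u, 80)
    addf(st, sf$verts, sf$nmono)
  }
  o2 <- orientation_distribution(take_snapshot(st))
  expect_gt(stats::median(o2$angles), 80)
  # isotropic in-plane orientations: mean angle near 45 degrees
  iso <- make_snapshot(morphology_spec("uniform", n_monomers = 40000,
                                       seed = 12))
  o3 <- orientation_distribution(iso)
  expect_equal(mean(o3$angles), 45, tolerance = 0.1)
})

test_that("U_Mech sums the four network terms and excludes the boundary", {
  en <- c(U_fil_str = 5, U_fil_bend = 10, U_vol = 0, U_motor_str = 3,
          U_linker_str = 2, U_boundary = 7, U_total = 27)
  snaps <- lapply(0:10, function(t) {
    s <- list(time = t, filaments = list(), energy = en, labeled = NULL,
              n_filaments = 0L)
    class(s) <- "acto_snapshot"; s
  })
  traj <- structure(list(snapshots = snaps), class = "acto_trajectory")
  ms <- mechanical_energy_series(traj, tail_window = 5)
  expect_true(all(ms$series$U_Mech == 20))
  expect_equal(ms$steady_mean, 20)
  snaps[[1]]$energy <- NULL
  traj2 <- structure(list(snapshots = snaps), class = "acto_trajectory")
  expect_error(mechanical_energy_series(traj2), "lack energy")
})

test_that("steady-state onset is detected from the length plateau", {
  mk <- function(lens) {
    snaps <- lapply(seq_along(lens), function(i) {
      s <- list(time = (i - 1) * 50,
                filaments = list(list(verts = rbind(c(0, 0, 0),
                                                    c(lens[i], 0, 0)),
                                      nmono = as.integer(lens[i] / 2.7),
                                      barbed = "BE")),
                n_filaments = 1L, energy = NULL, labeled = NULL)
      class(s) <- "acto_snapshot"; s
    })
    structure(list(snapshots = snaps), class = "acto_trajectory")
  }
  lens <- c(seq(100, 1000, length.out = 10), rep(1000, 10))
  on <- steady_state_onset(mk(lens), window = 100, tol_frac = 0.02)
  expect_true(is.finite(on))
  expect_gte(on, 400)
})
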