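test_that("diffusion hops conserve copies and reject bad moves", {
  st <- tiny_state(diameter = 2000,
                   config = list(use_grid = TRUE, compartment_edge_nm = 500))
  g <- st$grid
  vc <- which(g$valid)
  from <- vc[1]; to <- g$nbr[[from]][1]
  st$grid$counts[from, "G"] <- 5L
  diffusion_hop(st, "G", from, to)
  expect_equal(unname(st$grid$counts[c(from, to), "G"]), c(4L, 1L))
  expect_error(diffusion_hop(st, "G", to, from2 <- g$nbr[[to]][2]), NA)
  expect_error(diffusion_hop(st, "formin", from, to), "empty")
  far <- vc[length(vc)]
  expect_error(diffusion_hop(st, "G", from, far), "not neighbors")
})

test_that("symmetric diffusion equilibrates to a uniform occupancy", {
  set.seed(8)
  st <- tiny_state(diameter = 2000,
                   config = list(use_grid = TRUE, compartment_edge_nm = 500),
                   cp = quiet_chem(D_diff = 2e4))
  n_mol <- 400L
  scat(st, "G", n_mol)
  # long-run occupancy via the engine (hop rate D/l^2 per neighbor)
  occ <- rep(0, st$grid$n)
  nsamp <- 0
  for (rep in 1:60) {
    run_chemistry_window(st, st$time + 2, NULL)
    if (rep > 20) { occ <- occ + st$grid$counts[, "G"]; nsamp <- nsamp + 1 }
  }
  vc <- which(st$grid$valid)
  obs <- occ[vc] / nsamp
  expect_equal(sum(st$grid$counts[, "G"]), n_mol)  # conservation
  chi <- sum((obs - mean(obs))^2 / mean(obs)) * nsamp
  # chi^2 with ~|vc| dof, generous bound for autocorrelated samples
  expect_lt(chi / nsamp, 2 * length(vc))
})

test_that("polymerization grows ends and rolls over into new cylinders", {
  st <- tiny_state()
  sf <- sfil(c(-60, 0, 0), c(1, 0, 0), 39)
  addf(st, sf$verts, sf$nmono)
  scat(st, "G", 10)
  polymerize(st, 1L, "BE")
  expect_equal(st$fil[[1]]$nmono, 40L)
  polymerize(st, 1L, "BE")   # cylinder full: new collinear 1-monomer one
  expect_equal(st$fil[[1]]$nmono, c(40L, 1L))
  v <- st$fil[[1]]$verts
  d3 <- v[3, ] - v[2, ]
  expect_equal(sqrt(sum(d3^2)), 2.7, tolerance = 1e-9)
  expect_equal(d3 / 2.7, (v[2, ] - v[1, ]) / sqrt(sum((v[2, ] - v[1, ])^2)),
               tolerance = 1e-9)
  polymerize(st, 1L, "PE")   # first cylinder full: prepend a new one
  expect_equal(st$fil[[1]]$nmono, c(1L, 40L, 1L))
  st$grid$counts[1, "G"] <- 0L
  expect_error(polymerize(st, 1L, "BE"), "no local G-actin")
})

test_that("barbed-end elongation follows mass action through the engine", {
  set.seed(9)
  st <- tiny_state(diameter = 1200,
                   cp = quiet_chem(k_on_BE = 11.6))
  sf <- sfil(c(-30, 0, 0), c(1, 0, 0), 10)
  addf(st, sf$verts, sf$nmono)
  nG <- 2000L
  scat(st, "G", nG)
  conc0 <- copies_to_concentration(nG, effective_volume_L(st$geom))
  t_run <- 3
  run_chemistry_window(st, t_run, NULL)
  # G depletes exponentially at k_on * c1 per copy (c1 = one copy in uM):
  # expected additions are the integrated first-order decay
  c1 <- conc0 / nG
  expected <- nG * (1 - exp(-11.6 * c1 * t_run))
  got <- st$counters[["be_add"]]
  expect_lt(abs(got - expected) / expected, 3 / sqrt(expected) + 0.01)
})

test_that("depolymerization conserves monomers and hands off to
          destruction", {
  set.seed(10)
  st <- tiny_state(cp = quiet_chem())
  sf <- sfil(c(-10, 0, 0), c(1, 0, 0), 3)
  addf(st, sf$verts, sf$nmono)
  depolymerize(st, 1L, "PE")
  expect_equal(fil_monomers <- sum(st$fil[[1]]$nmono), 2L)
  expect_error(depolymerize(st, 1L, "PE"), "destruction")
  # engine view: depoly channels die, destruction becomes eligible
  mods <- actoring:::default_mods(st)
  Q <- actoring:::build_channels(st, mods)
  rows <- Q$rows_fil[["1"]]
  expect_equal(Q$a[rows[3]], 0)  # depoly BE off at 2 monomers
  st2 <- tiny_state(cp = quiet_chem(k_destruction = 1.9))
  sf2 <- sfil(c(-10, 0, 0), c(1, 0, 0), 2)
  addf(st2, sf2$verts, sf2$nmono)
  Q2 <- actoring:::build_channels(st2, actoring:::default_mods(st2))
  expect_equal(Q2$a[Q2$rows_fil[["1"]][5]], 1.9)
})

test_that("monomer count is conserved exactly over mixed event sequences", {
  set.seed(12)
  st <- tiny_state(diameter = 1600,
                   cp = chem_params(D_diff = 0, k_on_BE = 11.6,
                                    k_on_PE = 1.3, k_off_BE = 5,
                                    k_off_PE = 5, k_destruction = 1.9,
                                    k_nu = 0.05, k_off_formin = 0.1))
  for (k in 1:10) {
    p <- actoring:::sample_position_in(st, 1L)
    sf <- sfil(p, actoring:::sample_orientation(st$geom), 30)
    addf(st, sf$verts, sf$nmono)
  }
  scat(st, "G", 3000); scat(st, "formin", 60)
  tot0 <- actin_inventory(st)[["total"]]
  f0 <- formin_inventory(st)[["total"]]
  ev <- 0; w <- 0
  while (ev < 10500 && w < 400) {
    ev <- ev + run_chemistry_window(st, st$time + 0.25, NULL)$events
    w <- w + 1
  }
  expect_gt(ev, 10000)   # a real workout
  expect_identical(actin_inventory(st)[["total"]], tot0)
  expect_identical(formin_inventory(st)[["total"]], f0)
})

test_that("two-step nucleation has conserving stoichiometry", {
  st <- tiny_state(cp = quiet_chem(k_nu = 0.005))
  set.seed(13)
  scat(st, "formin", 1L); scat(st, "G", 3L)
  id <- nucleate_filament(st, 1L)
  expect_false(is.na(id))
  expect_equal(sum(st$fil[[id]]$nmono), 3L)
  expect_equal(st$fil[[id]]$barbed, "FBE")
  expect_equal(gtot(st$grid, "G"), 0L)
  expect_equal(gtot(st$grid, "formin"), 0L)
  expect_equal(gtot(st$grid, "intermediate"), 0L)
  # intermediate waits when G-actin is short
  st2 <- tiny_state(cp = quiet_chem(k_nu = 0.005))
  scat(st2, "formin", 1L); scat(st2, "G", 2L)
  id2 <- nucleate_filament(st2, 1L)
  expect_true(is.na(id2))
  expect_equal(gtot(st2$grid, "intermediate"), 1L)
  expect_error(nucleate_filament(st2, 1L), "requires")
})

test_that("nucleation propensity is k_nu per eligible formin", {
  set.seed(14)
  st <- tiny_state(diameter = 2000, cp = quiet_chem(k_nu = 0.005))
  scat(st, "formin", 100L); scat(st, "G", 100000L)
  run_chemistry_window(st, 100, NULL)
  # step-1 firings deplete formin; expected events solve dN/dt = -k N:
  # 100 (1 - e^-0.5) ~ 39.3
  expected <- 100 * (1 - exp(-0.005 * 100))
  got <- st$counters[["nuc"]]
  expect_lt(abs(got - expected), 3 * sqrt(expected))
})

test_that("formin dissociation frees the barbed end at the printed rate", {
  st <- tiny_state(cp = quiet_chem())
  set.seed(15)
  scat(st, "formin", 1L); scat(st, "G", 3L)
  id <- nucleate_filament(st, 1L)
  formin_dissociate(st, id)
  expect_equal(st$fil[[id]]$barbed, "BE")
  expect_equal(gtot(st$grid, "formin"), 1L)
  expect_error(formin_dissociate(st, id), "not formin-bound")
  # exponential survival: 200 formin-bound filaments, k = 0.01/s, 100 s
  set.seed(16)
  st2 <- tiny_state(diameter = 3000, cp = quiet_chem(k_off_formin = 0.01))
  for (k in 1:200) {
    p <- actoring:::sample_position_in(st2, 1L)
    sf <- sfil(p, actoring:::sample_orientation(st2$geom), 10)
    addf(st2, sf$verts, sf$nmono, barbed = "FBE")
  }
  run_chemistry_window(st2, 100, NULL)
  expected <- 200 * (1 - exp(-1))
  expect_lt(abs(gtot(st2$grid, "formin") - expected), 3 * sqrt(expected))
})

test_that("destruction removes 2-monomer filaments and recycles actin", {
  st <- tiny_state(cp = quiet_chem())
  sf <- sfil(c(-10, 0, 0), c(1, 0, 0), 2)
  addf(st, sf$verts, sf$nmono)
  destroy_filament(st, 1L)
  expect_null(st$fil[[1]])
  expect_equal(gtot(st$grid, "G"), 2L)
  sf3 <- sfil(c(-10, 0, 0), c(1, 0, 0), 3)
  addf(st, sf3$verts, sf3$nmono)
  expect_error(destroy_filament(st, 2L), "only to 2-monomer")
})

test_that("nucleation/disassembly balance yields a stationary filament
          count", {
  set.seed(17)
  st <- tiny_state(diameter = 2000,
                   cp = quiet_chem(k_nu = 0.05, k_off_PE = 3,
                                   k_destruction = 5, k_off_formin = 0.5))
  scat(st, "formin", 50L); scat(st, "G", 4000L)
  counts <- integer(60)
  for (w in 1:60) {
    run_chemistry_window(st, st$time + 2, NULL)
    counts[w] <- length(actoring:::fil_ids(st))
  }
  first <- mean(counts[31:45]); second <- mean(counts[46:60])
  expect_gt(first, 0)
  expect_lt(abs(second - first) / max(first, 1), 0.5)
})

test_that("binding-pair search matches the species span windows", {
  st <- tiny_state()
  two_parallel(st, 200)
  expect_gt(nrow(find_binding_pairs(st, "motor")), 0)
  expect_equal(nrow(find_binding_pairs(st, "linker")), 0)
  # short filaments so no axially offset site pair reaches the motor span
  st2 <- tiny_state()
  two_parallel(st2, 35, n_monomers = 20)
  expect_equal(nrow(find_binding_pairs(st2, "motor")), 0)
  expect_gt(nrow(find_binding_pairs(st2, "linker")), 0)
})

test_that("spatial-hash pair search equals the brute-force scan", {
  set.seed(18)
  for (rep in 1:3) {
    st <- tiny_state(diameter = 1600)
    for (k in 1:20) {
      p <- actoring:::sample_position_in(st, 1L)
      sf <- sfil(p, actoring:::sample_orientation(st$geom), 60)
      addf(st, sf$verts, sf$nmono)
    }
    for (sp in c("motor", "linker")) {
      a <- find_binding_pairs(st, sp)
      b <- brute_pairs(st, sp)
      expect_equal(a[, 1:6], b[, 1:6])
      expect_equal(a$dist, b$dist, tolerance = 1e-9)
    }
  }
})

test_that("motor binding sets a relaxed spring and samples heads
          uniformly", {
  set.seed(19)
  st <- tiny_state()
  two_parallel(st, 200)
  scat(st, "NMII", 5000L)
  prs <- find_binding_pairs(st, "motor")
  id <- bind_motor(st, prs[1, ])
  expect_equal(st$motors$l0[id], prs$dist[1], tolerance = 1e-9)
  sys <- actoring:::assemble_mechanics(st)
  eg <- actoring:::energy_gradient(sys$P, sys, st)
  expect_lt(eg$Ubr[["U_motor_str"]], 1e-12)
  unbind_element(st, "motor", id)
  # head-count sampling: uniform on 15..30
  draws <- integer(4000)
  for (k in seq_len(4000)) {
    id <- bind_motor(st, prs[1, ])
    draws[k] <- st$motors$n_heads[id]
    unbind_element(st, "motor", id)
  }
  expect_equal(gtot(st$grid, "NMII"), 5000L)  # conserved over cycles
  tab <- tabulate(draws - 14L, 16L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("binding sites are exclusively occupied per species class", {
  st <- tiny_state()
  two_parallel(st, 200)
  scat(st, "NMII", 10L)
  prs <- find_binding_pairs(st, "motor")
  bind_motor(st, prs[1, ])
  prs2 <- find_binding_pairs(st, "motor")
  # the used sites no longer appear among candidates
  expect_false(any(prs2$fa == prs$fa[1] & prs2$ca == prs$ca[1] &
                     prs2$sa == prs$sa[1]))
})

test_that("motor walking advances toward the barbed end and stops at the
          last site", {
  st <- tiny_state()
  two_parallel(st, 200, n_monomers = 80)
  scat(st, "NMII", 5L)
  prs <- find_binding_pairs(st, "motor")
  pick <- prs[which(prs$ca == 1 & prs$sa == 2)[1], ]
  id <- bind_motor(st, pick, n_heads = 20L)
  motor_walk(st, id, "a")
  expect_equal(st$motors$sa[id], pick$sa + 1L)
  # march to the barbed-most site
  for (k in 1:20) {
    nx <- actoring:::next_site_toward_barbed(st, id, "a")
    if (is.null(nx)) break
    motor_walk(st, id, "a")
  }
  expect_null(actoring:::next_site_toward_barbed(st, id, "a"))
  expect_error(motor_walk(st, id, "a"), "no next binding site")
})

test_that("unloaded walking speed matches the Poisson stepping rate", {
  set.seed(20)
  st <- tiny_state(diameter = 4000, cp = quiet_chem(k_walk0 = 7.4))
  # long antiparallel-ish pair: sites every 27 nm on full cylinders
  two_parallel(st, 200, n_monomers = 1200)
  scat(st, "NMII", 2L)
  prs <- find_binding_pairs(st, "motor")
  pick <- prs[which(prs$ca == 1 & prs$sa == 1)[1], ]
  id <- bind_motor(st, pick, n_heads = 20L)
  steps <- 0
  t_run <- 8
  st$motors$l0[id] <- 1e6   # slack spring: walking stays unloaded
  pos0 <- c(st$motors$ca[id], st$motors$sa[id])
  run_chemistry_window(st, t_run, NULL)
  pos1 <- c(st$motors$ca[id], st$motors$sa[id])
  steps <- (pos1[1] - pos0[1]) * 4 + (pos1[2] - pos0[2])
  # two ends walk independently; track end a only via site index
  expected <- 7.4 * t_run
  expect_lt(abs(steps - expected), 3 * sqrt(expected))
})

test_that("engine propensities equal a from-scratch recomputation", {
  set.seed(22)
  st <- tiny_state(diameter = 1600,
                   cp = chem_params(D_diff = 0, k_off_BE = 3, k_off_PE = 3,
                                    k_nu = 0.02, k_destruction = 1.5))
  for (k in 1:8) {
    p <- actoring:::sample_position_in(st, 1L)
    sf <- sfil(p, actoring:::sample_orientation(st$geom), 40)
    addf(st, sf$verts, sf$nmono)
  }
  scat(st, "G", 2000L); scat(st, "formin", 30L)
  scat(st, "NMII", 20L); scat(st, "linker", 50L)
  run_chemistry_window(st, 2, NULL)
  Q <- st$chanQ
  mods <- actoring:::default_mods(st)
  a_ref <- actoring:::channel_propensity(st, Q$kind, Q$e1, Q$e2, mods,
                                         Q$heads_next)
  expect_equal(Q$a, a_ref, tolerance = 1e-12)
})
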