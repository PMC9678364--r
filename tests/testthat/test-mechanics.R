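test_that("stretching energy is quadratic and symmetric", {
  expect_equal(stretch_energy(108, 108, 100), 0)
  expect_equal(stretch_energy(110, 108, 100), 200)   # 1/2*100*4
  expect_equal(stretch_energy(106, 108, 100), 200)   # compression symmetric
})

test_that("bending energy follows 1 - cos(theta)", {
  expect_equal(bend_energy(0, 672), 0)
  expect_equal(bend_energy(pi / 2, 672), 672)
  expect_equal(bend_energy(pi, 672), 1344)
  expect_equal(bend_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), pi / 2)
  expect_error(bend_angle(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)),
               "zero-length")
})

test_that("spring energy uses parallel-head motor stiffness", {
  expect_equal(spring_energy(200, 200, 55), 0)
  expect_equal(spring_energy(37, 35, 8), 16)          # linker +2 nm
  expect_equal(spring_energy(201, 200, 2.5 * 20), 25) # 20 heads, +1 nm
})

test_that("boundary repulsion decays exponentially from the shifted wall", {
  expect_equal(boundary_energy(100), 100)                # d = a0
  expect_equal(boundary_energy(100 + 2.7), 100 / exp(1))
  d <- seq(100, 400, by = 10)
  u <- boundary_energy(d)
  expect_true(all(diff(u) < 0))
  expect_lt(boundary_energy(1000), 1e-10)
})

test_that("excluded volume matches the far-field r^-4 asymptote", {
  L <- 1
  a1 <- c(0, 0, 0); b1 <- c(L, 0, 0)
  for (d in c(50, 100)) {
    u <- excluded_volume_energy(a1, b1, c(0, d, 0), c(L, d, 0), K_vol = 1e5)
    expect_equal(u, 1e5 * L^2 / d^4, tolerance = 0.01)
  }
  u1 <- excluded_volume_energy(a1, b1, c(0, 50, 0), c(L, 50, 0), K_vol = 1e5)
  u2 <- excluded_volume_energy(a1, b1, c(0, 100, 0), c(L, 100, 0),
                               K_vol = 1e5)
  expect_equal(u1 / u2, 16, tolerance = 0.01)
})

test_that("excluded volume quadrature matches an independent integrator", {
  skip_if_not_installed("pracma")
  set.seed(7)
  for (k in 1:20) {
    # separations comfortably beyond the segment lengths, where the
    # 16-point tensor rule is fully converged
    a1 <- runif(3, -50, 50); b1 <- a1 + runif(3, 10, 40)
    a2 <- a1 + c(0, runif(1, 80, 160), 0); b2 <- a2 + runif(3, 10, 40)
    L1 <- sqrt(sum((b1 - a1)^2)); L2 <- sqrt(sum((b2 - a2)^2))
    ref <- pracma::integral2(function(s, t) {
      dx <- (a1[1] + s * (b1[1] - a1[1])) - (a2[1] + t * (b2[1] - a2[1]))
      dy <- (a1[2] + s * (b1[2] - a1[2])) - (a2[2] + t * (b2[2] - a2[2]))
      dz <- (a1[3] + s * (b1[3] - a1[3])) - (a2[3] + t * (b2[3] - a2[3]))
      L1 * L2 / (dx^2 + dy^2 + dz^2)^2
    }, 0, 1, 0, 1, reltol = 1e-10)$Q
    u <- excluded_volume_energy(a1, b1, a2, b2, K_vol = 1, n = 16)
    expect_equal(u, ref, tolerance = 1e-6)
  }
})

test_that("near-intersecting segments are capped with a warning", {
  expect_warning(
    u <- excluded_volume_energy(c(-1, 0, 0), c(1, 0, 0),
                                c(0, -1, 0), c(0, 1, 0), K_vol = 1),
    "capped")
  expect_true(is.finite(u))
})

test_that("analytic gradients match central finite differences", {
  set.seed(11)
  for (rep in 1:3) {
    st <- tiny_state()
    sf <- sfil(c(-100, 0, 0), c(1, 0, 0), 100)
    addf(st, sf$verts + matrix(rnorm(length(sf$verts), 0, 4), ncol = 3),
         sf$nmono)
    sf2 <- sfil(c(-80, 35, 0), c(0.95, 0.31, 0), 85)
    addf(st, sf2$verts, sf2$nmono)
    scat(st, "linker", 3); scat(st, "NMII", 3)
    pl <- find_binding_pairs(st, "linker")
    pm <- find_binding_pairs(st, "motor")
    if (nrow(pl)) bind_linker(st, pl[1, ])
    if (nrow(pm)) bind_motor(st, pm[1, ])
    sys <- actoring:::assemble_mechanics(st)
    eg <- actoring:::energy_gradient(sys$P, sys, st)
    fd <- fd_gradient(st, sys$P, sys)
    expect_lt(max(abs(eg$G - fd)) / max(1, max(abs(fd))), 1e-5)
  }
})

test_that("excluded-volume gradients match finite differences", {
  set.seed(3)
  a1 <- runif(3, 0, 10); b1 <- a1 + runif(3, 5, 20)
  a2 <- a1 + c(0, 30, 0); b2 <- a2 + runif(3, 5, 20)
  ev <- excluded_volume_energy(a1, b1, a2, b2, K_vol = 1e3, grad = TRUE)
  h <- 1e-6
  for (pt in c("a1", "b1", "a2", "b2")) {
    for (k in 1:3) {
      pts <- list(a1 = a1, b1 = b1, a2 = a2, b2 = b2)
      pts[[pt]][k] <- pts[[pt]][k] + h
      up <- do.call(excluded_volume_energy,
                    c(unname(pts), list(K_vol = 1e3)))
      pts[[pt]][k] <- pts[[pt]][k] - 2 * h
      um <- do.call(excluded_volume_energy,
                    c(unname(pts), list(K_vol = 1e3)))
      expect_equal((up - um) / (2 * h), ev[[paste0("g_", pt)]][k],
                   tolerance = 1e-4)
    }
  }
})

test_that("compiled energy kernel agrees with the R reference", {
  set.seed(5)
  st <- tiny_state()
  sf <- sfil(c(-100, 0, 0), c(1, 0, 0), 100)
  addf(st, sf$verts + matrix(rnorm(length(sf$verts), 0, 5), ncol = 3),
       sf$nmono)
  sf2 <- sfil(c(-80, 35, 0), c(0.95, 0.31, 0), 85)
  addf(st, sf2$verts, sf2$nmono)
  scat(st, "linker", 3); scat(st, "NMII", 3)
  bind_linker(st, find_binding_pairs(st, "linker")[1, ])
  bind_motor(st, find_binding_pairs(st, "motor")[1, ])
  sys <- actoring:::assemble_mechanics(st)
  a <- actoring:::energy_gradient(sys$P, sys, st)
  b <- actoring:::energy_gradient_r(sys$P, sys, st)
  expect_equal(a$Ubr, b$Ubr, tolerance = 1e-12)
  expect_lt(max(abs(a$G - b$G)), 1e-9)
  expect_equal(a$tensions$motor, b$tensions$motor, tolerance = 1e-12)
})

test_that("minimization relaxes simple filaments to known minima", {
  # a stretched straight filament relaxes to its rest lengths
  st <- tiny_state()
  sf <- sfil(c(-150, 0, 0), c(1, 0, 0), 100)
  addf(st, sf$verts * 1.1, sf$nmono)      # 10% uniform stretch
  res <- minimize_state(st)
  expect_true(res$converged)
  expect_lt(res$energy[["U_fil_str"]] + res$energy[["U_fil_bend"]], 1e-4)
  # a bent two-cylinder filament straightens (tight force tolerance so
  # the soft bending mode is fully relaxed)
  st2 <- tiny_state(config = list(fire_tol = 0.02))
  verts <- rbind(c(-108, 0, 0), c(0, 0, 0), c(0, 108, 0))
  addf(st2, verts, c(40L, 40L))
  res2 <- minimize_state(st2)
  expect_true(res2$converged)
  expect_lt(res2$energy[["U_fil_bend"]], 1e-3)
})

test_that("both minimizers and an independent optimizer agree on a
          frustrated configuration", {
  # a filament longer than the disk chord must bend against the wall: the
  # minimum trades bending against boundary energy and is genuinely > 0
  build <- function(minimizer) {
    st <- tiny_state(diameter = 1200,
                     config = list(minimizer = minimizer,
                                   fire_tol = 0.01))
    # start on a circular arc near the buckled minimum so all optimizers
    # descend into the same basin
    n_mono <- 480; L <- n_mono * 2.7; r_arc <- 420
    phi <- seq(-L / (2 * r_arc), L / (2 * r_arc), length.out = 13)
    v <- cbind(r_arc * sin(phi), r_arc * (1 - cos(phi)), 0)
    addf(st, v, rep(40L, 12L))
    st
  }
  st <- build("lbfgs")
  res <- minimize_state(st)
  st2 <- build("fire")
  res2 <- minimize_state(st2)
  # independent route: conjugate gradients on the R-reference energy
  st3 <- build("lbfgs")
  sys <- actoring:::assemble_mechanics(st3)
  dm <- dim(sys$P)
  ref <- stats::optim(as.vector(sys$P),
                      function(x) actoring:::energy_gradient_r(
                        matrix(x, dm[1], dm[2]), sys, st3,
                        want_grad = FALSE)$U,
                      function(x) as.vector(actoring:::energy_gradient_r(
                        matrix(x, dm[1], dm[2]), sys, st3)$G),
                      method = "CG", control = list(maxit = 60000,
                                                    reltol = 1e-15))
  expect_gt(res$energy[["U_total"]], 1)   # genuinely frustrated
  # default minimizer against the independent optimizer: tight agreement
  expect_equal(res$energy[["U_total"]], ref$value, tolerance = 1e-3)
  # the inertial fallback reaches the same basin (it stops at its
  # iteration cap on this stiff landscape, so only coarse agreement)
  expect_equal(res$energy[["U_total"]], res2$energy[["U_total"]],
               tolerance = 0.1)
})

test_that("minimization never increases the energy and leaves chemistry
          untouched", {
  set.seed(31)
  st <- tiny_state()
  sf <- sfil(c(-150, 10, 0), c(1, 0.1, 0), 120)
  addf(st, sf$verts + matrix(rnorm(length(sf$verts), 0, 6), ncol = 3),
       sf$nmono)
  sys <- actoring:::assemble_mechanics(st)
  u0 <- actoring:::energy_gradient(sys$P, sys, st, want_grad = FALSE)$U
  nm0 <- st$fil[[1]]$nmono
  res <- minimize_state(st)
  expect_lte(res$energy[["U_total"]], u0 + 1e-9)
  expect_identical(st$fil[[1]]$nmono, nm0)
})

test_that("barbed-end load equals the boundary gradient at the end", {
  st <- tiny_state(diameter = 1000)
  # filament pointing radially outward, barbed end close to the wall
  sf <- sfil(c(100, 0, 0), c(1, 0, 0), 100)   # barbed end at x = 370
  addf(st, sf$verts, sf$nmono)
  # place barbed end near the shifted barrier (wall at x = 500, a0 = 100)
  st$fil[[1]]$verts[, 1] <- st$fil[[1]]$verts[, 1] + 25
  res <- minimize_state(st)
  # the reported load must equal the boundary gradient at the relaxed end
  V <- st$fil[[1]]$verts
  nv <- nrow(V)
  gb <- actoring:::boundary_field(V[nv, , drop = FALSE], st$geom, st$mp)$G
  u <- (V[nv, ] - V[nv - 1L, ])
  u <- u / sqrt(sum(u^2))
  expect_equal(res$end_loads[["1"]][["be"]], max(0, sum(gb * u)),
               tolerance = 1e-9)
  expect_gt(res$end_loads[["1"]][["be"]], 0)  # still pressing on the wall
})
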