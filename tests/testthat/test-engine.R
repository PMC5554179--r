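quick_protocol <- function(seed = NULL, ...) {
  sorption_protocol(h_start = 0.04, h_min = 0.04, h_max = 0.1,
                    relax_sweeps_per_step = 2, insertion_relax_sweeps = 3,
                    ramp_steps = 3, production_sweeps = 14,
                    equilibration_fraction = 1 / 7, frame_interval = 3,
                    prep_sweeps = 10, n_insertions = 500, seed = seed, ...)
}

test_that("relaxation preserves state for zero sweeps and accepts all ideal-gas
           moves", {
  cfg <- random_config(n_beads = 5, n_waters = 5, seed = 1)
  out <- relax(cfg, 0, 1)
  expect_identical(out$config$positions, cfg$positions)
  sp0 <- hs_species_table(bead_epsilon = 0, water_epsilon = 0)
  ideal <- random_config(n_beads = 5, n_waters = 5, seed = 2, species = sp0)
  set.seed(1)
  expect_equal(relax(ideal, 20, 1)$acceptance, 1)
})

test_that("relaxation samples the Boltzmann distribution of an LJ dimer", {
  # two waters in a periodic box: the sampled minimum-image separation must
  # follow p(r) ~ r^2 exp(-U(r)/T) for r below half the box
  t_ <- 1.0
  L <- 7
  rc <- 3.4
  cfg <- waters_at(rbind(c(1, 1, 1), c(2.2, 1, 1)), L = L, cutoff = rc)
  set.seed(99)
  out <- relax(cfg, 30000, t_, max_disp = 0.4, save_every = 5,
               water_jump_fraction = 0.5)
  r <- vapply(out$frames, function(f) {
    sqrt(sum(minimum_image(f$positions[2, ] - f$positions[1, ], f$box)^2))
  }, numeric(1))
  rmax <- L / 2 * 0.999
  r <- r[r < rmax]
  u <- function(x) ifelse(x >= rc, 0, 4 * ((1 / x)^12 - (1 / x)^6))
  dens <- function(x) x^2 * exp(-u(x) / t_)
  Z <- integrate(dens, 0, rmax, subdivisions = 500)$value
  cdf <- Vectorize(function(q) {
    integrate(dens, 0, q, subdivisions = 500)$value / Z
  })
  ks <- suppressWarnings(ks.test(r, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("removal candidates follow Boltzmann weights", {
  # two non-interacting waters: symmetric choice
  iso <- waters_at(rbind(c(2, 2, 2), c(12, 12, 12)), L = 24, cutoff = 3)
  set.seed(5)
  picks <- replicate(4000, select_removal_candidate(iso, 1))
  f1 <- mean(picks == 1)
  expect_lt(abs(f1 - 0.5), 3 * sqrt(0.25 / 4000))
  # a strongly bound water is (almost) never removed before a free one
  bound <- waters_at(rbind(c(2, 2, 2), c(2 + 2^(1 / 6) * 0.2, 2, 2),
                           c(12, 12, 12)),
                     L = 24, cutoff = 3)
  bound$species <- hs_species_table(water_epsilon = 50, water_sigma = 0.2)
  set.seed(6)
  picks2 <- replicate(300, select_removal_candidate(bound, 0.5))
  expect_true(all(picks2 == 3))
  # three-water fixture: frequencies match exact normalized weights
  tri <- waters_at(rbind(c(2, 2, 2), c(3.1, 2, 2), c(4.4, 2, 2)),
                   L = 20, cutoff = 5)
  t_ <- 0.9
  du <- vapply(1:3, function(i) delta_energy_remove(tri, i), numeric(1))
  w <- exp(-du / t_)
  p_exact <- w / sum(w)
  set.seed(7)
  picks3 <- replicate(20000, select_removal_candidate(tri, t_))
  obs <- tabulate(picks3, 3)
  expect_gt(chisq.test(obs, p = p_exact)$p.value, 0.001)
  expect_error(select_removal_candidate(random_config(n_waters = 0, seed = 1),
                                        1), "water")
})

test_that("removal steps keep the water ledger and descend in energy at low
           temperature", {
  cfg <- random_config(n_beads = 6, n_waters = 4, seed = 12)
  p <- quick_protocol()
  set.seed(31)
  out <- remove_water_step(cfg, p)
  expect_equal(n_waters(out), 3L)
  expect_equal(hydration_level(cfg) - hydration_level(out),
               18 / (6 * 110), tolerance = 1e-12)
  one <- waters_at(rbind(c(1, 1, 1)), L = 10)
  one$species_ids <- 3L
  # a single-water system empties in one step (needs a bead for h bookkeeping)
  single <- random_config(n_beads = 3, n_waters = 1, seed = 4)
  expect_equal(n_waters(remove_water_step(single, p)), 0L)
  # relaxation at low T lowers the energy after deletion, in expectation
  pl <- quick_protocol(temperature = 0.05)
  pl$relax_sweeps_per_step <- 10
  drops <- vapply(1:10, function(s) {
    set.seed(400 + s)
    dense <- random_config(n_beads = 8, n_waters = 8, seed = 90,
                           min_sep = 0.95)
    i <- select_removal_candidate(dense, pl$temperature)
    after_del <- remove_water(dense, i)
    e0 <- pair_energy(after_del)$total
    relaxed <- relax(after_del, pl$relax_sweeps_per_step, pl$temperature)
    pair_energy(relaxed$config)$total - e0
  }, numeric(1))
  expect_lt(mean(drops), 0)
})

test_that("continuous insertion ends fully coupled with finite energies", {
  cfg <- random_config(n_beads = 8, n_waters = 6, seed = 3)
  p <- quick_protocol()
  set.seed(21)
  out <- insert_water_continuous(cfg, p)
  expect_null(out$coupling)
  expect_equal(n_waters(out), 7L)
  expect_true(is.finite(pair_energy(out)$total))
  # single-step ramp degenerates to discrete insertion plus relaxation
  p1 <- quick_protocol()
  p1$ramp_steps <- 1
  set.seed(22)
  out1 <- insert_water_continuous(cfg, p1)
  expect_null(out1$coupling)
  expect_equal(n_waters(out1), 7L)
  # soft-core ramp stays finite even from a near-overlapping start
  crowd <- random_config(n_beads = 10, n_waters = 10, seed = 8, L = 5.5,
                         min_sep = 0.85, cutoff = 2.5)
  pc <- quick_protocol()
  pc$insertion_min_sep <- 0.2  # allow placements deep inside the repulsion
  set.seed(23)
  traj <- add_water(crowd, hydrosorb:::.find_insertion_point(crowd, pc),
                    lambda = 0)
  for (l in seq(0, 1, by = 0.1)) {
    expect_true(is.finite(lambda_scaled_energy(traj, l)))
  }
  # an over-packed box reports an insertion failure with the density
  jam <- quick_protocol()
  jam$insertion_min_sep <- 5
  jam$insertion_max_attempts <- 50
  expect_error(insert_water_continuous(cfg, jam), "density")
})

test_that("branches visit the hydration grid in order and conserve counts", {
  # bead mass chosen so one water spans one 0.02 g/g grid interval
  sp <- hs_species_table(bead_mass = 300)
  m <- generate_matrix(matrix_spec(n_chains = 1, chain_length = 3,
                                   bonded = TRUE, box_density = 0.05,
                                   seed = 2, species = sp,
                                   anneal_sweeps = 5))
  p <- quick_protocol()
  set.seed(77)
  m <- solvate(m, 0.04, p)
  expect_equal(n_waters(m), 2L)
  ads <- run_branch(m, p, "adsorb")
  h_seen <- vapply(ads$points, `[[`, numeric(1), "h")
  expect_equal(h_seen, c(0.04, 0.06, 0.08, 0.10), tolerance = 1e-9)
  expect_true(all(vapply(ads$points, function(pt) length(pt$frames) > 0,
                         logical(1))))
  des <- run_branch(ads$config, p, "desorb")
  expect_equal(vapply(des$points, `[[`, numeric(1), "h"),
               c(0.10, 0.08, 0.06, 0.04), tolerance = 1e-9)
  # a full adsorb/desorb loop returns the starting water count exactly
  expect_equal(n_waters(des$config), n_waters(m))
  # every insertion/removal is logged, one event per unit water change
  expect_equal(nrow(ads$events), 3)
  expect_true(all(ads$events$action == "insert"))
  expect_equal(diff(c(2L, ads$events$n_waters)), rep(1L, 3))
  expect_true(all(des$events$action == "remove"))
  expect_equal(des$events$n_waters, 4:2)
})

test_that("hysteresis area and maximum gap follow the quadrature rules", {
  h <- seq(0, 0.2, by = 0.02)
  same <- data.frame(h = h, rh = 50 + 100 * h)
  eq <- hysteresis_area(same, same)
  expect_equal(eq$area, 0)
  expect_equal(eq$max_gap, 0)
  # rectangle: constant 10-point RH offset over 0.2 g/g -> area 2
  rect <- hysteresis_area(data.frame(h = h, rh = rep(30, length(h))),
                          data.frame(h = h, rh = rep(20, length(h))))
  expect_equal(rect$area, 2)
  expect_equal(rect$max_gap, 10)
  # piecewise-linear synthetic branches against fine-grid quadrature
  set.seed(50)
  ha <- seq(0.04, 0.3, by = 0.02)
  ads <- data.frame(h = ha, rh = 20 + 250 * ha + rnorm(length(ha), 0, 3))
  des <- data.frame(h = ha, rh = 10 + 230 * ha + rnorm(length(ha), 0, 3))
  got <- hysteresis_area(ads, des)
  fine <- seq(0.04, 0.3, length.out = 4001)
  gap <- approx(ads$h, ads$rh, fine)$y - approx(des$h, des$rh, fine)$y
  want <- sum(diff(fine) * (head(gap, -1) + tail(gap, -1)) / 2)
  expect_equal(got$area, want, tolerance = 1e-6)
  expect_error(hysteresis_area(ads, data.frame(h = c(0.5, 0.6), rh = 1:2)),
               "overlap")
})

test_that("uptake at a target humidity interpolates the monotone envelope", {
  br <- data.frame(h = c(0.1, 0.2, 0.3, 0.4), rh = c(20, 60, 50, 90))
  expect_equal(uptake_at_rh(br, 40), 0.15)
  expect_equal(uptake_at_rh(br, 90), 0.4)
  expect_equal(uptake_at_rh(br, 95), Inf)
  expect_equal(uptake_at_rh(br, 10), 0.1)
})

test_that("identical protocol and seed reproduce an isotherm bit for bit", {
  sp <- hs_species_table(bead_mass = 300)
  spec <- matrix_spec(n_chains = 2, chain_length = 3, box_density = 0.05,
                      seed = 6, species = sp, anneal_sweeps = 5)
  p <- quick_protocol(seed = 314)
  mu_sat <- mu_saturation(p$temperature, 0.002)
  iso1 <- run_isotherm(generate_matrix(spec), p, mu_sat)
  iso2 <- run_isotherm(generate_matrix(spec), p, mu_sat)
  expect_identical(iso1$records, iso2$records)
  expect_identical(iso1$final_config$positions, iso2$final_config$positions)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_isotherm_csv(iso1, f1)
  write_isotherm_csv(iso2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_isotherm_csv(f1)
  expect_equal(back$h, iso1$records$h, tolerance = 1e-10)
})
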