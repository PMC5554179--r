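test_that("SASA matches closed-form sphere results", {
  sp <- hs_species_table()
  lone <- hs_configuration(matrix(c(5, 5, 5), 1), 1L, FALSE, hs_box(rep(10, 3)),
                           species = sp, cutoff = 3, validate = FALSE)
  probe <- 0.5
  R <- sp$sasa_radius[1] + probe
  got <- sasa(lone, probe_radius = probe)
  expect_equal(got$total, 4 * pi * R^2, tolerance = 0.01 * 4 * pi * R^2)
  # near-coincident pair: the shared surface is split between the two
  twin <- hs_configuration(rbind(c(5, 5, 5), c(5 + 1e-9, 5, 5)), c(1L, 1L),
                           c(FALSE, FALSE), hs_box(rep(10, 3)), species = sp,
                           cutoff = 3, validate = FALSE)
  expect_equal(sasa(twin, probe_radius = probe)$total, 4 * pi * R^2,
               tolerance = 0.02 * 4 * pi * R^2)
  # general two-sphere case against the spherical-cap formula
  sp2 <- sp
  sp2$sasa_radius <- c(0.7, 0.4, 0.5)
  for (d in c(0.9, 1.2, 1.5)) {
    two <- hs_configuration(rbind(c(4, 4, 4), c(4 + d, 4, 4)), c(1L, 2L),
                            c(FALSE, FALSE), hs_box(rep(12, 3)), species = sp2,
                            cutoff = 3, validate = FALSE)
    want <- oracle_two_sphere_area(0.7 + probe, 0.4 + probe, d)
    got <- sasa(two, probe_radius = probe, n_sphere_points = 960)$total
    expect_equal(got, want, tolerance = 0.01 * want)
  }
})

test_that("SASA never grows when a particle is buried deeper", {
  sp <- hs_species_table()
  area_at <- function(d) {
    cfg <- hs_configuration(rbind(c(5, 5, 5), c(5 + d, 5, 5), c(5, 6.5, 5)),
                            rep(1L, 3), rep(FALSE, 3), hs_box(rep(12, 3)),
                            species = sp, cutoff = 3, validate = FALSE)
    sasa(cfg)$total
  }
  areas <- vapply(c(2.2, 1.6, 1.1, 0.7, 0.3, 0.05), area_at, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("radius of gyration matches closed forms and the direct formula", {
  box <- hs_box(rep(20, 3))
  mk <- function(pos, bonds = NULL, chains = rep(1L, nrow(pos))) {
    hs_configuration(pos, rep(1L, nrow(pos)), rep(FALSE, nrow(pos)), box,
                     topology = hs_topology(bonds), chain_ids = chains,
                     cutoff = 3, validate = FALSE)
  }
  # two particles at distance d: Rg = d/2
  expect_equal(radius_of_gyration(mk(rbind(c(1, 1, 1), c(4, 1, 1))))$mean,
               1.5, tolerance = 1e-12)
  # unit cube corners: Rg = a sqrt(3) / 2
  a <- 2
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * a + 3
  expect_equal(radius_of_gyration(mk(corners))$mean, a * sqrt(3) / 2,
               tolerance = 1e-12)
  # bonded chain crossing the periodic boundary unwraps correctly
  chain <- rbind(c(19, 5, 5), c(19.8, 5, 5), c(0.6, 5, 5), c(1.4, 5, 5))
  bonded <- mk(chain, bonds = cbind(1:3, 2:4, 10, 0.8))
  straight <- mk(sweep(chain, 1, c(0, 0.8, 1.6, 2.4) - chain[, 1], `+`) * 0 +
                   cbind(c(0, 0.8, 1.6, 2.4) + 5, rep(5, 4), rep(5, 4)),
                 bonds = cbind(1:3, 2:4, 10, 0.8))
  expect_equal(radius_of_gyration(bonded)$mean,
               radius_of_gyration(straight)$mean, tolerance = 1e-12)
  # random group against the mass-weighted definition
  set.seed(8)
  pos <- matrix(runif(60, 4, 9), ncol = 3)
  sp <- hs_species_table()
  got <- radius_of_gyration(mk(pos))$mean
  m <- rep(sp$mass[1], 20)
  com <- colSums(pos * m) / sum(m)
  want <- sqrt(sum(m * rowSums(sweep(pos, 2, com)^2)) / sum(m))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("distance maps average per-frame shortest distances", {
  box <- hs_box(rep(30, 3))
  mk <- function(p1, p2) {
    hs_configuration(rbind(p1, p2), c(1L, 1L), c(FALSE, FALSE), box,
                     residue_ids = c(1L, 2L), cutoff = 3, validate = FALSE)
  }
  frames <- list(mk(c(1, 1, 1), c(6, 1, 1)), mk(c(2, 2, 2), c(7, 2, 2)))
  dm <- residue_distance_map(frames)
  expect_equal(dm$map[1, 2], 5)
  expect_equal(diag(dm$map), c(0, 0), ignore_attr = TRUE)
  expect_true(isSymmetric(unname(dm$map)))
  # brute-force triple loop on residues with several atoms each
  set.seed(14)
  nres <- 3
  frames2 <- lapply(1:2, function(f) {
    hs_configuration(matrix(runif(36, 0, 12), ncol = 3), rep(1L, 12),
                     rep(FALSE, 12), hs_box(rep(12, 3)),
                     residue_ids = rep(1:3, each = 4), cutoff = 3,
                     validate = FALSE)
  })
  got <- residue_distance_map(frames2)$map
  want <- matrix(0, nres, nres)
  for (i in 1:nres) for (j in 1:nres) {
    if (i == j) next
    per_frame <- vapply(frames2, function(fr) {
      ai <- which(fr$residue_ids == i)
      aj <- which(fr$residue_ids == j)
      m <- Inf
      for (a in ai) for (b in aj) {
        dv <- .owrap(fr$positions[b, ] - fr$positions[a, ], 12)
        m <- min(m, sqrt(sum(dv^2)))
      }
      m
    }, numeric(1))
    want[i, j] <- mean(per_frame)
  }
  expect_equal(unname(got), want, tolerance = 1e-12)
  # elementwise difference and shape checking
  expect_equal(unname(distance_map_difference(got, got)), matrix(0, 3, 3))
  expect_equal(unname(distance_map_difference(got * 1.1, got)),
               unname(got) * 0.1, tolerance = 1e-12)
  expect_error(distance_map_difference(got, matrix(0, 2, 2)), "dimension")
})

test_that("water clustering finds components, sizes and fractions", {
  row3 <- waters_at(cbind(c(0, 3, 6), 10, 10), L = 50, cutoff = 5)
  cl <- water_clusters(row3, cutoff = 3.5)
  expect_equal(cl$sizes, 3L)
  expect_equal(cl$largest_fraction, 1)
  sparse <- waters_at(cbind(c(0, 4, 8), 10, 10), L = 50, cutoff = 5)
  cl2 <- water_clusters(sparse, cutoff = 3.5)
  expect_equal(cl2$sizes, c(1L, 1L, 1L))
  expect_equal(cl2$largest_fraction, 1 / 3)
  # partition agrees with BFS on the minimum-image contact graph
  set.seed(9)
  for (k in 1:3) {
    fr <- waters_at(matrix(runif(90, 0, 12), ncol = 3), L = 12, cutoff = 3)
    got <- water_clusters(fr, cutoff = 1.4)
    want <- oracle_components(fr, 1.4)
    expect_equal(length(got$sizes), max(want))
    expect_equal(sort(got$sizes), sort(as.integer(table(want))))
    # same-component iff same-label
    expect_true(all(outer(got$labels, got$labels, `==`) ==
                      outer(want, want, `==`)))
  }
})

test_that("cluster results are invariant to relabeling and translation", {
  set.seed(10)
  fr <- waters_at(matrix(runif(60, 0, 10), ncol = 3), L = 10, cutoff = 3)
  base <- water_clusters(fr, cutoff = 1.5)
  # rigid translation mod box
  tr <- fr
  tr$positions <- (fr$positions + rep(c(3.3, -2.1, 7.7), each = 20)) %% 10
  moved <- water_clusters(tr, cutoff = 1.5)
  expect_equal(sort(moved$sizes), sort(base$sizes))
  expect_equal(moved$spanning, base$spanning)
  # permutation of particle order
  perm <- sample(20)
  pm <- fr
  pm$positions <- fr$positions[perm, ]
  permuted <- water_clusters(pm, cutoff = 1.5)
  expect_equal(sort(permuted$sizes), sort(base$sizes))
  expect_equal(permuted$spanning, base$spanning)
})

test_that("spanning detection matches the 3x3x3 replication oracle", {
  box <- hs_box(rep(12, 3))
  span <- generate_percolation_fixture(box, spacing = 1.2, spanning = TRUE,
                                       seed = 5, n_scatter = 4)
  got <- water_clusters(span, cutoff = 1.5)
  expect_true(got$spanning[1])
  expect_equal(got$spanning, oracle_spanning(span, 1.5))
  broken <- generate_percolation_fixture(box, spacing = 1.2, spanning = FALSE,
                                         seed = 5, n_scatter = 4)
  got2 <- water_clusters(broken, cutoff = 1.5)
  expect_false(got2$spanning[1])
  expect_equal(got2$spanning, oracle_spanning(broken, 1.5))
  # random dense fields
  set.seed(20)
  for (k in 1:3) {
    fr <- waters_at(matrix(runif(3 * 40, 0, 7), ncol = 3), L = 7, cutoff = 3)
    expect_equal(water_clusters(fr, cutoff = 1.2)$spanning,
                 oracle_spanning(fr, 1.2))
  }
})

test_that("largest-cluster curve reports planted fractions", {
  # two planted clusters of 7 and 3 waters far apart -> fraction 0.7
  tight <- function(center, n, spread = 0.3) {
    sweep(matrix(runif(3 * n, -spread, spread), ncol = 3), 2, center, `+`)
  }
  fr <- waters_at(rbind(tight(c(3, 3, 3), 7), tight(c(12, 12, 12), 3)),
                  L = 18, cutoff = 3)
  curve <- largest_cluster_curve(list(`0.1` = list(fr, fr, fr, fr, fr)),
                                 cutoff = 1.5)
  expect_equal(curve$largest_fraction, 0.7)
  expect_equal(curve$stderr, 0)
  # all singletons -> 1/N
  lone <- waters_at(cbind(seq(1, 16, by = 3), 8, 8), L = 18, cutoff = 3)
  c2 <- largest_cluster_curve(list(`0.2` = list(lone)), cutoff = 1.5)
  expect_equal(c2$largest_fraction, 1 / 6)
})

test_that("shell count distributions match brute-force counting", {
  box <- hs_box(rep(20, 3))
  # one centre with 4 partners inside the shell -> point mass at 4
  pos <- rbind(c(10, 10, 10), c(11, 10, 10), c(10, 11, 10), c(9, 10, 10),
               c(10, 10, 11), c(10, 3, 3))
  cfg <- hs_configuration(pos, rep(1L, 6), rep(FALSE, 6), box, cutoff = 3,
                          validate = FALSE)
  h <- shell_count_distribution(list(cfg), centers = 1, partners = 2:6,
                                cutoff = 2)
  expect_equal(h$counts$prob[h$counts$count == 4], 1)
  expect_equal(sum(h$counts$prob), 1, tolerance = 1e-12)
  # empty partner set -> point mass at zero
  h0 <- shell_count_distribution(list(cfg), centers = 1:3,
                                 partners = integer(0), cutoff = 2)
  expect_equal(h0$counts$prob, 1)
  expect_equal(h0$counts$count, 0L)
  # random frames against an independent double loop
  set.seed(33)
  fr <- waters_at(matrix(runif(120, 0, 9), ncol = 3), L = 9, cutoff = 3)
  centers <- 1:15; partners <- 10:40
  got <- shell_count_distribution(list(fr), centers, partners, cutoff = 2.2)
  counts <- vapply(centers, function(i) {
    n <- 0
    for (j in partners) {
      if (j == i) next
      dv <- .owrap(fr$positions[j, ] - fr$positions[i, ], 9)
      if (sum(dv^2) < 2.2^2) n <- n + 1
    }
    n
  }, numeric(1))
  want <- table(factor(counts, levels = 0:max(counts))) / length(counts)
  expect_equal(got$counts$prob, as.numeric(want), tolerance = 1e-12)
  expect_equal(got$mean_count, mean(counts))
})

test_that("the radial distribution function is flat for an ideal gas and
           localized for a fixed pair", {
  set.seed(44)
  frames <- lapply(1:25, function(k) {
    waters_at(matrix(runif(3 * 150, 0, 10), ncol = 3), L = 10, cutoff = 3)
  })
  g <- rdf(frames, 1:150, 1:150, r_max = 4.5, n_bins = 15)
  expect_lt(abs(mean(g$g) - 1), 0.05)
  expect_true(all(abs(g$g - 1) < 0.25))
  pairf <- waters_at(rbind(c(2, 5, 5), c(4.5, 5, 5)), L = 10, cutoff = 3)
  g2 <- rdf(list(pairf), 1, 2, r_max = 4, n_bins = 16)
  expect_equal(sum(g2$g > 0), 1)
  expect_equal(g2$r[g2$g > 0], 2.625)  # the bin holding r = 2.5
})

test_that("first_minimum locates the dip of a constructed g(r)", {
  f <- function(r) 1 + exp(-((r - 1) / 0.2)^2) - 0.6 * exp(-((r - 1.7) / 0.3)^2)
  r <- seq(0.025, 3, by = 0.05)
  g <- data.frame(r = r, g = f(r))
  true_min <- optimize(f, c(1.2, 2.2))$minimum
  expect_equal(first_minimum(g), true_min, tolerance = 0.05)
  expect_error(first_minimum(data.frame(r = r, g = rep(1, length(r)))),
               "maximum")
})

test_that("residue-level hydration differences detect planted asymmetry", {
  box <- hs_box(rep(40, 3))
  sp <- hs_species_table()
  mk <- function(extra_at_2 = 0) {
    bead <- rbind(c(5, 5, 5), c(20, 20, 20), c(35, 35, 35))
    wat <- rbind(c(6, 5, 5), c(21, 20, 20))
    if (extra_at_2 > 0) {
      wat <- rbind(wat, sweep(matrix(runif(3 * extra_at_2, -0.8, 0.8),
                                     ncol = 3), 2, c(20, 20, 21), `+`))
    }
    hs_configuration(rbind(bead, wat), c(rep(1L, 3), rep(3L, nrow(wat))),
                     c(rep(FALSE, 3), rep(TRUE, nrow(wat))), box,
                     species = sp, residue_ids = c(1:3, rep(0L, nrow(wat))),
                     cutoff = 3, validate = FALSE)
  }
  set.seed(3)
  ads <- lapply(1:5, function(k) mk(extra_at_2 = 2))
  des <- lapply(1:5, function(k) mk(extra_at_2 = 0))
  # identical sets give zero difference
  same <- local_hydration_difference(ads, ads, cutoff = 2.5)
  expect_true(all(same$difference == 0))
  # planted +2 waters at residue 2, matched elsewhere
  d <- local_hydration_difference(ads, des, cutoff = 2.5, h_tol = 1)
  expect_equal(d$difference[d$residue == "2"], 2)
  expect_equal(d$difference[d$residue == "1"], 0)
  expect_equal(d$difference[d$residue == "3"], 0)
  # swapping inputs negates the result
  dr <- local_hydration_difference(des, ads, cutoff = 2.5, h_tol = 1)
  expect_equal(dr$difference, -d$difference)
  # mismatched hydration levels are rejected
  expect_error(local_hydration_difference(ads, des, cutoff = 2.5,
                                          h_tol = 1e-9), "differ")
})

test_that("block averaging implements the 5-block convention", {
  expect_equal(block_average(rep(2.5, 40))$stderr, 0)
  ba <- block_average(1:5, 5)
  expect_equal(ba$mean, 3)
  expect_equal(ba$stderr, sd(1:5) / sqrt(5))
  # trailing remainder dropped: blocks of 2 from the first 10 elements
  ba2 <- block_average(c(1:10, 1000), 5)
  expect_equal(ba2$mean, mean(vapply(1:5, function(b)
    mean(c(2 * b - 1, 2 * b)), numeric(1))))
  expect_error(block_average(1:3, 5), "shorter")
})
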