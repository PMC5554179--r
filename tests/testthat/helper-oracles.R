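# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive every quantity with plain R loops, sharing no code
# with the package internals they check.

# shortest displacement by explicit search over the 27 neighbour images
oracle_min_image <- function(d, box) {
  best <- d
  bn <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    off <- c(i, j, k) * box$lengths * as.numeric(box$periodic)
    v <- d + off
    if (sum(v^2) < bn) {
      bn <- sum(v^2)
      best <- v
    }
  }
  best
}

.owrap <- function(d, L) d - L * floor(d / L + 0.5)

# plain double-loop energy with the same model contract: LJ with
# Lorentz-Berthelot mixing, affinity-scaled water-bead wells, bonded pairs
# excluded from the pair sum, soft-core lambda scaling, harmonic bonds and
# tethers
oracle_energy <- function(cfg, cutoff = cfg$cutoff) {
  sp <- cfg$species
  n <- nrow(cfg$positions)
  eps <- sp$epsilon[cfg$species_ids]
  sig <- sp$sigma[cfg$species_ids]
  aff <- sp$affinity[cfg$species_ids]
  isw <- cfg$is_water
  L <- cfg$box$lengths
  per <- cfg$box$periodic
  wrap3 <- function(d) ifelse(per, .owrap(d, L), d)
  b <- rbind(cfg$topology$chain_bonds, cfg$topology$crosslinks)
  excl <- matrix(FALSE, n, n)
  if (NROW(b) > 0) {
    for (r in seq_len(nrow(b))) {
      excl[b[r, 1], b[r, 2]] <- TRUE
      excl[b[r, 2], b[r, 1]] <- TRUE
    }
  }
  cp <- cfg$coupling
  pair <- 0; coup <- 0
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (excl[i, j]) next
        dv <- wrap3(cfg$positions[j, ] - cfg$positions[i, ])
        r2 <- sum(dv^2)
        if (r2 >= cutoff^2) next
        sij <- (sig[i] + sig[j]) / 2
        e <- sqrt(eps[i] * eps[j])
        if (isw[i] != isw[j]) e <- e * if (isw[i]) aff[j] else aff[i]
        lam <- 1
        coupled <- !is.null(cp) && (i == cp$index || j == cp$index)
        if (coupled) {
          lam <- cp$lambda
          r2 <- r2 + cfg$softcore_alpha * (1 - lam) * sij^2
        }
        s6 <- (sij^2 / r2)^3
        u <- lam * 4 * e * (s6^2 - s6)
        if (coupled) coup <- coup + u else pair <- pair + u
      }
    }
  }
  bonded <- 0
  if (NROW(b) > 0) {
    for (r in seq_len(nrow(b))) {
      dv <- wrap3(cfg$positions[b[r, 2], ] - cfg$positions[b[r, 1], ])
      bonded <- bonded + 0.5 * b[r, 3] * (sqrt(sum(dv^2)) - b[r, 4])^2
    }
  }
  tt <- cfg$topology$tethers
  if (NROW(tt) > 0) {
    for (r in seq_len(nrow(tt))) {
      dv <- wrap3(cfg$positions[tt[r, 1], ] - tt[r, 3:5])
      bonded <- bonded + 0.5 * tt[r, 2] * sum(dv^2)
    }
  }
  list(pair = unname(pair), bonded = unname(bonded), coupling = unname(coup),
       total = unname(pair + bonded + coup))
}

# analytic accessible area of two overlapping spheres (spherical caps)
oracle_two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  if (d <= abs(R1 - R2)) return(4 * pi * max(R1, R2)^2)
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- (d^2 + R2^2 - R1^2) / (2 * d)
  a1 <- 4 * pi * R1^2 - 2 * pi * R1 * (R1 - x1)
  a2 <- 4 * pi * R2^2 - 2 * pi * R2 * (R2 - x2)
  a1 + a2
}

# water connectivity by BFS on the minimum-image contact graph: returns the
# component label of every water (independent of union-find bookkeeping)
oracle_components <- function(frame, cutoff) {
  pos <- frame$positions[frame$is_water, , drop = FALSE]
  n <- nrow(pos)
  L <- frame$box$lengths
  per <- frame$box$periodic
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dv <- pos[j, ] - pos[i, ]
      dv <- ifelse(per, .owrap(dv, L), dv)
      adj[i, j] <- sum(dv^2) < cutoff^2
    }
  }
  comp <- integer(n)
  k <- 0
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    k <- k + 1
    q <- s
    comp[s] <- k
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      nb <- which(adj[v, ] & comp == 0)
      comp[nb] <- k
      q <- c(q, nb)
    }
  }
  comp
}

# spanning detection by explicit 3x3x3 replication: a cluster percolates
# along an axis iff some component of the replicated (open) contact graph
# contains two copies of the same water from cells differing on that axis
oracle_spanning <- function(frame, cutoff) {
  pos <- frame$positions[frame$is_water, , drop = FALSE]
  n <- nrow(pos)
  L <- frame$box$lengths
  cells <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  P <- NULL; base <- integer(0); cell_id <- NULL
  for (r in seq_len(nrow(cells))) {
    P <- rbind(P, sweep(pos, 2, cells[r, ] * L, `+`))
    base <- c(base, seq_len(n))
    cell_id <- rbind(cell_id, matrix(cells[r, ], n, 3, byrow = TRUE))
  }
  D <- as.matrix(dist(P))
  adj <- D < cutoff
  comp <- integer(nrow(P))
  k <- 0
  for (s in seq_len(nrow(P))) {
    if (comp[s] > 0) next
    k <- k + 1
    q <- s
    comp[s] <- k
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      nb <- which(adj[v, ] & comp == 0)
      comp[nb] <- k
      q <- c(q, nb)
    }
  }
  span <- c(FALSE, FALSE, FALSE)
  for (cc in seq_len(k)) {
    idx <- which(comp == cc)
    for (ax in 1:3) {
      for (b in unique(base[idx])) {
        if (length(unique(cell_id[idx[base[idx] == b], ax])) > 1) {
          span[ax] <- TRUE
        }
      }
    }
  }
  span
}

# random mixed bead/water configuration with a safe minimum separation
random_config <- function(n_beads = 6, n_waters = 6, L = 8, seed = 1,
                          bonds = FALSE, crosslink = FALSE, tether = FALSE,
                          coupling_lambda = NULL, min_sep = 0.9,
                          cutoff = 3.0, species = hs_species_table()) {
  set.seed(seed)
  n <- n_beads + n_waters
  pos <- matrix(NA_real_, n, 3)
  placed <- 0
  while (placed < n) {
    p <- runif(3) * L
    ok <- TRUE
    if (placed > 0) {
      d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, p)
      d <- .owrap(d, L)
      ok <- all(rowSums(d^2) >= min_sep^2)
    }
    if (ok) {
      placed <- placed + 1
      pos[placed, ] <- p
    }
  }
  sid <- c(sample(1:2, n_beads, replace = TRUE), rep(3L, n_waters))
  isw <- c(rep(FALSE, n_beads), rep(TRUE, n_waters))
  cb <- if (bonds && n_beads > 1) {
    cbind(1:(n_beads - 1), 2:n_beads, 25, 1.0)
  } else NULL
  xl <- if (crosslink && n_beads >= 4) cbind(1, n_beads, 30, 1.2) else NULL
  tt <- if (tether) cbind(2, 10, pos[2, 1], pos[2, 2], pos[2, 3]) else NULL
  cp <- if (!is.null(coupling_lambda)) {
    list(index = n, lambda = coupling_lambda)
  } else NULL
  hs_configuration(pos, sid, isw, hs_box(rep(L, 3)),
                   topology = hs_topology(cb, xl, tt), species = species,
                   chain_ids = c(rep(1L, n_beads), rep(0L, n_waters)),
                   coupling = cp, cutoff = cutoff)
}

# two-particle water dimer at separation r (for closed-form LJ checks)
water_dimer <- function(r, L = 12, cutoff = 5, lambda = NULL) {
  pos <- rbind(c(1, 1, 1), c(1 + r, 1, 1))
  cp <- if (!is.null(lambda)) list(index = 2L, lambda = lambda) else NULL
  hs_configuration(pos, c(3L, 3L), c(TRUE, TRUE), hs_box(rep(L, 3)),
                   coupling = cp, cutoff = cutoff)
}

# waters at given positions, no matrix
waters_at <- function(pos, L, cutoff = 3) {
  hs_configuration(pos, rep(3L, nrow(pos)), rep(TRUE, nrow(pos)),
                   hs_box(rep_len(L, 3)), cutoff = cutoff, validate = FALSE)
}
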