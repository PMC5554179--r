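#' Specification of a synthetic coarse-grained matrix
#'
#' Describes the bead matrix the generator builds: `n_chains` self-avoiding
#' random-walk chains of `chain_length` beads in a periodic box at
#' `box_density` beads per unit volume. `bonded = FALSE` drops the chain
#' bonds (the free amino-acid-mixture analog). `crosslink_fraction` is the
#' fraction of beads carrying non-local harmonic crosslinks (the
#' disulfide-bridge analog; 0.2 mirrors a cysteine-rich protein with about
#' 20 percent crosslink-forming residues). `hydrophilic_fraction` beads get
#' the high water affinity.
#'
#' @param n_chains,chain_length matrix size (chain_length >= 1).
#' @param bonded keep backbone (chain) bonds.
#' @param crosslink_fraction fraction of beads involved in crosslinks, in
#'   `[0, 1]`.
#' @param hydrophilic_fraction fraction of beads with affinity > 1.
#' @param box_density target bead number density (reduced units).
#' @param seed integer seed; the generator is deterministic given it.
#' @param bond_k,bond_r0 harmonic backbone parameters.
#' @param angle_k,angle_r0 next-nearest-neighbour harmonic parameters, a
#'   chain-persistence surrogate standing in for backbone bending
#'   stiffness (set `angle_k = 0` for freely jointed chains).
#' @param crosslink_k crosslink spring constant (rest length is the pair's
#'   separation at generation time, locking the generated geometry).
#' @param crosslink_max_r0 only spatially proximal pairs (separation below
#'   this) are eligible crosslink partners; widened automatically if the
#'   target count cannot be met.
#' @param anneal_sweeps Metropolis sweeps of seeded annealing after
#'   assembly.
#' @param temperature annealing temperature.
#' @param species species table, see [hs_species_table()].
#' @param cutoff pair cutoff stored on the configuration.
#' @return list of class `hs_matrix_spec`.
#' @export
matrix_spec <- function(n_chains = 10, chain_length = 20, bonded = TRUE,
                        crosslink_fraction = 0, hydrophilic_fraction = 0.4,
                        box_density = 0.15, seed = 1,
                        bond_k = 50, bond_r0 = 1.0,
                        angle_k = 10, angle_r0 = 1.7, crosslink_k = 200,
                        crosslink_max_r0 = 2.5, anneal_sweeps = 2000,
                        temperature = 0.75, species = hs_species_table(),
                        cutoff = 3.0) {
  if (chain_length < 1) stop("chain_length must be >= 1")
  if (crosslink_fraction < 0 || crosslink_fraction > 1) {
    stop("crosslink_fraction must be in [0, 1]")
  }
  if (hydrophilic_fraction < 0 || hydrophilic_fraction > 1) {
    stop("hydrophilic_fraction must be in [0, 1]")
  }
  structure(as.list(environment()), class = "hs_matrix_spec")
}

.random_unit_vector <- function() {
  repeat {
    v <- runif(3, -1, 1)
    n2 <- sum(v^2)
    if (n2 > 1e-12 && n2 <= 1) return(v / sqrt(n2))
  }
}

#' Generate a coarse-grained matrix configuration
#'
#' Places the chains as self-avoiding random walks, assigns hydrophilic and
#' hydrophobic species, adds chain bonds when `bonded`, samples non-local
#' crosslink pairs (chain separation > 2 or different chains) uniformly
#' among spatially proximal eligible pairs without replacement until the
#' bead-fraction target is met, then runs a short seeded annealing
#' relaxation. Deterministic given `spec$seed`.
#'
#' @param spec an [matrix_spec()].
#' @return a dry `hs_config` (no waters).
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "hs_matrix_spec"))
  set.seed(spec$seed)
  n <- spec$n_chains * spec$chain_length
  L <- (n / spec$box_density)^(1 / 3)
  box <- hs_box(rep(L, 3))
  sig_b <- spec$species$sigma[spec$species$name == "philic"][1]
  min_sep <- 0.85 * sig_b
  pos <- matrix(NA_real_, n, 3)
  placed <- 0L
  ok_point <- function(p, upto) {
    if (upto == 0) return(TRUE)
    d <- sweep(pos[seq_len(upto), , drop = FALSE], 2, p)
    d <- d - L * floor(d / L + 0.5)
    all(rowSums(d^2) >= min_sep^2)
  }
  for (c_ in seq_len(spec$n_chains)) {
    success <- FALSE
    for (try_chain in 1:200) {
      chain <- matrix(NA_real_, spec$chain_length, 3)
      chain[1, ] <- runif(3) * L
      if (!ok_point(chain[1, ], placed)) next
      good <- TRUE
      b <- 2
      while (good && b <= spec$chain_length) {
        ok <- FALSE
        for (t in 1:200) {
          p <- chain[b - 1, ] + spec$bond_r0 * .random_unit_vector()
          # avoid earlier beads of this chain (the bonded neighbour sits at
          # the bond length and is exempt) and all previously placed chains
          if (b > 2) {
            dd <- sweep(chain[seq_len(b - 2), , drop = FALSE], 2, p)
            dd <- dd - L * floor(dd / L + 0.5)
            if (any(rowSums(dd^2) < min_sep^2)) next
          }
          if (!ok_point(p, placed)) next
          chain[b, ] <- p
          ok <- TRUE
          break
        }
        if (!ok) good <- FALSE
        b <- b + 1
      }
      if (good) {
        pos[placed + seq_len(spec$chain_length), ] <- chain %% L
        placed <- placed + spec$chain_length
        success <- TRUE
        break
      }
    }
    if (!success) {
      stop("matrix density too high: could not place chains without overlap")
    }
  }
  chain_ids <- rep(seq_len(spec$n_chains), each = spec$chain_length)
  # species: hydrophilic_fraction of beads are 'philic'
  n_phil <- round(spec$hydrophilic_fraction * n)
  sp_phil <- which(spec$species$name == "philic")[1]
  sp_phob <- which(spec$species$name == "phobic")[1]
  species_ids <- rep(sp_phob, n)
  species_ids[sample.int(n, n_phil)] <- sp_phil
  chain_bonds <- NULL
  if (spec$bonded && spec$chain_length > 1) {
    i <- unlist(lapply(seq_len(spec$n_chains), function(c_) {
      base <- (c_ - 1) * spec$chain_length
      base + seq_len(spec$chain_length - 1)
    }))
    chain_bonds <- cbind(i, i + 1, spec$bond_k, spec$bond_r0)
    if (spec$angle_k > 0 && spec$chain_length > 2) {
      # persistence surrogate: harmonic next-nearest-neighbour restraints
      j <- unlist(lapply(seq_len(spec$n_chains), function(c_) {
        base <- (c_ - 1) * spec$chain_length
        base + seq_len(spec$chain_length - 2)
      }))
      chain_bonds <- rbind(chain_bonds,
                           cbind(j, j + 2, spec$angle_k, spec$angle_r0))
    }
  }
  # anneal the un-crosslinked matrix first, then lock crosslinks onto the
  # annealed geometry: crosslinked and crosslink-free matrices generated
  # from the same seed therefore share an identical dry structure, the way
  # oxidative crosslinking fixes an already-formed powder
  cfg <- hs_configuration(pos, species_ids, rep(FALSE, n), box,
                          topology = hs_topology(chain_bonds),
                          species = spec$species, chain_ids = chain_ids,
                          residue_ids = seq_len(n),
                          cutoff = min(spec$cutoff, L / 2 * 0.999))
  if (spec$anneal_sweeps > 0) {
    cfg <- relax(cfg, spec$anneal_sweeps, spec$temperature)$config
  }
  crosslinks <- .sample_crosslinks(cfg$positions, chain_ids, box, spec)
  cfg$topology <- hs_topology(chain_bonds, crosslinks)
  validate_config(cfg)
  cfg
}

.sample_crosslinks <- function(pos, chain_ids, box, spec) {
  n <- nrow(pos)
  target <- round(spec$crosslink_fraction * n / 2)
  if (target == 0) return(NULL)
  pos_in_chain <- stats::ave(seq_len(n), chain_ids, FUN = seq_along)
  r_lim <- spec$crosslink_max_r0
  repeat {
    D <- cpp_dist_mi(pos, pos, box$lengths, as.integer(box$periodic))
    cand <- which(upper.tri(D) & D < r_lim, arr.ind = TRUE)
    eligible <- cand[chain_ids[cand[, 1]] != chain_ids[cand[, 2]] |
                       abs(pos_in_chain[cand[, 1]] -
                             pos_in_chain[cand[, 2]]) > 2, , drop = FALSE]
    picked <- matrix(integer(0), 0, 2)
    used <- logical(n)
    if (nrow(eligible) > 0) {
      for (e in sample.int(nrow(eligible))) {
        i <- eligible[e, 1]; j <- eligible[e, 2]
        if (!used[i] && !used[j]) {
          picked <- rbind(picked, c(i, j))
          used[i] <- used[j] <- TRUE
          if (nrow(picked) == target) break
        }
      }
    }
    if (nrow(picked) == target || r_lim >= min(box$lengths) / 2) break
    r_lim <- min(r_lim * 1.5, min(box$lengths) / 2)
  }
  if (nrow(picked) < target) {
    stop("could not place the requested number of non-local crosslinks")
  }
  r0 <- vapply(seq_len(nrow(picked)), function(e) {
    sqrt(sum(minimum_image(pos[picked[e, 2], ] - pos[picked[e, 1], ], box)^2))
  }, numeric(1))
  cbind(picked[, 1], picked[, 2], spec$crosslink_k, r0)
}

#' Deterministic water arrangement that does (or does not) percolate
#'
#' Builds a jittered row of waters along the x axis. With `spanning = TRUE`
#' the row wraps across the periodic boundary and the cluster connects to
#' its own image; with `spanning = FALSE` one interior water is removed,
#' breaking the winding.
#'
#' @param box an [hs_box()].
#' @param spacing distance between consecutive row waters (must be below the
#'   intended clustering cutoff for a spanning construction).
#' @param spanning logical.
#' @param seed integer seed for the jitter.
#' @param n_scatter additional isolated waters placed far from the row.
#' @param species species table.
#' @return an `hs_config` of waters only.
#' @export
generate_percolation_fixture <- function(box, spacing, spanning, seed = 1,
                                         n_scatter = 0,
                                         species = hs_species_table()) {
  set.seed(seed)
  Lx <- box$lengths[1]
  n_row <- ceiling(Lx / spacing)
  if (n_row < 3) stop("infeasible geometry: fewer than 3 row waters")
  x <- (seq_len(n_row) - 1) * spacing
  jit <- matrix(runif(3 * n_row, -0.02, 0.02) * spacing, ncol = 3)
  pos <- cbind(x, box$lengths[2] / 2, box$lengths[3] / 2) + jit
  if (!spanning) pos <- pos[-(n_row %/% 2), , drop = FALSE]
  if (n_scatter > 0) {
    sc <- cbind(runif(n_scatter) * Lx,
                runif(n_scatter, 0.05, 0.25) * box$lengths[2],
                runif(n_scatter, 0.05, 0.25) * box$lengths[3])
    pos <- rbind(pos, sc)
  }
  wid <- which(species$name == "water")[1]
  hs_configuration(pos, rep(wid, nrow(pos)), rep(TRUE, nrow(pos)), box,
                   species = species,
                   cutoff = min(3, min(box$lengths) / 2 * 0.99),
                   validate = FALSE)
}

#' Gaussian work samples satisfying the Crooks fluctuation relation
#'
#' Forward (insertion) works are `Normal(delta_f + beta sigma^2 / 2,
#' sigma^2)` and reverse (deletion) works `Normal(-delta_f + beta sigma^2 /
#' 2, sigma^2)`, so the Crooks relation holds exactly with free-energy
#' difference `delta_f`. Used as a known-truth harness for
#' [bar_estimate()].
#'
#' @param delta_f true free-energy difference (k_B T units when `beta = 1`).
#' @param sigma work standard deviation (> 0).
#' @param n samples per direction (>= 2).
#' @param beta inverse temperature.
#' @param seed integer seed.
#' @return an [work_samples()] object.
#' @export
generate_crooks_samples <- function(delta_f, sigma, n, beta = 1, seed = 1) {
  if (n < 2) stop("n must be >= 2")
  if (sigma <= 0) stop("sigma must be > 0")
  set.seed(seed)
  fwd <- rnorm(n, delta_f + beta * sigma^2 / 2, sigma)
  rev <- rnorm(n, -delta_f + beta * sigma^2 / 2, sigma)
  work_samples(fwd, rev, beta)
}
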