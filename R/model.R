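#' @useDynLib hydrosorb, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx rnorm runif sd setNames uniroot
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Periodic simulation box
#'
#' @param lengths numeric vector of three positive extents (recycled if
#'   scalar), in reduced length units (or Angstrom for real trajectories).
#' @param periodic three logicals, one per axis. Default all `TRUE`.
#' @return an object of class `hs_box`.
#' @export
hs_box <- function(lengths, periodic = c(TRUE, TRUE, TRUE)) {
  lengths <- rep_len(as.numeric(lengths), 3L)
  periodic <- rep_len(as.logical(periodic), 3L)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("box lengths must be positive and finite")
  }
  structure(list(lengths = lengths, periodic = periodic), class = "hs_box")
}

#' Minimum-image displacement
#'
#' Wraps each periodic component of a displacement into `[-L/2, L/2)`.
#'
#' @param displacement a 3-vector or an n x 3 matrix of displacements.
#' @param box an [hs_box()].
#' @return object of the same shape with wrapped components.
#' @export
minimum_image <- function(displacement, box) {
  vec <- is.null(dim(displacement))
  d <- matrix(as.numeric(displacement), ncol = 3)
  L <- box$lengths
  for (a in 1:3) {
    if (box$periodic[a]) d[, a] <- d[, a] - L[a] * floor(d[, a] / L[a] + 0.5)
  }
  if (vec) drop(d) else d
}

#' Default coarse-grained species table
#'
#' Three species: hydrophilic and hydrophobic matrix beads and single-site
#' water. Energies and lengths are in reduced Lennard-Jones units
#' (water sigma = epsilon = kT-scale = 1); masses are gram-per-mole-scale
#' numbers used only for hydration-level (g/g) bookkeeping. The `affinity`
#' column multiplies the water--bead well depth: hydrophilic beads attract
#' water more strongly than water attracts itself, hydrophobic beads less.
#'
#' @param bead_mass,water_mass masses for h bookkeeping (residue-like 110
#'   and 18 by default).
#' @param bead_sigma,water_sigma Lennard-Jones diameters.
#' @param bead_epsilon,water_epsilon Lennard-Jones well depths.
#' @param philic_affinity,phobic_affinity water-attraction multipliers.
#' @return data.frame with columns `name`, `mass`, `epsilon`, `sigma`,
#'   `affinity`, `sasa_radius`.
#' @export
hs_species_table <- function(bead_mass = 110, water_mass = 18,
                             bead_sigma = 1.2, water_sigma = 1.0,
                             bead_epsilon = 0.8, water_epsilon = 1,
                             philic_affinity = 3.0, phobic_affinity = 0.4) {
  sp <- data.frame(
    name = c("philic", "phobic", "water"),
    mass = c(bead_mass, bead_mass, water_mass),
    epsilon = c(bead_epsilon, bead_epsilon, water_epsilon),
    sigma = c(bead_sigma, bead_sigma, water_sigma),
    affinity = c(philic_affinity, phobic_affinity, 1),
    sasa_radius = c(bead_sigma / 2, bead_sigma / 2, water_sigma / 2),
    stringsAsFactors = FALSE
  )
  .validate_species(sp)
  sp
}

.validate_species <- function(sp) {
  stopifnot(is.data.frame(sp),
            all(c("name", "mass", "epsilon", "sigma", "affinity",
                  "sasa_radius") %in% names(sp)))
  if (any(sp$mass <= 0)) stop("species mass must be > 0")
  if (any(sp$sigma <= 0)) stop("species sigma must be > 0")
  if (any(sp$epsilon < 0)) stop("species epsilon must be >= 0")
  if (any(sp$affinity < 0)) stop("species affinity must be >= 0")
  invisible(sp)
}

.empty_bonds <- function() matrix(numeric(0), 0, 4,
                                  dimnames = list(NULL, c("i", "j", "k", "r0")))
.empty_tethers <- function() matrix(numeric(0), 0, 5,
                                    dimnames = list(NULL, c("i", "k", "x", "y", "z")))

.as_bond_matrix <- function(m, what) {
  if (is.null(m) || NROW(m) == 0) return(.empty_bonds())
  m <- matrix(as.numeric(m), ncol = 4,
              dimnames = list(NULL, c("i", "j", "k", "r0")))
  if (any(m[, 1] == m[, 2])) stop(what, ": self-bonds are not allowed")
  if (any(m[, 3] < 0)) stop(what, ": spring constants must be >= 0")
  m
}

#' Bonded topology: chain bonds, non-local crosslinks, tethers
#'
#' Chain bonds and crosslinks are harmonic, `0.5 k (r - r0)^2`, given as
#' matrices with columns `i, j, k, r0` (1-based particle indices). Tethers
#' pin a bead to a fixed anchor, columns `i, k, x, y, z`. Crosslinks model
#' disulfide-like bridges and must connect beads that are non-adjacent along
#' a chain (chain separation > 2) or on different chains; this is checked
#' when a configuration is assembled.
#'
#' @param chain_bonds,crosslinks `n x 4` matrices (or `NULL`).
#' @param tethers `n x 5` matrix (or `NULL`).
#' @return object of class `hs_topology`.
#' @export
hs_topology <- function(chain_bonds = NULL, crosslinks = NULL, tethers = NULL) {
  tet <- if (is.null(tethers) || NROW(tethers) == 0) .empty_tethers() else {
    matrix(as.numeric(tethers), ncol = 5,
           dimnames = list(NULL, c("i", "k", "x", "y", "z")))
  }
  structure(list(chain_bonds = .as_bond_matrix(chain_bonds, "chain_bonds"),
                 crosslinks = .as_bond_matrix(crosslinks, "crosslinks"),
                 tethers = tet),
            class = "hs_topology")
}

.all_bonds <- function(topology) {
  rbind(topology$chain_bonds, topology$crosslinks)
}

#' Assemble a configuration
#'
#' A configuration is the simulated powder state: particle positions, species
#' assignments, water flags, bonded topology and periodic box, plus the model
#' parameters used by the energy routines (pair cutoff and the soft-core
#' shift constant for the partially coupled molecule). Matrix beads must come
#' before water particles in the particle ordering so that topology indices
#' stay valid as waters are inserted and removed. Positions are wrapped into
#' `[0, L)` on periodic axes.
#'
#' @param positions n x 3 numeric matrix.
#' @param species_ids integer row indices into `species`.
#' @param is_water logical per particle.
#' @param box an [hs_box()].
#' @param topology an [hs_topology()]; bonds may only reference matrix beads.
#' @param species species table, see [hs_species_table()].
#' @param residue_ids integer grouping labels for matrix particles; waters
#'   carry the reserved label 0. Defaults to one residue per bead.
#' @param chain_ids integer chain labels for matrix particles (0 for water).
#' @param coupling `NULL`, or `list(index =, lambda =)` for the single
#'   partially inserted water.
#' @param cutoff pair-interaction cutoff (reduced units; default 3 water
#'   sigma, no tail correction).
#' @param softcore_alpha separation-shift constant of the soft-core coupling
#'   potential.
#' @param validate set `FALSE` to skip invariant checks (internal hot paths).
#' @return object of class `hs_config`.
#' @export
hs_configuration <- function(positions, species_ids, is_water, box,
                             topology = hs_topology(),
                             species = hs_species_table(),
                             residue_ids = NULL, chain_ids = NULL,
                             coupling = NULL, cutoff = 3.0,
                             softcore_alpha = 0.5, validate = TRUE) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- nrow(positions)
  species_ids <- as.integer(species_ids)
  is_water <- as.logical(is_water)
  stopifnot(length(species_ids) == n, length(is_water) == n)
  for (a in 1:3) {
    if (box$periodic[a]) {
      L <- box$lengths[a]
      positions[, a] <- positions[, a] - L * floor(positions[, a] / L)
    }
  }
  if (is.null(residue_ids)) {
    residue_ids <- integer(n)
    residue_ids[!is_water] <- seq_len(sum(!is_water))
  }
  if (is.null(chain_ids)) {
    chain_ids <- integer(n)
    chain_ids[!is_water] <- seq_len(sum(!is_water))
  }
  cfg <- structure(list(positions = positions, species_ids = species_ids,
                        is_water = is_water, residue_ids = as.integer(residue_ids),
                        chain_ids = as.integer(chain_ids), topology = topology,
                        box = box, species = species, coupling = coupling,
                        cutoff = cutoff, softcore_alpha = softcore_alpha),
                   class = "hs_config")
  if (validate) validate_config(cfg)
  cfg
}

#' Check configuration invariants
#'
#' @param config an `hs_config`.
#' @return the configuration, invisibly; errors describe the violated
#'   invariant.
#' @export
validate_config <- function(config) {
  n <- nrow(config$positions)
  .validate_species(config$species)
  if (any(config$species_ids < 1 | config$species_ids > nrow(config$species))) {
    stop("species_ids out of range")
  }
  isw <- config$is_water
  if (any(isw) && any(!isw)) {
    if (min(which(isw)) <= max(which(!isw))) {
      stop("matrix beads must precede water particles in the particle order")
    }
  }
  b <- .all_bonds(config$topology)
  if (nrow(b) > 0) {
    idx <- c(b[, 1], b[, 2])
    if (any(idx < 1 | idx > n)) stop("bond indices out of range")
    if (any(isw[idx])) stop("water particles may not carry bonds or crosslinks")
  }
  xl <- config$topology$crosslinks
  if (nrow(xl) > 0) {
    for (r in seq_len(nrow(xl))) {
      i <- xl[r, 1]; j <- xl[r, 2]
      if (config$chain_ids[i] == config$chain_ids[j]) {
        ch <- which(config$chain_ids == config$chain_ids[i] & !isw)
        oi <- match(i, ch); oj <- match(j, ch)
        if (abs(oi - oj) <= 2) {
          stop("crosslinks must be non-local: chain separation > 2 required")
        }
      }
    }
  }
  cp <- config$coupling
  if (!is.null(cp)) {
    stopifnot(is.numeric(cp$lambda), length(cp$index) == 1)
    if (cp$lambda < 0 || cp$lambda > 1) stop("coupling lambda must be in [0, 1]")
    if (!isw[cp$index]) stop("coupling particle must be a water")
  }
  invisible(config)
}

# flat arrays consumed by the C++ kernels
.sim_args <- function(config, cutoff = NULL, lambda = NULL) {
  sp <- config$species
  sid <- config$species_ids
  cp <- config$coupling
  list(pos = config$positions,
       eps = sp$epsilon[sid], sig = sp$sigma[sid], aff = sp$affinity[sid],
       isw = as.integer(config$is_water),
       L = config$box$lengths, per = as.integer(config$box$periodic),
       rc = cutoff %||% config$cutoff,
       bonds = .all_bonds(config$topology), tethers = config$topology$tethers,
       cidx = if (is.null(cp)) -1L else as.integer(cp$index - 1L),
       clam = if (is.null(cp)) 1.0 else (lambda %||% cp$lambda),
       alpha = config$softcore_alpha)
}

.check_cutoff <- function(config, rc) {
  per <- config$box$periodic
  if (any(per)) {
    hm <- min(config$box$lengths[per]) / 2
    if (rc > hm) {
      stop(sprintf("cutoff %.3f exceeds half the smallest periodic extent %.3f",
                   rc, hm))
    }
  }
  invisible(rc)
}

#' Total configurational energy, by channel
#'
#' Lennard-Jones pair sum under the minimum-image convention (water--bead
#' well depths scaled by the bead's affinity; harmonically bonded pairs are
#' excluded from the pair sum), harmonic bond/crosslink/tether terms, and the
#' lambda-scaled soft-core contribution of a partially coupled water.
#'
#' @param config an `hs_config`.
#' @param cutoff optional override of the configuration's pair cutoff.
#' @return list of class `hs_energy` with `total`, `pair`, `bonded`,
#'   `coupling_part`; `total = pair + bonded + coupling_part`.
#' @export
pair_energy <- function(config, cutoff = NULL) {
  a <- .sim_args(config, cutoff = cutoff)
  .check_cutoff(config, a$rc)
  v <- cpp_energy_report(a$pos, a$eps, a$sig, a$aff, a$isw, a$L, a$per, a$rc,
                         a$bonds, a$tethers, a$cidx, a$clam, a$alpha)
  structure(list(total = sum(v), pair = v[1], bonded = v[2],
                 coupling_part = v[3]),
            class = "hs_energy")
}

#' Energy of a configuration at a given coupling strength
#'
#' Implements `U(lambda) = U_rest + lambda * U_inserted(lambda)` for the one
#' partially inserted water. `U_inserted` uses a separation-shifted
#' (soft-core) Lennard-Jones form, `r_eff^2 = r^2 + alpha (1 - lambda)
#' sigma^2`, finite at zero separation for `lambda < 1` and exactly the
#' plain pair potential at `lambda = 1`.
#'
#' @param config an `hs_config` with a coupling particle.
#' @param lambda coupling strength in `[0, 1]`; 0 means no interaction.
#' @return total energy (scalar).
#' @export
lambda_scaled_energy <- function(config, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    stop("lambda must be a scalar in [0, 1]")
  }
  if (is.null(config$coupling)) stop("configuration has no coupling particle")
  a <- .sim_args(config, lambda = lambda)
  v <- cpp_energy_report(a$pos, a$eps, a$sig, a$aff, a$isw, a$L, a$per, a$rc,
                         a$bonds, a$tethers, a$cidx, lambda, a$alpha)
  sum(v)
}

#' Energy change of removing one water
#'
#' `delta U = U(without molecule) - U(with molecule)`, computed incrementally
#' from the molecule's own interactions.
#'
#' @param config an `hs_config`.
#' @param water_index index of a fully coupled water particle.
#' @return scalar energy change.
#' @export
delta_energy_remove <- function(config, water_index) {
  if (!config$is_water[water_index]) stop("index does not refer to a water")
  cp <- config$coupling
  if (!is.null(cp) && cp$index == water_index) {
    stop("cannot remove the partially coupled water with this operation")
  }
  a <- .sim_args(config)
  -cpp_particle_energy(a$pos, a$eps, a$sig, a$aff, a$isw, a$L, a$per, a$rc,
                       a$bonds, a$tethers, a$cidx, a$clam, a$alpha,
                       as.integer(water_index))
}

#' Hydration level h (g water / g dry matrix)
#'
#' A partially coupled water counts with weight lambda.
#'
#' @param config an `hs_config` with at least one matrix bead.
#' @return scalar h in g/g.
#' @export
hydration_level <- function(config) {
  isw <- config$is_water
  if (!any(!isw)) stop("configuration has no matrix beads")
  m <- config$species$mass[config$species_ids]
  w <- as.numeric(isw)
  cp <- config$coupling
  if (!is.null(cp)) w[cp$index] <- cp$lambda
  sum(m * w * isw) / sum(m[!isw])
}

#' Number of fully coupled waters
#' @param config an `hs_config`.
#' @return integer count (the partially coupled water is excluded).
#' @export
n_waters <- function(config) {
  n <- sum(config$is_water)
  if (!is.null(config$coupling)) n <- n - 1L
  as.integer(n)
}

.water_species_id <- function(config) {
  id <- which(config$species$name == "water")
  if (length(id) == 0) {
    id <- unique(config$species_ids[config$is_water])
    if (length(id) != 1) stop("cannot identify the water species")
  }
  id[1]
}

#' Append a water particle
#'
#' @param config an `hs_config`.
#' @param position 3-vector (wrapped into the box).
#' @param lambda coupling strength; if `< 1` the new particle becomes the
#'   configuration's coupled particle (only one may exist).
#' @return updated configuration.
#' @export
add_water <- function(config, position, lambda = 1) {
  if (lambda < 1 && !is.null(config$coupling)) {
    stop("a partially coupled particle already exists")
  }
  L <- config$box$lengths
  p <- as.numeric(position)
  for (a in 1:3) if (config$box$periodic[a]) p[a] <- p[a] - L[a] * floor(p[a] / L[a])
  config$positions <- rbind(config$positions, p)
  rownames(config$positions) <- NULL
  config$species_ids <- c(config$species_ids, .water_species_id(config))
  config$is_water <- c(config$is_water, TRUE)
  config$residue_ids <- c(config$residue_ids, 0L)
  config$chain_ids <- c(config$chain_ids, 0L)
  if (lambda < 1) {
    config$coupling <- list(index = nrow(config$positions), lambda = lambda)
  }
  config
}

#' Delete a water particle
#'
#' Matrix beads always precede waters, so topology indices are unaffected.
#'
#' @param config an `hs_config`.
#' @param index index of the water to delete.
#' @return updated configuration.
#' @export
remove_water <- function(config, index) {
  if (!config$is_water[index]) stop("index does not refer to a water")
  config$positions <- config$positions[-index, , drop = FALSE]
  config$species_ids <- config$species_ids[-index]
  config$is_water <- config$is_water[-index]
  config$residue_ids <- config$residue_ids[-index]
  config$chain_ids <- config$chain_ids[-index]
  cp <- config$coupling
  if (!is.null(cp)) {
    if (cp$index == index) config$coupling <- NULL
    else if (cp$index > index) config$coupling$index <- cp$index - 1L
  }
  config
}

#' Set or clear the coupling strength of the coupled particle
#'
#' @param config an `hs_config` with a coupling particle.
#' @param lambda new strength in `[0, 1]`; at exactly 1 the particle becomes
#'   fully coupled and the coupling record is cleared.
#' @return updated configuration.
#' @export
set_coupling <- function(config, lambda) {
  if (is.null(config$coupling)) stop("configuration has no coupling particle")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (lambda >= 1) config$coupling <- NULL
  else config$coupling$lambda <- lambda
  config
}

#' @export
print.hs_config <- function(x, ...) {
  cat(sprintf("<hs_config> %d particles (%d beads, %d waters), box %s\n",
              nrow(x$positions), sum(!x$is_water), sum(x$is_water),
              paste(signif(x$box$lengths, 4), collapse = " x ")))
  cat(sprintf("  bonds: %d chain, %d crosslink, %d tether; h = %.4f g/g\n",
              nrow(x$topology$chain_bonds), nrow(x$topology$crosslinks),
              nrow(x$topology$tethers),
              if (any(!x$is_water)) hydration_level(x) else NA_real_))
  invisible(x)
}
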