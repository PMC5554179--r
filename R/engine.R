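#' Sorption protocol parameters
#'
#' Collects the knobs of the adsorption/desorption protocol. Relaxation is
#' measured in Metropolis sweeps (one sweep = N single-particle trial moves);
#' the defaults map the reference protocol's 200 ps removal relaxation,
#' 400 ps insertion ramp and long production relaxation at each saved
#' hydration grid point onto 200 / 400 / 5000 sweeps.
#'
#' @param h_start initial hydration level (g/g) of the run.
#' @param h_min,h_max hydration range covered by the branches (g/g).
#' @param h_save_interval grid spacing at which configurations are saved and
#'   the chemical potential is estimated (default 0.02 g/g).
#' @param relax_sweeps_per_step sweeps of relaxation after each water removal.
#' @param insertion_relax_sweeps total sweeps of relaxation spread over one
#'   insertion's lambda ramp.
#' @param ramp_steps number of lambda increments per continuous insertion.
#' @param production_sweeps sweeps of production relaxation at each grid
#'   point, of which the first `equilibration_fraction` is discarded.
#' @param equilibration_fraction fraction of production discarded (default 1/7).
#' @param frame_interval production frames are saved every this many sweeps.
#' @param prep_sweeps annealing sweeps used when solvating to `h_start`.
#' @param temperature reduced temperature (k_B = 1).
#' @param max_disp maximum Metropolis displacement per axis (reduced units).
#' @param water_jump_fraction fraction of water moves proposed as box-wide
#'   relocations (see [relax()]); encodes the water/matrix mobility
#'   separation.
#' @param insertion_min_sep non-overlap criterion: a trial insertion point is
#'   rejected when closer than this multiple of the mixed sigma to any
#'   particle.
#' @param insertion_max_attempts attempt cap before insertion fails.
#' @param n_insertions total test insertions per grid point for the chemical
#'   potential estimate (desk-scale default 1e5).
#' @param seed integer seed applied at the start of [run_isotherm()].
#' @return list of class `hs_protocol`.
#' @export
sorption_protocol <- function(h_start = 0.04, h_min = 0.04, h_max = 0.5,
                              h_save_interval = 0.02,
                              relax_sweeps_per_step = 200,
                              insertion_relax_sweeps = 400,
                              ramp_steps = 20,
                              production_sweeps = 5000,
                              equilibration_fraction = 1 / 7,
                              frame_interval = 10,
                              prep_sweeps = 500,
                              temperature = 0.75,
                              max_disp = 0.25,
                              water_jump_fraction = 0.2,
                              insertion_min_sep = 0.8,
                              insertion_max_attempts = 10000,
                              n_insertions = 1e5,
                              seed = NULL) {
  if (h_min >= h_max) stop("h_min must be < h_max")
  if (h_save_interval <= 0) stop("h_save_interval must be > 0")
  if (equilibration_fraction < 0 || equilibration_fraction >= 1) {
    stop("equilibration_fraction must be in [0, 1)")
  }
  if (temperature <= 0) stop("temperature must be > 0")
  structure(as.list(environment()), class = "hs_protocol")
}

#' Metropolis relaxation at fixed N, V, T
#'
#' Random single-particle displacement moves with the standard Metropolis
#' acceptance rule; bonded and tethered beads feel their harmonic terms, and
#' a partially coupled water moves under its soft-core potential. Uses R's
#' global random number stream.
#'
#' @param config an `hs_config`.
#' @param n_sweeps number of sweeps (N trial moves each).
#' @param temperature reduced temperature.
#' @param max_disp maximum displacement per axis.
#' @param save_every if `> 0`, a frame (configuration snapshot) is stored
#'   every `save_every` sweeps.
#' @param water_jump_fraction probability that a picked free molecule (a
#'   water, or an unbonded untethered bead) attempts a relocation to a
#'   uniform random point instead of a local displacement (symmetric
#'   proposal, detailed balance preserved). Models the fast diffusion of
#'   small molecules relative to matrix relaxation; bonded beads always
#'   move locally.
#' @return list with `config` (relaxed), `acceptance` (fraction of accepted
#'   moves) and `frames` (list of `hs_config` snapshots, possibly empty).
#' @export
relax <- function(config, n_sweeps, temperature, max_disp = 0.25,
                  save_every = 0, water_jump_fraction = 0) {
  if (n_sweeps < 0) stop("n_sweeps must be >= 0")
  if (n_sweeps == 0 || nrow(config$positions) == 0) {
    return(list(config = config, acceptance = NA_real_, frames = list()))
  }
  a <- .sim_args(config)
  .check_cutoff(config, a$rc)
  out <- cpp_relax(a$pos, a$eps, a$sig, a$aff, a$isw, a$L, a$per, a$rc,
                   a$bonds, a$tethers, a$cidx, a$clam, a$alpha,
                   as.integer(n_sweeps), 1 / temperature, max_disp,
                   as.integer(save_every), water_jump_fraction)
  config$positions <- out$positions
  frames <- lapply(out$frames, function(p) {
    f <- config
    f$positions <- p
    f
  })
  list(config = config, acceptance = out$acceptance, frames = frames)
}

#' Boltzmann-weighted choice of the water to remove
#'
#' Samples water i with probability proportional to `exp(-beta dU_i)`, where
#' `dU_i` is the energy change of removing water i ([delta_energy_remove()]).
#' Weights are normalized after subtracting the maximum exponent for
#' numerical stability; the draw is inverse-CDF on the cumulative weights
#' with a single uniform variate over the stable particle ordering.
#'
#' @param config an `hs_config` with at least one fully coupled water.
#' @param temperature reduced temperature.
#' @return the chosen water's particle index.
#' @export
select_removal_candidate <- function(config, temperature) {
  idx <- which(config$is_water)
  cp <- config$coupling
  if (!is.null(cp)) idx <- setdiff(idx, cp$index)
  if (length(idx) == 0) stop("no fully coupled waters to remove")
  a <- .sim_args(config)
  du <- cpp_deletion_energies(a$pos, a$eps, a$sig, a$aff, a$isw, a$L, a$per,
                              a$rc, a$bonds, a$tethers, a$cidx, a$clam, a$alpha)
  logw <- -du / temperature
  w <- exp(logw - max(logw))
  cw <- cumsum(w) / sum(w)
  idx[findInterval(runif(1), cw) + 1L]
}

#' One removal cycle: Boltzmann-weighted deletion plus relaxation
#'
#' @param config an `hs_config` with at least one water.
#' @param protocol an [sorption_protocol()].
#' @return relaxed configuration with one water fewer.
#' @export
remove_water_step <- function(config, protocol) {
  i <- select_removal_candidate(config, protocol$temperature)
  config <- remove_water(config, i)
  relax(config, protocol$relax_sweeps_per_step, protocol$temperature,
        protocol$max_disp,
        water_jump_fraction = protocol$water_jump_fraction)$config
}

.find_insertion_point <- function(config, protocol) {
  a <- .sim_args(config)
  sig_w <- config$species$sigma[.water_species_id(config)]
  for (t in seq_len(protocol$insertion_max_attempts)) {
    p <- runif(3) * config$box$lengths
    if (nrow(config$positions) == 0) return(p)
    r <- cpp_min_sep_ratio(a$pos, a$sig, a$L, a$per, p[1], p[2], p[3], sig_w)
    if (r >= protocol$insertion_min_sep) return(p)
  }
  stop(sprintf(paste0("no non-overlapping insertion point found in %d attempts",
                      " (number density %.3f)"),
               protocol$insertion_max_attempts,
               nrow(config$positions) / prod(config$box$lengths)))
}

#' Continuous (lambda-ramped) insertion of one water
#'
#' A water is placed at a non-overlapping random position with no interaction
#' (`lambda = 0`); its coupling is then ramped linearly to 1 over
#' `ramp_steps` increments, with `insertion_relax_sweeps / ramp_steps`
#' relaxation sweeps after each increment. The soft-core potential keeps the
#' energy finite at every intermediate lambda.
#'
#' @param config an `hs_config`.
#' @param protocol an [sorption_protocol()].
#' @return relaxed configuration with one more (fully coupled) water.
#' @export
insert_water_continuous <- function(config, protocol) {
  p <- .find_insertion_point(config, protocol)
  config <- add_water(config, p, lambda = 0)
  sweeps <- max(1L, as.integer(round(protocol$insertion_relax_sweeps /
                                       protocol$ramp_steps)))
  for (s in seq_len(protocol$ramp_steps)) {
    config <- if (s == protocol$ramp_steps) {
      # final increment: fully coupled
      if (!is.null(config$coupling)) set_coupling(config, 1) else config
    } else {
      set_coupling(config, s / protocol$ramp_steps)
    }
    config <- relax(config, sweeps, protocol$temperature, protocol$max_disp,
                    water_jump_fraction = protocol$water_jump_fraction)$config
  }
  config
}

.water_mass <- function(config) config$species$mass[.water_species_id(config)]

.matrix_mass <- function(config) {
  sum(config$species$mass[config$species_ids][!config$is_water])
}

# waters needed to sit at hydration level h
.n_for_h <- function(config, h) {
  as.integer(round(h * .matrix_mass(config) / .water_mass(config)))
}

#' Solvate a dry matrix to a target hydration level
#'
#' Desk-scale preparation: waters are placed at non-overlapping random
#' positions at full coupling, then the whole system is annealed for
#' `prep_sweeps`. Stands in for a long pre-equilibration of the hydrated
#' powder.
#'
#' @param config an `hs_config`.
#' @param h_target hydration level to reach (g/g).
#' @param protocol an [sorption_protocol()].
#' @return annealed configuration at `h_target`.
#' @export
solvate <- function(config, h_target, protocol) {
  n_add <- .n_for_h(config, h_target) - n_waters(config)
  for (k in seq_len(max(0L, n_add))) {
    config <- add_water(config, .find_insertion_point(config, protocol))
  }
  if (n_add > 0) {
    config <- relax(config, protocol$prep_sweeps, protocol$temperature,
                    protocol$max_disp,
                    water_jump_fraction = protocol$water_jump_fraction)$config
  }
  config
}

# production at one grid point: equilibrate, then save frames
.produce <- function(config, protocol) {
  eq <- as.integer(round(protocol$production_sweeps *
                           protocol$equilibration_fraction))
  config <- relax(config, eq, protocol$temperature, protocol$max_disp,
                  water_jump_fraction = protocol$water_jump_fraction)$config
  out <- relax(config, protocol$production_sweeps - eq, protocol$temperature,
               protocol$max_disp, save_every = protocol$frame_interval,
               water_jump_fraction = protocol$water_jump_fraction)
  list(config = out$config, frames = out$frames)
}

#' Run one sorption branch over the hydration grid
#'
#' Repeats single-water insertion (adsorption) or Boltzmann-weighted removal
#' (desorption) steps. Every time the water count crosses a grid point of
#' spacing `h_save_interval`, the system is given `production_sweeps` of
#' relaxation; frames from the tail of that relaxation (after discarding
#' `equilibration_fraction`) are stored for analysis and chemical-potential
#' estimation.
#'
#' @param config starting `hs_config` (typically at `h_start`).
#' @param protocol an [sorption_protocol()].
#' @param direction `"adsorb"` or `"desorb"`.
#' @return list with `points` (each: `h`, `n_waters`, `frames`) in visit
#'   order, `events`, a data.frame logging every insertion/removal
#'   (`step`, `action`, `n_waters`, `h`), and `config`, the final
#'   configuration of the branch.
#' @export
run_branch <- function(config, protocol, direction = c("adsorb", "desorb")) {
  direction <- match.arg(direction)
  int <- protocol$h_save_interval
  ks <- seq(ceiling(round(protocol$h_min / int, 9)),
            floor(round(protocol$h_max / int, 9)))
  grid_h <- ks * int
  grid_n <- vapply(grid_h, function(h) .n_for_h(config, h), integer(1))
  keep <- !duplicated(grid_n)
  grid_h <- grid_h[keep]; grid_n <- grid_n[keep]
  if (direction == "desorb") {
    grid_h <- rev(grid_h); grid_n <- rev(grid_n)
  }
  points <- list()
  record <- function(cfg) {
    pr <- .produce(cfg, protocol)
    points[[length(points) + 1L]] <<- list(h = hydration_level(pr$config),
                                           n_waters = n_waters(pr$config),
                                           frames = pr$frames)
    pr$config
  }
  pending <- 1L
  n_now <- n_waters(config)
  # grid points already satisfied by the starting state
  while (pending <= length(grid_n) && grid_n[pending] == n_now) {
    config <- record(config)
    pending <- pending + 1L
  }
  n_stop <- .n_for_h(config, if (direction == "adsorb") protocol$h_max
                             else protocol$h_min)
  events <- list()
  step <- 0L
  repeat {
    n_now <- n_waters(config)
    if (direction == "adsorb") {
      if (n_now >= n_stop) break
      config <- insert_water_continuous(config, protocol)
      action <- "insert"
    } else {
      if (n_now <= n_stop) break
      config <- remove_water_step(config, protocol)
      action <- "remove"
    }
    step <- step + 1L
    n_now <- n_waters(config)
    events[[step]] <- data.frame(step = step, action = action,
                                 n_waters = n_now,
                                 h = hydration_level(config))
    if (pending <= length(grid_n) && n_now == grid_n[pending]) {
      config <- record(config)
      pending <- pending + 1L
    }
  }
  list(points = points,
       events = if (length(events) > 0) do.call(rbind, events) else
         data.frame(step = integer(0), action = character(0),
                    n_waters = integer(0), h = numeric(0)),
       config = config)
}

#' Simulate a full sorption isotherm
#'
#' Solvates the matrix to `h_start` if needed, runs the adsorption branch up
#' to `h_max`, then the desorption branch back down to `h_min`, estimating
#' the water chemical potential (Bennett acceptance ratio over test
#' insertions and deletions) and relative humidity at every grid point.
#'
#' @param config a dry or pre-solvated `hs_config`.
#' @param protocol an [sorption_protocol()]; its `seed` (if any) seeds the
#'   run.
#' @param mu_sat chemical potential of saturated vapor, e.g. from
#'   [mu_saturation()] or [calibrate_mu_sat()].
#' @param branches subset of `c("adsorb", "desorb")` to run.
#' @param lambda3 thermal-wavelength reference constant; cancels in RH as
#'   long as the same value is used for `mu_sat`.
#' @param analyses optional named list of functions `f(frames)` evaluated at
#'   every grid point (e.g. a cluster-fraction summary); their results are
#'   returned per point.
#' @param keep_frames retain all production frames in the returned object
#'   (memory-heavy; off by default).
#' @return object of class `hs_isotherm`: `records` data.frame with columns
#'   `branch`, `h`, `n_waters`, `mu_w`, `mu_stderr`, `rh`; `analyses`;
#'   `final_config`; `metadata`.
#' @export
run_isotherm <- function(config, protocol, mu_sat,
                         branches = c("adsorb", "desorb"), lambda3 = 1,
                         analyses = NULL, keep_frames = FALSE) {
  if (!is.null(protocol$seed)) set.seed(protocol$seed)
  if (n_waters(config) < .n_for_h(config, protocol$h_start)) {
    config <- solvate(config, protocol$h_start, protocol)
  }
  records <- list()
  an_out <- list()
  frames_out <- list()
  eval_point <- function(pt, branch) {
    cpr <- chem_potential(pt$frames, n_insertions = protocol$n_insertions,
                          temperature = protocol$temperature, mu_sat = mu_sat,
                          lambda3 = lambda3)
    records[[length(records) + 1L]] <<- data.frame(
      branch = branch, h = pt$h, n_waters = pt$n_waters,
      mu_w = cpr$mu_total, mu_stderr = cpr$stderr, rh = cpr$rh)
    if (!is.null(analyses)) {
      an_out[[length(an_out) + 1L]] <<-
        c(list(branch = branch, h = pt$h),
          lapply(analyses, function(f) f(pt$frames)))
    }
    if (keep_frames) {
      frames_out[[length(frames_out) + 1L]] <<-
        list(branch = branch, h = pt$h, frames = pt$frames)
    }
  }
  for (branch in branches) {
    br <- run_branch(config, protocol,
                     direction = if (branch == "adsorb") "adsorb" else "desorb")
    for (pt in br$points) eval_point(pt, branch)
    config <- br$config
  }
  structure(list(records = do.call(rbind, records),
                 analyses = an_out,
                 final_config = config,
                 metadata = list(protocol = unclass(protocol),
                                 mu_sat = mu_sat, lambda3 = lambda3,
                                 n_beads = sum(!config$is_water))),
            class = "hs_isotherm")
}

#' @export
print.hs_isotherm <- function(x, ...) {
  cat(sprintf("<hs_isotherm> %d grid points\n", nrow(x$records)))
  print(x$records, digits = 4)
  invisible(x)
}

.branch_df <- function(iso, branch = NULL) {
  df <- if (inherits(iso, "hs_isotherm")) iso$records else as.data.frame(iso)
  if (!is.null(branch)) df <- df[df$branch == branch, , drop = FALSE]
  df[order(df$h), , drop = FALSE]
}

#' Quantify adsorption/desorption hysteresis
#'
#' Integrates `RH_ads(h) - RH_des(h)` over the common hydration range by the
#' trapezoid rule on the union grid (branch RH linearly interpolated), and
#' reports the maximum RH difference and its location.
#'
#' @param adsorption,desorption isotherm branches: data.frames with columns
#'   `h` and `rh`, or a single `hs_isotherm` can be passed as `adsorption`
#'   with `desorption = NULL`.
#' @return list of class `hs_hysteresis`: `area` (RH times g/g), `max_gap`,
#'   `h_at_max_gap`.
#' @export
hysteresis_area <- function(adsorption, desorption = NULL) {
  if (inherits(adsorption, "hs_isotherm") && is.null(desorption)) {
    des <- .branch_df(adsorption, "desorb")
    ads <- .branch_df(adsorption, "adsorb")
  } else {
    ads <- .branch_df(adsorption)
    des <- .branch_df(desorption)
  }
  lo <- max(min(ads$h), min(des$h))
  hi <- min(max(ads$h), max(des$h))
  if (!(lo < hi)) stop("branches do not cover an overlapping h range")
  grid <- sort(unique(c(ads$h[ads$h >= lo & ads$h <= hi],
                        des$h[des$h >= lo & des$h <= hi], lo, hi)))
  ra <- approx(ads$h, ads$rh, xout = grid, ties = mean)$y
  rd <- approx(des$h, des$rh, xout = grid, ties = mean)$y
  gap <- ra - rd
  area <- sum(diff(grid) * (head(gap, -1) + tail(gap, -1)) / 2)
  imax <- which.max(gap)
  structure(list(area = area, max_gap = gap[imax], h_at_max_gap = grid[imax]),
            class = "hs_hysteresis")
}

#' Hydration level reached at a given relative humidity
#'
#' Reads the uptake `h(RH)` off one branch. Because the measured RH(h) curve
#' is noisy, its running maximum over increasing h is used as a monotone
#' envelope before inverse interpolation.
#'
#' @param branch data.frame with columns `h` and `rh` (one branch).
#' @param rh_target relative humidity in percent.
#' @return the interpolated h at which the branch first reaches
#'   `rh_target`; `Inf` if the branch never reaches it (uptake exceeds the
#'   simulated range).
#' @export
uptake_at_rh <- function(branch, rh_target) {
  df <- .branch_df(branch)
  env <- cummax(df$rh)
  if (max(env) < rh_target) return(Inf)
  if (env[1] >= rh_target) return(df$h[1])
  i <- which(env >= rh_target)[1]
  h0 <- df$h[i - 1]; h1 <- df$h[i]
  r0 <- env[i - 1]; r1 <- env[i]
  if (r1 == r0) return(h1)
  h0 + (rh_target - r0) / (r1 - r0) * (h1 - h0)
}
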