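#' Forward/reverse work samples for free-energy estimation
#'
#' Containers for Bennett-acceptance-ratio input. `forward` holds test
#' insertion energy changes `dU_ins` (N to N+1 ghost particle); `reverse`
#' holds deletion energy changes `dU_del = U(N-1) - U(N)` of real waters
#' (the negative of the water's interaction energy), so a favourably bound
#' water has a positive `dU_del`.
#'
#' @param forward numeric vector of insertion energy changes.
#' @param reverse numeric vector of deletion energy changes (may be empty).
#' @param beta inverse temperature (> 0).
#' @return list of class `hs_work_samples` with counts `n_forward`,
#'   `n_reverse`.
#' @export
work_samples <- function(forward, reverse, beta) {
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0")
  structure(list(forward = as.numeric(forward),
                 reverse = as.numeric(reverse),
                 beta = beta,
                 n_forward = length(forward),
                 n_reverse = length(reverse)),
            class = "hs_work_samples")
}

#' Ghost insertion energies over a frame set
#'
#' For each frame, draws uniform random positions and records the energy
#' change of inserting a fully coupled test water there; configurations are
#' never modified. The total count is split evenly across frames.
#'
#' @param frames non-empty list of `hs_config` frames (no coupled particle).
#' @param n_insertions total number of test insertions (desk-scale default
#'   1e5).
#' @param keep_positions also return the sampled positions (for diagnostics
#'   and closed-form checks).
#' @return numeric vector of `dU_ins` values, or a list
#'   `(du, positions, frame)` when `keep_positions = TRUE`.
#' @export
sample_insertion_energies <- function(frames, n_insertions = 1e5,
                                      keep_positions = FALSE) {
  if (length(frames) == 0) stop("frames must be non-empty")
  per_frame <- max(1L, as.integer(ceiling(n_insertions / length(frames))))
  du <- vector("list", length(frames))
  pos <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    cfg <- frames[[f]]
    if (!is.null(cfg$coupling)) stop("frames must not carry a coupled particle")
    a <- .sim_args(cfg)
    wid <- .water_species_id(cfg)
    out <- cpp_insertion_energies(a$pos, a$eps, a$sig, a$aff, a$isw, a$L,
                                  a$per, a$rc, per_frame,
                                  cfg$species$epsilon[wid],
                                  cfg$species$sigma[wid])
    du[[f]] <- out$du
    if (keep_positions) pos[[f]] <- out$positions
  }
  if (keep_positions) {
    list(du = unlist(du), positions = do.call(rbind, pos),
         frame = rep(seq_along(frames), each = per_frame))
  } else {
    unlist(du)
  }
}

#' Ghost deletion energies over a frame set
#'
#' For each frame, records the energy change of removing each real water
#' (one reverse sample per water per frame); configurations are never
#' modified.
#'
#' @param frames list of `hs_config` frames.
#' @return numeric vector of `dU_del` values; empty (with attribute
#'   `widom_only = TRUE`) when the frames hold no waters.
#' @export
sample_deletion_energies <- function(frames) {
  if (length(frames) == 0) stop("frames must be non-empty")
  du <- lapply(frames, function(cfg) {
    a <- .sim_args(cfg)
    cpp_deletion_energies(a$pos, a$eps, a$sig, a$aff, a$isw, a$L, a$per,
                          a$rc, a$bonds, a$tethers, a$cidx, a$clam, a$alpha)
  })
  out <- unlist(du)
  if (length(out) == 0) attr(out, "widom_only") <- TRUE
  out
}

# Bennett self-consistency residual at trial free energy x = dF:
#   sum_F f(beta (u - x) + M) - sum_R f(beta (d + x) - M),  f = Fermi
# strictly increasing in x, so the root is unique.
.bar_residual <- function(x, u, d, beta, M) {
  sum(stats::plogis(-(beta * (u - x) + M))) -
    sum(stats::plogis(-(beta * (d + x) - M)))
}

#' Bennett acceptance ratio estimate of the excess chemical potential
#'
#' Solves Bennett's self-consistent equation over forward (insertion) and
#' reverse (deletion) energy samples by bracketed root-finding; the bracket
#' is expanded geometrically until it straddles the root and the equation is
#' solved to a residual below 1e-10. Falls back to a Widom average with a
#' warning when the reverse set is empty. The standard error comes from
#' re-estimating on `n_blocks` paired contiguous blocks of the samples.
#'
#' @param samples an [work_samples()] object.
#' @param n_blocks blocks for the standard error (default 5).
#' @return list of class `hs_chempot` with `mu_excess`, `stderr`, `method`
#'   (`"bar"` or `"widom"`), and sample-overlap diagnostics.
#' @export
bar_estimate <- function(samples, n_blocks = 5) {
  stopifnot(inherits(samples, "hs_work_samples"))
  u <- samples$forward
  d <- samples$reverse
  beta <- samples$beta
  if (length(u) == 0) stop("forward sample set is empty")
  if (all(!is.finite(u)) && length(u) > 0) {
    return(structure(list(mu_excess = Inf, stderr = NA_real_, method = "bar",
                          degenerate = TRUE),
                     class = "hs_chempot"))
  }
  if (length(d) == 0) {
    warning("reverse sample set empty; falling back to Widom insertion")
    mu <- widom_estimate(u, beta)
    se <- .block_se_widom(u, beta, n_blocks)
    return(structure(list(mu_excess = mu, stderr = se, method = "widom"),
                     class = "hs_chempot"))
  }
  M <- log(length(u) / length(d))
  point <- .bar_solve(u, d, beta, M)
  blocks <- .paired_blocks(u, d, n_blocks)
  ests <- vapply(blocks, function(b) {
    tryCatch(.bar_solve(b$u, b$d, beta, log(length(b$u) / length(b$d))),
             error = function(e) NA_real_)
  }, numeric(1))
  se <- if (all(is.finite(ests))) sd(ests) / sqrt(length(ests)) else NA_real_
  structure(list(mu_excess = point, stderr = se, method = "bar",
                 n_forward = length(u), n_reverse = length(d),
                 overlap = list(mean_forward = mean(u[is.finite(u)]),
                                mean_reverse = mean(d[is.finite(d)]))),
            class = "hs_chempot")
}

.bar_solve <- function(u, d, beta, M) {
  g <- function(x) .bar_residual(x, u, d, beta, M)
  x0 <- widom_estimate(u, beta)
  if (!is.finite(x0)) x0 <- mean(u[is.finite(u)])
  if (!is.finite(x0)) x0 <- 0
  w <- max(1, abs(x0))
  lo <- x0 - w; hi <- x0 + w
  for (k in 1:60) {
    if (g(lo) < 0 && g(hi) > 0) break
    w <- w * 2
    lo <- x0 - w; hi <- x0 + w
    if (k == 60) {
      stop(sprintf(paste0("BAR bracket failed: poor forward/reverse overlap ",
                          "(mean fwd %.3g, mean rev %.3g)"),
                   mean(u[is.finite(u)]), mean(d[is.finite(d)])))
    }
  }
  r <- uniroot(g, c(lo, hi), tol = 1e-13)
  # polish to the stated residual tolerance where the bracket allows it
  x <- r$root
  if (abs(g(x)) > 1e-10 * max(1, length(u))) {
    x <- tryCatch(
      uniroot(g, c(x - 1e-6, x + 1e-6),
              tol = .Machine$double.eps^0.75)$root,
      error = function(e) x)
  }
  x
}

.paired_blocks <- function(u, d, n_blocks) {
  nu <- length(u) %/% n_blocks
  nd <- length(d) %/% n_blocks
  if (nu == 0 || nd == 0) return(list())
  lapply(seq_len(n_blocks), function(b) {
    list(u = u[((b - 1) * nu + 1):(b * nu)],
         d = d[((b - 1) * nd + 1):(b * nd)])
  })
}

.block_se_widom <- function(u, beta, n_blocks) {
  m <- length(u) %/% n_blocks
  if (m == 0) return(NA_real_)
  ests <- vapply(seq_len(n_blocks), function(b) {
    widom_estimate(u[((b - 1) * m + 1):(b * m)], beta)
  }, numeric(1))
  if (all(is.finite(ests))) sd(ests) / sqrt(n_blocks) else NA_real_
}

#' Widom test-particle estimate of the excess chemical potential
#'
#' `mu_ex = -(1/beta) ln < exp(-beta dU) >` over forward insertion samples,
#' evaluated with max-shifted exponentials.
#'
#' @param forward numeric vector of insertion energy changes.
#' @param beta inverse temperature.
#' @return scalar `mu_ex`; `+Inf` when every insertion overflows.
#' @export
widom_estimate <- function(forward, beta) {
  if (length(forward) == 0) stop("forward sample set is empty")
  x <- -beta * forward
  x[is.na(x)] <- -Inf
  m <- max(x)
  if (!is.finite(m)) return(Inf)
  -(m + log(mean(exp(x - m)))) / beta
}

#' Chemical potential of saturated vapor from the ideal-gas law
#'
#' `mu_sat = kT ln(rho_sat Lambda^3)` with `rho_sat = p_sat / (kT)` (k_B = 1
#' in reduced units; for real-unit analyses pass a consistent unit system,
#' e.g. the reference vapor pressure 0.01 bar at 300 K). The `Lambda^3`
#' reference constant cancels against the matrix-phase ideal term as long as
#' the same value is used in both, so relative humidity does not depend on
#' it.
#'
#' @param temperature absolute temperature (> 0).
#' @param p_sat saturation vapor pressure (> 0) in units of `kT` per volume.
#' @param lambda3 thermal-wavelength reference constant (default 1).
#' @return scalar `mu_sat`.
#' @export
mu_saturation <- function(temperature, p_sat, lambda3 = 1) {
  if (temperature <= 0 || p_sat <= 0) stop("temperature and p_sat must be > 0")
  rho <- p_sat / temperature
  temperature * log(rho * lambda3)
}

#' Relative humidity from chemical potentials
#'
#' `RH = 100 exp((mu_w - mu_sat) / (R T))` (R = k_B = 1 in reduced units).
#' Values above 100 are returned as computed and flagged supersaturated.
#'
#' @param mu_w water chemical potential in the matrix.
#' @param mu_sat saturated-vapor chemical potential (same reference).
#' @param temperature absolute temperature.
#' @return RH in percent, with attribute `supersaturated`.
#' @export
relative_humidity <- function(mu_w, mu_sat, temperature) {
  if (temperature <= 0) stop("temperature must be > 0")
  rh <- 100 * exp((mu_w - mu_sat) / temperature)
  attr(rh, "supersaturated") <- rh > 100
  rh
}

#' Full chemical-potential estimate for a frame set
#'
#' Runs test insertions and deletions over the frames, estimates the excess
#' chemical potential by Bennett's acceptance ratio, adds the ideal-gas term
#' `kT ln(rho_w Lambda^3)` at the frames' water density, and converts to
#' relative humidity when `mu_sat` is given. The standard error is a 5-block
#' analysis over the sample stream.
#'
#' @param frames list of `hs_config` frames at one hydration level.
#' @param n_insertions total test insertions.
#' @param temperature reduced temperature.
#' @param mu_sat optional saturated-vapor chemical potential for RH.
#' @param lambda3 thermal-wavelength reference constant (must match the one
#'   in `mu_sat`).
#' @param n_blocks blocks for the standard error.
#' @return list of class `hs_chempot` with `mu_excess`, `mu_total`,
#'   `stderr`, `rh`, `method`.
#' @export
chem_potential <- function(frames, n_insertions = 1e5, temperature = 0.75,
                           mu_sat = NULL, lambda3 = 1, n_blocks = 5) {
  beta <- 1 / temperature
  fwd <- sample_insertion_energies(frames, n_insertions)
  rev <- sample_deletion_energies(frames)
  est <- if (length(rev) > 0) {
    bar_estimate(work_samples(fwd, rev, beta), n_blocks = n_blocks)
  } else {
    structure(list(mu_excess = widom_estimate(fwd, beta),
                   stderr = .block_se_widom(fwd, beta, n_blocks),
                   method = "widom"), class = "hs_chempot")
  }
  nw <- mean(vapply(frames, n_waters, integer(1)))
  V <- prod(frames[[1]]$box$lengths)
  mu_id <- if (nw > 0) temperature * log(nw / V * lambda3) else -Inf
  est$mu_total <- est$mu_excess + mu_id
  est$rh <- if (!is.null(mu_sat)) {
    as.numeric(relative_humidity(est$mu_total, mu_sat, temperature))
  } else NA_real_
  est
}

#' Calibrate the toy water's saturation chemical potential
#'
#' The reduced-unit water model has no tabulated vapor pressure, so the
#' saturation reference is measured directly: a dilute pure-water box at a
#' user-supplied coexistence vapor density is relaxed and Widom-sampled, and
#' `mu_sat = kT ln(rho_vap Lambda^3) + mu_ex(vapor)`.
#'
#' @param temperature reduced temperature.
#' @param rho_vap coexistence vapor number density of the water model.
#' @param n_molecules water molecules in the calibration box.
#' @param sweeps relaxation sweeps before sampling.
#' @param n_insertions Widom insertions.
#' @param lambda3 thermal-wavelength reference constant.
#' @param seed optional seed for the calibration run.
#' @param species species table supplying the water parameters.
#' @return scalar `mu_sat` with attribute `mu_ex_vapor`.
#' @export
calibrate_mu_sat <- function(temperature, rho_vap, n_molecules = 60,
                             sweeps = 200, n_insertions = 2e4, lambda3 = 1,
                             seed = NULL, species = hs_species_table()) {
  if (!is.null(seed)) set.seed(seed)
  L <- (n_molecules / rho_vap)^(1 / 3)
  wid <- which(species$name == "water")
  sig_w <- species$sigma[wid]
  box <- hs_box(rep(L, 3))
  rc <- min(3 * sig_w, L / 2 * 0.999)
  cfg <- hs_configuration(matrix(runif(3 * n_molecules) * L, ncol = 3),
                          rep(wid, n_molecules), rep(TRUE, n_molecules),
                          box, species = species, cutoff = rc,
                          validate = FALSE)
  cfg <- relax(cfg, sweeps, temperature)$config
  out <- relax(cfg, sweeps, temperature, save_every = max(1, sweeps %/% 10))
  fwd <- sample_insertion_energies(out$frames, n_insertions)
  mu_ex <- widom_estimate(fwd, 1 / temperature)
  mu <- temperature * log(rho_vap * lambda3) + mu_ex
  attr(mu, "mu_ex_vapor") <- mu_ex
  mu
}

#' @export
print.hs_chempot <- function(x, ...) {
  cat(sprintf("<hs_chempot> mu_excess = %.4f (stderr %.4f, %s)\n",
              x$mu_excess, x$stderr, x$method))
  if (!is.null(x$mu_total)) {
    cat(sprintf("  mu_total = %.4f, RH = %.2f%%\n", x$mu_total,
                x$rh %||% NA_real_))
  }
  invisible(x)
}
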