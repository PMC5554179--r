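#' Quasi-uniform points on the unit sphere (golden-spiral lattice)
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
golden_sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each particle's surface is the sphere of radius `sasa_radius + probe`;
#' the accessible fraction is the share of quasi-uniform surface points not
#' buried inside any neighbour's expanded sphere (periodic neighbours
#' included). By default only the matrix beads are considered -- water is
#' the solvent -- and interior cavity surface counts like any other surface.
#'
#' @param frame an `hs_config`.
#' @param probe_radius probe radius (reduced units; use 1.4 for Angstrom
#'   inputs).
#' @param n_sphere_points surface points per particle (>= 32; default 960).
#' @param include_water treat waters as part of the surface-bearing set.
#' @return list with `total` area and `per_particle` areas (named by
#'   particle index).
#' @export
sasa <- function(frame, probe_radius = 0.5, n_sphere_points = 960,
                 include_water = FALSE) {
  if (n_sphere_points < 32) stop("n_sphere_points must be >= 32")
  subset <- if (include_water) seq_len(nrow(frame$positions)) else
    which(!frame$is_water)
  if (length(subset) == 0) {
    return(list(total = 0, per_particle = numeric(0)))
  }
  radii <- frame$species$sasa_radius[frame$species_ids] + probe_radius
  pts <- golden_sphere_points(n_sphere_points)
  area <- cpp_sasa(frame$positions, radii, frame$box$lengths,
                   as.integer(frame$box$periodic), pts, as.integer(subset))
  names(area) <- subset
  list(total = sum(area), per_particle = area)
}

# unwrap a particle group across periodic images: walk the bond graph when
# the group is bonded; an entirely unbonded group (e.g. free beads) is
# unwrapped by minimum image relative to its first member, valid while the
# group's extent stays under half the box
.unwrap_group <- function(frame, idx) {
  pos <- frame$positions[idx, , drop = FALSE]
  n <- length(idx)
  if (n == 1) return(pos)
  b <- .all_bonds(frame$topology)
  adj <- vector("list", n)
  n_edges <- 0L
  if (nrow(b) > 0) {
    for (r in seq_len(nrow(b))) {
      i <- match(b[r, 1], idx); j <- match(b[r, 2], idx)
      if (!is.na(i) && !is.na(j)) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
        n_edges <- n_edges + 1L
      }
    }
  }
  out <- matrix(NA_real_, n, 3)
  out[1, ] <- pos[1, ]
  if (n_edges == 0L) {
    for (j in 2:n) {
      out[j, ] <- pos[1, ] + minimum_image(pos[j, ] - pos[1, ], frame$box)
    }
    return(out)
  }
  queue <- 1L
  seen <- c(TRUE, rep(FALSE, n - 1))
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    for (j in adj[[i]]) {
      if (!seen[j]) {
        seen[j] <- TRUE
        out[j, ] <- out[i, ] + minimum_image(pos[j, ] - pos[i, ], frame$box)
        queue <- c(queue, j)
      }
    }
  }
  if (!all(seen)) {
    stop("group is split across the box with no bonded path to unwrap it")
  }
  out
}

#' Mean radius of gyration over particle groups
#'
#' Each group (a chain by default) is unwrapped across periodic images by
#' walking its bonded topology, then the mass-weighted radius of gyration is
#' computed and averaged (unweighted) over groups.
#'
#' @param frame an `hs_config`.
#' @param grouping `"chain"` or an integer vector of group labels over the
#'   matrix particles.
#' @return list with `mean` and `per_group` values.
#' @export
radius_of_gyration <- function(frame, grouping = "chain") {
  beads <- which(!frame$is_water)
  labels <- if (identical(grouping, "chain")) frame$chain_ids[beads] else
    rep_len(grouping, length(beads))
  groups <- split(beads, labels)
  rg <- vapply(groups, function(idx) {
    if (length(idx) < 2) stop("each group needs >= 2 particles")
    up <- .unwrap_group(frame, idx)
    m <- frame$species$mass[frame$species_ids[idx]]
    com <- colSums(up * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(up, 2, com)^2)) / sum(m))
  }, numeric(1))
  list(mean = mean(rg), per_group = rg)
}

.residue_sets <- function(frame) {
  beads <- which(!frame$is_water)
  split(beads, frame$residue_ids[beads])
}

#' Averaged inter-residue shortest-distance map
#'
#' For every residue pair, the shortest minimum-image distance between any
#' two of their particles is taken per frame, then averaged over frames.
#' With `average_chains = TRUE` (and equal-length chains) the map is
#' computed per chain over within-chain residue position and averaged over
#' the chain copies, mirroring a per-protein map averaged over powder
#' copies.
#'
#' @param frames non-empty list of `hs_config` frames.
#' @param residues optional named list of particle-index vectors defining
#'   the residues; defaults to the frames' residue labels.
#' @param average_chains average per-chain maps over chain copies.
#' @return list of class `hs_distance_map` with `map` (symmetric matrix,
#'   zero diagonal) and `n_frames`.
#' @export
residue_distance_map <- function(frames, residues = NULL,
                                 average_chains = FALSE) {
  if (length(frames) == 0) stop("frames must be non-empty")
  f1 <- frames[[1]]
  sets_list <- if (!is.null(residues)) {
    list(residues)
  } else if (average_chains) {
    beads <- which(!f1$is_water)
    chains <- split(beads, f1$chain_ids[beads])
    len <- unique(vapply(chains, length, integer(1)))
    if (length(len) != 1) stop("average_chains requires equal-length chains")
    lapply(chains, function(ch) as.list(ch))
  } else {
    list(.residue_sets(f1))
  }
  maps <- lapply(sets_list, function(sets) {
    nr <- length(sets)
    acc <- matrix(0, nr, nr)
    for (fr in frames) {
      L <- fr$box$lengths; per <- as.integer(fr$box$periodic)
      for (i in seq_len(nr)) {
        pi <- fr$positions[unlist(sets[[i]]), , drop = FALSE]
        for (j in seq_len(nr)) {
          if (j <= i) next
          pj <- fr$positions[unlist(sets[[j]]), , drop = FALSE]
          acc[i, j] <- acc[i, j] + min(cpp_dist_mi(pi, pj, L, per))
        }
      }
    }
    acc <- acc / length(frames)
    acc + t(acc)
  })
  map <- Reduce(`+`, maps) / length(maps)
  dimnames(map) <- list(names(sets_list[[1]]), names(sets_list[[1]]))
  structure(list(map = map, n_frames = length(frames)),
            class = "hs_distance_map")
}

#' Elementwise difference of two distance maps
#'
#' Conventionally `map_high - map_low` (swelling gives positive
#' off-diagonal entries).
#'
#' @param map_high,map_low `hs_distance_map` objects or plain matrices of
#'   identical dimensions.
#' @return numeric matrix.
#' @export
distance_map_difference <- function(map_high, map_low) {
  a <- if (inherits(map_high, "hs_distance_map")) map_high$map else map_high
  b <- if (inherits(map_low, "hs_distance_map")) map_low$map else map_low
  if (!all(dim(a) == dim(b))) stop("distance maps have different dimensions")
  a - b
}

#' Water clustering with periodic spanning detection
#'
#' Two waters are connected when their minimum-image distance is below
#' `cutoff` (3.5 Angstrom in real units; for reduced-unit runs derive the
#' cutoff from the water-water radial distribution function, see
#' [derive_cutoffs()]). Connected components are found by union-find while
#' tracking each water's periodic image vector; a cluster spans an axis when
#' an edge closes a loop with a non-zero net image displacement, i.e. the
#' cluster connects to its own periodic image.
#'
#' @param frame an `hs_config`.
#' @param cutoff connectivity distance (> 0, at most half the smallest
#'   periodic extent).
#' @return list of class `hs_clusters`: `labels` (per water, 1..k in
#'   decreasing size order), `sizes`, `largest_fraction`, `spanning` (three
#'   logicals: any cluster spans that axis), `cluster_spanning` (k x 3).
#' @export
water_clusters <- function(frame, cutoff) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  wat <- which(frame$is_water)
  nw <- length(wat)
  empty <- list(labels = integer(0), sizes = integer(0),
                largest_fraction = NA_real_, spanning = rep(FALSE, 3),
                cluster_spanning = matrix(FALSE, 0, 3))
  if (nw == 0) return(structure(empty, class = "hs_clusters"))
  L <- frame$box$lengths
  per <- frame$box$periodic
  if (any(per) && cutoff > min(L[per]) / 2) {
    stop("cutoff must not exceed half the smallest periodic extent")
  }
  pos <- frame$positions[wat, , drop = FALSE]
  parent <- seq_len(nw)
  off <- matrix(0, nw, 3)           # integer image offset relative to parent
  wind <- matrix(FALSE, nw, 3)      # winding flags, stored at roots
  find <- function(i) {
    path <- integer(0)
    while (parent[i] != i) {
      path <- c(path, i)
      i <- parent[i]
    }
    # path compression with offset accumulation (root-ward order)
    for (p in rev(path)) {
      off[p, ] <<- off[p, ] + off[parent[p], ]
      parent[p] <<- i
    }
    i
  }
  d <- array(0, c(nw, nw, 3))
  for (a in 1:3) {
    da <- outer(pos[, a], pos[, a], `-`)
    if (per[a]) da <- da - L[a] * floor(da / L[a] + 0.5)
    d[, , a] <- da
  }
  r2 <- d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2
  pairs <- which(upper.tri(r2) & r2 < cutoff^2, arr.ind = TRUE)
  for (e in seq_len(nrow(pairs))) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    raw <- pos[j, ] - pos[i, ]
    s <- ifelse(per, -floor(raw / L + 0.5), 0)   # o_j - o_i along this edge
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[rj] <- ri
      off[rj, ] <- off[i, ] + s - off[j, ]
      wind[ri, ] <- wind[ri, ] | wind[rj, ]
    } else {
      mismatch <- (off[i, ] + s - off[j, ]) != 0
      wind[ri, ] <- wind[ri, ] | mismatch
    }
  }
  roots <- vapply(seq_len(nw), find, integer(1))
  sizes <- sort(table(roots), decreasing = TRUE)
  order_roots <- as.integer(names(sizes))
  labels <- match(roots, order_roots)
  cl_span <- wind[order_roots, , drop = FALSE]
  structure(list(labels = labels, sizes = as.integer(sizes),
                 largest_fraction = as.integer(sizes[1]) / nw,
                 spanning = apply(cl_span, 2, any),
                 cluster_spanning = cl_span),
            class = "hs_clusters")
}

#' Largest-cluster fraction versus hydration level
#'
#' @param trajectories named list: `h` value (as name or via the `h`
#'   attribute) mapping to a list of frames.
#' @param cutoff water-water connectivity cutoff.
#' @param n_blocks blocks for the per-h standard error.
#' @return data.frame with `h`, `largest_fraction`, `stderr`.
#' @export
largest_cluster_curve <- function(trajectories, cutoff, n_blocks = 5) {
  hs <- as.numeric(names(trajectories))
  rows <- lapply(seq_along(trajectories), function(k) {
    frames <- trajectories[[k]]
    fr <- vapply(frames, function(f) water_clusters(f, cutoff)$largest_fraction,
                 numeric(1))
    if (length(fr) >= n_blocks) {
      ba <- block_average(fr, n_blocks)
      data.frame(h = hs[k], largest_fraction = ba$mean, stderr = ba$stderr)
    } else {
      data.frame(h = hs[k], largest_fraction = mean(fr),
                 stderr = if (length(fr) > 1) sd(fr) / sqrt(length(fr))
                          else NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  out[order(out$h), , drop = FALSE]
}

#' Distribution of neighbour counts within a shell
#'
#' For each centre particle, counts partner particles within `cutoff`
#' (minimum image), pools the counts over centres and frames, and normalizes
#' to a probability distribution over integer counts.
#'
#' @param frames non-empty list of `hs_config` frames.
#' @param centers,partners integer particle-index vectors (constant across
#'   frames); a particle occurring in both sets never counts itself.
#' @param cutoff shell radius (> 0).
#' @return list of class `hs_shell_histogram`: `counts` data.frame
#'   (`count`, `prob`), `mean_count`, `cutoff`.
#' @export
shell_count_distribution <- function(frames, centers, partners, cutoff) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (length(centers) == 0) stop("centre set must be non-empty")
  all_counts <- integer(0)
  for (fr in frames) {
    D <- cpp_dist_mi(fr$positions[centers, , drop = FALSE],
                     fr$positions[partners, , drop = FALSE],
                     fr$box$lengths, as.integer(fr$box$periodic))
    self <- outer(centers, partners, `==`)
    cnt <- rowSums(D < cutoff & !self)
    all_counts <- c(all_counts, cnt)
  }
  tab <- table(factor(all_counts, levels = 0:max(all_counts)))
  prob <- as.numeric(tab) / sum(tab)
  structure(list(counts = data.frame(count = as.integer(names(tab)),
                                     prob = prob),
                 mean_count = mean(all_counts), cutoff = cutoff),
            class = "hs_shell_histogram")
}

#' Radial distribution function between two particle sets
#'
#' Standard pair-distance histogram normalized by the ideal-gas shell count
#' at the partners' mean density.
#'
#' @param frames non-empty list of `hs_config` frames.
#' @param set_a,set_b integer particle-index vectors.
#' @param r_max histogram range (at most half the smallest periodic extent).
#' @param n_bins number of bins.
#' @return data.frame with bin centres `r` and `g`.
#' @export
rdf <- function(frames, set_a, set_b, r_max, n_bins = 100) {
  f1 <- frames[[1]]
  per <- f1$box$periodic
  if (any(per) && r_max > min(f1$box$lengths[per]) / 2) {
    stop("r_max must not exceed half the smallest periodic extent")
  }
  edges <- seq(0, r_max, length.out = n_bins + 1)
  H <- numeric(n_bins)
  same <- identical(sort(set_a), sort(set_b))
  for (fr in frames) {
    D <- cpp_dist_mi(fr$positions[set_a, , drop = FALSE],
                     fr$positions[set_b, , drop = FALSE],
                     fr$box$lengths, as.integer(fr$box$periodic))
    self <- outer(set_a, set_b, `==`)
    d <- D[!self & D < r_max]
    H <- H + tabulate(findInterval(d, edges, rightmost.closed = TRUE),
                      nbins = n_bins)
  }
  V <- prod(f1$box$lengths)
  nb_eff <- if (same) length(set_b) - 1 else length(set_b)
  rho_b <- nb_eff / V
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(n_bins + 1)]^3)
  ideal <- length(frames) * length(set_a) * rho_b * shell
  data.frame(r = (edges[-1] + edges[-(n_bins + 1)]) / 2, g = H / ideal)
}

#' Location of the first minimum of a radial distribution function
#'
#' Finds the first local maximum, then the first local minimum after it,
#' refined by a parabola through the three neighbouring bins.
#'
#' @param g data.frame with columns `r` and `g` (as returned by [rdf()]).
#' @return the refined r of the first minimum.
#' @export
first_minimum <- function(g) {
  y <- g$g; r <- g$r
  n <- length(y)
  imax <- NA
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1]) { imax <- i; break }
  }
  if (is.na(imax)) stop("no maximum found in g(r)")
  imin <- NA
  for (i in (imax + 1):(n - 1)) {
    if (y[i] <= y[i - 1] && y[i] < y[i + 1]) { imin <- i; break }
  }
  if (is.na(imin)) stop("no minimum after the first maximum of g(r)")
  # parabolic refinement over (imin-1, imin, imin+1)
  y0 <- y[imin - 1]; y1 <- y[imin]; y2 <- y[imin + 1]
  denom <- y0 - 2 * y1 + y2
  shift <- if (denom != 0) 0.5 * (y0 - y2) / denom else 0
  r[imin] + shift * (r[2] - r[1])
}

#' Derive hydration-shell cutoffs from radial distribution functions
#'
#' Mirrors the reference procedure for reduced-unit runs: the water-water,
#' bead-water and bead-bead shell cutoffs are the first minima of the
#' corresponding radial distribution functions.
#'
#' @param frames frames at a well-hydrated state.
#' @param r_max,n_bins passed to [rdf()].
#' @return list with `water_water`, `bead_water`, `bead_bead` cutoffs.
#' @export
derive_cutoffs <- function(frames, r_max = NULL, n_bins = 60) {
  f1 <- frames[[1]]
  per <- f1$box$periodic
  r_max <- r_max %||% (min(f1$box$lengths[per]) / 2 * 0.99)
  wat <- which(f1$is_water)
  bead <- which(!f1$is_water)
  list(water_water = first_minimum(rdf(frames, wat, wat, r_max, n_bins)),
       bead_water = first_minimum(rdf(frames, bead, wat, r_max, n_bins)),
       bead_bead = first_minimum(rdf(frames, bead, bead, r_max, n_bins)))
}

#' Residue-level hydration difference between sorption branches
#'
#' Per residue, the mean number of waters within `cutoff` of any of its
#' particles on the adsorption branch minus the same on the desorption
#' branch, at matching hydration level, with block standard errors.
#'
#' @param ads_frames,des_frames frame lists at the same hydration level
#'   (asserted within `h_tol`).
#' @param cutoff hydration-shell radius.
#' @param n_blocks blocks per branch for the standard error.
#' @param h_tol tolerance on the branch h mismatch (g/g).
#' @return data.frame with `residue`, `difference`, `stderr`.
#' @export
local_hydration_difference <- function(ads_frames, des_frames, cutoff,
                                       n_blocks = 5, h_tol = 1e-6) {
  h_a <- mean(vapply(ads_frames, hydration_level, numeric(1)))
  h_d <- mean(vapply(des_frames, hydration_level, numeric(1)))
  if (abs(h_a - h_d) > h_tol) {
    stop(sprintf("branch hydration levels differ: %.4f vs %.4f g/g", h_a, h_d))
  }
  sets <- .residue_sets(ads_frames[[1]])
  count_per_frame <- function(frames) {
    vapply(frames, function(fr) {
      wat <- which(fr$is_water)
      vapply(sets, function(idx) {
        if (length(wat) == 0) return(0)
        D <- cpp_dist_mi(fr$positions[idx, , drop = FALSE],
                         fr$positions[wat, , drop = FALSE],
                         fr$box$lengths, as.integer(fr$box$periodic))
        sum(apply(D, 2, min) < cutoff)
      }, numeric(1))
    }, numeric(length(sets)))
  }
  ca <- count_per_frame(ads_frames)   # residues x frames
  cd <- count_per_frame(des_frames)
  stat <- function(m) {
    t(apply(m, 1, function(x) {
      if (length(x) >= n_blocks) unlist(block_average(x, n_blocks))
      else c(mean = mean(x), stderr = NA_real_)
    }))
  }
  sa <- stat(ca); sd_ <- stat(cd)
  data.frame(residue = names(sets),
             difference = sa[, "mean"] - sd_[, "mean"],
             stderr = sqrt(sa[, "stderr"]^2 + sd_[, "stderr"]^2),
             row.names = NULL)
}

#' Block-averaged mean and standard error
#'
#' Splits the series into `n_blocks` equal contiguous blocks (trailing
#' remainder elements are dropped); the standard error is the standard
#' deviation of the block means divided by `sqrt(n_blocks)`.
#'
#' @param series numeric vector, length at least `n_blocks`.
#' @param n_blocks number of blocks (default 5).
#' @return list with `mean` and `stderr`.
#' @export
block_average <- function(series, n_blocks = 5) {
  n <- length(series)
  if (n < n_blocks) stop("series shorter than the number of blocks")
  m <- n %/% n_blocks
  bm <- vapply(seq_len(n_blocks), function(b) {
    mean(series[((b - 1) * m + 1):(b * m)])
  }, numeric(1))
  list(mean = mean(bm), stderr = sd(bm) / sqrt(n_blocks))
}
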