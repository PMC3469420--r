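# Discrete vessel network: lattice occupancy, junction graph, tip-cell
# selection (mechanistic, V'-variant and legacy phenomenological modes),
# lattice-free tip migration, sprouting and anastomosis.
#
# Vessels are one cell wide; occupancy never decreases (no pruning).
# Junctions are 4-neighbour (face) adjacencies between occupied cells.

#' Create a vessel network from a geometry's seed cells
#'
#' Each seed becomes a stalk EC with the fresh initial intracellular state
#' (maximal VEGFR-2 and actin, no activity) on its own branch, positioned at
#' its cell centre.
#'
#' @param geometry An \code{ac_geometry}.
#' @param params Parameter registry.
#' @return An \code{ac_network}: occupancy matrix \code{occ}, EC registry
#'   \code{reg} (positions in um, phenotype, branch lineage, intracellular
#'   state), branch/id counters and the anastomosis event count.
#' @export
network_create <- function(geometry, params = default_params()) {
  n <- nrow(geometry$seeds)
  h <- geometry$spacing
  occ <- matrix(0L, geometry$nx, geometry$ny)
  if (n > 0) occ[geometry$seeds] <- 1L
  reg <- cbind(
    data.frame(id = seq_len(n),
               ix = as.integer(geometry$seeds[, 1]),
               iy = as.integer(geometry$seeds[, 2]),
               phen = rep("stalk", n),
               branch = seq_len(n),
               x = (geometry$seeds[, 1] - 0.5) * h,
               y = (geometry$seeds[, 2] - 0.5) * h,
               ux = rep(0, n), uy = rep(0, n),
               sprouted = rep(FALSE, n),
               stringsAsFactors = FALSE),
    ec_initial_state(n, params))
  net <- list(occ = occ, reg = reg, next_id = n + 1L, next_branch = n + 1L,
              n_anastomoses = 0L, nx = geometry$nx, ny = geometry$ny,
              spacing = h)
  class(net) <- c("ac_network", "list")
  net
}

# Row index of the EC occupying each grid cell (0 = empty).
net_idmap <- function(net) {
  m <- matrix(0L, net$nx, net$ny)
  if (nrow(net$reg)) m[cbind(net$reg$ix, net$reg$iy)] <- seq_len(nrow(net$reg))
  m
}

NB_OFFSETS <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))

# Junction adjacency: list of neighbouring EC row indices per EC.
net_adjacency <- function(net, idmap = net_idmap(net)) {
  n <- nrow(net$reg)
  lapply(seq_len(n), function(i) {
    ix <- net$reg$ix[i]; iy <- net$reg$iy[i]
    out <- integer(0)
    for (d in seq_len(4)) {
      jx <- ix + NB_OFFSETS[d, 1]; jy <- iy + NB_OFFSETS[d, 2]
      if (jx >= 1 && jx <= net$nx && jy >= 1 && jy <= net$ny) {
        j <- idmap[jx, jy]
        if (j > 0L) out <- c(out, j)
      }
    }
    out
  })
}

#' Tip-cell selection criterion
#'
#' Standard mode: \code{V > V_max/2} and \code{A > A*} (strict
#' inequalities). The \code{"Vprime"} variant replaces the VEGFR-2
#' requirement with one on active VEGFR-2 against a configurable threshold
#' (\code{params$vprime_crit}). The \code{"phenomenological"} legacy mode is
#' handled by the sprouting rules, not per-cell state; requesting it here is
#' an error.
#'
#' @param V,Vp,A State vectors.
#' @param mode One of \code{"V"}, \code{"Vprime"}.
#' @param params Parameter registry.
#' @return Logical vector.
#' @export
evaluate_tip_criterion <- function(V, Vp, A, mode = c("V", "Vprime"),
                                   params = default_params()) {
  mode <- match.arg(mode)
  switch(mode,
         V      = V > params$V_star & A > params$A_star,
         Vprime = Vp > params$vprime_crit & A > params$A_star)
}

#' Tip migration speed
#'
#' Zero at or below the activation threshold V'*, then a C1 cubic
#' (Hermite smoothstep) rise to the maximal speed of 35 um/day at the
#' saturation level \code{vp_sat}; continuous, monotone nondecreasing and
#' capped everywhere.
#'
#' @param Vp Active VEGFR-2 level(s), nonnegative.
#' @param params Parameter registry.
#' @return Speed(s) in um/day.
#' @export
tip_speed <- function(Vp, params = default_params()) {
  u <- (Vp - params$vp_star) / (params$vp_sat - params$vp_star)
  u <- pmin(pmax(u, 0), 1)
  params$tip_speed_max * (3 * u^2 - 2 * u^3)
}

# Bilinear interpolation of a cell-centered field and the gradient of the
# interpolant at a continuous position (um). Values outside the convex hull
# of cell centres clamp to the border.
interp_bilinear <- function(mat, x, y, h) {
  nx <- nrow(mat); ny <- ncol(mat)
  fx <- x / h + 0.5; fy <- y / h + 0.5     # fractional cell-centre coords
  i0 <- pmin(pmax(floor(fx), 1), nx - 1); j0 <- pmin(pmax(floor(fy), 1), ny - 1)
  tx <- pmin(pmax(fx - i0, 0), 1); ty <- pmin(pmax(fy - j0, 0), 1)
  f00 <- mat[cbind(i0, j0)];     f10 <- mat[cbind(i0 + 1, j0)]
  f01 <- mat[cbind(i0, j0 + 1)]; f11 <- mat[cbind(i0 + 1, j0 + 1)]
  val <- (1 - tx) * (1 - ty) * f00 + tx * (1 - ty) * f10 +
    (1 - tx) * ty * f01 + tx * ty * f11
  gx <- ((1 - ty) * (f10 - f00) + ty * (f11 - f01)) / h
  gy <- ((1 - tx) * (f01 - f00) + tx * (f11 - f10)) / h
  list(value = val, gx = gx, gy = gy)
}

#' Tip migration direction
#'
#' Normalised weighted sum of the unit chemotactic cue (gradient of the
#' angiogenic growth factor) and the unit haptotactic cue (gradient of total
#' matrix density), both interpolated bilinearly at the tip's continuous
#' position. If the combined cue is (numerically) zero the previous
#' direction is retained.
#'
#' @param x,y Tip position (um).
#' @param gvmat,mmat Field matrices (VEGF, total matrix density).
#' @param h Grid spacing (um).
#' @param prev Previous unit direction, length-2.
#' @param params Parameter registry.
#' @return Unit direction vector, length-2.
#' @export
tip_direction <- function(x, y, gvmat, mmat, h, prev = c(0, 0),
                          params = default_params()) {
  gg <- interp_bilinear(gvmat, x, y, h)
  gm <- interp_bilinear(mmat, x, y, h)
  cue <- c(0, 0)
  ng <- sqrt(gg$gx^2 + gg$gy^2)
  if (ng > 1e-300) cue <- cue + params$chemo_weight * c(gg$gx, gg$gy) / ng
  nm <- sqrt(gm$gx^2 + gm$gy^2)
  if (nm > 1e-300) cue <- cue + params$hapto_weight * c(gm$gx, gm$gy) / nm
  nc <- sqrt(sum(cue^2))
  if (nc < 1e-12) return(prev)
  cue / nc
}

# Stage 1: tips failing the active criterion revert to stalk, snapped to
# their cell centre.
retire_tips <- function(net, gvmat, mode, params) {
  tips <- which(net$reg$phen == "tip")
  if (!length(tips)) return(net)
  keep <- if (mode == "phenomenological") {
    gvmat[cbind(net$reg$ix[tips], net$reg$iy[tips])] >= params$legacy_gv_min
  } else {
    evaluate_tip_criterion(net$reg$V[tips], net$reg$Vp[tips],
                           net$reg$A[tips], mode, params)
  }
  drop <- tips[!keep]
  if (length(drop)) {
    net$reg$phen[drop] <- "stalk"
    net$reg$x[drop] <- (net$reg$ix[drop] - 0.5) * net$spacing
    net$reg$y[drop] <- (net$reg$iy[drop] - 0.5) * net$spacing
  }
  net
}

# Stage 2: lattice-free explicit-Euler movement of one tip; commits grid
# crossings (occupying new cells, spawning trailing stalk ECs) and detects
# anastomosis with foreign branches.
move_tip <- function(net, i, gvmat, mmat, geometry, dt, params) {
  h <- net$spacing
  s <- tip_speed(net$reg$Vp[i], params)
  if (s <= 0) return(net)
  u <- tip_direction(net$reg$x[i], net$reg$y[i], gvmat, mmat, h,
                     prev = c(net$reg$ux[i], net$reg$uy[i]), params)
  net$reg$ux[i] <- u[1]; net$reg$uy[i] <- u[2]
  if (all(u == 0)) return(net)
  xn <- net$reg$x[i] + s * u[1] * dt
  yn <- net$reg$y[i] + s * u[2] * dt
  tix <- as.integer(floor(xn / h)) + 1L
  tiy <- as.integer(floor(yn / h)) + 1L
  cix <- net$reg$ix[i]; ciy <- net$reg$iy[i]
  if (tix == cix && tiy == ciy) {             # same cell: just drift
    net$reg$x[i] <- xn; net$reg$y[i] <- yn
    return(net)
  }
  in_domain <- tix >= 1 && tix <= net$nx && tiy >= 1 && tiy <= net$ny &&
    geometry$active[tix, tiy]
  if (!in_domain) return(net)                 # clamp at the callus border
  if (net$occ[tix, tiy] == 0L) {
    # occupy the new cell; the vacated cell becomes a fresh trailing stalk EC
    net$occ[tix, tiy] <- 1L
    stalk <- cbind(
      data.frame(id = net$next_id, ix = cix, iy = ciy, phen = "stalk",
                 branch = net$reg$branch[i],
                 x = (cix - 0.5) * h, y = (ciy - 0.5) * h,
                 ux = 0, uy = 0, sprouted = FALSE, stringsAsFactors = FALSE),
      ec_initial_state(1L, params))
    net$next_id <- net$next_id + 1L
    net$reg$ix[i] <- tix; net$reg$iy[i] <- tiy
    net$reg$x[i] <- xn; net$reg$y[i] <- yn
    net$reg <- rbind(net$reg, stalk)
  } else {
    # movement into an occupied cell is refused; foreign branch => anastomosis:
    # the tip loses its phenotype and the two branches are merged (they now
    # form one connected loop), so repeated contact is not recounted
    occ_row <- net_idmap(net)[tix, tiy]
    if (occ_row > 0L && net$reg$branch[occ_row] != net$reg$branch[i]) {
      old_branch <- net$reg$branch[i]
      net$reg$branch[net$reg$branch == old_branch] <- net$reg$branch[occ_row]
      net$reg$phen[i] <- "stalk"
      net$reg$x[i] <- (cix - 0.5) * h
      net$reg$y[i] <- (ciy - 0.5) * h
      net$n_anastomoses <- net$n_anastomoses + 1L
    }
  }
  net
}

# Mother-vessel local axis at a cell, from its occupied 4-neighbours.
# Returns "x", "y" or NA (isolated cell).
mother_axis <- function(net, idmap, ix, iy) {
  nb <- logical(4)
  for (d in seq_len(4)) {
    jx <- ix + NB_OFFSETS[d, 1]; jy <- iy + NB_OFFSETS[d, 2]
    nb[d] <- jx >= 1 && jx <= net$nx && jy >= 1 && jy <= net$ny &&
      idmap[jx, jy] > 0L
  }
  nx_ct <- sum(nb[1:2]); ny_ct <- sum(nb[3:4])
  if (nx_ct == 0 && ny_ct == 0) return(NA_character_)
  if (nx_ct >= ny_ct) "x" else "y"   # tie breaks to the x axis
}

# Perpendicular sprout heading: the sense with the larger interpolated VEGF
# wins; exact tie breaks to the lexicographically smaller direction vector.
perp_direction <- function(axis, x, y, gvmat, h) {
  cand <- if (axis == "x") list(c(0, -1), c(0, 1)) else list(c(-1, 0), c(1, 0))
  v <- vapply(cand, function(u) {
    interp_bilinear(gvmat, x + u[1] * h / 2, y + u[2] * h / 2, h)$value
  }, numeric(1))
  if (v[1] == v[2]) {
    lex <- vapply(cand, function(u) u[1] * 10 + u[2], numeric(1))
    cand[[which.min(lex)]]
  } else cand[[which.max(v)]]
}

# Stage 3: every non-tip EC passing the criterion becomes a tip on a new
# branch, heading perpendicular to its mother vessel (up-gradient sense);
# isolated seeds head along the combined taxis cue directly.
sprout_check <- function(net, gvmat, mmat, geometry, mode, params) {
  cand <- which(net$reg$phen != "tip")
  if (!length(cand)) return(net)
  if (mode == "phenomenological") {
    return(legacy_tip_selection(net, cand, gvmat, mmat, params))
  }
  elig <- evaluate_tip_criterion(net$reg$V[cand], net$reg$Vp[cand],
                                 net$reg$A[cand], mode, params)
  cand <- cand[elig]
  if (!length(cand)) return(net)
  idmap <- net_idmap(net)
  h <- net$spacing
  for (i in cand) {
    ax <- mother_axis(net, idmap, net$reg$ix[i], net$reg$iy[i])
    u <- if (is.na(ax)) {
      tip_direction(net$reg$x[i], net$reg$y[i], gvmat, mmat, h,
                    prev = c(0, 1), params)
    } else {
      perp_direction(ax, net$reg$x[i], net$reg$y[i], gvmat, h)
    }
    net$reg$phen[i] <- "tip"
    net$reg$ux[i] <- u[1]; net$reg$uy[i] <- u[2]
    if (!net$reg$sprouted[i]) {
      # a first-time sprout founds a new branch; re-selected cells keep
      # their (possibly anastomosis-merged) branch
      net$reg$branch[i] <- net$next_branch
      net$next_branch <- net$next_branch + 1L
      net$reg$sprouted[i] <- TRUE
    }
  }
  net
}

#' Legacy phenomenological tip selection
#'
#' The comparison-mode rules: a candidate EC sprouts only if the local VEGF
#' concentration is at least 10 ng/ml, it lies at least 100 um from every
#' existing tip, and its intended movement direction makes an angle larger
#' than 24 degrees with the mother vessel's axis (isolated cells pass the
#' angle test). An optional refractory period between sprouting events is
#' exposed via \code{params$legacy_refractory_days} (0 = removed, the
#' default).
#'
#' @param net Network.
#' @param cand Candidate EC row indices (non-tips).
#' @param gvmat,mmat Field matrices.
#' @param params Parameter registry.
#' @return Updated network.
#' @export
legacy_tip_selection <- function(net, cand, gvmat, mmat, params) {
  h <- net$spacing
  idmap <- net_idmap(net)
  tips <- which(net$reg$phen == "tip")
  for (i in cand) {
    gv_here <- gvmat[net$reg$ix[i], net$reg$iy[i]]
    if (gv_here < params$legacy_gv_min) next
    if (length(tips)) {
      d2 <- (net$reg$x[tips] - net$reg$x[i])^2 +
        (net$reg$y[tips] - net$reg$y[i])^2
      if (min(d2) < params$legacy_tip_sep^2) next
    }
    u <- tip_direction(net$reg$x[i], net$reg$y[i], gvmat, mmat, h,
                       prev = c(0, 0), params)
    if (all(u == 0)) next
    ax <- mother_axis(net, idmap, net$reg$ix[i], net$reg$iy[i])
    if (!is.na(ax)) {
      axis_vec <- if (ax == "x") c(1, 0) else c(0, 1)
      ang <- acos(pmin(1, abs(sum(u * axis_vec)))) * 180 / pi
      if (ang <= params$legacy_min_angle) next
    }
    net$reg$phen[i] <- "tip"
    net$reg$ux[i] <- u[1]; net$reg$uy[i] <- u[2]
    if (!net$reg$sprouted[i]) {
      net$reg$branch[i] <- net$next_branch
      net$next_branch <- net$next_branch + 1L
      net$reg$sprouted[i] <- TRUE
    }
    tips <- c(tips, i)
  }
  net
}

#' One inner step of the vascular module
#'
#' Executes the four stages in their fixed order: (1) retire ineligible
#' tips, (2) move every tip (in id order), (3) sprout newly eligible cells,
#' (4) update the intracellular state of every EC synchronously against the
#' frozen fields.
#'
#' @param net Network.
#' @param gvmat,mmat Frozen field matrices (VEGF ng/ml, total matrix mg/ml).
#' @param geometry Geometry.
#' @param dt Inner step (days).
#' @param mode Tip-criterion mode: \code{"V"}, \code{"Vprime"} or
#'   \code{"phenomenological"}.
#' @param params Parameter registry.
#' @param vegfr2_block Receptor blockade scenario flag.
#' @return Updated network.
#' @export
network_inner_step <- function(net, gvmat, mmat, geometry, dt,
                               mode = "V", params = default_params(),
                               vegfr2_block = FALSE) {
  stopifnot(mode %in% c("V", "Vprime", "phenomenological"))
  net <- retire_tips(net, gvmat, mode, params)
  # registry rows are always in id order; new rows are only appended
  for (i in which(net$reg$phen == "tip")) {
    if (net$reg$phen[i] == "tip") {
      net <- move_tip(net, i, gvmat, mmat, geometry, dt, params)
    }
  }
  net <- sprout_check(net, gvmat, mmat, geometry, mode, params)
  idmap <- net_idmap(net)
  adj <- net_adjacency(net, idmap)
  gv <- gvmat[cbind(net$reg$ix, net$reg$iy)]
  st_cols <- names(ec_initial_state(0L, params))
  net$reg[st_cols] <- ec_inner_update(net$reg[st_cols], gv, adj, params,
                                      vegfr2_block = vegfr2_block)
  net
}

#' Export the per-EC state table
#'
#' @param net Network.
#' @param file Optional CSV path; when \code{NULL} the table is returned.
#' @return Data frame (invisibly when written).
#' @export
export_ec_table <- function(net, file = NULL) {
  tab <- net$reg[, c("id", "ix", "iy", "phen", "branch", "x", "y",
                     "V", "D", "A", "Vp", "Np")]
  if (!is.null(file)) {
    utils::write.csv(tab, file, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' @export
print.ac_network <- function(x, ...) {
  cat("<ac_network>", nrow(x$reg), "ECs,",
      sum(x$reg$phen == "tip"), "tips,",
      x$n_anastomoses, "anastomoses on a",
      x$nx, "x", x$ny, "lattice\n")
  invisible(x)
}
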