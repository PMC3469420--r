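# Grid, callus geometry, region labelling, boundary conditions and the
# simulation clock.
#
# Conventions: cell-centered grid, 25 um spacing, 1-based (ix, iy) indices
# in R with cell (1,1) at the domain corner; the centre of cell (ix, iy) is
# at ((ix - 0.5) h, (iy - 0.5) h) in um. Tip positions are continuous in um.

REGION_LEVELS <- c(outside = 0L, periosteal = 1L, intercortical = 2L,
                   endosteal = 3L, cortex = 4L)

#' Build a simulation geometry
#'
#' Two sources are supported. \code{"callus"} builds the bundled stylised
#' rasterisation of a week-3 fracture callus: a cortical bone band with a
#' fracture gap, a periosteal lobe above, an endosteal (marrow-side) lobe
#' below and the intercortical gap region, each labelled; initial endothelial
#' seed cells are placed along the cortex surfaces so that the seeded
#' occupancy fraction matches the stalled-run reference density (0.63\% by
#' default). \code{"reduced"} builds an all-callus rectangle for fast tests.
#'
#' @param source \code{"callus"} or \code{"reduced"}.
#' @param params Parameter registry from \code{\link{default_params}}.
#' @param nx,ny Grid dimensions (reduced source; callus ignores them).
#' @param seed_col Column index holding seed ECs (reduced source);
#'   \code{NA} for no seeds.
#' @param seed_every Row stride between seed cells (reduced source).
#' @param boundary Logical; attach the default boundary-release segments.
#' @return An \code{ac_geometry}: list with \code{nx}, \code{ny},
#'   \code{spacing}, integer \code{region} matrix, logical \code{mask}
#'   (all labelled cells) and \code{active} (labelled, non-cortex) matrices,
#'   \code{seeds} (two-column matrix of cell indices), \code{bc}
#'   (boundary-condition table) and the recorded \code{seed_fraction}.
#' @export
build_geometry <- function(source = c("callus", "reduced"),
                           params = default_params(),
                           nx = 30, ny = 30,
                           seed_col = 1L, seed_every = 2L,
                           boundary = TRUE) {
  source <- match.arg(source)
  g <- switch(source,
              callus  = callus_geometry(params),
              reduced = reduced_geometry(nx, ny, params, seed_col, seed_every,
                                         boundary))
  validate_geometry(g)
  g
}

new_geometry <- function(nx, ny, spacing, region, seeds, bc) {
  mask <- region > 0L
  active <- mask & region != REGION_LEVELS[["cortex"]]
  g <- list(nx = nx, ny = ny, spacing = spacing,
            region = region, mask = mask, active = active,
            seeds = seeds, bc = bc,
            n_callus = sum(active),
            seed_fraction = nrow(seeds) / sum(active))
  class(g) <- c("ac_geometry", "list")
  g
}

validate_geometry <- function(g) {
  stopifnot(g$spacing > 0, g$nx >= 1, g$ny >= 1)
  stopifnot(all(dim(g$region) == c(g$nx, g$ny)))
  # region labels partition the mask
  stopifnot(identical(g$mask, g$region > 0L))
  stopifnot(all(g$region %in% REGION_LEVELS))
  if (nrow(g$seeds) > 0) {
    stopifnot(all(g$active[g$seeds]))
  }
  if (nrow(g$bc) > 0) {
    # every boundary cell lies on the border of the evolving (active) domain:
    # it has an off-grid, unlabelled or cortex 4-neighbour
    on_border <- vapply(seq_len(nrow(g$bc)), function(k) {
      ix <- g$bc$ix[k]; iy <- g$bc$iy[k]
      nb <- rbind(c(ix - 1, iy), c(ix + 1, iy), c(ix, iy - 1), c(ix, iy + 1))
      any(nb[, 1] < 1 | nb[, 1] > g$nx | nb[, 2] < 1 | nb[, 2] > g$ny |
            !g$active[pmin(pmax(nb[, 1], 1), g$nx) +
                        (pmin(pmax(nb[, 2], 1), g$ny) - 1) * g$nx])
    }, logical(1))
    stopifnot(all(on_border))
  }
  invisible(g)
}

# Stylised rasterised callus: cortex band with a fracture gap at the right,
# elliptical periosteal and endosteal lobes, intercortical gap region.
callus_geometry <- function(params) {
  h <- params$spacing
  nx <- 100L; ny <- 100L                     # 2.5 mm x 2.5 mm at 25 um
  region <- matrix(REGION_LEVELS[["outside"]], nx, ny)
  xc <- (seq_len(nx) - 0.5) * h              # um
  yc <- (seq_len(ny) - 0.5) * h
  cortex_x_end <- 1500; cortex_y0 <- 1000; cortex_y1 <- 1250
  for (ix in seq_len(nx)) {
    x <- xc[ix]
    peri_h <- 1000 * sqrt(max(0, 1 - (x / 2300)^2))   # periosteal bulge, um
    endo_h <- 600 * sqrt(max(0, 1 - (x / 2000)^2))    # endosteal bulge, um
    for (iy in seq_len(ny)) {
      y <- yc[iy]
      if (x <= cortex_x_end && y >= cortex_y0 && y <= cortex_y1) {
        region[ix, iy] <- REGION_LEVELS[["cortex"]]
      } else if (x > cortex_x_end && y >= cortex_y0 && y <= cortex_y1) {
        region[ix, iy] <- REGION_LEVELS[["intercortical"]]
      } else if (y > cortex_y1 && y <= cortex_y1 + peri_h) {
        region[ix, iy] <- REGION_LEVELS[["periosteal"]]
      } else if (y < cortex_y0 && y >= cortex_y0 - endo_h) {
        region[ix, iy] <- REGION_LEVELS[["endosteal"]]
      }
    }
  }
  active <- region > 0L & region != REGION_LEVELS[["cortex"]]
  # Seed ECs on the callus cells hugging the cortex surfaces (the preexisting
  # vasculature of periosteum and marrow), evenly spaced so that the seeded
  # fraction matches params$seed_fraction.
  iy_top <- which(yc > cortex_y1)[1]
  iy_bot <- max(which(yc < cortex_y0))
  cand <- rbind(
    cbind(which(active[, iy_top]), iy_top),
    cbind(which(active[, iy_bot]), iy_bot))
  n_target <- max(1L, round(params$seed_fraction * sum(active)))
  pick <- unique(round(seq(1, nrow(cand), length.out = min(n_target, nrow(cand)))))
  seeds <- cand[pick, , drop = FALSE]
  bc <- callus_bc(region, nx, ny, params)
  new_geometry(nx, ny, h, region, seeds, bc)
}

# Default boundary-release table. Condition kinds: "value" (held level during
# the window) on listed fields; everything else defaults to no-flux.
callus_bc <- function(region, nx, ny, params) {
  tp <- params$tissue
  mask <- region > 0L
  outside_nb <- function(ix, iy) {
    nb <- rbind(c(ix - 1, iy), c(ix + 1, iy), c(ix, iy - 1), c(ix, iy + 1))
    off <- nb[, 1] < 1 | nb[, 1] > nx | nb[, 2] < 1 | nb[, 2] > ny
    out <- off
    inb <- nb[!off, , drop = FALSE]
    if (nrow(inb)) out[!off] <- !mask[inb]
    nb[out, , drop = FALSE]
  }
  rows <- list()
  add <- function(segment, ix, iy, field, value, t0, t1) {
    rows[[length(rows) + 1L]] <<- data.frame(
      segment = segment, ix = ix, iy = iy, field = field,
      value = value, t0 = t0, t1 = t1, stringsAsFactors = FALSE)
  }
  peri <- REGION_LEVELS[["periosteal"]]; endo <- REGION_LEVELS[["endosteal"]]
  inter <- REGION_LEVELS[["intercortical"]]; ctx <- REGION_LEVELS[["cortex"]]
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    r <- region[ix, iy]
    if (r == 0L || r == ctx) next
    nb_out <- nrow(outside_nb(ix, iy)) > 0
    nb_ctx <- FALSE
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      jx <- ix + d[1]; jy <- iy + d[2]
      if (jx >= 1 && jx <= nx && jy >= 1 && jy <= ny &&
          region[jx, jy] == ctx) nb_ctx <- TRUE
    }
    if (nb_out && (r == peri || r == endo)) {
      add("soft_tissue_release", ix, iy, "cm", tp$bc_cm, 0, tp$bc_cm_days)
      add("soft_tissue_release", ix, iy, "cf", tp$bc_cf, 0, tp$bc_cm_days)
    }
    if (nb_ctx && r != inter) {
      add("cortex_interface", ix, iy, "gb", tp$bc_gb, 0, tp$bc_gb_days)
    }
    if (nb_ctx && r == inter) {
      add("bone_end", ix, iy, "gc", tp$bc_gc, 0, tp$bc_gc_days)
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty_bc()
}

empty_bc <- function() {
  data.frame(segment = character(), ix = integer(), iy = integer(),
             field = character(), value = numeric(), t0 = numeric(),
             t1 = numeric(), stringsAsFactors = FALSE)
}

reduced_geometry <- function(nx, ny, params, seed_col, seed_every, boundary) {
  stopifnot(nx >= 1, ny >= 1)
  region <- matrix(REGION_LEVELS[["periosteal"]], nx, ny)
  if (!is.na(seed_col)) {
    iys <- seq(1L, ny, by = as.integer(seed_every))
    seeds <- cbind(rep(as.integer(seed_col), length(iys)), iys)
  } else {
    seeds <- matrix(integer(0), 0, 2)
  }
  bc <- empty_bc()
  if (boundary) {
    tp <- params$tissue
    # cells and osteogenic factor enter at the vascularised (left) border,
    # chondrogenic factor at the opposite (degrading bone end) border
    bc <- rbind(
      data.frame(segment = "left_release", ix = 1L, iy = seq_len(ny),
                 field = "cm", value = tp$bc_cm, t0 = 0, t1 = tp$bc_cm_days,
                 stringsAsFactors = FALSE),
      data.frame(segment = "left_release", ix = 1L, iy = seq_len(ny),
                 field = "cf", value = tp$bc_cf, t0 = 0, t1 = tp$bc_cm_days,
                 stringsAsFactors = FALSE),
      data.frame(segment = "left_release", ix = 1L, iy = seq_len(ny),
                 field = "gb", value = tp$bc_gb, t0 = 0, t1 = tp$bc_gb_days,
                 stringsAsFactors = FALSE),
      data.frame(segment = "right_release", ix = as.integer(nx),
                 iy = seq_len(ny),
                 field = "gc", value = tp$bc_gc, t0 = 0, t1 = tp$bc_gc_days,
                 stringsAsFactors = FALSE))
  }
  new_geometry(as.integer(nx), as.integer(ny), params$spacing, region, seeds, bc)
}

#' Derive the inner-loop step from an outer interval
#'
#' Splits an outer interval \eqn{\Delta T} into the smallest number of equal
#' inner steps not exceeding the maximal inner step \code{ee} (ceiling
#' convention, honouring \code{ee} as a maximum).
#'
#' @param dT Outer interval (days), positive.
#' @param ee Maximal inner step (days), positive.
#' @return List with \code{n_inner} and \code{dt} such that
#'   \code{n_inner * dt == dT} and \code{dt <= ee}.
#' @export
derive_inner_step <- function(dT, ee) {
  if (!is.finite(dT) || !is.finite(ee) || dT <= 0 || ee <= 0) {
    stop("dT and ee must be positive and finite")
  }
  n <- max(1L, as.integer(ceiling(dT / ee - 1e-9)))
  list(n_inner = n, dt = dT / n)
}

#' Region labels of a geometry
#'
#' @param g An \code{ac_geometry}.
#' @return Named integer vector mapping label names to codes.
#' @export
region_levels <- function(g = NULL) REGION_LEVELS

#' @export
print.ac_geometry <- function(x, ...) {
  cat("<ac_geometry>", x$nx, "x", x$ny, "cells at", x$spacing, "um\n")
  tab <- table(factor(x$region, levels = REGION_LEVELS,
                      labels = names(REGION_LEVELS)))
  print(tab)
  cat("  seeds:", nrow(x$seeds),
      sprintf("(%.3f%% of %d callus cells)\n",
              100 * x$seed_fraction, x$n_callus))
  invisible(x)
}
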