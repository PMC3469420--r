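# Continuum fracture-healing model: eleven coupled taxis-diffusion-reaction
# fields on the callus geometry, conservative finite-volume discretisation,
# IMEX time integration over each outer step with frozen vasculature.
#
# Fields (vectors over active cells): cm, cf, cc, cb (cell densities,
# normalised), mf, mc, mb (matrix densities, mg/ml), gb, gc, gv (growth
# factors, ng/ml), n (oxygen, normalised). Total matrix m = mf + mc + mb.

FIELD_NAMES <- c("cm", "cf", "cc", "cb", "mf", "mc", "mb",
                 "gb", "gc", "gv", "n")

#' Initial tissue fields
#'
#' The callus starts filled with granulation tissue only
#' (\code{mf = mf_init}, default 10 mg/ml); every other field is zero.
#'
#' @param ops Operator set from \code{\link{assemble_fv_operators}}.
#' @param params Parameter registry.
#' @return Named list of field vectors over active cells (class
#'   \code{ac_fields}).
#' @export
init_fields <- function(ops, params = default_params()) {
  f <- stats::setNames(
    lapply(FIELD_NAMES, function(nm) numeric(ops$na)), FIELD_NAMES)
  f$mf <- rep(params$tissue$mf_init, ops$na)
  class(f) <- c("ac_fields", "list")
  f
}

#' Assemble the finite-volume operators for a geometry
#'
#' Builds, over the active (non-cortex callus) cells: the unit-diffusivity
#' Laplacian with no-flux defaults (symmetric, zero row sums, hence exactly
#' conservative), the face list used by the upwind taxis fluxes, the
#' active-cell index maps and the boundary-condition lookup. Taxis fluxes
#' are first-order upwind in flux form, so they are conservative and, with
#' the positivity-limited step control, nonnegativity preserving.
#'
#' @param geometry An \code{ac_geometry}.
#' @param params Parameter registry.
#' @return Operator list: \code{na}, \code{act} (cell indices), \code{L},
#'   \code{faces}, index matrices and \code{bc_idx}.
#' @export
assemble_fv_operators <- function(geometry, params = default_params()) {
  act <- which(geometry$active)
  na <- length(act)
  amap <- matrix(0L, geometry$nx, geometry$ny)
  amap[act] <- seq_len(na)
  h <- geometry$spacing
  # active-active faces
  fi <- integer(0); fj <- integer(0)
  ij <- arrayInd(act, c(geometry$nx, geometry$ny))
  for (d in 1:2) {  # +x and +y neighbours only (each face once)
    jx <- ij[, 1] + (d == 1); jy <- ij[, 2] + (d == 2)
    ok <- jx <= geometry$nx & jy <= geometry$ny
    jrow <- rep(0L, na)
    jrow[ok] <- amap[cbind(jx[ok], jy[ok])]
    keep <- jrow > 0L
    fi <- c(fi, seq_len(na)[keep]); fj <- c(fj, jrow[keep])
  }
  w <- 1 / h^2
  L <- Matrix::sparseMatrix(
    i = c(fi, fj, fi, fj), j = c(fj, fi, fi, fj),
    x = c(rep(w, 2 * length(fi)), rep(-w, 2 * length(fi))),
    dims = c(na, na))
  bc <- geometry$bc
  bc_idx <- if (nrow(bc)) {
    data.frame(row = amap[cbind(bc$ix, bc$iy)], field = bc$field,
               value = bc$value, t0 = bc$t0, t1 = bc$t1,
               stringsAsFactors = FALSE)
  } else {
    data.frame(row = integer(), field = character(), value = numeric(),
               t0 = numeric(), t1 = numeric(), stringsAsFactors = FALSE)
  }
  bc_idx <- bc_idx[bc_idx$row > 0L, , drop = FALSE]
  list(na = na, act = act, amap = amap, h = h,
       faces = list(i = fi, j = fj), L = L, bc_idx = bc_idx,
       nx = geometry$nx, ny = geometry$ny)
}

# Upwind taxis divergence for field u drifting up the gradient of attractant
# a with coefficient chi; returns du/dt contribution (conservative).
taxis_rhs <- function(u, a, chi, ops) {
  if (chi == 0) return(numeric(ops$na))
  i <- ops$faces$i; j <- ops$faces$j
  v <- chi * (a[j] - a[i]) / ops$h          # face drift velocity, um/day
  up <- ifelse(v > 0, u[i], u[j])           # first-order upwind
  flux <- v * up / ops$h                    # per-volume rate
  out <- numeric(ops$na)
  out <- out - tab_sum(i, flux, ops$na) + tab_sum(j, flux, ops$na)
  out
}

tab_sum <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Reaction terms of the eleven-field system
#'
#' Evaluates the local (per-cell) source/sink vector of every field:
#' proliferation (logistic), growth-factor-driven differentiation of
#' mesenchymal stem cells into osteoblasts (oxygen-requiring) and
#' chondrocytes (hypoxia-favoured), endochondral replacement of chondrocytes
#' by osteoblasts where cartilage and oxygen are present, matrix production
#' with saturation and degradation, growth factor production/decay with
#' angiogenic factor production dominated by hypoxic chondrocytes
#' (\code{Ggvc}), and an oxygen source on vessel-occupied cells at half the
#' reference rate. Every production term carries its source population as a
#' factor, so the all-zero state with no vessels is a fixed point.
#'
#' @param f Field list.
#' @param occ Occupancy vector over active cells (0/1).
#' @param params Parameter registry.
#' @return Named list of time derivatives (per day).
#' @export
reaction_terms <- function(f, occ, params = default_params()) {
  tp <- params$tissue
  hyp <- 1 - f$n / (tp$kn + f$n)   # hypoxia switch in (0, 1]
  oxy <- f$n / (tp$kn + f$n)
  F1 <- tp$Y1 * f$gb / (tp$H1 + f$gb) * oxy       # MSC -> osteoblast
  F2 <- tp$Y2 * f$gc / (tp$H2 + f$gc) * hyp       # MSC -> chondrocyte
  F4 <- tp$Y3 * f$mc / (tp$Hmc + f$mc) * oxy      # endochondral replacement
  Sn <- tp$Sn_ref * tp$oxygen_halving
  list(
    cm = tp$Am * f$cm * (1 - f$cm) - (F1 + F2 + tp$Yf) * f$cm,
    cf = tp$Af * f$cf * (1 - f$cf) + tp$Yf * f$cm -
      tp$df * f$cf * oxy * f$mb / (tp$Hmb + f$mb),
    cc = F2 * f$cm + tp$Ac * f$cc * (1 - f$cc) - F4 * f$cc,
    cb = F1 * f$cm + F4 * f$cc + tp$Ab * f$cb * (1 - f$cb) - tp$db * f$cb,
    mf = tp$Pf * f$cf * (1 - f$mf / tp$Km) - tp$Qf * f$mf * (f$cc + f$cb),
    mc = tp$Pc * f$cc * (1 - f$mc / tp$Km) - tp$Qc * f$mc * f$cb,
    mb = tp$Pb * f$cb * (1 - f$mb / tp$Km),
    gb = tp$Egb * f$cb * oxy - tp$dgb * f$gb,
    gc = tp$Egc * f$cc * hyp - tp$dgc * f$gc,
    gv = tp$Ggvc * f$cc * hyp + tp$Ggvb * f$cb * hyp - tp$dgv * f$gv,
    n  = Sn * occ * (1 - f$n) - tp$Qn * f$n * (f$cm + f$cf + f$cc + f$cb)
  )
}

#' Scenario source/sink terms for the angiogenic growth factor
#'
#' \code{vegf_add(pct)} adds a constant source of \code{pct/100 * Ggvc} on
#' every callus cell. \code{vegf_remove(pct)} adds a sink of the same
#' magnitude, saturated (Michaelis form with a 0.1 ng/ml half-level) so that
#' no more VEGF than present can be removed. \code{vegfr2_block} is a no-op
#' here (it acts in the intracellular module by forcing V' to zero).
#'
#' @param rhs Derivative list from \code{\link{reaction_terms}}.
#' @param f Field list.
#' @param scenario List with \code{type} in \code{"none"},
#'   \code{"vegf_add"}, \code{"vegf_remove"}, \code{"vegfr2_block"} and
#'   \code{pct} (percent of \code{Ggvc}).
#' @param params Parameter registry.
#' @return Updated derivative list.
#' @export
apply_scenario_terms <- function(rhs, f, scenario, params = default_params()) {
  type <- scenario$type %||% "none"
  pct <- scenario$pct %||% 0
  if (type %in% c("vegf_add", "vegf_remove") && (pct < -5 || pct > 10)) {
    warning("scenario percentage outside the documented [-5, 10] range")
  }
  if (type == "vegf_add") {
    rhs$gv <- rhs$gv + (pct / 100) * params$tissue$Ggvc
  } else if (type == "vegf_remove") {
    r <- abs(pct) / 100 * params$tissue$Ggvc
    rhs$gv <- rhs$gv - r * f$gv / (0.1 + f$gv)
  }
  rhs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

diffusion_coefs <- function(params) {
  tp <- params$tissue
  c(cm = tp$Dm, cf = tp$Dfb, cc = 0, cb = 0, mf = 0, mc = 0, mb = 0,
    gb = tp$Dg, gc = tp$Dg, gv = tp$Dg, n = tp$Dn)
}

apply_dirichlet <- function(f, ops, t) {
  b <- ops$bc_idx
  if (!nrow(b)) return(f)
  live <- t >= b$t0 & t <= b$t1
  if (!any(live)) return(f)
  b <- b[live, , drop = FALSE]
  for (fn in unique(b$field)) {
    sel <- b$field == fn
    f[[fn]][b$row[sel]] <- b$value[sel]
  }
  f
}

#' Advance the tissue fields over one outer interval
#'
#' IMEX method of lines: within each substep the taxis and reaction terms
#' (plus scenario terms) are advanced explicitly with a positivity-limited
#' step, then diffusion is applied implicitly (backward Euler, sparse
#' Cholesky, unconditionally stable and nonnegativity preserving for the
#' M-matrix system), and the boundary release windows are enforced. The
#' substep is capped by \code{params$tissue_dt_max}; halving that cap is the
#' package's step-refinement control.
#'
#' @param f Field list.
#' @param occ Occupancy vector over active cells (frozen vasculature).
#' @param dT Outer interval (days).
#' @param ops Operator set.
#' @param params Parameter registry.
#' @param scenario Scenario list (see \code{\link{apply_scenario_terms}}).
#' @param t0 Absolute start time (days) for the boundary windows.
#' @return Updated field list.
#' @export
step_tissue <- function(f, occ, dT, ops, params = default_params(),
                        scenario = list(type = "none"), t0 = 0) {
  stopifnot(dT >= 0, length(occ) == ops$na)
  Dd <- diffusion_coefs(params)
  tp <- params$tissue
  fact_cache <- list()
  f <- apply_dirichlet(f, ops, t0)
  t <- 0
  while (t < dT - 1e-12) {
    dt <- min(params$tissue_dt_max, dT - t)
    m <- f$mf + f$mc + f$mb
    rhs <- reaction_terms(f, occ, params)
    rhs <- apply_scenario_terms(rhs, f, scenario, params)
    ga <- f$gb + f$gc + f$gv
    rhs$cm <- rhs$cm + taxis_rhs(f$cm, ga, tp$chi_g, ops) +
      taxis_rhs(f$cm, m, tp$chi_m, ops)
    rhs$cf <- rhs$cf + taxis_rhs(f$cf, ga, tp$chi_g, ops) +
      taxis_rhs(f$cf, m, tp$chi_m, ops)
    # positivity limit on the explicit part
    for (nm in FIELD_NAMES) {
      neg <- rhs[[nm]] < 0 & f[[nm]] > 0
      if (any(neg)) {
        dt <- min(dt, 0.9 * min(f[[nm]][neg] / -rhs[[nm]][neg]))
      }
    }
    dt <- max(dt, params$tissue_dt_min)
    dt <- min(dt, dT - t)
    for (nm in FIELD_NAMES) {
      u <- f[[nm]] + dt * rhs[[nm]]
      u[u < 0] <- 0                       # guard against roundoff only
      if (Dd[[nm]] > 0) {
        key <- paste0(signif(Dd[[nm]], 12), "_", signif(dt, 12))
        if (is.null(fact_cache[[key]])) {
          A <- Matrix::Diagonal(ops$na) - dt * Dd[[nm]] * ops$L
          fact_cache[[key]] <- list(
            A = A, fac = Matrix::Cholesky(methods::as(A, "symmetricMatrix")))
        }
        slv <- fact_cache[[key]]
        b <- u
        u <- as.numeric(Matrix::solve(slv$fac, b))
        # one step of iterative refinement keeps the discrete mass balance
        # (and hence conservation) at machine precision
        u <- u + as.numeric(Matrix::solve(slv$fac, b - as.numeric(slv$A %*% u)))
        # the backward-Euler M-matrix solution is nonnegative and mass-
        # conserving up to roundoff: clip the roundoff negatives and restore
        # the pre-diffusion mass exactly
        u[u < 0] <- 0
        su <- sum(u); mass <- sum(b)
        if (su > 0 && mass > 0) u <- u * (mass / su)
      }
      f[[nm]] <- u
    }
    t <- t + dt
    f <- apply_dirichlet(f, ops, t0 + t)
  }
  f
}

#' Expand an active-cell vector to a full grid matrix
#'
#' @param v Vector over active cells.
#' @param ops Operator set.
#' @return Matrix of dimension nx x ny with zeros outside the active set.
#' @export
field_matrix <- function(v, ops) {
  m <- matrix(0, ops$nx, ops$ny)
  m[ops$act] <- v
  m
}

occupancy_vector <- function(net, ops) {
  as.numeric(net$occ[ops$act])
}
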