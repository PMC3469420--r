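# Per-endothelial-cell Dll4-Notch1-VEGFR-2 signalling with translocation
# delays and filopodial actin bookkeeping.
#
# All update rules are discrete-time maps advanced once per inner step,
# applied synchronously across cells (Jacobi update: every cell reads the
# previous step's committed state of its neighbours). The state of one EC:
#   V   VEGFR-2 receptors               in [V_min, V_max]
#   D   Dll4 ligands                    in [0, D_max]
#   Vp  active VEGFR-2 (V')             in [0, V]
#   Np  active Notch1 (N')              in [0, N]
#   Vpp, Npp  effective active levels (V'', N''), delayed 3 inner steps
#   A   polymerised actin               in [0, A_max]
#   inact  inner steps since the last actin increment
# Delay buffers hold the last 3 V'/N' values (columns Vh1..Vh3, Nh1..Nh3,
# h1 most recent), zero-initialised for fresh cells.

#' Initial endothelial cell state table
#'
#' Fresh cells start with maximal VEGFR-2 and actin and no signalling
#' activity: V = V_max, D = D0 (default 0), V' = N' = V'' = N'' = 0,
#' A = A0 (default A_max), empty (zero) delay buffers.
#'
#' @param n Number of cells.
#' @param params Parameter registry.
#' @return Data frame with one row per cell.
#' @export
ec_initial_state <- function(n, params) {
  z <- numeric(n)
  data.frame(
    V = rep(params$V_max, n), D = rep(params$D0, n),
    Vp = z, Np = z, Vpp = z, Npp = z,
    A = rep(params$A0, n), inact = integer(n),
    Vh1 = z, Vh2 = z, Vh3 = z, Nh1 = z, Nh2 = z, Nh3 = z)
}

#' VEGFR-2 activation by local VEGF
#'
#' \eqn{V' = \min(V, V_{sink} \, g_v \, V / M_{tot})}: the fraction of VEGF
#' left over by the VEGFR-1 decoy receptors binds the available VEGFR-2,
#' normalised by the membrane-agent count; activation is clamped to the
#' receptors actually present. Monotone nondecreasing in both \code{gv} and
#' \code{V}.
#'
#' @param V VEGFR-2 level(s).
#' @param gv Local VEGF concentration(s), ng/ml, nonnegative.
#' @param params Parameter registry.
#' @return Active VEGFR-2 level(s) in [0, V].
#' @export
activate_vegfr2 <- function(V, gv, params) {
  if (any(gv < 0)) stop("negative VEGF concentration")
  pmin(V, params$V_sink * gv * V / params$M_tot)
}

#' Notch1 activation from junction Dll4 shares
#'
#' Each neighbouring EC presents its Dll4 uniformly across its cell-cell
#' junctions; the receiving cell binds the sum of the presented shares,
#' clamped at its (constant) Notch1 level N. The amounts actually consumed
#' from each junction are returned for Dll4 bookkeeping; under clamping the
#' consumption is scaled proportionally across junctions.
#'
#' @param shares Numeric vector of presented Dll4 shares (one per junction).
#' @param params Parameter registry.
#' @return List with \code{Np} (active Notch1) and \code{consumed}
#'   (per-junction amounts, summing to \code{Np}).
#' @export
compute_notch_activation <- function(shares, params) {
  if (any(shares < 0)) stop("negative Dll4 share")
  S <- sum(shares)
  Np <- min(params$N, S)
  f <- if (S > 0) Np / S else 0
  list(Np = Np, consumed = shares * f)
}

#' Dll4 update
#'
#' \eqn{D \leftarrow \mathrm{clamp}(D + \delta V'' - \mathrm{consumed},\,
#' 0,\, D_{max})}: production driven by the effective active VEGFR-2 at the
#' nucleus, minus the Dll4 bound (and removed) by Notch activation on
#' neighbouring cells.
#'
#' @param D Current Dll4 level(s).
#' @param Vpp Effective active VEGFR-2 level(s).
#' @param consumed Dll4 removed by neighbours this step (nonnegative).
#' @param params Parameter registry.
#' @return Updated Dll4 in [0, D_max].
#' @export
update_dll4 <- function(D, Vpp, consumed, params) {
  stopifnot(all(consumed >= 0))
  pmin(pmax(D + params$delta * Vpp - consumed, 0), params$D_max)
}

#' VEGFR-2 expression update (lateral inhibition)
#'
#' Memoryless down-regulation by effective active Notch1:
#' \eqn{V \leftarrow \mathrm{clamp}(V_{max} - \sigma N'',\, V_{min},\,
#' V_{max})}. With no Notch activity the receptor level is maximal; the map
#' is nonincreasing in \code{Npp} and idempotent for frozen \code{Npp}.
#'
#' @param Npp Effective active Notch1 level(s).
#' @param params Parameter registry.
#' @return Updated VEGFR-2 in [V_min, V_max].
#' @export
update_vegfr2_expression <- function(Npp, params) {
  pmin(pmax(params$V_max - params$sigma * Npp, params$V_min), params$V_max)
}

#' Actin (filopodia) update
#'
#' While active VEGFR-2 exceeds the threshold V'* the cell extends filopodia
#' (A incremented by dA, clamped at A_max, inactivity counter reset). After
#' \code{delay_steps} consecutive inactive steps the filopodia retract
#' (A reduced by 10 dA, clamped at 0) and the counter restarts, so retraction
#' recurs once per idle run of that length.
#'
#' @param A Actin level(s).
#' @param Vp Active VEGFR-2 level(s) for this step.
#' @param inact Inactivity counter(s), inner steps.
#' @param params Parameter registry.
#' @return List with updated \code{A} and \code{inact}.
#' @export
update_actin <- function(A, Vp, inact, params) {
  act <- Vp > params$vp_star
  inact_new <- ifelse(act, 0L, inact + 1L)
  A_new <- ifelse(act, pmin(A + params$dA, params$A_max), A)
  fire <- !act & inact_new >= params$delay_steps
  A_new <- ifelse(fire, pmax(A - 10 * params$dA, 0), A_new)
  inact_new <- ifelse(fire, 0L, inact_new)
  list(A = A_new, inact = as.integer(inact_new))
}

#' Advance the translocation delay buffers
#'
#' The effective active levels read the active levels three inner steps back:
#' \eqn{V''(t) = V'(t - 3\delta t)}, \eqn{N''(t) = N'(t - 3\delta t)}.
#' Fresh cells carry zero-filled buffers, so their effective levels stay zero
#' for the first three inner steps.
#'
#' @param st State table (rows = cells) holding buffer columns.
#' @param Vp_new,Np_new Values entering the buffers this step.
#' @return State table with \code{Vpp}, \code{Npp} set to the dequeued values
#'   and buffers shifted.
#' @export
advance_delays <- function(st, Vp_new, Np_new) {
  st$Vpp <- st$Vh3; st$Npp <- st$Nh3
  st$Vh3 <- st$Vh2; st$Vh2 <- st$Vh1; st$Vh1 <- Vp_new
  st$Nh3 <- st$Nh2; st$Nh2 <- st$Nh1; st$Nh1 <- Np_new
  st
}

# Synchronous inner-step update of a set of ECs.
#   st:  state table (ec_initial_state columns)
#   gv:  VEGF concentration per cell
#   adj: list of integer vectors, adjacency (cell-cell junctions)
#   vegfr2_block: pharmacological receptor blockade (forces V' = 0)
# Reads only the committed previous state; returns the new state table.
ec_inner_update <- function(st, gv, adj, params, vegfr2_block = FALSE) {
  n <- nrow(st)
  if (n == 0L) return(st)
  stopifnot(length(gv) == n, length(adj) == n)
  Vp_new <- activate_vegfr2(st$V, gv, params)
  if (vegfr2_block) Vp_new <- rep(0, n)
  # junction shares: each cell presents D/k across its k EC-EC junctions
  k <- lengths(adj)
  present <- ifelse(k > 0, st$D / pmax(k, 1L), 0)
  S <- vapply(seq_len(n), function(i) sum(present[adj[[i]]]), numeric(1))
  Np_new <- pmin(params$N, S)
  f <- ifelse(S > 0, Np_new / S, 0)
  consumed <- present * vapply(seq_len(n), function(i) sum(f[adj[[i]]]),
                               numeric(1))
  st <- advance_delays(st, Vp_new, Np_new)
  st$Vp <- Vp_new; st$Np <- Np_new
  st$D <- update_dll4(st$D, st$Vpp, consumed, params)
  st$V <- update_vegfr2_expression(st$Npp, params)
  up <- update_actin(st$A, st$Vp, st$inact, params)
  st$A <- up$A; st$inact <- up$inact
  st
}

#' Advance one endothelial cell by one inner step
#'
#' Composes, atomically and in order: VEGFR-2 activation, Notch activation
#' from the supplied neighbour Dll4 junction shares, delay-buffer advance,
#' Dll4 update, VEGFR-2 expression update and the actin rule.
#'
#' @param ec One-row state table (see \code{\link{ec_initial_state}}).
#' @param gv Local VEGF concentration (ng/ml).
#' @param neighbour_shares Numeric vector of presented Dll4 shares (one per
#'   junction with a neighbouring EC; may be empty).
#' @param consumed_by_neighbours Dll4 removed from this cell by its
#'   neighbours this step.
#' @param params Parameter registry.
#' @param vegfr2_block Force V' to zero (receptor blockade scenario).
#' @return Updated one-row state table.
#' @export
step_ec <- function(ec, gv, neighbour_shares = numeric(0),
                    consumed_by_neighbours = 0, params = default_params(),
                    vegfr2_block = FALSE) {
  stopifnot(nrow(ec) == 1L)
  Vp_new <- activate_vegfr2(ec$V, gv, params)
  if (vegfr2_block) Vp_new <- 0
  na <- compute_notch_activation(neighbour_shares, params)
  ec <- advance_delays(ec, Vp_new, na$Np)
  ec$Vp <- Vp_new; ec$Np <- na$Np
  ec$D <- update_dll4(ec$D, ec$Vpp, consumed_by_neighbours, params)
  ec$V <- update_vegfr2_expression(ec$Npp, params)
  up <- update_actin(ec$A, ec$Vp, ec$inact, params)
  ec$A <- up$A; ec$inact <- up$inact
  ec
}
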