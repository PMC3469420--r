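# Programmatic reduced-scale fixtures: a small row or ring of endothelial
# cells under a static VEGF field (the lateral-inhibition test harness), and
# reduced rectangular domains with prescribed VEGF profiles for
# vascular-module integration tests. No tissue solver is involved.

#' Build a row or ring of endothelial cells under a static VEGF field
#'
#' Cells carry the fresh initial intracellular state and are joined by
#' cell-cell junctions along the declared topology (a line's end cells have
#' one junction, a ring's cells two). The VEGF field is constant in time:
#' a single value, or a per-cell vector for gradients.
#'
#' @param k Number of cells (at least 2).
#' @param topology \code{"line"} or \code{"ring"}.
#' @param gv VEGF concentration (ng/ml): scalar or length-\code{k} vector.
#' @param params Parameter registry.
#' @return \code{ac_cellrow}: state table, adjacency list, gv vector.
#' @export
make_cell_row <- function(k, topology = c("line", "ring"), gv = 0,
                          params = default_params()) {
  topology <- match.arg(topology)
  if (k < 2) stop("k must be at least 2")
  gv <- rep_len(gv, k)
  adj <- lapply(seq_len(k), function(i) {
    nb <- c(i - 1L, i + 1L)
    if (topology == "ring") {
      nb <- ((nb - 1L) %% k) + 1L
    } else {
      nb <- nb[nb >= 1L & nb <= k]
    }
    unique(nb)
  })
  fix <- list(st = ec_initial_state(k, params), adj = adj, gv = gv,
              topology = topology, k = k, history = NULL)
  # self-validation: constructed junction counts match the declared topology
  deg <- lengths(adj)
  if (topology == "ring") stopifnot(all(deg == 2L))
  if (topology == "line") stopifnot(sum(deg == 1L) == 2L, all(deg <= 2L))
  class(fix) <- c("ac_cellrow", "list")
  fix
}

#' Iterate the intracellular dynamics on a cell-row fixture
#'
#' Advances every cell synchronously for \code{n_steps} inner steps against
#' the fixture's static VEGF field and records the per-step count of cells
#' satisfying the standard tip criterion.
#'
#' @param fix An \code{ac_cellrow}.
#' @param n_steps Number of inner steps.
#' @param params Parameter registry.
#' @param vegfr2_block Receptor blockade flag.
#' @return Updated fixture with \code{history} (data frame: step,
#'   n_eligible) appended.
#' @export
run_cell_row <- function(fix, n_steps, params = default_params(),
                         vegfr2_block = FALSE) {
  hist <- integer(n_steps)
  for (s in seq_len(n_steps)) {
    fix$st <- ec_inner_update(fix$st, fix$gv, fix$adj, params,
                              vegfr2_block = vegfr2_block)
    hist[s] <- sum(evaluate_tip_criterion(fix$st$V, fix$st$Vp, fix$st$A,
                                          "V", params))
  }
  new_hist <- data.frame(step = seq_len(n_steps) +
                           if (is.null(fix$history)) 0L else max(fix$history$step),
                         n_eligible = hist)
  fix$history <- rbind(fix$history, new_hist)
  fix
}

#' Build a reduced rectangular domain with a prescribed VEGF profile
#'
#' A fully-callus rectangle with seeded vessel columns and a static VEGF
#' matrix, suitable for vascular-module integration tests (chemotaxis,
#' sprout perpendicularity, anastomosis, growth arrest) without the tissue
#' solver.
#'
#' @param nx,ny Dimensions (at least 10 each).
#' @param seed_layout \code{"column"} (left column) or \code{"two_columns"}
#'   (left and right columns, for convergence/anastomosis setups).
#' @param gradient \code{"linear-x"} (VEGF rising with x),
#'   \code{"linear-y"}, \code{"peak-x"} (triangular profile peaking at the
#'   domain centre, for converging-growth setups) or \code{"uniform"}.
#' @param gv_max Peak VEGF (ng/ml); the non-uniform profiles rise from a
#'   floor of \code{gv_max/2} so that seed cells sit inside the activation
#'   window while a per-cell gradient remains.
#' @param seed_every Row stride between seeds.
#' @param params Parameter registry.
#' @return List: \code{geometry}, \code{gvmat}, \code{mmat} (uniform
#'   granulation matrix), \code{net}.
#' @export
make_reduced_domain <- function(nx, ny, seed_layout = c("column", "two_columns"),
                                gradient = c("linear-x", "linear-y", "peak-x",
                                             "uniform"),
                                gv_max = 50, seed_every = 2L,
                                params = default_params()) {
  seed_layout <- match.arg(seed_layout)
  gradient <- match.arg(gradient)
  if (nx < 10 || ny < 10) stop("reduced domain must be at least 10 x 10")
  geometry <- build_geometry("reduced", params, nx = nx, ny = ny,
                             seed_col = 1L, seed_every = seed_every,
                             boundary = FALSE)
  if (seed_layout == "two_columns") {
    iys <- seq(1L, ny, by = as.integer(seed_every))
    geometry$seeds <- rbind(geometry$seeds,
                            cbind(rep(as.integer(nx), length(iys)), iys))
    geometry$seed_fraction <- nrow(geometry$seeds) / geometry$n_callus
    validate_geometry(geometry)
  }
  lo <- gv_max / 2
  gvmat <- switch(gradient,
                  "linear-x" = matrix(rep(seq(lo, gv_max, length.out = nx), ny),
                                      nx, ny),
                  "linear-y" = matrix(rep(seq(lo, gv_max, length.out = ny),
                                          each = nx), nx, ny),
                  "peak-x" = matrix(rep(lo + (gv_max - lo) *
                                          (1 - abs(seq_len(nx) - (nx + 1) / 2) /
                                             ((nx - 1) / 2)), ny),
                                    nx, ny),
                  uniform = matrix(gv_max, nx, ny))
  mmat <- matrix(params$tissue$mf_init, nx, ny)
  net <- network_create(geometry, params)
  list(geometry = geometry, gvmat = gvmat, mmat = mmat, net = net)
}

#' Run the vascular module alone against static fields
#'
#' Iterates inner steps of maximal length \code{ee} for the requested
#' horizon, holding the supplied VEGF and matrix fields constant.
#'
#' @param dom Fixture from \code{\link{make_reduced_domain}}.
#' @param days Horizon (days).
#' @param mode Tip-criterion mode.
#' @param params Parameter registry.
#' @param vegfr2_block Receptor blockade flag.
#' @return Updated network.
#' @export
run_vascular_only <- function(dom, days, mode = "V",
                              params = default_params(),
                              vegfr2_block = FALSE) {
  n_steps <- ceiling(days / params$ee)
  net <- dom$net
  for (s in seq_len(n_steps)) {
    net <- network_inner_step(net, dom$gvmat, dom$mmat, dom$geometry,
                              params$ee, mode = mode, params = params,
                              vegfr2_block = vegfr2_block)
  }
  net
}
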