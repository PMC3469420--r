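# The coupling scheduler: outer tissue step with frozen vasculature, then
# the four-stage inner loop over tips and ECs, iterated to the end time.
#
# Outer-step boundaries are the sorted union of multiples of the maximal
# outer step (row), integer days (output marks) and the end time. Because
# the boundaries are absolute (not relative to the start), a run resumed
# from a checkpoint taken at any boundary reproduces the uninterrupted run
# bit for bit.

default_config <- function() {
  list(geometry = "reduced", nx = 30L, ny = 30L,
       seed_col = 1L, seed_every = 2L, boundary = TRUE,
       end_days = 7, tip_mode = "V",
       scenario = list(type = "none", pct = 0),
       params = list(), snapshot_every_days = 7)
}

#' Read a scenario/configuration file
#'
#' JSON key-value configuration: geometry choice and dimensions, end time,
#' tip-criterion mode, scenario knobs and parameter overrides. Unknown keys
#' are rejected.
#'
#' @param path Path to a JSON file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(default_config())
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  utils::modifyList(default_config(), cfg)
}

outer_boundaries <- function(t0, end, row) {
  ks <- seq_len(ceiling(end / row) + 1L) * row
  marks <- sort(unique(c(ks, seq_len(max(1, ceiling(end))), end)))
  marks <- marks[marks > t0 + 1e-12 & marks <= end + 1e-12]
  # drop near-duplicates deterministically
  if (length(marks) > 1) {
    marks <- marks[c(TRUE, diff(marks) > 1e-9)]
  }
  marks
}

#' Run one outer step
#'
#' Advances the tissue fields by \code{dT} (at most \code{row}) against the
#' frozen vasculature, then iterates the inner loop: the inner step count is
#' the smallest number of equal steps not exceeding \code{ee}, and each
#' inner step executes retire / move / sprout / intracellular-update in that
#' fixed order against the post-tissue-step fields (frozen during the inner
#' loop).
#'
#' @param state Simulation state (fields, net, t, geometry, ops, params,
#'   config).
#' @param dT Outer interval (days).
#' @return Updated state.
#' @export
run_outer_step <- function(state, dT) {
  p <- state$params
  stopifnot(dT <= p$row + 1e-9)
  occ <- occupancy_vector(state$net, state$ops)
  state$fields <- step_tissue(state$fields, occ, dT, state$ops, p,
                              scenario = state$config$scenario, t0 = state$t)
  gvmat <- field_matrix(state$fields$gv, state$ops)
  mmat <- field_matrix(state$fields$mf + state$fields$mc + state$fields$mb,
                       state$ops)
  inner <- derive_inner_step(dT, p$ee)
  block <- identical(state$config$scenario$type, "vegfr2_block")
  for (k in seq_len(inner$n_inner)) {
    state$net <- network_inner_step(state$net, gvmat, mmat, state$geometry,
                                    inner$dt, mode = state$config$tip_mode,
                                    params = p, vegfr2_block = block)
  }
  state$t <- state$t + dT
  state$realized_dt <- c(state$realized_dt, rep(inner$dt, inner$n_inner))
  state
}

summary_row <- function(state) {
  net <- state$net
  frac <- tissue_fractions_by_region(state$fields, state$geometry, state$ops,
                                     state$params)
  row <- data.frame(
    day = state$t,
    vascular_pct = vascular_surface_fraction(net, state$geometry),
    n_ecs = nrow(net$reg),
    n_tips = sum(net$reg$phen == "tip"),
    mean_V = if (nrow(net$reg)) mean(net$reg$V) else NA_real_,
    n_anastomoses = net$n_anastomoses)
  for (r in seq_len(nrow(frac))) {
    for (cl in c("fibrous", "cartilage", "bone")) {
      row[[paste0(frac$region[r], "_", cl)]] <- frac[[cl]][r]
    }
  }
  row
}

#' Run a full simulation
#'
#' Builds (or resumes) the simulation state and iterates outer steps to the
#' configured horizon, recording a daily summary series (vascular surface
#' fraction, EC/tip counts, mean VEGFR-2, region-wise tissue fractions) and
#' periodic field/network snapshots. A zero-day horizon returns the initial
#' state and its summary only.
#'
#' @param config Configuration list (see \code{\link{read_config}}); missing
#'   entries take defaults.
#' @param resume Optional state from a previous run's \code{$state} to
#'   continue from (the configured \code{end_days} must exceed its time).
#' @return \code{ac_sim} list: \code{summary} data frame, \code{snapshots},
#'   \code{state}, \code{params}, \code{geometry}.
#' @export
run_simulation <- function(config = list(), resume = NULL) {
  config <- utils::modifyList(default_config(), config)
  if (is.null(resume)) {
    params <- default_params(config$params)
    geometry <- build_geometry(config$geometry, params,
                               nx = config$nx, ny = config$ny,
                               seed_col = config$seed_col,
                               seed_every = config$seed_every,
                               boundary = config$boundary)
    ops <- assemble_fv_operators(geometry, params)
    state <- list(fields = init_fields(ops, params),
                  net = apply_initial_overrides(
                    network_create(geometry, params), params),
                  t = 0, geometry = geometry, ops = ops, params = params,
                  config = config, realized_dt = numeric(0))
  } else {
    state <- resume
    state$config$end_days <- config$end_days
    config <- state$config
  }
  summaries <- list(summary_row(state))
  snapshots <- list()
  marks <- outer_boundaries(state$t, config$end_days, state$params$row)
  last <- state$t
  for (tb in marks) {
    state <- run_outer_step(state, tb - last)
    state$t <- tb                      # keep boundary times exact
    last <- tb
    if (is_day_mark(tb)) summaries[[length(summaries) + 1L]] <- summary_row(state)
    if (config$snapshot_every_days > 0 &&
        is_day_mark(tb) && (round(tb) %% config$snapshot_every_days == 0)) {
      snapshots[[sprintf("day_%d", round(tb))]] <-
        list(fields = state$fields, occ = state$net$occ)
    }
  }
  out <- list(summary = do.call(rbind, summaries), snapshots = snapshots,
              state = state, params = state$params, geometry = state$geometry)
  class(out) <- c("ac_sim", "list")
  out
}

is_day_mark <- function(t) abs(t - round(t)) < 1e-9

# Initial-condition overrides used by the sensitivity sweep (A0, D0).
apply_initial_overrides <- function(net, params) {
  if (nrow(net$reg)) {
    net$reg$A <- params$A0
    net$reg$D <- params$D0
  }
  net
}

#' Save / load a simulation checkpoint
#'
#' The checkpoint captures the complete state: fields, vessel network
#' (including every EC's delay buffers and inactivity counters), clock and
#' configuration, so a resumed run is bit-identical to an uninterrupted one.
#'
#' @param state The \code{$state} element of an \code{ac_sim}.
#' @param path File path.
#' @return \code{checkpoint_load} returns the state.
#' @export
checkpoint_save <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname checkpoint_save
#' @export
checkpoint_load <- function(path) readRDS(path)

#' Write the daily summary series to CSV
#'
#' @param sim An \code{ac_sim}.
#' @param file Output path.
#' @return The summary data frame, invisibly.
#' @export
export_summary <- function(sim, file) {
  utils::write.csv(sim$summary, file, row.names = FALSE)
  invisible(sim$summary)
}

#' @export
print.ac_sim <- function(x, ...) {
  cat("<ac_sim>", nrow(x$summary), "summary rows to day",
      max(x$summary$day), "\n")
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf("  final: %.2f%% vascular, %d ECs (%d tips), mean V = %.0f\n",
              last$vascular_pct, last$n_ecs, last$n_tips, last$mean_V))
  invisible(x)
}
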