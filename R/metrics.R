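# Summary statistics and scenario sweeps: vascular surface fraction,
# region-wise tissue fractions, mean VEGFR-2, salt-and-pepper index and the
# sensitivity sweep runner.

#' Vascular surface fraction
#'
#' Percentage of callus (non-cortex) grid cells occupied by endothelial
#' cells, the model's measure of vascular density. The denominator is
#' configurable because the printed densities do not state whether cortex
#' cells count; the default excludes them.
#'
#' @param net Network.
#' @param geometry Geometry.
#' @param denominator \code{"callus"} (active cells, default) or
#'   \code{"mask"} (all labelled cells).
#' @return Percent in [0, 100].
#' @export
vascular_surface_fraction <- function(net, geometry,
                                      denominator = c("callus", "mask")) {
  denominator <- match.arg(denominator)
  denom_cells <- if (denominator == "callus") geometry$active else geometry$mask
  nd <- sum(denom_cells)
  if (nd == 0) stop("empty callus")
  100 * sum(net$occ == 1L & denom_cells) / nd
}

#' Region-wise tissue fractions
#'
#' Classifies every active cell by its dominant matrix type among those
#' exceeding the classification threshold (\code{m_threshold}, mg/ml) and
#' reports, per callus region, the percentage of cells classified as
#' fibrous, cartilage and bone.
#'
#' @param f Field list.
#' @param geometry Geometry.
#' @param ops Operator set for the same geometry.
#' @param params Parameter registry.
#' @return Data frame: region name, percent fibrous / cartilage / bone.
#' @export
tissue_fractions_by_region <- function(f, geometry, ops,
                                       params = default_params()) {
  thr <- params$tissue$m_threshold
  cls <- classify_matrix(f$mf, f$mc, f$mb, thr)
  reg <- geometry$region[ops$act]
  out <- lapply(c(periosteal = 1L, intercortical = 2L, endosteal = 3L),
                function(code) {
                  sel <- reg == code
                  n <- sum(sel)
                  if (n == 0) return(c(fibrous = 0, cartilage = 0, bone = 0))
                  c(fibrous = 100 * sum(cls[sel] == 1L) / n,
                    cartilage = 100 * sum(cls[sel] == 2L) / n,
                    bone = 100 * sum(cls[sel] == 3L) / n)
                })
  data.frame(region = names(out), do.call(rbind, out), row.names = NULL,
             stringsAsFactors = FALSE)
}

# 0 = none, 1 = fibrous, 2 = cartilage, 3 = bone; ties break to the
# first (fibrous < cartilage < bone) deterministically.
classify_matrix <- function(mf, mc, mb, thr) {
  vals <- cbind(mf, mc, mb)
  top <- max.col(vals, ties.method = "first")
  top[vals[cbind(seq_along(top), top)] <= thr] <- 0L
  as.integer(top)
}

#' Mean VEGFR-2 over endothelial cells
#'
#' @param net Network with at least one EC.
#' @return List: \code{mean} (arithmetic mean of V) and \code{frac_above}
#'   (fraction of ECs with V above the tip threshold V_max/2).
#' @param params Parameter registry.
#' @export
mean_vegfr2 <- function(net, params = default_params()) {
  if (nrow(net$reg) == 0) stop("no endothelial cells")
  list(mean = mean(net$reg$V),
       frac_above = mean(net$reg$V > params$V_star))
}

#' Salt-and-pepper index
#'
#' Fraction of junction-adjacent EC pairs whose VEGFR-2 levels straddle
#' V_max/2 (one above, one below); 1 indicates perfect alternation of
#' tip-like and inhibited states.
#'
#' @param net Network with at least one adjacent pair.
#' @param params Parameter registry.
#' @return Fraction in [0, 1].
#' @export
salt_pepper_index <- function(net, params = default_params()) {
  adj <- net_adjacency(net)
  i <- rep(seq_along(adj), lengths(adj))
  j <- unlist(adj)
  if (length(i) == 0) stop("no junction-adjacent EC pairs")
  keep <- i < j
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0) stop("no junction-adjacent EC pairs")
  hi <- net$reg$V > params$V_star
  mean(hi[i] != hi[j])
}

#' Run a one-axis sensitivity sweep
#'
#' Repeats a full simulation while varying a single parameter axis
#' (\code{sigma}, \code{delta}, \code{V_sink}, \code{vp_star} as multipliers
#' of the standard value; \code{A_0}, \code{D_0} as fractions of their
#' maxima; \code{vegf_add} / \code{vegf_remove} as scenario percentages),
#' holding geometry, seeds and every other parameter fixed, and reports the
#' vascular surface fraction at the requested days. Individual run failures
#' are recorded and the sweep continues.
#'
#' @param config Base configuration.
#' @param axis Axis name.
#' @param levels Numeric levels (multipliers, fractions or percents).
#' @param days Days at which to report the density.
#' @return Data frame: axis, level, day, vascular_pct (NA for failed runs).
#' @export
run_sensitivity_sweep <- function(config, axis, levels, days = c(7, 21, 35)) {
  axis <- match.arg(axis, c("sigma", "delta", "V_sink", "vp_star",
                            "A_0", "D_0", "vegf_add", "vegf_remove"))
  base <- utils::modifyList(default_config(), config)
  base$end_days <- max(days)
  rows <- list()
  for (lv in levels) {
    cfg <- base
    if (axis %in% c("sigma", "delta", "V_sink", "vp_star")) {
      nm <- if (axis == "vp_star") "vp_star" else axis
      std <- default_params()[[nm]]
      cfg$params[[nm]] <- std * lv
    } else if (axis == "A_0") {
      cfg$params$A0 <- default_params()$A_max * lv
    } else if (axis == "D_0") {
      cfg$params$D0 <- default_params()$D_max * lv
    } else {
      cfg$scenario <- list(type = axis,
                           pct = if (axis == "vegf_remove") -abs(lv) else lv)
    }
    res <- tryCatch(run_simulation(cfg), error = function(e) e)
    for (d in days) {
      val <- NA_real_
      if (!inherits(res, "error")) {
        hit <- which(abs(res$summary$day - d) < 1e-9)
        if (length(hit)) val <- res$summary$vascular_pct[hit[1]]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axis, level = lv, day = d, vascular_pct = val,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
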