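# Parameter registry shared by all modules.
#
# Intracellular values follow the published per-cell calibration (25 um wide
# endothelial cells, i.e. the 10 um agent values scaled by 2.5). Continuum
# parameters live in inst/extdata/tissue_parameters.tsv, a human-readable,
# versioned file (a documented synthetic reconstruction; see the methods
# vignette).

#' Load the continuum (tissue-level) parameter file
#'
#' Reads the bundled tab-separated parameter file into a named list. The file
#' is the single authoritative source for all continuum coefficients so that
#' the transcription can be reviewed line by line.
#'
#' @param path Optional path to an alternative parameter file.
#' @return Named list of numeric values.
#' @export
load_tissue_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tissue_parameters.tsv",
                        package = "angiocallus", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "value") %in% names(tab)))
  vals <- as.list(as.numeric(tab$value))
  names(vals) <- tab$name
  vals
}

#' Default parameter registry
#'
#' Assembles every model constant: the intracellular receptor/ligand bounds
#' and rates, the vascular migration constants, the simulation clock, and the
#' continuum coefficients. Individual entries can be overridden via
#' \code{overrides}, which is applied by name after defaults are built.
#'
#' Key intracellular entries (receptor/ligand counts per cell):
#' \code{M_tot} = 1500 membrane agents, \code{V_max} = 115000 and
#' \code{V_min} = 2500 VEGFR-2 bounds, \code{N} = 25000 Notch1 (constant),
#' \code{D_max} = 25000 Dll4, \code{A_max} = 5000 actin,
#' \code{V_sink} = 0.275 (VEGFR-1 decoy proportion), \code{sigma} = 47.40,
#' \code{delta} = 6.32, \code{vp_star} = 200 (active VEGFR-2 threshold),
#' \code{A_star} = 3500, \code{V_star} = \code{V_max}/2, \code{dA} = 50,
#' translocation/retraction delays of 3 inner steps, inner/outer maximal
#' steps \code{ee} = 1.2 h and \code{row} = 8.57 h.
#'
#' @param overrides Named list of replacement values.
#' @return Object of class \code{ac_params} (a named list).
#' @export
default_params <- function(overrides = list()) {
  p <- list(
    # intracellular (per-EC) constants
    M_tot  = 1500,
    V_max  = 115000,
    V_min  = 2500,
    N      = 25000,
    D_max  = 25000,
    A_max  = 5000,
    V_sink = 0.275,
    sigma  = 47.40,
    delta  = 6.32,
    vp_star = 200,
    A_star  = 3500,
    V_star  = 115000 / 2,
    dA      = 50,
    delay_steps = 3L,     # D1 = D2 = D3, in inner steps
    A0 = 5000,            # initial actin
    D0 = 0,               # initial Dll4
    # vascular / migration
    tip_speed_max = 35,   # um/day
    vp_sat        = 400,  # active-VEGFR-2 level where the speed cubic saturates
    chemo_weight  = 1,
    hapto_weight  = 0.1,
    vprime_crit   = 200,  # threshold for the V'-based criterion variant
    legacy_gv_min = 10,   # ng/ml, phenomenological sprouting threshold
    legacy_tip_sep = 100, # um, phenomenological tip separation
    legacy_min_angle = 24,   # degrees vs mother vessel
    legacy_refractory_days = 0,
    # clock (days)
    row = 8.57 / 24,
    ee  = 1.2 / 24,
    # grid
    spacing = 25,         # um
    seed_fraction = 0.0063,
    # tissue solver control
    tissue_dt_max = 0.02, # day, maximal explicit substep of the IMEX scheme
    tissue_dt_min = 1e-7
  )
  p$tissue <- load_tissue_params()
  p <- modify_params(p, overrides)
  validate_params(p)
  class(p) <- c("ac_params", "list")
  p
}

modify_params <- function(p, overrides) {
  for (nm in names(overrides)) {
    if (nm == "tissue") {
      for (tn in names(overrides$tissue)) p$tissue[[tn]] <- overrides$tissue[[tn]]
    } else {
      p[[nm]] <- overrides[[nm]]
    }
  }
  p
}

validate_params <- function(p) {
  stopifnot(
    p$V_min < p$V_star, p$V_star < p$V_max,
    p$A_star <= p$A_max,
    p$V_sink >= 0, p$sigma >= 0, p$delta >= 0,
    p$D_max > 0, p$N > 0, p$dA >= 0,
    p$row > 0, p$ee > 0, p$spacing > 0,
    p$vp_sat > p$vp_star,
    all(unlist(p$tissue) >= 0)
  )
  invisible(p)
}

#' @export
print.ac_params <- function(x, ...) {
  cat("<ac_params> intracellular/vascular/clock registry with",
      length(x$tissue), "continuum coefficients\n")
  cat("  V_max =", x$V_max, " V_sink =", x$V_sink,
      " sigma =", x$sigma, " delta =", x$delta, "\n")
  cat("  clock: row =", signif(x$row * 24, 4), "h, ee =",
      signif(x$ee * 24, 4), "h, spacing =", x$spacing, "um\n")
  invisible(x)
}
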