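make_ops <- function(nx = 16, ny = 16) {
  g <- build_geometry("reduced", PAR, nx = nx, ny = ny, seed_col = NA,
                      boundary = FALSE)
  list(g = g, ops = assemble_fv_operators(g, PAR))
}

test_that("constant fields produce zero diffusive and taxis fluxes", {
  w <- make_ops()
  u <- rep(3.7, w$ops$na)
  expect_equal(max(abs(as.numeric(w$ops$L %*% u))), 0, tolerance = 1e-12)
  a <- rep(1.4, w$ops$na)
  expect_equal(max(abs(angiocallus:::taxis_rhs(u, a, 1000, w$ops))), 0)
})

test_that("taxis fluxes are conservative for arbitrary fields", {
  w <- make_ops()
  set.seed(23)
  for (k in 1:10) {
    u <- runif(w$ops$na); a <- runif(w$ops$na, 0, 50)
    r <- angiocallus:::taxis_rhs(u, a, 1000, w$ops)
    expect_lt(abs(sum(r)), 1e-10 * max(abs(r), 1))
  }
})

test_that("reaction terms: fixed point at zero, oxygen source sign, oracle", {
  w <- make_ops(12, 12)
  f <- init_fields(w$ops, PAR)
  for (nm in names(f)) f[[nm]] <- numeric(w$ops$na)
  occ <- numeric(w$ops$na)
  r <- reaction_terms(f, occ, PAR)
  expect_true(all(vapply(r, function(v) all(v == 0), logical(1))))
  # vessels present, oxygen low: positive oxygen derivative at vessel cells
  occ[5] <- 1
  r <- reaction_terms(f, occ, PAR)
  expect_gt(r$n[5], 0)
  expect_equal(r$n[-5], numeric(w$ops$na - 1))
  # single-cell dual transcription oracle (independent arithmetic)
  tp <- PAR$tissue
  set.seed(31)
  for (k in 1:20) {
    s <- list(cm = runif(1), cf = runif(1), cc = runif(1), cb = runif(1),
              mf = runif(1, 0, 100), mc = runif(1, 0, 100),
              mb = runif(1, 0, 100), gb = runif(1, 0, 80),
              gc = runif(1, 0, 80), gv = runif(1, 0, 80), n = runif(1))
    oc <- sample(0:1, 1)
    got <- reaction_terms(lapply(s, identity), oc, PAR)
    hyp <- 1 - s$n / (0.1 + s$n); oxy <- s$n / (0.1 + s$n)
    F1 <- 0.5 * s$gb / (10 + s$gb) * oxy
    F2 <- 0.4 * s$gc / (10 + s$gc) * hyp
    F4 <- 0.6 * s$mc / (20 + s$mc) * oxy
    exp_cm <- 0.5 * s$cm * (1 - s$cm) - (F1 + F2 + 0.02) * s$cm
    exp_cb <- F1 * s$cm + F4 * s$cc + 0.1 * s$cb * (1 - s$cb) - 0.1 * s$cb
    exp_gv <- 100 * s$cc * hyp + 2 * s$cb * hyp - 1 * s$gv
    exp_n <- 40 * 0.5 * oc * (1 - s$n) - 2 * s$n * (s$cm + s$cf + s$cc + s$cb)
    expect_equal(got$cm, exp_cm, tolerance = 1e-12)
    expect_equal(got$cb, exp_cb, tolerance = 1e-12)
    expect_equal(got$gv, exp_gv, tolerance = 1e-12)
    expect_equal(got$n, exp_n, tolerance = 1e-12)
  }
})

test_that("scenario terms modify only the angiogenic factor, safely", {
  w <- make_ops(12, 12)
  f <- init_fields(w$ops, PAR)
  f$gv <- runif(w$ops$na, 0, 5)
  rhs <- reaction_terms(f, numeric(w$ops$na), PAR)
  r0 <- apply_scenario_terms(rhs, f, list(type = "vegf_add", pct = 0), PAR)
  expect_identical(r0, rhs)
  r10 <- apply_scenario_terms(rhs, f, list(type = "vegf_add", pct = 10), PAR)
  expect_equal(r10$gv - rhs$gv, rep(0.10 * PAR$tissue$Ggvc, w$ops$na))
  # saturated sink never drives gv negative where it is already zero
  f$gv <- numeric(w$ops$na)
  rhs0 <- reaction_terms(f, numeric(w$ops$na), PAR)
  rr <- apply_scenario_terms(rhs0, f, list(type = "vegf_remove", pct = -3), PAR)
  expect_equal(rr$gv, rhs0$gv)
  expect_warning(
    apply_scenario_terms(rhs0, f, list(type = "vegf_add", pct = 50), PAR))
})

test_that("tissue stepping preserves zero states and nonnegativity", {
  w <- make_ops(12, 12)
  f <- init_fields(w$ops, PAR)
  for (nm in names(f)) f[[nm]] <- numeric(w$ops$na)
  occ <- numeric(w$ops$na)
  f2 <- step_tissue(f, occ, PAR$row, w$ops, PAR)
  expect_true(all(vapply(f2, function(v) all(v == 0), logical(1))))
  # a busy state stays nonnegative throughout
  set.seed(41)
  f <- init_fields(w$ops, PAR)
  f$cm <- runif(w$ops$na); f$cc <- runif(w$ops$na); f$cb <- runif(w$ops$na)
  f$gb <- runif(w$ops$na, 0, 50); f$gc <- runif(w$ops$na, 0, 50)
  f$gv <- runif(w$ops$na, 0, 30); f$n <- runif(w$ops$na)
  occ <- as.numeric(runif(w$ops$na) < 0.05)
  for (k in 1:5) {
    f <- step_tissue(f, occ, PAR$row, w$ops, PAR)
    expect_true(all(vapply(f, function(v) all(v >= 0), logical(1))))
  }
})

test_that("boundary release drives inward spread of progenitor cells", {
  g <- build_geometry("reduced", PAR, nx = 16, ny = 16, seed_col = NA,
                      boundary = TRUE)
  ops <- assemble_fv_operators(g, PAR)
  f <- init_fields(ops, PAR)
  occ <- numeric(ops$na)
  t <- 0
  for (k in 1:12) {                     # ~4.3 days
    f <- step_tissue(f, occ, PAR$row, ops, PAR, t0 = t)
    t <- t + PAR$row
  }
  cmm <- field_matrix(f$cm, ops)
  expect_gt(cmm[1, 8], 0.2)             # released at the left border
  expect_gt(cmm[8, 8], 0)               # spread into the interior
  expect_gt(cmm[1, 8], cmm[8, 8])       # decreasing inward
})

test_that("step halving converges (integrator consistency)", {
  w <- make_ops(10, 10)
  set.seed(43)
  f <- init_fields(w$ops, PAR)
  f$cm <- runif(w$ops$na); f$cc <- runif(w$ops$na)
  f$gc <- runif(w$ops$na, 0, 40); f$gv <- runif(w$ops$na, 0, 20)
  f$n <- runif(w$ops$na, 0, 0.5)
  occ <- as.numeric(runif(w$ops$na) < 0.1)
  adv <- function(dtmax) {
    p2 <- PAR; p2$tissue_dt_max <- dtmax
    step_tissue(f, occ, PAR$row, w$ops, p2)
  }
  c1 <- adv(0.02); c2 <- adv(0.01); c3 <- adv(0.005)
  d12 <- max(abs(unlist(c1) - unlist(c2)))
  d23 <- max(abs(unlist(c2) - unlist(c3)))
  expect_lt(d23, d12)                 # first-order error contraction
  expect_lt(d23 / max(abs(unlist(c3)), 1), 0.02)
})
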