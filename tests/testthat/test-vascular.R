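test_that("tip criterion thresholds are strict and mode-aware", {
  expect_true(evaluate_tip_criterion(115000, 0, 5000, "V", PAR))
  expect_false(evaluate_tip_criterion(2500, 0, 5000, "V", PAR))
  expect_false(evaluate_tip_criterion(115000, 0, 3500, "V", PAR))  # boundary
  expect_false(evaluate_tip_criterion(57500, 0, 5000, "V", PAR))   # boundary
  expect_true(evaluate_tip_criterion(2500, 300, 5000, "Vprime", PAR))
  expect_false(evaluate_tip_criterion(115000, 150, 5000, "Vprime", PAR))
  expect_error(evaluate_tip_criterion(1, 1, 1, "bogus", PAR))
})

test_that("tip speed: zero below threshold, smooth monotone rise, capped", {
  expect_equal(tip_speed(0, PAR), 0)
  expect_equal(tip_speed(PAR$vp_star, PAR), 0)
  expect_equal(tip_speed(PAR$vp_sat, PAR), PAR$tip_speed_max)
  expect_equal(tip_speed(1e6, PAR), PAR$tip_speed_max)
  vp <- seq(0, 2 * PAR$vp_sat, length.out = 2000)
  s <- tip_speed(vp, PAR)
  expect_true(all(diff(s) >= -1e-12))
  expect_true(all(s >= 0 & s <= PAR$tip_speed_max))
  # numerical C0/C1 continuity at both knots
  eps <- 1e-6
  for (knot in c(PAR$vp_star, PAR$vp_sat)) {
    expect_lt(abs(tip_speed(knot + eps, PAR) - tip_speed(knot - eps, PAR)),
              1e-4)
    dl <- (tip_speed(knot, PAR) - tip_speed(knot - eps, PAR)) / eps
    dr <- (tip_speed(knot + eps, PAR) - tip_speed(knot, PAR)) / eps
    expect_lt(abs(dl - dr), 1e-3)
  }
})

test_that("tip direction follows single cues and falls back when degenerate", {
  h <- PAR$spacing
  gv <- matrix(rep(seq(0, 10, length.out = 10), 10), 10, 10)  # +x gradient
  flat <- matrix(5, 10, 10)
  u <- tip_direction(5 * h, 5 * h, gv, flat, h, prev = c(0, 1), PAR)
  expect_equal(u, c(1, 0), tolerance = 1e-12)
  u2 <- tip_direction(5 * h, 5 * h, flat, flat, h, prev = c(0, 1), PAR)
  expect_equal(u2, c(0, 1))                                   # retained
})

test_that("tip movement: drift, occupation of new cells, trailing stalks", {
  p <- PAR
  g <- build_geometry("reduced", p, nx = 12, ny = 12, seed_col = NA)
  gvmat <- matrix(rep(seq(10, 40, length.out = 12), 12), 12, 12)
  flat <- matrix(10, 12, 12)
  net <- manual_net(g, cbind(6L, 6L))
  net$reg$phen <- "tip"; net$reg$Vp <- p$vp_sat  # full speed, 35 um/day
  dt <- derive_inner_step(p$row, p$ee)$dt
  net1 <- angiocallus:::move_tip(net, 1L, gvmat, flat, g, dt, p)
  # sub-cell drift: displacement = s * dt, no new EC
  expect_equal(nrow(net1$reg), 1)
  disp <- sqrt((net1$reg$x - net$reg$x)^2 + (net1$reg$y - net$reg$y)^2)
  expect_equal(disp, 35 * dt, tolerance = 1e-9)
  # push the tip across a cell boundary: occupancy grows, stalk spawned
  net2 <- net
  net2$reg$x <- 6 * p$spacing - 0.1                   # 0.1 um from the face
  net2 <- angiocallus:::move_tip(net2, 1L, gvmat, flat, g, dt, p)
  expect_equal(nrow(net2$reg), 2)
  expect_equal(sum(net2$occ), 2)
  expect_equal(net2$reg$ix[1], 7L)                    # tip moved
  expect_equal(net2$reg$phen[2], "stalk")             # trailing cell
  expect_equal(net2$reg$ix[2], 6L)
  expect_equal(net2$reg$V[2], p$V_max)                # fresh initial state
})

test_that("movement into an occupied foreign cell triggers anastomosis once", {
  p <- PAR
  g <- build_geometry("reduced", p, nx = 12, ny = 12, seed_col = NA)
  gvmat <- matrix(rep(seq(10, 40, length.out = 12), 12), 12, 12)
  flat <- matrix(10, 12, 12)
  net <- manual_net(g, rbind(c(6L, 6L), c(7L, 6L)), branches = c(1L, 2L))
  net$reg$phen[1] <- "tip"; net$reg$Vp[1] <- p$vp_sat
  net$reg$x[1] <- 6 * p$spacing - 0.1
  dt <- derive_inner_step(p$row, p$ee)$dt
  net1 <- angiocallus:::move_tip(net, 1L, gvmat, flat, g, dt, p)
  expect_equal(net1$n_anastomoses, 1L)
  expect_equal(net1$reg$phen[1], "stalk")             # phenotype lost
  expect_equal(sum(net1$occ), 2)                      # no new occupancy
  expect_equal(net1$reg$branch[1], net1$reg$branch[2])  # branches merged
  # same-branch contact is refused silently
  net2 <- manual_net(g, rbind(c(6L, 6L), c(7L, 6L)), branches = c(1L, 1L))
  net2$reg$phen[1] <- "tip"; net2$reg$Vp[1] <- p$vp_sat
  net2$reg$x[1] <- 6 * p$spacing - 0.1
  net2 <- angiocallus:::move_tip(net2, 1L, gvmat, flat, g, dt, p)
  expect_equal(net2$n_anastomoses, 0L)
  expect_equal(net2$reg$ix[1], 6L)
})

test_that("sprouts head perpendicular to the mother vessel, up-gradient", {
  p <- PAR
  g <- build_geometry("reduced", p, nx = 12, ny = 12, seed_col = NA)
  # horizontal vessel along iy = 6; VEGF increases with y
  cells <- cbind(4:8, 6L)
  net <- manual_net(g, cells)
  gvmat <- matrix(rep(seq(5, 30, length.out = 12), each = 12), 12, 12)
  flat <- matrix(10, 12, 12)
  # make the middle cell eligible
  net$reg$V <- c(10000, 10000, 115000, 10000, 10000)
  net1 <- angiocallus:::sprout_check(net, gvmat, flat, g, "V", p)
  expect_equal(net1$reg$phen, c("stalk", "stalk", "tip", "stalk", "stalk"))
  expect_equal(c(net1$reg$ux[3], net1$reg$uy[3]), c(0, 1))
  expect_true(net1$reg$branch[3] != net$reg$branch[3])
  # no eligible cell: network unchanged
  net$reg$V <- rep(10000, 5)
  net2 <- angiocallus:::sprout_check(net, gvmat, flat, g, "V", p)
  expect_identical(net2$reg, net$reg)
})

test_that("a sprout flanked by occupied cells is selected but cannot move", {
  p <- PAR
  g <- build_geometry("reduced", p, nx = 12, ny = 12, seed_col = NA)
  cells <- rbind(c(6L, 5L), c(5L, 6L), c(6L, 6L), c(7L, 6L), c(6L, 7L))
  net <- manual_net(g, cells, branches = c(2L, 1L, 1L, 1L, 3L))
  gvmat <- matrix(20, 12, 12)
  flat <- matrix(10, 12, 12)
  net$reg$V <- c(10000, 10000, 115000, 10000, 10000)
  net1 <- angiocallus:::sprout_check(net, gvmat, flat, g, "V", p)
  expect_equal(net1$reg$phen[3], "tip")
  net1$reg$Vp[3] <- p$vp_sat
  dt <- derive_inner_step(p$row, p$ee)$dt
  before <- sum(net1$occ)
  for (k in 1:60) net1 <- angiocallus:::move_tip(net1, 3L, gvmat, flat, g, dt, p)
  expect_equal(sum(net1$occ), before)               # no movement committed
})

test_that("legacy phenomenological rules gate sprouting", {
  p <- PAR
  g <- build_geometry("reduced", p, nx = 20, ny = 12, seed_col = NA)
  flat <- matrix(10, 20, 12)
  gv_lo <- matrix(5, 20, 12)
  # VEGF too low
  net <- manual_net(g, cbind(10L, 6L))
  net1 <- angiocallus:::sprout_check(net, gv_lo, flat, g, "phenomenological", p)
  expect_true(all(net1$reg$phen == "stalk"))
  # candidate too close to an existing tip (80 um < 100 um separation)
  gvmat <- matrix(rep(seq(10, 30, length.out = 12), each = 20), 20, 12)
  net <- manual_net(g, rbind(c(10L, 6L), c(13L, 6L)))
  net$reg$phen[1] <- "tip"
  net2 <- angiocallus:::sprout_check(net, gvmat, flat, g, "phenomenological", p)
  expect_equal(net2$reg$phen[2], "stalk")           # 75 um away: blocked
  # candidate satisfying VEGF, separation and angle sprouts
  net <- manual_net(g, rbind(c(4L, 6L), c(10L, 6L), c(16L, 6L)))
  net$reg$phen[1] <- "tip"
  net3 <- angiocallus:::sprout_check(net, gvmat, flat, g, "phenomenological", p)
  expect_equal(net3$reg$phen[2], "tip")  # 150 um, gv ok, heading +y vs x-axis
})

test_that("tips failing the criterion retire to stalk at their cell centre", {
  p <- PAR
  g <- build_geometry("reduced", p, nx = 12, ny = 12, seed_col = NA)
  net <- manual_net(g, rbind(c(5L, 5L), c(8L, 8L)))
  net$reg$phen <- "tip"
  net$reg$x <- net$reg$x + 3; net$reg$y <- net$reg$y - 4
  net$reg$V <- c(40000, 115000)       # first fails V > V_max/2
  gvmat <- matrix(20, 12, 12)
  net1 <- angiocallus:::retire_tips(net, gvmat, "V", p)
  expect_equal(net1$reg$phen, c("stalk", "tip"))
  expect_equal(net1$reg$x[1], (5 - 0.5) * p$spacing)
  expect_equal(net1$reg$x[2], net$reg$x[2])          # survivor untouched
})

test_that("network snapshots are deterministic and occupancy never decreases", {
  p <- PAR
  dom <- make_reduced_domain(14, 14, "column", "linear-x", gv_max = 30,
                             params = p)
  net <- dom$net
  prev <- sum(net$occ)
  for (k in seq_len(200)) {
    net <- network_inner_step(net, dom$gvmat, dom$mmat, dom$geometry,
                              p$ee, "V", p)
    expect_gte(sum(net$occ), prev)
    prev <- sum(net$occ)
  }
  net1 <- run_vascular_only(dom, 10, "V", p)
  net2 <- run_vascular_only(dom, 10, "V", p)
  expect_identical(net1$occ, net2$occ)
  expect_identical(net1$reg, net2$reg)
  net <- net1
  # vessels stay one cell wide in the absence of anastomosis
  if (net$n_anastomoses == 0) {
    occ <- net$occ
    blocks <- 0L
    for (i in seq_len(nrow(occ) - 1)) for (j in seq_len(ncol(occ) - 1)) {
      if (occ[i, j] && occ[i + 1, j] && occ[i, j + 1] && occ[i + 1, j + 1]) {
        blocks <- blocks + 1L
      }
    }
    expect_equal(blocks, 0L)
  }
})
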