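# Shared helpers: cached parameter registries and random-state generators.

PAR <- default_params()

# Random (in-bounds) intracellular states for property tests.
random_ec_states <- function(n, params = PAR) {
  st <- ec_initial_state(n, params)
  st$V <- runif(n, params$V_min, params$V_max)
  st$D <- runif(n, 0, params$D_max)
  st$A <- runif(n, 0, params$A_max)
  st$Vh1 <- runif(n, 0, params$V_max); st$Vh2 <- runif(n, 0, params$V_max)
  st$Vh3 <- runif(n, 0, params$V_max)
  st$Nh1 <- runif(n, 0, params$N); st$Nh2 <- runif(n, 0, params$N)
  st$Nh3 <- runif(n, 0, params$N)
  st$inact <- sample(0:2, n, replace = TRUE)
  st
}

# Random adjacency on n cells (each pair linked with prob p, symmetric).
random_adjacency <- function(n, p = 0.3) {
  m <- matrix(runif(n * n) < p, n, n)
  m[lower.tri(m, diag = TRUE)] <- FALSE
  m <- m | t(m)
  lapply(seq_len(n), function(i) which(m[i, ]))
}

expect_in_bounds <- function(st, params = PAR) {
  expect_true(all(st$V >= params$V_min & st$V <= params$V_max))
  expect_true(all(st$D >= 0 & st$D <= params$D_max))
  expect_true(all(st$A >= 0 & st$A <= params$A_max))
  # V' is bounded by the V it was computed from (which the expression
  # update may since have lowered), hence by V_max
  expect_true(all(st$Vp >= 0 & st$Vp <= params$V_max))
  expect_true(all(st$Np >= 0 & st$Np <= params$N))
}

# Hand-built network occupying the given cells (two-column matrix), all
# stalk, one branch per `branches` entry (default: all one branch).
manual_net <- function(geometry, cells, params = PAR, branches = NULL) {
  g2 <- geometry
  g2$seeds <- cells
  g2$seed_fraction <- nrow(cells) / g2$n_callus
  net <- network_create(g2, params)
  if (!is.null(branches)) net$reg$branch <- branches
  net
}

# Small all-callus world with a frozen VEGF field for vascular tests.
static_world <- function(nx = 14, ny = 14, gv = 20, params = PAR) {
  make_reduced_domain(nx, ny, "column", "uniform", gv_max = gv,
                      params = params)
}
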