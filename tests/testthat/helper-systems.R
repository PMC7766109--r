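# Shared test constructors: small systems built in code, no stored fixtures.

# homogeneous fluid of random beads (any species) with Maxwell velocities
random_fluid <- function(n, L = c(10, 10, 10), seed = 1,
                         species = NULL, table = interaction_table(),
                         params = dpd_params(), kBT = 1) {
  set.seed(seed)
  pos <- cbind(runif(n, 0, L[1]), runif(n, 0, L[2]), runif(n, 0, L[3]))
  vel <- matrix(rnorm(3 * n, sd = sqrt(kBT)), n, 3)
  vel <- sweep(vel, 2, colMeans(vel)) # zero net momentum
  if (is.null(species)) species <- rep(5L, n)
  dpd_system(pos, box = L, species = species, velocities = vel,
             table = table, params = params)
}

# two beads at separation r along x, optional species/velocities
two_beads <- function(r, species = c(5L, 5L), vel = matrix(0, 2, 3),
                      table = interaction_table(), params = dpd_params(),
                      L = c(10, 10, 10)) {
  pos <- rbind(c(4, 5, 5), c(4 + r, 5, 5))
  dpd_system(pos, box = L, species = species, velocities = vel,
             table = table, params = params)
}

# three-bead angle triple with arms of given lengths and included angle theta,
# vertex at bead 2; non-interacting species so only the angle term acts
angle_triple <- function(theta, ktheta = 6, theta0 = pi, arm = 1.5,
                         L = c(20, 20, 20)) {
  pos <- rbind(c(10 + arm, 10, 10),
               c(10, 10, 10),
               c(10 + arm * cos(theta), 10 + arm * sin(theta), 10))
  tab <- interaction_table(overrides = list(
    "BRUSH_BACKBONE:BRUSH_BACKBONE" = 0))
  dpd_system(pos, box = L, species = rep(3L, 3),
             angles = cbind(i = 1, j = 2, k = 3, ktheta = ktheta,
                            theta0 = theta0),
             table = tab)
}

# total momentum of the free beads
total_momentum <- function(system) {
  fixed <- system$topology$fixed
  v <- system$state$velocities
  if (length(fixed)) v <- v[-fixed, , drop = FALSE]
  colSums(v)
}

# canonicalize a pair list for set comparison
pair_key <- function(pairs) {
  if (nrow(pairs) == 0) return(character())
  sort(paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2])))
}
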