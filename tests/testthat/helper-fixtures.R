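# shared fixture builders; everything is generated in code at test time

# trajectory from an (n_frames x n_particles) matrix of z coordinates,
# x = y = box/2
traj_from_z <- function(z, box = c(100, 100, 100), dt = 20,
                        wrapped = TRUE) {
  nf <- nrow(z); np <- ncol(z)
  co <- array(box[1] / 2, c(nf, np, 3))
  co[, , 3] <- z
  trajectory(co, box, dt, wrapped = wrapped)
}

fe <- function(mean, error = 0, n = 2L, units = "nA") {
  poreflux:::flow_estimate(mean, error, n, units = units)
}

# CylMap with given value matrix on unit bins
mk_map <- function(values, r_edges = seq(0, nrow(values)),
                   z_edges = seq(0, ncol(values))) {
  structure(list(values = values,
                 volume = matrix(1, nrow(values), ncol(values)),
                 r_edges = r_edges, z_edges = z_edges,
                 axis = c(0, 0), species = "test"),
            class = "CylMap")
}

rand_map <- function(nr = 6, nz = 8) mk_map(matrix(rnorm(nr * nz), nr, nz))

# standard small electrolyte spec
electrolyte_spec <- function(n = 50, v = 0.01, D = 0.04, Lz = 100,
                             duration = 2000, dt = 20, seed = 1,
                             water = 0) {
  sp <- data.frame(name = c("cation", "anion"),
                   count = c(n, n), charge = c(1, -1),
                   D = D, v = c(v, -v))
  if (water > 0)
    sp <- rbind(sp, data.frame(name = "water_oxygen", count = water,
                               charge = 0, D = D, v = v))
  synthetic_spec(c(50, 50, Lz), sp, frame_interval = dt,
                 duration = duration, seed = seed)
}
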