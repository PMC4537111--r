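# shared fixture builders (all generated in code)

uniform_landscape <- function(grid, value) {
  structure(list(grid = grid, R = rep(value, n_cells(grid)),
                 J = integer(n_cells(grid))), class = "landscape")
}

# hand-built environment vector: resources chosen so that with alpha = 0,
# delta = 0 the cell values V equal `R` exactly
make_env <- function(R, J = rep(0, length(R)), R_M = rep(0, length(R)),
                     J_M = rep(0, length(R)), cells = seq_along(R)) {
  structure(list(cells = cells, R = R, J = as.numeric(J), R_M = R_M,
                 J_M = J_M), class = "environment_vector")
}

# small random world for engine-equivalence and invariant sweeps
random_world <- function(n_agents = 6, nr = 5, nc = 5, toroidal = TRUE) {
  g <- grid_spec(nr, nc, toroidal)
  ph <- matrix(stats::runif(n_agents * 3), n_agents, 3,
               dimnames = list(NULL, c("alpha", "delta", "rho")))
  ph[, "delta"] <- ph[, "delta"] * 2      # allow strong competition aversion
  agents <- new_agents(ph, grid = g, biomass = stats::runif(n_agents, 0, 2))
  landscape <- init_resources(g, resource_params(R_min = 0, R_max = 6))
  list(grid = g, agents = agents, landscape = landscape)
}

table5_counts <- c("a1/a1" = 22, "a1/a2" = 38, "a2/a2" = 18,
                   "a2/a3" = 22, "a3/a3" = 14, "a1/a3" = 26)

make_pop <- function(mode, phenotype) {
  structure(list(mode = mode, phenotype = phenotype,
                 alleles = NULL, tags = NULL), class = "population")
}

# diploid population with explicitly chosen alleles (values and tags)
make_diploid <- function(a1, a2, tag1 = seq_len(nrow(a1)),
                         tag2 = nrow(a1) + seq_len(nrow(a1))) {
  n <- nrow(a1)
  alleles <- array(NA_real_, c(n, 3, 2),
                   dimnames = list(NULL, c("alpha", "delta", "rho"), NULL))
  alleles[, , 1] <- a1
  alleles[, , 2] <- a2
  tags <- array(NA_integer_, c(n, 3, 2))
  for (tr in 1:3) {
    tags[, tr, 1] <- tag1
    tags[, tr, 2] <- tag2
  }
  structure(list(mode = "diploid",
                 phenotype = (alleles[, , 1] + alleles[, , 2]) / 2,
                 alleles = alleles, tags = tags),
            class = "population")
}
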