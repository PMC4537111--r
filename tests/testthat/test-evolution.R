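test_that("annealed mutation scale follows its closed forms", {
  sch <- mutation_schedule()   # mu0 = 0.1, mu_inf = 0.001, psi = 50
  expect_equal(mutation_scale(0, sch), 0.1)
  expect_equal(mutation_scale(50, sch), (0.1 - 0.001) / 2 + 0.001)  # 0.0505
  expect_equal(mutation_scale(100, sch), 0.099 / 9 + 0.001)         # 0.012
  expect_equal(mutation_scale(1e9, sch), 0.001, tolerance = 1e-6)
  Ts <- seq(0, 400, by = 0.5)
  mu <- mutation_scale(Ts, sch)
  expect_true(all(diff(mu) <= 0))
  expect_true(all(mu > 0.001 - 1e-15 & mu <= 0.1))
  expect_error(mutation_scale(-1, sch), "non-negative")
  expect_error(mutation_schedule(mu0 = 0.001, mu_inf = 0.1), "mu0 >= mu_inf")
})

test_that("uniform mutations respect their bounds and are centered", {
  expect_identical(mutate_value(c(1, 2, 3), 0), c(1, 2, 3))
  set.seed(2)
  y <- mutate_value(rep(0.5, 1e4), 0.1)
  expect_true(all(y >= 0.4 & y <= 0.6))
  z <- mutate_value(rep(0, 1e5), 0.1)
  se <- (0.1 / sqrt(3)) / sqrt(1e5)
  expect_lt(abs(mean(z)), 3 * se)
})

test_that("hard selection keeps the top half with stable tie-breaking", {
  pop <- make_pop("clonal", matrix(1:12 / 12, 4, 3,
                  dimnames = list(NULL, c("alpha", "delta", "rho"))))
  sel <- select_fittest(pop, c(5, 3, 2, 1))
  expect_equal(sel$phenotype, pop$phenotype[1:2, ])
  tied <- select_fittest(pop, c(7, 7, 7, 7))
  expect_equal(tied$phenotype, pop$phenotype[1:2, ])   # first by index
  expect_error(select_fittest(pop, c(1, NaN, 2, 3)), "non-finite")
})

test_that("clonal reproduction keeps parents and bounds clone perturbations", {
  set.seed(10)
  parents <- select_fittest(init_population(8, "clonal"), 8:1)
  frozen <- mutation_schedule(mu0 = 0, mu_inf = 0, psi = 1)
  off <- reproduce_clonal(parents, T = 1, frozen)
  expect_equal(pop_size(off), 8)
  expect_equal(off$phenotype[1:4, ], parents$phenotype)
  expect_equal(off$phenotype[5:8, ], parents$phenotype) # exact cloning at mu = 0
  sch <- mutation_schedule()
  for (i in 1:200) {
    T <- sample(1:200, 1)
    mu <- mutation_scale(T, sch)
    off <- reproduce_clonal(parents, T, sch)
    expect_equal(off$phenotype[1:4, ], parents$phenotype)  # parents unmutated
    expect_true(all(abs(off$phenotype[5:8, ] - parents$phenotype) <= mu))
  }
})

test_that("averaging reproduction midpoints parents and fully replaces them", {
  frozen <- mutation_schedule(mu0 = 0, mu_inf = 0, psi = 1)
  ph <- matrix(0.3, 6, 3, dimnames = list(NULL, c("alpha", "delta", "rho")))
  same <- make_pop("averaging", ph)
  off <- reproduce_averaging(same, T = 1, frozen)
  expect_equal(pop_size(off), 12)                      # 3 pairs x 4 progeny
  expect_true(all(off$phenotype == 0.3))               # fixed point
  two <- make_pop("averaging", matrix(c(0, 1, 0, 1, 0.2, 0.6), 2, 3,
                  dimnames = list(NULL, c("alpha", "delta", "rho"))))
  set.seed(1)
  kids <- reproduce_averaging(two, T = 1, frozen)
  expect_equal(pop_size(kids), 4)
  expect_true(all(kids$phenotype[, "rho"] == 0.4))     # mean of 0.2 and 0.6
})

test_that("diploid segregation is Mendelian with tags inherited intact", {
  frozen <- mutation_schedule(mu0 = 0, mu_inf = 0, psi = 1)
  # homozygote x homozygote: transmitted alleles are certain
  hom <- make_diploid(matrix(0.045, 2, 3), matrix(c(0.045, 0.645), 2, 3),
                      tag1 = c(1L, 2L), tag2 = c(1L, 2L))
  hom$alleles[1, , 2] <- 0.045   # parent 1 homozygous 0.045
  hom$alleles[2, , ] <- 0.645    # parent 2 homozygous 0.645
  set.seed(4)
  kids <- reproduce_diploid(hom, T = 1, frozen)
  expect_equal(pop_size(kids), 4)
  expect_true(all(kids$phenotype[, "alpha"] == (0.045 + 0.645) / 2))  # 0.345
  # heterozygote x heterozygote: four genotypes each at frequency 1/4
  het <- make_diploid(matrix(c(0.1, 0.3), 2, 3), matrix(c(0.2, 0.4), 2, 3),
                      tag1 = c(1L, 3L), tag2 = c(2L, 4L))
  enumerated <- character(0)
  set.seed(9)
  draws <- character(0)
  for (rep in 1:2500) {
    kids <- reproduce_diploid(het, T = 1, frozen)
    gt <- paste(pmin(kids$tags[, 1, 1], kids$tags[, 1, 2]),
                pmax(kids$tags[, 1, 1], kids$tags[, 1, 2]), sep = "/")
    draws <- c(draws, gt)
  }
  tab <- table(draws)
  expect_setequal(names(tab), c("1/3", "1/4", "2/3", "2/4"))  # full enumeration
  chi <- chisq.test(tab, p = rep(0.25, 4))
  expect_gt(chi$p.value, 1e-4)
  # allele values segregate with their tags (mu = 0)
  set.seed(9)
  kids <- reproduce_diploid(het, T = 1, frozen)
  val_of_tag <- c(`1` = 0.1, `2` = 0.2, `3` = 0.3, `4` = 0.4)
  expect_equal(kids$alleles[, 1, 1],
               unname(val_of_tag[as.character(kids$tags[, 1, 1])]))
  expect_error(reproduce_diploid(init_population(4, "clonal"), 1, frozen),
               "diploid")
})

test_that("neutral diploid generations conserve allele frequencies in expectation", {
  frozen <- mutation_schedule(mu0 = 0, mu_inf = 0, psi = 1)
  set.seed(31)
  pop <- init_population(40, "diploid")
  tags0 <- c(pop$tags[, 1, 1], pop$tags[, 1, 2])
  p0 <- mean(tags0 <= 20)  # frequency of the "low tag" class
  shifts <- replicate(400, {
    kids <- reproduce_diploid(pop, T = 1, frozen)  # whole pool mates: no selection
    mean(c(kids$tags[, 1, 1], kids$tags[, 1, 2]) <= 20) - p0
  })
  se <- sd(shifts) / sqrt(length(shifts))
  expect_lt(abs(mean(shifts)), 4 * se + 1e-12)
})

test_that("population size is restored to N at the start of every generation in all modes", {
  set.seed(6)
  sch <- mutation_schedule()
  for (mode in c("clonal", "averaging", "diploid")) {
    pop <- init_population(8, mode)
    for (T in 1:5) {
      parents <- select_fittest(pop, runif(pop_size(pop)))
      pop <- switch(mode,
                    clonal = reproduce_clonal(parents, T, sch),
                    averaging = reproduce_averaging(parents, T, sch),
                    diploid = reproduce_diploid(parents, T, sch))
      expect_equal(pop_size(pop), 8)
    }
  }
})

test_that("epochs are reproducible bit-for-bit and record every generation", {
  cfg <- epoch_config(4, "clonal", n_ticks = 10, generations = 5,
                      grid = grid_spec(5, 5))
  a <- run_epoch(cfg, seed = 123)
  b <- run_epoch(cfg, seed = 123)
  expect_identical(a$generations, b$generations)
  expect_identical(a$final$fitness, b$final$fitness)
  expect_equal(nrow(a$generations), 5)
  cfg1 <- epoch_config(4, "diploid", n_ticks = 5, generations = 1,
                       grid = grid_spec(5, 5))
  one <- run_epoch(cfg1, seed = 5)
  expect_equal(nrow(one$generations), 1)
  expect_equal(pop_size(one$final$population), 4)
  # the two engines retrace the same trajectory
  cfg_ref <- epoch_config(4, "clonal", n_ticks = 10, generations = 5,
                          grid = grid_spec(5, 5), engine = "reference")
  expect_identical(run_epoch(cfg_ref, seed = 123)$generations, a$generations)
})

test_that("mean fitness rises from the founding generation and plateaus", {
  cfg <- epoch_config(10, "clonal", generations = 60)
  ep <- run_epoch(cfg, seed = 2)
  fit <- ep$generations$mean_fitness
  expect_gt(mean(fit[40:60]), fit[1])
})
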