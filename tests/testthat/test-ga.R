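# cheap analytic evaluator: a smooth landscape with a known optimum, so the
# genetic machinery can be exercised without cable simulations
toy_evaluator <- function(g) {
  v <- retsim:::genome_to_vec(g)
  obj1 <- 10 - (v["refilling_rate"] - 0.5)^2 - (v["offset"] - 0.5)^2
  list(obj1 = unname(obj1), obj2 = unname(1 - abs(v["scaling_factor"] -
                                                    0.2)),
       obj3 = 0)
}

test_that("mutation has the prescribed moments and feasibility clipping", {
  ones <- do.call(genome_params, as.list(setNames(rep(1, 8),
                                                  retsim:::.ga_param_names)))
  # probability 0: identity
  set.seed(1)
  expect_identical(retsim:::genome_to_vec(mutate_genome(ones, prob = 0)),
                   retsim:::genome_to_vec(ones))
  # forced mutation of a unit gene: mean ~ 1, sd ~ 0.5 before clipping
  set.seed(2)
  draws <- vapply(1:10000, function(i)
    retsim:::genome_to_vec(mutate_genome(ones, prob = 1))[["refilling_rate"]],
    numeric(1))
  expect_lt(abs(mean(draws) - 1), 3 * 0.5 / sqrt(10000) + 0.01)
  expect_equal(sd(draws), 0.5, tolerance = 0.06)
  expect_true(all(draws > 0))                      # negatives clipped
  # spatial genes never exceed the dendritic extent
  big <- genome_params(anatomical_transition_point = 209,
                       k_transition_end_point = 209)
  set.seed(3)
  for (i in 1:200) {
    v <- retsim:::genome_to_vec(mutate_genome(big, prob = 1, extent = 210))
    expect_lte(v[["anatomical_transition_point"]], 210)
    expect_lte(v[["k_transition_end_point"]], 210)
  }
})

test_that("crossover swaps whole genes between parents", {
  a <- genome_params(); b <- genome_params(refilling_rate = 0.2,
                                           offset = 0.3,
                                           scaling_factor = 0.1)
  va <- retsim:::genome_to_vec(a); vb <- retsim:::genome_to_vec(b)
  set.seed(4)
  none <- crossover_genomes(a, b, prob = 0)
  expect_identical(retsim:::genome_to_vec(none[[1]]), va)
  expect_identical(retsim:::genome_to_vec(none[[2]]), vb)
  full <- crossover_genomes(a, b, prob = 1)
  expect_identical(retsim:::genome_to_vec(full[[1]]), vb)
  expect_identical(retsim:::genome_to_vec(full[[2]]), va)
  # each offspring gene comes from exactly one parent (no blending)
  for (i in 1:20) {
    ch <- crossover_genomes(a, b, prob = 0.5)
    v1 <- retsim:::genome_to_vec(ch[[1]]); v2 <- retsim:::genome_to_vec(ch[[2]])
    expect_true(all(v1 == va | v1 == vb))
    expect_true(all((v1 == va & v2 == vb) | (v1 == vb & v2 == va)))
  }
})

test_that("objective vector applies weights, ceiling and penalty", {
  met <- list(max_exp = -20, max_col = -26, rt_exp = 50, rt_col = 80)
  o <- ga_objectives(met)
  expect_equal(o$obj1, 6)
  expect_equal(o$obj2, 30)
  expect_equal(o$obj3, 0)                          # below the -10 mV ceiling
  expect_equal(o$weighted, 1 * 6 + 0.3 * 30 + 0.08 * 0)
  # depolarization beyond -10 mV is penalized through obj3
  hot <- ga_objectives(list(max_exp = -4, max_col = -12, rt_exp = 10,
                            rt_col = 20))
  expect_equal(hot$obj3, -6)
  # identical responses: obj1 = 0 < 0.04 mV floors every objective at -50
  same <- ga_objectives(list(max_exp = -20, max_col = -20, rt_exp = 5,
                             rt_col = 5))
  expect_equal(unlist(same[c("obj1", "obj2", "obj3")]), c(obj1 = -50,
                                                          obj2 = -50,
                                                          obj3 = -50))
  expect_true(same$penalized)
})

test_that("inclusion filter applies the CF thresholds", {
  base <- as.data.frame(t(retsim:::genome_to_vec(genome_params())))
  df <- do.call(rbind, replicate(4, base, simplify = FALSE))
  df$refilling_rate <- df$refilling_rate + 1:4     # make genomes distinct
  df$gen <- 0
  df$obj1 <- c(3.9, 4.0, 6, 6)
  df$obj2 <- c(1, 0, -0.1, 2)
  df$obj3 <- c(0, 0, 0, -1)
  df$weighted <- 0
  keep <- inclusion_filter(df)
  expect_equal(keep$obj1, 4.0)                     # boundary included,
  expect_equal(nrow(keep), 1L)                     # 3.9 / rt / score fail
  expect_true(all(rownames(keep) %in% rownames(df)))
})

test_that("the search improves monotonically and is seed-reproducible", {
  cfg <- ga_config(population = 12, generations = 6, seed = 5)
  run <- run_ga(cfg, evaluator = toy_evaluator)
  df <- as.data.frame(run)
  best <- tapply(df$weighted, df$gen, max)
  expect_true(all(diff(best) >= -1e-12))           # elitist total_rank
  run2 <- run_ga(cfg, evaluator = toy_evaluator)
  expect_identical(as.data.frame(run2), df)
  # archive round-trips losslessly through serialization
  f <- tempfile(fileext = ".rds")
  saveRDS(run, f)
  expect_identical(as.data.frame(readRDS(f)), df)
  # the optimum region is approached
  expect_gt(max(df$obj1), 9.8)
})

test_that("nsga2 and ibea selections run and keep elites", {
  for (sel in c("nsga2", "ibea")) {
    run <- run_ga(ga_config(population = 8, generations = 3, seed = 6,
                            selection = sel), evaluator = toy_evaluator)
    df <- as.data.frame(run)
    expect_equal(nrow(df), 8 * 4)
    expect_true(all(is.finite(df$weighted)))
  }
  # degenerate all-equal fitness: total_rank still produces a full archive
  flat <- function(g) list(obj1 = 1, obj2 = 1, obj3 = 0)
  run <- run_ga(ga_config(population = 8, generations = 2, seed = 7),
                evaluator = flat)
  expect_equal(nrow(as.data.frame(run)), 8 * 3)
})
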