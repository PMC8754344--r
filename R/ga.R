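# ---------------------------------------------------------------------------
# Multi-objective genetic search over the 8 synaptic-genome parameters,
# maximizing centrifugal preference of a simulated SAC:
#   obj1 = Amp_CF - Amp_CP (mV)
#   obj2 = RT_CP - RT_CF  (ms)
#   obj3 = voltage ceiling score (0 while physiological, negative above)
# with weights (1, 0.3, 0.08) and a hard penalty (all objectives set to -50)
# when obj1 < 0.04 mV.
# ---------------------------------------------------------------------------

.ga_param_names <- c("refilling_rate", "release_probability",
                     "k_transition_start_point", "k_transition_end_point",
                     "synaptic_conductance", "anatomical_transition_point",
                     "scaling_factor", "offset")

#' First-generation parameter bounds of the genetic search
#'
#' @return named list of `c(lower, upper)` pairs for the 8 genome
#'   parameters.  Later generations may exceed these bounds within
#'   biological feasibility.
#' @export
ga_default_bounds <- function() {
  list(refilling_rate = c(0.01, 1),
       release_probability = c(0.01, 0.75),
       k_transition_start_point = c(0.01, 0.5),
       k_transition_end_point = c(2, 210),
       synaptic_conductance = c(1e-4, 0.2),
       anatomical_transition_point = c(2, 210),
       scaling_factor = c(0.01, 0.4),
       offset = c(0.1, 0.99))
}

.ga_weights <- c(1, 0.3, 0.08)
.ga_penalty <- -50

#' Genetic-algorithm configuration
#'
#' Defaults are desk-scale (population 20, 10 generations); the full-scale
#' configuration uses a population of 100 for 20-45 generations.
#'
#' @param population population size (even).
#' @param generations number of generations.
#' @param crossover_prob per-gene swap probability (0.4).
#' @param mutation_prob per-gene mutation probability (0.4).
#' @param selection `"total_rank"`, `"nsga2"` or `"ibea"`.
#' @param bounds initial sampling bounds, see [ga_default_bounds()].
#' @param kinetics_mode `"standard"`, `"reversed"` or `"fixed"` input
#'   kinetics for the evaluation assay.
#' @param elite individuals copied unchanged each generation.
#' @param seed RNG seed for the whole run.
#' @param dendritic_extent feasibility cap for the spatial parameters, um.
#' @return a `ga_config`.
#' @export
ga_config <- function(population = 20L, generations = 10L,
                      crossover_prob = 0.4, mutation_prob = 0.4,
                      selection = c("total_rank", "nsga2", "ibea"),
                      bounds = ga_default_bounds(),
                      kinetics_mode = "standard", elite = 2L, seed = 1L,
                      dendritic_extent = 210) {
  selection <- match.arg(selection)
  if (population %% 2L != 0L) stop("population size must be even")
  stopifnot(crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            all(.ga_param_names %in% names(bounds)))
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob, selection = selection,
                 bounds = bounds, kinetics_mode = kinetics_mode,
                 elite = as.integer(elite), seed = as.integer(seed),
                 dendritic_extent = dendritic_extent),
            class = "ga_config")
}

genome_from_vec <- function(v) do.call(genome_params, as.list(v))

genome_to_vec <- function(g) unlist(g)[.ga_param_names]

random_genome_vec <- function(bounds) {
  vapply(.ga_param_names, function(nm)
    runif(1L, bounds[[nm]][1], bounds[[nm]][2]), numeric(1))
}

clip_genome_vec <- function(v, extent) {
  v <- pmax(v, 1e-6)
  v["anatomical_transition_point"] <-
    min(v["anatomical_transition_point"], extent)
  v["k_transition_end_point"] <- min(v["k_transition_end_point"], extent)
  v
}

#' Mutate a genome
#'
#' Each gene is independently replaced (with probability `prob`) by a draw
#' from `Normal(gene, gene / 2)`, then clipped to biological feasibility
#' (positive, spatial parameters at most the dendritic extent).  Values may
#' exceed the initial sampling bounds.
#'
#' @param g a [genome_params()].
#' @param prob per-gene mutation probability.
#' @param extent dendritic extent cap, um.
#' @return mutated `genome_params`.  Uses R's RNG.
#' @export
mutate_genome <- function(g, prob = 0.4, extent = 210) {
  v <- genome_to_vec(g)
  hit <- runif(length(v)) < prob
  v[hit] <- rnorm(sum(hit), mean = v[hit], sd = v[hit] / 2)
  genome_from_vec(clip_genome_vec(v, extent))
}

#' Uniform per-gene crossover of two genomes
#'
#' Each gene is swapped between the parents with probability `prob`; no
#' blending, every offspring gene comes from exactly one parent.
#'
#' @param a,b parent [genome_params()].
#' @param prob per-gene swap probability.
#' @return list of two offspring `genome_params`.  Uses R's RNG.
#' @export
crossover_genomes <- function(a, b, prob = 0.4) {
  va <- genome_to_vec(a); vb <- genome_to_vec(b)
  swap <- runif(length(va)) < prob
  t1 <- va; t1[swap] <- vb[swap]
  t2 <- vb; t2[swap] <- va[swap]
  list(genome_from_vec(t1), genome_from_vec(t2))
}

#' Objective vector from single-SAC ring-response metrics
#'
#' @param metrics a [ring_response_metrics()] result.
#' @param amp_floor penalty threshold for obj1, mV (0.04).
#' @return list with obj1, obj2, obj3, the weighted total, and a `penalized`
#'   flag.
#' @export
ga_objectives <- function(metrics, amp_floor = 0.04) {
  obj1 <- metrics$max_exp - metrics$max_col
  obj2 <- metrics$rt_col - metrics$rt_exp
  obj3 <- if (metrics$max_exp < -10) 0 else -(metrics$max_exp + 10)
  if (!is.finite(obj1) || !is.finite(obj2) || obj1 < amp_floor) {
    obj1 <- obj2 <- obj3 <- .ga_penalty
  }
  list(obj1 = obj1, obj2 = obj2, obj3 = obj3,
       weighted = sum(.ga_weights * c(obj1, obj2, obj3)),
       penalized = obj1 == .ga_penalty)
}

# --- selection -------------------------------------------------------------

# TRUE if objective row a Pareto-dominates row b (maximization)
.dominates <- function(a, b) all(a >= b) && any(a > b)

.nsga2_rank <- function(objs) {
  n <- nrow(objs)
  dom_count <- integer(n)
  dominated_by <- vector("list", n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (.dominates(objs[i, ], objs[j, ]))
      dominated_by[[i]] <- c(dominated_by[[i]], j)
    else if (.dominates(objs[j, ], objs[i, ]))
      dom_count[i] <- dom_count[i] + 1L
  }
  front <- integer(n)
  current <- which(dom_count == 0L)
  f <- 1L
  while (length(current)) {
    front[current] <- f
    nxt <- integer(0)
    for (i in current) for (j in dominated_by[[i]]) {
      dom_count[j] <- dom_count[j] - 1L
      if (dom_count[j] == 0L) nxt <- c(nxt, j)
    }
    current <- unique(nxt)
    f <- f + 1L
  }
  front
}

.crowding <- function(objs) {
  n <- nrow(objs)
  cd <- numeric(n)
  for (k in seq_len(ncol(objs))) {
    o <- order(objs[, k])
    rng <- objs[o[n], k] - objs[o[1], k]
    cd[o[c(1, n)]] <- Inf
    if (n > 2 && rng > 0)
      cd[o[2:(n - 1)]] <- cd[o[2:(n - 1)]] +
        (objs[o[3:n], k] - objs[o[1:(n - 2)], k]) / rng
  }
  cd
}

# selection scores: larger is better; used for both survivor selection and
# parent tournaments
.selection_scores <- function(objs, method) {
  switch(method,
    total_rank = as.numeric(objs %*% .ga_weights),
    nsga2 = {
      fr <- .nsga2_rank(objs)
      cd <- numeric(nrow(objs))
      for (f in unique(fr)) {
        idx <- which(fr == f)
        cd[idx] <- if (length(idx) > 1) .crowding(objs[idx, , drop = FALSE])
                   else Inf
      }
      -fr + pmin(cd, 10) / 20        # front dominates; crowding tie-breaks
    },
    ibea = {
      rng <- apply(objs, 2, range)
      span <- pmax(rng[2, ] - rng[1, ], 1e-12)
      norm <- sweep(sweep(objs, 2, rng[1, ]), 2, span, "/")
      n <- nrow(objs)
      fit <- numeric(n)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        eps <- max(norm[i, ] - norm[j, ])   # I(j, i): eps to dominate i by j
        fit[i] <- fit[i] - exp(-eps / 0.05)
      }
      fit
    },
    stop("unknown selection method"))
}

binary_tournament <- function(scores) {
  n <- length(scores)
  pick <- function() {
    i <- sample.int(n, 1L); j <- sample.int(n, 1L)
    if (scores[i] > scores[j]) i
    else if (scores[j] > scores[i]) j
    else min(i, j)                       # stable tie-breaking
  }
  pick()
}

#' Run the genetic search
#'
#' Initializes the population uniformly within the configured bounds and
#' evolves it by per-gene crossover, Gaussian mutation and the configured
#' selection scheme, keeping `elite` top individuals unchanged each
#' generation.  Evaluations are cached by genome, and the whole run is
#' deterministic in the seed.
#'
#' @param config a [ga_config()].
#' @param evaluator function `f(genome)` returning `list(obj1, obj2, obj3)`
#'   (already penalized); `NULL` uses the single-SAC expanding/collapsing
#'   rings assay via [make_sac_evaluator()].
#' @param ... passed to [make_sac_evaluator()] when `evaluator` is NULL.
#' @return a `ga_run` with the generation-by-generation archive.
#' @export
run_ga <- function(config, evaluator = NULL, ...) {
  stopifnot(inherits(config, "ga_config"))
  if (is.null(evaluator))
    evaluator <- make_sac_evaluator(kinetics_mode = config$kinetics_mode,
                                    seed = config$seed, ...)
  set.seed(config$seed)
  n <- config$population
  pop <- t(vapply(seq_len(n), function(i) random_genome_vec(config$bounds),
                  numeric(length(.ga_param_names))))
  colnames(pop) <- .ga_param_names
  cache <- new.env(parent = emptyenv())
  eval_pop <- function(pop) {
    t(apply(pop, 1L, function(v) {
      key <- paste(signif(v, 12), collapse = "|")
      hit <- get0(key, envir = cache, inherits = FALSE)
      if (is.null(hit)) {
        o <- evaluator(genome_from_vec(v))
        hit <- c(o$obj1, o$obj2, o$obj3)
        assign(key, hit, envir = cache)
      }
      hit
    }))
  }
  archive <- vector("list", config$generations + 1L)
  for (gen in 0:config$generations) {
    objs <- eval_pop(pop)
    colnames(objs) <- c("obj1", "obj2", "obj3")
    archive[[gen + 1L]] <- data.frame(gen = gen, pop, objs,
                                      weighted = as.numeric(objs %*%
                                                              .ga_weights))
    if (gen == config$generations) break
    scores <- .selection_scores(objs, config$selection)
    elite_idx <- order(-scores, seq_len(n))[seq_len(config$elite)]
    offspring <- matrix(NA_real_, n - config$elite, ncol(pop),
                        dimnames = list(NULL, colnames(pop)))
    k <- 1L
    while (k <= nrow(offspring)) {
      p1 <- binary_tournament(scores)
      p2 <- binary_tournament(scores)
      ch <- crossover_genomes(genome_from_vec(pop[p1, ]),
                              genome_from_vec(pop[p2, ]),
                              config$crossover_prob)
      for (c_ in ch) {
        if (k > nrow(offspring)) break
        mut <- mutate_genome(c_, config$mutation_prob,
                             config$dendritic_extent)
        offspring[k, ] <- genome_to_vec(mut)
        k <- k + 1L
      }
    }
    pop <- rbind(pop[elite_idx, , drop = FALSE], offspring)
  }
  structure(list(config = config, archive = archive), class = "ga_run")
}

#' Flatten a GA run into one data frame
#'
#' @param x a `ga_run`.
#' @param ... unused.
#' @return data frame with one row per individual per generation (genome,
#'   objectives, weighted total).
#' @export
as.data.frame.ga_run <- function(x, ...) do.call(rbind, x$archive)

#' @export
print.ga_run <- function(x, ...) {
  df <- as.data.frame(x)
  best <- max(df$weighted)
  cat(sprintf(
    "<ga_run: %s selection, %d x %d individuals, best weighted total %.3f>\n",
    x$config$selection, length(x$archive), x$config$population, best))
  invisible(x)
}

#' Filter a GA archive for centrifugal-preferring genomes
#'
#' Keeps genomes with `Amp_CF - Amp_CP >= amp_min` (4 mV), a non-negative
#' rise-time criterion and a non-negative voltage score.  The rise-time
#' criterion defaults to `RT_CP - RT_CF >= 0` (centrifugal preference means
#' a shorter centrifugal rise time); `rt_criterion = "printed"` uses the
#' opposite sign.  Optionally also requires the dense-input anatomical
#' constraint (transition point within the inner 2/3 of the arbor).
#'
#' @param run a `ga_run` (or its data frame).
#' @param amp_min amplitude-difference threshold, mV.
#' @param rt_criterion `"cp_minus_cf"` or `"printed"`.
#' @param anatomical require `anatomical_transition_point <= 2/3 * extent`.
#' @param extent dendritic extent, um.
#' @return data frame of unique passing genomes with their objectives.
#' @export
inclusion_filter <- function(run, amp_min = 4,
                             rt_criterion = c("cp_minus_cf", "printed"),
                             anatomical = FALSE, extent = 210) {
  rt_criterion <- match.arg(rt_criterion)
  if (rt_criterion == "printed")
    message("using the printed rise-time sign RT_CF - RT_CP >= 0")
  df <- if (inherits(run, "ga_run")) as.data.frame(run) else run
  rt_ok <- if (rt_criterion == "cp_minus_cf") df$obj2 >= 0 else df$obj2 <= 0
  keep <- df$obj1 >= amp_min & rt_ok & df$obj3 >= 0
  if (anatomical)
    keep <- keep & df$anatomical_transition_point <= 2 / 3 * extent
  out <- df[keep, , drop = FALSE]
  out[!duplicated(out[, .ga_param_names]), , drop = FALSE]
}
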