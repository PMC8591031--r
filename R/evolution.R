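# Evolutionary parameter optimization. A simulation entry point asks for its
# parameters with get_gene(key, default) and reports its fitness with
# set_score(score); run standalone it simply gets the defaults, run under
# evolve() it receives the active individual's genome. Selection is
# truncation ("a fraction of individuals with the best score survive"),
# refill is by cloning uniformly chosen survivors and mutating each gene.

.evo_state <- new.env(parent = emptyenv())
.evo_state$active <- NULL

#' Get an evolution-managed parameter
#'
#' Inside an evaluation managed by [evolve()], returns the active
#' individual's value for `key`; standalone (or when the key is not yet part
#' of the genome) returns `default`, registering the key so it joins the
#' genome in the next generation. The same script therefore runs unchanged
#' with and without the optimizer.
#'
#' @param key gene name.
#' @param default value used when unmanaged or the gene is unknown.
#' @return numeric gene value.
#' @export
get_gene <- function(key, default) {
  st <- .evo_state$active
  if (is.null(st)) return(default)
  g <- st$genome[[key]]
  if (is.null(g)) {
    st$registered[[key]] <- default
    return(default)
  }
  g
}

#' Report the fitness of the current evaluation
#'
#' Records `score` (higher is better) for the active individual. Calling it
#' twice in one evaluation is an error; a NaN/NA score marks the individual
#' failed (it can never be selected as survivor). Standalone the call is a
#' no-op that stores the score in the returned value of [run_standalone()].
#'
#' @param score a real number.
#' @export
set_score <- function(score) {
  st <- .evo_state$active
  if (is.null(st)) {
    .evo_state$last_standalone_score <- score
    return(invisible(score))
  }
  if (st$score_set) stop("set_score() called twice in one evaluation")
  st$score_set <- TRUE
  st$score <- if (length(score) != 1 || is.na(score)) NaN else as.numeric(score)
  invisible(score)
}

#' Evolution configuration
#'
#' @param population_size individuals per generation (>= 2).
#' @param survivor_fraction fraction in (0, 1) kept by truncation selection;
#'   `ceiling(survivor_fraction * population_size)` must be >= 1. The
#'   degenerate value 1 keeps everyone (population never changes).
#' @param generations number of generations (>= 1).
#' @param mutation_sigma relative mutation step: each gene of a refill
#'   individual is multiplied by `exp(rnorm(1, 0, mutation_sigma))`
#'   (log-normal, scale-free). Genes listed in `additive` instead get
#'   `+ rnorm(1, 0, mutation_sigma)`.
#' @param seed integer seed; the whole run is reproducible from it.
#' @param genes named list of initial gene values; if omitted, genes are
#'   discovered from the first evaluation's `get_gene()` defaults.
#' @param bounds named list of `c(lo, hi)` clip bounds per gene (optional).
#' @param additive character vector of gene names mutated additively.
#' @param workers advisory parallel evaluation slots; evaluation here is
#'   sequential and selection is rank-based with deterministic tie-breaks,
#'   so results are independent of the worker count.
#' @return an `evo_config`.
#' @export
evo_config <- function(population_size = 20, survivor_fraction = 0.3,
                       generations = 30, mutation_sigma = 0.2, seed = 1,
                       genes = NULL, bounds = list(),
                       additive = character(0), workers = 1) {
  stopifnot(population_size >= 2, generations >= 1, mutation_sigma >= 0,
            survivor_fraction > 0, survivor_fraction <= 1)
  if (ceiling(survivor_fraction * population_size) < 1) {
    stop("survivor_fraction too small: no survivors")
  }
  structure(list(population_size = as.integer(population_size),
                 survivor_fraction = survivor_fraction,
                 generations = as.integer(generations),
                 mutation_sigma = mutation_sigma,
                 seed = as.integer(seed), genes = genes, bounds = bounds,
                 additive = additive, workers = workers),
            class = "evo_config")
}

#' Read an evolution config from a key=value text file
#'
#' Recognized keys: `population_size`, `survivor_fraction`, `generations`,
#' `mutation_sigma`, `seed`, `workers`, and `gene.<name> = <value>` for
#' initial genes. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return an `evo_config`.
#' @export
read_evo_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_.][A-Za-z0-9_.]*)\\s*=\\s*(\\S+)\\s*$", lines))
  args <- list()
  genes <- list()
  for (m in kv) {
    if (length(m) == 0) next
    key <- m[2]; val <- m[3]
    if (startsWith(key, "gene.")) {
      genes[[sub("^gene\\.", "", key)]] <- as.numeric(val)
    } else {
      args[[key]] <- as.numeric(val)
    }
  }
  if (length(genes) > 0) args$genes <- genes
  do.call(evo_config, args)
}

#' Run a scoring function standalone (defaults only)
#'
#' @param score_fn function taking no arguments, using [get_gene()] /
#'   [set_score()] internally.
#' @return the score it set (or NULL).
#' @export
run_standalone <- function(score_fn) {
  .evo_state$last_standalone_score <- NULL
  score_fn()
  .evo_state$last_standalone_score
}

# evaluate one individual; returns list(score, failed, registered)
evo_evaluate <- function(score_fn, genome, eval_seed) {
  st <- new.env(parent = emptyenv())
  st$genome <- genome
  st$registered <- list()
  st$score_set <- FALSE
  st$score <- NaN
  old <- .evo_state$active
  .evo_state$active <- st
  on.exit(.evo_state$active <- old, add = TRUE)
  ok <- TRUE
  err <- NULL
  stream <- new_rng_stream(eval_seed)
  tryCatch(
    with_stream(stream, function() score_fn()),
    error = function(e) {
      ok <<- FALSE
      err <<- conditionMessage(e)
    })
  if (!ok) {
    return(list(score = -Inf, failed = TRUE,
                diagnostic = sprintf("evaluation error: %s", err),
                registered = st$registered))
  }
  if (!st$score_set) {
    return(list(score = -Inf, failed = TRUE,
                diagnostic = "evaluation ended without calling set_score()",
                registered = st$registered))
  }
  if (is.nan(st$score)) {
    return(list(score = -Inf, failed = TRUE, diagnostic = "score was NaN/NA",
                registered = st$registered))
  }
  list(score = st$score, failed = FALSE, diagnostic = NA_character_,
       registered = st$registered)
}

#' Optimize parameters with an evolutionary loop
#'
#' Per generation: every unevaluated individual is scored by `score_fn`
#' (survivors keep their cached score — elitism, so the best score per
#' generation is non-decreasing), the top
#' `ceiling(survivor_fraction * population_size)` by score survive
#' (deterministic tie-break by lineage id), and the population is refilled
#' by cloning uniformly chosen survivors and mutating each gene
#' (multiplicative log-normal by default, additive optionally, clipped to
#' bounds). Failed evaluations (error, NaN score, or no `set_score()` call)
#' score `-Inf` and are never selected. If *all* individuals of a generation
#' fail, the run aborts with the history attached to the error condition.
#'
#' @param score_fn scoring function (no arguments; uses [get_gene()] and
#'   [set_score()]). Alternatively a path to an R script that does the same
#'   (it is `source()`d per evaluation).
#' @param config an [evo_config()].
#' @param run optional storage run (see [create_run()]); the history is then
#'   appended there as `evolution_history.csv`.
#' @return list with `best` (the best individual ever seen: `genome`,
#'   `score`, `generation`, `lineage`), `history` (one data.frame row per
#'   evaluation), `population` (final generation survivors) and
#'   `generation_best` (best score per generation; non-decreasing by
#'   elitism).
#' @examples
#' cfg <- evo_config(population_size = 10, generations = 5, seed = 1,
#'                   genes = list(x = 1))
#' res <- evolve(function() set_score(-(get_gene("x", 1) - 3)^2), cfg)
#' res$best$genome$x
#' @export
evolve <- function(score_fn, config, run = NULL) {
  if (is.character(score_fn)) {
    script <- score_fn
    if (!file.exists(script)) stop(sprintf("script '%s' not found", script))
    score_fn <- function() {
      sys.source(script, envir = new.env(parent = globalenv()))
    }
  }
  stopifnot(inherits(config, "evo_config"))
  rng <- new_rng_stream(derive_seed(config$seed, "evolution"))
  n_survive <- ceiling(config$survivor_fraction * config$population_size)

  lineage_counter <- 0L
  new_individual <- function(genome, generation) {
    lineage_counter <<- lineage_counter + 1L
    list(genome = genome, score = NA_real_, failed = FALSE,
         evaluated = FALSE, generation = generation,
         lineage = lineage_counter)
  }

  mutate_genome <- function(genome) {
    with_stream(rng, function() {
      for (nm in names(genome)) {
        v <- genome[[nm]]
        if (nm %in% config$additive) {
          v <- v + rnorm(1, 0, config$mutation_sigma)
        } else {
          v <- v * exp(rnorm(1, 0, config$mutation_sigma))
        }
        b <- config$bounds[[nm]]
        if (!is.null(b)) v <- min(max(v, b[1]), b[2])
        genome[[nm]] <- v
      }
      genome
    })
  }

  # initial genome: configured genes, or discovered from a probe evaluation
  base_genome <- config$genes
  if (is.null(base_genome)) {
    probe <- evo_evaluate(score_fn, list(),
                          derive_seed(config$seed, "discover"))
    base_genome <- probe$registered
    if (length(base_genome) == 0) {
      stop("no genes: config$genes is empty and the score function never called get_gene()")
    }
  }

  population <- vector("list", config$population_size)
  population[[1]] <- new_individual(base_genome, 1L)
  for (i in seq_len(config$population_size)[-1]) {
    population[[i]] <- new_individual(mutate_genome(base_genome), 1L)
  }

  history <- list()
  generation_best <- numeric(config$generations)
  best <- NULL
  for (gen in seq_len(config$generations)) {
    for (i in seq_along(population)) {
      ind <- population[[i]]
      if (ind$evaluated) next
      res <- evo_evaluate(score_fn, ind$genome,
                          derive_seed(config$seed,
                                      sprintf("eval/%d/%d", gen, ind$lineage)))
      ind$score <- res$score
      ind$failed <- res$failed
      ind$evaluated <- TRUE
      # genes asked for but absent join the genome for later generations
      for (nm in setdiff(names(res$registered), names(ind$genome))) {
        ind$genome[[nm]] <- res$registered[[nm]]
      }
      population[[i]] <- ind
      row <- c(list(generation = gen, lineage = ind$lineage),
               ind$genome,
               list(score = ind$score, failed = ind$failed))
      history[[length(history) + 1L]] <- row
    }
    if (all(vapply(population, function(p) p$failed, logical(1)))) {
      cond <- simpleError(sprintf("all %d individuals failed in generation %d",
                                  length(population), gen))
      cond$history <- evo_history_frame(history)
      stop(cond)
    }
    scores <- vapply(population, function(p) p$score, numeric(1))
    lineages <- vapply(population, function(p) p$lineage, integer(1))
    ord <- order(-scores, lineages)  # rank by score, deterministic ties
    survivors <- population[ord[seq_len(min(n_survive, length(population)))]]
    gen_best <- survivors[[1]]
    generation_best[gen] <- gen_best$score
    if (is.null(best) || gen_best$score > best$score) best <- gen_best
    if (gen < config$generations) {
      n_new <- config$population_size - length(survivors)
      offspring <- vector("list", n_new)
      for (j in seq_len(n_new)) {
        parent <- survivors[[with_stream(rng, function()
          sample.int(length(survivors), 1))]]
        offspring[[j]] <- new_individual(mutate_genome(parent$genome),
                                         gen + 1L)
      }
      population <- c(survivors, offspring)
    } else {
      population <- survivors
    }
  }

  hist_df <- evo_history_frame(history)
  if (!is.null(run)) {
    utils::write.csv(hist_df,
                     file.path(run$path, "evolution_history.csv"),
                     row.names = FALSE)
  }
  list(best = best, history = hist_df, population = population,
       generation_best = generation_best)
}

evo_history_frame <- function(history) {
  if (length(history) == 0) return(data.frame())
  cols <- unique(unlist(lapply(history, names)))
  rows <- lapply(history, function(r) {
    for (nm in setdiff(cols, names(r))) r[[nm]] <- NA
    as.data.frame(r[cols])
  })
  do.call(rbind, rows)
}
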