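#' Configuration for the genetic-programming regressor
#'
#' Defaults follow the study configuration: population 5000, 10000
#' generations, crossover probability 0.7, subtree-mutation probability 0.1
#' (the remaining 0.2 is plain reproduction), per-generation subsample
#' fraction 0.9, parsimony coefficient 0.01, with the squared Pearson
#' correlation (R-squared) as the fitness metric. Selection scheme, depth
#' limits, constant range and elitism are not part of that configuration and
#' are package design choices, all overridable here. Note the full-scale
#' defaults imply a long run; desk-scale experiments should pass smaller
#' `population_size`/`generations`.
#'
#' @param population_size Individuals per generation. Default 5000.
#' @param generations Number of generations. Default 10000.
#' @param p_crossover Probability an offspring is produced by subtree
#'   crossover. Default 0.7.
#' @param p_subtree_mutation Probability of subtree mutation. Default 0.1.
#'   Remaining probability mass is reproduction (copy).
#' @param max_samples Fraction of rows subsampled (without replacement) each
#'   generation for fitness evaluation. Default 0.9.
#' @param parsimony_coefficient Per-node fitness penalty. Default 0.01.
#' @param tournament_size Tournament size for parent selection. Default 20.
#' @param max_depth Hard cap on tree depth (leaf = depth 0). Default 8.
#' @param init_depth Length-2 integer range of initial tree depths for
#'   ramped half-and-half initialisation. Default `c(2, 6)`.
#' @param mutation_depth Maximum depth of a freshly grown mutant subtree.
#'   Default 4.
#' @param const_range Range of ephemeral random constants. Default
#'   `c(-5, 5)`.
#' @param p_const Probability a terminal is a constant rather than a
#'   feature. Default 0.3.
#' @param elitism Keep the best-so-far individual in every generation?
#'   Default `TRUE`.
#' @param seed Integer RNG seed; required, so every run is reproducible.
#' @return An object of class `gp_config`.
#' @export
gp_config <- function(population_size = 5000, generations = 10000,
                      p_crossover = 0.7, p_subtree_mutation = 0.1,
                      max_samples = 0.9, parsimony_coefficient = 0.01,
                      tournament_size = 20, max_depth = 8,
                      init_depth = c(2, 6), mutation_depth = 4,
                      const_range = c(-5, 5), p_const = 0.3,
                      elitism = TRUE, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  cfg <- structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         p_crossover = p_crossover,
         p_subtree_mutation = p_subtree_mutation,
         max_samples = max_samples,
         parsimony_coefficient = parsimony_coefficient,
         tournament_size = as.integer(tournament_size),
         max_depth = as.integer(max_depth),
         init_depth = as.integer(init_depth),
         mutation_depth = as.integer(mutation_depth),
         const_range = as.numeric(const_range),
         p_const = p_const,
         elitism = isTRUE(elitism),
         seed = as.integer(seed)),
    class = "gp_config"
  )
  validate_gp_config(cfg)
  cfg
}

validate_gp_config <- function(cfg) {
  with(cfg, {
    if (population_size < 2L) stop("population_size must be >= 2", call. = FALSE)
    if (generations < 1L) stop("generations must be >= 1", call. = FALSE)
    probs <- c(p_crossover, p_subtree_mutation)
    if (any(probs < 0) || any(probs > 1) || sum(probs) > 1) {
      stop("operator probabilities must lie in [0,1] and sum to <= 1",
           call. = FALSE)
    }
    if (max_samples <= 0 || max_samples > 1) {
      stop("max_samples must be in (0, 1]", call. = FALSE)
    }
    if (parsimony_coefficient < 0) {
      stop("parsimony_coefficient must be >= 0", call. = FALSE)
    }
    if (tournament_size < 1L) stop("tournament_size must be >= 1", call. = FALSE)
    if (max_depth < 1L) stop("max_depth must be >= 1", call. = FALSE)
    if (length(init_depth) != 2L || init_depth[1] > init_depth[2] ||
        init_depth[2] > max_depth) {
      stop("init_depth must be an increasing pair within max_depth",
           call. = FALSE)
    }
    if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  })
  invisible(cfg)
}

# Squared Pearson correlation with degenerate cases mapped to 0: a tree
# with constant or non-finite predictions carries no information about the
# response and scores zero rather than erroring, keeping fitness total.
gp_raw_r2 <- function(pred, y) {
  if (!all(is.finite(pred))) return(0)
  vp <- pred - mean(pred)
  sp <- sum(vp * vp)
  if (sp <= 0) return(0)
  vy <- y - mean(y)
  r <- sum(vp * vy)^2 / (sp * sum(vy * vy))
  if (!is.finite(r)) 0 else r
}

#' Fitness of an expression tree
#'
#' Raw fitness is the squared Pearson correlation between the tree's
#' predictions and the response on the evaluated rows; trees with constant
#' or non-finite predictions score 0 (no correlation). Penalised fitness
#' subtracts `parsimony_coefficient` times the node count
#' (maximisation convention), discouraging bloat.
#'
#' @param tree A tree node.
#' @param data Data frame of features plus response.
#' @param response Response column name.
#' @param config A [gp_config()].
#' @param rows Optional integer row subset; defaults to all rows.
#' @return Named list `raw` and `penalized`.
#' @export
gp_fitness <- function(tree, data, response, config, rows = NULL) {
  feats <- data[setdiff(names(data), response)]
  y <- data[[response]]
  if (!is.null(rows)) {
    feats <- lapply(feats, function(col) col[rows])
    y <- y[rows]
  }
  pred <- evaluate_tree(tree, feats)
  raw <- gp_raw_r2(pred, y)
  list(raw = raw,
       penalized = raw - config$parsimony_coefficient * tree_length(tree))
}

#' Subtree crossover
#'
#' Replaces a uniformly chosen subtree of `parent_a` with a uniformly chosen
#' subtree of `parent_b`. The depth cap is enforced by rejection: after
#' `max_tries` oversized children the result is a copy of `parent_a`.
#'
#' @param parent_a,parent_b Tree nodes.
#' @param max_depth Depth cap for the child.
#' @param max_tries Rejection attempts before falling back. Default 10.
#' @return A tree node.
#' @export
subtree_crossover <- function(parent_a, parent_b, max_depth = 8,
                              max_tries = 10) {
  la <- tree_length(parent_a)
  lb <- tree_length(parent_b)
  for (i in seq_len(max_tries)) {
    ka <- sample.int(la, 1L)
    kb <- sample.int(lb, 1L)
    child <- replace_subtree(parent_a, ka, get_subtree(parent_b, kb))
    if (tree_depth(child) <= max_depth) return(child)
  }
  parent_a
}

#' Subtree mutation
#'
#' Replaces a uniformly chosen subtree with a random tree grown to at most
#' `config$mutation_depth`; the overall depth cap is enforced by rejection
#' as in [subtree_crossover()].
#'
#' @param parent A tree node.
#' @param feature_names Feature names available as terminals.
#' @param config A [gp_config()].
#' @param max_tries Rejection attempts before falling back. Default 10.
#' @return A tree node.
#' @export
subtree_mutation <- function(parent, feature_names, config, max_tries = 10) {
  lp <- tree_length(parent)
  for (i in seq_len(max_tries)) {
    k <- sample.int(lp, 1L)
    sub <- random_tree(feature_names,
                       depth = sample.int(config$mutation_depth, 1L),
                       method = "grow",
                       const_range = config$const_range,
                       p_const = config$p_const)
    child <- replace_subtree(parent, k, sub)
    if (tree_depth(child) <= config$max_depth) return(child)
  }
  parent
}

#' Evolve a symbolic-regression model
#'
#' Genetic-programming regression of a response column on the remaining
#' columns of `data`, over the function set
#' `{add, sub, mul, div, sqrt, log, inv}` with protected semantics. Each
#' generation: a row subsample of `ceiling(max_samples * n)` is drawn
#' without replacement; the whole population is scored on it (penalised
#' fitness = raw R-squared minus the parsimony penalty); offspring are
#' produced by tournament selection followed by crossover, subtree mutation
#' or reproduction with the configured probabilities. The generation's best
#' individual is re-scored on the full dataset, and the best-so-far
#' individual (by full-data raw R-squared) is tracked, recorded in the
#' history, and — with elitism — copied into the next generation, making
#' the best-so-far curve non-decreasing. Fully reproducible given
#' `config$seed`.
#'
#' @param data Data frame: feature columns plus the response column. No
#'   missing values; the response must be non-constant.
#' @param config A [gp_config()].
#' @param response Response column name. Default `"response"`.
#' @return An object of class `gp_fit`: list with `best_tree`,
#'   `best_raw_r2` (full-data), `best_penalized`, `history` (tibble:
#'   `generation`, `best_raw_r2`), `config`, `feature_names`, `n`,
#'   `response`.
#' @examples
#' dat <- tibble::tibble(x0 = runif(50), x1 = runif(50))
#' dat$response <- 2 * dat$x0 + dat$x1
#' fit <- gp_evolve(dat, gp_config(population_size = 50, generations = 5,
#'                                 seed = 1))
#' glance(fit)
#' @export
gp_evolve <- function(data, config, response = "response") {
  stopifnot(is.data.frame(data))
  validate_gp_config(config)
  if (!response %in% names(data)) {
    stop("response column '", response, "' not found", call. = FALSE)
  }
  feature_names <- setdiff(names(data), response)
  if (length(feature_names) == 0L) {
    stop("no feature columns", call. = FALSE)
  }
  if (anyNA(data)) stop("data contains missing values", call. = FALSE)
  y <- data[[response]]
  if (stats::sd(y) == 0) {
    stop("response is constant; nothing to regress", call. = FALSE)
  }
  n <- nrow(data)
  feats <- lapply(as.list(data[feature_names]), as.numeric)
  y <- as.numeric(y)
  n_sub <- ceiling(config$max_samples * n)

  set.seed(config$seed)
  pop_size <- config$population_size
  # ramped half-and-half initialisation
  depths <- rep(seq(config$init_depth[1], config$init_depth[2]),
                length.out = pop_size)
  methods <- rep(c("grow", "full"), length.out = pop_size)
  population <- lapply(seq_len(pop_size), function(i) {
    random_tree(feature_names, depths[i], methods[i],
                config$const_range, config$p_const)
  })

  pc <- config$parsimony_coefficient
  best_tree <- NULL
  best_raw <- -Inf
  best_pen <- -Inf
  history_raw <- numeric(config$generations)

  for (gen in seq_len(config$generations)) {
    rows <- if (n_sub < n) sample.int(n, n_sub) else seq_len(n)
    sub_feats <- if (n_sub < n) lapply(feats, `[`, rows) else feats
    sub_y <- y[rows]

    pen <- numeric(pop_size)
    raw <- numeric(pop_size)
    for (i in seq_len(pop_size)) {
      pred <- gp_eval(population[[i]], sub_feats, n_sub)
      raw[i] <- gp_raw_r2(pred, sub_y)
      pen[i] <- raw[i] - pc * tree_length(population[[i]])
    }

    gb <- which.max(pen)
    full_raw <- gp_raw_r2(gp_eval(population[[gb]], feats, n), y)
    if (full_raw > best_raw) {
      best_raw <- full_raw
      best_tree <- population[[gb]]
      best_pen <- full_raw - pc * tree_length(best_tree)
    }
    history_raw[gen] <- best_raw

    if (gen == config$generations) break

    newpop <- vector("list", pop_size)
    start <- 1L
    if (config$elitism) {
      newpop[[1L]] <- best_tree
      start <- 2L
    }
    ts <- config$tournament_size
    for (i in start:pop_size) {
      cand <- sample.int(pop_size, ts, replace = ts > pop_size)
      parent <- population[[cand[which.max(pen[cand])]]]
      u <- stats::runif(1)
      if (u < config$p_crossover) {
        cand2 <- sample.int(pop_size, ts, replace = ts > pop_size)
        donor <- population[[cand2[which.max(pen[cand2])]]]
        newpop[[i]] <- subtree_crossover(parent, donor, config$max_depth)
      } else if (u < config$p_crossover + config$p_subtree_mutation) {
        newpop[[i]] <- subtree_mutation(parent, feature_names, config)
      } else {
        newpop[[i]] <- parent
      }
    }
    population <- newpop
  }

  structure(
    list(
      best_tree = best_tree,
      best_raw_r2 = best_raw,
      best_penalized = best_pen,
      history = tibble::tibble(generation = seq_len(config$generations),
                               best_raw_r2 = history_raw),
      config = config,
      feature_names = feature_names,
      n = n,
      response = response
    ),
    class = "gp_fit"
  )
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("<gp_fit>  symbolic regression by genetic programming\n")
  cat("  best expression: ", tree_to_infix(x$best_tree), "\n", sep = "")
  cat(sprintf("  raw R2 (full data) = %.6f   nodes = %d   depth = %d\n",
              x$best_raw_r2, tree_length(x$best_tree),
              tree_depth(x$best_tree)))
  cat(sprintf("  %d generations x %d individuals, seed %d\n",
              x$config$generations, x$config$population_size,
              x$config$seed))
  invisible(x)
}

#' Predictions from a fitted symbolic-regression model
#'
#' @param object A `gp_fit`.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Ignored.
#' @return Numeric vector of predictions.
#' @export
predict.gp_fit <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss) > 0L) {
    stop("newdata is missing feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  evaluate_tree(object$best_tree, newdata)
}

#' @rdname gp_evolve
#' @param x,... A `gp_fit`; further arguments ignored.
#' @export
tidy.gp_fit <- function(x, ...) {
  tibble::tibble(
    expression = tree_to_infix(x$best_tree),
    prefix = tree_to_prefix(x$best_tree),
    length = tree_length(x$best_tree),
    depth = tree_depth(x$best_tree)
  )
}

#' @rdname gp_evolve
#' @export
glance.gp_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$best_raw_r2,
    penalized = x$best_penalized,
    generations = x$config$generations,
    population = x$config$population_size,
    nobs = x$n
  )
}
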