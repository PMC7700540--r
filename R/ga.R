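#' Initialise a population of weight chromosomes
#'
#' Each chromosome is a continuous per-feature weight vector with genes
#' drawn i.i.d. uniform on `[0, 1]`. Deterministic given `seed`.
#'
#' @param n_members Population size (>= 2).
#' @param n_features Number of genes per chromosome (>= 1).
#' @param seed Integer seed.
#' @return List of numeric weight vectors.
#' @export
init_population <- function(n_members, n_features, seed = 1L) {
  if (n_members < 2) stop("population needs at least 2 members")
  if (n_features < 1) stop("chromosomes need at least 1 gene")
  withr::with_seed(as.integer(seed),
    lapply(seq_len(n_members), function(i) stats::runif(n_features)))
}

#' Single-point crossover
#'
#' Recombines two parents at a uniformly drawn cut point
#' `k in [1, n - 1]`: the first offspring takes genes `1..k` from
#' parent 1 and the rest from parent 2; the second is the mirror. The
#' positionwise gene multiset across the pair is conserved.
#'
#' @param parent1,parent2 Equal-length numeric weight vectors.
#' @param seed Optional integer seed; when `NULL` the ambient RNG
#'   stream is used (as inside [evolve()]).
#' @return List of two offspring vectors.
#' @export
crossover <- function(parent1, parent2, seed = NULL) {
  n <- length(parent1)
  if (n != length(parent2)) stop("parents must have equal gene counts")
  do_cross <- function() {
    if (n < 2) return(list(parent1, parent2))
    k <- sample.int(n - 1L, 1L)
    list(c(parent1[1:k], parent2[(k + 1):n]),
         c(parent2[1:k], parent1[(k + 1):n]))
  }
  if (is.null(seed)) do_cross()
  else withr::with_seed(as.integer(seed), do_cross())
}

#' Uniform-resample mutation
#'
#' Each gene is independently replaced by a fresh uniform `[0, 1]` draw
#' with probability `rate` (default 0.05), introducing another level of
#' randomisation that keeps the population diverse.
#'
#' @param chromosome Numeric weight vector.
#' @param rate Mutation probability per gene, in `[0, 1]`.
#' @param seed Optional integer seed (`NULL`: ambient RNG stream).
#' @return Mutated weight vector.
#' @export
mutate <- function(chromosome, rate = 0.05, seed = NULL) {
  if (rate < 0 || rate > 1) stop("mutation rate must lie in [0, 1]")
  do_mut <- function() {
    hit <- stats::runif(length(chromosome)) < rate
    if (any(hit)) chromosome[hit] <- stats::runif(sum(hit))
    chromosome
  }
  if (is.null(seed)) do_mut()
  else withr::with_seed(as.integer(seed), do_mut())
}

#' Reweight a feature table by a chromosome
#'
#' Multiplies feature column `j` by `weights[j]`; a zero weight zeroes
#' the column out, excluding the feature.
#'
#' @param table Data frame or matrix of numeric feature columns (no
#'   label column).
#' @param weights Numeric weight vector, one gene per column.
#' @return Object of the same type with reweighted columns.
#' @export
reweight <- function(table, weights) {
  m <- as.matrix(table)
  if (ncol(m) != length(weights))
    stop("weight count (", length(weights),
         ") does not match feature count (", ncol(m), ")")
  out <- sweep(m, 2, weights, `*`)
  if (is.data.frame(table)) as.data.frame(out) else out
}

#' Chromosome fitness: mean of linear-SVM and random-forest accuracy
#'
#' Reweights the features by the chromosome, makes a deterministic
#' stratified 80/20 split of the provided training partition, fits a
#' linear SVM (cost 1) and a random forest (100 trees) on the 80% and
#' records each one's hold-out accuracy; the combined fitness is their
#' mean.
#'
#' @param chromosome Numeric weight vector.
#' @param features Data frame or matrix of feature columns (no label).
#' @param labels Factor or character vector of class labels (>= 2
#'   classes, >= 5 samples per class).
#' @param seed Integer seed controlling the split and the forest.
#' @return List of class `har_fitness` with `acc_lsvm`, `acc_rf`,
#'   `combined`.
#' @export
ga_fitness <- function(chromosome, features, labels, seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("fitness needs at least 2 classes")
  if (min(table(labels)) < 5)
    stop("fitness needs at least 5 samples per class")
  m <- reweight(as.matrix(features), chromosome)
  idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(seq_along(labels), labels), function(i)
      sample(i, max(1L, round(0.8 * length(i))))))
  })
  tr_x <- m[idx, , drop = FALSE]; tr_y <- droplevels(labels[idx])
  te_x <- m[-idx, , drop = FALSE]; te_y <- labels[-idx]
  ## constant columns break svm scaling; scale only varying ones
  varying <- apply(tr_x, 2, function(v) stats::sd(v) > 0)
  svm_fit <- e1071::svm(tr_x, tr_y, kernel = "linear", cost = 1,
                        scale = varying)
  acc_lsvm <- mean(as.character(predict(svm_fit, te_x)) ==
                     as.character(te_y))
  rf_fit <- withr::with_seed(as.integer(seed) + 1L,
    randomForest::randomForest(tr_x, tr_y, ntree = 100))
  acc_rf <- mean(as.character(predict(rf_fit, te_x)) ==
                   as.character(te_y))
  structure(list(acc_lsvm = acc_lsvm, acc_rf = acc_rf,
                 combined = (acc_lsvm + acc_rf) / 2),
            class = "har_fitness")
}

#' @export
print.har_fitness <- function(x, ...) {
  cat(sprintf("<har_fitness> lsvm %.4f | rf %.4f | combined %.4f\n",
              x$acc_lsvm, x$acc_rf, x$combined))
  invisible(x)
}

#' Evolve feature weights with the reweighted genetic algorithm
#'
#' Tournament selection (size 3 by default), single-point crossover
#' (probability 0.8), per-gene uniform-resample mutation (rate 0.05)
#' and elitism (the best chromosome survives unchanged). One
#' deterministic fitness split is fixed per run, so fitness is a pure
#' function of the chromosome and the elitist best-fitness history is
#' non-decreasing. Evolution stops at `generations` or when the best
#' fitness has not improved for `patience` consecutive generations.
#'
#' @param features Data frame or matrix of feature columns (no label).
#' @param labels Class labels.
#' @param config A [har_config()]; `config$ga` holds the GA settings.
#' @param seed Integer seed for the whole run.
#' @return List of class `har_evolution`: `best` (weight vector),
#'   `best_fitness` (`har_fitness`), `history` (best combined fitness
#'   per generation, non-decreasing), `generations_run`.
#' @export
evolve <- function(features, labels, config = har_config(), seed = 1L) {
  ga <- config$ga
  n_feat <- ncol(as.matrix(features))
  fit_seed <- (as.integer(seed) * 131L + 17L) %% .Machine$integer.max
  pop <- init_population(ga$population, n_feat, seed = seed)
  evaluate_member <- function(ch) ga_fitness(ch, features, labels,
                                             seed = fit_seed)
  fits <- lapply(pop, evaluate_member)
  combined <- vapply(fits, `[[`, 0, "combined")
  best_i <- which.max(combined)
  best <- pop[[best_i]]; best_fit <- fits[[best_i]]
  history <- best_fit$combined
  stall <- 0L
  gen <- 1L
  withr::with_seed(as.integer(seed) + 1000L, {
    while (gen < ga$generations && stall < ga$patience) {
      new_pop <- vector("list", ga$population)
      ## elitism: carry over the best chromosome(s)
      n_elite <- min(ga$elitism, ga$population)
      order_fit <- order(combined, decreasing = TRUE)
      for (e in seq_len(n_elite)) new_pop[[e]] <- pop[[order_fit[e]]]
      i <- n_elite + 1L
      while (i <= ga$population) {
        tournament <- function() {
          cand <- sample.int(ga$population, min(ga$tournament, ga$population))
          pop[[cand[which.max(combined[cand])]]]
        }
        p1 <- tournament(); p2 <- tournament()
        if (stats::runif(1) < ga$crossover_prob) {
          off <- crossover(p1, p2)
        } else off <- list(p1, p2)
        new_pop[[i]] <- mutate(off[[1]], ga$mutation_rate)
        if (i + 1L <= ga$population)
          new_pop[[i + 1L]] <- mutate(off[[2]], ga$mutation_rate)
        i <- i + 2L
      }
      pop <- new_pop
      fits <- lapply(pop, evaluate_member)
      combined <- vapply(fits, `[[`, 0, "combined")
      gen_best <- which.max(combined)
      if (combined[gen_best] > best_fit$combined) {
        best <- pop[[gen_best]]; best_fit <- fits[[gen_best]]
        stall <- 0L
      } else stall <- stall + 1L
      history <- c(history, best_fit$combined)
      gen <- gen + 1L
    }
  })
  structure(list(best = best, best_fitness = best_fit,
                 history = history, generations_run = gen),
            class = "har_evolution")
}

#' @export
print.har_evolution <- function(x, ...) {
  cat(sprintf("<har_evolution> %d generation(s), best fitness %.4f (lsvm %.4f, rf %.4f)\n",
              x$generations_run, x$best_fitness$combined,
              x$best_fitness$acc_lsvm, x$best_fitness$acc_rf))
  invisible(x)
}

#' Select contributive features from an evolved chromosome
#'
#' A feature is contributive when its evolved weight reaches the mean
#' of all weights; at least one feature is always retained (the
#' maximum weight is never below the mean).
#'
#' @param weights Evolved weight vector (the best chromosome).
#' @param feature_names Character vector of feature names, one per
#'   gene.
#' @return Character vector of retained feature names.
#' @export
select_features <- function(weights, feature_names) {
  if (length(weights) != length(feature_names))
    stop("weights and feature_names must have equal length")
  feature_names[weights >= mean(weights)]
}
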