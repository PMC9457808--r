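# Descriptor pre-filtering and genetic-algorithm subset selection.

#' Pre-filter a descriptor table
#'
#' Drops constant (non-representative) columns, then resolves
#' inter-correlated pairs: while any pair of surviving columns has
#' |Pearson r| above the threshold, the most correlated pair is taken and
#' the member with the lower |correlation to the response| is dropped
#' (ties: the later column in input order).
#'
#' @param x descriptor table (data frame; `id`/`set`/`log_inv_c` columns
#'   are carried through untouched) or numeric matrix.
#' @param y response used to rank pair members.
#' @param corr_threshold pairwise |r| above which a pair is considered
#'   inter-correlated (default 0.90).
#' @return the reduced table, with attribute `"removed"`: a data frame
#'   logging each removal and its reason.
#' @export
prefilter <- function(x, y, corr_threshold = 0.90) {
  X <- .design_matrix(x)
  if (nrow(X) < 2) stop("need at least 2 rows")
  y <- as.numeric(y)
  removed <- data.frame(column = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  keep <- colnames(X)
  const <- vapply(keep, function(cn) stats::var(X[, cn]) == 0, TRUE)
  if (any(const)) {
    removed <- rbind(removed, data.frame(column = keep[const],
                                         reason = "constant column"))
    keep <- keep[!const]
  }
  repeat {
    if (length(keep) < 2) break
    cm <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= corr_threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- keep[min(idx)]; b <- keep[max(idx)]
    ca <- abs(stats::cor(X[, a], y)); cb <- abs(stats::cor(X[, b], y))
    drop_col <- if (ca > cb) b else if (cb > ca) a else b  # tie: later column
    removed <- rbind(removed, data.frame(
      column = drop_col,
      reason = sprintf("|r| = %.3f with %s", max(cm),
                       if (drop_col == a) b else a)))
    keep <- setdiff(keep, drop_col)
  }
  if (!length(keep)) stop("all descriptor columns removed by pre-filtering")
  out <- if (is.data.frame(x)) {
    carried <- intersect(c("id", "set", "log_inv_c"), names(x))
    x[, c(carried, keep), drop = FALSE]
  } else X[, keep, drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Genetic-algorithm configuration
#'
#' @param subset_size number of descriptors per model (default 10).
#' @param population chromosomes per generation.
#' @param generations number of generations.
#' @param crossover_rate,mutation_rate GA operator probabilities.
#' @param tournament_size selection tournament size.
#' @param fitness `"q2_loo"` (default) or `"r2"`.
#' @param elitism number of best chromosomes copied unchanged.
#' @param seed RNG seed.
#' @return list of class `"ga_config"`.
#' @export
ga_config <- function(subset_size = 10, population = 100, generations = 200,
                      crossover_rate = 0.8, mutation_rate = 0.1,
                      tournament_size = 3, fitness = c("q2_loo", "r2"),
                      elitism = 1, seed = 1) {
  fitness <- match.arg(fitness)
  stopifnot(crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            subset_size >= 1, population >= 1, generations >= 0)
  structure(list(subset_size = subset_size, population = population,
                 generations = generations, crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, tournament_size = tournament_size,
                 fitness = fitness, elitism = elitism, seed = seed),
            class = "ga_config")
}

#' Genetic-algorithm descriptor subset selection
#'
#' Chromosomes are fixed-size descriptor subsets.  Fitness is the chosen
#' validation statistic of an OLS fit on the supplied rows (leave-one-out
#' Q2 by default).  Selection is by tournament; uniform crossover of the
#' parents' union is repaired back to the fixed subset size; mutation swaps
#' one member for a random outsider; the best chromosome survives unchanged
#' (elitism).  Deterministic for a given seed.
#'
#' @param x prefiltered descriptor table or matrix.
#' @param y response.
#' @param cfg a [ga_config()].
#' @return data frame "hall of fame" of the top (up to 10) unique subsets,
#'   columns `subset` (comma-joined descriptor names) and `fitness`,
#'   best first; attribute `"best"` holds the best subset as a character
#'   vector.
#' @export
ga_select <- function(x, y, cfg = ga_config()) {
  X <- .design_matrix(x)
  y <- as.numeric(y)
  p <- ncol(X); k <- cfg$subset_size
  if (k > p) stop(sprintf("subset_size %d exceeds available descriptors %d", k, p))
  sst <- sum((y - mean(y))^2)
  n <- nrow(X)
  eval_subset <- function(idx) {
    X1 <- cbind(1, X[, idx, drop = FALSE])
    qx <- qr(X1)
    if (qx$rank < ncol(X1)) return(-Inf)
    res <- y - X1 %*% qr.coef(qx, y)
    if (cfg$fitness == "r2") return(1 - sum(res^2) / sst)
    h <- rowSums(qr.Q(qx)^2)
    if (any(h >= 1 - 1e-12)) return(-Inf)
    1 - sum((res / (1 - h))^2) / sst
  }
  set.seed(cfg$seed)
  pop <- replicate(cfg$population, sort(sample.int(p, k)), simplify = FALSE)
  fit <- vapply(pop, eval_subset, 1)
  hof <- new.env()
  hof_n <- 0L
  note <- function(idx, f) {
    key <- paste(idx, collapse = ",")
    if (is.null(hof[[key]])) {
      hof_n <<- hof_n + 1L
      hof[[key]] <- c(f, hof_n)  # fitness + first-seen rank for tie-breaks
    }
  }
  mapply(note, pop, fit)
  if (cfg$generations > 0) for (gen in seq_len(cfg$generations)) {
    ord <- order(fit, decreasing = TRUE)
    newpop <- pop[ord[seq_len(min(cfg$elitism, length(pop)))]]
    while (length(newpop) < cfg$population) {
      tourn <- function() {
        cand <- sample.int(length(pop), cfg$tournament_size, replace = TRUE)
        pop[[cand[which.max(fit[cand])]]]
      }
      p1 <- tourn(); p2 <- tourn()
      child <- if (stats::runif(1) < cfg$crossover_rate) {
        pool <- union(p1, p2)
        core <- intersect(p1, p2)
        free <- setdiff(pool, core)
        need <- k - length(core)
        sort(c(core, if (need > 0) sample(free, min(need, length(free)))))
      } else p1
      if (length(child) < k)
        child <- sort(c(child, sample(setdiff(seq_len(p), child), k - length(child))))
      if (stats::runif(1) < cfg$mutation_rate) {
        out <- sample(child, 1)
        child <- sort(c(setdiff(child, out),
                        sample(setdiff(seq_len(p), child), 1)))
      }
      newpop[[length(newpop) + 1L]] <- child
    }
    pop <- newpop
    fit <- vapply(pop, eval_subset, 1)
    mapply(note, pop, fit)
  }
  keys <- ls(hof)
  scores <- vapply(keys, function(kk) hof[[kk]][1], 1)
  seen <- vapply(keys, function(kk) hof[[kk]][2], 1)
  ord <- order(-scores, seen)
  top <- utils::head(ord, 10)
  nm <- colnames(X)
  subsets <- lapply(keys[top], function(kk) nm[as.integer(strsplit(kk, ",")[[1]])])
  out <- data.frame(subset = vapply(subsets, paste, "", collapse = ","),
                    fitness = scores[top], stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "best") <- subsets[[1]]
  out
}
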