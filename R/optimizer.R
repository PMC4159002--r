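#' Parameters for the replication-rate optimizer
#'
#' An elitist, mutation-only genetic algorithm that maximizes the
#' replication-rate proxy of a genotype in the absence of any interaction
#' between genetically different individuals (a null model for what pure
#' replication-rate selection would produce).
#'
#' @param pop_size Population size (>= 2).
#' @param generations Number of generations.
#' @param mut_rate Per-base substitution probability for offspring.
#' @param crossover_prob Probability that an offspring is produced by
#'   one-point recombination of two tournament winners (it is mutated
#'   either way). Recombination matters here: tail composition and core
#'   fold are quasi-independent modules, and mutation-only hill climbs
#'   stall on fragile local optima.
#' @param tournament_k Tournament size for parent selection.
#' @param n_elite Number of elites copied unchanged each generation.
#' @param n_starts Independent restarts; the best final genotype by fitness
#'   is returned. The feasible set is rare enough in random sequence space
#'   that individual runs can fail to reach it.
#' @param local_search Finish with steepest-ascent over single
#'   substitutions until a 1-opt local maximum of the constrained fitness
#'   is reached.
#' @param constraint `"both_catalytic"` (both strands must fold into the
#'   catalytic structure) or `"single_catalytic"` (exactly one strand
#'   must). Feasible genotypes must additionally classify as units of
#'   replication — an optimized replicator must itself be replicable.
#'   Infeasible genotypes have fitness 0; tournaments break fitness ties
#'   by the number of constraint conditions met, so the search can climb
#'   onto the feasible set from a random start.
#' @param seq_length Sequence length.
#' @return An object of class `optimizer_params`.
#' @export
optimizer_params <- function(pop_size = 100, generations = 300,
                             mut_rate = 0.01, crossover_prob = 0.7,
                             tournament_k = 3, n_elite = 2, n_starts = 5,
                             local_search = TRUE,
                             constraint = c("both_catalytic",
                                            "single_catalytic"),
                             seq_length = 50) {
  constraint <- match.arg(constraint)
  if (pop_size < 2) stop("population size must be >= 2")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 mut_rate = mut_rate, crossover_prob = crossover_prob,
                 tournament_k = as.integer(tournament_k),
                 n_elite = as.integer(n_elite),
                 n_starts = as.integer(n_starts),
                 local_search = isTRUE(local_search),
                 constraint = constraint,
                 seq_length = as.integer(seq_length)),
            class = "optimizer_params")
}

opt_evaluate <- function(seqs, constraint, engine, params) {
  gt <- genotype_table(seqs, engine, params)
  # the feasible set is units of replication (viable genotypes with a
  # replicase strand) satisfying the structural constraint: a replicator
  # optimized for replication rate must itself be replicable
  cat_ok <- switch(constraint,
                   both_catalytic = gt$p_cat & gt$m_cat,
                   single_catalytic = (gt$p_cat & !gt$m_cat) |
                                      (gt$m_cat & !gt$p_cat))
  feasible <- cat_ok & gt$func_class == "unit"
  cat_deg <- switch(constraint,
                    both_catalytic = gt$p_cat + gt$m_cat,
                    single_catalytic = as.integer(gt$p_cat | gt$m_cat) -
                                       as.integer(gt$p_cat & gt$m_cat))
  degree <- cat_deg + gt$p_has3 + gt$m_has3
  proxy <- proxy_from_table(gt, params)
  data.frame(sequence = seqs, feasible = feasible, degree = degree,
             proxy = proxy, fitness = ifelse(feasible, proxy, 0),
             stringsAsFactors = FALSE)
}

#' Seed sequences with a catalytic strand
#'
#' Draws uniform random sequences and keeps those where either strand folds
#' into the catalytic structure. Useful as a starting population for
#' [optimize_replication()] under an MFE engine, where the doubly
#' constrained feasible set (both strands catalytic *and* a viable
#' genotype) is so rare in random sequence space that an unseeded search
#' may spend its whole budget before finding it.
#'
#' @param n Number of seeds wanted.
#' @param engine A [fold_engine()].
#' @param nu Sequence length.
#' @param max_draws Screening budget; an error is raised when exhausted
#'   (the fallback engine, for instance, folds essentially no random
#'   sequence into the catalytic shape).
#' @return Character vector of `n` sequences.
#' @export
catalytic_seeds <- function(n, engine = fold_engine("vienna"), nu = 50,
                            max_draws = 2e5) {
  picked <- character(0)
  drawn <- 0
  while (length(picked) < n && drawn < max_draws) {
    chunk <- min(4000, max_draws - drawn)
    cand <- random_rna(chunk, nu)
    drawn <- drawn + chunk
    hit <- is_catalytic(fold(engine, cand)) |
           is_catalytic(fold(engine, reverse_complement(cand)))
    picked <- c(picked, cand[hit])
  }
  if (length(picked) < n)
    stop("found only ", length(picked), " catalytic folds in ", drawn,
         " draws")
  picked[seq_len(n)]
}

#' Optimize replication rate by evolutionary search
#'
#' Runs the elitist GA of [optimizer_params()]: fitness is the
#' [replication_rate_proxy()] of feasible genotypes (0 otherwise), parents
#' are chosen by tournament, offspring are mutated copies, and the best
#' genotypes survive unchanged. The best-fitness trajectory is
#' non-decreasing.
#'
#' @param params An [optimizer_params()] object.
#' @param engine A [fold_engine()].
#' @param energy An [energy_params()] object.
#' @param init Optional starting population: a character vector (used for
#'   every restart) or a function `function(n) -> sequences` called once
#'   per restart (e.g. built on [catalytic_seeds()]). Default: fresh
#'   uniform random sequences per restart.
#' @param verbose Print progress every 25 generations?
#' @return An object of class `replication_opt`: `best_sequence`, `best`
#'   (its [genotype()]), `best_fitness`, `trajectory` (per-generation data
#'   frame with a `start` column), `params`.
#' @export
optimize_replication <- function(params = optimizer_params(),
                                 engine = fold_engine("nussinov"),
                                 energy = energy_params(), init = NULL,
                                 verbose = FALSE) {
  n <- params$pop_size
  rank_key <- function(e) order(e$fitness, e$degree, e$proxy,
                                decreasing = TRUE)
  ga_once <- function(start_id) {
    pop <- if (is.null(init)) random_rna(n, params$seq_length)
           else if (is.function(init)) rep_len(as.character(init(n)), n)
           else rep_len(as.character(init), n)
    ev <- opt_evaluate(pop, params$constraint, engine, energy)
    traj <- data.frame(start = start_id, generation = 0L,
                       best_fitness = max(ev$fitness),
                       mean_fitness = mean(ev$fitness),
                       n_feasible = sum(ev$feasible))
    for (gen in seq_len(params$generations)) {
      ord <- rank_key(ev)
      elite <- ev$sequence[ord[seq_len(params$n_elite)]]
      pick <- function() {
        cand <- sample.int(n, params$tournament_k, replace = TRUE)
        best <- cand[order(ev$fitness[cand], ev$degree[cand],
                           ev$proxy[cand], decreasing = TRUE)[1]]
        ev$sequence[best]
      }
      offspring <- vapply(seq_len(n - params$n_elite), function(i) {
        s <- strsplit(pick(), "")[[1]]
        if (runif(1) < params$crossover_prob) {
          s2 <- strsplit(pick(), "")[[1]]
          cut <- sample.int(length(s) - 1L, 1L)
          s <- c(s[seq_len(cut)], s2[(cut + 1L):length(s2)])
        }
        hit <- which(runif(length(s)) < params$mut_rate)
        for (j in hit)
          s[j] <- sample(setdiff(c("A", "C", "G", "U"), s[j]), 1L)
        paste(s, collapse = "")
      }, "")
      pop <- c(elite, offspring)
      ev <- opt_evaluate(pop, params$constraint, engine, energy)
      traj <- rbind(traj, data.frame(start = start_id, generation = gen,
                                     best_fitness = max(ev$fitness),
                                     mean_fitness = mean(ev$fitness),
                                     n_feasible = sum(ev$feasible)))
      if (verbose && gen %% 25L == 0L)
        message(sprintf("start %d gen %d  best %.4f  feasible %d/%d",
                        start_id, gen, max(ev$fitness), sum(ev$feasible), n))
    }
    top <- ev[rank_key(ev)[1], ]
    list(sequence = top$sequence, fitness = top$fitness, traj = traj)
  }
  runs <- lapply(seq_len(params$n_starts), ga_once)
  fits <- vapply(runs, function(r) r$fitness, numeric(1))
  best <- runs[[which.max(fits)]]
  best_seq <- best$sequence
  best_fit <- best$fitness
  if (params$local_search) {
    # steepest ascent over single substitutions to a 1-opt local maximum
    for (it in 1:50) {
      ev <- opt_evaluate(hd1_mutants(best_seq), params$constraint, engine,
                         energy)
      if (max(ev$fitness) <= best_fit + 1e-12) break
      i <- which.max(ev$fitness)
      best_seq <- ev$sequence[i]
      best_fit <- ev$fitness[i]
    }
  }
  structure(list(best_sequence = best_seq,
                 best = genotype(best_seq, engine, energy),
                 best_fitness = best_fit,
                 trajectory = do.call(rbind, lapply(runs, function(r) r$traj)),
                 params = params),
            class = "replication_opt")
}

#' @export
print.replication_opt <- function(x, ...) {
  cat("Replication-rate optimization (", x$params$constraint, ")\n", sep = "")
  cat("  best fitness:", format(x$best_fitness, digits = 4), "\n")
  cat("  best sequence:", x$best_sequence, "\n")
  invisible(x)
}
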