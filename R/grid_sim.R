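#' Simulation parameters for the spatial replicator model
#'
#' Defaults reproduce the reference setting: a 512 x 512 toroidal grid of
#' 50-nt molecules, replication rate `kappa = 1`, decay probability
#' `d = 0.03` per step, and a probability 0.1 that a complex does not
#' attempt to move.
#'
#' @param width,height Grid dimensions (toroidal).
#' @param seq_length Sequence length `nu` in nucleotides.
#' @param replication_rate Replication probability `kappa` per eligible
#'   complex per step.
#' @param decay_rate Decay probability `d` per molecule per step.
#' @param complex_no_move_prob Probability that a complex skips its
#'   diffusion attempt.
#' @param mu Per-base substitution probability (the global rate in
#'   `"constant"` mode, the founder rate otherwise).
#' @param mu_mode `"constant"`, `"evolve_positive"` (a Uniform(0, eps) draw
#'   is added to the offspring's rate whenever a replication event carried
#'   at least one substitution) or `"evolve_unbiased"` (Uniform(-eps, eps)).
#' @param mu_step Half-width `eps` of the mutation-rate step.
#' @param check_invariants Verify occupancy/complex invariants after every
#'   step (debug mode).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(width = 512, height = 512, seq_length = 50,
                       replication_rate = 1, decay_rate = 0.03,
                       complex_no_move_prob = 0.1, mu = 0.015,
                       mu_mode = c("constant", "evolve_positive",
                                   "evolve_unbiased"),
                       mu_step = 5e-4, check_invariants = FALSE) {
  mu_mode <- match.arg(mu_mode)
  probs <- c(replication_rate, decay_rate, complex_no_move_prob, mu, mu_step)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(width = as.integer(width), height = as.integer(height),
                 seq_length = as.integer(seq_length),
                 replication_rate = replication_rate,
                 decay_rate = decay_rate,
                 complex_no_move_prob = complex_no_move_prob,
                 mu = mu, mu_mode = mu_mode, mu_step = mu_step,
                 check_invariants = isTRUE(check_invariants)),
            class = "sim_params")
}

#' Create an empty world
#'
#' @param params A [sim_params()] object.
#' @param engine A [fold_engine()]; the `"nussinov"` fallback keeps runs
#'   engine-free and fully deterministic, `"vienna"` folds new sequences
#'   with `RNAfold` as they arise.
#' @param energy An [energy_params()] object.
#' @return An object of class `world`.
#' @export
world_new <- function(params = sim_params(), engine = fold_engine("nussinov"),
                      energy = energy_params()) {
  mu_mode <- match(params$mu_mode,
                   c("constant", "evolve_positive", "evolve_unbiased")) - 1L
  ptr <- cpp_world_new(params$width, params$height, params$replication_rate,
                       params$decay_rate, params$complex_no_move_prob,
                       params$mu, params$mu_step, mu_mode, energy$ep20,
                       params$check_invariants)
  if (engine$type != "nussinov") {
    cpp_world_engine(ptr, 1L, function(s) fold(engine, s))
  } else {
    cpp_world_engine(ptr, 0L, function(s) s)
  }
  structure(list(ptr = ptr, params = params, engine = engine,
                 energy = energy),
            class = "world")
}

#' @export
print.world <- function(x, ...) {
  info <- cpp_world_info(x$ptr)
  cnt <- world_counts(x)
  cat(sprintf("World %dx%d, step %d, %d molecules (%d in complex)\n",
              x$params$width, x$params$height, info$step, cnt[["total"]],
              cnt[["complexed"]]))
  print(cnt[func_classes()])
  invisible(x)
}

#' Seed molecules into a world
#'
#' Places copies of the given sequences on random empty cells of the chosen
#' region.
#'
#' @param world A [world_new()] object.
#' @param seqs Character vector of sequences; recycled to `n`.
#' @param n Number of molecules to place (default: one per sequence).
#' @param region `"all"`, `"left"` or `"right"` half of the grid.
#' @param mu0 Founder per-base mutation rate(s); default: the world's `mu`.
#' @return The world, invisibly.
#' @export
world_seed <- function(world, seqs, n = length(seqs), region = "all",
                       mu0 = NULL) {
  if (!length(seqs)) stop("empty population")
  seqs <- rep_len(as.character(seqs), n)
  check_rna(seqs)
  if (is.null(mu0)) mu0 <- world$params$mu
  mu0 <- rep_len(mu0, n)
  W <- world$params$width; H <- world$params$height
  cols <- switch(region,
                 all = 0:(W - 1),
                 left = 0:(W %/% 2 - 1),
                 right = (W %/% 2):(W - 1),
                 stop("unknown region"))
  cells <- as.vector(outer(cols, 0:(H - 1), function(x, y) y * W + x))
  st <- cpp_world_state(world$ptr)
  cells <- setdiff(cells, st$y * W + st$x)
  if (length(cells) < n) stop("not enough empty cells in region")
  take <- if (length(cells) == 1L) cells else sample(cells, n)
  cpp_world_place(world$ptr, seqs, as.integer(take), as.numeric(mu0))
  invisible(world)
}

#' Initialize a competition experiment
#'
#' Seeds the left half of the field with one population and the right half
#' with another, at the given per-cell density.
#'
#' @param world An empty [world_new()] object.
#' @param popA,popB Nonempty character vectors of sequences.
#' @param density Fraction of cells of each half to occupy.
#' @return The world, invisibly.
#' @export
init_competition <- function(world, popA, popB, density = 0.1) {
  if (!length(popA) || !length(popB)) stop("empty population")
  half <- (world$params$width %/% 2) * world$params$height
  nA <- max(1L, round(density * half))
  world_seed(world, popA, n = nA, region = "left")
  world_seed(world, popB, n = nA, region = "right")
  invisible(world)
}

#' Advance a world by Monte Carlo steps
#'
#' One step visits every cell in a fresh random permutation and runs, per
#' occupied cell: complex formation/dissociation, replication (with
#' mutation), one random-walk diffusion step, and decay.
#'
#' @param world A [world_new()] object.
#' @param steps Number of Monte Carlo steps.
#' @return The world, invisibly.
#' @export
world_step <- function(world, steps = 1L) {
  cpp_world_step(world$ptr, as.integer(steps))
  invisible(world)
}

#' Per-class molecule counts
#'
#' @param world A [world_new()] object.
#' @return Named integer vector: the six classes, `complexed`, `total`.
#' @export
world_counts <- function(world) {
  setNames(cpp_world_counts(world$ptr),
           c(func_classes(), "complexed", "total"))
}

#' All molecules currently in the field
#'
#' @param world A [world_new()] object.
#' @return A data frame with one row per molecule: sequence, coordinates,
#'   id/parent/birth (for ancestry), functional class, complex membership,
#'   per-molecule mutation rate.
#' @export
world_molecules <- function(world) {
  st <- cpp_world_state(world$ptr)
  data.frame(sequence = st$sequence, x = st$x, y = st$y, id = st$id,
             parent = st$parent, birth = st$birth,
             func_class = class_factor(st$class_code),
             partner_id = st$partner_id, mu = st$mu,
             presents5 = st$presents5, inert = st$inert,
             stringsAsFactors = FALSE)
}

#' Plain-text snapshot of the field
#'
#' One string per grid row; single-character class codes (U, P, H, S, J and
#' Y for hybrid) with `.` for empty cells.
#'
#' @param world A [world_new()] object.
#' @return Character vector of length `height`.
#' @export
world_snapshot <- function(world) {
  cpp_world_snapshot(world$ptr)
}

#' Histogram of Hamming distances to a reference
#'
#' Each molecule contributes the minimum of the Hamming distance of its
#' sequence to the reference and of its reverse complement to the
#' reference, split by functional class.
#'
#' @param world A [world_new()] object.
#' @param reference The reference (master) sequence.
#' @return A data frame with columns `hd`, `func_class`, `count`.
#' @export
hd_histogram <- function(world, reference) {
  mol <- world_molecules(world)
  if (!nrow(mol))
    return(data.frame(hd = integer(0), func_class = character(0),
                      count = integer(0)))
  hd <- as.integer(cpp_genotype_hd(mol$sequence, reference))
  agg <- aggregate(list(count = rep(1L, nrow(mol))),
                   by = list(hd = hd, func_class = mol$func_class), FUN = sum)
  agg[order(agg$hd, agg$func_class), , drop = FALSE]
}

#' Ancestry records of every molecule ever born
#'
#' @param world A [world_new()] object.
#' @return A data frame of birth events: `id`, `parent` (0 for founders),
#'   `birth` step. Edges `parent -> id` form the ancestor forest.
#' @export
world_ancestry <- function(world) {
  a <- cpp_world_ancestry(world$ptr)
  data.frame(id = a$id, parent = a$parent, birth = a$birth)
}

#' Exclude a functional class from the field
#'
#' Two knockout interventions: `"remove_class"` deletes molecules of the
#' target class (leaving empty space) at the end of every step, starting
#' now; `"class_to_junk"` makes them inert (their dangling ends are ignored
#' for binding, so they never enter complexes) while leaving them in place.
#'
#' @param world A [world_new()] object.
#' @param kind `"remove_class"` or `"class_to_junk"`.
#' @param target A class label from [func_classes()].
#' @return The world, invisibly.
#' @export
apply_intervention <- function(world, kind = c("remove_class",
                                               "class_to_junk"),
                               target) {
  kind <- match.arg(kind)
  code <- match(target, func_classes())
  if (is.na(code)) stop("unknown functional class: ", target)
  mask <- bitwShiftL(1L, code - 1L)
  if (kind == "remove_class") cpp_world_intervention(world$ptr, mask, 0L)
  else cpp_world_intervention(world$ptr, 0L, mask)
  invisible(world)
}

#' Run a world with periodic observers
#'
#' @param world A [world_new()] object.
#' @param steps Total number of Monte Carlo steps.
#' @param sample_every Observation interval in steps.
#' @param observers Named list of functions `function(world) -> data.frame`
#'   (or vector); the results are row-bound with a `step` column. The
#'   string `"abundance"` is shorthand for per-class counts.
#' @return A named list of data frames, one per observer.
#' @export
world_run <- function(world, steps, sample_every = steps,
                      observers = list(abundance = "abundance")) {
  observers <- lapply(observers, function(f) {
    if (identical(f, "abundance"))
      function(w) as.data.frame(as.list(world_counts(w)))
    else f
  })
  out <- lapply(observers, function(f) list())
  done <- 0L
  record <- function() {
    for (nm in names(observers)) {
      d <- observers[[nm]](world)
      if (NROW(d)) {
        d$step <- cpp_world_info(world$ptr)$step
        out[[nm]][[length(out[[nm]]) + 1L]] <<- d
      }
    }
  }
  record()
  while (done < steps) {
    k <- min(sample_every, steps - done)
    world_step(world, k)
    done <- done + k
    record()
  }
  lapply(out, function(l) if (length(l)) do.call(rbind, l) else data.frame())
}

#' Mutate-and-complement copy of a template
#'
#' The replication operator: the reverse complement of the template with
#' each base independently substituted with probability `mu`, uniformly
#' among the three alternatives.
#'
#' @param template The template sequence.
#' @param mu Per-base substitution probability.
#' @return The offspring sequence.
#' @export
mutate_copy <- function(template, mu) {
  check_rna(template)
  ch <- strsplit(reverse_complement(template), "")[[1]]
  hit <- runif(length(ch)) < mu
  nt <- c("A", "C", "G", "U")
  for (i in which(hit)) ch[i] <- sample(setdiff(nt, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Offspring mutation rate under evolvable mutation
#'
#' In `"evolve_positive"` mode a Uniform(0, eps) draw is added to the
#' parent rate; in `"evolve_unbiased"` mode a Uniform(-eps, eps) draw. The
#' result is clamped to `[0, 1]`. Callers apply this only to replication
#' events that carried at least one substitution.
#'
#' @param parent_mu Parent per-base mutation rate.
#' @param params A [sim_params()] object in an evolvable-`mu` mode.
#' @return The offspring mutation rate.
#' @export
evolve_mu <- function(parent_mu, params) {
  draw <- switch(params$mu_mode,
                 evolve_positive = runif(1, 0, params$mu_step),
                 evolve_unbiased = runif(1, -params$mu_step, params$mu_step),
                 stop("evolvable-mu mode is not enabled"))
  min(1, max(0, parent_mu + draw))
}
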