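#' All single-substitution mutants of a sequence
#'
#' @param seq An RNA sequence of length `nu`.
#' @param positions Positions to mutate (default: all).
#' @return Character vector of `3 * length(positions)` mutant sequences.
#' @export
hd1_mutants <- function(seq, positions = seq_len(nchar(seq))) {
  check_rna(seq)
  nt <- c("A", "C", "G", "U")
  ch <- strsplit(seq, "")[[1]]
  out <- character(0)
  for (i in positions) {
    for (a in setdiff(nt, ch[i])) {
      m <- ch
      m[i] <- a
      out <- c(out, paste(m, collapse = ""))
    }
  }
  out
}

canonical_strand <- function(seqs) {
  rc <- reverse_complement(seqs)
  ifelse(seqs <= rc, seqs, rc)
}

new_spectrum_result <- function(reference, table, lambdas, capped = FALSE) {
  structure(list(reference = reference, table = table,
                 lambdas = lambdas, capped = capped),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat("Mutational-neighborhood spectrum of\n  ", x$reference, "\n")
  print(x$table, digits = 3, row.names = FALSE)
  if (length(x$lambdas))
    cat("lambda:", paste(sprintf("%s=%.3f", names(x$lambdas), x$lambdas),
                         collapse = "  "), "\n")
  invisible(x)
}

spectrum_row <- function(hd, classes) {
  fr <- class_fractions(classes)
  cbind(data.frame(hd = hd, n = length(classes)),
        as.data.frame(as.list(fr)))
}

#' Hamming-distance-1 mutational spectrum
#'
#' Enumerates all `3 * nu` single-substitution mutants of the plus strand,
#' classifies each mutant as a genotype, and reports the functional-class
#' fractions. The neutrality `lambda_neutral` is the fraction of mutants
#' that remain units of replication.
#'
#' @param seq The reference sequence (plus strand).
#' @param engine A [fold_engine()].
#' @param params An [energy_params()] object.
#' @param positions Restrict mutation to these positions (used by
#'   [tails_only_spectrum()]).
#' @return A `spectrum_result` with a single HD = 1 row and the per-class
#'   lambda values.
#' @export
hd1_spectrum <- function(seq, engine = fold_engine("nussinov"),
                         params = energy_params(),
                         positions = seq_len(nchar(seq))) {
  muts <- hd1_mutants(seq, positions)
  gt <- genotype_table(muts, engine, params)
  fr <- class_fractions(gt$func_class)
  lam <- setNames(fr, paste0("lambda_", c("neutral", "P", "H", "S", "J",
                                          "hybrid")))
  new_spectrum_result(seq, spectrum_row(1L, gt$func_class), lam)
}

#' Tails-only mutational spectrum
#'
#' As [hd1_spectrum()], but mutating only the dangling-end positions of the
#' catalytic (replicase-capable) strand. Measures how much of the neutrality
#' is carried by the tails alone.
#'
#' @inheritParams hd1_spectrum
#' @return A `spectrum_result` over the `3 * k` tail mutants.
#' @export
tails_only_spectrum <- function(seq, engine = fold_engine("nussinov"),
                                params = energy_params()) {
  gt <- genotype_table(seq, engine, params)
  if (gt$p_has5 && gt$p_cat) {
    strand <- seq
  } else if (gt$m_has5 && gt$m_cat) {
    strand <- reverse_complement(seq)
    gt <- genotype_table(strand, engine, params)
  } else {
    stop("genotype has no replicase-capable (catalytic) strand")
  }
  n5 <- nchar(gt$p_tail5)
  n3 <- nchar(gt$p_tail3)
  if (n5 + n3 == 0L || n5 + n3 >= nchar(strand))
    stop("catalytic strand has no proper dangling ends to mutate")
  pos <- c(seq_len(n5), seq(nchar(strand) - n3 + 1L, length.out = n3))
  hd1_spectrum(strand, engine, params, positions = pos)
}

#' Replication-rate proxy of a genotype
#'
#' Scalar in `[0, 1]` summarizing how well a genotype self-replicates: for a
#' replicase-capable strand `c` with complement `t`, the mean of the
#' probabilities that `c` binds (via its 5' tail) its own 3' tail and the
#' complement's 3' tail. The maximum 1 requires both binding probabilities
#' to be 1. Genotypes with no replicase-capable strand score 0; with two,
#' the better strand counts (the proxy is invariant under strand swap).
#'
#' @param seq The plus-strand sequence (or a `genotype` object).
#' @param engine A [fold_engine()].
#' @param params An [energy_params()] object.
#' @return A rate in `[0, 1]`.
#' @export
replication_rate_proxy <- function(seq, engine = fold_engine("nussinov"),
                                   params = energy_params()) {
  if (inherits(seq, "genotype")) seq <- seq$plus$sequence
  gt <- genotype_table(seq, engine, params)
  proxy_from_table(gt, params)
}

# vectorized on a genotype_table
proxy_from_table <- function(gt, params) {
  p_side <- function(t5c, t3c, t3t) {
    0.5 * (binding_probability(gmin(t5c, t3c, params)) +
           binding_probability(gmin(t5c, t3t, params)))
  }
  plus_ok <- gt$p_has5 & gt$p_cat
  minus_ok <- gt$m_has5 & gt$m_cat
  pp <- ifelse(plus_ok, p_side(gt$p_tail5, gt$p_tail3, gt$m_tail3), 0)
  pm <- ifelse(minus_ok, p_side(gt$m_tail5, gt$m_tail3, gt$p_tail3), 0)
  pmax(pp, pm)
}

#' Screen random sequences for units of replication
#'
#' Draws `n` uniform random sequences of length `nu`, classifies each
#' genotype, and collects the units of replication together with summary
#' statistics: overall class tallies, the fraction of units with both
#' strands catalytic, and (optionally) the mean HD = 1 neutrality of the
#' units found.
#'
#' @param n Number of random sequences to draw.
#' @param nu Sequence length (default 50).
#' @param engine A [fold_engine()].
#' @param params An [energy_params()] object.
#' @param neutrality Compute each found unit's HD = 1 neutrality (costs
#'   `3 * nu` foldings per unit)?
#' @return An object of class `screen_result`: `units` (data frame of found
#'   units with proxies and neutralities), `class_counts`, `n`,
#'   `both_catalytic_fraction`, `mean_neutrality`.
#' @export
screen_random <- function(n, nu = 50, engine = fold_engine("nussinov"),
                          params = energy_params(), neutrality = TRUE) {
  if (n < 1) {
    return(structure(list(units = data.frame(), n = 0,
                          class_counts = setNames(integer(6), func_classes()),
                          both_catalytic_fraction = NaN,
                          mean_neutrality = NaN),
                     class = "screen_result"))
  }
  seqs <- random_rna(n, nu)
  gt <- genotype_table(seqs, engine, params)
  counts <- table(gt$func_class)
  units <- gt[gt$func_class == "unit", , drop = FALSE]
  lam <- rep(NA_real_, nrow(units))
  if (neutrality && nrow(units) > 0) {
    lam <- vapply(units$sequence, function(s) {
      unname(hd1_spectrum(s, engine, params)$lambdas["lambda_neutral"])
    }, numeric(1))
  }
  udf <- data.frame(sequence = units$sequence,
                    both_catalytic = units$p_cat & units$m_cat,
                    proxy = proxy_from_table(units, params),
                    neutrality = lam,
                    stringsAsFactors = FALSE)
  structure(list(units = udf, n = n,
                 class_counts = setNames(as.integer(counts), func_classes()),
                 both_catalytic_fraction =
                   if (nrow(udf)) mean(udf$both_catalytic) else NaN,
                 mean_neutrality =
                   if (nrow(udf)) mean(udf$neutrality) else NaN),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Random-sequence screen:", x$n, "sequences\n")
  print(x$class_counts)
  cat(sprintf("units found: %d  both-catalytic: %.3f  mean neutrality: %.3f\n",
              nrow(x$units), x$both_catalytic_fraction, x$mean_neutrality))
  invisible(x)
}

# mean/sd of HD=1 class fractions over a set of units, with optional
# subsampling to keep the per-layer cost bounded
layer_stats <- function(hd, seqs, engine, params, stats_cap) {
  n_found <- length(seqs)
  take <- seqs
  if (length(take) > stats_cap) take <- sample(take, stats_cap)
  fr <- t(vapply(take, function(s) {
    class_fractions(genotype_table(hd1_mutants(s), engine, params)$func_class)
  }, numeric(6)))
  mns <- colMeans(fr)
  sds <- if (nrow(fr) > 1) apply(fr, 2, sd) else rep(0, 6)
  cbind(data.frame(hd = hd, n = n_found, n_stats = length(take)),
        as.data.frame(as.list(setNames(mns, func_classes()))),
        as.data.frame(as.list(setNames(sds, paste0(func_classes(), "_sd")))))
}

expand_neutral <- function(master, max_hd, cap_found, engine, params,
                           core = TRUE, stats_cap = 200L) {
  gt0 <- genotype_table(master, engine, params)
  if (gt0$func_class != "unit")
    stop("the reference must be a unit of replication")
  rate0 <- proxy_from_table(gt0, params)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  assign(canonical_strand(master), TRUE, envir = seen)
  layer <- master
  tabs <- list(layer_stats(0L, master, engine, params, stats_cap))
  capped <- FALSE
  for (hd in seq_len(max_hd)) {
    cand <- unique(canonical_strand(unlist(lapply(layer, hd1_mutants))))
    cand <- cand[!vapply(cand, function(s) exists(s, envir = seen),
                         logical(1))]
    for (s in cand) assign(s, TRUE, envir = seen)
    if (!length(cand)) break
    gt <- genotype_table(cand, engine, params)
    keep <- gt$func_class == "unit"
    if (core) keep <- keep & proxy_from_table(gt, params) >= rate0
    found <- gt$sequence[keep]
    if (length(found) > cap_found) {
      found <- sample(found, cap_found)
      capped <- TRUE
    }
    if (!length(found)) break
    tabs[[length(tabs) + 1L]] <- layer_stats(hd, found, engine, params,
                                             stats_cap)
    layer <- found
  }
  new_spectrum_result(master, do.call(rbind, tabs), numeric(0), capped)
}

#' Expand the core-neutral network of a master sequence
#'
#' Breadth-first expansion over single substitutions, retaining only units
#' of replication whose replication-rate proxy is at least that of the
#' master ("core neutral" mutants). At each Hamming distance the mean and
#' standard deviation of the retained units' own HD = 1 class fractions are
#' recorded. Layers are randomly subsampled to `cap_found` units when larger.
#'
#' @param master The master (reference) sequence; must classify as a unit.
#' @param max_hd Largest Hamming distance to expand to.
#' @param cap_found Retention cap per layer (default `1e4`).
#' @param engine A [fold_engine()].
#' @param params An [energy_params()] object.
#' @param stats_cap At most this many units per layer enter the HD = 1
#'   fraction statistics (each unit costs `3 * nu` classifications).
#' @return A `spectrum_result` with one row per Hamming distance.
#' @export
expand_core_neutral <- function(master, max_hd = 4, cap_found = 1e4,
                                engine = fold_engine("nussinov"),
                                params = energy_params(), stats_cap = 200L) {
  expand_neutral(master, max_hd, cap_found, engine, params, core = TRUE,
                 stats_cap = stats_cap)
}

#' Expand the pseudo-neutral network of a master sequence
#'
#' As [expand_core_neutral()] but retaining every unit of replication,
#' regardless of replication rate.
#'
#' @inheritParams expand_core_neutral
#' @return A `spectrum_result` with one row per Hamming distance.
#' @export
expand_pseudo_neutral <- function(master, max_hd = 4, cap_found = 1e4,
                                  engine = fold_engine("nussinov"),
                                  params = energy_params(),
                                  stats_cap = 200L) {
  expand_neutral(master, max_hd, cap_found, engine, params, core = FALSE,
                 stats_cap = stats_cap)
}

random_mutant_at_hd <- function(seq, hd) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(ch), hd)
  nt <- c("A", "C", "G", "U")
  for (i in pos) ch[i] <- sample(setdiff(nt, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Sample units of replication at fixed Hamming distances
#'
#' For each Hamming distance `h` in `hd_range`, draws uniform random mutants
#' of the master at exactly distance `h` (positions without replacement,
#' substitutions uniform over the three alternatives) and retains those that
#' classify as units of replication. Sampling at a distance stops when
#' `cap_found` units have been retained or `cap_tries` consecutive draws
#' yield no new unit, after which the search moves to the next distance.
#'
#' @param master The reference sequence.
#' @param hd_range Hamming distances to sample (default `1:10`).
#' @param cap_found Per-distance retention cap (default `1e4`).
#' @param cap_tries Per-distance cap on fruitless draws (default `1e5`).
#' @param chunk Number of mutants classified per batch.
#' @inheritParams expand_core_neutral
#' @return A `spectrum_result` with one row per sampled distance.
#' @export
sample_at_hd <- function(master, hd_range = 1:10, cap_found = 1e4,
                         cap_tries = 1e5, engine = fold_engine("nussinov"),
                         params = energy_params(), stats_cap = 200L,
                         chunk = 500L) {
  tabs <- list()
  for (hd in hd_range) {
    found <- character(0)
    fruitless <- 0
    while (length(found) < cap_found && fruitless < cap_tries) {
      m <- vapply(seq_len(chunk), function(i) random_mutant_at_hd(master, hd),
                  "")
      gt <- genotype_table(m, engine, params)
      hits <- unique(gt$sequence[gt$func_class == "unit"])
      hits <- setdiff(hits, found)
      if (length(hits)) {
        found <- c(found, hits)
        fruitless <- 0
      } else {
        fruitless <- fruitless + chunk
      }
    }
    if (length(found) > cap_found) found <- found[seq_len(cap_found)]
    if (length(found))
      tabs[[length(tabs) + 1L]] <- layer_stats(hd, found, engine, params,
                                               stats_cap)
  }
  tab <- if (length(tabs)) do.call(rbind, tabs) else
    cbind(data.frame(hd = integer(0), n = integer(0), n_stats = integer(0)))
  new_spectrum_result(master, tab, numeric(0))
}

#' Consensus and master sequence of a population
#'
#' Strands are aligned to a common orientation (each sequence or its reverse
#' complement, whichever is closer to the running plurality), then the
#' per-position plurality consensus and the modal (most abundant) sequence
#' are reported. Ties break lexicographically.
#'
#' @param population Character vector of equal-length sequences.
#' @param iterations Orientation refinement passes.
#' @return A list with elements `consensus` and `master`.
#' @export
consensus_and_master <- function(population, iterations = 3L) {
  if (!length(population)) stop("empty population")
  check_rna(population)
  canon <- canonical_strand(population)
  tab <- sort(table(canon), decreasing = TRUE)
  ref <- names(tab)[tab == max(tab)]
  ref <- sort(ref)[1]  # lexicographic tie-break
  rc <- reverse_complement(population)
  oriented <- population
  for (it in seq_len(iterations)) {
    d_plus <- cpp_hamming(population, rep(ref, length(population)))
    d_minus <- cpp_hamming(rc, rep(ref, length(population)))
    oriented <- ifelse(d_plus <= d_minus, population, rc)
    mat <- do.call(rbind, strsplit(oriented, ""))
    cons <- apply(mat, 2, function(col) {
      t <- sort(table(col), decreasing = TRUE)
      sort(names(t)[t == max(t)])[1]
    })
    newref <- paste(cons, collapse = "")
    if (identical(newref, ref)) break
    ref <- newref
  }
  tab2 <- sort(table(oriented), decreasing = TRUE)
  master <- sort(names(tab2)[tab2 == max(tab2)])[1]
  list(consensus = ref, master = master)
}

#' Quasispecies network of units of replication
#'
#' Builds the graph whose nodes are units of replication and whose edges
#' connect pairs at genotype Hamming distance 1 (minimum over strand
#' pairings). Nodes are annotated with the Hamming distance to the master,
#' abundance, the replication-rate proxy, a core-neutral flag (proxy at
#' least the master's), and optionally their own HD = 1 class fractions.
#'
#' @param units Character vector of unit-of-replication sequences.
#' @param master The master sequence.
#' @param abundances Optional abundance per unit (default 1).
#' @param engine A [fold_engine()].
#' @param params An [energy_params()] object.
#' @param neighborhood Compute each node's HD = 1 class fractions?
#' @return A list of class `quasispecies_network`: `graph` (igraph),
#'   `nodes`, `edges` (data frames).
#' @export
build_network <- function(units, master, abundances = NULL,
                          engine = fold_engine("nussinov"),
                          params = energy_params(), neighborhood = FALSE) {
  units <- as.character(units)
  if (is.null(abundances)) abundances <- rep(1, length(units))
  stopifnot(length(abundances) == length(units))
  gt <- genotype_table(units, engine, params)
  if (any(gt$func_class != "unit"))
    stop("all node sequences must classify as units of replication")
  proxy <- proxy_from_table(gt, params)
  proxy0 <- replication_rate_proxy(master, engine, params)
  nodes <- data.frame(sequence = units,
                      hd_to_master = as.integer(cpp_genotype_hd(units, master)),
                      abundance = abundances,
                      proxy = proxy,
                      core_neutral = proxy >= proxy0,
                      stringsAsFactors = FALSE)
  if (neighborhood) {
    fr <- t(vapply(units, function(s) {
      class_fractions(genotype_table(hd1_mutants(s), engine, params)$func_class)
    }, numeric(6)))
    colnames(fr) <- paste0("hd1_", func_classes())
    nodes <- cbind(nodes, as.data.frame(fr, row.names = NULL))
  }
  em <- cpp_hd1_edges(units)
  edges <- data.frame(from = em[, 1], to = em[, 2])
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else data.frame(from = integer(0), to = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(units), nodes))
  structure(list(graph = g, nodes = nodes, edges = edges),
            class = "quasispecies_network")
}

#' @export
print.quasispecies_network <- function(x, ...) {
  cat("Quasispecies network:", nrow(x$nodes), "units,",
      nrow(x$edges), "HD=1 edges\n")
  invisible(x)
}
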