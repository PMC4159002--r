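#' Hybridization energy parameters
#'
#' Base-pair contributions for the ungapped sliding-alignment energy score
#' used for complex formation between dangling ends, and the threshold below
#' which a dangling end is recognized as present. Energies are dimensionless
#' and must be multiples of 0.05: the package compares scores against
#' thresholds exactly, on an integer grid of twentieths, so that a score of
#' exactly -0.75 satisfies `G <= -0.75` without floating-point surprises.
#'
#' @param gc,au,gu Contributions of G-C, A-U and G-U pairs (all `<= 0`).
#' @param other Contribution of any other base combination (default 0).
#' @param tail_threshold A dangling end is counted as present when the score
#'   of the tail against its own reverse complement is `<= tail_threshold`.
#' @return An object of class `energy_params`.
#' @examples
#' ep <- energy_params()
#' pair_contribution("G", "C", ep)
#' @export
energy_params <- function(gc = -0.15, au = -0.10, gu = -0.05, other = 0,
                          tail_threshold = -0.75) {
  vals <- c(gc = gc, au = au, gu = gu, other = other,
            tail_threshold = tail_threshold)
  if (any(vals[1:4] > 0))
    stop("pair contributions must be <= 0")
  if (tail_threshold >= 0)
    stop("tail_threshold must be negative")
  v20 <- vals * 20
  if (any(abs(v20 - round(v20)) > 1e-9))
    stop("energies must be multiples of 0.05")
  structure(list(gc = gc, au = au, gu = gu, other = other,
                 tail_threshold = tail_threshold,
                 ep20 = round(v20)),
            class = "energy_params")
}

#' @export
print.energy_params <- function(x, ...) {
  cat("Hybridization energy parameters\n")
  cat(sprintf("  G-C %.2f  A-U %.2f  G-U %.2f  other %.2f\n",
              x$gc, x$au, x$gu, x$other))
  cat(sprintf("  dangling-end threshold: G <= %.2f\n", x$tail_threshold))
  invisible(x)
}

check_rna <- function(x) {
  bad <- grepl("[^ACGU]", x)
  if (any(bad))
    stop("sequence contains non-RNA symbols (alphabet is A, C, G, U): ",
         x[bad][1])
  invisible(x)
}

#' Contribution of a single base pair
#'
#' Symmetric in its arguments; canonical (G-C, A-U) and wobble (G-U) pairs
#' return their configured contributions, everything else `other`.
#'
#' @param b1,b2 Single nucleotides (A, C, G or U). Vectorized.
#' @param params An [energy_params()] object.
#' @return Numeric vector of contributions.
#' @export
pair_contribution <- function(b1, b2, params = energy_params()) {
  check_rna(b1); check_rna(b2)
  if (any(nchar(b1) != 1L) || any(nchar(b2) != 1L))
    stop("b1 and b2 must be single nucleotides")
  key <- paste0(pmin(b1, b2), pmax(b1, b2))
  out <- rep(params$other, length(key))
  out[key == "CG"] <- params$gc
  out[key == "AU"] <- params$au
  out[key == "GU"] <- params$gu
  out
}

#' Minimum hybridization score of two dangling ends
#'
#' Slides one tail along the other (no gaps) and returns the minimum total
#' base-pair contribution over all offsets. Both tails are given 5'->3'; they
#' are paired antiparallel, so position `i` of the 5' tail meets position
#' `length(tail3) - 1 - i - offset` of the 3' tail. Empty tails, or tails
#' with no negatively scoring offset, give 0.
#'
#' @param tail5,tail3 Character vectors of tail sequences (may be empty
#'   strings); recycled to a common length.
#' @param params An [energy_params()] object.
#' @return Numeric vector of scores (always `<= 0`).
#' @examples
#' gmin("CCCCC", "GGGGG")   # five G-C pairs: -0.75
#' @export
gmin <- function(tail5, tail3, params = energy_params()) {
  n <- max(length(tail5), length(tail3))
  tail5 <- rep_len(as.character(tail5), n)
  tail3 <- rep_len(as.character(tail3), n)
  cpp_gmin(tail5, tail3, params$ep20) / 20
}

#' Probability of complex formation from a hybridization score
#'
#' `P = 1 - exp(G)` for a score `G <= 0`.
#'
#' @param g Numeric vector of scores; positive values are an error.
#' @return Probabilities in `[0, 1)`.
#' @export
binding_probability <- function(g) {
  if (any(g > 0)) stop("hybridization scores must be <= 0")
  1 - exp(g)
}

#' Association and dissociation probabilities for a molecule pair
#'
#' Two molecules X and Y can bind in two configurations: X presenting its 5'
#' tail against Y's 3' tail, or the reverse. Both binding probabilities are
#' computed; if their sum exceeds 1 they are normalized to association
#' probabilities `k1`, and dissociation is `k2 = 1 - k1` for the realized
#' configuration.
#'
#' @param x5,x3 X's 5' and 3' dangling-end sequences.
#' @param y5,y3 Y's 5' and 3' dangling-end sequences.
#' @param params An [energy_params()] object.
#' @return A list of class `binding_result` with elements `g_xy`, `g_yx`,
#'   `p_xy`, `p_yx`, `k1_xy`, `k1_yx`, `k2_xy`, `k2_yx`.
#' @export
complex_rates <- function(x5, x3, y5, y3, params = energy_params()) {
  g_xy <- gmin(x5, y3, params)
  g_yx <- gmin(y5, x3, params)
  p_xy <- binding_probability(g_xy)
  p_yx <- binding_probability(g_yx)
  tot <- p_xy + p_yx
  norm <- tot > 1
  k1_xy <- ifelse(norm, p_xy / tot, p_xy)
  k1_yx <- ifelse(norm, p_yx / tot, p_yx)
  structure(list(g_xy = g_xy, g_yx = g_yx, p_xy = p_xy, p_yx = p_yx,
                 k1_xy = k1_xy, k1_yx = k1_yx,
                 k2_xy = 1 - k1_xy, k2_yx = 1 - k1_yx),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat("Complex formation probabilities\n")
  cat(sprintf("  X.Y: G = %.2f  P = %.4f  k1 = %.4f  k2 = %.4f\n",
              x$g_xy[1], x$p_xy[1], x$k1_xy[1], x$k2_xy[1]))
  cat(sprintf("  Y.X: G = %.2f  P = %.4f  k1 = %.4f  k2 = %.4f\n",
              x$g_yx[1], x$p_yx[1], x$k1_yx[1], x$k2_yx[1]))
  invisible(x)
}

#' Is a dangling end effectively present?
#'
#' A tail counts as a dangling end when the hybridization score of the tail
#' against its own reverse complement reaches the configured threshold
#' (default `G <= -0.75`, binding probability about one half).
#'
#' @param tail Character vector of tail sequences (empty string allowed).
#' @param params An [energy_params()] object.
#' @return Logical vector.
#' @examples
#' tail_present("GGGGG")    # TRUE:  5 G-C pairs reach -0.75
#' tail_present("AAAAAAA")  # FALSE: 7 A-U pairs give -0.70
#' @export
tail_present <- function(tail, params = energy_params()) {
  cpp_tail_present(as.character(tail), params$ep20)
}
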