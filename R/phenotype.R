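#' Functional class labels
#'
#' The six functional classes a genotype (a strand plus its reverse
#' complement) can fall into, in the package's fixed order.
#'
#' @return Character vector of class labels.
#' @export
func_classes <- function() {
  c("unit", "parasite", "helper", "staller", "junk", "hybrid")
}

class_factor <- function(codes) {
  factor(func_classes()[codes + 1L], levels = func_classes())
}

#' Reverse complement of an RNA sequence
#'
#' Watson-Crick complement (A-U, G-C), reversed (antiparallel orientation).
#'
#' @param seq Character vector of RNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GGC")  # "GCC"
#' @export
reverse_complement <- function(seq) {
  cpp_revcomp(as.character(seq))
}

#' Classify a 6-bit phenotype
#'
#' The phenotype of a genotype is coarse-grained to 6 bits: for each strand,
#' presence of a 5' dangling end, the catalytic fold, and a 3' dangling end.
#' A genotype is viable (replicable) iff both strands have 3' tails. Per
#' strand, the role is replicase-capable (5' tail and catalytic fold),
#' staller-like (5' tail, not catalytic) or inert (no 5' tail). The class is
#' then:
#'
#' * `unit`: viable with at least one replicase-capable strand;
#' * `parasite`: viable with none;
#' * `helper`: nonviable, a replicase strand, no staller-like strand;
#' * `staller`: nonviable, a staller-like strand, no replicase strand;
#' * `hybrid`: nonviable with one of each;
#' * `junk`: nonviable with no 5' tail on either strand.
#'
#' The map is total over all 64 bit vectors and symmetric in the strands.
#'
#' @param bits A logical vector of length 6 (`plus.has5, plus.catalytic,
#'   plus.has3, minus.has5, minus.catalytic, minus.has3`) or a 6-column
#'   logical matrix with one row per genotype.
#' @return A factor with levels [func_classes()].
#' @export
classify <- function(bits) {
  if (is.matrix(bits)) {
    stopifnot(ncol(bits) == 6L)
  } else {
    stopifnot(length(bits) == 6L)
    bits <- matrix(as.logical(bits), nrow = 1L)
  }
  class_factor(cpp_classify_bits(bits))
}

#' Per-strand functional role
#'
#' Used for field statistics, where the two strands of a hybrid genotype can
#' be told apart and assigned to the helper or staller pool.
#'
#' @param profile A [strand_profile()] (or any list with `has5` and
#'   `catalytic` fields).
#' @return One of `"replicase_like"`, `"staller_like"`, `"inert"`.
#' @export
strand_class <- function(profile) {
  if (!profile$has5) return("inert")
  if (profile$catalytic) "replicase_like" else "staller_like"
}

#' Build a genotype from a strand sequence
#'
#' A genotype is an unordered pair: a strand and its reverse complement.
#' Both strands are profiled, the 6 phenotype bits are assembled and the
#' functional class determined. `genotype(s)` and
#' `genotype(reverse_complement(s))` have the same class.
#'
#' @param seq An RNA sequence (the plus strand).
#' @param engine A [fold_engine()].
#' @param params An [energy_params()] object.
#' @return An object of class `genotype` with fields `plus`, `minus`
#'   (strand profiles), `bits` (named logical 6-vector) and `func_class`.
#' @export
genotype <- function(seq, engine = fold_engine("nussinov"),
                     params = energy_params()) {
  stopifnot(length(seq) == 1L)
  plus <- strand_profile(seq, engine, params)
  minus <- strand_profile(reverse_complement(seq), engine, params)
  bits <- c(plus.has5 = plus$has5, plus.catalytic = plus$catalytic,
            plus.has3 = plus$has3, minus.has5 = minus$has5,
            minus.catalytic = minus$catalytic, minus.has3 = minus$has3)
  structure(list(plus = plus, minus = minus, bits = bits,
                 func_class = classify(unname(bits))),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat("Genotype:", as.character(x$func_class), "\n")
  cat(sprintf("  + %s  [5' %d  cat %d  3' %d]\n", x$plus$sequence,
              x$bits[1], x$bits[2], x$bits[3]))
  cat(sprintf("  - %s  [5' %d  cat %d  3' %d]\n", x$minus$sequence,
              x$bits[4], x$bits[5], x$bits[6]))
  invisible(x)
}

# vectorized classification: one row per sequence, fold-cached via engine
genotype_table <- function(seqs, engine, params) {
  seqs <- as.character(seqs)
  rc <- reverse_complement(seqs)
  plus <- strand_table(seqs, engine, params)
  minus <- strand_table(rc, engine, params)
  bits <- cbind(plus$has5, plus$catalytic, plus$has3,
                minus$has5, minus$catalytic, minus$has3)
  data.frame(sequence = seqs,
             func_class = class_factor(cpp_classify_bits(bits)),
             p_has5 = plus$has5, p_cat = plus$catalytic, p_has3 = plus$has3,
             m_has5 = minus$has5, m_cat = minus$catalytic, m_has3 = minus$has3,
             p_tail5 = plus$tail5, p_tail3 = plus$tail3,
             m_tail5 = minus$tail5, m_tail3 = minus$tail3,
             stringsAsFactors = FALSE)
}

#' Functional class fractions of a set of genotypes
#'
#' @param x A factor/character vector of class labels, a list of
#'   [genotype()] objects, or a data frame with a `func_class` column.
#' @return Named numeric vector over the six classes, summing to 1.
#' @export
class_fractions <- function(x) {
  if (is.data.frame(x)) x <- x$func_class
  if (is.list(x)) x <- vapply(x, function(g) as.character(g$func_class), "")
  if (length(x) == 0L) stop("empty input")
  x <- factor(as.character(x), levels = func_classes())
  if (anyNA(x)) stop("unknown class label")
  tab <- table(x)
  fr <- as.numeric(tab) / sum(tab)
  names(fr) <- func_classes()
  fr
}
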