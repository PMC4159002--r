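#' The coarse catalytic target structure
#'
#' A sequence is catalytic when its minimum-free-energy structure
#' coarse-grains to a multiloop connecting a stem to two hairpins.
#'
#' @return The target coarse structure string.
#' @export
catalytic_structure <- function() "((((H)S)((H)S)M)S)"

#' Folding engines
#'
#' A fold engine maps RNA sequences to minimum-free-energy dot-bracket
#' structures. Three engine types are available:
#'
#' * `"vienna"`: shells out to the `RNAfold` program. By default it uses the
#'   Turner-1999 energy parameters with dangling-end model `-d1` (the
#'   classic configuration of the Vienna 1.x era); pass `param_file = NA`
#'   and/or `dangles = 2` for the modern defaults. Structure fractions
#'   reported in the literature for this kind of screen are known to depend
#'   on the folding engine version and configuration.
#' * `"nussinov"`: a deterministic, engine-free fallback built into the
#'   package (base-pair maximization, minimum hairpin size 3, leftmost-pair
#'   tie-breaking). Fast and platform-independent; used throughout the test
#'   suite. Not thermodynamic.
#' * `"custom"`: any function `function(seqs) -> dot-bracket strings`,
#'   useful for mocking phenotypes in tests.
#'
#' Engines cache folds by sequence: a given sequence is folded at most once
#' per engine object.
#'
#' @param type Engine type.
#' @param fold_fun For `type = "custom"`: a vectorized fold function.
#' @param param_file For `type = "vienna"`: path to an energy parameter
#'   file, `NULL` to auto-locate the Turner-1999 set next to the `RNAfold`
#'   binary, or `NA` to use `RNAfold`'s built-in defaults.
#' @param dangles For `type = "vienna"`: dangling-end model (0, 1, 2 or 3).
#' @return An object of class `fold_engine`.
#' @examples
#' eng <- fold_engine("nussinov")
#' fold(eng, "GGGAAACCC")
#' @export
fold_engine <- function(type = c("nussinov", "vienna", "custom"),
                        fold_fun = NULL, param_file = NULL, dangles = 1) {
  type <- match.arg(type)
  eng <- new.env(parent = emptyenv())
  eng$type <- type
  eng$cache <- new.env(parent = emptyenv(), hash = TRUE)
  eng$fold_calls <- 0L
  if (type == "custom") {
    if (!is.function(fold_fun)) stop("custom engine needs a fold function")
    eng$fold_fun <- fold_fun
    eng$id <- "custom"
  } else if (type == "vienna") {
    bin <- Sys.which("RNAfold")
    if (!nzchar(bin)) stop("RNAfold not found on PATH")
    if (is.null(param_file)) {
      param_file <- file.path(dirname(dirname(bin)), "share", "ViennaRNA",
                              "rna_turner1999.par")
      if (!file.exists(param_file)) param_file <- NA
    }
    eng$bin <- bin
    eng$param_file <- param_file
    eng$dangles <- dangles
    ver <- tryCatch(system2(bin, "--version", stdout = TRUE)[1],
                    error = function(e) "RNAfold")
    eng$id <- paste0(ver, " (params: ",
                     if (is.na(param_file)) "default" else basename(param_file),
                     ", dangles ", dangles, ")")
  } else {
    eng$id <- "nussinov fallback (base-pair maximization, hairpin >= 3)"
  }
  class(eng) <- "fold_engine"
  eng
}

#' @export
print.fold_engine <- function(x, ...) {
  cat("Fold engine:", x$id, "\n")
  cat("  cached structures:", length(ls(x$cache)),
      " fold calls:", x$fold_calls, "\n")
  invisible(x)
}

vienna_fold_many <- function(eng, seqs) {
  fin <- tempfile("rnafold_in_"); fout <- tempfile("rnafold_out_")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(seqs, fin)
  args <- c("--noPS", paste0("-d", eng$dangles))
  if (!is.na(eng$param_file))
    args <- c(args, paste0("--paramFile=", eng$param_file))
  status <- system2(eng$bin, args, stdout = fout, stdin = fin)
  if (status != 0) stop("RNAfold failed with status ", status)
  out <- readLines(fout)
  if (length(out) != 2L * length(seqs)) stop("unexpected RNAfold output")
  db <- sub(" .*$", "", out[seq(2L, length(out), by = 2L)])
  db
}

#' Fold sequences to dot-bracket structures
#'
#' @param engine A [fold_engine()].
#' @param seqs Character vector of RNA sequences.
#' @return Character vector of dot-bracket structures, one per sequence.
#' @export
fold <- function(engine, seqs) {
  seqs <- as.character(seqs)
  check_rna(seqs)
  out <- character(length(seqs))
  uniq <- unique(seqs)
  hit <- vapply(uniq, function(s) exists(s, envir = engine$cache), logical(1))
  todo <- uniq[!hit]
  if (length(todo)) {
    engine$fold_calls <- engine$fold_calls + length(todo)
    db <- switch(engine$type,
                 nussinov = cpp_nussinov(todo),
                 vienna = vienna_fold_many(engine, todo),
                 custom = as.character(engine$fold_fun(todo)))
    if (length(db) != length(todo) || any(nchar(db) != nchar(todo)))
      stop("fold engine returned structures of the wrong length")
    for (i in seq_along(todo)) assign(todo[i], db[i], envir = engine$cache)
  }
  for (i in seq_along(seqs)) out[i] <- get(seqs[i], envir = engine$cache)
  out
}

#' Coarse-grained (Shapiro-style) structure
#'
#' Collapses a dot-bracket structure to its loop tree with node labels
#' H (hairpin), S (maximal stem), B (bulge), I (interior loop) and
#' M (multiloop). Stems interrupted by bulges or interior loops are split;
#' exterior unpaired regions are excluded and no exterior node is emitted.
#'
#' @param dotbracket Character vector of balanced dot-bracket strings.
#' @return Character vector of coarse structure strings (the open chain
#'   gives the empty string).
#' @examples
#' coarse_shapiro("((((...)).((...))))")  # the catalytic target
#' @export
coarse_shapiro <- function(dotbracket) {
  cpp_coarse_shapiro(as.character(dotbracket))
}

#' Does a structure qualify as catalytic?
#'
#' TRUE iff the coarse structure equals [catalytic_structure()] exactly;
#' exterior dangling regions are ignored, but any bulge or interior loop in
#' the core disqualifies.
#'
#' @param dotbracket Character vector of dot-bracket strings.
#' @return Logical vector.
#' @export
is_catalytic <- function(dotbracket) {
  coarse_shapiro(dotbracket) == catalytic_structure()
}

#' Structural profile of a single strand
#'
#' Folds the sequence, extracts the maximal unpaired prefix and suffix of
#' the structure as the 5' and 3' dangling ends (an open chain counts, whole,
#' as both), tests each tail for effective presence, and tests the fold for
#' catalytic activity.
#'
#' @param seq An RNA sequence.
#' @param engine A [fold_engine()].
#' @param params An [energy_params()] object.
#' @return An object of class `strand_profile` with fields `sequence`,
#'   `dotbracket`, `coarse`, `tail5`, `tail3`, `has5`, `has3`, `catalytic`.
#' @export
strand_profile <- function(seq, engine = fold_engine("nussinov"),
                           params = energy_params()) {
  stopifnot(length(seq) == 1L)
  tab <- strand_table(seq, engine, params)
  structure(c(as.list(tab[1, ]), list(coarse = coarse_shapiro(tab$dotbracket[1]))),
            class = "strand_profile")
}

# vectorized internal workhorse: one row per sequence
strand_table <- function(seqs, engine, params) {
  db <- fold(engine, seqs)
  info <- cpp_strand_info(seqs, db, params$ep20)
  data.frame(sequence = seqs, dotbracket = db,
             tail5 = info$tail5, tail3 = info$tail3,
             has5 = info$has5, has3 = info$has3,
             catalytic = info$catalytic,
             stringsAsFactors = FALSE)
}

#' @export
print.strand_profile <- function(x, ...) {
  cat("Strand profile\n")
  cat(" ", x$sequence, "\n ", x$dotbracket, "\n")
  cat("  coarse:", if (nzchar(x$coarse)) x$coarse else "(open chain)", "\n")
  cat(sprintf("  5' tail: %-15s present: %s\n",
              sprintf("'%s'", x$tail5), x$has5))
  cat(sprintf("  3' tail: %-15s present: %s\n",
              sprintf("'%s'", x$tail3), x$has3))
  cat("  catalytic:", x$catalytic, "\n")
  invisible(x)
}
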