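#' Uniform random RNA sequences
#'
#' @param n Number of sequences.
#' @param len Sequence length.
#' @return Character vector of sequences over A, C, G, U.
#' @export
random_rna <- function(n, len = 50) {
  if (n < 1) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "U"), n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Read RNA sequences from a FASTA file
#'
#' DNA-alphabet input (T) is transparently mapped to U with a warning.
#'
#' @param path FASTA file path.
#' @return A data frame with columns `id` and `sequence` (zero rows for an
#'   empty file).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(id = character(0), sequence = character(0)))
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("malformed FASTA: line 1 does not start with '>'")
  grp <- cumsum(hdr)
  ids <- sub("^>", "", trimws(lines[hdr]))
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  seqs <- toupper(seqs)
  if (length(seqs) != length(ids)) stop("malformed FASTA: record with no sequence")
  if (any(grepl("T", seqs, fixed = TRUE))) {
    warning("DNA alphabet detected; mapping T to U")
    seqs <- gsub("T", "U", seqs, fixed = TRUE)
  }
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    rec <- which(bad)[1]
    stop(sprintf("malformed FASTA record %d ('%s'): non-RNA symbols", rec,
                 ids[rec]))
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write RNA sequences to a FASTA file
#'
#' @param records A data frame with columns `id` and `sequence`, or a
#'   (possibly named) character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids)) ids <- sprintf("seq%d", seq_along(records))
    records <- data.frame(id = ids, sequence = unname(records))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records)))
    writeLines(c(paste0(">", records$id[i]), records$sequence[i]), con)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML with optional sections `sim`, `energy`, `fold`, `optimizer`, `seed`.
#' Each section holds arguments for the corresponding constructor
#' ([sim_params()], [energy_params()], [fold_engine()],
#' [optimizer_params()]).
#'
#' @param path YAML file path.
#' @return A list with elements `sim`, `energy`, `fold`, `optimizer`
#'   (constructed objects) and `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, as.list(args))
  list(sim = build(sim_params, cfg$sim),
       energy = build(energy_params, cfg$energy),
       fold = build(fold_engine, cfg$fold),
       optimizer = build(optimizer_params, cfg$optimizer),
       seed = if (is.null(cfg$seed)) NULL else as.integer(cfg$seed))
}

#' Generate reproducible fixture files
#'
#' * `"random_sequences"`: `n` uniform random sequences.
#' * `"random_units"`: sequences screened from random draws until `n` units
#'   of replication are found (or `max_draws` is exhausted), with a TSV of
#'   screen statistics.
#' * `"toy_world"`: a small seeded world run briefly, dumped as a class-code
#'   snapshot plus a per-molecule TSV.
#'
#' @param kind Fixture kind.
#' @param n Number of records.
#' @param dir Output directory.
#' @param engine A [fold_engine()].
#' @param params An [energy_params()] object.
#' @param nu Sequence length.
#' @param max_draws Screening budget for `"random_units"`.
#' @return Character vector of the files written.
#' @export
generate_fixtures <- function(kind = c("random_sequences", "random_units",
                                       "toy_world"),
                              n = 10, dir = tempdir(),
                              engine = fold_engine("nussinov"),
                              params = energy_params(), nu = 50,
                              max_draws = 2e5) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "random_sequences") {
    f <- file.path(dir, "random_sequences.fasta")
    write_fasta(setNames(random_rna(n, nu), sprintf("rand%d", seq_len(n))), f)
    return(f)
  }
  if (kind == "random_units") {
    found <- character(0)
    drawn <- 0
    while (length(found) < n && drawn < max_draws) {
      chunk <- min(5000, max_draws - drawn)
      gt <- genotype_table(random_rna(chunk, nu), engine, params)
      found <- unique(c(found, gt$sequence[gt$func_class == "unit"]))
      drawn <- drawn + chunk
    }
    found <- head(found, n)
    ffa <- file.path(dir, "random_units.fasta")
    write_fasta(setNames(found, sprintf("unit%d", seq_along(found))), ffa)
    fst <- file.path(dir, "random_units_stats.tsv")
    stats <- data.frame(sequence = found,
                        proxy = vapply(found, function(s)
                          replication_rate_proxy(s, engine, params),
                          numeric(1)))
    write.table(stats, fst, sep = "\t", quote = FALSE, row.names = FALSE)
    return(c(ffa, fst))
  }
  w <- world_new(sim_params(width = 32, height = 32, mu = 0.01), engine,
                 params)
  world_seed(w, random_rna(n, nu), n = n)
  world_step(w, 5)
  fsnap <- file.path(dir, "toy_world_snapshot.txt")
  writeLines(world_snapshot(w), fsnap)
  fmol <- file.path(dir, "toy_world_molecules.tsv")
  write.table(world_molecules(w)[, c("sequence", "x", "y", "func_class")],
              fmol, sep = "\t", quote = FALSE, row.names = FALSE)
  c(fsnap, fmol)
}
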