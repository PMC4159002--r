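# Shared fixtures and independent oracles.

test_ep <- function() energy_params()

# A 50-mer constructed so that, under the fallback (base-pair maximization)
# engine, the plus strand folds exactly into the catalytic stem-multiloop
# with A-only dangling ends (A12 5', A8 3'): G/C stems are the unique
# maximum-pair matching, and A pairs with nothing in a U-free strand.  The
# genotype classifies as a unit of replication; its tests assert this.
nussinov_unit <- function() {
  paste0(strrep("A", 12), strrep("G", 4), strrep("C", 4), strrep("A", 3),
         strrep("G", 4), strrep("C", 4), strrep("A", 3),
         strrep("G", 4), strrep("C", 4), strrep("A", 8))
}

# Brute-force hybridization score: direct translation of the definition
# (all antiparallel offsets, summed pair contributions over the overlap),
# independent of the package's C++ path.
gmin_oracle <- function(t5, t3, ep = test_ep()) {
  n1 <- nchar(t5); n2 <- nchar(t3)
  if (n1 == 0 || n2 == 0) return(0)
  a <- strsplit(t5, "")[[1]]
  b <- strsplit(t3, "")[[1]]
  contrib <- function(x, y) {
    key <- paste0(min(x, y), max(x, y))
    switch(key, "CG" = ep$gc, "AU" = ep$au, "GU" = ep$gu, 0)
  }
  best <- 0
  for (off in (-(n1 - 1)):(n2 - 1)) {
    s <- 0
    for (i in seq_len(n1)) {
      j <- n2 - (i - 1) - off   # 1-based antiparallel partner
      if (j >= 1 && j <= n2) s <- s + contrib(a[i], b[j])
    }
    best <- min(best, s)
  }
  best
}

# R-side pair table (stack parse), independent of the C++ parser.
pair_table_oracle <- function(db) {
  ch <- strsplit(db, "")[[1]]
  p <- rep(NA_integer_, length(ch))
  st <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") st <- c(st, i)
    else if (ch[i] == ")") {
      j <- st[length(st)]
      st <- st[-length(st)]
      p[i] <- j; p[j] <- i
    }
  }
  stopifnot(length(st) == 0)
  p
}

# Loop-tree statistics computed directly from the pair table: number of
# hairpin loops, maximal helices, multiloops, and bulge/interior loops.
loop_stats_oracle <- function(db) {
  p <- pair_table_oracle(db)
  n <- nchar(db)
  helices <- 0; hairpins <- 0; multi <- 0; bulge <- 0; interior <- 0
  opens <- which(!is.na(p) & seq_len(n) < p)
  for (i in opens) {
    j <- p[i]
    # helix start: (i, j) not stacked on an enclosing pair
    if (!(i > 1 && j < n && !is.na(p[i - 1]) && p[i - 1] == j + 1))
      helices <- helices + 1
    # loop closed by the innermost pair of a helix
    if (!(i + 1 < j - 1 && !is.na(p[i + 1]) && p[i + 1] == j - 1)) {
      k <- i + 1; branches <- 0; unpaired_runs <- integer(0); run <- 0
      while (k < j) {
        if (is.na(p[k])) { run <- run + 1; k <- k + 1 }
        else { branches <- branches + 1; unpaired_runs <- c(unpaired_runs, run)
               run <- 0; k <- p[k] + 1 }
      }
      unpaired_runs <- c(unpaired_runs, run)
      if (branches == 0) hairpins <- hairpins + 1
      else if (branches == 1) {
        if (all(unpaired_runs > 0)) interior <- interior + 1
        else bulge <- bulge + 1
      } else multi <- multi + 1
    }
  }
  c(H = hairpins, S = helices, M = multi, B = bulge, I = interior)
}

# Random balanced dot-bracket structures with minimum hairpin size 3.
random_structure <- function(len, p_pair = 0.45) {
  gen <- function(n) {
    if (n < 5) return(strrep(".", n))
    u <- runif(1)
    if (u < p_pair) return(paste0("(", gen(n - 2), ")"))
    if (u < 0.85) {
      k <- sample.int(n - 1, 1)
      return(paste0(gen(k), gen(n - k)))
    }
    strrep(".", n)
  }
  for (try in 1:100) {
    s <- gen(len)
    if (!grepl("\\(\\.{0,2}\\)", s) && grepl("\\(", s)) return(s)
  }
  "((((...))))"
}

# Independent genotype classifier used by spectrum recount oracles:
# follows the verbal rules directly on strand bit vectors.
classify_oracle <- function(p5, pc, p3, m5, mc, m3) {
  viable <- p3 && m3
  roles <- c(if (p5) { if (pc) "R" else "S" } else "I",
             if (m5) { if (mc) "R" else "S" } else "I")
  nR <- sum(roles == "R"); nS <- sum(roles == "S")
  if (viable) return(if (nR >= 1) "unit" else "parasite")
  if (nR >= 1 && nS == 0) return("helper")
  if (nS >= 1 && nR == 0) return("staller")
  if (nR >= 1 && nS >= 1) return("hybrid")
  "junk"
}
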