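hamming_wrap <- function(a, ref) {
  vapply(a, function(x) sum(strsplit(x, "")[[1]] != strsplit(ref, "")[[1]]),
         1L)
}

test_that("single-substitution enumeration has size 3 nu and no duplicates", {
  s <- nussinov_unit()
  muts <- hd1_mutants(s)
  expect_equal(length(muts), 3 * nchar(s))
  expect_equal(anyDuplicated(muts), 0)
  expect_true(all(hamming_wrap(muts, s) == 1))
})

test_that("the HD=1 spectrum normalizes and matches a direct recount", {
  eng <- fold_engine("nussinov")
  ep <- test_ep()
  s <- nussinov_unit()
  sp <- hd1_spectrum(s, eng, ep)
  expect_equal(sp$table$n, 150)
  fr <- unlist(sp$table[1, func_classes()])
  expect_equal(sum(fr), 1)
  # independent recount: classify every mutant one by one via genotype()
  muts <- hd1_mutants(s)
  cls <- vapply(muts, function(m)
    as.character(genotype(m, eng, ep)$func_class), "")
  expect_equal(unname(fr["unit"]),
               mean(cls == "unit"))
  expect_equal(unname(sp$lambdas["lambda_neutral"]), mean(cls == "unit"))
  expect_equal(unname(fr["helper"]), mean(cls == "helper"))
})

test_that("a mock engine forcing open chains removes all neutrality", {
  ep <- test_ep()
  eng_open <- fold_engine("custom", fold_fun = function(s) strrep(".", nchar(s)))
  # short sequences: open-chain tails are too weak to bind, so all junk
  sp_short <- hd1_spectrum("ACGUA", eng_open, ep)
  expect_equal(unname(sp_short$lambdas["lambda_neutral"]), 0)
  expect_equal(unname(sp_short$table$junk[1]), 1)
  # long sequences: open chains have strong tails on both ends -> parasites
  sp_long <- hd1_spectrum(nussinov_unit(), eng_open, ep)
  expect_equal(unname(sp_long$lambdas["lambda_neutral"]), 0)
  expect_equal(unname(sp_long$table$parasite[1]), 1)
})

test_that("tails-only spectra mutate exactly the dangling ends of the catalytic strand", {
  eng <- fold_engine("nussinov")
  ep <- test_ep()
  s <- nussinov_unit()   # tails A12 + A8 -> 60 mutants
  sp <- tails_only_spectrum(s, eng, ep)
  expect_equal(sp$table$n, 3 * 20)
  expect_equal(sum(unlist(sp$table[1, func_classes()])), 1)
  # works identically when handed the non-catalytic strand
  sp2 <- tails_only_spectrum(reverse_complement(s), eng, ep)
  expect_equal(sp2$table$n, sp$table$n)
  expect_error(tails_only_spectrum("ACGUACGUA", eng, ep), "replicase")
})

test_that("replication-rate proxy is zero without a replicase and symmetric under strand swap", {
  eng <- fold_engine("nussinov")
  ep <- test_ep()
  # parasite-like: open chain on both strands of a long sequence
  eng_open <- fold_engine("custom", fold_fun = function(s) strrep(".", nchar(s)))
  expect_equal(replication_rate_proxy(strrep("A", 50), eng_open, ep), 0)
  s <- nussinov_unit()
  expect_equal(replication_rate_proxy(s, eng, ep),
               replication_rate_proxy(reverse_complement(s), eng, ep))
  p <- replication_rate_proxy(s, eng, ep)
  expect_gte(p, 0); expect_lte(p, 1)
  # near-perfect tails give a proxy approaching 1
  eng_mid <- fold_engine("custom", fold_fun = function(s) vapply(s, function(x)
    paste0(strrep(".", 15), "((((...)).((...))))", strrep(".", nchar(x) - 34)),
    ""))
  strong <- paste0(strrep("C", 15), "GGCAAACCAGGAAACCUCC", strrep("G", 16))
  expect_gt(replication_rate_proxy(strong, eng_mid, ep), 0.85)
})

test_that("random screening tallies classes deterministically", {
  eng <- fold_engine("nussinov")
  ep <- test_ep()
  expect_equal(screen_random(0)$n, 0)
  set.seed(401)
  sr <- screen_random(300, nu = 50, engine = eng, params = ep,
                      neutrality = FALSE)
  expect_equal(sum(sr$class_counts), 300)
  expect_equal(nrow(sr$units), unname(sr$class_counts["unit"]))
  # determinism under a fixed seed
  set.seed(401)
  sr2 <- screen_random(300, nu = 50, engine = eng, params = ep,
                       neutrality = FALSE)
  expect_identical(sr$class_counts, sr2$class_counts)
})

test_that("neutral-network expansion layers are consistent and capped", {
  eng <- fold_engine("nussinov")
  ep <- test_ep()
  s <- nussinov_unit()
  set.seed(402)
  core <- expand_core_neutral(s, max_hd = 2, cap_found = 50, engine = eng,
                              params = ep, stats_cap = 10)
  expect_equal(core$table$hd[1], 0)
  expect_equal(core$table$n[1], 1)
  set.seed(402)
  pseudo <- expand_pseudo_neutral(s, max_hd = 2, cap_found = 50, engine = eng,
                                  params = ep, stats_cap = 10)
  # pseudo-neutral retains a superset of core-neutral units per layer
  shared <- intersect(core$table$hd, pseudo$table$hd)
  for (h in shared) {
    expect_gte(pseudo$table$n[pseudo$table$hd == h],
               core$table$n[core$table$hd == h])
  }
  # per-layer fractions normalize
  for (i in seq_len(nrow(pseudo$table)))
    expect_equal(sum(unlist(pseudo$table[i, func_classes()])), 1)
  expect_error(expand_core_neutral("AAAAA", max_hd = 1, engine = eng,
                                   params = ep),
               "unit of replication")
})

test_that("fixed-distance sampling matches exhaustive HD=1 enumeration", {
  eng <- fold_engine("nussinov")
  ep <- test_ep()
  s <- nussinov_unit()
  # exhaustive truth at HD=1
  gt <- quasirep:::genotype_table(hd1_mutants(s), eng, ep)
  units_true <- sort(unique(gt$sequence[gt$func_class == "unit"]))
  set.seed(403)
  sp <- sample_at_hd(s, hd_range = 1, cap_found = 1e4, cap_tries = 3e4,
                     engine = eng, params = ep, stats_cap = 5, chunk = 400)
  expect_equal(sp$table$n[sp$table$hd == 1], length(units_true))
})

test_that("consensus and master recover the plurality sequence", {
  cm <- consensus_and_master(rep("ACGU", 5))
  expect_equal(cm$consensus, "ACGU")
  expect_equal(cm$master, "ACGU")
  cm2 <- consensus_and_master(c(rep("AAAA", 3), "AAAU"))
  expect_equal(cm2$consensus, "AAAA")
  expect_equal(cm2$master, "AAAA")
  # column-mode oracle on a pre-oriented toy set (no revcomp pairs)
  set.seed(404)
  pop <- c("ACGGA", "ACGGA", "ACGUA", "GCGGA", "ACAGA")
  cm3 <- consensus_and_master(pop)
  mat <- do.call(rbind, strsplit(pop, ""))
  mode_cons <- paste(apply(mat, 2, function(col)
    names(sort(table(col), decreasing = TRUE))[1]), collapse = "")
  expect_equal(cm3$consensus, mode_cons)
  expect_equal(cm3$master, "ACGGA")
  expect_error(consensus_and_master(character(0)), "empty")
})

test_that("the quasispecies network has exact HD=1 edges", {
  eng <- fold_engine("nussinov")
  ep <- test_ep()
  s <- nussinov_unit()
  gt <- quasirep:::genotype_table(hd1_mutants(s), eng, ep)
  units <- unique(gt$sequence[gt$func_class == "unit"])
  units <- c(s, units)
  net <- build_network(units, s, engine = eng, params = ep)
  expect_equal(nrow(net$nodes), length(units))
  # oracle: quadratic all-pairs genotype Hamming distances
  rc <- reverse_complement(units)
  truth <- 0L
  for (i in seq_along(units)) for (j in seq_len(i - 1L)) {
    d <- min(sum(strsplit(units[i], "")[[1]] != strsplit(units[j], "")[[1]]),
             sum(strsplit(units[i], "")[[1]] != strsplit(rc[j], "")[[1]]))
    if (d == 1) truth <- truth + 1L
  }
  expect_equal(nrow(net$edges), truth)
  expect_true(all(net$nodes$hd_to_master[-1] == 1))
  expect_equal(net$nodes$hd_to_master[1], 0)
  one <- build_network(s, s, engine = eng, params = ep)
  expect_equal(nrow(one$nodes), 1)
  expect_equal(nrow(one$edges), 0)
})
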