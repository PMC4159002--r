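unit_pair <- function() {
  s <- nussinov_unit()
  c(s, reverse_complement(s))
}

test_that("simulation parameters validate probabilities", {
  expect_error(sim_params(decay_rate = 1.5), "probabilities")
  expect_error(sim_params(mu = -0.1), "probabilities")
  p <- sim_params(width = 16, height = 16)
  expect_equal(p$replication_rate, 1)
  expect_equal(p$decay_rate, 0.03)
  expect_equal(p$complex_no_move_prob, 0.1)
})

test_that("occupancy and complex-adjacency invariants hold every step", {
  set.seed(501)
  w <- world_new(sim_params(width = 24, height = 24, mu = 0.02,
                            check_invariants = TRUE))
  world_seed(w, unit_pair(), n = 80)
  # check_invariants = TRUE makes every step self-verify in C++
  expect_silent(world_step(w, 40))
  mol <- world_molecules(w)
  expect_equal(anyDuplicated(mol[, c("x", "y")]), 0)
  # every complexed molecule has a mutual partner
  cm <- mol[!is.na(mol$partner_id), ]
  if (nrow(cm)) {
    expect_true(all(cm$partner_id %in% cm$id))
    expect_equal(sum(cm$presents5), nrow(cm) / 2)
  }
})

test_that("a lone molecule never replicates and decay is absorbing", {
  set.seed(502)
  w <- world_new(sim_params(width = 12, height = 12, mu = 0,
                            decay_rate = 0.1))
  world_seed(w, nussinov_unit(), n = 1)
  sizes <- integer(0)
  for (i in 1:60) {
    world_step(w, 1)
    sizes <- c(sizes, world_counts(w)[["total"]])
  }
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(sizes <= 1))
  expect_equal(sizes[length(sizes)], 0)   # extinct and stays extinct
  expect_equal(nrow(world_ancestry(w)), 1)  # founder only, no births
})

test_that("faithful replication closure at mu = 0", {
  set.seed(503)
  w <- world_new(sim_params(width = 24, height = 24, mu = 0, decay_rate = 0))
  world_seed(w, unit_pair(), n = 60)
  pops <- integer(0)
  for (i in 1:12) {
    world_step(w, 2)
    pops <- c(pops, world_counts(w)[["total"]])
  }
  expect_true(all(diff(c(60, pops)) >= 0))   # no decay: non-decreasing
  expect_gt(pops[length(pops)], 60)          # replication happened
  mol <- world_molecules(w)
  expect_true(all(mol$sequence %in% unit_pair()))
  expect_true(all(mol$func_class == "unit"))
})

test_that("population changes are accounted by births and deaths only", {
  set.seed(504)
  w <- world_new(sim_params(width = 20, height = 20, mu = 0.01))
  world_seed(w, unit_pair(), n = 50)
  world_step(w, 25)
  anc <- world_ancestry(w)
  expect_equal(anyDuplicated(anc$id), 0)
  # every non-founder has a recorded parent that was born before it
  born <- anc[anc$parent != 0, ]
  if (nrow(born)) {
    expect_true(all(born$parent %in% anc$id))
    parent_birth <- anc$birth[match(born$parent, anc$id)]
    expect_true(all(parent_birth <= born$birth))
  }
  # current population = births that have not died
  expect_lte(world_counts(w)[["total"]], nrow(anc))
})

test_that("seeded runs replay bit-identically", {
  run <- function() {
    set.seed(505)
    w <- world_new(sim_params(width = 16, height = 16, mu = 0.02))
    world_seed(w, unit_pair(), n = 40)
    world_step(w, 15)
    list(world_molecules(w), world_counts(w), world_snapshot(w))
  }
  expect_identical(run(), run())
})

test_that("fold results are cached per unique sequence", {
  set.seed(506)
  w <- world_new(sim_params(width = 20, height = 20, mu = 0, decay_rate = 0))
  world_seed(w, unit_pair(), n = 60)
  world_step(w, 10)
  info <- quasirep:::cpp_world_info(w$ptr)
  expect_equal(info$unique_strands, 2)
  expect_equal(info$fold_calls, 2)
})

test_that("mutate_copy is the mutated reverse complement", {
  set.seed(507)
  s <- nussinov_unit()
  expect_equal(mutate_copy(s, 0), reverse_complement(s))
  m1 <- mutate_copy(s, 1)
  rc <- strsplit(reverse_complement(s), "")[[1]]
  expect_true(all(strsplit(m1, "")[[1]] != rc))
  # substitution count is Binomial(nu, mu)
  nsub <- replicate(400, sum(strsplit(mutate_copy(s, 0.1), "")[[1]] !=
                               rc))
  expect_gt(mean(nsub), 50 * 0.1 * 0.7)
  expect_lt(mean(nsub), 50 * 0.1 * 1.3)
})

test_that("evolvable mutation rates drift as configured", {
  set.seed(508)
  p_pos <- sim_params(mu_mode = "evolve_positive", mu_step = 5e-4)
  draws <- replicate(200, evolve_mu(0.001, p_pos))
  expect_true(all(draws >= 0.001 & draws <= 0.001 + 5e-4))
  p_unb <- sim_params(mu_mode = "evolve_unbiased", mu_step = 5e-4)
  draws2 <- replicate(200, evolve_mu(0.001, p_unb))
  expect_true(any(draws2 < 0.001) && any(draws2 > 0.001))
  p_zero <- sim_params(mu_mode = "evolve_positive", mu_step = 0)
  expect_equal(evolve_mu(0.002, p_zero), 0.002)
  expect_error(evolve_mu(0.001, sim_params()), "not enabled")
  # in the field: offspring rates never fall below the founder rate
  set.seed(509)
  w <- world_new(sim_params(width = 20, height = 20, mu = 0.02,
                            mu_mode = "evolve_positive", mu_step = 5e-3))
  world_seed(w, unit_pair(), n = 60, mu0 = 0.02)
  world_step(w, 20)
  mol <- world_molecules(w)
  expect_true(all(mol$mu >= 0.02))
  expect_gt(max(mol$mu), 0.02)   # some mutated offspring drifted upward
})

test_that("class knockouts eliminate or inactivate the target class", {
  set.seed(510)
  w <- world_new(sim_params(width = 24, height = 24, mu = 0.05))
  world_seed(w, unit_pair(), n = 120)
  world_step(w, 10)
  apply_intervention(w, "remove_class", "helper")
  for (i in 1:8) {
    world_step(w, 1)
    expect_equal(world_counts(w)[["helper"]], 0L)
  }
  # intervention on an absent class is the identity
  cnt_before <- world_counts(w)
  apply_intervention(w, "remove_class", "hybrid")
  expect_equal(world_counts(w), cnt_before)
  # class_to_junk: stallers stay in the field but never complex
  set.seed(511)
  w2 <- world_new(sim_params(width = 24, height = 24, mu = 0.05))
  world_seed(w2, unit_pair(), n = 120)
  apply_intervention(w2, "class_to_junk", "staller")
  for (i in 1:10) {
    world_step(w2, 1)
    mol <- world_molecules(w2)
    st <- mol[mol$func_class == "staller", ]
    if (nrow(st)) {
      expect_true(all(st$inert))
      expect_true(all(is.na(st$partner_id)))
    }
  }
})

test_that("competition seeding fills the two half-fields", {
  set.seed(512)
  w <- world_new(sim_params(width = 20, height = 20, mu = 0))
  init_competition(w, "AAAAACCCCC", "GGGGGUUUUU", density = 0.3)
  mol <- world_molecules(w)
  left <- mol[mol$x < 10, ]; right <- mol[mol$x >= 10, ]
  expect_true(all(left$sequence == "AAAAACCCCC"))
  expect_true(all(right$sequence == "GGGGGUUUUU"))
  expect_equal(nrow(left), nrow(right))
  expect_error(init_competition(w, character(0), "A"), "empty")
})

test_that("observers report counts, distances and snapshots", {
  set.seed(513)
  w <- world_new(sim_params(width = 16, height = 16, mu = 0))
  # empty world: all observers are zero/empty
  expect_equal(world_counts(w)[["total"]], 0L)
  expect_equal(nrow(hd_histogram(w, nussinov_unit())), 0)
  world_seed(w, unit_pair(), n = 30)
  hh <- hd_histogram(w, nussinov_unit())
  # both the sequence and its reverse complement sit in bin 0
  expect_equal(unique(hh$hd), 0L)
  expect_equal(sum(hh$count), 30)
  snap <- world_snapshot(w)
  expect_equal(length(snap), 16)
  expect_true(all(nchar(snap) == 16))
  expect_equal(sum(strsplit(paste(snap, collapse = ""), "")[[1]] == "U"), 30)
  obs <- world_run(w, steps = 6, sample_every = 2)
  expect_equal(nrow(obs$abundance), 4)   # t=0 plus three samples
  expect_true(all(obs$abundance$total >= 0))
})
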