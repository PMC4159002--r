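test_that("pair contributions match the configured energies and are symmetric", {
  ep <- test_ep()
  expect_equal(pair_contribution("G", "C"), -0.15)
  expect_equal(pair_contribution("C", "G"), -0.15)
  expect_equal(pair_contribution("A", "U"), -0.10)
  expect_equal(pair_contribution("U", "G"), -0.05)
  expect_equal(pair_contribution("A", "A"), 0)
  expect_equal(pair_contribution("A", "C"), 0)
  nt <- c("A", "C", "G", "U")
  for (a in nt) for (b in nt)
    expect_equal(pair_contribution(a, b), pair_contribution(b, a))
  expect_error(pair_contribution("T", "A"), "non-RNA")
})

test_that("energy parameters are validated", {
  expect_error(energy_params(gc = 0.1), "<= 0")
  expect_error(energy_params(tail_threshold = 0.5), "negative")
  expect_error(energy_params(gc = -0.17), "multiples of 0.05")
})

test_that("gmin reproduces worked examples and the empty-tail rule", {
  expect_equal(gmin("CCCCC", "GGGGG"), -0.75)
  expect_equal(gmin("AAAA", ""), 0)
  expect_equal(gmin("", "GGG"), 0)
  # two bases sliding along a G-run can realize at most one C-G contact
  expect_equal(gmin("GC", "GGGG"), -0.15)
  expect_equal(gmin("GC", "GGGG"), gmin_oracle("GC", "GGGG"))
})

test_that("gmin equals the brute-force oracle on short random tails", {
  set.seed(101)
  nt <- c("A", "C", "G", "U")
  for (rep in 1:120) {
    n1 <- sample(0:8, 1); n2 <- sample(1:8, 1)
    t5 <- paste(sample(nt, n1, replace = TRUE), collapse = "")
    t3 <- paste(sample(nt, n2, replace = TRUE), collapse = "")
    expect_equal(gmin(t5, t3), gmin_oracle(t5, t3),
                 info = paste(t5, t3))
  }
})

test_that("gmin is antitone under tail extension", {
  set.seed(102)
  nt <- c("A", "C", "G", "U")
  for (rep in 1:60) {
    t5 <- paste(sample(nt, sample(1:6, 1), replace = TRUE), collapse = "")
    t3 <- paste(sample(nt, sample(1:6, 1), replace = TRUE), collapse = "")
    g0 <- gmin(t5, t3)
    expect_lte(gmin(paste0(t5, sample(nt, 1)), t3), g0)
    expect_lte(gmin(t5, paste0(sample(nt, 1), t3)), g0)
    expect_lte(g0, 0)
  }
})

test_that("G-C ladders score -0.15 n and the binding > dissociation threshold sits at 5 G-C / 7 A-U", {
  for (n in 1:8) {
    expect_equal(gmin(strrep("C", n), strrep("G", n)), -0.15 * n)
    expect_equal(gmin(strrep("A", n), strrep("U", n)), -0.10 * n)
  }
  over_half_gc <- which(vapply(1:10, function(n)
    binding_probability(gmin(strrep("C", n), strrep("G", n))) > 0.5,
    logical(1)))
  over_half_au <- which(vapply(1:10, function(n)
    binding_probability(gmin(strrep("A", n), strrep("U", n))) > 0.5,
    logical(1)))
  expect_equal(min(over_half_gc), 5)
  expect_equal(min(over_half_au), 7)
})

test_that("binding probability follows 1 - exp(G)", {
  expect_equal(binding_probability(0), 0)
  expect_equal(binding_probability(-0.75), 1 - exp(-0.75))
  expect_equal(round(binding_probability(-0.75), 4), 0.5276)
  expect_equal(round(binding_probability(-0.15), 4), 0.1393)
  expect_error(binding_probability(0.1), "<= 0")
})

test_that("complex rates normalize when the two configurations exceed 1", {
  # tails engineered to give the target probabilities are unnecessary:
  # check the normalization arithmetic through the public surface
  ep <- test_ep()
  cr <- complex_rates("CCCCCCCCCC", "AAAA", "AAAA", "GGGGGGGGGG", ep)
  # only the X-presents-5' configuration binds
  expect_gt(cr$p_xy, 0.7)
  expect_equal(cr$p_yx, 0)
  expect_equal(cr$k1_xy, cr$p_xy)
  expect_equal(cr$k2_xy, 1 - cr$k1_xy)
  # symmetric strong tails: both configurations normalized to 1/2
  cr2 <- complex_rates("CCCCCCCCCCCC", "GGGGGGGGGGGG",
                       "CCCCCCCCCCCC", "GGGGGGGGGGGG", ep)
  expect_equal(cr2$k1_xy, cr2$k1_yx)
  expect_equal(cr2$k1_xy + cr2$k1_yx, 1)
  expect_equal(cr2$k2_xy, 1 - cr2$k1_xy)
})

test_that("association probabilities always satisfy k1_xy + k1_yx <= 1", {
  set.seed(103)
  nt <- c("A", "C", "G", "U")
  for (rep in 1:50) {
    tails <- vapply(1:4, function(i)
      paste(sample(nt, sample(0:10, 1), replace = TRUE), collapse = ""), "")
    cr <- complex_rates(tails[1], tails[2], tails[3], tails[4])
    expect_lte(cr$k1_xy + cr$k1_yx, 1 + 1e-12)
    expect_gte(cr$k1_xy, 0)
    expect_gte(cr$k1_yx, 0)
  }
})

test_that("dangling-end presence uses the exact -0.75 threshold", {
  expect_true(tail_present("GGGGG"))    # 5 G-C pairs: exactly -0.75
  expect_true(tail_present("CCCCC"))
  expect_false(tail_present(""))
  expect_false(tail_present("AAAAAAA")) # 7 A-U pairs: -0.70
  expect_true(tail_present("AAAAAAAA")) # 8 A-U pairs: -0.80
  expect_false(tail_present("GGGG"))    # -0.60
})
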