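test_that("topology follows the model of evolution", {
  # single clone: germline child with a detectable CCF somewhere
  p1 <- sim_params(n_clones = 1, n_variants = 1, seed = 5)
  phy1 <- simulate_phylogeny(p1)
  expect_identical(phy1$parents, 0L)
  expect_true(any(phy1$ccf >= p1$detection_threshold))

  # linear evolution: each clone develops from the latest one
  phy <- simulate_phylogeny(sim_params(model = "linear", seed = 8))
  expect_identical(phy$parents, c(0L, 1L, 2L, 3L, 4L))

  # branched dependent: c2 linear from c1, c3 the first branch of c1
  for (seed in 1:10) {
    phyb <- simulate_phylogeny(sim_params(model = "branched_dependent",
                                          n_clones = 3, n_variants = 6,
                                          seed = seed))
    expect_identical(phyb$parents[1:3], c(0L, 1L, 1L))
  }

  # branched independent: c2 branches off the germline
  phyi <- simulate_phylogeny(sim_params(model = "branched_independent",
                                        n_clones = 4, n_variants = 8,
                                        seed = 2))
  expect_identical(phyi$parents[2], 0L)
})

test_that("linear trees have no branch point; branched trees have at least one", {
  branch_points <- function(phy) {
    sum(tabulate(phy$parents + 1L) >= 2)
  }
  for (seed in 1:25) {
    expect_identical(branch_points(simulate_phylogeny(
      sim_params(model = "linear", seed = seed))), 0L)
    expect_gte(branch_points(simulate_phylogeny(
      sim_params(model = "branched_dependent", seed = seed))), 1L)
    expect_gte(branch_points(simulate_phylogeny(
      sim_params(model = "branched_independent", seed = seed))), 1L)
  }
})

test_that("simulation is reproducible bit-for-bit given a seed", {
  p <- sim_params(model = "branched_independent", seed = 123)
  expect_identical(simulate_phylogeny(p), simulate_phylogeny(p))
  p2 <- sim_params(model = "branched_independent", seed = 124)
  expect_false(identical(simulate_phylogeny(p), simulate_phylogeny(p2)))
})

test_that("every simulated phylogeny passes the independent validator", {
  for (model in c("linear", "branched_dependent", "branched_independent")) {
    for (seed in 1:200) {
      p <- sim_params(model = model, seed = seed)
      expect_length(validate_phylogeny(simulate_phylogeny(p), p), 0)
    }
  }
})

test_that("the validator flags each violated constraint by name", {
  p <- toy_params()
  phy <- toy_phylogeny()
  expect_length(validate_phylogeny(phy, p), 0)

  child_high <- phy
  child_high$ccf[2, 1] <- 95          # above parent c1 at t1
  expect_match(validate_phylogeny(child_high, p), "child exceeds parent",
               all = FALSE)

  dead <- phy
  dead$ccf[3, ] <- c(10, 0, 5)
  expect_match(validate_phylogeny(dead, p), "re-appears", all = FALSE)

  faint <- phy
  faint$ccf[3, ] <- c(1, 0.5, 0.2)    # below the 2% detection threshold
  expect_match(validate_phylogeny(faint, p), "detection threshold",
               all = FALSE)

  close <- phy
  close$ccf[3, ] <- phy$ccf[2, ] - 1  # within 4% of clone 2 everywhere
  expect_match(validate_phylogeny(close, p), "too close", all = FALSE)

  # two siblings jointly exceeding their parent
  sib <- clone_phylogeny(parents = c(0L, 1L, 1L),
                         ccf = rbind(c(80, 80, 80),
                                     c(50, 50, 50),
                                     c(40, 44, 40)),
                         variants_per_clone = c(2L, 2L, 2L))
  expect_match(validate_phylogeny(sib, p), "children sum exceeds",
               all = FALSE)

  # independent clones beyond 100%
  ind <- clone_phylogeny(parents = c(0L, 0L, 1L),
                         ccf = rbind(c(70, 70, 70),
                                     c(40, 45, 40),
                                     c(30, 20, 10)),
                         variants_per_clone = c(2L, 2L, 2L))
  expect_match(validate_phylogeny(ind, p), "independent clones exceed",
               all = FALSE)

  cyc <- phy
  cyc$parents <- c(2L, 1L, 2L)
  expect_match(validate_phylogeny(cyc, p), "cycle", all = FALSE)

  wrong_total <- phy
  wrong_total$variants_per_clone <- c(2L, 2L, 3L)
  expect_match(validate_phylogeny(wrong_total, p), "variant counts",
               all = FALSE)

  bad <- phy
  bad$ccf <- phy$ccf[1:2, ]
  expect_error(validate_phylogeny(bad, p), "dimension mismatch")
})

test_that("generation never exhausts retries with relaxed constraints", {
  for (seed in 1:20) {
    p <- sim_params(model = "branched_dependent", n_timepoints = 10,
                    n_clones = 10, n_variants = 20,
                    detection_threshold = 0, min_clonal_distance = 0,
                    seed = seed)
    expect_length(validate_phylogeny(simulate_phylogeny(p), p), 0)
  }
})

test_that("variant counts cover every clone and sum to n_variants", {
  expect_identical(assign_variant_counts(sim_params(n_clones = 5,
                                                    n_variants = 5,
                                                    seed = 1)),
                   rep(1L, 5))
  counts <- assign_variant_counts(sim_params(seed = 3))
  expect_identical(sum(counts), 20L)
  expect_true(all(counts >= 1L))
  expect_error(assign_variant_counts(sim_params(n_clones = 5, n_variants = 3)),
               ">= n_clones")
})

test_that("surplus variants are split uniformly across clones", {
  set.seed(99)
  p <- sim_params(n_clones = 2, n_variants = 7)
  surplus1 <- replicate(10000, assign_variant_counts(p, seeded = TRUE)[1] - 1L)
  # each of the 5 surplus variants lands on clone 1 with probability 1/2
  tot <- sum(surplus1)
  chi <- stats::chisq.test(c(tot, 5 * 10000 - tot), p = c(0.5, 0.5))
  expect_gt(chi$p.value, 0.001)
})

test_that("edits are applied only when all constraints still hold", {
  p <- toy_params()
  phy <- toy_phylogeny()

  same <- edit_phylogeny(phy, p)
  expect_identical(same$phylogeny, phy)
  expect_identical(same$params, p)

  # extend an eradicated clone with an all-zero time point
  dead <- phy
  dead$ccf[3, 3] <- 0
  grown <- edit_phylogeny(dead, p, add_timepoint = c(60, 30, 0))
  expect_identical(ncol(grown$phylogeny$ccf), 4L)
  expect_identical(grown$params$n_timepoints, 4L)

  # raising a child above its parent is rejected with the named violation
  expect_error(
    edit_phylogeny(phy, p, ccf = data.frame(clone = 2, timepoint = 1,
                                            value = 95)),
    "child exceeds parent")
  # the caller's object is untouched by a rejected edit
  expect_identical(phy, toy_phylogeny())

  # re-parenting and clone removal keep the tree consistent
  rp <- edit_phylogeny(phy, p, parents = 3L, new_parent = 1L)
  expect_identical(rp$phylogeny$parents, c(0L, 1L, 1L))
  dropped <- edit_phylogeny(phy, p, drop_clone = 2L)
  expect_identical(dropped$phylogeny$parents, c(0L, 1L))
  expect_identical(dropped$params$n_clones, 2L)
  expect_identical(sum(dropped$phylogeny$variants_per_clone), 6L)
})
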