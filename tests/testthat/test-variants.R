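test_that("CNV types, coordinates, and clone budgets are respected", {
  p <- toy_params(cnv_types = "deletion", seed = 4)
  phy <- toy_phylogeny()

  only_del <- simulate_cnvs(phy, p, 6)
  expect_identical(unique(only_del$cnv_type), "deletion")

  p3 <- toy_params(seed = 4)
  one_each <- simulate_cnvs(phy, p3, 3)
  expect_setequal(one_each$cnv_type, c("deletion", "duplication", "LOH"))

  expect_error(simulate_cnvs(phy, p3, 2), "at least once")
  expect_identical(nrow(simulate_cnvs(phy, p3, 0)), 0L)

  # coordinate bounds and the 10 kb length cap over many CNVs
  set.seed(11)
  big_phy <- clone_phylogeny(0L, matrix(c(90, 90, 90), 1), 200L)
  big_p <- sim_params(n_clones = 1, n_variants = 200, seed = NULL)
  for (rep in 1:5) {
    cnvs <- simulate_cnvs(big_phy, big_p, 200)
    expect_true(all(cnvs$end - cnvs$start + 1 <= 10000))
    expect_true(all(cnvs$end - cnvs$start + 1 >= 1))
    expect_true(all(cnvs$start >= 1))
    expect_true(all(cnvs$end <= clonesim:::GRCH37_LENGTHS[cnvs$chrom]))
    expect_true(all(cnvs$chrom %in% 1:22))
  }

  # clone assignment never exceeds a clone's variant budget
  set.seed(12)
  for (rep in 1:20) {
    cnvs <- simulate_cnvs(phy, p3, 5)
    expect_true(all(tabulate(cnvs$clone, 3) <= phy$variants_per_clone))
  }
})

test_that("SNVs land outside every CNV, at unique positions, per clone budget", {
  phy <- clone_phylogeny(0L, matrix(c(90, 90, 90), 1), 200L)
  # a CNV blanket over the start of chromosome 1
  blanket <- data.frame(id = "cnv1", chrom = 1L, start = 1L, end = 10000L,
                        cnv_type = "deletion", clone = 1L,
                        stringsAsFactors = FALSE)
  set.seed(21)
  for (rep in 1:5) {
    snvs <- place_snvs(phy, blanket, 199)
    expect_false(any(snvs$chrom == 1 & snvs$pos <= 10000))
    expect_false(anyDuplicated(snvs[c("chrom", "pos")]) > 0)
    expect_true(all(snvs$ref != snvs$alt))
  }

  # with no CNVs any position is acceptable and budgets are met exactly
  phy5 <- simulate_phylogeny(sim_params(seed = 31))
  snvs <- place_snvs(phy5, NULL, 20)
  expect_identical(tabulate(snvs$clone, 5), phy5$variants_per_clone)
  expect_error(place_snvs(phy5, NULL, 19), "budget")
})

test_that("overlap configuration overlaps the requested number of SNVs", {
  set.seed(41)
  p <- sim_params(n_variants = 26, seed = 41)
  phy <- simulate_phylogeny(p)
  cnvs <- simulate_cnvs(phy, p, 6)
  snvs <- place_snvs(phy, cnvs, 20)

  # empty spec is a no-op
  untouched <- configure_overlap(snvs, cnvs, NULL, phy)
  expect_identical(untouched$snvs, snvs)

  spec <- data.frame(cnv_id = cnvs$id,
                     n_overlapping = c(1L, 1L, 1L, 2L, 2L, 3L),
                     scenario = "cnv_first", stringsAsFactors = FALSE)
  res <- configure_overlap(snvs, cnvs, spec, phy)
  over <- !is.na(res$snvs$overlap_cnv_id)
  expect_identical(sum(over), 10L)
  expect_identical(as.vector(table(res$snvs$overlap_cnv_id)[cnvs$id]),
                   c(1L, 1L, 1L, 2L, 2L, 3L))
  # overlapped SNVs sit inside their CNV; the rest stay outside all CNVs
  for (i in which(over)) {
    ci <- match(res$snvs$overlap_cnv_id[i], cnvs$id)
    expect_identical(res$snvs$chrom[i], cnvs$chrom[ci])
    expect_true(res$snvs$pos[i] >= cnvs$start[ci] &&
                  res$snvs$pos[i] <= cnvs$end[ci])
    # cnv_first: the SNV clone descends from (or is) the CNV clone
    expect_true(res$snvs$clone[i] == cnvs$clone[ci] ||
                  cnvs$clone[ci] %in% clonesim:::clone_ancestors(
                    phy$parents, res$snvs$clone[i]))
  }
  expect_false(any(clonesim:::inside_any_cnv(res$snvs$chrom[!over],
                                             res$snvs$pos[!over], cnvs)))
  # realized clone counts still cover the full variant budget
  expect_identical(sum(res$phylogeny$variants_per_clone), 26L)
  expect_identical(tabulate(res$snvs$clone, 5) + tabulate(cnvs$clone, 5),
                   res$phylogeny$variants_per_clone)
})

test_that("ancestry relations hold for every scenario of overlap", {
  set.seed(55)
  p <- sim_params(model = "branched_dependent", n_variants = 26, seed = 55)
  comparable <- function(phy, a, b) {
    a == b || a %in% clonesim:::clone_ancestors(phy$parents, b) ||
      b %in% clonesim:::clone_ancestors(phy$parents, a)
  }
  for (scen in c("cnv_first", "snv_first_affected",
                 "snv_first_unaffected", "parallel")) {
    b <- simulate_patient(p, n_cnvs = 6,
                          overlap = list(multiplicities = c(1, 1, 1, 2, 2, 3),
                                         scenario = scen))
    over <- which(!is.na(b$snvs$overlap_cnv_id))
    expect_length(over, 10)
    for (i in over) {
      ci <- match(b$snvs$overlap_cnv_id[i], b$cnvs$id)
      sc <- b$snvs$clone[i]
      cc <- b$cnvs$clone[ci]
      if (scen == "cnv_first") {
        expect_true(sc == cc ||
                      cc %in% clonesim:::clone_ancestors(b$phylogeny$parents, sc))
      } else if (scen == "parallel") {
        expect_true(sc != cc)
        expect_true(all(b$phylogeny$ccf[sc, ] + b$phylogeny$ccf[cc, ] <=
                          100 + 1e-8))
      } else {
        expect_true(sc == cc ||
                      sc %in% clonesim:::clone_ancestors(b$phylogeny$parents, cc))
      }
    }
  }
})

test_that("an unsatisfiable scenario is reported as infeasible", {
  # a dominant two-clone chain: every clone pair sums above 100% at t1
  phy <- clone_phylogeny(c(0L, 1L), rbind(c(90, 90, 90), c(60, 60, 60)),
                         c(2L, 2L))
  cnvs <- data.frame(id = "cnv1", chrom = 1L, start = 100L, end = 200L,
                     cnv_type = "deletion", clone = 2L,
                     stringsAsFactors = FALSE)
  snvs <- data.frame(id = c("snv1", "snv2", "snv3"),
                     chrom = 2L, pos = c(10L, 20L, 30L),
                     ref = "A", alt = "T", clone = c(1L, 1L, 2L),
                     overlap_cnv_id = NA_character_,
                     scenario = NA_character_, stringsAsFactors = FALSE)
  spec <- data.frame(cnv_id = "cnv1", n_overlapping = 1L,
                     scenario = "parallel", stringsAsFactors = FALSE)
  expect_error(configure_overlap(snvs, cnvs, spec, phy),
               "scenario infeasible")
})
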