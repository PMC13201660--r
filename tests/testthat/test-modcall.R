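test_that("per-read modification calls use the inclusive 0.95 threshold", {
  calls <- callModified(c(0.94, 0.95, 0.96), modConfig())
  expect_identical(calls, c(FALSE, TRUE, TRUE))
  expect_length(callModified(numeric(0)), 0L)
  expect_error(callModified(c(0.5, 1.2)), "probs")
  # a custom threshold shifts the boundary, still inclusive
  expect_identical(callModified(c(0.89, 0.9), modConfig(probThreshold = 0.9)),
                   c(FALSE, TRUE))
})

test_that("site stoichiometry divides modified by probability-bearing reads", {
  # 10 covering reads, 6 above threshold at position 150
  probs <- c(rep(0.99, 6), rep(0.01, 4))
  rs <- makeReads(rep(101L, 10), rep(200L, 10),
                  modPos = as.list(rep(150L, 10)),
                  modProb = as.list(probs))
  st <- siteStoichiometry(rs, modConfig(minCoverage = 5L))
  expect_identical(st$position, 150L)
  expect_equal(st$mod_ratio, 0.6)
  expect_identical(st$coverage, 10L)
  expect_false(st$low_coverage)

  # low-coverage flagging and NA (never 0) for uncovered positions
  st2 <- siteStoichiometry(rs, modConfig(minCoverage = 50L),
                           positions = c(150L, 900L))
  expect_true(all(st2$low_coverage))
  expect_true(is.na(st2$mod_ratio[st2$position == 900L]))
  expect_identical(st2$coverage[st2$position == 900L], 0L)

  # U-to-C mismatch ratio excludes deletions from the denominator and is
  # only computed at reference-U positions
  ref <- tinyRef(uAt = 150L)
  callPos <- c(as.list(rep(150L, 3)), rep(list(integer(0)), 7))
  callBase <- c(as.list(rep("C", 3)), rep(list(character(0)), 7))
  dels <- c(rep(list(IRanges::IRanges()), 8),
            rep(list(IRanges::IRanges(150L, 151L)), 2))
  rs3 <- makeReads(rep(101L, 10), rep(200L, 10),
                   modPos = as.list(rep(150L, 10)),
                   modProb = as.list(probs),
                   callPos = callPos, callBase = callBase,
                   deletions = dels, hasBasecalls = TRUE)
  st3 <- siteStoichiometry(rs3, modConfig(), pileup = mismatchPileup(rs3, ref),
                           positions = c(150L, 160L))
  expect_equal(st3$mismatch_c_ratio[st3$position == 150L], 3 / 8)
  expect_true(is.na(st3$mismatch_c_ratio[st3$position == 160L]))

  # raising the probability threshold never raises a ratio
  r1 <- siteStoichiometry(rs, modConfig(probThreshold = 0.5))$mod_ratio
  r2 <- siteStoichiometry(rs, modConfig(probThreshold = 0.99))$mod_ratio
  expect_lte(r2, r1)
})

test_that("the 10% site filter keeps sites passing in at least one condition", {
  stoich <- rbind(
    data.frame(position = c(10L, 20L, 30L), mod_ratio = c(0.12, 0.05, 0.10),
               mismatch_c_ratio = NA, coverage = 100L, n_prob_reads = 100L,
               low_coverage = FALSE, condition = "nuc"),
    data.frame(position = c(10L, 20L, 30L), mod_ratio = c(0.08, 0.08, 0.02),
               mismatch_c_ratio = NA, coverage = 100L, n_prob_reads = 100L,
               low_coverage = FALSE, condition = "cyt"))
  kept <- filterSites(stoich, modConfig())
  # 10: passes in nuc only -> retained; 20: below 10% everywhere -> removed;
  # 30: exactly 10% (inclusive) -> retained
  expect_identical(kept$position, c(10L, 30L))
  expect_identical(kept$conditions_passing[kept$position == 10L], "nuc")

  # an IVT-like condition with zero ratios contributes nothing on its own
  ivt <- stoich[stoich$condition == "cyt", ]
  ivt$mod_ratio <- 0
  expect_identical(nrow(filterSites(ivt, modConfig())), 0L)

  # per-condition independent filtering drops the sub-threshold condition
  each <- filterSites(stoich, modConfig(), mode = "each")
  expect_identical(each$position, c(10L, 30L))
  expect_identical(each$n_conditions_passing, c(1L, 1L))
})

test_that("planted stoichiometries are recovered within 3 binomial SDs", {
  ts <- tinyTemplates()
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  pos <- c(120L, 150L, 200L, 250L, 280L)
  cfg <- simConfig(seed = 55, nReads = 500L,
                   templateProportions = c(matA = 1),
                   plantedSites = data.frame(position = pos,
                                             stoichiometry = levels))
  rs <- simulateModifications(simulateReads(ts, cfg), cfg)
  st <- siteStoichiometry(rs, modConfig())
  for (i in seq_along(pos)) {
    got <- st$mod_ratio[st$position == pos[i]]
    tol <- 3 * sqrt(levels[i] * (1 - levels[i]) / 500) + 0.03
    expect_lt(abs(got - levels[i]), tol)
  }
})

test_that("modified and IVT conditions separate perfectly across seeds", {
  ts <- tinyTemplates()
  pos <- c(120L, 200L, 280L)
  for (seed in 1:20) {
    mkCfg <- function(st) simConfig(seed = seed, nReads = 100L,
      templateProportions = c(matA = 1),
      plantedSites = data.frame(position = pos, stoichiometry = st))
    mod <- simulateModifications(simulateReads(ts, mkCfg(c(0.5, 0.7, 0.9))),
                                 mkCfg(c(0.5, 0.7, 0.9)))
    ivt <- simulateModifications(simulateReads(ts, mkCfg(c(0, 0, 0))),
                                 mkCfg(c(0, 0, 0)))
    stoich <- rbind(
      cbind(siteStoichiometry(mod, modConfig()), cnd = "mod"),
      cbind(siteStoichiometry(ivt, modConfig()), cnd = "ivt"))
    stoich$condition <- stoich$cnd
    kept <- filterSites(stoich, modConfig())
    expect_identical(kept$position, pos)
    expect_true(all(kept$conditions_passing == "mod"))
  }
})

test_that("precursor-specific stoichiometry splits by assignment", {
  ts <- tinyTemplates()
  # matA reads fully modified at 150; matB reads unmodified at 700
  nA <- 40L; nB <- 30L
  rs <- makeReads(c(rep(101L, nA), rep(501L, nB)),
                  c(rep(300L, nA), rep(800L, nB)),
                  modPos = c(as.list(rep(150L, nA)),
                             as.list(rep(700L, nB))),
                  modProb = c(as.list(rep(0.99, nA)),
                              as.list(rep(0.01, nB))))
  asn <- assignReads(rs, ts)
  m <- precursorStoichiometry(asn, rs, modConfig(), ts = ts,
                              positions = c(150L, 700L))
  expect_equal(m["matA", "150"], 1)
  expect_equal(m["matB", "700"], 0)
  # sites outside a precursor's interval are NA for that row
  expect_true(is.na(m["matA", "700"]))
  expect_true(is.na(m["matB", "150"]))
  # the "all" row is the coverage-weighted mean of the per-precursor rows
  expect_equal(m["all", "150"], 1)
  expect_equal(m["all", "700"], 0)

  # hypomodified species show lower rows than mature ones
  cfgTpl <- simConfig(seed = 91, nReads = 600L,
    templateProportions = c(matA = 0.5, pre = 0.5),
    plantedSites = data.frame(position = 150L, stoichiometry = 1))
  rsSim <- simulateReads(ts, cfgTpl)
  # modify matA-origin reads at high, pre-origin at low stoichiometry
  truth <- simTruth(rsSim)
  keepA <- truth$template == "matA"
  probs <- ifelse(keepA, 0.99, 0.05)
  rsSim <- makeReads(GenomicRanges::start(readRanges(rsSim)),
                     GenomicRanges::end(readRanges(rsSim)),
                     readId = readIds(rsSim),
                     modPos = as.list(rep(150L, length(rsSim))),
                     modProb = as.list(probs))
  m2 <- precursorStoichiometry(assignReads(rsSim, ts), rsSim, modConfig(),
                               ts = ts, positions = 150L)
  expect_gt(m2["matA", "150"], 0.95)
  expect_lt(m2["pre", "150"], 0.05)
  w <- table(truth$template)
  expect_equal(m2["all", "150"],
               (m2["matA", "150"] * w[["matA"]] +
                  m2["pre", "150"] * w[["pre"]]) / sum(w))
})

test_that("signal windows summarise 21 offsets with semi-standard deviations", {
  # constant signal: all summaries zero
  tab <- expand.grid(read_id = sprintf("r%d", 1:5), offset = -10:10)
  tab$z_mean <- 0
  sw <- signalWindowSummary(tab, locus = 1248L)
  expect_identical(nrow(sw), 21L)
  expect_true(all(sw$mean_of_means == 0))
  expect_true(all(sw$semi_sd_lower == 0 & sw$semi_sd_upper == 0))
  expect_identical(sw$offset, -10L:10L)

  # read means {-1, -1, 2}: mean 0, lower semi-SD from {-1,-1}, upper {2}
  tab2 <- data.frame(read_id = c("a", "b", "c"), offset = 0L,
                     z_mean = c(-1, -1, 2))
  sw2 <- signalWindowSummary(tab2, locus = 100L)
  at0 <- sw2[sw2$offset == 0L, ]
  expect_equal(at0$mean_of_means, 0)
  expect_equal(at0$semi_sd_lower, 1)
  expect_equal(at0$semi_sd_upper, 2)
  expect_identical(at0$n_reads, 3L)
  # offsets nobody covers are NA with zero reads
  expect_true(all(is.na(sw2$mean_of_means[sw2$offset != 0L])))

  expect_error(signalWindowSummary(tab2[0, ], locus = 5L), "no reads")
  expect_error(signalWindowSummary(data.frame(read_id = "a", offset = 11L,
                                              z_mean = 1), locus = 5L),
               "-10..10")
})
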