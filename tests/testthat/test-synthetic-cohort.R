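test_that("bernoulli cohort honours degenerate detection probabilities", {
  always <- simulateBernoulliCohort(c(G = 1.0), 5, 3, seed = 1)
  pos <- vapply(profiles(always$cohort), function(p) {
    sum(presence(p))
  }, integer(1))
  expect_true(all(pos == 3L))  # p = 1 forces every biopsy positive

  never <- simulateBernoulliCohort(c(G = 0.0), 5, 3, seed = 1)
  expect_true(all(vapply(profiles(never$cohort), function(p) {
    nrow(presence(p)) == 0L
  }, logical(1))))

  expect_error(simulateBernoulliCohort(c(G = 1.2), 5, 3), "\\[0, 1\\]")
  expect_error(simulateBernoulliCohort(c(G = 0.5), 0, 3), ">= 1")
})

test_that("bernoulli cohort hits its detection rate within binomial error", {
  sim <- simulateBernoulliCohort(c(G = 0.6), 2000, 4, seed = 11)
  frac <- sum(sim$truth$n_positive) / sum(sim$truth$n_biopsies)
  se <- sqrt(0.6 * 0.4 / (2000 * 4))
  expect_lt(abs(frac - 0.6), 3 * se)
})

test_that("simulated truths are laminar and truncal mutations span all regions", {
  cfg <- simulationConfig(nPatients = 10)
  set.seed(33)
  seeds <- sample.int(1e6, 50)
  for (s in seeds) {
    truth <- simulateTumorTruth(cfg, seed = s)
    for (p in truth$patients) {
      if (nrow(p$mutations) == 0) next
      prof <- profiles(truthProfiles(truth))[[
        match(p$patientId, vapply(truth$patients, `[[`, character(1),
                                  "patientId"))]]
      expect_identical(nrow(checkCompatibility(prof)), 0L,
                       info = paste("seed", s, p$patientId))
      truncal <- p$mutations$class == "truncal"
      expect_true(all(
        p$mutations$region_set[truncal] ==
          paste(p$regions, collapse = ",")
      ))
    }
  }
})

test_that("degenerate rates produce the pure single-trunk and empty patterns", {
  onlyVHL <- simulationConfig(
    nPatients = 6,
    truncalRate = c(VHL = 1, PBRM1 = 0, SETD2 = 0, BAP1 = 0, KDM5C = 0),
    subclonalRate = c(VHL = 0, PBRM1 = 0, SETD2 = 0, BAP1 = 0, KDM5C = 0)
  )
  truth <- simulateTumorTruth(onlyVHL, seed = 5)
  for (p in truth$patients) {
    expect_identical(nrow(p$mutations), 1L)
    expect_identical(p$mutations$gene, "VHL")
    expect_identical(p$mutations$class, "truncal")
  }
  cats <- vapply(profiles(truthProfiles(truth)), classifyTopology,
                 character(1))
  expect_true(all(cats == "SINGLE_SHARED_ONLY"))

  nothing <- simulationConfig(
    nPatients = 4,
    truncalRate = setNames(rep(0, 5), defaultGenePanel()),
    subclonalRate = setNames(rep(0, 5), defaultGenePanel())
  )
  truth0 <- simulateTumorTruth(nothing, seed = 5)
  expect_true(all(vapply(truth0$patients, function(p) {
    nrow(p$mutations) == 0L
  }, logical(1))))
})

test_that("simulation is deterministic given config and seed", {
  cfg <- simulationConfig()
  t1 <- simulateTumorTruth(cfg, seed = 9)
  t2 <- simulateTumorTruth(cfg, seed = 9)
  expect_identical(t1, t2)
  c1 <- simulateVariantCalls(t1, cfg, seed = 10)
  c2 <- simulateVariantCalls(t2, cfg, seed = 10)
  expect_identical(c1, c2)
  expect_false(identical(
    simulateVariantCalls(t1, cfg, seed = 11), c1
  ))
})

test_that("read-count layer follows the heterozygous-diploid VAF model", {
  cfg <- simulationConfig(
    nPatients = 30, purity = 1, errorRate = 0,
    decoyRates = c(germline = 0, synonymous = 0, artifact = 0),
    truncalRate = c(VHL = 1, PBRM1 = 1, SETD2 = 1, BAP1 = 1, KDM5C = 1),
    subclonalRate = setNames(rep(0, 5), defaultGenePanel())
  )
  truth <- simulateTumorTruth(cfg, seed = 21)
  calls <- simulateVariantCalls(truth, cfg, seed = 22)
  expect_true(all(calls$origin == "somatic"))
  vaf <- calls$alt_reads / calls$depth
  # binomial mean 0.5 at depth ~950 over >400 sites: tight around 0.5
  se <- sqrt(0.25 / (950 * nrow(calls)))
  expect_lt(abs(mean(vaf) - 0.5), 4 * se)
  expect_gte(min(calls$depth), 1L)

  # zero error rate: no call outside a mutation's region set
  keysets <- do.call(rbind, lapply(truth$patients, function(p) p$mutations))
  for (i in seq_len(nrow(calls))) {
    truthRow <- keysets[keysets$variant_key == variantKey(calls[i, ]), ]
    regs <- strsplit(truthRow$region_set, ",")[[1]]
    expect_true(calls$region_id[i] %in% regs)
  }
})

test_that("injected decoys are all recoverable by the filter while true calls survive", {
  cfg <- simulationConfig(nPatients = 12, errorRate = 0, purity = 1,
                          decoyRates = c(germline = 1, synonymous = 0.8,
                                         artifact = 0.8))
  truth <- simulateTumorTruth(cfg, seed = 41)
  calls <- simulateVariantCalls(truth, cfg, seed = 42)
  expect_gt(sum(grepl("decoy$", calls$origin)), 20)
  res <- filterVariants(calls)
  expect_identical(sum(grepl("decoy$", res$retained$origin)), 0L)
  somatic <- calls$origin == "somatic"
  expect_identical(nrow(res$retained), sum(somatic))
  # replay the rules independently on the raw table
  vaf <- calls$alt_reads / calls$depth
  manual <- calls$consequence %in%
    c("missense", "nonsense", "frameshift_indel", "inframe_indel") &
    calls$depth >= 10 & vaf >= 0.05 & !(calls$in_dbsnp & !calls$is_indel)
  expect_identical(which(manual), as.integer(rownames(res$retained)))
})

test_that("the double-mutant option emits two same-gene mutations in disjoint sets", {
  cfg <- simulationConfig(
    nPatients = 40, doubleMutationRate = 1,
    truncalRate = setNames(rep(0, 5), defaultGenePanel()),
    subclonalRate = c(VHL = 0, PBRM1 = 0, SETD2 = 0, BAP1 = 1, KDM5C = 0)
  )
  truth <- simulateTumorTruth(cfg, seed = 55)
  doubles <- Filter(function(p) {
    sum(p$mutations$gene == "BAP1") == 2
  }, truth$patients)
  expect_gt(length(doubles), 10)
  for (p in doubles) {
    sets <- strsplit(p$mutations$region_set, ",")
    expect_length(intersect(sets[[1]], sets[[2]]), 0L)
  }
})
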