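test_that("presence matrices collapse identical variants and keep empty regions", {
  calls <- data.frame(
    patient_id = "T1",
    region_id = c("R1", "R2", "R3", "R1", "R2"),
    gene = c("VHL", "VHL", "VHL", "BAP1", "BAP1"),
    chrom = "3", pos = c(100L, 100L, 100L, 200L, 300L),
    ref = "C", alt = "T", depth = 100L, alt_reads = 50L,
    consequence = "missense", in_dbsnp = FALSE, is_indel = FALSE
  )
  regs <- data.frame(patient_id = "T1", region_id = c("R1", "R2", "R3"))
  prof <- buildPresenceMatrix(calls, regs)[["T1"]]

  # one VHL variant seen in all three regions collapses to one all-ones row
  expect_identical(unname(presence(prof)["3:100:C:T", ]), c(1L, 1L, 1L))
  # same gene, different keys -> two distinct rows
  expect_identical(unname(presence(prof)["3:200:C:T", ]), c(1L, 0L, 0L))
  expect_identical(unname(presence(prof)["3:300:C:T", ]), c(0L, 1L, 0L))
  expect_identical(nrow(presence(prof)), 3L)

  # no calls anywhere: all declared regions survive as an empty matrix
  none <- buildPresenceMatrix(
    calls[0, ], data.frame(patient_id = "T2", region_id = sprintf("R%d", 1:4))
  )[["T2"]]
  expect_identical(dim(presence(none)), c(0L, 4L))
  expect_identical(classifyTopology(none), "NO_MUTATIONS")

  # a call in an undeclared region is rejected
  stray <- calls
  stray$region_id[1] <- "R9"
  expect_error(buildPresenceMatrix(stray, regs), "undeclared region")
})

test_that("shared/nonshared labels follow the all-cores definition", {
  prof <- mkProfile("T1", 4, list(
    mut("VHL", sprintf("R%d", 1:4), "a"),
    mut("SETD2", sprintf("R%d", 1:3), "b")
  ))
  lab <- mutationLabels(prof)
  expect_identical(unname(lab["a"]), "shared")
  expect_identical(unname(lab["b"]), "nonshared")

  # single-region tumor: every mutation is trivially shared
  single <- mkProfile("T2", 1, list(mut("VHL", "R1", "c")))
  expect_identical(unname(mutationLabels(single)["c"]), "shared")
})

test_that("labels are invariant to call order", {
  calls <- data.frame(
    patient_id = "T1", region_id = c("R1", "R2", "R2", "R1"),
    gene = c("VHL", "VHL", "BAP1", "SETD2"),
    chrom = "3", pos = c(1L, 1L, 2L, 3L), ref = "A", alt = "G",
    depth = 50L, alt_reads = 25L, consequence = "missense",
    in_dbsnp = FALSE, is_indel = FALSE
  )
  regs <- data.frame(patient_id = "T1", region_id = c("R1", "R2"))
  ref <- buildPresenceMatrix(calls, regs)[["T1"]]
  set.seed(42)
  for (i in 1:10) {
    shuf <- buildPresenceMatrix(calls[sample(nrow(calls)), ], regs)[["T1"]]
    keys <- rownames(presence(ref))
    expect_identical(presence(shuf)[keys, ], presence(ref)[keys, ])
    expect_identical(mutationLabels(shuf)[keys], mutationLabels(ref)[keys])
  }
})

test_that("cohort frequencies reproduce the study's per-patient and per-core rates", {
  coh <- paperStyleCohort()
  freq <- cohortFrequencies(coh)
  rownames(freq) <- freq$gene

  expect_identical(freq["VHL", "n_patients_mutant"], 9L)
  expect_identical(freq["VHL", "n_patients"], 14L)
  expect_equal(freq["VHL", "patient_rate"], 9 / 14)
  expect_identical(freq["VHL", "n_biopsies_mutant"], 29L)
  expect_identical(freq["VHL", "n_biopsies"], 47L)

  expect_identical(freq[c("PBRM1", "SETD2", "BAP1", "KDM5C"),
                        "n_patients_mutant"], c(5L, 3L, 3L, 4L))
  expect_identical(freq[c("PBRM1", "SETD2", "BAP1", "KDM5C"),
                        "n_biopsies_mutant"], c(13L, 7L, 6L, 6L))

  expect_true(all(freq$n_patients_mutant <= freq$n_patients))
  expect_true(all(freq$n_biopsies_mutant <= freq$n_biopsies))
  expect_error(cohortFrequencies(cohortData(list())), "empty cohort")
})

test_that("ubiquity fractions match the cohort's per-gene sharing pattern", {
  coh <- paperStyleCohort()
  expect_equal(ubiquityFraction(coh, "VHL")$fraction, 1.0)
  expect_equal(ubiquityFraction(coh, "PBRM1")$fraction, 0.60)
  expect_equal(ubiquityFraction(coh, "SETD2")$fraction, 1 / 3)
  expect_equal(ubiquityFraction(coh, "BAP1")$fraction, 1 / 3)
  expect_equal(ubiquityFraction(coh, "KDM5C")$fraction, 0.25)

  # undefined (not zero) for a gene with no mutant tumor
  expect_error(ubiquityFraction(coh, "TP53"), class = "undefinedEstimate")
})

test_that("mutations-per-tumor histogram counts variant keys, not genes", {
  coh <- paperStyleCohort()
  h <- mutationsPerTumor(coh)
  expect_identical(unname(h["0"]), 3L)
  expect_identical(unname(h["1"]), 4L)
  # conservation: sum over bins equals the cohort's unique mutation total
  total <- sum(as.integer(names(h)) * h)
  direct <- sum(vapply(profiles(coh), function(p) nrow(presence(p)),
                       integer(1)))
  expect_identical(total, direct)
  # the double-mutant tumor contributes 5 mutations across 4 genes
  t08 <- profiles(coh)[[8]]
  expect_identical(nrow(presence(t08)), 5L)
  expect_identical(length(unique(mutationGenes(t08))), 4L)

  expect_length(mutationsPerTumor(cohortData(list())), 0L)
})
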