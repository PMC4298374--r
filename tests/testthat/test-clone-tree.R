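test_that("compatibility flags exactly the overlapping-without-nesting pairs", {
  # disjoint rows: compatible
  p1 <- mkProfile("a", 4, list(mut("VHL", c("R1", "R2"), "x"),
                               mut("BAP1", c("R3", "R4"), "y")))
  expect_identical(nrow(checkCompatibility(p1)), 0L)

  # overlap without nesting: one conflict
  p2 <- mkProfile("b", 3, list(mut("VHL", c("R1", "R2"), "x"),
                               mut("BAP1", c("R2", "R3"), "y")))
  conf <- checkCompatibility(p2)
  expect_identical(nrow(conf), 1L)
  expect_setequal(unlist(conf[1, ]), c("x", "y"))
  expect_error(buildCloneTree(p2), "no perfect phylogeny")

  # an all-ones row nests everything
  p3 <- mkProfile("c", 3, list(mut("VHL", sprintf("R%d", 1:3), "x"),
                               mut("BAP1", c("R2", "R3"), "y"),
                               mut("SETD2", "R1", "z")))
  expect_identical(nrow(checkCompatibility(p3)), 0L)
})

test_that("compatibility matches exhaustive tree enumeration on small inputs", {
  set.seed(101)
  for (i in 1:60) {
    k <- sample(2:4, 1)
    n <- sample(2:4, 1)
    m <- matrix(rbinom(n * k, 1, 0.5), nrow = n,
                dimnames = list(sprintf("m%d", 1:n), sprintf("R%d", 1:k)))
    m[rowSums(m) == 0, 1] <- 1L
    m <- m[!duplicated(rownames(m)), , drop = FALSE]
    prof <- tumorProfile("t", colnames(m), m,
                         setNames(rep("VHL", nrow(m)), rownames(m)))
    laminar <- nrow(checkCompatibility(prof)) == 0L
    expect_identical(laminar, bruteForceTreeExists(m),
                     info = paste("case", i))
    if (laminar) {
      tree <- buildCloneTree(prof)
      replay <- replayPresence(tree, regionOrder = colnames(m))
      expect_identical(replay[rownames(m), , drop = FALSE], m,
                       info = paste("replay case", i))
    }
  }
})

test_that("trunk and branch structure follow region-set containment", {
  # single shared mutation, four regions: trunk with four leaves
  single <- mkProfile("t", 4, list(mut("VHL", sprintf("R%d", 1:4), "v")))
  tree <- buildCloneTree(single)
  expect_identical(tree@root$mutations, "v")
  expect_identical(tree@root$regions, sprintf("R%d", 1:4))
  expect_length(tree@root$children, 0L)

  # shared VHL+PBRM1, nonshared SETD2 in {R1,R2} of 4: unique containment tree
  branched <- mkProfile("t", 4, list(
    mut("SETD2", c("R1", "R2"), "s"),
    mut("PBRM1", sprintf("R%d", 1:4), "p"),
    mut("VHL", sprintf("R%d", 1:4), "v")
  ))
  tr <- buildCloneTree(branched)
  # trunk carries both shared mutations in canonical panel order (VHL first)
  expect_identical(tr@root$mutations, c("v", "p"))
  expect_identical(tr@root$regions, c("R3", "R4"))
  expect_length(tr@root$children, 1L)
  expect_identical(tr@root$children[[1]]$mutations, "s")
  expect_identical(tr@root$children[[1]]$regions, c("R1", "R2"))

  # empty matrix: root-only tree carrying all leaves
  bare <- buildCloneTree(mkProfile("t", 3))
  expect_length(bare@root$mutations, 0L)
  expect_identical(bare@root$regions, sprintf("R%d", 1:3))

  # equal region-sets collapse onto one edge
  twin <- mkProfile("t", 3, list(mut("VHL", c("R1", "R2"), "a"),
                                 mut("BAP1", c("R1", "R2"), "b")))
  ttwin <- buildCloneTree(twin)
  expect_identical(ttwin@root$children[[1]]$mutations, c("a", "b"))
})

test_that("round trip reproduces presence on random laminar matrices", {
  set.seed(202)
  for (i in 1:100) {
    prof <- randLaminarProfile(sprintf("p%d", i))
    tree <- buildCloneTree(prof)
    m <- presence(prof)
    replay <- replayPresence(tree, regionOrder = colnames(m))
    expect_identical(replay[rownames(m), , drop = FALSE], m,
                     info = paste("seed case", i))
  }
})

test_that("topology classification partitions any cohort", {
  coh <- paperStyleCohort()
  cats <- vapply(profiles(coh), classifyTopology, character(1))
  tab <- table(factor(cats, levels = topologyCategories()))
  expect_identical(
    as.integer(tab),
    c(3L, 4L, 3L, 1L, 3L)  # single-shared, multi-shared, mixed, nonshared, none
  )
  expect_identical(sum(tab), length(profiles(coh)))

  one_ns <- mkProfile("t", 3, list(mut("KDM5C", "R1", "k")))
  expect_identical(classifyTopology(one_ns), "NONSHARED_ONLY")
})

test_that("newick rendering round-trips and DOT reflects the clone graph", {
  bare <- buildCloneTree(mkProfile("t", 3))
  expect_identical(renderTree(bare, "newick"), "(R1,R2,R3);")

  coh <- paperStyleCohort()
  for (p in profiles(coh)) {
    tree <- buildCloneTree(p)
    txt <- renderTree(tree, "newick")
    reparsed <- parseCloneTreeNewick(txt, patientId(tree))
    expect_identical(renderTree(reparsed, "newick"), txt,
                     info = patientId(p))
  }

  # single-trunk tumor: DOT has one clone box feeding all four region leaves
  single <- buildCloneTree(
    mkProfile("t", 4, list(mut("VHL", sprintf("R%d", 1:4), "v")))
  )
  dot <- renderTree(single, "dot")
  expect_identical(length(gregexpr("clone1 -> ", dot)[[1]]), 4L)
  expect_match(dot, "label=\"VHL\"")
  expect_error(renderTree(single, "svg"))
})

test_that("conflict repair mode drops a minimal greedy set and reports it", {
  prof <- mkProfile("t", 3, list(mut("VHL", c("R1", "R2"), "x"),
                                 mut("BAP1", c("R2", "R3"), "y"),
                                 mut("SETD2", sprintf("R%d", 1:3), "z")))
  tree <- buildCloneTree(prof, onConflict = "drop")
  dropped <- attr(tree, "dropped")
  expect_length(dropped, 1L)
  expect_true(dropped %in% c("x", "y"))
  kept <- setdiff(c("x", "y", "z"), dropped)
  replay <- replayPresence(tree, regionOrder = regions(prof))
  expect_identical(sort(rownames(replay)), sort(kept))
})
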