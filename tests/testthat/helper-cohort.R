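# Builders used across test files.

mut <- function(gene, set, key) list(gene = gene, set = set, key = key)

mkProfile <- function(pid, k, muts = list()) {
  regs <- sprintf("R%d", seq_len(k))
  if (!length(muts)) return(tumorProfile(pid, regs))
  keys <- vapply(muts, `[[`, character(1), "key")
  m <- matrix(0L, nrow = length(muts), ncol = k,
              dimnames = list(keys, regs))
  for (i in seq_along(muts)) m[i, muts[[i]]$set] <- 1L
  genes <- setNames(vapply(muts, `[[`, character(1), "gene"), keys)
  tumorProfile(pid, regs, m, genes)
}

# A 14-tumor / 47-core cohort constructed to satisfy the printed
# sentence-level counts of the study: VHL mutated in 9/14 patients and
# 29/47 cores (always ubiquitously), PBRM1 in 5 patients / 13 cores
# (ubiquitous in 3/5), SETD2 in 3 patients / 7 cores (1/3), BAP1 in
# 3 patients / 6 cores (1/3, one tumor with two distinct mutations in
# different cores), KDM5C in 4 patients / 6 cores (1/4); topology
# categories 3/4/3/1/3; three tumors with zero and four with exactly one
# mutation.
paperStyleCohort <- function() {
  all3 <- sprintf("R%d", 1:3)
  all4 <- sprintf("R%d", 1:4)
  all5 <- sprintf("R%d", 1:5)
  profs <- list(
    mkProfile("T01", 4, list(mut("VHL", all4, "vhl.1"))),
    mkProfile("T02", 3, list(mut("VHL", all3, "vhl.2"))),
    mkProfile("T03", 3, list(mut("VHL", all3, "vhl.3"))),
    mkProfile("T04", 3, list(mut("VHL", all3, "vhl.4"),
                             mut("PBRM1", all3, "pbrm1.1"))),
    mkProfile("T05", 3, list(mut("VHL", all3, "vhl.5"),
                             mut("KDM5C", all3, "kdm5c.1"))),
    mkProfile("T06", 3, list(mut("VHL", all3, "vhl.6"),
                             mut("PBRM1", all3, "pbrm1.2"))),
    mkProfile("T07", 3, list(mut("VHL", all3, "vhl.7"),
                             mut("BAP1", all3, "bap1.1"))),
    mkProfile("T08", 5, list(mut("SETD2", all5, "setd2.1"),
                             mut("KDM5C", "R1", "kdm5c.2"),
                             mut("BAP1", "R2", "bap1.2a"),
                             mut("BAP1", "R3", "bap1.2b"),
                             mut("PBRM1", c("R1", "R2"), "pbrm1.3"))),
    mkProfile("T09", 4, list(mut("VHL", all4, "vhl.8"),
                             mut("PBRM1", c("R1", "R2"), "pbrm1.4"),
                             mut("SETD2", "R1", "setd2.2"),
                             mut("KDM5C", "R1", "kdm5c.3"))),
    mkProfile("T10", 3, list(mut("VHL", all3, "vhl.9"),
                             mut("PBRM1", all3, "pbrm1.5"),
                             mut("SETD2", "R1", "setd2.3"),
                             mut("BAP1", "R2", "bap1.3"))),
    mkProfile("T11", 4, list(mut("KDM5C", "R1", "kdm5c.4"))),
    mkProfile("T12", 3),
    mkProfile("T13", 3),
    mkProfile("T14", 3)
  )
  cohortData(profs)
}

# Independent laminar-matrix generator (recursive random bipartition),
# separate from the package's simulator on purpose.
randLaminarProfile <- function(pid, maxMut = 6, maxReg = 5) {
  k <- sample(2:maxReg, 1)
  regs <- sprintf("R%d", seq_len(k))
  splitDown <- function(r) {
    if (length(r) <= 1) return(list())
    i <- sample.int(length(r) - 1, 1)
    idx <- sample.int(length(r), i)
    c(list(r[idx], r[-idx]), splitDown(r[idx]), splitDown(r[-idx]))
  }
  pool <- c(list(regs), splitDown(regs))
  n <- sample.int(maxMut, 1)
  sets <- pool[sample.int(length(pool), n, replace = TRUE)]
  m <- matrix(0L, nrow = n, ncol = k,
              dimnames = list(sprintf("m%d", seq_len(n)), regs))
  for (i in seq_len(n)) m[i, sets[[i]]] <- 1L
  genes <- setNames(rep("VHL", n), rownames(m))
  tumorProfile(pid, regs, m, genes)
}

# Random matrix with a planted nested-or-disjoint violation.
randConflictProfile <- function(pid, maxMut = 6, maxReg = 5) {
  k <- sample(3:maxReg, 1)
  regs <- sprintf("R%d", seq_len(k))
  n <- sample(2:maxMut, 1)
  m <- matrix(rbinom(n * k, 1, 0.5), nrow = n, ncol = k,
              dimnames = list(sprintf("m%d", seq_len(n)), regs))
  m[rowSums(m) == 0, 1] <- 1L
  trio <- sample.int(k, 3)
  m[1, trio] <- c(1L, 1L, 0L)
  m[2, trio] <- c(0L, 1L, 1L)
  genes <- setNames(rep("VHL", n), rownames(m))
  tumorProfile(pid, regs, m, genes)
}

# Exhaustive perfect-phylogeny oracle: enumerate every parent assignment
# of mutations (parent = another mutation or the wild-type root), and ask
# whether some assignment's path-closures cover every region's observed
# mutation set. Feasible for <= 4 mutations.
bruteForceTreeExists <- function(m) {
  n <- nrow(m)
  if (n <= 1) return(TRUE)
  stopifnot(n <= 4)
  regsets <- apply(m, 2, function(col) unname(which(col == 1L)),
                   simplify = FALSE)
  grids <- expand.grid(rep(list(0:n), n))
  for (g in seq_len(nrow(grids))) {
    par <- as.integer(grids[g, ])
    if (any(par == seq_len(n))) next
    ## path closure; reject cyclic assignments
    ok <- TRUE
    paths <- vector("list", n)
    for (i in seq_len(n)) {
      path <- integer()
      j <- i
      while (j != 0) {
        if (j %in% path) { ok <- FALSE; break }
        path <- c(path, j)
        j <- par[j]
      }
      if (!ok) break
      paths[[i]] <- sort(path)
    }
    if (!ok) next
    closures <- c(list(integer()), paths)
    fits <- all(vapply(regsets, function(rs) {
      any(vapply(closures, function(cl) identical(cl, sort(rs)), logical(1)))
    }, logical(1)))
    if (fits) return(TRUE)
  }
  FALSE
}
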