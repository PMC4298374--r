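#' Topology categories of clonal trees
#'
#' The five branching patterns a five-gene multi-region assay can reveal:
#' a single shared mutation only; multiple shared mutations only; both
#' shared and nonshared mutations; nonshared mutations only; and no
#' mutations at all.
#'
#' @return Character vector of the category codes.
#' @export
topologyCategories <- function() {
  c("SINGLE_SHARED_ONLY", "MULTIPLE_SHARED_ONLY", "SHARED_AND_NONSHARED",
    "NONSHARED_ONLY", "NO_MUTATIONS")
}

## region-sets per mutation as a named list of sorted character vectors
.regionSets <- function(profile) {
  p <- profile@presence
  if (nrow(p) == 0L) return(list())
  sets <- apply(p, 1L, function(r) sort(colnames(p)[r == 1L]),
                simplify = FALSE)
  names(sets) <- rownames(p)
  sets
}

#' Check perfect-phylogeny compatibility of a presence matrix
#'
#' Under the clonal-evolution model (every mutation gained once from an
#' all-wild-type ancestor, never lost), the observed mutations of a tumor
#' fit a single rooted tree iff the region-sets of any two mutations are
#' nested or disjoint (a laminar family). This returns every violating pair:
#' mutations whose region-sets overlap without either containing the other.
#'
#' @param profile A \linkS4class{TumorProfile}.
#' @return Data frame with columns \code{mut1}, \code{mut2} (variant keys);
#'   zero rows iff a perfect phylogeny exists.
#' @export
checkCompatibility <- function(profile) {
  sets <- .regionSets(profile)
  out <- data.frame(mut1 = character(), mut2 = character())
  n <- length(sets)
  if (n < 2L) return(out)
  keys <- names(sets)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- sets[[i]]; b <- sets[[j]]
      inter <- length(intersect(a, b))
      if (inter > 0L && inter < length(a) && inter < length(b)) {
        out <- rbind(out, data.frame(mut1 = keys[i], mut2 = keys[j]))
      }
    }
  }
  out
}

#' Reconstruct the clonal tree of one tumor
#'
#' Orders mutations by region-set containment: mutations detected in every
#' region (shared/truncal) form the trunk; each maximal region-set under
#' containment starts a branch; mutations with identical region-sets are
#' carried on one edge (the data cannot order or separate them); every
#' region attaches as a leaf to the clone whose accumulated mutation set
#' equals that region's observed mutations. Incompatible matrices are
#' refused with the conflict list unless \code{onConflict = "drop"}, which
#' greedily removes conflicting mutations (fewest-regions-first) and
#' reports them.
#'
#' @param profile A \linkS4class{TumorProfile}.
#' @param onConflict \code{"error"} (default) or \code{"drop"}.
#' @return A \linkS4class{CloneTree}. When mutations were dropped, their
#'   variant keys are in \code{attr(tree, "dropped")}.
#' @export
buildCloneTree <- function(profile, onConflict = c("error", "drop")) {
  onConflict <- match.arg(onConflict)
  conflicts <- checkCompatibility(profile)
  dropped <- character()
  sets <- .regionSets(profile)
  if (nrow(conflicts) > 0L) {
    if (onConflict == "error") {
      stop(
        "presence matrix admits no perfect phylogeny; conflicting pairs: ",
        paste(conflicts$mut1, conflicts$mut2, sep = " ~ ", collapse = "; "),
        call. = FALSE
      )
    }
    ## greedy repair: repeatedly drop the conflicting mutation covering the
    ## fewest regions (ties broken by variant key) until laminar
    repeat {
      inConflict <- unique(c(conflicts$mut1, conflicts$mut2))
      if (length(inConflict) == 0L) break
      sizes <- vapply(sets[inConflict], length, integer(1))
      victim <- inConflict[order(sizes, inConflict)][1L]
      dropped <- c(dropped, victim)
      sets <- sets[names(sets) != victim]
      conflicts <- conflicts[conflicts$mut1 != victim &
                             conflicts$mut2 != victim, , drop = FALSE]
      if (nrow(conflicts) == 0L) break
    }
  }

  allRegions <- profile@regions
  ## one edge per distinct region-set; canonical mutation order on each edge
  keys <- names(sets)
  setIds <- vapply(sets, .setKey, character(1))
  uniqIds <- unique(setIds)
  edges <- lapply(uniqIds, function(id) {
    muts <- keys[setIds == id]
    list(regions = sets[[which(setIds == id)[1L]]],
         mutations = .canonicalMutationOrder(muts, profile@genes))
  })
  sizes <- vapply(edges, function(e) length(e$regions), integer(1))
  edges <- edges[order(-sizes)]

  trunkIdx <- which(vapply(
    edges, function(e) length(e$regions) == length(allRegions), logical(1)
  ))
  trunkMuts <- if (length(trunkIdx)) edges[[trunkIdx]]$mutations else
    character()
  branches <- if (length(trunkIdx)) edges[-trunkIdx] else edges

  root <- .growNode(trunkMuts, sort(allRegions), branches)
  root <- .orderNode(root, allRegions)
  tree <- new("CloneTree", patientId = profile@patientId, root = root,
              genes = profile@genes)
  attr(tree, "dropped") <- dropped
  tree
}

## recursive laminar-forest construction: place maximal sets under the
## current node, attach uncovered regions as leaves here
.growNode <- function(mutations, regionSet, edges) {
  sizes <- vapply(edges, function(e) length(e$regions), integer(1))
  childIdx <- integer()
  claimed <- character()
  for (i in order(-sizes)) {
    r <- edges[[i]]$regions
    if (!all(r %in% regionSet)) next  # belongs to another subtree
    if (any(r %in% claimed)) next     # nested inside an already-chosen child
    childIdx <- c(childIdx, i)
    claimed <- c(claimed, r)
  }
  children <- lapply(childIdx, function(i) {
    inner <- Filter(function(e) {
      all(e$regions %in% edges[[i]]$regions) &&
        !identical(.setKey(e$regions), .setKey(edges[[i]]$regions))
    }, edges)
    .growNode(edges[[i]]$mutations, edges[[i]]$regions, inner)
  })
  list(
    mutations = mutations,
    regions = setdiff(regionSet, claimed),
    children = children
  )
}

## deterministic ordering: leaves in declared region order, children by
## their first region's declared position
.orderNode <- function(node, regionOrder) {
  node$regions <- node$regions[order(match(node$regions, regionOrder))]
  if (length(node$children)) {
    node$children <- lapply(node$children, .orderNode, regionOrder)
    first <- vapply(node$children, function(ch) {
      min(match(.nodeRegions(ch), regionOrder))
    }, numeric(1))
    node$children <- node$children[order(first)]
  }
  node
}

.nodeRegions <- function(node) {
  c(node$regions, unlist(lapply(node$children, .nodeRegions)))
}

## trunk-panel order (VHL, PBRM1, SETD2, BAP1, KDM5C, then alphabetical
## genes), ties within a gene by variant key
.canonicalMutationOrder <- function(keys, genes) {
  if (length(keys) < 2L) return(keys)
  g <- unname(genes[keys])
  g[is.na(g)] <- ""
  rank <- match(g, defaultGenePanel())
  rank[is.na(rank)] <- length(defaultGenePanel()) + 1L
  keys[order(rank, g, keys)]
}

#' Classify the branching topology of one tumor
#'
#' @param profile A \linkS4class{TumorProfile} (labels computed).
#' @return One of \code{\link{topologyCategories}()}:
#'   \code{NO_MUTATIONS} (zero mutations), \code{SINGLE_SHARED_ONLY}
#'   (exactly one mutation, shared), \code{MULTIPLE_SHARED_ONLY} (two or
#'   more, all shared), \code{NONSHARED_ONLY} (at least one mutation, none
#'   shared), \code{SHARED_AND_NONSHARED} otherwise.
#' @export
classifyTopology <- function(profile) {
  lab <- profile@labels
  n <- length(lab)
  nShared <- sum(lab == "shared")
  if (n == 0L) return("NO_MUTATIONS")
  if (nShared == n) {
    return(if (n == 1L) "SINGLE_SHARED_ONLY" else "MULTIPLE_SHARED_ONLY")
  }
  if (nShared == 0L) return("NONSHARED_ONLY")
  "SHARED_AND_NONSHARED"
}

#' Render a clone tree as Newick or Graphviz DOT text
#'
#' Newick output labels leaves with region ids and carries each edge's
#' mutation list in a \code{[&muts=a|b]} comment after the node; the dialect
#' round-trips losslessly through \code{\link{parseCloneTreeNewick}}. DOT
#' output has one node per clone (labelled with the gene names of the
#' mutations gained on its incoming edge) and one terminal node per region.
#'
#' @param tree A \linkS4class{CloneTree}.
#' @param format \code{"newick"} or \code{"dot"}.
#' @return Single character string.
#' @export
renderTree <- function(tree, format = c("newick", "dot")) {
  format <- match.arg(format)
  if (format == "newick") {
    paste0(.newickNode(tree@root), ";")
  } else {
    .dotTree(tree)
  }
}

.mutComment <- function(mutations) {
  if (length(mutations) == 0L) return("")
  sprintf("[&muts=%s]", paste(mutations, collapse = "|"))
}

.newickNode <- function(node) {
  parts <- c(
    vapply(node$children, .newickNode, character(1)),
    node$regions
  )
  if (length(parts) == 0L) parts <- ""
  paste0("(", paste(parts, collapse = ","), ")", .mutComment(node$mutations))
}

.dotTree <- function(tree) {
  lines <- c(sprintf("digraph clones_%s {", gsub("\\W", "_", tree@patientId)),
             "  node [shape=box];")
  counter <- new.env()
  counter$i <- 0L
  emit <- function(node, parentId) {
    counter$i <- counter$i + 1L
    id <- sprintf("clone%d", counter$i)
    genes <- unname(tree@genes[node$mutations])
    genes[is.na(genes)] <- node$mutations[is.na(genes)]
    label <- if (length(genes)) paste(genes, collapse = "\\n") else "WT"
    lines <<- c(lines, sprintf("  %s [label=\"%s\"];", id, label))
    if (!is.null(parentId)) {
      lines <<- c(lines, sprintf("  %s -> %s;", parentId, id))
    }
    for (r in node$regions) {
      lines <<- c(lines, sprintf(
        "  \"%s\" [shape=ellipse];\n  %s -> \"%s\";", r, id, r
      ))
    }
    for (ch in node$children) emit(ch, id)
  }
  emit(tree@root, NULL)
  paste(c(lines, "}"), collapse = "\n")
}

#' Parse the package's annotated Newick dialect back into a CloneTree
#'
#' Inverse of \code{renderTree(tree, "newick")}: internal nodes are
#' parenthesized groups optionally followed by a \code{[&muts=...]} comment,
#' leaves are bare region labels.
#'
#' @param text Newick string.
#' @param patientId Identifier for the resulting tree.
#' @return A \linkS4class{CloneTree} (gene map empty: the text does not
#'   carry it).
#' @export
parseCloneTreeNewick <- function(text, patientId = "parsed") {
  s <- sub(";\\s*$", "", trimws(text))
  pos <- 1L
  nchars <- nchar(s)
  peek <- function() if (pos <= nchars) substr(s, pos, pos) else ""
  advance <- function() pos <<- pos + 1L
  readLabel <- function() {
    start <- pos
    while (pos <= nchars && !(peek() %in% c("(", ")", ",", "[", ";"))) {
      advance()
    }
    substr(s, start, pos - 1L)
  }
  readComment <- function() {
    if (peek() != "[") return(character())
    close <- regexpr("]", substr(s, pos, nchars), fixed = TRUE)
    if (close < 0L) stop("unterminated [ comment in Newick", call. = FALSE)
    body <- substr(s, pos + 1L, pos + close - 2L)
    pos <<- pos + close
    if (!startsWith(body, "&muts=")) return(character())
    strsplit(sub("^&muts=", "", body), "|", fixed = TRUE)[[1]]
  }
  parseNode <- function() {
    if (peek() != "(") stop("expected '(' in Newick", call. = FALSE)
    advance()
    regions <- character()
    children <- list()
    repeat {
      if (peek() == "(") {
        children <- c(children, list(parseNode()))
      } else {
        lbl <- readLabel()
        if (nzchar(lbl)) regions <- c(regions, lbl)
      }
      if (peek() == ",") { advance(); next }
      if (peek() == ")") { advance(); break }
      stop("malformed Newick near position ", pos, call. = FALSE)
    }
    list(mutations = readComment(), regions = regions, children = children)
  }
  root <- parseNode()
  new("CloneTree", patientId = as.character(patientId), root = root,
      genes = character())
}

#' Replay a clone tree back into its presence matrix
#'
#' Walks the tree accumulating edge mutations from the root and assigns each
#' leaf region the mutation set of its clone. For any tree built from a
#' compatible profile this reproduces the input presence matrix exactly.
#'
#' @param tree A \linkS4class{CloneTree}.
#' @param regionOrder Optional column order; defaults to leaf order.
#' @return Integer 0/1 matrix, mutations x regions.
#' @export
replayPresence <- function(tree, regionOrder = NULL) {
  acc <- list()
  walk <- function(node, inherited) {
    here <- c(inherited, node$mutations)
    for (r in node$regions) acc[[r]] <<- here
    for (ch in node$children) walk(ch, here)
  }
  walk(tree@root, character())
  regs <- regionOrder %||% names(acc)
  muts <- unique(unlist(acc, use.names = FALSE))
  m <- matrix(0L, nrow = length(muts), ncol = length(regs),
              dimnames = list(muts, regs))
  for (r in regs) m[acc[[r]], r] <- 1L
  m
}
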