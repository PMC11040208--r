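# Protein p-distances, Saitou-Nei neighbor-joining and bootstrap supports.
#
# The NJ agglomeration and the bipartition bookkeeping are implemented here
# (deterministic tie-breaks, explicit clamping); trees are represented as ape
# "phylo" objects and written with ape.

#' Read an aligned protein FASTA
#'
#' @param path FASTA file of pre-aligned amino-acid sequences (gaps `-`).
#' @return named character vector of aligned sequences (equal lengths).
#' @export
read_alignment <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  aln <- setNames(as.character(s), names(s))
  validate_alignment(aln)
  aln
}

validate_alignment <- function(aln) {
  if (length(aln) < 2) stop2("alignment needs at least 2 sequences")
  w <- nchar(aln)
  if (length(unique(w)) != 1 || w[1] < 1)
    stop2("aligned sequences must all have the same non-zero length")
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    stop2("sequences must carry unique names")
  invisible(aln)
}

aln_matrix <- function(aln) {
  validate_alignment(aln)
  m <- do.call(rbind, strsplit(toupper(unname(aln)), ""))
  rownames(m) <- names(aln)
  m
}

#' Pairwise p-distances from an aligned protein set
#'
#' p-distance with pairwise deletion: for each pair, columns where either
#' sequence has a gap (`-`, `.`, `?`, `X`) are dropped and the distance is
#' the fraction of differing remaining columns.  This mirrors the common
#' quick-NJ default for protein alignments.  A Poisson correction
#' `-log(1 - p)` is available behind `model = "poisson"`.
#'
#' @param aln named character vector of aligned sequences (or an
#'   `AAStringSet`).
#' @param model `"p"` (default) or `"poisson"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
p_distance <- function(aln, model = c("p", "poisson")) {
  model <- match.arg(model)
  if (methods::is(aln, "AAStringSet")) aln <- setNames(as.character(aln), names(aln))
  m <- aln_matrix(aln)
  gap <- m %in% c("-", ".", "?", "X")
  dim(gap) <- dim(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- !gap[i, ] & !gap[j, ]
    nc <- sum(comp)
    if (nc == 0)
      stop2("no comparable columns between '", rownames(m)[i], "' and '",
            rownames(m)[j], "'")
    p <- sum(m[i, comp] != m[j, comp]) / nc
    if (model == "poisson") {
      if (p >= 1) stop2("saturated pair (p = 1): Poisson distance undefined")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

fmt_len <- function(x) sprintf("%.12g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly join the pair minimising
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j` (`R` = row sums over the `r` active
#' clusters), with branch lengths from the standard NJ formulas.  Exact on
#' additive matrices.  Ties in Q are broken by the lowest active-cluster
#' index pair, so the result is deterministic; negative branch lengths are
#' clamped to zero and logged.
#'
#' @param dm symmetric numeric matrix (or `dist`) with zero diagonal and
#'   taxon dimnames; at least 3 taxa.
#' @return an unrooted `ape::phylo` tree (basal trifurcation).
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop2("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", 1:n)
  if (max(abs(dm - t(dm))) > 1e-8) stop2("distance matrix is asymmetric")
  if (max(abs(diag(dm))) > 1e-12) stop2("distance matrix diagonal is not zero")
  labs <- rownames(dm)
  bad <- grepl("[ ():,;\\[\\]']", labs)
  if (any(bad))
    stop2("taxon labels unsafe for Newick: ", paste(labs[bad], collapse = ", "))
  sub <- labs                      # newick fragment per active cluster
  D <- dm
  clamped <- 0L
  clamp <- function(x) {
    if (x < 0) clamped <<- clamped + 1L
    max(0, x)
  }
  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    hit <- which(Q <= qmin + tol, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    li <- clamp(0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2)))
    lj <- clamp(D[i, j] - (0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))))
    newsub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt_len(li), sub[j], fmt_len(lj))
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    sub <- c(sub[keep], newsub)
    D <- D2
  }
  a <- clamp(0.5 * (D[1, 2] + D[1, 3] - D[2, 3]))
  b <- clamp(0.5 * (D[1, 2] + D[2, 3] - D[1, 3]))
  c3 <- clamp(0.5 * (D[1, 3] + D[2, 3] - D[1, 2]))
  if (clamped > 0) sh_log(clamped, " negative branch length(s) clamped to 0")
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1], fmt_len(a),
                 sub[2], fmt_len(b), sub[3], fmt_len(c3))
  ape::read.tree(text = nwk)
}

# Non-trivial bipartitions of an unrooted tree, one per internal edge, as
# canonical keys: the sorted tip labels of the side NOT containing the
# alphabetically first taxon, so keys are invariant to taxa order/rooting.
bipartitions <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  ref <- all_tips[1]
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  keys <- character(0)
  root <- ntip + 1L
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next                      # trivial split
    side <- sets[[child]]
    if (ref %in% side) side <- setdiff(all_tips, side)
    if (length(side) < 2 || length(side) > ntip - 2) next
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

# key -> internal node number of the original tree (for node labelling)
bipartition_nodes <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  ref <- all_tips[1]
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  nodes <- integer(0); keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next
    side <- sets[[child]]
    if (ref %in% side) side <- setdiff(all_tips, side)
    if (length(side) < 2 || length(side) > ntip - 2) next
    nodes <- c(nodes, child)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  setNames(nodes, keys)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Columns of the alignment are resampled with replacement `B` times; each
#' replicate is run through [p_distance()] and [neighbor_joining()], and the
#' support of each internal edge of the original tree is the fraction of
#' replicate trees containing the same bipartition (compared as label sets,
#' hence invariant to taxa input order).  Replicates in which some pair has
#' no comparable columns are dropped and logged.
#'
#' @param aln named character vector of aligned sequences.
#' @param B number of bootstrap replicates (default 1000, the convention for
#'   published NJ trees).  `B = 0` returns the tree with no supports and a
#'   warning.
#' @param seed optional integer seed (resampling is deterministic under it).
#' @param model distance model passed to [p_distance()].
#' @return object of class `nj_boot`: list with `tree` (node labels carry
#'   integer support percentages), `supports` (data.frame `bipartition`,
#'   `support`), `B`, `n_dropped`, `seed`.
#' @export
bootstrap_support <- function(aln, B = 1000, seed = NULL,
                              model = c("p", "poisson")) {
  model <- match.arg(model)
  if (methods::is(aln, "AAStringSet")) aln <- setNames(as.character(aln), names(aln))
  validate_alignment(aln)
  tree <- neighbor_joining(p_distance(aln, model))
  bn <- bipartition_nodes(tree)
  counts <- setNames(numeric(length(bn)), names(bn))
  L <- nchar(aln[1])
  m <- aln_matrix(aln)
  if (!is.null(seed)) set.seed(seed)
  dropped <- 0L
  if (B > 0) {
    for (b in seq_len(B)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- setNames(apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
                          rownames(m))
      dmb <- tryCatch(p_distance(rep_aln, model), error = function(e) NULL)
      if (is.null(dmb)) { dropped <- dropped + 1L; next }
      keys <- bipartitions(neighbor_joining(dmb))
      hitk <- intersect(keys, names(counts))
      counts[hitk] <- counts[hitk] + 1
    }
    if (dropped > 0) sh_log(dropped, " bootstrap replicate(s) dropped")
  } else {
    warn2("B = 0: tree returned without bootstrap supports")
  }
  eff <- B - dropped
  support <- if (eff > 0) counts / eff else rep(NA_real_, length(counts))
  ntip <- length(tree$tip.label)
  node_lab <- rep("", tree$Nnode)
  if (length(bn))
    node_lab[bn - ntip] <- if (eff > 0)
      sprintf("%d", as.integer(round(100 * support))) else ""
  tree$node.label <- node_lab
  structure(list(tree = tree,
                 supports = data.frame(
                   bipartition = vapply(strsplit(names(counts), "\r"),
                                        paste, "", collapse = ","),
                   support = unname(support), stringsAsFactors = FALSE),
                 B = B, n_dropped = dropped, seed = seed),
            class = "nj_boot")
}

#' @export
print.nj_boot <- function(x, ...) {
  cat(sprintf("NJ tree: %d tips, %d bootstrap replicates (%d dropped)\n",
              length(x$tree$tip.label), x$B, x$n_dropped))
  if (nrow(x$supports)) {
    cat("internal-edge supports:\n")
    print(x$supports, row.names = FALSE)
  }
  invisible(x)
}

#' Write a tree (with supports as node labels) to Newick
#' @param x an `nj_boot` bundle or an `ape::phylo` tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  tree <- if (inherits(x, "nj_boot")) x$tree else x
  ape::write.tree(tree, file = path)
  invisible(path)
}
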