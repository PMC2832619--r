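# Distance matrices, neighbour joining, bootstrap supports, newick I/O.
#
# NJ is the Saitou-Nei agglomeration with the rate-adjusted selection
# criterion Q(i,j) = (r-2) d(i,j) - R_i - R_j.  Ties are broken by the
# lexicographically smallest pair of taxon labels (each cluster is
# represented by the smallest label it contains) and negative branch
# lengths are clamped to zero, so results are reproducible.

#' Pairwise distance matrix from an alignment
#'
#' Distances use pairwise-complete deletion: for each pair only columns
#' where both sequences carry an unambiguous residue are compared.
#' Models: `p_nt`/`p_aa` uncorrected proportion of differences,
#' `jc69_nt` Jukes-Cantor `-(3/4) ln(1 - (4/3) p)`, `poisson_aa`
#' Poisson correction `-ln(1 - p)`.
#'
#' @param aln A `codon_alignment`, a character matrix (rows = taxa) or a
#'   list of [cea_seq] of equal length.
#' @param model One of `"p_nt"`, `"jc69_nt"`, `"p_aa"`, `"poisson_aa"`.
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
distance_matrix <- function(aln, model = c("p_nt", "jc69_nt", "p_aa",
                                           "poisson_aa")) {
  model <- match.arg(model)
  mat <- if (inherits(aln, "codon_alignment")) aln$mat
  else if (is.matrix(aln)) aln
  else {
    ids <- vapply(aln, function(s) s$id, character(1))
    m <- t(vapply(aln, function(s) strsplit(toupper(s$residues), "")[[1]],
                  character(nchar(aln[[1]]$residues))))
    rownames(m) <- ids
    m
  }
  n <- nrow(mat)
  if (n < 2) stop("need at least two rows", call. = FALSE)
  ok_chars <- if (endsWith(model, "nt")) c("A", "C", "G", "T")
  else setdiff(AA_CHARS, c("X", "*", "-"))
  valid <- matrix(mat %in% ok_chars, n)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- valid[i, ] & valid[j, ]
    if (!any(use))
      stop(sprintf("empty overlap for pair %s/%s", rownames(mat)[i],
                   rownames(mat)[j]), call. = FALSE)
    p <- mean(mat[i, use] != mat[j, use])
    v <- switch(model,
                p_nt = , p_aa = p,
                jc69_nt = {
                  if (p >= 0.75)
                    stop(sprintf("saturation for pair %s/%s (p=%.3f)",
                                 rownames(mat)[i], rownames(mat)[j], p),
                         call. = FALSE)
                  -0.75 * log(1 - 4 / 3 * p)
                },
                poisson_aa = {
                  if (p >= 1)
                    stop(sprintf("saturation for pair %s/%s (p=%.3f)",
                                 rownames(mat)[i], rownames(mat)[j], p),
                         call. = FALSE)
                  -log(1 - p)
                })
    d[i, j] <- d[j, i] <- v
  }
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining on a symmetric distance matrix.  Exact
#' on additive (tree-metric) inputs.  Negative branch lengths are
#' clamped to 0; ties in the selection criterion are broken by the
#' lexicographically smallest taxon-label pair.
#'
#' @param dm Symmetric numeric matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted tree of class `phylo` (ape).
#' @export
nj_tree <- function(dm) {
  labels <- rownames(dm)
  n <- length(labels)
  if (is.null(labels) || n < 3) stop("need >= 3 labelled taxa", call. = FALSE)
  if (!isTRUE(all.equal(dm, t(dm))) || any(diag(dm) != 0))
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  # each active cluster: newick fragment + smallest contained label
  frag <- labels
  minlab <- labels
  d <- dm
  fmt <- function(x) sprintf("%.10g", max(0, x))
  while (nrow(d) > 3) {
    r <- nrow(d)
    R <- rowSums(d)
    q <- (r - 2) * d - outer(R, R, `+`)
    diag(q) <- Inf
    best <- NULL; best_q <- Inf; best_key <- NULL
    for (i in seq_len(r - 1)) for (j in (i + 1):r) {
      key <- sort(c(minlab[i], minlab[j]))
      if (q[i, j] < best_q - 1e-12 ||
          (abs(q[i, j] - best_q) <= 1e-12 &&
           (is.null(best_key) ||
            key[1] < best_key[1] ||
            (key[1] == best_key[1] && key[2] < best_key[2])))) {
        best <- c(i, j); best_q <- q[i, j]; best_key <- key
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    new_min <- min(minlab[i], minlab[j])
    keep <- setdiff(seq_len(r), c(i, j))
    nd <- (d[i, keep] + d[j, keep] - d[i, j]) / 2
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], nd), c(nd, 0))
    frag <- c(frag[keep], new_frag)
    minlab <- c(minlab[keep], new_min)
    d <- d2
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(la), frag[2],
                 fmt(lb), frag[3], fmt(lc))
  ape::read.tree(text = txt)
}

# canonical keys of the non-trivial bipartitions of an unrooted tree:
# for each internal edge, the sorted tip labels of the side not
# containing the alphabetically first taxon (internal)
.tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  n_tip <- length(tree$tip.label)
  keys <- character(0)
  nodes <- integer(0)
  for (node in (n_tip + 1):(n_tip + tree$Nnode)) {
    desc <- tree$tip.label[.descendant_tips(tree, node)]
    if (ref %in% desc) desc <- setdiff(tips, desc)
    if (length(desc) < 2 || length(desc) > n_tip - 2) next
    keys <- c(keys, paste(sort(desc), collapse = "|"))
    nodes <- c(nodes, node)
  }
  stats::setNames(nodes, keys)
}

# tip indices descending from a node (internal)
.descendant_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  todo <- node
  tips <- integer(0)
  while (length(todo)) {
    cur <- todo[1]; todo <- todo[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    tips <- c(tips, kids[kids <= n_tip])
    todo <- c(todo, kids[kids > n_tip])
  }
  tips
}

#' Neighbour-joining tree with bootstrap supports
#'
#' Builds the point-estimate tree, then resamples alignment columns
#' with replacement `B` times (codon columns for a codon alignment,
#' single sites otherwise) and records, for each internal bipartition
#' of the point tree, the percentage of replicate trees containing it.
#' Supports are stored as internal node labels.  Deterministic given
#' `seed`.
#'
#' @param aln A `codon_alignment` or character matrix.
#' @param model Distance model, see [distance_matrix].
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Random seed (mandatory).
#' @return A `phylo` tree with `node.label` holding supports in
#'   `[0, 100]` (empty for the root/trivial splits).
#' @export
nj_bootstrap <- function(aln, model = "jc69_nt", B = 1000L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(B >= 1)
  set.seed(seed)
  is_codon <- inherits(aln, "codon_alignment")
  mat <- if (is_codon) aln$mat else aln
  point <- nj_tree(distance_matrix(aln, model))
  splits <- .tree_splits(point)
  hits <- stats::setNames(numeric(length(splits)), names(splits))
  n_col <- ncol(mat)
  if (is_codon) {
    n_unit <- n_col %/% 3L
    if (n_unit < 2) warning("degenerate alignment: resampling over ",
                            n_unit, " codon column(s)")
  } else if (n_col < 2) warning("degenerate alignment: 1 column")
  for (b in seq_len(B)) {
    cols <- if (is_codon) {
      u <- sample.int(n_col %/% 3L, replace = TRUE)
      as.vector(rbind(3L * u - 2L, 3L * u - 1L, 3L * u))
    } else sample.int(n_col, replace = TRUE)
    bmat <- mat[, cols, drop = FALSE]
    baln <- if (is_codon)
      build_codon_alignment(lapply(rownames(bmat), function(id)
        cea_seq(id, paste(bmat[id, ], collapse = ""), "nucleotide")))
    else bmat
    btree <- tryCatch(nj_tree(distance_matrix(baln, model)),
                      error = function(e) NULL)
    if (is.null(btree)) next
    bkeys <- names(.tree_splits(btree))
    found <- names(hits) %in% bkeys
    hits[found] <- hits[found] + 1
  }
  support <- round(100 * hits / B)
  n_tip <- length(point$tip.label)
  lab <- rep("", point$Nnode)
  lab[unname(splits) - n_tip] <- as.character(support)
  point$node.label <- lab
  point
}

#' Write a tree as newick text
#'
#' Bootstrap supports (node labels) are preserved as internal-node
#' labels.
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when `NULL` the newick string is
#'   returned.
#' @return The newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a newick tree
#'
#' @param text Newick string (or `file` given instead).
#' @param file Optional path to a newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE),
                                   collapse = "")
  bal <- cumsum((strsplit(text, "")[[1]] == "(") -
                (strsplit(text, "")[[1]] == ")"))
  if (length(bal) && (any(bal < 0) || utils::tail(bal, 1) != 0))
    stop("newick parse error: unbalanced parenthesis at offset ",
         if (any(bal < 0)) which(bal < 0)[1] else length(bal),
         call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop("newick parse error: missing ';' terminator at offset ",
         nchar(text), call. = FALSE)
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tr) || is.null(tr$tip.label))
    stop("newick parse error at offset 0: unparsable tree text",
         call. = FALSE)
  tr
}
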