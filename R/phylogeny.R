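# Distance-matrix construction and neighbor joining (Saitou & Nei 1987).
# The NJ implementation is deliberately in-package: tie-breaking in the
# Q-matrix is deterministic (lowest row, then column, index) and negative
# branch lengths are clamped to zero with the deficit moved to the sister
# branch so the joined pair's distance is preserved.

#' Pairwise distance matrix from an alignment
#'
#' @param aln an [alignment()].
#' @param method `"p"`, `"JC"` or `"K2P"`; pairwise deletion throughout.
#' @return a symmetric labeled numeric matrix with zero diagonal.
#' @export
build_matrix <- function(aln, method = c("p", "JC", "K2P")) {
  method <- match.arg(method)
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  saturated <- character()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pd <- p_distance(aln[i, ], aln[j, ])
    d <- tryCatch(switch(method,
                         p = pd$p,
                         JC = jukes_cantor(pd$p, pd$L)$d,
                         K2P = kimura_2p(pd$P, pd$Q)$d),
                  error = function(e) NA_real_)
    if (is.na(d))
      saturated <- c(saturated,
                     paste(rownames(aln)[i], rownames(aln)[j], sep = "|"))
    D[i, j] <- D[j, i] <- d
  }
  if (length(saturated))
    stop("saturated pairs: ", paste(saturated, collapse = ", "))
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly join the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch lengths
#' by the standard formulas. Ties in Q are broken by the lowest (row, column)
#' index pair. A negative branch length is clamped to 0 and its deficit moved
#' to the sister branch, preserving the pair distance.
#'
#' @param D symmetric labeled distance matrix (>= 3 taxa).
#' @return an unrooted [ape::phylo] tree with branch lengths.
#' @export
neighbor_joining <- function(D) {
  if (!isSymmetric(unname(D))) stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining requires at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  frag <- labels  # newick fragment per active node
  D <- unname(D)

  fmt <- function(x) sprintf("%.12g", x)

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    # lowest (row, col) pair among Q minima
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      q <- (m - 2) * D[i, j] - r[i] - r[j]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- D[i, j]; vi <- 0 }
    if (vj < 0) { vi <- D[i, j]; vj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(vi), frag[j], fmt(vj))
    keep <- setdiff(seq_len(m), c(i, j))
    dnew <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew), c(dnew, 0))
    frag <- c(frag[keep], newfrag)
  }
  # terminal 3-star
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(v[1]),
                 frag[2], fmt(v[2]), frag[3], fmt(v[3]))
  ape::read.tree(text = nwk)
}

#' Write a tree as a Newick string
#'
#' Serialises an [ape::phylo] tree with branch lengths at 6-decimal precision,
#' terminated by `";"`. Labels containing Newick metacharacters or empty
#' labels are rejected.
#'
#' @param tree an [ape::phylo] object.
#' @param path optional file to write to.
#' @param digits decimals for branch lengths (default 6).
#' @return the Newick string, invisibly if written to `path`.
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  labs <- tree$tip.label
  if (any(!nzchar(labs)) || anyNA(labs)) stop("empty tip label")
  bad <- grepl("[][():;,'\" \t\n]", labs)
  if (any(bad))
    stop("labels contain unescapable Newick characters: ",
         paste(labs[bad], collapse = ", "))
  n_tip <- length(labs)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) sprintf(paste0("%.", digits, "f"), x)
  rec <- function(node, edge_idx) {
    sub <- if (node <= n_tip) labs[node] else {
      kids <- children[[as.character(node)]]
      paste0("(", paste(vapply(kids, function(e)
        rec(tree$edge[e, 2], e), character(1)), collapse = ","), ")")
    }
    if (is.na(edge_idx)) sub
    else paste0(sub, ":", fmt(tree$edge.length[edge_idx]))
  }
  root <- n_tip + 1L
  nwk <- paste0(rec(root, NA_integer_), ";")
  if (!is.null(path)) { writeLines(nwk, path); return(invisible(nwk)) }
  nwk
}
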