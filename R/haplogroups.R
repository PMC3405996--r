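# Identity-threshold haplogroup classification and parental-origin assignment.
# A query belongs to a known haplogroup only if it shows strictly more than
# `threshold` percent identity to a reference; homeolog origin is the parent
# with the smaller corrected distance.

#' Classify a query sequence into a haplogroup by percent identity
#'
#' Percent identity to each reference is computed on pairwise-deleted sites as
#' `(1 - p) * 100`. The best reference is the one with maximal identity (ties
#' broken by input order and flagged). The call is `same_haplogroup` only when
#' identity is strictly greater than `threshold`; boundary equality is
#' `novel_haplogroup`.
#'
#' @param query query sequence (string or character vector) aligned to the
#'   references.
#' @param references an [alignment()] of reference sequences.
#' @param threshold percent identity threshold (default 98).
#' @return a `haplogroup_call` list: `query`, `best_reference`, `identity`
#'   (exact percent), `identity_pct` (rounded integer, as conventionally
#'   reported), `call`, `tie`.
#' @export
classify_haplogroup <- function(query, references, threshold = 98) {
  if (nrow(references) == 0L) stop("no reference sequences")
  qname <- if (!is.null(names(query))) names(query)[1] else "query"
  ids <- vapply(seq_len(nrow(references)), function(i) {
    pd <- p_distance(query, references[i, ])
    (1 - pd$p) * 100
  }, numeric(1))
  best <- which.max(ids)  # first index on ties
  tie <- sum(ids == ids[best]) > 1L
  res <- list(query = qname,
              best_reference = rownames(references)[best],
              identity = ids[best],
              identity_pct = as.integer(round(ids[best])),
              call = if (ids[best] > threshold) "same_haplogroup"
                     else "novel_haplogroup",
              tie = tie)
  class(res) <- "haplogroup_call"
  res
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat(sprintf("%s: %s (best reference %s, identity %.2f%%%s)\n",
              x$query, x$call, x$best_reference, x$identity,
              if (x$tie) ", tied" else ""))
  invisible(x)
}

#' Assign the parental origin of a homeolog by comparative divergence
#'
#' Computes the corrected distance from the query to an ortholog of each
#' candidate parent; the origin is the parent with the smaller distance.
#' Distances within `tol` of each other are reported as `ambiguous`. With a
#' single ortholog supplied (the other parent missing), the call is made from
#' that comparison alone and flagged `single_parent`.
#'
#' @param query query sequence aligned with the orthologs.
#' @param ortholog_p1,ortholog_p2 parental ortholog sequences; `ortholog_p2`
#'   may be `NULL`.
#' @param method `"JC"` (default) or `"p"`.
#' @param tol absolute tie tolerance on the distance (default 1e-9).
#' @return an `origin_call` list: `d_parent1`, `d_parent2`, `se_parent1`,
#'   `se_parent2`, `origin`, `single_parent`.
#' @export
assign_origin <- function(query, ortholog_p1, ortholog_p2 = NULL,
                          method = c("JC", "p"), tol = 1e-9) {
  method <- match.arg(method)
  dist1 <- function(ref) {
    pd <- p_distance(query, ref)
    if (method == "JC") {
      est <- jukes_cantor(pd$p, pd$L)
      c(d = est$d, se = est$SE)
    } else c(d = pd$p, se = sqrt(pd$p * (1 - pd$p) / pd$L))
  }
  e1 <- dist1(ortholog_p1)
  if (is.null(ortholog_p2)) {
    res <- list(d_parent1 = e1[["d"]], d_parent2 = NA_real_,
                se_parent1 = e1[["se"]], se_parent2 = NA_real_,
                origin = "parent1", single_parent = TRUE)
  } else {
    e2 <- dist1(ortholog_p2)
    origin <- if (abs(e1[["d"]] - e2[["d"]]) <= tol) "ambiguous"
              else if (e1[["d"]] < e2[["d"]]) "parent1" else "parent2"
    res <- list(d_parent1 = e1[["d"]], d_parent2 = e2[["d"]],
                se_parent1 = e1[["se"]], se_parent2 = e2[["se"]],
                origin = origin, single_parent = FALSE)
  }
  class(res) <- "origin_call"
  res
}

#' @export
print.origin_call <- function(x, ...) {
  cat(sprintf("Origin: %s (d1 = %.6f%s%s)\n", x$origin, x$d_parent1,
              if (is.na(x$d_parent2)) "" else sprintf(", d2 = %.6f", x$d_parent2),
              if (x$single_parent) ", single-parent comparison" else ""))
  invisible(x)
}
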