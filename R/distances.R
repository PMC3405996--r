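# Pairwise nucleotide distances: p-distance, Jukes-Cantor, Kimura 2-parameter,
# and Nei-Gojobori Ka/Ks. Conventions: pairwise deletion of gap/N sites by
# default; distances in substitutions per site.

.as_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(toupper(x), "")[[1]] else toupper(x)
}

#' Proportion of differing sites between two aligned sequences
#'
#' Computes the raw mismatch proportion `p` together with its transition (`P`)
#' and transversion (`Q`) components on the compared sites. Sites where either
#' sequence (pairwise deletion) or any sequence in the alignment (complete
#' deletion) carries a gap or `N` are excluded.
#'
#' @param a,b aligned sequences: strings or character vectors of equal length.
#' @param deletion `"pairwise"` (default) or `"complete"`. Complete deletion
#'   additionally requires `others`, the remaining alignment rows whose gaps
#'   also mask columns.
#' @param others optional character matrix of additional rows for complete
#'   deletion.
#' @return a `dist_estimate` list with elements `p`, `P`, `Q`, `L`.
#' @examples
#' p_distance("ACGT", "ACGA")  # one transversion: p = 0.25
#' @export
p_distance <- function(a, b, deletion = c("pairwise", "complete"),
                       others = NULL) {
  deletion <- match.arg(deletion)
  a <- .as_chars(a); b <- .as_chars(b)
  if (length(a) != length(b)) stop("sequences must have equal aligned length")
  ok <- !(a %in% c("-", "N")) & !(b %in% c("-", "N"))
  if (deletion == "complete" && !is.null(others)) {
    ok <- ok & !apply(others == "-" | others == "N", 2, any)
  }
  L <- sum(ok)
  if (L == 0L) stop("no comparable sites")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- diff & ((a %in% .PURINES) == (b %in% .PURINES))
  res <- list(p = sum(diff) / L, P = sum(ts) / L, Q = sum(diff & !ts) / L,
              L = L)
  class(res) <- "dist_estimate"
  res
}

#' @export
print.dist_estimate <- function(x, ...) {
  flds <- c("p", "P", "Q", "d", "SE", "L")
  vals <- unlist(x[intersect(flds, names(x))])
  cat("Distance estimate:\n")
  print(round(vals, 6))
  invisible(x)
}

#' Jukes-Cantor corrected distance
#'
#' `d = -(3/4) log(1 - 4p/3)` with analytic standard error
#' `SE = sqrt(p (1 - p) / (L (1 - 4p/3)^2))`.
#'
#' @param p mismatch proportion in `[0, 0.75)`.
#' @param L number of compared sites (for the SE).
#' @return a `dist_estimate` with `p`, `d`, `SE`, `L`.
#' @examples
#' jukes_cantor(0.1, 1000)  # d = 0.107326, SE = 0.010946
#' @export
jukes_cantor <- function(p, L) {
  if (p < 0) stop("p must be nonnegative")
  if (p >= 0.75) stop("saturated: p >= 0.75, Jukes-Cantor correction undefined")
  w <- 1 - 4 * p / 3
  res <- list(p = p, d = -0.75 * log(w),
              SE = sqrt(p * (1 - p) / (L * w^2)), L = L)
  class(res) <- "dist_estimate"
  res
}

#' Kimura two-parameter distance
#'
#' `d = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q)` from transition and
#' transversion proportions.
#'
#' @param P transition proportion.
#' @param Q transversion proportion.
#' @return a `dist_estimate` with `P`, `Q`, `d`.
#' @examples
#' kimura_2p(0.1, 0.05)  # d = 0.170181
#' @export
kimura_2p <- function(P, Q) {
  if (P < 0 || Q < 0) stop("P and Q must be nonnegative")
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("saturated: Kimura two-parameter correction undefined")
  res <- list(P = P, Q = Q, d = -0.5 * log(w1) - 0.25 * log(w2))
  class(res) <- "dist_estimate"
  res
}

# --- Nei-Gojobori ------------------------------------------------------------

# fraction of synonymous one-step changes at each codon position, summed / 3
.syn_sites_codon <- function(codon, code = GENETIC_CODE_STANDARD) {
  aa <- code[[codon]]
  if (is.null(aa) || aa == "*") stop("invalid or stop codon: ", codon)
  s <- 0
  cc <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (nb in setdiff(.BASES, cc[pos])) {
      mut <- cc; mut[pos] <- nb
      mut_aa <- code[[paste(mut, collapse = "")]]
      if (mut_aa != "*" && mut_aa == aa) s <- s + 1 / 3
    }
  }
  s
}

# average syn/nonsyn difference counts over all minimal substitution pathways
# between two codons; pathways through stop codons excluded (all-blocked pairs
# fall back to averaging over every pathway)
.codon_path_diffs <- function(c1, c2, code = GENETIC_CODE_STANDARD) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else {
    idx <- if (k == 2L) list(c(1, 2), c(2, 1)) else
      list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    lapply(idx, function(i) pos[i])
  }
  score_path <- function(order) {
    cur <- a; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (aa2 == "*" || aa1 == "*") return(NULL)
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  scores <- Filter(Negate(is.null), lapply(perms, score_path))
  if (!length(scores)) {  # all pathways blocked by stops: average over all
    score_any <- function(order) {
      cur <- a; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur; nxt[p] <- b[p]
        if (code[[paste(cur, collapse = "")]] ==
            code[[paste(nxt, collapse = "")]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    scores <- lapply(perms, score_any)
  }
  colMeans(do.call(rbind, scores))
}

#' Nei-Gojobori synonymous and nonsynonymous divergence
#'
#' Counts synonymous and nonsynonymous sites and differences per the
#' Nei-Gojobori (1986) unweighted-pathway method, then applies the
#' Jukes-Cantor correction to `Sd/S_sites` (Ks) and `Nd/N_sites` (Ka).
#' Multi-difference codons are scored by averaging over all minimal
#' substitution pathways with equal weights; pathways through stop codons are
#' excluded. Standard genetic code only.
#'
#' @param a,b in-frame coding sequences (strings), equal length, multiple of 3.
#' @return a `kaks_estimate` list: `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`,
#'   `pN`, `Ks`, `Ka` (NA with a `saturated` flag where the correction is
#'   undefined).
#' @examples
#' nei_gojobori("TTTGGGAAA", "TTCGGGAAA")  # Ks = 1.20708, Ka = 0
#' @export
nei_gojobori <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  if (nchar(a) %% 3 != 0) stop("length must be a multiple of 3 (in-frame)")
  n_codon <- nchar(a) / 3
  starts <- 3 * seq_len(n_codon) - 2
  ca <- substring(a, starts, starts + 2)
  cb <- substring(b, starts, starts + 2)
  if (any(GENETIC_CODE_STANDARD[ca] == "*") ||
      any(GENETIC_CODE_STANDARD[cb] == "*"))
    stop("internal stop codon in reading frame")
  Sa <- sum(vapply(ca, .syn_sites_codon, numeric(1)))
  Sb <- sum(vapply(cb, .syn_sites_codon, numeric(1)))
  S_sites <- (Sa + Sb) / 2
  N_sites <- 3 * n_codon - S_sites
  diffs <- vapply(seq_len(n_codon),
                  function(i) .codon_path_diffs(ca[i], cb[i]), numeric(2))
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  pS <- if (S_sites > 0) Sd / S_sites else 0
  pN <- if (N_sites > 0) Nd / N_sites else 0
  jc_or_na <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  res <- list(S_sites = S_sites, N_sites = N_sites, Sd = Sd, Nd = Nd,
              pS = pS, pN = pN, Ks = jc_or_na(pS), Ka = jc_or_na(pN),
              saturated = c(Ks = pS >= 0.75, Ka = pN >= 0.75))
  class(res) <- "kaks_estimate"
  res
}

#' @export
print.kaks_estimate <- function(x, ...) {
  cat(sprintf("Nei-Gojobori: S sites %.3f, N sites %.3f, Sd %.3f, Nd %.3f\n",
              x$S_sites, x$N_sites, x$Sd, x$Nd))
  cat(sprintf("  Ks = %s, Ka = %s\n",
              if (is.na(x$Ks)) "saturated" else sprintf("%.6f", x$Ks),
              if (is.na(x$Ka)) "saturated" else sprintf("%.6f", x$Ka)))
  invisible(x)
}

#' Mean corrected divergence between two sequence groups
#'
#' Averages all between-group pairwise corrected distances. The standard error
#' is the analytic per-pair formula when both groups are singletons, and
#' otherwise a nonparametric bootstrap over alignment columns.
#'
#' @param setA,setB [alignment()] objects (subsets of one alignment).
#' @param method distance method, `"JC"` (default) or `"p"`.
#' @param n_boot bootstrap replicates when either group has > 1 sequence.
#' @param seed optional seed for the bootstrap.
#' @param se_method `"auto"` (analytic for singleton pairs, bootstrap
#'   otherwise), `"analytic"`, or `"bootstrap"`.
#' @return list with `mean_d`, `SE`, `n_pairs`, `excluded` (saturated pairs).
#' @export
group_mean_divergence <- function(setA, setB, method = c("JC", "p"),
                                  n_boot = 1000, seed = NULL,
                                  se_method = c("auto", "analytic",
                                                "bootstrap")) {
  method <- match.arg(method)
  se_method <- match.arg(se_method)
  if (nrow(setA) == 0L || nrow(setB) == 0L) stop("empty sequence set")
  if (ncol(setA) != ncol(setB)) stop("sets must come from one alignment")
  if (!is.null(seed)) set.seed(seed)

  pair_d <- function(A, B) {
    ds <- c(); se1 <- NA_real_; excluded <- character()
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      pd <- p_distance(A[i, ], B[j, ])
      if (method == "JC" && pd$p >= 0.75) {
        excluded <- c(excluded, paste(rownames(A)[i], rownames(B)[j], sep = "|"))
        next
      }
      if (method == "JC") {
        est <- jukes_cantor(pd$p, pd$L); ds <- c(ds, est$d); se1 <- est$SE
      } else {
        ds <- c(ds, pd$p); se1 <- sqrt(pd$p * (1 - pd$p) / pd$L)
      }
    }
    list(ds = ds, se1 = se1, excluded = excluded)
  }

  obs <- pair_d(setA, setB)
  if (!length(obs$ds)) stop("all pairs saturated")
  singletons <- nrow(setA) == 1L && nrow(setB) == 1L
  use_analytic <- se_method == "analytic" ||
    (se_method == "auto" && singletons)
  if (use_analytic) {
    SE <- obs$se1
  } else {
    L <- ncol(setA)
    reps <- vapply(seq_len(n_boot), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      mean(pair_d(setA[, cols, drop = FALSE],
                  setB[, cols, drop = FALSE])$ds)
    }, numeric(1))
    SE <- stats::sd(reps)
  }
  list(mean_d = mean(obs$ds), SE = SE, n_pairs = length(obs$ds),
       excluded = obs$excluded)
}
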