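# Association between haplogroup distributions and population structure:
# contingency construction with the survey's exclusion rules, Cramer's V with
# Fisher-exact significance, marker frequencies over subgenome slots,
# Evanno's delta-K summary, and pollen-tube / silique cross scoring.

#' Build a marker x cluster contingency table from an accession panel
#'
#' One row per queried marker, one column per cluster. Accessions carrying
#' two or more of the queried markers (heterozygotes) or none of them are
#' excluded; the exclusion count is recorded in `attr(, "excluded")`.
#'
#' @param panel an `accession_panel` data frame (`accession`, `cluster`,
#'   `markers` semicolon-separated).
#' @param markers character vector of marker symbols to tabulate.
#' @param clusters optional named cluster assignment (names = accession ids)
#'   overriding the panel's `cluster` column.
#' @return an integer matrix (markers x clusters) with `excluded` attribute.
#' @export
build_contingency <- function(panel, markers, clusters = NULL) {
  if (!nrow(panel)) stop("empty panel")
  cl <- panel$cluster
  if (!is.null(clusters)) {
    if (is.null(names(clusters))) stop("clusters must be named by accession")
    missing <- setdiff(panel$accession, names(clusters))
    if (length(missing))
      stop("no cluster assignment for: ", paste(missing, collapse = ", "))
    cl <- unname(clusters[panel$accession])
  }
  mk <- strsplit(panel$markers, ";", fixed = TRUE)
  hits <- lapply(mk, intersect, x = markers)
  nhit <- lengths(hits)
  keep <- nhit == 1L
  if (!any(keep)) stop("empty table after exclusions")
  tab <- table(factor(unlist(hits[keep]), levels = markers),
               factor(cl[keep]))
  out <- unclass(as.matrix(tab))
  storage.mode(out) <- "integer"
  attr(out, "excluded") <- sum(!keep)
  out
}

.chi2_independence <- function(t) {
  n <- sum(t)
  E <- outer(rowSums(t), colSums(t)) / n
  sum((t - E)^2 / E)
}

#' Cramer's V association coefficient
#'
#' `V = sqrt(chi2 / (n (min(r, c) - 1)))` with the Pearson chi-square of
#' independence. Statistical significance is assessed by Fisher's exact test
#' (two-tailed). Rows or columns with zero margins are dropped with a
#' warning.
#'
#' @param t nonnegative integer matrix (r x c contingency table).
#' @param fisher_args list of extra arguments to [fisher_exact()].
#' @return an `association_result` list: `V`, `chi2`, `p_value`, `test`,
#'   `table`.
#' @examples
#' cramers_v(matrix(c(8, 2, 2, 8), 2, byrow = TRUE))
#' @export
cramers_v <- function(t, fisher_args = list()) {
  t <- as.matrix(t)
  if (any(t < 0) || any(t != round(t)))
    stop("counts must be nonnegative integers")
  zr <- rowSums(t) == 0; zc <- colSums(t) == 0
  if (any(zr) || any(zc)) {
    warning("dropping zero-margin rows/columns")
    t <- t[!zr, !zc, drop = FALSE]
  }
  if (sum(t) == 0) stop("empty table")
  if (nrow(t) < 2L || ncol(t) < 2L)
    stop("need at least 2 rows and 2 columns")
  chi2 <- .chi2_independence(t)
  V <- sqrt(chi2 / (sum(t) * (min(dim(t)) - 1)))
  fe <- do.call(fisher_exact, c(list(t), fisher_args))
  res <- list(V = V, chi2 = chi2, p_value = fe$p_two_tailed,
              test = "fisher_exact", table = t)
  class(res) <- "association_result"
  res
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Cramer's V = %.4f (chi2 = %.4f), Fisher exact p = %s\n",
              x$V, x$chi2, format(x$p_value, digits = 4)))
  invisible(x)
}

# probability of one r x c table under fixed margins
.table_prob_log <- function(t, lr, lc, ln) {
  lr + lc - ln - sum(lgamma(t + 1))
}

# recursive enumeration of all tables with the given margins, calling f(tab)
.enum_tables <- function(rs, cs, f) {
  r <- length(rs); c <- length(cs)
  tab <- matrix(0L, r, c)
  rec <- function(i, rem_cols) {
    if (i == r) {
      tab[r, ] <<- rem_cols
      f(tab)
      return(invisible())
    }
    cell <- integer(c)
    fill <- function(j, left) {
      if (j == c) {
        if (left <= rem_cols[c]) {
          cell[c] <<- left
          tab[i, ] <<- cell
          rec(i + 1L, rem_cols - cell)
        }
        return(invisible())
      }
      for (v in 0:min(left, rem_cols[j])) {
        cell[j] <<- v
        fill(j + 1L, left - v)
      }
    }
    fill(1L, rs[i])
    invisible()
  }
  rec(1L, as.integer(cs))
  invisible()
}

# cheap upper bound on the number of tables with the given margins:
# compositions of each row sum into c parts, ignoring column constraints
.bound_tables <- function(rs, cs) {
  c_ <- length(cs)
  prod(vapply(rs, function(r) choose(r + c_ - 1, c_ - 1), numeric(1)))
}

#' Fisher's exact test for r x c contingency tables
#'
#' For 2x2 tables the hypergeometric distribution gives the one-tailed p
#' (the tail containing the observed table in the direction of its deviation)
#' and the probability-mass two-tailed p (sum of probabilities of tables no
#' more probable than the observed, with relative tolerance 1e-7). Larger
#' tables are handled by total enumeration when at most `max_tables` tables
#' share the margins, otherwise by seeded Monte Carlo if `monte_carlo = TRUE`.
#'
#' @param t nonnegative integer contingency table.
#' @param monte_carlo allow Monte-Carlo estimation for large tables.
#' @param reps Monte-Carlo replicates.
#' @param seed Monte-Carlo seed.
#' @param max_tables enumeration guard (default 1e7).
#' @return list with `p_one_tailed` (2x2 only, otherwise `NA`),
#'   `p_two_tailed`, and `method`.
#' @examples
#' fisher_exact(matrix(c(4, 0, 1, 5), 2, byrow = TRUE))
#' @export
fisher_exact <- function(t, monte_carlo = FALSE, reps = 1e5, seed = 1,
                         max_tables = 1e7) {
  t <- as.matrix(t)
  if (any(t < 0) || any(t != round(t)))
    stop("counts must be nonnegative integers")
  rs <- rowSums(t); cs <- colSums(t); n <- sum(t)
  if (n == 0) stop("empty table")
  tol <- 1 + 1e-7
  if (nrow(t) == 2L && ncol(t) == 2L) {
    a <- t[1, 1]
    lo <- max(0L, rs[1] - cs[2]); hi <- min(rs[1], cs[1])
    supp <- lo:hi
    pr <- stats::dhyper(supp, cs[1], cs[2], rs[1])
    p_obs <- pr[supp == a]
    e_a <- rs[1] * cs[1] / n  # expected a under independence
    p_one <- if (a >= e_a) sum(pr[supp >= a]) else sum(pr[supp <= a])
    p_two <- sum(pr[pr <= p_obs * tol])
    return(list(p_one_tailed = min(p_one, 1), p_two_tailed = min(p_two, 1),
                method = "hypergeometric"))
  }
  lr <- sum(lgamma(rs + 1)); lc <- sum(lgamma(cs + 1)); ln <- lgamma(n + 1)
  lp_obs <- .table_prob_log(t, lr, lc, ln)
  n_tab <- .bound_tables(rs, cs)
  if (n_tab <= max_tables) {
    acc <- 0
    .enum_tables(rs, cs, function(tab) {
      lp <- .table_prob_log(tab, lr, lc, ln)
      if (exp(lp) <= exp(lp_obs) * tol) acc <<- acc + exp(lp)
    })
    return(list(p_one_tailed = NA_real_, p_two_tailed = min(acc, 1),
                method = "enumeration"))
  }
  if (!monte_carlo)
    stop("enumeration guard exceeded (", n_tab,
         " tables); set monte_carlo = TRUE")
  set.seed(seed)
  sims <- stats::r2dtable(reps, rs, cs)
  hits <- vapply(sims, function(tab)
    exp(.table_prob_log(tab, lr, lc, ln)) <= exp(lp_obs) * tol, TRUE)
  list(p_one_tailed = NA_real_,
       p_two_tailed = (sum(hits) + 1) / (reps + 1),
       method = "monte_carlo")
}

#' Marker frequencies over subgenome slots
#'
#' Each allotetraploid accession contributes two slots at each homeologous
#' locus (subgenome). An accession carrying a single marker of a subgenome is
#' scored as homozygous (both slots); an accession carrying two distinct
#' markers of the same subgenome contributes one slot each. Frequencies are
#' percentages of the `2N` slots of the marker's subgenome.
#'
#' @param panel an `accession_panel` data frame.
#' @param subgenomes named list mapping subgenome name to its marker symbols;
#'   defaults to the panel's `marker_subgenome` attribute.
#' @return data frame `marker`, `subgenome`, `slots`, `total_slots`,
#'   `frequency_pct`.
#' @export
marker_frequencies <- function(panel, subgenomes = NULL) {
  if (!nrow(panel)) stop("empty panel")
  if (is.null(subgenomes)) {
    sub_of <- attr(panel, "marker_subgenome")
    if (is.null(sub_of))
      stop("supply subgenomes: list(sub1 = c(...), sub2 = c(...))")
    subgenomes <- split(names(sub_of), unname(sub_of))
  }
  mk <- strsplit(panel$markers, ";", fixed = TRUE)
  out <- NULL
  for (sg in names(subgenomes)) {
    mks <- subgenomes[[sg]]
    total <- 2L * nrow(panel)
    per <- lapply(mk, intersect, x = mks)
    slots <- stats::setNames(rep(0L, length(mks)), mks)
    for (h in per) {
      if (length(h) == 1L) slots[h] <- slots[h] + 2L
      else if (length(h) > 1L) slots[h] <- slots[h] + 1L
    }
    out <- rbind(out, data.frame(marker = mks, subgenome = sg,
                                 slots = as.integer(slots),
                                 total_slots = total,
                                 frequency_pct = 100 * slots / total,
                                 stringsAsFactors = FALSE, row.names = NULL))
  }
  out
}

#' Evanno's delta-K from clustering log-likelihoods
#'
#' `L'(K) = mean L(K) - mean L(K-1)`, `|L''(K)| = |L'(K+1) - L'(K)|`,
#' `delta K = |L''(K)| / sd(L(K))` with the sample (n-1) standard deviation
#' across runs. Defined only for interior K; K values whose runs have zero
#' spread get `NA` with a flag.
#'
#' @param runs data frame with columns `K` and `lnP` (one row per run).
#' @return data frame `K`, `mean_lnP`, `sd_lnP`, `L1` (first difference),
#'   `absL2`, `deltaK`.
#' @examples
#' runs <- data.frame(K = rep(1:4, each = 2),
#'                    lnP = c(-101, -99, -51, -49, -42, -38, -39, -37))
#' delta_k(runs)
#' @export
delta_k <- function(runs) {
  if (!all(c("K", "lnP") %in% names(runs)))
    stop("runs must have columns K and lnP")
  ks <- sort(unique(runs$K))
  if (length(ks) < 3L) stop("need at least 3 consecutive K values")
  if (!all(diff(ks) == 1)) stop("K values must be consecutive")
  cnt <- table(factor(runs$K, levels = ks))
  if (any(cnt < 2L)) stop("need at least 2 runs per K (sd undefined)")
  mu <- tapply(runs$lnP, factor(runs$K, levels = ks), mean)
  sdv <- tapply(runs$lnP, factor(runs$K, levels = ks), stats::sd)
  nk <- length(ks)
  L1 <- c(NA, diff(mu))                       # L'(K), defined for K >= 2
  absL2 <- rep(NA_real_, nk)
  for (i in 2:(nk - 1)) absL2[i] <- abs(L1[i + 1] - L1[i])
  dk <- absL2 / as.numeric(sdv)
  dk[!is.na(absL2) & sdv == 0] <- NA_real_
  data.frame(K = ks, mean_lnP = as.numeric(mu), sd_lnP = as.numeric(sdv),
             L1 = as.numeric(L1), absL2 = absL2, deltaK = dk,
             row.names = NULL)
}

#' Score a cross as compatible or incompatible
#'
#' Pollen-tube criterion: fewer than 20 penetrating pollen tubes (fewer than
#' 10 with `stringent = TRUE`) is incompatible; 20 or more is compatible.
#' Silique criterion: length below 5 mm is incompatible. Exactly one
#' measurement must be supplied.
#'
#' @param pollen_tubes pollen-tube count.
#' @param silique_mm silique length in millimetres.
#' @param stringent use the stricter <10 pollen-tube criterion.
#' @return `"compatible"` or `"incompatible"`.
#' @examples
#' score_cross(pollen_tubes = 19)
#' score_cross(silique_mm = 7)
#' @export
score_cross <- function(pollen_tubes = NULL, silique_mm = NULL,
                        stringent = FALSE) {
  if (is.null(pollen_tubes) == is.null(silique_mm))
    stop("supply exactly one of pollen_tubes or silique_mm")
  if (!is.null(pollen_tubes)) {
    if (pollen_tubes < 0) stop("negative measurement")
    cutoff <- if (stringent) 10 else 20
    if (pollen_tubes < cutoff) "incompatible" else "compatible"
  } else {
    if (silique_mm < 0) stop("negative measurement")
    if (silique_mm < 5) "incompatible" else "compatible"
  }
}
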