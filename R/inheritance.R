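# Exact F2 class distributions under allopolyploid inheritance models.
#
# A locus is either disomic (F1 carries 2 allele copies; a gamete receives 1)
# or tetrasomic (F1 carries 4 copies; a gamete receives a random unordered
# pair of the 4 - random chromosome segregation, no double reduction). "-"
# denotes a null allele. F2 genotypes are unions of two independent gametes;
# classes are the presence/absence patterns of two scored markers. All
# probabilities are exact integer fractions.

#' Specify one locus of an inheritance model
#'
#' @param mode `"disomic"` or `"tetrasomic"`.
#' @param f1_genotype character vector of allele symbols carried by the F1 at
#'   this locus: length 2 (disomic) or 4 (tetrasomic); `"-"` is a null allele.
#' @return a `locus_spec` object.
#' @examples
#' locus_spec("disomic", c("A", "B"))
#' locus_spec("tetrasomic", c("A", "A", "-", "-"))
#' @export
locus_spec <- function(mode = c("disomic", "tetrasomic"), f1_genotype) {
  mode <- match.arg(mode)
  need <- if (mode == "disomic") 2L else 4L
  if (length(f1_genotype) != need)
    stop(sprintf("%s locus needs %d allele copies, got %d",
                 mode, need, length(f1_genotype)))
  structure(list(mode = mode, f1_genotype = as.character(f1_genotype)),
            class = "locus_spec")
}

#' Define a segregation model
#'
#' @param name model name.
#' @param loci list of [locus_spec()] objects.
#' @param markers two allele symbols scored by presence/absence; each must
#'   occur in exactly one locus' allele set.
#' @return a `segregation_model` object.
#' @export
segregation_model <- function(name, loci, markers = c("A", "B")) {
  if (inherits(loci, "locus_spec")) loci <- list(loci)
  if (!length(loci) || !all(vapply(loci, inherits, TRUE, "locus_spec")))
    stop("loci must be a list of locus_spec objects")
  if (length(markers) != 2L) stop("exactly two markers are scored")
  for (m in markers) {
    hit <- vapply(loci, function(l) m %in% l$f1_genotype, TRUE)
    if (sum(hit) != 1L)
      stop("marker ", m, " must appear in exactly one locus")
  }
  structure(list(name = name, loci = loci, markers = as.character(markers)),
            class = "segregation_model")
}

#' @export
print.segregation_model <- function(x, ...) {
  cat("Segregation model:", x$name, "\n")
  for (l in x$loci)
    cat(sprintf("  %s locus {%s}\n", l$mode,
                paste(l$f1_genotype, collapse = ",")))
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

#' The four standard allotetraploid inheritance models
#'
#' Presets for two markers at homeologous loci of an allotetraploid F1:
#' disomic-allelic (`{A,B}` at one disomic locus), disomic-nonallelic
#' (`{A,-}` and `{B,-}` at two disomic loci), tetrasomic-allelic
#' (`{A,A,B,B}` at one tetrasomic locus) and tetrasomic-nonallelic
#' (`{A,A,-,-}` and `{B,B,-,-}` at two tetrasomic loci).
#'
#' @param markers the two marker symbols (default `c("A", "B")`).
#' @return named list of four [segregation_model()] objects.
#' @export
segregation_models <- function(markers = c("A", "B")) {
  m1 <- markers[1]; m2 <- markers[2]
  list(
    disomic_allelic = segregation_model(
      "disomic_allelic", list(locus_spec("disomic", c(m1, m2))), markers),
    disomic_nonallelic = segregation_model(
      "disomic_nonallelic",
      list(locus_spec("disomic", c(m1, "-")),
           locus_spec("disomic", c(m2, "-"))), markers),
    tetrasomic_allelic = segregation_model(
      "tetrasomic_allelic",
      list(locus_spec("tetrasomic", c(m1, m1, m2, m2))), markers),
    tetrasomic_nonallelic = segregation_model(
      "tetrasomic_nonallelic",
      list(locus_spec("tetrasomic", c(m1, m1, "-", "-")),
           locus_spec("tetrasomic", c(m2, m2, "-", "-"))), markers)
  )
}

#' Gamete distribution of one locus
#'
#' Disomic: each of the two allele copies with probability 1/2 (gamete carries
#' one copy). Tetrasomic: each unordered pair of the four copies with
#' probability 1/6 (random chromosome segregation, no double reduction).
#' Probabilities are exact fractions over a common denominator.
#'
#' @param locus a [locus_spec()].
#' @return a `gamete_distribution`: data frame with columns `gamete`
#'   (sorted allele multiset, `/`-joined) and `num`, with denominator in
#'   `attr(, "den")`.
#' @examples
#' gametes(locus_spec("tetrasomic", c("A", "A", "B", "B")))
#' @export
gametes <- function(locus) {
  stopifnot(inherits(locus, "locus_spec"))
  g <- locus$f1_genotype
  if (locus$mode == "disomic") {
    keys <- g  # one copy per gamete
    den <- 2L
  } else {
    idx <- utils::combn(4L, 2L)
    keys <- apply(idx, 2, function(k) paste(sort(g[k]), collapse = "/"))
    den <- 6L
  }
  tab <- table(keys)
  out <- data.frame(gamete = names(tab), num = as.integer(tab),
                    stringsAsFactors = FALSE)
  red <- .reduce_frac(out$num, den)
  out$num <- red$num
  attr(out, "den") <- red$den
  class(out) <- c("gamete_distribution", class(out))
  out
}

#' @export
print.gamete_distribution <- function(x, ...) {
  den <- attr(x, "den")
  cat("Gamete distribution:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-8s %s\n", x$gamete[i], .frac_label(x$num[i], den)))
  invisible(x)
}

# joint gametes across loci: data.frame(num) + list of allele vectors;
# common denominator = product of per-locus denominators
.joint_gametes <- function(loci) {
  per <- lapply(loci, gametes)
  dens <- vapply(per, attr, integer(1), which = "den")
  alleles <- list(character(0)); num <- 1L
  for (k in seq_along(per)) {
    gk <- per[[k]]
    allelesk <- strsplit(gk$gamete, "/", fixed = TRUE)
    newa <- list(); newn <- integer(0)
    for (i in seq_along(alleles)) for (j in seq_len(nrow(gk))) {
      newa[[length(newa) + 1L]] <- c(alleles[[i]], allelesk[[j]])
      newn <- c(newn, num[i] * gk$num[j])
    }
    alleles <- newa; num <- newn
  }
  list(alleles = alleles, num = num, den = prod(dens))
}

.F2_CLASSES <- c("both", "marker1_only", "marker2_only", "neither")

#' Exact F2 class distribution of a segregation model
#'
#' Enumerates ordered pairs of independent F1 gametes; the F2 genotype is the
#' union of the two gametes across loci, and each individual falls in one of
#' four presence/absence classes of the two markers:
#' both, marker1 only, marker2 only, neither.
#'
#' @param model a [segregation_model()].
#' @return a `class_distribution`: data frame with `class`, `num`, `prob`,
#'   denominator in `attr(, "den")`.
#' @examples
#' f2_class_distribution(segregation_models()$disomic_allelic)
#' @export
f2_class_distribution <- function(model) {
  stopifnot(inherits(model, "segregation_model"))
  jg <- .joint_gametes(model$loci)
  m1 <- model$markers[1]; m2 <- model$markers[2]
  has1 <- vapply(jg$alleles, function(a) m1 %in% a, TRUE)
  has2 <- vapply(jg$alleles, function(a) m2 %in% a, TRUE)
  num <- stats::setNames(rep(0, 4L), .F2_CLASSES)
  G <- length(jg$num)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    p1 <- has1[i] || has1[j]
    p2 <- has2[i] || has2[j]
    cls <- if (p1 && p2) "both" else if (p1) "marker1_only"
           else if (p2) "marker2_only" else "neither"
    num[cls] <- num[cls] + jg$num[i] * jg$num[j]
  }
  den <- jg$den^2
  red <- .reduce_frac(num, den)
  out <- data.frame(class = .F2_CLASSES, num = red$num,
                    prob = red$num / red$den, stringsAsFactors = FALSE)
  attr(out, "den") <- red$den
  attr(out, "model") <- model$name
  class(out) <- c("class_distribution", class(out))
  out
}

#' @export
print.class_distribution <- function(x, ...) {
  den <- attr(x, "den")
  cat(sprintf("F2 class distribution (%s):\n",
              attr(x, "model") %||% "custom"))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-13s %-10s = %.6f\n", x$class[i],
                .frac_label(x$num[i], den), x$prob[i]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chi-square goodness of fit of observed F2 classes to a model
#'
#' Expected counts come from the exact class probabilities (`E_i = N p_i`),
#' never from rounded values. Classes with `E_i = 0` contribute nothing and
#' are excluded from the degrees of freedom; if such a class is observed the
#' model is rejected outright (`chi2 = Inf`, `p = 0`). No continuity
#' correction.
#'
#' @param observed integer counts in class order
#'   (both, marker1 only, marker2 only, neither).
#' @param dist a `class_distribution` from [f2_class_distribution()].
#' @return a `gof_result` list: `observed`, `expected`, `chi2`, `df`,
#'   `p_value`, `impossible_class`.
#' @examples
#' chisq_gof(c(53, 25, 17, 0),
#'           f2_class_distribution(segregation_models()$disomic_allelic))
#' @export
chisq_gof <- function(observed, dist) {
  stopifnot(inherits(dist, "class_distribution"))
  if (length(observed) != nrow(dist))
    stop("observed must have one count per class")
  if (any(observed < 0) || any(observed != round(observed)))
    stop("observed counts must be nonnegative integers")
  N <- sum(observed)
  if (N == 0) stop("N = 0: no observations")
  E <- N * dist$num / attr(dist, "den")
  pos <- E > 0
  impossible <- any(!pos & observed > 0)
  if (impossible) {
    chi2 <- Inf; df <- sum(pos) - 1L; p <- 0
  } else {
    chi2 <- sum((observed[pos] - E[pos])^2 / E[pos])
    df <- sum(pos) - 1L
    p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  }
  res <- list(observed = observed, expected = E, N = N, chi2 = chi2,
              df = df, p_value = p, impossible_class = impossible,
              model = attr(dist, "model"))
  class(res) <- "gof_result"
  res
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Goodness of fit%s: chi2 = %s, df = %d, p = %s\n",
              if (is.null(x$model)) "" else paste0(" (", x$model, ")"),
              if (is.infinite(x$chi2)) "Inf (impossible class observed)"
              else sprintf("%.4f", x$chi2),
              x$df, format(x$p_value, digits = 3)))
  invisible(x)
}

#' Fit candidate inheritance models to observed F2 class counts
#'
#' The central model-comparison routine: computes the exact class distribution
#' of every candidate model, tests each against the observed counts by Pearson
#' chi-square goodness of fit, and ranks models by descending p-value. The
#' best-supported model is flagged.
#'
#' @param observed integer counts in class order
#'   (both, marker1 only, marker2 only, neither).
#' @param models list of [segregation_model()] objects; defaults to the four
#'   standard allotetraploid presets of [segregation_models()].
#' @return a `seg_fit` object: ranked results table plus per-model details;
#'   methods: `print`, `summary`, `simulate`.
#' @examples
#' fit <- fit_segregation(c(53, 25, 17, 0))
#' fit
#' @export
fit_segregation <- function(observed, models = segregation_models()) {
  if (length(models) < 1L) stop("need at least one model")
  fits <- lapply(models, function(m) {
    dist <- f2_class_distribution(m)
    list(model = m, dist = dist, gof = chisq_gof(observed, dist))
  })
  tab <- data.frame(
    model = vapply(fits, function(f) f$model$name, character(1)),
    chi2 = vapply(fits, function(f) f$gof$chi2, numeric(1)),
    df = vapply(fits, function(f) f$gof$df, integer(1)),
    p_value = vapply(fits, function(f) f$gof$p_value, numeric(1)),
    impossible_class = vapply(fits, function(f) f$gof$impossible_class, TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(-tab$p_value, tab$chi2)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  res <- list(observed = observed, ranking = tab, fits = fits[ord],
              best = tab$model[1])
  class(res) <- "seg_fit"
  res
}

#' @rdname fit_segregation
#' @export
compare_models <- fit_segregation

#' @export
print.seg_fit <- function(x, ...) {
  cat("F2 segregation model comparison\n")
  cat("Observed classes (both, marker1 only, marker2 only, neither): ",
      paste(x$observed, collapse = ", "), "  (N = ", sum(x$observed), ")\n",
      sep = "")
  tab <- x$ranking
  tab$chi2 <- ifelse(is.infinite(tab$chi2), "Inf", sprintf("%.2f", tab$chi2))
  tab$p_value <- format(tab$p_value, digits = 3)
  print(tab[, c("rank", "model", "chi2", "df", "p_value")], row.names = FALSE)
  cat("Best-supported model:", x$best, "\n")
  invisible(x)
}

#' @export
summary.seg_fit <- function(object, ...) {
  cat("F2 segregation fit: N =", sum(object$observed), "\n\n")
  for (f in object$fits) {
    den <- attr(f$dist, "den")
    cat(sprintf("%s: chi2 = %s, df = %d, p = %s\n", f$model$name,
                if (is.infinite(f$gof$chi2)) "Inf"
                else sprintf("%.2f", f$gof$chi2),
                f$gof$df, format(f$gof$p_value, digits = 3)))
    for (i in seq_len(nrow(f$dist)))
      cat(sprintf("    %-13s expected %8.3f (%s)   observed %d\n",
                  f$dist$class[i], f$gof$expected[i],
                  .frac_label(f$dist$num[i], den), object$observed[i]))
  }
  invisible(object)
}

#' Simulate F2 populations from the best-supported model of a fit
#'
#' @param object a `seg_fit` from [fit_segregation()].
#' @param nsim number of replicate F2 populations.
#' @param seed RNG seed.
#' @param n F2 population size per replicate (defaults to the fitted N).
#' @param ... unused.
#' @return list of class-count vectors, one per replicate.
#' @export
simulate.seg_fit <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- sum(object$observed)
  best <- object$fits[[1]]$model
  lapply(seq_len(nsim), function(i) simulate_f2(best, n))
}
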