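# Seeded synthetic-data generators emulating the statistical structure of an
# allotetraploid S-locus survey: haplogroup sequence panels, accession
# genotype panels with cluster-structured subgenome alleles, and F2
# populations segregating under a chosen inheritance model.
#
# Sequences evolve under a per-site Jukes-Cantor substitution process on a
# star genealogy (haplogroup founders at branch length between/2 from a
# common ancestor; panel members at within/2 from their founder), so the JC
# estimator is the matched estimator and parameter-recovery tests are exact
# in expectation.

# probability a site differs after d expected substitutions/site under JC
.jc_p_expected <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# mutate a character vector of bases along a branch of length d
.jc_evolve <- function(seq, d) {
  p <- .jc_p_expected(d)
  hit <- stats::runif(length(seq)) < p
  if (any(hit)) {
    seq[hit] <- vapply(seq[hit],
                       function(b) sample(setdiff(.BASES, b), 1L),
                       character(1))
  }
  seq
}

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the study conditions the downstream analyses assume: five
#' haplogroups whose between-group identity is well below and within-group
#' identity well above the 98% classification threshold, a 49-accession
#' allotetraploid panel with two population clusters carrying
#' cluster-structured subgenome-1 alleles, a rare subgenome-1 heterozygote,
#' and a 95-individual F2 family under the disomic-allelic model.
#'
#' @param n_haplogroups number of haplogroups.
#' @param n_per_group sequences per haplogroup.
#' @param seq_length alignment length in sites.
#' @param between_divergence expected substitutions/site separating two
#'   haplogroup founders (total path length).
#' @param within_divergence expected substitutions/site separating two members
#'   of one haplogroup (total path length).
#' @param n_accessions panel size.
#' @param cluster_spec named list (one entry per cluster) of lists with
#'   per-subgenome marker-frequency vectors `sub1` and `sub2`; each vector
#'   named by marker and summing to 1.
#' @param heterozygote_rate probability that an accession carries two distinct
#'   subgenome-1 markers.
#' @param f2_model name of a preset in [segregation_models()].
#' @param f2_n F2 family size.
#' @param seed integer RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_haplogroups = 5, n_per_group = 3,
                              seq_length = 1000,
                              between_divergence = 0.10,
                              within_divergence = 0.01,
                              n_accessions = 49,
                              cluster_spec = list(
                                cluster1 = list(sub1 = c(A = 1),
                                                sub2 = c(D = 0.9, E = 0.1)),
                                cluster2 = list(sub1 = c(B = 0.9, C = 0.1),
                                                sub2 = c(D = 0.9, E = 0.1))),
                              heterozygote_rate = 0.02,
                              f2_model = "disomic_allelic",
                              f2_n = 95, seed = 1) {
  stopifnot(n_haplogroups >= 1, n_per_group >= 1, seq_length > 0,
            n_accessions >= 1, f2_n >= 0)
  if (heterozygote_rate < 0 || heterozygote_rate > 1)
    stop("heterozygote_rate must be in [0, 1]")
  if (within_divergence < 0 || between_divergence < within_divergence)
    stop("need between_divergence > within_divergence >= 0")
  for (lim in c(between_divergence, within_divergence)) {
    if (.jc_p_expected(lim) >= 0.75 - 1e-6)
      stop("saturated: requested divergence implies expected p-distance ",
           ">= 0.75; distance correction undefined")
  }
  if (!length(cluster_spec)) stop("cluster_spec must be non-empty")
  for (cl in names(cluster_spec)) for (sg in c("sub1", "sub2")) {
    fr <- cluster_spec[[cl]][[sg]]
    if (is.null(fr) || !length(fr))
      stop("empty frequency vector for ", cl, " ", sg)
    if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9)
      stop("frequencies for ", cl, " ", sg, " must be in [0,1] and sum to 1")
  }
  structure(list(n_haplogroups = n_haplogroups, n_per_group = n_per_group,
                 seq_length = seq_length,
                 between_divergence = between_divergence,
                 within_divergence = within_divergence,
                 n_accessions = n_accessions, cluster_spec = cluster_spec,
                 heterozygote_rate = heterozygote_rate,
                 f2_model = f2_model, f2_n = f2_n, seed = seed),
            class = "simulation_config")
}

#' Simulate an aligned haplogroup sequence panel
#'
#' Generates `n_haplogroups * n_per_group` aligned sequences on a star
#' genealogy under a per-site Jukes-Cantor substitution process. Haplogroup
#' membership is recorded in the labels (`<group>_<member>`, groups `H1`,
#' `H2`, ...). Fixed seed implies byte-identical output.
#'
#' @param config a [simulation_config()].
#' @return an [alignment()] with a `haplogroup` attribute (factor per row).
#' @export
simulate_haplogroup_sequences <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- config$seq_length
  root <- sample(.BASES, L, replace = TRUE)
  labels <- character(0); rows <- list(); groups <- character(0)
  for (g in seq_len(config$n_haplogroups)) {
    founder <- .jc_evolve(root, config$between_divergence / 2)
    for (k in seq_len(config$n_per_group)) {
      rows[[length(rows) + 1L]] <-
        .jc_evolve(founder, config$within_divergence / 2)
      labels <- c(labels, sprintf("H%d_%d", g, k))
      groups <- c(groups, sprintf("H%d", g))
    }
  }
  aln <- alignment(do.call(rbind, rows), labels = labels)
  attr(aln, "haplogroup") <- factor(groups)
  aln
}

#' Simulate an allotetraploid accession genotype panel
#'
#' Accessions are assigned to clusters as evenly as possible in input order.
#' Each accession draws one marker per homeologous subgenome from its
#' cluster's frequency vector; with probability `heterozygote_rate` a second,
#' distinct subgenome-1 marker is added (mirroring rare heterozygotes under
#' predominant selfing). Columns: `accession`, `cluster`, `markers`
#' (semicolon-separated).
#'
#' @param config a [simulation_config()].
#' @return an `accession_panel` data frame with a `marker_subgenome`
#'   attribute naming each marker's subgenome.
#' @export
simulate_panel <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cls <- names(config$cluster_spec)
  assign <- rep(cls, length.out = config$n_accessions)
  draw <- function(fr) {
    if (length(fr) == 1L) names(fr) else sample(names(fr), 1L, prob = fr)
  }
  acc <- sprintf("acc%03d", seq_len(config$n_accessions))
  markers <- character(config$n_accessions)
  for (i in seq_len(config$n_accessions)) {
    spec <- config$cluster_spec[[assign[i]]]
    m1 <- draw(spec$sub1)
    m2 <- draw(spec$sub2)
    mk <- c(m1, m2)
    if (length(spec$sub1) > 1L &&
        stats::runif(1) < config$heterozygote_rate) {
      alt <- setdiff(names(spec$sub1), m1)
      pr <- spec$sub1[alt]
      if (sum(pr) > 0) {
        mk <- c(m1, if (length(alt) == 1L) alt else
          sample(alt, 1L, prob = pr), m2)
      }
    }
    markers[i] <- paste(mk, collapse = ";")
  }
  panel <- data.frame(accession = acc, cluster = assign, markers = markers,
                      stringsAsFactors = FALSE)
  all1 <- unique(unlist(lapply(config$cluster_spec, function(s) names(s$sub1))))
  all2 <- unique(unlist(lapply(config$cluster_spec, function(s) names(s$sub2))))
  sub_of <- c(stats::setNames(rep("sub1", length(all1)), all1),
              stats::setNames(rep("sub2", length(all2)), all2))
  attr(panel, "marker_subgenome") <- sub_of
  class(panel) <- c("accession_panel", class(panel))
  panel
}

#' Simulate an F2 population under an inheritance model
#'
#' Draws `n` F2 individuals by sampling two independent gametes from the F1
#' gamete distribution of the model (per locus), forming the genotype union
#' and scoring the presence/absence class of the two markers.
#'
#' @param model a [segregation_model()] or the name of a preset in
#'   [segregation_models()].
#' @param n number of F2 individuals.
#' @param seed optional RNG seed.
#' @return named integer vector of class counts
#'   (both, marker1 only, marker2 only, neither), summing to `n`.
#' @examples
#' simulate_f2("disomic_allelic", 95, seed = 1)
#' @export
simulate_f2 <- function(model, n, seed = NULL) {
  if (is.character(model)) {
    presets <- segregation_models()
    if (!model %in% names(presets)) stop("unknown model preset: ", model)
    model <- presets[[model]]
  }
  stopifnot(inherits(model, "segregation_model"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::setNames(rep(0L, 4L), .F2_CLASSES)
  if (n == 0) return(counts)
  jg <- .joint_gametes(model$loci)
  m1 <- model$markers[1]; m2 <- model$markers[2]
  has1 <- vapply(jg$alleles, function(a) m1 %in% a, TRUE)
  has2 <- vapply(jg$alleles, function(a) m2 %in% a, TRUE)
  prob <- jg$num / jg$den
  g1 <- sample.int(length(prob), n, replace = TRUE, prob = prob)
  g2 <- sample.int(length(prob), n, replace = TRUE, prob = prob)
  p1 <- has1[g1] | has1[g2]
  p2 <- has2[g1] | has2[g2]
  cls <- ifelse(p1 & p2, "both",
                ifelse(p1, "marker1_only",
                       ifelse(p2, "marker2_only", "neither")))
  tab <- table(factor(cls, levels = .F2_CLASSES))
  counts[] <- as.integer(tab)
  counts
}

#' Write a simulated panel to TSV
#'
#' Header `accession<TAB>cluster<TAB>markers`, markers semicolon-separated.
#'
#' @param panel an `accession_panel` from [simulate_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an accession panel TSV
#' @param path TSV with columns `accession`, `cluster`, `markers`.
#' @return an `accession_panel` data frame.
#' @export
read_panel <- function(path) {
  panel <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  need <- c("accession", "cluster", "markers")
  if (!all(need %in% names(panel)))
    stop("panel must have columns: ", paste(need, collapse = ", "))
  class(panel) <- c("accession_panel", class(panel))
  panel
}
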