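# End-to-end orchestration: simulate -> distances -> classify/assign -> tree
# -> segregation -> association -> dating, with TSV/Newick/JSON outputs and a
# provenance record. Reruns with the same config are byte-identical.

#' Run the full analysis pipeline on a seeded synthetic bundle
#'
#' Executes the requested stages in dependency order on data produced by the
#' synthetic generators (or on user-supplied files), writing all reports to
#' `out_dir`: aligned FASTA and distance matrix TSV, Newick tree, haplogroup
#' call table, segregation model-comparison report, association report and a
#' dating report, plus a machine-readable `provenance.json`.
#'
#' @param config a [simulation_config()]; its seed drives every stage.
#' @param out_dir output directory (created if needed).
#' @param stages subset of
#'   `c("simulate", "distance", "tree", "classify", "segregation",
#'   "association", "divtime")`.
#' @param observed_f2 optional observed F2 class counts for the segregation
#'   stage; defaults to counts simulated under `config$f2_model`.
#' @param dist_method distance method for the matrix/tree stages.
#' @return (invisibly) named list of result objects per stage.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         stages = c("simulate", "distance", "tree",
                                    "classify", "segregation",
                                    "association", "divtime"),
                         observed_f2 = NULL,
                         dist_method = c("K2P", "JC", "p")) {
  stopifnot(inherits(config, "simulation_config"))
  dist_method <- match.arg(dist_method)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  fail <- function(stage, e) stop("stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)

  aln <- NULL
  if (any(c("simulate", "distance", "tree", "classify") %in% stages)) {
    aln <- tryCatch(simulate_haplogroup_sequences(config),
                    error = function(e) fail("simulate", e))
    write_alignment(aln, file.path(out_dir, "sequences.fasta"))
    panel <- simulate_panel(config)
    write_panel(panel, file.path(out_dir, "panel.tsv"))
    results$simulate <- list(alignment = aln, panel = panel)
  }

  if ("distance" %in% stages) {
    D <- tryCatch(build_matrix(aln, method = dist_method),
                  error = function(e) fail("distance", e))
    utils::write.table(round(D, 6), file.path(out_dir, "distances.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    results$distance <- D
  }

  if ("tree" %in% stages) {
    D <- results$distance %||% build_matrix(aln, method = dist_method)
    tree <- tryCatch(neighbor_joining(D), error = function(e) fail("tree", e))
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    results$tree <- tree
  }

  if ("classify" %in% stages) {
    groups <- attr(aln, "haplogroup")
    # first member of every haplogroup is the reference panel
    ref_idx <- !duplicated(groups)
    refs <- alignment(unclass(aln)[ref_idx, , drop = FALSE],
                      labels = rownames(aln)[ref_idx])
    calls <- lapply(which(!ref_idx), function(i) {
      cl <- classify_haplogroup(aln[i, ], refs)
      cl$query <- rownames(aln)[i]
      cl
    })
    tab <- data.frame(
      query = vapply(calls, `[[`, character(1), "query"),
      best_reference = vapply(calls, `[[`, character(1), "best_reference"),
      identity_pct = vapply(calls, `[[`, integer(1), "identity_pct"),
      call = vapply(calls, `[[`, character(1), "call"),
      stringsAsFactors = FALSE)
    utils::write.table(tab, file.path(out_dir, "haplogroup_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$classify <- tab
  }

  if ("segregation" %in% stages) {
    obs <- observed_f2 %||%
      tryCatch(simulate_f2(config$f2_model, config$f2_n, seed = config$seed),
               error = function(e) fail("segregation", e))
    fit <- fit_segregation(obs)
    seg <- fit$ranking
    utils::write.table(seg, file.path(out_dir, "segregation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$segregation <- fit
  }

  if ("association" %in% stages) {
    panel <- results$simulate$panel %||% simulate_panel(config)
    sub_of <- attr(panel, "marker_subgenome")
    sub1 <- names(sub_of)[sub_of == "sub1"]
    assoc <- tryCatch({
      tab <- build_contingency(panel, sub1)
      if (nrow(tab) >= 2 && ncol(tab) >= 2) cramers_v(tab) else NULL
    }, error = function(e) fail("association", e))
    freqs <- marker_frequencies(panel)
    utils::write.table(freqs, file.path(out_dir, "marker_frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(assoc)) {
      jsonlite::write_json(
        list(V = assoc$V, chi2 = assoc$chi2, p_value = assoc$p_value,
             excluded = attr(assoc$table, "excluded")),
        file.path(out_dir, "association.json"),
        auto_unbox = TRUE, digits = NA)
    }
    results$association <- list(assoc = assoc, frequencies = freqs)
  }

  if ("divtime" %in% stages) {
    # date the split of panel members from their haplogroup founders, using
    # the per-sequence JC divergence from each group's reference as loci
    if (is.null(aln)) aln <- simulate_haplogroup_sequences(config)
    groups <- attr(aln, "haplogroup")
    ref_idx <- which(!duplicated(groups))
    ks <- unlist(lapply(ref_idx, function(r) {
      members <- setdiff(which(groups == groups[r]), r)
      vapply(members, function(i) {
        pd <- p_distance(aln[i, ], aln[r, ])
        jukes_cantor(pd$p, pd$L)$d
      }, numeric(1))
    }))
    if (!length(ks)) ks <- 0
    km <- locus_mean_K(ks, SE = 0)
    est <- divergence_time(km$mean_K, km$ci, rate_model("ossowski"),
                           divergence_type = "K")
    jsonlite::write_json(
      list(T = est$T, T_lower = est$T_ci[1], T_upper = est$T_ci[2],
           K = est$K, rate_model = est$rate_model$name),
      file.path(out_dir, "divtime.json"), auto_unbox = TRUE, digits = NA)
    results$divtime <- est
  }

  prov <- list(package = "polysloc",
               version = as.character(utils::packageVersion("polysloc")),
               seed = config$seed, stages = stages,
               parameters = config[setdiff(names(config), "cluster_spec")],
               outputs = list.files(out_dir))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
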