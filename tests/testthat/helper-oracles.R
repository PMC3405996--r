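# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force / enumeration, never by calling the code paths
# they check.

# Brute-force F2 class distribution: enumerate gametes at the level of
# individually indexed chromosome copies (uniform atoms), not allele
# multisets. Returns exact integer counts per class plus the atom total.
oracle_f2_distribution <- function(model) {
  # per-locus gamete atoms: list of allele vectors, all equally likely
  locus_atoms <- function(locus) {
    g <- locus$f1_genotype
    if (locus$mode == "disomic") {
      lapply(1:2, function(i) g[i])
    } else {
      idx <- utils::combn(4L, 2L)
      lapply(seq_len(ncol(idx)), function(k) g[idx[, k]])
    }
  }
  per_locus <- lapply(model$loci, locus_atoms)
  # joint gamete atoms across loci
  joint <- list(character(0))
  for (atoms in per_locus) {
    joint <- unlist(lapply(joint, function(j)
      lapply(atoms, function(a) c(j, a))), recursive = FALSE)
  }
  m1 <- model$markers[1]; m2 <- model$markers[2]
  counts <- c(both = 0L, marker1_only = 0L, marker2_only = 0L, neither = 0L)
  for (g1 in joint) for (g2 in joint) {
    geno <- c(g1, g2)
    p1 <- m1 %in% geno; p2 <- m2 %in% geno
    cls <- if (p1 && p2) "both" else if (p1) "marker1_only"
           else if (p2) "marker2_only" else "neither"
    counts[cls] <- counts[cls] + 1L
  }
  list(counts = counts, total = length(joint)^2)
}

# random valid segregation model for property tests
random_segregation_model <- function() {
  n_loci <- sample(1:2, 1)
  marker_locus <- if (n_loci == 1) c(1L, 1L) else
    c(sample(1:2, 1), sample(1:2, 1))
  loci <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    mode <- sample(c("disomic", "tetrasomic"), 1)
    size <- if (mode == "disomic") 2L else 4L
    here <- c("A", "B")[marker_locus == l]
    pool <- c(here, "-", "x")
    filler <- sample(pool, size - length(here), replace = TRUE)
    loci[[l]] <- locus_spec(mode, sample(c(here, filler)))
  }
  segregation_model("random", loci, markers = c("A", "B"))
}

# Monte-Carlo expectation of the p-distance between two lineages separated by
# total path `d` under per-site Jukes-Cantor substitution (independent of the
# package's sequence machinery)
oracle_jc_p <- function(d, n_sites = 1e5, seed = 424242) {
  set.seed(seed)
  p_branch <- 0.75 * (1 - exp(-4 * (d / 2) / 3))
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, n_sites, replace = TRUE)
  evolve <- function(s) {
    hit <- runif(n_sites) < p_branch
    s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1),
                     character(1))
    s
  }
  mean(evolve(root) != evolve(root))
}

# deterministic mutation of a sequence string at chosen positions (for
# constructed classification/origin fixtures)
mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  ch[pos] <- vapply(ch[pos], function(b) bases[(match(b, bases)) %% 4 + 1],
                    character(1))
  paste(ch, collapse = "")
}

random_dna <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
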