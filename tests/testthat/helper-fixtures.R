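# Shared fixtures, memoized so expensive reference builds run once per file.

.fixture_env <- new.env(parent = emptyenv())

# Bundled p53 reference (~43.65 kDa), the benchmark protein.
p53_ref <- function() {
  if (is.null(.fixture_env$p53)) {
    .fixture_env$p53 <- protein_reference(fasta = p53_fasta_path())
  }
  .fixture_env$p53
}

# Small (~15 kDa) protein for fast detection tests; above the 14 kDa floor
# that guarantees five peaks in the upper-third window.
small_ref <- function() {
  if (is.null(.fixture_env$small)) {
    seq <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 7), collapse = "")
    .fixture_env$small <- protein_reference(seq)
  }
  .fixture_env$small
}

# Simple two-PTM test table with fixed masses and bounds.
toy_ptm_table <- function() {
  ptm_table(c("Ph", "Ox"), mass = c(79.966, 15.995), upper_bound = c(3L, 3L))
}

# Random bounded PTM instance for oracle-equivalence tests.
random_instance <- function(n_types = sample(2:4, 1), ub_max = 3) {
  masses <- round(stats::runif(n_types, 5, 130), 3)
  ptm_table(paste0("M", seq_len(n_types)), mass = masses,
            upper_bound = sample(0:ub_max, n_types, replace = TRUE))
}

# Brute-force optimum over the feasible set for a given objective.
oracle_best <- function(obs, table, cfg, objective) {
  pats <- enumerate_feasible_patterns(obs, table, cfg$eps_max,
                                      ub_cap = cfg$ub_cap)
  if (length(pats) == 0) return(NULL)
  vals <- vapply(pats, function(p) switch(objective,
    min_ptm = as.numeric(p$total_ptms),
    min_error = p$error,
    min_both = p$combined_score), 0)
  list(value = min(vals), pattern = pats[[which.min(vals)]], all = vals)
}
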