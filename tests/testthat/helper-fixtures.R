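# Shared fixtures and test-only oracles. All fixtures are built in code.

# Random annotated chain over the 20 standard amino acids.
random_chain <- function(id = "rc", L = 40, p = 0.2, seed = NULL) {
  draw <- function() {
    res <- paste(sample(fadpred:::AA20, L, replace = TRUE), collapse = "")
    annotated_chain(id, res, stats::rbinom(L, 1, p))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Random profile with distinct per-column values (catches column-order bugs).
column_coded_profile <- function(chain) {
  L <- length(chain)
  raw <- outer(seq_len(L), seq_len(20), function(i, j) (i * 20L + j) %% 13L - 6L)
  pssm_profile(chain$chain_id, raw, chain$residues)
}

# PSI-BLAST ASCII text for a profile, in both dialect flavours.
pssm_text <- function(profile, dialect = c("psiblast", "blastpgp")) {
  dialect <- match.arg(dialect)
  f <- withr::local_tempfile()
  write_pssm_ascii(profile, f)
  lines <- readLines(f)
  if (dialect == "blastpgp") {
    # legacy layout differs in its preamble: extra banner lines before the
    # column-header line, and trailing K/lambda footer
    lines <- c("", "BLASTPGP 2.2.26 profile", lines[-1],
               "                      K         Lambda",
               "Standard Ungapped    0.1352     0.3176")
  }
  lines
}

# Test-only decoder: inverse of the one-hot window encoding.
decode_binary <- function(v) {
  w <- length(v) / 21L
  chars <- vapply(seq_len(w), function(p) {
    block <- v[(21L * (p - 1L) + 1L):(21L * p)]
    fadpred:::ALPHABET21[which(block == 1)]
  }, character(1))
  paste(chars, collapse = "")
}

# Tiny linearly separable feature set: positives shifted along dim 1.
separable_toy <- function(n = 10) {
  x <- rbind(matrix(c(rep(2, n / 2), rep(0, n / 2)), ncol = 2),
             matrix(c(rep(-2, n / 2), rep(0, n / 2)), ncol = 2))
  list(x = x, labels = rep(c(1L, 0L), each = n / 2))
}

# Small synthetic benchmark shared across tests (cheap: 20 chains).
small_bench <- function(seed = 5, shift = 4) {
  cfg <- synthetic_config(n_chains = 20, length_range = c(80, 80),
                          composition_shift = shift, seed = seed)
  chains <- generate_chains(cfg)
  list(cfg = cfg, chains = chains,
       profiles = generate_profiles(chains, cfg))
}
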