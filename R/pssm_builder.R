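#' PSI-BLAST configuration
#'
#' Settings for generating evolutionary profiles: by convention three search
#' iterations against the non-redundant (nr) protein database with an
#' inclusion e-value of 0.001. Both the modern `psiblast` (BLAST+) and the
#' legacy `blastpgp` command syntaxes are supported; `style` is guessed from
#' the executable name when not given. The executable path can be overridden
#' with the `FADPRED_PSIBLAST` environment variable.
#'
#' @param iterations Search iterations (>= 1, default 3).
#' @param evalue_cutoff Inclusion e-value (> 0, default 0.001).
#' @param database Database name/path (default `"nr"`).
#' @param executable Tool path or name (default: `FADPRED_PSIBLAST` env var,
#'   else `"psiblast"`).
#' @param style `"psiblast"`, `"blastpgp"`, or `NULL` to guess from the
#'   executable name.
#' @return An object of class `psiblast_config`.
#' @export
psiblast_config <- function(iterations = 3L, evalue_cutoff = 0.001,
                            database = "nr", executable = NULL,
                            style = NULL) {
  if (iterations < 1L) stop_parameter("iterations must be >= 1")
  if (evalue_cutoff <= 0) stop_parameter("evalue_cutoff must be positive")
  if (is.null(executable)) {
    env <- Sys.getenv("FADPRED_PSIBLAST", "")
    executable <- if (nzchar(env)) env else "psiblast"
  }
  if (is.null(style))
    style <- if (grepl("blastpgp", basename(executable))) "blastpgp" else "psiblast"
  style <- match.arg(style, c("psiblast", "blastpgp"))
  structure(list(iterations = as.integer(iterations),
                 evalue_cutoff = evalue_cutoff, database = database,
                 executable = executable, style = style),
            class = "psiblast_config")
}

pssm_command_args <- function(config, query, out_pssm) {
  if (config$style == "psiblast")
    c("-query", query, "-db", config$database,
      "-num_iterations", config$iterations,
      "-inclusion_ethresh", format(config$evalue_cutoff, scientific = FALSE),
      "-out_ascii_pssm", out_pssm, "-out", "/dev/null")
  else
    c("-i", query, "-d", config$database, "-j", config$iterations,
      "-h", format(config$evalue_cutoff, scientific = FALSE),
      "-Q", out_pssm)
}

#' Build a PSSM profile by running PSI-BLAST
#'
#' Writes the chain as a plain FASTA query, invokes the configured
#' executable, and parses the resulting ASCII PSSM through
#' [parse_pssm_ascii()] (so length/residue consistency with the chain is
#' enforced). On any tool failure the work files are removed and a tool
#' error carrying the captured stderr is raised. This is the only operation
#' in the package that touches an external tool.
#'
#' @param chain An [annotated_chain].
#' @param config A [psiblast_config].
#' @param workdir Directory for query/PSSM files (default a fresh tempdir).
#' @param transform Normalization transform for the parsed profile.
#' @return A [pssm_profile].
#' @export
build_profile <- function(chain, config = psiblast_config(),
                          workdir = tempfile("pssm_"),
                          transform = "logistic") {
  stopifnot(inherits(chain, "annotated_chain"), inherits(config, "psiblast_config"))
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  query <- file.path(workdir, paste0(chain$chain_id, ".fa"))
  out_pssm <- file.path(workdir, paste0(chain$chain_id, ".pssm"))
  cleanup <- function() unlink(c(query, out_pssm))

  writeLines(c(paste0(">", chain$chain_id), chain$residues), query)
  if (Sys.which(config$executable) == "" && !file.exists(config$executable)) {
    cleanup()
    stop_tool("PSI-BLAST executable '%s' not found", config$executable)
  }
  err_file <- file.path(workdir, "stderr.log")
  status <- suppressWarnings(
    system2(config$executable, pssm_command_args(config, query, out_pssm),
            stdout = FALSE, stderr = err_file))
  if (status != 0L || !file.exists(out_pssm)) {
    err <- if (file.exists(err_file)) paste(readLines(err_file, warn = FALSE),
                                            collapse = "\n") else ""
    cleanup(); unlink(err_file)
    stop_tool("PSI-BLAST failed for chain '%s' (exit %d): %s",
              chain$chain_id, status, err)
  }
  prof <- parse_pssm_ascii(out_pssm, chain = chain, transform = transform)
  unlink(err_file)
  prof
}

#' Load a cached PSSM profile or build it
#'
#' Looks for `<chain_id>.pssm` in `pssm_dir`; on a miss, acts per
#' `fallback`: `"error"` raises a data error, `"build"` runs
#' [build_profile()] (and caches the result into `pssm_dir`),
#' `"downgrade"` returns `NULL` with a warning so callers can fall back to
#' binary-only prediction. Cached profiles are never regenerated silently.
#'
#' @param chain An [annotated_chain].
#' @param pssm_dir Directory of precomputed ASCII PSSMs.
#' @param config A [psiblast_config] (needed for `fallback = "build"`).
#' @param fallback Miss policy: `"error"` (default), `"build"`, or
#'   `"downgrade"`.
#' @param transform Normalization transform.
#' @return A [pssm_profile], or `NULL` under the downgrade policy.
#' @export
load_or_build <- function(chain, pssm_dir, config = psiblast_config(),
                          fallback = c("error", "build", "downgrade"),
                          transform = "logistic") {
  fallback <- match.arg(fallback)
  path <- file.path(pssm_dir, paste0(chain$chain_id, ".pssm"))
  if (file.exists(path))
    return(parse_pssm_ascii(path, chain = chain, transform = transform))
  switch(fallback,
    error = stop_data("no PSSM for chain '%s' in %s", chain$chain_id, pssm_dir),
    downgrade = {
      warn_fadpred("no PSSM for chain '%s'; downgrading to binary-only features",
                   chain$chain_id)
      NULL
    },
    build = {
      prof <- build_profile(chain, config, transform = transform)
      dir.create(pssm_dir, showWarnings = FALSE, recursive = TRUE)
      write_pssm_ascii(prof, path)
      prof
    })
}
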