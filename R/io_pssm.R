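#' PSSM profile
#'
#' Container for a per-chain position-specific scoring matrix: an L x 20
#' integer matrix of PSI-BLAST log-odds scores (columns in PSI-BLAST's
#' printed amino-acid order) plus its \[0, 1\]-normalized counterpart. A
#' profile of a chain with L residues always has exactly L rows.
#'
#' @param chain_id Character scalar.
#' @param raw_scores L x 20 integer matrix; columns are taken to be in
#'   PSI-BLAST order (`A R N D C Q E G H I L K M F P S T W Y V`).
#' @param residues Uppercase residue string of length L (used when writing
#'   the ASCII form and for consistency checks).
#' @param transform Normalization transform, `"logistic"` (default) or
#'   `"minmax"`; see [normalize_pssm_score()].
#' @return An object of class `pssm_profile` with elements `chain_id`,
#'   `raw_scores`, `normalized`, `residues`, `transform`.
#' @export
pssm_profile <- function(chain_id, raw_scores, residues,
                         transform = c("logistic", "minmax")) {
  transform <- match.arg(transform)
  raw_scores <- as.matrix(raw_scores)
  if (ncol(raw_scores) != 20L)
    stop_format("PSSM for '%s' must have 20 score columns, found %d",
                chain_id, ncol(raw_scores))
  if (nrow(raw_scores) != nchar(residues))
    stop_consistency("PSSM for '%s': %d rows for %d residues",
                     chain_id, nrow(raw_scores), nchar(residues))
  storage.mode(raw_scores) <- "integer"
  colnames(raw_scores) <- PSSM_AA_ORDER
  structure(list(
    chain_id   = chain_id,
    raw_scores = raw_scores,
    normalized = normalize_pssm_score(raw_scores, transform = transform,
                                      lo = min(raw_scores), hi = max(raw_scores)),
    residues   = toupper(residues),
    transform  = transform
  ), class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %s: %d x 20 (%s normalization)\n",
              x$chain_id, nrow(x$raw_scores), x$transform))
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the ASCII matrix written by `psiblast -out_ascii_pssm` or legacy
#' `blastpgp -Q`. Header lines are skipped by pattern (a line of 20+
#' single-letter amino-acid tokens marks the column header), not by fixed
#' line counts, so both dialects are accepted. Only the first 20 score
#' columns (log-odds) are used; the trailing weighted-percentage and
#' information columns are ignored.
#'
#' @param file Path to the ASCII PSSM, or `NULL` when `text` is given.
#' @param text Optional character vector of lines.
#' @param chain Optional [annotated_chain]: when given, row count must match
#'   chain length and the per-row residue letters must match the chain
#'   sequence (positions holding X in either are exempt).
#' @param transform Normalization transform passed to [pssm_profile()].
#' @return A [pssm_profile].
#' @export
parse_pssm_ascii <- function(file = NULL, text = NULL, chain = NULL,
                             transform = c("logistic", "minmax")) {
  transform <- match.arg(transform)
  lines <- if (!is.null(text)) text else readLines(file, warn = FALSE)

  tok <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  is_header <- vapply(tok, function(tk)
    length(tk) >= 20L && all(tk[1:20] %in% c(LETTERS, "*")), logical(1))
  hdr <- which(is_header)
  if (length(hdr) == 0L)
    stop_format("not a PSI-BLAST ASCII PSSM: no amino-acid column header found")

  if (hdr[1] >= length(lines))
    stop_format("no PSSM score rows found after header")
  rows <- list(); res <- character()
  for (i in seq(hdr[1] + 1L, length(lines))) {
    tk <- tok[[i]]
    if (length(tk) < 22L) break                       # blank line / footer
    if (is.na(suppressWarnings(as.integer(tk[1])))) break
    if (!tk[2] %in% c(LETTERS, "*")) break
    sc <- suppressWarnings(as.integer(tk[3:22]))
    if (anyNA(sc))
      stop_format("line %d: non-integer PSSM score", i)
    rows[[length(rows) + 1L]] <- sc
    res <- c(res, tk[2])
  }
  if (length(rows) == 0L)
    stop_format("no PSSM score rows found after header")
  raw <- do.call(rbind, rows)

  id <- if (!is.null(chain)) chain$chain_id else "pssm"
  if (!is.null(chain)) {
    if (nrow(raw) != length(chain))
      stop_consistency("PSSM has %d rows but chain '%s' has %d residues",
                       nrow(raw), chain$chain_id, length(chain))
    cc <- chain_chars(chain)
    pp <- toupper(res)
    mism <- which(cc != pp & cc != "X" & pp != "X")
    if (length(mism))
      stop_consistency("PSSM residue '%s' differs from chain residue '%s' at position %d",
                       pp[mism[1]], cc[mism[1]], mism[1])
    res <- cc
  }
  pssm_profile(id, raw, paste(res, collapse = ""), transform = transform)
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' Emits the 20-score-column ASCII form that [parse_pssm_ascii()] reads
#' (used by the synthetic-data generator so fixtures pass through the real
#' parser).
#'
#' @param profile A [pssm_profile].
#' @param file Output path or connection.
#' @return Invisibly, `file`.
#' @export
write_pssm_ascii <- function(profile, file) {
  stopifnot(inherits(profile, "pssm_profile"))
  raw <- profile$raw_scores
  res <- strsplit(profile$residues, "", fixed = TRUE)[[1]]
  out <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", PSSM_AA_ORDER), collapse = " "))
  )
  for (i in seq_len(nrow(raw))) {
    out <- c(out, paste0(sprintf("%5d %s  ", i, res[i]),
                         paste(sprintf("%3d", raw[i, ]), collapse = " ")))
  }
  writeLines(c(out, ""), file)
  invisible(file)
}
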