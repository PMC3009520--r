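#' Annotated protein chain
#'
#' Constructs an `annotated_chain`: a protein sequence with a per-residue
#' binary flag marking FAD-interacting residues (FIRs). Residues are stored
#' uppercase over the 21-letter alphabet (20 standard amino acids + X);
#' labels are 0/1 integers of the same length.
#'
#' @param chain_id Character scalar identifier. The `"PDBID_chain"` form
#'   (e.g. `"1abc_A"`) is conventional but not enforced.
#' @param residues Character scalar, uppercase sequence.
#' @param labels Integer vector of 0/1 flags, one per residue (1 = FIR).
#' @return An object of class `annotated_chain`.
#' @export
annotated_chain <- function(chain_id, residues, labels) {
  if (!is.character(chain_id) || length(chain_id) != 1L || !nzchar(chain_id))
    stop_parameter("chain_id must be a non-empty string")
  residues <- toupper(residues)
  if (nchar(residues) == 0L)
    stop_data("chain '%s' has an empty sequence", chain_id)
  labels <- as.integer(labels)
  if (length(labels) != nchar(residues))
    stop_consistency("chain '%s': %d labels for %d residues",
                     chain_id, length(labels), nchar(residues))
  if (!all(labels %in% c(0L, 1L)))
    stop_parameter("labels must be 0/1")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% ALPHABET21)
  if (length(bad))
    stop_format("chain '%s': illegal residue '%s' at position %d",
                chain_id, chars[bad[1]], bad[1])
  structure(list(chain_id = chain_id, residues = residues, labels = labels),
            class = "annotated_chain")
}

#' @export
print.annotated_chain <- function(x, ...) {
  cat(sprintf("<annotated_chain> %s: %d residues, %d FIR\n",
              x$chain_id, nchar(x$residues), sum(x$labels)))
  invisible(x)
}

#' @export
length.annotated_chain <- function(x) nchar(x$residues)

chain_chars <- function(chain) strsplit(chain$residues, "", fixed = TRUE)[[1]]

#' Read case-annotated FASTA
#'
#' Parses the annotated FASTA dialect in which residue case carries the
#' label: lowercase letters are FAD-interacting residues (label 1), uppercase
#' are non-interacting (label 0). Residues are upcased on output. The
#' nonstandard one-letter codes B, Z, J, U, O and the stop symbol `*` are
#' mapped to the dummy symbol X with a warning, so positions stay aligned
#' with PSSM rows; any other non-letter character is a format error.
#'
#' @param file Path to a FASTA file, or `NULL` when `text` is given.
#' @param text Optional character vector of lines (overrides `file`).
#' @return A list of [annotated_chain] objects, in file order.
#' @examples
#' chs <- parse_annotated_fasta(text = c(">1abc_A", "AKgLYs"))
#' chs[[1]]$labels   # 0 0 1 0 0 1
#' @export
parse_annotated_fasta <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else {
    if (is.null(file)) stop_parameter("either file or text must be given")
    readLines(file, warn = FALSE)
  }
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop_format("empty FASTA input")

  chains <- list()
  id <- NULL; seq_parts <- character(); start_line <- NA_integer_
  n_mapped <- 0L

  flush <- function() {
    if (is.null(id)) return()
    raw <- paste(seq_parts, collapse = "")
    if (nchar(raw) == 0L)
      stop_format("chain '%s' (line %d) has no sequence", id, start_line)
    chars <- strsplit(raw, "", fixed = TRUE)[[1]]
    labels <- as.integer(grepl("[a-z]", chars))
    up <- toupper(chars)
    ns <- up %in% NONSTANDARD_AA | up == "*"
    if (any(ns)) {
      n_mapped <<- n_mapped + sum(ns)
      up[ns] <- "X"
    }
    chains[[length(chains) + 1L]] <<-
      annotated_chain(id, paste(up, collapse = ""), labels)
  }

  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      flush()
      id <- trimws(sub("^>", "", ln))
      if (!nzchar(id)) id <- sprintf("chain_%d", length(chains) + 1L)
      seq_parts <- character(); start_line <- i
    } else {
      if (is.null(id))
        stop_format("line %d: sequence data before first '>' header", i)
      bad <- regmatches(ln, regexpr("[^A-Za-z*]", ln))
      if (length(bad))
        stop_format("line %d: illegal character '%s' in sequence", i, bad)
      seq_parts <- c(seq_parts, ln)
    }
  }
  flush()
  if (n_mapped > 0L)
    warn_fadpred("%d nonstandard residue(s) (B/Z/J/U/O/*) mapped to X", n_mapped)
  chains
}

#' Write case-annotated FASTA
#'
#' Inverse of [parse_annotated_fasta()]: label-1 residues are emitted in
#' lowercase, label-0 in uppercase, wrapped at 60 columns.
#'
#' @param chains A list of [annotated_chain] objects (or a single one).
#' @param file Output path or connection.
#' @return Invisibly, `file`.
#' @export
write_annotated_fasta <- function(chains, file) {
  if (inherits(chains, "annotated_chain")) chains <- list(chains)
  out <- character()
  for (ch in chains) {
    stopifnot(inherits(ch, "annotated_chain"))
    chars <- chain_chars(ch)
    chars[ch$labels == 1L] <- tolower(chars[ch$labels == 1L])
    s <- paste(chars, collapse = "")
    body <- substring(s, seq(1L, nchar(s), 60L),
                      pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s)))
    out <- c(out, paste0(">", ch$chain_id), body)
  }
  writeLines(out, file)
  invisible(file)
}
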